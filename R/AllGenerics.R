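#' @rdname PCTrack-accessors
#' @export
setGeneric("pcScores", function(x, pc = 1L) standardGeneric("pcScores"))

#' @rdname PCTrack-accessors
#' @export
setGeneric("varExplained", function(x, pc = NULL) standardGeneric("varExplained"))

#' @rdname PCTrack-accessors
#' @export
setGeneric("windowMids", function(x) standardGeneric("windowMids"))

#' @rdname PCTrack-accessors
#' @export
setGeneric("validWindows", function(x) standardGeneric("validWindows"))

#' @rdname PCTrack-accessors
#' @export
setGeneric("nVariantsUsed", function(x) standardGeneric("nVariantsUsed"))

#' @rdname PCTrack-accessors
#' @export
setGeneric("pctMissing", function(x) standardGeneric("pctMissing"))

#' @rdname PCTrack-accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname PCTrack-accessors
#' @export
setGeneric("trackParams", function(x) standardGeneric("trackParams"))

#' @export
#' @rdname polarizeTrack
setGeneric("polarizeTrack", function(track, pc = 1L, nPrev = 5L,
                                     guideSamples = NULL) {
  standardGeneric("polarizeTrack")
})

#' @export
#' @rdname flipChromosome
setGeneric("flipChromosome", function(track, pc = 1L) {
  standardGeneric("flipChromosome")
})

#' @export
#' @rdname flipWindows
setGeneric("flipWindows", function(track, intervals, pc = 1L) {
  standardGeneric("flipWindows")
})

#' PCTrack accessors
#'
#' @param x a [PCTrack-class].
#' @param pc principal component index (e.g. `1` for PC1); `varExplained`
#'   returns the full windows x PCs matrix when `pc` is `NULL`.
#' @return `pcScores`: windows x samples score matrix; `varExplained`:
#'   variance-explained fractions; `windowMids`: window midpoints in bp;
#'   `validWindows`: logical per window; `nVariantsUsed`, `pctMissing`:
#'   per-window metadata; `chromName`: the chromosome name.
#' @name PCTrack-accessors
NULL

#' @rdname PCTrack-accessors
#' @export
setMethod("pcScores", "PCTrack", function(x, pc = 1L) {
  nm <- paste0("PC", as.integer(pc))
  if (!nm %in% assayNames(x)) {
    stop("track does not carry ", nm, "; available: ",
         paste(assayNames(x), collapse = ", "), call. = FALSE)
  }
  assay(x, nm)
})

#' @rdname PCTrack-accessors
#' @export
setMethod("varExplained", "PCTrack", function(x, pc = NULL) {
  ve <- mcols(rowRanges(x))$var_explained
  if (is.null(pc)) return(ve)
  nm <- paste0("var_explained_pc", as.integer(pc))
  if (!nm %in% colnames(ve)) {
    stop("no variance-explained column for PC", pc, call. = FALSE)
  }
  ve[, nm]
})

#' @rdname PCTrack-accessors
#' @export
setMethod("windowMids", "PCTrack", function(x) mcols(rowRanges(x))$mid)

#' @rdname PCTrack-accessors
#' @export
setMethod("validWindows", "PCTrack", function(x) mcols(rowRanges(x))$valid)

#' @rdname PCTrack-accessors
#' @export
setMethod("nVariantsUsed", "PCTrack", function(x) mcols(rowRanges(x))$n_variants)

#' @rdname PCTrack-accessors
#' @export
setMethod("pctMissing", "PCTrack", function(x) mcols(rowRanges(x))$pct_missing)

#' @rdname PCTrack-accessors
#' @export
setMethod("chromName", "PCTrack", function(x) {
  as.character(seqnames(rowRanges(x)))[1]
})

#' @rdname PCTrack-accessors
#' @export
setMethod("trackParams", "PCTrack", function(x) metadata(x)$params)
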