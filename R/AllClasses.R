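#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom BiocGenerics start end
#' @import SummarizedExperiment
NULL

#' Scan parameters for a windowed principal-component analysis
#'
#' Holds the windowing and PCA settings shared by every stage of a scan:
#' window and step size in base pairs, the principal components to emit
#' (up to PC10), the minimum number of usable variants for a window to be
#' considered valid, the genotype standardization rule, and how genotype
#' fields are read from the input.
#'
#' @slot windowSize window span in bp (1-based, fully closed intervals).
#' @slot stepSize advance between successive window starts in bp.
#' @slot pcs integer vector of principal component indices to compute.
#' @slot minVariants minimum usable variants for a valid window result.
#' @slot scaler one of `"none"`, `"center"`, `"patterson"`.
#' @slot glField genotype field to read: `"GT"`, `"GL"` or `"PL"`.
#' @slot format input format tag: `"vcf"`, `"beagle"` or `"tsv"`.
#' @slot anchor window anchoring: `"position"` (windows start at bp 1) or
#'   `"variant"` (windows start at the first variant position).
#' @export
setClass("ScanParams", representation(
  windowSize = "numeric",
  stepSize = "numeric",
  pcs = "integer",
  minVariants = "integer",
  scaler = "character",
  glField = "character",
  format = "character",
  anchor = "character"
))

setValidity("ScanParams", function(object) {
  msg <- character()
  if (length(object@windowSize) != 1L || object@windowSize < 1) {
    msg <- c(msg, "windowSize must be a single positive number")
  }
  if (length(object@stepSize) != 1L || object@stepSize < 1) {
    msg <- c(msg, "stepSize must be a single positive number")
  }
  if (length(object@stepSize) == 1L && length(object@windowSize) == 1L &&
      object@stepSize > object@windowSize) {
    msg <- c(msg, "stepSize must not exceed windowSize")
  }
  if (length(object@pcs) < 1L || any(object@pcs < 1L) || any(object@pcs > 10L)) {
    msg <- c(msg, "pcs must be indices in 1..10")
  }
  if (object@minVariants < 2L) {
    msg <- c(msg, "minVariants must be >= 2")
  }
  if (!object@scaler %in% c("none", "center", "patterson")) {
    msg <- c(msg, "scaler must be one of none/center/patterson")
  }
  if (!object@glField %in% c("GT", "GL", "PL")) {
    msg <- c(msg, "glField must be one of GT/GL/PL")
  }
  if (!object@format %in% c("vcf", "beagle", "tsv")) {
    msg <- c(msg, "format must be one of vcf/beagle/tsv")
  }
  if (!object@anchor %in% c("position", "variant")) {
    msg <- c(msg, "anchor must be 'position' or 'variant'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct scan parameters
#'
#' @param windowSize window span in bp; default 1 Mbp.
#' @param stepSize step between window starts in bp; default `windowSize`
#'   (non-overlapping) unless given.
#' @param pcs integer vector of PC indices (1..10); default `c(1, 2)`.
#' @param minVariants minimum usable variants per window; default 20.
#' @param scaler genotype standardization: `"patterson"` (default) divides
#'   centered dosages by `sqrt(p*(1-p))` at allele frequency `p`; `"center"`
#'   only subtracts per-variant means; `"none"` leaves dosages untouched.
#' @param glField which genotype field to read (`"GT"`, `"GL"`, `"PL"`).
#' @param format input format tag (`"vcf"`, `"beagle"`, `"tsv"`).
#' @param anchor `"position"` anchors windows at bp 1; `"variant"` at the
#'   first variant position.
#' @return A [ScanParams-class] object.
#' @examples
#' scanParams(windowSize = 1e6, stepSize = 1e5)
#' @export
scanParams <- function(windowSize = 1e6, stepSize = 1e5, pcs = c(1L, 2L),
                       minVariants = 20L, scaler = "patterson",
                       glField = "GT", format = "vcf",
                       anchor = "position") {
  new("ScanParams",
    windowSize = as.numeric(windowSize), stepSize = as.numeric(stepSize),
    pcs = sort(unique(as.integer(pcs))), minVariants = as.integer(minVariants),
    scaler = scaler, glField = glField, format = format, anchor = anchor
  )
}

setMethod("show", "ScanParams", function(object) {
  cat("ScanParams: window", format(object@windowSize, big.mark = ","),
      "bp, step", format(object@stepSize, big.mark = ","),
      "bp, PCs", paste(object@pcs, collapse = ","),
      "| scaler", object@scaler,
      "| min variants", object@minVariants, "\n")
})

#' A set of biallelic variant records for one chromosome
#'
#' In-memory container for the biallelic records parsed from a VCF, BEAGLE
#' or TSV input, restricted to one chromosome and sorted by position.
#' Depending on the genotype field read, it carries either a hard-call
#' dosage matrix (alt-allele counts 0/1/2, `NA` for missing) or a
#' genotype-likelihood array (samples x variants x 3, each triplet
#' normalized to sum to 1).
#'
#' @slot chrom chromosome name.
#' @slot pos 1-based variant positions, nondecreasing.
#' @slot ref,alt allele strings (exactly one alt per record).
#' @slot sampleIds ordered sample names from the input header.
#' @slot dosage samples x variants dosage matrix, or a 0-row matrix when the
#'   payload is likelihoods.
#' @slot likelihoods samples x variants x 3 probability array, or a
#'   zero-length array when the payload is hard calls.
#' @slot skipped named integer counters of skipped records
#'   (multiallelic, malformed, ...).
#' @export
setClass("VariantSet", representation(
  chrom = "character",
  pos = "numeric",
  ref = "character",
  alt = "character",
  sampleIds = "character",
  dosage = "matrix",
  likelihoods = "array",
  skipped = "integer"
))

setValidity("VariantSet", function(object) {
  msg <- character()
  nv <- length(object@pos)
  ns <- length(object@sampleIds)
  if (nv && is.unsorted(object@pos)) {
    msg <- c(msg, "positions must be nondecreasing")
  }
  if (nv && any(object@pos < 1)) msg <- c(msg, "positions must be >= 1")
  hasDos <- nrow(object@dosage) > 0L || ncol(object@dosage) > 0L
  hasLik <- length(object@likelihoods) > 0L
  if (hasDos && !all(dim(object@dosage) == c(ns, nv))) {
    msg <- c(msg, "dosage must be samples x variants")
  }
  if (hasLik && !all(dim(object@likelihoods) == c(ns, nv, 3L))) {
    msg <- c(msg, "likelihoods must be samples x variants x 3")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "VariantSet", function(object) {
  payload <- if (length(object@likelihoods)) "genotype likelihoods" else "hard calls"
  cat("VariantSet:", length(object@pos), "biallelic variants on",
      object@chrom, "|", length(object@sampleIds), "samples |",
      payload, "\n")
  if (sum(object@skipped)) {
    cat("  skipped records:",
        paste(names(object@skipped), object@skipped, sep = "=", collapse = ", "),
        "\n")
  }
})

#' Per-window principal-component track for one chromosome
#'
#' `PCTrack` extends [SummarizedExperiment::RangedSummarizedExperiment]:
#' rows are genomic windows (a `GRanges` with window midpoints, variant
#' counts, missingness and variance-explained in `rowData`), columns are
#' samples, and each requested principal component is one assay matrix of
#' per-window, per-sample scores. Invalid windows (fewer usable variants
#' than `minVariants`) carry `NA` scores so tracks stay rectangular and
#' positionally continuous for polarization and plotting.
#'
#' Use [pcScores()], [varExplained()], [windowMids()], [validWindows()],
#' [nVariantsUsed()], [pctMissing()], [chromName()] and [scanParams()]
#' rather than touching slots or assays directly.
#'
#' @export
setClass("PCTrack", contains = "RangedSummarizedExperiment")

setValidity("PCTrack", function(object) {
  msg <- character()
  rr <- rowRanges(object)
  if (length(rr)) {
    if (length(unique(as.character(seqnames(rr)))) != 1L) {
      msg <- c(msg, "a PCTrack spans exactly one chromosome")
    }
    if (is.unsorted(start(rr), strictly = TRUE)) {
      msg <- c(msg, "windows must be strictly ordered by start")
    }
  }
  an <- assayNames(object)
  if (!length(an) || !all(grepl("^PC[0-9]+$", an))) {
    msg <- c(msg, "assays must be named PC<k>")
  }
  need <- c("mid", "n_variants", "pct_missing", "valid")
  if (!all(need %in% colnames(mcols(rr)))) {
    msg <- c(msg, paste("rowData must contain", paste(need, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PCTrack from per-window results
#'
#' @param chrom chromosome name.
#' @param starts,ends 1-based closed window bounds.
#' @param scores named list of windows x samples score matrices, one per
#'   assay, names `"PC1"`, `"PC2"`, ...
#' @param sampleIds ordered sample names (assay column names).
#' @param nVariants usable variants per window.
#' @param pctMissing fraction of missing entries per window before imputation.
#' @param valid logical; whether each window met the `minVariants` threshold.
#' @param varExplained windows x PCs matrix of variance-explained fractions.
#' @param params the [ScanParams-class] used for the scan.
#' @param converged optional logical per window (GL path iteration).
#' @return A [PCTrack-class].
#' @export
PCTrack <- function(chrom, starts, ends, scores, sampleIds,
                    nVariants, pctMissing, valid, varExplained,
                    params, converged = NULL) {
  mids <- floor((starts + ends) / 2)
  rd <- DataFrame(
    mid = mids,
    n_variants = as.integer(nVariants),
    pct_missing = as.numeric(pctMissing),
    valid = as.logical(valid)
  )
  colnames(varExplained) <- paste0("var_explained_pc", params@pcs)
  rd$var_explained <- varExplained
  if (!is.null(converged)) rd$converged <- as.logical(converged)
  rr <- GRanges(chrom, IRanges(start = starts, end = ends))
  mcols(rr) <- rd
  scores <- lapply(scores, function(m) {
    dimnames(m) <- list(NULL, sampleIds)
    m
  })
  se <- SummarizedExperiment(
    assays = scores, rowRanges = rr,
    colData = DataFrame(sample = sampleIds, row.names = sampleIds),
    metadata = list(params = params, polarized = character())
  )
  new("PCTrack", se)
}

setMethod("show", "PCTrack", function(object) {
  rr <- rowRanges(object)
  cat("PCTrack on", chromName(object), "|", length(rr), "windows (",
      sum(mcols(rr)$valid), "valid ) |", ncol(object), "samples\n")
  cat("  PCs:", paste(assayNames(object), collapse = ", "))
  pol <- metadata(object)$polarized
  if (length(pol)) cat("  | polarized:", paste(pol, collapse = ", "))
  cat("\n")
  if (length(rr)) {
    cat("  span:", min(start(rr)), "-", max(end(rr)), "bp\n")
  }
})
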