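# Gzipped text output of PC tracks: one file per PC plus a window-stats
# file, re-readable by the polarize/flip/plot stages.

#' Write a PCTrack to gzipped TSV files
#'
#' Emits `<prefix>.pc<k>.tsv.gz` (columns `chrom`, `start`, `end`, `mid`,
#' then one score column per sample; `NA` for invalid windows) for every PC
#' in the track, and `<prefix>.stats.tsv.gz` with per-window metadata
#' (`n_variants`, `pct_missing`, `var_explained_pc<k>`). Floating-point
#' values are written at 6 significant digits.
#'
#' @param track a [PCTrack-class].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writePCTrack <- function(track, prefix) {
  rr <- rowRanges(track)
  base <- data.frame(
    chrom = as.character(seqnames(rr)),
    start = start(rr), end = end(rr), mid = mcols(rr)$mid
  )
  paths <- character()
  for (nm in assayNames(track)) {
    k <- sub("^PC", "", nm)
    path <- paste0(prefix, ".pc", k, ".tsv.gz")
    m <- assay(track, nm)
    fm <- matrix(.fmtNum(m), nrow(m), ncol(m))
    tab <- cbind(base, as.data.frame(fm, stringsAsFactors = FALSE))
    colnames(tab) <- c(colnames(base), colnames(m))
    con <- gzfile(path, "wt")
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  ve <- mcols(rr)$var_explained
  stats <- cbind(
    base,
    n_variants = mcols(rr)$n_variants,
    pct_missing = .fmtNum(mcols(rr)$pct_missing)
  )
  for (j in colnames(ve)) stats[[j]] <- .fmtNum(ve[, j])
  if (!is.null(mcols(rr)$converged)) stats$converged <- mcols(rr)$converged
  statsPath <- paste0(prefix, ".stats.tsv.gz")
  con <- gzfile(statsPath, "wt")
  utils::write.table(stats, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(paths, statsPath))
}

#' Read a PCTrack back from gzipped TSV files
#'
#' Discovers `<prefix>.pc<k>.tsv.gz` files and the `<prefix>.stats.tsv.gz`
#' companion and reconstructs a [PCTrack-class]. Window and step size are
#' recovered from the window table.
#'
#' @param prefix path prefix used by [writePCTrack()].
#' @param pcs optional subset of PC indices to load.
#' @return A [PCTrack-class].
#' @export
readPCTrack <- function(prefix, pcs = NULL) {
  dir <- dirname(prefix)
  baseName <- basename(prefix)
  files <- list.files(dir, pattern = paste0(
    "^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", baseName),
    "\\.pc[0-9]+\\.tsv\\.gz$"
  ), full.names = TRUE)
  if (!length(files)) {
    stop("no track files found for prefix '", prefix, "'", call. = FALSE)
  }
  kAll <- as.integer(sub("^.*\\.pc([0-9]+)\\.tsv\\.gz$", "\\1", files))
  o <- order(kAll)
  files <- files[o]
  kAll <- kAll[o]
  if (!is.null(pcs)) {
    sel <- kAll %in% as.integer(pcs)
    files <- files[sel]
    kAll <- kAll[sel]
    if (!length(files)) stop("requested PCs not present", call. = FALSE)
  }
  tabs <- lapply(files, function(f) {
    data.table::fread(text = .readLinesAuto(f), header = TRUE, sep = "\t",
                      na.strings = "NA")
  })
  t1 <- tabs[[1]]
  sampleIds <- setdiff(colnames(t1), c("chrom", "start", "end", "mid"))
  scores <- lapply(tabs, function(tt) {
    m <- as.matrix(tt[, sampleIds, with = FALSE])
    storage.mode(m) <- "double"
    m
  })
  names(scores) <- paste0("PC", kAll)
  statsPath <- paste0(prefix, ".stats.tsv.gz")
  nW <- nrow(t1)
  if (file.exists(statsPath)) {
    st <- data.table::fread(text = .readLinesAuto(statsPath), header = TRUE,
                            sep = "\t", na.strings = "NA")
    nvar <- st$n_variants
    pmiss <- st$pct_missing
    veCols <- grep("^var_explained_pc", colnames(st), value = TRUE)
    ve <- as.matrix(st[, veCols, with = FALSE])
    conv <- st$converged
  } else {
    nvar <- rep(NA_integer_, nW)
    pmiss <- rep(NA_real_, nW)
    ve <- matrix(NA_real_, nW, length(kAll))
    conv <- NULL
  }
  valid <- rowSums(!is.na(scores[[1]])) > 0L
  windowSize <- t1$end[1] - t1$start[1] + 1
  stepSize <- if (nW > 1L) t1$start[2] - t1$start[1] else windowSize
  params <- scanParams(
    windowSize = windowSize, stepSize = stepSize, pcs = kAll,
    minVariants = 2L
  )
  ve2 <- matrix(NA_real_, nW, length(kAll))
  have <- match(paste0("var_explained_pc", kAll), colnames(ve))
  for (k in seq_along(kAll)) {
    if (!is.na(have[k])) ve2[, k] <- ve[, have[k]]
  }
  PCTrack(
    chrom = t1$chrom[1], starts = t1$start, ends = t1$end,
    scores = scores, sampleIds = sampleIds,
    nVariants = ifelse(is.na(nvar), 0L, nvar), pctMissing = pmiss,
    valid = valid, varExplained = ve2, params = params,
    converged = conv
  )
}
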