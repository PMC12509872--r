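# Programmatic fixtures shared across test files. Everything is generated
# in code at test time; nothing binary ships with the package.

# Write a minimal VCF with GT (and optionally PL) FORMAT fields.
writeTestVcf <- function(path, chrom, pos, ref, alt, gt, pl = NULL,
                         samples = colnames(gt)) {
  fmt <- if (is.null(pl)) "GT" else "GT:PL"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(pl)) "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_along(pos), function(i) {
    cells <- gt[i, ]
    if (!is.null(pl)) cells <- paste(cells, pl[i, ], sep = ":")
    paste(c(chrom, pos[i], ".", ref[i], alt[i], ".", "PASS", ".", fmt, cells),
          collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(c(hdr, rows), con)
  close(con)
  invisible(path)
}

# A deterministic strongly structured dosage matrix: two diverged groups
# plus binomial noise. samples x variants.
structuredMatrix <- function(nPerGroup = 6, nVariants = 60, seed = 42,
                             pA = 0.9, pB = 0.1) {
  set.seed(seed)
  g <- rbind(
    matrix(rbinom(nPerGroup * nVariants, 2, pA), nPerGroup, nVariants),
    matrix(rbinom(nPerGroup * nVariants, 2, pB), nPerGroup, nVariants)
  )
  rownames(g) <- c(sprintf("A%02d", seq_len(nPerGroup)),
                   sprintf("B%02d", seq_len(nPerGroup)))
  g
}

# Independent dense-eigendecomposition oracle for window PCA: standardize
# the same way, then take SVD scores (U * d). Shares no code with
# pcaWindow's covariance route.
oracleScores <- function(g, pcs = 1:2, scaler = "patterson") {
  p <- colMeans(g) / 2
  if (scaler == "patterson") {
    keep <- p > 0 & p < 1
    g <- g[, keep, drop = FALSE]
    p <- p[keep]
    x <- sweep(g, 2, 2 * p, "-")
    x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  } else if (scaler == "center") {
    x <- sweep(g, 2, colMeans(g), "-")
  } else {
    x <- g
  }
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  s <- svd(x)
  sc <- s$u %*% diag(s$d, nrow = length(s$d))
  sc[, pcs, drop = FALSE]
}

# Compare score matrices up to a global per-column sign.
expectScoresEqualUpToSign <- function(got, want, tol = 1e-8) {
  for (k in seq_len(ncol(want))) {
    d1 <- max(abs(got[, k] - want[, k]))
    d2 <- max(abs(got[, k] + want[, k]))
    expect_lt(min(d1, d2), tol)
  }
}

# Build a PCTrack directly from a windows x samples score matrix (smooth
# latent series fixtures for polarity tests).
trackFromScores <- function(m, chrom = "chr1", windowSize = 10L,
                            valid = rep(TRUE, nrow(m)),
                            sampleIds = paste0("s", seq_len(ncol(m)))) {
  n <- nrow(m)
  starts <- 1 + (seq_len(n) - 1) * windowSize
  ends <- starts + windowSize - 1
  m[!valid, ] <- NA_real_
  PCTrack(
    chrom = chrom, starts = starts, ends = ends,
    scores = list(PC1 = m), sampleIds = sampleIds,
    nVariants = ifelse(valid, 30L, 0L), pctMissing = rep(0, n),
    valid = valid, varExplained = matrix(0.5, n, 1),
    params = scanParams(windowSize = windowSize, stepSize = windowSize,
                        pcs = 1L, minVariants = 2L)
  )
}

# A smooth latent PC series with k isolated whole-window sign flips.
# Returns list(truth, flipped, flippedAt).
flippedTrackPair <- function(nWindows = 30, nSamples = 8, nFlips = 3,
                             seed = 1, minGap = 6) {
  set.seed(seed)
  base <- sort(runif(nSamples, -2, 2))
  base[1] <- -(max(abs(base)) + 1)  # one unambiguously extreme sample
  truth <- t(vapply(seq_len(nWindows), function(w) {
    base + 0.05 * sin(w / 4 + seq_len(nSamples))
  }, numeric(nSamples)))
  candidates <- 2:nWindows
  flips <- integer()
  while (length(flips) < nFlips && length(candidates)) {
    f <- candidates[sample.int(length(candidates), 1)]
    flips <- c(flips, f)
    candidates <- setdiff(candidates, (f - minGap):(f + minGap))
  }
  flipped <- truth
  for (f in flips) flipped[f, ] <- -flipped[f, ]
  list(truth = truth, flipped = flipped, flippedAt = sort(flips))
}
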