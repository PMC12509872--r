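# Per-window principal component computation. Hard calls go through mean
# imputation + standardization; genotype likelihoods go through an iterative
# expected-genotype scheme with individual allele frequencies.

#' Mean-impute missing genotype dosages
#'
#' Each missing entry is replaced by the mean dosage of the non-missing
#' entries at the same variant (column). Variants with no observed calls at
#' all cannot be imputed and are dropped; the count is reported in
#' `attr(, "nDropped")`.
#'
#' @param g samples x variants dosage matrix with `NA` for missing calls.
#' @return the completed matrix (possibly with fewer columns).
#' @examples
#' meanImpute(rbind(s1 = c(0, NA), s2 = c(2, 1)))
#' @export
meanImpute <- function(g) {
  nDropped <- 0L
  if (anyNA(g)) {
    nObs <- colSums(!is.na(g))
    empty <- nObs == 0L
    if (any(empty)) {
      nDropped <- sum(empty)
      g <- g[, !empty, drop = FALSE]
      nObs <- nObs[!empty]
    }
    mu <- colSums(g, na.rm = TRUE) / nObs
    idx <- which(is.na(g), arr.ind = TRUE)
    if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  }
  attr(g, "nDropped") <- nDropped
  g
}

#' Standardize a complete dosage matrix for PCA
#'
#' `"center"` subtracts the per-variant mean dosage; `"patterson"`
#' additionally divides by `sqrt(p*(1-p))` where `p = mean dosage / 2`, the
#' binomial unit-variance scaling standard in genetic eigenanalysis.
#' Monomorphic variants (`p` of 0 or 1, including post-imputation constants)
#' carry no information and are dropped before scaling; the count is in
#' `attr(, "nDropped")`.
#'
#' @param g complete samples x variants dosage matrix (no `NA`).
#' @param scaler `"none"`, `"center"` or `"patterson"`.
#' @return the standardized real-valued matrix.
#' @export
standardizeDosage <- function(g, scaler = c("patterson", "center", "none")) {
  scaler <- match.arg(scaler)
  nDropped <- 0L
  if (scaler != "none") {
    p <- colMeans(g) / 2
    if (scaler == "patterson") {
      mono <- p <= 0 | p >= 1
      if (any(mono)) {
        nDropped <- sum(mono)
        g <- g[, !mono, drop = FALSE]
        p <- p[!mono]
      }
      g <- sweep(g, 2L, 2 * p, "-")
      g <- sweep(g, 2L, sqrt(p * (1 - p)), "/")
    } else {
      g <- sweep(g, 2L, 2 * p, "-")
    }
  }
  attr(g, "nDropped") <- nDropped
  g
}

# Invalid-result placeholder (NA scores), keeping tracks rectangular.
.invalidResult <- function(nSamples, pcs, nVariants, pctMissing) {
  list(
    scores = matrix(NA_real_, nSamples, length(pcs),
                    dimnames = list(NULL, paste0("PC", pcs))),
    varExplained = rep(NA_real_, length(pcs)),
    nVariants = as.integer(nVariants), pctMissing = pctMissing,
    valid = FALSE, converged = NA
  )
}

# Shared scoring core: standardize a complete real-valued dosage-scale
# matrix, eigendecompose the sample-sample covariance, return canonical-sign
# scores for the requested PCs. Deterministic: full symmetric
# eigendecomposition, no randomized solver.
.pcaCore <- function(m, params, pctMissing = 0) {
  pcs <- params@pcs
  ns <- nrow(m)
  if (ns < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  # exact-constant columns (monomorphic after imputation) are uninformative
  keep <- matrixStats_colVars(m) > 0
  m <- m[, keep, drop = FALSE]
  nv <- ncol(m)
  if (nv < params@minVariants) {
    return(.invalidResult(ns, pcs, nv, pctMissing))
  }
  xs <- standardizeDosage(m, params@scaler)
  nv <- ncol(xs)
  if (nv < params@minVariants) {
    return(.invalidResult(ns, pcs, nv, pctMissing))
  }
  cov <- tcrossprod(xs)
  e <- eigen(cov, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  total <- sum(lambda)
  scores <- matrix(NA_real_, ns, length(pcs),
                   dimnames = list(NULL, paste0("PC", pcs)))
  ve <- rep(NA_real_, length(pcs))
  for (k in seq_along(pcs)) {
    j <- pcs[k]
    if (j > ns) next
    sc <- e$vectors[, j] * sqrt(lambda[j])
    # canonical sign: the most extreme sample positive (lowest index on ties)
    top <- which.max(abs(sc))
    if (sc[top] < 0) sc <- -sc
    scores[, k] <- sc
    ve[k] <- if (total > 0) lambda[j] / total else NA_real_
  }
  list(scores = scores, varExplained = ve, nVariants = as.integer(nv),
       pctMissing = pctMissing, valid = TRUE, converged = NA)
}

# colVars without an extra dependency
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m * m) - n * mu * mu) / (n - 1)
}

#' Principal components of one window of hard-called genotypes
#'
#' Missing calls are mean-imputed on the fly, the matrix is standardized
#' per `params@scaler`, and samples are projected onto the leading
#' eigenvectors of the sample-sample covariance. The per-window eigenvector
#' sign is canonicalized (most extreme sample positive) but remains
#' arbitrary across windows until polarization.
#'
#' @param g samples x variants dosage matrix (`NA` = missing).
#' @param params a [ScanParams-class].
#' @return list with `scores` (samples x PCs), `varExplained`, `nVariants`
#'   (usable variants after filtering), `pctMissing`, `valid`.
#' @examples
#' g <- rbind(a = c(0, 0, 2), b = c(0, 1, 2), c = c(2, 2, 0), d = c(2, 1, 0))
#' pcaWindow(g, scanParams(minVariants = 2))
#' @export
pcaWindow <- function(g, params = scanParams()) {
  if (nrow(g) < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  pctMissing <- if (length(g)) mean(is.na(g)) else 0
  g <- meanImpute(g)
  .pcaCore(g, params, pctMissing)
}

#' Posterior expected genotypes from likelihood triplets
#'
#' Combines each normalized likelihood triplet with a Hardy-Weinberg prior
#' at the supplied alternate-allele frequency and returns the posterior
#' mean dosage `sum_g g * P(g | likelihoods, prior)`.
#'
#' @param lik samples x variants x 3 likelihood array (triplets sum to 1).
#' @param freqs either a per-variant frequency vector (length = variants)
#'   or a samples x variants matrix of individual allele frequencies,
#'   values in (0, 1).
#' @return samples x variants matrix of expected dosages.
#' @export
expectedGenotypes <- function(lik, freqs) {
  ns <- dim(lik)[1]
  nv <- dim(lik)[2]
  f <- if (is.matrix(freqs)) freqs else matrix(freqs, ns, nv, byrow = TRUE)
  p0 <- lik[, , 1] * (1 - f)^2
  p1 <- lik[, , 2] * 2 * f * (1 - f)
  p2 <- lik[, , 3] * f^2
  tot <- p0 + p1 + p2
  (p1 + 2 * p2) / tot
}

#' Principal components of one window of genotype likelihoods
#'
#' Iterative expected-genotype PCA: (0) per-variant allele frequencies are
#' estimated from posterior mean dosages under a flat prior; (1) expected
#' genotypes are computed under Hardy-Weinberg priors at the current
#' (individual) allele frequencies; (2) the standardized expected-genotype
#' matrix is eigendecomposed; (3) individual allele frequencies are
#' reconstructed from the rank-`max(pcs)` fit and clamped to
#' `[1/(2N), 1 - 1/(2N)]`; steps 1-3 repeat until the root-mean-square
#' change in expected genotypes drops below `tol` or `maxIter` is reached.
#' With fully certain likelihoods the posterior ignores the prior and the
#' result equals [pcaWindow()] on the corresponding hard calls.
#'
#' @param lik samples x variants x 3 likelihood array.
#' @param params a [ScanParams-class].
#' @param maxIter iteration cap (default 100).
#' @param tol RMS convergence threshold on expected genotypes (default 1e-4).
#' @return as [pcaWindow()], plus `converged` (`FALSE` when `maxIter` was
#'   hit, never an error).
#' @export
glPcaWindow <- function(lik, params = scanParams(), maxIter = 100L,
                        tol = 1e-4) {
  ns <- dim(lik)[1]
  nv <- dim(lik)[2]
  if (ns < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  # uninformative (flat) triplets stand in for missing data on the GL path
  flat <- abs(lik[, , 1] - 1 / 3) < 1e-12 & abs(lik[, , 2] - 1 / 3) < 1e-12
  pctMissing <- if (nv) mean(flat) else 0
  if (nv < params@minVariants) {
    res <- .invalidResult(ns, params@pcs, nv, pctMissing)
    return(res)
  }
  eFlat <- lik[, , 2] + 2 * lik[, , 3]
  fClamp <- 1 / (2 * ns)
  f <- .clamp(colMeans(eFlat) / 2, fClamp, 1 - fClamp)
  rank <- min(max(params@pcs), ns - 1L)
  pv <- matrix(f, ns, nv, byrow = TRUE)
  e <- expectedGenotypes(lik, pv)
  converged <- FALSE
  sdv <- sqrt(2 * f * (1 - f))
  for (it in seq_len(maxIter)) {
    xs <- sweep(e, 2L, 2 * f, "-")
    xs <- sweep(xs, 2L, sdv, "/")
    eg <- eigen(tcrossprod(xs), symmetric = TRUE)
    u <- eg$vectors[, seq_len(rank), drop = FALSE]
    fit <- u %*% (crossprod(u, xs))
    pv <- sweep(sweep(fit, 2L, sdv, "*"), 2L, 2 * f, "+") / 2
    pv <- .clamp(pv, fClamp, 1 - fClamp)
    eNew <- expectedGenotypes(lik, pv)
    delta <- sqrt(mean((eNew - e)^2))
    e <- eNew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  res <- .pcaCore(e, params, pctMissing)
  res$converged <- converged
  res
}

#' Run a windowed PCA over a chromosome
#'
#' Enumerates rolling windows (anchored per `params@anchor`, full-length
#' windows only), computes per-window principal components through the
#' hard-call or genotype-likelihood path, assembles a [PCTrack-class], and
#' by default polarizes each requested PC adaptively across adjacent
#' windows (see [polarizeTrack()]).
#'
#' @param vs a [VariantSet-class].
#' @param params a [ScanParams-class].
#' @param chromSpan last usable position in bp; defaults to the last
#'   variant position when no chromosome length is supplied.
#' @param polarize apply default adaptive polarization (default `TRUE`).
#' @param nPrev polarization history depth (default 5).
#' @param guideSamples optional guide sample ids for guided polarization.
#' @param maxIter,tol GL-path iteration controls, see [glPcaWindow()].
#' @return A [PCTrack-class].
#' @export
runWindowedPCA <- function(vs, params = scanParams(), chromSpan = NULL,
                           polarize = TRUE, nPrev = 5L, guideSamples = NULL,
                           maxIter = 100L, tol = 1e-4) {
  glPath <- length(vs@likelihoods) > 0L
  nv <- length(vs@pos)
  if (is.null(chromSpan)) {
    if (!nv) {
      stop("no variants and no chromosome length for region '",
           vs@chrom, "'", call. = FALSE)
    }
    chromSpan <- max(vs@pos)
  }
  specs <- windowSpecs(vs@chrom, chromSpan, params@windowSize,
                       params@stepSize, anchor = params@anchor,
                       firstPos = if (nv) min(vs@pos) else 1)
  if (!nrow(specs)) {
    stop("zero windows on region '", vs@chrom, "'", call. = FALSE)
  }
  members <- windowMembership(vs@pos, specs)
  ns <- length(vs@sampleIds)
  nW <- nrow(specs)
  npc <- length(params@pcs)
  scores <- lapply(params@pcs, function(k) matrix(NA_real_, nW, ns))
  names(scores) <- paste0("PC", params@pcs)
  ve <- matrix(NA_real_, nW, npc)
  nvar <- integer(nW)
  pmiss <- numeric(nW)
  valid <- logical(nW)
  conv <- rep(NA, nW)
  for (w in seq_len(nW)) {
    j <- members[[w]]
    res <- if (glPath) {
      glPcaWindow(vs@likelihoods[, j, , drop = FALSE], params,
                  maxIter = maxIter, tol = tol)
    } else {
      pcaWindow(vs@dosage[, j, drop = FALSE], params)
    }
    for (k in seq_len(npc)) scores[[k]][w, ] <- res$scores[, k]
    ve[w, ] <- res$varExplained
    nvar[w] <- res$nVariants
    pmiss[w] <- res$pctMissing
    valid[w] <- res$valid
    conv[w] <- res$converged
  }
  if (!any(valid)) {
    warning("all ", nW, " windows fall below the minVariants threshold (",
            params@minVariants, ")", call. = FALSE)
  }
  track <- PCTrack(
    chrom = vs@chrom, starts = specs$start, ends = specs$end,
    scores = scores, sampleIds = vs@sampleIds,
    nVariants = nvar, pctMissing = pmiss, valid = valid,
    varExplained = ve, params = params,
    converged = if (glPath) conv else NULL
  )
  if (polarize) {
    for (k in params@pcs) {
      track <- polarizeTrack(track, pc = k, nPrev = nPrev,
                             guideSamples = guideSamples)
    }
  }
  track
}

#' One-call windowed PC scan from a variant file
#'
#' Convenience wrapper: [readVariants()] then [runWindowedPCA()].
#'
#' @inheritParams readVariants
#' @inheritParams runWindowedPCA
#' @param chromLength optional chromosome length in bp overriding the
#'   last-variant-position default span.
#' @return A [PCTrack-class].
#' @export
windowedScan <- function(path, params = scanParams(), region = NULL,
                         chromLength = NULL, polarize = TRUE, nPrev = 5L,
                         guideSamples = NULL) {
  vs <- readVariants(path, format = params@format, region = region,
                     glField = params@glField)
  runWindowedPCA(vs, params, chromSpan = chromLength, polarize = polarize,
                 nPrev = nPrev, guideSamples = guideSamples)
}
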