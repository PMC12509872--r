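# Sign harmonization across adjacent windows. Each window's eigenvector sign
# is arbitrary; polarization flips whole windows so per-sample score series
# are continuous along the chromosome.

# Mean of the signs (+1/-1, zero-score and NA terms excluded) of a history
# vector; 0 when no usable terms.
.signAverage <- function(x) {
  s <- sign(x[!is.na(x)])
  s <- s[s != 0]
  if (!length(s)) 0 else mean(s)
}

#' Polarize a PC across adjacent windows
#'
#' Works through the windows in positional order. The first valid window is
#' left as-is; for every later valid window the rule compares the sign of a
#' reference score in the current window against the average sign that the
#' same reference carried over the up-to-`nPrev` preceding valid, already
#' polarized windows, and negates the whole window (all samples) on
#' disagreement. In adaptive mode the reference is the sample with the
#' largest absolute score in the current window (lowest sample index on
#' ties); in guided mode it is the summed score of the user-supplied guide
#' samples. Invalid (`NA`) windows are skipped and do not consume history;
#' `NA` history terms are excluded from the sign average; a zero sign
#' average keeps the window's current orientation. The operation is
#' idempotent and recomputes polarity from the stored signs on every
#' invocation, so re-polarizing existing output is safe.
#'
#' @param track a [PCTrack-class].
#' @param pc PC index to polarize.
#' @param nPrev number of preceding polarized windows consulted (default 5).
#' @param guideSamples optional character vector of guide sample ids;
#'   unknown ids are a fatal error.
#' @return the polarized [PCTrack-class].
#' @rdname polarizeTrack
#' @export
setMethod("polarizeTrack", "PCTrack", function(track, pc = 1L, nPrev = 5L,
                                               guideSamples = NULL) {
  stopifnot(nPrev >= 1L)
  m <- pcScores(track, pc)
  guided <- !is.null(guideSamples) && length(guideSamples) > 0L
  if (guided) {
    bad <- setdiff(guideSamples, colnames(m))
    if (length(bad)) {
      stop("unknown guide sample(s): ", paste(bad, collapse = ", "),
           "; valid ids: ", paste(colnames(m), collapse = ", "),
           call. = FALSE)
    }
    gIdx <- match(guideSamples, colnames(m))
  }
  vIdx <- which(validWindows(track) & rowSums(!is.na(m)) > 0L)
  if (length(vIdx) > 1L) {
    for (k in 2:length(vIdx)) {
      i <- vIdx[k]
      prev <- vIdx[max(1L, k - nPrev):(k - 1L)]
      if (guided) {
        cur <- sum(m[i, gIdx], na.rm = TRUE)
        hist <- rowSums(m[prev, gIdx, drop = FALSE], na.rm = TRUE)
        hist[rowSums(!is.na(m[prev, gIdx, drop = FALSE])) == 0L] <- NA_real_
      } else {
        a <- abs(m[i, ])
        a[is.na(a)] <- -Inf
        j <- which.max(a)
        cur <- m[i, j]
        hist <- m[prev, j]
      }
      s <- .signAverage(hist)
      if (!is.na(cur) && sign(cur) != 0 && s != 0 && sign(cur) != sign(s)) {
        m[i, ] <- -m[i, ]
      }
    }
  }
  nm <- paste0("PC", as.integer(pc))
  assay(track, nm) <- m
  pol <- union(metadata(track)$polarized, nm)
  metadata(track)$polarized <- pol
  track
})

#' Reflect a PC for the whole chromosome
#'
#' Negates every window's scores for the given PC (an involution:
#' flipping twice restores the original track). Variance explained and all
#' between-sample distances are unchanged; `NA` windows stay `NA`.
#'
#' @param track a [PCTrack-class].
#' @param pc PC index to reflect.
#' @return the reflected [PCTrack-class].
#' @rdname flipChromosome
#' @export
setMethod("flipChromosome", "PCTrack", function(track, pc = 1L) {
  nm <- paste0("PC", as.integer(pc))
  assay(track, nm) <- -pcScores(track, pc)
  track
})

#' Flip individual windows selected by coordinate intervals
#'
#' Windows whose midpoint falls inside any of the (closed) intervals are
#' negated exactly once, regardless of interval overlap (set semantics).
#'
#' @param track a [PCTrack-class].
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @param pc PC index.
#' @return the modified [PCTrack-class].
#' @rdname flipWindows
#' @export
setMethod("flipWindows", "PCTrack", function(track, intervals, pc = 1L) {
  stopifnot(all(c("chrom", "start", "end") %in% colnames(intervals)))
  if (any(intervals$end < intervals$start)) {
    stop("malformed flip interval: end < start", call. = FALSE)
  }
  ours <- intervals$chrom == chromName(track)
  mids <- windowMids(track)
  hit <- rep(FALSE, length(mids))
  for (r in which(ours)) {
    hit <- hit | (mids >= intervals$start[r] & mids <= intervals$end[r])
  }
  if (any(hit)) {
    nm <- paste0("PC", as.integer(pc))
    m <- pcScores(track, pc)
    m[hit, ] <- -m[hit, , drop = FALSE]
    assay(track, nm) <- m
  }
  track
})
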