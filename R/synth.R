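# Synthetic cohorts with known population structure and a planted inversion
# polymorphism, emitted in all three supported input formats plus truth
# tables, so every pipeline stage is testable end to end.

#' Simulate genotype-likelihood triplets from read counts
#'
#' Emulates shotgun sequencing at a mean depth: the read count per site is
#' Poisson(`depth`), the alternate-read count is binomial given the true
#' genotype and the per-base error rate (alt-read probability `errorRate`,
#' `0.5`, `1 - errorRate` for genotypes 0/1/2), and the returned triplet is
#' the normalized binomial likelihood of the observed read pair under each
#' genotype. Zero reads give the flat triplet.
#'
#' @param genotype vector of true dosages in \{0, 1, 2\}.
#' @param depth mean sequencing depth (reads per site).
#' @param errorRate per-base error probability.
#' @return `length(genotype)` x 3 matrix of normalized likelihoods.
#' @export
simulateLikelihoods <- function(genotype, depth, errorRate = 0.01) {
  n <- length(genotype)
  stopifnot(all(genotype %in% 0:2), depth >= 0)
  reads <- stats::rpois(n, depth)
  pAlt <- c(errorRate, 0.5, 1 - errorRate)[genotype + 1L]
  altReads <- stats::rbinom(n, reads, pAlt)
  lik <- cbind(
    stats::dbinom(altReads, reads, errorRate),
    stats::dbinom(altReads, reads, 0.5),
    stats::dbinom(altReads, reads, 1 - errorRate)
  )
  s <- rowSums(lik)
  zero <- s <= 0 | reads == 0L
  lik <- lik / s
  lik[zero, ] <- 1 / 3
  lik
}

# Balding-Nichols draw: population frequency around ancestral p with
# divergence F (variance F*p*(1-p)).
.bnFreq <- function(p, f, n) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  .clamp(stats::rbeta(n, a, b), 0.01, 0.99)
}

#' Simulate a structured cohort with a planted inversion
#'
#' Draws per-variant ancestral allele frequencies Uniform(0.05, 0.95) and
#' population frequencies around them under a Balding-Nichols model with
#' divergence `divergence`; genotypes are Hardy-Weinberg within population.
#' Inside the optional inversion interval each sample carries an inversion
#' genotype in \{0, 1, 2\} drawn at haplotype frequency `q`, and alleles on
#' inverted versus standard haplotypes diverge with
#' `divergence * multiplier`, so windows inside the inversion show the
#' characteristic tripartite PC pattern while windows outside separate the
#' populations. Missing hard calls are sprinkled uniformly at the
#' configured rate; genotype likelihoods are generated from the true
#' genotypes by binomial read sampling at the configured depth
#' (see [simulateLikelihoods()]).
#'
#' A fixed `seed` makes the simulation (and any files written) fully
#' reproducible: one global RNG stream is seeded once and all output
#' formats are emitted from the same genotype draw.
#'
#' @param nSamplesPerPop samples per population (default 50).
#' @param nPopulations number of populations (default 2).
#' @param divergence Balding-Nichols F between populations, in (0, 1)
#'   (default 0.1).
#' @param chromLength chromosome length in bp (default 5e6).
#' @param variantDensity variants per bp (default 1/1000).
#' @param inversion `NULL` for no inversion, or a list with `start`, `end`,
#'   `q` (inversion haplotype frequency) and `multiplier` (divergence
#'   multiplier between inverted and standard haplotypes). The default
#'   plants an inversion over the middle fifth-to-three-fifths of the
#'   chromosome (2-3 Mbp on the default 5 Mbp chromosome) at `q = 0.5`.
#' @param missingness fraction of hard calls masked as missing (default 0).
#' @param depth mean sequencing depth for likelihood emission (default 8).
#' @param errorRate per-base error rate (default 0.01).
#' @param seed RNG seed.
#' @param chrom chromosome name (default `"chr1"`).
#' @param outPrefix when given, writes `<prefix>.vcf.gz`,
#'   `<prefix>.beagle.gz`, `<prefix>.tsv.gz`, `<prefix>.truth.tsv` and a
#'   metadata table `<prefix>.meta.tsv`.
#' @return list with `pos`, `dosage` (true genotypes, samples x variants),
#'   `observed` (dosages after missingness masking), `likelihoods`
#'   (samples x variants x 3), `truth` (per-sample population and inversion
#'   genotype), `sampleIds`, `inversion`, `chrom`, `chromLength` and (when
#'   written) `paths`.
#' @examples
#' sim <- simulateCohort(nSamplesPerPop = 5, chromLength = 1e5, seed = 1)
#' table(sim$truth$population)
#' @export
simulateCohort <- function(nSamplesPerPop = 50L, nPopulations = 2L,
                           divergence = 0.1, chromLength = 5e6,
                           variantDensity = 1 / 1000,
                           inversion = list(start = 0.4 * chromLength,
                                            end = 0.6 * chromLength,
                                            q = 0.5, multiplier = 5),
                           missingness = 0, depth = 8, errorRate = 0.01,
                           seed = 1L, chrom = "chr1", outPrefix = NULL) {
  stopifnot(nPopulations >= 1L, nSamplesPerPop >= 1L,
            divergence > 0, divergence < 1,
            missingness >= 0, missingness < 1)
  if (!is.null(inversion)) {
    stopifnot(inversion$start >= 1, inversion$end <= chromLength,
              inversion$end >= inversion$start,
              inversion$q > 0, inversion$q < 1)
  }
  set.seed(as.integer(seed))
  ns <- nSamplesPerPop * nPopulations
  nv <- max(1L, round(chromLength * variantDensity))
  pos <- sort(sample.int(chromLength, nv))
  pop <- rep(seq_len(nPopulations), each = nSamplesPerPop)
  sampleIds <- sprintf("pop%d_s%02d", pop,
                       stats::ave(pop, pop, FUN = seq_along))
  pAnc <- stats::runif(nv, 0.05, 0.95)
  inInv <- if (is.null(inversion)) rep(FALSE, nv) else {
    pos >= inversion$start & pos <= inversion$end
  }
  # population frequencies outside (and residually inside) the inversion
  popFreq <- vapply(seq_len(nPopulations), function(k) .bnFreq(pAnc, divergence, nv),
                    numeric(nv))
  g <- matrix(0, ns, nv)
  for (k in seq_len(nPopulations)) {
    rows <- which(pop == k)
    g[rows, ] <- matrix(
      stats::rbinom(length(rows) * nv, 2L,
                    rep(popFreq[, k], each = length(rows))),
      length(rows), nv
    )
  }
  invGeno <- rep(0L, ns)
  if (!is.null(inversion) && any(inInv)) {
    invGeno <- stats::rbinom(ns, 2L, inversion$q)
    fInv <- min(0.9, divergence * inversion$multiplier)
    j <- which(inInv)
    pStd <- .bnFreq(pAnc[j], fInv, length(j))
    pInv <- .bnFreq(pAnc[j], fInv, length(j))
    # per-haplotype draws: invGeno inverted haplotypes + (2-invGeno) standard
    for (s in seq_len(ns)) {
      g[s, j] <- stats::rbinom(length(j), 2L - invGeno[s], pStd) +
        stats::rbinom(length(j), invGeno[s], pInv)
    }
  }
  observed <- g
  if (missingness > 0) {
    mask <- stats::runif(length(g)) < missingness
    observed[mask] <- NA_real_
  }
  lik <- array(NA_real_, c(ns, nv, 3L))
  likFlat <- simulateLikelihoods(as.vector(g), depth, errorRate)
  for (gg in 1:3) lik[, , gg] <- matrix(likFlat[, gg], ns, nv)
  alleles <- c("A", "C", "G", "T")
  refIdx <- sample.int(4L, nv, replace = TRUE)
  altIdx <- ((refIdx - 1L + sample.int(3L, nv, replace = TRUE)) %% 4L) + 1L
  truth <- data.frame(
    sample = sampleIds,
    population = paste0("pop", pop),
    inversion_genotype = invGeno,
    phenotype = round(invGeno + stats::rnorm(ns, 0, 0.1), 4)
  )
  out <- list(
    chrom = chrom, chromLength = chromLength, pos = pos,
    ref = alleles[refIdx], alt = alleles[altIdx],
    dosage = structure(g, dimnames = list(sampleIds, NULL)),
    observed = structure(observed, dimnames = list(sampleIds, NULL)),
    likelihoods = lik, truth = truth, sampleIds = sampleIds,
    inversion = inversion
  )
  if (!is.null(outPrefix)) {
    out$paths <- .writeCohort(out, outPrefix)
  }
  out
}

# Emit the cohort in VCF (GT), BEAGLE (GL) and TSV (dosage) form, gzipped,
# plus plain-text truth and metadata tables.
.writeCohort <- function(sim, prefix) {
  ns <- length(sim$sampleIds)
  nv <- length(sim$pos)
  vcfPath <- paste0(prefix, ".vcf.gz")
  con <- gzfile(vcfPath, "wt")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", sim$chrom, as.integer(sim$chromLength)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sim$sampleIds), collapse = "\t")
  ), con)
  gtStr <- matrix("./.", ns, nv)
  obs <- sim$observed
  gtStr[!is.na(obs) & obs == 0] <- "0/0"
  gtStr[!is.na(obs) & obs == 1] <- "0/1"
  gtStr[!is.na(obs) & obs == 2] <- "1/1"
  rows <- vapply(seq_len(nv), function(j) {
    paste(c(sim$chrom, sim$pos[j], ".", sim$ref[j], sim$alt[j], ".", "PASS",
            ".", "GT", gtStr[, j]), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  close(con)

  beaglePath <- paste0(prefix, ".beagle.gz")
  con <- gzfile(beaglePath, "wt")
  writeLines(paste(c("marker", "allele1", "allele2",
                     rep(sim$sampleIds, each = 3L)), collapse = "\t"), con)
  allele2num <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  lik <- sim$likelihoods
  bRows <- vapply(seq_len(nv), function(j) {
    trip <- rbind(lik[, j, 1], lik[, j, 2], lik[, j, 3])
    paste(c(paste0(sim$chrom, "_", sim$pos[j]),
            allele2num[sim$ref[j]], allele2num[sim$alt[j]],
            formatC(as.vector(trip), format = "g", digits = 6)),
          collapse = "\t")
  }, character(1))
  writeLines(bRows, con)
  close(con)

  tsvPath <- paste0(prefix, ".tsv.gz")
  con <- gzfile(tsvPath, "wt")
  writeLines(paste(c("CHROM", "POS", sim$sampleIds), collapse = "\t"), con)
  obsChr <- matrix(as.character(obs), ns, nv)
  obsChr[is.na(obs)] <- "NA"
  tRows <- vapply(seq_len(nv), function(j) {
    paste(c(sim$chrom, sim$pos[j], obsChr[, j]), collapse = "\t")
  }, character(1))
  writeLines(tRows, con)
  close(con)

  truthPath <- paste0(prefix, ".truth.tsv")
  utils::write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  metaPath <- paste0(prefix, ".meta.tsv")
  utils::write.table(sim$truth, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(vcf = vcfPath, beagle = beaglePath, tsv = tsvPath,
    truth = truthPath, meta = metaPath)
}
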