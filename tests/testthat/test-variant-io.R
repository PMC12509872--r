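# VCF/BEAGLE/TSV parsing, likelihood decoding, windowing arithmetic and
# the metadata reader.

test_that("VCF parsing keeps biallelic records, counts skips, captures samples", {
  path <- tempfile(fileext = ".vcf")
  writeTestVcf(
    path, "chr1", pos = c(100, 200, 300),
    ref = c("A", "C", "G"), alt = c("G", "A,T", "T"),
    gt = matrix(c("0/0", "0/1", "0/1", "1/2", "1/1", "./."), 3, 2,
                byrow = TRUE, dimnames = list(NULL, c("s1", "s2")))
  )
  vs <- readVariants(path, "vcf", region = "chr1")
  expect_equal(vs@pos, c(100, 300))
  expect_equal(unname(vs@skipped["multiallelic"]), 1L)
  expect_equal(vs@sampleIds, c("s1", "s2"))
  # manual parse of the fixture: s1 = 0/0 -> 0, 1/1 -> 2; s2 = 0/1 -> 1, ./. -> NA
  expect_equal(unname(vs@dosage["s1", ]), c(0, 2))
  expect_equal(unname(vs@dosage["s2", ]), c(1, NA))
})

test_that("header-only VCF yields zero records but a populated sample list", {
  path <- tempfile(fileext = ".vcf")
  writeTestVcf(path, "chr1", pos = numeric(), ref = character(),
               alt = character(),
               gt = matrix(character(), 0, 3,
                           dimnames = list(NULL, c("a", "b", "c"))))
  vs <- readVariants(path, "vcf", region = "chr1")
  expect_length(vs@pos, 0)
  expect_equal(vs@sampleIds, c("a", "b", "c"))
})

test_that("requesting an absent chromosome warns and yields zero records", {
  path <- tempfile(fileext = ".vcf")
  writeTestVcf(path, "chr1", pos = 100, ref = "A", alt = "G",
               gt = matrix("0/1", 1, 2, dimnames = list(NULL, c("s1", "s2"))))
  expect_warning(vs <- readVariants(path, "vcf", region = "chr2"),
                 "chr2")
  expect_length(vs@pos, 0)
})

test_that("unsorted input and unreadable paths are fatal", {
  path <- tempfile(fileext = ".vcf")
  writeTestVcf(path, "chr1", pos = c(300, 100), ref = c("A", "C"),
               alt = c("G", "T"),
               gt = matrix("0/1", 2, 2, dimnames = list(NULL, c("s1", "s2"))))
  expect_error(readVariants(path, "vcf", region = "chr1"), "sorted")
  missing <- file.path(tempdir(), "no-such-file.vcf")
  expect_error(readVariants(missing, "vcf"), "no-such-file")
})

test_that("half calls are missing and haploid calls double with a warning", {
  path <- tempfile(fileext = ".vcf")
  writeTestVcf(path, "chr1", pos = c(10, 20), ref = c("A", "A"),
               alt = c("G", "G"),
               gt = matrix(c("./1", "1|1", "1", "0/1"), 2, 2, byrow = TRUE,
                           dimnames = list(NULL, c("s1", "s2"))))
  expect_warning(vs <- readVariants(path, "vcf", region = "chr1"),
                 "haploid")
  expect_equal(unname(vs@dosage["s1", ]), c(NA, 2))
  expect_equal(unname(vs@dosage["s2", ]), c(2, 1))
})

test_that("PL and GL triplets decode to normalized probabilities", {
  # hand computation: 10^(-PL/10) for PL 0,30,60 then normalize
  raw <- 10^(-c(0, 30, 60) / 10)
  want <- raw / sum(raw)
  got <- parseLikelihoodTriplets("0,30,60", "PL")
  expect_equal(unname(got[1, ]), want, tolerance = 1e-12)
  expect_equal(sum(got[1, ]), 1)
  # flat likelihoods, both encodings
  expect_equal(unname(parseLikelihoodTriplets("0,0,0", "PL")[1, ]),
               rep(1 / 3, 3))
  expect_equal(unname(parseLikelihoodTriplets("-1,-1,-1", "GL")[1, ]),
               rep(1 / 3, 3))
  # GL all <= 0: log10 convention; else plain probabilities
  gl <- parseLikelihoodTriplets("-0.1,-2,-4", "GL")[1, ]
  dec <- 10^c(-0.1, -2, -4)
  expect_equal(unname(gl), dec / sum(dec), tolerance = 1e-12)
  plain <- parseLikelihoodTriplets("0.8,0.15,0.05", "GL")[1, ]
  expect_equal(unname(plain), c(0.8, 0.15, 0.05), tolerance = 1e-12)
  # malformed entries are counted, not fatal
  bad <- parseLikelihoodTriplets(c("1,2", "x,y,z", "0,0,0"), "PL")
  expect_equal(attr(bad, "nMalformed"), 2L)
})

test_that("window count and bounds match brute-force enumeration", {
  # Full-windows-only convention: start + windowSize - 1 <= span.
  bruteCount <- function(span, w, s) {
    starts <- seq(1, span, by = s)
    sum(starts + w - 1 <= span)
  }
  set.seed(7)
  for (i in 1:100) {
    w <- sample(10:1000, 1)
    s <- sample(seq_len(w), 1)
    span <- w + sample(0:5000, 1)
    expect_identical(windowCount(span, w, s),
                     as.integer(bruteCount(span, w, s)))
  }
  # span equal to one window
  sp <- windowSpecs("c", 1e6, 1e6, 1e5)
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$start, sp$end), c(1, 1e6))
})

test_that("window membership matches a brute-force interval test", {
  pos <- 1:30
  specs <- windowSpecs("c", 30, 10, 5)
  expect_equal(specs$start, c(1, 6, 11, 16, 21))
  expect_equal(specs$end, c(10, 15, 20, 25, 30))
  members <- windowMembership(pos, specs)
  for (w in seq_len(nrow(specs))) {
    brute <- which(pos >= specs$start[w] & pos <= specs$end[w])
    expect_equal(sort(unname(members[[w]])), brute)
  }
  # random spans: every variant appears in the windows interval arithmetic says
  set.seed(11)
  for (i in 1:20) {
    w <- sample(5:50, 1); s <- sample(seq_len(w), 1)
    span <- w + sample(0:200, 1)
    p <- sort(sample.int(span, min(span, 40)))
    sp <- windowSpecs("c", span, w, s)
    mem <- windowMembership(p, sp)
    for (j in seq_along(p)) {
      inWin <- which(sp$start <= p[j] & p[j] <= sp$end)
      seen <- unname(which(vapply(mem, function(v) j %in% v, logical(1))))
      expect_equal(seen, inWin)
    }
  }
})

test_that("plain, gzip and bgzip inputs yield identical record streams", {
  skip_if_not_installed("Rsamtools")
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), 40, replace = TRUE),
               20, 2, dimnames = list(NULL, c("s1", "s2")))
  plain <- tempfile(fileext = ".vcf")
  writeTestVcf(plain, "chr1", pos = seq(10, 200, by = 10),
               ref = rep("A", 20), alt = rep("G", 20), gt = gt)
  gz <- tempfile(fileext = ".vcf.gz")
  con <- gzfile(gz, "wt"); writeLines(readLines(plain), con); close(con)
  bgz <- Rsamtools::bgzip(plain, tempfile(fileext = ".vcf.bgz"))
  v1 <- readVariants(plain, "vcf", "chr1")
  v2 <- readVariants(gz, "vcf", "chr1")
  v3 <- readVariants(bgz, "vcf", "chr1")
  expect_identical(v1@pos, v2@pos)
  expect_identical(v1@dosage, v2@dosage)
  expect_identical(v1@pos, v3@pos)
  expect_identical(v1@dosage, v3@dosage)
})

test_that("TSV genotype matrices round-trip bit-exactly", {
  sim <- simulateCohort(nSamplesPerPop = 4, chromLength = 5e4, seed = 3,
                        missingness = 0.1, inversion = NULL,
                        outPrefix = file.path(tempdir(), "rt"))
  orig <- readLines(gzfile(sim$paths["tsv"]))
  vs <- readVariants(sim$paths["tsv"], "tsv", "chr1")
  # re-serialize with the same schema
  body <- vapply(seq_along(vs@pos), function(j) {
    cells <- vs@dosage[, j]
    cells <- ifelse(is.na(cells), "NA", as.character(cells))
    paste(c(vs@chrom, format(vs@pos[j], scientific = FALSE), cells),
          collapse = "\t")
  }, character(1))
  redone <- c(paste(c("CHROM", "POS", vs@sampleIds), collapse = "\t"), body)
  expect_identical(redone, orig)
})

test_that("BEAGLE files parse into normalized likelihood triplets", {
  sim <- simulateCohort(nSamplesPerPop = 3, chromLength = 2e4, seed = 5,
                        depth = 10, inversion = NULL,
                        outPrefix = file.path(tempdir(), "bg"))
  vs <- readVariants(sim$paths["beagle"], "beagle", "chr1")
  expect_equal(vs@sampleIds, sim$sampleIds)
  expect_equal(vs@pos, as.numeric(sim$pos))
  sums <- vs@likelihoods[, , 1] + vs@likelihoods[, , 2] + vs@likelihoods[, , 3]
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
})

test_that("metadata rows are matched, dropped and NA-filled correctly", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tpopulation\tscore",
    "s1\tA\t2.0", "s2\tB\t4.0", "s3\tA\t6.0",
    "zz1\tC\t0", "zz2\tC\t0", "zz3\tC\t0"
  ), path)
  expect_warning(meta <- readSampleMetadata(path, c("s1", "s2", "s3", "s4")),
                 "3")
  expect_equal(nrow(meta), 4)
  expect_true(is.na(meta["s4", "population"]))
  expect_equal(meta$score[1:3], c(2, 4, 6))
  suppressWarnings(
    expect_error(readSampleMetadata(path, c("s1"), quantCol = "population"),
                 "not numeric")
  )
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tgroup", "s1\tA", "s1\tB"), dup)
  expect_error(readSampleMetadata(dup, "s1"), "duplicate")
})
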