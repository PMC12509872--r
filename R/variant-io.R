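# Input parsing: VCF (via vcfR), BEAGLE (ANGSD dialect) and TSV genotype
# matrices, plus the windowing arithmetic shared by the whole scan.

#' Decode genotype-likelihood triplets into normalized probabilities
#'
#' PL fields are phred-scaled (`10^(-PL/10)`); GL fields are log10-scaled
#' when every value in a triplet is <= 0 (the common VCF convention) and
#' plain probabilities otherwise. After decoding, each triplet is normalized
#' to sum to 1; an all-zero or missing triplet decodes to the uninformative
#' flat triplet (1/3, 1/3, 1/3).
#'
#' @param raw character vector of comma-separated triplets, e.g. `"0,30,60"`.
#' @param encoding `"GL"` or `"PL"`.
#' @return a `length(raw)` x 3 matrix of probabilities; rows of malformed
#'   entries (wrong arity, non-numeric) are `NA` and counted in
#'   `attr(, "nMalformed")`.
#' @examples
#' parseLikelihoodTriplets("0,30,60", "PL")
#' @export
parseLikelihoodTriplets <- function(raw, encoding = c("GL", "PL")) {
  encoding <- match.arg(encoding)
  n <- length(raw)
  out <- matrix(NA_real_, n, 3L)
  parts <- strsplit(raw, ",", fixed = TRUE)
  arity <- lengths(parts)
  missingField <- is.na(raw) | raw == "." | raw == ""
  ok <- !missingField & arity == 3L
  if (any(ok)) {
    vals <- suppressWarnings(as.numeric(unlist(parts[ok], use.names = FALSE)))
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    bad <- rowSums(is.na(m)) > 0L
    if (encoding == "PL") {
      m <- 10^(-m / 10)
    } else {
      logScaled <- rowSums(m > 0, na.rm = TRUE) == 0L
      m[logScaled, ] <- 10^m[logScaled, , drop = FALSE]
    }
    s <- rowSums(m)
    flat <- !bad & (!is.finite(s) | s <= 0)
    m <- m / s
    m[flat, ] <- 1 / 3
    m[bad, ] <- NA_real_
    out[ok, ] <- m
  }
  out[missingField, ] <- 1 / 3
  malformed <- !missingField & (arity != 3L | is.na(out[, 1]))
  attr(out, "nMalformed") <- sum(malformed)
  out
}

# Convert VCF GT strings ("0/1", "1|1", ".", "./1", "1") into dosages.
# Half calls are missing; haploid calls are doubled (with one warning).
.gtToDosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(s) {
    if (is.na(s) || s == "." || s == "./." || s == ".|.") return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    al <- sub(":.*$", "", al)
    if (length(al) == 1L) {
      if (al == ".") return(NA_real_)
      v <- suppressWarnings(as.numeric(al))
      if (is.na(v)) return(NA_real_)
      return(2 * v)  # haploid call doubled
    }
    if (length(al) != 2L || any(al == ".")) return(NA_real_)
    v <- suppressWarnings(as.numeric(al))
    if (anyNA(v)) return(NA_real_)
    sum(v)
  }, numeric(1))
  haploid <- any(!is.na(u) & !grepl("[/|]", u) & u != ".")
  if (haploid) {
    warning("haploid GT calls found; doubling to diploid dosage", call. = FALSE)
  }
  matrix(map[match(as.vector(gt), u)], nrow(gt), ncol(gt),
         dimnames = dimnames(gt))
}

.emptyVariantSet <- function(chrom, sampleIds, skipped = integer(),
                             likelihood = FALSE) {
  ns <- length(sampleIds)
  new("VariantSet",
    chrom = chrom %||% NA_character_, pos = numeric(), ref = character(),
    alt = character(), sampleIds = sampleIds,
    dosage = matrix(numeric(), ns * (!likelihood), 0L),
    likelihoods = if (likelihood) array(numeric(), c(ns, 0L, 3L)) else array(numeric(), c(0L, 0L, 0L)),
    skipped = skipped
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readVariantsVcf <- function(path, chrom, glField) {
  # vcfR keys compression off the extension; route gzip payloads that lack
  # a .gz suffix (and vice versa) through a correctly-named copy.
  gz <- .isGzip(path)
  extGz <- grepl("\\.gz$", path)
  if (gz != extGz) {
    tmp <- tempfile(fileext = if (gz) ".vcf.gz" else ".vcf")
    file.copy(path, tmp)
    path <- tmp
    on.exit(unlink(tmp))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  sampleIds <- colnames(v@gt)
  sampleIds <- sampleIds[sampleIds != "FORMAT"]
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record inputs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  skipped <- c(multiallelic = 0L, malformed = 0L, other_chrom = 0L)
  if (nrow(fix) == 0L) {
    return(.emptyVariantSet(chrom, sampleIds, skipped, glField != "GT"))
  }
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  alt <- fix[, "ALT"]
  keep <- rep(TRUE, nrow(fix))
  badPos <- is.na(pos)
  multi <- !badPos & (is.na(alt) | grepl(",", alt, fixed = TRUE) |
                        grepl("^<", alt))
  skipped["malformed"] <- sum(badPos)
  skipped["multiallelic"] <- sum(multi)
  keep <- keep & !badPos & !multi
  if (!is.null(chrom)) {
    onChrom <- fix[, "CHROM"] == chrom
    skipped["other_chrom"] <- sum(keep & !onChrom)
    if (!any(onChrom)) {
      warning("no records on requested chromosome '", chrom, "'",
              call. = FALSE)
    }
    keep <- keep & onChrom
  } else {
    chroms <- unique(fix[keep, "CHROM"])
    if (length(chroms) > 1L) {
      stop("input spans multiple chromosomes (", paste(chroms, collapse = ", "),
           "); supply a region", call. = FALSE)
    }
    chrom <- if (length(chroms)) chroms else NA_character_
  }
  idx <- which(keep)
  if (length(idx) && is.unsorted(pos[idx])) {
    stop("variant records out of position order on ", chrom,
         "; input must be coordinate-sorted", call. = FALSE)
  }
  if (!length(idx)) {
    return(.emptyVariantSet(chrom, sampleIds, skipped, glField != "GT"))
  }
  if (glField == "GT") {
    gt <- vcfR::extract.gt(v, element = "GT", IDtoRowNames = FALSE)
    dos <- t(.gtToDosage(gt[idx, , drop = FALSE]))
    rownames(dos) <- sampleIds
    new("VariantSet",
      chrom = chrom, pos = pos[idx], ref = fix[idx, "REF"], alt = alt[idx],
      sampleIds = sampleIds, dosage = dos,
      likelihoods = array(numeric(), c(0L, 0L, 0L)), skipped = skipped
    )
  } else {
    fld <- vcfR::extract.gt(v, element = glField, IDtoRowNames = FALSE)
    fld <- fld[idx, , drop = FALSE]
    trip <- parseLikelihoodTriplets(as.vector(t(fld)), encoding = glField)
    ns <- length(sampleIds)
    nv <- length(idx)
    lik <- array(NA_real_, c(ns, nv, 3L))
    for (g in 1:3) lik[, , g] <- matrix(trip[, g], ns, nv)
    # a malformed triplet anywhere drops the whole record
    badRec <- which(apply(is.na(lik[, , 1, drop = FALSE]), 2, any))
    if (length(badRec)) {
      skipped["malformed"] <- skipped["malformed"] + length(badRec)
      lik <- lik[, -badRec, , drop = FALSE]
      idx <- idx[-badRec]
    }
    new("VariantSet",
      chrom = chrom, pos = pos[idx], ref = fix[idx, "REF"], alt = alt[idx],
      sampleIds = sampleIds,
      dosage = matrix(numeric(), 0L, 0L),
      likelihoods = lik, skipped = skipped
    )
  }
}

.readVariantsBeagle <- function(path, chrom) {
  lines <- .readLinesAuto(path)
  if (!length(lines)) stop("empty BEAGLE file: ", path, call. = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 3L || (length(hdr) - 3L) %% 3L != 0L) {
    stop("malformed BEAGLE header in ", path, call. = FALSE)
  }
  sampleIds <- unique(hdr[-(1:3)])
  ns <- length(sampleIds)
  if (length(hdr) - 3L != 3L * ns) {
    # sample columns not named in repeated triplets; fall back to triplet order
    sampleIds <- hdr[seq(4L, length(hdr), by = 3L)]
    ns <- length(sampleIds)
  }
  skipped <- c(multiallelic = 0L, malformed = 0L, other_chrom = 0L)
  if (length(lines) == 1L) {
    return(.emptyVariantSet(chrom, sampleIds, skipped, likelihood = TRUE))
  }
  dt <- data.table::fread(text = lines[-1], header = FALSE, sep = "\t")
  marker <- as.character(dt[[1]])
  mchrom <- sub("_[0-9]+$", "", marker)
  mpos <- suppressWarnings(as.numeric(sub("^.*_", "", marker)))
  keep <- !is.na(mpos)
  skipped["malformed"] <- sum(!keep)
  if (!is.null(chrom)) {
    onChrom <- mchrom == chrom
    skipped["other_chrom"] <- sum(keep & !onChrom)
    if (!any(onChrom)) {
      warning("no records on requested chromosome '", chrom, "'", call. = FALSE)
    }
    keep <- keep & onChrom
  } else {
    chrom <- if (any(keep)) mchrom[keep][1] else NA_character_
  }
  idx <- which(keep)
  if (length(idx) && is.unsorted(mpos[idx])) {
    stop("BEAGLE markers out of position order on ", chrom, call. = FALSE)
  }
  if (!length(idx)) {
    return(.emptyVariantSet(chrom, sampleIds, skipped, likelihood = TRUE))
  }
  vals <- as.matrix(dt[idx, -(1:3), with = FALSE])  # variants x (3*ns)
  nv <- length(idx)
  lik <- array(NA_real_, c(ns, nv, 3L))
  for (g in 1:3) {
    lik[, , g] <- t(vals[, seq(g, 3L * ns, by = 3L), drop = FALSE])
  }
  s <- lik[, , 1] + lik[, , 2] + lik[, , 3]
  s[!is.finite(s) | s <= 0] <- NA_real_
  for (g in 1:3) {
    m <- lik[, , g] / s
    m[is.na(s)] <- 1 / 3
    lik[, , g] <- m
  }
  new("VariantSet",
    chrom = chrom, pos = mpos[idx],
    ref = as.character(dt[[2]])[idx], alt = as.character(dt[[3]])[idx],
    sampleIds = sampleIds,
    dosage = matrix(numeric(), 0L, 0L), likelihoods = lik, skipped = skipped
  )
}

.readVariantsTsv <- function(path, chrom) {
  lines <- .readLinesAuto(path)
  if (!length(lines)) stop("empty TSV file: ", path, call. = FALSE)
  dt <- data.table::fread(text = lines, header = TRUE, sep = "\t",
                          na.strings = "NA")
  if (!all(c("CHROM", "POS") %in% names(dt))) {
    stop("TSV genotype matrix must have CHROM and POS columns", call. = FALSE)
  }
  sampleIds <- setdiff(names(dt), c("CHROM", "POS"))
  skipped <- c(multiallelic = 0L, malformed = 0L, other_chrom = 0L)
  pos <- suppressWarnings(as.numeric(dt$POS))
  keep <- !is.na(pos)
  skipped["malformed"] <- sum(!keep)
  if (!is.null(chrom)) {
    onChrom <- dt$CHROM == chrom
    skipped["other_chrom"] <- sum(keep & !onChrom)
    if (!any(onChrom)) {
      warning("no records on requested chromosome '", chrom, "'", call. = FALSE)
    }
    keep <- keep & onChrom
  } else {
    chroms <- unique(dt$CHROM[keep])
    if (length(chroms) > 1L) {
      stop("input spans multiple chromosomes; supply a region", call. = FALSE)
    }
    chrom <- if (length(chroms)) chroms else NA_character_
  }
  idx <- which(keep)
  if (length(idx) && is.unsorted(pos[idx])) {
    stop("TSV records out of position order on ", chrom, call. = FALSE)
  }
  dos <- t(as.matrix(dt[idx, sampleIds, with = FALSE]))
  storage.mode(dos) <- "double"
  bad <- !is.na(dos) & !dos %in% c(0, 1, 2)
  if (any(bad)) {
    stop("TSV dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  new("VariantSet",
    chrom = chrom, pos = pos[idx],
    ref = rep(NA_character_, length(idx)), alt = rep(NA_character_, length(idx)),
    sampleIds = sampleIds, dosage = dos,
    likelihoods = array(numeric(), c(0L, 0L, 0L)), skipped = skipped
  )
}

#' Read biallelic variants from VCF, BEAGLE or TSV input
#'
#' Parses one chromosome's worth of biallelic records into a
#' [VariantSet-class]. Compression (gzip or bgzip) is auto-detected from the
#' leading magic bytes, so plain, gzip and bgzip inputs of identical content
#' yield identical record streams. Multiallelic records, symbolic alleles and
#' records with unparseable positions are skipped and counted, never split.
#' Inputs must be coordinate-sorted; out-of-order records are a fatal error.
#'
#' For VCF, `glField` selects the FORMAT field: `"GT"` yields a hard-call
#' dosage matrix (half calls such as `"./1"` become missing; haploid calls
#' are doubled with a warning), `"GL"`/`"PL"` yield normalized likelihood
#' triplets (see [parseLikelihoodTriplets()]). BEAGLE files (ANGSD dialect:
#' header `marker allele1 allele2` then three columns per sample, marker
#' `chrom_pos`) always carry likelihoods; TSV files (columns `CHROM`, `POS`,
#' then one dosage column per sample) always carry hard calls.
#'
#' @param path input file.
#' @param format `"vcf"`, `"beagle"` or `"tsv"`.
#' @param region chromosome name, optionally with a `start-end` suffix
#'   (`"chr1"` or `"chr1:1-5000000"`); `NULL` accepts a single-chromosome
#'   file as-is.
#' @param glField FORMAT field for VCF input: `"GT"`, `"GL"` or `"PL"`.
#' @return A [VariantSet-class].
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("CHROM\tPOS\ts1\ts2", "chr1\t100\t0\t2", "chr1\t200\t1\tNA"), tsv)
#' readVariants(tsv, format = "tsv", region = "chr1")
#' @export
readVariants <- function(path, format = c("vcf", "beagle", "tsv"),
                         region = NULL, glField = c("GT", "GL", "PL")) {
  format <- match.arg(format)
  glField <- match.arg(glField)
  if (!file.exists(path)) {
    stop("cannot read input file: ", path, call. = FALSE)
  }
  reg <- .parseRegion(region)
  vs <- switch(format,
    vcf = .readVariantsVcf(path, reg$chrom, glField),
    beagle = .readVariantsBeagle(path, reg$chrom),
    tsv = .readVariantsTsv(path, reg$chrom)
  )
  if (!is.null(reg$start)) {
    keep <- vs@pos >= reg$start & vs@pos <= reg$end
    vs <- vs[, keep]
  }
  vs
}

#' @describeIn VariantSet-class subset by variant index (columns).
#' @param x,i,j,...,drop subsetting as for matrices; `i` is unused.
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  if (!missing(i)) stop("subset VariantSet by variant via x[, j]")
  initialize(x,
    pos = x@pos[j], ref = x@ref[j], alt = x@alt[j],
    dosage = if (nrow(x@dosage)) x@dosage[, j, drop = FALSE] else x@dosage,
    likelihoods = if (length(x@likelihoods)) {
      x@likelihoods[, j, , drop = FALSE]
    } else {
      x@likelihoods
    }
  )
})

#' Number of full rolling windows on a span
#'
#' Windows are anchored at position 1 and advance by `stepSize`; only
#' full-length windows (`start + windowSize - 1 <= span`) are emitted, so
#' the count is `floor((span - windowSize)/stepSize) + 1`. A span shorter
#' than one window yields a single truncated window `[1, span]`.
#'
#' @param span last usable position in bp (chromosome length or last
#'   variant position).
#' @param windowSize,stepSize window span and step in bp.
#' @return integer window count.
#' @examples
#' windowCount(248956422, 1e6, 1e5)  # human chr1 at 1 Mbp / 100 kb
#' @export
windowCount <- function(span, windowSize, stepSize) {
  if (span < windowSize) return(1L)
  as.integer(floor((span - windowSize) / stepSize) + 1)
}

#' Enumerate rolling window intervals on a chromosome
#'
#' @inheritParams windowCount
#' @param chrom chromosome name.
#' @param anchor `"position"` (start at bp 1) or `"variant"` (start at
#'   `firstPos`).
#' @param firstPos first variant position, used by the `"variant"` anchor.
#' @return data.frame with columns `chrom`, `start`, `end`, `mid`
#'   (1-based closed intervals, `mid = floor((start+end)/2)`).
#' @export
windowSpecs <- function(chrom, span, windowSize, stepSize,
                        anchor = c("position", "variant"), firstPos = 1) {
  anchor <- match.arg(anchor)
  offset <- if (anchor == "variant") firstPos - 1 else 0
  usable <- span - offset
  if (usable < windowSize) {
    starts <- 1 + offset
    ends <- span
  } else {
    n <- windowCount(usable, windowSize, stepSize)
    starts <- 1 + offset + stepSize * (seq_len(n) - 1)
    ends <- starts + windowSize - 1
  }
  data.frame(
    chrom = chrom, start = starts, end = ends,
    mid = floor((starts + ends) / 2)
  )
}

#' Assign variants to rolling windows
#'
#' Membership is the closed-interval test `start <= pos <= end`; a variant
#' may fall in several overlapping windows. Implemented with
#' [IRanges::findOverlaps()].
#'
#' @param pos variant positions (bp, sorted).
#' @param specs window table from [windowSpecs()].
#' @return list (one element per window) of integer indices into `pos`.
#' @export
windowMembership <- function(pos, specs) {
  if (!length(pos)) {
    return(rep(list(integer()), nrow(specs)))
  }
  hits <- findOverlaps(
    IRanges(start = specs$start, end = specs$end),
    IRanges(start = pos, width = 1L)
  )
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(specs))))
}

#' Read a sample metadata table
#'
#' The first column holds sample ids; any further columns are annotations.
#' Rows are matched to `sampleIds` (the cohort order); metadata rows for
#' unknown samples are dropped with a warning, and cohort samples absent
#' from the table get `NA` annotations.
#'
#' @param path TSV file with a header row.
#' @param sampleIds ordered cohort sample names.
#' @param quantCol optional column name that must be numeric (for
#'   continuous coloring).
#' @return a [S4Vectors::DataFrame] with one row per cohort sample, in
#'   cohort order.
#' @export
readSampleMetadata <- function(path, sampleIds, quantCol = NULL) {
  dt <- data.table::fread(text = .readLinesAuto(path), header = TRUE,
                          sep = "\t", na.strings = "NA")
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(ids, sampleIds)
  if (length(extra)) {
    warning(length(extra), " metadata row(s) not matching any sample dropped",
            call. = FALSE)
  }
  m <- match(sampleIds, ids)
  ann <- dt[m, -1, with = FALSE]
  out <- DataFrame(sample = sampleIds, as.data.frame(ann),
                   row.names = sampleIds)
  if (!is.null(quantCol)) {
    if (!quantCol %in% colnames(out)) {
      stop("metadata has no column '", quantCol, "'; available: ",
           paste(setdiff(colnames(out), "sample"), collapse = ", "),
           call. = FALSE)
    }
    if (!is.numeric(out[[quantCol]])) {
      stop("metadata column '", quantCol, "' is not numeric", call. = FALSE)
    }
  }
  out
}
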