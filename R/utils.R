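# Small internal helpers shared across modules.

#' Detect gzip/bgzip compression from leading magic bytes
#'
#' bgzip is a gzip-compatible blocked variant, so both dialects share the
#' 0x1f 0x8b magic and both are readable through [base::gzfile()].
#'
#' @param path file path.
#' @return `TRUE` if the file starts with the gzip magic bytes.
#' @keywords internal
.isGzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Text connection that transparently decompresses gzip/bgzip input.
.openText <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read input file: ", path, call. = FALSE)
  }
  if (.isGzip(path)) gzfile(path, "rt") else file(path, "rt")
}

.readLinesAuto <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  readLines(con)
}

# Numeric formatting used by all track writers: 6 significant digits, NA -> "NA".
.fmtNum <- function(x) {
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  out[is.na(x)] <- "NA"
  out
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Parse a region string "chr1" or "chr1:100-200" into chrom/start/end.
.parseRegion <- function(region) {
  if (is.null(region) || !nzchar(region)) {
    return(list(chrom = NULL, start = NULL, end = NULL))
  }
  if (grepl(":", region, fixed = TRUE)) {
    chrom <- sub(":.*$", "", region)
    span <- sub("^[^:]*:", "", region)
    parts <- strsplit(span, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.numeric(parts)))) {
      stop("malformed region string: ", region, call. = FALSE)
    }
    list(chrom = chrom, start = as.numeric(parts[1]), end = as.numeric(parts[2]))
  } else {
    list(chrom = region, start = NULL, end = NULL)
  }
}
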