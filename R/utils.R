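## internal helpers shared across modules

#' @importFrom methods new validObject is setValidity slot
#' @importFrom stats quantile mad median rnorm runif rbinom
#' @importFrom utils head read.table write.table
NULL

## round half up (base round() is banker's rounding; 88.25 must report 88.3)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## derive a child RNG seed from a master seed; keeps results < 2^31
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

## parse "chr21:14300000-46700000" (0-based, half-open) into a GRanges row
parseInterval <- function(x) {
  if (is(x, "GRanges")) {
    if (length(x) != 1L) stop("interval must be a single range")
    return(x)
  }
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L)
    stop("cannot parse interval '", x, "'; expected chrom:start-end")
  start0 <- as.numeric(m[3]); end0 <- as.numeric(m[4])
  if (start0 >= end0) stop("interval start must be < end: '", x, "'")
  GenomicRanges::GRanges(m[2], IRanges::IRanges(start0 + 1, end0))
}

## hard error when two range sets share no chromosome names at all
## (a naming-style mismatch such as "21" vs "chr21" must never read as
## silent non-overlap)
checkChromCompat <- function(a, b, whatA, whatB) {
  ca <- unique(as.character(GenomicRanges::seqnames(a)))
  cb <- unique(as.character(GenomicRanges::seqnames(b)))
  if (length(ca) && length(cb) && !length(intersect(ca, cb)))
    stop("chromosome names in ", whatA, " (e.g. '", ca[1],
         "') share nothing with ", whatB, " (e.g. '", cb[1],
         "'); naming styles must match")
  invisible(TRUE)
}

## comma-join for report columns; deterministic order assumed by caller
joinSymbols <- function(x) paste(x, collapse = ",")

stopIfNot01 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single value in [0, 1]")
  invisible(TRUE)
}
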