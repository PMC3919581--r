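#' @import methods
#' @importFrom stats p.adjust phyper pbinom quantile setNames
#' @importFrom utils read.delim write.table
NULL

#' Deterministic child seed from a master seed and string labels
#'
#' Derives a reproducible 31-bit seed from a master seed plus identifying
#' labels (e.g. refseq and site ids), so per-site random draws are independent
#' of iteration order.
#'
#' @param seed master integer seed.
#' @param ... character or numeric labels mixed into the hash.
#' @return a positive integer seed below 2^31.
#' @export
deriveSeed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h) + 1L
}

# classed error helper
sbStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "siteburden_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Parse an aligned pair of equal-length gapped strings into a column table
# with 1-based ungapped coordinates (NA at gaps).
alignmentColumns <- function(refAln, chainAln) {
  r <- strsplit(refAln, "")[[1]]
  s <- strsplit(chainAln, "")[[1]]
  if (length(r) != length(s)) {
    sbStop("siteburden_format_error",
           "aligned sequences have different lengths (%d vs %d)",
           length(r), length(s))
  }
  refPos <- ifelse(r == "-", NA_integer_, cumsum(r != "-"))
  chainPos <- ifelse(s == "-", NA_integer_, cumsum(s != "-"))
  data.frame(refPos = as.integer(refPos), chainPos = as.integer(chainPos),
             refAA = r, chainAA = s, stringsAsFactors = FALSE)
}

# Identity over aligned (both non-gap) columns; coverage of the chain =
# fraction of chain residues sitting in an aligned column.
alignmentStats <- function(cols) {
  aligned <- !is.na(cols$refPos) & !is.na(cols$chainPos)
  nChain <- sum(!is.na(cols$chainPos))
  ident <- if (any(aligned)) {
    sum(cols$refAA[aligned] == cols$chainAA[aligned]) / sum(aligned)
  } else 0
  cov <- if (nChain > 0) sum(aligned) / nChain else 0
  list(identity = ident, coverage = cov, nAligned = sum(aligned))
}

# minimal euclidean pairwise minimum distance between two coordinate matrices
minPairDist <- function(a, b) {
  stopifnot(ncol(a) == 3, ncol(b) == 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}
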