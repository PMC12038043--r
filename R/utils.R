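#' @keywords internal
"_PACKAGE"

## NULL-coalescing helper used throughout.
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Package logging
#'
#' Messages are routed through a single gate so stages stay quiet under
#' `options(flcpipe.verbose = FALSE)`. Log text never lands in stage output
#' files, which keeps re-runs byte-identical.
#'
#' @param ... passed to [sprintf()].
#' @return `invisible(NULL)`.
#' @keywords internal
flc_log <- function(...) {
  if (isTRUE(getOption("flcpipe.verbose", TRUE))) {
    message("[flcpipe] ", sprintf(...))
  }
  invisible(NULL)
}

#' Truncated percentage
#'
#' Percentage of `num` out of `den`, truncated (not rounded) to a fixed
#' number of decimals. Truncation is used because the study's printed
#' numerator/denominator pairs (e.g. 328/684 -> 47.9) are consistent with
#' truncation but not with round-half-up.
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimals kept after truncation (default 1).
#' @return numeric percentage; `NA` when `den` is 0.
#' @export
#' @examples
#' percent_trunc(169, 386) # 43.7
#' percent_trunc(328, 684) # 47.9 (rounding would give 48.0)
percent_trunc <- function(num, den, digits = 1) {
  stopifnot(length(num) == length(den))
  out <- ifelse(den == 0, NA_real_,
                floor(100 * num / den * 10^digits + 1e-9) / 10^digits)
  out
}

#' Largest-remainder apportionment
#'
#' Split an integer total `n` across categories proportionally to `weights`
#' so the parts are exact integers summing to `n`. Used to turn the designed
#' genomic-context mix into exact placement counts.
#'
#' @param weights nonnegative weights (normalized internally).
#' @param n total count to apportion.
#' @return integer vector, same length as `weights`, summing to `n`.
#' @export
largest_remainder <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0, n >= 0)
  quota <- weights / sum(weights) * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    ## deterministic tie-break: larger remainder first, then earlier index
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

## Tiny FNV-1a hash of a character scalar; used to stamp a config digest
## into run logs without adding a digest dependency.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261 %% 2147483648
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

## Deterministic TSV writers/readers: all stage outputs share one dialect.
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
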