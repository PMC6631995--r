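#' @importFrom stats phyper rbinom rnbinom rbeta runif setNames quantile
#'   median wilcox.test fisher.test ks.test glm binomial coef plogis predict
#' @importFrom utils head tail
NULL

# let data.table's [ dispatch work from inside this package
.datatable.aware <- TRUE

#' Derive an independent sub-seed from a master seed
#'
#' Every stochastic operation in the package takes an explicit seed. Sub-seeds
#' for the individual synthetic-world artifacts are derived from the master
#' seed with a fixed affine splitting rule so that adding one artifact never
#' perturbs the random stream of another. The result always fits in a 32-bit
#' integer.
#'
#' @param seed master seed (single integer).
#' @param index non-negative integer index of the consumer stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(length(seed) == 1L, length(index) == 1L, !is.na(seed), !is.na(index))
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919 + 12345) %% 2147483647)
}

# reverse complement preserving case; N/n map to themselves
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtNn", "TGCAtgcaNn", x))
}

# positions are 0-based half-open throughout; substring is 1-based
seq_window <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# overlap test of [start,end) against interval table (same chrom assumed)
any_overlap <- function(start, end, starts, ends) {
  if (length(starts) == 0L) return(FALSE)
  any(start < ends & end > starts)
}

# upper-tail hypergeometric P(X >= q) with q observed successes among `draws`
# draws, `succ` successes in a universe of size `total`
hyper_upper <- function(q, succ, total, draws) {
  stats::phyper(q - 1, succ, total - succ, draws, lower.tail = FALSE)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
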