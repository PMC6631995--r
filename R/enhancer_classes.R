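# Per-enhancer deMP density and the fragile / regular / stable partition:
# deMP-containing enhancers are ranked by density and the top, middle and
# bottom 20% are labeled fragile, regular and stable.

#' deMP density of enhancers
#'
#' Count of deMP positions inside each enhancer divided by total enhancer
#' length (repeat-masked bases included in the denominator).
#'
#' @param enhancers interval `data.frame` with ids.
#' @param demps `data.frame` with chrom, pos of deMP positions.
#' @return `enhancers` with added `demp_count` and `density` columns.
#' @export
demp_density <- function(enhancers, demps) {
  if (any(enhancers$end - enhancers$start <= 0L))
    stop_fmt("zero-length enhancer")
  cnt <- integer(nrow(enhancers))
  for (i in seq_len(nrow(enhancers))) {
    d <- demps[demps$chrom == enhancers$chrom[i], , drop = FALSE]
    cnt[i] <- sum(d$pos >= enhancers$start[i] & d$pos < enhancers$end[i])
  }
  out <- enhancers
  out$demp_count <- cnt
  out$density <- cnt / (enhancers$end - enhancers$start)
  out
}

#' Partition deMP-containing enhancers into fragile / regular / stable
#'
#' Enhancers with at least one deMP are sorted by density (descending, ties
#' broken by id); the top `floor(0.2 n)` are fragile, the bottom
#' `floor(0.2 n)` stable, and the `floor(0.2 n)` starting at offset
#' `floor(0.4 n)` regular. Everything else (including deMP-free enhancers)
#' is unclassified.
#'
#' @param enhancers output of [demp_density()].
#' @return `enhancers` with a `class` column in
#'   `{fragile, regular, stable, unclassified}`.
#' @export
partition_quintiles <- function(enhancers) {
  out <- enhancers
  out$class <- "unclassified"
  with_demp <- which(out$demp_count >= 1L)
  n <- length(with_demp)
  if (n < 5L) stop_fmt("need at least 5 deMP-containing enhancers, have %d", n)
  ord <- with_demp[order(-out$density[with_demp], out$id[with_demp])]
  m <- floor(0.2 * n)
  out$class[ord[seq_len(m)]] <- "fragile"
  out$class[ord[floor(0.4 * n) + seq_len(m)]] <- "regular"
  out$class[ord[n - m + seq_len(m)]] <- "stable"
  out
}

#' Per-class summary statistics
#'
#' @param enhancers output of [partition_quintiles()].
#' @return `data.frame` with one row per class (fragile, regular, stable):
#'   n, mean/median density, mean length.
#' @export
class_summary <- function(enhancers) {
  cls <- c("fragile", "regular", "stable")
  do.call(rbind, lapply(cls, function(cl) {
    e <- enhancers[enhancers$class == cl, , drop = FALSE]
    data.frame(class = cl, n = nrow(e),
               mean_density = mean(e$density),
               median_density = stats::median(e$density),
               mean_length = mean(e$end - e$start),
               stringsAsFactors = FALSE)
  }))
}
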