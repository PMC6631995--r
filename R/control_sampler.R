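# GC/repeat/length-matched control extraction. For each enhancer, candidate
# windows of identical length are drawn uniformly from the genome and
# accepted when |dGC| <= max_dgc, |drepeat| <= max_drepeat, the window is
# N-free and does not overlap any exclusion interval or a previously
# accepted control. Any deficit after max_tries draws is filled by
# mononucleotide shuffles of the enhancer itself, flagged "shuffled".

# per-chromosome cumulative base statistics for O(1) window GC/repeat
.genome_cumstats <- function(genome) {
  lapply(unclass(genome), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    list(
      gc = cumsum(ch %in% c("G", "g", "C", "c")),
      acgt = cumsum(!ch %in% c("N", "n")),
      lower = cumsum(ch %in% c("a", "c", "g", "t", "n")),
      n = cumsum(ch %in% c("N", "n"))
    )
  })
}

.window_stats <- function(cs, start, end) {
  # 0-based half-open; cumulative vectors are 1-based
  at <- function(v, i) ifelse(i == 0L, 0L, v[i])
  len <- end - start
  gc_n <- at(cs$gc, end) - at(cs$gc, start)
  acgt <- at(cs$acgt, end) - at(cs$acgt, start)
  lower <- at(cs$lower, end) - at(cs$lower, start)
  nn <- at(cs$n, end) - at(cs$n, start)
  list(gc = ifelse(acgt == 0L, NA_real_, gc_n / acgt),
       repeat_frac = lower / len, n_count = nn)
}

#' Uniform mononucleotide shuffle of a sequence
#'
#' Letters are permuted uniformly at random with case travelling with its
#' letter, so the shuffle preserves GC content, repeat content and length
#' exactly.
#'
#' @param seq nucleotide string.
#' @param seed integer seed.
#' @return shuffled string.
#' @export
shuffle_fallback <- function(seq, seed) {
  stopifnot(nchar(seq) > 0L)
  set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(ch[sample.int(length(ch))], collapse = "")
}

#' Sample matched control sequences for one enhancer
#'
#' Implements whole-genome sampling of controls with the same length as the
#' enhancer and GC/repeat content within `max_dgc` / `max_drepeat`
#' (defaults 0.005 and 0.01). Controls may not overlap `exclusions` (pass
#' all enhancers) nor each other; windows containing `N` are rejected. When
#' fewer than `n` matched windows are found within `max_tries` draws, the
#' deficit is filled by [shuffle_fallback()] and flagged.
#'
#' @param enhancer one-row interval `data.frame` (must carry `id`).
#' @param genome a [genome()].
#' @param n number of controls (default 5).
#' @param max_dgc,max_drepeat matching tolerances.
#' @param exclusions interval `data.frame` controls must avoid.
#' @param seed integer seed.
#' @param max_tries draw budget per needed control.
#' @param cumstats optional precomputed `.genome_cumstats(genome)` (shared
#'   across calls for speed).
#' @return `data.frame` with columns id (enhancer id), origin
#'   (`sampled`/`shuffled`), chrom, start, end (NA for shuffled), seq,
#'   dgc, drepeat.
#' @export
sample_matched_controls <- function(enhancer, genome, n = 5L,
                                    max_dgc = 0.005, max_drepeat = 0.01,
                                    exclusions = NULL, seed = 1L,
                                    max_tries = 10000L, cumstats = NULL) {
  stopifnot(nrow(enhancer) == 1L)
  if (is.null(cumstats)) cumstats <- .genome_cumstats(genome)
  len <- enhancer$end - enhancer$start
  chrom_len <- setNames(nchar(genome), names(genome))
  if (all(chrom_len < len)) stop_fmt("genome shorter than enhancer (%d bp)", len)
  eseq <- extract_seq(genome, enhancer$chrom, enhancer$start, enhancer$end)
  est <- seq_stats(eseq)
  excl <- exclusions
  set.seed(seed)
  found <- list()
  budget <- max_tries * n
  tries <- 0L
  eligible <- names(genome)[chrom_len >= len]
  # draw chromosomes proportional to valid start count
  wts <- chrom_len[eligible] - len + 1
  while (length(found) < n && tries < budget) {
    m <- min(512L, budget - tries)
    tries <- tries + m
    chs <- sample(eligible, m, replace = TRUE, prob = wts)
    sts <- floor(runif(m) * (chrom_len[chs] - len + 1))
    for (i in seq_len(m)) {
      if (length(found) >= n) break
      ch <- chs[i]; st <- as.integer(sts[i]); en <- st + len
      ws <- .window_stats(cumstats[[ch]], st, en)
      if (ws$n_count > 0L || is.na(ws$gc)) next
      if (abs(ws$gc - est$gc) > max_dgc) next
      if (abs(ws$repeat_frac - est$repeat_frac) > max_drepeat) next
      if (!is.null(excl)) {
        ee <- excl[excl$chrom == ch, , drop = FALSE]
        if (any_overlap(st, en, ee$start, ee$end)) next
      }
      found[[length(found) + 1L]] <- data.frame(
        id = enhancer$id, origin = "sampled", chrom = ch, start = st,
        end = en, seq = extract_seq(genome, ch, st, en),
        dgc = abs(ws$gc - est$gc), drepeat = abs(ws$repeat_frac - est$repeat_frac),
        stringsAsFactors = FALSE)
      # later candidates may not overlap this control
      excl <- rbind(
        if (is.null(excl)) NULL else excl[, c("chrom", "start", "end")],
        data.frame(chrom = ch, start = st, end = en))
    }
  }
  n_missing <- n - length(found)
  if (n_missing > 0L) {
    for (j in seq_len(n_missing)) {
      found[[length(found) + 1L]] <- data.frame(
        id = enhancer$id, origin = "shuffled", chrom = NA_character_,
        start = NA_integer_, end = NA_integer_,
        seq = shuffle_fallback(eseq, derive_seed(seed, j)),
        dgc = 0, drepeat = 0, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, found)
  rownames(out) <- NULL
  out
}

#' Sample matched controls for a whole enhancer set
#'
#' Applies [sample_matched_controls()] to every enhancer with all enhancers
#' (and previously accepted controls) as exclusions.
#'
#' @param enhancers interval `data.frame` with ids.
#' @param genome a [genome()].
#' @inheritParams sample_matched_controls
#' @return combined control `data.frame` (one block of `n` rows per
#'   enhancer).
#' @export
sample_control_set <- function(enhancers, genome, n = 5L, max_dgc = 0.005,
                               max_drepeat = 0.01, seed = 1L,
                               max_tries = 10000L) {
  cumstats <- .genome_cumstats(genome)
  excl <- enhancers[, c("chrom", "start", "end")]
  out <- vector("list", nrow(enhancers))
  for (i in seq_len(nrow(enhancers))) {
    ctl <- sample_matched_controls(
      enhancers[i, , drop = FALSE], genome, n = n, max_dgc = max_dgc,
      max_drepeat = max_drepeat, exclusions = excl,
      seed = derive_seed(seed, i), max_tries = max_tries, cumstats = cumstats)
    out[[i]] <- ctl
    smp <- ctl[ctl$origin == "sampled", c("chrom", "start", "end")]
    if (nrow(smp)) excl <- rbind(excl, smp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Control sequences grouped by enhancer id
#'
#' @param controls output of [sample_control_set()].
#' @return named list id -> character vector of control sequences.
#' @export
control_seq_list <- function(controls) {
  split(controls$seq, controls$id)[unique(controls$id)]
}
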