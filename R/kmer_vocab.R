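# Canonical k-mer vocabularies: per signal track (and pooled), k-mers are
# partitioned into top / background / neutral by a one-sided Fisher
# enrichment test of enhancer vs matched-control occurrences. Top k-mers
# carry a log2 density-ratio weight; background and neutral k-mers weigh 0.

#' Canonical form of k-mers
#'
#' The canonical representative of a k-mer is the lexicographically smaller
#' of the k-mer and its reverse complement, so one count represents both
#' strands. Input must be uppercase `A/C/G/T`.
#'
#' @param kmers character vector of k-mers.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmers) {
  if (length(kmers) == 0L) return(character())
  bad <- stringi::stri_detect_regex(kmers, "[^ACGT]")
  if (any(bad)) stop_fmt("non-ACGT character in k-mer '%s'", kmers[bad][1])
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", kmers))
  out <- rc
  sel <- kmers <= rc
  out[sel] <- kmers[sel]
  out
}

#' Number of distinct canonical k-mers
#'
#' The number of equivalence classes of k-mers under reverse complementation:
#' `(4^k + 4^(k/2)) / 2` for even k (palindromes are their own class),
#' `4^k / 2` for odd k. For k = 8 this is 32,896.
#'
#' @param k word length.
#' @return integer count of canonical k-mers.
#' @export
count_distinct_canonical <- function(k) {
  stopifnot(k >= 1)
  if (k %% 2 == 0) (4^k + 4^(k / 2)) / 2 else 4^k / 2
}

#' Count canonical k-mer occurrences in a set of sequences
#'
#' Every length-k window is counted once under its canonical key. Windows
#' containing `N` or lowercase (repeat-masked) bases are skipped. Overlapping
#' windows are all counted.
#'
#' @param seqs character vector of sequences.
#' @param k word length.
#' @return named integer vector of counts, with attribute `total_windows` =
#'   total number of counted (unmasked) windows.
#' @export
kmer_occurrences <- function(seqs, k) {
  acc <- vector("list", length(seqs))
  for (j in seq_along(seqs)) {
    s <- seqs[[j]]
    if (nchar(s) < k) next
    # split on masked bases; count within clean stretches only
    clean <- stringi::stri_split_regex(s, "[^ACGT]+")[[1]]
    clean <- clean[nchar(clean) >= k]
    if (!length(clean)) next
    acc[[j]] <- unlist(lapply(clean, function(cs) {
      n <- nchar(cs)
      substring(cs, 1:(n - k + 1L), k:n)
    }), use.names = FALSE)
  }
  words <- unlist(acc, use.names = FALSE)
  if (!length(words)) {
    out <- integer(0)
    attr(out, "total_windows") <- 0L
    return(out)
  }
  can <- canonical_kmer(words)
  dt <- data.table::data.table(kmer = can)[, .N, by = "kmer"]
  out <- dt$N
  names(out) <- dt$kmer
  attr(out, "total_windows") <- length(words)
  out
}

#' Classify canonical k-mers into top / background / neutral
#'
#' For each canonical k-mer a one-sided Fisher exact test (enrichment
#' direction) is applied to the 2x2 table (this k-mer vs all other k-mer
#' occurrences) x (enhancers vs controls). A k-mer is `top` when its
#' Bonferroni-corrected p-value is at most `alpha` *and* its enhancer window
#' density exceeds its control density; `background` when the raw p-value is
#' strictly greater than `alpha`; `neutral` otherwise. The Bonferroni factor
#' is the size of the canonical universe ([count_distinct_canonical()]).
#' K-mers unobserved in both sets are background (p = 1) and are kept
#' implicit.
#'
#' Top k-mers receive weight `log2((d_e + eps_e) / (d_c + eps_c))` where
#' `d` are window densities (count / total windows) and each `eps` is one
#' pseudo-count over that set's total windows; other classes weigh 0.
#'
#' @param enh_counts,ctrl_counts outputs of [kmer_occurrences()] over the same
#'   canonical universe.
#' @param k word length.
#' @param alpha significance threshold (default 1e-3).
#' @param track label stored on the vocabulary (default `"pooled"`).
#' @return an object of class `"kmer_vocab"`: a list with `k`, `track`,
#'   `alpha`, `universe`, totals, and a `table` data.frame over the observed
#'   k-mers (kmer, enh_count, ctrl_count, p_raw, class, weight).
#' @export
classify_kmers <- function(enh_counts, ctrl_counts, k, alpha = 1e-3,
                           track = "pooled") {
  n_enh <- attr(enh_counts, "total_windows") %||% sum(enh_counts)
  n_ctrl <- attr(ctrl_counts, "total_windows") %||% sum(ctrl_counts)
  if (n_enh == 0L || n_ctrl == 0L)
    stop_fmt("empty k-mer universe (no countable windows)")
  kmers <- union(names(enh_counts), names(ctrl_counts))
  a <- ifelse(is.na(match(kmers, names(enh_counts))), 0L,
              enh_counts[match(kmers, names(enh_counts))])
  b <- ifelse(is.na(match(kmers, names(ctrl_counts))), 0L,
              ctrl_counts[match(kmers, names(ctrl_counts))])
  a <- as.integer(a); b <- as.integer(b)
  # one-sided Fisher exact p (enrichment in enhancers) == hypergeometric tail
  p_raw <- stats::phyper(a - 1, a + b, (n_enh - a) + (n_ctrl - b), n_enh,
                         lower.tail = FALSE)
  universe <- count_distinct_canonical(k)
  p_bonf <- pmin(1, p_raw * universe)
  d_e <- a / n_enh
  d_c <- b / n_ctrl
  cls <- ifelse(p_bonf <= alpha & d_e > d_c, "top",
                ifelse(p_raw > alpha, "background", "neutral"))
  w <- ifelse(cls == "top",
              log2((d_e + 1 / n_enh) / (d_c + 1 / n_ctrl)), 0)
  tab <- data.frame(kmer = kmers, enh_count = a, ctrl_count = b,
                    p_raw = p_raw, class = cls, weight = w,
                    stringsAsFactors = FALSE)
  is_top <- cls == "top"
  structure(list(k = as.integer(k), track = track, alpha = alpha,
                 universe = universe, n_enh_windows = n_enh,
                 n_ctrl_windows = n_ctrl, table = tab,
                 # compact lookup sets: weight is 0 outside `top`, class is
                 # background outside these two sets
                 top_kmers = kmers[is_top], top_weights = w[is_top],
                 neutral_kmers = kmers[cls == "neutral"]),
            class = "kmer_vocab")
}

#' Class of a k-mer under a vocabulary
#'
#' @param vocab a `"kmer_vocab"`.
#' @param kmers character vector (canonicalized internally).
#' @return character vector in `{"top","background","neutral"}`; k-mers not
#'   observed in either sequence set are background.
#' @export
kmer_class <- function(vocab, kmers) {
  can <- canonical_kmer(toupper(kmers))
  out <- rep("background", length(can))
  out[can %in% vocab$neutral_kmers] <- "neutral"
  out[can %in% vocab$top_kmers] <- "top"
  out
}

#' Enrichment weight of a k-mer under a vocabulary
#'
#' @param vocab a `"kmer_vocab"`.
#' @param kmers character vector (canonicalized internally).
#' @return numeric weights; 0 for background and neutral k-mers.
#' @export
kmer_weight <- function(vocab, kmers) {
  can <- canonical_kmer(toupper(kmers))
  i <- match(can, vocab$top_kmers)
  out <- vocab$top_weights[i]
  out[is.na(i)] <- 0
  out
}

#' Class sizes of a vocabulary over the full canonical universe
#'
#' @param vocab a `"kmer_vocab"`.
#' @return named integer vector with `top`, `background`, `neutral` counts
#'   summing to the canonical universe size.
#' @export
vocab_class_sizes <- function(vocab) {
  obs <- table(factor(vocab$table$class,
                      levels = c("top", "background", "neutral")))
  out <- as.integer(obs)
  names(out) <- names(obs)
  out["background"] <- out["background"] +
    as.integer(vocab$universe - nrow(vocab$table))
  out
}

#' Derive peak intervals from a signal track
#'
#' Peaks are the track bins whose value is at or above the given quantile of
#' all bin values, merged when adjacent.
#'
#' @param track a [signal_track()].
#' @param quantile quantile of bin values defining a peak bin (default 0.99).
#' @return interval `data.frame`.
#' @export
peaks_from_track <- function(track, quantile = 0.99) {
  thr <- stats::quantile(track$bins$value, quantile, names = FALSE)
  hot <- track$bins[track$bins$value >= thr, , drop = FALSE]
  if (!nrow(hot)) return(gintervals(character(), integer(), integer())[0, ])
  hot <- hot[order(hot$chrom, hot$start), ]
  keep <- !(c(FALSE, hot$chrom[-1] == hot$chrom[-nrow(hot)] &
                hot$start[-1] <= hot$end[-nrow(hot)]))
  grp <- cumsum(keep)
  gintervals(hot$chrom[keep], hot$start[keep],
             as.integer(tapply(hot$end, grp, max)))
}

#' Build the per-track and pooled k-mer vocabularies
#'
#' For each signal track, a vocabulary is built from the enhancers that
#' overlap that track's peaks (bins above `peak_quantile`), tested against
#' those enhancers' matched controls; a pooled vocabulary uses all enhancers.
#' One vocabulary is built per `(k, track)` pair.
#'
#' @param enh_seqs named character vector of enhancer sequences (names = ids).
#' @param ctrl_seqs list mapping enhancer id -> character vector of control
#'   sequences.
#' @param enhancers interval `data.frame` (ids matching `enh_seqs`).
#' @param tracks list of [signal_track()] objects.
#' @param k_sizes integer vector of word lengths.
#' @param alpha significance threshold.
#' @param peak_quantile quantile defining track peaks.
#' @return nested list `vocabs[[track]][[as.character(k)]]`; track names are
#'   the track names plus `"pooled"`.
#' @export
build_vocabularies <- function(enh_seqs, ctrl_seqs, enhancers, tracks,
                               k_sizes = c(4L, 6L, 8L, 10L, 12L),
                               alpha = 1e-3, peak_quantile = 0.99) {
  stopifnot(!is.null(names(enh_seqs)))
  subset_ids <- list(pooled = names(enh_seqs))
  for (tr in tracks) {
    pk <- peaks_from_track(tr, peak_quantile)
    sel <- vapply(seq_len(nrow(enhancers)), function(i) {
      p <- pk[pk$chrom == enhancers$chrom[i], , drop = FALSE]
      any_overlap(enhancers$start[i], enhancers$end[i], p$start, p$end)
    }, logical(1))
    subset_ids[[tr$name]] <- enhancers$id[sel]
  }
  out <- list()
  for (tname in names(subset_ids)) {
    ids <- intersect(subset_ids[[tname]], names(enh_seqs))
    if (!length(ids))
      stop_fmt("track '%s': no peak-overlapping enhancers", tname)
    es <- enh_seqs[ids]
    cs <- unlist(ctrl_seqs[ids], use.names = FALSE)
    out[[tname]] <- list()
    for (k in k_sizes) {
      out[[tname]][[as.character(k)]] <- classify_kmers(
        kmer_occurrences(es, k), kmer_occurrences(cs, k), k = k,
        alpha = alpha, track = tname)
    }
  }
  out
}

#' Write vocabularies to a TSV
#'
#' Columns: kmer, k, track, enh_count, ctrl_count, p_raw, class, weight.
#'
#' @param vocabs nested list from [build_vocabularies()].
#' @param path output path.
#' @export
write_vocab_tsv <- function(vocabs, path) {
  rows <- list()
  for (tname in names(vocabs)) for (kk in names(vocabs[[tname]])) {
    v <- vocabs[[tname]][[kk]]
    tab <- v$table
    tab$k <- v$k
    tab$track <- v$track
    rows[[length(rows) + 1L]] <-
      tab[, c("kmer", "k", "track", "enh_count", "ctrl_count", "p_raw",
              "class", "weight")]
  }
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}
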