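# PSSM scanning with false-positive-density calibration, binding-site
# enrichment (length-normalized density ratio), per-site deMP fragility,
# homotypic/heterotypic cluster typing and deMP position profiles.

#' Build a log-odds PSSM from a probability matrix
#'
#' @param tf factor name.
#' @param probs width x 4 matrix of base probabilities, columns A, C, G, T.
#' @param background background base probabilities (default uniform).
#' @return object of class `"pssm"` with fields tf, mat (log2-odds),
#'   width, and `threshold` (NA until calibrated).
#' @export
pssm <- function(tf, probs, background = rep(0.25, 4)) {
  stopifnot(ncol(probs) == 4L, nrow(probs) >= 4L,
            all(abs(rowSums(probs) - 1) < 1e-6))
  mat <- log2(sweep(probs, 2, background, "/"))
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(tf = tf, mat = mat, width = nrow(mat),
                 threshold = NA_real_), class = "pssm")
}

#' PSSM from a consensus string with designated second-best bases
#'
#' Each position gives probability `p_major` to the consensus base,
#' `p_second` to the designated second-best base, and splits the remainder
#' over the other two. A fixed cyclic information gradient
#' (`column_jitter`) varies `p_major` across positions so that the score
#' distribution has realistic, fine-grained levels — with identical columns
#' every single-mismatch word would tie, making false-positive-rate
#' calibration needlessly coarse.
#'
#' @param tf factor name.
#' @param consensus,second equal-length base strings.
#' @param p_major,p_second probabilities (defaults 0.85 / 0.09).
#' @param column_jitter half-range of the cyclic per-position modulation of
#'   `p_major` (default 0.03; `p_major + column_jitter + p_second` must stay
#'   below 1).
#' @return a [pssm()].
#' @export
pssm_from_consensus <- function(tf, consensus, second = NULL,
                                p_major = 0.85, p_second = 0.09,
                                column_jitter = 0.03) {
  w <- nchar(consensus)
  cb <- strsplit(toupper(consensus), "")[[1]]
  sb <- if (is.null(second)) NULL else strsplit(toupper(second), "")[[1]]
  bases <- c("A", "C", "G", "T")
  jit <- rep_len(c(-1, -0.5, 0, 0.5, 1) * column_jitter, w)
  probs <- matrix(0, nrow = w, ncol = 4, dimnames = list(NULL, bases))
  for (i in seq_len(w)) {
    s <- if (is.null(sb)) setdiff(bases, cb[i])[1] else sb[i]
    if (s == cb[i]) stop_fmt("second-best base equals consensus at position %d", i)
    pm <- p_major + jit[i]
    probs[i, ] <- (1 - pm - p_second) / 2
    probs[i, cb[i]] <- pm
    probs[i, s] <- p_second
  }
  pssm(tf, probs)
}

#' Read PSSMs from a TSV (tf, position, A, C, G, T)
#'
#' Values are base probabilities per position.
#'
#' @param path TSV path.
#' @return named list of [pssm()] objects.
#' @export
read_pssm_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  out <- list()
  for (tf in unique(df$tf)) {
    d <- df[df$tf == tf, , drop = FALSE]
    d <- d[order(d$position), ]
    out[[tf]] <- pssm(tf, as.matrix(d[, c("A", "C", "G", "T")]))
  }
  out
}

#' Write PSSMs to TSV
#'
#' Probabilities are recovered from the stored log2-odds against uniform.
#'
#' @param pssms list of [pssm()] objects.
#' @param path output path.
#' @export
write_pssm_tsv <- function(pssms, path) {
  rows <- lapply(pssms, function(p) {
    probs <- 2^p$mat * 0.25
    data.frame(tf = p$tf, position = seq_len(p$width), probs,
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

# raw window scores on the plus strand of seq (NA over masked windows)
.pssm_scores <- function(seq, p) {
  L <- nchar(seq)
  w <- p$width
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(ch, c("A", "C", "G", "T"))   # lowercase/N -> NA
  sc <- numeric(n)
  for (j in seq_len(w)) {
    b <- code[j:(j + n - 1L)]
    sc <- sc + p$mat[j, ][b]                  # NA propagates masked windows
  }
  sc
}

#' Calibrate a PSSM score threshold to a target false-positive density
#'
#' The threshold is the smallest score whose hit density over the supplied
#' background sequence, counting both strands, is at most `target_rate`
#' hits per `per_bp` bases.
#'
#' @param p a [pssm()].
#' @param background_seq background sequence (>= 100 kb recommended).
#' @param target_rate allowed hits per `per_bp` (default 5).
#' @param per_bp denominator in bp (default 10000, i.e. 5 per 10 kb).
#' @return the [pssm()] with `threshold` set.
#' @export
calibrate_pssm_threshold <- function(p, background_seq, target_rate = 5,
                                     per_bp = 10000) {
  L <- nchar(background_seq)
  if (L < 100000) warn_fmt("background of %d bp is short for calibration", L)
  sc <- c(.pssm_scores(background_seq, p),
          .pssm_scores(revcomp(background_seq), p))
  sc <- sc[!is.na(sc)]
  if (!length(sc)) stop_fmt("no scorable background windows")
  if (max(sc) - min(sc) < 1e-9)
    stop_fmt("degenerate PSSM: every window scores identically")
  allowed <- floor(L / per_bp * target_rate)
  s <- sort(sc)
  n <- length(s)
  u <- unique(s)
  cnt_ge <- n - match(u, s) + 1
  ok <- which(cnt_ge <= allowed)
  p$threshold <- if (length(ok)) u[min(ok)] else u[length(u)] + 1e-9
  p
}

#' Scan a sequence with a calibrated PSSM
#'
#' Both strands are scored at every position; windows containing N or
#' repeat-masked (lowercase) bases are skipped. Hits with score at or above
#' the threshold are returned; overlapping same-factor hits are not merged.
#'
#' @param seq sequence to scan.
#' @param p a calibrated [pssm()].
#' @param offset genomic start of `seq` (0-based) added to hit coordinates.
#' @param chrom chromosome for the hit records.
#' @return `data.frame` tf, chrom, start, end, strand, score.
#' @export
scan_pssm <- function(seq, p, offset = 0L, chrom = "chr1") {
  if (is.na(p$threshold)) stop_fmt("PSSM '%s' is not calibrated", p$tf)
  fwd <- .pssm_scores(seq, p)
  rc <- .pssm_scores(revcomp(seq), p)
  L <- nchar(seq)
  w <- p$width
  n <- L - w + 1L
  hits <- list()
  if (n >= 1L) {
    i <- which(!is.na(fwd) & fwd >= p$threshold)
    if (length(i))
      hits$f <- data.frame(tf = p$tf, chrom = chrom,
                           start = offset + i - 1L, end = offset + i - 1L + w,
                           strand = "+", score = fwd[i],
                           stringsAsFactors = FALSE)
    # window j (1-based) on the reverse strand maps to plus-strand start
    # L - w - j + 1 (0-based)
    j <- which(!is.na(rc) & rc >= p$threshold)
    if (length(j))
      hits$r <- data.frame(tf = p$tf, chrom = chrom,
                           start = offset + (L - w - j + 1L),
                           end = offset + (L - j + 1L),
                           strand = "-", score = rc[j],
                           stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(tf = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binding-site enrichment of an enhancer set against controls
#'
#' The hit density per non-repetitive base in the enhancer set divided by
#' the density in the control set. When the control count is zero a 0.5
#' continuity guard replaces it so the ratio stays finite.
#'
#' @param count_enh,count_ctrl hit counts.
#' @param nonrep_len_enh,nonrep_len_ctrl total non-repetitive lengths (bp).
#' @return fold enrichment (numeric).
#' @export
tfbs_enrichment <- function(count_enh, count_ctrl, nonrep_len_enh,
                            nonrep_len_ctrl) {
  if (nonrep_len_enh <= 0 || nonrep_len_ctrl <= 0)
    stop_fmt("zero non-repetitive length")
  cc <- if (count_ctrl == 0) 0.5 else count_ctrl
  (count_enh / nonrep_len_enh) / (cc / nonrep_len_ctrl)
}

#' Fraction of binding sites containing a deMP
#'
#' A hit counts once no matter how many deMPs it contains.
#'
#' @param hits hit `data.frame` (from [scan_pssm()]).
#' @param demps `data.frame` with chrom, pos.
#' @return fraction in `[0, 1]` (NA for zero hits).
#' @export
fraction_sites_with_demp <- function(hits, demps) {
  if (!nrow(hits)) return(NA_real_)
  has <- vapply(seq_len(nrow(hits)), function(i) {
    d <- demps[demps$chrom == hits$chrom[i], , drop = FALSE]
    any(d$pos >= hits$start[i] & d$pos < hits$end[i])
  }, logical(1))
  mean(has)
}

#' Find homotypic and heterotypic binding-site clusters
#'
#' Homotypic clusters are maximal runs of at least `min_sites` hits of one
#' factor spanning at most `max_span` bp; heterotypic clusters are maximal
#' windows of at least `min_sites` hits from at least `min_distinct`
#' distinct factors within `max_span`. Cluster typing is disjoint: a window
#' qualifying as homotypic (single factor) can never satisfy the distinct-
#' factor requirement.
#'
#' @param hits hit `data.frame` within one enhancer.
#' @param min_sites minimum member count (default 3).
#' @param max_span maximum span, max(end) - min(start), in bp (default 1000).
#' @param min_distinct distinct factors required for heterotypic (default =
#'   `min_sites`, the strict reading; set 2 for the lax reading).
#' @return `data.frame` with type, tf (NA for heterotypic), start, end,
#'   n_sites, member_rows (list of hit row indices).
#' @export
find_clusters <- function(hits, min_sites = 3L, max_span = 1000L,
                          min_distinct = min_sites) {
  empty <- data.frame(type = character(), tf = character(),
                      start = integer(), end = integer(),
                      n_sites = integer())
  empty$member_rows <- list()
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  row_ids <- seq_len(nrow(hits))
  out <- list()
  maximal_windows <- function(idx) {
    # idx: candidate hit rows sorted by start; returns maximal index windows
    # [i, j] with span <= max_span and >= min_sites members
    st <- hits$start[idx]; en <- hits$end[idx]
    n <- length(idx)
    res <- list()
    j <- 1L
    for (i in seq_len(n)) {
      j <- max(j, i)
      while (j < n && max(en[i:(j + 1L)]) - st[i] <= max_span) j <- j + 1L
      if (j - i + 1L >= min_sites &&
          (i == 1L || max(en[(i - 1L):j]) - st[i - 1L] > max_span))
        res[[length(res) + 1L]] <- idx[i:j]
    }
    res
  }
  for (tf in unique(hits$tf)) {
    for (mem in maximal_windows(row_ids[hits$tf == tf])) {
      out[[length(out) + 1L]] <- data.frame(
        type = "homotypic", tf = tf, start = min(hits$start[mem]),
        end = max(hits$end[mem]), n_sites = length(mem),
        stringsAsFactors = FALSE)
      out[[length(out)]]$member_rows <- list(mem)
    }
  }
  for (mem in maximal_windows(row_ids)) {
    if (length(unique(hits$tf[mem])) >= min_distinct) {
      out[[length(out) + 1L]] <- data.frame(
        type = "heterotypic", tf = NA_character_,
        start = min(hits$start[mem]), end = max(hits$end[mem]),
        n_sites = length(mem), stringsAsFactors = FALSE)
      out[[length(out)]]$member_rows <- list(mem)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of a factor's hits inside homotypic clusters
#'
#' @param tf factor name.
#' @param hits the hit `data.frame` passed to [find_clusters()] (same row
#'   order).
#' @param clusters output of [find_clusters()].
#' @return fraction of `tf` hits that belong to at least one homotypic
#'   cluster of `tf`.
#' @export
htc_fraction <- function(tf, hits, clusters) {
  hits_sorted <- hits[order(hits$start, hits$end), , drop = FALSE]
  tf_rows <- which(hits_sorted$tf == tf)
  if (!length(tf_rows)) stop_fmt("factor '%s' has no hits", tf)
  cl <- clusters[clusters$type == "homotypic" & clusters$tf == tf, ,
                 drop = FALSE]
  if (!nrow(cl)) return(0)
  members <- unique(unlist(cl$member_rows))
  mean(tf_rows %in% members)
}

#' deMP position profile along a motif
#'
#' For every deMP inside a hit, the bin is the offset from the hit start for
#' plus-strand hits and `width - 1 - offset` for minus-strand hits, so the
#' profile is expressed in motif coordinates.
#'
#' @param hits hits of one factor.
#' @param demps `data.frame` with chrom, pos.
#' @param width motif width.
#' @return integer vector of length `width`; sums to the number of
#'   (hit, deMP) containments.
#' @export
demp_motif_profile <- function(hits, demps, width) {
  prof <- integer(width)
  for (i in seq_len(nrow(hits))) {
    d <- demps[demps$chrom == hits$chrom[i] & demps$pos >= hits$start[i] &
                 demps$pos < hits$end[i], , drop = FALSE]
    if (!nrow(d)) next
    off <- d$pos - hits$start[i]
    bin <- if (hits$strand[i] == "-") width - 1L - off else off
    for (b in bin) prof[b + 1L] <- prof[b + 1L] + 1L
  }
  prof
}

#' Per-enhancer cluster flags
#'
#' @param hits all hits with an `enh_id` column.
#' @param min_sites,max_span,min_distinct see [find_clusters()].
#' @return `data.frame` enh_id, has_homotypic, has_heterotypic.
#' @export
enhancer_cluster_flags <- function(hits, min_sites = 3L, max_span = 1000L,
                                   min_distinct = min_sites) {
  ids <- unique(hits$enh_id)
  do.call(rbind, lapply(ids, function(id) {
    cl <- find_clusters(hits[hits$enh_id == id, , drop = FALSE],
                        min_sites, max_span, min_distinct)
    data.frame(enh_id = id,
               has_homotypic = any(cl$type == "homotypic"),
               has_heterotypic = any(cl$type == "heterotypic"),
               stringsAsFactors = FALSE)
  }))
}
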