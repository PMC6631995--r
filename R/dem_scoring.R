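# Candidate deactivating-mutation detection, Delta/S feature extraction
# across k sizes and signal tracks, linear weight fitting, score
# decomposition into WS(Delta) + WS(S) + b with score = logistic(margin),
# FPR threshold calibration, and deM/deMP calling.

#' Feature schema of the scorer
#'
#' The scorer integrates `N_k x N_signature x N_track` features: for every
#' word length k in `k_sizes` and every signal track, the motif-disruption
#' signature Delta and the neighborhood signature S.
#'
#' @param tracks ordered character vector of signal-track names (vocabulary
#'   keys; include `"pooled"` if the pooled vocabulary is a feature source).
#' @param k_sizes word lengths (default `c(4, 6, 8, 10, 12)`).
#' @param flank_window half-width in bp of the neighborhood window for S
#'   (default 100).
#' @return list of class `"feature_schema"`.
#' @export
feature_schema <- function(tracks, k_sizes = c(4L, 6L, 8L, 10L, 12L),
                           flank_window = 100L) {
  stopifnot(length(tracks) >= 1L, all(k_sizes >= 2L))
  structure(list(tracks = tracks, k_sizes = as.integer(k_sizes),
                 flank_window = as.integer(flank_window)),
            class = "feature_schema")
}

#' Feature names in schema order
#'
#' @param schema a [feature_schema()].
#' @return character vector `delta.k<k>.<track>` / `s.k<k>.<track>`, grouped
#'   by track, then k, with Delta before S.
#' @export
feature_names <- function(schema) {
  unlist(lapply(schema$tracks, function(tr)
    unlist(lapply(schema$k_sizes, function(k)
      sprintf(c("delta.k%d.%s", "s.k%d.%s"), k, tr)))))
}

# window weight/validity/canonical precomputation for one sequence and k.
# Windows overlapping N or lowercase are invalid and weigh 0.
.window_info <- function(seq, k, with_words = TRUE) {
  L <- nchar(seq)
  n_win <- L - k + 1L
  if (n_win < 1L)
    return(list(n = 0L, valid = logical(0), words = character(0)))
  words <- substring(seq, 1:n_win, k:L)
  valid <- !stringi::stri_detect_regex(words, "[^ACGT]")
  list(n = n_win, valid = valid, words = if (with_words) words else NULL)
}

.window_weights <- function(info, vocab) {
  w <- numeric(info$n)
  if (any(info$valid))
    w[info$valid] <- kmer_weight(vocab, info$words[info$valid])
  w
}

#' Candidate deactivating mutations of a sequence
#'
#' A substitution is a candidate iff at least one k=8 window covering it has
#' its reference word in the `top` class and the corresponding alternate
#' word in the `background` class of the supplied vocabulary. Windows
#' containing N or repeat-masked (lowercase) bases are skipped.
#'
#' @param seq the sequence to scan.
#' @param vocab_k8 a k=8 `"kmer_vocab"`.
#' @param offset genomic start of `seq` (0-based) added to reported
#'   positions.
#' @param chrom chromosome name for the output records.
#' @param region optional `c(start, end)` 0-based half-open sub-range of the
#'   *genomic* axis to restrict reported positions to.
#' @return `data.frame` chrom, pos, ref, alt.
#' @export
candidate_dems <- function(seq, vocab_k8, offset = 0L, chrom = "chr1",
                           region = NULL) {
  k <- vocab_k8$k
  info <- .window_info(seq, k)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
  if (info$n == 0L) return(empty)
  cls <- rep("background", info$n)
  cls[info$valid] <- kmer_class(vocab_k8, info$words[info$valid])
  top_idx <- which(cls == "top")
  if (!length(top_idx)) return(empty)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (s in top_idx) {           # s: 1-based window start index
    word <- info$words[s]
    for (off in seq_len(k)) {
      ref <- substr(word, off, off)
      for (alt in setdiff(bases, ref)) {
        aw <- word
        substr(aw, off, off) <- alt
        if (kmer_class(vocab_k8, aw) == "background") {
          pos <- offset + (s - 1L) + (off - 1L)
          out[[length(out) + 1L]] <- c(pos = pos, ref = ref, alt = alt)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  df <- data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  df <- unique(data.frame(chrom = chrom, pos = as.integer(df$pos),
                          ref = df$ref, alt = df$alt,
                          stringsAsFactors = FALSE))
  if (!is.null(region))
    df <- df[df$pos >= region[1] & df$pos < region[2], , drop = FALSE]
  df <- df[order(df$pos, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Motif-disruption feature Delta for one variant
#'
#' The maximum, over the k windows covering the variant, of
#' `weight(reference word) - weight(alternate word)`, floored at 0. Masked
#' windows are skipped.
#'
#' @param seq sequence containing the variant.
#' @param pos 0-based position of the variant within `seq`.
#' @param alt alternate base.
#' @param vocab the `"kmer_vocab"` for one (k, track).
#' @return non-negative numeric.
#' @export
delta_feature <- function(seq, pos, alt, vocab) {
  k <- vocab$k
  L <- nchar(seq)
  lo <- max(0L, pos - k + 1L)
  hi <- min(pos, L - k)
  if (hi < lo) return(0)
  starts <- lo:hi
  refw <- substring(seq, starts + 1L, starts + k)
  ok <- !stringi::stri_detect_regex(refw, "[^ACGT]")
  if (!any(ok)) return(0)
  # vectorized one-position replacement
  altw <- paste0(substring(refw, 1L, pos - starts), alt,
                 substring(refw, pos - starts + 2L, k))
  d <- kmer_weight(vocab, refw[ok]) - kmer_weight(vocab, altw[ok])
  max(0, d)
}

#' Neighborhood feature S for one variant
#'
#' The sum of weights of top-k-mer windows lying fully inside
#' `[pos - flank, pos + flank]` that do not cover the variant position.
#'
#' @inheritParams delta_feature
#' @param flank half-width of the neighborhood window in bp.
#' @return non-negative numeric.
#' @export
s_feature <- function(seq, pos, vocab, flank = 100L) {
  k <- vocab$k
  L <- nchar(seq)
  lo <- max(0L, pos - flank)
  hi <- min(L - k, pos + flank - k + 1L)
  if (hi < lo) return(0)
  starts <- lo:hi
  covers <- starts <= pos & pos <= starts + k - 1L
  starts <- starts[!covers]
  if (!length(starts)) return(0)
  words <- substring(seq, starts + 1L, starts + k)
  ok <- !stringi::stri_detect_regex(words, "[^ACGT]")
  if (!any(ok)) return(0)
  sum(kmer_weight(vocab, words[ok]))
}

#' Extract the full feature vector of one variant
#'
#' Concatenates [delta_feature()] and [s_feature()] over every (k, track)
#' pair of the schema, in [feature_names()] order.
#'
#' @param seq sequence context containing the variant.
#' @param pos 0-based position within `seq`.
#' @param alt alternate base.
#' @param vocabs nested list `vocabs[[track]][[as.character(k)]]`.
#' @param schema a [feature_schema()].
#' @return named numeric vector.
#' @export
extract_features <- function(seq, pos, alt, vocabs, schema) {
  out <- numeric(0)
  for (tr in schema$tracks) {
    if (is.null(vocabs[[tr]]))
      stop_fmt("missing vocabulary for track '%s'", tr)
    for (k in schema$k_sizes) {
      v <- vocabs[[tr]][[as.character(k)]]
      if (is.null(v)) stop_fmt("missing vocabulary for (k=%d, track '%s')", k, tr)
      out <- c(out, delta_feature(seq, pos, alt, v),
               s_feature(seq, pos, v, schema$flank_window))
    }
  }
  setNames(out, feature_names(schema))
}

# Batch feature extraction for variants that share one context sequence.
# ctx: sequence; pos: 0-based positions within ctx; alt: alternate bases.
# Precomputes window words/weights once per (k, track).
.features_on_context <- function(ctx, pos, alt, vocabs, schema) {
  n <- length(pos)
  fn <- feature_names(schema)
  X <- matrix(0, nrow = n, ncol = length(fn), dimnames = list(NULL, fn))
  L <- nchar(ctx)
  flank <- schema$flank_window
  for (k in schema$k_sizes) {
    info <- .window_info(ctx, k)
    if (info$n == 0L) next
    # per-track weight vectors + cumulative sums for range queries
    Ws <- lapply(schema$tracks, function(tr) {
      v <- vocabs[[tr]][[as.character(k)]]
      if (is.null(v)) stop_fmt("missing vocabulary for (k=%d, track '%s')", k, tr)
      w <- .window_weights(info, v)
      list(v = v, w = w, cs = cumsum(w))
    })
    names(Ws) <- schema$tracks
    rng_sum <- function(cs, lo, hi) {  # 1-based inclusive window indices
      if (hi < lo) return(0)
      cs[hi] - if (lo > 1L) cs[lo - 1L] else 0
    }
    for (i in seq_len(n)) {
      p <- pos[i]
      c_lo <- max(0L, p - k + 1L); c_hi <- min(p, L - k)
      starts <- if (c_hi >= c_lo) c_lo:c_hi else integer(0)
      altw_valid <- NULL
      if (length(starts)) {
        sv <- info$valid[starts + 1L]
        refw <- info$words[starts + 1L]
        altw <- paste0(substring(refw, 1L, p - starts), alt[i],
                       substring(refw, p - starts + 2L, k))
        altw_valid <- list(starts = starts[sv], refw = refw[sv],
                           altw = altw[sv])
      }
      s_lo <- max(0L, p - flank); s_hi <- min(L - k, p + flank - k + 1L)
      for (tr in schema$tracks) {
        W <- Ws[[tr]]
        dval <- 0
        if (!is.null(altw_valid) && length(altw_valid$starts)) {
          d <- W$w[altw_valid$starts + 1L] -
            kmer_weight(W$v, altw_valid$altw)
          dval <- max(0, d)
        }
        sval <- 0
        if (s_hi >= s_lo) {
          sval <- rng_sum(W$cs, s_lo + 1L, s_hi + 1L) -
            rng_sum(W$cs, max(s_lo, c_lo) + 1L, min(s_hi, min(p, L - k)) + 1L)
        }
        X[i, sprintf("delta.k%d.%s", k, tr)] <- dval
        X[i, sprintf("s.k%d.%s", k, tr)] <- sval
      }
    }
  }
  X
}

#' Extract features for arbitrary genomic variants
#'
#' Pulls a `flank + max(k)` context around each variant from the genome and
#' computes the schema's features.
#'
#' @param genome a [genome()].
#' @param variants `data.frame` with chrom, pos (0-based), alt.
#' @param vocabs nested vocabulary list.
#' @param schema a [feature_schema()].
#' @return numeric matrix, one row per variant, columns [feature_names()].
#' @export
extract_features_batch <- function(genome, variants, vocabs, schema) {
  kmax <- max(schema$k_sizes)
  pad <- schema$flank_window + kmax
  fn <- feature_names(schema)
  X <- matrix(0, nrow = nrow(variants), ncol = length(fn),
              dimnames = list(NULL, fn))
  if (!nrow(variants)) return(X)
  # variants close together share one context so the window precomputation
  # is reused (typical case: many scored variants inside one enhancer)
  ord <- order(variants$chrom, variants$pos)
  chrom_o <- variants$chrom[ord]
  pos_o <- variants$pos[ord]
  new_chunk <- c(TRUE, chrom_o[-1] != chrom_o[-length(ord)] |
                   diff(pos_o) > 2000L)
  chunk <- cumsum(new_chunk)
  for (cid in unique(chunk)) {
    sel <- ord[chunk == cid]
    ch <- variants$chrom[sel[1]]
    L <- nchar(genome[[ch]])
    a <- max(0L, min(variants$pos[sel]) - pad)
    b <- min(L, max(variants$pos[sel]) + pad + 1L)
    ctx <- substring(genome[[ch]], a + 1L, b)
    X[sel, ] <- .features_on_context(ctx, variants$pos[sel] - a,
                                     variants$alt[sel], vocabs, schema)
  }
  X
}

# rank-based AUC
.auc <- function(scores, y) {
  pos <- y == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the linear scorer
#'
#' A linear maximum-margin classifier (support-vector machine, linear
#' kernel) with the regularization cost chosen by 5-fold cross-validated
#' AUC over a fixed grid. A logistic probability map is then fitted on the
#' held-out decision values and folded into the returned weights, so that
#' `score = logistic(WS(Delta) + WS(S) + b)` holds exactly with the
#' returned weight set.
#'
#' @param X feature matrix (columns = [feature_names()]).
#' @param y labels: `"deactivating"`/`"neutral"`, or 0/1 with 1 = positive.
#' @param schema the [feature_schema()] (layout check).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param cost_grid SVM cost grid.
#' @return list of class `"weight_set"`: `weights` (named numeric),
#'   `intercept`, `cv` (per-cost mean AUC), `cost`, `cv_auc`.
#' @export
fit_weights <- function(X, y, schema, folds = 5L, seed = 1L,
                        cost_grid = c(0.01, 0.1, 1, 10)) {
  fn <- feature_names(schema)
  stopifnot(identical(colnames(X), fn))
  y01 <- if (is.numeric(y)) as.integer(y) else
    as.integer(y == "deactivating")
  if (length(unique(y01)) < 2L) stop_fmt("training labels are single-class")
  if (min(table(y01)) < 2L) stop_fmt("need >= 2 examples per class")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(X)))
  yf <- factor(y01, levels = c(0L, 1L))
  cv_fit <- function(cost) {
    dv_all <- numeric(nrow(X))
    auc_k <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
      dv <- attr(predict(m, X[!tr, , drop = FALSE], decision.values = TRUE),
                 "decision.values")[, 1]
      a <- .auc(dv, y01[!tr])
      if (!is.na(a) && a < 0.5) dv <- -dv      # orient toward positives
      dv_all[!tr] <- dv
      auc_k[f] <- .auc(dv, y01[!tr])
    }
    list(auc = mean(auc_k, na.rm = TRUE), dv = dv_all)
  }
  cv <- lapply(cost_grid, cv_fit)
  aucs <- vapply(cv, `[[`, 0, "auc")
  best <- which.max(aucs)
  # final max-margin fit on all data
  m <- e1071::svm(X, yf, kernel = "linear", cost = cost_grid[best],
                  scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  dv_full <- drop(X %*% w) + b
  if (.auc(dv_full, y01) < 0.5) { w <- -w; b <- -b }
  # probability map from held-out decision values, absorbed into weights;
  # perfect separation makes glm warn and drift, which the A <= 0 /
  # non-finite guard below already handles
  platt <- suppressWarnings(
    stats::glm(y01 ~ dv, family = stats::binomial(),
               data = data.frame(y01 = y01, dv = cv[[best]]$dv)))
  A <- unname(stats::coef(platt)[2]); B <- unname(stats::coef(platt)[1])
  if (!is.finite(A) || A <= 0) { A <- 1; B <- 0 }
  weights <- setNames(as.numeric(w[fn] * A), fn)
  structure(list(weights = weights, intercept = A * b + B,
                 cv = data.frame(cost = cost_grid, mean_auc = aucs),
                 cost = cost_grid[best], cv_auc = aucs[best]),
            class = "weight_set")
}

#' Score a feature vector and decompose it
#'
#' `WS(Delta)` is the weighted sum of the Delta features, `WS(S)` of the S
#' features; `margin = WS(Delta) + WS(S) + b` and
#' `score = logistic(margin)`.
#'
#' @param fv named feature vector or matrix with [feature_names()] columns.
#' @param weights a `"weight_set"`.
#' @return `data.frame` with ws_delta, ws_s, intercept, margin, score (one
#'   row per input row).
#' @export
score_and_decompose <- function(fv, weights) {
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1,
                                     dimnames = list(NULL, names(fv)))
  fn <- names(weights$weights)
  if (!identical(colnames(fv), fn))
    stop_fmt("feature layout mismatch: expected %d features", length(fn))
  is_d <- startsWith(fn, "delta.")
  ws_delta <- drop(fv[, is_d, drop = FALSE] %*% weights$weights[is_d])
  ws_s <- drop(fv[, !is_d, drop = FALSE] %*% weights$weights[!is_d])
  margin <- ws_delta + ws_s + weights$intercept
  data.frame(ws_delta = ws_delta, ws_s = ws_s,
             intercept = weights$intercept, margin = margin,
             score = stats::plogis(margin))
}

#' Calibrate the score threshold at a target false-positive rate
#'
#' Returns the smallest score `t` such that the fraction of negative-control
#' scores at or above `t` is at most `fpr` (the empirical upper
#' `(1 - fpr)`-quantile). Ties at the threshold count as calls.
#'
#' @param negative_scores numeric scores of negative controls.
#' @param fpr target false-positive rate (default 0.01).
#' @return numeric threshold.
#' @export
calibrate_fpr_threshold <- function(negative_scores, fpr = 0.01) {
  stopifnot(fpr > 0, fpr <= 1)
  n <- length(negative_scores)
  if (n == 0L) stop_fmt("no negative scores supplied")
  if (n < 1 / fpr)
    warn_fmt("only %d negative scores for FPR %.3g; threshold is unstable",
             n, fpr)
  s <- sort(negative_scores)
  u <- unique(s)
  frac_ge <- (n - match(u, s) + 1) / n
  ok <- which(frac_ge <= fpr)
  if (length(ok)) u[min(ok)] else u[length(u)] + 1e-9
}

#' Call deMs and deMPs over an enhancer set
#'
#' For every enhancer, all candidate substitutions (top-to-background k=8
#' flips under the pooled vocabulary) are scored and decomposed; a call with
#' `score >= threshold` is a deM, and a position holding at least one deM is
#' a deMP.
#'
#' @param genome a [genome()].
#' @param enhancers interval `data.frame` with ids.
#' @param vocabs nested vocabulary list (must contain the schema's tracks;
#'   candidates use `vocabs$pooled[["8"]]`).
#' @param schema a [feature_schema()].
#' @param weights a `"weight_set"`.
#' @param threshold calibrated score threshold.
#' @return list with `calls` (chrom, pos, ref, alt, enh_id, ws_delta, ws_s,
#'   margin, score, is_dem) and `demps` (chrom, pos, enh_id for deMP
#'   positions).
#' @export
call_demps <- function(genome, enhancers, vocabs, schema, weights, threshold) {
  v8 <- vocabs[["pooled"]][["8"]]
  if (is.null(v8)) stop_fmt("pooled k=8 vocabulary required for candidates")
  kmax <- max(schema$k_sizes)
  pad <- schema$flank_window + kmax
  call_list <- list()
  for (i in seq_len(nrow(enhancers))) {
    ch <- enhancers$chrom[i]
    L <- nchar(genome[[ch]])
    a <- max(0L, enhancers$start[i] - pad)
    b <- min(L, enhancers$end[i] + pad)
    ctx <- substring(genome[[ch]], a + 1L, b)
    cand <- candidate_dems(ctx, v8, offset = a, chrom = ch,
                           region = c(enhancers$start[i], enhancers$end[i]))
    if (!nrow(cand)) next
    X <- .features_on_context(ctx, cand$pos - a, cand$alt, vocabs, schema)
    dec <- score_and_decompose(X, weights)
    cand$enh_id <- enhancers$id[i]
    call_list[[length(call_list) + 1L]] <-
      cbind(cand, dec[, c("ws_delta", "ws_s", "margin", "score")])
  }
  if (!length(call_list)) {
    return(list(calls = data.frame(), demps = data.frame(
      chrom = character(), pos = integer(), enh_id = character())))
  }
  calls <- do.call(rbind, call_list)
  calls$is_dem <- calls$score >= threshold
  dem <- calls[calls$is_dem, c("chrom", "pos", "enh_id")]
  demps <- unique(dem)
  demps <- demps[order(demps$chrom, demps$pos), , drop = FALSE]
  rownames(calls) <- rownames(demps) <- NULL
  list(calls = calls, demps = demps)
}
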