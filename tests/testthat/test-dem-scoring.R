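# a tiny hand-built vocabulary: one top 8-mer with known weight, everything
# else background except one designated neutral word
toy_vocab <- function(top = "ACGTACGT", w = 1.5, neutral = "AAAATTTT", k = 8L) {
  v <- structure(list(k = k, track = "toy", alpha = 1e-3,
                      universe = count_distinct_canonical(k),
                      n_enh_windows = 1000L, n_ctrl_windows = 1000L,
                      top_kmers = canonical_kmer(top),
                      top_weights = w,
                      neutral_kmers = canonical_kmer(neutral)),
                 class = "kmer_vocab")
  v$table <- data.frame(kmer = c(v$top_kmers, v$neutral_kmers),
                        enh_count = c(10L, 5L), ctrl_count = c(0L, 2L),
                        p_raw = c(1e-9, 1e-4),
                        class = c("top", "neutral"), weight = c(w, 0))
  v
}

test_that("candidate detection agrees with an all-substitutions oracle", {
  v <- toy_vocab()
  seqs <- c(paste0("TTTTT", "ACGTACGT", "TTTTT"),
            rand_seq(40, seed = 3),
            paste0("ttttt", "ACGTACGT"))   # masked flank
  for (s in seqs) {
    got <- candidate_dems(s, v)
    # oracle: enumerate all 3L substitutions, loop over covering windows
    oracle <- list()
    L <- nchar(s)
    for (p in 0:(L - 1)) {
      ref <- substr(s, p + 1, p + 1)
      if (!ref %in% c("A", "C", "G", "T")) next
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        is_cand <- FALSE
        for (st in max(0, p - 7):min(p, L - 8)) {
          w_ref <- substr(s, st + 1, st + 8)
          if (grepl("[^ACGT]", w_ref)) next
          w_alt <- w_ref
          substr(w_alt, p - st + 1, p - st + 1) <- alt
          if (kmer_class(v, w_ref) == "top" &&
              kmer_class(v, w_alt) == "background") is_cand <- TRUE
        }
        if (is_cand)
          oracle[[length(oracle) + 1L]] <- data.frame(pos = p, ref = ref,
                                                      alt = alt)
      }
    }
    oracle_df <- if (length(oracle)) do.call(rbind, oracle) else
      data.frame(pos = integer(), ref = character(), alt = character())
    expect_equal(got[, c("pos", "ref", "alt")], oracle_df,
                 ignore_attr = TRUE)
  }
  # every window background -> empty; output bounded by 3L
  expect_equal(nrow(candidate_dems(rand_seq(30, seed = 12), v)), 0L)
})

test_that("Delta and S features match brute-force window scans", {
  v <- toy_vocab()
  s <- paste0(rand_seq(60, seed = 21), "ACGTACGT", rand_seq(20, seed = 22),
              "ACGTACGT", rand_seq(60, seed = 23))
  for (p in c(0L, 62L, 65L, 90L, 147L)) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(s, p + 1, p + 1))) {
      # oracle Delta
      dmax <- 0
      for (st in max(0, p - 7):min(p, nchar(s) - 8)) {
        w_ref <- substr(s, st + 1, st + 8)
        if (grepl("[^ACGT]", w_ref)) next
        w_alt <- w_ref
        substr(w_alt, p - st + 1, p - st + 1) <- alt
        dmax <- max(dmax, kmer_weight(v, w_ref) - kmer_weight(v, w_alt))
      }
      expect_equal(delta_feature(s, p, alt, v), dmax)
      # oracle S with flank 30
      ssum <- 0
      for (st in 0:(nchar(s) - 8)) {
        if (st < p - 30 || st + 7 > p + 30) next
        if (st <= p && p <= st + 7) next
        w_ref <- substr(s, st + 1, st + 8)
        if (grepl("[^ACGT]", w_ref)) next
        ssum <- ssum + kmer_weight(v, w_ref)
      }
      expect_equal(s_feature(s, p, v, flank = 30L), ssum)
    }
  }
  # flank devoid of top k-mers
  expect_equal(s_feature(rand_seq(50, seed = 31), 25L, v, flank = 20L), 0)
})

test_that("batch extraction matches the single-variant path and the schema size", {
  w <- tiny_world()
  vo <- tiny_vocabs()
  schema <- feature_schema(names(w$tracks))
  expect_length(feature_names(schema), 5 * 2 * 3)
  expect_length(feature_names(feature_schema("pooled")), 10)
  v <- w$variants[1:12, ]
  X <- extract_features_batch(w$genome, v, vo, schema)
  gseq <- w$genome[[1]]
  for (i in c(1L, 5L, 9L)) {
    pad <- schema$flank_window + max(schema$k_sizes)
    a <- max(0L, v$pos[i] - pad)
    ctx <- substring(gseq, a + 1L, v$pos[i] + pad + 1L)
    fv <- extract_features(ctx, v$pos[i] - a, v$alt[i], vo, schema)
    expect_equal(X[i, ], fv)
  }
  # missing vocabulary is reported by name
  expect_error(extract_features_batch(w$genome, v[1, ],
                                      vo["pooled"],
                                      feature_schema(c("pooled", "nope"))),
               "nope")
})

test_that("decomposition is exactly additive and logistic on random vectors", {
  set.seed(77)
  schema <- feature_schema(c("t1", "t2"))
  fn <- feature_names(schema)
  wts <- structure(list(weights = setNames(rnorm(length(fn)), fn),
                        intercept = rnorm(1)), class = "weight_set")
  X <- matrix(rnorm(500 * length(fn)), 500, dimnames = list(NULL, fn))
  dec <- score_and_decompose(X, wts)
  expect_lt(max(abs(dec$ws_delta + dec$ws_s + dec$intercept - dec$margin)),
            1e-9)
  # independent dot-product oracle
  oracle <- drop(X %*% wts$weights) + wts$intercept
  expect_equal(dec$margin, oracle, tolerance = 1e-12)
  expect_equal(dec$score, 1 / (1 + exp(-oracle)), tolerance = 1e-12)
  # all-zero weights give margin 0, score 0.5
  wts0 <- structure(list(weights = setNames(numeric(length(fn)), fn),
                         intercept = 0), class = "weight_set")
  expect_equal(score_and_decompose(X[1, ], wts0)$score, 0.5)
  # layout mismatch is an error
  expect_error(score_and_decompose(X[, -1], wts), "layout")
})

test_that("monotonicity: raising a positively weighted Delta never lowers the score", {
  schema <- feature_schema("t1")
  fn <- feature_names(schema)
  wts <- structure(list(weights = setNames(abs(rnorm(length(fn))), fn),
                        intercept = -1), class = "weight_set")
  fv <- setNames(runif(length(fn)), fn)
  base <- score_and_decompose(fv, wts)$score
  for (j in grep("^delta", fn)) {
    fv2 <- fv
    fv2[j] <- fv2[j] + 0.5
    expect_gte(score_and_decompose(fv2, wts)$score, base)
  }
})

test_that("weight fitting separates a separable toy set and is seed-stable", {
  set.seed(10)
  schema <- feature_schema("t1", k_sizes = c(4L, 6L), flank_window = 50L)
  fn <- feature_names(schema)
  n <- 120
  y <- rep(c("deactivating", "neutral"), each = n / 2)
  X <- matrix(rnorm(n * length(fn), sd = 0.2), n,
              dimnames = list(NULL, fn))
  X[y == "deactivating", 1] <- X[y == "deactivating", 1] + 3
  wt <- fit_weights(X, y, schema, seed = 5)
  dec <- score_and_decompose(X, wt)
  expect_equal(.mean_acc <- mean((dec$score >= 0.5) ==
                                   (y == "deactivating")), 1.0)
  wt2 <- fit_weights(X, y, schema, seed = 5)
  expect_identical(wt$weights, wt2$weights)
  expect_identical(wt$intercept, wt2$intercept)
  expect_error(fit_weights(X, rep("neutral", n), schema), "single-class")
})

test_that("permuted labels give a null cross-validated AUC", {
  set.seed(20)
  schema <- feature_schema("t1", k_sizes = c(4L, 6L))
  fn <- feature_names(schema)
  n <- 500
  X <- matrix(rnorm(n * length(fn)), n, dimnames = list(NULL, fn))
  y <- sample(rep(c("deactivating", "neutral"), each = n / 2))
  wt <- fit_weights(X, y, schema, seed = 6)
  expect_gte(wt$cv_auc, 0.4)
  expect_lte(wt$cv_auc, 0.6)
})

test_that("FPR threshold calibration follows the order-statistic rule", {
  # scores 1..100 at fpr 0.01: exactly one negative at or above threshold
  thr <- calibrate_fpr_threshold(1:100, fpr = 0.01)
  expect_equal(sum(1:100 >= thr), 1L)
  expect_equal(thr, 100)
  # fpr = 1 admits everything
  expect_equal(calibrate_fpr_threshold(c(5, 2, 9), fpr = 1), 2)
  expect_error(calibrate_fpr_threshold(numeric(0)), "no negative")
  expect_warning(calibrate_fpr_threshold(1:10, fpr = 0.01), "unstable")
  # ties: threshold keeps the at-or-above fraction within fpr
  s <- rep(1:10, each = 10)
  thr <- calibrate_fpr_threshold(s, fpr = 0.1)
  expect_lte(mean(s >= thr), 0.1)
})

test_that("deMP calling marks positions with at least one qualifying deM", {
  w <- tiny_world()
  vo <- tiny_vocabs()
  schema <- feature_schema(names(w$tracks))
  X <- extract_features_batch(w$genome, w$variants, vo, schema)
  wt <- fit_weights(X, w$variants$label, schema, seed = 11)
  enh <- w$enhancers[1:6, ]
  res_lo <- call_demps(w$genome, enh, vo, schema, wt, threshold = 0.99)
  res_hi <- call_demps(w$genome, enh, vo, schema, wt, threshold = 1 + 1e-9)
  # scores live in (0,1): an impossible threshold yields zero deMPs
  expect_equal(nrow(res_hi$demps), 0L)
  if (nrow(res_lo$calls)) {
    expect_setequal(unique(res_lo$calls$pos[res_lo$calls$is_dem]),
                    res_lo$demps$pos)
    # deMP count bounded by enhancer lengths
    expect_lte(nrow(res_lo$demps), sum(enh$end - enh$start))
    # additivity holds for every scored variant
    expect_lt(max(abs(res_lo$calls$ws_delta + res_lo$calls$ws_s +
                        wt$intercept - res_lo$calls$margin)), 1e-9)
  }
})

test_that("positives outscore matched negatives on the tiny world", {
  w <- tiny_world()
  vo <- tiny_vocabs()
  schema <- feature_schema(names(w$tracks))
  X <- extract_features_batch(w$genome, w$variants, vo, schema)
  wt <- fit_weights(X, w$variants$label, schema, seed = 11)
  dec <- score_and_decompose(X, wt)
  expect_gt(median(dec$score[w$variants$label == "deactivating"]),
            median(dec$score[w$variants$label == "neutral"]))
  expect_gte(wt$cv_auc, 0.85)
})

test_that("weight tables round-trip through TSV losslessly", {
  schema <- feature_schema(c("a", "b"))
  fn <- feature_names(schema)
  wt <- structure(list(weights = setNames(rnorm(length(fn)), fn),
                       intercept = 0.123), class = "weight_set")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_weights_tsv(wt, f)
  wt2 <- read_weights_tsv(f, schema)
  expect_equal(wt2$weights, wt$weights)
  expect_equal(wt2$intercept, wt$intercept)
})
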