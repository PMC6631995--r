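calibrated_pssm <- function(tf = "tsA", seed = 31, len = 100000L) {
  mot <- default_motifs()
  p <- pssm_from_consensus(tf, mot$consensus[mot$name == tf],
                           mot$second[mot$name == tf])
  suppressWarnings(calibrate_pssm_threshold(p, rand_seq(len, seed = seed)))
}

test_that("calibration holds the held-out false-positive density near target", {
  p <- calibrated_pssm(len = 200000L)
  held <- rand_seq(100000L, seed = 77)
  hits <- scan_pssm(held, p)
  expected <- 100000 / 10000 * 5
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected) + 1)
  # monotonicity: a higher threshold never raises the rate
  p2 <- p
  p2$threshold <- p$threshold + 1
  expect_lte(nrow(scan_pssm(held, p2)), nrow(hits))
  # degenerate matrix errors
  flat <- structure(list(tf = "flat",
                         mat = matrix(0, 8, 4,
                                      dimnames = list(NULL,
                                                      c("A", "C", "G", "T"))),
                         width = 8L, threshold = NA_real_), class = "pssm")
  expect_error(calibrate_pssm_threshold(flat, rand_seq(100000L, seed = 1)),
               "degenerate")
})

test_that("scanning finds planted consensus on both strands and respects masking", {
  p <- calibrated_pssm("tsB")
  cons <- default_motifs()$consensus[default_motifs()$name == "tsB"]
  s <- paste0(rand_seq(50, seed = 8), cons, rand_seq(50, seed = 9),
              oracle_revcomp(cons), rand_seq(50, seed = 10))
  hits <- scan_pssm(s, p)
  expect_true(any(hits$start == 50 & hits$strand == "+"))
  expect_true(any(hits$start == 108 & hits$strand == "-"))
  # lowercase-masked planted site yields no hit
  s2 <- paste0(rand_seq(50, seed = 8), tolower(cons), rand_seq(50, seed = 9))
  expect_false(any(scan_pssm(s2, p)$start == 50))
  # strand symmetry: scanning the reverse complement mirrors coordinates
  h1 <- scan_pssm(s, p)
  h2 <- scan_pssm(oracle_revcomp(s), p)
  L <- nchar(s)
  mirrored <- data.frame(start = L - h2$end, end = L - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         score = h2$score)
  o1 <- h1[order(h1$start, h1$strand), c("start", "end", "strand", "score")]
  o2 <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("enrichment follows the length-normalized ratio with a zero guard", {
  expect_equal(tfbs_enrichment(10, 2, 1000, 1000), 5.0)
  expect_equal(tfbs_enrichment(5, 5, 1000, 1000), 1.0)
  # zero control hits stay finite via the 0.5 guard
  expect_equal(tfbs_enrichment(10, 0, 1000, 2000),
               (10 / 1000) / (0.5 / 2000))
  expect_error(tfbs_enrichment(1, 1, 0, 10), "zero")
})

test_that("fraction of sites with a deMP counts each hit once", {
  hits <- data.frame(tf = "x", chrom = "chr1", start = c(0L, 20L, 40L),
                     end = c(8L, 28L, 48L), strand = "+", score = 1)
  demps <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L, 21L))
  expect_equal(fraction_sites_with_demp(hits, demps), 2 / 3)
  expect_equal(fraction_sites_with_demp(hits,
                                        data.frame(chrom = "chr1",
                                                   pos = 100L)), 0)
  # brute-force agreement on random layouts
  set.seed(55)
  for (r in 1:5) {
    h <- data.frame(tf = "x", chrom = "chr1",
                    start = sample(0:200, 10), strand = "+", score = 1)
    h$end <- h$start + 8L
    d <- data.frame(chrom = "chr1", pos = sample(0:210, 15))
    oracle <- mean(vapply(seq_len(10), function(i)
      any(d$pos >= h$start[i] & d$pos < h$end[i]), logical(1)))
    expect_equal(fraction_sites_with_demp(h, d), oracle)
  }
})

test_that("cluster typing matches the stated definitions on toy layouts", {
  mk <- function(tf, starts) data.frame(tf = tf, chrom = "chr1",
                                        start = starts, end = starts + 8L,
                                        strand = "+", score = 1,
                                        stringsAsFactors = FALSE)
  # 3 same-TF hits spanning 600 bp -> one homotypic cluster
  cl <- find_clusters(mk("a", c(0L, 300L, 592L)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$type, "homotypic")
  # 3 distinct TFs spanning 900 bp -> one heterotypic cluster
  h <- rbind(mk("a", 0L), mk("b", 500L), mk("c", 892L))
  cl <- find_clusters(h)
  expect_equal(cl$type, "heterotypic")
  # 3 same-TF hits spanning 1200 bp -> no cluster
  expect_equal(nrow(find_clusters(mk("a", c(0L, 600L, 1192L)))), 0L)
  # homotypic run is never double-reported as heterotypic (strict typing)
  cl <- find_clusters(mk("a", c(0L, 100L, 200L)))
  expect_equal(cl$type, "homotypic")
  # two TFs, lax reading: heterotypic appears only with min_distinct = 2
  h2 <- rbind(mk("a", c(0L, 100L)), mk("b", 200L))
  expect_false(any(find_clusters(h2)$type == "heterotypic"))
  expect_true(any(find_clusters(h2, min_distinct = 2L)$type == "heterotypic"))
})

test_that("homotypic-cluster membership fraction matches enumeration", {
  mk <- function(tf, starts) data.frame(tf = tf, chrom = "chr1",
                                        start = starts, end = starts + 8L,
                                        strand = "+", score = 1,
                                        stringsAsFactors = FALSE)
  hits <- rbind(mk("a", c(0L, 100L, 200L, 1500L)), mk("b", c(50L, 150L)))
  cl <- find_clusters(hits)
  # a's first three hits cluster; the 1500 hit and all b hits do not
  expect_equal(htc_fraction("a", hits, cl), 0.75)
  expect_error(htc_fraction("zzz", hits, cl), "no hits")
  expect_equal(htc_fraction("b", hits, cl), 0)
})

test_that("deMP motif profiles flip coordinates on the minus strand", {
  hits <- data.frame(tf = "x", chrom = "chr1", start = 10L, end = 18L,
                     strand = "+", score = 1, stringsAsFactors = FALSE)
  demps <- data.frame(chrom = "chr1", pos = 13L)   # offset 3
  expect_equal(which(demp_motif_profile(hits, demps, 8L) == 1L), 4L)
  hits$strand <- "-"
  expect_equal(which(demp_motif_profile(hits, demps, 8L) == 1L), 5L)
  # conservation: profile sums to the number of containments
  set.seed(66)
  h <- data.frame(tf = "x", chrom = "chr1", start = sample(0:100, 8),
                  strand = sample(c("+", "-"), 8, TRUE), score = 1,
                  stringsAsFactors = FALSE)
  h$end <- h$start + 8L
  d <- data.frame(chrom = "chr1", pos = sample(0:108, 20))
  containments <- sum(vapply(seq_len(8), function(i)
    sum(d$pos >= h$start[i] & d$pos < h$end[i]), 0L))
  expect_equal(sum(demp_motif_profile(h, d, 8L)), containments)
})

test_that("architecture-specific cluster usage is recovered on the tiny world", {
  w <- tiny_world()
  mot <- w$config$motifs
  set.seed(91)
  bg <- rand_seq(100000L)
  pssms <- lapply(seq_len(nrow(mot)), function(i)
    calibrate_pssm_threshold(pssm_from_consensus(mot$name[i],
                                                 mot$consensus[i],
                                                 mot$second[i]), bg))
  eseqs <- enhancer_seqs(w)
  hits <- list()
  for (i in seq_along(eseqs)) for (p in pssms) {
    h <- scan_pssm(eseqs[[i]], p, chrom = names(eseqs)[i])
    if (nrow(h)) { h$enh_id <- names(eseqs)[i]; hits[[length(hits) + 1]] <- h }
  }
  flags <- enhancer_cluster_flags(do.call(rbind, hits))
  flags$arch <- w$enhancers$architecture[match(flags$enh_id, w$enhancers$id)]
  expect_gte(mean(flags$has_homotypic[flags$arch == "homotypic"]), 0.9)
  expect_gte(mean(flags$has_heterotypic[flags$arch == "heterotypic"]), 0.9)
})
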