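test_that("identical config and seed give byte-identical worlds", {
  cfg <- world_config(seed = 11, genome_length = 200000L,
                      n_enhancers = c(homotypic = 8L, heterotypic = 8L),
                      n_pos = 40L, n_neg = 40L,
                      ld = list(n_snps = 100L, n_snps_enh = 40L,
                                block_length = 20000L, within_r2 = 0.9))
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(unclass(w1$genome), unclass(w2$genome))
  expect_identical(w1$enhancers, w2$enhancers)
  expect_identical(w1$sites, w2$sites)
  expect_identical(w1$variants, w2$variants)
  expect_identical(w1$ld, w2$ld)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(w1, d1); write_world(w2, d2)
  for (f in c("genome.fa", "enhancers.bed", "labels.tsv", "ld.tsv",
              "traits.tsv", "conserved.bed", "orthologs.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("declared counts and architecture split are honored", {
  w <- tiny_world()
  expect_equal(nrow(w$enhancers), 60L)
  expect_equal(unname(table(w$enhancers$architecture)["homotypic"]), 30L)
  expect_equal(nrow(w$variants), 300L)
  expect_equal(sum(w$variants$label == "deactivating"), 150L)
  # homotypic enhancers host 3-5 copies of a single pioneer motif;
  # heterotypic enhancers one copy each of 3-5 distinct ts motifs
  for (id in w$enhancers$id[1:10]) {
    st <- w$sites[w$sites$enh_id == id, ]
    arch <- w$enhancers$architecture[w$enhancers$id == id]
    expect_true(nrow(st) >= 3 && nrow(st) <= 5)
    if (arch == "homotypic") {
      expect_equal(length(unique(st$tf)), 1L)
      expect_true(all(st$group == "pioneer"))
    } else {
      expect_equal(length(unique(st$tf)), nrow(st))
      expect_true(all(st$group == "ts"))
    }
  }
})

test_that("planted sites are exactly recoverable by string search", {
  w <- tiny_world()
  gseq <- w$genome[[w$config$chrom]]
  # every recorded site matches its realized sequence at its coordinates
  ok <- vapply(seq_len(nrow(w$sites)), function(i) {
    s <- w$sites[i, ]
    substring(gseq, s$start + 1L, s$end) == s$seq
  }, logical(1))
  expect_true(all(ok))
  # consensus-string search recovers at least the non-degenerate copies in
  # each homotypic enhancer
  mot <- default_motifs()
  for (id in w$enhancers$id[w$enhancers$architecture == "homotypic"][1:8]) {
    st <- w$sites[w$sites$enh_id == id, ]
    e <- w$enhancers[w$enhancers$id == id, ]
    eseq <- substring(gseq, e$start + 1L, e$end)
    cons <- mot$consensus[mot$name == st$tf[1]]
    n_found <- stringi::stri_count_fixed(eseq, cons) +
      stringi::stri_count_fixed(eseq, oracle_revcomp(cons))
    expect_gte(n_found, sum(!st$degenerate))
  }
})

test_that("repeat masking stays outside planted sites and hits its fraction", {
  w <- tiny_world()
  expect_equal(seq_stats(w$genome[[1]])$repeat_frac, w$config$repeat_frac,
               tolerance = 0.02)
  for (i in seq_len(nrow(w$sites)))
    expect_false(grepl("[acgtn]", w$sites$seq[i]))
})

test_that("track coverage is elevated over target sites by the configured effect", {
  w <- tiny_world()
  cfg <- w$config
  tr <- w$tracks$dnase
  sites <- w$sites
  in_site <- rep(FALSE, nrow(tr$bins))
  for (j in seq_len(nrow(sites))) {
    b0 <- sites$start[j] %/% cfg$track_bin
    b1 <- (sites$end[j] - 1L) %/% cfg$track_bin
    in_site[(b0:b1) + 1L] <- TRUE
  }
  ratio <- mean(tr$bins$value[in_site]) / mean(tr$bins$value[!in_site])
  expect_gt(ratio, 4); expect_lt(ratio, 6)
  expect_true(all(tr$bins$value >= 0))
  # zero effect: site and background means differ only by sampling error
  cfg0 <- tiny_world_config(seed = 13)
  cfg0$tracks <- list(list(name = "flat", targets = "all", effect = 1,
                           dispersion = 0.3))
  w0 <- list(enhancers = w$enhancers, sites = w$sites)
  tr0 <- simulate_tracks(w$genome, w0, cfg0, seed = 99)$flat
  r0 <- mean(tr0$bins$value[in_site]) / mean(tr0$bins$value[!in_site])
  expect_equal(r0, 1, tolerance = 0.1)
})

test_that("training variants have the promised structure and matched covariates", {
  w <- tiny_world()
  v <- w$variants
  sites <- w$sites
  pos_v <- v[v$label == "deactivating", ]
  # every positive overlaps a planted site
  hit <- vapply(seq_len(nrow(pos_v)), function(i)
    any(sites$start <= pos_v$pos[i] & pos_v$pos[i] < sites$end), logical(1))
  expect_true(all(hit))
  # ref matches the genome and differs from alt
  expect_true(all(toupper(substring(w$genome[[1]], v$pos + 1, v$pos + 1)) ==
                    v$ref))
  expect_true(all(v$ref != v$alt))
  # matched covariates: MAF distributions indistinguishable (KS)
  ks <- suppressWarnings(stats::ks.test(v$maf[v$label == "deactivating"],
                                        v$maf[v$label == "neutral"]))
  expect_gt(ks$p.value, 0.05)
  expect_true(all(v$dist_enh == 0L))
  # over-asking errors
  expect_error(simulate_training_variants(w, w$genome, w$config, seed = 1,
                                          n_pos = 1e6L), "mutable")
})

test_that("LD panel has exact block structure and configured trait counts", {
  w <- tiny_world()
  ld <- w$ld
  expect_true(all(ld$ld$r2 == w$config$ld$within_r2))
  blk <- ld$snps$block[match(ld$ld$snpA, ld$snps$snp_id)]
  blk2 <- ld$snps$block[match(ld$ld$snpB, ld$snps$snp_id)]
  expect_true(all(blk == blk2))       # cross-block pairs absent
  # every within-block pair is present
  tb <- table(ld$snps$block)
  expect_equal(nrow(ld$ld), sum(choose(as.integer(tb), 2)))
  expect_equal(as.vector(table(ld$traits$disease_type)[c("immune", "metabolic")]),
               c(30L, 30L))
})

test_that("two-rate evolution masks behave as configured", {
  w <- tiny_world()
  ev <- w$evo
  ch <- w$config$chrom
  expect_true(all(which(ev$diverged[[ch]]) %in% which(ev$alignable[[ch]])))
  expect_true(all(ev$conserved$end <= nchar(w$genome[[ch]])))
  # neutral divergence rate within 3 binomial SDs on non-constrained bases
  constrained <- logical(nchar(w$genome[[ch]]))
  for (i in seq_len(nrow(ev$conserved)))
    constrained[(ev$conserved$start[i] + 1):ev$conserved$end[i]] <- TRUE
  for (i in seq_len(nrow(w$sites)))
    constrained[(w$sites$start[i] + 1):w$sites$end[i]] <- TRUE
  neut <- !constrained & ev$alignable[[ch]]
  p_obs <- sum(ev$diverged[[ch]][neut]) / sum(neut)
  p_exp <- w$config$evolution$neutral_rate
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / sum(neut)))
  # constrained rate zero removes divergence at planted sites
  cfg0 <- tiny_world_config()
  cfg0$evolution$constrained_rate <- 0
  ev0 <- simulate_evolution(w$genome, w, cfg0, seed = 42)
  site_idx <- unlist(mapply(function(s, e) (s + 1L):e, w$sites$start,
                            w$sites$end, SIMPLIFY = FALSE))
  expect_equal(sum(ev0$diverged[[ch]][site_idx]), 0L)
})

test_that("infeasible geometry is rejected before any output", {
  expect_error(generate_world(world_config(
    seed = 1, genome_length = 10000L,
    n_enhancers = c(homotypic = 50L, heterotypic = 50L))),
    "infeasible")
  expect_error(world_config(seed = 1, bogus_field = 2), "unknown")
})
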