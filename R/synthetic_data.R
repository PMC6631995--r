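# Synthetic "world" generator: a genome with planted enhancers of two
# architectures (homotypic clusters of one pioneer-like motif vs heterotypic
# mixtures of several tissue-specific-like motifs), chromatin signal tracks
# elevated over the planted sites, labeled training variants, a block-LD SNP
# panel with trait annotations, and two-rate evolutionary masks. Everything
# is deterministic under the master seed; each artifact consumes its own
# derived sub-seed (see derive_seed) so adding one output never perturbs
# another.

#' Built-in motif set for the synthetic world
#'
#' Eight 8-bp consensus motifs split into a pioneer-like group (planted as
#' homotypic clusters) and a tissue-specific-like group (planted as
#' heterotypic mixtures). `second` gives, per position, the designated
#' second-best base used when a planted copy is degenerate. No motif is the
#' reverse complement of another (asserted in the test suite).
#'
#' @return `data.frame` with columns name, consensus, second, group.
#' @export
default_motifs <- function() {
  consensus <- c("TGTTTGCA", "CATCTGAC", "AGATAAGC",
                 "TGACCTTG", "GGTCACAT", "CTAGCAAG", "GATGCAAT", "ACGTCAGT")
  data.frame(
    name = c("pioneerA", "pioneerB", "pioneerC",
             "tsA", "tsB", "tsC", "tsD", "tsE"),
    consensus = consensus,
    # fixed base rotation guarantees second != consensus at every position
    second = chartr("ACGT", "CGTA", consensus),
    group = c(rep("pioneer", 3), rep("ts", 5)),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic world
#'
#' Returns the default study conditions with any field overridden by name.
#' Defaults: a 5-Mb single-chromosome genome at GC 0.45 with 10% repeat
#' masking in 800-bp blocks; 200 enhancers per architecture of 300-600 bp;
#' homotypic enhancers carry 3-5 copies of one pioneer-like motif,
#' heterotypic enhancers one copy each of 3-5 distinct ts-like motifs, with
#' one second-best-base degeneracy per copy at probability 0.2; three
#' overdispersed count tracks (negative binomial, dispersion 0.3, 5x effect
#' over a background mean of 5 per 10-bp bin): accessibility over all planted
#' sites, a pioneer-factor ChIP analog over homotypic sites, a
#' tissue-specific-factor ChIP analog over heterotypic sites; 500 positive
#' and 500 negative training variants; a 2000 + 400-SNP LD panel in 50-kb
#' blocks at within-block r-squared 0.9 with two disease types of 30
#' trait-tagged SNPs; substitution rates 0.002 (constrained) / 0.01
#' (neutral), 95% alignability.
#'
#' @param seed master seed (mandatory).
#' @param ... overrides of the fields listed above.
#' @return a list of class `"world_config"`.
#' @export
world_config <- function(seed, ...) {
  stopifnot(!missing(seed))
  cfg <- list(
    genome_length = 5e6L,
    chrom = "chr1",
    n_enhancers = c(homotypic = 200L, heterotypic = 200L),
    enh_len_range = c(300L, 600L),
    enh_margin = 1000L,      # bp kept clear of chromosome ends
    enh_gap = 200L,          # minimum gap between enhancers
    motifs = default_motifs(),
    homotypic_copies = 3:5,
    heterotypic_tfs = 3:5,
    degeneracy_prob = 0.2,
    background_gc = 0.45,
    repeat_frac = 0.10,
    repeat_block_len = 800L,
    track_bin = 10L,
    track_background_mean = 5,
    tracks = list(
      list(name = "dnase", targets = "all", effect = 5, dispersion = 0.3),
      list(name = "pioneer_chip", targets = "homotypic", effect = 5,
           dispersion = 0.3),
      list(name = "ts_chip", targets = "heterotypic", effect = 5,
           dispersion = 0.3)),
    n_pos = 500L,
    n_neg = 500L,
    neg_homotypic_frac = 0.5,
    maf_beta = c(1, 3),
    ld = list(n_snps = 2000L, n_snps_enh = 400L, block_length = 50000L,
              within_r2 = 0.9),
    traits = list(disease_types = c(immune = 30L, metabolic = 30L),
                  bias = 0.8, traits_per_type = 3L),
    evolution = list(constrained_rate = 0.002, neutral_rate = 0.01,
                     alignable_frac = 0.95, snp_rate_scale = 0.8,
                     conserved_cover = c(homotypic = 0.5, heterotypic = 0.15),
                     ortholog_frac = 0.3,
                     ortholog_active = c(homotypic = 0.6, heterotypic = 0.3)),
    seed = as.integer(seed)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_fmt("unknown config field: %s", unknown[1])
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "world_config")
}

.validate_world_config <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  w <- max(nchar(cfg$motifs$consensus))
  min_len <- min(cfg$enh_len_range)
  max_sites <- max(max(cfg$homotypic_copies), max(cfg$heterotypic_tfs))
  if (min_len < w * max_sites * 2)
    stop_fmt("enhancer length %d too short for %d sites of width %d",
             min_len, max_sites, w)
  n_tot <- sum(cfg$n_enhancers)
  footprint <- n_tot * (max(cfg$enh_len_range) + cfg$enh_gap) +
    2 * cfg$enh_margin
  if (footprint > cfg$genome_length)
    stop_fmt("infeasible geometry: %d enhancers need %d bp, genome is %d bp",
             n_tot, footprint, cfg$genome_length)
  if (any(nchar(cfg$motifs$consensus) != nchar(cfg$motifs$second)))
    stop_fmt("motif 'second' strings must match consensus width")
  invisible(TRUE)
}

.sample_bases <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# place n non-overlapping intervals of given lengths; error on failure
.place_intervals <- function(lengths, genome_length, margin, gap,
                             max_rounds = 10000L) {
  n <- length(lengths)
  starts <- integer(0); ends <- integer(0); lens_placed <- integer(0)
  order_idx <- order(lengths, decreasing = TRUE)
  res_start <- integer(n); res_end <- integer(n)
  for (i in order_idx) {
    len <- lengths[i]
    placed <- FALSE
    for (r in seq_len(max_rounds)) {
      st <- as.integer(floor(runif(1, margin, genome_length - margin - len)))
      if (!any_overlap(st - gap, st + len + gap, starts, ends)) {
        starts <- c(starts, st); ends <- c(ends, st + len)
        res_start[i] <- st; res_end[i] <- st + len
        placed <- TRUE
        break
      }
    }
    if (!placed) stop_fmt("infeasible geometry: could not place interval %d", i)
  }
  data.frame(start = res_start, end = res_end)
}

# realize one planted copy: consensus with optional one-position
# second-best-base degeneracy; returns list(seq, degenerate)
.realize_copy <- function(consensus, second, degeneracy_prob) {
  if (runif(1) < degeneracy_prob) {
    p <- sample.int(nchar(consensus), 1L)
    s <- consensus
    substr(s, p, p) <- substr(second, p, p)
    list(seq = s, degenerate = TRUE)
  } else list(seq = consensus, degenerate = FALSE)
}

#' Generate the synthetic world
#'
#' Builds the genome, enhancers, truth table, signal tracks, labeled
#' training variants, LD panel and evolutionary tables from one
#' [world_config()]. Byte-identical outputs for identical config and seed.
#'
#' @param config a [world_config()].
#' @return a list of class `"synthetic_world"` with elements `genome`
#'   ([genome()]), `enhancers` (intervals with an `architecture` column),
#'   `sites` (planted-site truth: enh_id, tf, group, chrom, start, end,
#'   strand, seq, degenerate), `tracks` (list of [signal_track()]),
#'   `variants` (labeled training variants), `ld` (panel), `evo`
#'   (masks/tables), and `config`.
#' @export
generate_world <- function(config) {
  .validate_world_config(config)
  cfg <- config
  ## genome background -------------------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  bases <- .sample_bases(cfg$genome_length, cfg$background_gc)
  ## enhancers and planted sites ---------------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  n_h <- cfg$n_enhancers[["homotypic"]]
  n_t <- cfg$n_enhancers[["heterotypic"]]
  n_tot <- n_h + n_t
  lens <- as.integer(floor(runif(n_tot, cfg$enh_len_range[1],
                                 cfg$enh_len_range[2] + 1)))
  pos <- .place_intervals(lens, cfg$genome_length, cfg$enh_margin, cfg$enh_gap)
  arch <- rep(c("homotypic", "heterotypic"), c(n_h, n_t))
  ids <- sprintf("enh%04d", seq_len(n_tot))
  enhancers <- gintervals(cfg$chrom, pos$start, pos$end, "+", ids)
  enhancers$architecture <- arch
  mot <- cfg$motifs
  pio <- mot[mot$group == "pioneer", , drop = FALSE]
  tsm <- mot[mot$group == "ts", , drop = FALSE]
  w <- nchar(mot$consensus[1])
  site_rows <- list()
  for (i in seq_len(n_tot)) {
    L <- lens[i]
    if (arch[i] == "homotypic") {
      m <- pio[sample.int(nrow(pio), 1L), ]
      n_sites <- sample(cfg$homotypic_copies, 1L)
      tfs <- rep(m$name, n_sites)
      cons <- rep(m$consensus, n_sites)
      secs <- rep(m$second, n_sites)
    } else {
      n_sites <- sample(cfg$heterotypic_tfs, 1L)
      pick <- sample.int(nrow(tsm), n_sites)
      tfs <- tsm$name[pick]; cons <- tsm$consensus[pick]; secs <- tsm$second[pick]
    }
    # non-overlapping offsets with >= 2 bp clearance
    repeat {
      offs <- sort(sample.int(L - w + 1L, n_sites) - 1L)
      if (n_sites == 1L || all(diff(offs) >= w + 2L)) break
    }
    for (s in seq_len(n_sites)) {
      rc <- .realize_copy(cons[s], secs[s], cfg$degeneracy_prob)
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "-") revcomp(rc$seq) else rc$seq
      gstart <- pos$start[i] + offs[s]
      bases[(gstart + 1L):(gstart + w)] <- strsplit(planted, "")[[1]]
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        enh_id = ids[i], tf = tfs[s],
        group = if (arch[i] == "homotypic") "pioneer" else "ts",
        chrom = cfg$chrom, start = gstart, end = gstart + w,
        strand = strand, seq = planted, degenerate = rc$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  ## repeat masking outside enhancers ----------------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  target_rep <- floor(cfg$repeat_frac * cfg$genome_length)
  masked <- 0L
  rep_starts <- integer(0); rep_ends <- integer(0)
  guard <- 0L
  while (masked < target_rep && guard < 100000L) {
    guard <- guard + 1L
    st <- as.integer(floor(runif(1, 0, cfg$genome_length - cfg$repeat_block_len)))
    en <- st + cfg$repeat_block_len
    if (any_overlap(st, en, enhancers$start - 10L, enhancers$end + 10L)) next
    if (any_overlap(st, en, rep_starts, rep_ends)) next
    rep_starts <- c(rep_starts, st); rep_ends <- c(rep_ends, en)
    idx <- (st + 1L):en
    bases[idx] <- tolower(bases[idx])
    masked <- masked + cfg$repeat_block_len
  }
  g <- genome(setNames(paste(bases, collapse = ""), cfg$chrom))
  world <- structure(list(genome = g, enhancers = enhancers, sites = sites,
                          config = cfg), class = "synthetic_world")
  ## dependent artifacts ------------------------------------------------
  world$tracks <- simulate_tracks(g, world, cfg, seed = derive_seed(cfg$seed, 4L))
  world$variants <- simulate_training_variants(world, g, cfg,
                                               seed = derive_seed(cfg$seed, 5L))
  world$ld <- simulate_ld_panel(cfg, world, seed = derive_seed(cfg$seed, 6L))
  world$evo <- simulate_evolution(g, world, cfg, seed = derive_seed(cfg$seed, 7L))
  world
}

#' Simulate chromatin signal tracks
#'
#' Per-bin counts drawn from a negative binomial (overdispersed, size =
#' 1/dispersion) whose mean is the background mean except over bins touching
#' the track's target planted sites, where the mean is multiplied by the
#' configured effect. Targets: `"all"` sites, `"homotypic"`-architecture
#' sites, or `"heterotypic"`-architecture sites.
#'
#' @param genome a [genome()].
#' @param world a `"synthetic_world"` (needs `sites`, `enhancers`).
#' @param config the [world_config()].
#' @param seed integer seed.
#' @return list of [signal_track()] objects.
#' @export
simulate_tracks <- function(genome, world, config, seed = derive_seed(config$seed, 4L)) {
  set.seed(seed)
  L <- nchar(genome[[config$chrom]])
  bin <- config$track_bin
  n_bins <- ceiling(L / bin)
  starts <- (seq_len(n_bins) - 1L) * bin
  ends <- pmin(starts + bin, L)
  site_arch <- world$enhancers$architecture[
    match(world$sites$enh_id, world$enhancers$id)]
  out <- list()
  for (trk in config$tracks) {
    sel <- switch(trk$targets,
                  all = rep(TRUE, nrow(world$sites)),
                  homotypic = site_arch == "homotypic",
                  heterotypic = site_arch == "heterotypic",
                  stop_fmt("unknown track target '%s'", trk$targets))
    mu <- rep(config$track_background_mean, n_bins)
    tgt <- world$sites[sel, , drop = FALSE]
    if (nrow(tgt)) {
      for (j in seq_len(nrow(tgt))) {
        b0 <- tgt$start[j] %/% bin
        b1 <- (tgt$end[j] - 1L) %/% bin
        mu[(b0:b1) + 1L] <- config$track_background_mean * trk$effect
      }
    }
    vals <- stats::rnbinom(n_bins, mu = mu, size = 1 / trk$dispersion)
    out[[trk$name]] <- signal_track(trk$name, data.frame(
      chrom = config$chrom, start = starts, end = as.integer(ends),
      value = as.numeric(vals), stringsAsFactors = FALSE))
  }
  out
}

#' Simulate labeled training variants
#'
#' Positive ("deactivating") variants substitute a base of a planted site in
#' a heterotypic-architecture enhancer, where no redundant copy buffers the
#' loss. Negative ("neutral") variants are drawn inside enhancers: a
#' configured fraction at homotypic planted sites (buffered by redundant
#' copies of the same motif) and the rest at non-site enhancer positions.
#' Both classes therefore sit at distance 0 from the nearest enhancer, and
#' both receive a simulated minor-allele frequency from the same Beta
#' distribution, so the matched covariates are exchangeable by construction.
#' Site base positions are sampled without replacement within one call.
#'
#' @param world a `"synthetic_world"`.
#' @param genome a [genome()].
#' @param config the [world_config()].
#' @param seed integer seed.
#' @param n_pos,n_neg override the configured counts.
#' @return `data.frame` with chrom, pos, ref, alt, label
#'   (`deactivating`/`neutral`), site_tf (NA off-site), enh_id, dist_enh, maf.
#' @export
simulate_training_variants <- function(world, genome, config,
                                       seed = derive_seed(config$seed, 5L),
                                       n_pos = config$n_pos,
                                       n_neg = config$n_neg) {
  set.seed(seed)
  arch <- world$enhancers$architecture[match(world$sites$enh_id,
                                             world$enhancers$id)]
  het_sites <- world$sites[arch == "heterotypic", , drop = FALSE]
  hom_sites <- world$sites[arch == "homotypic", , drop = FALSE]
  site_bases <- function(st) {
    if (!nrow(st)) return(data.frame())
    n_b <- st$end - st$start
    data.frame(pos = unlist(mapply(function(s, e) s:(e - 1L), st$start,
                                   st$end, SIMPLIFY = FALSE)),
               tf = rep(st$tf, n_b), enh_id = rep(st$enh_id, n_b),
               stringsAsFactors = FALSE)
  }
  draw_site_variants <- function(pool, n, label) {
    if (n == 0L)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        label = character(), site_tf = character(),
                        enh_id = character(), stringsAsFactors = FALSE))
    if (n > nrow(pool))
      stop_fmt("requested %d %s variants but only %d mutable site bases",
               n, label, nrow(pool))
    pick <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    ref <- toupper(substring(genome[[config$chrom]], pick$pos + 1L,
                             pick$pos + 1L))
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    data.frame(chrom = config$chrom, pos = pick$pos, ref = ref, alt = alt,
               label = label, site_tf = pick$tf, enh_id = pick$enh_id,
               stringsAsFactors = FALSE)
  }
  pos_df <- draw_site_variants(site_bases(het_sites), n_pos, "deactivating")
  n_neg_hom <- round(n_neg * config$neg_homotypic_frac)
  n_neg_bg <- n_neg - n_neg_hom
  neg_hom <- draw_site_variants(site_bases(hom_sites), n_neg_hom, "neutral")
  # background negatives: enhancer positions not inside any planted site
  enh <- world$enhancers
  all_pos <- unlist(mapply(function(s, e) s:(e - 1L), enh$start, enh$end,
                           SIMPLIFY = FALSE))
  all_id <- rep(enh$id, enh$end - enh$start)
  in_site <- rep(FALSE, length(all_pos))
  for (j in seq_len(nrow(world$sites)))
    in_site[all_pos >= world$sites$start[j] & all_pos < world$sites$end[j]] <- TRUE
  bg_pool <- data.frame(pos = all_pos[!in_site], tf = NA_character_,
                        enh_id = all_id[!in_site], stringsAsFactors = FALSE)
  neg_bg <- draw_site_variants(bg_pool, n_neg_bg, "neutral")
  out <- rbind(pos_df, neg_hom, neg_bg)
  out$dist_enh <- 0L
  out$maf <- round(stats::rbeta(nrow(out), config$maf_beta[1],
                                config$maf_beta[2]) / 2, 4)
  rownames(out) <- NULL
  out
}

#' Simulate a block-structured LD panel with trait annotations
#'
#' SNPs are placed uniformly over the genome plus a quota inside enhancers;
#' LD blocks are fixed windows of the configured length, all within-block
#' pairs are recorded at the configured r-squared and cross-block pairs are
#' absent. Trait tags are drawn per disease type with a configurable bias
#' toward one enhancer architecture (immune -> heterotypic, metabolic ->
#' homotypic), emulating trait classes that concentrate in fragile vs stable
#' enhancers.
#'
#' @param config the [world_config()].
#' @param world optional `"synthetic_world"` supplying enhancers for the
#'   in-enhancer SNP quota and trait bias.
#' @param seed integer seed.
#' @return list with `snps` (snp_id, chrom, pos, block), `ld` (snpA, snpB,
#'   r2, dist) and `traits` (snp, trait, disease_type).
#' @export
simulate_ld_panel <- function(config, world = NULL,
                              seed = derive_seed(config$seed, 6L)) {
  set.seed(seed)
  L <- config$genome_length
  pos <- as.integer(floor(runif(config$ld$n_snps, 0, L)))
  if (!is.null(world) && config$ld$n_snps_enh > 0L) {
    enh <- world$enhancers
    widths <- enh$end - enh$start
    pick <- sample.int(nrow(enh), config$ld$n_snps_enh, replace = TRUE,
                       prob = widths)
    off <- floor(runif(config$ld$n_snps_enh) * widths[pick])
    pos <- c(pos, as.integer(enh$start[pick] + off))
  }
  pos <- sort(unique(pos))
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_along(pos)),
                     chrom = config$chrom, pos = pos,
                     block = pos %/% config$ld$block_length,
                     stringsAsFactors = FALSE)
  pairs <- list()
  for (b in split(seq_len(nrow(snps)), snps$block)) {
    if (length(b) < 2L) next
    cmb <- utils::combn(b, 2L)
    pairs[[length(pairs) + 1L]] <- data.frame(
      snpA = snps$snp_id[cmb[1, ]], snpB = snps$snp_id[cmb[2, ]],
      r2 = config$ld$within_r2,
      dist = snps$pos[cmb[2, ]] - snps$pos[cmb[1, ]],
      stringsAsFactors = FALSE)
  }
  ld <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(snpA = character(), snpB = character(), r2 = numeric(),
               dist = integer())
  rownames(ld) <- NULL
  ## trait tags -----------------------------------------------------------
  arch_of_snp <- rep(NA_character_, nrow(snps))
  if (!is.null(world)) {
    enh <- world$enhancers
    for (i in seq_len(nrow(enh))) {
      inside <- snps$pos >= enh$start[i] & snps$pos < enh$end[i]
      arch_of_snp[inside] <- enh$architecture[i]
    }
  }
  type_arch <- c(immune = "heterotypic", metabolic = "homotypic")
  trows <- list()
  for (dtype in names(config$traits$disease_types)) {
    n_tag <- config$traits$disease_types[[dtype]]
    pref <- type_arch[dtype]
    pool_pref <- which(!is.na(arch_of_snp) & arch_of_snp == pref)
    pool_other <- setdiff(seq_len(nrow(snps)), pool_pref)
    n_pref <- min(length(pool_pref), stats::rbinom(1, n_tag, config$traits$bias))
    sel <- c(if (n_pref > 0) sample(pool_pref, n_pref),
             sample(pool_other, n_tag - n_pref))
    trait_names <- sprintf("%s_trait%d", dtype,
                           (seq_len(n_tag) - 1L) %% config$traits$traits_per_type + 1L)
    trows[[length(trows) + 1L]] <- data.frame(
      snp = snps$snp_id[sel], trait = trait_names, disease_type = dtype,
      stringsAsFactors = FALSE)
  }
  traits <- do.call(rbind, trows)
  rownames(traits) <- NULL
  list(snps = snps, ld = ld, traits = traits)
}

#' Simulate two-rate evolutionary masks and ortholog activity
#'
#' Per-base substitution indicators are drawn at the constrained rate over
#' planted sites and conserved elements and at the neutral rate elsewhere;
#' diverged positions are restricted to the alignable mask (a configured
#' fraction of the genome). SNP positions use the same two-rate scheme
#' scaled by `snp_rate_scale`. Conserved elements are centered segments
#' covering a per-architecture fraction of each enhancer (wider for
#' homotypic enhancers). The ortholog table marks a higher active fraction
#' for homotypic-architecture enhancers.
#'
#' @param genome a [genome()].
#' @param world a `"synthetic_world"`.
#' @param config the [world_config()].
#' @param seed integer seed.
#' @return list with `alignable`/`diverged` (per-chrom logical vectors),
#'   `snp_positions` (0-based integer vector per chrom), `conserved`
#'   (interval `data.frame`), `orthologs` (enh_id, architecture,
#'   has_ortholog, ortholog_active).
#' @export
simulate_evolution <- function(genome, world, config,
                               seed = derive_seed(config$seed, 7L)) {
  set.seed(seed)
  ev <- config$evolution
  L <- nchar(genome[[config$chrom]])
  ## conserved elements: centered per-enhancer segments
  enh <- world$enhancers
  cov <- ev$conserved_cover[enh$architecture]
  clen <- pmax(8L, as.integer(round((enh$end - enh$start) * cov)))
  mid <- (enh$start + enh$end) %/% 2L
  cstart <- pmax(enh$start, mid - clen %/% 2L)
  conserved <- gintervals(config$chrom, cstart,
                          pmin(enh$end, cstart + clen),
                          id = paste0("ce_", enh$id))
  constrained <- logical(L)
  for (i in seq_len(nrow(conserved)))
    constrained[(conserved$start[i] + 1L):conserved$end[i]] <- TRUE
  for (i in seq_len(nrow(world$sites)))
    constrained[(world$sites$start[i] + 1L):world$sites$end[i]] <- TRUE
  alignable <- runif(L) < ev$alignable_frac
  rate <- ifelse(constrained, ev$constrained_rate, ev$neutral_rate)
  diverged <- (runif(L) < rate) & alignable
  snp_hit <- runif(L) < rate * ev$snp_rate_scale
  ## orthologs
  act_p <- ev$ortholog_active[enh$architecture]
  has_orth <- runif(nrow(enh)) < ev$ortholog_frac
  orth_active <- has_orth & (runif(nrow(enh)) < act_p)
  orthologs <- data.frame(enh_id = enh$id, architecture = enh$architecture,
                          has_ortholog = has_orth,
                          ortholog_active = orth_active,
                          stringsAsFactors = FALSE)
  list(alignable = setNames(list(alignable), config$chrom),
       diverged = setNames(list(diverged), config$chrom),
       snp_positions = setNames(list(which(snp_hit) - 1L), config$chrom),
       conserved = conserved, orthologs = orthologs)
}

#' Write a synthetic world to a directory
#'
#' Emits genome.fa, enhancers.bed (col4 = id, col5 = architecture),
#' tracks/*.bedgraph, variants.vcf + labels.tsv, ld.tsv, traits.tsv,
#' snps.tsv, divergence.tsv (diverged positions), align.tsv (unalignable
#' positions; every other position is alignable), snp_positions.tsv,
#' conserved.bed, orthologs.tsv and manifest.yaml.
#'
#' @param world a `"synthetic_world"`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  write_fasta(world$genome, file.path(dir, "genome.fa"))
  enh <- world$enhancers
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", enh$chrom, enh$start, enh$end,
                     enh$id, enh$architecture),
             file.path(dir, "enhancers.bed"))
  for (tr in world$tracks)
    write_bedgraph(tr, file.path(dir, "tracks", paste0(tr$name, ".bedgraph")))
  write_vcf_lite(world$variants, file.path(dir, "variants.vcf"))
  data.table::fwrite(world$variants, file.path(dir, "labels.tsv"), sep = "\t")
  data.table::fwrite(world$ld$ld, file.path(dir, "ld.tsv"), sep = "\t")
  data.table::fwrite(world$ld$traits, file.path(dir, "traits.tsv"), sep = "\t")
  data.table::fwrite(world$ld$snps, file.path(dir, "snps.tsv"), sep = "\t")
  ch <- world$config$chrom
  data.table::fwrite(
    data.frame(chrom = ch, pos = which(world$evo$diverged[[ch]]) - 1L, flag = 1L),
    file.path(dir, "divergence.tsv"), sep = "\t")
  data.table::fwrite(
    data.frame(chrom = ch, pos = which(!world$evo$alignable[[ch]]) - 1L, flag = 0L),
    file.path(dir, "align.tsv"), sep = "\t")
  data.table::fwrite(
    data.frame(chrom = ch, pos = world$evo$snp_positions[[ch]]),
    file.path(dir, "snp_positions.tsv"), sep = "\t")
  write_bed(world$evo$conserved, file.path(dir, "conserved.bed"))
  data.table::fwrite(world$evo$orthologs, file.path(dir, "orthologs.tsv"),
                     sep = "\t")
  data.table::fwrite(world$sites, file.path(dir, "sites.tsv"), sep = "\t")
  cfg <- world$config
  cfg$motifs <- NULL
  yaml::write_yaml(list(config = cfg,
                        motifs = as.list(world$config$motifs)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Enhancer sequences of a world
#'
#' @param world a `"synthetic_world"`.
#' @return named character vector (id -> sequence).
#' @export
enhancer_seqs <- function(world) {
  setNames(substring(world$genome[[world$config$chrom]],
                     world$enhancers$start + 1L, world$enhancers$end),
           world$enhancers$id)
}
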