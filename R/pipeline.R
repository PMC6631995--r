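# End-to-end orchestration: simulate -> controls -> vocab -> score ->
# classify -> tfbs -> evo -> gwas -> report, with one config, derived
# seeds per stage and a consolidated report.

#' Pipeline run configuration
#'
#' Bundles the world configuration with every analysis threshold. Defaults
#' are the method's reference values: 5 controls per enhancer at tolerances
#' 0.005 (GC) / 0.01 (repeat), k-mer significance alpha 1e-3
#' (Bonferroni for the top class), k sizes 4/6/8/10/12 with a 100-bp
#' neighborhood, deM FPR 0.01, PSSM calibration at 5 false positives per
#' 10 kb, clusters of at least 3 sites within 1 kb, and LD expansion at
#' r-squared > 0.8 within 500 kb.
#'
#' @param world a [world_config()].
#' @param ... overrides of: n_controls, max_dgc, max_drepeat, alpha,
#'   k_sizes, flank, fpr, n_cal_neg, target_rate, per_bp, min_sites,
#'   max_span, min_distinct, r2_min, max_dist, peak_quantile, calib_len,
#'   stages, write_world_files.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(world, ...) {
  rc <- list(
    world = world,
    n_controls = 5L, max_dgc = 0.005, max_drepeat = 0.01,
    alpha = 1e-3, k_sizes = c(4L, 6L, 8L, 10L, 12L), flank = 100L,
    fpr = 0.01, n_cal_neg = 2000L,
    target_rate = 5, per_bp = 10000, min_sites = 3L, max_span = 1000L,
    min_distinct = NULL,
    r2_min = 0.8, max_dist = 500000, peak_quantile = 0.99,
    calib_len = 100000L,
    stages = c("simulate", "controls", "vocab", "score", "classify",
               "tfbs", "evo", "gwas", "report"),
    write_world_files = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(rc))
  if (length(unknown)) stop_fmt("unknown run_config field: %s", unknown[1])
  for (nm in names(dots)) rc[[nm]] <- dots[[nm]]
  if (is.null(rc$min_distinct)) rc$min_distinct <- rc$min_sites
  structure(rc, class = "run_config")
}

.stage_msg <- function(stage, seed, t0) {
  message(sprintf("[%s] stage=%s seed=%d elapsed=%.1fs",
                  format(Sys.time(), "%H:%M:%S"), stage, seed,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic world and
#' writes every stage's tabular output plus a consolidated report to
#' `out_dir`. Fully deterministic under the world config's master seed.
#'
#' @param rc a [run_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) a list with the world, controls, vocabularies,
#'   schema, weights, threshold, calls, classed enhancers, tfbs / evo /
#'   gwas results and the report.
#' @export
run_pipeline <- function(rc, out_dir) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  seed <- rc$world$seed
  res <- list(config = rc)
  on_stage <- function(s) s %in% rc$stages

  ## simulate -----------------------------------------------------------
  .stage_msg("simulate", seed, t0)
  world <- generate_world(rc$world)
  res$world <- world
  if (on_stage("simulate") && rc$write_world_files)
    write_world(world, file.path(out_dir, "world"))
  g <- world$genome
  enh <- world$enhancers
  eseqs <- enhancer_seqs(world)

  ## controls -----------------------------------------------------------
  if (on_stage("controls")) {
    .stage_msg("controls", derive_seed(seed, 10L), t0)
    controls <- sample_control_set(enh, g, n = rc$n_controls,
                                   max_dgc = rc$max_dgc,
                                   max_drepeat = rc$max_drepeat,
                                   seed = derive_seed(seed, 10L))
    res$controls <- controls
    data.table::fwrite(controls, file.path(out_dir, "controls.tsv"),
                       sep = "\t")
  }

  ## vocab ---------------------------------------------------------------
  if (on_stage("vocab")) {
    .stage_msg("vocab", seed, t0)
    vocabs <- build_vocabularies(eseqs, control_seq_list(res$controls), enh,
                                 world$tracks, k_sizes = rc$k_sizes,
                                 alpha = rc$alpha,
                                 peak_quantile = rc$peak_quantile)
    res$vocabs <- vocabs
    write_vocab_tsv(vocabs, file.path(out_dir, "vocab.tsv"))
  }

  ## score ---------------------------------------------------------------
  if (on_stage("score")) {
    .stage_msg("score", derive_seed(seed, 11L), t0)
    schema <- feature_schema(tracks = names(world$tracks),
                             k_sizes = rc$k_sizes, flank_window = rc$flank)
    res$schema <- schema
    X <- extract_features_batch(g, world$variants, res$vocabs, schema)
    weights <- fit_weights(X, world$variants$label, schema,
                           seed = derive_seed(seed, 11L))
    res$weights <- weights
    write_weights_tsv(weights, file.path(out_dir, "weights.tsv"))
    cal_neg <- simulate_training_variants(world, g, rc$world,
                                          seed = derive_seed(seed, 12L),
                                          n_pos = 0L, n_neg = rc$n_cal_neg)
    Xn <- extract_features_batch(g, cal_neg, res$vocabs, schema)
    neg_scores <- score_and_decompose(Xn, weights)$score
    threshold <- calibrate_fpr_threshold(neg_scores, rc$fpr)
    res$threshold <- threshold
    calls <- call_demps(g, enh, res$vocabs, schema, weights, threshold)
    res$calls <- calls
    data.table::fwrite(calls$calls, file.path(out_dir, "dem_calls.tsv"),
                       sep = "\t")
    if (nrow(calls$demps))
      writeLines(sprintf("%s\t%d\t%d\t%s", calls$demps$chrom,
                         calls$demps$pos, calls$demps$pos + 1L,
                         calls$demps$enh_id),
                 file.path(out_dir, "demps.bed"))
    else file.create(file.path(out_dir, "demps.bed"))
  }

  ## classify ------------------------------------------------------------
  if (on_stage("classify")) {
    .stage_msg("classify", seed, t0)
    classed <- partition_quintiles(demp_density(enh, res$calls$demps))
    res$classes <- classed
    data.table::fwrite(
      classed[, c("id", "chrom", "start", "end", "architecture",
                  "demp_count", "density", "class")],
      file.path(out_dir, "classes.tsv"), sep = "\t")
    res$class_summary <- class_summary(classed)
  }

  ## tfbs ----------------------------------------------------------------
  if (on_stage("tfbs")) {
    .stage_msg("tfbs", derive_seed(seed, 13L), t0)
    res$tfbs <- .tfbs_stage(rc, world, res, out_dir)
  }

  ## evo -----------------------------------------------------------------
  if (on_stage("evo")) {
    .stage_msg("evo", seed, t0)
    res$evo <- .evo_stage(rc, world, res, out_dir)
  }

  ## gwas ----------------------------------------------------------------
  if (on_stage("gwas")) {
    .stage_msg("gwas", seed, t0)
    res$gwas <- .gwas_stage(rc, world, res, out_dir)
  }

  ## report --------------------------------------------------------------
  if (on_stage("report")) {
    .stage_msg("report", seed, t0)
    res$report <- write_report(res, out_dir)
  }
  invisible(res)
}

# TFBS stage: calibrate PSSMs on random background, scan enhancers and
# controls, per-class enrichment, site fragility, cluster flags, profiles.
.tfbs_stage <- function(rc, world, res, out_dir) {
  cfg <- rc$world
  set.seed(derive_seed(cfg$seed, 13L))
  bg <- paste(.sample_bases(rc$calib_len, cfg$background_gc), collapse = "")
  pssms <- lapply(seq_len(nrow(cfg$motifs)), function(i)
    calibrate_pssm_threshold(
      pssm_from_consensus(cfg$motifs$name[i], cfg$motifs$consensus[i],
                          cfg$motifs$second[i]),
      bg, target_rate = rc$target_rate, per_bp = rc$per_bp))
  names(pssms) <- cfg$motifs$name
  eseqs <- enhancer_seqs(world)
  enh <- res$classes %||% world$enhancers
  scan_set <- function(seqs, ids) {
    out <- list()
    for (i in seq_along(seqs)) {
      for (p in pssms) {
        h <- scan_pssm(seqs[[i]], p, offset = 0L, chrom = ids[i])
        if (nrow(h)) { h$enh_id <- ids[i]; out[[length(out) + 1L]] <- h }
      }
    }
    if (!length(out)) return(data.frame())
    do.call(rbind, out)
  }
  hits <- scan_set(eseqs, names(eseqs))
  # hit coordinates are enhancer-local (chrom = enhancer id); lift to genome
  if (nrow(hits)) {
    off <- world$enhancers$start[match(hits$enh_id, world$enhancers$id)]
    hits$chrom <- world$enhancers$chrom[match(hits$enh_id,
                                              world$enhancers$id)]
    hits$start <- hits$start + off
    hits$end <- hits$end + off
  }
  ctrl <- res$controls
  ctrl_hits <- scan_set(ctrl$seq, sprintf("ctrl%05d", seq_len(nrow(ctrl))))
  nonrep_len <- function(seqs)
    sum(nchar(seqs)) - sum(stringi::stri_count_regex(seqs, "[acgtn]"))
  ## per-class, per-TF enrichment and fragility
  classes <- c("fragile", "stable")
  demps <- res$calls$demps
  enr_rows <- list()
  for (cl in classes) {
    ids <- enh$id[enh$class == cl]
    ctl_idx <- ctrl$id %in% ids
    len_e <- nonrep_len(eseqs[ids])
    len_c <- nonrep_len(ctrl$seq[ctl_idx])
    ctrl_ids <- sprintf("ctrl%05d", which(ctl_idx))
    for (tf in names(pssms)) {
      he <- hits[hits$enh_id %in% ids & hits$tf == tf, , drop = FALSE]
      hc <- ctrl_hits[ctrl_hits$enh_id %in% ctrl_ids &
                        ctrl_hits$tf == tf, , drop = FALSE]
      enr_rows[[length(enr_rows) + 1L]] <- data.frame(
        class = cl, tf = tf, n_hits = nrow(he), n_ctrl_hits = nrow(hc),
        enrichment = tfbs_enrichment(nrow(he), nrow(hc), len_e, len_c),
        frac_with_demp = fraction_sites_with_demp(he, demps),
        stringsAsFactors = FALSE)
    }
  }
  enrichment <- do.call(rbind, enr_rows)
  data.table::fwrite(enrichment, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t")
  ## cluster flags per enhancer
  flags <- enhancer_cluster_flags(hits, rc$min_sites, rc$max_span,
                                  rc$min_distinct)
  flags$architecture <- world$enhancers$architecture[
    match(flags$enh_id, world$enhancers$id)]
  flags$class <- enh$class[match(flags$enh_id, enh$id)]
  data.table::fwrite(flags, file.path(out_dir, "clusters.tsv"), sep = "\t")
  ## deMP motif profiles
  profiles <- lapply(names(pssms), function(tf)
    demp_motif_profile(hits[hits$tf == tf, , drop = FALSE], demps,
                       pssms[[tf]]$width))
  names(profiles) <- names(pssms)
  list(pssms = pssms, hits = hits, ctrl_hits = ctrl_hits,
       enrichment = enrichment, flags = flags, profiles = profiles)
}

# Evolutionary statistics per class and architecture.
.evo_stage <- function(rc, world, res, out_dir) {
  enh <- res$classes %||% world$enhancers
  evo <- world$evo
  grp_stats <- function(sel, label) {
    iv <- enh[sel, , drop = FALSE]
    data.frame(group = label,
               n = nrow(iv),
               divergence = divergence_fraction(iv, evo, world$genome),
               snp_fraction = snp_fraction(iv, evo$snp_positions),
               stringsAsFactors = FALSE)
  }
  rows <- list(grp_stats(rep(TRUE, nrow(enh)), "all"))
  for (cl in c("fragile", "regular", "stable"))
    if ("class" %in% names(enh))
      rows[[length(rows) + 1L]] <- grp_stats(enh$class == cl, cl)
  for (ar in c("homotypic", "heterotypic"))
    rows[[length(rows) + 1L]] <- grp_stats(enh$architecture == ar,
                                           paste0("arch_", ar))
  report <- do.call(rbind, rows)
  cons <- conserved_fraction(enh, evo$conserved, world$genome,
                             group_col = if ("class" %in% names(enh))
                               "class" else "architecture",
                             groups = if ("class" %in% names(enh))
                               c("stable", "fragile") else
                                 c("homotypic", "heterotypic"))
  orth <- evo$orthologs
  if ("class" %in% names(enh)) {
    orth$class <- enh$class[match(orth$enh_id, enh$id)]
    orth_test <- ortholog_activity_test(orth, "class",
                                        c("stable", "fragile"))
  } else {
    orth_test <- ortholog_activity_test(orth, "architecture",
                                        c("homotypic", "heterotypic"))
  }
  data.table::fwrite(report, file.path(out_dir, "evo_report.tsv"),
                     sep = "\t")
  list(report = report, conserved = cons, ortholog_test = orth_test)
}

# GWAS stage: class tag SNPs, LD expansion, disease-type enrichment.
.gwas_stage <- function(rc, world, res, out_dir) {
  enh <- res$classes %||% world$enhancers
  ld <- world$ld
  use_class <- "class" %in% names(enh)
  sel_a <- if (use_class) enh$class == "stable" else
    enh$architecture == "homotypic"
  sel_b <- if (use_class) enh$class == "fragile" else
    enh$architecture == "heterotypic"
  tags_a <- snps_in_intervals(ld$snps, enh[sel_a, , drop = FALSE])
  tags_b <- snps_in_intervals(ld$snps, enh[sel_b, , drop = FALSE])
  set_a <- ld_expand(tags_a, ld$ld, rc$r2_min, rc$max_dist)
  set_b <- ld_expand(tags_b, ld$ld, rc$r2_min, rc$max_dist)
  disease_sets <- lapply(split(ld$traits$snp, ld$traits$disease_type),
                         function(s) ld_expand(unique(s), ld$ld, rc$r2_min,
                                               rc$max_dist))
  enr <- disease_type_enrichment(set_a, set_b, disease_sets)
  names(enr)[names(enr) == "neglog10p_a"] <-
    if (use_class) "neglog10p_stable" else "neglog10p_homotypic"
  names(enr)[names(enr) == "neglog10p_b"] <-
    if (use_class) "neglog10p_fragile" else "neglog10p_heterotypic"
  data.table::fwrite(enr, file.path(out_dir, "gwas_enrichment.tsv"),
                     sep = "\t")
  list(snps_a = set_a, snps_b = set_b, enrichment = enr)
}

#' Write the weight set to TSV
#'
#' One row per (k, track, signature) weight plus one intercept row.
#'
#' @param weights a `"weight_set"`.
#' @param path output path.
#' @export
write_weights_tsv <- function(weights, path) {
  nm <- names(weights$weights)
  parts <- stringi::stri_match_first_regex(nm, "^(delta|s)\\.k(\\d+)\\.(.+)$")
  df <- data.frame(k = as.integer(parts[, 3]), track = parts[, 4],
                   signature = ifelse(parts[, 2] == "delta", "delta", "s"),
                   weight = unname(weights$weights),
                   stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(k = NA_integer_, track = "intercept",
                             signature = "intercept",
                             weight = weights$intercept))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a weight set from TSV
#'
#' @param path TSV written by [write_weights_tsv()].
#' @param schema the [feature_schema()] giving the layout.
#' @return a `"weight_set"`.
#' @export
read_weights_tsv <- function(path, schema) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  b <- df$weight[df$signature == "intercept"]
  df <- df[df$signature != "intercept", , drop = FALSE]
  nm <- sprintf("%s.k%d.%s", ifelse(df$signature == "delta", "delta", "s"),
                df$k, df$track)
  w <- setNames(df$weight, nm)[feature_names(schema)]
  if (anyNA(w)) stop_fmt("weight table does not cover the schema layout")
  structure(list(weights = w, intercept = b), class = "weight_set")
}

#' Write the consolidated run report
#'
#' One row per metric, written both as TSV and JSON (value-for-value
#' identical). Metrics cover per-class deMP density, per-TF enrichment and
#' site fragility, cluster-usage rates, divergence fractions and
#' disease-type enrichment.
#'
#' @param res result list from [run_pipeline()].
#' @param out_dir run directory.
#' @return the report `data.frame`, invisibly.
#' @export
write_report <- function(res, out_dir) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                             value = as.numeric(value),
                                             stringsAsFactors = FALSE)
  if (!is.null(res$class_summary)) {
    for (i in seq_len(nrow(res$class_summary))) {
      add(paste0("mean_demp_density.", res$class_summary$class[i]),
          res$class_summary$mean_density[i])
      add(paste0("n_enhancers.", res$class_summary$class[i]),
          res$class_summary$n[i])
    }
  }
  if (!is.null(res$weights)) add("cv_auc", res$weights$cv_auc)
  if (!is.null(res$threshold)) add("dem_threshold", res$threshold)
  if (!is.null(res$calls)) add("n_demps", nrow(res$calls$demps))
  if (!is.null(res$tfbs)) {
    e <- res$tfbs$enrichment
    for (i in seq_len(nrow(e))) {
      add(sprintf("tfbs_enrichment.%s.%s", e$class[i], e$tf[i]),
          e$enrichment[i])
      add(sprintf("frac_sites_with_demp.%s.%s", e$class[i], e$tf[i]),
          e$frac_with_demp[i])
    }
    fl <- res$tfbs$flags
    for (ar in unique(fl$architecture)) {
      add(paste0("has_homotypic_rate.arch_", ar),
          mean(fl$has_homotypic[fl$architecture == ar]))
      add(paste0("has_heterotypic_rate.arch_", ar),
          mean(fl$has_heterotypic[fl$architecture == ar]))
    }
  }
  if (!is.null(res$evo)) {
    ev <- res$evo$report
    for (i in seq_len(nrow(ev))) {
      add(paste0("divergence.", ev$group[i]), ev$divergence[i])
      add(paste0("snp_fraction.", ev$group[i]), ev$snp_fraction[i])
    }
    add("ortholog_test_p", res$evo$ortholog_test$p_value)
  }
  if (!is.null(res$gwas)) {
    ge <- res$gwas$enrichment
    val_cols <- setdiff(names(ge), "disease_type")
    for (i in seq_len(nrow(ge)))
      for (vc in val_cols)
        add(sprintf("gwas.%s.%s", ge$disease_type[i], vc), ge[[vc]][i])
  }
  report <- do.call(rbind, rows)
  data.table::fwrite(report, file.path(out_dir, "report.tsv"), sep = "\t")
  jsonlite::write_json(setNames(as.list(report$value), report$metric),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
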