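# Evolutionary-constraint statistics (divergence, SNP density, conserved-
# element overlap, ortholog activity) and GWAS disease-type enrichment via
# one-round LD expansion and upper-tail hypergeometric tests.

#' Divergence fraction of an interval set
#'
#' Fraction of alignable, non-repeat-masked positions inside the intervals
#' that differ from the outgroup genome. Repeat-masked positions are
#' excluded from numerator and denominator.
#'
#' @param intervals interval `data.frame`.
#' @param masks list with per-chrom logical vectors `alignable` and
#'   `diverged` (as from [simulate_evolution()]).
#' @param genome optional [genome()]; when supplied, repeat-masked
#'   (lowercase) positions are excluded.
#' @return fraction, or NA with a warning when nothing is alignable.
#' @export
divergence_fraction <- function(intervals, masks, genome = NULL) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    idx <- (intervals$start[i] + 1L):intervals$end[i]
    ok <- masks$alignable[[ch]][idx]
    if (!is.null(genome)) {
      bases <- strsplit(substring(genome[[ch]], intervals$start[i] + 1L,
                                  intervals$end[i]), "")[[1]]
      ok <- ok & !(bases %in% c("a", "c", "g", "t", "n"))
    }
    den <- den + sum(ok)
    num <- num + sum(masks$diverged[[ch]][idx] & ok)
  }
  if (den == 0L) {
    warn_fmt("no alignable positions in interval set")
    return(NA_real_)
  }
  num / den
}

#' SNP fraction of an interval set
#'
#' Fraction of interval positions carrying a SNP.
#'
#' @param intervals interval `data.frame`.
#' @param snp_positions per-chrom list of 0-based SNP positions.
#' @return fraction.
#' @export
snp_fraction <- function(intervals, snp_positions) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[i]
    sp <- snp_positions[[ch]] %||% integer(0)
    num <- num + sum(sp >= intervals$start[i] & sp < intervals$end[i])
    den <- den + (intervals$end[i] - intervals$start[i])
  }
  if (den == 0L) return(NA_real_)
  num / den
}

#' Conserved-element coverage of enhancers and group comparison
#'
#' Per enhancer, the fraction of its non-repetitive positions covered by
#' conserved elements; two groups are compared with a rank-sum
#' (Mann-Whitney-Wilcoxon) test.
#'
#' @param enhancers interval `data.frame` with ids (optionally a `class` or
#'   `architecture` column named by `group_col`).
#' @param conserved conserved-element interval `data.frame`.
#' @param genome a [genome()] (repeat-masked positions excluded).
#' @param group_col optional column of `enhancers` defining two groups to
#'   compare.
#' @param groups length-2 character vector naming the groups.
#' @return list with `per_enhancer` (id, fraction) and, when groups are
#'   given, `test` (wilcox.test result) and `group_medians`.
#' @export
conserved_fraction <- function(enhancers, conserved, genome,
                               group_col = NULL, groups = NULL) {
  frac <- numeric(nrow(enhancers))
  for (i in seq_len(nrow(enhancers))) {
    ch <- enhancers$chrom[i]
    st <- enhancers$start[i]; en <- enhancers$end[i]
    bases <- strsplit(substring(genome[[ch]], st + 1L, en), "")[[1]]
    nonrep <- !(bases %in% c("a", "c", "g", "t", "n"))
    if (!any(nonrep)) {
      warn_fmt("enhancer %s entirely repeat-masked", enhancers$id[i])
      frac[i] <- NA_real_
      next
    }
    cov <- logical(en - st)
    cc <- conserved[conserved$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(cc))) {
      a <- max(st, cc$start[j]); b <- min(en, cc$end[j])
      if (b > a) cov[(a - st + 1L):(b - st)] <- TRUE
    }
    frac[i] <- sum(cov & nonrep) / sum(nonrep)
  }
  out <- list(per_enhancer = data.frame(id = enhancers$id, fraction = frac,
                                        stringsAsFactors = FALSE))
  if (!is.null(group_col)) {
    g <- enhancers[[group_col]]
    x <- frac[g == groups[1]]; y <- frac[g == groups[2]]
    out$test <- stats::wilcox.test(x, y)
    out$group_medians <- setNames(c(stats::median(x, na.rm = TRUE),
                                    stats::median(y, na.rm = TRUE)), groups)
  }
  out
}

#' Ortholog activity contrast between enhancer classes
#'
#' Among enhancers with orthologs, the active fraction per class and a
#' two-sided Fisher exact test of the 2x2 (class x ortholog-active) table
#' for the two named classes.
#'
#' @param ortholog_table `data.frame` with columns enh_id, class (or
#'   architecture), has_ortholog, ortholog_active.
#' @param class_col column holding the class labels.
#' @param classes length-2 character vector of classes to contrast.
#' @return list with `fractions` (per class) and `p_value`.
#' @export
ortholog_activity_test <- function(ortholog_table, class_col = "class",
                                   classes = c("stable", "fragile")) {
  tab <- ortholog_table[ortholog_table$has_ortholog, , drop = FALSE]
  counts <- lapply(classes, function(cl) {
    t2 <- tab[tab[[class_col]] == cl, , drop = FALSE]
    if (!nrow(t2)) stop_fmt("class '%s' has no enhancers with orthologs", cl)
    c(active = sum(t2$ortholog_active), total = nrow(t2))
  })
  m <- matrix(c(counts[[1]]["active"],
                counts[[1]]["total"] - counts[[1]]["active"],
                counts[[2]]["active"],
                counts[[2]]["total"] - counts[[2]]["active"]),
              nrow = 2, byrow = TRUE)
  list(fractions = setNames(vapply(counts, function(x)
    x["active"] / x["total"], 0), classes),
    p_value = stats::fisher.test(m)$p.value)
}

#' Expand tag SNPs by linkage disequilibrium
#'
#' One-round expansion: the tags plus every partner with `r2 > r2_min`
#' (strict) and distance at most `max_dist`. The LD table is treated as
#' symmetric.
#'
#' @param tag_snps character vector of SNP ids.
#' @param ld_table `data.frame` with snpA, snpB, r2, dist.
#' @param r2_min lower r-squared bound, strict (default 0.8).
#' @param max_dist maximum distance in bp (default 500000).
#' @return deduplicated character vector of SNP ids.
#' @export
ld_expand <- function(tag_snps, ld_table, r2_min = 0.8, max_dist = 500000) {
  keep <- ld_table$r2 > r2_min & ld_table$dist <= max_dist
  lt <- ld_table[keep, , drop = FALSE]
  partners <- c(lt$snpB[lt$snpA %in% tag_snps],
                lt$snpA[lt$snpB %in% tag_snps])
  sort(unique(c(tag_snps, partners)))
}

#' Disease-type enrichment between two SNP sets
#'
#' For the A-vs-B direction, the universe is the union of the two sets, the
#' draw is set A, the successes are the disease SNPs in the universe, and
#' the upper-tail hypergeometric p-value of the observed disease SNPs in A
#' is reported as -log10 p. The B-vs-A direction is computed symmetrically.
#'
#' @param snps_a,snps_b character vectors (e.g. LD-expanded SNPs of stable
#'   and fragile enhancers).
#' @param disease_sets named list disease type -> character vector of SNPs.
#' @return `data.frame` with disease_type, neglog10p_a, neglog10p_b.
#' @export
disease_type_enrichment <- function(snps_a, snps_b, disease_sets) {
  universe <- union(snps_a, snps_b)
  if (!length(universe)) stop_fmt("empty SNP universe")
  one <- function(draw, disease) {
    succ <- intersect(disease, universe)
    obs <- length(intersect(disease, draw))
    p <- hyper_upper(obs, length(succ), length(universe), length(draw))
    -log10(max(p, .Machine$double.xmin))
  }
  do.call(rbind, lapply(names(disease_sets), function(dt) {
    data.frame(disease_type = dt,
               neglog10p_a = one(snps_a, disease_sets[[dt]]),
               neglog10p_b = one(snps_b, disease_sets[[dt]]),
               stringsAsFactors = FALSE)
  }))
}

#' SNPs overlapping an interval set
#'
#' @param snps `data.frame` with snp_id, chrom, pos.
#' @param intervals interval `data.frame`.
#' @return character vector of snp ids.
#' @export
snps_in_intervals <- function(snps, intervals) {
  hit <- rep(FALSE, nrow(snps))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (snps$chrom == intervals$chrom[i] &
                    snps$pos >= intervals$start[i] &
                    snps$pos < intervals$end[i])
  }
  snps$snp_id[hit]
}
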