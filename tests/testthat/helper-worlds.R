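# Shared fixtures, built in code. The tiny world keeps unit tests fast;
# it is memoised so several test files can reuse one build.

.fixture_env <- new.env(parent = emptyenv())

tiny_world_config <- function(seed = 7L, ...) {
  world_config(
    seed = seed,
    genome_length = 600000L,
    n_enhancers = c(homotypic = 30L, heterotypic = 30L),
    n_pos = 150L, n_neg = 150L,
    ld = list(n_snps = 400L, n_snps_enh = 120L, block_length = 50000L,
              within_r2 = 0.9),
    ...
  )
}

tiny_world <- function() {
  if (is.null(.fixture_env$world))
    .fixture_env$world <- generate_world(tiny_world_config())
  .fixture_env$world
}

tiny_controls <- function() {
  if (is.null(.fixture_env$controls))
    .fixture_env$controls <- sample_control_set(tiny_world()$enhancers,
                                                tiny_world()$genome,
                                                seed = 3L)
  .fixture_env$controls
}

tiny_vocabs <- function() {
  if (is.null(.fixture_env$vocabs)) {
    w <- tiny_world()
    .fixture_env$vocabs <- build_vocabularies(
      enhancer_seqs(w), control_seq_list(tiny_controls()), w$enhancers,
      w$tracks)
  }
  .fixture_env$vocabs
}

# random uppercase sequence helper
rand_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# brute-force reverse complement (independent of the package's revcomp)
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", a = "t", c = "g", g = "c",
           t = "a", N = "N", n = "n")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}
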