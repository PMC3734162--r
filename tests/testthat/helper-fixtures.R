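# Shared in-code fixtures. All data are generated programmatically.

tiny_matrix <- function(nf = 3, ns = 4, prefix = "f", seed = 11) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(nf * ns), nf, ns),
                    feature_ids = paste0(prefix, seq_len(nf)),
                    sample_ids = paste0("S", seq_len(ns)))
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A small but non-degenerate fitted mixture shared by several tests.
quick_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sim <- simulate_scores(sim_config(n_pairs = 1200, seed = 99))
      memo <<- mq_mixture(sim$mq, sim$sigma2)
    }
    memo
  }
})

# Full small pipeline on synthetic two-platform data; returns scores + fit.
quick_pipeline <- function(seed = 3, n_pairs = 120, n_samples = 40,
                           n_boot = 60) {
  cfg <- sim_config(n_pairs = n_pairs, n_samples = n_samples, seed = seed)
  sim <- simulate_two_platform_data(cfg)
  maps <- simulate_methods(sim$true_map, cfg$method_specs, seed = seed + 10)
  pairs <- pool_pairs(maps)
  merged <- merge_by_sample(sim$primary, sim$secondary, pairs)
  scores <- suppressMessages(
    score_all_pairs(merged, n_boot = n_boot, master_seed = seed))
  list(sim = sim, maps = maps, pairs = pairs, merged = merged,
       scores = scores)
}
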