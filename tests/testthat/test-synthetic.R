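test_that("score-level simulation honours the mixture and its labels", {
  # degenerate setting: every pair coupled, no variance anywhere
  cfg0 <- sim_config(n_pairs = 50, group_probs = c(1, 0, 0), v_plus = 0,
                     sigma2_range = c(0, 0), seed = 2)
  sim0 <- simulate_scores(cfg0)
  expect_true(all(sim0$mq == cfg0$psi_plus))
  expect_true(all(sim0$group == "+"))

  # label frequencies within 3 binomial SEs at n = 5000
  cfg <- sim_config(n_pairs = 5000, seed = 6)
  sim <- simulate_scores(cfg)
  p_hat <- mean(sim$group == "+")
  se <- sqrt(0.4 * 0.6 / 5000)
  expect_lt(abs(p_hat - 0.4), 3 * se)
  expect_true(all(sim$sigma2 >= cfg$sigma2_range[1] &
                    sim$sigma2 <= cfg$sigma2_range[2]))

  # determinism
  expect_identical(sim, simulate_scores(cfg))
})

test_that("two-platform data couple, decouple and rewire as labelled", {
  # coupling without nuisance correlation is calibrated to the target
  cfg <- sim_config(n_pairs = 60, n_samples = 500,
                    coupled_corr_mean = 0.8, coupled_corr_sd = 0,
                    background_corr_sd = 0, noise_model = "gaussian",
                    group_probs = c(0.5, 0, 0.5), seed = 3)
  sim <- simulate_two_platform_data(cfg)
  band <- 4 * (1 - 0.8^2) / sqrt(500 - 3)
  for (i in which(sim$true_map$group == "+")) {
    r <- cor(sim$primary[sim$true_map$primary_id[i], ],
             sim$secondary[sim$true_map$secondary_id[i], ])
    expect_lt(abs(r - 0.8), band)
  }
  # mis-mapped pairs are uncorrelated with their listed partner ...
  x_rows <- which(sim$true_map$group == "x")
  rx <- vapply(x_rows, function(i) {
    cor(sim$primary[sim$true_map$primary_id[i], ],
        sim$secondary[sim$true_map$secondary_id[i], ])
  }, numeric(1))
  expect_true(all(abs(rx) < 4 / sqrt(500)))
  # ... yet keep realistic (non-degenerate) marginal spread
  expect_true(all(apply(sim$secondary[sim$true_map$secondary_id[x_rows], ],
                        1, sd) > 0.5))

  # matrices round-trip through the readers bit-identically
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$primary, path)
  expect_equal(read_expression_matrix(path), sim$primary, tolerance = 1e-12)

  # count link yields nonnegative integers
  simc <- simulate_two_platform_data(sim_config(n_pairs = 30, n_samples = 20,
                                                seed = 4))
  expect_true(all(simc$primary >= 0 & simc$primary == round(simc$primary)))
})

test_that("synthetic mapping methods hit their specified correctness rates", {
  cfg <- sim_config(n_pairs = 2000, seed = 7)
  set.seed(cfg$seed)
  g <- sample(c("+", "0", "x"), 2000, TRUE, cfg$group_probs)
  tm <- data.frame(primary_id = sprintf("p%d", 1:2000),
                   secondary_id = sprintf("s%d", 1:2000), group = g,
                   stringsAsFactors = FALSE)
  maps <- simulate_methods(tm, list(
    list(name = "pure", n_pairs = 400, frac_correct = 1.0),
    list(name = "mixed", n_pairs = 400, frac_correct = 0.6)), seed = 8)
  gg <- g[match(maps$pure$primary_id, tm$primary_id)]
  expect_true(all(gg %in% c("+", "0")))
  gm <- g[match(maps$mixed$primary_id, tm$primary_id)]
  expect_equal(mean(gm %in% c("+", "0")), 0.6, tolerance = 0.01)
  expect_identical(nrow(maps$mixed), 400L)
  expect_error(simulate_methods(tm, list(list(name = "a", n_pairs = 1,
                                              frac_correct = 1),
                                         list(name = "a", n_pairs = 1,
                                              frac_correct = 1))),
               "distinct")
})

test_that("event tables conserve genuine counts and mark noise by low scores", {
  cfg <- sim_config(n_pairs = 40, n_samples = 15, seed = 9)
  ev0 <- simulate_event_table(cfg, noise_fraction = 0)
  agg <- aggregate_events(ev0$events, proteins = rownames(ev0$true_counts),
                          samples = colnames(ev0$true_counts))
  expect_equal(agg, ev0$true_counts)

  ev <- simulate_event_table(cfg, noise_fraction = 0.3)
  n_noise <- nrow(ev$events) - sum(ev$true_counts)
  expect_equal(n_noise / nrow(ev$events), 0.3, tolerance = 0.01)
  # noise events sit in the low-score region of both quality measures
  ord1 <- sort(ev$events$score_1)
  expect_gt(mean(ev$events$score_1 > ord1[ceiling(0.4 * nrow(ev$events))]),
            0.55)
  # determinism
  ev2 <- simulate_event_table(cfg, noise_fraction = 0.3)
  expect_identical(ev$events, ev2$events)
})

test_that("the fixture workspace materializes every pipeline input", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_pairs = 25, n_samples = 12, seed = 10,
                    method_specs = list(
                      list(name = "A", n_pairs = 15, frac_correct = 0.6),
                      list(name = "B", n_pairs = 15, frac_correct = 0.4)))
  make_fixture_workspace(dir, cfg)
  expect_true(all(file.exists(file.path(dir,
    c("primary.tsv", "secondary.tsv", "truth.tsv", "verdicts.tsv",
      "events.tsv", "sim_config.yaml", "maps/A.tsv", "maps/B.tsv")))))
  m <- read_expression_matrix(file.path(dir, "primary.tsv"))
  expect_identical(dim(m), c(25L, 12L))
  v <- read_filter_verdicts(file.path(dir, "verdicts.tsv"))
  expect_true(is.logical(v$strict))
})
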