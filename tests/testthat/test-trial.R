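test_that("trial configuration validates its inputs", {
  conn <- test_connectome(seed = 1)
  expect_error(trial_config(conn, n_runs = 1), "n_runs")
  expect_error(trial_config(conn, metrics = "entropy"), "unknown")
  cfg <- trial_config(conn, n_runs = 2, n_cycles = 3)
  expect_s3_class(cfg, "trial_config")
})

test_that("per-cycle t-tests match a hand-computed Welch statistic", {
  x <- c(1.0, 1.2, 0.9)
  y <- c(1.6, 1.5, 1.9)
  cond <- fake_metrics("a", 1, runs = 3)
  cond$value <- x
  ctrl <- fake_metrics("control", 1, runs = 3)
  ctrl$value <- y
  cmp <- compare_to_control(cond, ctrl)
  sx <- var(x) / 3; sy <- var(y) / 3
  tstat <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / 2 + sy^2 / 2)
  expect_equal(cmp$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_false(cmp$normal)  # significantly lower than control
})

test_that("normality flags follow 'not significantly lower than control'", {
  base <- sin(seq_len(20)) + 5
  ctrl <- fake_metrics("control", base, noise = 0.1)
  same <- fake_metrics("a", base, noise = 0.1)
  expect_true(all(compare_to_control(same, ctrl)$normal))
  worse <- fake_metrics("b", base - 10, noise = 0.1)
  expect_false(any(compare_to_control(worse, ctrl)$normal))
  # significantly HIGHER than control still counts as normal
  better <- fake_metrics("c", base + 10, noise = 0.1)
  expect_true(all(compare_to_control(better, ctrl)$normal))
  # zero variance in both groups: defined by equality of means
  flat_c <- fake_metrics("control", base, noise = 0)
  flat_e <- fake_metrics("d", base, noise = 0)
  cmp <- compare_to_control(flat_e, flat_c)
  expect_true(all(is.na(cmp$p_value)))
  expect_true(all(cmp$normal))
})

test_that("performance ratios count normal cycles against the untreated arm", {
  mk <- function(name, n_normal, n_cycles = 30) {
    r <- structure(list(
      strategy = builtin_strategy("no_intervention"),
      metrics = fake_metrics(name, c(rep(5, n_normal),
                                     rep(-5, n_cycles - n_normal)),
                             noise = 0.1),
      node_strength = tibble::tibble(), failed_runs = integer(0)),
      class = "condition_result")
    r
  }
  ctrl <- mk("control", 30)
  cond <- mk("a", 20)
  ref <- mk("no_intervention", 10)
  sc <- performance_score(cond, ctrl, ref, "connectivity")
  expect_equal(sc$normal_cycles, 20)
  expect_equal(sc$ratio, 2.0)
  # a condition identical to the untreated arm scores exactly 1
  expect_equal(performance_score(ref, ctrl, ref, "connectivity")$ratio, 1)
  # a condition identical to control scores at least 1
  expect_gte(performance_score(ctrl, ctrl, ref, "connectivity")$ratio, 1)
  # an untreated arm with zero normal cycles yields the infinite marker
  none <- mk("no_intervention", 0)
  expect_identical(performance_score(cond, ctrl, none,
                                     "connectivity")$ratio, Inf)
})

small_cfg <- function(seed = 11, n_cycles = 4, metrics = "rel_alpha") {
  conn <- synthetic_connectome(n_nodes = 6, n_modules = 2, intra_p = 1,
                               inter_p = 0.6, hub_count = 0, g = 4,
                               seed = 2)
  trial_config(conn, n_runs = 2, n_cycles = n_cycles, duration = 3,
               base_seed = seed, metrics = metrics,
               add = add_params(lam = 0.05))
}

test_that("conditions run the full grid deterministically", {
  cfg <- small_cfg()
  ctl <- run_condition(cfg, "control")
  expect_setequal(unique(ctl$metrics$run), 1:2)
  expect_setequal(unique(ctl$metrics$cycle), 1:4)
  # control never degenerates: node strength stays exactly 1
  expect_true(all(ctl$node_strength$strength_ratio == 1))
  # untreated arm: strength ratios are non-increasing in virtual time
  ni <- run_condition(cfg, "no_intervention")
  by_node <- split(ni$node_strength,
                   list(ni$node_strength$run, ni$node_strength$node))
  for (b in by_node) {
    expect_true(all(diff(b$strength_ratio[order(b$cycle)]) <= 1e-15))
  }
  # same base seed, bit-identical results
  ni2 <- run_condition(small_cfg(), "no_intervention")
  expect_identical(ni$metrics, ni2$metrics)
})

test_that("timing arms share their pre-intervention trajectory", {
  cfg <- small_cfg(n_cycles = 8)
  tr <- timing_experiment(cfg, "stim_excitatory", start_cycles = c(0, 6))
  expect_named(tr$conditions,
               c("control", "no_intervention",
                 "stim_excitatory_start0", "stim_excitatory_start6"))
  late <- tr$conditions$stim_excitatory_start6$metrics
  ni <- tr$conditions$no_intervention$metrics
  pre <- function(df) df[df$cycle < 6, c("run", "cycle", "metric", "value")]
  expect_equal(pre(late), pre(ni))
  # the early-start arm deviates from the untreated arm
  early <- tr$conditions$stim_excitatory_start0$metrics
  expect_false(isTRUE(all.equal(pre(early)$value, pre(ni)$value)))
})

test_that("threshold sweeps produce one condition per value and guard ranges", {
  cfg <- small_cfg(n_cycles = 3)
  sw <- vd_sweep(cfg, "global_stim", vd_values = c(4, 4.5, 5),
                 start_cycle = 2)
  expect_named(sw$conditions,
               c("control", "no_intervention", "global_stim_vd4",
                 "global_stim_vd4.5", "global_stim_vd5"))
  expect_error(vd_sweep(cfg, "global_stim", vd_values = c(3, 5)), "extreme")
  expect_error(vd_sweep(cfg, "warp", vd_values = 5), "unknown")
  # a single-value sweep matches a direct run of the same custom strategy
  one <- vd_sweep(cfg, "stim_excitatory", vd_values = 5, start_cycle = 2)
  direct <- run_condition(cfg, custom_strategy(5, 7, start_cycle = 2))
  expect_equal(one$conditions$stim_excitatory_vd5$metrics$value,
               direct$metrics$value)
})

test_that("tidiers, glance and plots expose the trial in tidy form", {
  cfg <- small_cfg(n_cycles = 3, metrics = c("rel_alpha", "pli"))
  tr <- run_trial(cfg, strategies = "stim_excitatory", start_cycle = 2)
  td <- tidy(tr)
  expect_setequal(unique(td$condition),
                  c("control", "no_intervention", "stim_excitatory"))
  gl <- glance(tr)
  expect_true(all(c("ratio_oscillatory", "ratio_connectivity",
                    "ratio_topology") %in% names(gl)))
  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(plot_node_strength(tr$conditions$no_intervention),
                  "ggplot")
})

test_that("trial configurations round-trip through JSON", {
  cfg <- small_cfg(n_cycles = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_trial_config(cfg, f)
  back <- read_trial_config(f)
  expect_equal(back$connectome$W0, cfg$connectome$W0, ignore_attr = TRUE)
  expect_equal(back$mass, cfg$mass)
  expect_equal(back$add, cfg$add)
  expect_equal(back$n_cycles, cfg$n_cycles)
  expect_equal(back$metrics, cfg$metrics)
  # and a run from the restored config reproduces the original
  a <- run_condition(cfg, "control")
  b <- run_condition(back, "control")
  expect_equal(a$metrics, b$metrics)
})
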