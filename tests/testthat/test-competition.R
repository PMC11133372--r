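rab1 <- function(conc, kd = 1) {
  data.frame(rab_id = "r1", epitope_id = "E1", concentration = conc,
             kd_rab = kd, channel = "AF647", stringsAsFactors = FALSE)
}
blocker <- list(clone_id = "b", blocked_epitope = "E1", kd_qab = 1)
nonblocker <- list(clone_id = "nb", blocked_epitope = NA_character_,
                   kd_qab = Inf)

test_that("occupancy fractions match the closed forms", {
  # zero ligand
  expect_equal(unname(rab_occupancy_fraction(nonblocker, rab1(0), 100, 1)), 0)
  # half saturation at c = KD for a non-blocking clone
  expect_equal(unname(rab_occupancy_fraction(nonblocker, rab1(5, kd = 5),
                                             100, 1)), 0.5)
  # symmetric competition: x = 1 and C_q/K_q = 1 gives 1/3
  expect_equal(unname(rab_occupancy_fraction(blocker, rab1(1), 1, 1)), 1 / 3)
  # full blockade limit
  expect_lte(unname(rab_occupancy_fraction(blocker, rab1(1), 1e9, 1)), 1e-8)
})

test_that("occupancy is monotone in concentration and in qAb load", {
  concs <- c(0.1, 1, 10, 100)
  p_conc <- vapply(concs, function(co) {
    unname(rab_occupancy_fraction(blocker, rab1(co), 50, 1))
  }, numeric(1L))
  expect_true(all(diff(p_conc) > 0))
  loads <- c(0, 10, 100, 1000)
  p_load <- vapply(loads, function(q) {
    unname(rab_occupancy_fraction(blocker, rab1(1), q, 1))
  }, numeric(1L))
  expect_true(all(diff(p_load) < 0))
  # a non-blocking clone is invariant in qAb load
  p_nb <- vapply(loads, function(q) {
    unname(rab_occupancy_fraction(nonblocker, rab1(1), q, 1))
  }, numeric(1L))
  expect_equal(diff(p_nb), rep(0, 3L))
})

test_that("invalid binding inputs error", {
  expect_error(rab_occupancy_fraction(blocker, rab1(-1), 10, 1), "negative")
  expect_error(rab_occupancy_fraction(blocker, rab1(1), -10, 1), ">= 0")
  expect_error(rab_occupancy_fraction(blocker, rab1(1, kd = 0), 10, 1), "kd_rab")
})

test_that("simulated events honour degenerate limits", {
  cfg0 <- sim_config(n_cells = 0)
  ev0 <- simulate_cell_events(cfg0, one_clone("Per"), rab_panel(1))
  expect_equal(nrow(ev0), 0L)
  expect_true(all(c("clone_id", "A", "Q", "AF647", "AF488") %in% names(ev0)))
  expect_error(
    simulate_cell_events(sim_config(n_cells = 10), ref14[0, ], rab_panel(1)),
    "empty library")
  # zero noise, Q pinned at 0, single rAb at its KD: F = gain * A / 2 exactly
  cfg <- sim_config(n_cells = 500, noise_sd = 0, antigen_negative_fraction = 0,
                    log10_q_median = -300, log10_q_sd = 1e-12, seed = 3)
  ev <- simulate_cell_events(cfg, one_clone("Per"), rab1(1, kd = 1))
  expect_equal(ev$AF647, cfg$gain * ev$A * 0.5, tolerance = 1e-12)
})

test_that("mean fluorescence matches the log-normal closed form", {
  # one non-blocking clone, p = 0.5; E[F] = gain * E[A] * p with
  # E[A] = 10^mu * exp((sd*ln10)^2/2)
  cfg <- sim_config(n_cells = 1e4, log10_a_median = 3, log10_a_sd = 0.3,
                    noise_sd = 1e-9, antigen_negative_fraction = 0, seed = 11)
  ev <- simulate_cell_events(cfg, one_clone("Dac"), rab1(2, kd = 2))
  s <- 0.3 * log(10)
  expected <- cfg$gain * 10^3 * exp(s^2 / 2) * 0.5
  se <- stats::sd(ev$AF647) / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$AF647) - expected), 3 * se)
})

test_that("identical seeds give bit-identical event lists", {
  cfg <- sim_config(n_cells = 2000, seed = 99)
  ev1 <- simulate_cell_events(cfg, ref14, rab_panel(0.1))
  ev2 <- simulate_cell_events(cfg, ref14, rab_panel(0.1))
  expect_identical(ev1, ev2)
  ev3 <- simulate_cell_events(cfg, ref14, rab_panel(0.1), seed = 100)
  expect_false(identical(ev1, ev3))
})

test_that("gating handles degenerate thresholds and hand-built events", {
  ev <- make_events(c(1, 2, 10, 20))
  all_in <- gate_and_sort(ev, "AF647", Inf)
  expect_equal(all_in$percent_negative, 100)
  expect_equal(sum(all_in$counts), 4L)
  none <- gate_and_sort(ev, "AF647", 0)
  expect_equal(none$percent_negative, 0)
  expect_equal(nrow(none$negatives), 0L)
  half <- gate_and_sort(ev, "AF647", 5)
  expect_equal(half$percent_negative, 50)
  expect_equal(half$negatives$AF647, c(1, 2))
  expect_error(gate_and_sort(ev, "AF488", 5), "unknown channel")
})

test_that("the automatic gate sits at the background quantile", {
  cfg <- sim_config(n_cells = 1000, noise_sd = 20, q_gate = 0.995,
                    n_background = 2e5, seed = 5)
  ev <- simulate_cell_events(cfg, one_clone("Per"), rab_panel(0.1)[1L, ])
  g <- gate_and_sort(ev, "AF647", "auto", cfg)
  # 99.5% quantile of a zero-clipped N(0, 20) background
  expect_equal(g$threshold, 20 * stats::qnorm(0.995), tolerance = 0.05)
  # and it is reproducible for the same config
  expect_identical(g$threshold, gate_and_sort(ev, "AF647", "auto", cfg)$threshold)
})

test_that("quadrant percentages partition events and sum to 100", {
  ev <- make_events(c(1, 1, 10, 10))
  ev$AF488 <- c(1, 10, 1, 10)
  q <- quadrant_percentages(ev, "AF647", "AF488", 5, 5)
  expect_equal(unname(q), c(25, 25, 25, 25))
  expect_equal(sum(q), 100, tolerance = 1e-9)
  one_quad <- quadrant_percentages(make_events(0)[, ], "AF647", "AF647", 5, 5)
  expect_equal(unname(one_quad["neg_neg"]), 100)
  expect_error(quadrant_percentages(make_events(numeric(0L)), "AF647",
                                    "AF647", 1, 1), "no events")
})

test_that("percent rAb(-) falls as rAb concentration rises", {
  pcts <- vapply(c(0.1, 1, 10, 100), function(co) {
    percent_rab_negative("Per", rab = rab_panel(co)[1L, ],
                         config = sensitivity_config(n_cells = 2e4),
                         seed = 7)$percent_negative
  }, numeric(1L))
  expect_true(all(diff(pcts) < 0))
})

test_that("raising antigen expression lowers percent rAb(-)", {
  lo <- sim_config(n_cells = 2e4, log10_a_median = 4.5)
  hi <- sim_config(n_cells = 2e4, log10_a_median = 5.5)
  p_lo <- percent_rab_negative("Per", config = lo, seed = 13)$percent_negative
  p_hi <- percent_rab_negative("Per", config = hi, seed = 13)$percent_negative
  expect_gt(p_lo, p_hi)
})

test_that("rAb(-) cells show higher qAb and lower antigen expression", {
  res <- percent_rab_negative("Per", config = sensitivity_config(n_cells = 4e4),
                              seed = 17)
  g <- gate_and_sort(res$events, "AF647", res$threshold)
  neg <- res$events$AF647 < res$threshold
  expect_gt(mean(res$events$Q[neg]), mean(res$events$Q[!neg]))
  expect_lt(mean(res$events$A[neg]), mean(res$events$A[!neg]))
})

test_that("non-binder clones show no rAb(-) population at any concentration", {
  pcts <- vapply(c(0.1, 1, 10, 100), function(co) {
    percent_rab_negative("Dac", rab = rab_panel(co)[1L, ],
                         config = sensitivity_config(n_cells = 2e4),
                         seed = 19)$percent_negative
  }, numeric(1L))
  # small everywhere (the antigen-silenced floor), never a real population
  expect_true(all(pcts <= 1.5))
})

test_that("dual-rAb staining places a blocking clone in its quadrant", {
  cfg <- sim_config(n_cells = 2e4, seed = 23)
  rabs <- rab_panel(0.1)
  thr <- vapply(c("AF647", "AF488"), function(ch) {
    gate_and_sort(make_events(0, channel = ch), ch, "auto", cfg)$threshold
  }, numeric(1L))
  ev_per <- simulate_cell_events(cfg, one_clone("Per"), rabs)
  q_per <- quadrant_percentages(ev_per, "AF647", "AF488",
                                thr["AF647"], thr["AF488"])
  # majority of pertuzumab-blocking events: pertuzumab(-) / trastuzumab(+)
  expect_gt(q_per["neg_pos"], 50)
  expect_equal(names(which.max(q_per)), "neg_pos")
  ev_dac <- simulate_cell_events(cfg, one_clone("Dac"), rabs, seed = 24)
  q_dac <- quadrant_percentages(ev_dac, "AF647", "AF488",
                                thr["AF647"], thr["AF488"])
  expect_gt(q_dac["pos_pos"], 95)
})
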