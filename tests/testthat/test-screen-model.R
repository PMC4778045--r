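test_that("Poisson occupancy matches the closed form and sums to one", {
  occ <- poisson_occupancy(0.1, 2)
  expect_equal(round(occ$prob, 3), c(0.905, 0.090, 0.005))
  expect_equal(sum(occ$prob), 1, tolerance = 1e-12)

  occ0 <- poisson_occupancy(0, 3)
  expect_equal(occ0$prob, c(1, 0, 0, 0))

  occ33 <- poisson_occupancy(0.33, 4)
  expect_equal(occ33$prob[occ33$k == 2], exp(-0.33) * 0.33^2 / 2,
               tolerance = 1e-12)
  expect_equal(round(occ33$prob[occ33$k == 2], 4), 0.0391)

  # monotone decreasing in k for lam < 1
  for (lam in c(0.05, 0.1, 0.33, 0.9)) {
    p <- poisson_occupancy(lam, 6)$prob
    expect_true(all(diff(p[1:6]) < 0))
  }
  expect_error(poisson_occupancy(-0.1), "non-negative")
})

test_that("expected binder-drop count follows N_drop * lam / N_library", {
  x <- expected_binder_drops(3e6, 0.1, 8000)
  expect_equal(x$expected, 37.5)
  expect_equal(x$rounded, 38)
  expect_equal(x$drops_per_hit, 8e4)

  expect_equal(expected_binder_drops(1e6, 0.1, 8000)$expected, 12.5)
  # single-member library: every template is the binder
  expect_equal(expected_binder_drops(5e5, 0.2, 1)$expected, 1e5)
  expect_error(expected_binder_drops(1e6, 0.1, 0), "positive")
})

test_that("drop volume from diameter scales cubically", {
  expect_equal(signif(drop_volume_from_diameter(24), 2), 7.2)
  expect_equal(drop_volume_from_diameter(48) / drop_volume_from_diameter(24), 8)
  expect_equal(drop_volume_from_diameter(10), pi / 6, tolerance = 1e-12)
})

test_that("simulated encapsulation reproduces Poisson occupancy", {
  cfg <- screen_config(n_drops = 1e5, lam = 0.1, leakage_rate = 0,
                       seed = 101)
  pop <- simulate_encapsulation(cfg)
  p0 <- mean(pop$drops$n_templates == 0)
  se <- sqrt(0.905 * 0.095 / 1e5)
  expect_lt(abs(p0 - exp(-0.1)), 3 * se)

  # vanishing loading leaves effectively all drops empty
  cfg_tiny <- screen_config(n_drops = 1000, lam = 1e-6, leakage_rate = 0,
                            seed = 102)
  pop_tiny <- simulate_encapsulation(cfg_tiny)
  expect_true(all(pop_tiny$drops$n_templates == 0))

  # occupied-drop ratio between lam = 0.33 and 0.1 follows 1 - exp(-lam)
  occ_frac <- vapply(c(0.33, 0.1), function(l) {
    p <- simulate_encapsulation(
      screen_config(n_drops = 2e5, lam = l, leakage_rate = 0, seed = 103)
    )
    mean(p$drops$n_templates > 0)
  }, numeric(1))
  expect_equal(occ_frac[1] / occ_frac[2],
               (1 - exp(-0.33)) / (1 - exp(-0.1)), tolerance = 0.05)
})

test_that("per-variant template totals follow the abundance weights", {
  d <- library_design(scaffold = "FW", variable_positions = 2L)
  w <- setNames(c(0.5, 0.3, 0.2), c("W", "F", "L"))
  cfg <- screen_config(design = d, n_drops = 1e5, lam = 0.5,
                       leakage_rate = 0, binders = "W", weights = w,
                       seed = 104)
  pop <- simulate_encapsulation(cfg)
  tmpl <- pop$molecules[pop$molecules$kind == "template", ]
  n <- nrow(tmpl)
  for (pep in names(w)) {
    obs <- sum(tmpl$peptide == pep)
    expect_lt(abs(obs - n * w[[pep]]),
              4 * sqrt(n * w[[pep]] * (1 - w[[pep]])))
  }
  # everything not named gets zero weight
  expect_true(all(tmpl$peptide %in% names(w)))
})

test_that("fluorescence peaks sit at 1.0, ~2.0 and above 3.5 by binder occupancy", {
  d <- library_design(scaffold = "FW", variable_positions = 2L)
  cfg <- screen_config(design = d, n_drops = 4e4, lam = 0.5,
                       leakage_rate = 0, binders = "W",
                       weights = setNames(1, "W"), seed = 105)
  pop <- simulate_fluorescence(simulate_encapsulation(cfg))
  f <- pop$drops$fluorescence
  k <- pop$drops$n_binders
  sd <- cfg$fluorescence$noise_sd
  for (kk in 0:1) {
    mu <- c(1.0, 2.0)[kk + 1]
    n_k <- sum(k == kk)
    expect_gt(n_k, 50)
    expect_lt(abs(mean(f[k == kk]) - mu), 3 * sd / sqrt(n_k))
  }
  expect_gte(min(f), 0)
  expect_true(mean(f[k == 2]) >= 3.5)
  # leaked transcripts add no fluorescence
  cfg_leak <- screen_config(design = d, n_drops = 2e4, lam = 1e-6,
                            leakage_rate = 2, binders = "W",
                            weights = setNames(1, "W"), seed = 106)
  pop_leak <- simulate_fluorescence(simulate_encapsulation(cfg_leak))
  leaky <- pop_leak$drops$n_leaked > 0
  expect_gt(sum(leaky), 100)
  expect_lt(abs(mean(pop_leak$drops$fluorescence[leaky]) - 1.0),
            3 * sd / sqrt(sum(leaky)))
})

test_that("drop sorting partitions drops and is monotone in the threshold", {
  cfg <- screen_config(n_drops = 5e4, seed = 107)
  pop <- simulate_fluorescence(simulate_encapsulation(cfg))
  sr <- sort_drops(pop)
  expect_true(all(sr$drops$pool[!sr$drops$gate_pass] == "excluded"))
  expect_true(all(sr$drops$pool %in% c("bright", "dark", "excluded")))
  expect_equal(sum(sr$summary$n_drops), 5e4)

  fracs <- vapply(c(0.5, 1.3, 2.5, 5), function(th) {
    sort_drops(pop, threshold = th)$bright_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  # a gate below every fluorescence value marks all gate-passers bright
  expect_equal(sort_drops(pop, threshold = 1e-9)$bright_fraction, 1)
})

test_that("a pure high-affinity library yields bright fraction 1 - exp(-lam)", {
  d <- library_design(scaffold = "FW", variable_positions = 2L)
  cfg <- screen_config(design = d, n_drops = 1e5, lam = 0.1,
                       leakage_rate = 0, binders = "W",
                       weights = setNames(1, "W"),
                       fluorescence = fluorescence_model(width_gate_outlier_rate = 0),
                       seed = 108)
  pop <- simulate_fluorescence(simulate_encapsulation(cfg))
  sr <- sort_drops(pop)
  p <- 1 - exp(-0.1)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(sr$bright_fraction - p), 3 * se)
})

test_that("sorting requires fluorescence and encapsulation is seed-reproducible", {
  cfg <- screen_config(n_drops = 1000, seed = 109)
  pop <- simulate_encapsulation(cfg)
  expect_error(sort_drops(pop), "fluorescence not assigned")
  pop2 <- simulate_encapsulation(cfg)
  expect_identical(pop$drops, pop2$drops)
  expect_identical(pop$molecules, pop2$molecules)
})
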