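test_that("darkness keeps PSII and the quenching complex empty", {
  sim <- simulate_leaf(eiko, light_dark(), 600, output_step = 10)
  expect_true(all(sim$states[, "E_PSII"] == 0))
  expect_true(all(sim$states[, "Q"] == 0))
  expect_true(all(sim$fluxes[, "ETR"] == 0))
  expect_true(all(sim$fluxes[, "NPQ"] == 0))
  # NADPH drains toward zero, so A decays to zero (up to solver tolerance)
  expect_gt(min(sim$fluxes[, "A"]), -1e-8)
  expect_lt(sim$fluxes[nrow(sim$fluxes), "A"], sim$fluxes[2, "A"])
  # first output row is the initial condition
  expect_identical(sim$states[1, ], initial_state())
})

test_that("NADPH + NADP+ is conserved to solver tolerance on every run", {
  for (case in list(list(eiko, const_protocol), list(minngold, fluct_protocol))) {
    sim <- simulate_leaf(case[[1]], case[[2]], 1800)
    expect_lt(max(abs(rowSums(sim$states[, c("NADPH", "NADPplus")]) - 10)),
              1e-6)
  }
})

test_that("constant light reaches the NADPH steady-state balance within 1%", {
  sim <- simulate_leaf(eiko, const_protocol, 3600)
  n <- nrow(sim$fluxes)
  etr <- sim$fluxes[n, "ETR"]; a <- sim$fluxes[n, "A"]
  expect_lt(abs(etr * eiko[["eta_NADPplus"]] - a * eiko[["eta_NADPH"]]) /
              (etr * eiko[["eta_NADPplus"]]), 0.01)
})

test_that("state bounds and P_NPQ/R monotonicity hold on random models", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_params()
    sim <- simulate_leaf(p, random_square(), 240)
    expect_true(all(sim$states >= -1e-9))
    expect_lt(max(sim$states[, "E_PSII"]), p[["E_star_PSII"]] * (1 + 1e-9))
    expect_lt(max(sim$states[, "Q"]), p[["Q_star"]] * (1 + 1e-9))
    expect_lte(max(sim$states[, "P_NPQ"]), 1 + 1e-9)
    expect_lte(max(sim$states[, "R"]), 1 + 1e-9)
    expect_true(all(diff(sim$states[, "P_NPQ"]) >= -1e-9))
    expect_true(all(diff(sim$states[, "R"]) >= -1e-9))
  }
})

test_that("fixed-step RK4 reference agrees with the adaptive solver", {
  d1 <- compare_to_fixed_step_oracle(eiko, const_protocol, 60, dt = 1e-3)
  expect_lt(max(d1), 1e-4)
  d2 <- compare_to_fixed_step_oracle(minngold, fluct_protocol, 120, dt = 1e-3)
  expect_lt(max(d2), 1e-4)
  d3 <- compare_to_fixed_step_oracle(eiko, light_dark(), 30, dt = 1e-3)
  expect_identical(unname(d3[c("E_PSII", "Q")]), c(0, 0))
})

test_that("results are insensitive to a 10x tolerance refinement", {
  s1 <- simulate_leaf(eiko, fluct_protocol, 600)
  s2 <- simulate_leaf(eiko, fluct_protocol, 600, rtol = 1e-9, atol = 1e-11)
  for (q in c("ETR", "A", "NPQ")) {
    rel <- max(abs(s1$fluxes[, q] - s2$fluxes[, q])) / max(abs(s1$fluxes[, q]))
    expect_lt(rel, 1e-3)
  }
})

test_that("segmentation does not alter a constant protocol", {
  # a square wave with equal levels is a constant protocol with spurious
  # segment boundaries
  seg <- simulate_leaf(eiko, light_square(650, 650, period = 60), 300)
  unseg <- simulate_leaf(eiko, light_constant(650), 300)
  expect_lt(max(abs(seg$states - unseg$states)), 1e-5)
})

test_that("a dark pre-phase leaves MinnGold's NPQ proteins exactly inactive", {
  sim <- simulate_leaf(minngold, light_dark(), 300)
  expect_true(all(sim$states[, "P_NPQ"] == 0))
})

test_that("steady-state summaries integrate and average the fluxes", {
  sim <- simulate_leaf(eiko, fluct_protocol, 3600)
  s <- steady_state_summary(sim, 2400, 3600)
  expect_identical(s$flux, c("ETR", "A", "NPQ"))
  expect_equal(s$cumulative, s$mean * 1200)
  # hand trapezoid of the stored series
  sel <- sim$times >= 2400 & sim$times <= 3600
  t <- sim$times[sel]; y <- sim$fluxes[sel, "A"]
  expect_equal(s$cumulative[s$flux == "A"],
               sum(diff(t) * (y[-1] + y[-length(y)]) / 2))
  # entrained steady state: mean invariant to shifting the window by a cycle
  s_shift <- steady_state_summary(sim, 2400 - 120, 3600 - 120)
  expect_lt(max(abs(s_shift$mean - s$mean) / s$mean), 0.005)
  expect_error(steady_state_summary(sim, 3000, 4000), "window")
})

test_that("trajectories export to a tidy data frame", {
  sim <- simulate_leaf(eiko, fluct_protocol, 120, output_step = 30)
  df <- as.data.frame(sim)
  expect_identical(names(df), c("time_s", "par", "E_PSII", "Q", "P_NPQ",
                                "NADPH", "NADPplus", "R", "ETR", "A", "NPQ"))
  expect_identical(nrow(df), 5L)
  expect_identical(df$par, c(780, 780, 520, 520, 780))
})
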