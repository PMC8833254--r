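test_that("dark-adapted initial state matches the published starting values", {
  s <- initial_state()
  expect_identical(unname(s[c("E_PSII", "Q", "P_NPQ")]), c(0, 0, 0))
  expect_identical(unname(s[c("NADPH", "NADPplus")]), c(5, 5))
  expect_identical(s[["R"]], 0.001)
})

test_that("parameter presets validate and reject bad inputs", {
  expect_s3_class(eiko, "leaf_params")
  expect_identical(eiko[["v_NPQ"]], 70.58)
  expect_identical(minngold[["v_R"]], 14e-4)
  expect_lt(eiko[["c_y"]], 0)  # sign-unconstrained parameter
  expect_length(calibrated_parameters(), 13)
  expect_false("alpha" %in% calibrated_parameters())
  expect_error(leaf_params("eiko", v_C = -1), "positive")
  expect_error(leaf_params("eiko", alpha = 1.2), "alpha")
  expect_error(leaf_params("eiko", nosuch = 1), "unknown")
  expect_error(validate_leaf_params(unclass(eiko)[-3]), "missing")
})

test_that("cyclic electron flow follows its closed form", {
  # dark + empty PSII: both terms vanish
  expect_identical(compute_cef(initial_state(), 0, eiko), 0)
  # input term only: 0.78 * 0.23 * 650
  expect_equal(compute_cef(initial_state(), 650, eiko), 116.61,
               tolerance = 1e-12)
  # at carrying capacity the input term is zero, leaving -v_ETR * E* * NADP+
  st <- initial_state()
  st["E_PSII"] <- eiko[["E_star_PSII"]]
  expect_equal(compute_cef(st, 1234, eiko),
               -eiko[["v_ETR"]] * eiko[["E_star_PSII"]] * 5)
})

test_that("derivatives reproduce hand-evaluated dark dynamics", {
  d <- leaf_derivs(initial_state(), 0, minngold)
  expect_identical(unname(d[c("E_PSII", "Q", "P_NPQ")]), c(0, 0, 0))
  # Calvin drain: -v_C * R * NADPH * eta_NADPH = -13.04 * 0.001 * 5 * 4.10
  expect_equal(d[["NADPH"]], -0.26732, tolerance = 1e-10)
  expect_equal(d[["NADPplus"]], 0.26732, tolerance = 1e-10)
  # Rubisco: v_R * (1 - R) * min(d, 1) = 14e-4 * 0.999 * 1
  expect_equal(d[["R"]], 1.3986e-3, tolerance = 1e-10)
  # MinnGold c_y = 0 and CEF = 0 in darkness: switch stays off
  expect_identical(d[["P_NPQ"]], 0)
  # Eiko c_y = -4: NPQ proteins activate even in darkness (CEF = 0 > -4)
  de <- leaf_derivs(initial_state(), 0, eiko)
  expect_equal(de[["P_NPQ"]], eiko[["v_p"]])
})

test_that("NADPH/NADP+ rates cancel exactly and saturation switches off growth", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_params()
    st <- random_state(p)
    d <- leaf_derivs(st, runif(1, 0, 1000), p)
    expect_identical(d[["NADPH"]] + d[["NADPplus"]], 0)
  }
  # fully active NPQ proteins stop accumulating even with the switch on
  st <- random_state(eiko)
  st["P_NPQ"] <- 1
  st["E_PSII"] <- 0  # CEF = input > c_y
  expect_identical(leaf_derivs(st, 650, eiko)[["P_NPQ"]], 0)
})

test_that("derived fluxes follow their definitions", {
  st <- initial_state()
  st["E_PSII"] <- 10
  f <- compute_fluxes(st, 650, eiko)
  expect_equal(f[["ETR"]], 0.78 * 10 * 5)
  st2 <- initial_state(); st2["Q"] <- 0.05
  expect_equal(compute_fluxes(st2, 0, eiko)[["NPQ"]], 70.58 * 0.05)
  f0 <- compute_fluxes(initial_state(), 650, eiko)
  expect_equal(f0[["A"]], eiko[["v_C"]] * 0.001 * 5)
  expect_equal(f0[["CEF"]], compute_cef(initial_state(), 650, eiko))
  expect_equal(f0[["delta_pH"]], 1)
})

test_that("PSII energy balance holds identically: input = dE + ETR + dissipation", {
  set.seed(12)
  for (i in 1:25) {
    p <- random_params()
    st <- random_state(p)
    par <- runif(1, 0, 1000)
    d <- leaf_derivs(st, par, p)
    f <- compute_fluxes(st, par, p)
    input <- p[["alpha"]] * p[["c_in"]] * par *
      (1 - st[["E_PSII"]] / p[["E_star_PSII"]])
    diss <- p[["v_d"]] * st[["E_PSII"]] * st[["P_NPQ"]] *
      (1 - st[["Q"]] / p[["Q_star"]])
    expect_equal(input, d[["E_PSII"]] + f[["ETR"]] + diss,
                 tolerance = 1e-12)
  }
})

test_that("degenerate pools are rejected rather than divided by", {
  st <- initial_state()
  st["NADPplus"] <- -0.1
  expect_error(leaf_derivs(st, 650, eiko), "degenerate")
  expect_error(compute_fluxes(st, 650, eiko), "degenerate")
  # a vanishing (but valid) pool is guarded, not an error
  st["NADPplus"] <- 0; st["NADPH"] <- 10
  expect_true(is.finite(compute_fluxes(st, 650, eiko)[["delta_pH"]]))
})

test_that("parameter sets round-trip losslessly through JSON and YAML", {
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_params(minngold, f)
    back <- read_params(f)
    expect_identical(unclass(back), unclass(minngold))
    unlink(f)
  }
})
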