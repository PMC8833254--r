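# Short synthetic series keep each objective evaluation cheap: 20 min of the
# fluctuating protocol sampled every 30 s (41 points per quantity).
noiseless <- generate_observed(eiko, fluct_protocol, duration = 1200,
                               noise_sd = c(ETR = 0, A = 0, NPQ = 0),
                               n_reps = 3, seed = 101, variety = "eiko")

test_that("the objective vanishes at the generating parameters", {
  expect_lt(objective(eiko, noiseless), 1e-12)
})

test_that("perturbing any influential parameter raises the objective", {
  for (nm in c("c_in", "E_star_PSII", "v_C", "eta_NADPH")) {
    p <- unclass(eiko)
    p[[nm]] <- p[[nm]] * 1.2
    expect_gt(objective(validate_leaf_params(p), noiseless), 1e-4)
  }
})

test_that("the objective ignores replicate ordering", {
  set.seed(4)
  shuffled <- noiseless[sample(nrow(noiseless)), ]
  shuffled <- observed_series(shuffled$time_s, shuffled$replicate,
                              shuffled$ETR, shuffled$A, shuffled$NPQ,
                              attr(noiseless, "protocol"), "eiko")
  p <- leaf_params("eiko", v_C = 13)
  expect_equal(objective(p, noiseless), objective(p, shuffled))
})

test_that("noiseless data are recovered: trajectory exactly, sensitive parameters closely", {
  fit <- calibrate(noiseless, n_starts = 3, seed = 7)
  mns <- replicate_means(noiseless)
  data_var <- sum(vapply(c("ETR", "A", "NPQ"), function(q)
    stats::var(mns[[q]] / diff(range(mns[[q]]))), numeric(1)))
  expect_lt(fit$objective, 1e-6 * data_var)
  expect_true(all(fit$r_squared > 0.999))
  # the two most sensitive parameters come back within 10%
  cc <- coef(fit)
  expect_lt(abs(cc[["c_in"]] / eiko[["c_in"]] - 1), 0.1)
  expect_lt(abs(cc[["E_star_PSII"]] / eiko[["E_star_PSII"]] - 1), 0.1)
  # R^2 reported matches recomputation via validate()
  expect_equal(unname(fit$r_squared), unname(validate(fit$params, noiseless)))
})

test_that("calibration is deterministic given the seed", {
  f1 <- suppressWarnings(calibrate(noiseless, n_starts = 2, seed = 33, maxiter = 10))
  f2 <- suppressWarnings(calibrate(noiseless, n_starts = 2, seed = 33, maxiter = 10))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$diagnostics, f2$diagnostics)
})

test_that("fitted parameters respect their bounds", {
  b <- default_bounds(eiko)
  expect_identical(unname(b$lower["c_y"]), -10)
  fit <- suppressWarnings(calibrate(noiseless, bounds = b, n_starts = 2,
                                    seed = 5, maxiter = 15))
  cc <- coef(fit)
  expect_true(all(cc >= b$lower - 1e-12 & cc <= b$upper + 1e-12))
})

test_that("validation separates matched from swapped parameter sets", {
  r2_match <- validate(eiko, noiseless)
  expect_true(all(r2_match > 0.999))
  r2_swap <- validate(minngold, noiseless)
  expect_true(all(r2_swap < r2_match))
})

test_that("validation R^2 degrades as measurement noise grows", {
  r2_at_noise <- function(k) {
    obs <- generate_observed(eiko, fluct_protocol, duration = 1200,
                             noise_sd = c(ETR = 5, A = 1, NPQ = 0.1) * k,
                             seed = 202)
    mean(validate(eiko, obs))
  }
  r2 <- vapply(c(0, 1, 4), r2_at_noise, numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("fit object methods are coherent", {
  fit <- suppressWarnings(calibrate(noiseless, n_starts = 1, seed = 1,
                                    maxiter = 5))
  expect_named(coef(fit), calibrated_parameters(), ignore.order = TRUE)
  res <- residuals(fit)
  expect_identical(nrow(res), nrow(replicate_means(noiseless)))
  pred <- predict(fit)
  expect_s3_class(pred, "leaf_sim")
  expect_equal(max(pred$times), 1200)
  pred2 <- predict(fit, newprotocol = light_constant(650), duration = 300)
  expect_identical(unique(pred2$par), 650)
  expect_output(print(fit), "parity R")
})
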