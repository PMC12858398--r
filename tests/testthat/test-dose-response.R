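test_that("ll4_response matches its closed form and limits", {
  # inflection midpoint
  expect_equal(ll4_response(0.3, b = 2, c = 0.1, d = 0.9, e = 0.3), 0.5)
  # closed form one log-unit above the inflection
  expect_equal(ll4_response(exp(1), b = 1, c = 0, d = 1, e = 1),
               1 / (1 + exp(1)), tolerance = 1e-12)
  # steep-slope step limit
  expect_equal(ll4_response(0.5, b = 500, c = 0, d = 1, e = 1), 1, tolerance = 1e-9)
  expect_equal(ll4_response(2, b = 500, c = 0, d = 1, e = 1), 0, tolerance = 1e-9)
  expect_error(ll4_response(-1, 1, 0, 1, 1), "positive")
})

test_that("noiseless LL4 parameters are recovered almost exactly", {
  cv <- make_curve(b = 1.5, c = 0.1, d = 1.0, e = 0.3)
  fit <- fit_dose_response(cv$doses, cv$responses)
  expect_true(fit$converged)
  expect_equal(fit$b, 1.5, tolerance = 1e-4)
  expect_equal(fit$c, 0.1, tolerance = 1e-4)
  expect_equal(fit$d, 1.0, tolerance = 1e-4)
  expect_equal(fit$e, 0.3, tolerance = 1e-4)
  expect_lt(fit$p_fit, 1e-8)
})

test_that("LL3_upper1 agrees with LL4 on data generated with d = 1", {
  cv <- make_curve(b = 2, c = 0.05, d = 1, e = 0.8)
  f4 <- fit_dose_response(cv$doses, cv$responses, mode = "LL4")
  f3 <- fit_dose_response(cv$doses, cv$responses, mode = "LL3_upper1")
  expect_equal(f3$b, f4$b, tolerance = 1e-3)
  expect_equal(f3$c, f4$c, tolerance = 1e-3)
  expect_equal(f3$e, f4$e, tolerance = 1e-3)
  expect_equal(ec50(f3), 0.8, tolerance = 1e-3)
})

test_that("constant responses give p_fit near 1 and no effectiveness", {
  doses <- exp(seq(log(0.01), log(10), length.out = 8))
  fit <- fit_dose_response(doses, rep(1, 8))
  expect_gte(fit$p_fit, 0.5)
  expect_false(is_effective(fit))
  expect_true(is.na(ec50(fit)))  # flat curve: inflection unidentifiable
})

test_that("too few distinct doses skips the fit with a reason", {
  fit <- fit_dose_response(c(0.1, 1, 10), c(1, 0.5, 0), mode = "LL4")
  expect_false(fit$converged)
  expect_identical(fit$reason, "insufficient_doses")
  expect_true(is.na(compute_aac(fit)))
})

test_that("AAC identities: flat curves and log-symmetric logistic", {
  doses <- exp(seq(log(0.01), log(10), length.out = 9))
  flat1 <- fit_dose_response(doses, rep(1, 9))
  flat1$b <- 1; flat1$c <- 1; flat1$d <- 1; flat1$e <- 1  # force exact asymptotes
  expect_equal(compute_aac(flat1), 0, tolerance = 1e-12)
  flat0 <- flat1; flat0$c <- 0; flat0$d <- 0
  expect_equal(compute_aac(flat0), 1, tolerance = 1e-12)
  mid <- flat1
  mid$c <- 0; mid$d <- 1; mid$b <- 1.7; mid$e <- sqrt(0.01 * 10)
  expect_equal(compute_aac(mid), 0.5, tolerance = 1e-12)
})

test_that("AAC is monotone in the curve and stable under grid refinement", {
  doses <- exp(seq(log(0.01), log(10), length.out = 8))
  set.seed(31)
  for (i in 1:20) {
    e1 <- exp(runif(1, log(0.05), log(5)))
    b1 <- runif(1, 0.5, 3)
    fitA <- fit_dose_response(doses, ll4_response(doses, b1, 0, 1, e1))
    # curve B everywhere above curve A (higher viability): shift EC50 up
    fitB <- fit_dose_response(doses, ll4_response(doses, b1, 0.2, 1, e1 * 4))
    expect_gte(compute_aac(fitA), compute_aac(fitB))
    expect_lt(abs(compute_aac(fitA, 101) - compute_aac(fitA, 1001)), 1e-4)
  }
})

test_that("effectiveness needs significance and > 50% modelled response", {
  doses <- exp(seq(log(0.01), log(10), length.out = 8))
  kill <- fit_dose_response(doses, ll4_response(doses, 2, 0, 1, 0.02) +
                              c(0.01, -0.01, 0.005, -0.005, 0.01, -0.01, 0.005, -0.005))
  expect_true(kill$converged)
  expect_true(is_effective(kill))

  # curve reaching exactly 50% inhibition at its plateau: strict inequality fails
  half <- kill
  half$c <- 0.5; half$d <- 1; half$b <- 3; half$e <- 0.05; half$p_fit <- 1e-9
  half$converged <- TRUE
  expect_false(is_effective(half))
  half$c <- 0.49
  expect_true(is_effective(half))
})

test_that("EC50 recovery is accurate at the nanomolar scale", {
  cv <- make_curve(b = 1.2, c = 0, d = 1, e = 0.004)
  fit <- fit_dose_response(cv$doses, cv$responses, mode = "LL3_upper1")
  expect_equal(ec50(fit), 0.004, tolerance = 1e-3)
})

test_that("the dose-effect F-test is valid (conservative) on constant true curves", {
  ## The LL4 family is locally unidentifiable at flat curves (c = d leaves b
  ## and e without effect), so the nested F-test under-uses its nominal
  ## numerator df there and rejects *below* the nominal rate. The property
  ## that matters for the EC-window weights is type-I validity: flat curves
  ## must not be declared effective more often than alpha.
  doses <- exp(seq(log(0.01), log(10), length.out = 8))
  set.seed(17)
  pvals <- replicate(1000, {
    y <- 1 + rnorm(8, 0, 0.05)
    fit_dose_response(doses, y)$p_fit
  })
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0)
  expect_lte(frac, 0.07)
  expect_gt(median(pvals), 0.5)  # bulk of null p-values is large
})

test_that("fit_screen_table returns one scored row per curve", {
  sim <- simulate_screens(screen_sim_config(n_compounds = 8, n_lines_target = 3,
                                            n_lines_background = 3,
                                            planted_set_size = 2,
                                            missing_frac = 0, seed = 12))
  fits <- fit_screen_table(sim$screen_table)
  expect_equal(nrow(fits), 3 * 6 * 8)
  expect_true(all(is.finite(fits$aac)))
  expect_true(all(fits$aac >= 0 & fits$aac <= 1))
  ## planted compounds on target lines are the most sensitive curves
  grp <- sim$lineage$group[match(fits$cell_line, sim$lineage$cell_line)]
  planted <- fits$compound_id %in% sim$truth$planted_compound_ids
  expect_gt(mean(fits$aac[planted & grp == "target"]),
            mean(fits$aac[planted & grp == "background"]))
})
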