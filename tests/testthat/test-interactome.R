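mk_design <- function(n_bait = 4, n_ctrl = 4) {
  data.frame(sample = c(sprintf("bait_%d", seq_len(n_bait)),
                        sprintf("control_%d", seq_len(n_ctrl))),
             condition = rep(c("bait", "control"), c(n_bait, n_ctrl)),
             replicate = c(seq_len(n_bait), seq_len(n_ctrl)),
             stringsAsFactors = FALSE)
}

test_that("quantile normalization equalises sample distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5), tolerance = 1e-12)
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5), tolerance = 1e-12)

  ## identical columns are a fixed point
  m2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2, tolerance = 1e-12)

  ## after normalization all sorted observed columns coincide; idempotent
  set.seed(9)
  m3 <- matrix(rnorm(600, 24, 3), 100, 6, dimnames = list(NULL, letters[1:6]))
  qn3 <- quantile_normalize(m3)
  ref <- sort(qn3[, 1])
  for (j in 2:6) expect_equal(sort(qn3[, j]), ref, tolerance = 1e-12)
  expect_equal(quantile_normalize(qn3), qn3, tolerance = 1e-12)

  ## ties get the mean of the spanned quantiles
  m4 <- cbind(a = c(1, 1, 3), b = c(10, 20, 30))
  qn4 <- quantile_normalize(m4)
  expect_equal(qn4[1, "a"], qn4[2, "a"])

  ## missing cells stay missing
  m5 <- m3; m5[sample(length(m5), 50)] <- NA
  expect_identical(is.na(quantile_normalize(m5)), is.na(m5))
  expect_error(quantile_normalize(m3[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("quantile normalization matches limma on complete matrices", {
  skip_if_not_installed("limma")
  set.seed(10)
  m <- matrix(rnorm(500, 20, 4), 100, 5)
  colnames(m) <- paste0("s", 1:5)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m, ties = TRUE)),
               tolerance = 1e-10)
})

test_that("missingness classification follows the detected-replicate rule", {
  d <- mk_design(4, 4)
  m <- matrix(rnorm(24, 20), 3, 8,
              dimnames = list(c("p1", "p2", "p3"), d$sample))
  m["p1", 5:8] <- NA                      # 0/4 detected in control -> MNAR
  m["p2", c(1, 2)] <- NA                  # 2/4 detected in bait -> MAR
  mask <- classify_missingness(m, d)
  expect_true(all(mask["p1", 5:8] == "MNAR"))
  expect_true(all(mask["p2", c(1, 2)] == "MAR"))  # 2 is not fewer than 2
  expect_true(all(mask["p3", ] == "observed"))
  expect_true(all(mask[!is.na(m)] == "observed"))

  ## exactly one detected replicate -> MNAR
  m["p3", 2:4] <- NA
  expect_true(all(classify_missingness(m, d)["p3", 2:4] == "MNAR"))

  d1 <- d[d$sample != "control_1", ]
  expect_error(classify_missingness(m[, d1$sample], rbind(d1[1:4, ],
               data.frame(sample = c("control_2", "control_3", "control_4"),
                          condition = c("control", "control", "c2"),
                          replicate = 1:3))), "fewer than 2")
})

test_that("mixed imputation fills MNAR low and MAR by conditional expectation", {
  set.seed(11)
  d <- mk_design(4, 4)
  ## complete base matrix with strong inter-sample correlation
  mu <- rnorm(5000, 22, 3)
  m <- mu + matrix(rnorm(5000 * 8, 0, 3 * sqrt(1 / 0.9 - 1)), 5000, 8)
  dimnames(m) <- list(sprintf("p%04d", 1:5000), d$sample)

  ## no missing cells: identity
  mask0 <- classify_missingness(m, d)
  expect_identical(impute_mixed(m, mask0, seed = 1), m)

  ## an all-MNAR block is drawn near the per-sample 1% quantile
  m1 <- m
  m1[1:2500, 1] <- NA
  m1[1:2500, 2] <- NA  # < 2 detected bait replicates only if 3,4 also missing
  m1[1:2500, 3] <- NA
  m1[1:2500, 4] <- NA
  mask1 <- classify_missingness(m1, d)
  expect_true(all(mask1[1:2500, 1:4] == "MNAR"))
  imp1 <- impute_mixed(m1, mask1, seed = 2)
  expect_false(anyNA(imp1))
  for (j in 1:4) {
    q01 <- quantile(m1[!is.na(m1[, j]), j], 0.01)
    expect_lt(abs(mean(imp1[1:2500, j]) - q01), 0.2)
    expect_lt(mean(imp1[1:2500, j]), median(m1[, j], na.rm = TRUE))  # left-shifted
  }

  ## MAR deletion: EM beats column-mean imputation on correlated data
  m2 <- m
  holes <- cbind(sample(1:5000, 3000, replace = TRUE), sample(1:8, 3000, replace = TRUE))
  holes <- holes[!duplicated(holes), ]
  ## keep at least 2 observed bait and control cells per protein: delete at
  ## most one column per condition per protein
  holes <- holes[!duplicated(holes[, 1]), , drop = FALSE]
  m2[holes] <- NA
  mask2 <- classify_missingness(m2, d)
  expect_true(all(mask2[holes] == "MAR"))
  imp2 <- impute_mixed(m2, mask2, seed = 3)
  rmse_em <- sqrt(mean((imp2[holes] - m[holes])^2))
  colmeans <- colMeans(m2, na.rm = TRUE)
  rmse_cm <- sqrt(mean((colmeans[holes[, 2]] - m[holes])^2))
  expect_lt(rmse_em, rmse_cm)

  ## determinism given seed
  expect_identical(impute_mixed(m1, mask1, seed = 2), imp1)
})

test_that("moderated t matches the direct-formula oracle and limma", {
  set.seed(12)
  d <- mk_design(4, 4)
  m <- matrix(rnorm(3000 * 8, 20, 1), 3000, 8,
              dimnames = list(sprintf("p%04d", 1:3000), d$sample))
  ## heterogeneous true variances so shrinkage is non-trivial
  m <- m * sqrt(rchisq(3000, 5) / 5)
  res <- moderated_test(m, d)
  or <- oracle_moderated_t(m, 1:4, 5:8)
  expect_equal(res$t_mod, unname(or$t_mod), tolerance = 1e-8)
  expect_equal(res$p, unname(or$p), tolerance = 1e-8)
  expect_equal(unique(res$df_total), or$df_total, tolerance = 1e-6)

  skip_if_not_installed("limma")
  design_mat <- cbind(intercept = 1, bait = as.integer(d$condition == "bait"))
  fit <- limma::eBayes(limma::lmFit(m, design_mat))
  expect_equal(res$d0[1], fit$df.prior, tolerance = 1e-6)
  expect_equal(res$s0_sq[1], fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, "bait"]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, "bait"]), tolerance = 1e-6)
})

test_that("shrinkage limits recover the ordinary t and full shrinkage", {
  set.seed(13)
  d <- mk_design(3, 3)
  m <- matrix(rnorm(200 * 6, 18, 1.5), 200, 6,
              dimnames = list(sprintf("p%03d", 1:200), d$sample))
  plain <- moderated_test(m, d, d0 = 0, s0_sq = 1)
  tt <- apply(m, 1, function(x) t.test(x[1:3], x[4:6], var.equal = TRUE)$statistic)
  expect_equal(plain$t_mod, unname(tt), tolerance = 1e-12)
  full <- moderated_test(m, d, d0 = Inf, s0_sq = 2.5)
  expect_true(all(full$s2_post == 2.5))
  ## posterior variance lies between s2 and the prior
  est <- moderated_test(m, d)
  expect_true(all(est$s2_post >= pmin(est$s2, est$s0_sq) - 1e-12))
  expect_true(all(est$s2_post <= pmax(est$s2, est$s0_sq) + 1e-12))
})

test_that("contaminant downweighting divides by floored background", {
  fc <- data.frame(protein = c("a", "b", "c"), fc_over_ig = c(6, 4, 2))
  bg <- data.frame(protein = c("a", "b"), avg_background = c(3, 0.1))
  res <- contaminant_downweight(fc, bg, floor = 1)
  expect_equal(res$score, c(6 / 3, 4 / 1, 2 / 1))  # floored at 1; absent -> fc
  expect_error(contaminant_downweight(fc,
               data.frame(protein = "a", avg_background = -1)), "non-negative")
})
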