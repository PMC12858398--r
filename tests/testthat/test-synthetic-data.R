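test_that("noiseless generator reproduces the closed-form logistic", {
  grid <- exp(seq(log(0.01), log(1), length.out = 8))
  e_mid <- sqrt(min(grid) * max(grid))
  cfg <- screen_sim_config(
    n_screens = 1, doses_per_screen = list(grid),
    n_lines_target = 1, n_lines_background = 1, n_compounds = 1,
    planted_set_size = 0, planted_shift = 50,
    ec50_log_mu = log(e_mid), ec50_log_sigma = 0,
    frac_ineffective = 0, noise_sd = 0, missing_frac = 0, seed = 11)
  sim <- simulate_screens(cfg)
  tr <- sim$truth$params[1, ]
  expect_equal(tr$e, e_mid)
  one <- sim$screen_table[sim$screen_table$cell_line == "TGT01", ]
  expect_equal(one$viability,
               ll4_response(one$dose, tr$b, tr$c, 1, tr$e), tolerance = 1e-12)
})

test_that("screen simulation is deterministic given the seed", {
  cfg <- screen_sim_config(n_compounds = 15, n_lines_target = 3,
                           n_lines_background = 4, planted_set_size = 3, seed = 5)
  s1 <- simulate_screens(cfg)
  s2 <- simulate_screens(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_screens(screen_sim_config(n_compounds = 15, n_lines_target = 3,
                                           n_lines_background = 4,
                                           planted_set_size = 3, seed = 6))
  expect_false(identical(s1$screen_table$viability, s3$screen_table$viability))
})

test_that("planted compounds have EC50 divided by planted_shift in target lines", {
  cfg <- screen_sim_config(n_compounds = 40, planted_set_size = 8,
                           planted_shift = 50, n_lines_target = 6,
                           n_lines_background = 9, seed = 3)
  sim <- simulate_screens(cfg)
  pars <- sim$truth$params
  grp <- sim$lineage$group[match(pars$cell_line, sim$lineage$cell_line)]
  for (cpd in sim$truth$planted_compound_ids) {
    e_t <- pars$e[pars$compound_id == cpd & grp == "target"]
    e_b <- pars$e[pars$compound_id == cpd & grp == "background"]
    expect_equal(unique(e_b) / unique(e_t), 50, tolerance = 1e-12)
    expect_equal(mean(e_t), mean(e_b) / 50, tolerance = 1e-12)
  }
})

test_that("ineffective compounds sit 1000x above the widest tested window", {
  cfg <- screen_sim_config(n_compounds = 40, planted_set_size = 5,
                           frac_ineffective = 0.25, seed = 9)
  sim <- simulate_screens(cfg)
  max_dose <- max(unlist(cfg$doses_per_screen))
  ineff <- sim$truth$ineffective_compound_ids
  expect_length(ineff, 10)  # floor(0.25 * 40)
  e_ineff <- sim$truth$params$e[sim$truth$params$compound_id %in% ineff]
  expect_true(all(e_ineff == 1e3 * max_dose))
})

test_that("viability is clamped and whole assays are dropped by missingness", {
  cfg <- screen_sim_config(n_compounds = 20, n_lines_target = 4,
                           n_lines_background = 6, planted_set_size = 2,
                           noise_sd = 0.5, missing_frac = 0.3, seed = 21)
  sim <- simulate_screens(cfg)
  expect_true(all(sim$screen_table$viability >= -0.2))
  expect_true(all(sim$screen_table$viability <= 1.5))
  ## dropped units are whole (screen, line, compound) assays: every retained
  ## assay has its full dose grid
  key <- paste(sim$screen_table$screen_id, sim$screen_table$cell_line,
               sim$screen_table$compound_id)
  counts <- table(key)
  grid_sizes <- lengths(cfg$doses_per_screen)
  expect_true(all(counts %in% grid_sizes))
  n_expected <- 3 * 10 * 20
  expect_lt(length(counts), n_expected)  # some assays dropped at 30%
})

test_that("simulator config errors name the offending field", {
  expect_error(screen_sim_config(planted_set_size = 30, n_compounds = 20),
               "planted_set_size")
  expect_error(screen_sim_config(noise_sd = -1), "noise_sd")
  expect_error(screen_sim_config(missing_frac = 2), "missing_frac")
  expect_error(coip_sim_config(n_reps_bait = 1), "n_reps_bait")
  expect_error(coip_sim_config(lod_slope = 0), "lod_slope")
  expect_error(coip_sim_config(n_interactors = 10, n_proteins = 5), "n_interactors")
})

test_that("saturating detection yields a complete intensity matrix", {
  cfg <- coip_sim_config(n_proteins = 300, n_interactors = 10,
                         lod_mid = -100, lod_slope = 5, seed = 2)
  sim <- simulate_interactome(cfg)
  expect_false(anyNA(sim$intensity))
  expect_identical(dim(sim$intensity), c(300L, 8L))
})

test_that("with effect_delta = 0 the bait-control mean difference is null", {
  cfg <- coip_sim_config(n_proteins = 3000, n_interactors = 100, effect_delta = 0,
                         lod_mid = -100, lod_slope = 5, seed = 8)
  sim <- simulate_interactome(cfg)
  bait <- sim$design$sample[sim$design$condition == "bait"]
  diffs <- rowMeans(sim$intensity[, bait]) -
    rowMeans(sim$intensity[, setdiff(colnames(sim$intensity), bait)])
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("detection midpoint at the abundance centre censors about half the cells", {
  cfg <- coip_sim_config(n_proteins = 4000, n_interactors = 0, effect_delta = 0,
                         base_mu = 25, lod_mid = 25, seed = 13)
  sim <- simulate_interactome(cfg)
  expect_equal(mean(is.na(sim$intensity)), 0.5, tolerance = 0.1)
  expect_lt(abs(mean(is.na(sim$intensity)) - 0.5), 0.05)
})

test_that("interactome missingness is left-censoring", {
  for (seed in 1:5) {
    sim <- simulate_interactome(coip_sim_config(n_proteins = 1000,
                                                n_interactors = 20, seed = seed))
    obs <- sim$intensity[!is.na(sim$intensity)]
    expect_gt(mean(is.na(sim$intensity)), 0)
    ## mean of observed values exceeds the base abundance mean (missing cells
    ## are preferentially low)
    expect_gt(mean(obs), 25)
    expect_identical(sim$intensity,
                     simulate_interactome(coip_sim_config(n_proteins = 1000,
                                                          n_interactors = 20,
                                                          seed = seed))$intensity)
  }
})
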