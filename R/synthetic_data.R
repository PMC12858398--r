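## Synthetic-data generators for both pipelines.
##
## The screen generator emulates multi-screen dose-response panels of the kind
## released by the public CTD2/GDSC/PRISM portals: each screen tests every
## compound on every cell line over its own log-spaced concentration window,
## relative viability is measured with Gaussian assay noise, and a planted
## compound class has its EC50 divided by a known fold-change in the target
## lineage.  The interactome generator emulates AP-MS log2-intensity matrices
## with bait-specific interactors and intensity-dependent (left-censored)
## detection.

#' Configuration for the drug-screen simulator
#'
#' Builds and validates the parameter set for [simulate_screens()]. Defaults
#' describe a three-screen panel of 120 compounds tested on 15 target-lineage
#' (B-lymphoid) and 40 background (solid-tumour) cell lines, with a planted
#' 10-compound class whose EC50 is 50-fold lower in the target lineage.
#'
#' @param n_screens Number of screens.
#' @param doses_per_screen List of length `n_screens`; each element a strictly
#'   positive, log-spaced dose grid in micromolar. `NULL` picks built-in
#'   windows that differ between screens (including width and placement).
#' @param n_lines_target,n_lines_background Cell-line counts per lineage group.
#' @param n_compounds Total number of compounds.
#' @param planted_set_size Size of the planted selective compound class.
#' @param planted_shift Fold-change (> 1) by which the planted-class EC50 is
#'   divided in target-lineage lines.
#' @param ec50_log_mu,ec50_log_sigma Mean and SD of log EC50 (natural log,
#'   micromolar) for the background EC50 distribution.
#' @param frac_ineffective Fraction of (non-planted) compounds whose EC50 is
#'   placed at 1000 times the maximal tested dose, so no screen window can
#'   elicit a response.
#' @param noise_sd Standard deviation of the Gaussian viability noise.
#' @param missing_frac Fraction of (screen, line, compound) assays dropped.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A validated list of class `"screen_sim_config"`.
#' @export
screen_sim_config <- function(n_screens = 3L,
                              doses_per_screen = NULL,
                              n_lines_target = 15L,
                              n_lines_background = 40L,
                              n_compounds = 120L,
                              planted_set_size = 10L,
                              planted_shift = 50,
                              ec50_log_mu = 0,
                              ec50_log_sigma = 1,
                              frac_ineffective = 0.15,
                              noise_sd = 0.05,
                              missing_frac = 0.05,
                              seed = 1L) {
  cfg <- list(
    n_screens = check_count(n_screens, "n_screens"),
    n_lines_target = check_count(n_lines_target, "n_lines_target"),
    n_lines_background = check_count(n_lines_background, "n_lines_background"),
    n_compounds = check_count(n_compounds, "n_compounds"),
    planted_set_size = check_count(planted_set_size, "planted_set_size", min = 0L),
    planted_shift = check_positive(planted_shift, "planted_shift"),
    ec50_log_mu = if (is.numeric(ec50_log_mu) && length(ec50_log_mu) == 1L &&
                      is.finite(ec50_log_mu)) as.numeric(ec50_log_mu) else
                    fail_field("ec50_log_mu", "must be a single finite number"),
    ec50_log_sigma = check_positive(ec50_log_sigma, "ec50_log_sigma", strict = FALSE),
    frac_ineffective = check_fraction(frac_ineffective, "frac_ineffective"),
    noise_sd = check_positive(noise_sd, "noise_sd", strict = FALSE),
    missing_frac = check_fraction(missing_frac, "missing_frac"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$planted_set_size > cfg$n_compounds) {
    fail_field("planted_set_size", "cannot exceed n_compounds")
  }
  if (cfg$planted_shift <= 1) fail_field("planted_shift", "must be > 1")
  if (is.null(doses_per_screen)) {
    doses_per_screen <- default_dose_grids(cfg$n_screens)
  }
  if (!is.list(doses_per_screen) || length(doses_per_screen) != cfg$n_screens) {
    fail_field("doses_per_screen", "must be a list with one dose grid per screen")
  }
  for (g in doses_per_screen) {
    if (!is.numeric(g) || length(g) < 2L || any(g <= 0) || is.unsorted(g, strictly = TRUE)) {
      fail_field("doses_per_screen", "each grid must be >= 2 strictly increasing positive doses")
    }
  }
  cfg$doses_per_screen <- lapply(doses_per_screen, as.numeric)
  class(cfg) <- "screen_sim_config"
  cfg
}

## Built-in screen windows (micromolar): deliberately unequal in width,
## density and placement, mimicking how CTD2/GDSC windows differ.
default_dose_grids <- function(n_screens) {
  base <- list(
    exp(seq(log(0.001), log(10), length.out = 9L)),
    exp(seq(log(0.005), log(20), length.out = 8L)),
    exp(seq(log(0.002), log(5), length.out = 7L))
  )
  base[((seq_len(n_screens) - 1L) %% length(base)) + 1L]
}

#' Simulate a multi-screen drug-sensitivity panel
#'
#' Draws per-compound four-parameter log-logistic curves, plants a selective
#' compound class, and tabulates noisy relative viabilities on each screen's
#' dose grid. Sub-draws use one RNG stream seeded from `config$seed`, in a
#' fixed order (curve parameters, then viability noise, then missingness), so
#' outputs are stable for a given seed.
#'
#' Lineage selectivity is deterministic at the curve level: for a planted
#' compound, every target-lineage line has a true EC50 equal to the
#' background EC50 divided by `planted_shift`. Ineffective compounds get an
#' EC50 of 1000 times the maximal dose across screens, so their curves stay
#' flat over every tested window.
#'
#' @param config A [screen_sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{screen_table}{Long-format data frame (`screen_id`, `cell_line`,
#'       `compound_id`, `dose`, `viability`), one row per surviving assay
#'       point. Viability is clamped to `[-0.2, 1.5]`.}
#'     \item{lineage}{Lineage annotation (`cell_line`, `group`, `disease`).}
#'     \item{targets}{Compound-to-target table; the planted class shares the
#'       target `"PLANTED"`, remaining compounds are grouped into decoy
#'       targets of about 8 members.}
#'     \item{truth}{Ground truth: `planted_compound_ids`,
#'       `ineffective_compound_ids`, and `params`, the per (compound, line)
#'       true curve parameters `b`, `c`, `d`, `e`.}
#'   }
#' @export
#' @examples
#' sim <- simulate_screens(screen_sim_config(n_compounds = 20, seed = 7))
#' head(sim$screen_table)
simulate_screens <- function(config) {
  if (!inherits(config, "screen_sim_config")) config <- do.call(screen_sim_config, config)
  set.seed(config$seed)
  n_cpd <- config$n_compounds
  compounds <- sprintf("CPD%03d", seq_len(n_cpd))
  lines_t <- sprintf("TGT%02d", seq_len(config$n_lines_target))
  lines_b <- sprintf("BGD%02d", seq_len(config$n_lines_background))
  lines <- c(lines_t, lines_b)
  group <- c(rep("target", length(lines_t)), rep("background", length(lines_b)))

  ## --- stage 1: curve parameters -----------------------------------------
  planted <- sort(sample(compounds, config$planted_set_size))
  non_planted <- setdiff(compounds, planted)
  n_ineff <- floor(config$frac_ineffective * n_cpd)
  ineffective <- sort(sample(non_planted, min(n_ineff, length(non_planted))))
  b_cpd <- stats::runif(n_cpd, 0.75, 2.5)
  c_cpd <- stats::runif(n_cpd, 0, 0.15)
  e_base <- exp(stats::rnorm(n_cpd, config$ec50_log_mu, config$ec50_log_sigma))
  names(b_cpd) <- names(c_cpd) <- names(e_base) <- compounds
  max_dose <- max(vapply(config$doses_per_screen, max, numeric(1)))
  e_base[ineffective] <- 1e3 * max_dose

  ## per (compound, line) truth: EC50 depends only on compound and lineage
  params <- expand.grid(compound_id = compounds, cell_line = lines,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  params$b <- b_cpd[params$compound_id]
  params$c <- c_cpd[params$compound_id]
  params$d <- 1
  shift <- ifelse(params$compound_id %in% planted &
                    group[match(params$cell_line, lines)] == "target",
                  config$planted_shift, 1)
  params$e <- e_base[params$compound_id] / shift

  ## --- stage 2: tabulate + noise ------------------------------------------
  tabs <- vector("list", config$n_screens)
  for (s in seq_len(config$n_screens)) {
    doses <- config$doses_per_screen[[s]]
    tab <- params[rep(seq_len(nrow(params)), each = length(doses)),
                  c("compound_id", "cell_line", "b", "c", "d", "e")]
    tab$screen_id <- sprintf("SCREEN%d", s)
    tab$dose <- rep(doses, times = nrow(params))
    tab$viability <- ll4_response(tab$dose, tab$b, tab$c, tab$d, tab$e)
    tabs[[s]] <- tab
  }
  tab <- do.call(rbind, tabs)
  tab$viability <- clamp(tab$viability + stats::rnorm(nrow(tab), 0, config$noise_sd),
                         -0.2, 1.5)

  ## --- stage 3: missingness at the whole-assay level ----------------------
  key <- paste(tab$screen_id, tab$cell_line, tab$compound_id, sep = "\r")
  assays <- unique(key)
  drop <- assays[stats::runif(length(assays)) < config$missing_frac]
  if (length(drop)) tab <- tab[!(key %in% drop), , drop = FALSE]

  screen_table <- data.frame(
    screen_id = tab$screen_id, cell_line = tab$cell_line,
    compound_id = tab$compound_id, dose = tab$dose,
    viability = tab$viability, stringsAsFactors = FALSE,
    row.names = NULL
  )
  screen_table <- screen_table[order(screen_table$screen_id, screen_table$cell_line,
                                     screen_table$compound_id, screen_table$dose), ]
  rownames(screen_table) <- NULL

  diseases_t <- c("B-ALL", "MCL", "DLBCL")
  diseases_b <- c("colon", "lung", "skin", "breast")
  lineage <- data.frame(
    cell_line = lines, group = group,
    disease = c(rep_len(diseases_t, length(lines_t)), rep_len(diseases_b, length(lines_b))),
    stringsAsFactors = FALSE
  )

  ## decoy target groups of ~8 compounds so enrichment has a set universe
  decoy <- split(non_planted, ceiling(seq_along(non_planted) / 8))
  targets <- rbind(
    if (length(planted)) data.frame(compound_id = planted, target = "PLANTED",
                                    stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_along(decoy), function(i) {
      data.frame(compound_id = decoy[[i]], target = sprintf("DECOY%02d", i),
                 stringsAsFactors = FALSE)
    }))
  )
  rownames(targets) <- NULL

  list(
    screen_table = screen_table,
    lineage = lineage,
    targets = targets,
    truth = list(planted_compound_ids = planted,
                 ineffective_compound_ids = ineffective,
                 params = params[, c("compound_id", "cell_line", "b", "c", "d", "e")],
                 lineage = lineage)
  )
}

#' Configuration for the AP-MS interactome simulator
#'
#' Parameters for [simulate_interactome()]. The defaults emulate a
#' four-versus-four bait/control co-IP experiment quantified at 2,000
#' proteins, with 50 true interactors enriched 4-fold (2 log2 units) in the
#' bait pulldown and a logistic detection model producing intensity-dependent
#' left-censoring.
#'
#' @param n_proteins Number of proteins.
#' @param n_interactors Number of true bait interactors (may be 0).
#' @param effect_delta Log2 intensity increase of interactors in bait samples.
#' @param n_reps_bait,n_reps_control Replicate counts (each >= 2).
#' @param base_mu,base_sd Mean and SD of the protein-level log2 abundance
#'   distribution.
#' @param rep_sd Replicate-level (within-protein) log2 noise SD.
#' @param lod_mid,lod_slope Logistic detection model: a cell with true log2
#'   intensity `v` is observed with probability `plogis(lod_slope * (v -
#'   lod_mid))`; `lod_slope` must be positive so censoring is left-sided.
#' @param seed Integer seed.
#' @return A validated list of class `"coip_sim_config"`.
#' @export
coip_sim_config <- function(n_proteins = 2000L,
                            n_interactors = 50L,
                            effect_delta = 2,
                            n_reps_bait = 4L,
                            n_reps_control = 4L,
                            base_mu = 25,
                            base_sd = 2,
                            rep_sd = 0.5,
                            lod_mid = 21,
                            lod_slope = 0.8,
                            seed = 1L) {
  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins"),
    n_interactors = check_count(n_interactors, "n_interactors", min = 0L),
    effect_delta = as.numeric(effect_delta),
    n_reps_bait = check_count(n_reps_bait, "n_reps_bait", min = 2L),
    n_reps_control = check_count(n_reps_control, "n_reps_control", min = 2L),
    base_mu = as.numeric(base_mu),
    base_sd = check_positive(base_sd, "base_sd", strict = FALSE),
    rep_sd = check_positive(rep_sd, "rep_sd", strict = FALSE),
    lod_mid = as.numeric(lod_mid),
    lod_slope = check_positive(lod_slope, "lod_slope"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_interactors > cfg$n_proteins) {
    fail_field("n_interactors", "cannot exceed n_proteins")
  }
  class(cfg) <- "coip_sim_config"
  cfg
}

#' Simulate an AP-MS intensity matrix with planted interactors
#'
#' Protein-level log2 abundances are drawn from `Normal(base_mu, base_sd)`,
#' replicate measurements add `Normal(0, rep_sd)` noise, and the planted
#' interactors gain `effect_delta` log2 units in bait samples. Each cell is
#' then independently censored with probability `1 - plogis(lod_slope *
#' (value - lod_mid))`, i.e. low-intensity measurements are preferentially
#' missing. Sub-draws are ordered (abundances, interactor identities,
#' replicate noise, detection) under one seeded RNG stream.
#'
#' @param config A [coip_sim_config()].
#' @return List with `intensity` (proteins x samples matrix, `NA` = not
#'   detected), `design` (data frame `sample`, `condition`, `replicate`), and
#'   `interactors` (character vector of planted interactor protein ids).
#' @export
simulate_interactome <- function(config) {
  if (!inherits(config, "coip_sim_config")) config <- do.call(coip_sim_config, config)
  set.seed(config$seed)
  p <- config$n_proteins
  proteins <- sprintf("P%04d", seq_len(p))
  samples <- c(sprintf("bait_%d", seq_len(config$n_reps_bait)),
               sprintf("control_%d", seq_len(config$n_reps_control)))
  condition <- rep(c("bait", "control"), c(config$n_reps_bait, config$n_reps_control))

  mu <- stats::rnorm(p, config$base_mu, config$base_sd)
  interactors <- sort(sample(proteins, config$n_interactors))
  shift <- matrix(0, p, length(samples))
  shift[proteins %in% interactors, condition == "bait"] <- config$effect_delta
  truth <- mu + shift + matrix(stats::rnorm(p * length(samples), 0, config$rep_sd),
                               p, length(samples))
  detected <- stats::runif(p * length(samples)) <
    stats::plogis(config$lod_slope * (truth - config$lod_mid))
  intensity <- ifelse(detected, truth, NA_real_)
  dimnames(intensity) <- list(proteins, samples)

  design <- data.frame(
    sample = samples, condition = condition,
    replicate = c(seq_len(config$n_reps_bait), seq_len(config$n_reps_control)),
    stringsAsFactors = FALSE
  )
  list(intensity = intensity, design = design, interactors = interactors)
}
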