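## End-to-end orchestration of the two sub-pipelines.
##
## Each run writes its result tables as TSV plus a JSON manifest recording
## the seed, every decision parameter (meta-analysis combiner, NES
## convention, imputation settings) and an MD5 inventory of the outputs, so
## a run is reproducible from its manifest alone.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

write_manifest <- function(out_dir, params, files) {
  inventory <- lapply(files, function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)))
  })
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   params = params, files = inventory)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the drug-screen selectivity pipeline
#'
#' Fits every curve, computes AAC and EC-window weights, scores per-screen
#' differential selectivity, combines screens by weighted meta-analysis,
#' and (when annotation is available) runs compound-set enrichment and
#' biomarker correlation. All stages write TSVs into `out_dir` together
#' with a JSON manifest; a stage failure aborts with the stage name.
#'
#' @param screen_table Long-format screen data frame, or a path readable by
#'   [read_screen_table()].
#' @param lineage Lineage annotation data frame or path.
#' @param targets Optional compound-target data frame or path; when absent
#'   the enrichment stage is skipped with a warning.
#' @param expression Optional genes x lines expression matrix (or path) for
#'   the biomarker stage.
#' @param biomarker_compound Compound id whose per-line AAC is correlated
#'   with expression; required for the biomarker stage.
#' @param out_dir Output directory (created).
#' @param config Configuration list as from [default_config()] /
#'   [load_config()]; `config$screen` supplies all tuning parameters.
#' @param seed Seed for the enrichment permutations (overrides
#'   `config$seed`).
#' @return Invisibly, a list with all result tables (`fits`, `weights`,
#'   `differential`, `meta`, `enrichment`, `biomarker`).
#' @export
run_screen_pipeline <- function(screen_table, lineage, targets = NULL,
                                expression = NULL, biomarker_compound = NULL,
                                out_dir, config = default_config(),
                                seed = config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$screen
  if (is.character(screen_table)) screen_table <- read_screen_table(screen_table)
  if (is.character(lineage)) lineage <- read_lineage_annotation(lineage)
  if (is.character(targets)) targets <- read_compound_targets(targets)
  if (is.character(expression)) expression <- read_expression_matrix(expression)

  fits <- run_stage("dose_response", fit_screen_table(
    screen_table, mode = sc$mode, grid_n = sc$grid_n,
    alpha = sc$alpha, response_threshold = sc$response_threshold))
  weights <- run_stage("screen_weight", screen_weights(fits))
  differential <- run_stage("differential", screen_differential(
    fits, lineage, min_group_size = sc$min_group_size))
  meta <- run_stage("meta_analysis", combine_screens(differential, weights))

  files <- c(
    write_tsv(fits, file.path(out_dir, "fits.tsv")),
    write_tsv(weights, file.path(out_dir, "weights.tsv")),
    write_tsv(differential, file.path(out_dir, "differential.tsv")),
    write_tsv(meta, file.path(out_dir, "meta.tsv"))
  )

  enrichment <- NULL
  if (!is.null(targets)) {
    sets <- run_stage("set_enrichment",
                      build_compound_sets(targets, meta$compound_id,
                                          min_size = sc$min_set_size))
    if (length(sets)) {
      enrichment <- run_stage("set_enrichment", compound_set_enrichment(
        meta, sets, n_perm = sc$n_perm, seed = seed, exponent = sc$exponent))
      files <- c(files, write_tsv(enrichment, file.path(out_dir, "enrichment.tsv")))
    }
  } else {
    warning("no compound-target table supplied; enrichment stage skipped",
            call. = FALSE)
  }

  biomarker <- NULL
  if (!is.null(expression) && !is.null(biomarker_compound)) {
    sens <- run_stage("biomarker", {
      rows <- fits$compound_id == biomarker_compound & is.finite(fits$aac)
      if (!any(rows)) stop("no AAC values for compound ", biomarker_compound)
      tapply(fits$aac[rows], fits$cell_line[rows], mean)
    })
    biomarker <- run_stage("biomarker", biomarker_correlation(
      expression, stats::setNames(as.numeric(sens), names(sens)),
      method = sc$biomarker_method, min_n = sc$biomarker_min_n))
    files <- c(files, write_tsv(biomarker, file.path(out_dir, "biomarker.tsv")))
  }

  params <- list(
    pipeline = "screen", seed = seed, mode = sc$mode,
    grid_n = sc$grid_n, alpha = sc$alpha,
    response_threshold = sc$response_threshold,
    min_group_size = sc$min_group_size, n_perm = sc$n_perm,
    min_set_size = sc$min_set_size, exponent = sc$exponent,
    effect_combiner = "weighted_mean_r",
    significance_combiner = "weighted_stouffer_z",
    nes_convention = "same_sign_mean_abs",
    biomarker_method = sc$biomarker_method
  )
  write_manifest(out_dir, params, files)
  invisible(list(fits = fits, weights = weights, differential = differential,
                 meta = meta, enrichment = enrichment, biomarker = biomarker))
}

#' Run the co-IP interactome scoring pipeline
#'
#' Quantile normalization, MNAR/MAR classification, mixed imputation,
#' empirical-Bayes moderated testing (bait vs control) and contaminant
#' downweighting, writing all intermediate and final tables plus a JSON
#' manifest into `out_dir`.
#'
#' @param intensity Proteins x samples matrix, or a path (then `design` must
#'   be a path too and both are read by [read_intensity_matrix()]).
#' @param design Data frame (`sample`, `condition`, `replicate`) or path.
#' @param background Optional contaminant table (`protein`,
#'   `avg_background`) or path; proteins absent from it are treated as
#'   having background at the floor.
#' @param out_dir Output directory.
#' @param config Configuration list; `config$coip` supplies all parameters.
#' @param seed Seed for the MinProb draws.
#' @return Invisibly, a list with `normalized`, `mask`, `imputed`,
#'   `moderated`, `downweighted`.
#' @export
run_interactome_pipeline <- function(intensity, design, background = NULL,
                                     out_dir, config = default_config(),
                                     seed = config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kc <- config$coip
  if (is.character(intensity)) {
    loaded <- read_intensity_matrix(intensity, design)
    intensity <- loaded$intensity
    design <- loaded$design
  }
  if (is.character(background)) {
    background <- utils::read.delim(background, sep = .delim_for(background),
                                    stringsAsFactors = FALSE)
  }

  normalized <- run_stage("quantile_normalize", quantile_normalize(intensity))
  mask <- run_stage("classify_missingness", classify_missingness(normalized, design))
  imputed <- run_stage("impute_mixed", impute_mixed(
    normalized, mask, minprob_q = kc$minprob_q, minprob_scale = kc$minprob_scale,
    tol = kc$em_tol, max_iter = kc$em_max_iter, seed = seed))
  moderated <- run_stage("moderated_test", moderated_test(
    imputed, design, bait = kc$bait, control = kc$control))

  fc_table <- data.frame(protein = moderated$protein,
                         fc_over_ig = moderated$log_fc, stringsAsFactors = FALSE)
  if (is.null(background)) {
    background <- data.frame(protein = character(0), avg_background = numeric(0))
  }
  downweighted <- run_stage("contaminant_downweight", contaminant_downweight(
    fc_table, background, floor = kc$background_floor))

  mask_summary <- as.data.frame(table(label = as.vector(mask),
                                      sample = rep(colnames(mask), each = nrow(mask))))
  files <- c(
    write_matrix_tsv(normalized, file.path(out_dir, "normalized.tsv"), "protein"),
    write_tsv(mask_summary, file.path(out_dir, "mask_summary.tsv")),
    write_matrix_tsv(imputed, file.path(out_dir, "imputed.tsv"), "protein"),
    write_tsv(moderated, file.path(out_dir, "moderated.tsv")),
    write_tsv(downweighted, file.path(out_dir, "downweighted.tsv"))
  )
  params <- list(
    pipeline = "interactome", seed = seed,
    bait = kc$bait, control = kc$control,
    minprob_q = kc$minprob_q, minprob_scale = kc$minprob_scale,
    em_tol = kc$em_tol, em_max_iter = kc$em_max_iter,
    background_floor = kc$background_floor,
    detected_rule = "non_missing_after_normalization",
    mar_model = "joint_gaussian_em_conditional_mean",
    test_values = "imputed_complete"
  )
  write_manifest(out_dir, params, files)
  invisible(list(normalized = normalized, mask = mask, imputed = imputed,
                 moderated = moderated, downweighted = downweighted))
}
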