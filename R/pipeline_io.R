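## Readers/writers and run configuration.
##
## Public drug-screen exports (CTD2/GDSC/PRISM releases) name their columns
## differently between releases, so the screen reader maps configurable
## aliases onto fixed canonical names. All validation drops are logged; no
## silent filtering.

#' Default column aliases for screen tables
#'
#' Maps each canonical column to the header names accepted in input files
#' (first match wins). Extend or override to accommodate a particular
#' release's export.
#'
#' @return Named list of character vectors.
#' @export
default_dialect <- function() {
  list(
    screen_id = c("screen_id", "screen", "dataset", "study"),
    cell_line = c("cell_line", "ccle_name", "cell_id", "sample"),
    compound_id = c("compound_id", "compound", "drug", "drug_id", "name"),
    dose = c("dose", "concentration", "conc", "dose_um"),
    viability = c("viability", "relative_viability", "response", "intensity_pct")
  )
}

.delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read and validate a long-format screen table
#'
#' Reads a delimited file (TSV by default, CSV by extension), maps column
#' aliases to the canonical names, and enforces the table invariants:
#' strictly positive doses, unique (screen, line, compound, dose) keys
#' (first row kept), and at least two distinct doses per (screen, line,
#' compound) group. Violating rows are dropped with a logged count. Inputs
#' whose viability looks like percent (maximum above 5) are rescaled to the
#' 1-equals-untreated-control convention and logged.
#'
#' @param path File path with a header row.
#' @param dialect Alias mapping, see [default_dialect()].
#' @return Validated data frame with the canonical columns.
#' @export
read_screen_table <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE,
                           check.names = FALSE)
  canon <- names(default_dialect())
  picked <- vapply(canon, function(cn) {
    hit <- intersect(dialect[[cn]] %||% cn, names(raw))
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  if (anyNA(picked)) {
    stop("screen table is missing required column(s): ",
         paste(canon[is.na(picked)], collapse = ", "), call. = FALSE)
  }
  tab <- stats::setNames(raw[, picked, drop = FALSE], canon)

  for (col in c("dose", "viability")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at file line(s) %s", col,
                   paste(utils::head(bad + 1L, 5), collapse = ", ")), call. = FALSE)
    }
    tab[[col]] <- v
  }
  tab <- tab[stats::complete.cases(tab[, c("dose", "viability")]), , drop = FALSE]

  if (any(tab$viability > 5, na.rm = TRUE)) {
    ss_log("INFO", "viability maximum %.1f looks like percent; rescaling by 1/100",
           max(tab$viability))
    tab$viability <- tab$viability / 100
  }
  nonpos <- tab$dose <= 0
  if (any(nonpos)) {
    warning(sprintf("dropped %d row(s) with non-positive dose", sum(nonpos)),
            call. = FALSE)
    tab <- tab[!nonpos, , drop = FALSE]
  }
  key <- paste(tab$screen_id, tab$cell_line, tab$compound_id, tab$dose, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    ss_log("WARN", "deduplicated %d row(s) with repeated (screen, line, compound, dose) keys",
           sum(dup))
    tab <- tab[!dup, , drop = FALSE]
  }
  gkey <- paste(tab$screen_id, tab$cell_line, tab$compound_id, sep = "\r")
  ndose <- stats::ave(tab$dose, gkey, FUN = function(d) length(unique(d)))
  if (any(ndose < 2)) {
    ss_log("INFO", "dropped %d row(s) from groups with < 2 distinct doses",
           sum(ndose < 2))
    tab <- tab[ndose >= 2, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Read a lineage annotation table
#'
#' Expects columns `cell_line`, `group` (values `"target"` / `"background"`)
#' and optionally `disease`. Duplicate cell lines keep their first row with a
#' logged count.
#'
#' @param path Delimited file with a header.
#' @return Data frame with one row per cell line.
#' @export
read_lineage_annotation <- function(path) {
  tab <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_line", "group"), names(tab))
  if (length(miss)) stop("lineage annotation missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !tab$group %in% c("target", "background")
  if (any(bad)) stop("lineage group must be 'target' or 'background'", call. = FALSE)
  dup <- duplicated(tab$cell_line)
  if (any(dup)) {
    ss_log("WARN", "deduplicated %d repeated cell line annotation(s)", sum(dup))
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Read a compound-to-target annotation table
#'
#' @param path Delimited file with columns `compound_id` and `target`.
#' @return Data frame of unique (compound, target) pairs.
#' @export
read_compound_targets <- function(path) {
  tab <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  miss <- setdiff(c("compound_id", "target"), names(tab))
  if (length(miss)) stop("target table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dup <- duplicated(tab[, c("compound_id", "target")])
  if (any(dup)) {
    ss_log("WARN", "deduplicated %d repeated compound-target pair(s)", sum(dup))
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Read a genes x cell-lines expression matrix
#'
#' First column (or row names) holds gene identifiers; remaining columns are
#' cell lines with log2 expression values.
#'
#' @param path Delimited file with a header.
#' @return Numeric matrix with gene row names.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE,
                           check.names = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers", call. = FALSE)
  if (!all(is.finite(m))) stop("expression matrix must be finite", call. = FALSE)
  m
}

#' Read a proteins x samples intensity matrix with its design
#'
#' @param intensity_path Wide delimited file: first column protein ids,
#'   remaining columns samples; empty cells or `NA` mean not detected.
#' @param design_path Delimited file with columns `sample`, `condition`,
#'   `replicate`.
#' @return List with `intensity` (numeric matrix) and `design` (data frame).
#' @export
read_intensity_matrix <- function(intensity_path, design_path) {
  tab <- utils::read.delim(intensity_path, sep = .delim_for(intensity_path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           row.names = 1L)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  design <- utils::read.delim(design_path, sep = .delim_for(design_path),
                              stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "condition"), names(design))
  if (length(miss)) stop("design missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  check_design(m, design)
  list(intensity = m, design = design)
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output path (directories are created).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a matrix as TSV with an id column
#'
#' @param m Matrix with row names.
#' @param path Output path.
#' @param id_name Header of the id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_tsv(df, path)
}

#' Default run configuration
#'
#' Returns the full default configuration for both pipelines. Every key can
#' be overridden from a YAML/JSON file via [load_config()]; unknown keys are
#' rejected.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    screen = list(
      mode = "LL4",
      grid_n = 101L,
      alpha = 0.05,
      response_threshold = 0.5,
      min_group_size = 3L,
      n_perm = 10000L,
      min_set_size = 6L,
      exponent = 1,
      biomarker_method = "pearson",
      biomarker_min_n = 10L
    ),
    coip = list(
      bait = "bait",
      control = "control",
      minprob_q = 0.01,
      minprob_scale = 0.3,
      em_tol = 1e-6,
      em_max_iter = 100L,
      background_floor = 1
    )
  )
}

check_config <- function(cfg) {
  s <- cfg$screen
  if (s$n_perm < 0) fail_field("screen.n_perm", "must be non-negative")
  check_count(s$grid_n, "screen.grid_n", min = 2L)
  check_count(s$min_group_size, "screen.min_group_size")
  check_count(s$min_set_size, "screen.min_set_size")
  check_fraction(s$alpha, "screen.alpha")
  check_fraction(s$response_threshold, "screen.response_threshold")
  if (!s$mode %in% c("LL4", "LL3_upper1")) fail_field("screen.mode", "must be LL4 or LL3_upper1")
  if (!s$biomarker_method %in% c("pearson", "spearman")) {
    fail_field("screen.biomarker_method", "must be pearson or spearman")
  }
  k <- cfg$coip
  check_fraction(k$minprob_q, "coip.minprob_q")
  check_positive(k$minprob_scale, "coip.minprob_scale", strict = FALSE)
  check_positive(k$background_floor, "coip.background_floor")
  check_count(k$em_max_iter, "coip.em_max_iter")
  invisible(cfg)
}

merge_config <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) stop("configuration key must be a mapping: ", full,
                                      call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else if (!is.null(user[[key]])) {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration from YAML or JSON
#'
#' Fills unspecified keys with the defaults of [default_config()], rejects
#' unknown keys by name, and validates value ranges. An empty file yields
#' the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Validated nested list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  check_config(merge_config(default_config(), user))
}

#' Write a run configuration as YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
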