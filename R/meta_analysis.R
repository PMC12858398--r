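## Weighted meta-analysis across screens.
##
## Screens test different concentration windows; a screen whose window sits
## far below the EC50s of a compound class is uninformative for it.  Each
## screen is therefore weighted by the fraction of its curves that are
## "effective" (significant fit with > 50% modelled response; see
## is_effective()), and per-screen effect sizes are combined with those
## weights: a weighted mean for the effect size r (the single differential
## score) and weighted Stouffer combination of the signed z for significance.

#' EC-window weight of one screen
#'
#' The weight is the fraction of attempted curves flagged effective,
#' `w = n_effective / n_total`.
#'
#' @param fit_table Per-curve table for a single screen (from
#'   [fit_screen_table()]), with logical column `effective`.
#' @return One-row data frame: `screen_id`, `w`, `n_effective`, `n_total`.
#' @export
screen_weight <- function(fit_table) {
  stopifnot(all(c("screen_id", "effective") %in% names(fit_table)))
  if (nrow(fit_table) == 0) stop("empty screen: no curves to weight", call. = FALSE)
  sid <- unique(fit_table$screen_id)
  if (length(sid) != 1L) {
    stop("screen_weight() expects curves from a single screen", call. = FALSE)
  }
  n_eff <- sum(fit_table$effective, na.rm = TRUE)
  n_tot <- nrow(fit_table)
  data.frame(screen_id = sid, w = n_eff / n_tot,
             n_effective = n_eff, n_total = n_tot, stringsAsFactors = FALSE)
}

#' EC-window weights for every screen in a fit table
#'
#' @param fit_table Per-curve table from [fit_screen_table()], any number of
#'   screens.
#' @return Data frame with one row per screen (see [screen_weight()]).
#' @export
screen_weights <- function(fit_table) {
  parts <- split(fit_table, fit_table$screen_id)
  res <- do.call(rbind, lapply(parts, screen_weight))
  rownames(res) <- NULL
  res
}

#' Combine per-screen differential results into one score per compound
#'
#' For every compound, over the screens that scored it and have positive
#' weight:
#' `combined_r = sum(w_s * r_s) / sum(w_s)` (the single differential score),
#' `combined_z = sum(w_s * z_s) / sqrt(sum(w_s^2))` (weighted Stouffer on the
#' signed z), and `combined_p` the two-sided normal tail of `combined_z`.
#' Zero-weight screens are excluded; compounds scored in no positive-weight
#' screen are dropped with a logged count.
#'
#' @param differentials Data frame from [screen_differential()] (possibly
#'   several screens stacked).
#' @param weights Data frame from [screen_weights()].
#' @return Data frame: `compound_id`, `combined_r`, `combined_z`,
#'   `combined_p`, `n_screens`, `screens_used`, `weights_used`
#'   (semicolon-joined).
#' @export
#' @examples
#' d <- data.frame(screen_id = c("s1", "s2"), compound_id = "c1",
#'                 delta_aac = 0, r = c(0.5, -0.5), z = c(2, -2), p = 0.05,
#'                 n_target = 5, n_background = 5)
#' w <- data.frame(screen_id = c("s1", "s2"), w = c(1, 1),
#'                 n_effective = 10, n_total = 10)
#' combine_screens(d, w)$combined_r  # 0: equal weights cancel
combine_screens <- function(differentials, weights) {
  stopifnot(all(c("screen_id", "compound_id", "r", "z", "p") %in% names(differentials)),
            all(c("screen_id", "w") %in% names(weights)))
  w_of <- stats::setNames(weights$w, weights$screen_id)
  unknown <- setdiff(unique(differentials$screen_id), names(w_of))
  if (length(unknown)) {
    stop("no weight available for screen(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  d <- differentials
  d$w <- unname(w_of[d$screen_id])
  d <- d[d$w > 0, , drop = FALSE]
  dropped <- setdiff(unique(differentials$compound_id), unique(d$compound_id))
  if (length(dropped)) {
    ss_log("INFO", "%d compounds scored only in zero-weight screens were dropped",
           length(dropped))
  }
  if (nrow(d) == 0) stop("all screens have zero weight", call. = FALSE)

  groups <- split(seq_len(nrow(d)), d$compound_id)
  res <- do.call(rbind, lapply(groups, function(rows) {
    w <- d$w[rows]
    z <- sum(w * d$z[rows]) / sqrt(sum(w^2))
    data.frame(
      compound_id = d$compound_id[rows[1]],
      combined_r = sum(w * d$r[rows]) / sum(w),
      combined_z = z,
      combined_p = max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
      n_screens = length(rows),
      screens_used = paste(d$screen_id[rows], collapse = ";"),
      weights_used = paste(format(w, digits = 6, trim = TRUE), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  res[order(res$compound_id), , drop = FALSE]
}
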