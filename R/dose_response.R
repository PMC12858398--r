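## Log-logistic dose-response modelling.
##
## The model is the conventional four-parameter log-logistic (LL4):
##
##   f(x) = c + (d - c) / (1 + exp(b * (log x - log e)))
##
## with slope b > 0 for curves that decrease with dose, lower asymptote c,
## upper asymptote d and inflection concentration e (the relative EC50).
## LL3_upper1 fixes d = 1, appropriate when viability is normalised to an
## untreated control. Each curve is summarised by the area above the curve
## (AAC) over the tested log-concentration window, and by an effectiveness
## flag (significant fit and modelled inhibition > 50%) that feeds the
## EC-window screen weights of the meta-analysis.

#' Four-parameter log-logistic response
#'
#' Evaluates `f(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))`.
#' With `b > 0` the response decreases with dose; at `x = e` the response is
#' the midpoint `(c + d) / 2`.
#'
#' @param dose Strictly positive dose(s).
#' @param b Slope (Hill coefficient); positive for decreasing curves.
#' @param c,d Lower and upper asymptotes (relative viability).
#' @param e Inflection concentration, the relative EC50 (same units as dose).
#' @return Modelled viability, vectorised over all arguments.
#' @export
#' @examples
#' ll4_response(0.3, b = 1.5, c = 0.1, d = 1, e = 0.3)  # (c + d) / 2
ll4_response <- function(dose, b, c, d, e) {
  if (any(dose <= 0)) stop("dose must be strictly positive", call. = FALSE)
  if (any(e <= 0)) stop("e (EC50) must be strictly positive", call. = FALSE)
  c + (d - c) / (1 + exp(b * (log(dose) - log(e))))
}

## Parameter bounds shared by fitting and the convergence check.
## e is handled on the log scale for numerical stability.
ll4_bounds <- function(dose_min, dose_max, mode) {
  lower <- c(b = 1e-3, c = -0.2, d = 0, loge = log(dose_min / 100))
  upper <- c(b = 50, c = 1.2, d = 1.5, loge = log(100 * dose_max))
  if (mode == "LL3_upper1") {
    lower <- lower[c("b", "c", "loge")]
    upper <- upper[c("b", "c", "loge")]
  }
  list(lower = lower, upper = upper)
}

## theta is positional: (b, c, d, loge) for LL4, (b, c, loge) for LL3_upper1.
.ll4_resid <- function(theta, lx, y, ll4) {
  if (ll4) {
    theta[2L] + (theta[3L] - theta[2L]) / (1 + exp(theta[1L] * (lx - theta[4L]))) - y
  } else {
    theta[2L] + (1 - theta[2L]) / (1 + exp(theta[1L] * (lx - theta[3L]))) - y
  }
}

#' Fit a log-logistic dose-response curve
#'
#' Least-squares fit of the LL4 model (or LL3 with the upper asymptote fixed
#' at 1) by bounded Levenberg-Marquardt, with a deterministic multi-start over
#' initial slopes `b0 in {0.5, 1, 3}` keeping the lowest residual sum of
#' squares. A lack-of-dose-effect p-value (`p_fit`) is computed from the
#' extra-sum-of-squares F-test of the fitted model against the constant-mean
#' model.
#'
#' The `converged` flag requires the optimiser to report success, the
#' parameters to be interior to their bounds, an ordered asymptote pair
#' (`c <= d`), and a minimally identifiable dynamic range (`d - c > 0.01`);
#' non-converged fits keep their best-found parameters (so AAC is still
#' defined) but are excluded from EC-window weights and return a missing
#' EC50.
#'
#' @param doses,responses Numeric vectors of equal length; doses > 0.
#' @param mode `"LL4"` (four free parameters, needs >= 4 distinct doses) or
#'   `"LL3_upper1"` (d fixed at 1, needs >= 3 distinct doses).
#' @return An object of class `"dose_response_fit"`: a list with parameters
#'   `b`, `c`, `d`, `e`, plus `rss`, `n_points`, `p_fit`, `dose_min`,
#'   `dose_max`, `converged`, `mode` and (for skipped fits) `reason`.
#' @export
#' @examples
#' d <- exp(seq(log(0.01), log(10), length.out = 8))
#' y <- ll4_response(d, 1.5, 0.1, 1, 0.3)
#' fit <- fit_dose_response(d, y)
#' c(fit$b, fit$c, fit$d, fit$e)
fit_dose_response <- function(doses, responses, mode = c("LL4", "LL3_upper1")) {
  mode <- match.arg(mode)
  stopifnot(length(doses) == length(responses))
  keep <- is.finite(doses) & is.finite(responses)
  doses <- doses[keep]; responses <- responses[keep]
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  n_par <- if (mode == "LL4") 4L else 3L
  out <- list(b = NA_real_, c = NA_real_, d = if (mode == "LL4") NA_real_ else 1,
              e = NA_real_, rss = NA_real_, n_points = length(responses),
              p_fit = NA_real_, dose_min = suppressWarnings(min(doses)),
              dose_max = suppressWarnings(max(doses)),
              converged = FALSE, mode = mode, reason = NA_character_)
  class(out) <- "dose_response_fit"
  if (length(unique(doses)) < n_par) {
    out$reason <- "insufficient_doses"
    return(out)
  }

  lx <- log(doses)
  y <- responses
  bnd <- ll4_bounds(min(doses), max(doses), mode)
  c0 <- clamp(min(y), -0.2, 1.2)
  d0 <- if (mode == "LL4") clamp(max(y), 0, 1.5) else 1
  e0 <- doses[which.min(abs(y - (c0 + d0) / 2))]
  best <- NULL
  for (b0 in c(0.5, 1, 3)) {
    start <- c(b = b0, c = c0, d = d0, loge = log(e0))
    if (mode == "LL3_upper1") start <- start[c("b", "c", "loge")]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = bnd$lower, upper = bnd$upper,
                         fn = .ll4_resid, lx = lx, y = y, ll4 = (mode == "LL4"),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    out$reason <- "optimizer_failure"
    return(out)
  }

  th <- best$par
  out$b <- unname(th["b"])
  out$c <- unname(th["c"])
  out$d <- if (mode == "LL4") unname(th["d"]) else 1
  out$e <- exp(unname(th["loge"]))
  out$rss <- best$deviance
  rss0 <- sum((y - mean(y))^2)
  df2 <- length(y) - n_par
  if (df2 > 0) {
    if (rss0 <= out$rss + 1e-300 || out$rss <= 0) {
      out$p_fit <- 1
    } else {
      F <- ((rss0 - out$rss) / (n_par - 1)) / (out$rss / df2)
      out$p_fit <- stats::pf(F, n_par - 1, df2, lower.tail = FALSE)
    }
  }
  interior <- all(th > bnd$lower + 1e-6 * pmax(1, abs(bnd$lower))) &&
    all(th < bnd$upper - 1e-6 * pmax(1, abs(bnd$upper)))
  out$converged <- (best$info %in% 1:4) && interior &&
    (out$c <= out$d) && (out$d - out$c > 0.01)
  out
}

## Clamped fitted viabilities on a uniform log-dose grid; shared by AAC and
## the effectiveness flag.
fit_grid <- function(fit, grid_n) {
  lx <- seq(log(fit$dose_min), log(fit$dose_max), length.out = grid_n)
  v <- fit$c + (fit$d - fit$c) / (1 + exp(fit$b * (lx - log(fit$e))))
  clamp(v, 0, 1)
}

#' Area above the fitted dose-response curve
#'
#' AAC is one minus the mean clamped fitted viability over the tested
#' log-concentration window:
#' `1 - (1 / (log(dmax) - log(dmin))) * integral of clamp(f, 0, 1) d log(x)`,
#' evaluated by the trapezoid rule on a uniform log-dose grid. Normalising by
#' the log-window width makes screens with different windows comparable;
#' clamping keeps AAC in `[0, 1]` even when asymptotes stray outside.
#' Non-converged fits still yield an AAC from their best-found parameters.
#'
#' @param fit A `"dose_response_fit"`.
#' @param grid_n Number of grid points (>= 2).
#' @return AAC in `[0, 1]`; 0 means no effect, 1 complete kill. `NA` if the
#'   fit was skipped.
#' @export
compute_aac <- function(fit, grid_n = 101L) {
  stopifnot(inherits(fit, "dose_response_fit"), grid_n >= 2)
  if (!is.finite(fit$dose_min) || !is.finite(fit$dose_max) ||
      fit$dose_min >= fit$dose_max) {
    stop("AAC needs a non-degenerate dose window (dose_min < dose_max)", call. = FALSE)
  }
  if (!is.finite(fit$b)) return(NA_real_)
  v <- fit_grid(fit, grid_n)
  mean_v <- (sum(v) - (v[1] + v[grid_n]) / 2) / (grid_n - 1)  # trapezoid mean
  1 - mean_v
}

#' Is a curve effective within its tested window?
#'
#' A curve lies "within the EC window" when the fit converged, the
#' dose-effect F-test is significant at `alpha`, and the maximal modelled
#' response (1 minus the minimum clamped fitted viability over the window)
#' strictly exceeds `response_threshold`. The fraction of effective curves
#' per screen is the screen weight used by [combine_screens()].
#'
#' @param fit A `"dose_response_fit"`.
#' @param alpha Significance cutoff for `p_fit`.
#' @param response_threshold Minimal modelled inhibition (strict inequality).
#' @param grid_n Grid size for the window minimum.
#' @return Logical flag; `FALSE` for non-converged or skipped fits.
#' @export
is_effective <- function(fit, alpha = 0.05, response_threshold = 0.5, grid_n = 101L) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!isTRUE(fit$converged)) return(FALSE)
  if (!is.finite(fit$p_fit) || fit$p_fit >= alpha) return(FALSE)
  max_response <- 1 - min(fit_grid(fit, grid_n))
  max_response > response_threshold
}

#' Relative EC50 of a converged fit
#'
#' Returns the inflection parameter `e`. Non-converged fits (including flat
#' curves, where the inflection is unidentifiable) return `NA`.
#'
#' @param fit A `"dose_response_fit"`.
#' @return EC50 in dose units, or `NA`.
#' @export
ec50 <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (isTRUE(fit$converged)) fit$e else NA_real_
}

#' Fit every curve of a long-format screen table
#'
#' Groups the table by (screen, cell line, compound), fits each group with
#' [fit_dose_response()], and returns the per-curve fit table used downstream
#' (AAC, effectiveness flag, EC-window weights). Groups with fewer distinct
#' doses than the model needs are retained with `reason =
#' "insufficient_doses"` and missing parameters.
#'
#' @param screen_table Data frame with columns `screen_id`, `cell_line`,
#'   `compound_id`, `dose`, `viability`.
#' @param mode Model mode passed to [fit_dose_response()].
#' @param grid_n AAC grid size.
#' @param alpha,response_threshold Effectiveness cutoffs, see [is_effective()].
#' @return Data frame with one row per curve: identifiers, `b`, `c`, `d`,
#'   `e`, `rss`, `n_points`, `p_fit`, `aac`, `effective`, `converged`,
#'   `reason`.
#' @export
fit_screen_table <- function(screen_table, mode = "LL4", grid_n = 101L,
                             alpha = 0.05, response_threshold = 0.5) {
  need <- c("screen_id", "cell_line", "compound_id", "dose", "viability")
  miss <- setdiff(need, names(screen_table))
  if (length(miss)) stop("screen table lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  key <- paste(screen_table$screen_id, screen_table$cell_line,
               screen_table$compound_id, sep = "\r")
  groups <- split(seq_len(nrow(screen_table)), key)
  n <- length(groups)
  res <- data.frame(
    screen_id = character(n), cell_line = character(n), compound_id = character(n),
    b = numeric(n), c = numeric(n), d = numeric(n), e = numeric(n),
    rss = numeric(n), n_points = integer(n), p_fit = numeric(n),
    aac = numeric(n), effective = logical(n), converged = logical(n),
    reason = character(n), stringsAsFactors = FALSE
  )
  dose_col <- screen_table$dose
  via_col <- screen_table$viability
  for (i in seq_len(n)) {
    rows <- groups[[i]]
    r1 <- rows[1]
    fit <- fit_dose_response(dose_col[rows], via_col[rows], mode = mode)
    res$screen_id[i] <- screen_table$screen_id[r1]
    res$cell_line[i] <- screen_table$cell_line[r1]
    res$compound_id[i] <- screen_table$compound_id[r1]
    res$b[i] <- fit$b; res$c[i] <- fit$c; res$d[i] <- fit$d; res$e[i] <- fit$e
    res$rss[i] <- fit$rss; res$n_points[i] <- fit$n_points; res$p_fit[i] <- fit$p_fit
    res$aac[i] <- if (is.finite(fit$b)) compute_aac(fit, grid_n) else NA_real_
    res$effective[i] <- is_effective(fit, alpha, response_threshold, grid_n)
    res$converged[i] <- fit$converged
    res$reason[i] <- fit$reason
  }
  rownames(res) <- NULL
  res
}
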