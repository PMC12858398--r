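## Co-IP proteomics scoring.
##
## Protein log2 intensities are quantile-normalized across samples; missing
## values are classified per (protein, condition) as MNAR (left-censored:
## detected in fewer than two replicates of that condition) or MAR
## (otherwise), then imputed by a MinProb draw (MNAR) or by
## maximum-likelihood conditional means under a joint Gaussian across
## samples (MAR).  Differential enrichment between bait and control uses a
## two-group linear model with empirical-Bayes variance moderation, and the
## display score divides the bait/control fold change by average background
## binding from a contaminant (CRAPome-style) table.

#' Quantile-normalize an intensity matrix
#'
#' Maps each sample's observed values onto the cross-sample mean quantile
#' distribution: after normalization every sample's sorted observed values
#' follow the same reference vector (the mean of the per-sample quantile
#' functions), tied values receive the mean of the quantiles they span, and
#' missing cells stay missing. Samples with unequal numbers of observed
#' values are aligned by linear interpolation of their quantile functions.
#'
#' @param mat Numeric matrix, proteins x samples, `NA` allowed.
#' @return Matrix of the same shape with normalized observed values.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("quantile normalization needs >= 2 samples", call. = FALSE)
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs < 2)) {
    stop("sample(s) with fewer than 2 observed values: ",
         paste(colnames(mat)[n_obs < 2], collapse = ", "), call. = FALSE)
  }
  m <- max(n_obs)
  probs_ref <- seq(0, 1, length.out = m)
  ## reference: mean of per-sample quantile functions on a common grid
  qfuns <- vapply(seq_len(ncol(mat)), function(j) {
    v <- sort(mat[, j])
    if (length(v) == m) v else
      stats::approx(seq(0, 1, length.out = length(v)), v, probs_ref)$y
  }, numeric(m))
  ref <- rowMeans(qfuns)

  out <- mat
  for (j in seq_len(ncol(mat))) {
    obs <- which(!is.na(mat[, j]))
    v <- mat[obs, j]
    nj <- length(v)
    target <- if (nj == m) ref else
      stats::approx(probs_ref, ref, seq(0, 1, length.out = nj))$y
    vals <- numeric(nj)
    vals[order(v)] <- target
    out[obs, j] <- stats::ave(vals, factor(v))  # ties: mean of spanned quantiles
  }
  out
}

#' Classify missing cells as MNAR or MAR
#'
#' Per (protein, condition): if the protein was detected in fewer than two
#' replicates of that condition, its missing cells in that condition are
#' labelled MNAR (assumed left-censored); otherwise MAR. "Detected" means
#' non-missing; no intensity threshold is applied. Observed cells are
#' labelled `"observed"`.
#'
#' @param mat Proteins x samples matrix with `NA` for missing.
#' @param design Data frame with columns `sample` and `condition`; every
#'   condition needs at least 2 replicates.
#' @return Character matrix of the same shape with entries `"observed"`,
#'   `"MNAR"`, `"MAR"`.
#' @export
classify_missingness <- function(mat, design) {
  check_design(mat, design)
  mask <- matrix("observed", nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (cond in unique(design$condition)) {
    cols <- which(colnames(mat) %in% design$sample[design$condition == cond])
    detected <- rowSums(!is.na(mat[, cols, drop = FALSE]))
    lab <- ifelse(detected < 2, "MNAR", "MAR")
    for (j in cols) {
      miss <- is.na(mat[, j])
      mask[miss, j] <- lab[miss]
    }
  }
  mask
}

check_design <- function(mat, design) {
  stopifnot(is.matrix(mat), all(c("sample", "condition") %in% names(design)))
  if (is.null(colnames(mat)) || !all(colnames(mat) %in% design$sample)) {
    stop("every matrix column must appear in design$sample", call. = FALSE)
  }
  reps <- table(design$condition[design$sample %in% colnames(mat)])
  if (any(reps < 2)) {
    stop("condition(s) with fewer than 2 replicates: ",
         paste(names(reps)[reps < 2], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mixed MNAR/MAR imputation
#'
#' MNAR cells are imputed by MinProb: independent draws from
#' `Normal(q_j, minprob_scale * sd_j)` where `q_j` is the `minprob_q`
#' quantile and `sd_j` the standard deviation of sample `j`'s observed
#' values. MAR cells are imputed by maximum likelihood: an EM fit of a joint
#' Gaussian over samples (proteins as observations), with MNAR-imputed cells
#' treated as observed, filled in with the conditional expectations at
#' convergence (parameter change below `tol`, or `max_iter` reached with a
#' warning).
#'
#' @param mat Proteins x samples matrix with `NA` for missing.
#' @param mask Classification from [classify_missingness()].
#' @param minprob_q Low quantile at which MinProb draws are centred.
#' @param minprob_scale Multiplier on the per-sample SD for MinProb draws.
#' @param tol,max_iter EM convergence controls.
#' @param seed Integer seed for the MinProb draws (deterministic given seed).
#' @return Complete matrix (no missing cells).
#' @export
impute_mixed <- function(mat, mask, minprob_q = 0.01, minprob_scale = 0.3,
                         tol = 1e-6, max_iter = 100L, seed = 1L) {
  stopifnot(is.matrix(mat), identical(dim(mat), dim(mask)))
  if (any((mask == "observed") != !is.na(mat))) {
    stop("mask is inconsistent with the matrix: 'observed' must match non-missing cells",
         call. = FALSE)
  }
  set.seed(seed)
  out <- mat
  ## MinProb for left-censored cells, per sample
  for (j in seq_len(ncol(mat))) {
    mnar <- which(mask[, j] == "MNAR")
    if (length(mnar)) {
      obs <- mat[!is.na(mat[, j]), j]
      centre <- stats::quantile(obs, minprob_q, names = FALSE)
      out[mnar, j] <- stats::rnorm(length(mnar), centre, minprob_scale * stats::sd(obs))
    }
  }
  ## EM conditional means for MAR cells
  mar <- mask == "MAR"
  if (any(mar)) {
    work <- out
    work[mar] <- NA_real_
    filled <- em_gaussian_impute(work, tol = tol, max_iter = max_iter)
    out[mar] <- filled[mar]
  }
  out
}

## EM for a multivariate Gaussian over the columns (samples), rows are iid
## observations. Missing entries are filled with conditional expectations;
## the M-step includes the conditional-covariance correction. Rows are
## grouped by missingness pattern so each pattern's linear solve happens
## once per iteration.
em_gaussian_impute <- function(x, tol = 1e-6, max_iter = 100L, ridge = 1e-8) {
  p <- ncol(x)
  miss <- is.na(x)
  if (any(rowSums(miss) == p)) {
    stop("EM imputation cannot handle rows with no observed value", call. = FALSE)
  }
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- stats::cov(x, use = "pairwise.complete.obs")
  sigma[!is.finite(sigma)] <- 0
  diag(sigma) <- pmax(diag(sigma), 1e-6)
  pat <- apply(miss, 1L, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(nrow(x)), pat)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    xhat <- x
    cc_sum <- matrix(0, p, p)  # sum of conditional covariances
    for (g in names(groups)) {
      if (g == "") next
      rows <- groups[[g]]
      mi <- as.integer(strsplit(g, ",")[[1]])
      oi <- setdiff(seq_len(p), mi)
      s_oo <- sigma[oi, oi, drop = FALSE] + diag(ridge, length(oi))
      s_mo <- sigma[mi, oi, drop = FALSE]
      beta <- s_mo %*% solve(s_oo)
      dev <- t(x[rows, oi, drop = FALSE]) - mu[oi]
      xhat[rows, mi] <- matrix(mu[mi], length(rows), length(mi), byrow = TRUE) +
        t(beta %*% dev)
      cond_cov <- sigma[mi, mi, drop = FALSE] - beta %*% t(s_mo)
      cc_sum[mi, mi] <- cc_sum[mi, mi] + length(rows) * cond_cov
    }
    mu_new <- colMeans(xhat)
    centred <- sweep(xhat, 2L, mu_new)
    sigma_new <- (crossprod(centred) + cc_sum) / nrow(x)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("EM imputation did not converge in %d iterations; using best iterate",
                    max_iter), call. = FALSE)
  }
  ## final fill at the converged parameters
  xhat <- x
  for (g in names(groups)) {
    if (g == "") next
    rows <- groups[[g]]
    mi <- as.integer(strsplit(g, ",")[[1]])
    oi <- setdiff(seq_len(p), mi)
    s_oo <- sigma[oi, oi, drop = FALSE] + diag(ridge, length(oi))
    beta <- sigma[mi, oi, drop = FALSE] %*% solve(s_oo)
    dev <- t(x[rows, oi, drop = FALSE]) - mu[oi]
    xhat[rows, mi] <- matrix(mu[mi], length(rows), length(mi), byrow = TRUE) +
      t(beta %*% dev)
  }
  xhat
}

## Newton inversion of the trigamma function, used by the empirical-Bayes
## hyperparameter fit.  Solves trigamma(x) = y for x > 0 to ~1e-10.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderated two-group test
#'
#' Per protein, fits the two-group linear model (`log_fc` = mean(bait) -
#' mean(control)) and moderates the residual variance by shrinking toward a
#' prior: hyperparameters `d0` (prior df) and `s0_sq` (prior variance) are
#' estimated by moment matching on `log(s2)` using digamma/trigamma
#' relations, the posterior variance is
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, and the moderated t is
#' `log_fc / sqrt(s2_post * (1/n1 + 1/n2))` on `d0 + df` degrees of freedom.
#'
#' @param mat Complete (imputed) proteins x samples matrix.
#' @param design Data frame with `sample` and `condition`.
#' @param bait,control Condition labels contrasted as bait - control.
#' @param d0,s0_sq Optional overrides of the estimated hyperparameters
#'   (`d0 = 0` gives the ordinary t; `d0 = Inf` full shrinkage to `s0_sq`).
#' @return Data frame: `protein`, `log_fc`, `s2`, `s2_post`, `t_mod`,
#'   `df_total`, `p`, `q`, plus the shared `d0` and `s0_sq`.
#' @export
moderated_test <- function(mat, design, bait = "bait", control = "control",
                           d0 = NULL, s0_sq = NULL) {
  check_design(mat, design)
  if (anyNA(mat)) stop("moderated_test() needs a complete (imputed) matrix", call. = FALSE)
  cols_b <- which(colnames(mat) %in% design$sample[design$condition == bait])
  cols_c <- which(colnames(mat) %in% design$sample[design$condition == control])
  if (length(cols_b) < 2 || length(cols_c) < 2) {
    stop("both contrasted conditions need >= 2 replicates", call. = FALSE)
  }
  n1 <- length(cols_b); n2 <- length(cols_c)
  xb <- mat[, cols_b, drop = FALSE]; xc <- mat[, cols_c, drop = FALSE]
  mb <- rowMeans(xb); mc <- rowMeans(xc)
  log_fc <- mb - mc
  df <- n1 + n2 - 2
  s2 <- (rowSums((xb - mb)^2) + rowSums((xc - mc)^2)) / df
  v <- 1 / n1 + 1 / n2

  if (is.null(d0) || is.null(s0_sq)) {
    pos <- s2 > 0
    if (!any(pos)) stop("all residual variances are zero; cannot estimate prior",
                        call. = FALSE)
    est <- fit_variance_prior(s2[pos], df)
    if (is.null(d0)) d0 <- est$d0
    if (is.null(s0_sq)) s0_sq <- est$s0_sq
  }

  if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 <= 0) {
    s2_post <- s2
    df_total <- rep(df, length(s2))
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- rep(d0 + df, length(s2))
  }
  t_mod <- log_fc / sqrt(s2_post * v)
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  data.frame(
    protein = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    log_fc = log_fc, s2 = s2, s2_post = s2_post, t_mod = t_mod,
    df_total = df_total, p = p, q = stats::p.adjust(p, method = "BH"),
    d0 = d0, s0_sq = s0_sq, row.names = NULL, stringsAsFactors = FALSE
  )
}

## Moment matching of a scaled-inverse-chi^2 prior on the sample variances:
## e_g = log(s2_g) - digamma(df/2) + log(df/2) has mean log(s0_sq) -
## digamma(d0/2) + log(d0/2) and variance trigamma(df/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, df) {
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Downweight common contaminants by average background binding
#'
#' Divides each protein's fold change over the Ig control pulldown by its
#' average background binding from a contaminant (CRAPome-style) table,
#' floored at `floor` so near-zero backgrounds cannot inflate the score.
#' Proteins absent from the background table keep their fold change
#' unchanged (background treated as `floor`).
#'
#' @param fc_table Data frame with `protein` and `fc_over_ig`.
#' @param background_table Data frame with `protein` and `avg_background`
#'   (non-negative).
#' @param floor Positive lower bound on the divisor.
#' @return Data frame: `protein`, `fc_over_ig`, `avg_background`, `score`.
#' @export
contaminant_downweight <- function(fc_table, background_table, floor = 1.0) {
  stopifnot(all(c("protein", "fc_over_ig") %in% names(fc_table)),
            all(c("protein", "avg_background") %in% names(background_table)),
            floor > 0)
  if (any(background_table$avg_background < 0, na.rm = TRUE)) {
    stop("avg_background must be non-negative", call. = FALSE)
  }
  bg <- background_table$avg_background[match(fc_table$protein, background_table$protein)]
  bg[is.na(bg)] <- floor
  data.frame(
    protein = fc_table$protein,
    fc_over_ig = fc_table$fc_over_ig,
    avg_background = bg,
    score = fc_table$fc_over_ig / pmax(bg, floor),
    stringsAsFactors = FALSE
  )
}
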