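# Independent oracles used to validate the package's statistics. These are
# written against the definitions directly (enumeration, naive loops,
# closed-form algebra) and share no code with the implementation paths they
# check.

# Exhaustive enumeration of the rank-sum permutation distribution (mid-ranks
# kept, so tied data are handled by conditioning on the observed ranks).
oracle_ranksum <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  rk <- rank(c(x, y), ties.method = "average")
  combs <- utils::combn(N, n1)
  Us <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(U = U, null = Us,
       p = min(1, 2 * min(mean(Us <= U), mean(Us >= U))))
}

# Normal-approximation z with tie correction and continuity correction,
# written out from the contract (independent of the package code).
oracle_ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y), ties.method = "average")
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tt <- table(rk)
  s2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  dev <- U - n1 * n2 / 2
  if (dev == 0 || s2 <= 0) 0 else (dev - sign(dev) * 0.5) / sqrt(s2)
}

# Naive O(N * |members|) running-sum enrichment score.
oracle_es <- function(scores, members, exponent = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit <- names(s) %in% members
  s <- unname(s)
  N <- length(s); Nh <- sum(hit)
  denom <- sum(abs(s[hit])^exponent)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (denom > 0) abs(s[i])^exponent / denom else 1 / Nh
    } else {
      -1 / (N - Nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Direct closed-form moderated t, independent of the package path: pooled
# variances, moment matching on log s2 with a uniroot-based trigamma
# inversion (the package uses Newton iteration).
oracle_moderated_t <- function(mat, bait_cols, control_cols) {
  n1 <- length(bait_cols); n2 <- length(control_cols)
  xb <- mat[, bait_cols, drop = FALSE]; xc <- mat[, control_cols, drop = FALSE]
  fc <- rowMeans(xb) - rowMeans(xc)
  df <- n1 + n2 - 2
  s2 <- (rowSums((xb - rowMeans(xb))^2) + rowSums((xc - rowMeans(xc))^2)) / df
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    half_d0 <- uniroot(function(x) trigamma(x) - evar,
                       lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    d0 <- 2 * half_d0
    s0 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
    s2_post <- (d0 * s0 + df * s2) / (d0 + df)
    dft <- d0 + df
  } else {
    s2_post <- rep(exp(mean(e)), length(s2))
    dft <- Inf
  }
  t_mod <- fc / sqrt(s2_post * (1 / n1 + 1 / n2))
  list(t_mod = t_mod, p = 2 * pt(-abs(t_mod), dft), df_total = dft)
}

# Small complete-data dose-response fixture from known parameters.
make_curve <- function(b, c, d, e, n = 8, span = 30, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  doses <- exp(seq(log(e / span), log(span * e), length.out = n))
  list(doses = doses,
       responses = ll4_response(doses, b, c, d, e) + rnorm(n, 0, noise))
}
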