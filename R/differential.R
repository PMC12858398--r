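## Per-screen differential sensitivity scoring.
##
## For every compound in one screen, the AAC values of target-lineage cell
## lines are contrasted against the background panel with a rank-sum test.
## The signed effect size r = z / sqrt(N) is positive when the target group
## is more sensitive (higher AAC), so a positive r reads as target-selective
## toxicity.

#' Signed Wilcoxon rank-sum effect size
#'
#' Mann-Whitney statistic with mid-ranks for ties; `z` from the normal
#' approximation with tie-corrected variance and a continuity correction;
#' `r = z / sqrt(n1 + n2)`, positive when `values_target` tends larger. The
#' two-sided p-value is computed exactly (by enumerating the permutation
#' distribution of the rank sum, conditional on the observed ranks) whenever
#' `choose(n1 + n2, n1) <= exact_max`, and from the normal approximation
#' otherwise.
#'
#' @param values_target,values_background Numeric vectors.
#' @param exact_max Enumeration budget: the exact p-value is used when the
#'   number of group assignments does not exceed this.
#' @return List with `r`, `z`, `p`, `n_target`, `n_background` and `exact`
#'   (whether p came from enumeration).
#' @export
#' @examples
#' wilcoxon_effect_size(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
wilcoxon_effect_size <- function(values_target, values_background,
                                 exact_max = 20000) {
  x <- as.numeric(values_target); y <- as.numeric(values_background)
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  rk <- rank(c(x, y), ties.method = "average")
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_tab <- table(rk)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(r = 0, z = 0, p = 1, n_target = n1, n_background = n2, exact = TRUE))
  }
  dev <- U - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)  # continuity correction
  if (dev == 0) z <- 0
  r <- z / sqrt(N)

  if (choose(N, n1) <= exact_max) {
    sums <- utils::combn(N, n1, FUN = function(i) sum(rk[i]))
    Us <- sums - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    exact <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(r = r, z = z, p = max(p, .Machine$double.xmin),
       n_target = n1, n_background = n2, exact = exact)
}

#' Per-screen differential selectivity of every compound
#'
#' For each (screen, compound) with at least `min_group_size` annotated cell
#' lines in both the target and background groups, computes the difference in
#' mean AAC (`delta_aac = mean AAC target - mean AAC background`) and the
#' signed Wilcoxon effect size of [wilcoxon_effect_size()]. Cell lines absent
#' from the lineage annotation are excluded with a logged count; compounds
#' below the group-size minimum are skipped with reason
#' `"insufficient_lines"`.
#'
#' @param aac_table Per-curve table from [fit_screen_table()] (needs
#'   `screen_id`, `cell_line`, `compound_id`, `aac`).
#' @param lineage Annotation data frame with `cell_line` and `group`
#'   (`"target"` / `"background"`).
#' @param min_group_size Minimum lines per group (default 3; below that the
#'   normal approximation and the effect size are not meaningful).
#' @return Data frame with one row per scored (screen, compound):
#'   `delta_aac`, `r`, `z`, `p`, `n_target`, `n_background`.
#' @export
screen_differential <- function(aac_table, lineage, min_group_size = 3L) {
  stopifnot(all(c("screen_id", "cell_line", "compound_id", "aac") %in% names(aac_table)),
            all(c("cell_line", "group") %in% names(lineage)))
  grp <- lineage$group[match(aac_table$cell_line, lineage$cell_line)]
  n_unannot <- sum(is.na(grp))
  if (n_unannot == nrow(aac_table) || nrow(aac_table) == 0) {
    stop("no annotated cell lines in the AAC table", call. = FALSE)
  }
  if (n_unannot > 0) {
    ss_log("INFO", "excluding %d AAC rows from unannotated cell lines", n_unannot)
  }
  tab <- aac_table[!is.na(grp) & is.finite(aac_table$aac), , drop = FALSE]
  grp <- grp[!is.na(grp) & is.finite(aac_table$aac)]

  key <- paste(tab$screen_id, tab$compound_id, sep = "\r")
  groups <- split(seq_len(nrow(tab)), key)
  out <- vector("list", length(groups))
  n_skipped <- 0L
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    tgt <- tab$aac[rows][grp[rows] == "target"]
    bgd <- tab$aac[rows][grp[rows] == "background"]
    if (length(tgt) < min_group_size || length(bgd) < min_group_size) {
      n_skipped <- n_skipped + 1L
      next
    }
    w <- wilcoxon_effect_size(tgt, bgd)
    out[[i]] <- data.frame(
      screen_id = tab$screen_id[rows[1]], compound_id = tab$compound_id[rows[1]],
      delta_aac = mean(tgt) - mean(bgd),
      r = w$r, z = w$z, p = w$p,
      n_target = w$n_target, n_background = w$n_background,
      stringsAsFactors = FALSE
    )
  }
  if (n_skipped > 0) {
    ss_log("INFO", "skipped %d (screen, compound) pairs: insufficient_lines", n_skipped)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) stop("no (screen, compound) pair met the group-size minimum",
                         call. = FALSE)
  rownames(res) <- NULL
  res
}
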