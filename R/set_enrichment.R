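## Permutation compound-set enrichment over a ranked compound list.
##
## Compounds are ranked by their combined selectivity score; each
## compound-target set is tested with the weighted Kolmogorov-Smirnov
## running-sum statistic of the preranked-enrichment convention: hit
## increments proportional to |score|^exponent (normalised to sum 1 over the
## set), miss decrements 1/(N - set size), ES the signed extremum of the
## running sum.  The null is built by drawing size-matched random member sets
## from the universe; NES divides ES by the mean |ES| of same-sign
## permutations.

#' Build compound sets from a compound-to-target table
#'
#' One set per target, restricted to compounds present in the ranked
#' universe; sets with more than five in-universe members are kept (strictly
#' more, i.e. `min_size = 6` by default).
#'
#' @param targets Data frame with columns `compound_id` and `target`.
#' @param universe Character vector of ranked compound ids.
#' @param min_size Minimal member count for a set to be kept.
#' @return Named list of character vectors (set id -> member compounds);
#'   empty list (with a warning) when no set qualifies.
#' @export
build_compound_sets <- function(targets, universe, min_size = 6L) {
  stopifnot(all(c("compound_id", "target") %in% names(targets)))
  targets <- unique(targets[, c("compound_id", "target")])
  targets <- targets[targets$compound_id %in% universe, , drop = FALSE]
  sets <- split(targets$compound_id, targets$target)
  sets <- lapply(sets, unique)
  sets <- sets[vapply(sets, length, integer(1)) >= min_size]
  if (length(sets) == 0) {
    warning("no compound set with enough in-universe members; enrichment skipped",
            call. = FALSE)
  }
  sets
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' @param scores Named numeric vector of per-compound scores; sorted in
#'   decreasing order internally.
#' @param members Character vector of set member ids (must be a strict,
#'   non-empty subset of the score names).
#' @param exponent Weighting exponent on |score| for hit increments.
#' @return The signed enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(scores, members, exponent = 1) {
  es_running(scores, members, exponent)$es
}

## Running-sum details shared by enrichment_score() and the permutation
## engine: returns the ES, its position, and the leading-edge members.
es_running <- function(scores, members, exponent = 1) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be uniquely named by compound id", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  ids <- names(s)
  hit <- ids %in% members
  N <- length(s); Nh <- sum(hit)
  if (Nh == 0) stop("no set member present in the ranked universe", call. = FALSE)
  if (Nh == N) stop("member set equals the ranked universe", call. = FALSE)
  w <- abs(s)^exponent
  denom_hit <- sum(w[hit])
  inc <- if (denom_hit > 0) {
    ifelse(hit, w / denom_hit, -1 / (N - Nh))
  } else {
    ifelse(hit, 1 / Nh, -1 / (N - Nh))  # all hit scores zero: unweighted
  }
  running <- cumsum(inc)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) ids[hit & seq_len(N) <= i_ext] else ids[hit & seq_len(N) > i_ext]
  list(es = es, position = i_ext, leading_edge = leading, running = running)
}

#' Permutation compound-set enrichment analysis
#'
#' Ranks compounds by `combined_r` and scores every set with
#' [enrichment_score()]. For each set size, `n_perm` random size-matched
#' member sets are drawn from the universe; the normalized enrichment score
#' is `es / mean(|es_perm|)` over same-sign permutations, the permutation
#' p-value is `(1 + #{same-sign |es_perm| >= |es|}) / (1 + #same-sign)`, and
#' q is Benjamini-Hochberg across sets. Deterministic given `seed`.
#'
#' @param meta Data frame from [combine_screens()] (needs `compound_id` and
#'   the ranking column), or any data frame with those columns.
#' @param sets Named list from [build_compound_sets()].
#' @param n_perm Number of permutations (a warning is raised below 100).
#' @param seed Integer seed for the permutation draws.
#' @param rank_by Column of `meta` to rank by (default `"combined_r"`).
#' @param exponent Hit-weight exponent.
#' @return Data frame: `set_id`, `size`, `es`, `nes`, `p_perm`, `q`,
#'   `leading_edge` (semicolon-joined), sorted by decreasing `nes`.
#' @export
compound_set_enrichment <- function(meta, sets, n_perm = 10000L, seed = 1L,
                                    rank_by = "combined_r", exponent = 1) {
  stopifnot(all(c("compound_id", rank_by) %in% names(meta)))
  if (length(sets) == 0) stop("no compound sets to test", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives unstable q-values", call. = FALSE)
  scores <- stats::setNames(meta[[rank_by]], meta$compound_id)
  universe <- names(scores)

  set.seed(seed)
  sizes <- sort(unique(vapply(sets, function(m) sum(m %in% universe), integer(1))))
  null_es <- lapply(stats::setNames(sizes, sizes), function(k) {
    vapply(seq_len(n_perm), function(b) {
      enrichment_score(scores, sample(universe, k), exponent)
    }, numeric(1))
  })

  rows <- lapply(names(sets), function(sid) {
    obs <- es_running(scores, sets[[sid]], exponent)
    k <- sum(sets[[sid]] %in% universe)
    perm <- null_es[[as.character(k)]]
    same <- perm[sign(perm) == sign(obs$es)]
    if (length(same) == 0) {
      nes <- NA_real_; p <- 1 / (1 + 0)
    } else {
      nes <- obs$es / mean(abs(same))
      p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    }
    data.frame(set_id = sid, size = k, es = obs$es, nes = nes, p_perm = p,
               leading_edge = paste(obs$leading_edge, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p_perm, method = "BH")
  res <- res[order(-res$nes), c("set_id", "size", "es", "nes", "p_perm", "q",
                                "leading_edge")]
  rownames(res) <- NULL
  res
}
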