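#' Filter gene sets against an analysis universe
#'
#' Each set is intersected with the universe first; sets whose remaining
#' size is strictly greater than `min_size` and strictly less than
#' `max_size` are retained.
#'
#' @param sets Named list of character vectors (gene sets).
#' @param universe Character vector of analyzable genes.
#' @param min_size,max_size Exclusive size bounds (defaults 15 / 500).
#' @return Named list of filtered sets.
#' @export
filter_sets <- function(sets, universe, min_size = 15, max_size = 500) {
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) > 0) {
    abort("Gene sets must have unique names.")
  }
  out <- purrr::map(sets, ~ intersect(.x, universe))
  sizes <- lengths(out)
  out[sizes > min_size & sizes < max_size]
}

# Sort a named score vector into GSEA rank order: decreasing score with
# lexicographic gene-id tie-break (determinism).
rank_scores <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)) > 0) {
    abort("Ranking scores must be a named vector with unique gene ids.")
  }
  scores[order(-scores, names(scores), method = "radix")]
}

#' GSEA weighted running-sum enrichment score
#'
#' Walks the ranked gene list; genes in the set increment the running sum
#' by `|score|^weight / sum(|score|^weight over the set)`, genes outside
#' decrement it by `1 / (N - n_set)`. The enrichment score is the
#' extremum of the running sum.
#'
#' @param scores Named numeric vector of ranking scores (e.g. moderated
#'   t); sorted internally.
#' @param set Character vector of set members (must intersect the list).
#' @param weight Weighting exponent on the hit increments (default 1).
#' @return List with `es`, and `running`: a tibble
#'   (`position`, `gene_id`, `hit`, `running_sum`).
#' @export
enrichment_score <- function(scores, set, weight = 1) {
  s <- rank_scores(scores)
  hit <- names(s) %in% set
  if (!any(hit)) abort("Gene set is disjoint from the ranked list.")
  n <- length(s)
  n_set <- sum(hit)
  w <- abs(s)^weight
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  if (n > n_set) inc[!hit] <- -1 / (n - n_set)
  run <- cumsum(inc)
  es <- run[which.max(abs(run))]
  list(es = es,
       running = tibble(position = seq_len(n), gene_id = names(s),
                        hit = hit, running_sum = run))
}

# ES only, for permutation loops (same walk, no bookkeeping).
es_value <- function(abs_w, hit_idx, n) {
  inc <- rep(-1 / (n - length(hit_idx)), n)
  inc[hit_idx] <- abs_w[hit_idx] / sum(abs_w[hit_idx])
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Pre-ranked GSEA with gene-set permutation
#'
#' For every gene set, the observed enrichment score is compared with a
#' null distribution of scores from `n_perm` random gene sets of the same
#' size drawn from the ranked universe. The normalized enrichment score
#' divides the ES by the mean absolute null ES of matching sign; nominal
#' p-values are the same-sign exceedance fraction (with a +1 pseudocount,
#' so the floor is `1/(n_perm+1)`); FDR q-values follow the sign-stratified
#' GSEA procedure: for a set with normalized score `nes`,
#' `q = [share of pooled null NES at least as extreme, same sign] /
#'      [share of observed NES at least as extreme, same sign]`,
#' capped at 1 and made monotone in `|nes|`.
#'
#' @param scores Named numeric ranking vector (the universe).
#' @param sets Named list of gene sets, already passed through
#'   [filter_sets()].
#' @param n_perm Number of gene-set permutations (default 1000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param weight Hit-weighting exponent (default 1).
#' @return A tibble of class `enrichment_result`: `set_name`, `size`,
#'   `es`, `nes`, `p_nominal`, `fdr_q`.
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, seed = 1,
                           weight = 1) {
  if (length(sets) == 0) {
    out <- tibble(set_name = character(), size = integer(), es = numeric(),
                  nes = numeric(), p_nominal = numeric(), fdr_q = numeric())
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  if (n_perm < 100) warn("n_perm < 100 gives very coarse p-values.")
  s <- rank_scores(scores)
  n <- length(s)
  abs_w <- abs(s)^weight

  obs <- vapply(sets, function(st) {
    es_value(abs_w, which(names(s) %in% st), n)
  }, numeric(1))

  sizes <- lengths(purrr::map(sets, ~ intersect(.x, names(s))))
  if (any(sizes == 0)) abort("A gene set is disjoint from the ranked list.")

  withr::with_seed(seed, {
    null_by_size <- purrr::map(
      setNames(unique(sizes), unique(sizes)),
      function(sz) {
        vapply(seq_len(n_perm), function(b) {
          es_value(abs_w, sort(sample.int(n, sz)), n)
        }, numeric(1))
      })
  })

  norm_one <- function(es, null_es) {
    pos_mean <- mean(abs(null_es[null_es >= 0]))
    neg_mean <- mean(abs(null_es[null_es < 0]))
    if (es >= 0) {
      list(nes = if (is.nan(pos_mean)) NA_real_ else es / pos_mean,
           null_nes = c(null_es[null_es >= 0] / pos_mean,
                        null_es[null_es < 0] / neg_mean))
    } else {
      list(nes = if (is.nan(neg_mean)) NA_real_ else es / neg_mean,
           null_nes = c(null_es[null_es >= 0] / pos_mean,
                        null_es[null_es < 0] / neg_mean))
    }
  }

  nes <- numeric(length(sets)); p_nom <- numeric(length(sets))
  null_nes_pool <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    null_es <- null_by_size[[as.character(sizes[k])]]
    same_sign <- if (obs[k] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p_nom[k] <- (1 + sum(abs(same_sign) >= abs(obs[k]))) /
      (1 + length(same_sign))
    nrm <- norm_one(obs[k], null_es)
    nes[k] <- nrm$nes
    null_nes_pool[[k]] <- nrm$null_nes[is.finite(nrm$null_nes)]
  }

  pool <- unlist(null_nes_pool)
  fdr_q <- vapply(seq_along(sets), function(k) {
    v <- nes[k]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num_d <- sum(pool >= 0); obs_d <- sum(nes >= 0, na.rm = TRUE)
      num <- if (num_d == 0) 1 else sum(pool >= v) / num_d
      den <- if (obs_d == 0) 1 else sum(nes >= v, na.rm = TRUE) / obs_d
    } else {
      num_d <- sum(pool < 0); obs_d <- sum(nes < 0, na.rm = TRUE)
      num <- if (num_d == 0) 1 else sum(pool <= v) / num_d
      den <- if (obs_d == 0) 1 else sum(nes <= v, na.rm = TRUE) / obs_d
    }
    min(1, num / den)
  }, numeric(1))

  # enforce monotonicity: a more extreme |NES| never gets a larger q
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & (if (sgn > 0) nes >= 0 else nes < 0))
    if (length(idx) > 1) {
      ord <- idx[order(abs(nes[idx]))]  # least extreme first
      fdr_q[ord] <- cummin(fdr_q[ord])  # q(set) = min over itself + less extreme
    }
  }

  out <- tibble(set_name = names(sets), size = unname(sizes),
                es = unname(obs), nes = unname(nes),
                p_nominal = unname(p_nom), fdr_q = unname(fdr_q))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_sets = nrow(x), n_significant = sum(x$fdr_q < 0.05, na.rm = TRUE),
         n_perm = attr(x, "n_perm") %||% NA_integer_)
}
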