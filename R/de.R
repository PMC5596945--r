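#' Log counts-per-million transform
#'
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`, the transform applied to
#' count matrices before linear modelling on the log scale.
#'
#' @param counts Non-negative integer matrix (genes x samples) or an
#'   `expression_study` in counts mode.
#' @param lib_size Optional vector of library sizes; defaults to column
#'   sums.
#' @return Matrix of log2-CPM values (or an `expression_study` in
#'   normalized mode when one was supplied).
#' @export
log_cpm <- function(counts, lib_size = NULL) {
  if (inherits(counts, "expression_study")) {
    if (counts$mode != "counts") abort("Study is already normalized.")
    out <- counts
    out$matrix <- log_cpm(counts$matrix, lib_size)
    out$mode <- "normalized"
    return(out)
  }
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  t(log2(t(counts + 0.5) / (lib_size + 1) * 1e6))
}

# Newton inversion of the trigamma function, used by the empirical-Bayes
# variance moment estimator. Converges quadratically from the standard
# starting value 0.5 + 1/x.
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50) {
  vapply(x, function(xi) {
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in seq_len(max_iter)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < tol) break
    }
    y
  }, numeric(1))
}

# Moment estimation of the scaled inverse-chi-square prior (d0, s0^2) from
# per-gene sample variances with df degrees of freedom (Smyth's EB scheme,
# on the log-variance scale).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok)) abort("All genes have zero variance; cannot moderate.")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s0_2 = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(d0 = d0, s0_2 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderated paired t-test
#'
#' Differential expression between the two groups of a paired study,
#' computed as a one-sample moderated t on within-subject differences
#' (equivalent to the paired contrast). Per-gene variances are shrunk
#' toward a common prior fitted by method of moments on the log sample
#' variances: `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)` and
#' `t = mean(d) / (s_post / sqrt(n))` on `df + d0` degrees of freedom.
#'
#' @param expr An `expression_study` (normalized mode; use [log_cpm()]
#'   first for counts).
#' @param group_a,group_b Group labels; log2 fold change is
#'   `group_a - group_b`. Defaults to the sorted group labels.
#' @param lfc_cutoff Absolute log2-fold-change threshold for the DE call
#'   (default 2).
#' @param fdr_cutoff BH FDR threshold for the DE call (default 0.05).
#' @param d0 Optional fixed prior degrees of freedom; `d0 = 0` recovers
#'   the classical paired t, `NULL` (default) estimates it from the data.
#' @return A tibble of class `de_result` with columns `gene_id`,
#'   `log2_fc`, `t_mod`, `p_value`, `fdr`, `is_de`, and attributes
#'   `d0`, `s0_2`, `df`.
#' @export
moderated_paired_t <- function(expr, group_a = study_groups(expr)[1],
                               group_b = study_groups(expr)[2],
                               lfc_cutoff = 2, fdr_cutoff = 0.05,
                               d0 = NULL) {
  if (!inherits(expr, "expression_study")) {
    abort("`expr` must be an expression_study.")
  }
  if (expr$mode != "normalized") {
    abort("Run log_cpm() first: moderated t expects log-scale values.")
  }
  d <- paired_differences(expr, group_a, group_b)
  n <- ncol(d)
  if (n < 3) abort("Need at least 3 subject pairs.")
  df <- n - 1
  m <- rowMeans(d)
  s2 <- rowSums((d - m)^2) / df

  if (all(s2 == 0)) {
    # degenerate all-constant differences (e.g. identical groups):
    # zero-difference genes get t = 0, p = 1; anything else is infinite
    t_mod <- ifelse(m == 0, 0, Inf * sign(m))
    p <- ifelse(m == 0, 1, 0)
    out <- tibble(gene_id = rownames(d), log2_fc = unname(m),
                  t_mod = unname(t_mod), p_value = unname(p),
                  fdr = p.adjust(unname(p), method = "BH"),
                  is_de = unname(p.adjust(p, method = "BH") < fdr_cutoff &
                                   abs(m) > lfc_cutoff))
    attr(out, "d0") <- NA_real_
    attr(out, "s0_2") <- 0
    attr(out, "df") <- df
    attr(out, "groups") <- c(group_a, group_b)
    class(out) <- c("de_result", class(out))
    return(out)
  }

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, df)
    d0 <- prior$d0; s0_2 <- prior$s0_2
  } else if (d0 == 0) {
    s0_2 <- 0
  } else {
    s0_2 <- fit_variance_prior(s2, df)$s0_2
  }
  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  t_mod <- m / sqrt(s2_post / n)
  t_mod[s2_post == 0 & m == 0] <- 0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  fdr <- p.adjust(p, method = "BH")
  out <- tibble(gene_id = rownames(d), log2_fc = unname(m),
                t_mod = unname(t_mod), p_value = unname(p),
                fdr = unname(fdr),
                is_de = unname(fdr < fdr_cutoff & abs(m) > lfc_cutoff))
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "df") <- df
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("de_result", class(out))
  out
}

#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x), n_de = sum(x$is_de),
         n_up = sum(x$is_de & x$log2_fc > 0),
         n_down = sum(x$is_de & x$log2_fc < 0),
         d0 = attr(x, "d0"), s0_2 = attr(x, "s0_2"), df = attr(x, "df"))
}

#' Per-gene F-test for differential expression variance
#'
#' Compares gene-wise expression variance between the two groups:
#' `F = s2_a / s2_b`, two-sided p-value from the F distribution, BH FDR,
#' and the fraction of genes in each group with significantly greater
#' variance at the FDR threshold.
#'
#' @param expr An `expression_study`.
#' @param group_a,group_b Group labels (numerator / denominator).
#' @param fdr_cutoff FDR threshold used for the per-group fractions.
#' @return A tibble of class `variance_f_result` with columns `gene_id`,
#'   `var_a`, `var_b`, `f_stat`, `p_value`, `fdr`, `higher_in`, plus a
#'   `fractions` attribute (named vector: share of genes with
#'   significantly greater variance in each group).
#' @export
variance_f_test <- function(expr, group_a = study_groups(expr)[1],
                            group_b = study_groups(expr)[2],
                            fdr_cutoff = 0.05) {
  a <- group_matrix(expr, group_a)
  b <- group_matrix(expr, group_b)
  if (ncol(a) < 2 || ncol(b) < 2) abort("Need >= 2 samples per group.")
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  df1 <- ncol(a) - 1; df2 <- ncol(b) - 1
  f <- va / vb
  p <- ifelse(vb == 0,
              ifelse(va == 0, 1, 0),  # one-sided limit, flagged below
              2 * pmin(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE)))
  p <- pmin(p, 1)
  fdr <- p.adjust(p, method = "BH")
  higher <- ifelse(fdr < fdr_cutoff,
                   ifelse(f > 1, group_a, group_b), NA_character_)
  out <- tibble(gene_id = rownames(a), var_a = unname(va), var_b = unname(vb),
                f_stat = unname(f), p_value = unname(p), fdr = unname(fdr),
                higher_in = unname(higher),
                degenerate = unname(vb == 0 | va == 0))
  sig <- !is.na(out$higher_in)
  attr(out, "fractions") <- setNames(
    c(mean(sig & out$higher_in == group_a), mean(sig & out$higher_in == group_b)),
    c(group_a, group_b))
  class(out) <- c("variance_f_result", class(out))
  out
}
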