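#' Degree differences between two regulatory networks
#'
#' TF out-degrees (row sums of the edge-weight matrix) and gene
#' in-degrees (column sums) for each network, and their difference
#' `A - B`. Positive differences mean higher targeting in group A. TFs
#' are ranked by absolute out-degree difference.
#'
#' @param net_a,net_b `regulatory_network` objects (or bare TF x gene
#'   matrices) on identical TF/gene id spaces.
#' @return An object of class `targeting_diff`: list with `tf` (tibble:
#'   `tf`, `out_degree_a`, `out_degree_b`, `diff`, `abs_rank`), `gene`
#'   (tibble: `gene`, `in_degree_a`, `in_degree_b`, `diff`) and
#'   `edge_diff` (TF x gene matrix `W_A - W_B`).
#' @export
degree_differences <- function(net_a, net_b) {
  wa <- if (inherits(net_a, "regulatory_network")) net_a$W else net_a
  wb <- if (inherits(net_b, "regulatory_network")) net_b$W else net_b
  if (!identical(dimnames(wa), dimnames(wb))) {
    abort("Networks must share identical TF and gene id spaces.")
  }
  out_a <- rowSums(wa); out_b <- rowSums(wb)
  in_a <- colSums(wa); in_b <- colSums(wb)
  tf <- tibble(tf = rownames(wa), out_degree_a = unname(out_a),
               out_degree_b = unname(out_b),
               diff = unname(out_a - out_b)) |>
    dplyr::mutate(abs_rank = rank(-abs(.data$diff), ties.method = "first"))
  gene <- tibble(gene = colnames(wa), in_degree_a = unname(in_a),
                 in_degree_b = unname(in_b), diff = unname(in_a - in_b))
  structure(list(tf = tf, gene = gene, edge_diff = wa - wb),
            class = "targeting_diff")
}

#' @export
print.targeting_diff <- function(x, ...) {
  cat("<targeting_diff> ", nrow(x$tf), " TFs, ", nrow(x$gene), " genes; ",
      "top |out-degree diff| TF: ",
      x$tf$tf[x$tf$abs_rank == 1][1], "\n", sep = "")
  invisible(x)
}

#' @export
tidy.targeting_diff <- function(x, type = c("tf", "gene"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' Per-TF paired t-test on outgoing edge weights
#'
#' For every TF, a paired t across genes comparing its outgoing edge
#' weights in the two networks (equivalently a one-sample t on its row
#' of the edge-weight difference matrix), with BH correction across TFs.
#' TFs whose edge differences have zero variance are flagged and given
#' `p = 1` when the mean difference is also zero.
#'
#' @param diff A [degree_differences()] result.
#' @return Tibble: `tf`, `mean_diff`, `t_stat`, `p_value`, `fdr`,
#'   `degenerate`.
#' @export
tf_differential_targeting <- function(diff) {
  d <- diff$edge_diff
  n <- ncol(d)
  if (n < 3) abort("Need at least 3 genes.")
  m <- rowMeans(d)
  s <- apply(d, 1, sd)
  degen <- s == 0
  t_stat <- ifelse(degen, ifelse(m == 0, 0, Inf * sign(m)),
                   m / (s / sqrt(n)))
  p <- ifelse(degen & m == 0, 1, 2 * pt(-abs(t_stat), df = n - 1))
  tibble(tf = rownames(d), mean_diff = unname(m), t_stat = unname(t_stat),
         p_value = unname(p), fdr = p.adjust(unname(p), method = "BH"),
         degenerate = unname(degen))
}

#' Pathway targeting test on gene in-degree differences
#'
#' Welch two-sample t comparing the in-degree differences of a gene set
#' against all other genes. A negative statistic means the set is less
#' strongly targeted in group A than the background.
#'
#' @param diff A [degree_differences()] result.
#' @param sets Named list of gene sets (or a single character vector).
#' @return Tibble: `set_name`, `n_set`, `n_rest`, `t_stat`, `p_value`,
#'   `fdr` (BH across the supplied sets).
#' @export
pathway_targeting_test <- function(diff, sets) {
  if (is.character(sets)) sets <- list(set = sets)
  gene_diff <- setNames(diff$gene$diff, diff$gene$gene)
  res <- purrr::imap_dfr(sets, function(set, nm) {
    inside <- names(gene_diff) %in% set
    n1 <- sum(inside); n2 <- sum(!inside)
    if (n1 < 2 || n2 < 2) {
      abort(paste0("Set '", nm, "': need >= 2 genes inside and outside."))
    }
    # Welch t computed directly so that noise-free separations yield an
    # infinite statistic instead of an error
    x <- gene_diff[inside]; y <- gene_diff[!inside]
    se2 <- var(x) / n1 + var(y) / n2
    delta <- mean(x) - mean(y)
    if (se2 == 0) {
      t_stat <- if (delta == 0) 0 else Inf * sign(delta)
      p <- if (delta == 0) 1 else 0
    } else {
      t_stat <- delta / sqrt(se2)
      df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
      p <- 2 * pt(-abs(t_stat), df)
    }
    tibble(set_name = nm, n_set = n1, n_rest = n2,
           t_stat = t_stat, p_value = p)
  })
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res
}

#' Correlation of expression change with targeting change
#'
#' For each TF, the Spearman correlation (average ranks for ties)
#' between the per-gene log2 fold change and the TF's per-gene
#' edge-weight difference, over the genes of a named set. A negative
#' correlation says the genes most over-expressed in group A are the
#' ones the TF targets least there.
#'
#' @param diff A [degree_differences()] result.
#' @param de A [moderated_paired_t()] result (same A-B orientation).
#' @param set Character vector of gene ids (>= 4 present in both
#'   inputs).
#' @param tfs TFs to test (default: all in the networks).
#' @return Tibble of class `targeting_correlation`: `tf`, `rho`,
#'   `n_genes`.
#' @export
targeting_expression_correlation <- function(diff, de, set,
                                             tfs = rownames(diff$edge_diff)) {
  genes <- intersect(intersect(set, colnames(diff$edge_diff)), de$gene_id)
  if (length(genes) < 4) {
    abort("Need at least 4 set genes present in both the DE table and the networks.")
  }
  lfc <- de$log2_fc[match(genes, de$gene_id)]
  d <- diff$edge_diff[tfs, genes, drop = FALSE]
  rho <- suppressWarnings(as.vector(cor(lfc, t(d), method = "spearman")))
  out <- tibble(tf = tfs, rho = rho, n_genes = length(genes))
  attr(out, "set_genes") <- genes
  class(out) <- c("targeting_correlation", class(out))
  out
}

#' Permutation significance for targeting-expression correlations
#'
#' Calibrates the observed per-TF correlations against a null built from
#' random gene sets of the same size drawn (without replacement) from
#' the genes shared by the DE table and the networks. The default
#' alternative is one-sided negative (`rho` smaller than expected), the
#' direction of repressive de-targeting; p-values carry a +1 pseudocount
#' in numerator and denominator. BH correction across the tested TFs.
#'
#' @param observed A [targeting_expression_correlation()] result.
#' @param diff,de The same inputs that produced `observed`.
#' @param set_size Size of the random sets; defaults to the observed
#'   set's size.
#' @param n_perm Number of random gene sets (default 1000).
#' @param seed Integer seed.
#' @param alternative `"less"` (default), `"greater"`, or
#'   `"two.sided"`.
#' @return The `observed` tibble with `p_perm` and `fdr` columns added.
#' @export
permutation_fdr <- function(observed, diff, de,
                            set_size = observed$n_genes[1], n_perm = 1000,
                            seed = 1,
                            alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) warn("n_perm < 100 gives very coarse p-values.")
  universe <- intersect(colnames(diff$edge_diff), de$gene_id)
  if (set_size > length(universe)) {
    abort("`set_size` exceeds the shared gene universe.")
  }
  tfs <- observed$tf
  d <- diff$edge_diff[tfs, universe, drop = FALSE]
  lfc <- de$log2_fc[match(universe, de$gene_id)]

  null_rho <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(length(universe), set_size)
      suppressWarnings(as.vector(
        cor(lfc[idx], t(d[, idx, drop = FALSE]), method = "spearman")))
    }, numeric(length(tfs)))
  })
  if (length(tfs) == 1) null_rho <- matrix(null_rho, nrow = 1)

  obs <- observed$rho
  p <- vapply(seq_along(tfs), function(k) {
    nr <- null_rho[k, ]
    switch(alternative,
           less = (1 + sum(nr <= obs[k])) / (1 + n_perm),
           greater = (1 + sum(nr >= obs[k])) / (1 + n_perm),
           two.sided = (1 + sum(abs(nr) >= abs(obs[k]))) / (1 + n_perm))
  }, numeric(1))
  out <- observed
  out$p_perm <- p
  out$fdr <- p.adjust(p, method = "BH")
  attr(out, "n_perm") <- n_perm
  attr(out, "alternative") <- alternative
  attr(out, "seed") <- seed
  out
}
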