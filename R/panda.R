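#' Message-passing parameters
#'
#' @param alpha Update step size in (0, 1]; default 0.1.
#' @param tol Convergence threshold on the Hamming distance (mean
#'   absolute change of the regulatory network between iterations);
#'   default 0.001.
#' @param max_iter Iteration cap guarding against non-convergence;
#'   default 200.
#' @return An object of class `panda_params`.
#' @export
panda_params <- function(alpha = 0.1, tol = 0.001, max_iter = 200) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  if (tol <= 0) abort("`tol` must be positive.")
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  structure(list(alpha = alpha, tol = tol, max_iter = max_iter),
            class = "panda_params")
}

#' Gene-gene co-expression matrix
#'
#' Pearson correlation between gene expression vectors, the seed of the
#' co-regulation network. Constant genes get 0 off-diagonal correlation
#' (flagged in the `constant_genes` attribute); the diagonal is 1.
#'
#' @param expr An `expression_study`, or a genes x samples matrix.
#' @param group When `expr` is a study, which group's samples to use
#'   (default: all samples).
#' @param genes Optional gene subset (character), in the given order.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
coexpression <- function(expr, group = NULL, genes = NULL) {
  m <- if (inherits(expr, "expression_study")) {
    if (is.null(group)) expr$matrix else group_matrix(expr, group)
  } else {
    expr
  }
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss) > 0) abort("Genes missing from expression matrix.")
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 3) abort("Co-expression needs at least 3 samples.")
  sds <- apply(m, 1, sd)
  const <- sds == 0
  cc <- suppressWarnings(cor(t(m)))
  if (any(const)) {
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  diag(cc) <- 1
  attr(cc, "constant_genes") <- rownames(m)[const]
  cc
}

#' Continuous Tanimoto similarity between row and column vectors
#'
#' `T(x, y) = (x . y) / sqrt(||x||^2 + ||y||^2 - |x . y|)`, evaluated for
#' every row of `X` against every column of `Y`. This is the similarity
#' kernel of the message-passing updates. Pairs where the denominator is
#' zero (both vectors zero) are defined as 0 and flagged.
#'
#' @param X Matrix whose rows are the left vectors.
#' @param Y Matrix whose columns are the right vectors;
#'   `ncol(X) == nrow(Y)`.
#' @return `nrow(X)` x `ncol(Y)` similarity matrix.
#' @export
tanimoto <- function(X, Y) {
  if (ncol(X) != nrow(Y)) abort("Inner dimensions must agree.")
  dot <- X %*% Y
  denom2 <- outer(rowSums(X^2), colSums(Y^2), `+`) - abs(dot)
  out <- dot / sqrt(denom2)
  zero <- denom2 <= 0
  if (any(zero)) {
    out[zero] <- 0
    attr(out, "zero_pairs") <- sum(zero)
  }
  out
}

#' Mean absolute entrywise difference between two networks
#'
#' The convergence criterion of the message passing ("Hamming distance"
#' between successive continuous iterates).
#'
#' @param w_new,w_old Matrices of identical shape.
#' @return Scalar mean absolute difference.
#' @export
hamming_distance <- function(w_new, w_old) {
  if (!identical(dim(w_new), dim(w_old))) abort("Shape mismatch.")
  mean(abs(w_new - w_old))
}

# Combined row/column z-score normalization applied to each prior before
# message passing: z = (z_row + z_col) / sqrt(2). Entries whose row (or
# column) is constant take the global z-score for that component, so hub
# structure is preserved without dividing by zero.
normalize_network <- function(m) {
  mu_r <- rowMeans(m); sd_r <- apply(m, 1, sd)
  mu_c <- colMeans(m); sd_c <- apply(m, 2, sd)
  mu_g <- mean(m); sd_g <- sd(as.vector(m))
  if (sd_g == 0) sd_g <- 1
  zr <- (m - mu_r) / sd_r
  zc <- sweep(sweep(m, 2, mu_c), 2, sd_c, `/`)
  zg <- (m - mu_g) / sd_g
  if (any(sd_r == 0)) zr[sd_r == 0, ] <- zg[sd_r == 0, ]
  if (any(sd_c == 0)) zc[, sd_c == 0] <- zg[, sd_c == 0]
  (zr + zc) / sqrt(2)
}

# Diagonal update for the cooperativity / co-regulation similarity
# matrices: the self-similarity is replaced by the row-wise sd of the
# off-diagonal entries scaled by the matrix size and an exponential in
# the step count. The growing diagonal dominates the Tanimoto
# denominators in later iterations, progressively damping the updates —
# this is what drives the Hamming distance to zero.
update_diagonal <- function(m, alpha, step) {
  n <- nrow(m)
  diag(m) <- NA
  row_sd <- apply(m, 1, sd, na.rm = TRUE)
  row_sd[is.na(row_sd)] <- 0
  diag(m) <- row_sd * n * exp(2 * alpha * step)
  m
}

symmetrize <- function(m) (m + t(m)) / 2

#' Infer a regulatory network by message passing
#'
#' Makes the motif prior, the TF-TF cooperativity prior and the gene-gene
#' co-expression mutually consistent. All three inputs are z-score
#' normalized (combined row/column scheme), then iterated:
#' responsibility `R = T(P, W)` (how strongly a TF and its partners agree
#' on a gene), availability `A = T(W, C)` (how strongly a gene's
#' co-expression neighbourhood supports the TF),
#' `W <- (1 - alpha) W + alpha (R + A) / 2`, with the cooperativity `P`
#' and co-regulation `C` nudged toward the Tanimoto similarity of W rows
#' and W columns respectively (same `alpha`) and re-symmetrized. The
#' self-similarity diagonals of `P` and `C` are replaced each step by a
#' size-scaled, exponentially growing term (see the package vignette):
#' the growing diagonals dominate the Tanimoto denominators and damp
#' later updates, which is what drives convergence. Iteration stops when
#' the Hamming distance between successive `W` falls below `tol`.
#'
#' @param priors A [prior_pair()].
#' @param expr An `expression_study`, a genes x samples matrix, or a
#'   precomputed gene-gene correlation matrix (square, matching the
#'   prior's gene ids).
#' @param params A [panda_params()].
#' @param group Group passed to [coexpression()] when `expr` is a study.
#' @return An object of class `regulatory_network`: list with `W`
#'   (TF x gene edge weights, z-score scale), `tf_ids`, `gene_ids`,
#'   `iterations`, `hamming_trace`, `converged`, `params`.
#' @export
run_panda <- function(priors, expr, params = panda_params(), group = NULL) {
  if (!inherits(priors, "prior_pair")) abort("`priors` must be a prior_pair.")
  genes <- priors$gene_ids

  if (is.matrix(expr) && nrow(expr) == ncol(expr) &&
      identical(rownames(expr), colnames(expr)) &&
      all(genes %in% rownames(expr))) {
    c0 <- expr[genes, genes]
  } else {
    c0 <- coexpression(expr, group = group, genes = genes)
  }

  w <- normalize_network(priors$motif_prior)
  p <- symmetrize(normalize_network(priors$ppi_prior))
  cm <- symmetrize(normalize_network(c0))

  alpha <- params$alpha
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < params$max_iter) {
    iter <- iter + 1
    resp <- tanimoto(p, w)
    avail <- tanimoto(w, cm)
    w_new <- (1 - alpha) * w + alpha * (resp + avail) / 2
    p_sim <- update_diagonal(tanimoto(w_new, t(w_new)), alpha, iter - 1)
    p <- symmetrize((1 - alpha) * p + alpha * p_sim)
    c_sim <- update_diagonal(tanimoto(t(w_new), w_new), alpha, iter - 1)
    cm <- symmetrize((1 - alpha) * cm + alpha * c_sim)
    h <- hamming_distance(w_new, w)
    trace <- c(trace, h)
    w <- w_new
    if (h < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("Message passing did not reach tol = ", params$tol,
                " within ", params$max_iter, " iterations."))
  }
  structure(list(W = w, tf_ids = priors$tf_ids, gene_ids = genes,
                 iterations = iter, hamming_trace = trace,
                 converged = converged, params = params),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", length(x$tf_ids), " TFs x ",
      length(x$gene_ids), " genes; ", x$iterations, " iterations; ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.regulatory_network <- function(x, prior = NULL, ...) {
  out <- as_tibble(x$W, rownames = "tf") |>
    tidyr::pivot_longer(-"tf", names_to = "gene", values_to = "weight")
  if (!is.null(prior)) {
    pr <- as_tibble(prior, rownames = "tf") |>
      tidyr::pivot_longer(-"tf", names_to = "gene", values_to = "prior")
    out <- dplyr::left_join(out, pr, by = c("tf", "gene")) |>
      dplyr::select("tf", "gene", "prior", "weight")
  }
  out
}

#' @export
glance.regulatory_network <- function(x, ...) {
  tibble(n_tfs = length(x$tf_ids), n_genes = length(x$gene_ids),
         iterations = x$iterations,
         final_hamming = if (length(x$hamming_trace)) {
           x$hamming_trace[length(x$hamming_trace)]
         } else NA_real_,
         converged = x$converged)
}

#' Bootstrap stability of the inferred network
#'
#' Repeatedly re-infers the network on random subsamples of paired
#' subjects (drawn without replacement) and summarizes edge-weight
#' stability against the all-sample network.
#'
#' @param expr An `expression_study`.
#' @param priors A [prior_pair()].
#' @param params A [panda_params()].
#' @param group Group label whose samples feed the co-expression.
#' @param n_boot Number of bootstrap networks (default 100).
#' @param subsample Number of paired subjects per draw (default 40).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_networks`: list with `edge_mean`
#'   and `edge_sd` (TF x gene matrices across bootstrap networks),
#'   `full` (the all-sample `regulatory_network`), `edge_cor` (Pearson
#'   correlation of mean bootstrap edge weights with the all-sample
#'   network), and `degrees` (tibble of per-draw out-/in-degree
#'   summaries).
#' @export
bootstrap_networks <- function(expr, priors, params = panda_params(),
                               group = NULL, n_boot = 100, subsample = 40,
                               seed = 1) {
  if (!inherits(expr, "expression_study")) {
    abort("`expr` must be an expression_study.")
  }
  subjects <- sort(unique(expr$samples$subject_id))
  if (subsample > length(subjects)) {
    abort("`subsample` exceeds the number of paired subjects.")
  }
  grp <- group %||% study_groups(expr)[1]
  full <- run_panda(priors, expr, params, group = grp)

  acc <- matrix(0, nrow(full$W), ncol(full$W))
  acc2 <- matrix(0, nrow(full$W), ncol(full$W))
  degrees <- vector("list", n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      subj <- sample(subjects, subsample)
      m <- group_matrix(expr, grp, subjects = sort(subj))
      net <- run_panda(priors, m[priors$gene_ids, , drop = FALSE], params)
      acc <- acc + net$W
      acc2 <- acc2 + net$W^2
      degrees[[b]] <- tibble(draw = b,
                             out_degree_mean = mean(rowSums(net$W)),
                             in_degree_mean = mean(colSums(net$W)))
    }
  })
  edge_mean <- acc / n_boot
  edge_var <- pmax(0, acc2 / n_boot - edge_mean^2)
  dimnames(edge_mean) <- dimnames(full$W)
  structure(list(edge_mean = edge_mean,
                 edge_sd = sqrt(edge_var * n_boot / max(1, n_boot - 1)),
                 full = full,
                 edge_cor = cor(as.vector(edge_mean), as.vector(full$W)),
                 degrees = dplyr::bind_rows(degrees),
                 n_boot = n_boot, subsample = subsample, seed = seed),
            class = "bootstrap_networks")
}

#' @export
print.bootstrap_networks <- function(x, ...) {
  cat("<bootstrap_networks> ", x$n_boot, " draws of ", x$subsample,
      " subjects; edge-weight correlation with full network = ",
      round(x$edge_cor, 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.bootstrap_networks <- function(x, ...) {
  tibble(n_boot = x$n_boot, subsample = x$subsample,
         edge_cor = x$edge_cor, mean_edge_sd = mean(x$edge_sd))
}
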