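# Small fixtures shared across test files. Everything is generated in
# code; seeds are fixed so failures are reproducible.

tiny_study <- function(seed = 42, n_genes = 30, n_pairs = 10, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * 2 * n_pairs, sd = sd), n_genes, 2 * n_pairs)
    rownames(m) <- sprintf("g%03d", seq_len(n_genes))
    colnames(m) <- c(paste0("S", seq_len(n_pairs), "_A"),
                     paste0("S", seq_len(n_pairs), "_B"))
    expression_study(
      m,
      data.frame(sample_id = colnames(m),
                 subject_id = rep(paste0("S", seq_len(n_pairs)), 2),
                 group = rep(c("A", "B"), each = n_pairs)))
  })
}

tiny_priors <- function(seed = 7, n_tfs = 5, n_genes = 20, density = 0.3) {
  withr::with_seed(seed, {
    motif <- matrix(rbinom(n_tfs * n_genes, 1, density), n_tfs, n_genes,
                    dimnames = list(sprintf("TF%02d", seq_len(n_tfs)),
                                    sprintf("g%03d", seq_len(n_genes))))
    for (t in which(rowSums(motif) == 0)) motif[t, 1] <- 1
    ppi <- matrix(runif(n_tfs^2), n_tfs, n_tfs)
    ppi <- (ppi + t(ppi)) / 2
    diag(ppi) <- 1
    dimnames(ppi) <- list(rownames(motif), rownames(motif))
    prior_pair(motif, ppi)
  })
}

# Quadratic brute-force interval intersection used as the independent
# oracle for promoter-peak annotation (half-open intervals).
brute_force_bound <- function(peaks, promoters) {
  tfs <- sort(unique(peaks$tf))
  out <- list()
  for (tf in tfs) {
    pk <- peaks[peaks$tf == tf, ]
    bound <- character(0)
    for (i in seq_len(nrow(promoters))) {
      for (j in seq_len(nrow(pk))) {
        if (promoters$chrom[i] == pk$chrom[j] &&
            promoters$start[i] < pk$end[j] &&
            pk$start[j] < promoters$end[i]) {
          bound <- c(bound, promoters$gene_id[i])
          break
        }
      }
    }
    out[[tf]] <- sort(unique(bound))
  }
  out
}

# Step-up BH oracle (textbook definition, no vectorization tricks).
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# O(N) cumulative-sum enrichment walk, independent of the package's
# implementation details.
brute_force_es <- function(scores, set, weight = 1) {
  s <- scores[order(-scores, names(scores), method = "radix")]
  running <- 0
  best <- 0
  in_set <- names(s) %in% set
  denom_hit <- sum(abs(s[in_set])^weight)
  denom_miss <- length(s) - sum(in_set)
  for (i in seq_along(s)) {
    running <- running +
      if (in_set[i]) abs(s[i])^weight / denom_hit else -1 / denom_miss
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}
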