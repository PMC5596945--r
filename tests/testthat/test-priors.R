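test_that("information content matches entropy limits and a cell-by-cell oracle", {
  L <- 6
  uniform <- pwm("m_u", "TFU", matrix(0.25, L, 4))
  expect_equal(motif_information_content(uniform), 0)

  onehot <- matrix(0, L, 4)
  onehot[cbind(seq_len(L), rep_len(1:4, L))] <- 1
  expect_equal(motif_information_content(pwm("m_o", "TFO", onehot)), 2 * L)

  mixed <- pwm("m_m", "TFM", rbind(c(0.7, 0.1, 0.1, 0.1),
                                   c(0.25, 0.25, 0.25, 0.25),
                                   c(0.5, 0.3, 0.1, 0.1)))
  # frozen value from independent per-cell summation
  expect_equal(motif_information_content(mixed), 0.9577450533, tolerance = 1e-9)

  # invariant to within-position column permutation; bounded by [0, 2L]
  perm <- pwm("m_p", "TFM", mixed$matrix[, c(3, 1, 4, 2)])
  expect_equal(motif_information_content(perm), motif_information_content(mixed))
  withr::with_seed(11, {
    for (i in 1:20) {
      raw <- matrix(rexp(4 * 5), 5, 4)
      p <- pwm(paste0("m", i), "TFX", raw / rowSums(raw))
      ic <- motif_information_content(p)
      expect_gte(ic, -1e-12)
      expect_lte(ic, 10 + 1e-12)
    }
  })
})

test_that("invalid PWMs are rejected", {
  expect_error(pwm("m", "t", matrix(c(0.5, 0.2, 0.2, 0.2), 1, 4)), "sum to 1")
  expect_error(pwm("m", "t", matrix(c(1.2, -0.2, 0, 0), 1, 4)), "non-negative")
})

test_that("best-motif selection prefers information content with lexicographic ties", {
  sharp <- matrix(0.01, 4, 4); sharp[, 1] <- 0.97
  flat <- matrix(0.25, 4, 4)
  pwms <- list(pwm("zzz_hi", "TF1", sharp), pwm("aaa_lo", "TF1", flat),
               pwm("b_tie", "TF2", sharp), pwm("a_tie", "TF2", sharp))
  best <- select_best_motif(pwms)
  expect_equal(best$motif_id[best$tf_name == "TF1"], "zzz_hi")
  expect_equal(best$motif_id[best$tf_name == "TF2"], "a_tie")
})

test_that("promoter windows use -750/+250 offsets, mirror on minus strand, clip at 0", {
  expect_equal(promoter_window(1000, "+"), tibble::tibble(start = 250L, end = 1250L))
  expect_equal(promoter_window(1000, "-"), tibble::tibble(start = 750L, end = 1750L))
  expect_equal(promoter_window(100, "+"), tibble::tibble(start = 0L, end = 350L))
  expect_error(promoter_window(100, "*"), "strand")
  expect_error(promoter_window(-5, "+"), "non-negative")
})

test_that("motif prior reproduces a row-by-row filter/overlap/collapse oracle", {
  withr::with_seed(3, {
    genes <- sprintf("g%02d", 1:12)
    promoters <- add_promoter_windows(
      tibble::tibble(gene_id = genes, chrom = "chr1",
                     tss = 1000 + (seq_along(genes) - 1) * 5000,
                     strand = rep(c("+", "-"), 6)))
    sharp <- matrix(0.01, 4, 4); sharp[, 1] <- 0.97
    flat <- matrix(0.25, 4, 4)
    pwms <- list(pwm("TFA_hi", "TFA", sharp), pwm("TFA_lo", "TFA", flat),
                 pwm("TFB_hi", "TFB", sharp))
    hits <- tibble::tibble(
      motif_id = sample(c("TFA_hi", "TFA_lo", "TFB_hi"), 50, replace = TRUE),
      gene_id = sample(genes, 50, replace = TRUE),
      strand = "+",
      score = runif(50, 5, 20),
      p_value = 10^runif(50, -8, -2))
    # place hits around each hit's own promoter so that in/out-of-window
    # and p-value filtering are both exercised
    win <- promoters[match(hits$gene_id, promoters$gene_id), ]
    hits$start <- pmax(0L, win$start + sample(-800:1500, 50, replace = TRUE))
    hits$stop <- hits$start + 8L

    prior <- build_motif_prior(hits, promoters, pwms, genes, p_max = 1e-5)

    # independent oracle: per-hit filter, any-overlap, collapse to TFs
    best_motifs <- c(TFA = "TFA_hi", TFB = "TFB_hi")
    oracle <- matrix(0, 2, length(genes), dimnames = list(c("TFA", "TFB"), genes))
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      tf <- sub("_.*", "", h$motif_id)
      if (h$motif_id != best_motifs[[tf]]) next
      if (h$p_value >= 1e-5) next
      w <- promoters[promoters$gene_id == h$gene_id, ]
      if (h$start < w$end && h$stop > w$start) oracle[tf, h$gene_id] <- 1
    }
    oracle <- oracle[rowSums(oracle) > 0, , drop = FALSE]
    expect_identical(prior, oracle)
  })
})

test_that("raising the p-value cut-off never removes a motif-prior edge", {
  withr::with_seed(9, {
    genes <- sprintf("g%02d", 1:10)
    promoters <- add_promoter_windows(
      tibble::tibble(gene_id = genes, chrom = "chr1",
                     tss = 1000 + (seq_along(genes) - 1) * 3000, strand = "+"))
    sharp <- matrix(0.01, 4, 4); sharp[, 1] <- 0.97
    pwms <- list(pwm("TFA_m", "TFA", sharp))
    hits <- tibble::tibble(motif_id = "TFA_m",
                           gene_id = sample(genes, 40, replace = TRUE),
                           start = sample(300:1200, 40), strand = "+",
                           score = 10, p_value = 10^runif(40, -8, -3))
    hits$stop <- hits$start + 8L
    loose <- build_motif_prior(hits, promoters, pwms, genes, p_max = 1e-3)
    strict <- build_motif_prior(hits, promoters, pwms, genes, p_max = 1e-6)
    expect_true(all(loose[rownames(strict), ] >= strict))
  })
})

test_that("single excluded hit leaves an all-zero prior and raises an error", {
  promoters <- add_promoter_windows(
    tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 1000, strand = "+"))
  sharp <- matrix(0.01, 4, 4); sharp[, 1] <- 0.97
  hits <- tibble::tibble(motif_id = "TFA_m", gene_id = "g1", start = 400L,
                         stop = 408L, strand = "+", score = 9, p_value = 1e-4)
  expect_error(
    build_motif_prior(hits, promoters, list(pwm("TFA_m", "TFA", sharp)), "g1"),
    "survive")
})

test_that("PPI prior scales, symmetrizes by max, and pins the diagonal", {
  tfs <- c("t1", "t2", "t3")
  empty <- build_ppi_prior(tibble::tibble(protein1 = character(),
                                          protein2 = character(),
                                          combined_score = numeric()), tfs)
  expect_identical(unname(empty), diag(3))

  one <- build_ppi_prior(tibble::tibble(protein1 = "t1", protein2 = "t2",
                                        combined_score = 800), tfs)
  expect_equal(one["t1", "t2"], 0.8)
  expect_equal(one["t2", "t1"], 0.8)

  dup <- build_ppi_prior(tibble::tibble(protein1 = c("t1", "t2"),
                                        protein2 = c("t2", "t1"),
                                        combined_score = c(600, 700)), tfs)
  expect_equal(dup["t1", "t2"], 0.7)
  expect_equal(dup["t2", "t1"], 0.7)

  expect_error(build_ppi_prior(tibble::tibble(protein1 = "t1", protein2 = "t2",
                                              combined_score = 1200), tfs),
               "0, 1000")
})

test_that("prior_pair enforces its matrix invariants", {
  pp <- tiny_priors()
  expect_true(all(pp$motif_prior %in% c(0, 1)))
  expect_true(all(pp$ppi_prior >= 0 & pp$ppi_prior <= 1))
  expect_identical(pp$ppi_prior, t(pp$ppi_prior))
  expect_true(all(diag(pp$ppi_prior) == 1))
  bad_ppi <- pp$ppi_prior; bad_ppi[1, 2] <- 2
  expect_error(prior_pair(pp$motif_prior, bad_ppi))
})
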