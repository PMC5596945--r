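test_that("promoter-peak annotation respects half-open boundary semantics", {
  promoters <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 1000,
                              strand = "+", start = 250L, end = 1250L)
  inside <- tibble::tibble(chrom = "chr1", start = 300L, end = 400L, tf = "T")
  expect_equal(annotate_promoter_peaks(inside, promoters)$genes[[1]], "g1")
  touching <- tibble::tibble(chrom = "chr1", start = 1250L, end = 1300L, tf = "T")
  expect_length(annotate_promoter_peaks(touching, promoters)$genes[[1]], 0)
  one_bp <- tibble::tibble(chrom = "chr1", start = 1249L, end = 1250L, tf = "T")
  expect_equal(annotate_promoter_peaks(one_bp, promoters)$genes[[1]], "g1")
  other_chrom <- tibble::tibble(chrom = "chr2", start = 300L, end = 400L, tf = "T")
  expect_length(annotate_promoter_peaks(other_chrom, promoters)$genes[[1]], 0)
})

test_that("annotation equals the quadratic intersection oracle on random inputs", {
  withr::with_seed(15, {
    promoters <- add_promoter_windows(
      tibble::tibble(gene_id = sprintf("g%04d", 1:300),
                     chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
                     tss = sample(1000:500000, 300),
                     strand = sample(c("+", "-"), 300, replace = TRUE)))
    start <- sample(0:500000, 1000)
    peaks <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 1000,
                                           replace = TRUE),
                            start = start,
                            end = start + sample(50:500, 1000, replace = TRUE),
                            tf = sample(c("TFA", "TFB", "TFC"), 1000,
                                        replace = TRUE))
  })
  got <- annotate_promoter_peaks(peaks, promoters)
  oracle <- brute_force_bound(peaks, promoters)
  for (i in seq_len(nrow(got))) {
    expect_identical(got$genes[[i]], oracle[[got$tf[i]]])
  }
  expect_equal(got$fraction_of_universe, got$n_bound / nrow(promoters))
})

test_that("annotation is invariant to peak order and to splitting a peak", {
  promoters <- add_promoter_windows(
    tibble::tibble(gene_id = paste0("g", 1:5), chrom = "chr1",
                   tss = seq(2000, 42000, by = 10000), strand = "+"))
  peaks <- tibble::tibble(chrom = "chr1", start = c(1500L, 21500L),
                          end = c(1700L, 21700L), tf = "T")
  base <- annotate_promoter_peaks(peaks, promoters)
  shuffled <- annotate_promoter_peaks(peaks[2:1, ], promoters)
  expect_identical(base$genes, shuffled$genes)
  split <- tibble::tibble(chrom = "chr1",
                          start = c(1500L, 1600L, 21500L),
                          end = c(1650L, 1700L, 21700L), tf = "T")
  expect_identical(annotate_promoter_peaks(split, promoters)$genes, base$genes)
})

test_that("generated peaks round-trip to the exact truth bound sets", {
  st <- generate_study(synthetic_config(n_tfs = 10, n_genes = 100,
                                        n_pairs = 12, planted_set_size = 20,
                                        repressor_tf_count = 4, seed = 19))
  bound <- annotate_promoter_peaks(st$peaks, st$promoters)
  truth <- split(st$truth$bound_pairs$gene, st$truth$bound_pairs$tf)
  expect_setequal(bound$tf, names(truth))
  for (i in seq_len(nrow(bound))) {
    expect_identical(bound$genes[[i]], sort(unique(truth[[bound$tf[i]]])))
  }
  # oracle agreement on the same peaks
  oracle <- brute_force_bound(st$peaks, st$promoters)
  for (i in seq_len(nrow(bound))) {
    expect_identical(bound$genes[[i]], oracle[[bound$tf[i]]])
  }
})

test_that("peaks for an empty truth are all decoys outside promoters", {
  promoters <- add_promoter_windows(
    tibble::tibble(gene_id = paste0("g", 1:10), chrom = "chr1",
                   tss = 5000 + (0:9) * 10000, strand = "+"))
  truth <- list(bound_pairs = tibble::tibble(tf = character(),
                                             gene = character()),
                repressor_tfs = "TFX")
  withr::with_seed(2, pk <- generate_peaks(truth, promoters, n_decoys = 5))
  expect_equal(nrow(pk), 5)
  expect_length(annotate_promoter_peaks(pk, promoters)$genes[[1]], 0)
})

test_that("correlation contrast matches a rank oracle and detects opposite coupling", {
  withr::with_seed(28, {
    n <- 40
    tf_a <- rnorm(n); tf_b <- rnorm(n)
    genes <- paste0("g", 1:50)
    # group A: targets anti-correlated with the TF; group B: correlated
    xa <- t(sapply(seq_along(genes), function(i) -tf_a + rnorm(n, sd = 0.8)))
    xb <- t(sapply(seq_along(genes), function(i) tf_b + rnorm(n, sd = 0.8)))
    m <- rbind(cbind(xa, xb), TF = c(tf_a, tf_b))
    rownames(m) <- c(genes, "TF")
    colnames(m) <- c(paste0("S", 1:n, "_A"), paste0("S", 1:n, "_B"))
    es <- expression_study(m, data.frame(
      sample_id = colnames(m), subject_id = rep(paste0("S", 1:n), 2),
      group = rep(c("A", "B"), each = n)))
  })
  ct <- group_correlation_contrast(es, "TF", genes)
  expect_lt(ct$wilcox_p, 0.05)
  expect_lt(ct$medians["A"], ct$medians["B"])
  # oracle: rank-then-pearson per gene in group A
  ma <- group_matrix(es, "A")
  for (g in sample(genes, 10)) {
    o <- cor(rank(ma["TF", ]), rank(ma[g, ]))
    expect_equal(ct$rho$rho[ct$rho$group == "A" & ct$rho$gene == g], o,
                 tolerance = 1e-12)
  }
})

test_that("identical expression in both groups gives identical rho vectors", {
  withr::with_seed(30, {
    half <- matrix(rnorm(21 * 10), 21, 10)
    m <- cbind(half, half)
    rownames(m) <- c(paste0("g", 1:20), "TF")
    colnames(m) <- c(paste0("S", 1:10, "_A"), paste0("S", 1:10, "_B"))
    es <- expression_study(m, data.frame(
      sample_id = colnames(m), subject_id = rep(paste0("S", 1:10), 2),
      group = rep(c("A", "B"), each = 10)))
  })
  ct <- group_correlation_contrast(es, "TF", paste0("g", 1:20))
  expect_identical(ct$rho$rho[ct$rho$group == "A"],
                   ct$rho$rho[ct$rho$group == "B"])
  # constant TF in a group errors
  es$matrix["TF", es$samples$group == "A"] <- 1
  expect_error(group_correlation_contrast(es, "TF", paste0("g", 1:20)),
               "constant")
})
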