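make_nets <- function(seed = 25, n_tf = 5, n_g = 20) {
  withr::with_seed(seed, {
    wa <- matrix(rnorm(n_tf * n_g), n_tf, n_g,
                 dimnames = list(sprintf("TF%02d", 1:n_tf),
                                 sprintf("g%03d", 1:n_g)))
    wb <- wa + matrix(rnorm(n_tf * n_g, sd = 0.3), n_tf, n_g)
    list(wa = wa, wb = wb)
  })
}

test_that("degree differences equal loop-based sums and conserve totals", {
  n <- make_nets()
  d <- degree_differences(n$wa, n$wb)
  for (i in 1:5) {
    expect_equal(d$tf$out_degree_a[i], sum(n$wa[i, ]))
    expect_equal(d$tf$diff[i], sum(n$wa[i, ]) - sum(n$wb[i, ]))
  }
  for (j in 1:20) {
    expect_equal(d$gene$in_degree_a[j], sum(n$wa[, j]))
  }
  # sum of out-degrees == sum of in-degrees == total edge weight
  expect_equal(sum(d$tf$out_degree_a), sum(d$gene$in_degree_a),
               tolerance = 1e-8)
  expect_equal(sum(d$tf$out_degree_a), sum(n$wa), tolerance = 1e-8)
  # ranking is by absolute difference
  expect_equal(d$tf$abs_rank, rank(-abs(d$tf$diff), ties.method = "first"))
})

test_that("a single perturbed edge moves exactly one out- and one in-degree", {
  n <- make_nets()
  wb <- n$wa
  wb["TF03", "g007"] <- wb["TF03", "g007"] - 1
  d <- degree_differences(n$wa, wb)
  expect_equal(d$tf$diff[d$tf$tf == "TF03"], 1)
  expect_true(all(d$tf$diff[d$tf$tf != "TF03"] == 0))
  expect_equal(d$gene$diff[d$gene$gene == "g007"], 1)
  expect_true(all(d$gene$diff[d$gene$gene != "g007"] == 0))
})

test_that("swapping the networks negates differences and t statistics", {
  n <- make_nets()
  ab <- degree_differences(n$wa, n$wb)
  ba <- degree_differences(n$wb, n$wa)
  expect_equal(ab$tf$diff, -ba$tf$diff)
  expect_equal(ab$gene$diff, -ba$gene$diff)
  t_ab <- tf_differential_targeting(ab)
  t_ba <- tf_differential_targeting(ba)
  expect_equal(t_ab$t_stat, -t_ba$t_stat)
  expect_equal(t_ab$p_value, t_ba$p_value)
})

test_that("per-TF paired t equals the textbook paired t and handles degeneracy", {
  n <- make_nets()
  d <- degree_differences(n$wa, n$wb)
  res <- tf_differential_targeting(d)
  for (i in 1:5) {
    tt <- t.test(n$wa[i, ], n$wb[i, ], paired = TRUE)
    expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # identical networks: all-zero differences -> t = 0, p = 1 by convention
  d0 <- degree_differences(n$wa, n$wa)
  r0 <- tf_differential_targeting(d0)
  expect_true(all(r0$t_stat == 0))
  expect_true(all(r0$p_value == 1))
  expect_true(all(r0$degenerate))
  # constant shift on one row: near-noise-free, explosive t
  wb <- n$wa; wb["TF02", ] <- wb["TF02", ] - 0.5
  rs <- tf_differential_targeting(degree_differences(n$wa, wb))
  expect_gt(rs$t_stat[rs$tf == "TF02"], 1e6)
  expect_lt(rs$p_value[rs$tf == "TF02"], 1e-12)
})

test_that("pathway targeting test separates a fully shifted set", {
  n <- make_nets(n_g = 30)
  wb <- n$wa
  set <- sprintf("g%03d", 1:10)
  wb[, set] <- wb[, set] + 1  # set less targeted in A by exactly 1 per TF
  d <- degree_differences(n$wa, wb)
  r <- pathway_targeting_test(d, list(planted = set))
  expect_lt(r$t_stat, 0)
  expect_lt(r$p_value, 1e-10)
  expect_error(pathway_targeting_test(d, list(bad = "g001")), ">= 2")
})

test_that("pathway targeting test matches Welch's t on noisy differences", {
  n <- make_nets(seed = 61, n_g = 40)
  d <- degree_differences(n$wa, n$wb)
  set <- sprintf("g%03d", 5:18)
  r <- pathway_targeting_test(d, list(s = set))
  inside <- d$gene$gene %in% set
  tt <- t.test(d$gene$diff[inside], d$gene$diff[!inside])
  expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("pathway targeting p-values are uniform over random sets", {
  withr::with_seed(33, {
    wa <- matrix(rnorm(20 * 1000), 20, 1000,
                 dimnames = list(sprintf("TF%02d", 1:20),
                                 sprintf("g%04d", 1:1000)))
    wb <- wa + matrix(rnorm(20 * 1000, sd = 0.2), 20, 1000)
    d <- degree_differences(wa, wb)
    sets <- lapply(1:1000, function(i) sample(colnames(wa), sample(20:100, 1)))
    names(sets) <- paste0("s", 1:1000)
  })
  r <- pathway_targeting_test(d, sets)
  expect_gt(stats::ks.test(r$p_value, "punif")$p.value, 0.01)
})

test_that("targeting-expression correlation matches a rank-then-pearson oracle", {
  n <- make_nets(n_g = 25)
  d <- degree_differences(n$wa, n$wb)
  de <- withr::with_seed(3, {
    structure(tibble::tibble(gene_id = colnames(n$wa),
                             log2_fc = rnorm(25)),
              class = c("de_result", class(tibble::tibble())))
  })
  set <- sprintf("g%03d", 3:20)
  res <- targeting_expression_correlation(d, de, set)
  for (i in seq_len(nrow(res))) {
    x <- de$log2_fc[match(set, de$gene_id)]
    y <- d$edge_diff[res$tf[i], set]
    expect_equal(res$rho[i], cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  # perfect (anti-)alignment gives rho of +-1
  de2 <- de
  de2$log2_fc <- d$edge_diff["TF01", de$gene_id]
  r2 <- targeting_expression_correlation(d, de2, set, tfs = "TF01")
  expect_equal(r2$rho, 1)
  de2$log2_fc <- -de2$log2_fc
  r3 <- targeting_expression_correlation(d, de2, set, tfs = "TF01")
  expect_equal(r3$rho, -1)
  expect_error(targeting_expression_correlation(d, de, set[1:3]), "at least 4")
})

test_that("permutation p-values are seed-stable and centered for null TFs", {
  withr::with_seed(44, {
    wa <- matrix(rnorm(10 * 200), 10, 200,
                 dimnames = list(sprintf("TF%02d", 1:10),
                                 sprintf("g%04d", 1:200)))
    wb <- wa + matrix(rnorm(10 * 200, sd = 0.5), 10, 200)
    de <- structure(tibble::tibble(gene_id = colnames(wa),
                                   log2_fc = rnorm(200)),
                    class = c("de_result", class(tibble::tibble())))
    set <- sample(colnames(wa), 40)
  })
  d <- degree_differences(wa, wb)
  obs <- targeting_expression_correlation(d, de, set)
  r1 <- permutation_fdr(obs, d, de, n_perm = 400, seed = 9)
  r2 <- permutation_fdr(obs, d, de, n_perm = 400, seed = 9)
  expect_identical(r1$p_perm, r2$p_perm)
  # null rho ~ symmetric: one-sided p near 0.5 on average, none at the floor
  expect_gt(mean(r1$p_perm), 0.3)
  expect_lt(mean(r1$p_perm), 0.7)
  expect_true(all(r1$p_perm >= 1 / 401))
  # two-sided option
  r3 <- permutation_fdr(obs, d, de, n_perm = 400, seed = 9,
                        alternative = "two.sided")
  expect_true(all(r3$p_perm > 0 & r3$p_perm <= 1))
})
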