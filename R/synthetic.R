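#' Configuration of a synthetic paired regulatory study
#'
#' Defines the study conditions for [generate_study()]: a paired
#' two-group design in which a planted gene set (a cell-cycle-like
#' program) is over-expressed in group A while a handful of
#' repressor-like TFs lose targeting strength on exactly those genes.
#'
#' @param n_tfs Number of TFs (default 20).
#' @param n_genes Number of target genes (default 500).
#' @param n_pairs Number of paired subjects per group (default 60).
#' @param prior_density Expected motif-prior edge density (default
#'   0.09).
#' @param planted_set_size Genes in the planted set (default 60).
#' @param repressor_tf_count TFs whose targeting of the planted set is
#'   attenuated in group A (default 8, the number of repressor-like
#'   regulators the planted program loses).
#' @param targeting_attenuation Mean multiplier in `[0, 1]` applied to
#'   repressor -> planted-gene regulatory strength in group A (default
#'   0.7; 1 = no attenuation). The planted program additionally loses a
#'   mild, flat share of its coupling to every other targeting TF
#'   (`1 - (1 - targeting_attenuation) * 5/6`, i.e. 0.75 at the
#'   default), so the set shows the broad de-targeting the repressors
#'   are the extremes of; at `targeting_attenuation = 1` both effects
#'   vanish and the two groups are exchangeable.
#' @param expression_shift Mean log2 shift added to planted genes in
#'   group A (default 2; 0 = no shift).
#' @param noise_sd Expression noise standard deviation (default 0.5).
#' @param activity_design `"auto"` (default), `"orthonormal"` or
#'   `"iid"`. Orthonormal draws the latent activity components from a
#'   random orthonormal basis so within-group activities are
#'   empirically uncorrelated with unit realized variance; `"auto"`
#'   uses it whenever `3 * n_tfs <= n_pairs`. `"iid"` draws plain
#'   Gaussian activities — use it when downstream checks assume
#'   Gaussian sampling variation of per-gene variances (e.g.
#'   calibration of the variance F-test).
#' @param seed Integer seed; identical seeds give bit-identical studies.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_tfs = 20, n_genes = 500, n_pairs = 60,
                             prior_density = 0.09, planted_set_size = 60,
                             repressor_tf_count = 8,
                             targeting_attenuation = 0.7,
                             expression_shift = 2, noise_sd = 0.5,
                             activity_design = c("auto", "orthonormal", "iid"),
                             seed = 1) {
  activity_design <- match.arg(activity_design)
  if (n_tfs < 1 || n_genes < 1 || n_pairs < 1) {
    abort("Dimensions must be positive.")
  }
  if (prior_density <= 0 || prior_density >= 1) {
    abort("`prior_density` must lie in (0, 1).")
  }
  if (planted_set_size >= n_genes) {
    abort("`planted_set_size` must be smaller than `n_genes`.")
  }
  if (repressor_tf_count > n_tfs) {
    abort("`repressor_tf_count` cannot exceed `n_tfs`.")
  }
  if (targeting_attenuation < 0 || targeting_attenuation > 1) {
    abort("`targeting_attenuation` must lie in [0, 1].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(list(n_tfs = n_tfs, n_genes = n_genes, n_pairs = n_pairs,
                 prior_density = prior_density,
                 planted_set_size = planted_set_size,
                 repressor_tf_count = repressor_tf_count,
                 targeting_attenuation = targeting_attenuation,
                 expression_shift = expression_shift, noise_sd = noise_sd,
                 activity_design = activity_design, seed = seed),
            class = "synthetic_config")
}

# Genomic layout used by the generator: one gene per 10 kb on one
# chromosome, TSS mid-slot, alternating strands, so promoter windows
# never touch and decoy peaks have room between them.
synth_promoters <- function(ids) {
  n <- length(ids)
  tss <- 5000L + (seq_len(n) - 1L) * 10000L
  strand <- rep(c("+", "-"), length.out = n)
  add_promoter_windows(
    tibble(gene_id = ids, chrom = "chr1", tss = tss, strand = strand))
}

# One-hot-ish high-information PWM vs a flat low-information one; the
# prior builder must pick the first.
synth_pwms <- function(tf_ids) {
  sharp <- matrix(0.03, 8, 4); sharp[cbind(1:8, rep(1:4, 2))] <- 0.91
  flat <- matrix(c(0.4, 0.2, 0.2, 0.2), 8, 4, byrow = TRUE)
  out <- list()
  for (tf in tf_ids) {
    out[[paste0(tf, "_M1")]] <- pwm(paste0(tf, "_M1"), tf, sharp)
    out[[paste0(tf, "_M2")]] <- pwm(paste0(tf, "_M2"), tf, flat)
  }
  out
}

#' Generate a seeded synthetic study with planted targeting structure
#'
#' Expression follows a linear latent-activity model: gene `g` in
#' subject `s` of group `G` is
#' `sum_t prior(t, g) * strength(t, g, G) * activity(t, s, G) +
#'  shift(g, G) + noise`.
#' Latent TF activities are standard normal with a shared subject
#' component (correlation 0.5 between a subject's two samples, matching
#' the paired design); at the default scale they are drawn from a random
#' orthonormal basis so that within-group activities are empirically
#' uncorrelated (see the vignette for why this matters at small n).
#' Base strengths are log-normal (meanlog 0, sdlog 0.25), so all edges
#' are positive, heterogeneous targeting magnitudes. In group A the planted program is de-targeted on two
#' levels: every TF's coupling to planted genes is scaled by a mild
#' flat factor (`1 - (1 - attenuation) * 5/6`), and on top of that the
#' repressor TFs' couplings are scaled by a per-gene `attenuation_g`
#' whose depth follows the same dose `w_g ~ U(0.1, 1.9)` that scales
#' the expression shift `shift_g` — the genes shifted up the most are
#' de-targeted the most, which is the planted dose-response the
#' correlation stage looks for. Gene-specific noise replaces the lost
#' regulatory variance so marginal variances stay comparable across
#' groups. The TFs' own expression (activity plus noise) is appended
#' as extra rows.
#'
#' The motif-hit table contains exactly one significant in-window hit
#' per true prior edge (best motif), plus decoy hits that fail the
#' p-value filter, fall outside the windows, or belong to the inferior
#' motif, so [build_motif_prior()] recovers the truth prior exactly.
#' Forced repressor -> planted edges are counted toward the configured
#' overall density; the remaining edges are Bernoulli draws.
#'
#' @param config A [synthetic_config()].
#' @param mode `"normalized"` (default, log-intensity scale) or
#'   `"counts"` (Poisson-lognormal counts for the log-CPM path).
#' @return An object of class `synthetic_study`: list with `expression`
#'   (an `expression_study`), `motif_hits`, `ppi`, `promoters`, `pwms`,
#'   `peaks`, `gene_sets`, and `truth` (planted genes, repressor TFs,
#'   per-gene shifts/attenuations, prior matrix, bound pairs).
#' @export
generate_study <- function(config = synthetic_config(),
                           mode = c("normalized", "counts")) {
  mode <- match.arg(mode)
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be a synthetic_config.")
  }
  cf <- config
  tf_ids <- sprintf("TF%02d", seq_len(cf$n_tfs))
  gene_ids <- sprintf("G%04d", seq_len(cf$n_genes))

  withr::with_seed(cf$seed, {
    planted <- sort(sample(gene_ids, cf$planted_set_size))
    repressors <- sort(sample(tf_ids, cf$repressor_tf_count))

    # motif prior: forced repressor x planted block + Bernoulli rest,
    # with the Bernoulli rate chosen so the expected overall density is
    # prior_density
    prior <- matrix(0, cf$n_tfs, cf$n_genes,
                    dimnames = list(tf_ids, gene_ids))
    prior[repressors, planted] <- 1
    n_forced <- sum(prior)
    n_free <- length(prior) - n_forced
    p_free <- max(0, (cf$prior_density * length(prior) - n_forced) / n_free)
    free <- prior == 0
    prior[free] <- rbinom(n_free, 1, p_free)
    # every TF needs at least one target for the prior invariant
    for (t in which(rowSums(prior) == 0)) {
      prior[t, sample.int(cf$n_genes, 1)] <- 1
    }

    strength <- matrix(rlnorm(length(prior), 0, 0.25),
                       cf$n_tfs, cf$n_genes, dimnames = dimnames(prior))
    strength <- strength * prior

    # per-gene dose: the genes shifted up the most are de-targeted the
    # most, giving the within-set dose-response the correlation stage
    # looks for
    dose <- setNames(runif(cf$planted_set_size, 0.1, 1.9), planted)
    shift_g <- cf$expression_shift * dose
    atten_g <- pmin(pmax(1 - (1 - cf$targeting_attenuation) * dose, 0), 1)
    broad <- 1 - (1 - cf$targeting_attenuation) * 5 / 6

    strength_a <- strength
    strength_a[, planted] <- broad * strength_a[, planted]
    strength_a[repressors, planted] <-
      sweep(strength[repressors, planted, drop = FALSE], 2,
            atten_g[planted], `*`)

    # program-intrinsic variability replaces the lost regulatory input,
    # keeping each planted gene's marginal variance equal across groups
    lost_var <- colSums(strength[, planted, drop = FALSE]^2) -
      colSums(strength_a[, planted, drop = FALSE]^2)
    lost_var <- pmax(0, lost_var)

    subjects <- sprintf("S%03d", seq_len(cf$n_pairs))
    # Latent activity design: each TF's activity has a shared subject
    # component (pair correlation exactly 0.5) and a group-specific
    # component. When the subject dimension allows (3 * n_tfs <=
    # n_pairs), the components are drawn as disjoint blocks of a random
    # orthonormal basis, so within-group activities are *empirically*
    # uncorrelated and have unit realized variance — at these sample
    # sizes iid draws would leave +-(1/sqrt(n)) spurious correlations
    # between regulators that swamp the planted contrasts. Smaller
    # configurations fall back to iid draws.
    use_ortho <- switch(cf$activity_design %||% "auto",
                        auto = 3 * cf$n_tfs <= cf$n_pairs,
                        orthonormal = TRUE,
                        iid = FALSE)
    if (use_ortho && 3 * cf$n_tfs > cf$n_pairs) {
      abort("Orthonormal activity design needs 3 * n_tfs <= n_pairs.")
    }
    if (use_ortho) {
      q <- qr.Q(qr(matrix(rnorm(cf$n_pairs^2), cf$n_pairs)))
      sc <- sqrt(cf$n_pairs / 2)
      act_by_group <- list(
        A = sc * t(q[, seq_len(cf$n_tfs)] + q[, cf$n_tfs + seq_len(cf$n_tfs)]),
        B = sc * t(q[, seq_len(cf$n_tfs)] + q[, 2 * cf$n_tfs + seq_len(cf$n_tfs)]))
    } else {
      act_shared <- matrix(rnorm(cf$n_tfs * cf$n_pairs), cf$n_tfs, cf$n_pairs)
      act_by_group <- list(
        A = sqrt(0.5) * act_shared +
          sqrt(0.5) * matrix(rnorm(cf$n_tfs * cf$n_pairs), cf$n_tfs, cf$n_pairs),
        B = sqrt(0.5) * act_shared +
          sqrt(0.5) * matrix(rnorm(cf$n_tfs * cf$n_pairs), cf$n_tfs, cf$n_pairs))
    }
    planted_idx <- match(planted, gene_ids)
    make_group <- function(strength_mat, shift_vec, act, compensate = FALSE) {
      x <- t(strength_mat) %*% act +
        matrix(rnorm(cf$n_genes * cf$n_pairs, sd = cf$noise_sd),
               cf$n_genes, cf$n_pairs)
      if (compensate) {
        x[planted_idx, ] <- x[planted_idx, ] + sqrt(lost_var) *
          matrix(rnorm(cf$planted_set_size * cf$n_pairs),
                 cf$planted_set_size, cf$n_pairs)
      }
      x <- x + shift_vec
      tf_expr <- act + matrix(rnorm(cf$n_tfs * cf$n_pairs, sd = cf$noise_sd),
                              cf$n_tfs, cf$n_pairs)
      rbind(x, tf_expr)
    }
    shift_vec <- setNames(numeric(cf$n_genes), gene_ids)
    shift_vec[planted] <- shift_g
    xa <- make_group(strength_a, shift_vec, act_by_group$A, compensate = TRUE)
    xb <- make_group(strength, 0, act_by_group$B)
    rownames(xa) <- rownames(xb) <- c(gene_ids, tf_ids)

    mat <- cbind(xa, xb)
    colnames(mat) <- c(paste0(subjects, "_A"), paste0(subjects, "_B"))
    if (mode == "counts") {
      # Poisson-lognormal counts around a per-gene baseline
      mu <- 2^(mat + 5)
      mat <- matrix(rpois(length(mu), as.vector(mu)), nrow(mu), ncol(mu),
                    dimnames = dimnames(mat))
    }
    samples <- tibble(sample_id = colnames(mat),
                      subject_id = rep(subjects, 2),
                      group = rep(c("A", "B"), each = cf$n_pairs))
    expression <- expression_study(mat, samples, mode = mode)

    promoters <- synth_promoters(c(gene_ids, tf_ids))
    pwms <- synth_pwms(tf_ids)
    motif_hits <- synth_motif_hits(prior, promoters)
    ppi <- synth_ppi(tf_ids)
    gene_sets <- synth_gene_sets(planted, gene_ids)

    truth <- list(planted_genes = planted, repressor_tfs = repressors,
                  shift = shift_g, attenuation = atten_g,
                  prior = prior,
                  bound_pairs = tidyr::expand_grid(tf = repressors,
                                                   gene = planted))
    peaks <- generate_peaks(truth, promoters)
  })

  structure(list(expression = expression, motif_hits = motif_hits,
                 ppi = ppi, promoters = promoters, pwms = pwms,
                 peaks = peaks, gene_sets = gene_sets, truth = truth,
                 config = cf),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cf <- x$config
  cat("<synthetic_study> ", cf$n_tfs, " TFs x ", cf$n_genes, " genes x ",
      cf$n_pairs, " pairs; planted set of ", cf$planted_set_size,
      " genes, ", cf$repressor_tf_count, " repressor TFs\n", sep = "")
  invisible(x)
}

# One significant in-window hit per true edge for the best motif, plus
# three kinds of decoys exercising each filter: weak p-values, hits
# outside the window, hits of the inferior motif.
synth_motif_hits <- function(prior, promoters) {
  edge <- which(prior == 1, arr.ind = TRUE)
  tf <- rownames(prior)[edge[, 1]]
  gene <- colnames(prior)[edge[, 2]]
  win <- promoters[match(gene, promoters$gene_id), ]
  off <- sample.int(900, nrow(edge), replace = TRUE)
  start <- win$start + off
  true_hits <- tibble(motif_id = paste0(tf, "_M1"), gene_id = gene,
                      start = start, stop = start + 8L, strand = "+",
                      score = round(runif(nrow(edge), 10, 25), 3),
                      p_value = 10^runif(nrow(edge), -9, -5.1))
  n_decoy <- max(10L, nrow(edge) %/% 5L)
  dg <- sample(promoters$gene_id, 3 * n_decoy, replace = TRUE)
  dw <- promoters[match(dg, promoters$gene_id), ]
  dtf <- sample(rownames(prior), 3 * n_decoy, replace = TRUE)
  kind <- rep(c("weak_p", "outside", "bad_motif"), each = n_decoy)
  dstart <- ifelse(kind == "outside", dw$end + 500L,
                   dw$start + sample.int(900, 3 * n_decoy, replace = TRUE))
  decoys <- tibble(
    motif_id = ifelse(kind == "bad_motif", paste0(dtf, "_M2"),
                      paste0(dtf, "_M1")),
    gene_id = dg, start = as.integer(dstart), stop = as.integer(dstart) + 8L,
    strand = "-", score = round(runif(3 * n_decoy, 5, 12), 3),
    p_value = ifelse(kind == "weak_p", 10^runif(n_decoy * 3, -4.9, -2),
                     10^runif(n_decoy * 3, -9, -5.1)))
  dplyr::arrange(dplyr::bind_rows(true_hits, decoys),
                 .data$motif_id, .data$gene_id, .data$start)
}

# Sparse random StringDb-style interaction rows among the TFs.
synth_ppi <- function(tf_ids) {
  pairs <- t(utils::combn(tf_ids, 2))
  keep <- runif(nrow(pairs)) < 0.2
  pairs <- pairs[keep, , drop = FALSE]
  tibble(protein1 = pairs[, 1], protein2 = pairs[, 2],
         combined_score = sample(150:999, nrow(pairs), replace = TRUE))
}

# Planted set plus size-matched-ish random null sets; sizes adapt to
# small gene universes.
synth_gene_sets <- function(planted, gene_ids, n_null = 30) {
  lo <- min(20L, max(2L, length(gene_ids) %/% 4L))
  hi <- min(100L, length(gene_ids))
  sets <- list(cell_cycle_like = planted)
  for (i in seq_len(n_null)) {
    sets[[sprintf("random_set_%02d", i)]] <-
      sort(sample(gene_ids, sample(lo:hi, 1)))
  }
  sets
}

#' Generate ChIP-style peaks matching a study's truth
#'
#' One peak inside each truly bound gene's promoter window per bound
#' TF, plus decoy peaks placed outside every promoter window, in
#' narrowPeak-like columns.
#'
#' @param truth List with a `bound_pairs` tibble (`tf`, `gene`).
#' @param promoters Promoter table with windows.
#' @param n_decoys Decoy peaks per TF (default 20).
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal_value`, `p_value`, `q_value`, `peak`, `tf`.
#' @export
generate_peaks <- function(truth, promoters, n_decoys = 20) {
  bp <- as_tibble(truth$bound_pairs)
  tfs <- unique(c(bp$tf, truth$repressor_tfs))
  if (nrow(bp) > 0) {
    miss <- setdiff(bp$gene, promoters$gene_id)
    if (length(miss) > 0) {
      abort(paste0("Promoter table is missing truth genes: ",
                   paste(head(miss, 3), collapse = ", "), "."))
    }
    win <- promoters[match(bp$gene, promoters$gene_id), ]
    off <- sample.int(850, nrow(bp), replace = TRUE)
    start <- win$start + off
    bound_peaks <- tibble(chrom = win$chrom, start = start,
                          end = start + 100L, tf = bp$tf)
  } else {
    bound_peaks <- tibble(chrom = character(), start = integer(),
                          end = integer(), tf = character())
  }
  # decoys in the dead zone between promoter windows (slots are 10 kb,
  # windows 1 kb around mid-slot)
  n_slots <- nrow(promoters)
  decoys <- purrr::map_dfr(tfs, function(tf) {
    slot <- sample.int(n_slots, min(n_decoys, n_slots))
    start <- (slot - 1L) * 10000L + 8000L
    tibble(chrom = "chr1", start = start, end = start + 200L, tf = tf)
  })
  pk <- dplyr::bind_rows(bound_peaks, decoys) |>
    dplyr::arrange(.data$tf, .data$chrom, .data$start)
  pk |>
    dplyr::mutate(name = paste0(.data$tf, "_peak_", dplyr::row_number()),
                  score = 0L, strand = ".",
                  signal_value = round(runif(nrow(pk), 1, 50), 3),
                  p_value = round(runif(nrow(pk), 5, 30), 3),
                  q_value = -1, peak = 50L) |>
    dplyr::select("chrom", "start", "end", "name", "score", "strand",
                  "signal_value", "p_value", "q_value", "peak", "tf")
}
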