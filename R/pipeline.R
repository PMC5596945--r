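#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: motif-hit
#' p-value cut-off 1e-5, message-passing `alpha` 0.1 and Hamming
#' tolerance 0.001, 1000 gene-set permutations, 100 bootstrap networks
#' of 40 paired subjects, DE thresholds |log2FC| > 2 and FDR < 0.05,
#' and gene-set size bounds strictly between 15 and 500.
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed Global integer seed; stage seeds derive from it.
#' @param synthetic A [synthetic_config()] for the simulate stage
#'   (seeded from `seed` by default).
#' @param p_max Motif-hit p-value cut-off.
#' @param alpha,tol,max_iter Message-passing parameters.
#' @param n_perm Permutations for GSEA and the targeting correlation.
#' @param n_boot,subsample Bootstrap parameters.
#' @param lfc_cutoff,fdr_cutoff DE call thresholds.
#' @param min_size,max_size Exclusive gene-set size bounds.
#' @param focus_set Name of the gene set carried into the
#'   targeting-correlation and ChIP stages.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(outdir, seed = 1,
                            synthetic = synthetic_config(seed = seed),
                            p_max = 1e-5, alpha = 0.1, tol = 0.001,
                            max_iter = 200, n_perm = 1000, n_boot = 100,
                            subsample = 40, lfc_cutoff = 2,
                            fdr_cutoff = 0.05, min_size = 15,
                            max_size = 500,
                            focus_set = "cell_cycle_like") {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, p_max = p_max, alpha = alpha,
                 tol = tol, max_iter = max_iter, n_perm = n_perm,
                 n_boot = n_boot, subsample = subsample,
                 lfc_cutoff = lfc_cutoff, fdr_cutoff = fdr_cutoff,
                 min_size = min_size, max_size = max_size,
                 focus_set = focus_set),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; synthetic-study
#' fields go under a `synthetic:` mapping. Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file (e.g. from a
#'   `key=value` sweep).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- modifyList(raw, overrides)
  syn_args <- raw$synthetic %||% list()
  raw$synthetic <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown config keys: ", paste(bad, collapse = ", "), "."))
  }
  if (!is.null(raw$seed) && is.null(syn_args$seed)) {
    syn_args$seed <- raw$seed
  }
  raw$synthetic <- do.call(synthetic_config, syn_args)
  do.call(pipeline_config, raw)
}

pipeline_stages <- c("simulate", "priors", "de", "gsea", "panda",
                     "compare", "chip")

stage_deps <- list(
  simulate = character(0),
  priors = "simulate",
  de = "simulate",
  gsea = c("simulate", "de"),
  panda = c("simulate", "priors"),
  compare = c("simulate", "de", "panda"),
  chip = "simulate")

stage_outputs <- function(dir) list(
  simulate = file.path(dir, c("study_expression.tsv", "study_samples.tsv",
                              "motif_hits.tsv", "ppi.tsv", "gene_sets.gmt",
                              "promoters.bed", "peaks.narrowPeak",
                              "pwms.txt", "truth.json")),
  priors = file.path(dir, c("motif_prior.tsv", "ppi_prior.tsv")),
  de = file.path(dir, c("de.tsv", "variance_f.tsv")),
  gsea = file.path(dir, "gsea.tsv"),
  panda = file.path(dir, c("network_A.tsv", "network_B.tsv",
                           "panda_diagnostics.json")),
  compare = file.path(dir, c("tf_targeting.tsv", "gene_targeting.tsv",
                             "pathway_targeting.tsv",
                             "targeting_correlation.tsv")),
  chip = file.path(dir, c("bound_genes.tsv", "chip_contrast.tsv",
                          "chip_summary.json")))

check_upstream <- function(stage, dir, requested) {
  for (dep in stage_deps[[stage]]) {
    if (dep %in% requested) next
    if (!all(file.exists(stage_outputs(dir)[[dep]]))) {
      abort(paste0("Stage '", stage, "' needs outputs of stage '", dep,
                   "'; run '", dep, "' first."))
    }
  }
}

write_provenance <- function(dir, stage, params, seed, inputs, outputs) {
  md5 <- tools::md5sum(inputs)
  names(md5) <- basename(inputs)
  prov <- list(stage = stage, params = params, seed = seed,
               input_md5 = as.list(md5),
               outputs = basename(outputs))
  jsonlite::write_json(prov, file.path(dir, paste0("provenance_", stage,
                                                   ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order: `simulate`
#' (synthetic study) -> `priors` (motif + PPI priors) -> `de`
#' (moderated paired t, variance F) / `panda` (per-group networks) ->
#' `gsea` / `compare` (degree differences, TF and pathway targeting
#' tests, permutation-calibrated targeting correlation) -> `chip`
#' (promoter-peak annotation and TF-target correlation contrast). Every
#' stage reads its inputs from, and writes its artifacts to,
#' `config$outdir`, alongside a provenance JSON (parameters, seed,
#' input checksums). Rerunning with an identical configuration
#' reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, the vector of stages that ran.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0) {
    abort(paste0("Unknown stages: ", paste(bad, collapse = ", "), "."))
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir <- config$outdir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (stage in stages) {
    check_upstream(stage, dir, stages[seq_len(match(stage, stages) - 1)])
    t0 <- Sys.time()
    switch(stage,
           simulate = stage_simulate(config, dir),
           priors = stage_priors(config, dir),
           de = stage_de(config, dir),
           gsea = stage_gsea(config, dir),
           panda = stage_panda(config, dir),
           compare = stage_compare(config, dir),
           chip = stage_chip(config, dir))
    inform(sprintf("[%s] done in %.1fs (seed %d)", stage,
                   as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   config$seed))
  }
  invisible(stages)
}

stage_simulate <- function(config, dir) {
  study <- generate_study(config$synthetic)
  write_study(study, dir)
  write_provenance(dir, "simulate", unclass(config$synthetic),
                   config$synthetic$seed, character(0),
                   stage_outputs(dir)$simulate)
}

stage_priors <- function(config, dir) {
  hits <- read_fimo(file.path(dir, "motif_hits.tsv"))
  promoters <- read_promoter_bed(file.path(dir, "promoters.bed"))
  pwms <- read_pwms(file.path(dir, "pwms.txt"))
  expr <- read_expression(file.path(dir, "study"))
  ppi_tbl <- read_ppi(file.path(dir, "ppi.tsv"))
  genes <- intersect(promoters$gene_id, rownames(expr$matrix))
  genes <- genes[!genes %in% unique(purrr::map_chr(pwms, "tf_name"))]
  motif <- build_motif_prior(hits, promoters, pwms, genes,
                             p_max = config$p_max)
  ppi <- build_ppi_prior(ppi_tbl, rownames(motif))
  write_matrix_tsv(motif, file.path(dir, "motif_prior.tsv"))
  write_matrix_tsv(ppi, file.path(dir, "ppi_prior.tsv"))
  write_provenance(dir, "priors", list(p_max = config$p_max), config$seed,
                   file.path(dir, c("motif_hits.tsv", "promoters.bed",
                                    "pwms.txt", "ppi.tsv")),
                   stage_outputs(dir)$priors)
}

stage_de <- function(config, dir) {
  expr <- read_expression(file.path(dir, "study"))
  de <- moderated_paired_t(expr, lfc_cutoff = config$lfc_cutoff,
                           fdr_cutoff = config$fdr_cutoff)
  readr::write_tsv(de, file.path(dir, "de.tsv"))
  vf <- variance_f_test(expr, fdr_cutoff = config$fdr_cutoff)
  readr::write_tsv(vf, file.path(dir, "variance_f.tsv"))
  write_provenance(dir, "de",
                   list(lfc_cutoff = config$lfc_cutoff,
                        fdr_cutoff = config$fdr_cutoff,
                        d0 = attr(de, "d0"), s0_2 = attr(de, "s0_2")),
                   config$seed,
                   file.path(dir, c("study_expression.tsv",
                                    "study_samples.tsv")),
                   stage_outputs(dir)$de)
}

stage_gsea <- function(config, dir) {
  de <- readr::read_tsv(file.path(dir, "de.tsv"), show_col_types = FALSE)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  scores <- setNames(de$t_mod, de$gene_id)
  sets <- filter_sets(sets, names(scores), config$min_size,
                      config$max_size)
  res <- gsea_preranked(scores, sets, n_perm = config$n_perm,
                        seed = config$seed + 11L)
  readr::write_tsv(res, file.path(dir, "gsea.tsv"))
  write_provenance(dir, "gsea",
                   list(n_perm = config$n_perm, min_size = config$min_size,
                        max_size = config$max_size),
                   config$seed + 11L,
                   file.path(dir, c("de.tsv", "gene_sets.gmt")),
                   stage_outputs(dir)$gsea)
}

stage_panda <- function(config, dir) {
  expr <- read_expression(file.path(dir, "study"))
  motif <- read_matrix_tsv(file.path(dir, "motif_prior.tsv"))
  ppi <- read_matrix_tsv(file.path(dir, "ppi_prior.tsv"))
  priors <- prior_pair(motif, ppi)
  params <- panda_params(config$alpha, config$tol, config$max_iter)
  nets <- purrr::map(study_groups(expr),
                     ~ run_panda(priors, expr, params, group = .x))
  names(nets) <- study_groups(expr)
  write_matrix_tsv(nets[[1]]$W, file.path(dir, "network_A.tsv"))
  write_matrix_tsv(nets[[2]]$W, file.path(dir, "network_B.tsv"))
  jsonlite::write_json(
    purrr::map(nets, ~ list(iterations = .x$iterations,
                            hamming_trace = .x$hamming_trace,
                            converged = .x$converged)),
    file.path(dir, "panda_diagnostics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(dir, "panda",
                   list(alpha = config$alpha, tol = config$tol,
                        max_iter = config$max_iter),
                   config$seed,
                   file.path(dir, c("study_expression.tsv",
                                    "motif_prior.tsv", "ppi_prior.tsv")),
                   stage_outputs(dir)$panda)
}

stage_compare <- function(config, dir) {
  wa <- read_matrix_tsv(file.path(dir, "network_A.tsv"))
  wb <- read_matrix_tsv(file.path(dir, "network_B.tsv"))
  de <- readr::read_tsv(file.path(dir, "de.tsv"), show_col_types = FALSE)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  diff <- degree_differences(wa, wb)

  tf_test <- tf_differential_targeting(diff)
  tf_tbl <- dplyr::left_join(diff$tf, tf_test, by = "tf")
  readr::write_tsv(tf_tbl, file.path(dir, "tf_targeting.tsv"))
  readr::write_tsv(diff$gene, file.path(dir, "gene_targeting.tsv"))

  sets_f <- filter_sets(sets, colnames(wa), config$min_size,
                        config$max_size)
  readr::write_tsv(pathway_targeting_test(diff, sets_f),
                   file.path(dir, "pathway_targeting.tsv"))

  focus <- sets[[config$focus_set]]
  if (is.null(focus)) {
    abort(paste0("Focus set '", config$focus_set, "' not in the GMT."))
  }
  obs <- targeting_expression_correlation(diff, de, focus)
  res <- permutation_fdr(obs, diff, de, n_perm = config$n_perm,
                         seed = config$seed + 23L)
  readr::write_tsv(res, file.path(dir, "targeting_correlation.tsv"))
  write_provenance(dir, "compare",
                   list(n_perm = config$n_perm,
                        focus_set = config$focus_set,
                        min_size = config$min_size,
                        max_size = config$max_size),
                   config$seed + 23L,
                   file.path(dir, c("network_A.tsv", "network_B.tsv",
                                    "de.tsv", "gene_sets.gmt")),
                   stage_outputs(dir)$compare)
}

stage_chip <- function(config, dir) {
  peaks <- read_narrowpeak(file.path(dir, "peaks.narrowPeak"))
  promoters <- read_promoter_bed(file.path(dir, "promoters.bed"))
  expr <- read_expression(file.path(dir, "study"))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  focus <- sets[[config$focus_set]]
  bound <- annotate_promoter_peaks(peaks, promoters, query_set = focus)
  readr::write_tsv(
    tidyr::unnest(dplyr::mutate(bound, gene = .data$genes),
                  "gene")[, c("tf", "gene", "n_bound",
                              "fraction_of_universe",
                              "fraction_of_query_set")],
    file.path(dir, "bound_genes.tsv"))

  contrasts <- purrr::map(seq_len(nrow(bound)), function(i) {
    genes <- bound$genes[[i]]
    if (length(genes) < 2) return(NULL)
    group_correlation_contrast(expr, bound$tf[i], genes)
  })
  keep <- !purrr::map_lgl(contrasts, is.null)
  rho_tbl <- purrr::map2_dfr(contrasts[keep], bound$tf[keep],
                             ~ dplyr::mutate(tidy(.x), tf = .y)) |>
    dplyr::select("tf", "group", "gene", "rho")
  readr::write_tsv(rho_tbl, file.path(dir, "chip_contrast.tsv"))
  jsonlite::write_json(
    purrr::map2(contrasts[keep], which(keep), function(ct, i) {
      list(tf = bound$tf[i], n_bound = bound$n_bound[i],
           fraction_of_universe = bound$fraction_of_universe[i],
           fraction_of_query_set = bound$fraction_of_query_set[i],
           wilcox_p = ct$wilcox_p, medians = as.list(ct$medians))
    }),
    file.path(dir, "chip_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(dir, "chip", list(focus_set = config$focus_set),
                   config$seed,
                   file.path(dir, c("peaks.narrowPeak", "promoters.bed",
                                    "study_expression.tsv")),
                   stage_outputs(dir)$chip)
}
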