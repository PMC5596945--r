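#' Annotate ChIP peaks to gene promoters
#'
#' A gene counts as bound by a TF when at least one of the TF's peaks
#' intersects (>= 1 bp, half-open intervals) the gene's promoter window
#' (same -750/+250 windows as the motif prior). Peaks from multiple
#' replicate files should be concatenated first; the union is annotated.
#'
#' @param peaks Data frame of peak intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `tf` (the assayed TF).
#' @param promoters Promoter table with windows (see
#'   [add_promoter_windows()]); windows are recomputed when absent.
#' @param query_set Optional gene set over which to report the bound
#'   fraction (e.g. a pathway).
#' @return An object of class `bound_genes`: tibble with one row per TF,
#'   columns `tf`, `genes` (list column), `n_bound`,
#'   `fraction_of_universe`, and `fraction_of_query_set` when
#'   `query_set` is given.
#' @export
annotate_promoter_peaks <- function(peaks, promoters, query_set = NULL) {
  peaks <- as_tibble(peaks)
  need <- c("chrom", "start", "end", "tf")
  if (!all(need %in% names(peaks))) {
    abort(paste0("Peak table needs columns: ", paste(need, collapse = ", "), "."))
  }
  if (nrow(peaks) > 0 && any(peaks$start >= peaks$end)) {
    abort("Peak intervals must satisfy start < end.")
  }
  if (!all(c("start", "end") %in% names(promoters))) {
    promoters <- add_promoter_windows(promoters)
  }
  promoters <- as_tibble(promoters)
  n_universe <- nrow(promoters)

  bound_for <- function(pk) {
    hits <- character(0)
    for (ch in unique(pk$chrom)) {
      pr <- promoters[promoters$chrom == ch, ]
      if (nrow(pr) == 0) next
      pc <- pk[pk$chrom == ch, ]
      # half-open BED intervals -> 1-based closed for IRanges
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(pr$start + 1L, pr$end),
        IRanges::IRanges(pc$start + 1L, pc$end))
      hits <- c(hits, pr$gene_id[unique(S4Vectors::queryHits(ov))])
    }
    sort(unique(hits))
  }

  tfs <- sort(unique(peaks$tf))
  out <- purrr::map_dfr(tfs, function(tf) {
    g <- bound_for(peaks[peaks$tf == tf, ])
    tibble(tf = tf, genes = list(g), n_bound = length(g),
           fraction_of_universe = length(g) / n_universe)
  })
  if (!is.null(query_set)) {
    out$fraction_of_query_set <- purrr::map_dbl(
      out$genes, ~ length(intersect(.x, query_set)) / length(query_set))
  }
  class(out) <- c("bound_genes", class(out))
  out
}

#' Contrast TF-target expression correlations between groups
#'
#' Within each group, the Spearman correlation between the TF's
#' expression and each bound gene's expression across that group's
#' samples; the two groups' correlation distributions are compared with
#' a two-sided Wilcoxon rank-sum test.
#'
#' @param expr An `expression_study` whose matrix contains a row for the
#'   TF (its expression) and rows for the genes.
#' @param tf Gene/row id of the TF.
#' @param genes Character vector of bound gene ids (or a one-row
#'   `bound_genes` subset, whose `genes` column is used).
#' @param group_a,group_b Group labels.
#' @return An object of class `cor_contrast`: list with `rho` (tibble:
#'   `group`, `gene`, `rho`), `wilcox_p`, `medians` (named vector), `tf`.
#' @export
group_correlation_contrast <- function(expr, tf, genes,
                                       group_a = study_groups(expr)[1],
                                       group_b = study_groups(expr)[2]) {
  if (inherits(genes, "bound_genes")) {
    if (nrow(genes) != 1) abort("Pass one TF's bound_genes row.")
    genes <- genes$genes[[1]]
  }
  genes <- setdiff(genes, tf)
  if (!tf %in% rownames(expr$matrix)) abort("TF not present in the expression matrix.")
  miss <- setdiff(genes, rownames(expr$matrix))
  if (length(miss) > 0) {
    abort(paste0(length(miss), " bound genes missing from the expression matrix."))
  }
  if (length(genes) < 2) abort("Need at least 2 bound genes.")

  rho_group <- function(group) {
    m <- group_matrix(expr, group)
    tf_x <- m[tf, ]
    if (sd(tf_x) == 0) {
      abort(paste0("TF '", tf, "' is constant in group '", group, "'."))
    }
    r <- suppressWarnings(
      as.vector(cor(tf_x, t(m[genes, , drop = FALSE]), method = "spearman")))
    tibble(group = group, gene = genes, rho = r)
  }
  rho <- dplyr::bind_rows(rho_group(group_a), rho_group(group_b))
  wt <- suppressWarnings(
    wilcox.test(rho$rho[rho$group == group_a], rho$rho[rho$group == group_b]))
  med <- c(median(rho$rho[rho$group == group_a], na.rm = TRUE),
           median(rho$rho[rho$group == group_b], na.rm = TRUE))
  structure(list(rho = rho, wilcox_p = wt$p.value,
                 medians = setNames(med, c(group_a, group_b)), tf = tf),
            class = "cor_contrast")
}

#' @export
print.cor_contrast <- function(x, ...) {
  cat("<cor_contrast> TF ", x$tf, ": median rho ",
      paste(names(x$medians), round(x$medians, 3), sep = " = ",
            collapse = ", "),
      "; Wilcoxon p = ", signif(x$wilcox_p, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cor_contrast <- function(x, ...) x$rho

#' @export
glance.cor_contrast <- function(x, ...) {
  tibble(tf = x$tf, wilcox_p = x$wilcox_p,
         median_rho_a = x$medians[1], median_rho_b = x$medians[2],
         n_genes = nrow(x$rho) / 2)
}
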