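#' Position probability matrix for a TF binding motif
#'
#' @param motif_id Motif identifier.
#' @param tf_name Name of the TF the motif belongs to.
#' @param matrix Positions x 4 matrix of base probabilities (columns
#'   A, C, G, T); every row must sum to 1 within 1e-6.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, tf_name, matrix) {
  if (!is.matrix(matrix) || ncol(matrix) != 4 || nrow(matrix) < 1) {
    abort("PWM matrix must have >= 1 position and exactly 4 base columns.")
  }
  if (any(matrix < 0)) abort("PWM probabilities must be non-negative.")
  if (any(abs(rowSums(matrix) - 1) > 1e-6)) {
    abort("Every PWM row must sum to 1 (tolerance 1e-6).")
  }
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, tf_name = tf_name, matrix = matrix),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, " (", x$tf_name, "), ", nrow(x$matrix),
      " positions, IC = ", round(motif_information_content(x), 2),
      " bits\n", sep = "")
  invisible(x)
}

#' Information content of a motif, in bits
#'
#' Computed against the uniform background as
#' `sum over positions of (2 + sum_b p_b log2 p_b)`, with `0 log 0 = 0`.
#' Ranges from 0 (all rows uniform) to `2 * L` (one-hot rows).
#'
#' @param x A [pwm()] object.
#' @return Total information content in bits.
#' @export
motif_information_content <- function(x) {
  if (!inherits(x, "pwm")) abort("`x` must be a pwm object.")
  p <- x$matrix
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + rowSums(plogp))
}

#' Pick the highest-information-content motif per TF
#'
#' Mirrors the common practice of retaining one representative motif per
#' TF before building a binary regulatory prior. Ties are broken by
#' lexicographic motif id for determinism.
#'
#' @param pwms List of [pwm()] objects.
#' @return Tibble with columns `tf_name`, `motif_id`, `ic`, one row per TF.
#' @export
select_best_motif <- function(pwms) {
  if (length(pwms) == 0) abort("No PWMs supplied.")
  tbl <- purrr::map_dfr(pwms, function(p) {
    tibble(tf_name = p$tf_name, motif_id = p$motif_id,
           ic = motif_information_content(p))
  })
  tbl |>
    dplyr::arrange(.data$tf_name, dplyr::desc(.data$ic), .data$motif_id) |>
    dplyr::distinct(.data$tf_name, .keep_all = TRUE)
}

#' Promoter window around a TSS
#'
#' The promoter is the interval from 750 bp upstream to 250 bp downstream
#' of the transcription start site. Coordinates are BED-style 0-based
#' half-open; minus-strand windows mirror the offsets around the TSS so
#' that "upstream-heavy" is preserved. Windows are clipped at 0.
#'
#' @param tss Integer vector of TSS coordinates (0-based).
#' @param strand Character vector of `"+"` / `"-"` (recycled).
#' @param upstream,downstream Window extents in bp (defaults 750 / 250).
#' @return Tibble with columns `start`, `end` (half-open).
#' @export
#' @examples
#' promoter_window(1000, "+")  # [250, 1250)
#' promoter_window(1000, "-")  # [750, 1750)
promoter_window <- function(tss, strand, upstream = 750, downstream = 250) {
  if (any(tss < 0)) abort("TSS coordinates must be non-negative.")
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    abort(paste0("Unknown strand symbol: '",
                 paste(unique(strand[bad]), collapse = "', '"), "'."))
  }
  n <- max(length(tss), length(strand))
  tss <- rep_len(tss, n); strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream)
  tibble(start = pmax(0L, as.integer(start)), end = as.integer(end))
}

#' Attach promoter windows to a promoter table
#'
#' @param promoters Data frame with columns `gene_id`, `chrom`, `tss`,
#'   `strand`.
#' @param upstream,downstream Passed to [promoter_window()].
#' @return The table as a tibble with `start`/`end` window columns added
#'   (existing ones are recomputed).
#' @export
add_promoter_windows <- function(promoters, upstream = 750, downstream = 250) {
  promoters <- as_tibble(promoters)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(promoters))) {
    abort(paste0("Promoter table needs columns: ", paste(need, collapse = ", "), "."))
  }
  w <- promoter_window(promoters$tss, promoters$strand, upstream, downstream)
  promoters$start <- w$start
  promoters$end <- w$end
  promoters
}

#' Build the binary TF x gene motif prior
#'
#' Keeps motif hits with `p_value < p_max` whose interval overlaps (>= 1 bp,
#' half-open intervals) the gene's promoter window, collapses motifs to TFs
#' by [select_best_motif()], and sets entry (TF, gene) to 1 when at least one
#' retained hit remains. TFs without a single significant promoter hit are
#' dropped, as are genes absent from `expressed_genes`.
#'
#' @param hits Motif hit table: columns `motif_id`, `gene_id`, `start`,
#'   `stop` (half-open, same coordinate system as the promoter windows),
#'   `strand`, `score`, `p_value`.
#' @param promoters Promoter table (see [add_promoter_windows()]); windows
#'   are recomputed from `tss`/`strand` when absent.
#' @param pwms List of [pwm()] objects mapping motifs to TFs.
#' @param expressed_genes Character vector of genes to retain as columns.
#' @param p_max Hit p-value cut-off (default 1e-5; strictly below).
#' @return Binary matrix TFs x genes with dimnames.
#' @export
build_motif_prior <- function(hits, promoters, pwms, expressed_genes,
                              p_max = 1e-5) {
  hits <- as_tibble(hits)
  need <- c("motif_id", "gene_id", "start", "stop", "p_value")
  if (!all(need %in% names(hits))) {
    abort(paste0("Hit table needs columns: ", paste(need, collapse = ", "), "."))
  }
  if (any(hits$p_value <= 0 | hits$p_value > 1)) {
    abort("Hit p-values must lie in (0, 1].")
  }
  if (any(hits$start > hits$stop)) abort("Hit intervals must have start <= stop.")
  if (!all(c("start", "end") %in% names(promoters))) {
    promoters <- add_promoter_windows(promoters)
  }
  best <- select_best_motif(pwms)

  kept <- hits |>
    dplyr::filter(.data$p_value < p_max) |>
    dplyr::inner_join(best[, c("tf_name", "motif_id")], by = "motif_id") |>
    dplyr::inner_join(
      dplyr::select(as_tibble(promoters), "gene_id",
                    win_start = "start", win_end = "end"),
      by = "gene_id") |>
    dplyr::filter(.data$start < .data$win_end, .data$stop > .data$win_start) |>
    dplyr::filter(.data$gene_id %in% expressed_genes)

  if (nrow(kept) == 0) {
    abort("No motif hits survive the p-value/promoter/expression filters.")
  }
  tfs <- sort(unique(kept$tf_name))
  genes <- expressed_genes
  prior <- matrix(0, length(tfs), length(genes),
                  dimnames = list(tfs, genes))
  prior[cbind(match(kept$tf_name, tfs), match(kept$gene_id, genes))] <- 1
  prior
}

#' Build the TF x TF protein-protein interaction prior
#'
#' Interaction scores on the StringDb 0-1000 scale are restricted to the
#' given TFs, divided by 1000, symmetrized by the maximum of the two
#' directions, missing pairs set to 0 and self-interactions to 1.
#'
#' @param scores Data frame with columns `protein1`, `protein2`,
#'   `combined_score` (0-1000).
#' @param tf_ids Character vector of TFs defining the matrix order.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
build_ppi_prior <- function(scores, tf_ids) {
  if (length(tf_ids) == 0) abort("`tf_ids` must be non-empty.")
  ppi <- matrix(0, length(tf_ids), length(tf_ids),
                dimnames = list(tf_ids, tf_ids))
  scores <- as_tibble(scores)
  if (nrow(scores) > 0) {
    need <- c("protein1", "protein2", "combined_score")
    if (!all(need %in% names(scores))) {
      abort(paste0("Score table needs columns: ", paste(need, collapse = ", "), "."))
    }
    if (any(scores$combined_score < 0 | scores$combined_score > 1000)) {
      abort("Interaction scores must lie in [0, 1000].")
    }
    sc <- scores |>
      dplyr::filter(.data$protein1 %in% tf_ids, .data$protein2 %in% tf_ids)
    if (nrow(sc) > 0) {
      i <- match(sc$protein1, tf_ids); j <- match(sc$protein2, tf_ids)
      v <- sc$combined_score / 1000
      for (k in seq_along(v)) {  # max-symmetrization over duplicate rows
        ppi[i[k], j[k]] <- max(ppi[i[k], j[k]], v[k])
        ppi[j[k], i[k]] <- max(ppi[j[k], i[k]], v[k])
      }
    }
  }
  diag(ppi) <- 1
  ppi
}

#' Pair of structural priors for network inference
#'
#' @param motif_prior Binary TF x gene matrix from [build_motif_prior()].
#' @param ppi_prior Symmetric TF x TF matrix from [build_ppi_prior()];
#'   must share the motif prior's TF order.
#' @return An object of class `prior_pair`.
#' @export
prior_pair <- function(motif_prior, ppi_prior) {
  if (!identical(rownames(motif_prior), rownames(ppi_prior)) ||
      !identical(rownames(ppi_prior), colnames(ppi_prior))) {
    abort("motif and PPI priors must share an identical TF id space.")
  }
  if (!all(motif_prior %in% c(0, 1))) abort("Motif prior must be binary.")
  if (any(rowSums(motif_prior) == 0)) {
    abort("Every retained TF needs at least one motif-prior edge.")
  }
  if (max(abs(ppi_prior - t(ppi_prior))) > 1e-12 ||
      any(ppi_prior < 0 | ppi_prior > 1) || any(diag(ppi_prior) != 1)) {
    abort("PPI prior must be symmetric in [0,1] with unit diagonal.")
  }
  structure(list(motif_prior = motif_prior, ppi_prior = ppi_prior,
                 tf_ids = rownames(motif_prior),
                 gene_ids = colnames(motif_prior)),
            class = "prior_pair")
}

#' @export
print.prior_pair <- function(x, ...) {
  cat("<prior_pair> ", length(x$tf_ids), " TFs x ", length(x$gene_ids),
      " genes; motif density ",
      round(mean(x$motif_prior), 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.prior_pair <- function(x, ...) {
  as_tibble(x$motif_prior, rownames = "tf") |>
    tidyr::pivot_longer(-"tf", names_to = "gene", values_to = "prior")
}
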