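#' Paired two-group expression study
#'
#' Bundles a genes x samples expression matrix with its sample metadata.
#' The design is paired: every subject contributes exactly one sample to
#' each of the two groups. Values are either already on a normalized
#' log2 scale (`mode = "normalized"`) or raw counts (`mode = "counts"`,
#' to be transformed with [log_cpm()]).
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param samples Data frame with columns `sample_id`, `subject_id`,
#'   `group`; one row per column of `matrix`.
#' @param mode `"normalized"` (log scale) or `"counts"`.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `matrix`, `samples` (tibble) and `mode`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    subject_id = rep(c("p1", "p2"), 2),
#'                    group = rep(c("A", "B"), each = 2))
#' es <- expression_study(m, meta)
#' es
expression_study <- function(matrix, samples, mode = c("normalized", "counts")) {
  mode <- match.arg(mode)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    abort("`matrix` must have gene rownames and sample colnames.")
  }
  if (anyNA(matrix)) abort("Expression matrix contains missing values.")
  samples <- as_tibble(samples)
  need <- c("sample_id", "subject_id", "group")
  if (!all(need %in% names(samples))) {
    abort(paste0("`samples` must have columns: ", paste(need, collapse = ", "), "."))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$subject_id <- as.character(samples$subject_id)
  samples$group <- as.character(samples$group)
  if (!setequal(samples$sample_id, colnames(matrix)) ||
      anyDuplicated(samples$sample_id) > 0) {
    abort("`samples$sample_id` must match the matrix column names exactly.")
  }
  samples <- samples[match(colnames(matrix), samples$sample_id), ]
  groups <- unique(samples$group)
  if (length(groups) != 2) {
    abort("An expression study must have exactly two groups.")
  }
  tab <- table(samples$subject_id, samples$group)
  if (any(tab != 1)) {
    abort("Unpaired design: every subject must appear exactly once per group.")
  }
  if (mode == "counts" && (any(matrix < 0) || any(matrix != round(matrix)))) {
    abort("Counts mode requires non-negative integer values.")
  }
  structure(list(matrix = matrix, samples = samples, mode = mode),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples (", x$mode, ")\n", sep = "")
  cat("  groups: ", paste(study_groups(x), collapse = " / "),
      "; ", n_pairs(x), " subject pairs\n", sep = "")
  invisible(x)
}

#' @export
tidy.expression_study <- function(x, ...) {
  as_tibble(x$matrix, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "value") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' Group labels of a study, in stable (sorted) order
#' @param x An `expression_study`.
#' @return Character vector of length 2.
#' @export
study_groups <- function(x) sort(unique(x$samples$group))

#' Number of subject pairs in a study
#' @param x An `expression_study`.
#' @return Integer count of subjects.
#' @export
n_pairs <- function(x) length(unique(x$samples$subject_id))

#' Extract one group's submatrix with columns ordered by subject
#'
#' Columns are ordered by `subject_id` so that matrices extracted for the
#' two groups are column-aligned by subject (the paired contrast).
#'
#' @param x An `expression_study`.
#' @param group Group label.
#' @param subjects Optional subject subset (character), kept in the given
#'   order; defaults to all subjects sorted.
#' @return Numeric matrix genes x subjects (colnames = subject ids).
#' @export
group_matrix <- function(x, group, subjects = NULL) {
  if (!group %in% x$samples$group) {
    abort(paste0("Unknown group: '", group, "'."))
  }
  meta <- x$samples[x$samples$group == group, ]
  if (is.null(subjects)) subjects <- sort(meta$subject_id)
  idx <- match(subjects, meta$subject_id)
  if (anyNA(idx)) abort("Requested subjects missing from the study.")
  m <- x$matrix[, meta$sample_id[idx], drop = FALSE]
  colnames(m) <- subjects
  m
}

#' Matrix of within-subject differences between the two groups
#'
#' @param x An `expression_study` (normalized mode).
#' @param group_a,group_b Group labels; difference is `group_a - group_b`.
#' @return Genes x subjects matrix of paired differences.
#' @export
paired_differences <- function(x, group_a = study_groups(x)[1],
                               group_b = study_groups(x)[2]) {
  group_matrix(x, group_a) - group_matrix(x, group_b)
}
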