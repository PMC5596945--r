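#' Read and write study components in standard text formats
#'
#' Readers and writers for the plain-text formats the pipeline consumes
#' and emits: expression TSV (genes x samples, first column `gene_id`),
#' sample metadata TSV, FIMO-style motif hit TSV, StringDb-style PPI
#' TSV, GMT gene sets, BED6 promoters, narrowPeak peaks, MEME-like PWM
#' text and long-format network TSV.
#'
#' @param path File path.
#' @name study_io
NULL

#' @rdname study_io
#' @param expr An `expression_study`.
#' @param prefix Output path prefix; writes `<prefix>_expression.tsv`
#'   and `<prefix>_samples.tsv`.
#' @export
write_expression <- function(expr, prefix) {
  readr::write_tsv(as_tibble(expr$matrix, rownames = "gene_id"),
                   paste0(prefix, "_expression.tsv"))
  readr::write_tsv(expr$samples, paste0(prefix, "_samples.tsv"))
  invisible(prefix)
}

#' @rdname study_io
#' @param mode Expression mode, `"normalized"` or `"counts"`.
#' @export
read_expression <- function(prefix, mode = "normalized") {
  mat_tbl <- readr::read_tsv(paste0(prefix, "_expression.tsv"),
                             show_col_types = FALSE)
  m <- as.matrix(mat_tbl[, -1])
  rownames(m) <- mat_tbl$gene_id
  samples <- readr::read_tsv(paste0(prefix, "_samples.tsv"),
                             show_col_types = FALSE)
  expression_study(m, samples, mode = mode)
}

#' @rdname study_io
#' @param hits Motif hit tibble (see [build_motif_prior()]).
#' @export
write_fimo <- function(hits, path) {
  out <- hits
  names(out) <- c("motif_id", "sequence_name", "start", "stop", "strand",
                  "score", "p-value")[seq_along(out)]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_fimo <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[names(tbl) == "sequence_name"] <- "gene_id"
  names(tbl)[names(tbl) == "p-value"] <- "p_value"
  tbl
}

#' @rdname study_io
#' @param sets Named list of gene sets.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, function(genes, nm) {
    paste(c(nm, "synthetic", genes), collapse = "\t")
  })
  writeLines(unname(lines), path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- purrr::map(parts, ~ .x[-(1:2)])
  names(sets) <- purrr::map_chr(parts, 1)
  sets
}

#' @rdname study_io
#' @param promoters Promoter table with windows.
#' @export
write_promoter_bed <- function(promoters, path) {
  readr::write_tsv(
    tibble(chrom = promoters$chrom, start = promoters$start,
           end = promoters$end, name = promoters$gene_id,
           score = 0L, strand = promoters$strand,
           tss = promoters$tss),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_promoter_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "name", "score", "strand",
                                             "tss"),
                         show_col_types = FALSE)
  tibble(gene_id = tbl$name, chrom = tbl$chrom, tss = tbl$tss,
         strand = tbl$strand, start = tbl$start, end = tbl$end)
}

#' @rdname study_io
#' @param peaks Peak tibble from [generate_peaks()] or with the same
#'   columns.
#' @export
write_narrowpeak <- function(peaks, path) {
  readr::write_tsv(peaks[, c("chrom", "start", "end", "name", "score",
                             "strand", "signal_value", "p_value",
                             "q_value", "peak")],
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @param tf_from_name Parse the assayed TF from the peak name prefix
#'   (`<tf>_peak_<i>`)?
#' @export
read_narrowpeak <- function(path, tf_from_name = TRUE) {
  tbl <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "signal_value", "p_value", "q_value", "peak"),
    show_col_types = FALSE)
  if (tf_from_name) tbl$tf <- sub("_peak_\\d+$", "", tbl$name)
  tbl
}

#' @rdname study_io
#' @param scores PPI tibble (`protein1`, `protein2`, `combined_score`).
#' @export
write_ppi <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_ppi <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' @rdname study_io
#' @param pwms List of [pwm()] objects.
#' @export
write_pwms <- function(pwms, path) {
  lines <- unlist(purrr::map(pwms, function(p) {
    c(paste("MOTIF", p$motif_id, p$tf_name),
      paste0("letter-probability matrix: alength= 4 w= ", nrow(p$matrix)),
      apply(p$matrix, 1, function(r) paste(format(r, digits = 6),
                                           collapse = " ")),
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  purrr::map(starts, function(i) {
    hdr <- strsplit(lines[i], " +")[[1]]
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[i + 1]))
    rows <- lines[(i + 2):(i + 1 + w)]
    m <- do.call(rbind, purrr::map(rows, ~ as.numeric(strsplit(trimws(.x),
                                                               " +")[[1]])))
    pwm(hdr[2], hdr[3], m)
  }) |>
    (\(x) setNames(x, purrr::map_chr(x, "motif_id")))()
}

#' @rdname study_io
#' @param m Matrix with dimnames (prior or network).
#' @export
write_matrix_tsv <- function(m, path) {
  readr::write_tsv(as_tibble(m, rownames = "id"), path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_matrix_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$id
  m
}

#' @rdname study_io
#' @param net A `regulatory_network`.
#' @param prior Optional motif prior matrix to include as a column.
#' @export
write_network <- function(net, path, prior = NULL) {
  readr::write_tsv(tidy(net, prior = prior), path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_network_long <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' Write every component of a synthetic study to a directory
#'
#' Emits the study in the same standard formats the pipeline reads back:
#' expression + samples TSV, FIMO-style hits, PPI TSV, GMT, BED6
#' promoters, narrowPeak peaks, MEME-like PWMs, and a truth JSON.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(study$expression, file.path(dir, "study"))
  write_fimo(study$motif_hits, file.path(dir, "motif_hits.tsv"))
  write_ppi(study$ppi, file.path(dir, "ppi.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_promoter_bed(study$promoters, file.path(dir, "promoters.bed"))
  write_narrowpeak(study$peaks, file.path(dir, "peaks.narrowPeak"))
  write_pwms(study$pwms, file.path(dir, "pwms.txt"))
  truth <- study$truth
  jsonlite::write_json(
    list(planted_genes = truth$planted_genes,
         repressor_tfs = truth$repressor_tfs,
         shift = as.list(truth$shift),
         attenuation = as.list(truth$attenuation),
         bound_pairs = truth$bound_pairs),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_matrix_tsv(truth$prior, file.path(dir, "truth_prior.tsv"))
  invisible(dir)
}
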