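#' Peptide Index: average spectral count per cell line
#'
#' The Peptide Index (P_i) of a peptide in a cell line is its average spectral
#' count over that line's replicates. The mean is zero-inclusive: replicates
#' where the peptide was not observed contribute a count of 0 and the divisor
#' is always `total_reps`, which keeps P_i comparable across peptides with
#' different detection rates. Peptides never observed in a cell line have
#' P_i = 0 there.
#'
#' @param peptides Tibble of peptide records, normally already passed through
#'   [replicate_consistency_filter()].
#' @param total_reps Number of biological replicates per cell line (default 3).
#' @param cell_lines Optional character vector fixing the cell-line set and
#'   order (defaults to the lines present in `peptides`).
#' @return A long tibble `sequence`, `cell_line`, `p_i`, complete over the
#'   full sequence-by-cell-line grid (absent combinations carry `p_i = 0`).
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   sequence = "KLVANNTRL", protein_id = NA, start = NA, end = NA,
#'   cell_line = "L1", replicate = c("r1", "r2", "r3"),
#'   spectral_count = c(3L, 5L, 4L), intensity = NA
#' )
#' peptide_index(tbl, total_reps = 3)
peptide_index <- function(peptides, total_reps = 3L, cell_lines = NULL) {
  if (total_reps <= 0) abort("total_reps must be positive")
  if (is.null(cell_lines)) cell_lines <- sort(unique(peptides$cell_line))
  observed <- peptides %>%
    group_by(.data$sequence, .data$cell_line) %>%
    summarise(p_i = sum(.data$spectral_count) / total_reps, .groups = "drop")
  tidyr::expand_grid(
    sequence = sort(unique(peptides$sequence)),
    cell_line = cell_lines
  ) %>%
    left_join(observed, by = c("sequence", "cell_line")) %>%
    mutate(p_i = tidyr::replace_na(.data$p_i, 0))
}

#' Epitope Index matrix
#'
#' The Epitope Index (E_i) of an epitope in a cell line is the sum of the
#' Peptide Indices of all its constituent peptides in that line. The result is
#' an epitopes-by-cell-lines matrix; compute it separately for the class I and
#' class II epitope groups by filtering `epitopes` first.
#'
#' @param epitopes Epitope tibble (with `constituents` list column).
#' @param pi_tbl Long Peptide Index tibble from [peptide_index()].
#' @return An `ei_matrix`: a numeric matrix (rows = epitope ids, columns =
#'   cell lines) with class `"ei_matrix"`.
#' @export
epitope_index <- function(epitopes, pi_tbl) {
  cell_lines <- unique(pi_tbl$cell_line)
  pw <- tidyr::pivot_wider(pi_tbl,
    names_from = "cell_line", values_from = "p_i", values_fill = 0
  )
  pm <- as.matrix(pw[, cell_lines, drop = FALSE])
  rownames(pm) <- pw$sequence
  vals <- matrix(0, nrow(epitopes), length(cell_lines),
    dimnames = list(epitopes$epitope_id, cell_lines)
  )
  for (i in seq_len(nrow(epitopes))) {
    cs <- epitopes$constituents[[i]]
    idx <- match(cs, rownames(pm))
    if (anyNA(idx)) {
      abort(sprintf(
        "constituent peptide %s of %s has no Peptide Index entry",
        cs[is.na(idx)][1], epitopes$epitope_id[i]
      ))
    }
    vals[i, ] <- colSums(pm[idx, , drop = FALSE])
  }
  structure(vals, class = c("ei_matrix", class(vals)))
}

#' @export
print.ei_matrix <- function(x, ...) {
  cat(sprintf(
    "Epitope Index matrix: %d epitopes x %d cell lines\n", nrow(x), ncol(x)
  ))
  print(head(unclass(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more epitopes\n", nrow(x) - 6))
  invisible(x)
}

#' Tidy an Epitope Index matrix into long form
#' @param x An `ei_matrix`.
#' @param ... Unused.
#' @return Tibble `epitope_id`, `cell_line`, `e_i`.
#' @export
tidy.ei_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    epitope_id = rep(rownames(m), times = ncol(m)),
    cell_line = rep(colnames(m), each = nrow(m)),
    e_i = as.vector(m)
  )
}

#' One-row summary of an Epitope Index matrix
#' @param x An `ei_matrix`.
#' @param ... Unused.
#' @return Tibble with epitope/cell-line counts, total index mass and the
#'   fraction of zero cells.
#' @export
glance.ei_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    n_epitopes = nrow(m), n_cell_lines = ncol(m),
    total_ei = sum(m), frac_zero = mean(m == 0)
  )
}

#' Write / read an Epitope Index matrix as TSV
#'
#' Rows are epitopes, columns cell lines; the first column holds epitope ids.
#' This is also the input format for the clustering stage.
#'
#' @param ei An `ei_matrix`.
#' @param path TSV path.
#' @return `path` (write) or an `ei_matrix` (read).
#' @export
write_ei_matrix <- function(ei, path) {
  df <- as_tibble(unclass(ei), rownames = "epitope_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_ei_matrix
#' @export
read_ei_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    epitope_id = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$epitope_id
  structure(m, class = c("ei_matrix", class(m)))
}

#' Heatmap of an Epitope Index matrix
#' @param object An `ei_matrix`.
#' @param log1p_scale Show log1p-transformed values (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ei_matrix <- function(object, log1p_scale = TRUE, ...) {
  long <- tidy(object)
  if (log1p_scale) long$e_i <- log1p(long$e_i)
  ggplot(long, aes(
    x = .data$cell_line,
    y = factor(.data$epitope_id, levels = rev(rownames(object))),
    fill = .data$e_i
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "grey10",
      name = if (log1p_scale) "log1p(E_i)" else "E_i"
    ) +
    ggplot2::labs(x = "cell line", y = "epitope") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Classify peptides as affected by an HLA knockdown
#'
#' Computes a knockdown/control presentation ratio per peptide from normalized
#' intensities. Peptides found only in the knockdown sample receive an
#' arbitrary high ratio (`exclusive_high`, default 50); peptides found only in
#' the control receive the reciprocal (`exclusive_low`, default 0.02). A
#' peptide is called `affected` when its ratio is at or below
#' `knockdown_factor` - by default 0.21, matching a knockdown leaving 21% of
#' the targeted HLA protein.
#'
#' @param kd,ctrl Tibbles with columns `sequence` and `intensity` for the
#'   knockdown and control samples.
#' @param exclusive_high,exclusive_low Ratios assigned to peptides exclusive
#'   to the knockdown / control sample.
#' @param knockdown_factor Affected-call cutoff (ratio <= cutoff).
#' @param normalize `"total"` scales each sample to unit total intensity
#'   before forming ratios; `"none"` uses raw intensities.
#' @return Tibble `sequence`, `ratio`, `affected` over the union of peptides.
#' @export
knockdown_classification <- function(kd, ctrl, exclusive_high = 50,
                                     exclusive_low = 0.02,
                                     knockdown_factor = 0.21,
                                     normalize = c("total", "none")) {
  normalize <- arg_match(normalize)
  if (knockdown_factor <= 0) abort("knockdown_factor must be positive")
  if (normalize == "total") {
    kd <- mutate(kd, intensity = .data$intensity / sum(.data$intensity))
    ctrl <- mutate(ctrl, intensity = .data$intensity / sum(.data$intensity))
  }
  all_seq <- sort(union(kd$sequence, ctrl$sequence))
  kd_i <- kd$intensity[match(all_seq, kd$sequence)]
  ct_i <- ctrl$intensity[match(all_seq, ctrl$sequence)]
  ratio <- dplyr::case_when(
    !is.na(kd_i) & !is.na(ct_i) ~ kd_i / ct_i,
    is.na(ct_i) ~ exclusive_high,
    TRUE ~ exclusive_low
  )
  tibble(
    sequence = all_seq,
    ratio = ratio,
    affected = ratio <= knockdown_factor
  )
}
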