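#' Parse a binder-prediction export into annotation calls
#'
#' Ingests the tabular output of an external MHC binding predictor (a
#' NetMHCpan-style table carrying a percentile rank per peptide-allele pair)
#' and maps ranks to calls: `strong` at or below `strong_cutoff`, `weak` at
#' or below `weak_cutoff`, `none` otherwise. The prediction tools themselves
#' are never executed by this package; only their exports are read. Default
#' cutoffs are the conventional parser defaults for class I (0.5 / 2.0);
#' class II tools conventionally use 1 / 5.
#'
#' @param path TSV with columns `sequence` (or `peptide`), `allele`, `rank`.
#' @param strong_cutoff,weak_cutoff Percentile-rank cutoffs.
#' @return Tibble `sequence`, `allele`, `call` (one row per pair).
#' @export
read_binder_annotations <- function(path, strong_cutoff = 0.5, weak_cutoff = 2.0) {
  raw <- readr::read_tsv(path, col_types = readr::cols())
  names(raw) <- tolower(names(raw))
  if ("peptide" %in% names(raw) && !"sequence" %in% names(raw)) {
    raw <- rename(raw, sequence = "peptide")
  }
  need <- c("sequence", "allele", "rank")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("binder table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  raw %>%
    mutate(call = dplyr::case_when(
      .data$rank <= strong_cutoff ~ "strong",
      .data$rank <= weak_cutoff ~ "weak",
      TRUE ~ "none"
    )) %>%
    select("sequence", "allele", "call")
}

#' Confusion counts and precision against external binder calls
#'
#' Scores a retained/rejected split of sequences against binder annotations:
#' a sequence is a binder when at least one queried allele calls it `strong`
#' or `weak`. Retained binders are true positives, retained non-binders false
#' positives, rejected binders false negatives, rejected non-binders true
#' negatives; precision (positive predictive value) is `TP / (TP + FP)`.
#'
#' @param retained,rejected Disjoint character vectors of sequences.
#' @param annotations Tibble `sequence`, `allele`, `call` (e.g. from
#'   [read_binder_annotations()]); every sequence must be annotated against
#'   every queried allele.
#' @param queried_alleles Alleles to consider (default: all in
#'   `annotations`).
#' @return One-row tibble `tp`, `fp`, `fn`, `tn`, `precision`. Precision is
#'   `NA` with a warning when nothing was retained.
#' @export
#' @examples
#' ann <- tibble::tibble(
#'   sequence = c("AAAAAAAAA", "CCCCCCCCC"), allele = "A*02:01",
#'   call = c("strong", "none")
#' )
#' confusion_and_precision("AAAAAAAAA", "CCCCCCCCC", ann)
confusion_and_precision <- function(retained, rejected, annotations,
                                    queried_alleles = NULL) {
  if (length(intersect(retained, rejected)) > 0) {
    abort("retained and rejected sets overlap")
  }
  if (is.null(queried_alleles)) queried_alleles <- unique(annotations$allele)
  ann <- filter(annotations, .data$allele %in% queried_alleles)
  all_seq <- c(retained, rejected)
  n_ann <- ann %>%
    filter(.data$sequence %in% all_seq) %>%
    count(.data$sequence)
  unannotated <- setdiff(all_seq, n_ann$sequence[n_ann$n >= length(queried_alleles)])
  if (length(unannotated) > 0) {
    abort(sprintf(
      "sequence %s is not annotated against every queried allele", unannotated[1]
    ))
  }
  binders <- ann %>%
    filter(.data$call %in% c("strong", "weak")) %>%
    pull(.data$sequence) %>%
    unique()
  tp <- sum(retained %in% binders)
  fp <- length(retained) - tp
  fn <- sum(rejected %in% binders)
  tn <- length(rejected) - fn
  precision <- if (tp + fp == 0) {
    warn("no retained sequences: precision undefined")
    NA_real_
  } else {
    tp / (tp + fp)
  }
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision)
}

#' Random negative-control peptides
#'
#' Generates sequences with residues drawn uniformly from the 20 standard
#' amino acids and lengths uniform over `length_range`, reproducibly under
#' `seed`. Used as soluble-peptide negative controls when probing the
#' false-binder rate of prediction tools.
#'
#' @param n Number of peptides.
#' @param length_range Inclusive `c(lo, hi)` length bounds.
#' @param seed RNG seed.
#' @return Character vector of `n` sequences.
#' @export
#' @examples
#' random_peptides(3, c(9, 11), seed = 7)
random_peptides <- function(n, length_range = c(9L, 11L), seed = 1L) {
  if (n < 1) abort("n must be >= 1")
  lo <- length_range[1]
  hi <- length_range[2]
  if (lo < 1 || lo > hi) abort("invalid length_range")
  with_local_seed(seed, {
    lens <- sample(seq(lo, hi), n, replace = TRUE)
    map_chr(lens, function(L) paste(sample(AA20, L, replace = TRUE), collapse = ""))
  })
}
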