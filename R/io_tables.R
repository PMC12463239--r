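#' Column dialects for peptide identification tables
#'
#' Search engines export peptide tables under different column headers. A
#' dialect maps the logical fields the pipeline needs onto the column names of
#' a particular export. Built-in dialects cover a plain `standard` layout and
#' typical MaxQuant / FragPipe flavours; any field can be overridden by passing
#' a named list to [read_peptide_table()].
#'
#' Logical fields: `sequence`, `cell_line`, `replicate`, `spectral_count`
#' (required) and `protein_id`, `start`, `end`, `intensity` (optional; `NA`
#' drops the field).
#'
#' @param name Dialect name: `"standard"`, `"maxquant"` or `"fragpipe"`, or a
#'   named list/character vector of field -> column-name mappings (unnamed
#'   fields fall back to the `standard` dialect).
#' @return Named character vector mapping logical fields to column names.
#' @export
#' @examples
#' peptide_dialect("maxquant")[["sequence"]]
peptide_dialect <- function(name = "standard") {
  dialects <- list(
    standard = c(
      sequence = "sequence", protein_id = "protein_id", start = "start",
      end = "end", cell_line = "cell_line", replicate = "replicate",
      spectral_count = "spectral_count", intensity = "intensity"
    ),
    maxquant = c(
      sequence = "Sequence", protein_id = "Leading razor protein",
      start = "Start position", end = "End position",
      cell_line = "Experiment", replicate = "Replicate",
      spectral_count = "MS/MS count", intensity = "Intensity"
    ),
    fragpipe = c(
      sequence = "Peptide Sequence", protein_id = "Protein ID",
      start = "Start", end = "End", cell_line = "Experiment",
      replicate = "Replicate", spectral_count = "Spectral Count",
      intensity = "Intensity"
    )
  )
  if (is.character(name) && length(name) == 1 && is.null(names(name))) {
    if (!name %in% names(dialects)) {
      abort(sprintf(
        "unknown dialect '%s'; available: %s",
        name, paste(names(dialects), collapse = ", ")
      ))
    }
    return(dialects[[name]])
  }
  custom <- unlist(name)
  base <- dialects$standard
  unknown <- setdiff(names(custom), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("unknown dialect field(s): %s", paste(unknown, collapse = ", ")))
  }
  base[names(custom)] <- custom
  base[!is.na(base)]
}

#' Read a peptide identification table
#'
#' Reads a TSV of per-peptide observations (one row per peptide per cell line
#' per replicate) as exported by a search engine, mapping columns through a
#' [peptide_dialect()]. Sequences are validated against the 20-letter amino
#' acid alphabet; ambiguity codes (B, J, O, U, X, Z) are rejected.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Dialect name or named mapping, see [peptide_dialect()].
#' @return A tibble with columns `sequence`, `protein_id`, `start`, `end`,
#'   `cell_line`, `replicate`, `spectral_count`, `intensity`. Optional columns
#'   absent from the file are `NA`. Row order of the file is preserved.
#' @export
read_peptide_table <- function(path, dialect = "standard") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  map <- peptide_dialect(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("sequence", "cell_line", "replicate", "spectral_count")
  missing_req <- required[!map[required] %in% names(raw)]
  if (length(missing_req) > 0) {
    abort(sprintf(
      "peptide table %s lacks required column(s): %s",
      path, paste(map[missing_req], collapse = ", ")
    ))
  }
  get_col <- function(field) {
    col <- map[[field]]
    if (is.null(col) || is.na(col) || !col %in% names(raw)) rep(NA_character_, nrow(raw)) else raw[[col]]
  }
  out <- tibble(
    sequence = toupper(get_col("sequence")),
    protein_id = get_col("protein_id"),
    start = suppressWarnings(as.integer(get_col("start"))),
    end = suppressWarnings(as.integer(get_col("end"))),
    cell_line = get_col("cell_line"),
    replicate = get_col("replicate"),
    spectral_count = suppressWarnings(as.integer(get_col("spectral_count"))),
    intensity = suppressWarnings(as.numeric(get_col("intensity")))
  )
  bad_row <- which(is.na(out$sequence) | out$sequence == "" |
    is.na(out$cell_line) | is.na(out$replicate) | is.na(out$spectral_count) |
    out$spectral_count < 0)
  if (length(bad_row) > 0) {
    abort(sprintf("malformed peptide table row %d in %s", bad_row[1], path))
  }
  check_sequences(out$sequence, context = "peptide sequence")
  coord_bad <- which(!is.na(out$start) & !is.na(out$end) &
    (out$end - out$start + 1L) != nchar(out$sequence))
  if (length(coord_bad) > 0) {
    abort(sprintf(
      "row %d: coordinates %d-%d inconsistent with sequence length %d",
      coord_bad[1], out$start[coord_bad[1]], out$end[coord_bad[1]],
      nchar(out$sequence[coord_bad[1]])
    ))
  }
  out
}

#' Write a peptide table
#'
#' Writes peptide records in the `standard` dialect so that
#' [read_peptide_table()] round-trips all fields.
#'
#' @param peptides Tibble of peptide records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  readr::write_tsv(peptides, path)
  invisible(path)
}

#' Keep peptides observed in enough replicates
#'
#' A peptide is considered identified in a cell line only when it was observed
#' (spectral count > 0) in at least `min_reps` distinct biological replicates
#' of that cell line; retention is decided per cell line independently, so a
#' peptide may survive in one line and be dropped from another. The default
#' 2-of-3 rule produces a confident, reproducible peptide set.
#'
#' @param peptides Tibble of peptide records (see [read_peptide_table()]).
#' @param min_reps Minimum number of distinct replicates with a positive
#'   spectral count (default 2).
#' @param total_reps Total replicates per cell line (default 3); only used to
#'   validate `min_reps`.
#' @return The subset of `peptides` passing the filter, records unmodified.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   sequence = "KLVANNTRL", protein_id = NA, start = NA, end = NA,
#'   cell_line = "L1", replicate = c("r1", "r2"), spectral_count = c(3L, 1L),
#'   intensity = NA
#' )
#' replicate_consistency_filter(tbl, min_reps = 2, total_reps = 3)
replicate_consistency_filter <- function(peptides, min_reps = 2L, total_reps = 3L) {
  if (min_reps < 1) abort("min_reps must be >= 1")
  if (min_reps > total_reps) {
    abort(sprintf("min_reps (%d) exceeds total_reps (%d)", min_reps, total_reps))
  }
  keep <- peptides %>%
    filter(.data$spectral_count > 0) %>%
    distinct(.data$sequence, .data$cell_line, .data$replicate) %>%
    count(.data$sequence, .data$cell_line, name = "n_reps") %>%
    filter(.data$n_reps >= min_reps) %>%
    select("sequence", "cell_line")
  semi_join(peptides, keep, by = c("sequence", "cell_line"))
}

#' Drop peptides too short to occupy an MHC groove
#'
#' The MHC binding groove prefers 9-mers and longer; peptides of 8 or fewer
#' residues are rejected before condensation.
#'
#' @param peptides Tibble of peptide records.
#' @param min_length Minimum retained length (default 9).
#' @return Filtered tibble.
#' @export
drop_short_peptides <- function(peptides, min_length = 9L) {
  filter(peptides, nchar(.data$sequence) >= min_length)
}

#' Read an HLA genotype table
#'
#' Expects a TSV with columns `cell_line`, `locus`, `allele1`, `allele2` (one
#' row per cell line per locus; the two allele names may be identical for a
#' homozygous locus).
#'
#' @param path Path to the genotype TSV.
#' @return Tibble with those four columns.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  g <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("cell_line", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0) {
    abort(sprintf("genotype table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  g[need]
}

#' Write a genotype table
#' @param genotypes Tibble with `cell_line`, `locus`, `allele1`, `allele2`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  readr::write_tsv(genotypes, path)
  invisible(path)
}

#' Write epitope sequences as FASTA
#'
#' The record identifier is the epitope id; the description carries the MHC
#' class and, when an Epitope Index matrix is supplied, a per-line E_i summary.
#'
#' @param epitopes Epitope tibble from [classify_epitopes()].
#' @param path Output FASTA path.
#' @param ei Optional [epitope_index()] matrix used for the description line.
#' @return `path`, invisibly.
#' @export
write_epitope_fasta <- function(epitopes, path, ei = NULL) {
  desc <- paste0("class=", epitopes$mhc_class)
  if (!is.null(ei)) {
    m <- unclass(ei)
    idx <- match(epitopes$epitope_id, rownames(m))
    eisum <- ifelse(is.na(idx), "", paste0(
      " Ei=", map_chr(idx, function(i) {
        if (is.na(i)) "" else paste(sprintf("%s:%.3g", colnames(m), m[i, ]), collapse = ",")
      })
    ))
    desc <- paste0(desc, eisum)
  }
  lines <- as.vector(rbind(
    paste0(">", epitopes$epitope_id, " ", desc),
    epitopes$sequence
  ))
  writeLines(lines, path)
  invisible(path)
}
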