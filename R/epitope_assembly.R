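# longest suffix(u)==prefix(v) overlap; returns 0 if none >= min_overlap.
# containment is handled separately by callers.
suffix_prefix_overlap <- function(u, v, min_overlap) {
  kmax <- min(nchar(u), nchar(v))
  if (kmax < min_overlap) return(0L)
  for (k in seq(kmax, min_overlap)) {
    if (substr(u, nchar(u) - k + 1L, nchar(u)) == substr(v, 1L, k)) return(k)
  }
  0L
}

# best merge of two strings: containment wins, else longest end overlap in
# either direction. Returns NULL when no merge >= min_overlap exists.
best_pair_merge <- function(u, v, min_overlap) {
  if (grepl(v, u, fixed = TRUE)) return(list(merged = u, overlap = nchar(v)))
  if (grepl(u, v, fixed = TRUE)) return(list(merged = v, overlap = nchar(u)))
  kuv <- suffix_prefix_overlap(u, v, min_overlap)
  kvu <- suffix_prefix_overlap(v, u, min_overlap)
  if (kuv == 0L && kvu == 0L) return(NULL)
  if (kuv >= kvu) {
    list(merged = paste0(u, substr(v, kuv + 1L, nchar(v))), overlap = kuv)
  } else {
    list(merged = paste0(v, substr(u, kvu + 1L, nchar(u))), overlap = kvu)
  }
}

# merge one component of overlapping sequences into its maximal superstring.
# Greedy: repeatedly merge the pair with the longest overlap; deterministic
# tie-break on the lexicographic pair. Errors when members end up inconsistent.
merge_component <- function(seqs, min_overlap) {
  members <- sort(unique(seqs))
  pool <- members
  while (length(pool) > 1L) {
    best <- NULL
    for (i in seq_along(pool)) {
      for (j in seq_along(pool)) {
        if (i >= j) next
        m <- best_pair_merge(pool[i], pool[j], min_overlap)
        if (is.null(m)) next
        key <- list(overlap = m$overlap, a = min(pool[i], pool[j]), b = max(pool[i], pool[j]))
        if (is.null(best) || m$overlap > best$key$overlap ||
          (m$overlap == best$key$overlap &&
            (key$a < best$key$a || (key$a == best$key$a && key$b < best$key$b)))) {
          best <- list(i = i, j = j, merged = m$merged, key = key)
        }
      }
    }
    if (is.null(best)) {
      abort(sprintf(
        "component {%s} cannot be merged into a single sequence (overlaps conflict)",
        paste(members, collapse = ", ")
      ))
    }
    pool <- c(pool[-c(best$i, best$j)], best$merged)
  }
  final <- pool[[1]]
  not_in <- members[!map_lgl(members, ~ grepl(.x, final, fixed = TRUE))]
  if (length(not_in) > 0) {
    abort(sprintf(
      "component {%s} implies conflicting letters at shared positions (member %s not contained in merge %s)",
      paste(members, collapse = ", "), not_in[1], final
    ))
  }
  final
}

# connected components under the string-overlap relation
string_components <- function(seqs, min_overlap) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (!is.null(best_pair_merge(seqs[i], seqs[j], min_overlap))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  map_int(seq_len(n), find)
}

#' Condense overlapping peptides into maximal epitopes
#'
#' Peptides whose sequences overlap are condensed into the longest possible
#' outcome, the epitope; peptides overlapping nothing become single-peptide
#' epitopes. Two modes are supported. In `coordinates` mode peptides sharing a
#' source protein are merged whenever their protein intervals overlap by at
#' least one residue; each maximal connected component becomes one epitope
#' spanning the union interval. In `string` mode (for tables without protein
#' coordinates) two peptides overlap when one contains the other or a suffix
#' of one equals a prefix of the other over at least `min_overlap` residues,
#' and each component is merged into its maximal superstring. The result does
#' not depend on the input row order.
#'
#' Peptide sequences mapping to several proteins are assigned to the
#' lexicographically smallest accession so that every peptide belongs to
#' exactly one epitope.
#'
#' @param peptides Tibble of peptide observations (see [read_peptide_table()]).
#' @param mode `"coordinates"` or `"string"`.
#' @param min_overlap Minimum end-overlap length for string mode (default 5;
#'   short accidental 1-2 residue overlaps would glue unrelated peptides).
#' @return A tibble with one row per epitope: `epitope_id`, `sequence`,
#'   `length`, `protein_id`, `start`, `end`, `n_constituents` (distinct
#'   constituent peptide sequences), `constituents` (list column of those
#'   sequences), `total_spectral_count` (summed over all observations of the
#'   constituents, every cell line and replicate).
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   sequence = c("KLVANNTRL", "VANNTRLEF"), protein_id = NA, start = NA,
#'   end = NA, cell_line = "L1", replicate = "r1", spectral_count = 2L,
#'   intensity = NA
#' )
#' condense_peptides(tbl, mode = "string")$sequence
condense_peptides <- function(peptides, mode = c("coordinates", "string"),
                              min_overlap = 5L) {
  mode <- arg_match(mode)
  if (nrow(peptides) == 0) abort("no peptides to condense: input table is empty")

  if (mode == "coordinates") {
    ent <- distinct(peptides, .data$sequence, .data$protein_id, .data$start, .data$end)
    if (any(is.na(ent$protein_id) | is.na(ent$start) | is.na(ent$end))) {
      abort("coordinates mode requires protein_id/start/end on every peptide")
    }
    multi <- ent %>%
      group_by(.data$sequence) %>%
      filter(n_distinct(.data$protein_id) > 1) %>%
      ungroup()
    if (nrow(multi) > 0) {
      inform(sprintf(
        "%d peptide sequence(s) map to multiple proteins; assigned to the smallest accession",
        n_distinct(multi$sequence)
      ))
    }
    ent <- ent %>%
      group_by(.data$sequence) %>%
      arrange(.data$protein_id, .data$start, .by_group = TRUE) %>%
      slice(1) %>%
      ungroup()
    ent <- ent %>%
      arrange(.data$protein_id, .data$start, .data$end, .data$sequence) %>%
      group_by(.data$protein_id) %>%
      mutate(
        new_comp = .data$start > dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf),
        comp = cumsum(.data$new_comp)
      ) %>%
      ungroup()
    groups <- ent %>%
      group_by(.data$protein_id, .data$comp) %>%
      summarise(
        seqs = list(tibble(sequence = sequence, start = start)),
        constituents = list(sort(unique(.data$sequence))),
        start = min(.data$start), end = max(.data$end),
        .groups = "drop"
      ) %>%
      arrange(.data$protein_id, .data$start)
    seqs <- pmap(
      list(groups$seqs, groups$start, groups$end),
      function(members, span_start, span_end) {
        span <- rep(NA_character_, span_end - span_start + 1L)
        for (k in seq_len(nrow(members))) {
          letters_k <- strsplit(members$sequence[k], "")[[1]]
          pos <- members$start[k] - span_start + seq_along(letters_k)
          clash <- !is.na(span[pos]) & span[pos] != letters_k
          if (any(clash)) {
            abort(sprintf(
              "peptides {%s} imply conflicting letters at shared protein positions",
              paste(members$sequence, collapse = ", ")
            ))
          }
          span[pos] <- letters_k
        }
        paste(span, collapse = "")
      }
    )
    out <- tibble(
      sequence = unlist(seqs),
      protein_id = groups$protein_id,
      start = groups$start,
      end = groups$end,
      constituents = groups$constituents
    )
  } else {
    seqs <- sort(unique(peptides$sequence))
    comp <- string_components(seqs, min_overlap)
    comp_list <- split(seqs, comp)
    merged <- map_chr(comp_list, merge_component, min_overlap = min_overlap)
    out <- tibble(
      sequence = unname(merged),
      protein_id = NA_character_,
      start = NA_integer_,
      end = NA_integer_,
      constituents = map(comp_list, ~ sort(unname(.x)))
    ) %>%
      arrange(.data$sequence)
  }

  counts <- peptides %>%
    group_by(.data$sequence) %>%
    summarise(total = sum(.data$spectral_count), .groups = "drop")
  out %>%
    mutate(
      epitope_id = sprintf("E%04d", row_number()),
      length = nchar(.data$sequence),
      n_constituents = lengths(.data$constituents),
      total_spectral_count = map_int(.data$constituents, function(cs) {
        as.integer(sum(counts$total[match(cs, counts$sequence)]))
      })
    ) %>%
    select(
      "epitope_id", "sequence", "length", "protein_id", "start", "end",
      "n_constituents", "constituents", "total_spectral_count"
    )
}

#' Sort condensed epitopes into MHC class I and II groups
#'
#' Applies the quality and length filters that define the epitope classes:
#' epitopes with a total spectral count of `min_total_count - 1` or fewer are
#' removed (low technical confidence), epitopes of 8 or fewer residues are
#' rejected, 9-11-mers form the MHC I group, and 12-20-mers form the MHC II
#' group provided they are composed of at least `mhc2_min_constituents`
#' distinct overlapping peptides (nested, ragged ends being the hallmark of
#' MHC II presentation). Condensed spans longer than the class II upper bound
#' are rejected with a warning unless `retain_long = TRUE`, in which case they
#' are kept with class `"unclassified"`.
#'
#' @param epitopes Tibble from [condense_peptides()].
#' @param min_total_count Minimum total spectral count to retain (default 3,
#'   i.e. epitopes with a total of 2 or fewer spectra are removed).
#' @param mhc1_range,mhc2_range Length ranges (inclusive) for the two classes.
#' @param mhc2_min_constituents Minimum distinct constituent peptides for a
#'   class II call (default 3).
#' @param retain_long Keep over-length condensed spans as `"unclassified"`.
#' @return The input tibble with `mhc_class` (`"I"`, `"II"`, `"rejected"`, or
#'   `"unclassified"`) and `reject_reason` columns added.
#' @export
classify_epitopes <- function(epitopes, min_total_count = 3L,
                              mhc1_range = c(9L, 11L), mhc2_range = c(12L, 20L),
                              mhc2_min_constituents = 3L, retain_long = FALSE) {
  if (mhc1_range[2] >= mhc2_range[1]) {
    abort("mhc1_range and mhc2_range overlap; class ranges must be disjoint")
  }
  n_long <- sum(epitopes$length > mhc2_range[2])
  if (n_long > 0 && !retain_long) {
    warn(sprintf(
      "%d condensed span(s) longer than %d residues rejected", n_long, mhc2_range[2]
    ))
  }
  epitopes %>%
    mutate(
      reject_reason = dplyr::case_when(
        .data$total_spectral_count < min_total_count ~ "low_spectral_count",
        .data$length <= 8L ~ "too_short",
        .data$length > mhc2_range[2] & retain_long ~ "",
        .data$length > mhc2_range[2] ~ "too_long",
        .data$length >= mhc2_range[1] &
          .data$n_constituents < mhc2_min_constituents ~ "too_few_nested_peptides",
        .data$length > mhc1_range[2] & .data$length < mhc2_range[1] ~ "between_classes",
        TRUE ~ ""
      ),
      mhc_class = dplyr::case_when(
        .data$reject_reason != "" ~ "rejected",
        .data$length > mhc2_range[2] ~ "unclassified",
        .data$length >= mhc1_range[1] & .data$length <= mhc1_range[2] ~ "I",
        TRUE ~ "II"
      )
    )
}

#' Write an epitope table
#'
#' Flattens the constituents list column into a comma-separated field so the
#' table serializes to plain TSV.
#'
#' @param epitopes Epitope tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_epitope_table <- function(epitopes, path) {
  flat <- mutate(epitopes,
    constituents = map_chr(.data$constituents, paste, collapse = ",")
  )
  readr::write_tsv(flat, path)
  invisible(path)
}
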