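#' Theoretical allele presence profiles from HLA genotypes
#'
#' For each distinct allele across the panel, builds the binary vector of the
#' cell lines whose genotype carries it. Because epitopes presented by an
#' allele can only appear in cell lines carrying that allele, these profiles
#' are the theoretical counterparts of binarized E_i profiles and the key to
#' tracing epitopes back to their presenting allele.
#'
#' @param genotypes Tibble `cell_line`, `locus`, `allele1`, `allele2` (see
#'   [read_genotype_table()]).
#' @param loci Optional subset of loci to use (default: all present).
#' @param cell_lines Optional panel ordering (default: order of first
#'   appearance in `genotypes`).
#' @return Tibble `allele`, `locus`, `profile` (list of named 0/1 integer
#'   vectors over the panel), ordered by locus then allele name.
#' @export
theoretical_profiles <- function(genotypes, loci = NULL, cell_lines = NULL) {
  if (is.null(cell_lines)) cell_lines <- unique(genotypes$cell_line)
  if (is.null(loci)) loci <- sort(unique(genotypes$locus))
  g <- filter(genotypes, .data$locus %in% loci)
  missing <- tidyr::expand_grid(cell_line = cell_lines, locus = loci) %>%
    dplyr::anti_join(g, by = c("cell_line", "locus"))
  if (nrow(missing) > 0) {
    abort(sprintf(
      "cell line %s is not genotyped at locus %s",
      missing$cell_line[1], missing$locus[1]
    ))
  }
  long <- bind_rows(
    select(g, "cell_line", "locus", allele = "allele1"),
    select(g, "cell_line", "locus", allele = "allele2")
  ) %>% distinct()
  long %>%
    group_by(.data$locus, .data$allele) %>%
    summarise(carriers = list(unique(.data$cell_line)), .groups = "drop") %>%
    arrange(.data$locus, .data$allele) %>%
    mutate(profile = map(.data$carriers, function(cc) {
      setNames(as.integer(cell_lines %in% cc), cell_lines)
    })) %>%
    select("allele", "locus", "profile")
}

#' Assign epitopes to candidate HLA alleles by profile matching
#'
#' Binarizes each epitope's observed E_i vector as presence (`E_i > floor`)
#' and returns every allele whose theoretical profile lies within Hamming
#' distance `max_mismatch` of it. Co-segregating alleles (identical profiles
#' in the panel) are all returned, preserving the ambiguity; an epitope
#' matching no allele is flagged as a putative contaminant.
#'
#' @param ei An [epitope_index()] matrix, or a tibble `epitope_id`,
#'   `cell_line`, `e_i` in long form.
#' @param profiles Tibble from [theoretical_profiles()].
#' @param max_mismatch Maximum Hamming distance for a candidate (default 0).
#' @param floor Presence threshold on E_i (default 0, i.e. any signal; a small
#'   positive floor can absorb noise).
#' @return Long tibble `epitope_id`, `allele`, `locus`, `hamming`; epitopes
#'   with no candidate appear once with `allele = NA` and `contaminant =
#'   TRUE`.
#' @export
assign_alleles <- function(ei, profiles, max_mismatch = 0L, floor = 0) {
  if (inherits(ei, "ei_matrix") || is.matrix(ei)) {
    long <- tidy(structure(unclass(ei), class = c("ei_matrix", "matrix")))
  } else {
    long <- ei
  }
  panel <- names(profiles$profile[[1]])
  wide <- tidyr::pivot_wider(long, names_from = "cell_line", values_from = "e_i")
  if (!setequal(setdiff(names(wide), "epitope_id"), panel)) {
    abort("E_i cell lines do not match the profile panel")
  }
  obs <- as.matrix(wide[, panel, drop = FALSE]) > floor
  pm <- do.call(rbind, profiles$profile)
  out <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    hd <- rowSums(sweep(pm, 2, as.integer(obs[i, ]), `!=`))
    hit <- which(hd <= max_mismatch)
    if (length(hit) == 0) {
      out[[i]] <- tibble(
        epitope_id = wide$epitope_id[i], allele = NA_character_,
        locus = NA_character_, hamming = NA_integer_, contaminant = TRUE
      )
    } else {
      out[[i]] <- tibble(
        epitope_id = wide$epitope_id[i], allele = profiles$allele[hit],
        locus = profiles$locus[hit], hamming = as.integer(hd[hit]),
        contaminant = FALSE
      )
    }
  }
  bind_rows(out)
}

#' Assign dendrogram nodes to candidate alleles
#'
#' Node-level variant of [assign_alleles()]: each node's mean E_i profile is
#' binarized and matched against the theoretical allele profiles.
#'
#' @param nodes Tibble from [extract_nodes()] with `mean_profile` attached.
#' @param profiles Tibble from [theoretical_profiles()].
#' @param max_mismatch,floor As in [assign_alleles()].
#' @return Long tibble `node_id`, `allele`, `locus`, `hamming`, `contaminant`.
#' @export
assign_node_alleles <- function(nodes, profiles, max_mismatch = 0L, floor = 0) {
  if (!"mean_profile" %in% names(nodes)) {
    abort("nodes need a mean_profile column (pass ei to extract_nodes)")
  }
  long <- nodes %>%
    select("node_id", "mean_profile") %>%
    mutate(prof = map(.data$mean_profile, ~ tibble(
      cell_line = names(.x), e_i = unname(.x)
    ))) %>%
    select("node_id", "prof") %>%
    tidyr::unnest("prof") %>%
    rename(epitope_id = "node_id")
  assign_alleles(long, profiles, max_mismatch = max_mismatch, floor = floor) %>%
    rename(node_id = "epitope_id")
}

#' Count alleles uniquely traceable in a cell-line panel
#'
#' An allele is uniquely traceable when no other allele in the panel shares
#' its presence profile: an epitope matching that profile can then be
#' attributed unambiguously. Adding cell lines (extending every profile)
#' never decreases this count.
#'
#' @param profiles Tibble from [theoretical_profiles()].
#' @param per_locus Restrict the uniqueness comparison to alleles of the same
#'   locus (default `FALSE`: uniqueness across all loci, the stricter
#'   criterion).
#' @return Integer count, with the uniquely traceable allele names attached
#'   as attribute `"alleles"`.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   cell_line = rep(c("f", "m"), each = 2), locus = "A",
#'   allele1 = c("A*01", "A*01", "A*02", "A*02"),
#'   allele2 = c("A*03", "A*03", "A*24", "A*24")
#' )
#' traceable_allele_count(theoretical_profiles(g))
traceable_allele_count <- function(profiles, per_locus = FALSE) {
  if (nrow(profiles) == 0) abort("no profiles supplied")
  key <- map_chr(profiles$profile, paste, collapse = "")
  if (per_locus) key <- paste(profiles$locus, key, sep = "|")
  dup <- key %in% key[duplicated(key)]
  structure(sum(!dup), alleles = profiles$allele[!dup])
}

#' Allele traceability as a panel grows
#'
#' Recomputes [traceable_allele_count()] over nested panels obtained by
#' adding cell lines one at a time in the order given, quantifying how much
#' each added line improves the ability to trace a ligand back to its
#' presenting allele.
#'
#' @param genotypes Genotype tibble covering all panel lines.
#' @param order Cell-line ordering (default: order of appearance).
#' @param loci Optional locus subset.
#' @param per_locus See [traceable_allele_count()].
#' @return Tibble `n_lines`, `cell_line` (the line added), `n_alleles`
#'   (distinct alleles in the panel so far), `n_traceable`.
#' @export
trace_panel <- function(genotypes, order = NULL, loci = NULL, per_locus = FALSE) {
  if (is.null(order)) order <- unique(genotypes$cell_line)
  rows <- map(seq_along(order), function(k) {
    sub <- filter(genotypes, .data$cell_line %in% order[seq_len(k)])
    prof <- theoretical_profiles(sub, loci = loci, cell_lines = order[seq_len(k)])
    tibble(
      n_lines = k, cell_line = order[k], n_alleles = nrow(prof),
      n_traceable = as.integer(traceable_allele_count(prof, per_locus = per_locus))
    )
  })
  bind_rows(rows)
}

#' Plot allele traceability against panel size
#' @param panel Tibble from [trace_panel()].
#' @return A ggplot object.
#' @export
plot_traceability <- function(panel) {
  ggplot(panel, aes(x = .data$n_lines, y = .data$n_traceable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = panel$n_lines) +
    ggplot2::labs(
      x = "cell lines in panel",
      y = "uniquely traceable alleles"
    ) +
    ggplot2::theme_minimal()
}
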