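#' Pipeline configuration
#'
#' Collects every stage parameter of the analysis workflow with its default.
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param ... Overrides for any of: `min_reps`, `total_reps`,
#'   `apply_replicate_filter`, `min_peptide_length`, `condense_mode`,
#'   `min_overlap`, `min_total_count`, `mhc1_range`, `mhc2_range`,
#'   `mhc2_min_constituents`, `metric`, `node_min_size`, `node_max_size`,
#'   `max_len_mhc1`, `max_len_mhc2`, `substitution_matrix`,
#'   `bootstrap_reps`, `logo_seed`, `max_mismatch`, `ei_floor`.
#' @return A named list of resolved parameters (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_reps = 2L, total_reps = 3L, apply_replicate_filter = TRUE,
    min_peptide_length = 9L, condense_mode = "coordinates", min_overlap = 5L,
    min_total_count = 3L, mhc1_range = c(9L, 11L), mhc2_range = c(12L, 20L),
    mhc2_min_constituents = 3L, metric = "correlation",
    node_min_size = 9L, node_max_size = 100L,
    max_len_mhc1 = 12L, max_len_mhc2 = 30L,
    substitution_matrix = "BLOSUM62", bootstrap_reps = 200L, logo_seed = 1L,
    max_mismatch = 0L, ei_floor = 0
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown pipeline option(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "pipeline_config")
}

#' Run the full MAE epitope analysis workflow
#'
#' Wires the stages end to end: replicate-consistency filter, short-peptide
#' rejection, condensation into epitopes, class assignment, Peptide/Epitope
#' Index computation, centroid-linkage clustering of each class's E_i matrix
#' in both dimensions, node extraction, offset alignment, logo and consensus
#' computation, and allele deconvolution against the panel genotypes. Every
#' stage result is returned; when `out_dir` is given every intermediate
#' artifact is also written there as plain text.
#'
#' @param peptides Peptide observation tibble (see [read_peptide_table()]).
#' @param genotypes Genotype tibble (see [read_genotype_table()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory for all stage outputs.
#' @return An `mae_run` list: `peptides_filtered`, `epitopes`, `pi`,
#'   `ei` (per class), `line_dendrograms`, `epitope_dendrograms`, `nodes`,
#'   `alignments`, `logos`, `consensus`, `profiles`, `epitope_assignments`,
#'   `node_assignments`, `summary`, `config`.
#' @export
run_pipeline <- function(peptides, genotypes, config = pipeline_config(),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  filtered <- stage("filter", {
    out <- if (config$apply_replicate_filter) {
      replicate_consistency_filter(peptides, config$min_reps, config$total_reps)
    } else {
      peptides
    }
    drop_short_peptides(out, config$min_peptide_length)
  })
  epitopes <- stage("condense", {
    condense_peptides(filtered, mode = config$condense_mode, min_overlap = config$min_overlap)
  })
  epitopes <- stage("classify", {
    classify_epitopes(
      epitopes,
      min_total_count = config$min_total_count,
      mhc1_range = config$mhc1_range, mhc2_range = config$mhc2_range,
      mhc2_min_constituents = config$mhc2_min_constituents
    )
  })
  cell_lines <- sort(unique(peptides$cell_line))
  pi_tbl <- stage("index", {
    peptide_index(filtered, total_reps = config$total_reps, cell_lines = cell_lines)
  })
  classes <- intersect(c("I", "II"), unique(epitopes$mhc_class))
  ei <- stage("index", {
    setNames(
      map(classes, ~ epitope_index(filter(epitopes, .data$mhc_class == .x), pi_tbl)),
      classes
    )
  })

  line_dend <- list()
  epi_dend <- list()
  nodes <- list()
  alignments <- list()
  logos <- list()
  consensus <- list()
  for (cl in classes) {
    m <- ei[[cl]]
    if (nrow(m) >= 2) {
      epi_dend[[cl]] <- stage("cluster", cluster_ei(m, "epitopes", config$metric))
      line_dend[[cl]] <- stage("cluster", cluster_ei(m, "cell_lines", config$metric))
      nodes[[cl]] <- stage("nodes", {
        extract_nodes(epi_dend[[cl]], config$node_min_size, config$node_max_size, ei = m)
      })
      max_len <- if (cl == "I") config$max_len_mhc1 else config$max_len_mhc2
      epi_seq <- setNames(epitopes$sequence, epitopes$epitope_id)
      aln_cl <- list()
      logo_cl <- list()
      cons_cl <- list()
      for (ni in seq_len(nrow(nodes[[cl]]))) {
        nid <- nodes[[cl]]$node_id[ni]
        ids <- nodes[[cl]]$members[[ni]]
        seqs <- unname(epi_seq[ids])
        keep <- nchar(seqs) <= max_len
        if (sum(keep) < 2) next
        if (any(!keep)) {
          warn(sprintf(
            "node %s: dropped %d sequence(s) longer than max_len %d",
            nid, sum(!keep), max_len
          ))
        }
        wts <- rowSums(unclass(m)[ids[keep], , drop = FALSE])
        aln <- stage("align", {
          align_node(seqs[keep],
            max_len = max_len, matrix = config$substitution_matrix,
            weights = wts, ids = ids[keep]
          )
        })
        lg <- stage("logo", {
          logo_columns(aln,
            bootstrap_reps = config$bootstrap_reps,
            seed = config$logo_seed
          )
        })
        aln_cl[[nid]] <- aln
        logo_cl[[nid]] <- lg
        cons_cl[[nid]] <- render_consensus(lg, "full")$text
      }
      alignments[[cl]] <- aln_cl
      logos[[cl]] <- logo_cl
      consensus[[cl]] <- cons_cl
    }
  }

  profiles <- stage("deconvolute", theoretical_profiles(genotypes, cell_lines = cell_lines))
  epi_assign <- stage("deconvolute", {
    setNames(
      map(classes, ~ assign_alleles(ei[[.x]], profiles,
        max_mismatch = config$max_mismatch, floor = config$ei_floor
      )),
      classes
    )
  })
  node_assign <- stage("deconvolute", {
    out <- list()
    for (cl in classes) {
      if (!is.null(nodes[[cl]]) && nrow(nodes[[cl]]) > 0) {
        out[[cl]] <- assign_node_alleles(nodes[[cl]], profiles,
          max_mismatch = config$max_mismatch, floor = config$ei_floor
        )
      }
    }
    out
  })

  summary <- tibble(
    n_peptide_observations = nrow(peptides),
    n_peptides_filtered = dplyr::n_distinct(filtered$sequence),
    n_epitopes = nrow(epitopes),
    n_mhc1 = sum(epitopes$mhc_class == "I"),
    n_mhc2 = sum(epitopes$mhc_class == "II"),
    n_rejected = sum(epitopes$mhc_class == "rejected"),
    n_nodes_mhc1 = if (is.null(nodes[["I"]])) 0L else nrow(nodes[["I"]]),
    n_nodes_mhc2 = if (is.null(nodes[["II"]])) 0L else nrow(nodes[["II"]])
  )

  run <- structure(
    list(
      peptides_filtered = filtered, epitopes = epitopes, pi = pi_tbl, ei = ei,
      line_dendrograms = line_dend, epitope_dendrograms = epi_dend,
      nodes = nodes, alignments = alignments, logos = logos,
      consensus = consensus, profiles = profiles,
      epitope_assignments = epi_assign, node_assignments = node_assign,
      summary = summary, config = config
    ),
    class = "mae_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.mae_run <- function(x, ...) {
  cat("MAE epitope analysis run\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x An `mae_run`.
#' @param ... Unused.
#' @return The run's summary tibble.
#' @export
glance.mae_run <- function(x, ...) x$summary

#' Write every artifact of a pipeline run to a directory
#'
#' @param run An `mae_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_peptide_table(run$peptides_filtered, file.path(dir, "peptides_filtered.tsv"))
  write_epitope_table(run$epitopes, file.path(dir, "epitopes.tsv"))
  write_epitope_fasta(
    filter(run$epitopes, .data$mhc_class %in% c("I", "II")),
    file.path(dir, "epitopes.fasta")
  )
  readr::write_tsv(run$pi, file.path(dir, "peptide_index.tsv"))
  for (cl in names(run$ei)) {
    tag <- if (cl == "I") "mhc1" else "mhc2"
    write_ei_matrix(run$ei[[cl]], file.path(dir, sprintf("ei_%s.tsv", tag)))
    if (!is.null(run$epitope_dendrograms[[cl]])) {
      as_newick(run$epitope_dendrograms[[cl]], file.path(dir, sprintf("epitopes_%s.nwk", tag)))
      as_newick(run$line_dendrograms[[cl]], file.path(dir, sprintf("cell_lines_%s.nwk", tag)))
    }
    if (!is.null(run$nodes[[cl]]) && nrow(run$nodes[[cl]]) > 0) {
      write_node_table(run$nodes[[cl]], file.path(dir, sprintf("nodes_%s.tsv", tag)))
    }
    if (!is.null(run$consensus[[cl]]) && length(run$consensus[[cl]]) > 0) {
      writeLines(
        sprintf("%s\t%s", names(run$consensus[[cl]]), unlist(run$consensus[[cl]])),
        file.path(dir, sprintf("consensus_%s.txt", tag))
      )
    }
    if (!is.null(run$epitope_assignments[[cl]])) {
      readr::write_tsv(
        run$epitope_assignments[[cl]],
        file.path(dir, sprintf("assignments_%s.tsv", tag))
      )
    }
  }
  readr::write_tsv(run$summary, file.path(dir, "summary.tsv"))
  jsonlite::write_json(
    as.list(run$summary),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}
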