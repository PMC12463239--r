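#' Configuration for the synthetic family peptidome generator
#'
#' Defines the study conditions the simulator emulates: a consanguineous
#' family panel (two parents plus `n_children` children, seven lines by
#' default) typed at classical class I and class II loci, allele-specific
#' binding motifs with high-probability anchor residues (MHC I anchors at
#' core positions 2 and 9; MHC II core anchors at 1, 4, 6 and 9), nested
#' ragged MHC II peptide sets sharing a 9-mer binding core, triplicate
#' acquisition with per-replicate dropout, Poisson spectral counts, and a
#' background of non-specific contaminant peptides present in every line.
#'
#' @param n_children Children in the family (default 5).
#' @param loci_mhc1,loci_mhc2 Locus names contributing MHC I / II epitopes.
#' @param alleles_per_locus Distinct alleles in the population pool per locus
#'   (default 4).
#' @param allele_pool Optional named list locus -> allele names, overriding
#'   the generated pool.
#' @param epitopes_per_allele Epitopes generated per allele (default 12).
#' @param mhc1_length_weights Named weights over MHC I epitope lengths 9-11.
#' @param mhc1_anchors,mhc2_core_anchors Anchor positions within the 9-mer
#'   binding core.
#' @param anchor_prob Probability of the designated anchor residue at an
#'   anchor position (default 0.8).
#' @param nested_min,nested_max Number of nested peptides per MHC II epitope.
#' @param count_lambda Poisson mean spectral count per replicate (default 5).
#' @param replicate_dropout Probability a peptide is missed in a replicate.
#' @param contaminant_fraction Fraction of all emitted peptide sequences that
#'   are non-specific contaminants (default 0.2).
#' @param n_replicates Biological replicates per cell line (default 3).
#' @param flank_len Protein flank length around each embedded epitope.
#' @param seed Base RNG seed (default 42).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_children = 5L,
                              loci_mhc1 = c("A", "B", "C"),
                              loci_mhc2 = c("DRB1", "DQA1", "DQB1"),
                              alleles_per_locus = 4L,
                              allele_pool = NULL,
                              epitopes_per_allele = 12L,
                              mhc1_length_weights = c(`9` = 0.6, `10` = 0.25, `11` = 0.15),
                              mhc1_anchors = c(2L, 9L),
                              mhc2_core_anchors = c(1L, 4L, 6L, 9L),
                              anchor_prob = 0.8,
                              nested_min = 3L, nested_max = 6L,
                              count_lambda = 5,
                              replicate_dropout = 0.1,
                              contaminant_fraction = 0.2,
                              n_replicates = 3L,
                              flank_len = 15L,
                              seed = 42L) {
  loci <- c(loci_mhc1, loci_mhc2)
  if (is.null(allele_pool)) {
    allele_pool <- setNames(
      map(loci, ~ sprintf("%s*%02d", .x, seq_len(alleles_per_locus))),
      loci
    )
  }
  stopifnot(
    replicate_dropout >= 0, replicate_dropout <= 1,
    contaminant_fraction >= 0, contaminant_fraction < 1,
    anchor_prob >= 0, anchor_prob <= 1,
    all(mhc1_anchors %in% 1:9), all(mhc2_core_anchors %in% 1:9),
    count_lambda > 0, nested_min >= 3, nested_min <= nested_max
  )
  structure(
    list(
      n_children = n_children, loci_mhc1 = loci_mhc1, loci_mhc2 = loci_mhc2,
      allele_pool = allele_pool, epitopes_per_allele = epitopes_per_allele,
      mhc1_length_weights = mhc1_length_weights, mhc1_anchors = mhc1_anchors,
      mhc2_core_anchors = mhc2_core_anchors, anchor_prob = anchor_prob,
      nested_min = nested_min, nested_max = nested_max,
      count_lambda = count_lambda, replicate_dropout = replicate_dropout,
      contaminant_fraction = contaminant_fraction,
      n_replicates = n_replicates, flank_len = flank_len, seed = seed
    ),
    class = "simulation_config"
  )
}

#' Simulate a consanguineous family's HLA genotypes
#'
#' Each parent receives two multi-locus haplotypes whose alleles are drawn
#' without replacement per locus from the locus pool (independently per
#' parent, so parents may share alleles, as is common in consanguineous
#' panels). Each child inherits one complete haplotype from each parent with
#' no recombination, mirroring the tight linkage of the HLA region.
#'
#' @param config A [simulation_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return Genotype tibble `cell_line`, `locus`, `allele1`, `allele2` for the
#'   2 parents plus `n_children` children. The per-line haplotype origins are
#'   attached as attribute `"haplotypes"`.
#' @export
simulate_family <- function(config = simulation_config(), seed = config$seed) {
  pool <- config$allele_pool
  short <- names(pool)[map_int(pool, length) < 2]
  if (length(short) > 0) {
    abort(sprintf(
      "allele pool too small at locus %s: need at least 2 alleles to form distinct parental haplotype entries",
      short[1]
    ))
  }
  loci <- names(pool)
  with_local_seed(seed, {
    draw_parent <- function() {
      # two haplotypes: per locus, two alleles without replacement
      h <- map(pool, ~ sample(.x, 2, replace = FALSE))
      list(
        h1 = map_chr(h, 1),
        h2 = map_chr(h, 2)
      )
    }
    father <- draw_parent()
    mother <- draw_parent()
    lines <- c("father", "mother", sprintf("child%d", seq_len(config$n_children)))
    hap_choice <- tibble(
      cell_line = lines,
      paternal = c("h1", "h2", sample(c("h1", "h2"), config$n_children, replace = TRUE)),
      maternal = c("h2", "h1", sample(c("h1", "h2"), config$n_children, replace = TRUE))
    )
    geno <- map(seq_along(lines), function(i) {
      ln <- lines[i]
      if (ln == "father") {
        a1 <- father$h1
        a2 <- father$h2
      } else if (ln == "mother") {
        a1 <- mother$h1
        a2 <- mother$h2
      } else {
        a1 <- father[[hap_choice$paternal[i]]]
        a2 <- mother[[hap_choice$maternal[i]]]
      }
      tibble(cell_line = ln, locus = loci, allele1 = unname(a1), allele2 = unname(a2))
    })
    out <- bind_rows(geno)
    attr(out, "haplotypes") <- hap_choice
    out
  })
}

# sample one sequence from a position-weight matrix (columns = positions)
sample_from_pwm <- function(pwm) {
  paste(
    map_chr(seq_len(ncol(pwm)), function(j) sample(AA20, 1, prob = pwm[, j])),
    collapse = ""
  )
}

# build an allele's 9-mer core PWM: anchor positions concentrate anchor_prob
# on a designated residue, the rest uniform
allele_pwm <- function(anchors, anchor_residues, anchor_prob) {
  pwm <- matrix(1 / 20, 20, 9, dimnames = list(AA20, NULL))
  for (k in seq_along(anchors)) {
    col <- rep((1 - anchor_prob) / 19, 20)
    names(col) <- AA20
    col[anchor_residues[k]] <- anchor_prob
    pwm[, anchors[k]] <- col
  }
  pwm
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Simulate the family's MAE peptidome with known ground truth
#'
#' For every allele in the panel a position-weight matrix with distinct
#' high-probability anchor residues is drawn; each of its epitopes is
#' embedded in a synthetic protein at known coordinates. MHC I epitopes
#' (lengths 9-11, anchors at core positions 2 and 9) emit one or two
#' peptides; MHC II epitopes emit a nested set of ragged peptides of lengths
#' 12-20 sharing the 9-mer core (anchors 1, 4, 6, 9). An epitope's peptides
#' appear only in cell lines whose genotype carries its allele; spectral
#' counts are Poisson per replicate with dropout; contaminant peptides
#' (random sequences of 9-20 residues) appear in every line at the
#' configured fraction of all emitted peptide sequences.
#'
#' @param genotypes Tibble from [simulate_family()].
#' @param config A [simulation_config()].
#' @param seed RNG seed (default `config$seed + 1` so the family and the
#'   peptidome draw from distinct streams).
#' @return A list of class `mae_simulation`: `peptides` (observation tibble
#'   in the standard dialect), `proteins` (named character vector of protein
#'   sequences), `truth` (one row per emitted peptide observation:
#'   `sequence`, `cell_line`, `replicate`, `epitope_id`, `allele`,
#'   `protein_id`, `start`, `end`), `epitopes` (ground-truth epitope table
#'   with allele, class, protein span and the union span of emitted
#'   peptides), and `motifs` (per-allele anchor residues).
#' @export
simulate_peptidome <- function(genotypes, config = simulation_config(),
                               seed = config$seed + 1L) {
  loci1 <- config$loci_mhc1
  loci2 <- config$loci_mhc2
  panel <- unique(genotypes$cell_line)
  alleles <- genotypes %>%
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") %>%
    distinct(.data$locus, .data$allele) %>%
    arrange(.data$locus, .data$allele) %>%
    mutate(class = ifelse(.data$locus %in% loci1, "I", "II"))
  carriers <- function(a) {
    unique(genotypes$cell_line[genotypes$allele1 == a | genotypes$allele2 == a])
  }

  with_local_seed(seed, {
    # per-allele motifs
    motifs <- map(seq_len(nrow(alleles)), function(i) {
      anchors <- if (alleles$class[i] == "I") config$mhc1_anchors else config$mhc2_core_anchors
      list(
        allele = alleles$allele[i], class = alleles$class[i], anchors = anchors,
        anchor_residues = sample(AA20, length(anchors), replace = FALSE)
      )
    })
    names(motifs) <- alleles$allele

    peptide_rows <- list()
    epitope_rows <- list()
    proteins <- character()
    uid <- 0L
    for (mi in seq_along(motifs)) {
      mot <- motifs[[mi]]
      pwm <- allele_pwm(mot$anchors, mot$anchor_residues, config$anchor_prob)
      for (k in seq_len(config$epitopes_per_allele)) {
        uid <- uid + 1L
        eid <- sprintf("T%04d", uid)
        core <- sample_from_pwm(pwm)
        if (mot$class == "I") {
          len <- as.integer(sample(
            names(config$mhc1_length_weights), 1,
            prob = config$mhc1_length_weights
          ))
          span <- if (len > 9) paste0(core, random_aa(len - 9)) else core
          # one or two peptides: the span, plus sometimes its 9-mer core
          peps <- span
          if (len > 9 && runif(1) < 0.5) peps <- c(peps, core)
          starts <- rep(1L, length(peps))
        } else {
          fl <- sample(2:5, 1)
          fr <- sample(2:5, 1)
          span <- paste0(random_aa(fl), core, random_aa(fr))
          len <- nchar(span)
          cand <- tidyr::expand_grid(s = seq_len(fl + 1L), e = seq(fl + 9L, len)) %>%
            filter(.data$e - .data$s + 1L >= 12L)
          n_pep <- min(sample(seq(config$nested_min, config$nested_max), 1), nrow(cand))
          pick <- cand[sample.int(nrow(cand), n_pep), ]
          peps <- map_chr(seq_len(n_pep), ~ substr(span, pick$s[.x], pick$e[.x]))
          starts <- pick$s
          if (length(unique(peps)) < 3) {
            # top up with the full span to keep >= 3 distinct nested peptides
            peps <- c(peps, span)
            starts <- c(starts, 1L)
          }
        }
        prot_id <- sprintf("PROT_%s", eid)
        prot_seq <- paste0(random_aa(config$flank_len), span, random_aa(config$flank_len))
        proteins[prot_id] <- prot_seq
        pep_start <- config$flank_len + starts
        epitope_rows[[uid]] <- tibble(
          epitope_id = eid, allele = mot$allele, class = mot$class,
          protein_id = prot_id, span = span,
          span_start = config$flank_len + 1L,
          span_end = config$flank_len + nchar(span),
          pep_start = min(pep_start),
          pep_end = max(pep_start + nchar(peps) - 1L)
        )
        peptide_rows[[uid]] <- tibble(
          sequence = peps, epitope_id = eid, allele = mot$allele,
          protein_id = prot_id, start = as.integer(pep_start),
          end = as.integer(pep_start + nchar(peps) - 1L)
        )
      }
    }
    true_peps <- bind_rows(peptide_rows) %>% distinct()

    # contaminants: random soluble peptides present in every line
    n_cont <- round(
      config$contaminant_fraction / (1 - config$contaminant_fraction) *
        dplyr::n_distinct(true_peps$sequence)
    )
    cont_rows <- NULL
    if (n_cont > 0) {
      cont_seq <- map_chr(sample(9:20, n_cont, replace = TRUE), random_aa)
      cont_id <- sprintf("CONT_%04d", seq_len(n_cont))
      for (i in seq_len(n_cont)) proteins[cont_id[i]] <- cont_seq[i]
      cont_rows <- tibble(
        sequence = cont_seq, epitope_id = cont_id, allele = "contaminant",
        protein_id = cont_id, start = 1L, end = nchar(cont_seq)
      )
    }

    # emit observations: carrier lines x replicates, Poisson counts, dropout
    emit <- function(pep_tbl, lines_for) {
      grid <- pep_tbl %>%
        mutate(lines = map(.data$allele, lines_for)) %>%
        tidyr::unnest("lines") %>%
        rename(cell_line = "lines") %>%
        tidyr::expand_grid(replicate = sprintf("r%d", seq_len(config$n_replicates)))
      n <- nrow(grid)
      kept <- runif(n) >= config$replicate_dropout
      cnt <- rpois(n, config$count_lambda)
      grid %>%
        mutate(spectral_count = as.integer(cnt), intensity = NA_real_) %>%
        filter(kept & cnt > 0)
    }
    obs_true <- emit(true_peps, function(a) carriers(a))
    obs_cont <- if (!is.null(cont_rows)) emit(cont_rows, function(a) panel) else NULL
    obs <- bind_rows(obs_true, obs_cont)

    peptides <- select(
      obs, "sequence", "protein_id", "start", "end", "cell_line",
      "replicate", "spectral_count", "intensity"
    )
    truth <- select(
      obs, "sequence", "cell_line", "replicate", "epitope_id", "allele",
      "protein_id", "start", "end"
    )
    structure(
      list(
        peptides = peptides, proteins = proteins, truth = truth,
        epitopes = bind_rows(epitope_rows), motifs = motifs,
        config = config, panel = panel
      ),
      class = "mae_simulation"
    )
  })
}

#' @export
print.mae_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated MAE peptidome: %d observations, %d peptide sequences, %d true epitopes, %d cell lines\n",
    nrow(x$peptides), dplyr::n_distinct(x$peptides$sequence),
    nrow(x$epitopes), length(x$panel)
  ))
  invisible(x)
}

#' Ground-truth epitope spans realized by the emitted peptides
#'
#' The realized span of a true epitope is the union interval of the peptides
#' actually emitted for it - the maximal sequence condensation can possibly
#' reconstruct.
#'
#' @param sim An `mae_simulation`.
#' @return Tibble `epitope_id`, `allele`, `class`, `protein_id`, `start`,
#'   `end`, `sequence` (the realized span sequence).
#' @export
truth_epitope_spans <- function(sim) {
  spans <- sim$truth %>%
    filter(.data$allele != "contaminant") %>%
    group_by(.data$epitope_id, .data$allele, .data$protein_id) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  spans %>%
    left_join(select(sim$epitopes, "epitope_id", "class"), by = "epitope_id") %>%
    mutate(sequence = substr(
      sim$proteins[.data$protein_id], .data$start, .data$end
    ))
}

#' Write the simulated dataset to a directory
#'
#' Emits the exact TSV dialect [read_peptide_table()] reads, the genotype
#' TSV, the protein FASTA, and the truth table.
#'
#' @param sim An `mae_simulation`.
#' @param genotypes The matching genotype tibble.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, genotypes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_peptide_table(sim$peptides, file.path(dir, "peptides.tsv"))
  write_genotype_table(genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  writeLines(
    as.vector(rbind(paste0(">", names(sim$proteins)), sim$proteins)),
    file.path(dir, "proteins.fasta")
  )
  invisible(dir)
}
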