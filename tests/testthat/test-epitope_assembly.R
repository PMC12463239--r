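test_that("coordinate condensation merges overlapping intervals per protein", {
  # peptides at 10-18 and 12-22 sharing letters DEFGHIK on the overlap
  tbl <- dplyr::bind_rows(
    pep_tbl("ACDEFGHIK", protein_id = "X", start = 10, end = 18),
    pep_tbl("DEFGHIKLMNP", protein_id = "X", start = 12, end = 22)
  )
  ep <- condense_peptides(tbl, mode = "coordinates")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, 10L)
  expect_equal(ep$end, 22L)
  expect_equal(ep$length, 13L)
  expect_equal(ep$sequence, "ACDEFGHIKLMNP")

  disjoint <- dplyr::bind_rows(
    pep_tbl("ACDEFGHIK", protein_id = "X", start = 10, end = 18),
    pep_tbl("DEFGHIKLM", protein_id = "X", start = 30, end = 38)
  )
  expect_equal(nrow(condense_peptides(disjoint, "coordinates")), 2)

  # conflicting letters on a shared position are an error
  clash <- dplyr::bind_rows(
    pep_tbl("ACDEFGHIK", protein_id = "X", start = 10, end = 18),
    pep_tbl("WWWWWWWWW", protein_id = "X", start = 12, end = 20)
  )
  expect_error(condense_peptides(clash, "coordinates"), "conflicting letters")
})

test_that("string condensation finds the maximal superstring", {
  tbl <- pep_tbl(c("KLVANNTRL", "VANNTRLEF"))
  ep <- condense_peptides(tbl, mode = "string", min_overlap = 5)
  expect_equal(ep$sequence, "KLVANNTRLEF")
  expect_equal(sort(ep$constituents[[1]]), sort(c("KLVANNTRL", "VANNTRLEF")))
  # the exhaustive merge-order search agrees
  expect_equal(oracle_condense(tbl$sequence, 5), "KLVANNTRLEF")

  # containment collapses to the container
  tb2 <- pep_tbl(c("KLVANNTRLEF", "VANNTRL"))
  expect_equal(condense_peptides(tb2, "string")$sequence, "KLVANNTRLEF")

  # a component whose overlaps cannot be reconciled errors
  bad <- pep_tbl(c("AAAAAGGGGG", "GGGGGTTTTT", "GGGGGCCCCC"))
  expect_error(condense_peptides(bad, "string"), "conflict|cannot be merged")

  expect_error(condense_peptides(pep_tbl(character(0))), "empty")
})

test_that("condensation partitions peptides and ignores input order", {
  withr::local_seed(421)
  for (rep in 1:10) {
    comp <- nested_component(sample(3:6, 1))
    extra <- rand_seq(12) # unrelated singleton
    seqs <- c(comp$peptides, extra)
    tbl <- pep_tbl(seqs, spectral_count = sample(1:5, length(seqs), replace = TRUE))
    ep <- condense_peptides(tbl, "string", min_overlap = 5)
    # partition: every distinct peptide in exactly one epitope
    all_constituents <- unlist(ep$constituents)
    expect_setequal(all_constituents, unique(seqs))
    expect_equal(length(all_constituents), length(unique(seqs)))
    # permutation invariance
    shuf <- tbl[sample(nrow(tbl)), ]
    ep2 <- condense_peptides(shuf, "string", min_overlap = 5)
    expect_equal(ep2$sequence, ep$sequence)
    expect_equal(ep2$constituents, ep$constituents)
  }
})

test_that("string mode reproduces coordinate-mode epitopes on simulated data", {
  cfg <- simulation_config(
    epitopes_per_allele = 2, replicate_dropout = 0,
    contaminant_fraction = 0, seed = 11
  )
  g <- simulate_family(cfg)
  sim <- simulate_peptidome(g, cfg)
  by_coord <- condense_peptides(sim$peptides, "coordinates")
  by_string <- condense_peptides(sim$peptides, "string", min_overlap = 5)
  expect_setequal(by_string$sequence, by_coord$sequence)
})

test_that("multi-protein peptides are deterministically assigned to one accession", {
  tbl <- dplyr::bind_rows(
    pep_tbl("ACDEFGHIK", protein_id = "ZZZ", start = 5, end = 13),
    pep_tbl("ACDEFGHIK", protein_id = "AAA", start = 50, end = 58)
  )
  expect_message(ep <- condense_peptides(tbl, "coordinates"), "multiple proteins")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$protein_id, "AAA")
})

test_that("classification applies count, length and nesting filters", {
  mk <- function(len, n_const, total) {
    tibble::tibble(
      epitope_id = "E0001", sequence = strrep("A", len), length = len,
      protein_id = NA, start = NA, end = NA, n_constituents = n_const,
      constituents = list(as.character(seq_len(n_const))),
      total_spectral_count = total
    )
  }
  expect_equal(classify_epitopes(mk(10, 1, 5))$mhc_class, "I")
  expect_equal(classify_epitopes(mk(15, 3, 9))$mhc_class, "II")
  # total spectral count of 2 or fewer is removed
  expect_equal(classify_epitopes(mk(10, 1, 2))$mhc_class, "rejected")
  # a 12-20-mer from a single peptide is not a credible MHC II epitope
  cls <- classify_epitopes(mk(15, 1, 9))
  expect_equal(cls$mhc_class, "rejected")
  expect_equal(cls$reject_reason, "too_few_nested_peptides")
  # short epitopes rejected
  expect_equal(classify_epitopes(mk(8, 1, 9))$mhc_class, "rejected")
  # over-length spans are rejected with a warning, or retained unclassified
  expect_warning(long <- classify_epitopes(mk(25, 4, 9)), "longer than")
  expect_equal(long$mhc_class, "rejected")
  expect_equal(
    classify_epitopes(mk(25, 4, 9), retain_long = TRUE)$mhc_class,
    "unclassified"
  )
  expect_error(
    classify_epitopes(mk(10, 1, 5), mhc1_range = c(9, 13)),
    "overlap"
  )
})

test_that("epitope tables and FASTA export serialize", {
  ep <- classify_epitopes(tibble::tibble(
    epitope_id = "E0001", sequence = "KLVANNTRLE", length = 10L,
    protein_id = "P1", start = 4L, end = 13L, n_constituents = 2L,
    constituents = list(c("KLVANNTRL", "LVANNTRLE")),
    total_spectral_count = 7L
  ))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_epitope_table(ep, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$constituents, "KLVANNTRL,LVANNTRLE")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_epitope_fasta(ep, fa)
  lines <- readLines(fa)
  expect_equal(lines[1], ">E0001 class=I")
  expect_equal(lines[2], "KLVANNTRLE")
})
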