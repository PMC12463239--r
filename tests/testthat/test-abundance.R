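test_that("Peptide Index is the zero-inclusive mean spectral count", {
  tbl <- pep_tbl("KLVANNTRL",
    replicate = c("r1", "r2", "r3"),
    spectral_count = c(3L, 5L, 4L)
  )
  pi1 <- peptide_index(tbl, total_reps = 3)
  expect_equal(pi1$p_i, 4.0)
  # missing replicate contributes zero to the mean
  pi2 <- peptide_index(tbl[1:2, ], total_reps = 3)
  expect_equal(pi2$p_i, 8 / 3)
  # a peptide absent from a line has P_i = 0 there
  two_lines <- dplyr::bind_rows(tbl, pep_tbl("AAWGCFMTV", cell_line = "L2"))
  pi3 <- peptide_index(two_lines, total_reps = 3)
  expect_equal(
    pi3$p_i[pi3$sequence == "KLVANNTRL" & pi3$cell_line == "L2"], 0
  )
  expect_equal(nrow(pi3), 4) # full grid
  expect_error(peptide_index(tbl, total_reps = 0), "positive")
})

make_ei_fixture <- function() {
  peps <- dplyr::bind_rows(
    pep_tbl("AAACCCDDD", cell_line = "L1", spectral_count = 6L),
    pep_tbl("CCCDDDEEE", cell_line = "L1", spectral_count = 9L),
    pep_tbl("AAACCCDDD", cell_line = "L2", spectral_count = 3L),
    pep_tbl("WWWYYYHHH", cell_line = "L2", spectral_count = 12L)
  )
  eps <- tibble::tibble(
    epitope_id = c("E0001", "E0002"),
    sequence = c("AAACCCDDDEEE", "WWWYYYHHH"),
    length = c(12L, 9L), protein_id = NA, start = NA, end = NA,
    n_constituents = c(2L, 1L),
    constituents = list(c("AAACCCDDD", "CCCDDDEEE"), "WWWYYYHHH"),
    total_spectral_count = c(18L, 12L)
  )
  list(peps = peps, eps = eps)
}

test_that("Epitope Index sums constituent Peptide Indices per cell line", {
  fx <- make_ei_fixture()
  pi_tbl <- peptide_index(fx$peps, total_reps = 3)
  ei <- epitope_index(fx$eps, pi_tbl)
  expect_s3_class(ei, "ei_matrix")
  expect_equal(ei["E0001", "L1"], 6 / 3 + 9 / 3)
  expect_equal(ei["E0001", "L2"], 1)
  expect_equal(ei["E0002", "L1"], 0)
  # conservation: column sums of E_i equal the total P_i mass per line
  totals <- dplyr::summarise(
    dplyr::group_by(pi_tbl, cell_line),
    s = sum(p_i)
  )
  expect_equal(unname(colSums(ei)[totals$cell_line]), totals$s)
  # linearity: doubling all counts doubles every E_i
  doubled <- dplyr::mutate(fx$peps, spectral_count = spectral_count * 2L)
  ei2 <- epitope_index(fx$eps, peptide_index(doubled, total_reps = 3))
  expect_equal(unclass(ei2), unclass(ei) * 2)
  # an unknown constituent is an error naming the sequence
  bad <- fx$eps
  bad$constituents[[1]] <- c("AAACCCDDD", "MISSINGPEP")
  expect_error(epitope_index(bad, pi_tbl), "MISSINGPEP")
})

test_that("ei_matrix round-trips as TSV and has tidy/glance methods", {
  fx <- make_ei_fixture()
  ei <- epitope_index(fx$eps, peptide_index(fx$peps, total_reps = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ei_matrix(ei, path)
  back <- read_ei_matrix(path)
  expect_equal(unclass(back), unclass(ei))
  long <- generics::tidy(ei)
  expect_equal(nrow(long), 4)
  expect_equal(
    long$e_i[long$epitope_id == "E0001" & long$cell_line == "L1"],
    ei["E0001", "L1"]
  )
  gl <- generics::glance(ei)
  expect_equal(gl$n_epitopes, 2)
  expect_equal(gl$total_ei, sum(ei))
  p <- ggplot2::autoplot(ei)
  expect_s3_class(p, "ggplot")
})

test_that("knockdown ratios use exclusive sentinels and the knockdown factor", {
  kd <- tibble::tibble(
    sequence = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
    intensity = c(10, 1.5, 9)
  )
  ctrl <- tibble::tibble(
    sequence = c("AAAAAAAAA", "CCCCCCCCC", "EEEEEEEEE"),
    intensity = c(10, 10, 4)
  )
  res <- knockdown_classification(kd, ctrl, normalize = "none")
  expect_equal(res$ratio[res$sequence == "DDDDDDDDD"], 50) # knockdown-only
  expect_equal(res$ratio[res$sequence == "EEEEEEEEE"], 0.02) # control-only
  expect_true(res$affected[res$sequence == "CCCCCCCCC"]) # 0.15 <= 0.21
  expect_false(res$affected[res$sequence == "AAAAAAAAA"]) # 1.0
  expect_true(res$affected[res$sequence == "EEEEEEEEE"])
  expect_error(
    knockdown_classification(kd, ctrl, knockdown_factor = 0),
    "positive"
  )
})

test_that("lowering a knockdown intensity never rescues a peptide", {
  withr::local_seed(99)
  base <- tibble::tibble(
    sequence = vapply(1:20, function(i) rand_seq(9), character(1)),
    intensity = stats::runif(20, 0.1, 10)
  )
  kd <- base
  res1 <- knockdown_classification(kd, base, normalize = "none")
  kd2 <- dplyr::mutate(kd, intensity = intensity * stats::runif(20, 0.05, 1))
  res2 <- knockdown_classification(kd2, base, normalize = "none")
  # monotone: affected set can only grow when kd intensities drop
  expect_true(all(res2$affected[res1$affected]))
})
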