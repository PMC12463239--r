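one_col <- function(residues) {
  matrix(residues, ncol = 1)
}

test_that("column information matches the closed forms", {
  # 100 identical residues: E = log2(20) - 19/(2 ln2 * 100)
  lg <- logo_columns(one_col(rep("L", 100)), bootstrap_reps = 50, seed = 1)
  expect_equal(lg$columns$e, log2(20) - 19 / (2 * log(2) * 100), tolerance = 1e-12)
  expect_equal(lg$columns$w, 1)
  # all 20 residues once each: entropy log2(20), clamped to 0
  lg2 <- logo_columns(one_col(AA), bootstrap_reps = 50, seed = 1)
  expect_equal(lg2$columns$e, 0)
  # occupancy weight is N_n / M
  lg3 <- logo_columns(one_col(c("L", "L", "V", "V", rep("-", 4))),
    bootstrap_reps = 50, seed = 1
  )
  expect_equal(lg3$columns$w, 0.5)
  expect_equal(lg3$columns$n_n, 4L)
  # an all-gap column is null
  lg4 <- logo_columns(matrix(c("L", "L", "-", "-"), 2), bootstrap_reps = 20, seed = 1)
  expect_true(lg4$columns$null[2])
  expect_true(is.na(lg4$columns$e[2]))
})

test_that("positional score and threshold formulas are exact", {
  expect_identical(positional_score(2, 4, 1.5, 0.5), 0.375)
  expect_equal(positional_threshold(1.2, 0.9), 0.3)
  expect_equal(positional_score(4, 4, 2.0, 1.0), 2.0)
  expect_equal(positional_score(0, 4, 2.0, 1.0), 0)
})

test_that("scores distribute E*W over residue frequencies exactly", {
  withr::local_seed(12)
  for (rep in 1:10) {
    m <- matrix(sample(c(AA, "-"), 8 * 6, replace = TRUE, prob = c(rep(1, 20), 3)), 8, 6)
    lg <- logo_columns(m, bootstrap_reps = 30, seed = rep)
    sums <- dplyr::summarise(
      dplyr::group_by(lg$residues, position),
      s_sum = sum(s)
    )
    cols <- dplyr::filter(lg$columns, n_n > 0)
    joined <- dplyr::left_join(cols, sums, by = "position")
    joined$s_sum[is.na(joined$s_sum)] <- 0
    expect_equal(joined$s_sum, joined$e * joined$w, tolerance = 1e-12)
    # invariants of the column statistics
    expect_true(all(joined$l <= joined$e + 1e-12))
    expect_true(all(joined$r >= 0))
    expect_true(all(lg$residues$s <= joined$e[match(lg$residues$position, joined$position)] *
      joined$w[match(lg$residues$position, joined$position)] + 1e-12))
  }
})

test_that("the bootstrap lower bound is deterministic under a fixed seed", {
  m <- matrix(sample(AA[1:5], 60, replace = TRUE), 12, 5)
  a <- logo_columns(m, bootstrap_reps = 100, seed = 42)
  b <- logo_columns(m, bootstrap_reps = 100, seed = 42)
  expect_identical(a$columns$l, b$columns$l)
  expect_identical(a$columns$r, b$columns$r)
  c <- logo_columns(m, bootstrap_reps = 100, seed = 43)
  expect_false(identical(a$columns$l, c$columns$l))
})

test_that("planted anchors are the significant positions", {
  withr::local_seed(7)
  n <- 30
  seqs <- vapply(seq_len(n), function(i) {
    s <- rand_seq(9)
    substr(s, 2, 2) <- if (stats::runif(1) < 0.85) "L" else sample(AA, 1)
    substr(s, 9, 9) <- if (stats::runif(1) < 0.85) "V" else sample(AA, 1)
    s
  }, character(1))
  m <- do.call(rbind, strsplit(seqs, ""))
  lg <- logo_columns(m, bootstrap_reps = 200, seed = 3)
  sig_pos <- lg$columns$position[!lg$columns$null]
  expect_true(all(c(2, 9) %in% sig_pos))
  # anchors dominate: the two highest-S residues sit at the anchor columns
  top2 <- head(dplyr::arrange(lg$residues, dplyr::desc(s)), 2)
  expect_setequal(top2$position, c(2, 9))
  expect_setequal(top2$residue, c("L", "V"))
})

test_that("group significance rescues residues that fail individually", {
  # half S, half T at one position: individually diluted, jointly strong
  m <- one_col(c(rep("S", 10), rep("T", 10)))
  lg <- logo_columns(m, bootstrap_reps = 200, seed = 5)
  res <- lg$residues
  if (!any(res$significant)) {
    expect_true(all(res$group_only[res$residue %in% c("S", "T")]))
  }
  # group-only flags never co-occur with individual significance in a group
  expect_false(any(res$significant & res$group_only))
})

test_that("consensus rendering follows the dash/bracket/top-4 conventions", {
  lg <- list(
    columns = tibble::tibble(
      position = 1:5, n_n = 10L, m = 10L, w = 1,
      e = c(0, 2, 0, 1.5, 1), l = c(0, 1.8, 0, 1.2, 0.9),
      r = c(0, 0.2, 0, 0.3, 0.1), null = c(TRUE, FALSE, TRUE, FALSE, FALSE)
    ),
    residues = tibble::tibble(
      position = c(2L, 4L, 4L, 5L),
      residue = c("L", "S", "T", "V"),
      count = c(10L, 5L, 5L, 4L),
      s = c(2, 0.75, 0.7, 0.4),
      significant = c(TRUE, TRUE, TRUE, FALSE),
      group_only = c(FALSE, FALSE, FALSE, TRUE),
      shade = c(1, 0.75, 0.7, 0.4)
    )
  )
  class(lg) <- "logo"
  full <- render_consensus(lg, "full")
  expect_equal(full$text, "-L-[ST]v")
  # top4 keeps the four highest-S entries; here all four qualify
  top4 <- render_consensus(lg, "top4")
  expect_equal(top4$text, "2:L 4:[ST] 5:v")
  dashed <- render_consensus(lg, "top4_dashed")
  expect_equal(dashed$text, "L-[ST]v")
  # a fifth entry would drop the lowest-S one
  lg$residues <- rbind(
    lg$residues,
    tibble::tibble(
      position = 1L, residue = "K", count = 3L, s = 0.5,
      significant = TRUE, group_only = FALSE, shade = 0.5
    )
  )
  lg$columns$null[1] <- FALSE
  top4b <- render_consensus(lg, "top4")
  expect_false(grepl("v", top4b$text)) # S=0.4 entry dropped
  expect_true(grepl("K", top4b$text))
  # shades are clamped to [0.2, 1]
  expect_true(all(lg$residues$shade >= 0.2 & lg$residues$shade <= 1))
})

test_that("logo table export carries counts and statistics per column", {
  m <- matrix(c("L", "L", "L", "V"), 2)
  lg <- logo_columns(m, bootstrap_reps = 20, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_logo_table(lg, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$L, c(2L, 1L))
  expect_equal(tab$V, c(0L, 1L))
  expect_equal(tab$n_n, c(2L, 2L))
  p <- ggplot2::autoplot(lg)
  expect_s3_class(p, "ggplot")
})
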