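family_genotypes <- function() {
  tibble::tribble(
    ~cell_line, ~locus, ~allele1, ~allele2,
    "father", "A", "A*01", "A*02",
    "mother", "A", "A*03", "A*04",
    "child1", "A", "A*01", "A*03",
    "child2", "A", "A*02", "A*04",
    "father", "B", "B*07", "B*08",
    "mother", "B", "B*07", "B*35",
    "child1", "B", "B*07", "B*07",
    "child2", "B", "B*08", "B*35"
  )
}

test_that("theoretical profiles are genotype carrier vectors", {
  prof <- theoretical_profiles(family_genotypes())
  panel <- c("father", "mother", "child1", "child2")
  a1 <- prof$profile[[which(prof$allele == "A*01")]]
  expect_equal(a1, setNames(c(1L, 0L, 1L, 0L), panel))
  # allele present in every line via both parents
  b7 <- prof$profile[[which(prof$allele == "B*07")]]
  expect_equal(unname(b7), c(1L, 1L, 1L, 0L))
  # ordering is locus then allele name, and only observed alleles appear
  expect_equal(prof$locus, sort(prof$locus))
  expect_false("A*99" %in% prof$allele)
  # ungenotyped line at a requested locus is an error naming both
  expect_error(
    theoretical_profiles(family_genotypes()[-5, ]),
    "father.*B"
  )
})

test_that("epitopes are assigned to all alleles matching their presence", {
  prof <- theoretical_profiles(family_genotypes())
  panel <- c("father", "mother", "child1", "child2")
  ei <- matrix(
    c(
      5, 0, 3, 0, # matches A*01 exactly
      2, 2, 2, 0, # matches B*07 exactly
      1, 1, 1, 1 # present everywhere: matches no allele here
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("E0001", "E0002", "E0003"), panel)
  )
  asn <- assign_alleles(ei, prof, max_mismatch = 0)
  expect_equal(asn$allele[asn$epitope_id == "E0001"], "A*01")
  expect_equal(asn$allele[asn$epitope_id == "E0002"], "B*07")
  e3 <- asn[asn$epitope_id == "E0003", ]
  expect_true(e3$contaminant)
  expect_true(is.na(e3$allele))

  # co-segregating duplicate profiles are both returned
  prof2 <- dplyr::bind_rows(
    prof,
    tibble::tibble(
      allele = "C*05", locus = "C",
      profile = list(prof$profile[[which(prof$allele == "A*01")]])
    )
  )
  asn2 <- assign_alleles(ei[1, , drop = FALSE], prof2)
  expect_setequal(asn2$allele, c("A*01", "C*05"))

  # mismatch tolerance widens the candidate set
  ei_noisy <- ei[1, , drop = FALSE]
  ei_noisy[1, "child1"] <- 0
  expect_true(assign_alleles(ei_noisy, prof, max_mismatch = 0)$contaminant[1])
  asn3 <- assign_alleles(ei_noisy, prof, max_mismatch = 1)
  expect_true("A*01" %in% asn3$allele)
  expect_error(
    assign_alleles(ei[, 1:3], prof),
    "panel"
  )
})

test_that("node-level assignment uses binarized mean profiles", {
  prof <- theoretical_profiles(family_genotypes())
  nodes <- tibble::tibble(
    node_id = "N001", n_members = 2L,
    members = list(c("E0001", "E0002")),
    mean_profile = list(setNames(
      c(2.5, 0, 1.5, 0),
      c("father", "mother", "child1", "child2")
    ))
  )
  asn <- assign_node_alleles(nodes, prof)
  expect_equal(asn$allele, "A*01")
  expect_error(
    assign_node_alleles(dplyr::select(nodes, -mean_profile), prof),
    "mean_profile"
  )
})

test_that("traceability counts alleles with unique presence vectors", {
  mk_prof <- function(vectors) {
    tibble::tibble(
      allele = sprintf("X*%02d", seq_along(vectors)), locus = "X",
      profile = lapply(vectors, function(v) {
        setNames(as.integer(v), sprintf("L%d", seq_along(v)))
      })
    )
  }
  p <- mk_prof(list(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
  expect_equal(as.integer(traceable_allele_count(p)), 3)
  p2 <- mk_prof(list(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1)))
  tc <- traceable_allele_count(p2)
  expect_equal(as.integer(tc), 1)
  expect_equal(attr(tc, "alleles"), "X*03")
  # extending the panel can split a duplicate pair, gaining two
  p3 <- mk_prof(list(c(1, 1, 0, 1), c(1, 1, 0, 0), c(0, 1, 1, 0)))
  expect_equal(as.integer(traceable_allele_count(p3)), 3)
  # per-locus uniqueness is laxer than across-loci
  p4 <- mk_prof(list(c(1, 0), c(1, 0)))
  p4$locus <- c("X", "Y")
  expect_equal(as.integer(traceable_allele_count(p4)), 0)
  expect_equal(as.integer(traceable_allele_count(p4, per_locus = TRUE)), 2)
})

test_that("traceable count never decreases as lines are appended", {
  withr::local_seed(17)
  for (rep in 1:40) {
    n_alleles <- sample(3:12, 1)
    n_lines <- sample(2:6, 1)
    m <- matrix(stats::rbinom(n_alleles * n_lines, 1, 0.5), n_alleles, n_lines)
    prof <- tibble::tibble(
      allele = sprintf("X*%02d", seq_len(n_alleles)), locus = "X",
      profile = lapply(
        seq_len(n_alleles),
        function(i) setNames(m[i, ], sprintf("L%d", seq_len(n_lines)))
      )
    )
    base_count <- as.integer(traceable_allele_count(prof))
    # brute-force all-pairs oracle agrees
    expect_equal(base_count, oracle_traceable(m))
    ext <- cbind(m, rbinom(n_alleles, 1, 0.5))
    prof_ext <- prof
    prof_ext$profile <- lapply(
      seq_len(n_alleles),
      function(i) setNames(ext[i, ], sprintf("L%d", seq_len(n_lines + 1)))
    )
    expect_gte(as.integer(traceable_allele_count(prof_ext)), base_count)
  }
})

test_that("trace_panel reports monotone growth over nested panels", {
  g <- family_genotypes()
  tp <- trace_panel(g)
  expect_equal(tp$n_lines, 1:4)
  expect_true(all(diff(tp$n_traceable) >= 0))
  expect_true(all(diff(tp$n_alleles) >= 0))
  p <- plot_traceability(tp)
  expect_s3_class(p, "ggplot")
})
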