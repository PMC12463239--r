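# convenience constructor for peptide observation tibbles
pep_tbl <- function(sequence, cell_line = "L1", replicate = "r1",
                    spectral_count = 3L, protein_id = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    intensity = NA_real_) {
  tibble::tibble(
    sequence = sequence, protein_id = protein_id,
    start = as.integer(start), end = as.integer(end),
    cell_line = cell_line, replicate = replicate,
    spectral_count = as.integer(spectral_count), intensity = intensity
  )
}

AA <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

rand_seq <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# a nested component: random base sequence plus k substrings covering it,
# all pairwise linked through a shared central window
nested_component <- function(k, base_len = sample(15:20, 1)) {
  base <- rand_seq(base_len)
  mid <- floor(base_len / 2)
  subs <- character(k)
  starts <- integer(k)
  ends <- integer(k)
  for (i in seq_len(k)) {
    s <- sample(seq_len(mid - 4), 1)
    e <- sample(seq(mid + 4, base_len), 1)
    starts[i] <- s
    ends[i] <- e
    subs[i] <- substr(base, s, e)
  }
  list(
    base = base, peptides = subs,
    span = substr(base, min(starts), max(ends))
  )
}

# node of sequences sharing a planted 9-mer core with random flanks;
# total length stays within max_total (the MHC I alignment cap)
core_node <- function(n_seq, flank_max = 2, mutate_prob = 0.1, max_total = 12) {
  core <- rand_seq(9)
  seqs <- character(n_seq)
  for (i in seq_len(n_seq)) {
    s <- core
    for (p in 1:9) {
      if (stats::runif(1) < mutate_prob) {
        substr(s, p, p) <- sample(AA, 1)
      }
    }
    left <- sample(0:min(flank_max, max_total - 9), 1)
    right <- sample(0:min(flank_max, max_total - 9 - left), 1)
    seqs[i] <- paste0(rand_seq(left), s, rand_seq(right))
  }
  seqs
}
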