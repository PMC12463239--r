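# fetch a substitution matrix by name from Biostrings and subset it to the
# 20 standard residues
substitution_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  ok <- tryCatch(
    {
      data(list = name, package = "Biostrings", envir = env)
      TRUE
    },
    warning = function(w) FALSE,
    error = function(e) FALSE
  )
  if (!ok || !exists(name, envir = env)) {
    abort(sprintf("unknown substitution matrix '%s'", name))
  }
  m <- get(name, envir = env)
  m[AA20, AA20]
}

#' Gapless offset alignment of a node's epitopes
#'
#' Aligns the epitope sequences of one node by integer offsets only: no
#' internal gaps are ever introduced, and terminal overhangs are unpenalized.
#' At the short lengths of MHC ligands a prohibitive gap-open penalty makes
#' classic progressive alignment effectively gapless, so the offset model
#' captures the same regime while remaining exactly specifiable.
#'
#' Alignment is progressive. The seed is the sequence with the highest weight
#' (by convention its total E_i; ties go to the longest, then lexicographically
#' smallest sequence). Each remaining sequence, in the same priority order, is
#' placed at the integer offset maximizing its summed substitution score
#' against the current column profile, subject to the resulting alignment
#' width staying within `max_len`; offset ties are broken by the smaller
#' resulting width, then the smaller offset. Placed offsets are never
#' revisited.
#'
#' @param sequences Character vector of epitope sequences (each no longer
#'   than `max_len`).
#' @param max_len Maximum alignment width: 12 for MHC I nodes (epitopes are
#'   9-11-mers), 30 for MHC II nodes.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param weights Optional numeric priority weights (e.g. total E_i per
#'   sequence); equal by default.
#' @param ids Optional sequence identifiers (epitope ids).
#' @return A `node_alignment`: list with `alignment` (tibble `id`,
#'   `sequence`, `offset` in input order), `width`, `score` (sum-of-pairs
#'   substitution score over co-occupied columns), `seed_id` (the id of the
#'   seed sequence), and `matrix`.
#' @export
#' @examples
#' align_node(c("KLDEVWKRM", "LDEVWKRMA"), max_len = 12)$alignment$offset
align_node <- function(sequences, max_len, matrix = "BLOSUM62",
                       weights = NULL, ids = NULL) {
  if (length(sequences) < 2) abort("need at least 2 sequences to align")
  check_sequences(sequences, context = "epitope sequence")
  too_long <- nchar(sequences) > max_len
  if (any(too_long)) {
    abort(sprintf(
      "sequence %s is longer than max_len = %d and should have been filtered upstream",
      sequences[too_long][1], max_len
    ))
  }
  if (is.null(weights)) weights <- rep(1, length(sequences))
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(sequences))
  B <- substitution_matrix(matrix)

  ord <- order(-weights, -nchar(sequences), sequences)
  # absolute coordinate system: profile counts over columns lo..hi
  lo <- 1L
  hi <- nchar(sequences[ord[1]])
  prof <- matrix(0L, 20L, max_len * 3L, dimnames = list(AA20, NULL))
  col0 <- max_len # column c maps to prof index c + col0
  add_seq <- function(s, off) {
    r <- strsplit(s, "")[[1]]
    for (p in seq_along(r)) {
      prof[r[p], off + p + col0] <<- prof[r[p], off + p + col0] + 1L
    }
  }
  offsets <- integer(length(sequences))
  offsets[ord[1]] <- 0L
  add_seq(sequences[ord[1]], 0L)

  for (k in seq_along(ord)[-1]) {
    s <- sequences[ord[k]]
    L <- nchar(s)
    r <- strsplit(s, "")[[1]]
    o_min <- hi - max_len
    o_max <- lo - 1L + max_len - L
    best <- NULL
    for (o in seq(o_min, o_max)) {
      sc <- 0
      for (p in seq_len(L)) {
        cnt <- prof[, o + p + col0]
        sc <- sc + sum(cnt * B[r[p], ])
      }
      w <- max(hi, o + L) - min(lo, o + 1L) + 1L
      if (is.null(best) || sc > best$sc ||
        (sc == best$sc && (w < best$w || (w == best$w && o < best$o)))) {
        best <- list(sc = sc, w = w, o = o)
      }
    }
    offsets[ord[k]] <- best$o
    add_seq(s, best$o)
    lo <- min(lo, best$o + 1L)
    hi <- max(hi, best$o + nchar(s))
  }

  offsets <- offsets - (lo - 1L)
  width <- hi - lo + 1L
  aln <- tibble(id = ids, sequence = sequences, offset = offsets)
  structure(
    list(
      alignment = aln, width = width, matrix = matrix,
      seed_id = ids[ord[1]],
      score = alignment_score(sequences, offsets, B)
    ),
    class = "node_alignment"
  )
}

# sum-of-pairs substitution score over co-occupied columns; terminal gaps
# contribute nothing
alignment_score <- function(sequences, offsets, B) {
  chars <- map2(sequences, offsets, function(s, o) {
    r <- strsplit(s, "")[[1]]
    setNames(r, o + seq_along(r))
  })
  total <- 0
  n <- length(chars)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- intersect(names(chars[[i]]), names(chars[[j]]))
      if (length(shared) > 0) {
        total <- total + sum(B[cbind(chars[[i]][shared], chars[[j]][shared])])
      }
    }
  }
  total
}

#' @export
print.node_alignment <- function(x, ...) {
  cat(sprintf(
    "Offset alignment of %d sequences, width %d, %s sum-of-pairs score %.1f\n",
    nrow(x$alignment), x$width, x$matrix, x$score
  ))
  m <- as_alignment_matrix(x)
  for (i in seq_len(min(nrow(m), 12))) {
    cat(sprintf("  %-12s %s\n", x$alignment$id[i], paste(m[i, ], collapse = "")))
  }
  if (nrow(m) > 12) cat(sprintf("  ... and %d more\n", nrow(m) - 12))
  invisible(x)
}

#' Expand a node alignment into a character matrix
#'
#' Rows are sequences, columns alignment positions; positions outside a
#' sequence's span hold `"-"`.
#'
#' @param x A `node_alignment`.
#' @return Character matrix with sequence ids as row names.
#' @export
as_alignment_matrix <- function(x) {
  m <- matrix("-", nrow(x$alignment), x$width,
    dimnames = list(x$alignment$id, NULL)
  )
  for (i in seq_len(nrow(x$alignment))) {
    r <- strsplit(x$alignment$sequence[i], "")[[1]]
    m[i, x$alignment$offset[i] + seq_along(r)] <- r
  }
  m
}

#' Tidy a node alignment
#' @param x A `node_alignment`.
#' @param ... Unused.
#' @return Tibble `id`, `sequence`, `offset`, `length`.
#' @export
tidy.node_alignment <- function(x, ...) {
  mutate(x$alignment, length = nchar(.data$sequence))
}

#' One-row alignment summary
#' @param x A `node_alignment`.
#' @param ... Unused.
#' @return Tibble `n_sequences`, `width`, `score`, `matrix`.
#' @export
glance.node_alignment <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$alignment), width = x$width,
    score = x$score, matrix = x$matrix
  )
}

#' Write an alignment as FASTA-with-dashes or Clustal-like text
#' @param x A `node_alignment`.
#' @param path Output path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, format = c("fasta", "clustal")) {
  format <- arg_match(format)
  m <- as_alignment_matrix(x)
  rows <- apply(m, 1, paste, collapse = "")
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", names(rows)), rows)), path)
  } else {
    writeLines(
      c(
        "CLUSTAL-like offset alignment", "",
        sprintf("%-16s %s", names(rows), rows)
      ),
      path
    )
  }
  invisible(path)
}
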