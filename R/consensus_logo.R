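#' Default physicochemical residue groups
#'
#' Used when deciding whether residues that individually fail the positional
#' threshold pass it collectively: aliphatic, aromatic, basic, acidic,
#' polar-uncharged, cysteine, and conformationally special residues.
#'
#' @return Named list of character vectors.
#' @export
physicochemical_groups <- function() {
  list(
    aliphatic = c("A", "V", "L", "I", "M"),
    aromatic = c("F", "W", "Y"),
    basic = c("K", "R", "H"),
    acidic = c("D", "E"),
    polar = c("S", "T", "N", "Q"),
    cysteine = "C",
    special = c("G", "P")
  )
}

#' Amino Acid Positional Score and Positional Threshold Score
#'
#' The elementary score formulas underlying consensus calling:
#' `positional_score()` computes `S = (A_x / N_n) * E * W`, the share of a
#' column's occupancy-weighted information attributable to residue x, and
#' `positional_threshold()` computes `R = E - L`, the column's significance
#' threshold (information minus its lower 95% bound). A residue is called
#' significant when `S > R`.
#'
#' @param a_x Occurrences of the residue in the column.
#' @param n_n Total residues in the column (non-gap).
#' @param e Column information content in bits.
#' @param w Column occupancy weight `N_n / M`.
#' @param l Lower 95% bound of `e`.
#' @return A numeric scalar (vectorized over its arguments).
#' @export
#' @examples
#' positional_score(2, 4, 1.5, 0.5) # 0.375
#' positional_threshold(1.2, 0.9) # 0.3
positional_score <- function(a_x, n_n, e, w) {
  (a_x / n_n) * e * w
}

#' @rdname positional_score
#' @export
positional_threshold <- function(e, l) {
  e - l
}

# run code under a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# information content (bits) of a count vector with small-sample correction:
# E = max(0, log2(20) - H - e_n), e_n = 19 / (2 ln2 N)
column_information <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  h <- -sum(p * log2(p))
  e_n <- 19 / (2 * log(2) * n)
  max(0, log2(20) - h - e_n)
}

#' Per-column logo statistics of a node alignment
#'
#' For every alignment column computes the occupancy weight `W = N_n / M`
#' (fraction of sequences with a residue there), the information content
#' `E = max(0, log2(20) - H - e_n)` in bits, where `H` is the Shannon entropy
#' of the column's residue frequencies and `e_n = 19 / (2 ln2 N_n)` is the
#' small-sample correction compensating compositional bias at low counts, and
#' `L`, the lower bound of the 95% interval of `E`, estimated by a seeded
#' multinomial bootstrap (resampling `N_n` residues from the column
#' frequencies), floored at 0 and clamped to `E`. From these, every residue's
#' Amino Acid Positional Score `S = (A_x / N_n) * E * W` and the column's
#' Positional Threshold Score `R = E - L` are filled in, along with
#' significance flags: a residue is significant when `S > R`, and a
#' physicochemical group is significant when the summed `S` of its members
#' exceeds `R` while no member passes individually.
#'
#' All-gap columns are marked null.
#'
#' @param alignment A [align_node()] result or a character matrix with `"-"`
#'   for unoccupied positions.
#' @param bootstrap_reps Bootstrap resamples for `L` (default 200).
#' @param seed RNG seed for the bootstrap (default 1); fixed seed gives
#'   identical `L` and `R` across runs.
#' @param groups Physicochemical groups, see [physicochemical_groups()].
#' @return A `logo` object: list with `columns` (tibble `position`, `n_n`,
#'   `m`, `w`, `e`, `l`, `r`, `null`) and `residues` (tibble `position`,
#'   `residue`, `count`, `s`, `significant`, `group_only`, `shade`).
#' @export
logo_columns <- function(alignment, bootstrap_reps = 200L, seed = 1L,
                         groups = physicochemical_groups()) {
  m <- if (inherits(alignment, "node_alignment")) {
    as_alignment_matrix(alignment)
  } else {
    alignment
  }
  M <- nrow(m)
  if (M < 1) abort("alignment has no sequences")
  width <- ncol(m)

  cols <- vector("list", width)
  res <- vector("list", width)
  with_local_seed(seed, {
    for (pos in seq_len(width)) {
      residues <- m[, pos]
      residues <- residues[residues != "-"]
      counts <- table(factor(residues, levels = AA20))
      counts <- setNames(as.integer(counts), AA20)
      n_n <- sum(counts)
      if (n_n == 0) {
        cols[[pos]] <- tibble(
          position = pos, n_n = 0L, m = M, w = 0, e = NA_real_,
          l = NA_real_, r = NA_real_, null = TRUE
        )
        next
      }
      w <- n_n / M
      e <- column_information(counts)
      p <- counts / n_n
      boots <- rmultinom(bootstrap_reps, n_n, p)
      e_b <- apply(boots, 2, column_information)
      l <- max(0, unname(quantile(e_b, 0.025)))
      l <- min(l, e)
      r <- positional_threshold(e, l)
      s <- positional_score(counts, n_n, e, w)
      sig <- s > r
      grp_only <- rep(FALSE, 20)
      names(grp_only) <- AA20
      for (g in groups) {
        if (any(sig[g])) next
        present <- g[counts[g] > 0]
        if (length(present) > 0 && sum(s[g]) > r) grp_only[present] <- TRUE
      }
      cols[[pos]] <- tibble(
        position = pos, n_n = n_n, m = M, w = w, e = e, l = l, r = r,
        null = !any(sig) && !any(grp_only)
      )
      keep <- counts > 0
      res[[pos]] <- tibble(
        position = pos, residue = AA20[keep], count = counts[keep],
        s = unname(s[keep]), significant = unname(sig[keep]),
        group_only = unname(grp_only[keep]),
        shade = pmin(pmax(unname(s[keep]), 0.2), 1.0)
      )
    }
  })
  structure(
    list(columns = bind_rows(cols), residues = bind_rows(res)),
    class = "logo"
  )
}

#' @export
print.logo <- function(x, ...) {
  cat(sprintf(
    "Logo over %d columns (%d significant)\n",
    nrow(x$columns), sum(!x$columns$null)
  ))
  cat(" ", format(render_consensus(x, "full")), "\n")
  invisible(x)
}

#' Tidy logo statistics
#' @param x A `logo`.
#' @param ... Unused.
#' @return Residue-level tibble joined with the per-column statistics.
#' @export
tidy.logo <- function(x, ...) {
  left_join(x$residues, x$columns, by = "position")
}

#' One-row logo summary
#' @param x A `logo`.
#' @param ... Unused.
#' @return Tibble `width`, `n_significant_positions`, `max_s`, `total_information`.
#' @export
glance.logo <- function(x, ...) {
  tibble(
    width = nrow(x$columns),
    n_significant_positions = sum(!x$columns$null),
    max_s = if (nrow(x$residues)) max(x$residues$s) else NA_real_,
    total_information = sum(x$columns$e, na.rm = TRUE)
  )
}

#' Render a one-line consensus from logo statistics
#'
#' Three styles condense a logo into one line of text per node. `full`
#' renders every position: a dash where nothing passes the positional
#' threshold, a single letter for one significant residue, and a
#' `[XY]`-style class (residues ordered by decreasing `S`) where several
#' pass. Residues significant only through their physicochemical group are
#' written in lowercase; individually significant residues are uppercase
#' (the text stand-in for bold). `top4` keeps only the four
#' (position, residue) entries with the highest `S` among those passing the
#' threshold, written as `position:token` pairs; `top4_dashed` renders the
#' span from the first to the last retained position, dashing the
#' non-significant positions in between.
#'
#' @param logo A [logo_columns()] result.
#' @param style `"full"`, `"top4"` or `"top4_dashed"`.
#' @return A `consensus_line`: list with `text`, `style`, and `tokens`
#'   (tibble `position`, `residue`, `s`, `shade`, `bold`).
#' @export
render_consensus <- function(logo, style = c("full", "top4", "top4_dashed")) {
  style <- arg_match(style)
  sig <- filter(logo$residues, .data$significant | .data$group_only) %>%
    arrange(.data$position, dplyr::desc(.data$s))
  if (style %in% c("top4", "top4_dashed")) {
    sig <- head(arrange(sig, dplyr::desc(.data$s)), 4) %>%
      arrange(.data$position, dplyr::desc(.data$s))
  }
  token_at <- function(pos) {
    ent <- filter(sig, .data$position == pos)
    if (nrow(ent) == 0) {
      return("-")
    }
    letters_out <- ifelse(ent$significant, ent$residue, tolower(ent$residue))
    if (length(letters_out) == 1) letters_out else paste0("[", paste(letters_out, collapse = ""), "]")
  }
  width <- nrow(logo$columns)
  text <- switch(style,
    full = paste(map_chr(seq_len(width), token_at), collapse = ""),
    top4 = paste(
      map_chr(unique(sig$position), ~ sprintf("%d:%s", .x, token_at(.x))),
      collapse = " "
    ),
    top4_dashed = if (nrow(sig) == 0) {
      ""
    } else {
      span <- seq(min(sig$position), max(sig$position))
      paste(map_chr(span, token_at), collapse = "")
    }
  )
  structure(
    list(
      text = text, style = style,
      tokens = select(
        mutate(sig, bold = .data$significant),
        "position", "residue", "s", "shade", "bold"
      )
    ),
    class = "consensus_line"
  )
}

#' @export
format.consensus_line <- function(x, ...) x$text

#' @export
print.consensus_line <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Write WebLogo-style per-column statistics as TSV
#'
#' One row per column: position, the 20 residue counts, `n_n`, `e`, `l`,
#' `w`, `r`.
#'
#' @param logo A `logo`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_logo_table <- function(logo, path) {
  counts <- logo$residues %>%
    select("position", "residue", "count") %>%
    tidyr::pivot_wider(
      names_from = "residue", values_from = "count", values_fill = 0L
    )
  for (aa in setdiff(AA20, names(counts))) counts[[aa]] <- 0L
  out <- left_join(logo$columns, counts, by = "position") %>%
    mutate(across(all_of(AA20), ~ tidyr::replace_na(.x, 0L))) %>%
    select("position", all_of(AA20), "n_n", "e", "l", "w", "r")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Plot a sequence logo from positional scores
#'
#' Letters are stacked per column with heights equal to their Amino Acid
#' Positional Scores; letters passing the positional threshold individually
#' are solid, group-only letters are translucent.
#'
#' @param object A `logo`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logo <- function(object, ...) {
  df <- object$residues %>%
    arrange(.data$position, .data$s) %>%
    group_by(.data$position) %>%
    mutate(ymax = cumsum(.data$s), ymin = .data$ymax - .data$s) %>%
    ungroup() %>%
    filter(.data$s > 0)
  ggplot(df, aes(
    x = .data$position, y = (.data$ymin + .data$ymax) / 2,
    label = .data$residue
  )) +
    ggplot2::geom_text(aes(
      size = .data$s,
      alpha = ifelse(.data$significant, 1, 0.45)
    ), fontface = "bold") +
    ggplot2::scale_alpha_identity() +
    ggplot2::scale_size_continuous(range = c(2, 8), guide = "none") +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(object$columns))) +
    ggplot2::labs(x = "alignment position", y = "positional score S") +
    ggplot2::theme_minimal()
}
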