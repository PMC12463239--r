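# distance between two centroid vectors under the configured metric.
# Correlation distance is 1 - Pearson; zero-variance vectors are at distance 0
# from an identical vector and 1 from anything else.
centroid_distance <- function(x, y, metric) {
  if (metric == "euclidean") {
    return(sqrt(sum((x - y)^2)))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(if (isTRUE(all(x == y))) 0 else 1)
  }
  1 - cor(x, y)
}

#' Centroid-linkage hierarchical clustering of an Epitope Index matrix
#'
#' Agglomerative clustering of either the epitope rows or the cell-line
#' columns of an E_i matrix. The distance between two clusters is the metric
#' distance between their centroids (arithmetic mean vectors), recomputed from
#' the original rows at every step, so heights may be non-monotone - the
#' accepted behaviour of classic centroid linkage. Ties in the minimal
#' distance are broken deterministically by the lexicographically smallest
#' pair of cluster representatives (a cluster is represented by its smallest
#' member id).
#'
#' @param ei An [epitope_index()] matrix (or any numeric matrix with row and
#'   column names).
#' @param axis Cluster `"epitopes"` (rows) or `"cell_lines"` (columns).
#' @param metric `"correlation"` (1 - Pearson, the default: E_i profiles are
#'   compared by shape, not magnitude) or `"euclidean"`.
#' @return An `ei_dendrogram`: list with `leaves` (item ids in input order)
#'   and `merges`, a tibble of `a`, `b`, `height` in merge order using the
#'   usual agglomeration coding (negative values are leaf indices, positive
#'   values refer to earlier merges).
#' @export
cluster_ei <- function(ei, axis = c("epitopes", "cell_lines"),
                       metric = c("correlation", "euclidean")) {
  axis <- arg_match(axis)
  metric <- arg_match(metric)
  m <- unclass(ei)
  if (axis == "cell_lines") m <- t(m)
  if (nrow(m) < 2) abort(sprintf("need at least 2 %s to cluster", axis))
  leaves <- rownames(m)
  if (is.null(leaves)) leaves <- as.character(seq_len(nrow(m)))

  members <- as.list(seq_len(nrow(m))) # leaf indices per active cluster
  code <- -seq_len(nrow(m)) # agglomeration coding of each active cluster
  cents <- map(members, function(ix) colMeans(m[ix, , drop = FALSE]))
  reps <- map_chr(members, function(ix) min(leaves[ix]))
  k <- length(members)
  # pairwise centroid distances; only the merged cluster's row changes per step
  D <- matrix(Inf, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      D[i, j] <- D[j, i] <- centroid_distance(cents[[i]], cents[[j]], metric)
    }
  }
  ma <- integer(k - 1)
  mb <- integer(k - 1)
  mh <- numeric(k - 1)
  for (step in seq_len(k - 1)) {
    dmin <- min(D[upper.tri(D)])
    cand <- which(upper.tri(D) & D == dmin, arr.ind = TRUE)
    pr <- cbind(
      pmin(reps[cand[, 1]], reps[cand[, 2]]),
      pmax(reps[cand[, 1]], reps[cand[, 2]])
    )
    pick <- order(pr[, 1], pr[, 2])[1]
    i <- cand[pick, 1]
    j <- cand[pick, 2]
    ab <- c(code[i], code[j])[order(c(reps[i], reps[j]))]
    ma[step] <- ab[1]
    mb[step] <- ab[2]
    mh[step] <- dmin
    members[[i]] <- c(members[[i]], members[[j]])
    cents[[i]] <- colMeans(m[members[[i]], , drop = FALSE])
    reps[i] <- min(reps[i], reps[j])
    code[i] <- step
    members[[j]] <- NULL
    cents[[j]] <- NULL
    reps <- reps[-j]
    code <- code[-j]
    D <- D[-j, -j, drop = FALSE]
    if (length(members) > 1) {
      i2 <- if (j < i) i - 1L else i
      for (q in seq_along(members)) {
        if (q == i2) next
        D[i2, q] <- D[q, i2] <- centroid_distance(cents[[i2]], cents[[q]], metric)
      }
    }
  }
  structure(
    list(
      leaves = leaves, merges = tibble(a = ma, b = mb, height = mh),
      axis = axis, metric = metric
    ),
    class = "ei_dendrogram"
  )
}

#' @export
print.ei_dendrogram <- function(x, ...) {
  cat(sprintf(
    "Dendrogram over %d %s (%s metric, centroid linkage), %d merges\n",
    length(x$leaves), x$axis, x$metric, nrow(x$merges)
  ))
  invisible(x)
}

# leaf index set under merge vertex v (1-based merge index)
leafset_of <- function(dend, v) {
  expand <- function(code) {
    if (code < 0) {
      return(-code)
    }
    c(
      expand(dend$merges$a[code]),
      expand(dend$merges$b[code])
    )
  }
  expand(v)
}

#' Tidy a dendrogram into its merge table
#' @param x An `ei_dendrogram`.
#' @param ... Unused.
#' @return Tibble `merge`, `a`, `b`, `height`, `n_leaves` (leaves under the
#'   merged vertex).
#' @export
tidy.ei_dendrogram <- function(x, ...) {
  tibble(
    merge = seq_len(nrow(x$merges)),
    a = x$merges$a,
    b = x$merges$b,
    height = x$merges$height,
    n_leaves = map_int(seq_len(nrow(x$merges)), ~ length(leafset_of(x, .x)))
  )
}

#' Serialize a dendrogram to Newick format
#'
#' Branch lengths are differences between a vertex's merge height and its
#' child's; with centroid linkage these can occasionally be negative
#' (height inversions) and are written as computed.
#'
#' @param dend An `ei_dendrogram`.
#' @param path Optional path; when given the tree is written there.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(dend, path = NULL, digits = 8) {
  fmt <- function(code, parent_h) {
    if (code < 0) {
      lab <- gsub("[,:;()\\s]", "_", dend$leaves[-code])
      return(sprintf("%s:%.*g", lab, digits, parent_h))
    }
    h <- dend$merges$height[code]
    sprintf(
      "(%s,%s):%.*g",
      fmt(dend$merges$a[code], h), fmt(dend$merges$b[code], h),
      digits, parent_h - h
    )
  }
  root <- nrow(dend$merges)
  h <- dend$merges$height[root]
  nwk <- sprintf(
    "(%s,%s);",
    fmt(dend$merges$a[root], h), fmt(dend$merges$b[root], h)
  )
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Extract size-filtered epitope nodes from a dendrogram
#'
#' Every internal dendrogram vertex whose leaf count lies within
#' `[min_size, max_size]` yields one node; nested nodes are all retained.
#' The defaults follow the node quality filter used for motif analysis:
#' nodes with fewer than 9 or more than 100 epitopes align poorly and are
#' discarded.
#'
#' @param dend An `ei_dendrogram` over the epitope axis.
#' @param min_size,max_size Inclusive bounds on node membership.
#' @param ei Optional `ei_matrix` used to attach each node's mean E_i profile.
#' @return Tibble `node_id`, `n_members`, `members` (list of epitope ids),
#'   and `mean_profile` (list of named numeric vectors) when `ei` is given.
#' @export
extract_nodes <- function(dend, min_size = 9L, max_size = 100L, ei = NULL) {
  if (min_size > max_size) abort("min_size must not exceed max_size")
  sizes <- map_int(seq_len(nrow(dend$merges)), ~ length(leafset_of(dend, .x)))
  keep <- which(sizes >= min_size & sizes <= max_size)
  out <- tibble(
    node_id = sprintf("N%03d", keep),
    n_members = sizes[keep],
    members = map(keep, ~ sort(dend$leaves[leafset_of(dend, .x)]))
  )
  if (!is.null(ei)) {
    m <- unclass(ei)
    out$mean_profile <- map(out$members, function(ids) {
      colMeans(m[ids, , drop = FALSE])
    })
  }
  out
}

#' Write node membership as TSV
#' @param nodes Tibble from [extract_nodes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(nodes, path) {
  long <- tidyr::unnest(
    select(nodes, "node_id", "members"),
    cols = "members"
  ) %>%
    rename(epitope_id = "members")
  readr::write_tsv(long, path)
  invisible(path)
}

#' Plot a dendrogram
#' @param object An `ei_dendrogram`.
#' @param labels Draw leaf labels (default TRUE when <= 50 leaves).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ei_dendrogram <- function(object, labels = length(object$leaves) <= 50, ...) {
  n <- length(object$leaves)
  xpos <- numeric(n)
  segs <- list()
  counter <- 0
  build <- function(code) {
    if (code < 0) {
      counter <<- counter + 1
      xpos[-code] <<- counter
      return(c(counter, 0))
    }
    pa <- build(object$merges$a[code])
    pb <- build(object$merges$b[code])
    h <- object$merges$height[code]
    segs[[length(segs) + 1]] <<- tibble(
      x = c(pa[1], pa[1], pb[1]), xend = c(pa[1], pb[1], pb[1]),
      y = c(pa[2], h, h), yend = c(h, h, pb[2])
    )
    c(mean(c(pa[1], pb[1])), h)
  }
  build(nrow(object$merges))
  df <- bind_rows(segs)
  p <- ggplot(df) +
    ggplot2::geom_segment(aes(
      x = .data$x, xend = .data$xend,
      y = .data$y, yend = .data$yend
    )) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("%s distance (centroid linkage)", object$metric)
    ) +
    ggplot2::theme_minimal()
  if (labels) {
    lab <- tibble(x = xpos, label = object$leaves)
    p <- p + ggplot2::geom_text(
      data = lab, aes(x = .data$x, y = 0, label = .data$label),
      angle = 90, hjust = 1.1, size = 3
    ) +
      ggplot2::expand_limits(y = -0.2 * max(object$merges$height))
  }
  p
}
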