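# ---- brute-force centroid-linkage clustering ---------------------------------
# From-scratch agglomeration: at every step recomputes every centroid from the
# original matrix and every pairwise distance, then applies the same minimal
# distance / lexicographic representative-pair rule. Structured deliberately
# differently from the package implementation (no cached distance matrix).
oracle_distance <- function(x, y, metric) {
  if (metric == "euclidean") {
    return(sqrt(sum((x - y)^2)))
  }
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(if (all(x == y)) 0 else 1)
  }
  1 - stats::cor(x, y)
}

oracle_cluster <- function(m, metric = "correlation") {
  leaves <- rownames(m)
  clusters <- lapply(seq_len(nrow(m)), function(i) i)
  codes <- -seq_len(nrow(m))
  out <- data.frame(a = integer(), b = integer(), height = numeric())
  while (length(clusters) > 1) {
    k <- length(clusters)
    best_d <- Inf
    best <- NULL
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        ci <- colMeans(m[clusters[[i]], , drop = FALSE])
        cj <- colMeans(m[clusters[[j]], , drop = FALSE])
        d <- oracle_distance(ci, cj, metric)
        ri <- min(leaves[clusters[[i]]])
        rj <- min(leaves[clusters[[j]]])
        pair <- sort(c(ri, rj))
        if (d < best_d ||
          (d == best_d && (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best_d <- d
          best <- list(i = i, j = j, pair = pair, ri = ri, rj = rj)
        }
      }
    }
    ab <- c(codes[best$i], codes[best$j])[order(c(best$ri, best$rj))]
    out <- rbind(out, data.frame(a = ab[1], b = ab[2], height = best_d))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    codes[best$i] <- nrow(out)
    clusters[[best$j]] <- NULL
    codes <- codes[-best$j]
  }
  out
}

# ---- exhaustive offset-alignment search --------------------------------------
# Best sum-of-pairs score over ALL offset vectors with width <= max_len,
# normalized so the minimum offset is 0.
oracle_align_score <- function(sequences, max_len, B) {
  k <- length(sequences)
  lens <- nchar(sequences)
  ranges <- lapply(lens, function(L) 0:(max_len - L))
  grid <- expand.grid(ranges)
  grid <- grid[apply(grid, 1, min) == 0, , drop = FALSE]
  chars <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    offs <- as.integer(grid[r, ])
    sc <- 0
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        lo <- max(offs[i] + 1, offs[j] + 1)
        hi <- min(offs[i] + lens[i], offs[j] + lens[j])
        if (lo > hi) next
        ai <- chars[[i]][(lo:hi) - offs[i]]
        aj <- chars[[j]][(lo:hi) - offs[j]]
        sc <- sc + sum(B[cbind(ai, aj)])
      }
    }
    if (sc > best) best <- sc
  }
  best
}

# ---- exhaustive merge-order condensation search ------------------------------
# Explores every order of pairwise merges (using the same containment /
# end-overlap merge definition) and returns the set of terminal single
# sequences reachable.
oracle_overlap_merges <- function(u, v, min_overlap) {
  out <- character()
  if (grepl(v, u, fixed = TRUE)) out <- c(out, u)
  if (grepl(u, v, fixed = TRUE)) out <- c(out, v)
  kmax <- min(nchar(u), nchar(v))
  if (kmax >= min_overlap) {
    for (k in min_overlap:kmax) {
      if (substr(u, nchar(u) - k + 1, nchar(u)) == substr(v, 1, k)) {
        out <- c(out, paste0(u, substr(v, k + 1, nchar(v))))
      }
      if (substr(v, nchar(v) - k + 1, nchar(v)) == substr(u, 1, k)) {
        out <- c(out, paste0(v, substr(u, k + 1, nchar(u))))
      }
    }
  }
  unique(out)
}

oracle_condense <- function(seqs, min_overlap = 5) {
  memo <- new.env(parent = emptyenv())
  recurse <- function(pool) {
    key <- paste(sort(pool), collapse = "|")
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    if (length(pool) == 1) {
      memo[[key]] <- pool
      return(pool)
    }
    finals <- character()
    n <- length(pool)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        merges <- oracle_overlap_merges(pool[i], pool[j], min_overlap)
        for (mg in merges) {
          finals <- c(finals, recurse(c(pool[-c(i, j)], mg)))
        }
      }
    }
    finals <- unique(finals)
    memo[[key]] <- finals
    finals
  }
  recurse(unique(seqs))
}

# ---- brute-force allele traceability -----------------------------------------
# An allele is uniquely traceable iff its presence vector differs from every
# other allele's in at least one cell line (all-pairs comparison).
oracle_traceable <- function(profile_matrix) {
  n <- nrow(profile_matrix)
  unique_flag <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(profile_matrix[i, ] == profile_matrix[j, ])) {
        unique_flag[i] <- FALSE
      }
    }
  }
  sum(unique_flag)
}
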