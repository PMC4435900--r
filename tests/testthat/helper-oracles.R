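# Independent oracles used across the suite. Each reimplements the quantity
# under test from first principles, without touching the package internals.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_aa <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- Smith-Waterman with affine gaps: plain three-matrix DP ---------------
sw_oracle <- function(s1, s2, submat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)       # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1)    # gap in s2 (vertical)
  Y <- matrix(-Inf, n + 1, m + 1)    # gap in s1 (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# --- Pruning likelihood by exhaustive enumeration -------------------------
enum_likelihood <- function(tree, x, a, b, prior) {
  ti <- motiftrace:::tree_index(tree)
  n_tip <- ti$n_tip
  n_int <- ti$n_node
  n_all <- n_tip + n_int
  states <- integer(n_all)
  states[seq_len(n_tip)] <- x[ti$labels[seq_len(n_tip)]]
  ids <- (n_tip + 1L):n_all
  total <- 0
  marg <- matrix(0, n_all, 2)
  for (mask in 0:(2^n_int - 1)) {
    states[ids] <- as.integer(bitwAnd(mask, 2^(seq_len(n_int) - 1)) > 0)
    lik <- prior[states[ti$root] + 1]
    for (v in seq_len(n_all)) {
      if (v == ti$root) next
      P <- transition_matrix(a, b, ti$brlen[v])
      lik <- lik * P[states[ti$parent[v]] + 1, states[v] + 1]
    }
    total <- total + lik
    for (v in seq_len(n_all)) {
      marg[v, states[v] + 1] <- marg[v, states[v] + 1] + lik
    }
  }
  list(likelihood = total, marginals = marg / total,
       labels = ti$labels)
}

# random small tree with branch lengths, internal labels
rand_small_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$tip.label <- sprintf("t%02d", seq_len(n_leaves))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  make_node_labels(tr, overwrite = TRUE)
}

# --- brute-force tandem-repeat scanner ------------------------------------
brute_tandem <- function(seq, min_period, max_period, min_copies,
                         min_identity) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sat <- function(a, b, p) { # does [a,b] satisfy constraints for period p
    L <- b - a + 1
    if (L < min_copies * p || b > n) return(FALSE)
    idx <- a:(b - p)
    mean(ch[idx] == ch[idx + p]) >= min_identity
  }
  calls <- NULL
  for (p in min_period:max_period) {
    if (ceiling(min_copies * p) > n) break
    for (a in 1:n) for (b in a:n) {
      if (!sat(a, b, p)) next
      # maximal: no valid strict extension with the same period
      if (a > 1 && sat(a - 1, b, p)) next
      if (b < n && sat(a, b + 1, p)) next
      mc <- sum(ch[a:(b - p)] == ch[(a + p):b])
      calls <- rbind(calls, data.frame(start = a, end = b, period = p,
                                       matching_cols = mc))
    }
  }
  if (is.null(calls)) return(calls)
  # greedy overlap resolution: most matching columns, shorter period,
  # earlier start
  calls <- calls[order(-calls$matching_cols, calls$period, calls$start), ]
  kept <- calls[0, ]
  for (i in seq_len(nrow(calls))) {
    if (nrow(kept) == 0 ||
        all(calls$start[i] > kept$end | calls$end[i] < kept$start)) {
      kept <- rbind(kept, calls[i, ])
    }
  }
  kept[order(kept$start), ]
}

# --- brute-force orthology classification from raw score matrices ---------
# sm: scores A x B; wa, wb: within-genome score matrices (diag ignored).
brute_classify <- function(sm, wa, wb) {
  an <- rownames(sm); bn <- colnames(sm)
  best_in <- function(scores, names) {
    mx <- max(scores)
    sort(names[scores == mx])[1] # lexicographic tie-break
  }
  out <- NULL
  bestA <- vapply(an, function(p) best_in(sm[p, ], bn), "")
  bestB <- vapply(bn, function(p) best_in(sm[, p], an), "")
  add <- function(pa, pb, cls) {
    out <<- rbind(out, data.frame(protein_a = pa, protein_b = pb,
                                  class = cls, stringsAsFactors = FALSE))
  }
  for (pa in an) {
    pb <- bestA[[pa]]
    if (bestB[[pb]] == pa) {
      mwa <- if (is.null(wa)) -Inf else max(wa[pa, setdiff(an, pa)], -Inf)
      mwb <- if (is.null(wb)) -Inf else max(wb[pb, setdiff(bn, pb)], -Inf)
      cls <- if (mwa > sm[pa, pb] || mwb > sm[pa, pb]) "ortholog"
             else "one_to_one"
      add(pa, pb, cls)
    } else {
      add(pa, pb, "best_hit")
    }
  }
  for (pb in bn) {
    pa <- bestB[[pb]]
    if (bestA[[pa]] == pb) next
    add(pa, pb, "best_hit")
  }
  out[order(out$protein_a, out$protein_b), ]
}

# build a best_hits()-style table directly from a score matrix
hits_from_matrix <- function(sm, ga, gb) {
  rows <- list()
  push <- function(qg, q, sg, subj, sc, best) {
    rows[[length(rows) + 1]] <<- data.frame(
      qgenome = qg, query = q, sgenome = sg, subject = subj,
      score = sc, best = best, stringsAsFactors = FALSE)
  }
  for (pa in rownames(sm)) {
    sc <- sm[pa, ]
    mx <- max(sc)
    bsubj <- sort(colnames(sm)[sc == mx])[1]
    for (pb in colnames(sm)) push(ga, pa, gb, pb, sm[pa, pb], pb == bsubj)
  }
  for (pb in colnames(sm)) {
    sc <- sm[, pb]
    mx <- max(sc)
    bsubj <- sort(rownames(sm)[sc == mx])[1]
    for (pa in rownames(sm)) push(gb, pb, ga, pa, sm[pa, pb], pa == bsubj)
  }
  do.call(rbind, rows)
}

within_from_matrix <- function(wm, g) {
  idx <- which(row(wm) != col(wm), arr.ind = TRUE)
  data.frame(genome = g, query = rownames(wm)[idx[, 1]],
             subject = colnames(wm)[idx[, 2]], score = wm[idx],
             stringsAsFactors = FALSE)
}

# adjusted Rand index (mclust's implementation is the oracle of record in
# the acceptance suite; this fallback keeps unit tests self-contained)
ari <- function(x, y) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(x, y))
  }
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- b * c / choose(n, 2)
  (a - e) / ((b + c) / 2 - e)
}
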