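#' Transition probability matrix of the two-state gain/loss process
#'
#' Closed-form matrix exponential for the continuous-time Markov chain on
#' states {0 = absent, 1 = present} with gain rate `a` (0 -> 1) and loss
#' rate `b` (1 -> 0). With `s = a + b`:
#' \deqn{P_{00}(t) = (b + a e^{-st})/s, \quad P_{01}(t) = a(1 - e^{-st})/s,}
#' \deqn{P_{10}(t) = b(1 - e^{-st})/s, \quad P_{11}(t) = (a + b e^{-st})/s.}
#' The degenerate case `a = b = 0` is the identity for every `t`.
#'
#' @param a gain rate (>= 0).
#' @param b loss rate (>= 0).
#' @param t branch length (>= 0).
#' @return 2x2 matrix, rows = state at branch start (`"0"`, `"1"`), columns
#'   = state at branch end; rows sum to 1.
#' @examples
#' transition_matrix(1, 1, log(2))["0", "1"]  # 0.375
#' @export
transition_matrix <- function(a, b, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) stop("'t' must be >= 0")
  if (a < 0 || b < 0) stop("rates must be >= 0")
  s <- a + b
  if (s == 0) {
    p <- diag(2)
  } else {
    e <- exp(-s * t)
    p <- matrix(c((b + a * e) / s, b * (1 - e) / s,
                  a * (1 - e) / s, (a + b * e) / s),
                2L, 2L)
  }
  dimnames(p) <- list(c("0", "1"), c("0", "1"))
  p
}

# Resolve a root prior specification to c(P0, P1).
.root_prior <- function(root_prior, a, b) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != 2L || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-9) {
      stop("numeric 'root_prior' must be two nonnegative values summing to 1")
    }
    return(root_prior)
  }
  root_prior <- match.arg(root_prior, c("stationary", "flat"))
  if (root_prior == "flat" || a + b == 0) c(0.5, 0.5)
  else c(b, a) / (a + b)
}

# Coerce leaf states (named vector or leaves x characters matrix) to an
# integer matrix aligned with the tree's tip labels.
.leaf_state_matrix <- function(ti, leaf_states) {
  if (is.null(dim(leaf_states))) {
    leaf_states <- matrix(leaf_states, ncol = 1L,
                          dimnames = list(names(leaf_states), NULL))
  }
  if (is.null(rownames(leaf_states))) {
    stop("leaf states must be named by leaf label")
  }
  missing <- setdiff(ti$labels[seq_len(ti$n_tip)], rownames(leaf_states))
  if (length(missing)) {
    stop("missing states for leaves: ", paste(missing, collapse = ", "))
  }
  m <- leaf_states[ti$labels[seq_len(ti$n_tip)], , drop = FALSE]
  if (!all(m %in% c(0L, 1L))) stop("leaf states must be 0 or 1")
  storage.mode(m) <- "integer"
  m
}

# Felsenstein post-order pass, vectorized across characters.
# Returns per-node conditional likelihood matrices L0, L1 (all nodes x
# characters) and the per-character log scaling accumulated at internal
# nodes.
.pruning_pass <- function(ti, states, a, b) {
  n_all <- ti$n_tip + ti$n_node
  n_char <- ncol(states)
  L0 <- matrix(0, n_all, n_char)
  L1 <- matrix(0, n_all, n_char)
  tips <- seq_len(ti$n_tip)
  L0[tips, ] <- as.numeric(states == 0L)
  L1[tips, ] <- as.numeric(states == 1L)
  scale <- numeric(n_char)
  for (u in ti$postorder) {
    v <- ti$children[[u]]
    p1 <- transition_matrix(a, b, ti$brlen[v[1L]])
    p2 <- transition_matrix(a, b, ti$brlen[v[2L]])
    m1_0 <- p1[1L, 1L] * L0[v[1L], ] + p1[1L, 2L] * L1[v[1L], ]
    m1_1 <- p1[2L, 1L] * L0[v[1L], ] + p1[2L, 2L] * L1[v[1L], ]
    m2_0 <- p2[1L, 1L] * L0[v[2L], ] + p2[1L, 2L] * L1[v[2L], ]
    m2_1 <- p2[2L, 1L] * L0[v[2L], ] + p2[2L, 2L] * L1[v[2L], ]
    l0 <- m1_0 * m2_0
    l1 <- m1_1 * m2_1
    mx <- pmax(l0, l1)
    pos <- mx > 0
    l0[pos] <- l0[pos] / mx[pos]
    l1[pos] <- l1[pos] / mx[pos]
    scale <- scale + ifelse(pos, log(mx), -Inf)
    L0[u, ] <- l0
    L1[u, ] <- l1
  }
  list(L0 = L0, L1 = L1, scale = scale)
}

#' Log likelihood of leaf states under the two-state model
#'
#' Felsenstein pruning (post-order dynamic programming) with per-node
#' scaling. Accepts a single character (named 0/1 vector over leaves) or a
#' leaves x characters matrix, in which case one log likelihood per
#' character is returned.
#'
#' @param tree an [ape::phylo] with internal node labels.
#' @param leaf_states named 0/1 vector, or 0/1 matrix with leaf labels as
#'   row names.
#' @param a,b gain and loss rates.
#' @param root_prior `"stationary"` (default; `c(b, a)/(a + b)`), `"flat"`,
#'   or a numeric probability pair `c(P0, P1)`.
#' @return Numeric vector of log likelihoods (length = number of
#'   characters). Impossible configurations (e.g. `a = b = 0` with mixed
#'   leaf states) give `-Inf`.
#' @export
pruning_loglik <- function(tree, leaf_states, a, b,
                           root_prior = "stationary") {
  if (a < 0 || b < 0) stop("rates must be >= 0")
  ti <- tree_index(tree)
  states <- .leaf_state_matrix(ti, leaf_states)
  pr <- .root_prior(root_prior, a, b)
  pp <- .pruning_pass(ti, states, a, b)
  lik <- pr[1L] * pp$L0[ti$root, ] + pr[2L] * pp$L1[ti$root, ]
  out <- ifelse(lik > 0, log(lik) + pp$scale, -Inf)
  as.numeric(out)
}

#' Maximum-likelihood gain and loss rates
#'
#' Maximizes the pruning log likelihood over `(log a, log b)` with
#' box constraints `[1e-8, 1e3]` on each rate, starting L-BFGS-B from the
#' best points of a 5x5 log-spaced grid. When a matrix of characters is
#' supplied the rates are shared and per-character log likelihoods are
#' summed (a joint fit, used for simulation calibration); per-motif
#' analyses fit each character separately.
#'
#' @inheritParams pruning_loglik
#' @param n_starts how many of the best grid points to polish (>= 1).
#' @param fix_a,fix_b optionally pin a rate at a given value and profile
#'   the likelihood over the other (e.g. `fix_b = 1e-8` fits a
#'   near-irreversible gain model).
#' @return A list: `a`, `b`, `loglik`, `boundary` (TRUE when either rate
#'   ended within tolerance of a box bound, e.g. for invariant characters),
#'   `grid_loglik` (5x5 matrix of start-point log likelihoods; `NULL` when
#'   a rate is pinned).
#' @export
fit_rates <- function(tree, leaf_states, root_prior = "stationary",
                      n_starts = 3L, fix_a = NULL, fix_b = NULL) {
  ti <- tree_index(tree)
  states <- .leaf_state_matrix(ti, leaf_states)
  lo <- 1e-8
  hi <- 1e3
  nll <- function(par) {
    a <- exp(par[1L]); b <- exp(par[2L])
    pr <- .root_prior(root_prior, a, b)
    pp <- .pruning_pass(ti, states, a, b)
    lik <- pr[1L] * pp$L0[ti$root, ] + pr[2L] * pp$L1[ti$root, ]
    if (any(lik <= 0)) return(1e10)
    -sum(log(lik) + pp$scale)
  }
  if (!is.null(fix_a) || !is.null(fix_b)) {
    if (!is.null(fix_a) && !is.null(fix_b)) {
      return(list(a = fix_a, b = fix_b,
                  loglik = -nll(log(c(fix_a, fix_b))),
                  boundary = FALSE, grid_loglik = NULL))
    }
    free_nll <- if (is.null(fix_a)) {
      function(la) nll(c(la, log(fix_b)))
    } else {
      function(lb) nll(c(log(fix_a), lb))
    }
    o <- stats::optimize(free_nll, c(log(lo), log(hi)), tol = 1e-9)
    free_hat <- exp(o$minimum)
    a_hat <- if (is.null(fix_a)) free_hat else fix_a
    b_hat <- if (is.null(fix_b)) free_hat else fix_b
    return(list(a = a_hat, b = b_hat, loglik = -o$objective,
                boundary = free_hat <= lo * 1.01 || free_hat >= hi * 0.99,
                grid_loglik = NULL))
  }
  grid <- 10^seq(-3, 2, length.out = 5L)
  gl <- matrix(NA_real_, 5L, 5L, dimnames = list(a = grid, b = grid))
  for (i in 1:5) for (j in 1:5) {
    gl[i, j] <- -nll(log(c(grid[i], grid[j])))
  }
  ord <- order(gl, decreasing = TRUE)
  starts <- utils::head(ord, max(1L, n_starts))
  best <- NULL
  for (k in starts) {
    i <- (k - 1L) %% 5L + 1L
    j <- (k - 1L) %/% 5L + 1L
    fit <- stats::optim(log(c(grid[i], grid[j])), nll, method = "L-BFGS-B",
                        lower = log(lo), upper = log(hi),
                        control = list(factr = 1e4, maxit = 500L))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  a_hat <- exp(best$par[1L])
  b_hat <- exp(best$par[2L])
  list(
    a = a_hat, b = b_hat, loglik = -best$value,
    boundary = a_hat <= lo * 1.01 || a_hat >= hi * 0.99 ||
      b_hat <= lo * 1.01 || b_hat >= hi * 0.99,
    grid_loglik = gl
  )
}

#' Marginal ancestral state probabilities
#'
#' Exact per-node posterior probabilities of absence/presence given all leaf
#' states, computed by combining the post-order (pruning) pass with a
#' pre-order "outside" pass. Leaf marginals are degenerate on the observed
#' states; every row sums to 1.
#'
#' @inheritParams pruning_loglik
#' @param leaf_states named 0/1 vector over the leaves (single character).
#' @return Matrix (all nodes x 2), columns `P0`, `P1`, row names = tip then
#'   internal node labels.
#' @export
marginal_ancestral <- function(tree, leaf_states, a, b,
                               root_prior = "stationary") {
  if (a < 0 || b < 0) stop("rates must be >= 0")
  ti <- tree_index(tree)
  states <- .leaf_state_matrix(ti, leaf_states)
  if (ncol(states) != 1L) stop("one character at a time")
  pr <- .root_prior(root_prior, a, b)
  pp <- .pruning_pass(ti, states, a, b)
  n_all <- ti$n_tip + ti$n_node
  L <- cbind(pp$L0[, 1L], pp$L1[, 1L])
  G <- matrix(0, n_all, 2L)
  G[ti$root, ] <- pr
  for (u in rev(ti$postorder)) {
    v <- ti$children[[u]]
    for (k in 1:2) {
      w <- v[3L - k]
      pv <- transition_matrix(a, b, ti$brlen[v[k]])
      pw <- transition_matrix(a, b, ti$brlen[w])
      sib <- as.numeric(pw %*% L[w, ]) # message from sibling, per parent state
      h <- G[u, ] * sib
      g <- as.numeric(t(pv) %*% h)
      tot <- sum(g)
      G[v[k], ] <- if (tot > 0) g / tot else c(0.5, 0.5)
    }
  }
  post <- G * L
  tot <- rowSums(post)
  bad <- tot <= 0
  post[!bad, ] <- post[!bad, , drop = FALSE] / tot[!bad]
  post[bad, ] <- NA_real_
  dimnames(post) <- list(ti$labels, c("P0", "P1"))
  post
}

#' Infer gain and loss events from node marginals
#'
#' A node is called present when its marginal presence probability reaches
#' `tau` and absent when it is at most `1 - tau`. A gain event is a
#' presence onset: a present node whose parent is below `tau` (the root
#' counts when the root prior favours absence); each maximal present
#' subtree therefore contributes one gain at its stem. Losses are the
#' symmetric absence onsets inside present subtrees. The acquisition call
#' is `"once"` for exactly one gain, `"multiple"` for two or more,
#' `"ancestral"` for a present root with no other gain, `"absent"` when no
#' node is called present, and `"uncertain"` when only leaves are called
#' (no internal signal). The scaled likelihood of gain — the confidence
#' number reported per motif — is the largest marginal presence
#' probability among gain nodes (the root marginal for ancestral motifs).
#'
#' @param tree an [ape::phylo] with internal node labels.
#' @param marginals output of [marginal_ancestral()].
#' @param tau confidence threshold in (0.5, 1).
#' @param root_prior_p1 prior presence probability at the root used for the
#'   root gain/loss rule, or `NULL` to skip root events.
#' @return A list: `events` (data.frame `type`, `node`, `parent`, `p_node`,
#'   `p_parent`), `n_gains`, `n_losses`, `call`, `scaled_likelihood`.
#' @export
infer_gains <- function(tree, marginals, tau = 0.92, root_prior_p1 = NULL) {
  if (!is.numeric(tau) || tau <= 0.5 || tau >= 1) {
    stop("'tau' must lie in (0.5, 1)")
  }
  ti <- tree_index(tree)
  p1 <- marginals[ti$labels, "P1"]
  present <- p1 >= tau
  absent <- p1 <= 1 - tau
  type <- character(0); node <- character(0); par_lab <- character(0)
  p_node <- numeric(0); p_parent <- numeric(0)
  add <- function(ty, v, pl, pp) {
    type <<- c(type, ty); node <<- c(node, ti$labels[v])
    par_lab <<- c(par_lab, pl); p_node <<- c(p_node, p1[v])
    p_parent <<- c(p_parent, pp)
  }
  for (v in seq_along(p1)) {
    if (v == ti$root) {
      if (is.null(root_prior_p1)) next
      if (present[v] && root_prior_p1 < 0.5) {
        add("gain", v, NA_character_, root_prior_p1)
      } else if (absent[v] && root_prior_p1 > 0.5) {
        add("loss", v, NA_character_, root_prior_p1)
      }
      next
    }
    u <- ti$parent[v]
    if (present[v] && !present[u]) add("gain", v, ti$labels[u], p1[u])
    if (absent[v] && !absent[u]) add("loss", v, ti$labels[u], p1[u])
  }
  events <- data.frame(type = type, node = node, parent = par_lab,
                       p_node = p_node, p_parent = p_parent,
                       stringsAsFactors = FALSE)
  n_gains <- sum(events$type == "gain")
  # losses are only meaningful below an established presence: keep absence
  # onsets whose parent is called present
  keep_loss <- events$type == "loss" &
    (is.na(events$parent) | events$p_parent >= tau)
  events <- events[events$type == "gain" | keep_loss, , drop = FALSE]
  n_losses <- sum(events$type == "loss")
  acq <- if (n_gains >= 2L) {
    "multiple"
  } else if (n_gains == 1L) {
    if (present[ti$root] && is.null(root_prior_p1)) "ancestral" else "once"
  } else if (present[ti$root]) {
    "ancestral"
  } else if (!any(present)) {
    "absent"
  } else {
    "uncertain" # presence only at leaves, no supported onset
  }
  sl <- if (n_gains > 0) {
    max(events$p_node[events$type == "gain"])
  } else if (acq == "ancestral") {
    p1[ti$root]
  } else {
    NA_real_
  }
  list(events = events, n_gains = n_gains, n_losses = n_losses,
       call = acq, scaled_likelihood = unname(sl))
}

#' Per-motif gain/loss report
#'
#' Runs the full ancestral workflow for every row of a presence/absence
#' matrix: fit gain/loss rates by maximum likelihood, compute marginal node
#' probabilities, and infer gain and loss events at confidence `tau`.
#'
#' @param tree an [ape::phylo] with internal node labels.
#' @param pm binary matrix, motifs x species; column names must match the
#'   tree's leaf labels.
#' @param tau confidence threshold for hard calls (default 0.92).
#' @param root_prior root prior passed to the likelihood machinery.
#' @return A list with `report` (data.frame: motif, a, b, loglik, n_gains,
#'   n_losses, gain_nodes, scaled_likelihood, call, boundary) and
#'   `marginals` (named list of per-motif marginal matrices).
#' @export
gain_report <- function(tree, pm, tau = 0.92, root_prior = "stationary") {
  ti <- tree_index(tree)
  leaves <- ti$labels[seq_len(ti$n_tip)]
  missing <- setdiff(leaves, colnames(pm))
  if (length(missing)) {
    stop("presence matrix lacks species present in the tree: ",
         paste(missing, collapse = ", "))
  }
  rows <- vector("list", nrow(pm))
  margs <- vector("list", nrow(pm))
  for (i in seq_len(nrow(pm))) {
    x <- stats::setNames(as.integer(pm[i, leaves]), leaves)
    fit <- fit_rates(tree, x, root_prior = root_prior)
    mar <- marginal_ancestral(tree, x, fit$a, fit$b, root_prior = root_prior)
    prior_p1 <- .root_prior(root_prior, fit$a, fit$b)[2L]
    ig <- infer_gains(tree, mar, tau = tau, root_prior_p1 = prior_p1)
    gains <- ig$events$node[ig$events$type == "gain"]
    rows[[i]] <- data.frame(
      motif = rownames(pm)[i],
      a = fit$a, b = fit$b, loglik = fit$loglik,
      n_gains = ig$n_gains, n_losses = ig$n_losses,
      gain_nodes = paste(gains, collapse = ","),
      scaled_likelihood = ig$scaled_likelihood,
      call = ig$call, boundary = fit$boundary,
      stringsAsFactors = FALSE
    )
    margs[[i]] <- mar
  }
  names(margs) <- rownames(pm)
  list(report = do.call(rbind, rows), marginals = margs)
}
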