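# Two-state CTMC machinery: transition probabilities, pruning likelihood,
# rate fitting, marginal reconstruction, gain/loss inference.

test_that("transition matrices match closed forms and the Markov property", {
  expect_equal(transition_matrix(0.7, 0.3, 0), diag(2),
               ignore_attr = TRUE)
  P <- transition_matrix(1, 1, log(2))
  expect_equal(P["0", "1"], 0.375, tolerance = 1e-12)
  expect_equal(P["0", "0"], 0.625, tolerance = 1e-12)
  expect_equal(transition_matrix(0, 0, 5), diag(2), ignore_attr = TRUE)
  set.seed(1)
  for (i in 1:50) {
    a <- stats::runif(1, 0, 3); b <- stats::runif(1, 0, 3)
    t1 <- stats::runif(1, 0, 2); t2 <- stats::runif(1, 0, 2)
    P1 <- transition_matrix(a, b, t1)
    P2 <- transition_matrix(a, b, t2)
    P12 <- transition_matrix(a, b, t1 + t2)
    expect_true(all(abs(rowSums(P1) - 1) < 1e-12))
    expect_true(all(abs(P1 %*% P2 - P12) < 1e-10)) # Chapman-Kolmogorov
    # stationary limit
    Pinf <- transition_matrix(a, b, 50 / (a + b))
    expect_true(all(abs(Pinf[, "1"] - a / (a + b)) < 1e-12))
  }
  expect_error(transition_matrix(1, 1, -1), "t")
})

test_that("the two-leaf likelihood equals its closed form", {
  t2 <- ape::read.tree(text = sprintf("(A:%.12f,B:%.12f)r;",
                                      log(2), log(2)))
  ll <- pruning_loglik(t2, c(A = 1, B = 1), 1, 1, root_prior = "flat")
  expect_equal(exp(ll), 0.265625, tolerance = 1e-12)
})

test_that("impossible configurations yield -Inf", {
  t2 <- ape::read.tree(text = "(A:1,B:1)r;")
  ll <- pruning_loglik(t2, c(A = 1, B = 0), 0, 0, root_prior = "flat")
  expect_equal(ll, -Inf)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    tr <- rand_small_tree(n)
    x <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    a <- stats::runif(1, 0.05, 2)
    b <- stats::runif(1, 0.05, 2)
    prior <- c(b, a) / (a + b)
    want <- enum_likelihood(tr, x, a, b, prior)
    got <- pruning_loglik(tr, x, a, b, root_prior = "stationary")
    expect_lt(abs(got - log(want$likelihood)), 1e-8)
  }
})

test_that("pruning is invariant under child reordering", {
  set.seed(12)
  tr <- rand_small_tree(6)
  x <- stats::setNames(sample(0:1, 6, replace = TRUE), tr$tip.label)
  ll1 <- pruning_loglik(tr, x, 0.8, 0.4)
  # swap the two children of every internal node
  tr2 <- tr
  for (u in unique(tr2$edge[, 1])) {
    rows <- which(tr2$edge[, 1] == u)
    tr2$edge[rows, ] <- tr2$edge[rev(rows), ]
    tr2$edge.length[rows] <- tr2$edge.length[rev(rows)]
  }
  ll2 <- pruning_loglik(tr2, x, 0.8, 0.4)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("marginals equal the enumeration oracle and sum to one", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    tr <- rand_small_tree(n)
    x <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    a <- stats::runif(1, 0.05, 2)
    b <- stats::runif(1, 0.05, 2)
    prior <- c(b, a) / (a + b)
    want <- enum_likelihood(tr, x, a, b, prior)
    got <- marginal_ancestral(tr, x, a, b, root_prior = "stationary")
    expect_lt(max(abs(got[want$labels, ] - want$marginals)), 1e-10)
    expect_true(all(abs(rowSums(got) - 1) < 1e-9))
    # leaf marginals are degenerate on the observation
    expect_equal(unname(got[names(x), "P1"]), unname(x))
  }
})

test_that("symmetric discordant leaves give an even root marginal", {
  t2 <- ape::read.tree(text = "(A:0.7,B:0.7)r;")
  m <- marginal_ancestral(t2, c(A = 1, B = 0), 1, 1, root_prior = "flat")
  expect_equal(unname(m["r", ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("without loss, presence probability grows toward present leaves", {
  tr <- sample_tree(8, seed = 31)
  x <- stats::setNames(rep(1L, 8), tr$tip.label)
  m <- marginal_ancestral(tr, x, a = 0.5, b = 0, root_prior = "flat")
  ti <- motiftrace:::tree_index(tr)
  for (v in seq_len(ti$n_tip + ti$n_node)) {
    if (v == ti$root) next
    expect_gte(m[ti$labels[v], "P1"] + 1e-12,
               m[ti$labels[ti$parent[v]], "P1"])
  }
})

test_that("rate fitting beats its grid starts and flags boundaries", {
  tr <- sample_tree(16, seed = 41)
  sim <- simulate_binary_character(tr, 0.6, 0.3, 0, seed = 42, n_char = 5)
  x <- sim$leaf_states[, 1]
  expect_gt(length(unique(x)), 1) # seed chosen to give a variable character
  fit <- fit_rates(tr, x)
  expect_gte(fit$loglik + 1e-6, max(fit$grid_loglik))
  # invariant character: boundary MLE, flagged, no exception
  x0 <- stats::setNames(rep(0L, 16), tr$tip.label)
  fit0 <- fit_rates(tr, x0)
  expect_true(fit0$boundary)
  expect_lte(fit0$a, 1e-6 * 1e3)
})

test_that("rate estimates agree with an independent ML implementation", {
  tr <- sample_tree(24, seed = 3)
  sim <- simulate_binary_character(tr, 0.6, 0.3, 0, seed = 4)
  x <- sim$leaf_states[, 1]
  expect_gt(length(unique(x)), 1)
  fit <- fit_rates(tr, x, root_prior = "flat")
  a <- ape::ace(x[tr$tip.label], tr, type = "discrete", model = "ARD")
  # ace's index matrix: rates[1] = 1->0, rates[2] = 0->1; its loglik omits
  # the flat root prior factor 1/2
  expect_equal(fit$a, a$rates[2], tolerance = 1e-3)
  expect_equal(fit$b, a$rates[1], tolerance = 1e-3)
  expect_equal(fit$loglik, a$loglik - log(2), tolerance = 1e-5)
  m <- marginal_ancestral(tr, x, fit$a, fit$b, root_prior = "flat")
  root_lab <- tr$node.label[1]
  expect_equal(unname(m[root_lab, "P1"]),
               unname(a$lik.anc[1, 2]), tolerance = 1e-4)
})

test_that("profile fitting with a pinned rate works", {
  tr <- sample_tree(16, seed = 44)
  sim <- simulate_binary_character(tr, 0.3, 0, 0, seed = 45)
  x <- sim$leaf_states[, 1]
  expect_gt(length(unique(x)), 1)
  fit <- fit_rates(tr, x, fix_b = 1e-8)
  expect_equal(fit$b, 1e-8)
  expect_gt(fit$a, 0)
  # pinned fit can never beat the free optimum
  free <- fit_rates(tr, x)
  expect_lte(fit$loglik, free$loglik + 1e-6)
})

test_that("joint rate recovery sharpens with more characters", {
  tr <- sample_tree(32, seed = 51)
  set.seed(52)
  err <- function(n_char) {
    sim <- simulate_binary_character(tr, 0.5, 0.2, 0,
                                     seed = sample.int(1e8, 1),
                                     n_char = n_char)
    fit <- fit_rates(tr, sim$leaf_states)
    c(fit$a - 0.5, fit$b - 0.2)
  }
  e_small <- t(vapply(1:8, function(i) err(20), numeric(2)))
  e_large <- t(vapply(1:8, function(i) err(200), numeric(2)))
  expect_lt(sqrt(mean(e_large^2)), sqrt(mean(e_small^2)))
})

test_that("gain inference classifies hand-built marginal patterns", {
  tr <- sample_tree(8, seed = 61)
  ti <- motiftrace:::tree_index(tr)
  mk <- function(p1) {
    m <- cbind(P0 = 1 - p1, P1 = p1)
    rownames(m) <- ti$labels
    m
  }
  # everything absent
  ig0 <- infer_gains(tr, mk(rep(0.01, 15)), 0.92, root_prior_p1 = 0.2)
  expect_equal(ig0$n_gains, 0)
  expect_equal(ig0$call, "absent")
  # everything present with a presence-favouring prior: ancestral
  ig1 <- infer_gains(tr, mk(rep(0.99, 15)), 0.92, root_prior_p1 = 0.8)
  expect_equal(ig1$call, "ancestral")
  expect_equal(ig1$scaled_likelihood, 0.99)
  # presence confined to one clade: single gain at its stem
  v <- which(ti$labels == "n003")
  below <- c(v)
  repeat {
    kids <- unlist(ti$children[below])
    if (!length(setdiff(kids, below))) break
    below <- union(below, kids)
  }
  p1 <- rep(0.02, 15)
  p1[below] <- 0.98
  ig2 <- infer_gains(tr, mk(p1), 0.92, root_prior_p1 = 0.2)
  expect_equal(ig2$call, "once")
  expect_equal(ig2$events$node[ig2$events$type == "gain"], "n003")
  expect_equal(ig2$scaled_likelihood, 0.98)
  # two separated present leaves: multiple
  p2 <- rep(0.02, 15)
  p2[c(1, ti$n_tip)] <- 1
  ig3 <- infer_gains(tr, mk(p2), 0.92, root_prior_p1 = 0.2)
  expect_equal(ig3$call, "multiple")
  expect_equal(ig3$n_gains, 2)
  expect_error(infer_gains(tr, mk(p1), 0.4), "tau")
})

test_that("gain_report handles invariant, clade and ancestral motifs", {
  tr <- sample_tree(12, seed = 71)
  ti <- motiftrace:::tree_index(tr)
  leaves <- tr$tip.label
  pm <- rbind(
    all0 = rep(0L, 12),
    all1 = rep(1L, 12)
  )
  colnames(pm) <- leaves
  gr <- gain_report(tr, pm, tau = 0.92)
  expect_equal(gr$report$call[gr$report$motif == "all0"], "absent")
  expect_equal(gr$report$call[gr$report$motif == "all1"], "ancestral")
  expect_true(all(abs(rowSums(gr$marginals[["all1"]]) - 1) < 1e-9))
  expect_error(gain_report(tr, pm[, 1:5]), "lacks")
})
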