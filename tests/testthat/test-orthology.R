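# Smith-Waterman scoring and the best-hit / ortholog / one-to-one rules.

test_that("local alignment scores match worked examples and stay symmetric", {
  expect_equal(local_align_score("ACDE", "ACDE"), 24) # 4 + 9 + 6 + 5
  expect_equal(local_align_score("W", "P"), 0)        # local floor
  s1 <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  s2 <- "MKTAYIAKQRNISFVKSHFSRQLEERLGLIEVQA"
  expect_equal(local_align_score(s1, s2), local_align_score(s2, s1))
  expect_error(local_align_score("", "AC"), "nonempty")
})

test_that("scores equal an independent affine-gap DP on random sequences", {
  submat <- motiftrace:::.resolve_submat("BLOSUM62")
  set.seed(7)
  for (i in 1:60) {
    s1 <- rand_aa(50)
    s2 <- rand_aa(50)
    expect_equal(local_align_score(s1, s2), sw_oracle(s1, s2, submat))
  }
})

test_that("best hits pick the top subject with lexicographic tie-break", {
  pa <- c(a1 = "MKTAYIAKQR")
  pb <- c(b2 = "MKTAYIAKQR", b1 = "MKTAYIAKQR") # equal scores
  h <- best_hits(pa, pb, "gA", "gB")
  best <- h[h$qgenome == "gA" & h$best, ]
  expect_equal(best$subject, "b1")

  pb2 <- c(b1 = "MKTAYIAKQR", b2 = "MKTAYIAKAA")
  h2 <- best_hits(pa, pb2, "gA", "gB")
  expect_equal(h2$subject[h2$qgenome == "gA" & h2$best], "b1")
  expect_warning(best_hits(character(0), pb, "gA", "gB"), "empty")
  expect_error(best_hits(pa, pb, "g", "g"), "distinct")
})

test_that("pair classification applies the quoted rules", {
  # single mutually-best pair, no paralogs -> one_to_one
  pa <- c(a1 = "MKTAYIAKQRQISFVK")
  pb <- c(b1 = "MKTAYIAKQRQISFVR")
  h <- best_hits(pa, pb, "gA", "gB")
  cp <- classify_pairs(h, within_hits(pa, "gA"), within_hits(pb, "gB"))
  expect_equal(cp$class, "one_to_one")

  # a higher-scoring within-genome paralog downgrades to ortholog
  pa2 <- c(a1 = "MKTAYIAKQRQISFVK", a2 = "MKTAYIAKQRQISFVK")
  h2 <- best_hits(pa2, pb, "gA", "gB")
  cp2 <- classify_pairs(h2, within_hits(pa2, "gA"), within_hits(pb, "gB"))
  row <- cp2[cp2$protein_a == "a1" & cp2$protein_b == "b1", ]
  expect_equal(row$class, "ortholog")

  # non-reciprocal best hits stay best_hit
  pa3 <- c(a1 = "MKTAYIAKQR")
  pb3 <- c(b1 = "MKTAYIAKQRQQQQQQ", b2 = "MKTAYIAKQRAAAAAA")
  sm <- matrix(c(50, 40), 1, dimnames = list("a1", c("b1", "b2")))
  wm <- NULL
  bf <- brute_classify(sm, NULL, NULL)
  expect_true(all(bf$class %in% c("best_hit", "ortholog", "one_to_one")))
})

test_that("classification equals brute force on random score tables", {
  set.seed(31)
  for (rep in 1:200) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    sm <- matrix(sample(1:60, na * nb, replace = TRUE), na, nb,
                 dimnames = list(sprintf("a%d", 1:na),
                                 sprintf("b%d", 1:nb)))
    wa <- if (na > 1) {
      m <- matrix(sample(1:60, na * na, replace = TRUE), na, na,
                  dimnames = list(rownames(sm), rownames(sm)))
      m
    } else NULL
    wb <- if (nb > 1) {
      m <- matrix(sample(1:60, nb * nb, replace = TRUE), nb, nb,
                  dimnames = list(colnames(sm), colnames(sm)))
      m
    } else NULL
    hits <- hits_from_matrix(sm, "A", "B")
    got <- classify_pairs(hits,
                          if (is.null(wa)) NULL else within_from_matrix(wa, "A"),
                          if (is.null(wb)) NULL else within_from_matrix(wb, "B"))
    got <- got[order(got$protein_a, got$protein_b),
               c("protein_a", "protein_b", "class")]
    want <- brute_classify(sm, wa, wb)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("classification is invariant under genome relabelling", {
  set.seed(5)
  pa <- c(p1 = rand_aa(40), p2 = rand_aa(40))
  pb <- c(q1 = rand_aa(40), q2 = rand_aa(40))
  h_ab <- best_hits(pa, pb, "gA", "gB")
  h_ba <- best_hits(pb, pa, "gB", "gA")
  c1 <- classify_pairs(h_ab, within_hits(pa, "gA"), within_hits(pb, "gB"))
  c2 <- classify_pairs(h_ba, within_hits(pb, "gB"), within_hits(pa, "gA"))
  k1 <- sort(paste(c1$protein_a, c1$protein_b, c1$class))
  k2 <- sort(paste(c2$protein_b, c2$protein_a, c2$class))
  expect_equal(k1, k2)
})

test_that("one-to-one pairs recover the simulator's ortholog map", {
  p <- evol_params(n_taxa = 6, n_decoys = 2, id_substitution_rate = 1)
  ds <- simulate_dataset(p, seed = 61)
  pairs <- orthology_all(ds$proteomes)
  o2o <- pairs[pairs$class == "one_to_one", ]
  # truth: every cross-genome pair of proteins with the same id
  expect_true(all(o2o$protein_a == o2o$protein_b))
  genomes <- names(ds$proteomes)
  prots <- names(ds$proteomes[[1]])
  want_n <- length(prots) * choose(length(genomes), 2)
  expect_equal(nrow(o2o), want_n)
  # class hierarchy: one_to_one and ortholog are reciprocal-best pairs
  expect_true(all(pairs$class %in% c("best_hit", "ortholog", "one_to_one")))
})

test_that("the orthology graph has the expected edges", {
  cp <- data.frame(genome_a = "A", protein_a = c("p", "q"),
                   genome_b = "B", protein_b = c("p", "q"),
                   score = c(10, 20), class = c("one_to_one", "best_hit"),
                   stringsAsFactors = FALSE)
  g <- build_graph(cp, "one_to_one")
  expect_equal(igraph::ecount(g), 1)
  g2 <- build_graph(cp[cp$class == "best_hit", ], "one_to_one",
                    vertices = c("A|p", "B|p"))
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 4)
})
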