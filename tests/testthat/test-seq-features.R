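# Composition bias, tandem repeats, hydrophobic moment, disorder heuristic,
# pattern scan and noncatalytic extraction.

uniform_bg <- stats::setNames(rep(0.05, 20), AA)

test_that("composition-bias probabilities are exact binomial tails", {
  s <- paste0(strrep("G", 40), strrep("R", 30), strrep("G", 40))
  res <- lps_scan(s, uniform_bg, p_max = 1e-15, min_len = 10)
  rseg <- res[res$signature == "R", ]
  expect_equal(nrow(rseg), 1)
  expect_equal(rseg$start, 41)
  expect_equal(rseg$end, 70)
  # pure run: P(X >= n) = p^n
  expect_equal(rseg$log10_p, 30 * log10(0.05), tolerance = 1e-12)
  expect_equal(rseg$p_value, 0.05^30, tolerance = 1e-12)

  # every reported probability equals an independent tail summation
  set.seed(8)
  s2 <- paste0(rand_aa(60), strrep("Q", 35), rand_aa(60))
  res2 <- lps_scan(s2, uniform_bg, p_max = 1e-10, min_len = 10)
  for (i in seq_len(nrow(res2))) {
    ch <- strsplit(s2, "")[[1]][res2$start[i]:res2$end[i]]
    k <- sum(ch == res2$signature[i])
    n <- length(ch)
    tail_log <- matrixStats_logsum <- log(sum(exp(
      stats::dbinom(k:n, n, 0.05, log = TRUE))))
    expect_equal(res2$log10_p[i], tail_log / log(10), tolerance = 1e-9)
  }
})

test_that("weak enrichment is not flagged at the stringent threshold", {
  bg <- uniform_bg
  bg["R"] <- 0.214
  bg <- bg / sum(bg)
  res <- lps_scan(strrep("R", 5), bg, p_max = 1e-15, min_len = 5)
  expect_equal(nrow(res), 0)
  # direct check of the 0.214^5 example value
  expect_equal(0.214^5, 4.49e-4, tolerance = 1e-2)
})

test_that("i.i.d. background sequences are almost never flagged", {
  set.seed(10)
  n_hit <- 0
  for (i in 1:200) {
    s <- rand_aa(300)
    if (nrow(lps_scan(s, uniform_bg, p_max = 1e-15, min_len = 10)) > 0) {
      n_hit <- n_hit + 1
    }
  }
  expect_equal(n_hit, 0)
})

test_that("composition profiles cluster into their generating groups", {
  rnq <- uniform_bg
  rnq[c("R", "N", "Q")] <- c(0.214, 0.101, 0.091)
  rnq <- rnq / sum(rnq)
  aepv <- uniform_bg
  aepv[c("A", "E", "P", "V")] <- c(0.208, 0.138, 0.106, 0.127)
  aepv <- aepv / sum(aepv)
  set.seed(12)
  prof <- t(vapply(1:40, function(i) {
    p <- if (i <= 20) rnq else aepv
    ch <- sample(AA, 400, replace = TRUE, prob = p)
    as.numeric(table(factor(ch, levels = AA))) / 400
  }, numeric(20)))
  colnames(prof) <- AA
  res <- cluster_cb_segments(prof, k = 2, seed = 1)
  expect_equal(ari(res$groups, rep(1:2, each = 20)), 1)
  # centroids close to the generators (L1 < 0.1)
  cen <- res$centroids
  d_rnq <- min(sum(abs(cen[1, ] - rnq)), sum(abs(cen[2, ] - rnq)))
  d_aepv <- min(sum(abs(cen[1, ] - aepv)), sum(abs(cen[2, ] - aepv)))
  expect_lt(d_rnq, 0.1)
  expect_lt(d_aepv, 0.1)

  expect_equal(cluster_cb_segments(prof[1:3, ], 3, seed = 1)$groups, 1:3)
  expect_error(cluster_cb_segments(prof[1:3, ], 4, seed = 1), "exceeds")
  one <- cluster_cb_segments(prof[c(1, 1), ], 1, seed = 1)
  expect_equal(length(unique(one$groups)), 1)
})

test_that("tandem repeats match worked examples", {
  r <- find_tandem_repeats("REEREEREEREE", 3, 3, 3, 1)
  expect_equal(r$period, 3)
  expect_equal(r$copies, 4)
  expect_equal(r$consensus, "REE")
  expect_equal(r$start, 1)
  expect_equal(r$end, 12)

  r2 <- find_tandem_repeats("AEVPAEVPAEVPAEVPAEVP", 4, 4, 3, 1)
  expect_equal(r2$period, 4)
  expect_equal(r2$copies, 5)
  expect_equal(r2$consensus, "AEVP")

  r3 <- find_tandem_repeats("REEREEREAREE", 3, 3, 3, 0.8)
  expect_equal(nrow(r3), 1)
  expect_equal(r3$period, 3)
  expect_gte(r3$copies, 3.5)
})

test_that("tandem repeats agree with the brute-force scanner", {
  set.seed(14)
  for (rep in 1:12) {
    # small alphabet and planted unit make repeats plentiful
    s <- rand_aa(sample(30:55, 1), alphabet = c("R", "E", "A", "P"))
    unit <- rand_aa(sample(2:4, 1), alphabet = c("R", "E", "A", "P"))
    at <- sample(1:20, 1)
    ins <- strrep(unit, 4)
    substr(s, at, at + nchar(ins) - 1) <- ins
    p <- sample(2:4, 1)
    got <- find_tandem_repeats(s, p, p, 3, 0.8)
    want <- brute_tandem(s, p, p, 3, 0.8)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("start", "end", "period", "matching_cols")],
                   want[, c("start", "end", "period", "matching_cols")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("hydrophobic moment closed forms hold", {
  eis <- motiftrace:::EISENBERG
  # aligned phases: moment = |mean H|
  expect_equal(hydrophobic_moment("AILV", delta = 0),
               abs(mean(eis[c("A", "I", "L", "V")])), tolerance = 1e-12)
  # alternating apolar/charged 18-mer at 180 degrees
  s <- paste(rep(c("I", "R"), 9), collapse = "")
  expect_equal(hydrophobic_moment(s, delta = 180),
               (eis[["I"]] - eis[["R"]]) / 2, tolerance = 1e-12)
  # homopolymer: geometric series in the phase factor
  L <- 12; delta <- 100
  z <- sum(exp(1i * (0:(L - 1)) * delta * pi / 180))
  expect_equal(hydrophobic_moment(strrep("L", L), delta = 100),
               eis[["L"]] * Mod(z) / L, tolerance = 1e-12)
  # reversal with delta -> -delta leaves the moment unchanged
  set.seed(15)
  for (i in 1:20) {
    s <- rand_aa(15)
    sr <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(hydrophobic_moment(s, 100), hydrophobic_moment(sr, -100),
                 tolerance = 1e-12)
  }
  expect_warning(hydrophobic_moment("AXL", 100), "unknown")
})

test_that("disorder heuristic evaluates its formula", {
  expect_equal(disorder_index(strrep("E", 9), 5)[1],
               2.785 * ((-3.5 + 4.5) / 9) - 1 - 1.151, tolerance = 1e-9)
  expect_equal(disorder_index(strrep("I", 9), 5)[1],
               2.785 * 1 - 1.151, tolerance = 1e-9)
  expect_equal(disorder_index(strrep("G", 9), 5)[1],
               2.785 * ((-0.4 + 4.5) / 9) - 1.151, tolerance = 1e-9)
  expect_error(disorder_index("AAAA", 4), "odd")
})

test_that("pattern scan finds all overlapping matches", {
  expect_equal(pattern_scan("CPHCSGAG", "CPxCxGxG"), 1)
  expect_equal(pattern_scan("CPHCSGAT", "CPxCxGxG"), integer(0))
  expect_equal(pattern_scan("CPACAGAGCPACAGAG", "CPxCxGxG"), c(1, 9))
  expect_equal(pattern_scan("AAAA", "AA"), 1:3)
  expect_error(pattern_scan("AAAA", ""), "nonempty")
})

test_that("noncatalytic extraction respects 1-based inclusive coordinates", {
  s <- rand_aa(1061)
  nc <- extract_noncatalytic(s, 529)
  expect_equal(nchar(nc), 532)
  expect_equal(nc, substr(s, 530, 1061))
  expect_equal(extract_noncatalytic(s, 0), s)
  expect_equal(nchar(extract_noncatalytic(s, 1060)), 1)
  expect_error(extract_noncatalytic(s, 1061), "core_end")
})

test_that("segment coordinates round-trip through TSV", {
  df <- data.frame(protein = "p1", kind = "composition_bias",
                   start = c(41L, 120L), end = c(70L, 180L),
                   score = c(-39.03, -17.2), signature = c("R", "Q"),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_tsv(df, path)
  back <- read_tsv(path)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$signature, df$signature)
})
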