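# ZOOPS motif model: scoring, EM discovery, scanning, presence encoding,
# MEME-format interchange.

uniform_bg20 <- stats::setNames(rep(0.05, 20), AA)

det_pwm <- function(consensus) {
  ch <- strsplit(consensus, "")[[1]]
  pwm <- matrix(0, 20, length(ch), dimnames = list(AA, NULL))
  pwm[cbind(match(ch, AA), seq_along(ch))] <- 1
  pwm
}

test_that("site scores follow the log-odds definition", {
  # PWM equal to background scores 0 everywhere
  m0 <- motif_model(matrix(uniform_bg20, 20, 10, dimnames = list(AA, NULL)),
                    uniform_bg20)
  expect_equal(score_site(m0, strrep("A", 10)), 0)
  # deterministic PWM, uniform background: w * log2(20) at the consensus
  m1 <- motif_model(det_pwm("ACDEFGHIKL"), uniform_bg20)
  expect_equal(score_site(m1, "ACDEFGHIKL"), 10 * log2(20),
               tolerance = 1e-12)
  expect_equal(max_score(m1), 10 * log2(20), tolerance = 1e-12)
  expect_error(score_site(m1, "ACDE"), "width")
  # random PWMs against a position-by-position hand computation
  set.seed(3)
  for (i in 1:100) {
    w <- sample(10:25, 1)
    pwm <- matrix(stats::rgamma(20 * w, 1), 20, w)
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
    rownames(pwm) <- AA
    m <- motif_model(pwm, uniform_bg20)
    site <- rand_aa(w)
    ch <- strsplit(site, "")[[1]]
    want <- sum(vapply(seq_len(w), function(j) {
      log2(pwm[ch[j], j] / 0.05)
    }, 0))
    expect_equal(score_site(m, site), want, tolerance = 1e-12)
  }
})

test_that("a planted motif is recovered exactly and EM is monotone", {
  set.seed(21)
  planted <- "WHKDFYMECNIT" # width 12
  seqs <- vapply(1:30, function(i) {
    s <- rand_aa(120)
    pos <- sample(1:(120 - 12 + 1), 1)
    substr(s, pos, pos + 11) <- planted
    s
  }, "")
  names(seqs) <- sprintf("s%02d", 1:30)
  ms <- discover_motifs(seqs, n_motifs = 1, seed = 5)
  expect_equal(length(ms), 1)
  m <- ms[[1]]
  expect_equal(m$consensus, planted)
  expect_gte(m$gamma, 0.95)
  trace <- attr(m, "ll_trace")
  expect_true(all(diff(trace) > -1e-6 * abs(trace[-length(trace)])))
})

test_that("sequential discovery with erasure finds two disjoint motifs", {
  set.seed(22)
  p1 <- "WHKDFYMECNITQHS"
  p2 <- "MYCGHWDETLIKFPR"
  seqs <- vapply(1:40, function(i) {
    s <- rand_aa(260)
    a <- sample(1:100, 1)
    substr(s, a, a + 14) <- p1
    b <- sample(140:240, 1)
    substr(s, b, b + 14) <- p2
    s
  }, "")
  names(seqs) <- sprintf("s%02d", 1:40)
  ms <- discover_motifs(seqs, n_motifs = 2, seed = 6)
  cons <- vapply(ms, function(m) m$consensus, "")
  found <- vapply(c(p1, p2), function(p) {
    any(vapply(cons, function(cc) grepl(p, cc, fixed = TRUE) ||
                 grepl(cc, p, fixed = TRUE), TRUE))
  }, TRUE)
  expect_true(all(found))
})

test_that("scanning reports one best leftmost site per sequence", {
  m <- motif_model(det_pwm("ACDEFGHIKL"), uniform_bg20, gamma = 0.5,
                   rank = 1L)
  # two equal best windows: leftmost wins
  s <- c(x = paste0("WW", "ACDEFGHIKL", "WWWW", "ACDEFGHIKL", "WW"))
  occ <- scan_sequences(m, s)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$start, 3L)
  # below-threshold sequences yield nothing
  occ2 <- scan_sequences(m, c(y = rand_aa(50)), min_bits = 30)
  expect_equal(nrow(occ2), 0)
  # shorter-than-width sequences are skipped with a warning
  expect_warning(scan_sequences(m, c(z = "ACDE")), "shorter")
})

test_that("presence encoding respects the one-strain-per-species rule", {
  manifest <- data.frame(genome = c("gB", "gA", "gC"),
                         species = c("s1", "s1", "s2"),
                         stringsAsFactors = FALSE)
  # occurrence only in the lexicographically second strain of s1
  occ <- data.frame(genome = "gB", motif = 1L, start = 5L, score = 40,
                    stringsAsFactors = FALSE)
  pm <- presence_matrix(occ, manifest)
  expect_equal(pm["1", "s1"], 0L) # retained strain gA has no occurrence
  pm2 <- presence_matrix(occ, manifest, one_strain_per_species = FALSE)
  expect_equal(pm2["1", "s1"], 1L)
  # empty occurrences -> all-zero matrix
  pm0 <- presence_matrix(occ[0, ], manifest)
  expect_equal(nrow(pm0), 0)
  expect_error(presence_matrix(data.frame(genome = "gZ", motif = 1L),
                               manifest), "absent")
})

test_that("motifs round-trip through MEME minimal format", {
  set.seed(30)
  pwm <- matrix(stats::rgamma(20 * 12, 1), 20, 12)
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  rownames(pwm) <- AA
  m <- motif_model(pwm, uniform_bg20, gamma = 0.4, rank = 1L)
  path <- tempfile(fileext = ".meme")
  write_meme(list(m), path)
  back <- read_meme(path)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$width, 12)
  expect_equal(back[[1]]$consensus, m$consensus)
  expect_equal(back[[1]]$pwm, m$pwm, tolerance = 1e-4)
  expect_equal(back[[1]]$background, m$background, tolerance = 1e-4)
})
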