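# Synthetic evolution: determinism, composition, truth-coordinate validity.

test_that("generator parameters are validated", {
  expect_error(evol_params(n_taxa = 1), "n_taxa")
  expect_error(evol_params(gain_rate = -1), "gain_rate")
  bad_prof <- list(stats::setNames(rep(0.06, 20), AA)) # sums to 1.2
  expect_error(evol_params(composition_profiles = bad_prof), "summing to 1")
  expect_error(motif_spec("ACDEF"), "width")
  expect_error(motif_spec("ACDEFGHIKLMN", anchor = 1.5), "anchor")
})

test_that("datasets are byte-identical for a fixed seed", {
  p <- evol_params(n_taxa = 6)
  d1 <- simulate_dataset(p, seed = 5)
  d2 <- simulate_dataset(p, seed = 5)
  expect_identical(d1$proteomes, d2$proteomes)
  expect_identical(d1$truth$characters, d2$truth$characters)
  d3 <- simulate_dataset(p, seed = 6)
  expect_false(identical(d1$proteomes, d3$proteomes))
})

test_that("disordered-region composition matches the configured profiles", {
  # background only: no repeat tracks and no motif gains, so the segments
  # are pure draws from (and substitutions under) their profiles
  p <- evol_params(n_taxa = 10, id_length_mean = 450, id_length_sd = 0,
                   repeat_tracks = list(), gain_rate = 0)
  ds <- simulate_dataset(p, seed = 7)
  cb <- ds$truth$cb_segments
  for (lab in c("RNQ", "AEPV")) {
    seg <- cb[cb$label == lab, ]
    pooled <- paste(vapply(seq_len(nrow(seg)), function(i) {
      substr(ds$proteomes[[seg$genome[i]]][["P1"]], seg$start[i], seg$end[i])
    }, ""), collapse = "")
      expect_gt(nchar(pooled), 2000)
    f <- residue_frequencies(pooled)
    tv <- 0.5 * sum(abs(f - p$composition_profiles[[lab]][names(f)]))
    expect_lt(tv, 0.05)
  }
})

test_that("planted motif instances are found at their recorded coordinates", {
  p <- evol_params(n_taxa = 8)
  ds <- simulate_dataset(p, seed = 11)
  bg <- stats::setNames(rep(0.05, 20), AA)
  inst <- ds$truth$motif_instances
  expect_gt(nrow(inst), 0)
  for (mi in seq_along(p$motif_specs)) {
    nm <- names(p$motif_specs)[mi]
    mm <- motif_model(p$motif_specs[[mi]]$pwm, bg, rank = mi)
    sub <- inst[inst$motif == nm, ]
    for (i in seq_len(nrow(sub))) {
      seqs <- stats::setNames(ds$proteomes[[sub$genome[i]]]["P1"], "x")
      occ <- scan_sequences(mm, seqs)
      expect_equal(occ$start, sub$start[i])
    }
  }
  # characters with state 0 have no instance row
  chars <- ds$truth$characters
  for (mi in rownames(chars)) {
    absent <- colnames(chars)[chars[mi, ] == 0]
    expect_false(any(inst$genome[inst$motif == mi] %in% absent))
  }
})

test_that("repeat tracks are present at truth coordinates", {
  p <- evol_params(n_taxa = 6)
  ds <- simulate_dataset(p, seed = 13)
  reps <- ds$truth$repeats
  for (i in seq_len(nrow(reps))) {
    s <- substr(ds$proteomes[[reps$genome[i]]][["P1"]],
                reps$start[i], reps$end[i])
    unit <- reps$label[i]
    expect_equal(s, paste(rep(strsplit(unit, "")[[1]],
                              length.out = nchar(s)), collapse = ""))
    tr <- find_tandem_repeats(s, nchar(unit), nchar(unit), 3, 1)
    expect_gte(nrow(tr), 1)
  }
})

test_that("background without repeat tracks yields no strict tandem calls", {
  unif <- list(U = stats::setNames(rep(0.05, 20), AA))
  p <- evol_params(n_taxa = 2, repeat_tracks = list(), n_decoys = 0,
                   core_length = 0L, id_length_mean = 300,
                   id_length_sd = 0, composition_profiles = unif)
  set.seed(17)
  n_calls <- 0
  for (i in 1:50) {
    ds <- simulate_dataset(p, seed = 1000 + i)
    for (g in names(ds$proteomes)) {
      r <- find_tandem_repeats(ds$proteomes[[g]][["P1"]],
                               min_period = 3, max_period = 6,
                               min_copies = 3, min_identity = 1)
      n_calls <- n_calls + nrow(r)
    }
  }
  expect_equal(n_calls, 0)
})

test_that("single-residue indels keep truth coordinates consistent", {
  p <- evol_params(n_taxa = 6, indel_rate = 0.02)
  ds <- simulate_dataset(p, seed = 19)
  # lengths now vary across species
  lens <- vapply(ds$proteomes, function(x) nchar(x[["P1"]]), 0L)
  expect_gt(length(unique(lens)), 1)
  bg <- stats::setNames(rep(0.05, 20), AA)
  inst <- ds$truth$motif_instances
  for (i in seq_len(nrow(inst))) {
    mi <- match(inst$motif[i], names(p$motif_specs))
    mm <- motif_model(p$motif_specs[[mi]]$pwm, bg, rank = mi)
    seqs <- stats::setNames(ds$proteomes[[inst$genome[i]]]["P1"], "x")
    occ <- scan_sequences(mm, seqs)
    expect_equal(occ$start, inst$start[i])
  }
})

test_that("truth bundles round-trip to disk", {
  p <- evol_params(n_taxa = 5)
  ds <- simulate_dataset(p, seed = 23)
  dir <- tempfile()
  write_truth_bundle(ds, dir)
  chars <- read_presence_matrix(file.path(dir, "characters.tsv"))
  expect_equal(chars, ds$truth$characters, ignore_attr = TRUE)
  inst <- read_tsv(file.path(dir, "motif_instances.tsv"))
  expect_equal(inst$start, ds$truth$motif_instances$start)
  tr <- read_species_tree(file.path(dir, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(names(ds$proteomes)))
})
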