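# ZOOPS motif discovery and annotation.
#
# Motifs are position weight matrices (PWMs) of width 10-25 learned from
# unaligned sequences under the "zero or one occurrence per sequence"
# (ZOOPS) likelihood by expectation-maximization, then used to annotate
# sequences by best-window log-odds scanning and to encode per-species
# presence/absence.

.encode_seqs <- function(seqs) {
  lapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    i <- match(ch, AA20)
    i[is.na(i)] <- 0L # X or mask: excluded from counts and windows
    i
  })
}

#' Construct a motif model
#'
#' @param pwm numeric matrix, 20 residues x width; columns must sum to 1.
#'   Rows are taken in the package residue order unless row names are given.
#' @param background named background frequencies over the 20 residues.
#' @param gamma site prior: probability that a sequence contains the motif.
#' @param rank discovery rank (optional).
#' @return An object of class `motif_model` with fields `width`, `pwm`,
#'   `background`, `gamma`, `rank`, `consensus`, `ic` (information content,
#'   bits, relative to the background).
#' @export
motif_model <- function(pwm, background, gamma = 0.5, rank = NA_integer_) {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 20L) stop("'pwm' must have 20 rows (residues)")
  if (is.null(rownames(pwm))) rownames(pwm) <- AA20
  pwm <- pwm[AA20, , drop = FALSE]
  w <- ncol(pwm)
  if (w < 1L) stop("empty PWM")
  if (any(abs(colSums(pwm) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  if (gamma <= 0 || gamma > 1) stop("'gamma' must lie in (0, 1]")
  background <- background[AA20]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-6) {
    stop("'background' must cover the 20 residues and sum to 1")
  }
  ic <- sum(pwm * log2(pmax(pwm, 1e-300) /
                         matrix(background, 20L, w)))
  structure(
    list(width = w, pwm = pwm, background = background, gamma = gamma,
         rank = rank, consensus = paste(AA20[apply(pwm, 2L, which.max)],
                                        collapse = ""),
         ic = ic),
    class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: width", x$width, " consensus", x$consensus,
      sprintf(" IC %.1f bits  gamma %.2f", x$ic, x$gamma),
      if (!is.na(x$rank)) paste0(" rank ", x$rank), "\n")
  invisible(x)
}

#' Log-odds score of a site against a motif
#'
#' `sum_j log2(pwm[site_j, j] / background[site_j])`, in bits. Unknown
#' residues contribute 0.
#'
#' @param motif a [motif_model()].
#' @param site string of length exactly `motif$width`.
#' @return Score in bits.
#' @export
score_site <- function(motif, site) {
  ch <- strsplit(site, "", fixed = TRUE)[[1L]]
  if (length(ch) != motif$width) {
    stop("site length ", length(ch), " != motif width ", motif$width)
  }
  i <- match(ch, AA20)
  keep <- !is.na(i)
  if (!any(keep)) return(0)
  j <- which(keep)
  sum(log2(motif$pwm[cbind(i[keep], j)] / motif$background[i[keep]]))
}

# Per-window log-odds (bits) over one encoded sequence; windows overlapping
# masked positions score -Inf. Returns numeric(0) for sequences shorter
# than the motif.
.window_scores <- function(motif, iseq) {
  w <- motif$width
  L <- length(iseq)
  if (L < w) return(numeric(0))
  lo <- log2(motif$pwm / matrix(motif$background, 20L, w))
  lo <- rbind(`0` = -Inf, lo) # masked residue kills the window
  n_win <- L - w + 1L
  sc <- numeric(n_win)
  for (k in seq_len(w)) {
    sc <- sc + lo[iseq[k:(k + n_win - 1L)] + 1L, k]
  }
  sc
}

#' Maximum attainable log-odds score of a motif
#' @param motif a [motif_model()].
#' @return Bits.
#' @export
max_score <- function(motif) {
  lo <- log2(motif$pwm / matrix(motif$background, 20L, motif$width))
  sum(apply(lo, 2L, max))
}

#' Annotate sequences with a motif (ZOOPS scanning)
#'
#' Reports, for each sequence, its single best-scoring window (leftmost on
#' ties) when the log-odds score reaches `min_bits`; at most one occurrence
#' per sequence.
#'
#' @param motif a [motif_model()].
#' @param seqs named character vector of sequences.
#' @param min_bits score threshold; default 60 percent of the motif's
#'   maximum attainable score.
#' @return data.frame: `protein` (sequence name), `motif` (rank), `start`
#'   (1-based), `score` (bits).
#' @export
scan_sequences <- function(motif, seqs, min_bits = NULL) {
  if (is.null(min_bits)) min_bits <- 0.6 * max_score(motif)
  if (!is.finite(min_bits)) stop("'min_bits' must be finite")
  iseqs <- .encode_seqs(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  rows <- list()
  for (i in seq_along(iseqs)) {
    sc <- .window_scores(motif, iseqs[[i]])
    if (!length(sc)) {
      warning("sequence '", ids[i], "' shorter than motif width; skipped")
      next
    }
    best <- which.max(sc) # which.max returns the leftmost maximum
    if (sc[best] >= min_bits) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein = ids[i], motif = motif$rank, start = as.integer(best),
        score = sc[best], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(protein = character(0), motif = integer(0),
                      start = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# One ZOOPS EM run at fixed width from a given starting PWM.
# iseqs: encoded sequences; bg: background over AA20; returns pwm, gamma,
# loglik (full data log likelihood incl. background constants), ll_trace.
.zoops_em <- function(iseqs, pwm0, bg, gamma0 = 0.5, pseudo = 0.01,
                      max_iter = 200L, tol = 1e-6) {
  w <- ncol(pwm0)
  usable <- vapply(iseqs, function(s) length(s) >= w, TRUE)
  iseqs <- iseqs[usable]
  n <- length(iseqs)
  # background constant: sum of log bg over all unmasked residues
  lbg <- log(bg)
  bg_const <- sum(vapply(iseqs, function(s) sum(lbg[s[s > 0L]]), 0))
  # per-sequence one-hot residue matrices (L x 20), fixed across iterations
  onehot <- lapply(iseqs, function(s) {
    A <- matrix(0, length(s), 20L)
    pos <- which(s > 0L)
    A[cbind(pos, s[pos])] <- 1
    A
  })
  pwm <- pwm0
  gamma <- gamma0
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lr <- rbind(-Inf, log(pwm / matrix(bg, 20L, w))) # row 1 = masked
    counts <- matrix(0, 20L, w)
    z_tot <- 0
    ll <- bg_const
    for (i in seq_len(n)) {
      s <- iseqs[[i]]
      L <- length(s)
      n_win <- L - w + 1L
      P <- lr[s + 1L, , drop = FALSE] # L x w: lr of residue t at column k
      r <- P[seq_len(n_win), 1L]
      for (k in seq_len(w)[-1L]) r <- r + P[k:(k + n_win - 1L), k]
      valid <- is.finite(r)
      m_i <- sum(valid)
      if (m_i == 0L) {
        ll <- ll + log(1 - gamma) # only the background explanation remains
        next
      }
      mx <- max(r[valid])
      R <- exp(r - mx)
      R[!valid] <- 0
      denom <- (1 - gamma) * exp(-mx) + (gamma / m_i) * sum(R)
      ll <- ll + log(denom) + mx
      z <- (gamma / m_i) * R / denom
      z_tot <- z_tot + sum(z)
      Zm <- matrix(0, L, w)
      for (k in seq_len(w)) Zm[k:(k + n_win - 1L), k] <- z
      counts <- counts + crossprod(onehot[[i]], Zm)
    }
    ll_trace <- c(ll_trace, ll)
    pwm <- sweep(counts + pseudo, 2L, colSums(counts) + 20 * pseudo, "/")
    gamma <- min(max(z_tot / n, 1e-6), 1 - 1e-9)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) break
    ll_old <- ll
  }
  list(pwm = pwm, gamma = gamma, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, n_iter = length(ll_trace))
}

# Starting PWM from a seed subsequence: 60% mass on the seed residue,
# remainder spread as the background.
.seed_pwm <- function(iseed, bg) {
  w <- length(iseed)
  pwm <- matrix(bg, 20L, w)
  pwm <- pwm * 0.4
  pwm[cbind(iseed, seq_len(w))] <- pwm[cbind(iseed, seq_len(w))] + 0.6
  rownames(pwm) <- AA20
  pwm
}

# Candidate seed windows for a width: the most frequent exact w-mers plus
# random windows (covers both noise-free and degenerate motifs).
.seed_windows <- function(seqs, w, n_top, n_rand) {
  wins <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < w) return(character(0))
    substring(s, seq_len(L - w + 1L), w:L)
  }), use.names = FALSE)
  wins <- wins[!grepl(sprintf("[^%s]", paste(AA20, collapse = "")), wins)]
  if (!length(wins)) return(list())
  tab <- sort(table(wins), decreasing = TRUE)
  seeds <- utils::head(names(tab)[tab >= 2L], n_top)
  if (n_rand > 0L) {
    seeds <- c(seeds, wins[sample.int(length(wins),
                                      min(n_rand, length(wins)))])
  }
  lapply(unique(seeds), function(s) match(strsplit(s, "")[[1L]], AA20))
}

#' Discover motifs by sequential ZOOPS EM
#'
#' Finds up to `n_motifs` motifs of width `w_min` to `w_max` in unaligned
#' sequences. For each motif, EM is run at a coarse grid of widths (step 3)
#' from data-derived seed PWMs (frequent exact words plus random windows,
#' a few iterations each), the most promising width is refined by one
#' residue on either side, and the best start is run to convergence. Widths
#' are compared by a BIC-penalized log likelihood (19 free frequencies per
#' column, effective sample size = expected site count), which prevents the
#' spurious widening that raw likelihood would reward. Discovered
#' occurrences are then erased (masked with a neutral symbol, preserving
#' coordinates) and the search repeats. Motifs are ranked in discovery
#' order and carry a significance score `ic * gamma * n` (information
#' content times expected site count); discovery stops early when this
#' falls below `sig_floor`.
#'
#' @param seqs named character vector of (unaligned) sequences, each longer
#'   than `w_max`; shorter sequences are excluded with a warning.
#' @param w_min,w_max width bounds (defaults 10 and 25).
#' @param n_motifs maximum number of motifs (default 30).
#' @param seed integer seed (controls seed-window sampling only).
#' @param background background frequencies; default the input's global
#'   residue frequencies.
#' @param n_top_words,n_rand_seeds number of frequent-word and random seed
#'   windows per width.
#' @param sig_floor stop when a motif's significance drops below this.
#' @param pseudo Dirichlet pseudocount per residue per column.
#' @param em_iter,em_tol full-run EM budget and relative tolerance.
#' @return List of [motif_model()] objects, ranked; each carries
#'   `significance` and the EM log-likelihood trace as attributes
#'   `significance` and `ll_trace`.
#' @export
discover_motifs <- function(seqs, w_min = 10L, w_max = 25L, n_motifs = 30L,
                            seed = NULL, background = NULL,
                            n_top_words = 5L, n_rand_seeds = 30L,
                            sig_floor = 10, pseudo = 0.01,
                            em_iter = 200L, em_tol = 1e-6) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (w_min < 2L || w_max < w_min) stop("bad width bounds")
  short <- nchar(seqs) < w_min
  if (all(short)) stop("all sequences shorter than 'w_min'")
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than 'w_min' excluded")
    seqs <- seqs[!short]
  }
  if (is.null(background)) background <- residue_frequencies(seqs)
  background <- background[AA20]
  iseqs <- .encode_seqs(seqs)
  n <- length(iseqs)
  widths <- unique(c(seq(w_min, w_max, by = 3L), w_max))

  # BIC-style width penalty with an effective parameter count per column:
  # informative PWM columns are near-sparse (a handful of residues carry
  # almost all mass), so charging the nominal 19 free frequencies per
  # column overshoots and truncates genuine motifs with few sites; 15
  # effective parameters still dominates the ~9.5 nat expected overfit
  # gain of a background column.
  pen_ll <- function(fit, w) {
    n_eff <- max(fit$gamma * n, 2)
    fit$loglik - 0.5 * (15 * w + 1) * log(n_eff)
  }
  run_width <- function(w, n_iter) {
    seeds <- .seed_windows(seqs, w, n_top_words, n_rand_seeds)
    if (!length(seeds)) return(NULL)
    best <- NULL
    for (sd in seeds) {
      fit <- .zoops_em(iseqs, .seed_pwm(sd, background), background,
                       pseudo = pseudo, max_iter = n_iter, tol = em_tol)
      if (is.null(best) || fit$loglik > best$fit$loglik) {
        best <- list(fit = fit, seed = sd)
      }
    }
    best
  }

  with_seed(seed, {
    motifs <- list()
    for (rank in seq_len(n_motifs)) {
      cand <- list()
      for (w in widths) {
        b <- run_width(w, 4L)
        if (!is.null(b)) cand[[as.character(w)]] <- b
      }
      if (!length(cand)) break
      scores <- vapply(names(cand), function(w) {
        pen_ll(cand[[w]]$fit, as.integer(w))
      }, 0)
      # hill-climb the width one residue at a time around the coarse best
      w_star <- as.integer(names(cand)[which.max(scores)])
      repeat {
        improved <- FALSE
        for (w in intersect(c(w_star - 1L, w_star + 1L), w_min:w_max)) {
          if (!as.character(w) %in% names(cand)) {
            b <- run_width(w, 4L)
            if (!is.null(b)) cand[[as.character(w)]] <- b
          }
          if (as.character(w) %in% names(cand) &&
              pen_ll(cand[[as.character(w)]]$fit, w) >
                pen_ll(cand[[as.character(w_star)]]$fit, w_star)) {
            w_star <- w
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      full <- .zoops_em(iseqs, .seed_pwm(cand[[as.character(w_star)]]$seed,
                                         background),
                        background, pseudo = pseudo,
                        max_iter = em_iter, tol = em_tol)
      m <- motif_model(full$pwm, background, gamma = full$gamma, rank = rank)
      sig <- m$ic * m$gamma * n
      if (sig < sig_floor) break
      attr(m, "significance") <- sig
      attr(m, "ll_trace") <- full$ll_trace
      motifs[[rank]] <- m
      # erase: mask the best window of each sequence annotated by the motif
      occ <- suppressWarnings(scan_sequences(m, seqs))
      ids <- names(seqs)
      if (is.null(ids)) ids <- as.character(seq_along(seqs))
      for (i in seq_len(nrow(occ))) {
        si <- match(occ$protein[i], ids)
        pos <- occ$start[i]:(occ$start[i] + m$width - 1L)
        iseqs[[si]][pos] <- 0L
        substr(seqs[si], occ$start[i],
               occ$start[i] + m$width - 1L) <- strrep("X", m$width)
      }
    }
    motifs
  })
}

#' Scan sequences with several motifs
#'
#' @param motifs list of [motif_model()] objects.
#' @param seqs named character vector.
#' @param min_bits per-motif threshold (recycled) or `NULL` for the
#'   per-motif default of [scan_sequences()].
#' @return Combined occurrence data.frame (`protein`, `motif`, `start`,
#'   `score`).
#' @export
scan_motifs <- function(motifs, seqs, min_bits = NULL) {
  occ <- lapply(seq_along(motifs), function(i) {
    mb <- if (is.null(min_bits)) NULL else rep(min_bits,
                                               length(motifs))[i]
    scan_sequences(motifs[[i]], seqs, mb)
  })
  do.call(rbind, occ)
}

#' Presence/absence matrix of motifs over species
#'
#' Encodes, per motif and species, whether the species' retained strain
#' carries an occurrence. With `one_strain_per_species` the retained strain
#' is the lexicographically first genome id of each species.
#'
#' @param occurrences occurrence data.frame with columns `genome` and
#'   `motif` (e.g. [scan_motifs()] output joined to genomes).
#' @param manifest data.frame with columns `genome`, `species`.
#' @param one_strain_per_species keep one strain per species (default TRUE).
#' @return Binary integer matrix, motifs x species.
#' @export
presence_matrix <- function(occurrences, manifest,
                            one_strain_per_species = TRUE) {
  if (!all(c("genome", "species") %in% names(manifest))) {
    stop("manifest needs 'genome' and 'species' columns")
  }
  bad <- setdiff(occurrences$genome, manifest$genome)
  if (length(bad)) {
    stop("occurrence genomes absent from manifest: ",
         paste(bad, collapse = ", "))
  }
  manifest <- manifest[order(manifest$genome, method = "radix"), ,
                       drop = FALSE]
  if (one_strain_per_species) {
    manifest <- manifest[!duplicated(manifest$species), , drop = FALSE]
  }
  species <- sort(unique(manifest$species), method = "radix")
  motifs <- sort(unique(occurrences$motif))
  pm <- matrix(0L, length(motifs), length(species),
               dimnames = list(as.character(motifs), species))
  if (nrow(occurrences)) {
    occ <- occurrences[occurrences$genome %in% manifest$genome, ,
                       drop = FALSE]
    sp <- manifest$species[match(occ$genome, manifest$genome)]
    pm[cbind(match(as.character(occ$motif), rownames(pm)),
             match(sp, species))] <- 1L
  }
  pm
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs list of [motif_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  bg <- motifs[[1L]]$background[AA_MEME]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(AA_MEME, collapse = "")), "",
               "Background letter frequencies"), con)
  writeLines(paste(paste(AA_MEME, sprintf("%.6f", bg)), collapse = " "),
             con)
  for (m in motifs) {
    writeLines(c("", paste0("MOTIF m", m$rank, " ", m$consensus),
                 sprintf(
                   "letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
                   m$width, max(1L, round(m$gamma * 100)))), con)
    pwm <- m$pwm[AA_MEME, , drop = FALSE]
    for (j in seq_len(m$width)) {
      writeLines(paste(sprintf("%.6f", pwm[, j]), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' Understands the subset written by [write_meme()] (version header,
#' background line, letter-probability matrices).
#'
#' @param path MEME-format file.
#' @return List of [motif_model()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  alpha_i <- grep("^ALPHABET=", lines)
  alphabet <- strsplit(sub("^ALPHABET=\\s*", "", lines[alpha_i]), "")[[1L]]
  bg_i <- grep("^Background letter frequencies", lines)
  toks <- strsplit(trimws(lines[bg_i + 1L]), "\\s+")[[1L]]
  bg <- stats::setNames(as.numeric(toks[seq(2, length(toks), 2)]),
                        toks[seq(1, length(toks), 2)])[AA20]
  bg <- bg / sum(bg) # undo printed rounding
  motif_i <- grep("^MOTIF ", lines)
  out <- list()
  for (mi in seq_along(motif_i)) {
    hdr <- grep("^letter-probability matrix:", lines)
    hdr <- hdr[hdr > motif_i[mi]][1L]
    w <- as.integer(sub(".* w= *(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    pwm_t <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                   as.numeric))
    pwm <- t(pwm_t)
    rownames(pwm) <- alphabet
    pwm <- sweep(pwm, 2L, colSums(pwm), "/") # renormalize printed rounding
    rank <- suppressWarnings(
      as.integer(sub("^MOTIF m?(\\d+).*", "\\1", lines[motif_i[mi]])))
    out[[mi]] <- motif_model(pwm[AA20, , drop = FALSE], bg, gamma = 0.5,
                             rank = rank)
  }
  out
}
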