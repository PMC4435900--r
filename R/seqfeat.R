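# Annotation of the hallmarks of intrinsically disordered noncatalytic
# regions: composition-biased segments, tandem repeats, amphipathic-helix
# candidates, fixed patterns, and a sequence-only disorder heuristic.
# All coordinates are 1-based inclusive residue positions.

# Eisenberg consensus hydrophobicity scale (normalized consensus of several
# experimental scales).
EISENBERG <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
               Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
               L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
               S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Global residue frequencies of a sequence set
#'
#' Frequencies over the 20 canonical residues (other letters ignored), the
#' default background for [lps_scan()] and motif discovery.
#'
#' @param seqs character vector of protein sequences.
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
residue_frequencies <- function(seqs) {
  ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(ch, levels = AA20))
  n <- sum(counts)
  if (n == 0) stop("no canonical residues found")
  stats::setNames(as.numeric(counts) / n, AA20)
}

#' Scan for single-residue composition-biased segments
#'
#' For every residue type and every window of length `min_len` to
#' `max_len`, computes the exact binomial tail probability
#' `P(X >= k)` of seeing `k` copies of the residue in a window of that
#' length under the background frequency, and reports maximal windows with
#' probability at most `p_max`. Overlapping significant windows of the same
#' residue are merged and represented by their lowest-probability window.
#' Probabilities are handled in log space, so segments far below the double
#' underflow limit keep an exact `log10_p`.
#'
#' @param seq protein sequence (single string).
#' @param background named residue frequencies summing to 1 (e.g.
#'   [residue_frequencies()] over the proteome).
#' @param p_max significance threshold on the binomial tail probability;
#'   default the stringent 1e-15 used to confine composition bias to
#'   disordered regions.
#' @param min_len,max_len window length bounds (residues). `max_len` caps
#'   the quadratic enumeration; composition-biased segments in this family
#'   are well under 500 residues.
#' @return data.frame of segments: `start`, `end`, `kind`, `signature`
#'   (the residue), `count`, `p_value`, `log10_p`. Zero rows when nothing
#'   reaches `p_max`.
#' @examples
#' bg <- stats::setNames(rep(0.05, 20), motiftrace:::AA20)
#' lps_scan(strrep("R", 30), bg, p_max = 1e-15, min_len = 10)
#' @export
lps_scan <- function(seq, background, p_max = 1e-15,
                     min_len = 10L, max_len = 500L) {
  if (min_len < 1L || max_len < min_len) stop("inconsistent window bounds")
  if (!is.numeric(p_max) || p_max <= 0 || p_max >= 1) {
    stop("'p_max' must lie in (0, 1)")
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  log_pmax <- log(p_max)
  out <- list()
  for (r in intersect(unique(chars), names(background))) {
    p <- background[[r]]
    if (p <= 0 || p >= 1) next
    total <- sum(chars == r)
    # best achievable tail is p^k at k = n_r; skip residues that cannot reach
    if (total * log(p) > log_pmax) next
    cs <- c(0L, cumsum(chars == r))
    hits <- list()
    for (L in seq.int(min_len, min(max_len, n))) {
      starts <- seq_len(n - L + 1L)
      k <- cs[starts + L] - cs[starts]
      cand <- which(k > 0L)
      if (!length(cand)) next
      logp <- stats::pbinom(k[cand] - 1L, L, p,
                            lower.tail = FALSE, log.p = TRUE)
      sig <- logp <= log_pmax
      if (any(sig)) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = starts[cand][sig], end = starts[cand][sig] + L - 1L,
          count = k[cand][sig], logp = logp[sig])
      }
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    # merge overlapping windows; keep the lowest-probability representative
    h <- h[order(h$start, h$end), , drop = FALSE]
    grp <- integer(nrow(h))
    g <- 0L
    reach <- -1L
    for (i in seq_len(nrow(h))) {
      if (h$start[i] > reach) g <- g + 1L
      grp[i] <- g
      reach <- max(reach, h$end[i])
    }
    for (g_i in seq_len(g)) {
      sub <- h[grp == g_i, , drop = FALSE]
      best <- sub[order(sub$logp, -(sub$end - sub$start),
                        sub$start), , drop = FALSE][1L, ]
      out[[length(out) + 1L]] <- data.frame(
        start = best$start, end = best$end, kind = "composition_bias",
        signature = r, count = best$count,
        p_value = exp(best$logp), log10_p = best$logp / log(10),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0), signature = character(0),
                      count = integer(0), p_value = numeric(0),
                      log10_p = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$signature), , drop = FALSE]
}

#' Cluster composition profiles of biased segments
#'
#' k-means (Euclidean) over per-segment residue-frequency vectors with a
#' seeded deterministic initialization; used to separate e.g. RNQ-rich from
#' AEPV-rich segment classes.
#'
#' @param profiles numeric matrix, segments x residues; each row sums to 1.
#' @param k number of groups (1 <= k <= nrow(profiles)).
#' @param seed integer seed.
#' @param nstart random restarts handed to [stats::kmeans()].
#' @return A list: `groups` (integer vector over segments), `centroids`
#'   (k x residues matrix of mean frequencies).
#' @export
cluster_cb_segments <- function(profiles, k, seed = NULL, nstart = 10L) {
  profiles <- as.matrix(profiles)
  if (k < 1L) stop("'k' must be >= 1")
  if (k > nrow(profiles)) {
    stop("'k' (", k, ") exceeds the number of profiles (", nrow(profiles), ")")
  }
  if (any(abs(rowSums(profiles) - 1) > 1e-6)) {
    stop("each profile must sum to 1")
  }
  with_seed(seed, {
    if (k == nrow(profiles)) {
      # kmeans() refuses k == n with duplicate rows; the answer is trivial
      return(list(groups = seq_len(nrow(profiles)), centroids = profiles))
    }
    km <- stats::kmeans(profiles, centers = k, nstart = nstart)
    list(groups = as.integer(km$cluster), centroids = km$centers)
  })
}

#' Detect tandem repeats in a protein sequence
#'
#' Finds maximal regions `[a, b]` in which positions one period apart agree:
#' for a period `p`, the region must span at least `min_copies * p` residues
#' and the fraction of matching position pairs `seq[i] == seq[i + p]`
#' (for `i` in `a .. b - p`) must be at least `min_identity`. Overlapping
#' calls (within or across periods) are resolved greedily in favour of the
#' call with the most matching columns (ties: shorter period, then earlier
#' start).
#'
#' @param seq protein sequence (single string).
#' @param min_period,max_period period bounds in residues.
#' @param min_copies minimum (possibly fractional) copy number (>= 2).
#' @param min_identity minimum fraction of matching position pairs (0, 1].
#' @return data.frame: `start`, `end`, `period`, `copies` (length/period),
#'   `identity`, `matching_cols`, `consensus` (column-majority unit).
#' @examples
#' find_tandem_repeats("REEREEREEREE", min_period = 3, max_period = 3,
#'                     min_copies = 3, min_identity = 1)
#' @export
find_tandem_repeats <- function(seq, min_period = 1L, max_period = 12L,
                                min_copies = 3L, min_identity = 0.8) {
  if (min_period < 1L || max_period < min_period) stop("bad period bounds")
  if (min_copies < 2L) stop("'min_copies' must be >= 2")
  if (min_identity <= 0 || min_identity > 1) {
    stop("'min_identity' must lie in (0, 1]")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  calls <- list()
  for (p in seq.int(min_period, max_period)) {
    min_len <- ceiling(min_copies * p)
    if (min_len > n) break
    m <- chars[seq_len(n - p)] == chars[(p + 1L):n]
    cs <- c(0L, cumsum(m))
    bmax <- rep(NA_integer_, n)
    for (a in seq_len(n - min_len + 1L)) {
      bs <- seq.int(a + min_len - 1L, n)
      idt <- (cs[bs - p + 1L] - cs[a]) / (bs - p - a + 1L)
      ok <- idt >= min_identity
      if (any(ok)) bmax[a] <- max(bs[ok])
    }
    for (a in which(!is.na(bmax))) {
      b <- bmax[a]
      # maximal: not extendable left (right-maximality is by construction)
      if (a > 1L && !is.na(bmax[a - 1L]) && bmax[a - 1L] >= b) next
      if (a > 1L) {
        idt_left <- (cs[b - p + 1L] - cs[a - 1L]) / (b - p - a + 2L)
        if (idt_left >= min_identity) next
      }
      mc <- cs[b - p + 1L] - cs[a]
      calls[[length(calls) + 1L]] <- data.frame(
        start = a, end = b, period = p,
        copies = (b - a + 1L) / p,
        identity = mc / (b - p - a + 1L),
        matching_cols = mc,
        consensus = .repeat_consensus(chars, a, b, p),
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = numeric(0),
                      identity = numeric(0), matching_cols = integer(0),
                      consensus = character(0), stringsAsFactors = FALSE)
  if (!length(calls)) return(empty)
  calls <- do.call(rbind, calls)
  calls <- calls[order(-calls$matching_cols, calls$period, calls$start), ,
                 drop = FALSE]
  kept <- empty
  for (i in seq_len(nrow(calls))) {
    if (nrow(kept) == 0L ||
        all(calls$start[i] > kept$end | calls$end[i] < kept$start)) {
      kept <- rbind(kept, calls[i, ])
    }
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

.repeat_consensus <- function(chars, a, b, p) {
  unit <- character(p)
  for (k in seq_len(p)) {
    pos <- seq.int(a + k - 1L, b, by = p)
    tab <- sort(table(chars[pos]), decreasing = TRUE)
    unit[k] <- names(tab)[1L]
  }
  paste(unit, collapse = "")
}

#' Hydrophobic moment of a peptide window
#'
#' Mean vector magnitude of per-residue hydrophobicities placed around a
#' helical wheel: `muH = |sum_n H(r_n) * exp(i * n * delta)| / L`, with
#' `delta = 100` degrees for an alpha helix. High values flag amphipathic
#' helix candidates such as membrane targeting sequences.
#'
#' @param window peptide (single string, length >= 2).
#' @param delta rotation per residue in degrees (100 for alpha helix).
#' @param scale named hydrophobicity scale; default the Eisenberg consensus
#'   scale. Unknown residues score 0 with a warning.
#' @return Hydrophobic moment per residue (single number).
#' @export
hydrophobic_moment <- function(window, delta = 100, scale = NULL) {
  if (is.null(scale)) scale <- EISENBERG
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (length(chars) < 2L) stop("window must contain at least 2 residues")
  h <- scale[chars]
  if (anyNA(h)) {
    warning("unknown residues scored 0: ",
            paste(unique(chars[is.na(h)]), collapse = ", "))
    h[is.na(h)] <- 0
  }
  phi <- (seq_along(chars) - 1L) * delta * pi / 180
  Mod(sum(h * exp(1i * phi))) / length(chars)
}

#' Sequence-only disorder heuristic
#'
#' A charge-hydropathy index computed in a sliding window:
#' `2.785 * <H_norm> - |<q>| - 1.151`, where `H_norm` is Kyte-Doolittle
#' hydropathy rescaled to `[0, 1]` (`(H + 4.5)/9`) and `q` is the net
#' charge (K, R = +1; D, E = -1). Negative values flag predicted disorder:
#' low mean hydropathy and/or high net charge place a window on the
#' unfolded side of the charge-hydropathy boundary. This is a transparent
#' heuristic devised for this package, not a trained disorder predictor,
#' and is labelled as such in all outputs.
#'
#' @param seq protein sequence (single string).
#' @param window odd window size >= 5; windows are centered and truncated
#'   at the sequence ends.
#' @return Numeric vector, one index per residue (negative = predicted
#'   disordered).
#' @examples
#' disorder_index(strrep("E", 9), window = 5)[1]  # about -1.84: disordered
#' @export
disorder_index <- function(seq, window = 21L) {
  if (window < 5L || window %% 2L == 0L) stop("'window' must be odd and >= 5")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  h <- (KYTE_DOOLITTLE[chars] + 4.5) / 9
  h[is.na(h)] <- 0.5
  q <- numeric(n)
  q[chars %in% c("K", "R")] <- 1
  q[chars %in% c("D", "E")] <- -1
  half <- (window - 1L) %/% 2L
  ch <- c(0, cumsum(h))
  cq <- c(0, cumsum(q))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  len <- hi - lo + 1L
  mean_h <- (ch[hi + 1L] - ch[lo]) / len
  mean_q <- (cq[hi + 1L] - cq[lo]) / len
  unname(2.785 * mean_h - abs(mean_q) - 1.151)
}

#' Scan for a fixed pattern with wildcards
#'
#' Finds all (possibly overlapping) matches of a residue pattern in which
#' `x` matches any residue, e.g. the Zn-link signature `CPxCxGxG`.
#'
#' @param seq protein sequence (single string).
#' @param pattern residue letters and `x` wildcards.
#' @return Integer vector of 1-based match start positions.
#' @examples
#' pattern_scan("CPHCSGAG", "CPxCxGxG")  # 1
#' @export
pattern_scan <- function(seq, pattern) {
  if (!nzchar(pattern)) stop("pattern must be nonempty")
  if (grepl("[^A-Zx]", pattern)) {
    stop("pattern may contain only residue letters and 'x'")
  }
  rx <- paste0("(?=", gsub("x", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Extract the noncatalytic region
#'
#' Removes the N-terminal conserved catalytic core, returning residues
#' `core_end + 1` to the C-terminus (1-based inclusive coordinates).
#'
#' @param seq protein sequence (single string).
#' @param core_end last residue of the catalytic core; 0 keeps the whole
#'   sequence.
#' @return The C-terminal subsequence.
#' @export
extract_noncatalytic <- function(seq, core_end) {
  n <- nchar(seq)
  if (core_end < 0 || core_end >= n) {
    stop("'core_end' must satisfy 0 <= core_end < sequence length (", n, ")")
  }
  substr(seq, core_end + 1L, n)
}
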