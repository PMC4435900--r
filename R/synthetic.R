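# Synthetic evolution of a protein family with a disordered C-terminal
# region. The generator is the forward model of everything the analysis
# assumes: a Yule species tree, binary motif characters evolving under the
# two-state gain/loss process, and per-genome proteomes in which the focal
# family carries a conserved core, a composition-biased disordered region
# with tandem repeats, and planted motif instances wherever the character
# is present. Every random draw flows from one named seed, and a truth
# bundle records coordinates, states and events for downstream tests.

#' Specify a planted motif
#'
#' @param consensus residue string of width 10 to 25 (the discovery range),
#'   or `NULL` when `pwm` is given.
#' @param pwm optional 20 x width matrix of column frequencies.
#' @param anchor relative position of the instance inside the disordered
#'   region, in `[0, 1]`.
#' @param noise per-site emission noise: probability mass spread off the
#'   consensus residue at each column.
#' @return A `motif_spec` list: `pwm`, `width`, `anchor`, `consensus`.
#' @export
motif_spec <- function(consensus = NULL, pwm = NULL, anchor = 0.5,
                       noise = 0.02) {
  if (is.null(pwm)) {
    if (is.null(consensus)) stop("give 'consensus' or 'pwm'")
    ch <- strsplit(consensus, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% AA20)) stop("consensus must use the 20 residues")
    w <- length(ch)
    pwm <- matrix(noise / 19, 20L, w, dimnames = list(AA20, NULL))
    pwm[cbind(match(ch, AA20), seq_len(w))] <- 1 - noise
  } else {
    pwm <- as.matrix(pwm)
    if (is.null(rownames(pwm))) rownames(pwm) <- AA20
    pwm <- pwm[AA20, , drop = FALSE]
    w <- ncol(pwm)
    if (any(abs(colSums(pwm) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  }
  if (w < 10L || w > 25L) stop("motif width must lie in 10..25")
  if (anchor < 0 || anchor > 1) stop("'anchor' must lie in [0, 1]")
  structure(list(pwm = pwm, width = w, anchor = anchor,
                 consensus = paste(AA20[apply(pwm, 2L, which.max)],
                                   collapse = "")),
            class = "motif_spec")
}

#' Parameters of the synthetic-evolution generator
#'
#' Defaults describe the study conditions the analysis targets, scaled to a
#' desk-size family: a moderate clade (16 taxa), motif characters evolving
#' with a gain rate of 0.5 and a loss rate of 0.2 per unit branch length, a
#' conserved 200-residue catalytic core followed by a disordered region of
#' about 250 residues organized as an RNQ-rich half (R 0.214, N 0.101,
#' Q 0.091) followed by an AEPV-rich half (A 0.208, E 0.138, P 0.106,
#' V 0.127), REE/AEVP tandem repeat tracks, and two planted 15-residue
#' motifs at opposite ends of the disordered region.
#'
#' @param n_taxa,birth_rate Yule tree size and rate.
#' @param gain_rate,loss_rate,root_state two-state character process.
#' @param core_length conserved core length (residues).
#' @param id_length_mean,id_length_sd disordered-region length draw.
#' @param composition_profiles named list of residue-frequency vectors
#'   (each summing to 1), applied to consecutive equal shares of the
#'   disordered region.
#' @param repeat_tracks list of `c(unit, copies)` pairs; track `i` is
#'   inserted into profile segment `i` (recycled).
#' @param motif_specs list of [motif_spec()] objects.
#' @param substitution_rate substitutions per residue per unit branch
#'   length in the conserved core (slow: the core stays alignable).
#' @param id_substitution_rate substitutions per residue per unit branch
#'   length in the disordered background (fast: across the tree the
#'   disordered region keeps only its composition, not its sequence, so
#'   planted motifs are the only conserved signal there, as in real
#'   disordered regions). The default (3) outpaces even the shallowest
#'   species splits of a Yule tree, emulating one-strain-per-species
#'   sampling of deeply diverged taxa. Replacements are drawn from the
#'   local composition profile, so bias survives saturation.
#' @param indel_rate single-residue indels per residue per unit branch
#'   length, confined to the disordered region; the default 0 keeps truth
#'   coordinates identical across taxa.
#' @param n_decoys unrelated families included per genome.
#' @param decoy_length decoy protein length.
#' @param n_paralogs extra within-genome copies of the focal protein
#'   (default 0, mirroring the near-absence of species paralogs in the
#'   target family).
#' @return A validated `evol_params` list.
#' @export
evol_params <- function(n_taxa = 16L, birth_rate = 1,
                        gain_rate = 0.5, loss_rate = 0.2, root_state = 0L,
                        core_length = 200L,
                        id_length_mean = 250, id_length_sd = 25,
                        composition_profiles = NULL,
                        repeat_tracks = list(c("REE", "5"), c("AEVP", "4")),
                        motif_specs = NULL,
                        substitution_rate = 0.05, id_substitution_rate = 3,
                        indel_rate = 0,
                        n_decoys = 3L, decoy_length = 300L,
                        n_paralogs = 0L) {
  if (is.null(composition_profiles)) {
    composition_profiles <- list(
      RNQ = .biased_profile(c(R = 0.214, N = 0.101, Q = 0.091)),
      AEPV = .biased_profile(c(A = 0.208, E = 0.138, P = 0.106, V = 0.127))
    )
  }
  if (is.null(motif_specs)) {
    # anchors chosen well clear of the default repeat tracks: repeat-motif
    # erasure during discovery may mask a few residues beyond a track, so
    # planted instances keep a margin from it
    motif_specs <- list(
      m1 = motif_spec("LRDLFSQAGIRELHE", anchor = 0.35),
      m2 = motif_spec("WQKPYTVGSNHEAFM", anchor = 0.62)
    )
  }
  p <- list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
            gain_rate = gain_rate, loss_rate = loss_rate,
            root_state = as.integer(root_state),
            core_length = as.integer(core_length),
            id_length_mean = id_length_mean, id_length_sd = id_length_sd,
            composition_profiles = composition_profiles,
            repeat_tracks = repeat_tracks, motif_specs = motif_specs,
            substitution_rate = substitution_rate,
            id_substitution_rate = id_substitution_rate,
            indel_rate = indel_rate,
            n_decoys = as.integer(n_decoys),
            decoy_length = as.integer(decoy_length),
            n_paralogs = as.integer(n_paralogs))
  .validate_evol_params(p)
  structure(p, class = "evol_params")
}

.biased_profile <- function(biased) {
  rest <- setdiff(AA20, names(biased))
  out <- stats::setNames(rep((1 - sum(biased)) / length(rest), 20L), AA20)
  out[names(biased)] <- biased
  out
}

.validate_evol_params <- function(p) {
  stopifnot(p$n_taxa >= 2L, p$birth_rate > 0,
            p$gain_rate >= 0, p$loss_rate >= 0,
            p$root_state %in% c(0L, 1L),
            p$core_length >= 0L, p$id_length_mean > 0,
            p$id_length_sd >= 0, p$substitution_rate >= 0,
            p$id_substitution_rate >= 0,
            p$indel_rate >= 0, p$n_decoys >= 0L, p$n_paralogs >= 0L)
  for (pr in p$composition_profiles) {
    if (abs(sum(pr) - 1) > 1e-9 || any(pr < 0)) {
      stop("every composition profile must be a nonnegative vector ",
           "summing to 1 (within 1e-9)")
    }
  }
  for (ms in p$motif_specs) {
    if (!inherits(ms, "motif_spec")) stop("motif_specs must be motif_spec()s")
  }
  invisible(p)
}

# Draw n residues from a frequency profile.
.draw_residues <- function(n, profile) {
  sample(AA20, n, replace = TRUE, prob = profile)
}

# Shift tracked 1-based coordinates for a single-residue insertion before
# position p / deletion of position p.
.shift_ins <- function(x, p) ifelse(x >= p, x + 1L, x)
.shift_del <- function(x, p) ifelse(x > p, x - 1L, x)

# Evolve a lineage state (chars, zone, feature coords) along one branch.
# zone: 1 = core, 1+i = composition profile segment i. feats: data.frame
# kind/label/start/end; anchors: per-motif instance start positions.
.evolve_branch <- function(st, t_len, p) {
  L <- length(st$chars)
  core_pos <- which(st$zone == 1L)
  id_pos <- which(st$zone > 1L)
  n_core <- stats::rpois(1L, p$substitution_rate * length(core_pos) * t_len)
  if (n_core > 0L && length(core_pos)) {
    for (q in core_pos[sample.int(length(core_pos), n_core,
                                  replace = TRUE)]) {
      st$chars[q] <- sample(AA20, 1L)
    }
  }
  n_id <- stats::rpois(1L,
                       p$id_substitution_rate * length(id_pos) * t_len)
  if (n_id > 0L && length(id_pos)) {
    for (q in id_pos[sample.int(length(id_pos), n_id, replace = TRUE)]) {
      st$chars[q] <- sample(AA20, 1L,
                            prob = p$composition_profiles[[st$zone[q] - 1L]])
    }
  }
  if (p$indel_rate > 0) {
    n_ind <- stats::rpois(1L, p$indel_rate * L * t_len)
    for (k in seq_len(n_ind)) {
      idr <- which(st$zone > 1L)
      if (length(idr) < 2L) break
      q <- sample(idr, 1L)
      if (stats::runif(1L) < 0.5) { # insertion before q
        prof <- p$composition_profiles[[st$zone[q] - 1L]]
        st$chars <- append(st$chars, sample(AA20, 1L, prob = prof), q - 1L)
        st$zone <- append(st$zone, st$zone[q], q - 1L)
        st$feats$start <- .shift_ins(st$feats$start, q)
        st$feats$end <- ifelse(st$feats$end >= q - 1L &
                                 st$feats$start < q,
                               st$feats$end + 1L,
                               .shift_ins(st$feats$end, q))
        st$anchors <- .shift_ins(st$anchors, q)
      } else { # deletion of q
        st$chars <- st$chars[-q]
        st$zone <- st$zone[-q]
        inside <- st$feats$start <= q & st$feats$end >= q
        st$feats$end[inside] <- st$feats$end[inside] - 1L
        st$feats$start <- .shift_del(st$feats$start, q)
        st$feats$end[!inside] <- .shift_del(st$feats$end[!inside], q)
        st$feats <- st$feats[st$feats$end >= st$feats$start, , drop = FALSE]
        st$anchors <- .shift_del(st$anchors, q)
      }
    }
  }
  st
}

# Build the root state of the focal family.
.root_state_focal <- function(p) {
  core <- .draw_residues(p$core_length, rep(1 / 20, 20L))
  id_len <- max(p$core_length > 0L, round(stats::rnorm(
    1L, p$id_length_mean, p$id_length_sd)))
  id_len <- max(id_len, 50L)
  n_seg <- length(p$composition_profiles)
  seg_len <- diff(round(seq(0, id_len, length.out = n_seg + 1L)))
  id_chars <- character(0)
  zone <- rep(1L, p$core_length)
  feats <- data.frame(kind = character(0), label = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  offset <- p$core_length
  for (i in seq_len(n_seg)) {
    seg <- .draw_residues(seg_len[i], p$composition_profiles[[i]])
    # drop a repeat track into the middle of its segment
    if (length(p$repeat_tracks) >= 1L) {
      tr <- p$repeat_tracks[[(i - 1L) %% length(p$repeat_tracks) + 1L]]
      unit <- strsplit(tr[1L], "", fixed = TRUE)[[1L]]
      ncop <- as.integer(tr[2L])
      rep_seq <- rep(unit, ncop)
      if (length(rep_seq) < seg_len[i]) {
        at <- max(1L, (seg_len[i] - length(rep_seq)) %/% 2L)
        seg[at:(at + length(rep_seq) - 1L)] <- rep_seq
        feats <- rbind(feats, data.frame(
          kind = "repeat", label = tr[1L],
          start = offset + at, end = offset + at + length(rep_seq) - 1L,
          stringsAsFactors = FALSE))
      }
    }
    feats <- rbind(feats, data.frame(
      kind = "cb_segment", label = names(p$composition_profiles)[i],
      start = offset + 1L, end = offset + seg_len[i],
      stringsAsFactors = FALSE))
    id_chars <- c(id_chars, seg)
    zone <- c(zone, rep(i + 1L, seg_len[i]))
    offset <- offset + seg_len[i]
  }
  # motif anchors: instance start positions inside the disordered region
  anchors <- vapply(p$motif_specs, function(ms) {
    a <- p$core_length + 1L + round(ms$anchor * (id_len - ms$width))
    if (a < p$core_length + 1L || a + ms$width - 1L > p$core_length + id_len) {
      stop("motif anchor falls outside the disordered region")
    }
    as.integer(a)
  }, 0L)
  list(chars = c(core, id_chars), zone = zone, feats = feats,
       anchors = anchors)
}

#' Generate proteomes on a tree with planted motif characters
#'
#' Evolves the focal family (conserved core + disordered region) and decoy
#' families along the tree by per-residue substitution (and optional
#' single-residue indels in the disordered region), then, at each leaf and
#' for each motif whose character is 1, overwrites the residues at the
#' motif's anchor with an instance drawn from its PWM. Replacement (rather
#' than insertion) keeps the length distribution independent of character
#' state, so motif presence is a sequence signal, not a length signal.
#'
#' @param tree an [ape::phylo] from [sample_tree()] (or compatible).
#' @param params an [evol_params()] object.
#' @param characters integer matrix motifs x leaves (0/1), e.g. from
#'   [simulate_binary_character()]; row order = `params$motif_specs`.
#' @param seed integer seed.
#' @return A list: `proteomes` (named list genome -> named character vector
#'   of protein sequences), `manifest` (data.frame genome, species), and
#'   `truth` (list with tree text, characters, motif instance coordinates,
#'   composition-bias segments, repeats, core boundaries, family map).
#' @export
generate_proteome <- function(tree, params, characters, seed = NULL) {
  .validate_evol_params(params)
  ti <- tree_index(tree)
  leaves <- ti$labels[seq_len(ti$n_tip)]
  n_motif <- length(params$motif_specs)
  if (is.null(dim(characters))) {
    characters <- matrix(characters, nrow = n_motif)
  }
  if (nrow(characters) != n_motif || ncol(characters) != length(leaves)) {
    stop("'characters' must be a motifs x leaves matrix")
  }
  if (is.null(colnames(characters))) colnames(characters) <- leaves
  if (is.null(rownames(characters))) {
    rownames(characters) <- names(params$motif_specs)
  }

  with_seed(seed, {
    root_focal <- .root_state_focal(params)
    decoy_roots <- lapply(seq_len(params$n_decoys), function(d) {
      .draw_residues(params$decoy_length, rep(1 / 20, 20L))
    })
    # preorder sequence evolution; lineage states stored per node
    states <- vector("list", ti$n_tip + ti$n_node)
    dstates <- vector("list", ti$n_tip + ti$n_node)
    states[[ti$root]] <- root_focal
    dstates[[ti$root]] <- decoy_roots
    for (u in rev(ti$postorder)) {
      for (v in ti$children[[u]]) {
        states[[v]] <- .evolve_branch(states[[u]], ti$brlen[v], params)
        dstates[[v]] <- lapply(dstates[[u]], function(dc) {
          st <- list(chars = dc, zone = rep(1L, length(dc)),
                     feats = data.frame(), anchors = integer(0))
          .evolve_branch(st, ti$brlen[v], params)$chars
        })
      }
    }

    proteomes <- list()
    inst <- list(); cbs <- list(); reps <- list(); cores <- list()
    for (li in seq_along(leaves)) {
      leaf <- leaves[li]
      v <- which(ti$labels == leaf)
      st <- states[[v]]
      core_end <- sum(st$zone == 1L)
      # re-stamp repeat tracks (slippage maintains repeats against drift)
      if (nrow(st$feats)) {
        for (fi in which(st$feats$kind == "repeat")) {
          unit <- strsplit(st$feats$label[fi], "", fixed = TRUE)[[1L]]
          span <- st$feats$start[fi]:st$feats$end[fi]
          st$chars[span] <- rep(unit, length.out = length(span))
        }
      }
      # plant motif instances where the character is present
      for (mi in seq_len(n_motif)) {
        if (characters[mi, leaf] != 1L) next
        ms <- params$motif_specs[[mi]]
        a <- st$anchors[mi]
        a <- min(max(a, core_end + 1L), length(st$chars) - ms$width + 1L)
        site <- vapply(seq_len(ms$width), function(k) {
          sample(AA20, 1L, prob = ms$pwm[, k])
        }, "")
        st$chars[a:(a + ms$width - 1L)] <- site
        inst[[length(inst) + 1L]] <- data.frame(
          genome = leaf, protein = "P1", motif = rownames(characters)[mi],
          start = a, end = a + ms$width - 1L, stringsAsFactors = FALSE)
      }
      prot <- c(P1 = paste(st$chars, collapse = ""))
      # paralogs: extra focal copies diverged by an extra unit of evolution
      for (pk in seq_len(params$n_paralogs)) {
        pst <- .evolve_branch(st, 1, params)
        prot[[paste0("P1b", pk)]] <- paste(pst$chars, collapse = "")
      }
      for (d in seq_len(params$n_decoys)) {
        prot[[sprintf("D%d", d)]] <- paste(dstates[[v]][[d]], collapse = "")
      }
      proteomes[[leaf]] <- prot
      if (nrow(st$feats)) {
        fk <- cbind(genome = leaf, protein = "P1", st$feats,
                    stringsAsFactors = FALSE)
        cbs[[length(cbs) + 1L]] <- fk[fk$kind == "cb_segment", ]
        reps[[length(reps) + 1L]] <- fk[fk$kind == "repeat", ]
      }
      cores[[length(cores) + 1L]] <- data.frame(
        genome = leaf, protein = "P1", core_end = core_end,
        stringsAsFactors = FALSE)
    }
    bind <- function(x) if (length(x)) do.call(rbind, x) else
      data.frame(genome = character(0))
    families <- data.frame(
      protein = c("P1", sprintf("D%d", seq_len(params$n_decoys))),
      family = c("focal", sprintf("decoy%d", seq_len(params$n_decoys))),
      stringsAsFactors = FALSE)
    list(
      proteomes = proteomes,
      manifest = data.frame(genome = leaves, species = leaves,
                            stringsAsFactors = FALSE),
      truth = list(
        tree_newick = ape::write.tree(tree),
        characters = characters,
        motif_instances = bind(inst),
        cb_segments = bind(cbs),
        repeats = bind(reps),
        core_boundaries = bind(cores),
        families = families
      )
    )
  })
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper: Yule tree, one binary character per configured
#' motif, and proteomes, all from a single master seed. The returned truth
#' bundle additionally carries the true node states and flip events of
#' every character.
#'
#' @param params an [evol_params()] object.
#' @param seed master integer seed.
#' @param characters optional fixed motifs x leaves 0/1 matrix (column
#'   names = leaf labels) overriding the forward character simulation,
#'   e.g. to confine each motif to a chosen clade.
#' @return A list: `tree`, `proteomes`, `manifest`, `truth` (as in
#'   [generate_proteome()], plus `node_states` and `events` per motif when
#'   characters were simulated).
#' @export
simulate_dataset <- function(params = evol_params(), seed = 1L,
                             characters = NULL) {
  tree <- sample_tree(params$n_taxa, params$birth_rate,
                      seed = derive_seed(seed, 1L))
  n_motif <- length(params$motif_specs)
  node_states <- list(); events <- list()
  if (is.null(characters)) {
    chars <- matrix(0L, n_motif, params$n_taxa,
                    dimnames = list(names(params$motif_specs),
                                    tree$tip.label))
    for (mi in seq_len(n_motif)) {
      sim <- simulate_binary_character(
        tree, params$gain_rate, params$loss_rate, params$root_state,
        seed = derive_seed(seed, 100L + mi))
      chars[mi, ] <- sim$leaf_states[tree$tip.label, 1L]
      node_states[[mi]] <- sim$node_states[, 1L]
      events[[mi]] <- sim$events
    }
    names(node_states) <- names(events) <- rownames(chars)
  } else {
    chars <- characters[, tree$tip.label, drop = FALSE]
  }
  gp <- generate_proteome(tree, params, chars,
                          seed = derive_seed(seed, 2L))
  gp$tree <- tree
  gp$truth$node_states <- node_states
  gp$truth$events <- events
  gp
}
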