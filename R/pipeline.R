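# End-to-end driver: simulate (or load) proteomes, infer the orthology
# graph, extract families, annotate the noncatalytic region, discover
# motifs, encode presence/absence, reconstruct ancestral states, and emit
# a per-motif gain report. Stages are checkpointed by directory with a
# config-hash marker so a rerun with the same config and seed either skips
# cleanly or reproduces every output byte-identically.

#' Assemble and validate a pipeline configuration
#'
#' Either `simulate` (an [evol_params()] object) or `input` (paths to
#' existing data) must be given.
#'
#' @param outdir output directory; stage subdirectories are created inside.
#' @param seed master seed for every stochastic stage.
#' @param simulate an [evol_params()] object, or `NULL`.
#' @param input list with `proteome_dir`, `tree`, `manifest` (TSV with
#'   columns genome, species) and optionally `core_tsv` (TSV with columns
#'   genome, protein, core_end), or `NULL`.
#' @param orthology list: `matrix`, `gap_open`, `gap_extend`,
#'   `score_floor`, `class_filter`.
#' @param mcl list: `inflation`.
#' @param features list: `p_max`, `min_len`, `max_len` for the
#'   composition-bias scan; `min_period`, `max_period`, `min_copies`,
#'   `min_identity` for tandem repeats.
#' @param motifs list: `w_min`, `w_max`, `n_motifs`, `sig_floor`,
#'   `min_bits` (NULL = per-motif default).
#' @param ancestral list: `tau`, `root_prior`.
#' @param report list: `presence_cutoff`, `clade_labels` (named vector
#'   internal-node label -> clade name; default: every internal node is
#'   its own clade).
#' @param focal_family optional cluster id to use as the focal family
#'   instead of the widest-coverage cluster.
#' @param simulate_characters optional fixed character matrix handed to
#'   [simulate_dataset()] (simulate mode only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed,
                            simulate = NULL, input = NULL,
                            orthology = list(), mcl = list(),
                            features = list(), motifs = list(),
                            ancestral = list(), report = list(),
                            focal_family = NULL,
                            simulate_characters = NULL) {
  if (is.null(simulate) == is.null(input)) {
    stop("give exactly one of 'simulate' or 'input'")
  }
  if (!is.null(simulate)) .validate_evol_params(simulate)
  if (!is.null(input)) {
    need <- c("proteome_dir", "tree", "manifest")
    miss <- setdiff(need, names(input))
    if (length(miss)) stop("input lacks: ", paste(miss, collapse = ", "))
    for (f in unlist(input[need])) {
      if (!file.exists(f)) stop("input path does not exist: ", f)
    }
  }
  if (is.null(seed)) stop("a seed is mandatory")
  merge_defaults <- function(user, defs) {
    for (k in names(user)) defs[[k]] <- user[[k]]
    defs
  }
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    simulate = simulate, input = input,
    orthology = merge_defaults(orthology, list(
      matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
      score_floor = 0, class_filter = "one_to_one")),
    mcl = merge_defaults(mcl, list(inflation = 2)),
    features = merge_defaults(features, list(
      p_max = 1e-15, min_len = 10L, max_len = 500L,
      min_period = 1L, max_period = 12L, min_copies = 3L,
      min_identity = 0.8)),
    motifs = merge_defaults(motifs, list(
      w_min = 10L, w_max = 25L, n_motifs = 30L, sig_floor = 10,
      min_bits = NULL)),
    ancestral = merge_defaults(ancestral, list(
      tau = 0.92, root_prior = "stationary")),
    report = merge_defaults(report, list(
      presence_cutoff = 0.5, clade_labels = NULL)),
    focal_family = focal_family,
    simulate_characters = simulate_characters
  )
  class(cfg) <- "pipeline_config"
  cfg
}

# Hash a config (or any R object) through a serialized temp file.
.obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}

# A stage is current when its marker carries the same config hash.
.stage_done <- function(dir, hash) {
  marker <- file.path(dir, ".done")
  file.exists(marker) && identical(readLines(marker, warn = FALSE)[1L], hash)
}
.stage_mark <- function(dir, hash) {
  writeLines(hash, file.path(dir, ".done"))
}

#' Run the full gain/loss analysis pipeline
#'
#' Executes, in order: simulate (or load inputs), orthology, clustering,
#' noncatalytic extraction + features, motif discovery and scanning,
#' presence matrix, ancestral reconstruction, and the final report. Each
#' stage writes its outputs into a numbered subdirectory of
#' `config$outdir` and is skipped on rerun when already current for this
#' config. A failure aborts with the stage name and the offending input.
#'
#' @param config a [pipeline_config()].
#' @param force rerun all stages even when current.
#' @return Invisibly, a list with the final `report` (data.frame), the
#'   `gain` results, `presence` matrix, discovered `motifs`, `tree`, and
#'   paths of all stage directories.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must come from pipeline_config()")
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .obj_hash(config[setdiff(names(config), "outdir")])
  stage_dirs <- file.path(outdir, c(
    "01_simulate", "02_orthology", "03_cluster", "04_features",
    "05_motifs", "06_presence", "07_ancestral", "08_report"))
  names(stage_dirs) <- c("simulate", "orthology", "cluster", "features",
                         "motifs", "presence", "ancestral", "report")
  run_stage <- function(name, fun) {
    d <- stage_dirs[[name]]
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    tryCatch(fun(d), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## 1. inputs -------------------------------------------------------------
  d1 <- stage_dirs[["simulate"]]
  if (!is.null(config$simulate)) {
    if (force || !.stage_done(d1, hash)) {
      dir.create(d1, showWarnings = FALSE, recursive = TRUE)
      ds <- simulate_dataset(config$simulate, seed = config$seed,
                             characters = config$simulate_characters)
      write_proteomes(ds$proteomes, file.path(d1, "proteomes"))
      writeLines(ape::write.tree(ds$tree), file.path(d1, "tree.nwk"))
      write_tsv(ds$manifest, file.path(d1, "manifest.tsv"))
      write_truth_bundle(ds, file.path(d1, "truth"))
      .stage_mark(d1, hash)
    }
    proteomes <- read_proteomes(file.path(d1, "proteomes"))
    tree <- read_species_tree(file.path(d1, "tree.nwk"))
    manifest <- read_tsv(file.path(d1, "manifest.tsv"))
    core_tab <- read_tsv(file.path(d1, "truth", "core_boundaries.tsv"))
  } else {
    proteomes <- read_proteomes(config$input$proteome_dir)
    tree <- read_species_tree(config$input$tree)
    manifest <- read_tsv(config$input$manifest)
    core_tab <- if (!is.null(config$input$core_tsv)) {
      read_tsv(config$input$core_tsv)
    } else {
      NULL
    }
  }

  ## 2. orthology ----------------------------------------------------------
  d2 <- run_stage("orthology", function(d) {
    if (!force && .stage_done(d, hash)) return(d)
    oc <- config$orthology
    pairs <- orthology_all(proteomes, matrix = oc$matrix,
                           gap_open = oc$gap_open,
                           gap_extend = oc$gap_extend,
                           score_floor = oc$score_floor)
    write_tsv(pairs, file.path(d, "pairs.tsv"))
    all_nodes <- unlist(lapply(names(proteomes), function(g) {
      paste(g, names(proteomes[[g]]), sep = "|")
    }))
    g <- build_graph(pairs, oc$class_filter, vertices = all_nodes)
    el <- igraph::as_edgelist(g)
    write_tsv(data.frame(a = el[, 1L], b = el[, 2L],
                         stringsAsFactors = FALSE),
              file.path(d, "edges.tsv"))
    writeLines(sort(all_nodes, method = "radix"),
               file.path(d, "nodes.txt"))
    .stage_mark(d, hash)
    d
  })
  pairs <- read_tsv(file.path(d2, "pairs.tsv"))
  nodes <- readLines(file.path(d2, "nodes.txt"))
  graph <- build_graph(pairs, config$orthology$class_filter,
                       vertices = nodes)

  ## 3. families -----------------------------------------------------------
  d3 <- run_stage("cluster", function(d) {
    if (!force && .stage_done(d, hash)) return(d)
    cl <- mcl_cluster(graph, inflation = config$mcl$inflation)
    write_tsv(data.frame(node = names(cl$membership),
                         cluster = unname(cl$membership),
                         stringsAsFactors = FALSE),
              file.path(d, "clusters.tsv"))
    write_tsv(family_summary(cl$membership),
              file.path(d, "families.tsv"))
    .stage_mark(d, hash)
    d
  })
  clusters <- read_tsv(file.path(d3, "clusters.tsv"))
  fam <- read_tsv(file.path(d3, "families.tsv"))
  focal_cluster <- config$focal_family
  if (is.null(focal_cluster)) {
    # widest species coverage; ties broken by mean protein length (the
    # focal family's long noncatalytic extension), then by cluster id
    node_len <- vapply(clusters$node, function(nd) {
      g <- sub("\\|.*$", "", nd)
      p <- sub("^[^|]*\\|", "", nd)
      nchar(proteomes[[g]][[p]])
    }, 0L)
    mean_len <- tapply(node_len, clusters$cluster, mean)
    fam$mean_len <- as.numeric(mean_len[as.character(fam$cluster)])
    fam <- fam[order(-fam$n_genomes, -fam$mean_len, fam$cluster), ,
               drop = FALSE]
    focal_cluster <- fam$cluster[1L]
  }
  focal_nodes <- sort(clusters$node[clusters$cluster == focal_cluster],
                      method = "radix")
  focal_genome <- sub("\\|.*$", "", focal_nodes)
  focal_nodes <- focal_nodes[!duplicated(focal_genome)] # one member/genome
  focal_genome <- focal_genome[!duplicated(focal_genome)]
  focal_protein <- sub("^[^|]*\\|", "", focal_nodes)
  focal_seqs <- vapply(seq_along(focal_nodes), function(i) {
    proteomes[[focal_genome[i]]][[focal_protein[i]]]
  }, "")
  names(focal_seqs) <- focal_genome

  ## 4. noncatalytic region + features -------------------------------------
  core_end_of <- function(genome, protein) {
    if (is.null(core_tab)) return(0L)
    hit <- core_tab$core_end[core_tab$genome == genome &
                               core_tab$protein == protein]
    if (length(hit)) as.integer(hit[1L]) else 0L
  }
  core_ends <- vapply(seq_along(focal_genome), function(i) {
    core_end_of(focal_genome[i], focal_protein[i])
  }, 0L)
  noncat <- vapply(seq_along(focal_seqs), function(i) {
    extract_noncatalytic(focal_seqs[[i]], core_ends[i])
  }, "")
  names(noncat) <- focal_genome
  d4 <- run_stage("features", function(d) {
    if (!force && .stage_done(d, hash)) return(d)
    fc <- config$features
    bg <- residue_frequencies(unlist(proteomes, use.names = FALSE))
    feats <- list()
    for (g in names(noncat)) {
      cb <- lps_scan(noncat[[g]], bg, p_max = fc$p_max,
                     min_len = fc$min_len, max_len = fc$max_len)
      if (nrow(cb)) {
        feats[[length(feats) + 1L]] <- data.frame(
          genome = g, kind = "composition_bias",
          start = cb$start + core_ends[match(g, focal_genome)],
          end = cb$end + core_ends[match(g, focal_genome)],
          score = cb$log10_p, signature = cb$signature,
          stringsAsFactors = FALSE)
      }
      tr <- find_tandem_repeats(noncat[[g]], fc$min_period, fc$max_period,
                                fc$min_copies, fc$min_identity)
      if (nrow(tr)) {
        feats[[length(feats) + 1L]] <- data.frame(
          genome = g, kind = "tandem_repeat",
          start = tr$start + core_ends[match(g, focal_genome)],
          end = tr$end + core_ends[match(g, focal_genome)],
          score = tr$identity, signature = tr$consensus,
          stringsAsFactors = FALSE)
      }
      di <- disorder_index(noncat[[g]])
      feats[[length(feats) + 1L]] <- data.frame(
        genome = g, kind = "disorder_fraction_heuristic",
        start = core_ends[match(g, focal_genome)] + 1L,
        end = core_ends[match(g, focal_genome)] + nchar(noncat[[g]]),
        score = mean(di < 0), signature = "charge-hydropathy",
        stringsAsFactors = FALSE)
    }
    write_tsv(if (length(feats)) do.call(rbind, feats) else
      data.frame(), file.path(d, "features.tsv"))
    .stage_mark(d, hash)
    d
  })

  ## 5. motif discovery and scanning ---------------------------------------
  d5 <- run_stage("motifs", function(d) {
    if (!force && .stage_done(d, hash)) return(d)
    mc <- config$motifs
    motifs <- discover_motifs(noncat, w_min = mc$w_min, w_max = mc$w_max,
                              n_motifs = mc$n_motifs,
                              sig_floor = mc$sig_floor,
                              seed = derive_seed(config$seed, 50L))
    if (length(motifs)) {
      write_meme(motifs, file.path(d, "motifs.meme"))
      occ <- scan_motifs(motifs, noncat, mc$min_bits)
      occ$genome <- occ$protein
      occ$start <- occ$start + core_ends[match(occ$genome, focal_genome)]
      write_tsv(occ[, c("genome", "motif", "start", "score")],
                file.path(d, "occurrences.tsv"))
    } else {
      writeLines(character(0), file.path(d, "motifs.meme"))
      write_tsv(data.frame(genome = character(0), motif = integer(0),
                           start = integer(0), score = numeric(0)),
                file.path(d, "occurrences.tsv"))
    }
    .stage_mark(d, hash)
    d
  })
  motifs <- if (file.size(file.path(d5, "motifs.meme")) > 0) {
    read_meme(file.path(d5, "motifs.meme"))
  } else {
    list()
  }
  occ <- read_tsv(file.path(d5, "occurrences.tsv"))

  ## 6. presence matrix -----------------------------------------------------
  d6 <- run_stage("presence", function(d) {
    if (!force && .stage_done(d, hash)) return(d)
    pm <- presence_matrix(occ, manifest)
    write_presence_matrix(pm, file.path(d, "presence.tsv"))
    .stage_mark(d, hash)
    d
  })
  pm <- read_presence_matrix(file.path(d6, "presence.tsv"))

  ## 7. ancestral reconstruction --------------------------------------------
  d7 <- run_stage("ancestral", function(d) {
    if (!force && .stage_done(d, hash)) return(d)
    if (nrow(pm)) {
      gr <- gain_report(tree, pm, tau = config$ancestral$tau,
                        root_prior = config$ancestral$root_prior)
      write_tsv(gr$report, file.path(d, "gain_report.tsv"))
      marg <- do.call(rbind, lapply(names(gr$marginals), function(m) {
        x <- gr$marginals[[m]]
        data.frame(motif = m, node = rownames(x), P0 = x[, 1L],
                   P1 = x[, 2L], stringsAsFactors = FALSE)
      }))
      write_tsv(marg, file.path(d, "marginals.tsv"))
    } else {
      write_tsv(data.frame(), file.path(d, "gain_report.tsv"))
      write_tsv(data.frame(), file.path(d, "marginals.tsv"))
    }
    .stage_mark(d, hash)
    d
  })
  gain <- read_tsv(file.path(d7, "gain_report.tsv"))

  ## 8. report ---------------------------------------------------------------
  d8 <- run_stage("report", function(d) {
    if (!force && .stage_done(d, hash)) return(d)
    if (nrow(gain)) {
      txd <- taxonomic_distribution(pm, tree,
                                    config$report$clade_labels,
                                    config$report$presence_cutoff)
      widths <- vapply(motifs, function(m) m$width, 0L)
      cons <- vapply(motifs, function(m) m$consensus, "")
      ranks <- vapply(motifs, function(m) m$rank, 0L)
      i <- match(gain$motif, as.character(ranks))
      rep_df <- data.frame(
        rank = gain$motif,
        width = widths[i],
        consensus = cons[i],
        taxonomic_distribution = vapply(
          as.character(gain$motif),
          function(m) paste(txd[[m]], collapse = ","), ""),
        gain = round(gain$scaled_likelihood, 2),
        n_gains = gain$n_gains,
        gain_nodes = gain$gain_nodes,
        call = gain$call,
        stringsAsFactors = FALSE)
      write_tsv(rep_df, file.path(d, "report.tsv"))
    } else {
      write_tsv(data.frame(), file.path(d, "report.tsv"))
    }
    .stage_mark(d, hash)
    d
  })
  report <- read_tsv(file.path(d8, "report.tsv"))

  invisible(list(report = report, gain = gain, presence = pm,
                 motifs = motifs, tree = tree, manifest = manifest,
                 stage_dirs = stage_dirs))
}

#' Clade distribution of motifs on the tree
#'
#' For each motif, lists the labelled clades in which the fraction of leaf
#' species carrying the motif reaches `presence_cutoff`. Clades are
#' reported shallowest-first (by node depth from the root); nested clades
#' can both appear.
#'
#' @param pm binary presence matrix, motifs x species.
#' @param tree an [ape::phylo] with internal node labels.
#' @param clade_labels named character vector: internal node label ->
#'   clade name; `NULL` labels every internal node with itself.
#' @param presence_cutoff fraction in (0, 1].
#' @return Named list: motif -> character vector of clade names.
#' @export
taxonomic_distribution <- function(pm, tree, clade_labels = NULL,
                                   presence_cutoff = 0.5) {
  ti <- tree_index(tree)
  if (is.null(clade_labels)) {
    clade_labels <- stats::setNames(tree$node.label, tree$node.label)
  }
  bad <- setdiff(names(clade_labels), tree$node.label)
  if (length(bad)) {
    stop("unknown clade nodes: ", paste(bad, collapse = ", "))
  }
  depth <- integer(ti$n_tip + ti$n_node)
  for (u in rev(ti$postorder)) {
    for (v in ti$children[[u]]) depth[v] <- depth[u] + 1L
  }
  # leaves under each labelled node
  leaves_under <- function(v) {
    out <- integer(0)
    stack <- v
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      if (x <= ti$n_tip) out <- c(out, x) else
        stack <- c(ti$children[[x]], stack)
    }
    ti$labels[out]
  }
  node_ids <- match(names(clade_labels), tree$node.label) + ti$n_tip
  ord <- order(depth[node_ids], names(clade_labels), method = "radix")
  node_ids <- node_ids[ord]
  clade_names <- unname(clade_labels[ord])
  out <- list()
  for (m in rownames(pm)) {
    hit <- character(0)
    for (k in seq_along(node_ids)) {
      lv <- leaves_under(node_ids[k])
      lv <- intersect(lv, colnames(pm))
      if (length(lv) && mean(pm[m, lv]) >= presence_cutoff) {
        hit <- c(hit, clade_names[k])
      }
    }
    out[[m]] <- hit
  }
  out
}

#' Choose two disjoint clades with long stem branches
#'
#' Scenario helper for simulation studies: among internal (non-root) nodes
#' with `min_leaves` to `max_leaves` descendant species, picks the clade
#' with the longest stem branch, then the longest-stem clade disjoint from
#' it. Characters gained on long stem branches are the identifiable cases
#' for ancestral reconstruction, mirroring the deep inter-order stems on
#' which confidently dated motif acquisitions sit in real species trees.
#'
#' @param tree an [ape::phylo] with internal node labels.
#' @param min_leaves,max_leaves clade size bounds.
#' @return A list with `clade_a`, `clade_b` (internal node labels),
#'   `leaves_a`, `leaves_b` (species sets), or `NULL` when no disjoint
#'   pair exists.
#' @export
pick_scenario_clades <- function(tree, min_leaves = 4L, max_leaves = 8L) {
  ti <- tree_index(tree)
  n <- ti$n_tip
  leaves_under <- function(v) {
    out <- integer(0); stack <- v
    while (length(stack)) {
      x <- stack[[1L]]; stack <- stack[-1L]
      if (x <= n) out <- c(out, x) else stack <- c(ti$children[[x]], stack)
    }
    ti$labels[out]
  }
  ints <- setdiff(seq(n + 1L, n + ti$n_node), ti$root)
  sz <- vapply(ints, function(v) length(leaves_under(v)), 0L)
  try_bounds <- function(lo, hi) {
    cand <- ints[sz >= lo & sz <= hi]
    if (length(cand) < 2L) return(NULL)
    cand <- cand[order(-ti$brlen[cand], ti$labels[cand])]
    for (a in cand) {
      la <- leaves_under(a)
      rest <- cand[vapply(cand, function(v) {
        v != a && !length(intersect(leaves_under(v), la))
      }, TRUE)]
      if (length(rest)) {
        b <- rest[1L]
        return(list(clade_a = ti$labels[a], clade_b = ti$labels[b],
                    leaves_a = la, leaves_b = leaves_under(b)))
      }
    }
    NULL
  }
  # widen the size bounds stepwise when this tree shape offers no
  # disjoint pair in the requested range
  for (slack in 0:(n %/% 2L)) {
    hit <- try_bounds(max(2L, min_leaves - slack), max_leaves + slack)
    if (!is.null(hit)) return(hit)
  }
  NULL
}
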