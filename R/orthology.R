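#' Best hits between two proteomes
#'
#' Scores every protein of genome A against every protein of genome B with
#' exact Smith-Waterman (see [local_align_score()]) and flags, for every
#' query protein, its single highest-scoring partner in the other genome.
#' Ties are broken lexicographically by subject protein id; scores below
#' `score_floor` are dropped.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences; names are protein ids, unique within each genome.
#' @param genome_a,genome_b genome identifiers.
#' @param matrix,gap_open,gap_extend scoring parameters, BLASTP defaults.
#' @param score_floor minimum score retained (default 0 = keep all).
#' @return A data.frame hit table covering both query directions:
#'   `qgenome`, `query`, `sgenome`, `subject`, `score`, `best` (logical:
#'   subject is the query's best hit in the subject genome).
#' @export
best_hits <- function(proteome_a, proteome_b, genome_a = "A", genome_b = "B",
                      matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                      score_floor = 0) {
  if (identical(genome_a, genome_b)) stop("genomes must be distinct")
  if (length(proteome_a) == 0L || length(proteome_b) == 0L) {
    warning("empty proteome: returning empty hit table")
    return(.empty_hits())
  }
  .check_proteome(proteome_a); .check_proteome(proteome_b)
  submat <- .resolve_submat(matrix)
  sm <- .score_matrix(proteome_a, proteome_b, submat, gap_open, gap_extend)
  rbind(
    .direction_hits(sm, genome_a, genome_b, score_floor),
    .direction_hits(t(sm), genome_b, genome_a, score_floor)
  )
}

.check_proteome <- function(p) {
  if (is.null(names(p)) || anyDuplicated(names(p))) {
    stop("proteomes must be named character vectors with unique protein ids")
  }
  if (any(!nzchar(p))) stop("empty protein sequence")
  invisible(p)
}

.empty_hits <- function() {
  data.frame(qgenome = character(0), query = character(0),
             sgenome = character(0), subject = character(0),
             score = numeric(0), best = logical(0), stringsAsFactors = FALSE)
}

.direction_hits <- function(sm, qg, sg, floor) {
  subj_order <- order(colnames(sm), method = "radix")
  rows <- lapply(seq_len(nrow(sm)), function(i) {
    sc <- sm[i, ]
    keep <- sc >= floor
    if (!any(keep)) return(NULL)
    # best: highest score, lexicographically-first subject id on ties
    best_j <- subj_order[which.max(sc[subj_order])]
    data.frame(qgenome = qg, query = rownames(sm)[i],
               sgenome = sg, subject = colnames(sm)[keep],
               score = unname(sc[keep]),
               best = colnames(sm)[keep] == colnames(sm)[best_j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .empty_hits() else out
}

#' Within-genome paralog scores
#'
#' Scores every ordered pair of distinct proteins of one genome with the
#' same Smith-Waterman scorer used between genomes; self-hits are excluded.
#' Used by [classify_pairs()] to detect species paralogs.
#'
#' @inheritParams best_hits
#' @param proteome named character vector of protein sequences.
#' @param genome genome identifier.
#' @return data.frame: `genome`, `query`, `subject`, `score`.
#' @export
within_hits <- function(proteome, genome = "A", matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  .check_proteome(proteome)
  if (length(proteome) < 2L) {
    return(data.frame(genome = character(0), query = character(0),
                      subject = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  submat <- .resolve_submat(matrix)
  sm <- .score_matrix(proteome, proteome, submat, gap_open, gap_extend)
  idx <- which(row(sm) != col(sm), arr.ind = TRUE)
  data.frame(genome = genome,
             query = rownames(sm)[idx[, 1L]],
             subject = colnames(sm)[idx[, 2L]],
             score = sm[idx], stringsAsFactors = FALSE)
}

#' Classify protein pairs as best hit, ortholog, or one-to-one ortholog
#'
#' Applies the reciprocal-best-hit orthology rules: if protein `a` of genome
#' A is the best hit of protein `b` of genome B and `b` is the best hit of
#' `a`, then `(a, b)` are orthologs; otherwise the best-hit relation alone
#' is recorded. An ortholog pair is additionally one-to-one when neither
#' genome contains a species paralog scoring higher than the pair itself,
#' i.e. no within-genome score involving `a` (or `b`) strictly exceeds
#' `score(a, b)`.
#'
#' @param hits hit table from [best_hits()] (both directions).
#' @param within_a,within_b within-genome score tables from [within_hits()],
#'   or `NULL` when a genome has a single protein (no paralogs possible).
#' @return data.frame: `genome_a`, `protein_a`, `genome_b`, `protein_b`,
#'   `score`, `class` (one of `"best_hit"`, `"ortholog"`, `"one_to_one"`),
#'   with genome_a/genome_b in the order of the first direction found in
#'   `hits`. Classification is symmetric in the two genomes.
#' @export
classify_pairs <- function(hits, within_a = NULL, within_b = NULL) {
  if (nrow(hits) == 0L) {
    return(data.frame(genome_a = character(0), protein_a = character(0),
                      genome_b = character(0), protein_b = character(0),
                      score = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  genomes <- unique(hits$qgenome)
  if (length(genomes) != 2L) stop("hit table must cover exactly two genomes")
  ga <- genomes[1L]; gb <- genomes[2L]
  ab <- hits[hits$qgenome == ga & hits$best, , drop = FALSE]
  ba <- hits[hits$qgenome == gb & hits$best, , drop = FALSE]
  # sanity: consistent universes
  if (!all(ab$subject %in% hits$query[hits$qgenome == gb]) ||
      !all(ba$subject %in% hits$query[hits$qgenome == ga])) {
    stop("inconsistent protein universes between hit directions")
  }
  best_of <- function(tab) stats::setNames(tab$subject, tab$query)
  b_ab <- best_of(ab)
  b_ba <- best_of(ba)
  max_within <- function(w) {
    if (is.null(w) || nrow(w) == 0L) return(function(p) -Inf)
    mx <- tapply(w$score, w$query, max)
    function(p) if (p %in% names(mx)) unname(mx[[p]]) else -Inf
  }
  mw_a <- max_within(within_a)
  mw_b <- max_within(within_b)

  seen <- character(0)
  rows <- list()
  add_row <- function(pa, pb, score, cls) {
    key <- paste(pa, pb, sep = "\r")
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    rows[[length(rows) + 1L]] <<- data.frame(
      genome_a = ga, protein_a = pa, genome_b = gb, protein_b = pb,
      score = score, class = cls, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ab))) {
    pa <- ab$query[i]; pb <- ab$subject[i]; sc <- ab$score[i]
    if (!is.na(b_ba[pb]) && b_ba[pb] == pa) {
      cls <- if (mw_a(pa) > sc || mw_b(pb) > sc) "ortholog" else "one_to_one"
      add_row(pa, pb, sc, cls)
    } else {
      add_row(pa, pb, sc, "best_hit")
    }
  }
  for (i in seq_len(nrow(ba))) {
    pb <- ba$query[i]; pa <- ba$subject[i]; sc <- ba$score[i]
    if (!is.na(b_ab[pa]) && b_ab[pa] == pb) next # already added as reciprocal
    add_row(pa, pb, sc, "best_hit")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the orthology graph
#'
#' Unweighted, undirected graph over proteins with an edge for every pair
#' whose class passes the filter (`"one_to_one"` keeps only one-to-one
#' orthologs; `"ortholog"` also keeps plain orthologs). Node names are
#' `genome|protein`.
#'
#' @param pairs classified pairs, possibly concatenated over many genome
#'   pairs (rbind of [classify_pairs()] outputs).
#' @param class_filter `"one_to_one"` (default) or `"ortholog"`.
#' @param vertices optional character vector of node names to include even
#'   when isolated.
#' @return An [igraph::graph] object.
#' @export
build_graph <- function(pairs, class_filter = c("one_to_one", "ortholog"),
                        vertices = NULL) {
  class_filter <- match.arg(class_filter)
  keep_classes <- if (class_filter == "one_to_one") "one_to_one"
                  else c("one_to_one", "ortholog")
  keep <- pairs$class %in% keep_classes
  va <- paste(pairs$genome_a, pairs$protein_a, sep = "|")
  vb <- paste(pairs$genome_b, pairs$protein_b, sep = "|")
  verts <- unique(c(vertices, va, vb))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(match(va[keep], verts),
                                    match(vb[keep], verts)))
  }
  igraph::simplify(g)
}

#' Orthology analysis across a set of proteomes
#'
#' Runs [best_hits()] over every genome pair, [within_hits()] per genome,
#' and [classify_pairs()] per pair, returning the pooled classified pairs.
#'
#' @param proteomes named list: genome id -> named character vector of
#'   protein sequences.
#' @inheritParams best_hits
#' @return data.frame of classified pairs over all genome pairs.
#' @export
orthology_all <- function(proteomes, matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1, score_floor = 0) {
  gids <- names(proteomes)
  if (is.null(gids) || anyDuplicated(gids)) {
    stop("'proteomes' must be a named list with unique genome ids")
  }
  within <- lapply(gids, function(g) {
    within_hits(proteomes[[g]], g, matrix, gap_open, gap_extend)
  })
  names(within) <- gids
  out <- list()
  for (i in seq_along(gids)) {
    for (j in seq_along(gids)) {
      if (j <= i) next
      h <- best_hits(proteomes[[i]], proteomes[[j]], gids[i], gids[j],
                     matrix, gap_open, gap_extend, score_floor)
      out[[length(out) + 1L]] <-
        classify_pairs(h, within[[gids[i]]], within[[gids[j]]])
    }
  }
  do.call(rbind, out)
}
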