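# Readers and writers for the plain-text formats the pipeline exchanges:
# per-genome FASTA proteomes with "genome|protein" headers, tab-separated
# tables, and the presence/absence matrix.

#' Write proteomes as per-genome FASTA files
#'
#' @param proteomes named list: genome id -> named character vector of
#'   protein sequences.
#' @param dir output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_proteomes <- function(proteomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in names(proteomes)) {
    x <- Biostrings::AAStringSet(proteomes[[g]])
    names(x) <- paste(g, names(proteomes[[g]]), sep = "|")
    path <- file.path(dir, paste0(g, ".faa"))
    Biostrings::writeXStringSet(x, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read per-genome FASTA proteomes
#'
#' Accepts a directory of `*.faa` / `*.fasta` files or an explicit file
#' vector; headers must be `genome|protein`.
#'
#' @param path directory or files.
#' @return Named list: genome id -> named character vector.
#' @export
read_proteomes <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.(faa|fa|fasta)$", full.names = TRUE)
  } else {
    path
  }
  if (!length(files)) stop("no FASTA files found under ", path)
  out <- list()
  for (f in sort(files, method = "radix")) {
    x <- Biostrings::readAAStringSet(f)
    hdr <- sub("\\s.*$", "", names(x))
    if (any(!grepl("\\|", hdr))) {
      stop("FASTA headers must be 'genome|protein' in ", f)
    }
    genome <- sub("\\|.*$", "", hdr)
    prot <- sub("^[^|]*\\|", "", hdr)
    for (g in unique(genome)) {
      sel <- genome == g
      out[[g]] <- c(out[[g]],
                    stats::setNames(as.character(x[sel]), prot[sel]))
    }
  }
  out
}

#' Write / read a tab-separated table
#'
#' Deterministic TSV with unix line endings and no quoting, so repeated
#' runs are byte-identical and coordinates round-trip unchanged.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Write / read a presence/absence matrix as TSV
#'
#' Motifs in rows (first column `motif`), species in columns.
#'
#' @param pm binary matrix motifs x species.
#' @param path file path.
#' @return `path` invisibly (writer); integer matrix (reader).
#' @export
write_presence_matrix <- function(pm, path) {
  df <- data.frame(motif = rownames(pm), pm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- read_tsv(path)
  pm <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(pm) <- "integer"
  rownames(pm) <- as.character(df[[1L]])
  pm
}

#' Write the truth bundle of a simulated dataset
#'
#' Plain-text ground truth: Newick tree, character matrix, per-feature
#' coordinate tables, per-character node states and flip events, and a
#' JSON index.
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_truth_bundle <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- ds$truth
  writeLines(tr$tree_newick, file.path(dir, "tree.nwk"))
  write_presence_matrix(tr$characters, file.path(dir, "characters.tsv"))
  write_tsv(tr$motif_instances, file.path(dir, "motif_instances.tsv"))
  write_tsv(tr$cb_segments, file.path(dir, "cb_segments.tsv"))
  write_tsv(tr$repeats, file.path(dir, "repeats.tsv"))
  write_tsv(tr$core_boundaries, file.path(dir, "core_boundaries.tsv"))
  write_tsv(tr$families, file.path(dir, "families.tsv"))
  if (!is.null(tr$node_states)) {
    ns <- do.call(rbind, lapply(names(tr$node_states), function(m) {
      data.frame(motif = m, node = names(tr$node_states[[m]]),
                 state = unname(tr$node_states[[m]]),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(ns, file.path(dir, "node_states.tsv"))
    ev <- do.call(rbind, lapply(names(tr$events), function(m) {
      e <- tr$events[[m]]
      if (nrow(e)) cbind(motif = m, e, stringsAsFactors = FALSE) else NULL
    }))
    if (!is.null(ev)) write_tsv(ev, file.path(dir, "events.tsv"))
  }
  jsonlite::write_json(
    list(files = sort(list.files(dir)), n_motifs = nrow(tr$characters)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
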