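#' Smith-Waterman local alignment score
#'
#' Exact local alignment score with affine gap penalties, the deterministic
#' scoring engine behind the orthology rules (raw scores in substitution
#' matrix units; a gap of length L costs `gap_open + L * gap_extend`).
#' Unknown residues are scored through the matrix's `X` column. Local
#' scores are floored at 0.
#'
#' @param seq1,seq2 nonempty amino-acid strings.
#' @param matrix substitution matrix name (a data set of Biostrings, e.g.
#'   `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend positive gap penalties.
#' @return A single nonnegative score; symmetric in its sequence arguments.
#' @examples
#' local_align_score("ACDE", "ACDE")  # 24 under BLOSUM62
#' local_align_score("W", "P")        # 0: local scores never go negative
#' @export
local_align_score <- function(seq1, seq2, matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("sequences must be nonempty")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  submat <- .resolve_submat(matrix)
  s <- Biostrings::pairwiseAlignment(
    pattern = seq1, subject = seq2, type = "local",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  )
  max(0, s)
}

.resolve_submat <- function(matrix) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  } else {
    matrix
  }
}

# All-vs-all local alignment scores between two named sequence vectors.
# Returns a numeric matrix (rows = a, cols = b), floored at 0.
.score_matrix <- function(seqs_a, seqs_b, submat, gap_open, gap_extend) {
  sb <- Biostrings::AAStringSet(seqs_b)
  out <- matrix(0, length(seqs_a), length(seqs_b),
                dimnames = list(names(seqs_a), names(seqs_b)))
  for (i in seq_along(seqs_a)) {
    s <- Biostrings::pairwiseAlignment(
      pattern = sb, subject = seqs_a[[i]], type = "local",
      substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
    out[i, ] <- pmax(0, s)
  }
  out
}
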