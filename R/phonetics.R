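#' Segment-level Levenshtein distance
#'
#' Minimal number of single-segment substitutions, deletions, and additions
#' transforming one transcription into the other.  Segments are
#' single-character tokens (see [staged_lexicon]); the distance is therefore
#' computed on characters, which is exactly segment-level under that
#' contract.  Vectorised over pairs.
#'
#' @param a,b character vectors of transcriptions (recycled to a common
#'   length)
#' @return integer vector of edit distances
#' @examples
#' edit_distance("bat", "pat")  # 1
#' @export
edit_distance <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("transcriptions must be non-empty")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  d <- integer(n)
  for (i in seq_len(n)) d[i] <- utils::adist(a[i], b[i])[1L, 1L]
  d
}

# full cross distance matrix, used by the neighbour finder
edit_distance_matrix <- function(a, b) utils::adist(a, b)

#' One-segment neighbour pairs within a stage vocabulary
#'
#' Finds all unordered pairs of word forms at edit distance exactly 1
#' (substitution, deletion, or addition neighbours).  Candidate pairs are
#' pruned by length: forms whose phoneme counts differ by more than one can
#' never be neighbours, so only equal-length and adjacent-length groups are
#' compared (output-equivalent to the all-pairs scan).
#'
#' @param lexicon a `staged_lexicon`, or a character vector of phon forms
#' @param stage stage whose cumulative vocabulary is scanned (ignored when
#'   `lexicon` is already a character vector)
#' @return data.frame with columns `phon_a`, `phon_b` (each unordered pair
#'   once, `phon_a < phon_b` lexicographically)
#' @export
find_neighbors <- function(lexicon, stage = N_STAGES) {
  forms <- if (inherits(lexicon, "staged_lexicon"))
    stage_vocab(lexicon, stage) else as.character(lexicon)
  forms <- unique(forms)
  if (length(forms) < 2L)
    return(data.frame(phon_a = character(), phon_b = character(),
                      stringsAsFactors = FALSE))
  len <- nchar(forms, type = "chars")
  groups <- split(forms, len)
  lens <- as.integer(names(groups))
  pairs_a <- character(0); pairs_b <- character(0)
  collect <- function(m, rows, cols) {
    hit <- which(m == 1L, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs_a <<- c(pairs_a, rows[hit[, 1L]])
      pairs_b <<- c(pairs_b, cols[hit[, 2L]])
    }
  }
  for (i in seq_along(lens)) {
    g <- groups[[i]]
    if (length(g) > 1L) {
      m <- edit_distance_matrix(g, g)
      m[lower.tri(m, diag = TRUE)] <- NA_integer_  # each pair once
      collect(m, g, g)
    }
    j <- match(lens[i] + 1L, lens)
    if (!is.na(j))
      collect(edit_distance_matrix(g, groups[[j]]), g, groups[[j]])
  }
  if (!length(pairs_a))
    return(data.frame(phon_a = character(), phon_b = character(),
                      stringsAsFactors = FALSE))
  a <- pmin(pairs_a, pairs_b); b <- pmax(pairs_a, pairs_b)
  o <- order(a, b)
  data.frame(phon_a = a[o], phon_b = b[o], stringsAsFactors = FALSE)
}

#' Reverse-rescale a phonetic distance to an integer similarity weight
#'
#' Distances in \[0, 1\] (0 = homophones, 1 = maximal distance) become
#' integer similarity scores in \[0, 100\] (100 = perfect similarity) via
#' `round((1 - d) * 100)`, with halves rounded up.
#'
#' @param d numeric vector of distances in \[0, 1\]
#' @return integer vector of similarity weights
#' @examples
#' rescale_similarity(c(0, 1, 0.368426))  # 100 0 63
#' @export
rescale_similarity <- function(d) {
  if (any(is.na(d)) || any(d < 0) || any(d > 1))
    stop("distances must lie in [0, 1]")
  as.integer(round_half_up((1 - d) * 100))
}
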