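#' Staged lexica: reading, validation, and normalisation
#'
#' A staged lexicon holds one row per phonemic word form with its
#' age-of-acquisition (AoA) stage (1-6, mapped from the CEFR proficiency
#' levels A1-C2), raw and log lexical frequency, phoneme count, and the
#' word's neighbourhood density in a first-language (L1) reference lexicon.
#' Stage vocabularies are cumulative: a word known at stage s is known at all
#' later stages.
#'
#' Transcriptions are strings of single-character segment symbols drawn from
#' a declared inventory; multi-character phonetic symbols (affricates, long
#' vowels, rhotacised vowels ...) must be recoded to unique single characters
#' upstream, which is what makes segment-level edit distance equivalent to
#' character-level edit distance.
#'
#' @name staged_lexicon
NULL

N_STAGES <- 6L

#' Base-10 log-frequency transform
#'
#' `log10(x + 1)`, so that zero frequencies map to zero.
#'
#' @param freq_raw non-negative numeric vector of lexical frequency rates
#' @return non-negative numeric vector
#' @examples
#' log_frequency(99)   # 2
#' log_frequency(0)    # 0
#' @export
log_frequency <- function(freq_raw) {
  if (!is.numeric(freq_raw) || any(is.na(freq_raw)) || any(freq_raw < 0))
    stop("freq_raw must be non-negative and non-missing")
  log10(freq_raw + 1)
}

#' Count segments in a transcription
#'
#' @param phon character vector of transcriptions (single-character segments)
#' @return integer vector of phoneme counts
#' @examples
#' phoneme_count("TINk")  # 4
#' @export
phoneme_count <- function(phon) {
  if (any(is.na(phon)) || any(!nzchar(phon)))
    stop("empty transcription")
  nchar(phon, type = "chars")
}

#' Split a transcription into its segment tokens
#'
#' @param phon a single transcription string
#' @return character vector of segments
#' @export
phon_segments <- function(phon) {
  stopifnot(length(phon) == 1L, nzchar(phon))
  strsplit(phon, "", fixed = TRUE)[[1L]]
}

#' Merge homophonous rows into one lexicon entry
#'
#' Word forms spelled differently but sharing one transcription are merged
#' into a single phonological entry: the raw frequency is the arithmetic mean
#' of the members' frequencies, the AoA stage is the earliest member stage (a
#' form counts as known once any of its spellings is learned), and the
#' orthographic field concatenates the members.
#'
#' @param rows data.frame with columns `orth`, `phon`, `aoa`, `freq_raw`,
#'   `l1_density`, all sharing one `phon`
#' @return one-row data.frame
#' @examples
#' merge_homophones(data.frame(orth = c("plain", "plane"), phon = "pleIn",
#'   aoa = 2L, freq_raw = c(21.8, 95.5), l1_density = 10L))
#' @export
merge_homophones <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("merge_homophones needs at least one row")
  if (length(unique(rows$phon)) != 1L)
    stop("all rows must share one phon form")
  data.frame(
    orth       = paste(unique(rows$orth), collapse = "/"),
    phon       = rows$phon[1L],
    aoa        = as.integer(min(rows$aoa)),
    freq_raw   = mean(rows$freq_raw),
    l1_density = as.integer(max(rows$l1_density)),
    stringsAsFactors = FALSE
  )
}

#' Construct a staged lexicon from a normalized entry table
#'
#' @param entries data.frame with columns `orth`, `phon`, `aoa`, `freq_raw`,
#'   `l1_density`; one row per unique phon form
#' @param inventory character vector of valid segment symbols, or NULL to
#'   accept the symbols present
#' @param dropped integer count of rows discarded during ingestion
#' @return object of class `staged_lexicon`
#' @export
staged_lexicon <- function(entries, inventory = NULL, dropped = 0L) {
  req <- c("orth", "phon", "aoa", "freq_raw", "l1_density")
  miss <- setdiff(req, names(entries))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(entries$phon))
    stop("duplicate phon forms; merge homophones first")
  if (any(!entries$aoa %in% seq_len(N_STAGES)))
    stop("aoa must be an integer stage in 1..", N_STAGES)
  if (any(entries$freq_raw < 0)) stop("freq_raw must be non-negative")
  if (any(entries$l1_density < 0)) stop("l1_density must be non-negative")
  entries$aoa <- as.integer(entries$aoa)
  entries$l1_density <- as.integer(entries$l1_density)
  entries$freq_log <- log_frequency(entries$freq_raw)
  entries$length <- phoneme_count(entries$phon)
  if (is.null(inventory))
    inventory <- sort(unique(unlist(strsplit(entries$phon, "", fixed = TRUE))))
  bad <- !vapply(strsplit(entries$phon, "", fixed = TRUE),
                 function(s) all(s %in% inventory), logical(1L))
  if (any(bad))
    stop("transcription(s) outside the inventory: ",
         paste(utils::head(entries$phon[bad], 5L), collapse = ", "))
  entries <- entries[order(entries$aoa, entries$phon),
                     c("orth", "phon", "aoa", "freq_raw", "freq_log",
                       "length", "l1_density")]
  rownames(entries) <- NULL
  structure(
    list(entries = entries, inventory = inventory,
         dropped = as.integer(dropped)),
    class = "staged_lexicon"
  )
}

#' @export
print.staged_lexicon <- function(x, ...) {
  cat("Staged lexicon:", nrow(x$entries), "word forms,",
      length(x$inventory), "segment symbols\n")
  tab <- table(factor(x$entries$aoa, levels = seq_len(N_STAGES)))
  cum <- cumsum(tab)
  cat("  unique per stage:    ", paste(sprintf("%d", tab), collapse = " "), "\n")
  cat("  cumulative per stage:", paste(sprintf("%d", cum), collapse = " "), "\n")
  if (x$dropped > 0L)
    cat("  rows dropped at ingestion:", x$dropped, "\n")
  invisible(x)
}

#' Cumulative vocabulary at a stage
#'
#' @param lexicon a `staged_lexicon`
#' @param stage integer stage 1-6
#' @return character vector of phon forms known at `stage`
#' @export
stage_vocab <- function(lexicon, stage) {
  stopifnot(inherits(lexicon, "staged_lexicon"),
            stage %in% seq_len(N_STAGES))
  lexicon$entries$phon[lexicon$entries$aoa <= stage]
}

#' Read staged word lists into a staged lexicon
#'
#' Reads one or several tab-separated files (columns `orth`, `stage`, `freq`,
#' `phon`, `l1_density`; header required), drops rows whose transcription
#' contains symbols outside the declared inventory (counting them), merges
#' homophones, and returns a validated [staged_lexicon()].
#'
#' @param paths character vector of TSV file paths (e.g. one per stage)
#' @param inventory character vector of valid single-character segment
#'   symbols; NULL accepts all symbols observed
#' @param merge_homophones merge rows sharing a phon form (mean frequency,
#'   earliest stage)?  When FALSE, duplicated phon forms with conflicting
#'   stages are a fatal error (they signal unmerged homophones).
#' @param sep field separator, tab by default
#' @return a `staged_lexicon`; the number of dropped rows is in `$dropped`
#' @export
read_word_lists <- function(paths, inventory = NULL,
                            merge_homophones = TRUE, sep = "\t") {
  stopifnot(length(paths) >= 1L, all(file.exists(paths)))
  raw <- do.call(rbind, lapply(paths, function(p)
    utils::read.table(p, header = TRUE, sep = sep, quote = "",
                      colClasses = "character", fileEncoding = "UTF-8",
                      stringsAsFactors = FALSE)))
  req <- c("orth", "stage", "freq", "phon", "l1_density")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  raw$aoa <- as.integer(raw$stage)
  raw$freq_raw <- as.numeric(raw$freq)
  raw$l1_density <- as.integer(raw$l1_density)
  if (any(is.na(raw$aoa)) || any(is.na(raw$freq_raw)) ||
      any(is.na(raw$l1_density)))
    stop("non-numeric stage, freq, or l1_density field")

  # rows with out-of-inventory symbols are dropped and counted, mirroring the
  # removal of forms absent from the reference corpus
  if (!is.null(inventory)) {
    ok <- vapply(strsplit(raw$phon, "", fixed = TRUE),
                 function(s) length(s) > 0L && all(s %in% inventory),
                 logical(1L))
  } else {
    ok <- nzchar(raw$phon)
  }
  dropped <- sum(!ok)
  raw <- raw[ok, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no valid rows after filtering")

  if (merge_homophones) {
    pieces <- split(raw[c("orth", "phon", "aoa", "freq_raw", "l1_density")],
                    raw$phon)
    entries <- do.call(rbind, lapply(pieces, phonogrow::merge_homophones))
  } else {
    dup <- duplicated(raw$phon) | duplicated(raw$phon, fromLast = TRUE)
    if (any(dup)) {
      conf <- tapply(raw$aoa, raw$phon, function(a) length(unique(a)) > 1L)
      if (any(conf))
        stop("duplicate phon with conflicting aoa (unmerged homophones): ",
             paste(utils::head(names(conf)[conf], 5L), collapse = ", "))
      raw <- raw[!duplicated(raw$phon), , drop = FALSE]
    }
    entries <- raw[c("orth", "phon", "aoa", "freq_raw", "l1_density")]
  }
  staged_lexicon(entries, inventory = inventory, dropped = dropped)
}

#' Write a staged lexicon back to the normalized TSV schema
#'
#' Emits the same `orth`/`stage`/`freq`/`phon`/`l1_density` schema that
#' [read_word_lists()] consumes, so a read-write-read cycle is lossless.
#'
#' @param lexicon a `staged_lexicon`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_word_lists <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "staged_lexicon"))
  e <- lexicon$entries
  out <- data.frame(orth = e$orth, stage = e$aoa,
                    freq = format(e$freq_raw, trim = TRUE, digits = 15),
                    phon = e$phon, l1_density = e$l1_density,
                    stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
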