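#' Miniature lexicon reproducing the canonical worked numbers
#'
#' A hand-crafted staged lexicon of three disjoint word families, built so
#' the pipeline's own computations land exactly on the reference worked
#' examples:
#'
#' * `/bad/` reaches a final degree of 16, gaining 8 neighbours at its entry
#'   stage and 3 at the next — proportional degree gains of 50% and 19%
#'   (cumulative 69%).
#' * `/lo/` has an L1 density of 15 and gains 2, 0, 2, 1 neighbours —
#'   saturations 13%, 13%, 26%, and a maximum of 33%.
#' * `/hi/` starts with 7 neighbours of summed similarity weight 352
#'   (average 50.3 per neighbour, unchanged over the no-growth second
#'   spurt), then expands to 12 neighbours of summed weight 704 (58.7).
#'
#' The weight targets are met through a dedicated feature table in which the
#' uppercase consonants' place values are tuned so that onset substitutions
#' against /h/ score the required integer similarities; use
#' [worked_example_features()] wherever the fixture's networks are built
#' with weights.
#'
#' @return a `staged_lexicon`
#' @export
make_worked_example_fixture <- function() {
  rows <- list(
    # "bad" family: final degree 16, gains 8/3/2/2/1/0
    c("bad", 1), c("pad", 1), c("tad", 1), c("kad", 1), c("gad", 1),
    c("mad", 1), c("nad", 1), c("sad", 1), c("zad", 1),
    c("bap", 2), c("bat", 2), c("bak", 2),
    c("ad", 3), c("ba", 3),
    c("badz", 4), c("bads", 4),
    c("abad", 5),
    # "lo" family: L1 density 15, gains 2/0/2/1/0/0
    c("lo", 1), c("ro", 1), c("fo", 1),
    c("vo", 3), c("lof", 3),
    c("lov", 4),
    # "hi" family: weighted degree 352 over 7, then 704 over 12
    c("hi", 1),
    c("Qi", 1), c("Ci", 1), c("Xi", 1), c("Ji", 1), c("Wi", 1), c("Yi", 1),
    c("Zi", 1),
    c("Ki", 3), c("Li", 3), c("Mi", 3), c("Ni", 3), c("Pi", 3)
  )
  entries <- data.frame(
    phon = vapply(rows, `[`, character(1L), 1L),
    aoa = as.integer(vapply(rows, `[`, character(1L), 2L)),
    stringsAsFactors = FALSE
  )
  entries$orth <- entries$phon
  entries$freq_raw <- 10 + 2 * seq_len(nrow(entries))
  entries$l1_density <- 50L
  entries$l1_density[entries$phon == "bad"] <- 20L
  entries$l1_density[entries$phon == "lo"] <- 15L
  entries$l1_density[entries$phon == "hi"] <- 14L
  staged_lexicon(entries)
}

#' Feature table for the worked-example fixture
#'
#' Lowercase segments carry their usual feature values; the uppercase
#' consonants are plain voiceless stops whose place values are tuned so the
#' /hi/ family's edge weights sum to the reference totals (352 over 7
#' neighbours, 704 over 12): an onset substitution between two-segment
#' forms has weight `round(100 - 2 * delta)`, and delta here is the place
#' salience (40) times the place difference.
#'
#' @return an `aline_features` object
#' @export
worked_example_features <- function() {
  base <- read_feature_segments(
    {
      p <- system.file("extdata", "aline_features.tsv",
                       package = "phonogrow")
      if (nzchar(p)) p else "inst/extdata/aline_features.tsv"
    }
  )
  stop_row <- function(segment, place) {
    out <- base[base$segment == "t", , drop = FALSE]
    out$segment <- segment
    out$place <- place
    out
  }
  extra <- rbind(
    # weight 50 needs delta 25 = 40 * (1.0 - 0.375); h sits at place 1.0
    stop_row("Q", 0.375), stop_row("C", 0.375), stop_row("X", 0.375),
    stop_row("J", 0.375), stop_row("W", 0.375), stop_row("Y", 0.375),
    stop_row("Z", 0.4),     # weight 52 (delta 24)
    stop_row("K", 0.625), stop_row("L", 0.625), stop_row("M", 0.625),
    stop_row("N", 0.625),   # weight 70 (delta 15)
    stop_row("P", 0.65)     # weight 72 (delta 14)
  )
  h <- base$segment == "h"
  base$place[h] <- 1.0
  base$manner[h] <- 1.0   # treat /h/ as a stop here so only place differs
  feature_table(rbind(base, extra))
}
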