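test_that("log frequency is base-10 on x + 1", {
  expect_equal(log_frequency(0), 0)
  expect_equal(log_frequency(99), 2)
  expect_equal(log_frequency(58.65), log10(59.65))
  expect_error(log_frequency(-1), "non-negative")
})

test_that("phoneme counting works on recoded single-token segments", {
  expect_equal(phoneme_count("TINk"), 4L)
  expect_equal(phoneme_count("a"), 1L)
  # a long vowel recoded to the single token "3" counts once
  expect_equal(phoneme_count("b3d"), 3L)
  expect_identical(phon_segments("b3d"), c("b", "3", "d"))
  expect_error(phoneme_count(""), "empty")
})

test_that("homophone merging averages frequency and keeps earliest stage", {
  merged <- merge_homophones(data.frame(
    orth = c("plain", "plane"), phon = "pleIn", aoa = c(3L, 2L),
    freq_raw = c(21.8, 95.5), l1_density = 10L))
  expect_equal(merged$freq_raw, 58.65)
  expect_equal(round(merged$freq_raw, 1), 58.6)  # 1-dp display, half-even
  expect_equal(merged$aoa, 2L)

  one <- data.frame(orth = "a", phon = "eI", aoa = 1L, freq_raw = 5,
                    l1_density = 3L)
  expect_equal(merge_homophones(one)$freq_raw, 5)
  three <- data.frame(orth = c("x", "y", "z"), phon = "k@t", aoa = 4L,
                      freq_raw = c(10, 20, 30), l1_density = 1L)
  expect_equal(merge_homophones(three)$freq_raw, 20)
  expect_error(merge_homophones(three[0, ]), "at least one")
})

test_that("homophone merging is idempotent and order-independent", {
  rows <- data.frame(orth = c("two", "too", "to"), phon = "tu",
                     aoa = c(2L, 1L, 3L), freq_raw = c(30, 10, 80),
                     l1_density = 7L)
  m1 <- merge_homophones(rows)
  m2 <- merge_homophones(rows[c(3, 1, 2), ])
  expect_equal(m1$freq_raw, m2$freq_raw)
  expect_equal(m1$aoa, m2$aoa)
  expect_equal(merge_homophones(m1)$freq_raw, m1$freq_raw)
})

write_stage_files <- function(df, dir) {
  paths <- character(0)
  for (s in sort(unique(df$stage))) {
    p <- file.path(dir, sprintf("stage%d.tsv", s))
    utils::write.table(df[df$stage == s, ], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  paths
}

test_that("reading word lists yields cumulative stages and drop counts", {
  dir <- withr::local_tempdir()
  set.seed(42)
  inv <- c(letters[1:10])
  good <- data.frame(
    orth = sprintf("w%03d", 1:100),
    stage = rep(1:5, each = 20),
    freq = round(runif(100, 1, 200), 1),
    phon = unique(random_forms(400, inv, 2, 5))[1:100],
    l1_density = sample(0:30, 100, replace = TRUE))
  # four transcriptions get a symbol outside the inventory
  bad_rows <- which(good$orth %in% sprintf("w%03d", c(5, 25, 60, 90)))
  good$phon[bad_rows] <- paste0(substr(good$phon[bad_rows], 1, 2), "Z")

  paths <- write_stage_files(good, dir)
  lex <- read_word_lists(paths, inventory = inv)
  expect_s3_class(lex, "staged_lexicon")
  expect_equal(lex$dropped, 4L)
  expect_equal(nrow(lex$entries), 96L)
  # cumulativity: stage s vocabulary is a subset of stage s+1
  for (s in 1:5)
    expect_true(all(stage_vocab(lex, s) %in% stage_vocab(lex, s + 1)))
})

test_that("clitic-split rows load as independent entries", {
  dir <- withr::local_tempdir()
  df <- data.frame(orth = c("it", "is"), stage = 1L, freq = c(900, 800),
                   phon = c("It", "Iz"), l1_density = c(20L, 15L))
  p <- file.path(dir, "s1.tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  lex <- read_word_lists(p)
  expect_equal(nrow(lex$entries), 2L)
})

test_that("conflicting unmerged homophones are fatal, merging resolves them", {
  dir <- withr::local_tempdir()
  df <- data.frame(orth = c("plain", "plane"), stage = c(2L, 3L),
                   freq = c(21.8, 95.5), phon = "pleIn",
                   l1_density = c(10L, 10L))
  p <- file.path(dir, "dups.tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_word_lists(p, merge_homophones = FALSE),
               "conflicting aoa")
  lex <- read_word_lists(p, merge_homophones = TRUE)
  expect_equal(nrow(lex$entries), 1L)
  expect_equal(lex$entries$freq_raw, 58.65)
  expect_equal(lex$entries$aoa, 2L)
})

test_that("missing columns are fatal", {
  dir <- withr::local_tempdir()
  df <- data.frame(orth = "a", stage = 1L, phon = "eI")
  p <- file.path(dir, "bad.tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_word_lists(p), "missing column")
})

test_that("write-read round trip reproduces the normalized table", {
  dir <- withr::local_tempdir()
  lex <- tiny_lexicon(c("bat", "pat", "sat", "ba"), c(1L, 2L, 3L, 4L),
                      freq = c(10.5, 3.25, 0.125, 999))
  p1 <- file.path(dir, "out1.tsv"); p2 <- file.path(dir, "out2.tsv")
  write_word_lists(lex, p1)
  lex2 <- read_word_lists(p1)
  expect_equal(lex2$entries, lex$entries)
  write_word_lists(lex2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
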