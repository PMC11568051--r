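ft <- default_feature_table()

# six-word fixture with hand-enumerable trajectories:
#   /ba/ (aoa 1) gains da at stage 1, ka at stage 2, bat at stage 4
#   /da/ (aoa 1), /ka/ (aoa 2), /bat/ (aoa 4), /zu/ hermit (aoa 2),
#   /zut/ (aoa 5) neighbour of zu
hand_lexicon <- function() {
  tiny_lexicon(c("ba", "da", "ka", "bat", "zu", "zut"),
               c(1L, 1L, 2L, 4L, 2L, 5L), l1 = 10L)
}

test_that("trajectories match hand enumeration on the six-word fixture", {
  lex <- hand_lexicon()
  nets <- build_all_networks(lex, ft)
  tr <- compute_trajectory("ba", nets, lex)
  expect_equal(tr$spurts$neighbors_added, c(1L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(tr$spurts$cumulative_degree, c(1L, 2L, 2L, 3L, 3L, 3L))
  expect_equal(nrow(tr$spurts), 6L)            # 7 - aoa spurts

  tr5 <- compute_trajectory("zut", nets, lex)
  expect_equal(nrow(tr5$spurts), 2L)           # acquired at stage 5
  trh <- compute_trajectory("zu", nets, lex)
  expect_equal(trh$spurts$neighbors_added, c(0L, 0L, 0L, 1L, 0L))

  expect_error(compute_trajectory("nope", nets, lex), "not in lexicon")

  # batch computation agrees with the single-word path
  all_tr <- compute_trajectories(nets, lex)
  expect_equal(all_tr[["ba"]]$spurts, tr$spurts)
  expect_equal(all_tr[["zu"]]$spurts, trh$spurts)
})

test_that("spurt gains conserve the final degree and proportions sum to 100", {
  set.seed(41)
  forms <- unique(random_forms(80, c("b", "d", "g", "a", "i"), 2, 4))
  lex <- tiny_lexicon(forms, sample(1:6, length(forms), replace = TRUE))
  nets <- build_all_networks(lex)
  for (tr in compute_trajectories(nets, lex)) {
    expect_equal(sum(tr$spurts$neighbors_added),
                 tail(tr$spurts$cumulative_degree, 1))
    expect_true(all(diff(tr$spurts$cumulative_degree) >= 0))
    if (tail(tr$spurts$cumulative_degree, 1) > 0) {
      props <- vapply(tr$spurts$spurt, function(j)
        proportional_degree_gain(tr, j), numeric(1))
      expect_equal(sum(props), 100)
    }
  }
})

test_that("proportional degree gain rejects never-growing words", {
  lex <- hand_lexicon()
  nets <- build_all_networks(lex)
  tr <- compute_trajectories(nets, lex)[["zu"]]
  # zu grows at stage 4 so it qualifies; a truly isolated word does not
  lex2 <- tiny_lexicon(c("ba", "zu"), c(1L, 2L))
  tr_iso <- compute_trajectories(build_all_networks(lex2), lex2)[["zu"]]
  expect_error(proportional_degree_gain(tr_iso, 1), "never grew")
  expect_error(proportional_degree_gain(tr, 99), "invalid spurt")
})

test_that("saturation follows cumulative degree over the L1 benchmark", {
  lex <- hand_lexicon()
  nets <- build_all_networks(lex)
  tr <- compute_trajectories(nets, lex)[["ba"]]
  expect_equal(saturation(tr, through_spurt = 1), 10)    # 1 of 10
  expect_equal(saturation(tr, through_spurt = 4), 30)
  # the published ratios: 4 of 5 -> 80%, 17 of 50 -> 34%
  expect_equal(4 / 5 * 100, 80)
  expect_equal(saturation(tr, l1_density = 10, through_spurt = 6), 30)
  expect_error(saturation(tr, l1_density = 0, through_spurt = 1),
               "no L1 neighbours")
  # monotone and bounded when the L2 lexicon is a subset of the reference
  sats <- vapply(1:6, function(j) saturation(tr, through_spurt = j),
                 numeric(1))
  expect_true(all(diff(sats) >= 0))
  expect_true(all(sats <= 100))
})

test_that("average weighted degree supports both published readings", {
  lex <- make_worked_example_fixture()
  nets <- build_all_networks(lex, worked_example_features())
  tr <- compute_trajectories(nets, lex)[["hi"]]
  # printed computation: cumulative weight / current neighbour count
  expect_equal(avg_weighted_degree_new(tr, 1), 352 / 7)
  expect_equal(avg_weighted_degree_new(tr, 2), 352 / 7)   # carried forward
  expect_equal(avg_weighted_degree_new(tr, 3), 704 / 12)
  # per-new-neighbour reading: (704 - 352) / 5
  expect_equal(avg_weighted_degree_new(tr, 3, method = "new"), 352 / 5)
  expect_equal(avg_weighted_degree_new(tr, 2, method = "new"), 352 / 7)
  # empty neighbourhood scores zero
  lex2 <- tiny_lexicon(c("ba", "zu"), c(1L, 2L))
  tr0 <- compute_trajectories(build_all_networks(lex2, ft), lex2)[["zu"]]
  expect_equal(avg_weighted_degree_new(tr0, 1), 0)
})

test_that("uniform edge weights give that weight at every growing spurt", {
  lex <- hand_lexicon()
  nets <- build_all_networks(lex, ft)
  # overwrite weights with a constant to isolate the averaging logic
  for (s in 1:6) {
    n <- nets[[s]]
    if (nrow(n$edges)) {
      n$edges$similarity_int <- 60L
      n$weighted_degree <- n$degree * 60L
      nets[[s]] <- n
    }
  }
  tr <- compute_trajectories(nets, lex)[["ba"]]
  grown <- tr$spurts$cumulative_degree > 0
  for (j in tr$spurts$spurt[grown])
    expect_equal(avg_weighted_degree_new(tr, j), 60)
})

test_that("growth patterns partition the eligible trajectories", {
  mk <- function(gains, aoa = 1L) {
    structure(list(phon = "x", aoa = aoa, l1_density = 10L,
                   spurts = data.frame(
                     spurt = seq_along(gains),
                     neighbors_added = gains,
                     cumulative_degree = cumsum(gains),
                     added_weight = gains,
                     cumulative_weight = cumsum(gains),
                     saturation_pct = cumsum(gains))),
              class = "growth_trajectory")
  }
  expect_equal(classify_growth_pattern(mk(c(8, 0, 0, 0, 0, 0))), "initial")
  expect_equal(classify_growth_pattern(mk(c(3, 1, 2, 1, 1, 1))), "continuous")
  expect_equal(classify_growth_pattern(mk(c(2, 0, 1, 2, 1, 1))), "delayed")
  expect_equal(classify_growth_pattern(mk(c(2, 0, 0, 1, 1, 1))), "delayed")
  expect_equal(classify_growth_pattern(mk(c(2, 0, 0, 0, 1, 1))), "other")
  expect_equal(classify_growth_pattern(mk(c(2, 1, 0, 1, 1, 1))), "other")
  expect_error(classify_growth_pattern(mk(c(1, 1), aoa = 5L)), "3 spurts")

  # exhaustive partition over all 0/1 gain profiles of length 4
  profiles <- expand.grid(rep(list(0:1), 4))
  labels <- apply(profiles, 1, function(g)
    classify_growth_pattern(mk(as.integer(g), aoa = 3L)))
  expect_true(all(labels %in% c("initial", "continuous", "delayed", "other")))
  expect_equal(length(labels), 16L)
})

test_that("the squeeze transform maps [0,1] into (0,1) monotonically", {
  expect_equal(sv_transform(0, 100), 0.005)
  expect_equal(sv_transform(1, 100), 0.995)
  expect_equal(sv_transform(0.5, 7), 0.5)
  expect_equal(sv_transform(0.5, 12345), 0.5)
  y <- seq(0, 1, by = 0.05)
  z <- sv_transform(y, 50)
  expect_true(all(diff(z) > 0))
  expect_true(all(z > 0 & z < 1))
  expect_error(sv_transform(1.01, 10), "0, 1")
})

test_that("the model table covers growing words with valid spurt indices", {
  lex <- hand_lexicon()
  nets <- build_all_networks(lex, ft)
  trs <- compute_trajectories(nets, lex)
  tab <- build_model_table(trs, lex)
  # zu grows (stage 4), so only no word is excluded here except none;
  # spurt counts per word must equal 7 - aoa
  cnt <- table(tab$phon)
  aoa <- lex$entries$aoa[match(names(cnt), lex$entries$phon)]
  expect_equal(as.integer(cnt), 7L - aoa)
  expect_true(all(tab$prop_degree_gain >= 0 & tab$prop_degree_gain <= 1))
  expect_true(all(tab$sv_degree_gain > 0 & tab$sv_degree_gain < 1))
  expect_true(all(abs(tab$wd_new_int - tab$avg_weighted_degree) <= 0.5))

  # a non-growing word contributes no rows
  lex2 <- tiny_lexicon(c("ba", "da", "zu"), c(1L, 1L, 2L))
  trs2 <- compute_trajectories(build_all_networks(lex2, ft), lex2)
  tab2 <- build_model_table(trs2, lex2)
  expect_false("zu" %in% tab2$phon)
  # 2 words with aoa 1 -> 6 rows each
  expect_equal(nrow(tab2), 12L)
})
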