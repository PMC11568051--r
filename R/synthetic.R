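#' Synthetic staged lexica with tunable obsolescence
#'
#' The generator emulates the statistical structure the growth analysis
#' assumes, so the whole pipeline can be exercised without external data:
#' a pool of CV(C...) word forms over a small synthetic inventory serves as
#' the L1 reference lexicon (its one-segment neighbourhood graph defines the
#' L1 densities, so L2 saturation can never exceed 100%); the staged L2
#' lexicon samples words from the pool stage by stage.  Selection combines a
#' stage-decaying preference for short, frequent forms (so early-stage words
#' are shorter and more frequent, as in real proficiency-staged vocabulary)
#' with an attachment kernel over the words already present: a candidate's
#' weight grows with the recency-discounted mass of its already-known
#' neighbours, `sum((1 + age)^(-alpha))^gamma` (power-law node aging).
#' With `gamma = 1` this is linear preferential attachment; the aging
#' strength `alpha` controls obsolescence (0 = none, a word keeps
#' attracting its neighbours at a constant rate; large = neighbours arrive
#' predominantly at the word's own entry stage, producing the
#' first-spurt-dominant growth profile).
#'
#' @name synthetic_lexicon
NULL

#' Generator configuration
#'
#' @param n_consonants,n_vowels synthetic inventory sizes
#' @param words_per_stage integer vector of 6 unique-word counts per AoA
#'   stage; the default mirrors a realistic staged vocabulary (584, 899,
#'   1345, 1657, 946, 936)
#' @param len_min,len_max word length range in segments (onset consonant +
#'   vowel + 0..k coda consonants)
#' @param zipf_exponent exponent of the rank-frequency law for pool
#'   frequencies
#' @param ease_strength scale of the stage-decaying preference for short,
#'   frequent forms (0 = homogeneous base rates; 1 = default gradient).
#'   Because short forms live in dense neighbourhoods, a positive gradient
#'   by itself front-loads neighbour arrivals; set it to 0 in experiments
#'   that isolate the aging mechanism
#' @param aging_alpha aging strength alpha >= 0 (0 = no obsolescence)
#' @param pa_exponent exponent gamma on the recency-discounted neighbour
#'   mass (1 = linear preferential attachment)
#' @param l1_inflation pool size as a multiple of the total L2 vocabulary
#'   (>= 1); large values approximate an unconstrained form pool
#' @param seed integer RNG seed; the generator is deterministic given the
#'   config
#' @return list of class `generator_config`
#' @export
generator_config <- function(n_consonants = 14, n_vowels = 6,
                             words_per_stage = c(584, 899, 1345, 1657,
                                                 946, 936),
                             len_min = 2, len_max = 5,
                             zipf_exponent = 1,
                             ease_strength = 1,
                             aging_alpha = 1,
                             pa_exponent = 1,
                             l1_inflation = 3,
                             seed = 1L) {
  stopifnot(n_consonants >= 2, n_vowels >= 1,
            length(words_per_stage) == N_STAGES, all(words_per_stage >= 1),
            len_min >= 2, len_max >= len_min,
            zipf_exponent > 0, ease_strength >= 0, aging_alpha >= 0,
            pa_exponent >= 0, l1_inflation >= 1)
  structure(list(
    n_consonants = as.integer(n_consonants), n_vowels = as.integer(n_vowels),
    words_per_stage = as.integer(words_per_stage),
    len_min = as.integer(len_min), len_max = as.integer(len_max),
    zipf_exponent = zipf_exponent, ease_strength = ease_strength,
    aging_alpha = aging_alpha,
    pa_exponent = pa_exponent, l1_inflation = l1_inflation,
    seed = as.integer(seed)), class = "generator_config")
}

GEN_CONSONANTS <- c("p", "t", "k", "b", "d", "g", "m", "n", "s", "z",
                    "f", "v", "l", "r", "w", "j", "h", "ʃ")
GEN_VOWELS <- c("a", "e", "i", "o", "u", "y")

# attachment-kernel scale: how strongly the recency-discounted neighbour
# mass dominates over the baseline arrival rate
GEN_C_ATT <- 1

# enumerate candidate forms of a given length: onset C + vowel + coda C*
enumerate_forms <- function(cons, vows, len) {
  if (len == 2) {
    as.vector(outer(cons, vows, paste0))
  } else {
    codas <- Reduce(function(acc, i) as.vector(outer(acc, cons, paste0)),
                    seq_len(len - 3L), cons)
    as.vector(outer(as.vector(outer(cons, vows, paste0)), codas, paste0))
  }
}

#' Generate a synthetic staged lexicon
#'
#' @param config a [generator_config()]
#' @return object of class `synthetic_lexicon`: `lexicon` (a
#'   `staged_lexicon`), `ground_truth` (per-word entry stage, pool degree,
#'   per-spurt neighbour gains, and the growth-pattern label where >= 3
#'   spurts exist), `pool` (the full L1 reference pool with frequencies and
#'   densities), and `config`
#' @export
generate <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  cons <- GEN_CONSONANTS[seq_len(cfg$n_consonants)]
  vows <- GEN_VOWELS[seq_len(cfg$n_vowels)]
  n_total <- sum(cfg$words_per_stage)
  n_pool <- ceiling(cfg$l1_inflation * n_total)

  # shorter lengths are denser and more plausible as a vocabulary backbone;
  # sample the pool with a decreasing length profile
  lens <- cfg$len_min:cfg$len_max
  avail <- vapply(lens, function(L)
    cfg$n_consonants * cfg$n_vowels * cfg$n_consonants^(max(L - 2L, 0L)),
    numeric(1L))
  if (sum(avail) < n_pool)
    stop("infeasible config: pool of ", n_pool,
         " forms requested but only ", sum(avail), " distinct forms exist")
  if (n_total > sum(avail))
    stop("infeasible config: more words requested than forms exist")
  want <- n_pool * (0.5^seq_along(lens)) / sum(0.5^seq_along(lens))
  # redistribute demand that exceeds a stratum's supply to longer forms
  take <- numeric(length(lens))
  carry <- 0
  for (i in seq_along(lens)) {
    take[i] <- min(avail[i], round(want[i] + carry))
    carry <- want[i] + carry - take[i]
  }
  while (sum(take) < n_pool) {
    room <- which(take < avail)
    take[room[length(room)]] <- take[room[length(room)]] + 1
  }
  pool <- unlist(lapply(seq_along(lens), function(i) {
    forms <- enumerate_forms(cons, vows, lens[i])
    sample(forms, take[i])
  }))
  pool_len <- nchar(pool, type = "chars")

  # Zipf frequencies, rank correlated with length (short words frequent)
  rank_key <- pool_len + stats::runif(n_pool, 0, 2)
  rk <- rank(rank_key, ties.method = "first")
  freq <- 2000 / rk^cfg$zipf_exponent

  # L1 reference network over the pool
  edges <- find_neighbors(pool)
  adj <- make_adjacency(pool, edges)
  l1_density <- lengths(adj)

  # standardized "ease" (short + frequent); its selection weight decays to
  # zero across stages so late stages draw longer, rarer forms
  ease <- as.numeric(scale(log10(freq + 1))) - as.numeric(scale(pool_len))
  ease_scale <- cfg$ease_strength * seq(1, 0, length.out = N_STAGES)

  entry <- integer(n_pool)            # 0 = not (yet) acquired
  # arrivals[i, t]: how many of word i's pool neighbours entered at stage t;
  # the recency-discounted mass uses power-law aging (1 + age)^(-alpha)
  arrivals <- matrix(0L, n_pool, N_STAGES)
  remaining <- seq_len(n_pool)
  for (s in seq_len(N_STAGES)) {
    n_s <- cfg$words_per_stage[s]
    if (n_s > length(remaining))
      stop("infeasible config: stage ", s, " requests ", n_s,
           " words but only ", length(remaining), " pool forms remain")
    M <- if (s > 1L) {
      age_w <- (1 + s - seq_len(s - 1L))^(-cfg$aging_alpha)
      drop(arrivals[, seq_len(s - 1L), drop = FALSE] %*% age_w)
    } else numeric(n_pool)
    for (k in seq_len(n_s)) {
      w <- exp(ease_scale[s] * ease[remaining]) *
        (1 + GEN_C_ATT * M[remaining]^cfg$pa_exponent)
      pick_idx <- sample.int(length(remaining), 1L, prob = w)
      pick <- remaining[pick_idx]
      entry[pick] <- s
      remaining <- remaining[-pick_idx]
      nb <- adj[[pick]]
      if (length(nb)) {
        M[nb] <- M[nb] + 1            # age 0 within the entry stage
        arrivals[nb, s] <- arrivals[nb, s] + 1L
      }
    }
  }

  sampled <- which(entry > 0L)
  entries <- data.frame(
    orth = paste0("w_", pool[sampled]),
    phon = pool[sampled],
    aoa = entry[sampled],
    freq_raw = freq[sampled],
    l1_density = l1_density[sampled],
    stringsAsFactors = FALSE
  )
  lex <- staged_lexicon(entries, inventory = c(cons, vows))

  gt <- ground_truth_from_entry(pool, adj, entry, sampled)
  structure(
    list(lexicon = lex, ground_truth = gt,
         pool = data.frame(phon = pool, freq_raw = freq,
                           length = pool_len, l1_density = l1_density,
                           stringsAsFactors = FALSE),
         config = cfg),
    class = "synthetic_lexicon"
  )
}

make_adjacency <- function(forms, edges) {
  adj <- vector("list", length(forms))
  if (nrow(edges)) {
    ia <- match(edges$phon_a, forms)
    ib <- match(edges$phon_b, forms)
    for (e in seq_along(ia)) {
      adj[[ia[e]]] <- c(adj[[ia[e]]], ib[e])
      adj[[ib[e]]] <- c(adj[[ib[e]]], ia[e])
    }
  }
  adj
}

# per-word spurt gains implied by the entry stages (the generating truth,
# identical by construction to what the pipeline recovers from the emitted
# word lists)
ground_truth_from_entry <- function(pool, adj, entry, sampled) {
  gains <- vector("list", length(sampled))
  labels <- character(length(sampled))
  for (i in seq_along(sampled)) {
    p <- sampled[i]
    a <- entry[p]
    nb_entry <- entry[adj[[p]]]
    nb_entry <- nb_entry[nb_entry > 0L]
    n_spurts <- N_STAGES + 1L - a
    g <- integer(n_spurts)
    g[1L] <- sum(nb_entry <= a)
    if (n_spurts > 1L)
      for (j in 2:n_spurts) g[j] <- sum(nb_entry == a + j - 1L)
    gains[[i]] <- g
    labels[i] <- if (n_spurts >= 3L && sum(g) > 0L)
      classify_gain_vector(g) else NA_character_
  }
  data.frame(phon = pool[sampled], aoa = entry[sampled],
             l1_density = lengths(adj)[sampled],
             n_spurts = N_STAGES + 1L - entry[sampled],
             final_degree = vapply(gains, sum, integer(1L)),
             gains = I(gains),
             pattern = labels,
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_lexicon <- function(x, ...) {
  cat("Synthetic staged lexicon (seed", x$config$seed, ")\n")
  cat("  pool size:", nrow(x$pool), " sampled:", nrow(x$lexicon$entries),
      "\n")
  cat("  aging alpha:", x$config$aging_alpha,
      " PA exponent:", x$config$pa_exponent, "\n")
  print(x$lexicon)
  invisible(x)
}

#' Per-spurt share of final degree from generator ground truth
#'
#' For growing words acquired at `aoa`, the mean share each spurt
#' contributes to the word's final degree — the quantity whose profile over
#' spurts reveals obsolescence (flat when `aging_alpha = 0` and the pool is
#' unconstrained; front-loaded when aging is strong).
#'
#' @param synth a `synthetic_lexicon`
#' @param aoa entry stage of the words summarised (stage 1 words see all
#'   six spurts)
#' @return numeric vector of mean shares, one per spurt
#' @export
spurt_share_profile <- function(synth, aoa = 1L) {
  stopifnot(inherits(synth, "synthetic_lexicon"))
  gt <- synth$ground_truth
  sel <- gt$aoa == aoa & gt$final_degree > 0L
  if (!any(sel)) return(rep(NA_real_, N_STAGES + 1L - aoa))
  shares <- t(vapply(gt$gains[sel], function(g) g / sum(g),
                     numeric(N_STAGES + 1L - aoa)))
  colMeans(shares)
}
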