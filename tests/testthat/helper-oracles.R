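# Independent oracles and fixture builders shared across tests.

# Levenshtein distance by its naive recursive definition (exponential; only
# for short strings).
naive_levenshtein <- function(a, b) {
  rec <- function(sa, sb) {
    if (!length(sa)) return(length(sb))
    if (!length(sb)) return(length(sa))
    min(rec(sa[-1], sb) + 1L,
        rec(sa, sb[-1]) + 1L,
        rec(sa[-1], sb[-1]) + (sa[1] != sb[1]))
  }
  rec(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
}

# Exhaustive enumeration of every alignment (skip / substitute / expand in
# either direction), maximising the same segment-pair scores the DP uses;
# independent of the DP's recurrence and order of evaluation.
naive_align_score <- function(a, b, ft) {
  sub <- phonogrow:::aline_sub_score
  expn <- phonogrow:::aline_exp_score
  skip <- ft$params$c_skip
  rec <- function(sa, sb) {
    if (!length(sa) && !length(sb)) return(0)
    best <- -Inf
    if (length(sa)) best <- max(best, rec(sa[-1], sb) + skip)
    if (length(sb)) best <- max(best, rec(sa, sb[-1]) + skip)
    if (length(sa) && length(sb))
      best <- max(best, rec(sa[-1], sb[-1]) + sub(sa[1], sb[1], ft))
    if (length(sa) && length(sb) >= 2)
      best <- max(best, rec(sa[-1], sb[-c(1, 2)]) +
                    expn(sa[1], sb[1], sb[2], ft))
    if (length(sa) >= 2 && length(sb))
      best <- max(best, rec(sa[-c(1, 2)], sb[-1]) +
                    expn(sb[1], sa[1], sa[2], ft))
    best
  }
  rec(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
}

naive_aline_distance <- function(a, b, ft) {
  if (a == b) return(0)
  s <- max(0, naive_align_score(a, b, ft))
  den <- naive_align_score(a, a, ft) + naive_align_score(b, b, ft)
  min(1, max(0, 1 - 2 * s / den))
}

# random transcriptions over an alphabet
random_forms <- function(n, alphabet, len_min = 2, len_max = 5) {
  vapply(seq_len(n), function(i) {
    L <- sample(len_min:len_max, 1)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

# neighbour pairs by unpruned all-pairs scan
brute_force_neighbors <- function(forms) {
  forms <- unique(forms)
  m <- utils::adist(forms, forms)
  hit <- which(m == 1L & upper.tri(m), arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(phon_a = character(), phon_b = character(),
                      stringsAsFactors = FALSE))
  a <- pmin(forms[hit[, 1]], forms[hit[, 2]])
  b <- pmax(forms[hit[, 1]], forms[hit[, 2]])
  o <- order(a, b)
  data.frame(phon_a = a[o], phon_b = b[o], stringsAsFactors = FALSE)
}

# assortativity by literally expanding the oriented endpoint-degree pairs
# and calling cor()
brute_force_assortativity <- function(edges) {
  nodes <- unique(c(edges$phon_a, edges$phon_b))
  deg <- table(factor(c(edges$phon_a, edges$phon_b), levels = nodes))
  x <- c(deg[edges$phon_a], deg[edges$phon_b])
  y <- c(deg[edges$phon_b], deg[edges$phon_a])
  stats::cor(as.numeric(x), as.numeric(y))
}

# random simple graph as an edge data.frame over letter-named nodes
random_graph_edges <- function(n_nodes, p_edge) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  data.frame(phon_a = pairs[1, keep], phon_b = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# build a staged_lexicon directly from (phon, aoa) pairs
tiny_lexicon <- function(phons, aoas, l1 = 50L, freq = NULL) {
  staged_lexicon(data.frame(
    orth = phons, phon = phons, aoa = aoas,
    freq_raw = freq %||% rep(10, length(phons)),
    l1_density = rep_len(l1, length(phons)),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small generator config used across tests; ease = 0 gives the homogeneous
# base rates that isolate the aging mechanism
small_config <- function(seed, alpha = 1, words = rep(40L, 6),
                         inflation = 8, pa = 1, ease = 1) {
  generator_config(n_consonants = 10, n_vowels = 4,
                   words_per_stage = words, len_min = 2, len_max = 4,
                   ease_strength = ease, aging_alpha = alpha,
                   pa_exponent = pa, l1_inflation = inflation, seed = seed)
}

# simulate a spurt-style model table from known quasi-binomial coefficients
simulate_proportional_table <- function(n, beta, phi = 1, n_spurts = 3,
                                        n_aoa = 2) {
  spurt <- factor(sample(seq_len(n_spurts), n, replace = TRUE))
  aoa <- factor(sample(seq_len(n_aoa), n, replace = TRUE))
  freq <- stats::rnorm(n)
  len <- stats::rnorm(n)
  X <- stats::model.matrix(~ spurt + aoa + freq + len)
  stopifnot(ncol(X) == length(beta))
  mu <- stats::plogis(drop(X %*% beta))
  m <- 40                                   # binomial denominators
  y <- stats::rbinom(n, m, mu) / m
  y <- phonogrow::sv_transform(y, n)
  data.frame(spurt = as.integer(as.character(spurt)),
             aoa = as.integer(as.character(aoa)),
             freq_log = freq, length = len,
             sv_degree_gain = y, prop_degree_gain = y)
}

# simulate counts from a known zero-inflated negative binomial model
simulate_zinb_table <- function(n, beta_count, beta_zero, theta,
                                n_spurts = 3, n_aoa = 2) {
  spurt <- factor(sample(seq_len(n_spurts), n, replace = TRUE))
  aoa <- factor(sample(seq_len(n_aoa), n, replace = TRUE))
  freq <- stats::rnorm(n)
  len <- stats::rnorm(n)
  X <- stats::model.matrix(~ spurt + aoa + freq + len)
  stopifnot(ncol(X) == length(beta_count), ncol(X) == length(beta_zero))
  mu <- exp(drop(X %*% beta_count))
  pz <- stats::plogis(drop(X %*% beta_zero))
  y <- ifelse(stats::rbinom(n, 1, pz) == 1, 0L,
              stats::rnbinom(n, mu = mu, size = theta))
  data.frame(spurt = as.integer(as.character(spurt)),
             aoa = as.integer(as.character(aoa)),
             freq_log = freq, length = len, wd_new_int = y)
}
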