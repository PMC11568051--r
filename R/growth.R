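#' Per-word growth trajectories across AoA stages
#'
#' A word entering the lexicon at AoA stage a can undergo `7 - a` growth
#' spurts: spurt 1 comprises the neighbours already present at its entry
#' stage, and spurt j > 1 the neighbours gained between stages a+j-2 and
#' a+j-1.  A trajectory records, per spurt, the neighbours added, the
#' cumulative degree, the summed similarity weight added, and the saturation
#' of the word's L1-reference neighbourhood.
#'
#' @name growth_trajectory
NULL

#' Compute one word's growth trajectory
#'
#' @param phon a phon form present in the lexicon
#' @param networks list of `phon_network` for stages 1..6 (see
#'   [build_all_networks()])
#' @param lexicon the `staged_lexicon` the networks were built from
#' @return object of class `growth_trajectory`: `phon`, `aoa`,
#'   `l1_density`, and a `spurts` data.frame with columns `spurt`,
#'   `neighbors_added`, `cumulative_degree`, `added_weight`,
#'   `cumulative_weight`, `saturation_pct`
#' @export
compute_trajectory <- function(phon, networks, lexicon) {
  stopifnot(inherits(lexicon, "staged_lexicon"), length(phon) == 1L)
  i <- match(phon, lexicon$entries$phon)
  if (is.na(i)) stop("phon form not in lexicon: ", phon)
  aoa <- lexicon$entries$aoa[i]
  l1 <- lexicon$entries$l1_density[i]
  stages <- aoa:N_STAGES
  deg <- vapply(stages, function(s) {
    net <- networks[[as.character(s)]]
    if (!phon %in% net$nodes) stop("phon absent from stage ", s, " network")
    unname(net$degree[phon])
  }, integer(1L))
  wdeg <- vapply(stages, function(s)
    unname(networks[[as.character(s)]]$weighted_degree[phon]), integer(1L))
  added <- diff(c(0L, deg))
  wadded <- diff(c(0L, wdeg))
  sat <- if (l1 > 0) deg / l1 * 100 else rep(NA_real_, length(deg))
  structure(
    list(phon = phon, aoa = aoa, l1_density = l1,
         spurts = data.frame(
           spurt = seq_along(stages),
           neighbors_added = added,
           cumulative_degree = deg,
           added_weight = wadded,
           cumulative_weight = wdeg,
           saturation_pct = sat)),
    class = "growth_trajectory"
  )
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat("Growth trajectory for /", x$phon, "/ (AoA ", x$aoa,
      ", L1 density ", x$l1_density, ")\n", sep = "")
  print(x$spurts, row.names = FALSE)
  invisible(x)
}

#' Compute trajectories for every word in the lexicon
#'
#' @inheritParams compute_trajectory
#' @return named list of `growth_trajectory` keyed by phon form
#' @export
compute_trajectories <- function(networks, lexicon) {
  stopifnot(inherits(lexicon, "staged_lexicon"))
  phons <- lexicon$entries$phon
  aoas <- lexicon$entries$aoa
  l1s <- lexicon$entries$l1_density
  # degree / weighted-degree per word per stage, assembled once
  D <- matrix(0L, length(phons), N_STAGES, dimnames = list(phons, NULL))
  W <- matrix(0L, length(phons), N_STAGES, dimnames = list(phons, NULL))
  for (s in seq_len(N_STAGES)) {
    net <- networks[[as.character(s)]]
    idx <- match(net$nodes, phons)
    D[idx, s] <- as.integer(net$degree)
    W[idx, s] <- as.integer(net$weighted_degree)
  }
  out <- vector("list", length(phons))
  names(out) <- phons
  for (k in seq_along(phons)) {
    stages <- aoas[k]:N_STAGES
    deg <- D[k, stages]; wdeg <- W[k, stages]
    sat <- if (l1s[k] > 0) deg / l1s[k] * 100 else rep(NA_real_, length(deg))
    out[[k]] <- structure(
      list(phon = phons[k], aoa = aoas[k], l1_density = l1s[k],
           spurts = data.frame(
             spurt = seq_along(stages),
             neighbors_added = diff(c(0L, deg)),
             cumulative_degree = unname(deg),
             added_weight = diff(c(0L, wdeg)),
             cumulative_weight = unname(wdeg),
             saturation_pct = unname(sat))),
      class = "growth_trajectory")
  }
  out
}

final_degree <- function(traj) {
  utils::tail(traj$spurts$cumulative_degree, 1L)
}

#' Proportional degree gain of one spurt
#'
#' Neighbours added at the spurt as a percentage of the degree the word
#' finally reaches at stage 6 ("bad": 8 of an eventual 16 in spurt 1 = 50%).
#' Only words that experience growth enter this analysis; a word with final
#' degree 0 is an error here.
#'
#' @param traj a `growth_trajectory`
#' @param spurt spurt index (1 .. 7 - aoa)
#' @return percentage in \[0, 100\]
#' @export
proportional_degree_gain <- function(traj, spurt) {
  stopifnot(inherits(traj, "growth_trajectory"))
  fd <- final_degree(traj)
  if (fd == 0L)
    stop("word never grew neighbours; excluded from the growth analysis")
  s <- traj$spurts
  if (!spurt %in% s$spurt) stop("invalid spurt index ", spurt)
  s$neighbors_added[s$spurt == spurt] / fd * 100
}

#' Neighbourhood saturation against the L1 benchmark
#'
#' Cumulative degree through a spurt as a percentage of the word's
#' neighbourhood density in the L1 reference lexicon ("any": 2 of 15 L1
#' neighbours = 13%).
#'
#' @param traj a `growth_trajectory`
#' @param l1_density L1 reference neighbour count (defaults to the
#'   trajectory's own)
#' @param through_spurt spurt index through which degree is accumulated
#' @return percentage >= 0
#' @export
saturation <- function(traj, l1_density = traj$l1_density, through_spurt) {
  stopifnot(inherits(traj, "growth_trajectory"))
  if (is.na(l1_density) || l1_density <= 0)
    stop("word has no L1 neighbours; excluded from the saturation analysis",
         call. = FALSE)
  s <- traj$spurts
  if (!through_spurt %in% s$spurt) stop("invalid spurt index ", through_spurt)
  s$cumulative_degree[s$spurt == through_spurt] / l1_density * 100
}

#' Average weighted degree per neighbour at a spurt
#'
#' The default (`method = "cumulative"`) follows the published worked
#' computation: the word's cumulative weighted degree divided by its current
#' neighbour count ("be": 352/7 = 50.3 at spurts 1-2, then 704/12 = 58.7),
#' which automatically carries the previous per-neighbour average through
#' no-growth spurts; 0 while the neighbourhood is empty.  `method = "new"`
#' is the alternative reading: weight added at the spurt divided by
#' neighbours added at the spurt (352/5 = 70.4 in the example above),
#' carrying the previous value through no-growth spurts.
#'
#' @param traj a `growth_trajectory`
#' @param spurt spurt index
#' @param method `"cumulative"` (default, the published computation) or
#'   `"new"` (per newly added neighbour)
#' @return non-negative average weight
#' @export
avg_weighted_degree_new <- function(traj, spurt,
                                    method = c("cumulative", "new")) {
  stopifnot(inherits(traj, "growth_trajectory"))
  method <- match.arg(method)
  s <- traj$spurts
  if (!spurt %in% s$spurt) stop("invalid spurt index ", spurt)
  j <- which(s$spurt == spurt)
  if (method == "cumulative") {
    if (s$cumulative_degree[j] == 0L) return(0)
    return(s$cumulative_weight[j] / s$cumulative_degree[j])
  }
  vals <- numeric(nrow(s))
  for (k in seq_len(nrow(s))) {
    if (s$neighbors_added[k] > 0L) {
      vals[k] <- s$added_weight[k] / s$neighbors_added[k]
    } else if (k > 1L) {
      vals[k] <- vals[k - 1L]
    } else vals[k] <- 0
  }
  vals[j]
}

#' Classify a word's growth pattern
#'
#' Over the spurt gains after entry: *initial* growth is confined to the
#' entry spurt; *continuous* growth occurs at every spurt; *delayed* growth
#' is dormant for the first one or two post-entry spurts and then grows at
#' every remaining spurt; anything else is *other*.  Requires at least three
#' spurts (the pattern analysis covers words acquired at stages 1-3, which
#' retain enough spurts to distinguish the profiles).
#'
#' @param traj a `growth_trajectory`
#' @return one of `"initial"`, `"continuous"`, `"delayed"`, `"other"`
#' @export
classify_growth_pattern <- function(traj) {
  stopifnot(inherits(traj, "growth_trajectory"))
  g <- traj$spurts$neighbors_added
  if (length(g) < 3L)
    stop("pattern classification needs at least 3 spurts (AoA <= 4)")
  classify_gain_vector(g)
}

# classification on a raw gain vector (used for generator ground truth too)
classify_gain_vector <- function(g) {
  n <- length(g)
  if (all(g[-1L] == 0L)) return("initial")
  if (all(g > 0L)) return("continuous")
  if (g[2L] == 0L && all(g[3:n] > 0L)) return("delayed")
  if (n >= 4L && g[2L] == 0L && g[3L] == 0L && all(g[4:n] > 0L))
    return("delayed")
  "other"
}

#' Squeeze proportions away from 0 and 1
#'
#' The Smithson-Verkuilen transform `(y * (n - 1) + 0.5) / n`, mapping
#' \[0, 1\] into (0, 1) so logit-family models are well defined.
#'
#' @param y proportions in \[0, 1\]
#' @param n positive sample size
#' @return transformed proportions in (0, 1)
#' @examples
#' sv_transform(c(0, 1, 0.5), 100)  # 0.005 0.995 0.5
#' @export
sv_transform <- function(y, n) {
  if (any(is.na(y)) || any(y < 0) || any(y > 1))
    stop("y must lie in [0, 1]")
  if (n < 1) stop("n must be a positive sample size")
  (y * (n - 1) + 0.5) / n
}

#' Assemble the spurt-level model table
#'
#' One row per growing word per spurt, with the three dependent variables
#' (proportional degree gain, proportional saturation gain, average weighted
#' degree of the current neighbourhood) and the covariates the regressions
#' use.  Words that never grow are excluded; words without L1 neighbours
#' have `NA` saturation columns and are excluded from the saturation model
#' only.  Smithson-Verkuilen columns are added with n = the number of rows
#' entering the respective model (recorded in `attr(, "sv_n")`).
#'
#' @param trajectories list of `growth_trajectory` (see
#'   [compute_trajectories()])
#' @param lexicon the originating `staged_lexicon` (for covariates)
#' @return data.frame of class `spurt_model_table`
#' @export
build_model_table <- function(trajectories, lexicon) {
  stopifnot(inherits(lexicon, "staged_lexicon"))
  keep <- vapply(trajectories, function(t) final_degree(t) > 0L, logical(1L))
  trajectories <- trajectories[keep]
  if (!length(trajectories)) stop("no growing words")
  rows <- lapply(trajectories, function(t) {
    s <- t$spurts
    fd <- final_degree(t)
    awd <- vapply(s$spurt, function(j)
      avg_weighted_degree_new(t, j, method = "cumulative"), numeric(1L))
    sat_gain <- if (t$l1_density > 0)
      pmin(1, s$neighbors_added / t$l1_density) else rep(NA_real_, nrow(s))
    data.frame(
      phon = t$phon, aoa = t$aoa, spurt = s$spurt,
      neighbors_added = s$neighbors_added,
      prop_degree_gain = s$neighbors_added / fd,
      prop_saturation_gain = sat_gain,
      avg_weighted_degree = awd,
      wd_new_int = as.integer(round_half_up(awd)),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  e <- lexicon$entries[match(tab$phon, lexicon$entries$phon), ]
  tab$freq_log <- e$freq_log
  tab$length <- e$length
  n_deg <- nrow(tab)
  n_sat <- sum(!is.na(tab$prop_saturation_gain))
  tab$sv_degree_gain <- sv_transform(tab$prop_degree_gain, n_deg)
  tab$sv_saturation_gain <- NA_real_
  ok <- !is.na(tab$prop_saturation_gain)
  if (any(ok))
    tab$sv_saturation_gain[ok] <- sv_transform(tab$prop_saturation_gain[ok],
                                               n_sat)
  attr(tab, "sv_n") <- c(degree = n_deg, saturation = n_sat)
  class(tab) <- c("spurt_model_table", "data.frame")
  tab
}
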