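#' Run the full staged-network growth analysis
#'
#' Orchestrates the pipeline end to end: stage networks with weighted
#' one-segment edges, per-stage summary statistics (sizes, hermit fractions,
#' degree assortativity), per-word growth trajectories, the spurt-level
#' model table with per-spurt means, growth-pattern counts for words
#' acquired at stages 1-3, and (optionally) the three regressions with
#' pairwise spurt contrasts.  The run is deterministic given its inputs;
#' the report carries an MD5 hash of the configuration so artifacts can be
#' matched to the run that produced them.
#'
#' @param lexicon a `staged_lexicon`
#' @param ft an `aline_features` table for edge weights
#' @param fit_models fit the quasi-binomial and zero-inflated regressions?
#'   (skipping them is useful for small fixtures where the factors are
#'   nearly constant)
#' @param out_dir optional directory; when given, the report JSON, the
#'   model table, trajectory table, and per-stage edge lists are written
#'   there
#' @return object of class `phonogrow_run`
#' @export
pg_run_all <- function(lexicon, ft = default_feature_table(),
                       fit_models = TRUE, out_dir = NULL) {
  stopifnot(inherits(lexicon, "staged_lexicon"))
  networks <- build_all_networks(lexicon, ft)
  per_stage <- data.frame(
    stage = seq_len(N_STAGES),
    n_nodes = vapply(networks, function(n) length(n$nodes), integer(1L)),
    n_edges = vapply(networks, function(n) nrow(n$edges), integer(1L)),
    assortativity = vapply(networks, function(n)
      tryCatch(assortativity_degree(n), error = function(e) NA_real_),
      numeric(1L)),
    hermit_fraction = vapply(seq_len(N_STAGES), function(s)
      tryCatch(hermit_fraction(lexicon, s, networks[[as.character(s)]]),
               error = function(e) NA_real_), numeric(1L))
  )

  trajectories <- compute_trajectories(networks, lexicon)
  table <- build_model_table(trajectories, lexicon)

  by_spurt <- stats::aggregate(
    cbind(prop_degree_gain, avg_weighted_degree) ~ spurt,
    data = table, FUN = mean)
  sat_ok <- !is.na(table$prop_saturation_gain)
  if (any(sat_ok)) {
    sat_by_spurt <- stats::aggregate(prop_saturation_gain ~ spurt,
                                     data = table[sat_ok, ], FUN = mean)
    by_spurt <- merge(by_spurt, sat_by_spurt, by = "spurt", all.x = TRUE)
  } else by_spurt$prop_saturation_gain <- NA_real_

  # pattern counts: growing words acquired early enough to show a profile
  eligible <- vapply(trajectories, function(t)
    t$aoa <= 3L && final_degree(t) > 0L, logical(1L))
  patterns <- vapply(trajectories[eligible], classify_growth_pattern,
                     character(1L))
  pattern_counts <- table(factor(patterns, levels = c("initial",
                                                      "continuous",
                                                      "delayed", "other")))

  models <- NULL
  if (fit_models) {
    models <- list(
      degree = fit_proportional_model(table, "degree_gain"),
      saturation = if (any(sat_ok))
        fit_proportional_model(table, "saturation_gain") else NULL,
      weighted = fit_zinb_model(table)
    )
    models$contrasts <- tryCatch(
      lapply(models[c("degree", "saturation")], function(m)
        if (!is.null(m)) pairwise_spurt_contrasts(m)),
      error = function(e) NULL)
  }

  run <- structure(
    list(lexicon = lexicon, networks = networks,
         trajectories = trajectories, model_table = table,
         per_stage = per_stage, by_spurt = by_spurt,
         pattern_counts = pattern_counts, models = models,
         config_hash = hash_object(list(lexicon$entries,
                                        ft$segments, ft$params))),
    class = "phonogrow_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.phonogrow_run <- function(x, ...) {
  cat("Staged phonological network growth run  [config",
      substr(x$config_hash, 1, 8), "]\n\n")
  cat("Per-stage networks:\n")
  print(transform(x$per_stage,
                  assortativity = round(assortativity, 3),
                  hermit_fraction = round(hermit_fraction, 3)),
        row.names = FALSE)
  cat("\nMean outcomes by spurt (growing words):\n")
  print(transform(x$by_spurt,
                  prop_degree_gain = round(prop_degree_gain, 4),
                  avg_weighted_degree = round(avg_weighted_degree, 1),
                  prop_saturation_gain = round(prop_saturation_gain, 4)),
        row.names = FALSE)
  cat("\nGrowth patterns (AoA 1-3, growing words):\n")
  print(x$pattern_counts)
  if (!is.null(x$models)) {
    cat("\nDegree-gain model McFadden R2:",
        round(x$models$degree$mcfadden_r2, 3), "\n")
    if (!is.null(x$models$saturation))
      cat("Saturation-gain model McFadden R2:",
          round(x$models$saturation$mcfadden_r2, 3), "\n")
  }
  invisible(x)
}

#' Summarise a run as a plain list (JSON-ready)
#'
#' Everything in the report is recomputable from the run's intermediate
#' artifacts; no timestamps are embedded, so two runs on identical inputs
#' serialise byte-identically.
#'
#' @param run a `phonogrow_run`
#' @return nested list
#' @export
run_report <- function(run) {
  stopifnot(inherits(run, "phonogrow_run"))
  list(
    config_hash = run$config_hash,
    n_words = nrow(run$lexicon$entries),
    dropped_rows = run$lexicon$dropped,
    per_stage = run$per_stage,
    by_spurt = run$by_spurt,
    pattern_counts = as.list(run$pattern_counts),
    models = if (!is.null(run$models)) list(
      degree = list(
        mcfadden_r2 = run$models$degree$mcfadden_r2,
        dispersion = run$models$degree$dispersion,
        n = run$models$degree$n),
      saturation = if (!is.null(run$models$saturation)) list(
        mcfadden_r2 = run$models$saturation$mcfadden_r2,
        dispersion = run$models$saturation$dispersion,
        n = run$models$saturation$n),
      weighted = list(theta = run$models$weighted$theta,
                      n = run$models$weighted$n,
                      converged = run$models$weighted$converged))
  )
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(run_report(run),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(run$model_table,
                     file.path(out_dir, "model_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  traj <- do.call(rbind, lapply(run$trajectories, function(t)
    cbind(phon = t$phon, aoa = t$aoa, t$spurts)))
  utils::write.table(traj, file.path(out_dir, "trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  for (s in seq_len(N_STAGES))
    write_edge_list(run$networks[[as.character(s)]],
                    file.path(out_dir, sprintf("edges_stage%d.tsv", s)))
  invisible(out_dir)
}
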