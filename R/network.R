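#' Stage networks of one-segment neighbours
#'
#' A `phon_network` is the undirected graph over the cumulative vocabulary
#' at one AoA stage: nodes are phonemic word forms, edges connect forms at
#' edit distance exactly 1, and each edge carries the integer phonetic
#' similarity weight from [aline_similarity()].  Self-loops and parallel
#' edges cannot occur (the neighbour relation is irreflexive and the edge
#' set has set semantics).
#'
#' @name phon_network
NULL

#' Build the weighted phonological network at a stage
#'
#' @param lexicon a `staged_lexicon`
#' @param stage integer stage 1-6; the node set is the cumulative vocabulary
#'   at this stage
#' @param ft an `aline_features` table used for edge weights; NULL skips
#'   weighting (all weights NA) when only degrees are needed
#' @return object of class `phon_network`: list with `stage`, `nodes`,
#'   `edges` (data.frame `phon_a`, `phon_b`, `aline_distance`,
#'   `similarity_int`), `degree` and `weighted_degree` (named integer
#'   vectors over nodes)
#' @export
build_stage_network <- function(lexicon, stage, ft = NULL) {
  stopifnot(inherits(lexicon, "staged_lexicon"), stage %in% seq_len(N_STAGES))
  nodes <- stage_vocab(lexicon, stage)
  edges <- find_neighbors(nodes)
  if (nrow(edges)) {
    if (!is.null(ft)) {
      edges$aline_distance <- aline_distance(edges$phon_a, edges$phon_b, ft)
      edges$similarity_int <- rescale_similarity(edges$aline_distance)
    } else {
      edges$aline_distance <- NA_real_
      edges$similarity_int <- NA_integer_
    }
  } else {
    edges$aline_distance <- numeric(0)
    edges$similarity_int <- integer(0)
  }
  deg <- integer(length(nodes)); names(deg) <- nodes
  wdeg <- integer(length(nodes)); names(wdeg) <- nodes
  if (nrow(edges)) {
    dt <- table(factor(c(edges$phon_a, edges$phon_b), levels = nodes))
    deg[names(dt)] <- as.integer(dt)
    if (!is.null(ft)) {
      wt <- tapply(c(edges$similarity_int, edges$similarity_int),
                   factor(c(edges$phon_a, edges$phon_b), levels = nodes),
                   sum)
      wdeg[!is.na(wt)] <- as.integer(wt[!is.na(wt)])
    } else {
      wdeg[] <- NA_integer_
    }
  }
  structure(
    list(stage = as.integer(stage), nodes = nodes, edges = edges,
         degree = deg, weighted_degree = wdeg),
    class = "phon_network"
  )
}

#' @export
print.phon_network <- function(x, ...) {
  cat("Phonological network, stage", x$stage, "—",
      length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (length(x$degree)) {
    cat("  mean degree:", round(mean(x$degree), 2),
        " hermits:", sum(x$degree == 0L), "\n")
  }
  invisible(x)
}

#' Build all six stage networks
#'
#' @inheritParams build_stage_network
#' @param stages integer vector of stages to build
#' @return list of `phon_network`, named "1".."6"
#' @export
build_all_networks <- function(lexicon, ft = NULL, stages = seq_len(N_STAGES)) {
  nets <- lapply(stages, function(s) build_stage_network(lexicon, s, ft))
  names(nets) <- as.character(stages)
  nets
}

#' Degree assortativity of a stage network
#'
#' Pearson correlation between the degrees at the two endpoints of each
#' edge, with every edge counted in both orientations (the standard
#' degree-correlation convention for undirected graphs).  Positive values
#' mean dense neighbourhoods connect to dense neighbourhoods.
#'
#' @param net a `phon_network`, or a two-column edge data.frame/matrix
#' @return Pearson r in \[-1, 1\]
#' @export
assortativity_degree <- function(net) {
  if (inherits(net, "phon_network")) {
    ea <- net$edges$phon_a; eb <- net$edges$phon_b
    deg <- net$degree
  } else {
    ea <- as.character(net[[1L]]); eb <- as.character(net[[2L]])
    nodes <- unique(c(ea, eb))
    dt <- table(factor(c(ea, eb), levels = nodes))
    deg <- as.integer(dt); names(deg) <- nodes
  }
  if (!length(ea)) stop("assortativity undefined: network has no edges")
  # oriented endpoint degree pairs: (x, y) and (y, x) for every edge
  x <- c(deg[ea], deg[eb])
  y <- c(deg[eb], deg[ea])
  # closed-form Pearson moments; cross-checked against cor() and igraph
  n <- length(x)
  mx <- mean(x)                      # == mean(y) by symmetry
  vx <- sum((x - mx)^2) / n
  if (vx == 0)
    stop("assortativity undefined: endpoint degrees are constant")
  sum((x - mx) * (y - mx)) / (n * vx)
}

#' Fraction of uniquely acquired words that stay without neighbours
#'
#' Of the words first acquired at `stage`, the fraction that are lexical
#' hermits (degree 0) in the network `net`.  Judged in the acquisition
#' stage's own network by default, matching the per-stage accounting of
#' non-growing words; pass the final-stage network to ask which words never
#' connect at all.
#'
#' @param lexicon a `staged_lexicon`
#' @param stage acquisition stage whose unique words form the denominator
#' @param net a `phon_network` in which isolation is judged (defaults to the
#'   network of `stage` itself, built unweighted)
#' @return fraction in \[0, 1\]
#' @export
hermit_fraction <- function(lexicon, stage, net = NULL) {
  stopifnot(inherits(lexicon, "staged_lexicon"), stage %in% seq_len(N_STAGES))
  new_words <- lexicon$entries$phon[lexicon$entries$aoa == stage]
  if (!length(new_words)) stop("no words uniquely acquired at stage ", stage)
  if (is.null(net)) net <- build_stage_network(lexicon, stage, ft = NULL)
  stopifnot(inherits(net, "phon_network"), all(new_words %in% net$nodes))
  mean(net$degree[new_words] == 0L)
}

#' Export a stage network as an edge-list TSV
#'
#' @param net a `phon_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "phon_network"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert a stage network to an igraph object
#'
#' Node attributes `aoa`, `freq_log`, `length`, `l1_density` are attached
#' when the originating lexicon is supplied; the edge attribute is
#' `similarity_int`.
#'
#' @param net a `phon_network`
#' @param lexicon optional `staged_lexicon` for node attributes
#' @return an igraph graph
#' @export
as_igraph <- function(net, lexicon = NULL) {
  stopifnot(inherits(net, "phon_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[c("phon_a", "phon_b", "similarity_int")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
  if (!is.null(lexicon)) {
    e <- lexicon$entries[match(net$nodes, lexicon$entries$phon), ]
    g <- igraph::set_vertex_attr(g, "aoa", value = e$aoa)
    g <- igraph::set_vertex_attr(g, "freq_log", value = e$freq_log)
    g <- igraph::set_vertex_attr(g, "length", value = e$length)
    g <- igraph::set_vertex_attr(g, "l1_density", value = e$l1_density)
  }
  g
}

#' Export a stage network to GraphML
#'
#' @inheritParams as_igraph
#' @param path output `.graphml` path
#' @return `path`, invisibly
#' @export
write_graphml <- function(net, path, lexicon = NULL) {
  igraph::write_graph(as_igraph(net, lexicon), path, format = "graphml")
  invisible(path)
}
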