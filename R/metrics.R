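#' Sampled path-stress of a layout
#'
#' The multidimensional-scaling objective the layout minimizes, estimated
#' by sampling: terms are drawn with a uniform anchor over all steps and a
#' uniform partner on the anchor's path (no Zipf bias, so evaluation is
#' decoupled from the training sampler), and the mean normalized squared
#' residual ((ld - nd) / max(nd, 1))^2 is reported. Stress is 0 iff every
#' sampled term satisfies ld = nd. In 1D, terms pairing a step with itself
#' are dropped (a node is a single coordinate there, so the term is not
#' measurable). Uses R's RNG: seed with [set.seed()].
#'
#' @param g a `variation_graph`.
#' @param index a `path_index` (built if `NULL`).
#' @param layout a `layout_1d` or `layout_2d` covering all nodes.
#' @param n_terms number of sampled terms, >= 1.
#' @return object of class `stress_report`: list(n_terms, stress).
#' @export
sampled_path_stress <- function(g, index = NULL, layout, n_terms = 10000L) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  if (is.null(index)) index <- build_path_index(g)
  terms <- sample_terms_uniform(index, n_terms)
  if (inherits(layout, "layout_1d")) {
    terms <- term_subset(terms, terms$rank_a != terms$rank_b)
    ld <- abs(layout[terms$node_a] - layout[terms$node_b])
  } else {
    i <- layout_rows(terms$node_a, terms$end_a)
    j <- layout_rows(terms$node_b, terms$end_b)
    d <- layout[i, , drop = FALSE] - layout[j, , drop = FALSE]
    ld <- sqrt(rowSums(d * d))
  }
  res <- ((ld - terms$nd) / pmax(terms$nd, 1))^2
  structure(list(n_terms = length(res), stress = mean(res)),
            class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  cat("sampled path-stress: ", format(x$stress), " (", x$n_terms, " terms)\n",
      sep = "")
  invisible(x)
}

term_subset <- function(terms, keep) lapply(terms, `[`, keep)

# every unordered pair of distinct steps of one path, as terms
all_step_pair_terms <- function(index, path = 1L) {
  m <- index$path_steps[path]
  if (m < 2L) stop("path has fewer than 2 steps")
  pairs <- utils::combn(m, 2L) - 1L
  term_from_steps(index, rep(path, ncol(pairs)), pairs[1L, ], pairs[2L, ])
}

# exact stress over an explicit term set
exact_stress <- function(layout, terms) {
  if (inherits(layout, "layout_1d")) {
    terms <- term_subset(terms, terms$rank_a != terms$rank_b)
    ld <- abs(layout[terms$node_a] - layout[terms$node_b])
  } else {
    i <- layout_rows(terms$node_a, terms$end_a)
    j <- layout_rows(terms$node_b, terms$end_b)
    d <- layout[i, , drop = FALSE] - layout[j, , drop = FALSE]
    ld <- sqrt(rowSums(d * d))
  }
  mean(((ld - terms$nd) / pmax(terms$nd, 1))^2)
}

#' 1D order recovery against a path
#'
#' Spearman rank correlation between node coordinates and first-visit path
#' ranks: +1 when the layout sorts the nodes exactly as the path walks
#' them, -1 for the exact reverse. Nodes not on the path are ignored.
#'
#' @param layout a `layout_1d`.
#' @param g the graph.
#' @param path_name path to compare against.
#' @return correlation in `[-1, 1]`.
#' @export
order_recovery <- function(layout, g, path_name) {
  p <- g$paths[[path_name]]
  if (is.null(p)) stop("unknown path: ", path_name)
  ranks <- match(p$node_id, g$nodes$id)
  first <- !duplicated(ranks)
  nr <- ranks[first]
  stats::cor(as.numeric(layout)[nr], seq_along(nr), method = "spearman")
}

#' 2D linearity of a layout along a path
#'
#' Projects the path's node-end points onto their first principal axis and
#' correlates the projections with the corresponding path nucleotide
#' offsets. A layout that renders the path as a straight line scores 1;
#' the value is sign-corrected to be >= 0.
#'
#' @param layout a `layout_2d`.
#' @param g the graph.
#' @param path_name path providing the coordinate system.
#' @return correlation in `[0, 1]`.
#' @export
linearity_2d <- function(layout, g, path_name) {
  p <- g$paths[[path_name]]
  if (is.null(p)) stop("unknown path: ", path_name)
  index <- build_path_index(g)
  path <- match(path_name, index$path_names)
  first <- !duplicated(index$step_node[index$ptr[path]:(index$ptr[path + 1L] - 1L)])
  ranks0 <- which(first) - 1L
  eo <- step_end_offsets(index, rep(path, length(ranks0)), ranks0)
  sl <- index$ptr[path] + ranks0
  nodes <- index$step_node[sl]
  pts <- rbind(layout[2L * nodes - 1L, , drop = FALSE],
               layout[2L * nodes, , drop = FALSE])
  offs <- c(eo[, "start"], eo[, "end"])
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  proj <- as.numeric(pts %*% pc$rotation[, 1L])
  abs(stats::cor(proj, offs))
}
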