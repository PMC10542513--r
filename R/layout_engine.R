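#' Configuration for a path-guided SGD run
#'
#' The annealing step size eta decays geometrically from `eta_max` to
#' `eta_min` over `iter_max` iterations; the per-term learning rate is
#' mu = min(eta * w, 1) with w = 1/max(nd,1)^2, so early iterations move
#' nearly every term at full rate (global untangling) and late iterations
#' make vanishing local refinements.
#'
#' @param iter_max total iterations (epochs). Default: 30 in 1D, 100 in 2D
#'   (resolved by [run_pgsgd()]).
#' @param min_term_updates term updates per iteration. Default: 10 x total
#'   path steps.
#' @param eta_max,eta_min annealing endpoints. Defaults: (max path
#'   nucleotide length)^2 and `epsilon`.
#' @param epsilon final learning-rate scale, default 0.01.
#' @param sampler a [sampler_config()].
#' @param init_mode layout initialization: 1D `"input_order"` or
#'   `"random"`; 2D `"order_uniform"`, `"order_gaussian"`, `"hilbert"` or
#'   `"path_fixed"`. `NULL` picks the dimension default (input_order /
#'   order_gaussian).
#' @param sigma noise scale of the order_* 2D initializations (nucleotides).
#' @param fix_path path name for `init_mode = "path_fixed"`.
#' @param threads workers performing lock-free interleaved updates. With
#'   1 thread runs are bit-deterministic under a fixed seed; with more they
#'   are only statistically reproducible.
#' @param seed integer seed driving all engine randomness.
#' @param delta early-stop threshold on an iteration's max |r| (0 = off).
#' @return object of class `sgd_config`.
#' @export
sgd_config <- function(iter_max = NULL, min_term_updates = NULL,
                       eta_max = NULL, eta_min = NULL, epsilon = 0.01,
                       sampler = sampler_config(), init_mode = NULL,
                       sigma = 1.0, fix_path = NULL,
                       threads = 1L, seed = 42L, delta = 0) {
  stopifnot(is.null(iter_max) || iter_max >= 1,
            inherits(sampler, "sampler_config"), threads >= 1, epsilon > 0)
  structure(list(iter_max = iter_max, min_term_updates = min_term_updates,
                 eta_max = eta_max, eta_min = eta_min, epsilon = epsilon,
                 sampler = sampler, init_mode = init_mode, sigma = sigma,
                 fix_path = fix_path, threads = as.integer(threads),
                 seed = as.integer(seed), delta = delta),
            class = "sgd_config")
}

#' Annealing schedule
#'
#' Geometric decay eta_t = eta_max * (eta_min/eta_max)^(t/(iter_max-1));
#' for `iter_max = 1` the single value is `eta_max`.
#'
#' @param eta_max,eta_min endpoints, `eta_max >= eta_min > 0`.
#' @param iter_max number of iterations.
#' @param t 0-based iteration index (vectorized), in `[0, iter_max)`.
#' @return numeric vector of step sizes.
#' @export
eta_schedule <- function(eta_max, eta_min, iter_max, t) {
  stopifnot(eta_max >= eta_min, eta_min > 0, iter_max >= 1)
  if (any(t < 0 | t >= iter_max)) stop("iteration index out of range")
  if (iter_max == 1L) return(rep(eta_max, length(t)))
  eta_max * (eta_min / eta_max)^(t / (iter_max - 1))
}

layout_rows <- function(node, end) 2L * (node - 1L) + ifelse(end == "start", 1L, 2L)

#' Apply one term update to a 2D layout
#'
#' The SGD step: with w = 1/max(nd,1)^2 and mu = min(eta*w, 1), both chosen
#' node ends move r = mu*(ld - nd)/2 toward each other along the line
#' joining them (negative r pushes them apart), where ld is their current
#' Euclidean distance. Since mu <= 1 the update never overshoots:
#' |ld_new - nd| <= |ld_old - nd|. Coincident points (ld below `ld_floor`)
#' are separated along a pseudo-random unit direction drawn from R's RNG so
#' that runs remain reproducible without biasing an axis. Frozen nodes'
#' ends do not move (the partner end still does).
#'
#' @param layout a `layout_2d` (matrix 2N x 2; rows 2k-1/2k = start/end end
#'   of node rank k).
#' @param term one-row data.frame as produced by [sample_term()].
#' @param eta annealing step size.
#' @param ld_floor distance below which the direction is randomized.
#' @return `list(layout=, r=)`: the updated layout and the applied
#'   displacement magnitude.
#' @export
apply_term_update_2d <- function(layout, term, eta, ld_floor = 1e-9) {
  i <- layout_rows(term$node_a, term$end_a)
  j <- layout_rows(term$node_b, term$end_b)
  A <- layout[i, ]; B <- layout[j, ]
  if (!all(is.finite(A)) || !all(is.finite(B))) stop("non-finite layout coordinates")
  w <- 1 / max(term$nd, 1)^2
  mu <- min(eta * w, 1)
  d <- B - A
  ld <- sqrt(sum(d * d))
  if (ld < ld_floor) {
    ang <- stats::runif(1) * 2 * pi
    u <- c(cos(ang), sin(ang))
  } else {
    u <- d / ld
  }
  r <- mu * (ld - term$nd) / 2
  frozen <- attr(layout, "frozen")
  if (is.null(frozen)) frozen <- rep(FALSE, nrow(layout) / 2L)
  if (!frozen[term$node_a]) layout[i, ] <- A + r * u
  if (!frozen[term$node_b]) layout[j, ] <- B - r * u
  list(layout = layout, r = r)
}

#' Apply one term update to a 1D layout
#'
#' As [apply_term_update_2d()] with scalar coordinates; each node
#' contributes its single position. Terms joining a node to itself are
#' no-ops in 1D. A zero layout distance is resolved by a random sign.
#'
#' @param layout a `layout_1d` (numeric, one coordinate per node rank).
#' @inheritParams apply_term_update_2d
#' @return `list(layout=, r=)`.
#' @export
apply_term_update_1d <- function(layout, term, eta) {
  if (term$node_a == term$node_b && term$rank_a == term$rank_b) {
    return(list(layout = layout, r = 0))
  }
  xa <- layout[term$node_a]; xb <- layout[term$node_b]
  if (!is.finite(xa) || !is.finite(xb)) stop("non-finite layout coordinates")
  w <- 1 / max(term$nd, 1)^2
  mu <- min(eta * w, 1)
  ld <- abs(xb - xa)
  s <- if (ld == 0) (if (stats::runif(1) < 0.5) -1 else 1) else sign(xb - xa)
  r <- mu * (ld - term$nd) / 2
  frozen <- attr(layout, "frozen")
  if (is.null(frozen)) frozen <- rep(FALSE, length(layout))
  if (!frozen[term$node_a]) layout[term$node_a] <- xa + r * s
  if (!frozen[term$node_b]) layout[term$node_b] <- xb - r * s
  list(layout = layout, r = r)
}

node_prefix_offsets <- function(g) {
  len <- nchar(g$nodes$sequence)
  cumsum(c(0, len[-length(len)]))
}

#' Initialize a 1D layout
#'
#' `input_order`: node k (in graph id order) gets the cumulative nucleotide
#' offset of nodes 1..k-1 (prefix sums). `random`: a uniform random
#' permutation of those offsets (uses R's RNG).
#'
#' @param g a `variation_graph`.
#' @param mode `"input_order"` or `"random"`.
#' @return a `layout_1d`: numeric vector, one coordinate per node rank,
#'   with attribute `node_id`.
#' @export
init_layout_1d <- function(g, mode = c("input_order", "random")) {
  mode <- match.arg(mode)
  x <- node_prefix_offsets(g)
  if (mode == "random") x <- sample(x)
  structure(x, node_id = g$nodes$id, frozen = rep(FALSE, length(x)),
            class = "layout_1d")
}

#' Initialize a 2D layout
#'
#' `order_uniform` / `order_gaussian`: X of each node end is its cumulative
#' nucleotide offset in graph order (a node's two ends are separated by its
#' length); Y is Uniform(0, sigma) or Normal(0, sigma) noise per end.
#' `hilbert`: node ends are placed along a Hilbert curve of order
#' ceil(log4(total length)) scaled to a square of side = total length, a
#' locality-preserving initialization that favors planar final layouts.
#' `path_fixed`: nodes on `path` take their (first-visit) path offsets as X
#' and are frozen — never moved by updates — pinning the layout to a
#' reference genome; remaining nodes are initialized as `order_gaussian`.
#'
#' @param g a `variation_graph`.
#' @param mode one of `"order_uniform"`, `"order_gaussian"`, `"hilbert"`,
#'   `"path_fixed"`.
#' @param sigma noise scale (nucleotides) for the order_* modes.
#' @param path path name (`path_fixed` only).
#' @return a `layout_2d`: matrix (2N x 2, columns X,Y; rows 2k-1/2k =
#'   sequence-start/sequence-end end of node rank k) with attributes
#'   `node_id` and `frozen` (logical per node).
#' @export
init_layout_2d <- function(g, mode = c("order_gaussian", "order_uniform",
                                       "hilbert", "path_fixed"),
                           sigma = 1.0, path = NULL) {
  mode <- match.arg(mode)
  n <- nrow(g$nodes)
  len <- nchar(g$nodes$sequence)
  off <- node_prefix_offsets(g)
  xs <- as.vector(rbind(off, off + len))  # start,end interleaved
  npts <- 2L * n
  if (mode == "order_uniform") {
    xy <- cbind(xs, stats::runif(npts, 0, sigma))
  } else if (mode == "order_gaussian" || mode == "path_fixed") {
    xy <- cbind(xs, stats::rnorm(npts, 0, sigma))
  } else { # hilbert
    total <- sum(len)
    ord <- max(1L, as.integer(ceiling(log(total, base = 4))))
    side <- 2^ord
    d <- pmin(round(xs / total * (4^ord - 1)), 4^ord - 1)
    xy <- hilbert_d2xy(ord, d) * (total / side)
  }
  frozen <- rep(FALSE, n)
  if (mode == "path_fixed") {
    if (is.null(path) || is.na(match(path, names(g$paths)))) {
      stop("path_fixed initialization: unknown path name '", path, "'")
    }
    p <- g$paths[[path]]
    ranks <- match(p$node_id, g$nodes$id)
    poff <- cumsum(c(0, len[ranks][-length(ranks)]))
    first <- !duplicated(ranks)
    for (k in which(first)) {
      nr <- ranks[k]
      o <- poff[k]; l <- len[nr]
      if (p$is_reverse[k]) {
        xy[2L * nr - 1L, ] <- c(o + l, 0)  # sequence start at larger coord
        xy[2L * nr, ] <- c(o, 0)
      } else {
        xy[2L * nr - 1L, ] <- c(o, 0)
        xy[2L * nr, ] <- c(o + l, 0)
      }
      frozen[nr] <- TRUE
    }
  }
  dimnames(xy) <- list(NULL, c("X", "Y"))
  structure(xy, node_id = g$nodes$id, frozen = frozen, class = "layout_2d")
}

#' Map distances along a Hilbert curve to 2D cells
#'
#' Standard iterative bit-twiddling conversion from curve distance to cell
#' coordinates on a 2^order x 2^order grid. The curve starts at (0,0).
#'
#' @param order curve order (grid side 2^order).
#' @param d integer curve distances in `[0, 4^order)` (vectorized).
#' @return matrix with columns x, y.
#' @export
hilbert_d2xy <- function(order, d) {
  n <- 2^order
  t <- as.numeric(d)
  x <- y <- numeric(length(d))
  s <- 1
  while (s < n) {
    rx <- (t %/% 2) %% 2
    ry <- (t %% 2 + rx) %% 2  # bit0(t) xor rx
    # rotate quadrant
    swap <- ry == 0
    flip <- swap & rx == 1
    x[flip] <- s - 1 - x[flip]
    y[flip] <- s - 1 - y[flip]
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
    x <- x + s * rx
    y <- y + s * ry
    t <- t %/% 4
    s <- s * 2
  }
  cbind(x = x, y = y)
}

#' Run path-guided stochastic gradient descent
#'
#' The core loop: initialize a layout, then for each iteration t draw the
#' annealing step size eta_t and perform `min_term_updates` term updates
#' (sample a term with the current progress fraction, move the two chosen
#' node ends toward/away from each other). The hot loop runs in compiled
#' code; with `threads > 1`, workers interleave updates lock-free
#' (HOGWILD-style) with per-coordinate atomic writes.
#'
#' @param g a `variation_graph` with at least one path.
#' @param index a `path_index` (built from `g` if `NULL`).
#' @param config an [sgd_config()].
#' @param dims 1 (sorting) or 2 (drawing).
#' @param layout optional starting layout; when `NULL` it is initialized
#'   per `config$init_mode` with R's RNG seeded from `config$seed`.
#' @param callback optional `function(t, eta, max_r)` called after every
#'   iteration (e.g. for logging); return `FALSE` to stop early.
#' @return the final layout (`layout_1d` or `layout_2d`) with attribute
#'   `schedule`: data.frame(iter, eta, max_r).
#' @export
run_pgsgd <- function(g, index = NULL, config = sgd_config(), dims = 2,
                      layout = NULL, callback = NULL) {
  if (length(g$paths) < 1L) stop("PG-SGD requires embedded paths: graph has none")
  if (is.null(index)) index <- build_path_index(g)
  stopifnot(dims %in% c(1, 2))

  iter_max <- config$iter_max %||% if (dims == 1) 30L else 100L
  mtu <- config$min_term_updates %||% (10 * index$total_steps)
  eta_max <- config$eta_max %||% max(index$path_len)^2
  eta_min <- config$eta_min %||% config$epsilon
  sam <- config$sampler

  if (is.null(layout)) {
    set.seed(config$seed)
    layout <- if (dims == 1) {
      init_layout_1d(g, config$init_mode %||% "input_order")
    } else {
      init_layout_2d(g, config$init_mode %||% "order_gaussian",
                     sigma = config$sigma, path = config$fix_path)
    }
  }
  frozen <- attr(layout, "frozen") %||% rep(FALSE, nrow(g$nodes))

  coords <- as.double(layout)  # column-major copy; mutated in place by C++
  ptr0 <- index$ptr - 1L
  etas <- eta_schedule(eta_max, eta_min, iter_max, seq_len(iter_max) - 1L)
  max_rs <- numeric(iter_max)
  ran <- 0L
  for (t in seq_len(iter_max) - 1L) {
    progress <- t / iter_max
    spec <- if (progress >= sam$cooling_start) sam$cooled_zipf else sam$zipf
    mr <- pgsgd_iter_cpp(
      as.integer(dims), coords, frozen,
      index$step_node - 1L, index$step_rev, index$step_len, index$step_off,
      ptr0, etas[t + 1L], spec$theta, as.integer(spec$window),
      sam$flip_probability, as.numeric(mtu), config$threads,
      config$seed, as.integer(t))
    max_rs[t + 1L] <- mr
    ran <- t + 1L
    if (!is.null(callback)) {
      if (identical(callback(t, etas[t + 1L], mr), FALSE)) break
    }
    if (config$delta > 0 && mr < config$delta) break
  }
  if (dims == 1) {
    # a mirror image is an equally good minimizer; canonicalize the sign so
    # the first path runs in increasing coordinate direction
    if (!any(frozen) && index$path_steps[1] > 1L) {
      sl <- index$ptr[1]:(index$ptr[2] - 1L)
      nr <- index$step_node[sl][!duplicated(index$step_node[sl])]
      if (length(nr) > 1L &&
          stats::cor(coords[nr], seq_along(nr), method = "spearman") < 0) {
        coords <- -coords
      }
    }
    out <- structure(coords, node_id = attr(layout, "node_id"),
                     frozen = frozen, class = "layout_1d")
  } else {
    m <- matrix(coords, ncol = 2, dimnames = list(NULL, c("X", "Y")))
    out <- structure(m, node_id = attr(layout, "node_id"),
                     frozen = frozen, class = "layout_2d")
  }
  attr(out, "schedule") <- data.frame(iter = seq_len(ran) - 1L,
                                      eta = etas[seq_len(ran)],
                                      max_r = max_rs[seq_len(ran)])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the node order implied by a 1D layout
#'
#' @param layout a `layout_1d`.
#' @return integer vector of node ids sorted by coordinate (ties broken by
#'   id).
#' @export
layout_node_order <- function(layout) {
  ids <- attr(layout, "node_id")
  ids[order(as.numeric(layout), ids)]
}

#' Write a 2D layout as TSV
#'
#' Header `idx  X  Y`; rows 2k/2k+1 (0-based idx) are the sequence-start /
#' sequence-end ends of the node with 0-based rank k. Coordinates are
#' printed with 17 significant digits, enough to round-trip doubles.
#'
#' @param layout a `layout_2d`.
#' @param file output path or connection.
#' @export
write_layout_tsv <- function(layout, file) {
  n <- nrow(layout)
  lines <- c("idx\tX\tY",
             sprintf("%d\t%.17g\t%.17g", seq_len(n) - 1L, layout[, 1], layout[, 2]))
  writeLines(lines, file)
  invisible(file)
}

#' Read a 2D layout TSV
#'
#' @param file path to a TSV written by [write_layout_tsv()].
#' @param g optional graph; when given, row count is checked against 2N and
#'   node ids/frozen attributes attached.
#' @return a `layout_2d`.
#' @export
read_layout_tsv <- function(file, g = NULL) {
  d <- utils::read.delim(file, header = TRUE, sep = "\t")
  if (!all(c("idx", "X", "Y") %in% names(d))) stop("not a layout TSV: ", file)
  m <- cbind(X = d$X, Y = d$Y)
  node_id <- NULL
  if (!is.null(g)) {
    if (nrow(m) != 2L * nrow(g$nodes)) {
      stop("layout TSV has ", nrow(m), " rows; graph needs ", 2L * nrow(g$nodes))
    }
    node_id <- g$nodes$id
  }
  structure(m, node_id = node_id,
            frozen = rep(FALSE, nrow(m) / 2L), class = "layout_2d")
}

#' @export
print.layout_2d <- function(x, ...) {
  cat("layout_2d: ", nrow(x) / 2L, " nodes (", nrow(x), " end points)\n", sep = "")
  invisible(x)
}

#' @export
print.layout_1d <- function(x, ...) {
  cat("layout_1d: ", length(x), " nodes\n", sep = "")
  invisible(x)
}
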