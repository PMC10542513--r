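#' Build a path position index
#'
#' The positional system of path-guided SGD: for every step of every path,
#' its cumulative nucleotide offset from the path start, plus a global
#' (path-major, rank-minor) enumeration of all steps supporting uniform
#' sampling. Stored as plain dense integer/double arrays in CSR-like layout;
#' nucleotide distances between any two steps of a path are then O(1)
#' lookups, with no pairwise distance matrix.
#'
#' @param g a `variation_graph` with at least one path.
#' @return an object of class `path_index` with fields:
#'   `path_names`; `ptr` (1-based start of each path's slice in the flat
#'   arrays, length n_paths+1); flat per-step arrays `step_node` (node rank
#'   in the graph's id-sorted node table), `step_rev`, `step_len`,
#'   `step_off` (cumulative nucleotide offset); `path_steps`, `path_len`
#'   (per-path step counts and nucleotide lengths); `total_steps`;
#'   `node_len` and `node_id` per node rank.
#' @export
build_path_index <- function(g) {
  if (!inherits(g, "variation_graph")) stop("need a variation_graph")
  if (length(g$paths) < 1L) stop("PG-SGD requires embedded paths: graph has none")
  node_len <- nchar(g$nodes$sequence)
  per <- lapply(g$paths, function(p) {
    rank <- match(p$node_id, g$nodes$id)
    len <- node_len[rank]
    list(rank = rank, rev = p$is_reverse, len = len,
         off = cumsum(c(0, len[-length(len)])))
  })
  path_steps <- vapply(per, function(x) length(x$rank), integer(1))
  idx <- structure(list(
    path_names = names(g$paths),
    n_paths = length(per),
    ptr = as.integer(c(1L, 1L + cumsum(path_steps))),
    step_node = unlist(lapply(per, `[[`, "rank"), use.names = FALSE),
    step_rev = unlist(lapply(per, `[[`, "rev"), use.names = FALSE),
    step_len = as.double(unlist(lapply(per, `[[`, "len"), use.names = FALSE)),
    step_off = as.double(unlist(lapply(per, `[[`, "off"), use.names = FALSE)),
    path_steps = unname(path_steps),
    path_len = unname(vapply(per, function(x) sum(x$len), numeric(1))),
    total_steps = sum(path_steps),
    node_len = as.double(node_len),
    node_id = g$nodes$id
  ), class = "path_index")
  idx
}

check_step_ref <- function(index, path, rank) {
  path <- as.integer(path); rank <- as.integer(rank)
  bad <- path < 1L | path > index$n_paths
  if (any(bad)) stop("step ref: path ", path[bad][1L], " out of range")
  bad <- rank < 0L | rank >= index$path_steps[path]
  if (any(bad)) {
    stop("step ref: rank ", rank[bad][1L], " out of range for path ",
         path[bad][1L])
  }
  list(path = path, rank = rank)
}

#' Nucleotide offset of a path step
#'
#' Cumulative length of steps 0..rank-1 of the path; the offset of a
#' step's "left" edge in path coordinates (0-based, half-open).
#'
#' @param index a `path_index`.
#' @param path 1-based path number(s).
#' @param rank 0-based step rank(s) within the path.
#' @return numeric vector of offsets. O(1) per query.
#' @export
step_offset <- function(index, path, rank) {
  r <- check_step_ref(index, path, rank)
  index$step_off[index$ptr[r$path] + r$rank]
}

#' Path coordinates of a step's two node ends
#'
#' A node laid out in 2D is a segment with two ends: its sequence start and
#' sequence end. For a forward step the sequence-start end sits at the
#' step's offset and the sequence-end end at offset + node length; a
#' reverse-strand step swaps the two (the node's sequence start sits at the
#' larger path coordinate).
#'
#' @inheritParams step_offset
#' @return a two-column matrix `cbind(start, end)` of path coordinates of
#'   the node's sequence-start and sequence-end ends.
#' @export
step_end_offsets <- function(index, path, rank) {
  r <- check_step_ref(index, path, rank)
  i <- index$ptr[r$path] + r$rank
  off <- index$step_off[i]; len <- index$step_len[i]; rev <- index$step_rev[i]
  cbind(start = ifelse(rev, off + len, off),
        end = ifelse(rev, off, off + len))
}

#' Sample steps uniformly from all steps of all paths
#'
#' Each step of every path has probability 1/total_steps, so paths are
#' implicitly weighted by their step counts. Uses R's RNG (seed with
#' [set.seed()] for reproducibility).
#'
#' @param index a `path_index`.
#' @param n number of draws.
#' @return data.frame with columns `path` (1-based), `rank` (0-based), and
#'   `flat` (1-based global step number).
#' @export
sample_global_step <- function(index, n = 1L) {
  stopifnot(index$total_steps >= 1L)
  flat <- sample.int(index$total_steps, n, replace = TRUE)
  flat_to_step(index, flat)
}

flat_to_step <- function(index, flat) {
  path <- findInterval(flat, index$ptr)
  data.frame(path = path, rank = flat - index$ptr[path], flat = flat)
}

#' @export
print.path_index <- function(x, ...) {
  cat("path_index: ", x$n_paths, " path(s), ", x$total_steps, " steps, ",
      sum(x$path_len), " bp of path sequence\n", sep = "")
  invisible(x)
}
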