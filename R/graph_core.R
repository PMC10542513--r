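#' Construct a variation graph
#'
#' A variation graph is a sequence graph G = (V, E, P): nodes carry
#' nucleotide sequences, edges connect ordered pairs of oriented node ends,
#' and paths embed genomes as walks over oriented nodes. Every node has an
#' implicit reverse complement; reverse-strand traversal is never stored
#' explicitly.
#'
#' @param nodes data.frame with integer column `id` (unique, positive) and
#'   character column `sequence` (non-empty, alphabet ACGTN; stored
#'   upper-case).
#' @param edges data.frame with columns `from`, `from_rev`, `to`, `to_rev`:
#'   node ids and logical strand flags (`TRUE` = reverse). The implicit
#'   symmetric traversal (reverse of both strands, swapped) is honored by
#'   validation without being stored.
#' @param paths named list; each element is `list(name=, node_id=, is_reverse=)`
#'   where `node_id` is an integer vector of steps and `is_reverse` a logical
#'   vector of the same length.
#' @param validate validate invariants (default `TRUE`).
#' @return An object of class `variation_graph` with elements `nodes`,
#'   `edges`, `paths`. Nodes are kept sorted by id; node "rank" means the
#'   position in this sorted order.
#' @export
variation_graph <- function(nodes, edges = NULL, paths = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sequence") %in% names(nodes)))
  nodes$id <- as.integer(nodes$id)
  nodes$sequence <- toupper(as.character(nodes$sequence))
  nodes <- nodes[order(nodes$id), c("id", "sequence"), drop = FALSE]
  rownames(nodes) <- NULL
  if (is.null(edges)) {
    edges <- data.frame(from = integer(), from_rev = logical(),
                        to = integer(), to_rev = logical())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  edges$from_rev <- as.logical(edges$from_rev)
  edges$to_rev <- as.logical(edges$to_rev)
  rownames(edges) <- NULL
  paths <- lapply(paths, function(p) {
    list(name = as.character(p$name),
         node_id = as.integer(p$node_id),
         is_reverse = as.logical(p$is_reverse))
  })
  names(paths) <- vapply(paths, `[[`, character(1), "name")
  g <- structure(list(nodes = nodes, edges = edges, paths = paths),
                 class = "variation_graph")
  if (validate) validate_variation_graph(g)
  g
}

#' Validate variation-graph invariants
#'
#' Checks id uniqueness, sequence alphabet, edge endpoint existence, edge
#' uniqueness, and that consecutive path steps are connected by an edge
#' (either as stored or via the implicit reverse traversal).
#'
#' @param g a `variation_graph`.
#' @return `g`, invisibly; stops with a descriptive error on violation.
#' @export
validate_variation_graph <- function(g) {
  n <- g$nodes
  if (nrow(n) < 1L) stop("graph has no nodes")
  if (anyDuplicated(n$id)) {
    stop("duplicate node id: ", n$id[duplicated(n$id)][1L])
  }
  if (any(n$id < 1L)) stop("node ids must be positive integers")
  bad <- grepl("[^ACGTN]", n$sequence)
  if (any(bad)) stop("node ", n$id[bad][1L], ": sequence has characters outside ACGTN")
  if (any(nchar(n$sequence) < 1L)) {
    stop("node ", n$id[nchar(n$sequence) < 1L][1L], ": empty sequence")
  }
  e <- g$edges
  if (nrow(e)) {
    miss <- setdiff(c(e$from, e$to), n$id)
    if (length(miss)) stop("edge references unknown node ", miss[1L])
    key <- edge_keys(e$from, e$from_rev, e$to, e$to_rev)
    if (anyDuplicated(key)) stop("duplicate edge: ", key[duplicated(key)][1L])
  }
  ek <- edge_key_set(g)
  for (p in g$paths) {
    if (length(p$node_id) < 1L) stop("path ", p$name, ": has no steps")
    miss <- setdiff(p$node_id, n$id)
    if (length(miss)) stop("path ", p$name, ": references unknown node ", miss[1L])
    m <- length(p$node_id)
    if (m > 1L) {
      k <- edge_keys(p$node_id[-m], p$is_reverse[-m], p$node_id[-1L], p$is_reverse[-1L])
      bad <- !(k %in% ek)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop("path ", p$name, ": steps ", i, "-", i + 1L,
             " (", k[bad][1L], ") not connected by an edge")
      }
    }
  }
  if (anyDuplicated(names(g$paths))) stop("duplicate path name")
  invisible(g)
}

edge_keys <- function(from, from_rev, to, to_rev) {
  paste0(from, ifelse(from_rev, "-", "+"), ">", to, ifelse(to_rev, "-", "+"))
}

# set of traversable oriented edges: stored records plus their implicit
# reverse (swap endpoints, flip both strands)
edge_key_set <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(character())
  unique(c(edge_keys(e$from, e$from_rev, e$to, e$to_rev),
           edge_keys(e$to, !e$to_rev, e$from, !e$from_rev)))
}

#' Reverse complement of a nucleotide string
#'
#' `N` complements to `N`.
#' @param s character vector over ACGTN.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Concatenated nucleotide sequence of a path
#'
#' Walks the path's steps, reverse-complementing reverse-strand steps.
#' @param g a `variation_graph`.
#' @param path_name path to walk.
#' @return single string.
#' @export
path_sequence <- function(g, path_name) {
  p <- g$paths[[path_name]]
  if (is.null(p)) stop("unknown path: ", path_name)
  seqs <- g$nodes$sequence[match(p$node_id, g$nodes$id)]
  seqs[p$is_reverse] <- reverse_complement(seqs[p$is_reverse])
  paste(seqs, collapse = "")
}

#' Parse a GFA1 document into a variation graph
#'
#' Accepts GFA1 S/L/P records (tab-separated). `H` lines and unrecognized
#' optional tags are ignored; `W` lines and rGFA `SN:`-tagged segments are
#' rejected. Segment names must be positive integers (the node id domain).
#' Link and path overlaps must be `0M` or `*`.
#'
#' @param x a file path, or a character vector of GFA lines (a single string
#'   containing newlines is split).
#' @return a validated `variation_graph`.
#' @export
parse_gfa <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines)]
  rectype <- substr(lines, 1L, 1L)
  if (any(rectype == "W")) stop("GFA W lines are not supported (GFA1 S/L/P only)")
  fields <- strsplit(lines, "\t", fixed = TRUE)

  seg_name <- character(); seg_seq <- character()
  e_from <- integer(); e_frev <- logical(); e_to <- integer(); e_trev <- logical()
  paths <- list()

  parse_id <- function(name, line) {
    if (!grepl("^[0-9]+$", name) || name == "0") {
      stop("segment name '", name, "' is not a positive integer (line: ", line, ")")
    }
    as.integer(name)
  }
  orient <- function(ch, line) {
    if (!all(ch %in% c("+", "-"))) stop("bad orientation in line: ", line)
    ch == "-"
  }

  for (i in seq_along(lines)) {
    f <- fields[[i]]
    t <- f[[1L]]
    if (t == "H" || t == "#") next
    if (t == "S") {
      if (length(f) == 2L) stop("segment ", f[[2L]], ": empty sequence")
      if (length(f) < 3L) stop("malformed S line: ", lines[i])
      if (any(grepl("^SN:Z:", f[-(1:3)]))) {
        stop("rGFA SN tag not supported (line: ", lines[i], ")")
      }
      nm <- f[[2L]]
      if (nm %in% seg_name) stop("duplicate segment name ", nm)
      if (!nzchar(f[[3L]]) || f[[3L]] == "*") stop("segment ", nm, ": empty sequence")
      seg_name <- c(seg_name, nm)
      seg_seq <- c(seg_seq, f[[3L]])
    } else if (t == "L") {
      if (length(f) < 6L) stop("malformed L line: ", lines[i])
      if (!(f[[6L]] %in% c("0M", "*"))) {
        stop("unsupported overlap '", f[[6L]], "' (only 0M/* blunt links): ", lines[i])
      }
      e_from <- c(e_from, parse_id(f[[2L]], lines[i]))
      e_frev <- c(e_frev, orient(f[[3L]], lines[i]))
      e_to <- c(e_to, parse_id(f[[4L]], lines[i]))
      e_trev <- c(e_trev, orient(f[[5L]], lines[i]))
    } else if (t == "P") {
      if (length(f) < 3L) stop("malformed P line: ", lines[i])
      steps <- strsplit(f[[3L]], ",", fixed = TRUE)[[1L]]
      if (!length(steps)) stop("path ", f[[2L]], " has no steps")
      ids <- vapply(substr(steps, 1L, nchar(steps) - 1L), parse_id,
                    integer(1), line = lines[i], USE.NAMES = FALSE)
      rev <- orient(substr(steps, nchar(steps), nchar(steps)), lines[i])
      if (length(f) >= 4L && f[[4L]] != "*") {
        ov <- strsplit(f[[4L]], ",", fixed = TRUE)[[1L]]
        if (!all(ov %in% c("0M", "*"))) {
          stop("unsupported path overlap in line: ", lines[i])
        }
      }
      paths[[length(paths) + 1L]] <- list(name = f[[2L]], node_id = ids, is_reverse = rev)
    }
    # other record types silently ignored
  }
  if (!length(seg_name)) stop("GFA document contains no S lines")
  ids <- vapply(seg_name, parse_id, integer(1), line = "S", USE.NAMES = FALSE)
  known <- ids
  for (p in paths) {
    miss <- setdiff(p$node_id, known)
    if (length(miss)) stop("path ", p$name, " references unknown segment ", miss[1L])
  }
  miss <- setdiff(c(e_from, e_to), known)
  if (length(miss)) stop("link references unknown segment ", miss[1L])
  variation_graph(
    nodes = data.frame(id = ids, sequence = seg_seq, stringsAsFactors = FALSE),
    edges = data.frame(from = e_from, from_rev = e_frev, to = e_to, to_rev = e_trev),
    paths = paths
  )
}

#' Write a variation graph as a canonical GFA1 document
#'
#' Record order is deterministic: one `H` line, `S` lines by node id, `L`
#' lines ordered by (from, from strand, to, to strand), `P` lines in path
#' insertion order. Link overlaps are written as `0M`, path overlaps as `*`.
#'
#' @param g a `variation_graph`.
#' @param file optional output path; when `NULL` the document is returned.
#' @return the document as a single string (invisibly when `file` given).
#' @export
write_gfa <- function(g, file = NULL) {
  n <- g$nodes
  s_lines <- paste("S", n$id, n$sequence, sep = "\t")
  e <- g$edges
  l_lines <- character()
  if (nrow(e)) {
    o <- order(e$from, e$from_rev, e$to, e$to_rev)
    e <- e[o, , drop = FALSE]
    l_lines <- paste("L", e$from, ifelse(e$from_rev, "-", "+"),
                     e$to, ifelse(e$to_rev, "-", "+"), "0M", sep = "\t")
  }
  p_lines <- vapply(g$paths, function(p) {
    paste("P", p$name,
          paste0(p$node_id, ifelse(p$is_reverse, "-", "+"), collapse = ","),
          "*", sep = "\t")
  }, character(1), USE.NAMES = FALSE)
  doc <- paste0(paste(c("H\tVN:Z:1.0", s_lines, l_lines, p_lines), collapse = "\n"), "\n")
  if (is.null(file)) return(doc)
  writeLines(doc, file, sep = "")
  invisible(doc)
}

#' Renumber graph nodes according to an ordering
#'
#' Materializes a 1D sort: the node listed at position k of `order` receives
#' id k. Edges and path steps are rewritten consistently; sequences and the
#' nucleotide content of every path are unchanged.
#'
#' @param g a `variation_graph`.
#' @param order integer vector: a permutation of exactly the graph's node ids.
#' @return a new `variation_graph` with ids 1..N.
#' @export
apply_node_order <- function(g, order) {
  order <- as.integer(order)
  if (length(order) != nrow(g$nodes) || !setequal(order, g$nodes$id) ||
      anyDuplicated(order)) {
    stop("order must be a permutation of the graph's node ids")
  }
  remap <- function(ids) match(ids, order)
  nodes <- data.frame(id = remap(g$nodes$id), sequence = g$nodes$sequence,
                      stringsAsFactors = FALSE)
  edges <- g$edges
  if (nrow(edges)) {
    edges$from <- remap(edges$from)
    edges$to <- remap(edges$to)
  }
  paths <- lapply(g$paths, function(p) {
    list(name = p$name, node_id = remap(p$node_id), is_reverse = p$is_reverse)
  })
  variation_graph(nodes, edges, paths)
}

#' @export
print.variation_graph <- function(x, ...) {
  cat("variation_graph: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(x$paths), " path(s), ",
      sum(nchar(x$nodes$sequence)), " bp\n", sep = "")
  invisible(x)
}
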