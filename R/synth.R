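# Seeded synthetic variation graphs: small stand-ins for pangenome data
# exercising every structure the layout engine must handle. Sequences are
# uniform ACGT; only lengths matter to the layout.

rand_seqs <- function(n, node_len) {
  len <- if (length(node_len) == 2L) {
    sample(node_len[1]:node_len[2], n, replace = TRUE)
  } else {
    rep(as.integer(node_len), n)
  }
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

#' Linear synthetic graph
#'
#' A chain of forward-linked nodes traversed by one path.
#'
#' @param n_nodes number of nodes.
#' @param node_len length-2 range (uniform draw) or a single fixed length.
#' @param seed RNG seed (NULL = use current RNG state).
#' @return a `variation_graph` with path `"p"`.
#' @export
make_linear <- function(n_nodes, node_len = c(1L, 32L), seed = 1L) {
  stopifnot(n_nodes >= 1)
  with_seed(seed, {
    nodes <- data.frame(id = seq_len(n_nodes),
                        sequence = rand_seqs(n_nodes, node_len))
    edges <- if (n_nodes > 1L) {
      data.frame(from = seq_len(n_nodes - 1L), from_rev = FALSE,
                 to = 2:n_nodes, to_rev = FALSE)
    } else NULL
    variation_graph(nodes, edges, list(list(
      name = "p", node_id = seq_len(n_nodes),
      is_reverse = rep(FALSE, n_nodes))))
  })
}

#' Synthetic graph with biallelic SNP bubbles
#'
#' A chain of anchor nodes; between consecutive anchors, with probability
#' `bubble_rate`, a bubble of two alternative single-base nodes (the two
#' alleles). Each path picks one allele per bubble at random.
#'
#' @param n_anchors number of anchor nodes.
#' @param bubble_rate per-gap probability of a bubble.
#' @param n_paths number of embedded paths.
#' @param node_len anchor length range.
#' @param seed RNG seed.
#' @return a `variation_graph` with paths `"p1"..`.
#' @export
make_snp_bubbles <- function(n_anchors, bubble_rate = 0.5, n_paths = 2L,
                             node_len = c(1L, 32L), seed = 1L) {
  stopifnot(n_anchors >= 2)
  with_seed(seed, {
    ids <- integer(); seqs <- character()
    new_node <- function(s) {
      id <- length(ids) + 1L
      ids <<- c(ids, id); seqs <<- c(seqs, s)
      id
    }
    anchors <- vapply(rand_seqs(n_anchors, node_len), new_node, integer(1))
    e <- list()
    add_edge <- function(a, b) e[[length(e) + 1L]] <<- c(a, b)
    # per gap: either a direct link or a bubble of two allele nodes
    bubbled <- stats::runif(n_anchors - 1L) < bubble_rate
    alleles <- vector("list", n_anchors - 1L)
    for (i in seq_len(n_anchors - 1L)) {
      if (bubbled[i]) {
        alt <- c(new_node(rand_seqs(1L, 1L)), new_node(rand_seqs(1L, 1L)))
        alleles[[i]] <- alt
        add_edge(anchors[i], alt[1L]); add_edge(anchors[i], alt[2L])
        add_edge(alt[1L], anchors[i + 1L]); add_edge(alt[2L], anchors[i + 1L])
      } else {
        add_edge(anchors[i], anchors[i + 1L])
      }
    }
    paths <- lapply(seq_len(n_paths), function(k) {
      steps <- anchors[1L]
      for (i in seq_len(n_anchors - 1L)) {
        if (bubbled[i]) steps <- c(steps, sample(alleles[[i]], 1L))
        steps <- c(steps, anchors[i + 1L])
      }
      list(name = paste0("p", k), node_id = steps,
           is_reverse = rep(FALSE, length(steps)))
    })
    em <- do.call(rbind, e)
    variation_graph(data.frame(id = ids, sequence = seqs),
                    data.frame(from = em[, 1], from_rev = FALSE,
                               to = em[, 2], to_rev = FALSE),
                    paths)
  })
}

#' Synthetic graph with indel bubbles
#'
#' As [make_snp_bubbles()] but each bubble is an insertion: one allele is a
#' node, the other a direct edge between the flanking anchors (deletion).
#'
#' @inheritParams make_snp_bubbles
#' @param indel_rate per-gap probability of an indel bubble.
#' @param indel_len length range of inserted nodes.
#' @export
make_indel_bubbles <- function(n_anchors, indel_rate = 0.5, n_paths = 2L,
                               node_len = c(1L, 32L), indel_len = c(1L, 16L),
                               seed = 1L) {
  stopifnot(n_anchors >= 2)
  with_seed(seed, {
    ids <- integer(); seqs <- character()
    new_node <- function(s) {
      id <- length(ids) + 1L
      ids <<- c(ids, id); seqs <<- c(seqs, s)
      id
    }
    anchors <- vapply(rand_seqs(n_anchors, node_len), new_node, integer(1))
    e <- list()
    add_edge <- function(a, b) e[[length(e) + 1L]] <<- c(a, b)
    bubbled <- stats::runif(n_anchors - 1L) < indel_rate
    ins <- vector("list", n_anchors - 1L)
    for (i in seq_len(n_anchors - 1L)) {
      add_edge(anchors[i], anchors[i + 1L])  # deletion allele
      if (bubbled[i]) {
        v <- new_node(rand_seqs(1L, indel_len))
        ins[[i]] <- v
        add_edge(anchors[i], v); add_edge(v, anchors[i + 1L])
      }
    }
    paths <- lapply(seq_len(n_paths), function(k) {
      steps <- anchors[1L]
      for (i in seq_len(n_anchors - 1L)) {
        if (bubbled[i] && stats::runif(1) < 0.5) steps <- c(steps, ins[[i]])
        steps <- c(steps, anchors[i + 1L])
      }
      list(name = paste0("p", k), node_id = steps,
           is_reverse = rep(FALSE, length(steps)))
    })
    em <- do.call(rbind, e)
    variation_graph(data.frame(id = ids, sequence = seqs),
                    data.frame(from = em[, 1], from_rev = FALSE,
                               to = em[, 2], to_rev = FALSE),
                    paths)
  })
}

#' Synthetic graph with an inversion
#'
#' A linear chain whose single path traverses a middle block of `inv_span`
#' nodes on the reverse strand (in reversed order), exercising the implicit
#' reverse complement. `inv_span = 0` reduces to [make_linear()].
#'
#' @param n_nodes chain length.
#' @param inv_span number of inverted nodes (centered).
#' @param node_len node length range.
#' @param seed RNG seed.
#' @export
make_inversion <- function(n_nodes, inv_span, node_len = c(1L, 32L), seed = 1L) {
  stopifnot(n_nodes >= 1, inv_span >= 0, inv_span <= n_nodes)
  if (inv_span == 0) return(make_linear(n_nodes, node_len, seed))
  with_seed(seed, {
    nodes <- data.frame(id = seq_len(n_nodes),
                        sequence = rand_seqs(n_nodes, node_len))
    a <- max(1L, (n_nodes - inv_span) %/% 2L + 1L)
    b <- a + inv_span - 1L
    steps_id <- c(seq_len(a - 1L), b:a, if (b < n_nodes) (b + 1L):n_nodes)
    steps_rev <- c(rep(FALSE, a - 1L), rep(TRUE, inv_span),
                   rep(FALSE, n_nodes - b))
    m <- length(steps_id)
    edges <- data.frame(from = steps_id[-m], from_rev = steps_rev[-m],
                        to = steps_id[-1L], to_rev = steps_rev[-1L])
    variation_graph(nodes, edges,
                    list(list(name = "p", node_id = steps_id,
                              is_reverse = steps_rev)))
  })
}

#' Synthetic graph with a tandem repeat loop
#'
#' A linear chain whose path traverses a middle block of `repeat_span`
#' nodes `n_copies` times via a back edge, so some nodes carry multiple
#' path steps (as repetitive sequence does in real pangenome graphs).
#'
#' @param n_nodes chain length.
#' @param repeat_span nodes in the repeated block (centered).
#' @param n_copies times the block is traversed, >= 1.
#' @param node_len node length range.
#' @param seed RNG seed.
#' @export
make_tandem_loop <- function(n_nodes, repeat_span, n_copies = 2L,
                             node_len = c(1L, 32L), seed = 1L) {
  stopifnot(n_nodes >= 1, repeat_span >= 0, repeat_span <= n_nodes, n_copies >= 1)
  if (repeat_span == 0 || n_copies == 1L) return(make_linear(n_nodes, node_len, seed))
  with_seed(seed, {
    nodes <- data.frame(id = seq_len(n_nodes),
                        sequence = rand_seqs(n_nodes, node_len))
    a <- max(1L, (n_nodes - repeat_span) %/% 2L + 1L)
    b <- a + repeat_span - 1L
    block <- a:b
    steps_id <- c(seq_len(a - 1L), rep(block, n_copies),
                  if (b < n_nodes) (b + 1L):n_nodes)
    m <- length(steps_id)
    edges <- unique(data.frame(from = steps_id[-m], from_rev = FALSE,
                               to = steps_id[-1L], to_rev = FALSE))
    variation_graph(nodes, edges,
                    list(list(name = "p", node_id = steps_id,
                              is_reverse = rep(FALSE, m))))
  })
}

#' Shuffle node ids
#'
#' Renumbers the graph by a seeded random permutation — the unsorted input
#' that the 1D sorter must fix.
#'
#' @param g a `variation_graph`.
#' @param seed RNG seed.
#' @return a `variation_graph` with permuted ids.
#' @export
shuffle_ids <- function(g, seed = 1L) {
  with_seed(seed, apply_node_order(g, sample(g$nodes$id)))
}

#' Dispatch a synthetic graph by kind
#'
#' @param kind one of `"linear"`, `"snp_bubbles"`, `"indel_bubbles"`,
#'   `"inversion"`, `"tandem_loop"`.
#' @param n_nodes size parameter (anchors for bubble kinds).
#' @param seed RNG seed.
#' @param ... forwarded to the generator.
#' @export
synth_graph <- function(kind = c("linear", "snp_bubbles", "indel_bubbles",
                                 "inversion", "tandem_loop"),
                        n_nodes = 50L, seed = 1L, ...) {
  kind <- match.arg(kind)
  switch(kind,
         linear = make_linear(n_nodes, seed = seed, ...),
         snp_bubbles = make_snp_bubbles(n_nodes, seed = seed, ...),
         indel_bubbles = make_indel_bubbles(n_nodes, seed = seed, ...),
         inversion = make_inversion(n_nodes, inv_span = max(1L, n_nodes %/% 3L),
                                    seed = seed, ...),
         tandem_loop = make_tandem_loop(n_nodes,
                                        repeat_span = max(1L, n_nodes %/% 5L),
                                        seed = seed, ...))
}
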