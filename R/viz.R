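#' Render a 2D layout as SVG
#'
#' Each node is drawn as a line segment between its two end points (round
#' line caps keep zero-length segments visible as dots); edges are
#' optionally drawn as thinner lines between the corresponding node ends.
#' Layout coordinates are affinely mapped to the canvas preserving the
#' aspect ratio. Output is deterministic for fixed inputs.
#'
#' @param g a `variation_graph`.
#' @param layout a `layout_2d` covering all nodes.
#' @param file optional output path; when `NULL` the SVG text is returned.
#' @param canvas canvas size in px (longer side), > 0.
#' @param stroke_width node stroke width in px.
#' @param draw_edges draw graph edges.
#' @param color_path optional path name: nodes on it are highlighted.
#' @return SVG document as a single string (invisibly when `file` given).
#' @export
render_svg <- function(g, layout, file = NULL, canvas = 800,
                       stroke_width = 2, draw_edges = TRUE,
                       color_path = NULL) {
  stopifnot(canvas > 0)
  if (nrow(layout) != 2L * nrow(g$nodes)) {
    stop("layout does not cover all nodes")
  }
  if (!all(is.finite(layout))) stop("non-finite layout coordinates")
  pad <- 0.05 * canvas
  rngx <- range(layout[, 1]); rngy <- range(layout[, 2])
  span <- max(rngx[2] - rngx[1], rngy[2] - rngy[1], 1e-12)
  sc <- (canvas - 2 * pad) / span
  px <- function(v) sprintf("%.3f", pad + (v - rngx[1]) * sc)
  py <- function(v) sprintf("%.3f", pad + (v - rngy[1]) * sc)
  w <- round(pad * 2 + (rngx[2] - rngx[1]) * sc, 3)
  h <- round(pad * 2 + (rngy[2] - rngy[1]) * sc, 3)

  n <- nrow(g$nodes)
  srow <- 2L * seq_len(n) - 1L
  col <- rep("#333333", n)
  if (!is.null(color_path)) {
    p <- g$paths[[color_path]]
    if (is.null(p)) stop("unknown path: ", color_path)
    col[g$nodes$id %in% p$node_id] <- "#d62728"
  }

  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%s" height="%s" viewBox="0 0 %s %s">'),
                   w, h, w, h),
           '<rect width="100%" height="100%" fill="white"/>')
  if (draw_edges && nrow(g$edges)) {
    e <- g$edges
    rank_from <- match(e$from, g$nodes$id)
    rank_to <- match(e$to, g$nodes$id)
    # an edge leaves its from-node at the sequence end (start if reverse)
    # and enters its to-node at the sequence start (end if reverse)
    i <- 2L * rank_from - ifelse(e$from_rev, 1L, 0L)
    j <- 2L * rank_to - ifelse(e$to_rev, 0L, 1L)
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%.3f"/>',
      px(layout[i, 1]), py(layout[i, 2]), px(layout[j, 1]), py(layout[j, 2]),
      stroke_width / 2))
  }
  out <- c(out, sprintf(
    paste0('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" ',
           'stroke-width="%.3f" stroke-linecap="round"/>'),
    px(layout[srow, 1]), py(layout[srow, 2]),
    px(layout[srow + 1L, 1]), py(layout[srow + 1L, 2]), col, stroke_width))
  out <- c(out, "</svg>")
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(file)) return(doc)
  writeLines(doc, file, sep = "")
  invisible(doc)
}
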