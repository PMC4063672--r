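#' Construct a planar arena with rectangular holes
#'
#' An arena is an axis-aligned `width` x `height` rectangle (metres, origin at
#' the lower-left corner) from which a list of axis-aligned rectangular holes
#' is removed. For a connected arena the true Betti numbers are
#' `(beta0, beta1) = (1, number of holes)`.
#'
#' @param width,height outer dimensions in metres.
#' @param holes list of holes, each a numeric vector `c(x0, y0, x1, y1)` in
#'   metres. Holes must lie strictly inside the outer rectangle and be
#'   pairwise disjoint.
#' @return an object of class `arena` with elements `width`, `height`,
#'   `holes` (list of 4-vectors) and `true_betti` (length-2 integer).
#' @examples
#' a <- make_arena(1, 1, holes = list(c(0.35, 0.35, 0.65, 0.65)))
#' a$true_betti  # (1, 1)
#' @export
make_arena <- function(width, height, holes = list()) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  holes <- lapply(holes, function(h) {
    h <- as.numeric(h)
    if (length(h) != 4) stop("each hole must be c(x0, y0, x1, y1)")
    if (h[1] >= h[3] || h[2] >= h[4]) stop("hole has non-positive extent")
    if (h[1] <= 0 || h[2] <= 0 || h[3] >= width || h[4] >= height)
      stop("holes must lie strictly inside the arena boundary")
    h
  })
  if (length(holes) > 1) {
    for (i in seq_along(holes)) {
      for (j in seq_len(i - 1)) {
        a <- holes[[i]]; b <- holes[[j]]
        if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
          stop("holes must be pairwise disjoint")
      }
    }
  }
  structure(
    list(width = width, height = height, holes = holes,
         true_betti = c(1L, length(holes))),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("arena %gx%g m, %d hole(s), true Betti (%d, %d)\n",
              x$width, x$height, length(x$holes),
              x$true_betti[1], x$true_betti[2]))
  invisible(x)
}

# TRUE for points inside any hole
in_hole <- function(arena, x, y) {
  inside <- rep(FALSE, length(x))
  for (h in arena$holes)
    inside <- inside | (x > h[1] & x < h[3] & y > h[2] & y < h[4])
  inside
}

# TRUE for valid positions (inside outer rectangle, outside all holes)
in_arena <- function(arena, x, y) {
  x >= 0 & x <= arena$width & y >= 0 & y <= arena$height & !in_hole(arena, x, y)
}

#' Partition an arena into vertical strips with trivial intersections
#'
#' Cuts the arena into `k` regions by vertical lines. Each region inherits the
#' holes that fall fully inside it, hence its own true Betti numbers; a cut
#' line through a hole would make the region intersection topologically
#' non-trivial and is an error. Used for piecewise (Mayer-Vietoris style)
#' learning, where per-region homologies add up to the whole-arena homology.
#'
#' @param arena an [make_arena()] object.
#' @param k number of regions (1 to 4).
#' @param cuts optional increasing vector of `k - 1` x-coordinates; defaults
#'   to equal-width strips.
#' @return list of `arena_region` objects, each with `id`, `rect`
#'   (`c(x0, y0, x1, y1)`), `holes` and `true_betti`.
#' @export
partition_arena <- function(arena, k, cuts = NULL) {
  stopifnot(inherits(arena, "arena"), k >= 1, k <= 4)
  if (is.null(cuts)) cuts <- arena$width * seq_len(k - 1) / k
  cuts <- as.numeric(cuts)
  if (length(cuts) != k - 1 || is.unsorted(cuts, strictly = TRUE) ||
      any(cuts <= 0) || any(cuts >= arena$width))
    stop("cuts must be ", k - 1, " strictly increasing interior x-coordinates")
  for (cx in cuts)
    for (h in arena$holes)
      if (cx > h[1] && cx < h[3])
        stop("cut line at x = ", cx, " passes through a hole; ",
             "region intersections would be topologically non-trivial")
  edges <- c(0, cuts, arena$width)
  lapply(seq_len(k), function(i) {
    rect <- c(edges[i], 0, edges[i + 1], arena$height)
    hs <- Filter(function(h) h[1] >= rect[1] && h[3] <= rect[3], arena$holes)
    structure(
      list(id = i, rect = rect, holes = hs,
           true_betti = c(1L, length(hs)),
           closed_right = (i == k)),
      class = "arena_region"
    )
  })
}

in_region <- function(region, x, y) {
  r <- region$rect
  # cut-line ties go to the lower-index region: left edge open, right closed,
  # except the first region whose left edge is the arena boundary
  left_ok <- if (region$id == 1) x >= r[1] else x > r[1]
  right_ok <- if (isTRUE(region$closed_right)) x <= r[3] else x <= r[3]
  left_ok & right_ok & y >= r[2] & y <= r[4]
}

region_area <- function(region) {
  r <- region$rect
  (r[3] - r[1]) * (r[4] - r[2]) -
    sum(vapply(region$holes, function(h) (h[3] - h[1]) * (h[4] - h[2]), 0))
}
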