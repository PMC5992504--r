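#' Synthetic edge scenes with exact corner/endpoint ground truth
#'
#' Every detector stage in this package is tested against scenes whose ground
#' truth is known by construction: 1-pixel-wide digital lines rasterized with
#' the integer midpoint (Bresenham) algorithm, annotated with the positions of
#' their corners (polyline vertices, with interior angle) and non-intersection
#' endpoints (open polyline ends). Pixel coordinates are 0-based, x = column,
#' y = row with y growing downward.
#'
#' @name scene
#' @keywords internal
NULL

new_scene <- function(edge, corners, endpoints, description,
                      intensity = NULL, seed = NA_integer_) {
  structure(list(edge = edge, intensity = intensity,
                 corners = corners, endpoints = endpoints,
                 seed = seed, description = description),
            class = "ht3d_scene")
}

#' @export
print.ht3d_scene <- function(x, ...) {
  cat(sprintf("ht3d_scene: %s\n", x$description))
  cat(sprintf("  %dx%d, %d edge pixels, %d corners, %d endpoints\n",
              ncol(x$edge), nrow(x$edge), sum(x$edge != 0),
              nrow(x$corners), nrow(x$endpoints)))
  invisible(x)
}

#' Ground truth of a scene as a single table
#'
#' @param scene An `ht3d_scene`.
#' @return A data.frame with columns `x`, `y`, `kind` ("corner"/"endpoint")
#'   and `angle` (interior angle in degrees, `NA` for endpoints).
#' @export
scene_ground_truth <- function(scene) {
  co <- scene$corners
  ep <- scene$endpoints
  rbind(
    if (nrow(co)) data.frame(x = co$x, y = co$y, kind = "corner", angle = co$angle),
    if (nrow(ep)) data.frame(x = ep$x, y = ep$y, kind = "endpoint", angle = NA_real_)
  )
}

#' Rasterize a digital straight line
#'
#' Integer midpoint (Bresenham) rasterization; produces `max(|dx|, |dy|) + 1`
#' pixels forming an 8-connected 1-pixel-wide line.
#'
#' @param p0,p1 Integer pixel coordinates `c(x, y)`.
#' @return A two-column integer matrix of (x, y) pixels from p0 to p1.
#' @export
raster_line <- function(p0, p1) {
  x0 <- as.integer(p0[1]); y0 <- as.integer(p0[2])
  x1 <- as.integer(p1[1]); y1 <- as.integer(p1[2])
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  n <- max(dx, dy)
  if (n == 0L) return(cbind(x = x0, y = y0))
  # parametric form with half-up rounding reproduces the midpoint walk
  t <- 0:n
  xs <- x0 + as.integer(round_half_up(t * (x1 - x0) / n))
  ys <- y0 + as.integer(round_half_up(t * (y1 - y0) / n))
  cbind(x = xs, y = ys)
}

blank_edge <- function(size) {
  matrix(0L, nrow = size[2], ncol = size[1]) # [height, width]
}

stamp_pixels <- function(edge, px) {
  edge[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- 1L
  edge
}

check_inside <- function(pts, size) {
  if (any(pts[, 1] < 0 | pts[, 1] >= size[1] | pts[, 2] < 0 | pts[, 2] >= size[2]))
    stop("scene points must lie inside the image")
}

#' Scene: a single straight segment
#'
#' @param p0,p1 Endpoint pixels `c(x, y)` (distinct, inside the image).
#' @param size Image size `c(width, height)`.
#' @return An `ht3d_scene` whose ground truth is the two endpoints.
#' @examples
#' sc <- make_segment(c(5, 5), c(5, 20), size = c(32, 32))
#' sum(sc$edge) # 16 pixels
#' @export
make_segment <- function(p0, p1, size) {
  if (all(p0 == p1)) stop("degenerate segment: p0 == p1")
  check_inside(rbind(p0, p1), size)
  px <- raster_line(p0, p1)
  new_scene(stamp_pixels(blank_edge(size), px),
            corners = data.frame(x = integer(), y = integer(), angle = numeric()),
            endpoints = data.frame(x = c(p0[1], p1[1]), y = c(p0[2], p1[2])),
            description = sprintf("segment (%d,%d)-(%d,%d)", p0[1], p0[2], p1[1], p1[2]))
}

interior_angle <- function(prev, v, nxt) {
  a <- c(prev[1] - v[1], prev[2] - v[2])
  b <- c(nxt[1] - v[1], nxt[2] - v[2])
  ang <- acos(pmin(pmax(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1))
  ang * 180 / pi
}

#' Scene: an open or closed polyline
#'
#' Consecutive vertices are joined by digital lines. Interior vertices are
#' annotated as corners with their interior angle; for an open polyline the
#' two extreme vertices are annotated as non-intersection endpoints.
#'
#' @param vertices Two-column matrix (or list of `c(x, y)`) of vertex pixels.
#' @param size Image size `c(width, height)`.
#' @param closed Join the last vertex back to the first?
#' @return An `ht3d_scene`.
#' @export
make_polygon <- function(vertices, size, closed = TRUE) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  storage.mode(vertices) <- "integer"
  nv <- nrow(vertices)
  stopifnot(nv >= 2)
  check_inside(vertices, size)
  edge <- blank_edge(size)
  segs <- if (closed) cbind(1:nv, c(2:nv, 1)) else cbind(1:(nv - 1), 2:nv)
  for (k in seq_len(nrow(segs)))
    edge <- stamp_pixels(edge, raster_line(vertices[segs[k, 1], ], vertices[segs[k, 2], ]))
  corner_ids <- if (closed) 1:nv else if (nv > 2) 2:(nv - 1) else integer()
  corners <- data.frame(x = integer(), y = integer(), angle = numeric())
  for (i in corner_ids) {
    prev <- vertices[if (i == 1) nv else i - 1, ]
    nxt <- vertices[if (i == nv) 1 else i + 1, ]
    corners <- rbind(corners, data.frame(x = vertices[i, 1], y = vertices[i, 2],
                                         angle = interior_angle(prev, vertices[i, ], nxt)))
  }
  endpoints <- if (closed) data.frame(x = integer(), y = integer())
               else data.frame(x = vertices[c(1, nv), 1], y = vertices[c(1, nv), 2])
  new_scene(edge, corners, endpoints,
            description = sprintf("%s polyline, %d vertices", if (closed) "closed" else "open", nv))
}

#' Scene: an axis-aligned rectangle outline
#'
#' @param corner Top-left pixel `c(x, y)`.
#' @param w,h Side lengths in pixels.
#' @param size Image size `c(width, height)`.
#' @return An `ht3d_scene` with four 90-degree corners and no endpoints.
#' @export
make_rectangle <- function(corner, w, h, size) {
  x0 <- corner[1]; y0 <- corner[2]
  make_polygon(rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h)),
               size = size, closed = TRUE)
}

#' Scene: an "L" of two arms meeting at a given angle
#'
#' The first arm points in direction `arm1_dir` (degrees, image convention)
#' from the vertex; the second arm is rotated by the interior `angle` from the
#' first. Ground truth: one corner (the vertex) and two endpoints (arm tips).
#'
#' @param vertex Vertex pixel `c(x, y)`.
#' @param arm_len Arm length(s) in pixels (recycled to 2).
#' @param angle Interior angle in degrees, in (0, 180).
#' @param size Image size `c(width, height)`.
#' @param arm1_dir Direction of the first arm in degrees (default 0 = +x).
#' @return An `ht3d_scene`.
#' @export
make_L <- function(vertex, arm_len, angle, size, arm1_dir = 0) {
  stopifnot(angle > 0, angle < 180)
  arm_len <- rep_len(arm_len, 2)
  a1 <- arm1_dir * pi / 180
  a2 <- (arm1_dir + angle) * pi / 180
  tip <- function(a, len) c(vertex[1] + round_half_up(len * cos(a)),
                            vertex[2] + round_half_up(len * sin(a)))
  t1 <- tip(a1, arm_len[1]); t2 <- tip(a2, arm_len[2])
  sc <- make_polygon(rbind(t1, vertex, t2), size = size, closed = FALSE)
  sc$description <- sprintf("L at (%d,%d), %g deg", vertex[1], vertex[2], angle)
  sc
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Degrade a scene with gaps and spurious edge pixels
#'
#' Removes a seeded random fraction of the edge pixels and adds seeded random
#' spurious ones. Ground truth is left unchanged (it describes the underlying
#' clean geometry).
#'
#' @param scene An `ht3d_scene`.
#' @param gap_fraction Fraction of edge pixels to remove, in \[0, 1\].
#' @param spurious_count Number of random non-edge pixels to switch on.
#' @param seed Integer seed; the same seed gives the identical degraded scene.
#' @param protect Optional two-column matrix of (x, y) pixels never removed
#'   (e.g. the ground-truth points themselves).
#' @return The degraded `ht3d_scene`.
#' @export
degrade <- function(scene, gap_fraction = 0, spurious_count = 0, seed = 1,
                    protect = NULL) {
  stopifnot(gap_fraction >= 0, gap_fraction <= 1)
  if (gap_fraction == 0 && spurious_count == 0) return(scene)
  edge <- scene$edge
  with_seed(seed, {
    on_idx <- which(edge != 0)
    if (!is.null(protect) && nrow(protect))
      on_idx <- setdiff(on_idx, (protect[, 1]) * nrow(edge) + protect[, 2] + 1L)
    n_rm <- floor(gap_fraction * length(on_idx))
    if (n_rm > 0) edge[sample(on_idx, n_rm)] <- 0L
    if (spurious_count > 0) {
      off_idx <- which(edge == 0)
      edge[sample(off_idx, min(spurious_count, length(off_idx)))] <- 1L
    }
  })
  out <- scene
  out$edge <- edge
  out$seed <- as.integer(seed)
  out$description <- sprintf("%s [degraded gap=%.2f spur=%d seed=%d]",
                             scene$description, gap_fraction, spurious_count, seed)
  out
}

#' Remove specific edge pixels from a scene
#'
#' Deterministic companion to [degrade()] for threshold studies: knocks out an
#' explicit list of pixels (e.g. interior pixels of a terminal piece of
#' segment).
#'
#' @param scene An `ht3d_scene`.
#' @param pixels Two-column matrix of (x, y) pixels to switch off.
#' @return The modified scene.
#' @export
knock_out_pixels <- function(scene, pixels) {
  out <- scene
  out$edge[cbind(pixels[, 2] + 1L, pixels[, 1] + 1L)] <- 0L
  out$description <- sprintf("%s [%d pixels knocked out]", scene$description, nrow(pixels))
  out
}

#' Render a grayscale intensity image for a scene
#'
#' Paints the scene's shapes at the foreground level over a uniform
#' background. Closed shapes are filled (even-odd rule against the edge
#' drawing is not attempted; filling uses the convex trace of each row between
#' outline pixels), open polylines are drawn as strokes. An optional small box
#' blur softens the step edges. The edge map remains the ground-truth source.
#'
#' @param scene An `ht3d_scene`.
#' @param foreground,background Gray levels in \[0, 255\].
#' @param blur Box-blur radius in pixels (0 = none).
#' @param fill Fill between the leftmost and rightmost outline pixel of every
#'   row (suitable for convex outlines)? Default TRUE when the scene has no
#'   endpoints (closed shape).
#' @return A numeric matrix \[height, width\] of gray levels; also stored in
#'   the returned scene by [with_intensity()].
#' @export
render_intensity <- function(scene, foreground = 255, background = 32, blur = 0,
                             fill = nrow(scene$endpoints) == 0) {
  stopifnot(foreground >= 0, foreground <= 255, background >= 0, background <= 255)
  edge <- scene$edge
  img <- matrix(background, nrow(edge), ncol(edge))
  if (fill) {
    for (r in seq_len(nrow(edge))) {
      on <- which(edge[r, ] != 0)
      if (length(on)) img[r, min(on):max(on)] <- foreground
    }
  } else {
    img[edge != 0] <- foreground
  }
  if (blur > 0) {
    k <- 2 * blur + 1
    # separable box blur with edge replication
    pad <- function(m, n, dim) {
      if (dim == 1) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
      else m[, c(rep(1, n), seq_len(ncol(m)), rep(ncol(m), n)), drop = FALSE]
    }
    m <- pad(img, blur, 1)
    cs <- apply(m, 2, cumsum)
    img <- (cs[seq_len(nrow(img)) + k - 1L, , drop = FALSE] -
              rbind(0, cs)[seq_len(nrow(img)), , drop = FALSE]) / k
    m <- pad(img, blur, 2)
    cs <- t(apply(m, 1, cumsum))
    img <- (cs[, seq_len(ncol(img)) + k - 1L, drop = FALSE] -
              cbind(0, cs)[, seq_len(ncol(img)), drop = FALSE]) / k
  }
  img
}

#' Attach an intensity rendering to a scene
#' @param scene An `ht3d_scene`.
#' @param ... Passed to [render_intensity()].
#' @return The scene with `$intensity` set.
#' @export
with_intensity <- function(scene, ...) {
  scene$intensity <- render_intensity(scene, ...)
  scene
}

#' Edge pixels of a scene as a coordinate list
#' @param edge Binary edge matrix \[height, width\] (or an `ht3d_scene`).
#' @return Two-column integer matrix of 0-based (x, y).
#' @export
edge_points <- function(edge) {
  if (inherits(edge, "ht3d_scene")) edge <- edge$edge
  idx <- which(edge != 0, arr.ind = TRUE)
  cbind(x = as.integer(idx[, 2] - 1L), y = as.integer(idx[, 1] - 1L))
}
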