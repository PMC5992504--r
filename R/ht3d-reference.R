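#' Parameters of the corner/endpoint cell patterns
#'
#' A "full" piece of segment is a run of `eta` Hough cells whose accumulated
#' vote difference exceeds `tau_F`; an "empty" piece has a difference below
#' the near-zero `tau_E`. A corner additionally needs support from a second
#' orientation layer at an angular offset within \[phi_min, phi_max\].
#'
#' @param eta Cells per full piece (taken from the spec when omitted).
#' @param tau_F Full-piece threshold (strict `>`); default `eta * delta_p - 2`,
#'   tolerating two missing pixels in a full piece.
#' @param tau_E Empty-piece threshold (strict `<`); default 1, i.e. a truly
#'   empty piece.
#' @param lateral_cells Cells in the lateral empty run of the corner pattern:
#'   `eta - 1` (default, the run excludes the top cell) or `eta`.
#' @param phi_min,phi_max Corner opening range between the two supporting
#'   orientations, radians. Defaults 35 and 145 degrees.
#' @return An object of class `pattern_params`.
#' @export
pattern_params <- function(eta = NULL, tau_F = NULL, tau_E = 1,
                           lateral_cells = NULL,
                           phi_min = 35 * pi / 180, phi_max = 145 * pi / 180) {
  structure(list(eta = eta, tau_F = tau_F, tau_E = tau_E,
                 lateral_cells = lateral_cells,
                 phi_min = phi_min, phi_max = phi_max),
            class = "pattern_params")
}

resolve_pattern_params <- function(params, spec) {
  if (is.null(params)) params <- pattern_params()
  if (is.null(params$eta)) params$eta <- spec$eta
  if (is.null(params$tau_F)) params$tau_F <- params$eta * spec$delta_p - 2
  if (is.null(params$lateral_cells)) params$lateral_cells <- params$eta - 1L
  stopifnot(params$tau_F > params$tau_E, params$tau_E >= 0,
            params$phi_min > 0, params$phi_min < params$phi_max,
            params$phi_max < pi)
  params
}

#' First voting stage: one vote per edge point per orientation layer
#'
#' Each edge point votes once per layer, at the cell of the first segment it
#' could terminate: the (d, p) of the point itself on the layer's angle.
#'
#' @param points Two-column matrix of 0-based (x, y) edge pixels (or an
#'   `ht3d_scene`).
#' @param spec A [hough_spec()].
#' @return An object of class `hough_accumulator`: list with `spec`, `votes`
#'   (integer array \[n_rows, n_d, n_theta\]) and `accumulated = FALSE`.
#' @export
vote_first_stage <- function(points, spec) {
  if (inherits(points, "ht3d_scene")) points <- edge_points(points)
  votes <- array(0L, dim = c(spec$n_rows, spec$n_d, spec$n_theta))
  if (!is.null(points) && nrow(points)) {
    if (any(points[, 1] < 0 | points[, 1] >= spec$width |
            points[, 2] < 0 | points[, 2] >= spec$height))
      stop("edge points out of image bounds")
    cen <- image_to_centered(points[, 1], points[, 2], spec)
    for (t in seq_len(spec$n_theta) - 1L) {
      lp <- line_params(cen$x, cen$y, layer_angle(t, spec))
      # clamp: half-up rounding can land exactly one bin past the last column
      di <- pmin(pmax(as.integer(round_half_up((lp$d + spec$R) / spec$delta_d)), 0L),
                 spec$n_d - 1L)
      ri <- pmin(pmax(as.integer(round_half_up(lp$p + spec$R)), 0L),
                 spec$n_rows - 1L)
      idx <- di * spec$n_rows + ri + 1L
      tab <- tabulate(idx, nbins = spec$n_rows * spec$n_d)
      votes[, , t + 1L] <- votes[, , t + 1L] + tab
    }
  }
  structure(list(spec = spec, votes = votes, accumulated = FALSE),
            class = "hough_accumulator")
}

#' Accumulation stage: in-column prefix sum along p
#'
#' After this stage cell (theta, d, p) holds the number of points of line
#' (theta, d) at positions <= p — the complete voting scheme in which every
#' point votes for all cells above its own position.
#'
#' @param acc A `hough_accumulator` from [vote_first_stage()].
#' @return The accumulator with `votes` replaced by column prefix sums and
#'   `accumulated = TRUE`.
#' @export
accumulate_along_p <- function(acc) {
  stopifnot(inherits(acc, "hough_accumulator"))
  if (acc$accumulated) return(acc)
  v <- acc$votes
  for (t in seq_len(dim(v)[3]))
    v[, , t] <- matrix(apply(v[, , t, drop = FALSE], 2, cumsum),
                       nrow = dim(v)[1])
  acc$votes <- v
  acc$accumulated <- TRUE
  acc
}

#' Full HT3D accumulator for an edge image
#' @param edge Binary edge matrix \[height, width\], an `ht3d_scene`, or a
#'   point matrix.
#' @param spec A [hough_spec()].
#' @return An accumulated `hough_accumulator`.
#' @export
ht3d_transform <- function(edge, spec) {
  pts <- if (is.matrix(edge) && ncol(edge) == 2 && !is.logical(edge)) edge
         else edge_points(edge)
  accumulate_along_p(vote_first_stage(pts, spec))
}

# safe accumulator lookup: rows below the parameter space count 0
acc_at <- function(votes, t, d, rows) {
  n <- max(length(rows), length(d), length(t))
  rows <- rep_len(rows, n); d <- rep_len(d, n); t <- rep_len(t, n)
  out <- numeric(n)
  ok <- rows >= 0
  out[ok] <- votes[cbind(rows[ok] + 1L, d[ok] + 1L, t[ok] + 1L)]
  out
}

#' Number of edge points between two positions on a discrete line
#'
#' The accumulated column is monotone in p, so the absolute difference of two
#' cells counts the points strictly between their positions.
#'
#' @param acc Accumulated `hough_accumulator`.
#' @param theta_idx,d_idx 0-based layer and column indices.
#' @param row_i,row_j 0-based 1-pixel row indices (vectorized).
#' @return Non-negative counts.
#' @export
segment_point_count <- function(acc, theta_idx, d_idx, row_i, row_j) {
  stopifnot(acc$accumulated)
  abs(acc_at(acc$votes, theta_idx, d_idx, row_i) -
      acc_at(acc$votes, theta_idx, d_idx, row_j))
}

#' Full / empty piece-of-segment tests
#'
#' A piece of `length_rows` 1-pixel rows ending at `row` is *full* when its
#' vote difference strictly exceeds `tau_F`, and *empty* when it is strictly
#' below `tau_E`.
#'
#' @param acc Accumulated `hough_accumulator`.
#' @param theta_idx,d_idx 0-based indices.
#' @param row Top row of the piece (0-based).
#' @param length_rows Piece length in rows; `row - length_rows >= -1`.
#' @param tau_F,tau_E Thresholds.
#' @return Logical.
#' @export
is_full_segment <- function(acc, theta_idx, d_idx, row, length_rows, tau_F) {
  if (any(row - length_rows < -1) || any(row >= acc$spec$n_rows))
    stop("piece extends outside the parameter space")
  (acc_at(acc$votes, theta_idx, d_idx, row) -
     acc_at(acc$votes, theta_idx, d_idx, row - length_rows)) > tau_F
}

#' @rdname is_full_segment
#' @export
is_empty_segment <- function(acc, theta_idx, d_idx, row, length_rows, tau_E) {
  if (any(row - length_rows < -1) || any(row >= acc$spec$n_rows))
    stop("piece extends outside the parameter space")
  (acc_at(acc$votes, theta_idx, d_idx, row) -
     acc_at(acc$votes, theta_idx, d_idx, row - length_rows)) < tau_E
}

# Pattern scan of one orientation layer. Returns, per strided cell, logical
# matrices of endpoint hits (normal/flipped) and corner half-pattern hits.
# Cells are indexed j = 0..n_p-1, cell j covering rows [j*dp, (j+1)*dp - 1];
# its top row is r_j = (j+1)*dp - 1. Patterns anchored at cell j:
#   normal:  full piece = cells j-eta+1..j, empty cell above = j+1
#   flipped: full piece = cells j..j+eta-1, empty cell below = j-1
scan_layer_patterns <- function(M, spec, pp) {
  dp <- spec$delta_p; eta <- pp$eta
  n_p <- spec$n_p; n_d <- spec$n_d
  rj <- (seq_len(n_p)) * dp - 1L          # top row (0-based) of cell j, j = 0..
  Hat <- function(rows) {                 # [n_p, n_d] accumulator at given rows
    out <- matrix(0, n_p, n_d)
    ok <- rows >= 0
    if (any(ok)) out[ok, ] <- M[rows[ok] + 1L, , drop = FALSE]
    out
  }
  H_j   <- Hat(rj)
  full_n <- (H_j - Hat(rj - eta * dp)) > pp$tau_F          # c-difference at j
  cell_n <- (H_j - Hat(rj - dp))                           # u-difference at j
  lat_len <- pp$lateral_cells * dp
  s_n <- (H_j - Hat(rj - lat_len))                         # s-difference at j

  shift_j <- function(m, k, fill = 0) {                    # value at cell j+k
    out <- matrix(fill, n_p, n_d)
    src <- seq_len(n_p) + k
    ok <- src >= 1 & src <= n_p
    out[ok, ] <- m[src[ok], , drop = FALSE]
    out
  }
  shift_d <- function(m, k, fill = 0) {                    # value at column d+k
    out <- matrix(fill, n_p, n_d)
    src <- seq_len(n_d) + k
    ok <- src >= 1 & src <= n_d
    out[, ok] <- m[, src[ok], drop = FALSE]
    out
  }

  empty_above <- shift_j(cell_n, +1, fill = Inf) < pp$tau_E
  empty_below <- cell_n < pp$tau_E
  # endpoint pattern, normal version: central full, cell above empty in all
  # three columns, lateral columns not full
  ep_n <- full_n &
    empty_above & shift_d(empty_above, -1, FALSE) & shift_d(empty_above, +1, FALSE) &
    !shift_d(full_n, -1, TRUE) & !shift_d(full_n, +1, TRUE)
  # flipped: full piece = cells j..j+eta-1 -> c-difference at cell j+eta-1;
  # empty cell below = u-difference at cell j-1
  full_f <- shift_j(full_n, eta - 1L, fill = FALSE)
  below <- shift_j(empty_below, -1, fill = FALSE)
  ep_f <- full_f &
    below & shift_d(below, -1, FALSE) & shift_d(below, +1, FALSE) &
    !shift_d(full_f, -1, TRUE) & !shift_d(full_f, +1, TRUE)

  # corner half-pattern: central full piece plus at least one empty lateral
  # run of `lateral_cells` cells starting one cell in from the anchor
  lat_n <- shift_j(s_n, -1, fill = Inf) < pp$tau_E         # cells j-lat..j-1
  co_n <- full_n & (shift_d(lat_n, -1, FALSE) | shift_d(lat_n, +1, FALSE))
  lat_f <- shift_j(s_n, pp$lateral_cells, fill = Inf) < pp$tau_E # cells j+1..j+lat
  co_f <- full_f & (shift_d(lat_f, -1, FALSE) | shift_d(lat_f, +1, FALSE))

  # mask cells whose pattern would reach outside the parameter space, and the
  # two border d-columns (no lateral neighbor)
  j0 <- seq_len(n_p)                                       # j+1 (1-based)
  ok_n <- (j0 - 1L >= eta - 1L) & (j0 - 1L <= n_p - 2L)
  ok_f <- (j0 - 1L >= 1L) & (j0 - 1L + eta - 1L <= n_p - 1L)
  dmask <- c(FALSE, rep(TRUE, max(n_d - 2L, 0L)), FALSE)[seq_len(n_d)]
  mask <- function(m, okj) m & matrix(okj, n_p, n_d) & matrix(dmask, n_p, n_d, byrow = TRUE)
  list(ep_n = mask(ep_n, ok_n), ep_f = mask(ep_f, ok_f),
       co_n = mask(co_n, ok_n), co_f = mask(co_f, ok_f))
}

# anchor position in (d, p): feature sits at the extreme row of the full piece
anchor_p_row <- function(j, flipped, spec) {
  if (flipped) j * spec$delta_p else (j + 1L) * spec$delta_p - 1L
}

#' Hough-space pattern detection (array-based detector)
#'
#' Scans every orientation layer for the endpoint pattern (both versions) and
#' the corner half-pattern; a corner is confirmed when a second layer at an
#' angular offset within \[phi_min, phi_max\] holds a half-pattern mapping to
#' the same image position (within `max(delta_d, delta_p)` pixels).
#'
#' @param acc Accumulated `hough_accumulator`.
#' @param params A [pattern_params()] (NULL = defaults for `acc$spec`).
#' @return Data.frame of Hough-space detections: `kind`, `flipped`,
#'   `theta_idx`, `d_idx`, `row_idx`, `x`, `y` (image pixel of the cell
#'   anchor, rounded), `score` (vote difference of the central piece).
#' @export
detect_patterns <- function(acc, params = NULL) {
  stopifnot(acc$accumulated)
  spec <- acc$spec
  pp <- resolve_pattern_params(params, spec)
  eps <- list(); cos_ <- list()
  hit <- function(t, m, kind, flipped) {
    idx <- which(m, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    j <- idx[, 1] - 1L; d <- idx[, 2] - 1L
    row <- anchor_p_row(j, flipped, spec)
    th <- layer_angle(t, spec)
    un <- undiscretize_hough(t, d, row, spec)
    ctr <- hough_to_image_center(th, un$d, un$p)
    px <- round_half_up(ctr$x + (spec$width - 1) / 2)
    py <- round_half_up(ctr$y + (spec$height - 1) / 2)
    sc <- if (flipped)
      segment_point_count(acc, t, d, pmin(row + pp$eta * spec$delta_p - 1L,
                                          spec$n_rows - 1L), row - 1L)
    else
      segment_point_count(acc, t, d, row, row - pp$eta * spec$delta_p)
    data.frame(kind = kind, flipped = flipped, theta_idx = t, d_idx = d,
               row_idx = row, x = px, y = py, score = sc)
  }
  for (t in seq_len(spec$n_theta) - 1L) {
    pats <- scan_layer_patterns(acc$votes[, , t + 1L], spec, pp)
    eps[[t + 1L]] <- rbind(hit(t, pats$ep_n, "endpoint", FALSE),
                           hit(t, pats$ep_f, "endpoint", TRUE))
    cos_[[t + 1L]] <- rbind(hit(t, pats$co_n, "corner", FALSE),
                            hit(t, pats$co_f, "corner", TRUE))
  }
  ep <- do.call(rbind, eps)
  co <- do.call(rbind, cos_)
  # cross-layer confirmation of corners
  if (!is.null(co) && nrow(co)) {
    tol <- max(spec$delta_d, spec$delta_p)
    keep <- logical(nrow(co))
    for (i in seq_len(nrow(co))) {
      dth <- abs(co$theta_idx - co$theta_idx[i]) * spec$delta_theta
      dth <- pmin(dth, pi - dth)
      near <- dth >= pp$phi_min & dth <= pp$phi_max &
        abs(co$x - co$x[i]) <= tol & abs(co$y - co$y[i]) <= tol
      keep[i] <- any(near)
    }
    co <- co[keep, , drop = FALSE]
  }
  out <- rbind(ep, co)
  if (is.null(out)) out <- data.frame(kind = character(), flipped = logical(),
                                      theta_idx = integer(), d_idx = integer(),
                                      row_idx = integer(), x = numeric(),
                                      y = numeric(), score = numeric())
  rownames(out) <- NULL
  out
}

# minimum eigenvalue of the 2x2 gradient covariance over a pixel neighborhood
min_eig_map <- function(img) {
  h <- nrow(img); w <- ncol(img)
  sh <- function(m, dy, dx) {
    ys <- pmin(pmax(seq_len(h) + dy, 1), h)
    xs <- pmin(pmax(seq_len(w) + dx, 1), w)
    m[ys, xs, drop = FALSE]
  }
  # 3x3 Sobel derivatives
  gx <- (sh(img, -1, 1) + 2 * sh(img, 0, 1) + sh(img, 1, 1) -
           sh(img, -1, -1) - 2 * sh(img, 0, -1) - sh(img, 1, -1))
  gy <- (sh(img, 1, -1) + 2 * sh(img, 1, 0) + sh(img, 1, 1) -
           sh(img, -1, -1) - 2 * sh(img, -1, 0) - sh(img, -1, 1))
  box5 <- function(m) {
    s <- m * 0
    for (dy in -2:2) for (dx in -2:2) s <- s + sh(m, dy, dx)
    s
  }
  sxx <- box5(gx * gx); syy <- box5(gy * gy); sxy <- box5(gx * gy)
  tr <- sxx + syy
  det <- sxx * syy - sxy * sxy
  (tr - sqrt(pmax(tr * tr - 4 * det, 0))) / 2
}

#' Coarse-to-fine localization of a Hough-space detection
#'
#' Searches the image window of the detection's Hough cell for the pixel
#' maximizing the minimum eigenvalue of the local gradient covariance
#' (the classic corner strength); a constant window scores 0 and falls back
#' to the window center.
#'
#' @param detection One row of [detect_patterns()] output.
#' @param intensity Grayscale matrix \[height, width\].
#' @param spec A [hough_spec()].
#' @param eig Optional precomputed [min_eig_map] of `intensity`.
#' @return List `x`, `y`, `score`, or NULL when the window misses the image.
#' @export
localize_in_image <- function(detection, intensity, spec, eig = NULL) {
  if (is.null(eig)) eig <- min_eig_map(intensity)
  half <- max(spec$delta_d, spec$delta_p)
  cx <- detection$x; cy <- detection$y
  xs <- max(0, cx - half):min(spec$width - 1, cx + half)
  ys <- max(0, cy - half):min(spec$height - 1, cy + half)
  if (!length(xs) || !length(ys) || cx + half < 0 || cx - half > spec$width - 1 ||
      cy + half < 0 || cy - half > spec$height - 1) return(NULL)
  win <- eig[ys + 1L, xs + 1L, drop = FALSE]
  best <- which.max(win)
  score <- win[best]
  if (score <= 0)
    return(list(x = round_half_up(mean(xs)), y = round_half_up(mean(ys)), score = 0))
  by <- (best - 1L) %% length(ys)
  bx <- (best - 1L) %/% length(ys)
  list(x = xs[bx + 1L], y = ys[by + 1L], score = score)
}

# merge raw detections that refer to the same image feature
merge_detections <- function(det, radius) {
  if (!nrow(det)) return(det)
  # corners outrank endpoints when clusters mix kinds
  ord <- order(det$kind != "corner", -det$score, det$y, det$x)
  det <- det[ord, , drop = FALSE]
  taken <- rep(FALSE, nrow(det))
  keep <- integer()
  for (i in seq_len(nrow(det))) {
    if (taken[i]) next
    close_by <- !taken & abs(det$x - det$x[i]) <= radius & abs(det$y - det$y[i]) <= radius
    taken[close_by] <- TRUE
    keep <- c(keep, i)
  }
  out <- det[keep, , drop = FALSE]
  out[order(out$y, out$x), , drop = FALSE]
}

#' Array-based HT3D corner/endpoint detector
#'
#' The full reference pipeline: two-stage voting, pattern detection in Hough
#' space, optional intensity-based localization, and merging of cells that
#' describe the same image feature.
#'
#' @param edge Binary edge matrix, `ht3d_scene`, or point matrix.
#' @param spec A [hough_spec()] (defaults to the scene's size with package
#'   default steps).
#' @param params A [pattern_params()] (NULL = defaults).
#' @param intensity Optional grayscale image for localization; when NULL the
#'   detection position is the Hough-cell anchor.
#' @return Data.frame of detections (CSV schema of [write_detections()]),
#'   one row per distinct image feature.
#' @export
ht3d_detect <- function(edge, spec = NULL, params = NULL, intensity = NULL) {
  if (inherits(edge, "ht3d_scene")) {
    if (is.null(intensity)) intensity <- edge$intensity
    if (is.null(spec)) spec <- hough_spec(ncol(edge$edge), nrow(edge$edge))
  }
  stopifnot(inherits(spec, "hough_spec"))
  acc <- ht3d_transform(edge, spec)
  det <- detect_patterns(acc, params)
  if (!nrow(det)) return(det)
  # drop detections whose window center misses the image
  half <- max(spec$delta_d, spec$delta_p)
  inside <- det$x >= -half & det$x <= spec$width - 1 + half &
    det$y >= -half & det$y <= spec$height - 1 + half
  det <- det[inside, , drop = FALSE]
  if (!is.null(intensity) && nrow(det)) {
    eig <- min_eig_map(intensity)
    loc <- lapply(seq_len(nrow(det)), function(i)
      localize_in_image(det[i, ], intensity, spec, eig))
    keep <- !vapply(loc, is.null, logical(1))
    det <- det[keep, , drop = FALSE]
    loc <- loc[keep]
    det$x <- vapply(loc, `[[`, numeric(1), "x")
    det$y <- vapply(loc, `[[`, numeric(1), "y")
    det$score <- vapply(loc, `[[`, numeric(1), "score")
  } else {
    det <- det[det$x >= 0 & det$x < spec$width & det$y >= 0 & det$y < spec$height, ,
               drop = FALSE]
  }
  merge_detections(det, radius = max(spec$delta_d, spec$delta_p))
}
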