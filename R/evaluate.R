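#' Match detections against ground truth
#'
#' A detection matches a ground-truth point when their Euclidean distance,
#' rounded to an integer (approximating the acceptance area by a circular
#' image patch), is at most `max_dist` pixels. The assignment is one-to-one,
#' greedy by ascending distance with ties broken in raster order, which is
#' optimal whenever distances are distinct.
#'
#' @param detections Data.frame with `x`, `y` (anything from
#'   [ht3d_snn_detect()], [ht3d_detect()] or [read_detections()]).
#' @param ground_truth Data.frame with `x`, `y` (e.g.
#'   [scene_ground_truth()]).
#' @param max_dist Matching radius in pixels (default 3).
#' @return An object of class `match_result`: counts `NEp_g` (ground-truth
#'   points), `NEp_d` (detections), `NEp_c` (correct matchings), the ratios
#'   `hit_rate` (NEp_c/NEp_g, NA when no ground truth) and `precision_ratio`
#'   (NEp_c/NEp_d, NA when no detections), and `pairs` (matched index pairs
#'   with distances).
#' @export
match_points <- function(detections, ground_truth, max_dist = 3) {
  nd <- nrow(detections); ng <- nrow(ground_truth)
  pairs <- data.frame(detection = integer(), ground_truth = integer(),
                      distance = numeric())
  if (nd && ng) {
    dx <- outer(detections$x, ground_truth$x, "-")
    dy <- outer(detections$y, ground_truth$y, "-")
    dist <- sqrt(dx^2 + dy^2)
    ok <- which(round_half_up(dist) <= max_dist, arr.ind = TRUE)
    if (nrow(ok)) {
      cand <- data.frame(detection = ok[, 1], ground_truth = ok[, 2],
                         distance = dist[ok])
      cand <- cand[order(cand$distance, cand$detection, cand$ground_truth), ,
                   drop = FALSE]
      used_d <- logical(nd); used_g <- logical(ng)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!used_d[cand$detection[i]] && !used_g[cand$ground_truth[i]]) {
          keep[i] <- TRUE
          used_d[cand$detection[i]] <- TRUE
          used_g[cand$ground_truth[i]] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  nc <- nrow(pairs)
  structure(list(NEp_g = ng, NEp_d = nd, NEp_c = nc,
                 hit_rate = if (ng > 0) nc / ng else NA_real_,
                 precision_ratio = if (nd > 0) nc / nd else NA_real_,
                 pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d ground truth, %d detections, %d correct\n",
              x$NEp_g, x$NEp_d, x$NEp_c))
  cat(sprintf("  hit rate NEp_c/NEp_g = %s, precision NEp_c/NEp_d = %s\n",
              format(x$hit_rate, digits = 4),
              format(x$precision_ratio, digits = 4)))
  invisible(x)
}

#' Run both detectors on one edge image and compare
#'
#' Checks the core equivalence contract - every Hough relay neuron's spike
#' count equals the accumulated reference transform, and every
#' vote-difference neuron's spike count equals the corresponding accumulator
#' difference - then reports how the two detectors' outputs align.
#'
#' @param edge Binary edge matrix or `ht3d_scene`.
#' @param spec A [hough_spec()].
#' @param snn_par An [snn_params()].
#' @param pattern_par A [pattern_params()] or NULL.
#' @param net Optional prebuilt `ht3d_snn` (rebuilt when NULL).
#' @param max_dist Matching radius for the detection agreement, pixels.
#' @return List: `hough_mismatches`, `subpattern_mismatches` (cell counts,
#'   both 0 on a correct build), `snn` and `reference` detection tables, and
#'   `agreement` (a [match_points()] of SNN vs reference detections).
#' @export
compare_detectors <- function(edge, spec, snn_par = snn_params(),
                              pattern_par = NULL, net = NULL, max_dist = 3) {
  if (inherits(edge, "ht3d_scene")) edge <- edge$edge
  if (is.null(net)) net <- ht3d_snn_build(spec, snn_par)
  run <- ht3d_snn_detect(edge, net)
  acc <- ht3d_transform(edge, spec)
  hc <- hough_spike_counts(run$spike_count, net)
  hough_mism <- sum(hc != acc$votes)
  sub <- subpattern_spike_counts(run$spike_count, net)
  ref_diff <- reference_subpattern_counts(acc)
  sub_mism <- sum(sub$u != ref_diff$u) + sum(sub$s != ref_diff$s) +
    sum(sub$c != ref_diff$c)
  ref_det <- ht3d_detect(edge, spec, pattern_par)
  list(hough_mismatches = hough_mism, subpattern_mismatches = sub_mism,
       snn = run$detections, reference = ref_det,
       agreement = match_points(run$detections, ref_det, max_dist))
}

#' Accumulator differences matching the subpattern neurons
#'
#' For every strided cell j (top row r_j), the u/s/c differences
#' `H(r_j) - H(r_j - l)` with l = delta_p, (eta-1)*delta_p, eta*delta_p;
#' rows below the parameter space count zero.
#'
#' @param acc Accumulated `hough_accumulator`.
#' @return List of arrays `u`, `s`, `c`, each \[n_p, n_d, n_theta\].
#' @export
reference_subpattern_counts <- function(acc) {
  spec <- acc$spec
  rj <- seq_len(spec$n_p) * spec$delta_p - 1L
  at <- function(rows) {
    out <- array(0L, dim = c(spec$n_p, spec$n_d, spec$n_theta))
    ok <- rows >= 0
    if (any(ok)) out[ok, , ] <- acc$votes[rows[ok] + 1L, , , drop = FALSE]
    out
  }
  H <- at(rj)
  list(u = H - at(rj - spec$delta_p),
       s = H - at(rj - (spec$eta - 1L) * spec$delta_p),
       c = H - at(rj - spec$eta * spec$delta_p))
}
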