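# Small shared configurations. eta >= 4 keeps the full-piece orientation
# tolerance below the corner-range minimum, so corner tests are free of the
# coarse-eta cross-confirmation artifact.

tiny_spec <- function(width = 32, height = 32, delta_theta = 0.15, eta = 3,
                      delta_d = 2, delta_p = 2) {
  hough_spec(width, height, delta_d, delta_p, delta_theta, eta)
}

# thresholds scaled to the pattern length eta * delta_p, mirroring the
# reference set (which assumes eta * delta_p = 12)
scaled_params <- function(spec, ...) {
  len <- spec$eta * spec$delta_p
  snn_params(theta_p1 = len - 2, theta_p2 = len - 1.5, ...)
}

# brute-force HT3D: every point votes for every cell it belongs to, by
# direct evaluation of the line-membership and position inequalities
brute_force_ht3d <- function(points, spec) {
  votes <- array(0L, dim = c(spec$n_rows, spec$n_d, spec$n_theta))
  if (nrow(points) == 0) return(votes)
  cen <- image_to_centered(points[, 1], points[, 2], spec)
  for (t in seq_len(spec$n_theta) - 1L) {
    th <- t * spec$delta_theta
    d <- cen$x * cos(th) + cen$y * sin(th)
    p <- -cen$x * sin(th) + cen$y * cos(th)
    di <- pmin(pmax(ht3dsnn:::round_half_up((d + spec$R) / spec$delta_d), 0),
               spec$n_d - 1)
    ri <- pmin(pmax(ht3dsnn:::round_half_up(p + spec$R), 0), spec$n_rows - 1)
    for (i in seq_along(di))
      for (r in ri[i]:(spec$n_rows - 1L))
        votes[r + 1L, di[i] + 1L, t + 1L] <- votes[r + 1L, di[i] + 1L, t + 1L] + 1L
  }
  votes
}

random_sparse_points <- function(n, width, height) {
  idx <- sample.int(width * height, n)
  cbind(x = (idx - 1L) %% width, y = (idx - 1L) %/% width)
}
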