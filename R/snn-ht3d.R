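#' Parameters of the spiking HT3D network
#'
#' Defaults are the reference parameter set used throughout: excitatory
#' pattern weight `w_cE = 1`; lateral penalization factors
#' `rho_p1 = rho_p2 = 0.25`; pattern firing thresholds `theta_p1 = 6.5`
#' (endpoints) and `theta_p2 = 8` (corner half-patterns); membrane leak
#' `lambda = 0.2` per tick; corner opening range 35-145 degrees. The derived
#' inhibitory weights follow `w_uI = -eta * delta_p * w_cE` (a single spike
#' in a supposedly empty top cell vetoes the endpoint pattern),
#' `w_cI = -rho_p1 * w_cE` and `w_sI = -rho_p2 * w_cE` (graded penalties for
#' non-empty lateral pieces).
#'
#' @param w_cE Excitatory weight of the central-piece synapse.
#' @param rho_p1,rho_p2 Lateral penalization factors.
#' @param theta_p1,theta_p2 Firing thresholds of the p1/p2 pattern neurons.
#' @param lambda Membrane leak per tick (all relay/difference/pattern
#'   neurons).
#' @param corner_angle_min,corner_angle_max Corner opening range, degrees.
#' @param theta_pi Threshold of the corner coincidence (prod) units: above
#'   one input spike, below two, so local and pooled remote corner evidence
#'   must coincide.
#' @param lambda_pi Leak of the coincidence units per tick; NULL (default)
#'   uses `(2 * w_cE - theta_pi) / (eta * delta_p)`, making the coincidence
#'   window `eta * delta_p` ticks.
#' @param lambda_e Leak of the endpoint-sheet integrators (default 0: pure
#'   evidence accumulation).
#' @param inhibition_window Surround-inhibition window w (pixels, odd); NULL
#'   uses `2 * max(delta_d, delta_p) + 1`.
#' @param edge_gating Restrict endpoint-sheet winners to edge pixels?
#' @param endpoint_threshold Minimum accumulated detector evidence for an
#'   endpoint-sheet winner (default 2: support from at least two detector
#'   cells, i.e. more than one orientation layer).
#' @return An object of class `snn_params`.
#' @export
snn_params <- function(w_cE = 1, rho_p1 = 0.25, rho_p2 = 0.25,
                       theta_p1 = 6.5, theta_p2 = 8, lambda = 0.2,
                       corner_angle_min = 35, corner_angle_max = 145,
                       theta_pi = 1.8, lambda_pi = NULL, lambda_e = 0,
                       inhibition_window = NULL, edge_gating = TRUE,
                       endpoint_threshold = 2) {
  stopifnot(w_cE > 0, rho_p1 >= 0, rho_p2 >= 0, lambda >= 0,
            corner_angle_min > 0, corner_angle_min < corner_angle_max,
            corner_angle_max < 180)
  structure(list(w_cE = w_cE, rho_p1 = rho_p1, rho_p2 = rho_p2,
                 theta_p1 = theta_p1, theta_p2 = theta_p2, lambda = lambda,
                 corner_angle_min = corner_angle_min,
                 corner_angle_max = corner_angle_max,
                 theta_pi = theta_pi, lambda_pi = lambda_pi,
                 lambda_e = lambda_e, inhibition_window = inhibition_window,
                 edge_gating = edge_gating,
                 endpoint_threshold = endpoint_threshold),
            class = "snn_params")
}

#' Derived synaptic weights of the pattern stage
#'
#' @param eta,delta_p Pattern geometry.
#' @param w_cE,rho_p1,rho_p2 See [snn_params()].
#' @return List with `w_uI`, `w_cI`, `w_sI`.
#' @examples
#' snn_weights(eta = 6, delta_p = 2) # w_uI = -12, w_cI = -0.25
#' @export
snn_weights <- function(eta, delta_p, w_cE = 1, rho_p1 = 0.25, rho_p2 = 0.25) {
  list(w_uI = -eta * delta_p * w_cE, w_cI = -rho_p1 * w_cE,
       w_sI = -rho_p2 * w_cE)
}

#' Build the spiking HT3D network
#'
#' Creates the full architecture: per orientation layer, a sheet of Hough
#' relay neurons (one per d-column and 1-pixel p-row) joined by feedforward
#' column synapses (1 tick per row) that realize the accumulation stage as
#' spike propagation; u/s/c vote-difference neurons with paired excitatory
#' and delayed inhibitory inputs; p1/p2 pattern neurons in normal and flipped
#' versions; sum/prod corner-confirmation units pooling half-patterns across
#' layers at in-range angular offsets; and an image-registered endpoint sheet
#' of integrators fed by reverse-voting projections from the detector cells.
#'
#' @param spec A [hough_spec()].
#' @param params An [snn_params()].
#' @return An object of class `c("ht3d_snn", "snn_network")` usable with
#'   [snn_run()]; carries the spec, parameters, derived weights and the
#'   neuron block offsets.
#' @export
ht3d_snn_build <- function(spec, params = snn_params()) {
  stopifnot(inherits(spec, "hough_spec"), inherits(params, "snn_params"))
  if (spec$eta * spec$delta_p >= spec$n_rows)
    stop("pattern support empty: eta * delta_p must be smaller than the p-range")
  off_lo <- as.integer(ceiling(params$corner_angle_min * pi / 180 / spec$delta_theta))
  off_hi <- as.integer(floor(params$corner_angle_max * pi / 180 / spec$delta_theta))
  off_hi <- min(off_hi, spec$n_theta - 1L)
  lambda_pi <- params$lambda_pi
  if (is.null(lambda_pi))
    lambda_pi <- (2 * params$w_cE - params$theta_pi) / (spec$eta * spec$delta_p)
  built <- ht3d_build_cpp(spec$width, spec$height, spec$n_theta, spec$n_d,
                          spec$n_rows, spec$n_p, spec$delta_d, spec$delta_p,
                          spec$delta_theta, spec$eta, spec$R,
                          params$w_cE, params$rho_p1, params$rho_p2,
                          params$theta_p1, params$theta_p2, params$lambda,
                          params$theta_pi, lambda_pi, params$lambda_e,
                          off_lo, off_hi)
  structure(list(n = built$n_neurons, threshold = built$threshold,
                 decay = built$decay,
                 syn = list(ptr = built$syn_ptr, post = built$syn_post,
                            weight = built$syn_weight, delay = built$syn_delay),
                 spec = spec, params = params,
                 weights = snn_weights(spec$eta, spec$delta_p, params$w_cE,
                                       params$rho_p1, params$rho_p2),
                 offsets = list(sub = built$off_sub, pattern = built$off_pattern,
                                combiner = built$off_combiner,
                                endpoint = built$off_endpoint),
                 combiner_offsets = c(off_lo, off_hi)),
            class = c("ht3d_snn", "snn_network"))
}

#' @export
print.ht3d_snn <- function(x, ...) {
  cat(sprintf("ht3d_snn: %d neurons, %d synapses (%dx%d image, %d layers)\n",
              x$n, length(x$syn$post), x$spec$width, x$spec$height,
              x$spec$n_theta))
  invisible(x)
}

# --- neuron id arithmetic (1-based ids; mirrors the C++ layout) -----------
hough_id <- function(net, t, d, r) {
  ((t * net$spec$n_d + d) * net$spec$n_rows + r) + 1L
}
sub_id <- function(net, t, d, j, type = c("u", "s", "c")) {
  type_i <- match(match.arg(type), c("u", "s", "c")) - 1L
  net$offsets$sub + (((t * net$spec$n_d + d) * net$spec$n_p + j) * 3 + type_i) + 1L
}
pattern_id <- function(net, t, d, j,
                       which = c("p1n", "p1f", "p2n", "p2f")) {
  k <- match(match.arg(which), c("p1n", "p1f", "p2n", "p2f")) - 1L
  net$offsets$pattern + (((t * net$spec$n_d + d) * net$spec$n_p + j) * 4 + k) + 1L
}
combiner_id <- function(net, t, d, j,
                        which = c("sum_n", "sum_f", "prod_n", "prod_f")) {
  k <- match(match.arg(which), c("sum_n", "sum_f", "prod_n", "prod_f")) - 1L
  net$offsets$combiner + (((t * net$spec$n_d + d) * net$spec$n_p + j) * 4 + k) + 1L
}
endpoint_id <- function(net, x, y) {
  net$offsets$endpoint + (y * net$spec$width + x) + 1L
}

# discrete Hough cell of each pixel in one layer (clamped like the builder)
pixel_cells <- function(px, py, t, spec) {
  cen <- image_to_centered(px, py, spec)
  lp <- line_params(cen$x, cen$y, layer_angle(t, spec))
  d_idx <- pmin(pmax(as.integer(round_half_up((lp$d + spec$R) / spec$delta_d)), 0L),
                spec$n_d - 1L)
  row <- pmin(pmax(as.integer(round_half_up(lp$p + spec$R)), 0L),
              spec$n_rows - 1L)
  list(d_idx = d_idx, row = row, j = row %/% spec$delta_p)
}

#' Initial spike events for an edge image
#'
#' Every edge pixel excites, per orientation layer, the Hough neuron of the
#' first segment it could terminate (the cell of its own (d, p)). To keep the
#' one-spike-per-vote code exact, votes that quantize into the same cell are
#' injected as a burst on successive ticks, with burst offsets chosen so that
#' no two votes of a column ever coincide at any downstream neuron (within a
#' column, a vote injected at row r with offset k occupies the propagation
#' phase k - r, which is kept unique).
#'
#' @param edge Binary edge matrix \[height, width\] or an `ht3d_scene`.
#' @param net An `ht3d_snn` network (or a bare [hough_spec()] together with
#'   `spec`).
#' @return Data.frame of events (`time`, `neuron`, `weight`) for [snn_run()].
#' @export
inject_edges <- function(edge, net) {
  if (inherits(edge, "ht3d_scene")) edge <- edge$edge
  spec <- net$spec
  if (nrow(edge) != spec$height || ncol(edge) != spec$width)
    stop("edge image does not match the network's image size")
  pts <- edge_points(edge)
  if (!nrow(pts))
    return(data.frame(time = integer(), neuron = integer(), weight = numeric()))
  evs <- vector("list", spec$n_theta)
  for (t in seq_len(spec$n_theta) - 1L) {
    cell <- pixel_cells(pts[, 1], pts[, 2], t, spec)
    k <- integer(nrow(pts))
    key <- cell$d_idx * spec$n_rows + cell$row
    if (anyDuplicated(key)) {
      for (col in unique(cell$d_idx[duplicated(key)])) {
        sel <- which(cell$d_idx == col)
        sel <- sel[order(cell$row[sel], sel)]
        used <- integer(0)
        for (i in sel) {
          kk <- 0L
          while ((kk - cell$row[i]) %in% used) kk <- kk + 1L
          used <- c(used, kk - cell$row[i])
          k[i] <- kk
        }
      }
    }
    evs[[t + 1L]] <- data.frame(time = k,
                                neuron = hough_id(net, t, cell$d_idx, cell$row),
                                weight = 1)
  }
  do.call(rbind, evs)
}

# horizon covering full propagation, the deepest synaptic path and bursts
snn_horizon <- function(net, events) {
  t0 <- if (nrow(events)) max(events$time) else 0L
  as.integer(t0 + net$spec$n_rows + net$spec$eta * net$spec$delta_p + 16L)
}

#' Run the spiking detector on an edge image
#'
#' Injects the edge spikes, runs the network to quiescence, reads the
#' endpoint-sheet potentials, and resolves winners by surround inhibition:
#' greedy by descending potential, suppressing a w x w neighborhood around
#' each winner (ties in raster order), keeping only pixels whose accumulated
#' evidence reaches the endpoint threshold and - under edge gating - that
#' carry an edge pixel. The reported kind is the pattern family (endpoint p1
#' vs corner coincidence) that contributed most evidence at the winner.
#'
#' @param edge Binary edge matrix or `ht3d_scene`.
#' @param net An `ht3d_snn` network from [ht3d_snn_build()].
#' @param record Extra neuron ids whose spike times to return.
#' @return List with `detections` (CSV schema of [write_detections()]),
#'   `spike_count`, `potential_map` (\[height, width\] endpoint-sheet
#'   potentials), `spikes` (recorded trains) and `horizon`.
#' @export
ht3d_snn_detect <- function(edge, net, record = integer()) {
  if (inherits(edge, "ht3d_scene")) edge <- edge$edge
  spec <- net$spec
  params <- net$params
  events <- inject_edges(edge, net)
  horizon <- snn_horizon(net, events)
  res <- snn_run(net, events, horizon, record = record)
  pot_vec <- res$potential[(net$offsets$endpoint + 1L):net$n]
  pot <- t(matrix(pot_vec, nrow = spec$width))       # [height, width]
  w <- params$inhibition_window
  if (is.null(w)) w <- 2L * max(spec$delta_d, spec$delta_p) + 1L
  half <- w %/% 2L
  avail <- pot
  if (params$edge_gating) avail[edge == 0] <- -Inf
  detections <- list()
  repeat {
    m <- which.max(avail)
    if (!length(m) || !is.finite(avail[m]) ||
        avail[m] < params$endpoint_threshold) break
    py <- (m - 1L) %% spec$height
    px <- (m - 1L) %/% spec$height
    detections[[length(detections) + 1L]] <-
      snn_attribute(px, py, net, res$spike_count, pot[py + 1L, px + 1L])
    ys <- max(0L, py - half):min(spec$height - 1L, py + half)
    xs <- max(0L, px - half):min(spec$width - 1L, px + half)
    avail[ys + 1L, xs + 1L] <- -Inf
  }
  det <- if (length(detections)) do.call(rbind, detections)
         else data.frame(x = integer(), y = integer(), kind = character(),
                         flipped = logical(), theta_idx = integer(),
                         d_idx = integer(), row_idx = integer(),
                         score = numeric())
  rownames(det) <- NULL
  list(detections = det, spike_count = res$spike_count, potential_map = pot,
       spikes = res$spikes, horizon = horizon)
}

# classify a winner pixel by the detector spikes that reached it
snn_attribute <- function(px, py, net, spike_count, score) {
  spec <- net$spec
  ts <- seq_len(spec$n_theta) - 1L
  cen <- image_to_centered(px, py, spec)
  th <- layer_angle(ts, spec)
  dd <- cen$x * cos(th) + cen$y * sin(th)
  pp <- -cen$x * sin(th) + cen$y * cos(th)
  d_idx <- pmin(pmax(as.integer(round_half_up((dd + spec$R) / spec$delta_d)), 0L),
                spec$n_d - 1L)
  row <- pmin(pmax(as.integer(round_half_up(pp + spec$R)), 0L), spec$n_rows - 1L)
  j <- row %/% spec$delta_p
  base <- ((ts * spec$n_d + d_idx) * spec$n_p + j) * 4
  p1n <- spike_count[net$offsets$pattern + base + 1L]
  p1f <- spike_count[net$offsets$pattern + base + 2L]
  prn <- spike_count[net$offsets$combiner + base + 3L]
  prf <- spike_count[net$offsets$combiner + base + 4L]
  corner_ev <- sum(prn + prf)
  ep_ev <- sum(p1n + p1f)
  kind <- if (corner_ev >= ep_ev && corner_ev > 0) "corner" else "endpoint"
  ev <- if (kind == "corner") prn + prf else p1n + p1f
  best <- which.max(ev)
  flipped <- if (kind == "corner") prf[best] > prn[best] else p1f[best] > p1n[best]
  data.frame(x = px, y = py, kind = kind, flipped = flipped,
             theta_idx = ts[best], d_idx = d_idx[best], row_idx = row[best],
             score = score)
}

#' Hough-neuron spike counts as an accumulator-shaped array
#'
#' The spike train of every Hough relay neuron encodes the votes of its cell;
#' summed over a settled run the counts equal the accumulated reference
#' transform exactly.
#'
#' @param spike_count Spike-count vector from [ht3d_snn_detect()]/[snn_run()].
#' @param net The `ht3d_snn` network.
#' @return Integer array \[n_rows, n_d, n_theta\], comparable with the
#'   `votes` of an accumulated [ht3d_transform()].
#' @export
hough_spike_counts <- function(spike_count, net) {
  spec <- net$spec
  array(spike_count[seq_len(spec$n_theta * spec$n_d * spec$n_rows)],
        dim = c(spec$n_rows, spec$n_d, spec$n_theta))
}

#' Subpattern-neuron spike counts
#'
#' @inheritParams hough_spike_counts
#' @return List of integer arrays `u`, `s`, `c`, each \[n_p, n_d, n_theta\]:
#'   the spike counts of the vote-difference neurons, equal to the
#'   accumulator differences over pieces of length `delta_p`,
#'   `(eta-1)*delta_p` and `eta*delta_p`.
#' @export
subpattern_spike_counts <- function(spike_count, net) {
  spec <- net$spec
  n_pos <- spec$n_theta * spec$n_d * spec$n_p
  block <- spike_count[net$offsets$sub + seq_len(3 * n_pos)]
  a <- array(block, dim = c(3, spec$n_p, spec$n_d, spec$n_theta))
  list(u = a[1, , , , drop = TRUE], s = a[2, , , , drop = TRUE],
       c = a[3, , , , drop = TRUE])
}

#' Neuron accounting of the architecture
#'
#' Per orientation layer, with n d-columns and m strided p-cells: the Hough
#' sheet holds n * m * delta_p relay neurons (1-pixel rows), the subpattern
#' stage n * m * 3, and the pattern stage n * m * 8 (p1/p2 in both versions
#' plus the two corner-confirmation units per version); the endpoint sheet
#' adds width * height integrators.
#'
#' @param spec A [hough_spec()].
#' @return List with per-type counts and `total`.
#' @export
count_neurons <- function(spec) {
  per_pos <- spec$n_theta * spec$n_d * spec$n_p
  out <- list(hough = per_pos * spec$delta_p,
              subpattern = per_pos * 3,
              pattern = per_pos * 8,
              endpoint = spec$width * spec$height)
  out$total <- out$hough + out$subpattern + out$pattern + out$endpoint
  out
}
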