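#' Deterministic event-driven spiking networks
#'
#' A small, general simulator for networks of leaky integrate-and-fire (LIF)
#' neurons with weighted, integer-delayed synapses. On every input arrival at
#' tick t a neuron first leaks linearly toward its resting potential of zero,
#'
#'   P' = sign(P) * max(|P| - lambda * dt, 0),
#'
#' then adds the summed weighted input of that tick, and fires (emitting one
#' spike and resetting to zero, with no refractory period) when the result
#' reaches its threshold. Potentials change only when input arrives; there is
#' no randomness anywhere, so identical inputs give identical spike trains.
#'
#' @param neurons Data.frame with columns `threshold` and `decay` (leak rate
#'   per tick), one row per neuron; neuron ids are the row numbers (1-based).
#' @param synapses Data.frame with columns `pre`, `post` (neuron ids),
#'   `weight` (real, either sign) and `delay` (ticks, integer >= 0).
#' @return An object of class `snn_network` holding the neuron table and the
#'   synapses in compressed sparse row form.
#' @examples
#' net <- snn_network(
#'   neurons = data.frame(threshold = c(1, 2), decay = 0),
#'   synapses = data.frame(pre = 1, post = 2, weight = 1, delay = 1))
#' res <- snn_run(net, events = data.frame(time = 0:3, neuron = 1), horizon = 10)
#' res$spike_count
#' @export
snn_network <- function(neurons, synapses = NULL) {
  stopifnot(is.data.frame(neurons), all(c("threshold", "decay") %in% names(neurons)))
  n <- nrow(neurons)
  if (is.null(synapses) || !nrow(synapses)) {
    syn <- list(ptr = rep(0L, n + 1L), post = integer(), weight = numeric(),
                delay = integer())
  } else {
    stopifnot(all(c("pre", "post", "weight", "delay") %in% names(synapses)))
    if (any(synapses$pre < 1 | synapses$pre > n | synapses$post < 1 | synapses$post > n))
      stop("synapse endpoint out of range")
    if (any(synapses$delay < 0)) stop("synaptic delays must be >= 0")
    if (any(synapses$delay == 0 & synapses$pre == synapses$post))
      stop("zero-delay self-synapses are not allowed (instantaneous loop)")
    ord <- order(synapses$pre, seq_len(nrow(synapses)))
    sy <- synapses[ord, , drop = FALSE]
    deg <- tabulate(sy$pre, nbins = n)
    syn <- list(ptr = c(0L, cumsum(deg)), post = as.integer(sy$post),
                weight = as.numeric(sy$weight), delay = as.integer(sy$delay))
  }
  structure(list(n = n, threshold = as.numeric(neurons$threshold),
                 decay = as.numeric(neurons$decay), syn = syn),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("snn_network: %d neurons, %d synapses\n", x$n, length(x$syn$post)))
  invisible(x)
}

#' Run a spiking network to a time horizon
#'
#' Events are processed in non-decreasing time, ties in presynaptic-id order;
#' simultaneous inputs to one neuron within a tick are summed before the
#' threshold test. Every output spike schedules deliveries at `t + delay`;
#' deliveries falling past the horizon are dropped (the network settles).
#'
#' @param net An [snn_network()] (or an `ht3d_snn` network).
#' @param events Data.frame of external input spikes with columns `time`
#'   (tick >= 0), `neuron` (target id) and optionally `weight` (default 1).
#' @param horizon Last simulated tick (finite).
#' @param record Neuron ids whose individual spike times should be returned.
#' @param strict Fire on `P > threshold` instead of the default `P >= threshold`.
#' @return List with `spike_count` (integer vector over all neurons),
#'   `spikes` (data.frame `neuron`, `time` for recorded ids, time-ordered)
#'   and `potential` (membrane potentials after the last update of each
#'   neuron).
#' @export
snn_run <- function(net, events, horizon, record = integer(), strict = FALSE) {
  stopifnot(is.finite(horizon), horizon >= 0)
  if (is.null(events) || !nrow(events)) {
    events <- data.frame(time = integer(), neuron = integer(), weight = numeric())
  }
  if (is.null(events$weight)) events$weight <- rep(1, nrow(events))
  res <- snn_simulate_cpp(net$threshold, net$decay,
                          net$syn$ptr, net$syn$post, net$syn$weight, net$syn$delay,
                          as.integer(events$time), as.integer(events$neuron),
                          as.numeric(events$weight), as.integer(horizon),
                          as.integer(record), strict)
  spikes <- data.frame(neuron = res$rec_neuron, time = res$rec_time)
  spikes <- spikes[order(spikes$time, spikes$neuron), , drop = FALSE]
  rownames(spikes) <- NULL
  list(spike_count = res$spike_count, spikes = spikes, potential = res$potential)
}

#' Membrane-potential trajectory of a single LIF neuron (pure R)
#'
#' Reference implementation of the neuron dynamics, independent of the
#' compiled event engine; used as its cross-check and for worked examples.
#' Input spikes at the same tick are summed before the threshold test.
#'
#' @param times Integer ticks of the input spikes (non-decreasing or not;
#'   sorted internally).
#' @param weights Input weights (recycled to `length(times)`).
#' @param threshold Firing threshold.
#' @param decay Leak rate per tick.
#' @param strict Fire on `P > threshold` instead of `P >= threshold`.
#' @return Data.frame with one row per distinct input tick: `time`,
#'   `potential` (after integration, before any reset), `fired`.
#' @examples
#' # five unit inputs on consecutive ticks, threshold 4, leak 0.2/tick:
#' lif_trajectory(1:5, 1, threshold = 4, decay = 0.2)
#' @export
lif_trajectory <- function(times, weights = 1, threshold, decay, strict = FALSE) {
  weights <- rep_len(weights, length(times))
  ord <- order(times)
  times <- times[ord]; weights <- weights[ord]
  tt <- unique(times)
  pot <- 0; last <- tt[1]
  out <- data.frame(time = tt, potential = NA_real_, fired = FALSE)
  for (i in seq_along(tt)) {
    dt <- tt[i] - last
    if (dt > 0) pot <- sign(pot) * max(abs(pot) - decay * dt, 0)
    pot <- pot + sum(weights[times == tt[i]])
    last <- tt[i]
    out$potential[i] <- pot
    fired <- if (strict) pot > threshold else pot >= threshold
    if (fired) {
      out$fired[i] <- TRUE
      pot <- 0
    }
  }
  out
}

#' Spike raster as CSV (`neuron_id,time_tick`)
#' @param spikes Data.frame from [snn_run()]'s `spikes` element.
#' @param path Output path.
#' @export
write_spike_raster <- function(spikes, path) {
  utils::write.csv(data.frame(neuron_id = spikes$neuron, time_tick = spikes$time),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
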