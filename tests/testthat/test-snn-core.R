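test_that("single-neuron membrane arithmetic matches hand calculation", {
  # leak applies before each input: consecutive unit spikes gain 0.8 each
  tr <- lif_trajectory(1:5, 1, threshold = 4, decay = 0.2)
  expect_equal(tr$potential, c(1, 1.8, 2.6, 3.4, 4.2))
  expect_equal(which(tr$fired), 5L)
  # idle gaps leak at 0.2 per tick from either sign
  tr2 <- lif_trajectory(c(0, 3), 1, threshold = 10, decay = 0.2)
  expect_equal(tr2$potential[2], 0.4 + 1)
  tr3 <- lif_trajectory(c(0, 10), c(-0.5, 0), threshold = 10, decay = 0.2)
  expect_equal(tr3$potential[2], 0) # negative residue decays to rest
  # single overwhelming input fires immediately
  tr4 <- lif_trajectory(0, 7, threshold = 4, decay = 0.2)
  expect_true(tr4$fired[1])
})

test_that("compiled engine reproduces the pure-R neuron on random inputs", {
  set.seed(31)
  for (rep in 1:20) {
    n_in <- sample(3:12, 1)
    times <- sort(sample(0:30, n_in))
    weights <- round(runif(n_in, -1, 2), 2)
    th <- runif(1, 0.5, 3); lam <- runif(1, 0, 0.5)
    oracle <- lif_trajectory(times, weights, threshold = th, decay = lam)
    net <- snn_network(data.frame(threshold = th, decay = lam))
    res <- snn_run(net, data.frame(time = times, neuron = 1, weight = weights),
                   horizon = 40, record = 1)
    expect_equal(res$spikes$time, oracle$time[oracle$fired])
    expect_equal(res$spike_count[1], sum(oracle$fired))
  }
})

test_that("spikes traverse a relay chain at one tick per synapse", {
  k <- 6
  net <- snn_network(data.frame(threshold = rep(1, k), decay = 0),
                     data.frame(pre = 1:(k - 1), post = 2:k, weight = 1, delay = 1))
  res <- snn_run(net, data.frame(time = 0, neuron = 1), horizon = 20, record = k)
  expect_equal(res$spikes$time, k - 1)
  expect_equal(res$spike_count, rep(1L, k))
})

test_that("same-tick inputs are summed before the threshold test", {
  net <- snn_network(data.frame(threshold = 2, decay = 0.2))
  two <- snn_run(net, data.frame(time = c(3, 3), neuron = 1), horizon = 5)
  expect_equal(two$spike_count[1], 1L)
  # equal and opposite inputs cancel without touching the neuron
  cancel <- snn_run(net, data.frame(time = c(3, 3), neuron = 1,
                                    weight = c(1, -1)), horizon = 5)
  expect_equal(cancel$spike_count[1], 0L)
  expect_equal(cancel$potential[1], 0)
})

test_that("simulation is deterministic and respects the energy bound", {
  set.seed(32)
  for (rep in 1:5) {
    n <- 12
    neurons <- data.frame(threshold = runif(n, 0.5, 2), decay = runif(n, 0, 0.3))
    ns <- 30
    synapses <- data.frame(pre = sample(n, ns, TRUE), post = sample(n, ns, TRUE),
                           weight = round(runif(ns, -1, 1.5), 2),
                           delay = sample(1:3, ns, TRUE))
    net <- snn_network(neurons, synapses)
    events <- data.frame(time = sample(0:10, 15, TRUE), neuron = sample(n, 15, TRUE),
                         weight = 1)
    r1 <- snn_run(net, events, horizon = 60, record = 1:n)
    r2 <- snn_run(net, events, horizon = 60, record = 1:n)
    expect_identical(r1, r2)
    # total spikes of any neuron bounded by its total weighted excitation
    exc_in <- vapply(seq_len(n), function(i) {
      syn <- sum(synapses$weight[synapses$post == i & synapses$weight > 0] *
                   pmax(r1$spike_count[synapses$pre[synapses$post == i & synapses$weight > 0]], 0))
      ext <- sum(events$weight[events$neuron == i])
      syn + ext
    }, numeric(1))
    expect_true(all(r1$spike_count <= exc_in / neurons$threshold + 1e-9))
  }
})

test_that("with no leak and unit weights a neuron chain is a pure relay", {
  net <- snn_network(data.frame(threshold = c(1, 1), decay = 0),
                     data.frame(pre = 1, post = 2, weight = 1, delay = 2))
  times <- c(0, 4, 9, 15)
  res <- snn_run(net, data.frame(time = times, neuron = 1), horizon = 30, record = 2)
  expect_equal(res$spike_count, c(4L, 4L))
  expect_equal(res$spikes$time, times + 2)
})

test_that("events beyond the horizon are dropped and the network settles", {
  net <- snn_network(data.frame(threshold = 1, decay = 0))
  res <- snn_run(net, data.frame(time = c(1, 50), neuron = 1), horizon = 10)
  expect_equal(res$spike_count[1], 1L)
})
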