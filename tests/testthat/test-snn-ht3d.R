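test_that("neuron accounting follows the per-layer formulas", {
  sp <- tiny_spec()
  cn <- count_neurons(sp)
  per_pos <- sp$n_theta * sp$n_d * sp$n_p
  expect_equal(cn$hough, per_pos * sp$delta_p)
  expect_equal(cn$hough, sp$n_theta * sp$n_d * sp$n_rows) # n_p * delta_p = n_rows
  expect_equal(cn$subpattern, per_pos * 3)
  expect_equal(cn$pattern, per_pos * 8)
  expect_equal(cn$endpoint, sp$width * sp$height)
  # halving the angular resolution halves every layer-type total
  sp2 <- tiny_spec(delta_theta = 0.3)
  cn2 <- count_neurons(sp2)
  expect_equal(cn2$hough / cn$hough, cn2$pattern / cn$pattern)
  expect_equal(cn2$hough, cn$hough * sp2$n_theta / sp$n_theta)
})

test_that("a built network carries the derived weights and matches the count", {
  sp <- tiny_spec(delta_theta = 0.3, eta = 6)
  net <- ht3d_snn_build(sp, snn_params())
  expect_equal(net$weights$w_uI, -12)
  expect_equal(net$weights$w_cI, -0.25)
  expect_equal(net$weights$w_sI, -0.25)
  expect_equal(net$n, count_neurons(sp)$total)
  # degenerate geometry is rejected at build time
  tiny <- hough_spec(4, 4, delta_p = 2, delta_theta = 0.5, eta = 4)
  expect_error(ht3d_snn_build(tiny, snn_params()), "pattern support")
})

test_that("edge injection conserves one spike per pixel per layer", {
  sp <- tiny_spec()
  net <- ht3d_snn_build(sp, scaled_params(sp))
  blank <- matrix(0L, 32, 32)
  expect_equal(nrow(inject_edges(blank, net)), 0)
  one <- blank; one[6, 11] <- 1L
  ev1 <- inject_edges(one, net)
  expect_equal(nrow(ev1), sp$n_theta)
  set.seed(41)
  k <- 23
  img <- blank; img[random_sparse_points(k, 32, 32)[, 2:1] + 1L] <- 1L
  evk <- inject_edges(img, net)
  expect_equal(nrow(evk), k * sp$n_theta)
  # burst offsets never duplicate a propagation phase within a column
  run <- snn_run(net, evk, horizon = ht3dsnn:::snn_horizon(net, evk))
  hc <- hough_spike_counts(run$spike_count, net)
  expect_equal(sum(hc[sp$n_rows, , ]), k * sp$n_theta) # all votes reach the top
})

test_that("hough and subpattern spike counts equal the reference transform", {
  set.seed(42)
  configs <- list(
    list(w = 32, h = 32, dt = 0.3, eta = 3, dd = 2, dp = 2, n = 30),
    list(w = 48, h = 40, dt = 0.35, eta = 4, dd = 2, dp = 2, n = 50),
    list(w = 40, h = 48, dt = 0.4, eta = 5, dd = 3, dp = 3, n = 40)
  )
  for (cf in configs) {
    sp <- hough_spec(cf$w, cf$h, cf$dd, cf$dp, cf$dt, cf$eta)
    net <- ht3d_snn_build(sp, scaled_params(sp))
    pts <- random_sparse_points(cf$n, cf$w, cf$h)
    edge <- matrix(0L, cf$h, cf$w); edge[pts[, 2:1] + 1L] <- 1L
    run <- ht3d_snn_detect(edge, net)
    acc <- ht3d_transform(pts, sp)
    expect_identical(hough_spike_counts(run$spike_count, net) + 0L,
                     acc$votes + 0L)
    sub <- subpattern_spike_counts(run$spike_count, net)
    ref <- reference_subpattern_counts(acc)
    expect_identical(sub$u + 0L, ref$u + 0L)
    expect_identical(sub$s + 0L, ref$s + 0L)
    expect_identical(sub$c + 0L, ref$c + 0L)
  }
})

test_that("difference neurons above a terminated segment stay silent", {
  # common votes cancel exactly: any u/s/c neuron whose whole window lies
  # above the segment top sees identical excitation and delayed inhibition
  sp <- tiny_spec()
  sc <- make_segment(c(15, 5), c(15, 24), c(32, 32))
  net <- ht3d_snn_build(sp, scaled_params(sp))
  run <- ht3d_snn_detect(sc, net)
  sub <- subpattern_spike_counts(run$spike_count, net)
  # p grows with y: the segment's top position in p is the y = 24 endpoint
  top_cell <- ht3dsnn:::pixel_cells(15, 24, 0, sp)
  d <- top_cell$d_idx + 1L
  above_u <- (top_cell$j + 1L):(sp$n_p - 1L) # windows beyond the segment top
  expect_true(all(sub$u[above_u + 1L, d, 1] == 0))
  above_c <- (top_cell$j + sp$eta):(sp$n_p - 1L)
  expect_true(all(sub$c[above_c + 1L, d, 1] == 0))
})

test_that("adding edge pixels never decreases a hough spike count", {
  sp <- tiny_spec()
  net <- ht3d_snn_build(sp, scaled_params(sp))
  set.seed(43)
  pts <- random_sparse_points(30, 32, 32)
  edge_small <- matrix(0L, 32, 32); edge_small[pts[1:15, 2:1] + 1L] <- 1L
  edge_big <- matrix(0L, 32, 32); edge_big[pts[, 2:1] + 1L] <- 1L
  c_small <- hough_spike_counts(ht3d_snn_detect(edge_small, net)$spike_count, net)
  c_big <- hough_spike_counts(ht3d_snn_detect(edge_big, net)$spike_count, net)
  expect_true(all(c_big >= c_small))
})

test_that("detections translate with the scene", {
  sp <- tiny_spec()
  net <- ht3d_snn_build(sp, scaled_params(sp))
  a <- ht3d_snn_detect(make_segment(c(12, 6), c(12, 21), c(32, 32)), net)$detections
  b <- ht3d_snn_detect(make_segment(c(14, 8), c(14, 23), c(32, 32)), net)$detections
  expect_equal(nrow(a), nrow(b))
  tol <- max(sp$delta_d, sp$delta_p)
  for (i in seq_len(nrow(a))) {
    dist <- sqrt((b$x - (a$x[i] + 2))^2 + (b$y - (a$y[i] + 2))^2)
    expect_lte(min(dist), tol)
  }
})

test_that("the spiking pipeline recovers segment endpoints end to end", {
  sp <- hough_spec(64, 64) # reference parameter set on a 64x64 scene
  net <- ht3d_snn_build(sp, snn_params())
  sc <- make_segment(c(14, 50), c(50, 17), c(64, 64))
  run <- ht3d_snn_detect(sc, net)
  mr <- match_points(run$detections, scene_ground_truth(sc))
  expect_equal(mr$hit_rate, 1)
  expect_true(all(run$detections$kind == "endpoint"))
  # mismatched image size is rejected
  expect_error(ht3d_snn_detect(matrix(0L, 32, 32), net), "image size")
})

test_that("both detectors agree through the comparison helper", {
  sp <- tiny_spec(eta = 4, delta_theta = 0.12)
  sc <- make_segment(c(15, 9), c(15, 22), c(32, 32))
  res <- compare_detectors(sc, sp, scaled_params(sp))
  expect_equal(res$hough_mismatches, 0)
  expect_equal(res$subpattern_mismatches, 0)
  expect_gte(res$agreement$NEp_c, 1)
})
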