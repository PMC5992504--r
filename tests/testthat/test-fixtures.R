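test_that("digital lines have the midpoint pixel count", {
  expect_equal(nrow(raster_line(c(5, 5), c(5, 14))), 10)
  expect_equal(nrow(raster_line(c(2, 3), c(9, 10))), 8) # 45 degrees
  expect_equal(nrow(raster_line(c(0, 0), c(7, 3))), 8)  # max(|dx|,|dy|) + 1
  # horizontal line is symmetric under x-flip
  a <- raster_line(c(2, 6), c(11, 6))
  b <- raster_line(c(11, 6), c(2, 6))
  expect_setequal(paste(a[, 1], a[, 2]), paste(b[, 1], b[, 2]))
})

test_that("segment scenes carry their endpoints as ground truth", {
  sc <- make_segment(c(5, 5), c(5, 14), c(24, 24))
  expect_equal(sum(sc$edge), 10)
  expect_equal(nrow(sc$corners), 0)
  expect_setequal(sc$endpoints$y, c(5, 14))
  expect_error(make_segment(c(3, 3), c(3, 3), c(24, 24)), "degenerate")
  expect_error(make_segment(c(0, 0), c(30, 0), c(24, 24)), "inside")
})

test_that("polygon scenes annotate corners with interior angles", {
  rect <- make_rectangle(c(4, 6), 10, 8, c(32, 32))
  expect_equal(nrow(rect$corners), 4)
  expect_true(all(rect$corners$angle == 90))
  expect_equal(nrow(rect$endpoints), 0)
  tri <- make_polygon(rbind(c(4, 4), c(24, 6), c(10, 20)), c(32, 32))
  expect_equal(sum(tri$corners$angle), 180, tolerance = 1e-6)
  open3 <- make_polygon(rbind(c(4, 4), c(14, 4), c(14, 14), c(24, 14)),
                        c(32, 32), closed = FALSE)
  expect_equal(nrow(open3$corners), 2) # k - 2 interior vertices
  expect_equal(nrow(open3$endpoints), 2)
  ell <- make_L(c(8, 20), 10, 120, c(32, 32))
  expect_equal(nrow(ell$corners), 1)
  expect_equal(ell$corners$angle, 120, tolerance = 1)
  expect_equal(nrow(ell$endpoints), 2)
})

test_that("every ground-truth point lies on an edge pixel", {
  scenes <- list(make_segment(c(3, 4), c(19, 11), c(28, 28)),
                 make_rectangle(c(4, 6), 12, 9, c(28, 28)),
                 make_L(c(8, 18), 9, 75, c(28, 28)),
                 standard_scene("L120", c(64, 64)))
  for (sc in scenes) {
    gt <- scene_ground_truth(sc)
    expect_true(all(sc$edge[cbind(gt$y + 1, gt$x + 1)] == 1))
  }
})

test_that("degradation is seeded, bounded and protects listed pixels", {
  sc <- make_segment(c(5, 5), c(5, 24), c(32, 32))
  expect_identical(degrade(sc, 0, 0), sc)
  d1 <- degrade(sc, 0.3, 5, seed = 7)
  d2 <- degrade(sc, 0.3, 5, seed = 7)
  expect_identical(d1$edge, d2$edge)
  expect_false(identical(d1$edge, degrade(sc, 0.3, 5, seed = 8)$edge))
  gt <- as.matrix(scene_ground_truth(sc)[, c("x", "y")])
  d3 <- degrade(sc, 0.9, 0, seed = 7, protect = gt)
  expect_true(all(d3$edge[cbind(gt[, 2] + 1, gt[, 1] + 1)] == 1))
  expect_equal(sum(sc$edge) - sum(d3$edge), floor(0.9 * (sum(sc$edge) - 2)))
})

test_that("intensity rendering produces step edges and a flat degenerate case", {
  rect <- make_rectangle(c(6, 8), 12, 10, c(32, 32))
  img <- render_intensity(rect, foreground = 200, background = 20, blur = 0)
  expect_setequal(unique(as.vector(img)), c(20, 200))
  expect_true(all(img[cbind(rect$corners$y + 1, rect$corners$x + 1)] == 200))
  flat <- render_intensity(rect, foreground = 77, background = 77)
  expect_true(all(flat == 77))
  # corner strength peaks at a sharp corner
  eig <- ht3dsnn:::min_eig_map(img)
  for (i in seq_len(nrow(rect$corners))) {
    win <- eig[rect$corners$y[i] + 1 + (-3:3), rect$corners$x[i] + 1 + (-3:3)]
    peak <- which(win == max(win), arr.ind = TRUE)
    # peak within the 8-neighborhood of the true vertex
    expect_lte(min(pmax(abs(peak[, 1] - 4), abs(peak[, 2] - 4))), 1)
  }
})
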