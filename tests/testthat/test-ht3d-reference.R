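test_that("first-stage voting conserves one vote per point per layer", {
  sp <- tiny_spec()
  set.seed(21)
  pts <- random_sparse_points(17, sp$width, sp$height)
  acc <- vote_first_stage(pts, sp)
  for (t in seq_len(sp$n_theta))
    expect_equal(sum(acc$votes[, , t]), nrow(pts))
  # empty input
  expect_true(all(vote_first_stage(pts[0, , drop = FALSE], sp)$votes == 0))
  expect_error(vote_first_stage(cbind(99, 0), sp), "bounds")
})

test_that("a vertical segment votes its pixels into one column of the aligned layer", {
  sp <- tiny_spec()
  sc <- make_segment(c(15, 10), c(15, 15), c(32, 32)) # 6 pixels
  acc <- vote_first_stage(sc, sp)
  layer0 <- acc$votes[, , 1] # theta = 0 holds x = const lines
  col <- which(colSums(layer0) > 0)
  expect_length(col, 1)
  expect_equal(sum(layer0[, col]), 6)
  expect_equal(sum(layer0[, col] == 1), 6) # 6 distinct rows
})

test_that("accumulation is an in-column prefix sum", {
  sp <- tiny_spec()
  acc <- vote_first_stage(cbind(3, 4), sp)
  acc$votes[, , ] <- 0L
  acc$votes[1:4, 1, 1] <- c(1L, 0L, 1L, 0L)
  out <- accumulate_along_p(acc)
  expect_equal(out$votes[1:4, 1, 1], c(1, 1, 2, 2))
  # single point: 0 below its row, 1 at and above
  acc2 <- accumulate_along_p(vote_first_stage(cbind(10L, 7L), sp))
  ix <- discretize_hough(0, line_params(10 - 15.5, 7 - 15.5, 0)$d,
                         line_params(10 - 15.5, 7 - 15.5, 0)$p, sp)
  col <- acc2$votes[, ix$d_idx + 1L, 1]
  expect_true(all(col[seq_len(ix$row_idx)] == 0))
  expect_true(all(col[(ix$row_idx + 1L):sp$n_rows] == 1))
})

test_that("accumulated transform equals the brute-force voting scheme", {
  set.seed(22)
  for (rep in 1:3) {
    sp <- hough_spec(16, 16, delta_d = sample(1:2, 1), delta_p = 2,
                     delta_theta = runif(1, 0.25, 0.5), eta = 3)
    pts <- random_sparse_points(sample(5:20, 1), 16, 16)
    acc <- ht3d_transform(pts, sp)
    expect_identical(acc$votes + 0L, brute_force_ht3d(pts, sp) + 0L)
  }
})

test_that("segment point counts are differences of accumulated cells", {
  sp <- tiny_spec()
  sc <- make_segment(c(15, 10), c(15, 15), c(32, 32))
  acc <- ht3d_transform(sc, sp)
  ix <- ht3dsnn:::pixel_cells(15, 15, 0, sp) # lower endpoint cell
  top <- ix$row; bot <- top - 8L
  expect_equal(segment_point_count(acc, 0, ix$d_idx, top, top), 0)
  expect_equal(segment_point_count(acc, 0, ix$d_idx, top, bot),
               segment_point_count(acc, 0, ix$d_idx, bot, top)) # symmetry
  # a window spanning all 6 pixels counts exactly 6
  expect_equal(segment_point_count(acc, 0, ix$d_idx, top, top - 10L), 6)
})

test_that("full/empty piece tests use strict thresholds", {
  sp <- tiny_spec()
  sc <- make_segment(c(15, 10), c(15, 15), c(32, 32))
  acc <- ht3d_transform(sc, sp)
  ix <- ht3dsnn:::pixel_cells(15, 15, 0, sp)
  expect_true(is_full_segment(acc, 0, ix$d_idx, ix$row, 10L, tau_F = 4))
  expect_false(is_full_segment(acc, 0, ix$d_idx, ix$row, 10L, tau_F = 6)) # == is not >
  expect_true(is_empty_segment(acc, 0, 0, 20L, 6L, tau_E = 1)) # empty column
  expect_false(is_empty_segment(acc, 0, ix$d_idx, ix$row, 10L, tau_E = 1))
  expect_error(is_full_segment(acc, 0, 0, 3L, 10L, 4), "outside")
})

test_that("an isolated segment yields one normal and one flipped endpoint", {
  sp <- hough_spec(28, 28, delta_d = 2, delta_p = 2, delta_theta = 0.1, eta = 4)
  sc <- make_segment(c(13, 8), c(13, 17), c(28, 28)) # 10 pixels
  det <- ht3d_detect(sc, sp)
  ep <- det[det$kind == "endpoint", ]
  expect_equal(nrow(det), 2)
  expect_equal(nrow(ep), 2)
  expect_setequal(ep$flipped, c(TRUE, FALSE))
  mr <- match_points(det, scene_ground_truth(sc))
  expect_equal(mr$hit_rate, 1)
  # blank image: nothing
  blank <- matrix(0L, 28, 28)
  expect_equal(nrow(ht3d_detect(blank, sp)), 0)
})

test_that("an L junction produces a corner detection at the vertex", {
  sp <- hough_spec(48, 48, delta_d = 2, delta_p = 2, delta_theta = 0.1, eta = 4)
  sc <- make_L(c(14, 34), 20, 90, c(48, 48), arm1_dir = -90)
  det <- ht3d_detect(sc, sp)
  co <- det[det$kind == "corner", ]
  expect_gte(nrow(co), 1)
  dist <- sqrt((co$x - 14)^2 + (co$y - 34)^2)
  expect_lte(min(dist), 3)
  mr <- match_points(det, scene_ground_truth(sc))
  expect_equal(mr$hit_rate, 1)
})

test_that("detections rotate with the scene across aligned layers", {
  sp <- hough_spec(32, 32, delta_d = 2, delta_p = 2, delta_theta = pi / 18, eta = 4)
  v <- ht3d_detect(make_segment(c(15, 8), c(15, 23), c(32, 32)), sp)
  h <- ht3d_detect(make_segment(c(8, 16), c(23, 16), c(32, 32)), sp)
  # the horizontal scene is the vertical one rotated by 90 deg about the
  # center (a multiple of delta_theta); endpoints must map accordingly
  expect_equal(nrow(v), nrow(h))
  rot <- data.frame(x = 31 - (v$y + 0.5) + 0.5, y = v$x) # (x,y) -> (31-y, x)
  tol <- max(sp$delta_d, sp$delta_p)
  for (i in seq_len(nrow(rot))) {
    dist <- sqrt((h$x - rot$x[i])^2 + (h$y - rot$y[i])^2)
    expect_lte(min(dist), tol)
  }
})

test_that("localization snaps to the intensity corner and handles flat windows", {
  sc <- make_L(c(14, 34), 18, 90, c(48, 48), arm1_dir = -90)
  img <- render_intensity(sc, fill = FALSE)
  sp <- hough_spec(48, 48, delta_d = 2, delta_p = 2, delta_theta = 0.1, eta = 4)
  fake <- data.frame(x = 15, y = 33) # one pixel off the true corner
  loc <- localize_in_image(fake, img, sp)
  expect_lte(max(abs(loc$x - 14), abs(loc$y - 34)), 1)
  flat <- matrix(128, 48, 48)
  loc0 <- localize_in_image(fake, flat, sp)
  expect_equal(loc0$score, 0)
  expect_equal(c(loc0$x, loc0$y), c(15, 33)) # window-center fallback
})
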