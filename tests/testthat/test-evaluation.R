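test_that("signed distance volume matches sphere geometry and sign convention", {
  msk <- make_activation_mask(c(0, 0, 0), 5, c(32, 32, 32), 1)
  sdv <- signed_distance_volume(msk)
  # value at the centre: -(radius) within one voxel
  ctr <- solve(msk$voxel_to_world) %*% c(0, 0, 0, 1)
  v_ctr <- sdv$values[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1]
  expect_lt(abs(v_ctr + 5), 1)
  # a voxel 3 mm outside the surface: ~ +3 within one voxel
  out_pt <- solve(msk$voxel_to_world) %*% c(8, 0, 0, 1)
  v_out <- sdv$values[out_pt[1] + 1, out_pt[2] + 1, out_pt[3] + 1]
  expect_lt(abs(v_out - 3), 1)
  # sign matches mask membership voxelwise
  expect_true(all((sdv$values < 0) == (msk$data > 0)))
})

test_that("distance transform equals brute force on a random toy mask", {
  set.seed(1)
  arr <- array(runif(1000) < 0.1, dim = c(10, 10, 10))
  spacing <- c(1.5, 2, 1)
  msk <- volume_mask(arr, diag(c(spacing, 1)))
  sdv <- signed_distance_volume(msk)
  fg <- which(arr, arr.ind = TRUE)
  bg <- which(!arr, arr.ind = TRUE)
  fg_mm <- sweep(fg - 1, 2, spacing, "*")
  bg_mm <- sweep(bg - 1, 2, spacing, "*")
  bf <- array(0, dim(arr))
  for (i in seq_len(nrow(bg)))
    bf[bg[i, 1], bg[i, 2], bg[i, 3]] <-
      sqrt(min(rowSums(sweep(fg_mm, 2, bg_mm[i, ])^2)))
  for (i in seq_len(nrow(fg)))
    bf[fg[i, 1], fg[i, 2], fg[i, 3]] <-
      -sqrt(min(rowSums(sweep(bg_mm, 2, fg_mm[i, ])^2)))
  expect_equal(sdv$values, bf, tolerance = 1e-12)
  expect_error(signed_distance_volume(volume_mask(array(0, c(4, 4, 4)))),
               "no foreground")
})

test_that("tract minimum signed distance reports depth and gap on a sphere", {
  msk <- make_activation_mask(c(0, 0, 0), 5, c(40, 40, 40), 1)
  sdv <- signed_distance_volume(msk)
  through <- tractogram(list(straight_fiber(c(-15, 0, 0), c(15, 0, 0), 31)), "t")
  res <- tract_min_signed_distance(through, sdv, activation_name = "sphere")
  expect_lt(abs(res$min_signed_distance + 5), 1)
  expect_true(res$intersects)
  # closest approach 3 mm outside the surface (line at y = 8)
  outside <- tractogram(list(straight_fiber(c(-15, 8, 0), c(15, 8, 0), 31)), "t")
  res_o <- tract_min_signed_distance(outside, sdv)
  expect_lt(abs(res_o$min_signed_distance - 3), 1)
  expect_false(res_o$intersects)
  # grazing the surface: |distance| within one voxel
  graze <- tractogram(list(straight_fiber(c(-15, 5, 0), c(15, 5, 0), 31)), "t")
  res_g <- tract_min_signed_distance(graze, sdv)
  expect_lt(abs(res_g$min_signed_distance), 1)
  expect_error(tract_min_signed_distance(tractogram(), sdv), "empty")
})

test_that("interpolated tract distance matches a brute-force point search", {
  set.seed(6)
  arr <- array(runif(1000) < 0.15, dim = c(10, 10, 10))
  msk <- volume_mask(arr, diag(4))
  sdv <- signed_distance_volume(msk)
  fib <- straight_fiber(c(0.7, 1.2, 0.4), c(8.3, 7.9, 8.8), 40)
  res <- tract_min_signed_distance(tractogram(list(fib), "t"), sdv, step = 0.25)
  # oracle: brute-force per-voxel signed distances (no package distance
  # transform) interpolated by a hand-written trilinear stencil at dense
  # fiber samples
  fg <- which(arr, arr.ind = TRUE) - 1
  bg <- which(!arr, arr.ind = TRUE) - 1
  bf <- array(0, dim(arr))
  for (i in seq_len(nrow(bg)))
    bf[bg[i, 1] + 1, bg[i, 2] + 1, bg[i, 3] + 1] <-
      sqrt(min(rowSums(sweep(fg, 2, bg[i, ])^2)))
  for (i in seq_len(nrow(fg)))
    bf[fg[i, 1] + 1, fg[i, 2] + 1, fg[i, 3] + 1] <-
      -sqrt(min(rowSums(sweep(bg, 2, fg[i, ])^2)))
  dense <- resample_fiber(fib, 400)
  tri <- apply(dense, 1, function(p) {
    l <- pmin(pmax(floor(p), 0), dim(arr) - 2)
    u <- p - l
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, u, 1 - u))
      v <- v + w * bf[l[1] + dx + 1, l[2] + dy + 1, l[3] + dz + 1]
    }
    v
  })
  expect_lt(abs(res$min_signed_distance - min(tri)), 0.5)
})

test_that("intersection summaries count per group and total exactly", {
  s <- intersection_summary(rep("motor", 3), c(TRUE, FALSE, TRUE))
  expect_equal(s$x, 2L)
  expect_equal(s$y, 3L)
  s2 <- intersection_summary(c("a", "a", "b"), c(TRUE, TRUE, FALSE))
  expect_equal(attr(s2, "total_x"), 2L)
  expect_equal(attr(s2, "total_y"), 3L)
  expect_equal(attr(s2, "total_x"), sum(s2$x))
  expect_equal(attr(s2, "total_y"), sum(s2$y))
  e <- intersection_summary(character(0), logical(0))
  expect_true(attr(e, "empty"))
  expect_equal(attr(e, "total_y"), 0L)
})

test_that("consistency summary reports exact detection fractions", {
  all_present <- matrix(TRUE, 10, 4)
  r <- consistency_summary(all_present)
  expect_true(all(r$summary$percent == 100))
  # 712 of 800 rows present in all 10 subjects: 89%
  pres <- matrix(TRUE, 800, 10)
  pres[713:800, 1] <- FALSE
  r2 <- consistency_summary(pres)
  expect_equal(r2$summary$count[r2$summary$min_subjects == 10], 712L)
  expect_equal(r2$summary$percent[r2$summary$min_subjects == 10], 89L)
  # a subject with nothing detected empties the all-subjects bin
  pres3 <- matrix(TRUE, 20, 3)
  pres3[, 2] <- FALSE
  r3 <- consistency_summary(pres3)
  expect_equal(r3$summary$count[r3$summary$min_subjects == 3], 0L)
  expect_error(consistency_summary(list(rep(TRUE, 5), rep(TRUE, 6))), "cluster count")
})

test_that("tract volume counts occupied voxels in cc and grows monotonically", {
  expect_equal(tract_volume(tractogram()), 0)
  one <- tractogram(list(straight_fiber(c(0.5, 0.5, 0.5), c(10.5, 0.5, 0.5), 11)), "t")
  v <- tract_volume(one, voxel_size = 1)
  expect_gte(v, 0.010)
  expect_lte(v, 0.011)
  two <- tractogram(c(one$fibers,
                      list(straight_fiber(c(0.5, 5.5, 0.5), c(10.5, 5.5, 0.5), 11))), "t")
  expect_gte(tract_volume(two, 1), v)
})
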