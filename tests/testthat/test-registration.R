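# shared small registration settings for the toy cohorts
toy_reg_config <- function(...) {
  defaults <- list(fibers_per_subject = 100L, min_fiber_length = 40,
                   n_points = 10L, max_iterations_per_stage = 2L, seed = 7L)
  do.call(registration_config, utils::modifyList(defaults, list(...)))
}

test_that("entropy objective prefers aligned fibers and ignores fiber order", {
  pool <- tractogram(random_fibers(40, seed = 5), "p")
  aligned <- pool
  shifted <- apply_transform(pool, linear_transform(rbind(cbind(diag(3), c(20, 0, 0)),
                                                          c(0, 0, 0, 1))))
  c_aligned <- entropy_objective(aligned, pool, sigma = 10)
  c_shifted <- entropy_objective(shifted, pool, sigma = 10)
  expect_lt(c_aligned, c_shifted)
  # order invariance
  perm <- tractogram(pool$fibers[c(3:40, 1:2)], "p")
  expect_equal(entropy_objective(perm, pool, sigma = 10), c_aligned)
  # very large sigma: affinity means -> 1, cost -> 0
  expect_lt(abs(entropy_objective(aligned, pool, sigma = 1e6)), 1e-3)
  # same-subject exclusion with a single-subject pool has nothing left
  expect_error(entropy_objective(pool, pool, sigma = 10, exclude_same_subject = TRUE),
               "empty")
})

test_that("affine registration recovers planted transforms", {
  specs <- default_bundle_specs(n_fibers = 10, dispersion = 2)
  pool <- make_subject(specs, bilateral = TRUE, seed = 21)
  cfg <- toy_reg_config()
  # self-registration: near identity
  tr0 <- register_affine_to_pool(pool, pool, cfg)
  expect_lt(max(abs(tr0$matrix[1:3, 4])), 1)
  ang0 <- acos(pmin(1, (sum(diag(tr0$matrix[1:3, 1:3])) - 1) / 2)) * 180 / pi
  expect_lt(ang0, 1)

  # known translation
  tt <- linear_transform(rbind(cbind(diag(3), c(8, -5, 3)), c(0, 0, 0, 1)))
  moved <- apply_transform(pool, tt)
  tr <- register_affine_to_pool(moved, pool, cfg)
  expect_lt(max(abs(tr$matrix[1:3, 4] - c(-8, 5, -3))), 1)

  # known rotation about z (about the data centroid)
  rot <- tractatlas:::params_to_affine(c(0, 0, 0, 0, 0, 10, rep(0, 6)),
                                       tractatlas:::flat_centroid(
                                         tractatlas:::flatten_fibers(pool$fibers, 10)))
  moved_r <- apply_transform(pool, rot)
  tr_r <- register_affine_to_pool(moved_r, pool, cfg)
  recovered_angle <- atan2(tr_r$matrix[2, 1], tr_r$matrix[1, 1]) * 180 / pi
  expect_lt(abs(recovered_angle + 10), 1)

  # accepted objective trajectory is non-increasing within each kernel level
  for (level in attr(tr, "trajectory"))
    expect_true(all(diff(level) <= 1e-9))
})

test_that("groupwise registration is unbiased and aligns a jittered cohort", {
  specs <- default_bundle_specs(n_fibers = 12, dispersion = 2)
  coh <- make_cohort(specs, n_subjects = 3, seed = 42)
  cfg <- toy_reg_config()
  pre <- mean_corresponding_distance(coh$subjects)
  ts <- register_groupwise(coh$subjects, cfg)
  reg <- lapply(seq_along(coh$subjects), function(i)
    apply_transform(coh$subjects[[i]], ts$transforms[[i]]))
  post <- mean_corresponding_distance(reg)
  expect_lt(post, 0.5 * pre)
  # group-average affine is the identity (unbiasedness is exact by
  # construction of the final normalization)
  mbar <- Reduce(`+`, lapply(ts$transforms, function(t) t$matrix)) / 3
  expect_lt(max(abs(mbar - diag(4))), 1e-10)
  # recovered o applied deviates from identity by < 2 mm mean displacement
  tpl <- make_subject(specs, bilateral = TRUE, seed = 42)
  pts <- do.call(rbind, tpl$fibers)
  disp <- vapply(1:3, function(i) {
    M <- ts$transforms[[i]]$matrix %*% coh$true_transforms[[i]]$matrix
    moved <- cbind(pts, 1) %*% t(M)
    mean(sqrt(rowSums((moved[, 1:3] - pts)^2)))
  }, numeric(1))
  expect_lt(mean(disp), 2)
})

test_that("identical untransformed subjects register to near-identity transforms", {
  specs <- default_bundle_specs(n_fibers = 10, dispersion = 2)
  coh <- make_cohort(specs, n_subjects = 3, max_translation = 0, max_rotation = 0,
                     scale_range = c(1, 1), seed = 5)
  ts <- register_groupwise(coh$subjects, toy_reg_config())
  for (tr in ts$transforms) {
    expect_lt(max(abs(tr$matrix[1:3, 4])), 1)
    ang <- acos(pmin(1, (sum(diag(tr$matrix[1:3, 1:3])) - 1) / 2)) * 180 / pi
    expect_lt(ang, 1)
  }
})

test_that("b-spline refinement reduces residual of a planted smooth warp", {
  specs <- default_bundle_specs(n_fibers = 8, dispersion = 2)
  coh <- make_cohort(specs, n_subjects = 3, max_translation = 0, max_rotation = 0,
                     scale_range = c(1, 1), seed = 2)
  tg <- coh$subjects[[1]]
  pts <- do.call(rbind, tg$fibers)
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  tg$fibers <- lapply(tg$fibers, function(f)
    f + tractatlas:::sinusoidal_warp(f, lo, hi, 4))
  coh$subjects[[1]] <- tg
  cfg <- toy_reg_config(fibers_per_subject = 60,
                        stages = c("affine", "bspline"),
                        bspline_grids = list(c(4L, 4L, 4L), c(6L, 6L, 6L)))
  ts_aff <- register_groupwise(coh$subjects, cfg)
  d_aff <- mean_corresponding_distance(
    lapply(1:3, function(i) apply_transform(coh$subjects[[i]], ts_aff$transforms[[i]])))
  ts_bsp <- register_groupwise_bspline(coh$subjects, ts_aff, cfg)
  d_bsp <- mean_corresponding_distance(
    lapply(1:3, function(i) apply_transform(coh$subjects[[i]], ts_bsp$transforms[[i]])))
  expect_lt(d_bsp, d_aff)
  # zero iterations: transforms pass through unchanged
  cfg0 <- cfg
  cfg0$max_iterations_per_stage <- 0L
  expect_identical(register_groupwise_bspline(coh$subjects, ts_aff, cfg0), ts_aff)
  # displacement bound: 0.4 x control spacing (folding guard)
  for (tr in ts_bsp$transforms) {
    g <- tr[[2]]
    spacing <- (g$domain_bounds[c(2, 4, 6)] - g$domain_bounds[c(1, 3, 5)]) /
      (g$grid_shape - 3)
    expect_lte(max(abs(g$control_displacements)), 0.4 * min(spacing) + 1e-9)
  }
})

test_that("transforms apply, compose and invert as expected", {
  tg <- tractogram(random_fibers(4, seed = 8))
  expect_equal(apply_transform(tg, linear_transform(diag(4)))$fibers, tg$fibers)
  tt <- linear_transform(rbind(cbind(diag(3), c(1, 2, 3)), c(0, 0, 0, 1)))
  back <- apply_transform(apply_transform(tg, tt), invert_transform(tt))
  expect_lt(max(abs(do.call(rbind, back$fibers) - do.call(rbind, tg$fibers))), 1e-9)
  sc <- linear_transform(diag(c(2, 2, 2, 1)))
  doubled <- apply_transform(tg, sc)
  expect_equal(vapply(doubled$fibers, fiber_length, numeric(1)),
               2 * vapply(tg$fibers, fiber_length, numeric(1)))
  gt <- grid_transform(array(0, c(4, 4, 4, 3)), c(-100, 100, -100, 100, -100, 100))
  expect_error(invert_transform(gt), "not supported")
  # zero displacement grid is the identity
  expect_equal(apply_transform(tg, gt)$fibers, tg$fibers)
})
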