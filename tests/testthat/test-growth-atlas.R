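test_that("degenerate label histories short-circuit to constants", {
  ga <- seq(29, 44, length.out = 20)
  f0 <- fit_voxel_logistic(ga, rep(0, 20))
  expect_equal(f0$status, "constant-0"); expect_equal(f0$p_const, 0)
  f1 <- fit_voxel_logistic(ga, rep(1, 20))
  expect_equal(f1$status, "constant-1"); expect_equal(f1$p_const, 1)
  ffew <- fit_voxel_logistic(c(30, 31), c(0, 1))
  expect_equal(ffew$status, "failed"); expect_equal(ffew$p_const, 0.5)
  fone <- fit_voxel_logistic(rep(35, 10), c(rep(0, 5), rep(1, 5)))
  expect_equal(fone$status, "failed")
  expect_error(fit_voxel_logistic(ga, rep(2, 20)), "binary")
})

test_that("the logistic fit recovers generating parameters at n = 400", {
  set.seed(31)
  ga <- runif(400, 29, 44)
  y <- rbinom(400, 1, plogis(2 * (ga - 40)))
  fit <- fit_voxel_logistic(ga, y)
  expect_equal(fit$status, "fitted")
  expect_lt(abs(fit$t0 - 40), 0.5)
  expect_lt(abs(fit$k - 2) / 2, 0.3)
})

test_that("atlas queries are bounded, monotone and exact at the midpoint", {
  ref <- phantom_spec(grid_shape = c(16, 16, 10), seed = 1)
  coh <- generate_cohort(cohort_spec(80, c(29, 44), onset_table(), seed = 9),
                         ref)
  atl <- build_atlas(coh)
  for (t in c(29, 33.5, 40, 44)) {
    p <- query_atlas(atl, t)
    expect_true(all(p >= 0 & p <= 1))
  }
  # monotone non-decreasing in age at every voxel (k >= 0 everywhere)
  p30 <- query_atlas(atl, 30); p37 <- query_atlas(atl, 37)
  p44 <- query_atlas(atl, 44)
  expect_true(all(p37 - p30 >= -1e-12))
  expect_true(all(p44 - p37 >= -1e-12))
  # voxels that never myelinate stay at zero
  masks <- attr(coh, "structure_masks")
  bg <- !Reduce(`|`, masks)
  expect_true(all(p44[bg] == 0))
  expect_warning(query_atlas(atl, 50), "extrapolat")
})

test_that("a fitted voxel crosses half its asymptote at its midpoint", {
  set.seed(32)
  ga <- runif(300, 29, 44)
  y <- rbinom(300, 1, plogis(3 * (ga - 36)))
  fit <- fit_voxel_logistic(ga, y)
  p_mid <- fit$c * plogis(fit$k * (fit$t0 - fit$t0))
  expect_equal(p_mid, fit$c / 2)
})

test_that("atlas recovery: queried curves track the generating curves", {
  ref <- phantom_spec(grid_shape = c(16, 16, 10), seed = 1)
  on <- onset_table(t0 = c(32, 36, 40), k = 3)
  coh <- generate_cohort(cohort_spec(150, c(29, 44), on, seed = 10), ref)
  atl <- build_atlas(coh)
  masks <- attr(coh, "structure_masks")
  ages <- seq(30, 43, by = 0.5)
  only <- lapply(1:3, function(j) {
    Reduce(`&`, c(masks[on$label[j]],
                  lapply(masks[setdiff(names(masks), on$label[j])], `!`)))
  })
  for (j in 1:3) {
    gen <- plogis(3 * (ages - on$t0[j]))
    got <- vapply(ages, function(t) {
      mean(query_atlas(atl, t)[only[[j]]])
    }, numeric(1))
    expect_lt(mean(abs(got - gen)), 0.05)
  }
})

test_that("milestones are recovered, censored or absent as constructed", {
  ref <- phantom_spec(grid_shape = c(16, 16, 10), seed = 1)
  on <- onset_table(t0 = c(25, 40, 52), k = 8)
  coh <- generate_cohort(cohort_spec(200, c(29, 44), on, seed = 11), ref)
  atl <- build_atlas(coh)
  masks <- attr(coh, "structure_masks")
  # sharp onset at 40 weeks: milestone within half a week
  ms <- milestone(atl, masks$STN)
  expect_equal(ms$status, "reached")
  expect_lt(abs(ms$ga_weeks - 40), 0.5)
  # myelinated before the cohort window: left-censored
  early <- milestone(atl, masks$VLN)
  expect_equal(early$status, "le_range_start")
  expect_equal(early$label, "<=29 weeks")
  # never myelinated in the window
  never <- milestone(atl, masks$PLIC)
  expect_equal(never$status, "not_reached")
  expect_error(milestone(atl, array(FALSE, dim(masks$STN))), "empty")
})

test_that("atlases round-trip through NIfTI + JSON", {
  ref <- phantom_spec(grid_shape = c(10, 10, 8), seed = 1)
  coh <- generate_cohort(cohort_spec(30, c(29, 44), onset_table(), seed = 12),
                         ref)
  atl <- build_atlas(coh)
  dir <- withr::local_tempdir()
  write_atlas(atl, dir)
  back <- read_atlas(dir)
  expect_equal(back$ga_range_weeks, atl$ga_range_weeks)
  expect_identical(back$status, atl$status)
  expect_equal(back$t0, atl$t0, tolerance = 1e-6)
  expect_equal(query_atlas(back, 40), query_atlas(atl, 40), tolerance = 1e-6)
})
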