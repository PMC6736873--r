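test_that("m_step_means solves the constrained system (hand cases)", {
  roi <- array(TRUE, c(3, 1, 1))
  y <- array(c(0, 2, 1), c(3, 1, 1))
  P <- array(0, c(3, 1, 1, 3))
  P[1, 1, 1, 1] <- 1  # MLS
  P[2, 1, 1, 3] <- 1  # BKG
  P[3, 1, 1, 2] <- 1  # PV
  mu <- m_step_means(volume_grid(y, c(1, 1, 1)), roi, P)
  expect_equal(mu$mu_mls, 0, tolerance = 1e-12)
  expect_equal(mu$mu_bkg, 2, tolerance = 1e-12)
  expect_equal(mu$mu_pv, 1, tolerance = 1e-12)
  # PV-free limit reduces to plain weighted means
  set.seed(3)
  y2 <- array(rnorm(20, 10, 4), c(20, 1, 1))
  P2 <- array(0, c(20, 1, 1, 3))
  w <- runif(20)
  P2[, 1, 1, 1] <- w; P2[, 1, 1, 3] <- 1 - w
  mu2 <- m_step_means(volume_grid(y2, c(1, 1, 1)), array(TRUE, c(20, 1, 1)), P2)
  expect_equal(mu2$mu_mls, sum(y2 * w) / sum(w), tolerance = 1e-12)
  expect_equal(mu2$mu_bkg, sum(y2 * (1 - w)) / sum(1 - w), tolerance = 1e-12)
})

test_that("m_step_means agrees with a numeric constrained maximizer", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    y <- rnorm(n, 150, 50)
    p <- matrix(runif(3 * n), n, 3)
    p <- p / rowSums(p)
    roi <- array(TRUE, c(n, 1, 1))
    P <- array(0, c(n, 1, 1, 3))
    for (k in 1:3) P[, 1, 1, k] <- p[, k]
    got <- m_step_means(volume_grid(array(y, c(n, 1, 1)), c(1, 1, 1)), roi, P)
    want <- m_step_oracle(y, p)
    expect_equal(got$mu_mls, want$mu_mls, tolerance = 1e-6)
    expect_equal(got$mu_bkg, want$mu_bkg, tolerance = 1e-6)
    expect_equal(got$mu_pv, (got$mu_mls + got$mu_bkg) / 2, tolerance = 1e-12)
  }
})

test_that("degenerate posterior mass is reported as an error", {
  y <- array(1:4, c(4, 1, 1))
  roi <- array(TRUE, c(4, 1, 1))
  P <- array(0, c(4, 1, 1, 3))
  P[, 1, 1, 2] <- 1   # everything PV
  expect_error(m_step_means(volume_grid(y, c(1, 1, 1)), roi, P), "PV")
})

test_that("m_step_variance matches the shared-variance formula", {
  set.seed(4)
  n <- 30
  y <- rnorm(n, 0, 2)
  p <- matrix(runif(3 * n), n, 3); p <- p / rowSums(p)
  P <- array(0, c(n, 1, 1, 3)); for (k in 1:3) P[, 1, 1, k] <- p[, k]
  roi <- array(TRUE, c(n, 1, 1))
  means <- list(mu_mls = -1, mu_pv = 0.2, mu_bkg = 1.5)
  mus <- c(-1, 0.2, 1.5)
  direct <- 0
  for (k in 1:3) for (i in 1:n) direct <- direct + p[i, k] * (y[i] - mus[k])^2
  got <- m_step_variance(volume_grid(array(y, c(n, 1, 1)), c(1, 1, 1)),
                         roi, P, means)
  expect_equal(got, direct / n, tolerance = 1e-12)
  # single-class limit: population variance about that class mean
  P1 <- array(0, c(n, 1, 1, 3)); P1[, 1, 1, 3] <- 1
  got1 <- m_step_variance(volume_grid(array(y, c(n, 1, 1)), c(1, 1, 1)),
                          roi, P1, list(mu_mls = 0, mu_pv = 0, mu_bkg = mean(y)))
  expect_equal(got1, mean((y - mean(y))^2), tolerance = 1e-12)
  # exact fit is floored, not zero
  yf <- array(c(0, 2, 1), c(3, 1, 1))
  Pf <- array(0, c(3, 1, 1, 3))
  Pf[1, 1, 1, 1] <- 1; Pf[2, 1, 1, 3] <- 1; Pf[3, 1, 1, 2] <- 1
  gotf <- m_step_variance(volume_grid(yf, c(1, 1, 1)), array(TRUE, c(3, 1, 1)),
                          Pf, list(mu_mls = 0, mu_pv = 1, mu_bkg = 2),
                          variance_floor = 1e-8)
  expect_equal(gotf, 1e-8)
})

test_that("percentile initialization selects the stated fraction of voxels", {
  set.seed(5)
  y <- array(sample(1:100), c(100, 1, 1))
  roi <- array(TRUE, c(100, 1, 1))
  P6 <- initialize_posteriors(volume_grid(y, c(1, 1, 1)), roi, 6)
  expect_equal(sum(P6[, , , 1]), 6)
  expect_true(all(y[P6[, , , 1] == 1] <= 6))   # the 6 lowest intensities
  P25 <- initialize_posteriors(volume_grid(y, c(1, 1, 1)), roi, 25)
  expect_equal(sum(P25[, , , 1]), 25)
  # PV starts empty; assignments are one-hot within the ROI
  expect_equal(sum(P6[, , , 2]), 0)
  expect_equal(sum(P6), 100)
  # constant image: deterministic tie-break by voxel order, count preserved
  yc <- array(7, c(50, 1, 1))
  Pc <- initialize_posteriors(volume_grid(yc, c(1, 1, 1)),
                              array(TRUE, c(50, 1, 1)), 10)
  expect_equal(sum(Pc[, , , 1]), 5)
  expect_equal(which(Pc[, , , 1] == 1), 1:5)
  expect_error(initialize_posteriors(volume_grid(yc, c(1, 1, 1)),
                                     array(FALSE, c(50, 1, 1)), 10), "ROI")
})

test_that("posteriors stay normalized and constraints hold through EM", {
  ph <- small_phantom(seed = 6)
  fit <- run_em(ph$image, ph$roi, em_config(max_iter = 6))
  psum <- fit$posteriors[, , , 1] + fit$posteriors[, , , 2] +
    fit$posteriors[, , , 3]
  expect_lt(max(abs(psum[ph$roi] - 1)), 1e-10)
  expect_true(all(psum[!ph$roi] == 0))
  expect_equal(fit$state$mu_pv, (fit$state$mu_mls + fit$state$mu_bkg) / 2,
               tolerance = 1e-9)
  expect_true(all(is.finite(fit$trace)))
  expect_gte(fit$state$sigma2, 0)
})

test_that("EM recovers the generating mixture on the standard phantom", {
  ph <- standard_phantom(seed = 1)
  fit <- run_em(ph$image, ph$roi)
  expect_true(fit$converged)
  expect_lt(abs(fit$state$mu_mls - 100) / 100, 0.02)
  expect_lt(abs(fit$state$mu_bkg - 200) / 200, 0.02)
  seg <- finalize_mls(fit)
  expect_gte(dice(seg$mask, truth_mask(ph)), 0.9)
})

test_that("a noiseless PV-free phantom is recovered to machine precision", {
  ph <- pv_free_phantom()
  fit <- run_em(ph$image, ph$roi,
                em_config(t1 = 0, t2 = 0, t3 = 0, init_percentile = 25))
  expect_lt(abs(fit$state$mu_mls - 100), 1e-6)
  expect_lt(abs(fit$state$mu_bkg - 200), 1e-6)
  expect_equal(fit$state$mu_pv, 150, tolerance = 1e-6)
})

test_that("segmentation is insensitive to the initialization percentile", {
  ph <- standard_phantom(seed = 2)
  m4 <- finalize_mls(run_em(ph$image, ph$roi, em_config(init_percentile = 4)))
  m8 <- finalize_mls(run_em(ph$image, ph$roi, em_config(init_percentile = 8)))
  expect_gte(dice(m4$mask, m8$mask), 0.95)
})

test_that("objective trace rises to convergence before the iteration cap", {
  ph <- small_phantom(seed = 8)
  fit <- run_em(ph$image, ph$roi)
  expect_true(fit$converged)
  expect_lt(fit$iterations, fit$config$max_iter)
  rel <- abs(diff(tail(fit$trace, 2))) / abs(tail(fit$trace, 2)[1])
  expect_lt(rel, fit$config$rel_tol)
})
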