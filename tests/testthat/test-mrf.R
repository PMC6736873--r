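test_that("connectivity tensor entries follow the triplet penalty rules", {
  tn <- build_connectivity_tensor(0.05, 0.03, 0.01)
  # homogeneous pure pair: 0 for own class, t1 for the other pure, t3 for PV
  expect_equal(tn["MLS", "MLS", "MLS"], 0)
  expect_equal(tn["BKG", "MLS", "MLS"], 0.05)
  expect_equal(tn["PV", "MLS", "MLS"], 0.01)
  expect_equal(tn["BKG", "BKG", "BKG"], 0)
  expect_equal(tn["MLS", "BKG", "BKG"], 0.05)
  expect_equal(tn["PV", "BKG", "BKG"], 0.01)
  # mixed pure pair: t2 for the pure classes, 0 for PV
  expect_equal(tn["MLS", "MLS", "BKG"], 0.03)
  expect_equal(tn["BKG", "MLS", "BKG"], 0.03)
  expect_equal(tn["PV", "MLS", "BKG"], 0)
  # any pair involving PV carries no penalty, for every k
  expect_true(all(tn[, "PV", ] == 0))
  expect_true(all(tn[, , "PV"] == 0))
  # symmetric in (k1, k2) and restricted to the stated penalty set
  for (k in 1:3) expect_equal(unclass(tn)[k, , ], t(unclass(tn)[k, , ]))
  expect_true(all(unclass(tn) %in% c(0, 0.05, 0.03, 0.01)))
  expect_error(build_connectivity_tensor(-0.1, 0, 0), ">= 0")
})

test_that("zero penalties give an all-zero tensor and a uniform prior", {
  tn <- build_connectivity_tensor(0, 0, 0)
  expect_true(all(unclass(tn) == 0))
  v <- c(2, 1, 3)
  u <- vapply(1:3, function(k) mrf_energy(v, tn, k), numeric(1))
  expect_equal(mrf_prior(u), rep(1 / 3, 3))
})

test_that("neighbor aggregation weights neighbors by inverse distance", {
  nb <- neighborhood_system(c(1, 1, 1))
  expect_equal(nrow(nb$offsets), 26L)
  expect_true(all(nb$weights > 0))
  P <- array(0, c(3, 3, 3, 3))
  # all neighbors zero
  expect_equal(neighbor_aggregate(P, nb, c(2, 2, 2)), c(0, 0, 0))
  # one face neighbor at unit distance, certain MLS
  P[1, 2, 2, 1] <- 1
  expect_equal(neighbor_aggregate(P, nb, c(2, 2, 2)), c(1, 0, 0))
  # add a corner neighbor, certain PV: contributes 1/sqrt(3)
  P[3, 3, 3, 2] <- 1
  expect_equal(neighbor_aggregate(P, nb, c(2, 2, 2)),
               c(1, 1 / sqrt(3), 0))
  # anisotropic spacing changes the face distance
  nb2 <- neighborhood_system(c(0.86, 0.86, 1))
  expect_equal(neighbor_aggregate(P, nb2, c(2, 2, 2))[1], 1 / 0.86)
  # voxels outside the ROI contribute zero
  roi <- array(TRUE, c(3, 3, 3)); roi[1, 2, 2] <- FALSE
  expect_equal(neighbor_aggregate(P, nb, c(2, 2, 2), roi)[1], 0)
  # at a grid corner only in-grid neighbors contribute: (1,2,2) is the
  # edge-adjacent neighbor of (1,1,1) at distance sqrt(2)
  expect_equal(neighbor_aggregate(P, nb, c(1, 1, 1))[1], 1 / sqrt(2))
  expect_equal(neighbor_aggregate(array(0, c(3, 3, 3, 3)), nb,
                                  c(1, 1, 1)), c(0, 0, 0))
})

test_that("mrf_energy matches a brute-force triple loop on random cases", {
  set.seed(101)
  for (i in 1:50) {
    tn <- build_connectivity_tensor(runif(1), runif(1), runif(1))
    v <- runif(3, 0, 5)
    for (k in 1:3) {
      expect_equal(mrf_energy(v, tn, k), mrf_energy_loop(v, tn, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("single-neighbor configuration reproduces hand-computed energies", {
  tn <- build_connectivity_tensor(0.05, 0.03, 0.01)
  v <- c(1, 0, 0)   # pure MLS neighborhood of unit aggregate
  expect_equal(mrf_energy(v, tn, 1), 0)
  expect_equal(mrf_energy(v, tn, 2), 0.01)
  expect_equal(mrf_energy(v, tn, 3), 0.05)
})

test_that("mrf_prior is a shift-invariant softmax", {
  u <- c(0, 0.01, 0.05)
  p <- mrf_prior(u)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, exp(-u) / sum(exp(-u)), tolerance = 1e-12)
  expect_equal(mrf_prior(u + 7), p, tolerance = 1e-12)
  expect_equal(mrf_prior(c(1, 1, 1)), rep(1 / 3, 3))
  expect_error(mrf_prior(c(0, Inf, 0)), "finite")
})

test_that("field aggregation and priors agree with per-voxel evaluation", {
  set.seed(7)
  dm <- c(5, 5, 5)
  roi <- array(TRUE, dm); roi[1, 1, ] <- FALSE
  P <- random_posterior_field(dm, roi)
  nb <- neighborhood_system(c(0.86, 0.86, 1))
  tn <- build_connectivity_tensor(0.05, 0.03, 0.01)
  y <- array(rnorm(prod(dm), 150, 40), dm)
  state <- list(mu_mls = 100, mu_pv = 150, mu_bkg = 200, sigma2 = 400)
  es <- e_step(volume_grid(y, c(0.86, 0.86, 1)), roi, state, P, tn, nb)
  # pick interior and border voxels and recompute the whole chain by hand
  for (vx in list(c(3, 3, 3), c(2, 5, 4), c(5, 5, 5), c(2, 1, 1))) {
    v <- neighbor_aggregate(P, nb, vx)
    u <- vapply(1:3, function(k) mrf_energy_loop(v, tn, k), numeric(1))
    pri <- mrf_prior(u)
    g <- dnorm(y[vx[1], vx[2], vx[3]],
               c(state$mu_mls, state$mu_pv, state$mu_bkg), sqrt(state$sigma2))
    expected <- g * pri / sum(g * pri)
    expect_equal(es$posteriors[vx[1], vx[2], vx[3], ], expected,
                 tolerance = 1e-12)
  }
})
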