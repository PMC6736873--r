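# Shared fixtures and independent oracles. Everything is generated in code;
# nothing is read from disk.

# The standard noisy phantom: default deep-brain-like structures, noise at
# 5% of the MLS/BKG contrast.
standard_phantom <- function(seed = 1, sigma = 5, grid_shape = c(40, 40, 20)) {
  generate_phantom(phantom_spec(grid_shape = grid_shape, sigma = sigma,
                                seed = seed))
}

# A smaller phantom for cheap structural tests.
small_phantom <- function(seed = 1, sigma = 5) {
  standard_phantom(seed = seed, sigma = sigma, grid_shape = c(24, 24, 12))
}

# A phantom with no PV voxels at all: a flat slab whose faces lie exactly on
# voxel boundaries and whose lateral extent exceeds the grid. MLS occupies
# 4 of 12 slices, so the brainstem-style 25th-percentile init is right.
pv_free_phantom <- function(seed = 1, sigma = 0) {
  slab <- shape_slab(center = c(8 * 0.86, 8 * 0.86, 6), radii = c(1e3, 1e3),
                     thickness = 4, curvature = 0, label = "block")
  generate_phantom(phantom_spec(grid_shape = c(16, 16, 12),
                                mu_mls = 100, mu_bkg = 200, sigma = sigma,
                                structures = list(slab), seed = seed))
}

# Brute-force triple-loop evaluation of the MRF energy (independent of the
# quadratic-form implementation).
mrf_energy_loop <- function(v, tensor, k) {
  Tn <- unclass(tensor)
  u <- 0
  for (k1 in 1:3) for (k2 in 1:3) u <- u + v[k1] * Tn[k, k1, k2] * v[k2]
  u
}

# Numeric maximizer of the constrained Gaussian objective the M-step solves
# in closed form: minimize sum_i sum_k p_ik (y_i - mu_k)^2 over (mu_mls,
# mu_bkg) with mu_pv tied to their midpoint. Analytic gradient so the
# quasi-Newton solver reaches machine precision.
m_step_oracle <- function(y, p) {
  f <- function(mu) {
    mus <- c(mu[1], (mu[1] + mu[2]) / 2, mu[2])
    sum(vapply(1:3, function(k) sum(p[, k] * (y - mus[k])^2), numeric(1)))
  }
  g <- function(mu) {
    mpv <- mean(mu)
    c(-2 * (sum(p[, 1] * (y - mu[1])) + 0.5 * sum(p[, 2] * (y - mpv))),
      -2 * (sum(p[, 3] * (y - mu[2])) + 0.5 * sum(p[, 2] * (y - mpv))))
  }
  fit <- optim(c(mean(y) - sd(y), mean(y) + sd(y)), f, gr = g,
               method = "L-BFGS-B",
               control = list(factr = 1, pgtol = 1e-12, maxit = 2000))
  list(mu_mls = fit$par[1], mu_pv = mean(fit$par), mu_bkg = fit$par[2])
}

# Random normalized posterior field on a small grid (zero outside roi).
random_posterior_field <- function(dim3, roi = array(TRUE, dim3)) {
  P <- array(runif(prod(dim3) * 3), c(dim3, 3))
  s <- P[, , , 1] + P[, , , 2] + P[, , , 3]
  for (k in 1:3) {
    pk <- P[, , , k] / s
    pk[!roi] <- 0
    P[, , , k] <- pk
  }
  P
}

# Default onset table for the reference structures.
onset_table <- function(t0 = c(26, 28, 40), k = 3, c = 1, gradient = 0) {
  tibble::tibble(label = c("VLN", "STN", "PLIC"), t0 = t0, k = k, c = c,
                 gradient_weeks = gradient)
}

# Sharp-onset cohort with a within-structure myelination wave: the fixture
# for age-prediction tests (continuous age information, noiseless labels).
# The onset windows overlap so at least two structure frontiers are active
# through most of the 29-44 week range. The full-size variant (n = 114
# subjects, 32 x 32 x 16 grid) mirrors the cohort scale of the clinical
# study design; unit tests use smaller variants.
wave_cohort <- function(n = 60, seed = 5, grid_shape = c(24, 24, 12),
                        label_noise_rate = 0) {
  ref <- phantom_spec(grid_shape = grid_shape, seed = 1)
  on <- tibble::tibble(label = c("VLN", "STN", "PLIC"),
                       t0 = c(33, 37, 41), k = 60, c = 1,
                       gradient_weeks = c(13, 13, 7))
  generate_cohort(cohort_spec(n, c(29, 44), on, seed = seed,
                              label_noise_rate = label_noise_rate), ref)
}
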