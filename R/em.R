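#' Configuration of the MLS segmenter
#'
#' Collects the tunable parameters of the three-class EM model. The MRF
#' penalties `t1`, `t2`, `t3` default to the values found to maximize Dice
#' agreement with manual annotation (0.05, 0.03, 0.01). `init_percentile` is
#' the fraction of lowest-intensity ROI voxels seeded as MLS: 6 for the deep
#' brain region, 25 for the brainstem.
#'
#' @param t1 penalty for a pure-class voxel inside a homogeneous neighborhood
#'   of the other pure class.
#' @param t2 penalty for a pure-class voxel whose neighborhood mixes MLS and
#'   BKG (encourages the PV class at boundaries).
#' @param t3 penalty for a PV voxel inside a homogeneous pure-class
#'   neighborhood (prevents PV over-estimation).
#' @param init_percentile percentage in (0, 100) of lowest-intensity ROI
#'   voxels assigned to MLS at initialization.
#' @param rel_tol stopping threshold on the relative change of the objective
#'   (default `1e-4`, i.e. 0.01%).
#' @param max_iter iteration cap.
#' @param variance_floor lower bound on the shared variance; `NULL` means
#'   `1e-8 * (intensity range)^2`, resolved at run time.
#' @param distance_units `"mm"` (default): neighbor distances use the voxel
#'   spacing; `"voxel"`: unit spacing.
#' @return An `em_config` object.
#' @export
em_config <- function(t1 = 0.05, t2 = 0.03, t3 = 0.01,
                      init_percentile = 6, rel_tol = 1e-4, max_iter = 100L,
                      variance_floor = NULL,
                      distance_units = c("mm", "voxel")) {
  distance_units <- match.arg(distance_units)
  if (any(c(t1, t2, t3) < 0)) stop("penalties must be >= 0", call. = FALSE)
  if (init_percentile <= 0 || init_percentile >= 100) {
    stop("`init_percentile` must be in (0, 100)", call. = FALSE)
  }
  if (rel_tol <= 0) stop("`rel_tol` must be > 0", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, t3 = t3,
                 init_percentile = init_percentile, rel_tol = rel_tol,
                 max_iter = as.integer(max_iter),
                 variance_floor = variance_floor,
                 distance_units = distance_units),
            class = "em_config")
}

#' Build the 3D connectivity tensor of the second-order MRF
#'
#' `T[k, k1, k2]` is the penalty applied to a voxel of class `k` when classes
#' `k1` and `k2` are both present in its neighborhood. The rules, by the
#' unordered neighbor pair:
#' \itemize{
#'   \item (MLS, MLS) or (BKG, BKG): 0 if `k` equals the pair's class, `t1`
#'     if `k` is the other pure class, `t3` if `k` is PV.
#'   \item (MLS, BKG): `t2` if `k` is MLS or BKG, 0 if `k` is PV.
#'   \item any pair involving PV: 0 for every `k`.
#' }
#' Both ordered entries of an off-diagonal pair carry the full rule value, so
#' the quadratic form of the energy counts each unordered pair twice; the
#' brute-force evaluation in the tests uses the same convention.
#'
#' @param t1,t2,t3 non-negative penalties.
#' @return A 3 x 3 x 3 numeric array of class `connectivity_tensor` with
#'   dimnames `MLS`, `PV`, `BKG` on every axis.
#' @examples
#' tn <- build_connectivity_tensor(0.05, 0.03, 0.01)
#' tn["PV", "MLS", "MLS"]   # t3
#' tn["BKG", "MLS", "MLS"]  # t1
#' @export
build_connectivity_tensor <- function(t1 = 0.05, t2 = 0.03, t3 = 0.01) {
  if (any(c(t1, t2, t3) < 0)) stop("penalties must be >= 0", call. = FALSE)
  T <- array(0, c(3, 3, 3), dimnames = list(CLASS_NAMES, CLASS_NAMES,
                                            CLASS_NAMES))
  # homogeneous pure pairs
  T[BKG, MLS, MLS] <- t1
  T[PV,  MLS, MLS] <- t3
  T[MLS, BKG, BKG] <- t1
  T[PV,  BKG, BKG] <- t3
  # mixed pure pair, symmetrized over (k1, k2)
  T[MLS, MLS, BKG] <- T[MLS, BKG, MLS] <- t2
  T[BKG, MLS, BKG] <- T[BKG, BKG, MLS] <- t2
  # pairs involving PV stay 0
  structure(T, class = c("connectivity_tensor", "array"),
            penalties = c(t1 = t1, t2 = t2, t3 = t3))
}

#' 26-neighborhood system with inverse-distance weights
#'
#' The 26 offsets of the 3x3x3 cube around a voxel, each weighted by
#' `1 / d`, `d` the Euclidean distance to the neighbor in mm (so face, edge
#' and corner neighbors differ, and anisotropic grids make the three face
#' distances unequal).
#'
#' @param spacing_mm voxel spacing used for the distances.
#' @return list with `offsets` (26 x 3 integer matrix) and `weights`
#'   (length 26, `1/d`).
#' @export
neighborhood_system <- function(spacing_mm = c(0.86, 0.86, 1)) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  d <- sqrt((off[, 1] * spacing_mm[1])^2 + (off[, 2] * spacing_mm[2])^2 +
              (off[, 3] * spacing_mm[3])^2)
  list(offsets = off, weights = 1 / d, spacing_mm = spacing_mm)
}

#' Inverse-distance aggregation of neighbor posteriors at one voxel
#'
#' Computes `v_k = sum_j p_jk / d_ij` over the 26-neighborhood of `voxel`.
#' Neighbors outside the grid or outside the ROI contribute zero.
#'
#' @param posteriors 4D array `x, y, z, class` of per-voxel posteriors
#'   (zero outside the ROI).
#' @param neighborhood a [neighborhood_system()].
#' @param voxel integer length-3 voxel index.
#' @param roi optional logical array; `NULL` treats all voxels as inside.
#' @return numeric vector of length `dim(posteriors)[4]`.
#' @export
neighbor_aggregate <- function(posteriors, neighborhood, voxel, roi = NULL) {
  dm <- dim(posteriors)
  K <- dm[4]
  v <- numeric(K)
  for (j in seq_along(neighborhood$weights)) {
    at <- voxel + neighborhood$offsets[j, ]
    if (any(at < 1L) || any(at > dm[1:3])) next
    if (!is.null(roi) && !roi[at[1], at[2], at[3]]) next
    v <- v + posteriors[at[1], at[2], at[3], ] * neighborhood$weights[j]
  }
  v
}

#' MRF energy of one class given aggregated neighborhood probabilities
#'
#' The quadratic form `v' T_k v` of the connectivity tensor: large when a
#' penalized pair of classes is strongly present around the voxel.
#'
#' @param v non-negative length-K vector of aggregated neighbor
#'   probabilities (from [neighbor_aggregate()]).
#' @param tensor a [build_connectivity_tensor()].
#' @param k class index (1 = MLS, 2 = PV, 3 = BKG).
#' @return scalar energy, `>= 0`.
#' @export
mrf_energy <- function(v, tensor, k) {
  if (any(v < 0)) stop("`v` must be non-negative", call. = FALSE)
  Tk <- unclass(tensor)[k, , ]
  as.numeric(t(v) %*% Tk %*% v)
}

#' Spatial prior from MRF energies
#'
#' Softmax of the negative energies over classes; shift-invariant and
#' normalized to 1.
#'
#' @param energies finite numeric vector of per-class energies.
#' @return probability vector of the same length.
#' @export
mrf_prior <- function(energies) {
  if (any(!is.finite(energies))) stop("energies must be finite", call. = FALSE)
  e <- exp(-(energies - min(energies)))
  e / sum(e)
}

# ---- vectorized field versions used inside the EM loop -----------------

# Shift a 3D array by integer offset o: out[i] = a[i + o], zero-filled.
shift_array <- function(a, o) {
  n <- dim(a)
  out <- array(0, n)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (o[ax] >= 0) {
      dst[[ax]] <- seq_len(n[ax] - o[ax])
      src[[ax]] <- dst[[ax]] + o[ax]
    } else {
      dst[[ax]] <- seq(1L - o[ax], n[ax])
      src[[ax]] <- dst[[ax]] + o[ax]
    }
    if (!length(dst[[ax]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# v_k fields for all voxels: list of K 3D arrays.
aggregate_field <- function(P, nbhd) {
  dm <- dim(P)
  K <- dm[4]
  lapply(seq_len(K), function(k) {
    vk <- array(0, dm[1:3])
    Pk <- array(P[, , , k], dm[1:3])
    for (j in seq_along(nbhd$weights)) {
      vk <- vk + shift_array(Pk, nbhd$offsets[j, ]) * nbhd$weights[j]
    }
    vk
  })
}

# Per-voxel MRF prior fields from previous posteriors; list of K arrays.
prior_field <- function(P, nbhd, tensor) {
  dm <- dim(P)
  K <- dm[4]
  V <- aggregate_field(P, nbhd)
  Tn <- unclass(tensor)
  U <- lapply(seq_len(K), function(k) {
    u <- array(0, dm[1:3])
    for (k1 in seq_len(K)) for (k2 in seq_len(K)) {
      if (Tn[k, k1, k2] != 0) u <- u + Tn[k, k1, k2] * V[[k1]] * V[[k2]]
    }
    u
  })
  umin <- Reduce(pmin, U)
  E <- lapply(U, function(u) exp(-(u - umin)))
  es <- Reduce(`+`, E)
  lapply(E, function(e) e / es)
}

#' One mean-field E-step of the GMM-PV-MRF model
#'
#' Updates every voxel's posterior from the Gaussian likelihoods and the MRF
#' spatial prior computed from the previous iteration's posteriors
#' (synchronous mean-field update). Voxels outside the ROI keep posterior 0.
#'
#' @param image a [volume_grid()] or 3D array.
#' @param roi logical array.
#' @param state named list with `mu_mls`, `mu_pv`, `mu_bkg`, `sigma2`.
#' @param posteriors_prev 4D posterior array from the previous iteration.
#' @param tensor a [build_connectivity_tensor()].
#' @param neighborhood a [neighborhood_system()].
#' @return list with `posteriors` (4D array, normalized per ROI voxel) and
#'   `loglik`, the MRF-regularized incomplete-data log-likelihood
#'   `sum_i log sum_k G(y_i; mu_k, sigma) prior_ik`.
#' @export
e_step <- function(image, roi, state, posteriors_prev, tensor, neighborhood) {
  vg <- as_volume_grid(image)
  y <- vg$intensities
  dm <- dim(y)
  prior <- prior_field(posteriors_prev, neighborhood, tensor)
  mu <- c(state$mu_mls, state$mu_pv, state$mu_bkg)
  sdv <- sqrt(state$sigma2)
  num <- vector("list", 3)
  for (k in 1:3) {
    g <- pmax(dnorm(y, mu[k], sdv), 1e-300)
    num[[k]] <- g * prior[[k]]
  }
  den <- Reduce(`+`, num)
  bad <- den == 0 & roi
  if (any(bad)) {
    warning(sum(bad), " voxel(s) underflowed in the E-step; assigned uniform")
    for (k in 1:3) num[[k]][bad] <- 1 / 3
    den[bad] <- 1
  }
  P <- array(0, c(dm, 3))
  for (k in 1:3) {
    pk <- num[[k]] / den
    pk[!roi] <- 0
    P[, , , k] <- pk
  }
  list(posteriors = P, loglik = sum(log(den)[roi]))
}

#' M-step for the constrained class means
#'
#' Solves the 2x2 linear system that maximizes the Gaussian log-likelihood
#' under the constraints that the PV mean is the arithmetic mean of the pure
#' tissue means and that all classes share one variance. With
#' `A_k = sum_i y_i p_ik` and `B_k = sum_i p_ik`:
#' \deqn{(B_{MLS} + B_{PV}/4)\,\mu_{MLS} + (B_{PV}/4)\,\mu_{BKG} = A_{MLS} + A_{PV}/2}
#' \deqn{(B_{PV}/4)\,\mu_{MLS} + (B_{BKG} + B_{PV}/4)\,\mu_{BKG} = A_{BKG} + A_{PV}/2}
#'
#' @inheritParams e_step
#' @param posteriors 4D posterior array.
#' @return named list `mu_mls`, `mu_pv`, `mu_bkg`.
#' @export
m_step_means <- function(image, roi, posteriors) {
  vg <- as_volume_grid(image)
  y <- vg$intensities[roi]
  A <- B <- numeric(3)
  for (k in 1:3) {
    pk <- array(posteriors[, , , k], dim(roi))[roi]
    A[k] <- sum(y * pk)
    B[k] <- sum(pk)
  }
  M <- matrix(c(B[MLS] + B[PV] / 4, B[PV] / 4,
                B[PV] / 4, B[BKG] + B[PV] / 4), 2, 2)
  rhs <- c(A[MLS] + A[PV] / 2, A[BKG] + A[PV] / 2)
  if (rcond(M) < 1e-12) {
    stop("degenerate M-step: posterior mass does not determine both pure-",
         "tissue means (e.g. all mass in the PV class)", call. = FALSE)
  }
  mu <- solve(M, rhs)
  list(mu_mls = mu[1], mu_pv = (mu[1] + mu[2]) / 2, mu_bkg = mu[2])
}

#' M-step for the shared variance
#'
#' The single variance shared by all three classes:
#' `sigma2 = (1/N) sum_l sum_i p_il (y_i - mu_l)^2`, floored at
#' `variance_floor` to prevent collapse on degenerate fits.
#'
#' @inheritParams m_step_means
#' @param means list from [m_step_means()].
#' @param variance_floor small positive scalar.
#' @return scalar `sigma2`.
#' @export
m_step_variance <- function(image, roi, posteriors, means,
                            variance_floor = 1e-12) {
  vg <- as_volume_grid(image)
  y <- vg$intensities[roi]
  mu <- c(means$mu_mls, means$mu_pv, means$mu_bkg)
  s2 <- 0
  for (k in 1:3) {
    pk <- array(posteriors[, , , k], dim(roi))[roi]
    s2 <- s2 + sum(pk * (y - mu[k])^2)
  }
  max(s2 / length(y), variance_floor)
}

#' Percentile initialization of the posteriors
#'
#' Hard-assigns the `init_percentile` percent lowest-intensity ROI voxels to
#' MLS and the rest to BKG; the PV class starts empty. Ties are broken by the
#' (deterministic) linear voxel index.
#'
#' @inheritParams e_step
#' @param init_percentile percentage in (0, 100).
#' @return 4D posterior array (one-hot per ROI voxel, zero outside).
#' @export
initialize_posteriors <- function(image, roi, init_percentile = 6) {
  vg <- as_volume_grid(image)
  n_roi <- sum(roi)
  if (n_roi < 2L) stop("ROI must contain at least 2 voxels", call. = FALSE)
  y <- vg$intensities[roi]
  n_mls <- max(1L, floor(init_percentile / 100 * n_roi))
  ord <- order(y)                      # stable: ties keep voxel order
  P <- array(0, c(dim(vg$intensities), 3))
  idx_roi <- which(roi)
  mls_idx <- idx_roi[ord[seq_len(n_mls)]]
  bkg_idx <- setdiff(idx_roi, mls_idx)
  nvox <- prod(dim(vg$intensities))
  P[mls_idx + (MLS - 1L) * nvox] <- 1
  P[bkg_idx + (BKG - 1L) * nvox] <- 1
  P
}

#' Percentile thresholding baseline
#'
#' The binary mask of the `percentile` percent lowest-intensity ROI voxels —
#' by construction identical to the MLS labels of [initialize_posteriors()].
#'
#' @inheritParams initialize_posteriors
#' @param percentile percentage in (0, 100).
#' @return logical array.
#' @export
run_threshold <- function(image, roi, percentile = 6) {
  P <- initialize_posteriors(image, roi, percentile)
  array(P[, , , MLS] == 1, dim(roi))
}

em_objective_converged <- function(trace, rel_tol) {
  m <- length(trace)
  m >= 2 && abs(trace[m] - trace[m - 1]) / abs(trace[m - 1]) < rel_tol
}

#' Run the GMM-PV-MRF segmenter
#'
#' Full expectation-maximization with the explicit partial-volume class and
#' the connectivity-tensor MRF prior. Starting from the percentile
#' initialization, E- and M-steps are interleaved until the relative change
#' of the objective (the MRF-regularized incomplete-data log-likelihood)
#' falls below `rel_tol` or `max_iter` is reached.
#'
#' @param image a [volume_grid()] or 3D array.
#' @param roi logical array marking the region of interest.
#' @param config an [em_config()].
#' @param spacing_mm spacing used when `image` is a plain array.
#' @return An object of class `mls_em` with elements `posteriors` (4D array,
#'   classes ordered MLS, PV, BKG), `state` (`mu_mls`, `mu_pv`, `mu_bkg`,
#'   `sigma2`), `trace` (objective per iteration), `iterations`, `converged`,
#'   `method`, `config`, `roi` and `image`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 10), seed = 2))
#' fit <- run_em(ph$image, ph$roi, em_config(max_iter = 15))
#' tidy(fit)
#' @export
run_em <- function(image, roi, config = em_config(),
                   spacing_mm = c(0.86, 0.86, 1)) {
  vg <- as_volume_grid(image, spacing_mm)
  run_em_impl(vg, roi, config, method = "gmm-pv-mrf")
}

#' @describeIn run_em the GMM-PV baseline: same three-class constrained
#'   mixture but a uniform spatial prior (all penalties zero).
#' @export
run_gmm_pv <- function(image, roi, config = em_config(),
                       spacing_mm = c(0.86, 0.86, 1)) {
  vg <- as_volume_grid(image, spacing_mm)
  config$t1 <- config$t2 <- config$t3 <- 0
  run_em_impl(vg, roi, config, method = "gmm-pv")
}

run_em_impl <- function(vg, roi, config, method) {
  assert_same_grid(vg$intensities, roi, "image and ROI")
  y <- vg$intensities
  floor_ <- config$variance_floor %||%
    (1e-8 * diff(range(y[roi]))^2)
  if (floor_ <= 0) floor_ <- 1e-12
  tensor <- build_connectivity_tensor(config$t1, config$t2, config$t3)
  nb_spacing <- if (config$distance_units == "mm") vg$spacing_mm else c(1, 1, 1)
  nbhd <- neighborhood_system(nb_spacing)
  P <- initialize_posteriors(vg, roi, config$init_percentile)
  state <- m_step_means(vg, roi, P)
  state$sigma2 <- m_step_variance(vg, roi, P, state, floor_)
  trace <- numeric(0)
  # The percentile initialization is a hard threshold, not a posterior
  # belief: the spatial prior is uniform on the first iteration and the MRF
  # engages once the posteriors are soft.
  tensor_flat <- build_connectivity_tensor(0, 0, 0)
  for (m in seq_len(config$max_iter)) {
    es <- e_step(vg, roi, state, P, if (m == 1L) tensor_flat else tensor,
                 nbhd)
    P <- es$posteriors
    state <- tryCatch(m_step_means(vg, roi, P), error = function(e) {
      stop(sprintf("iteration %d: %s", m, conditionMessage(e)), call. = FALSE)
    })
    state$sigma2 <- m_step_variance(vg, roi, P, state, floor_)
    trace <- c(trace, es$loglik)
    if (em_objective_converged(trace, config$rel_tol)) break
  }
  structure(list(posteriors = P, state = state, trace = trace,
                 iterations = length(trace),
                 converged = em_objective_converged(trace, config$rel_tol),
                 method = method, config = config, roi = roi, image = vg,
                 classes = CLASS_NAMES),
            class = "mls_em")
}

#' @describeIn run_em two-class (MLS, BKG) Gaussian mixture without the PV
#'   class or spatial prior; shared variance, percentile initialization.
#' @export
run_gmm <- function(image, roi, config = em_config(),
                    spacing_mm = c(0.86, 0.86, 1)) {
  vg <- as_volume_grid(image, spacing_mm)
  assert_same_grid(vg$intensities, roi, "image and ROI")
  y <- vg$intensities
  yr <- y[roi]
  floor_ <- config$variance_floor %||% (1e-8 * diff(range(yr))^2)
  if (floor_ <= 0) floor_ <- 1e-12
  P3 <- initialize_posteriors(vg, roi, config$init_percentile)
  p1 <- array(P3[, , , MLS], dim(roi))[roi]
  trace <- numeric(0)
  for (m in seq_len(config$max_iter)) {
    b1 <- sum(p1); b2 <- sum(1 - p1)
    if (b1 == 0 || b2 == 0) {
      stop(sprintf("iteration %d: a class lost all posterior mass", m),
           call. = FALSE)
    }
    mu1 <- sum(yr * p1) / b1
    mu2 <- sum(yr * (1 - p1)) / b2
    s2 <- max((sum(p1 * (yr - mu1)^2) + sum((1 - p1) * (yr - mu2)^2)) /
                length(yr), floor_)
    g1 <- pmax(dnorm(yr, mu1, sqrt(s2)), 1e-300) / 2
    g2 <- pmax(dnorm(yr, mu2, sqrt(s2)), 1e-300) / 2
    p1 <- g1 / (g1 + g2)
    trace <- c(trace, sum(log(g1 + g2)))
    if (em_objective_converged(trace, config$rel_tol)) break
  }
  P <- array(0, c(dim(y), 2))
  tmp <- array(0, dim(y)); tmp[roi] <- p1; P[, , , 1] <- tmp
  tmp <- array(0, dim(y)); tmp[roi] <- 1 - p1; P[, , , 2] <- tmp
  structure(list(posteriors = P,
                 state = list(mu_mls = mu1, mu_bkg = mu2, sigma2 = s2),
                 trace = trace, iterations = length(trace),
                 converged = em_objective_converged(trace, config$rel_tol),
                 method = "gmm", config = config, roi = roi, image = vg,
                 classes = c("MLS", "BKG")),
            class = "mls_em")
}

#' @export
print.mls_em <- function(x, ...) {
  cat("<mls_em> method ", x$method, ", ", x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  mus <- unlist(x$state[startsWith(names(x$state), "mu")])
  cat("  means: ", paste(sprintf("%s = %.4g", names(mus), mus),
                         collapse = ", "),
      "; sigma2 = ", signif(x$state$sigma2, 5), "\n", sep = "")
  invisible(x)
}

#' Segment a volume with any of the compared methods
#'
#' Dispatcher over the proposed model and its baselines, as used in the
#' method-comparison tables: `"threshold"` (percentile cut), `"gmm"`
#' (two-class mixture), `"gmm-pv"` (explicit PV class, uniform prior) and
#' `"gmm-pv-mrf"` (the full model).
#'
#' @inheritParams run_em
#' @param method one of `"threshold"`, `"gmm"`, `"gmm-pv"`, `"gmm-pv-mrf"`.
#' @return For `"threshold"` a logical mask; otherwise an `mls_em` fit.
#' @export
segment <- function(image, roi,
                    method = c("gmm-pv-mrf", "gmm-pv", "gmm", "threshold"),
                    config = em_config(), spacing_mm = c(0.86, 0.86, 1)) {
  method <- match.arg(method)
  switch(method,
         "threshold"  = run_threshold(image, roi, config$init_percentile),
         "gmm"        = run_gmm(image, roi, config, spacing_mm),
         "gmm-pv"     = run_gmm_pv(image, roi, config, spacing_mm),
         "gmm-pv-mrf" = run_em(image, roi, config, spacing_mm))
}

#' Write a fitted posterior map as 4D NIfTI with a JSON sidecar
#'
#' One volume per class in the fixed order MLS, PV, BKG (MLS, BKG for the
#' two-class baseline); the sidecar records the class order, mixture state,
#' objective trace and configuration.
#'
#' @param fit an `mls_em`.
#' @param path output path for the 4D NIfTI (sidecar gets extension
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_posteriors <- function(fit, path) {
  stopifnot(inherits(fit, "mls_em"))
  img <- RNifti::asNifti(fit$posteriors)
  RNifti::pixdim(img) <- c(fit$image$spacing_mm, 1)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(classes = fit$classes, state = fit$state, trace = fit$trace,
         iterations = fit$iterations, converged = fit$converged,
         method = fit$method, config = unclass(fit$config)),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
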