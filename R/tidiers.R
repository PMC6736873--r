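#' Tidy and glance methods
#'
#' broom-style summaries of the fitted objects: `tidy()` returns the
#' estimated quantities one row per term/voxel/subject, `glance()` a one-row
#' model summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return A [tibble::tibble].
#' @name neomyelin-tidiers
NULL

#' @rdname neomyelin-tidiers
#' @export
tidy.mls_em <- function(x, ...) {
  mus <- unlist(x$state[startsWith(names(x$state), "mu")])
  tibble(class = sub("mu_", "", names(mus)) |> toupper(),
         mean = unname(mus), sigma2 = x$state$sigma2)
}

#' @rdname neomyelin-tidiers
#' @export
glance.mls_em <- function(x, ...) {
  tibble(method = x$method, iterations = x$iterations,
         converged = x$converged, objective = x$trace[x$iterations],
         sigma2 = x$state$sigma2, n_roi = sum(x$roi))
}

#' @rdname neomyelin-tidiers
#' @export
tidy.growth_atlas <- function(x, ...) {
  idx <- which(x$status != "outside")
  co <- arrayInd(idx, x$grid_shape)
  tibble(i = co[, 1], j = co[, 2], k_index = co[, 3],
         t0 = x$t0[idx], k = x$k[idx], c = x$c[idx],
         status = x$status[idx], p_const = x$p_const[idx])
}

#' @rdname neomyelin-tidiers
#' @export
glance.growth_atlas <- function(x, ...) {
  st <- x$status
  tibble(n_voxels = length(st),
         n_fitted = sum(st == "fitted"),
         n_constant0 = sum(st == "constant-0"),
         n_constant1 = sum(st == "constant-1"),
         n_failed = sum(st == "failed"),
         ga_start = x$ga_range_weeks[1], ga_end = x$ga_range_weeks[2])
}

#' @rdname neomyelin-tidiers
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname neomyelin-tidiers
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(model = x$model, a = x$a, b = x$b, r2 = x$r2, n = nrow(x$data))
}

#' @rdname neomyelin-tidiers
#' @export
glance.ga_loo <- function(x, ...) {
  tibble(n = nrow(x), rmse_weeks = attr(x, "rmse_weeks"),
         grid_step = attr(x, "grid_step"))
}

#' @rdname neomyelin-tidiers
#' @export
glance.mls_comparison <- function(x, ...) {
  per <- attr(x, "per_subject")
  tibble(n_subjects = length(unique(per$subject)),
         n_methods = length(unique(per$method)),
         reference = attr(x, "reference"))
}
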