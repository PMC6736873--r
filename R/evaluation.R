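#' Dice overlap between two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`. When both masks are empty the overlap is
#' defined as 1 (needed for early-gestation volumes that contain no MLS).
#'
#' @param a,b logical (or 0/1) arrays on the same grid.
#' @return scalar in \[0, 1\].
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, , ] <- TRUE
#' dice(m, m)
#' @export
dice <- function(a, b) {
  assert_same_grid(a, b, "masks")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Compare segmentation methods on a cohort of phantoms
#'
#' Runs each method on every phantom, scores the final MLS mask against the
#' phantom ground truth with Dice, and reports mean ± sd per method together
#' with paired two-tailed t-tests of each method against a reference method
#' (reporting plumbing in the style of the method-comparison tables).
#'
#' @param phantoms list of `mls_phantom` objects (>= 2).
#' @param methods character vector of methods understood by [segment()].
#' @param reference the method the others are tested against.
#' @param config an [em_config()] shared by all methods.
#' @return A [tibble::tibble] with columns `method`, `mean_dice`, `sd_dice`,
#'   `mean_diff` (reference minus method) and `p_value`; per-subject scores
#'   are attached as attribute `"per_subject"` and via [tidy()].
#' @export
compare_methods <- function(phantoms,
                            methods = c("threshold", "gmm", "gmm-pv",
                                        "gmm-pv-mrf"),
                            reference = "gmm-pv-mrf",
                            config = em_config()) {
  if (length(phantoms) < 2L) {
    stop("at least 2 phantom subjects are required", call. = FALSE)
  }
  if (!reference %in% methods) methods <- c(methods, reference)
  per <- purrr::map_dfr(seq_along(phantoms), function(i) {
    ph <- phantoms[[i]]
    truth <- truth_mask(ph)
    purrr::map_dfr(methods, function(m) {
      res <- segment(ph$image, ph$roi, method = m, config = config)
      mask <- if (is.logical(res)) res else finalize_mls(res)$mask
      tibble(subject = i, method = m, dice = dice(mask, truth))
    })
  })
  ref_dice <- per$dice[per$method == reference]
  summary <- per |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_dice = mean(.data$dice),
                     sd_dice = sd(.data$dice), .groups = "drop") |>
    dplyr::mutate(
      mean_diff = purrr::map_dbl(.data$method, function(m) {
        mean(ref_dice - per$dice[per$method == m])
      }),
      p_value = purrr::map_dbl(.data$method, function(m) {
        d <- ref_dice - per$dice[per$method == m]
        if (all(d == 0)) return(1)   # identical outputs: no difference
        t.test(d)$p.value            # paired two-tailed, 5% convention
      })) |>
    dplyr::arrange(match(.data$method, methods))
  out <- structure(summary, per_subject = per, reference = reference)
  class(out) <- c("mls_comparison", class(summary))
  out
}

#' @export
tidy.mls_comparison <- function(x, ...) attr(x, "per_subject")
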