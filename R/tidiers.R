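#' Tidiers for Gaussian fits and bimodality results
#'
#' broom-style accessors: `tidy()` returns one row per mixture component,
#' `glance()` a one-row model summary, and `augment()` (for bimodality fits)
#' the per-sample values with mode assignments and ON-mode posteriors.
#'
#' @param x a `gmm_fit` or `bimodality_fit`.
#' @param ... unused.
#' @return A tibble.
#' @name switchscan-tidiers
NULL

#' @rdname switchscan-tidiers
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k_components),
                 mode = if (x$k_components == 2L) c("low", "high") else "all",
                 weight = x$weights, mean = x$means, variance = x$variances,
                 sd = sqrt(x$variances))
}

#' @rdname switchscan-tidiers
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(k_components = x$k_components, log_likelihood = x$log_likelihood,
                 n_params = x$n_params, aic = x$aic, n = x$n,
                 converged = x$converged, variance_floored = x$floored)
}

#' @rdname switchscan-tidiers
#' @export
tidy.bimodality_fit <- function(x, ...) {
  tidy.gmm_fit(x$fit2)
}

#' @rdname switchscan-tidiers
#' @export
glance.bimodality_fit <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, delta_aic = x$delta_aic,
                 aic_1 = x$fit1$aic, aic_2 = x$fit2$aic, n_used = x$n_used,
                 weight_high = x$fit2$weights[2L],
                 kurtosis = x$kurtosis, mixture_separation = x$mixture_separation,
                 em_converged = x$fit2$converged)
}

#' @rdname switchscan-tidiers
#' @export
augment.bimodality_fit <- function(x, ...) {
  obs <- !is.na(x$values)
  post <- rep(NA_real_, length(x$values))
  post[obs] <- x$posterior_high
  tibble::tibble(sample = seq_along(x$values), value = x$values,
                 mode = x$mode_assignment, posterior_high = post)
}
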