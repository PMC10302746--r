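#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the model-order evidence table
#'
#' @param x An `nmr_evidence` object.
#' @param ... Unused.
#' @return A tibble with columns `K`, `free_energy`, `posterior`.
#' @export
tidy.nmr_evidence <- function(x, ...) x$table

#' One-row summary of a model-order selection
#'
#' @param x An `nmr_evidence` object.
#' @param ... Unused.
#' @return A tibble with `k_map`, its posterior probability, and the free
#'   energy gap to the runner-up model.
#' @export
glance.nmr_evidence <- function(x, ...) {
  tab <- x$table
  best <- which.max(tab$posterior)
  tibble::tibble(
    k_map = tab$K[best],
    posterior_k_map = tab$posterior[best],
    free_energy_gap = min(tab$free_energy[-best]) - tab$free_energy[best]
  )
}

#' Tidy posterior draws into long format
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return A tibble with columns `.draw`, `component`, `parameter`, `value`.
#' @export
tidy.posterior_draws <- function(x, ...) {
  d <- tibble::as_tibble(as.data.frame(x$draws))
  d$.draw <- seq_len(nrow(d))
  out <- tidyr::pivot_longer(d, -".draw", names_to = "name",
                             values_to = "value")
  out <- tidyr::separate(out, "name", into = c("parameter", "component"),
                         sep = "_")
  out$component <- as.integer(out$component)
  out[, c(".draw", "component", "parameter", "value")]
}

#' One-row summary of posterior draws
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return A tibble with the number of draws, K, and the maximum log
#'   posterior density.
#' @export
glance.posterior_draws <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$draws), K = x$K,
    max_log_posterior = max(x$log_posterior)
  )
}

#' Tidy a full deconvolution result
#'
#' @param x An `nmr_deconvolution` object.
#' @param ... Unused.
#' @return The per-component summary tibble (MAP and credible intervals), or
#'   a zero-row tibble when the pure-noise model was selected.
#' @export
tidy.nmr_deconvolution <- function(x, ...) {
  if (is.null(x$summary)) {
    return(tibble::tibble(component = integer(), parameter = character(),
                          map = numeric(), lower = numeric(),
                          upper = numeric(), level = numeric()))
  }
  x$summary
}

#' One-row summary of a full deconvolution
#'
#' @param x An `nmr_deconvolution` object.
#' @param ... Unused.
#' @return A tibble with the selected K, its posterior probability, and the
#'   plug-in noise level.
#' @export
glance.nmr_deconvolution <- function(x, ...) {
  g <- glance.nmr_evidence(x$evidence)
  g$noise_sigma <- x$config$noise_sigma
  g
}
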