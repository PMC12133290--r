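#' Broom-style tidiers and plots
#'
#' `tidy()` returns per-unit tibbles (optimizer history, per-individual
#' scores, per-SNP responses), `glance()` one-row model summaries, and
#' `autoplot()` quick ggplot2 diagnostics.
#'
#' @param x a `beacon_reconstruction`, `recon_evaluation`,
#'   `beacon_response` or `becn_experiment` object.
#' @param ... unused, for generic consistency.
#' @name generics-tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname generics-tidiers
#' @export
tidy.beacon_reconstruction <- function(x, ...) x$history

#' @rdname generics-tidiers
#' @export
glance.beacon_reconstruction <- function(x, ...) {
  last <- utils::tail(x$history, 1L)
  tibble::tibble(
    n = nrow(x$genotypes), m_prime = ncol(x$genotypes), mode = x$mode,
    iterations = x$iterations, converged = x$converged,
    l_corr = last$l_corr, l_mse = last$l_mse, flips = last$flips,
    n_known = length(x$known_rows), seed = x$config$seed
  )
}

#' @rdname generics-tidiers
#' @export
tidy.recon_evaluation <- function(x, ...) {
  tibble::tibble(
    individual = seq_along(x$per_individual_f1),
    matched_row = x$row_assignment,
    f1 = x$per_individual_f1
  )
}

#' @rdname generics-tidiers
#' @export
glance.recon_evaluation <- function(x, ...) {
  tibble::tibble(
    precision = x$precision, recall = x$recall, f1 = x$f1,
    frobenius_gap = x$frobenius_gap,
    tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, match = x$match
  )
}

#' @rdname generics-tidiers
#' @param object a fitted object (for `autoplot()` methods).
#' @export
autoplot.beacon_reconstruction <- function(object, ...) {
  h <- tidy(object)
  long <- tibble::tibble(
    iter = rep(h$iter, 3),
    metric = rep(c("l_corr", "l_mse", "flips"), each = nrow(h)),
    value = c(h$l_corr, h$l_mse, h$flips)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "outer alternation", y = NULL,
                  title = "Reconstruction attack trajectory") +
    ggplot2::theme_minimal()
}

#' @rdname generics-tidiers
#' @export
autoplot.becn_experiment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$n), y = .data$f1,
                               colour = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_grid(ggplot2::vars(.data$mode),
                        ggplot2::vars(.data$m_prime),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "beacon size N", y = "F1",
                  title = "Reconstruction performance across the grid") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
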