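#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-individual diagnostics of a co-segregation result
#'
#' @param x a `coseg_lr` from [compute_lr()].
#' @param ... unused.
#' @return A tibble with one row per pedigree member: observed genotype,
#'   log-likelihood contributions under the carrier and noncarrier
#'   hypotheses, and the posterior carrier probability under the
#'   pathogenic model.
#' @method tidy coseg_lr
#' @export
tidy.coseg_lr <- function(x, ...) x$per_individual

#' One-row summary of a co-segregation result
#'
#' @param x a `coseg_lr`.
#' @param ... unused.
#' @return A one-row tibble: `lr`, `log_numerator`, `log_denominator`,
#'   `n_configs`, and the analysis settings.
#' @method glance coseg_lr
#' @export
glance.coseg_lr <- function(x, ...) {
  s <- x$settings
  tibble::tibble(lr = x$lr, log_numerator = x$log_numerator,
                 log_denominator = x$log_denominator,
                 n_configs = x$n_configs, gene = s$gene,
                 population = s$population, mode = s$mode,
                 allele_frequency = s$allele_frequency,
                 family_id = s$family_id)
}

#' @rdname tidy.coseg_lr
#' @method tidy pen_fit
#' @export
tidy.pen_fit <- function(x, ...) {
  tibble::tibble(term = c("r", "mu", "sigma"),
                 estimate = c(x$params$r, x$params$mu, x$params$sigma))
}

#' @rdname glance.coseg_lr
#' @method glance pen_fit
#' @export
glance.pen_fit <- function(x, ...) {
  tibble::tibble(r = x$params$r, mu = x$params$mu, sigma = x$params$sigma,
                 sse = x$sse, n_intervals = x$n_intervals,
                 at_bound = x$at_bound, convergence = x$convergence)
}

#' Plot a fitted penetrance curve against the incidence data
#'
#' @param object a `pen_fit` from [fit_penetrance()].
#' @param ... unused.
#' @return A ggplot: observed interval rates (steps) and the fitted
#'   smooth hazard.
#' @method autoplot pen_fit
#' @export
autoplot.pen_fit <- function(object, ...) {
  tab <- object$data
  grid <- seq(min(tab$age_start), max(tab$age_end), length.out = 200)
  fitted <- pen_curve(object$params, grid)
  obs <- tibble::tibble(
    age = c(rbind(tab$age_start, tab$age_end)),
    rate = rep(tab$rate, each = 2))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = obs,
                       ggplot2::aes(x = .data$age, y = .data$rate),
                       colour = "grey40") +
    ggplot2::geom_line(data = fitted,
                       ggplot2::aes(x = .data$t, y = .data$h),
                       colour = "#B2182B", linewidth = 0.8) +
    ggplot2::labs(x = "age (years)", y = "incidence rate (per person-year)",
                  title = sprintf("scaled truncated-normal hazard fit: r = %.3g, mu = %.3g, sigma = %.3g",
                                  object$params$r, object$params$mu,
                                  object$params$sigma)) +
    ggplot2::theme_minimal()
}

#' Likelihood ratio as a function of one member's age
#'
#' Recomputes the pedigree LR over a grid of ages for one individual
#' under a chosen affection status and genotype — the standard what-if
#' sweep for judging how the evidence depends on a single relative.
#' For `affected = TRUE` the member is given a first breast cancer at
#' each grid age (and censored there); for `affected = FALSE` the member
#' is unaffected and censored at each grid age.
#'
#' @param ped a `coseg_pedigree`.
#' @param id member to sweep.
#' @param ages numeric grid of ages in years.
#' @param affected logical affection status at each age.
#' @param genotype "carrier", "noncarrier" or "untested".
#' @param ... passed to [compute_lr()].
#' @return A `coseg_lr_curve`: tibble with columns `age` and `lr`,
#'   plottable with [autoplot()].
#' @export
lr_by_age <- function(ped, id, ages = 20:85, affected = TRUE,
                      genotype = "carrier", ...) {
  stopifnot(inherits(ped, "coseg_pedigree"))
  lr <- vapply(ages, function(a) {
    p <- update_member(ped, id, censor_age = a,
                       bc1_age = if (affected) a else NA_real_,
                       bc2_age = NA_real_,
                       genotype = genotype)
    compute_lr(p, ...)$lr
  }, numeric(1))
  structure(tibble::tibble(age = ages, lr = lr),
            id = id, affected = affected, genotype = genotype,
            class = c("coseg_lr_curve", class(tibble::tibble())))
}

#' @rdname lr_by_age
#' @param object a `coseg_lr_curve`.
#' @method autoplot coseg_lr_curve
#' @export
autoplot.coseg_lr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$lr)) +
    ggplot2::geom_line(colour = "#2166AC", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("age of '%s' (years)", attr(object, "id")),
                  y = "likelihood ratio",
                  title = sprintf("%s, %s",
                                  if (attr(object, "affected")) "affected" else "unaffected",
                                  attr(object, "genotype"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
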