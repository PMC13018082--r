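#' Age-specific penetrance curves from scaled truncated-normal models
#'
#' A penetrance curve describes the cumulative probability `F(t)` that a
#' person (a pathogenic-variant carrier, or a member of the general
#' population) develops a given cancer by age `t`. The curve is modelled as
#' a normal distribution of age at onset, truncated at age 0 and
#' renormalised on `[0, Inf)`, scaled by the lifetime risk `r`:
#' `F(t) = r * F0(t; mu, sigma)` where `F0` is the truncated-normal CDF.
#' The survival, density and hazard follow as `S = 1 - F`, `f = r * f0`,
#' `h = f / S`.
#'
#' @param r lifetime cumulative risk, in (0, 1).
#' @param mu mean age at onset in years, in (0, 130).
#' @param sigma standard deviation of age at onset in years, > 0.
#' @param gene,cancer,sex,carrier_status,population optional metadata
#'   labels carried along for bookkeeping.
#' @return An object of class `pen_params`.
#' @examples
#' p <- pen_params(r = 0.6, mu = 55, sigma = 15)
#' pen_curve(p, c(0, 45, 70))
#' @export
pen_params <- function(r, mu, sigma, gene = NA_character_,
                       cancer = NA_character_, sex = NA_character_,
                       carrier_status = NA_character_,
                       population = NA_character_) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0 || r >= 1) {
    stop_coseg("`r` (lifetime risk) must be a single number in (0, 1)")
  }
  if (!is.numeric(mu) || mu <= 0 || mu >= 130) {
    stop_coseg("`mu` (mean age at onset) must be in (0, 130) years")
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop_coseg("`sigma` must be > 0")
  }
  structure(
    list(r = as.numeric(r), mu = as.numeric(mu), sigma = as.numeric(sigma),
         gene = gene, cancer = cancer, sex = sex,
         carrier_status = carrier_status, population = population),
    class = "pen_params"
  )
}

#' @export
print.pen_params <- function(x, ...) {
  cat(sprintf("<pen_params> r = %.4g, mu = %.4g y, sigma = %.4g y\n",
              x$r, x$mu, x$sigma))
  meta <- unlist(x[c("gene", "cancer", "sex", "carrier_status", "population")])
  meta <- meta[!is.na(meta)]
  if (length(meta)) cat("  ", paste(names(meta), meta, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# truncated-normal (at 0) CDF and density, vectorised in t
tnorm_cdf <- function(t, mu, sigma) {
  z0 <- pnorm(0, mu, sigma)
  out <- (pnorm(t, mu, sigma) - z0) / (1 - z0)
  out[t <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

tnorm_pdf <- function(t, mu, sigma) {
  z0 <- pnorm(0, mu, sigma)
  out <- dnorm(t, mu, sigma) / (1 - z0)
  out[t < 0] <- 0
  out
}

# inverse truncated-normal CDF (for simulation)
tnorm_quantile <- function(p, mu, sigma) {
  z0 <- pnorm(0, mu, sigma)
  qnorm(z0 + p * (1 - z0), mu, sigma)
}

#' Evaluate a penetrance curve
#'
#' Returns the cumulative risk `F`, survival `S`, density `f` and hazard `h`
#' of the scaled truncated-normal penetrance model at the requested ages.
#'
#' @param params a [pen_params] object.
#' @param t ages in years (vectorised), `t >= 0`.
#' @return A tibble with columns `t`, `F`, `S`, `f`, `h`.
#' @export
pen_curve <- function(params, t) {
  stopifnot(inherits(params, "pen_params"))
  if (any(t < 0)) stop_coseg("ages must be non-negative")
  Ft <- params$r * tnorm_cdf(t, params$mu, params$sigma)
  ft <- params$r * tnorm_pdf(t, params$mu, params$sigma)
  St <- 1 - Ft
  tibble::tibble(t = t, F = Ft, S = St, f = ft, h = ft / St)
}

# log-scale survival and density (numerically safer for deep tails)
pen_log_S <- function(params, t) log1p(-params$r * tnorm_cdf(t, params$mu, params$sigma))

pen_log_f <- function(params, t) {
  log(params$r) + dnorm(t, params$mu, params$sigma, log = TRUE) -
    log1p(-pnorm(0, params$mu, params$sigma))
}

#' Constant-hazard model for contralateral breast cancer
#'
#' Contralateral breast cancer (CBC) is modelled conditionally on the first
#' breast cancer: the waiting time from first BC to CBC has constant hazard
#' `rate`, i.e. density `f(u) = rate * exp(-rate * u)` and survival
#' `S(u) = exp(-rate * u)`, where `u` is years since the first diagnosis.
#'
#' @param rate constant CBC hazard per year since first BC, > 0.
#' @param lifetime_cap optional probability bound in (0, 1]; informational.
#' @param gene,carrier_status optional metadata labels.
#' @return An object of class `cbc_model`.
#' @export
cbc_model <- function(rate, lifetime_cap = NULL, gene = NA_character_,
                      carrier_status = NA_character_) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop_coseg("CBC `rate` must be a single number > 0")
  }
  structure(list(rate = as.numeric(rate), lifetime_cap = lifetime_cap,
                 gene = gene, carrier_status = carrier_status),
            class = "cbc_model")
}

#' @export
print.cbc_model <- function(x, ...) {
  cat(sprintf("<cbc_model> constant hazard %.4g / year since first BC\n", x$rate))
  invisible(x)
}

cbc_log_f <- function(model, u) log(model$rate) - model$rate * u
cbc_log_S <- function(model, u) -model$rate * u

check_incidence_table <- function(table, what = "incidence table") {
  need <- c("age_start", "age_end", "rate")
  if (!all(need %in% names(table))) {
    stop_coseg(sprintf("%s must have columns %s", what,
                       paste(need, collapse = ", ")))
  }
  if (nrow(table) == 0L) stop_coseg(sprintf("%s is empty", what))
  if (any(table$rate < 0)) stop_coseg(sprintf("%s has negative rates", what))
  if (any(table$age_end <= table$age_start)) {
    stop_coseg(sprintf("%s has empty or reversed age intervals", what))
  }
  tab <- dplyr::arrange(table, .data$age_start)
  if (any(tab$age_start < 0) || any(tab$age_end > 130)) {
    stop_coseg(sprintf("%s ages must lie in [0, 130]", what))
  }
  if (nrow(tab) > 1L &&
      any(tab$age_start[-1] < tab$age_end[-nrow(tab)] - 1e-9)) {
    stop_coseg(sprintf("%s has overlapping age intervals", what))
  }
  tab
}

#' Carrier incidence rates from population rates and relative risks
#'
#' Age-specific carrier incidence is constructed by multiplying
#' general-population incidence rates by published age-specific relative
#' risks. The two tables may be binned on different age grids: the product
#' is computed on the refined grid formed by the union of interval
#' boundaries. Ages not covered by the relative-risk table get RR = 1.
#'
#' @param population_rates tibble with columns `age_start`, `age_end`,
#'   `rate` (events per person-year).
#' @param relative_risks tibble with columns `age_start`, `age_end`, `rr`.
#' @return A tibble with columns `age_start`, `age_end`, `rate` on the
#'   refined grid covering the population table's age range.
#' @export
carrier_incidence <- function(population_rates, relative_risks) {
  pop <- check_incidence_table(population_rates, "population rate table")
  if (!all(c("age_start", "age_end", "rr") %in% names(relative_risks))) {
    stop_coseg("relative-risk table must have columns age_start, age_end, rr")
  }
  if (any(relative_risks$rr < 0)) stop_coseg("relative risks must be >= 0")
  rr <- dplyr::arrange(relative_risks, .data$age_start)
  if (max(rr$age_end) <= min(pop$age_start) ||
      min(rr$age_start) >= max(pop$age_end)) {
    stop_coseg("population and relative-risk tables cover disjoint age ranges")
  }
  cuts <- sort(unique(c(pop$age_start, pop$age_end, rr$age_start, rr$age_end)))
  cuts <- cuts[cuts >= min(pop$age_start) & cuts <= max(pop$age_end)]
  starts <- head(cuts, -1)
  ends <- tail(cuts, -1)
  mids <- (starts + ends) / 2
  pop_idx <- findInterval(mids, pop$age_start)
  covered <- pop_idx >= 1 & mids < pop$age_end[pmax(pop_idx, 1)]
  if (!all(covered)) {
    # gaps inside the population grid carry no rate information; drop them
    starts <- starts[covered]; ends <- ends[covered]; mids <- mids[covered]
    pop_idx <- pop_idx[covered]
  }
  rr_idx <- findInterval(mids, rr$age_start)
  rr_val <- rep(1, length(mids))
  in_rr <- rr_idx >= 1 & mids < rr$age_end[pmax(rr_idx, 1)]
  rr_val[in_rr] <- rr$rr[rr_idx[in_rr]]
  tibble::tibble(age_start = starts, age_end = ends,
                 rate = pop$rate[pop_idx] * rr_val)
}

# sum-of-squares objective between observed rates and model hazard,
# evaluated at interval midpoints and weighted by interval width
pen_fit_objective <- function(par, mids, rates, weights) {
  r <- par[1]; mu <- par[2]; sigma <- par[3]
  Fm <- tnorm_cdf(mids, mu, sigma)
  fm <- tnorm_pdf(mids, mu, sigma)
  h <- r * fm / (1 - r * Fm)
  if (any(!is.finite(h)) || any(h < 0)) return(1e10)
  sum(weights * (rates - h)^2)
}

#' Fit a scaled truncated-normal penetrance model to incidence rates
#'
#' Estimates the lifetime risk `r`, mean onset age `mu` and onset spread
#' `sigma` by least squares between the observed age-specific incidence
#' rates and the model hazard
#' `h(t) = r f0(t; mu, sigma) / (1 - r F0(t; mu, sigma))`,
#' evaluated at interval midpoints with interval-width weights.
#' A deterministic multi-start L-BFGS-B search over a coarse grid of eight
#' starting points guards against local minima.
#'
#' @param table incidence tibble with columns `age_start`, `age_end`, `rate`.
#' @param init optional numeric start `c(r, mu, sigma)` tried in addition
#'   to the default grid of starts.
#' @param bounds list with elements `r`, `mu`, `sigma`, each `c(lower,
#'   upper)`; defaults r in (1e-4, 0.999), mu in (20, 100), sigma in (2, 40).
#' @param ... passed to [stats::optim()].
#' @return A `pen_fit` object: the fitted [pen_params] plus fit
#'   diagnostics (`sse`, `at_bound`, `convergence`, data used).
#' @seealso [synth_incidence()] for the forward generator.
#' @export
fit_penetrance <- function(table, init = NULL,
                           bounds = list(r = c(1e-4, 0.999),
                                         mu = c(20, 100),
                                         sigma = c(2, 40)), ...) {
  tab <- check_incidence_table(table)
  if (nrow(tab) < 4L) stop_coseg("need at least 4 age intervals to fit")
  if (all(tab$rate == 0)) stop_coseg("no events to fit: all rates are zero")
  mids <- (tab$age_start + tab$age_end) / 2
  # rescale so the objective is O(1) regardless of how rare the cancer is;
  # a monotone rescaling leaves the minimiser unchanged but keeps the
  # optimiser's relative stopping rules meaningful
  weights <- (tab$age_end - tab$age_start) / max(tab$rate)^2
  lower <- c(bounds$r[1], bounds$mu[1], bounds$sigma[1])
  upper <- c(bounds$r[2], bounds$mu[2], bounds$sigma[2])
  starts <- as.matrix(expand.grid(r = c(0.05, 0.4),
                                  mu = c(45, 65), sigma = c(8, 20)))
  if (!is.null(init)) starts <- rbind(init, starts)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(pmin(pmax(starts[k, ], lower), upper), pen_fit_objective,
            mids = mids, rates = tab$rate, weights = weights,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e2), ...),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_coseg("penetrance fit failed from every start")
  # derivative-free polish; bound violations are penalised in the objective
  polish <- optim(best$par, function(par) {
    if (any(par < lower) || any(par > upper)) return(1e10)
    pen_fit_objective(par, mids, tab$rate, weights)
  }, method = "Nelder-Mead",
  control = list(maxit = 2000, reltol = 1e-14))
  if (polish$value < best$value) best <- polish
  par <- pmin(pmax(best$par, lower), upper)
  tol <- 1e-6
  at_bound <- any(par <= lower * (1 + tol) + tol) || any(par >= upper * (1 - tol) - tol)
  if (at_bound) {
    rlang::warn("fitted penetrance parameter pinned at an optimisation bound")
  }
  structure(
    list(params = pen_params(par[1], par[2], par[3]),
         sse = best$value, convergence = best$convergence,
         at_bound = at_bound, n_intervals = nrow(tab), data = tab),
    class = "pen_fit"
  )
}

#' @export
print.pen_fit <- function(x, ...) {
  cat("Penetrance fit (scaled truncated-normal hazard, least squares)\n")
  print(x$params)
  cat(sprintf("  SSE = %.3g over %d intervals%s\n", x$sse, x$n_intervals,
              if (x$at_bound) " [parameter at bound]" else ""))
  invisible(x)
}

#' Fit the constant conditional hazard for contralateral breast cancer
#'
#' CBC incidence conditional on a first breast cancer shows no clear trend
#' in time since diagnosis, so the conditional hazard is taken constant.
#' The least-squares constant for piecewise-constant rates is their
#' interval-width-weighted mean.
#'
#' @param conditional_rates tibble with columns `age_start`, `age_end`
#'   (years since first BC) and `rate` (CBC events per person-year).
#' @param ... metadata passed to [cbc_model()].
#' @return A [cbc_model].
#' @export
fit_cbc <- function(conditional_rates, ...) {
  tab <- check_incidence_table(conditional_rates, "conditional CBC rate table")
  if (all(tab$rate == 0)) stop_coseg("no CBC events to fit: all rates are zero")
  w <- tab$age_end - tab$age_start
  cbc_model(sum(w * tab$rate) / sum(w), ...)
}
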