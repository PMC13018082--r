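#' Phenotype likelihood contribution of one individual
#'
#' Computes the log-likelihood of one individual's cancer history under a
#' hypothesised genotype, following the survival formulation: an
#' individual affected by a modelled cancer at age `t` contributes the
#' density `f(t)` for that cancer; an individual free of it until the
#' censoring age `c` contributes the survival `S(c)`. Carriers are
#' evaluated with the carrier curves, noncarriers with the
#' general-population curves. Contralateral breast cancer (CBC) is
#' modelled conditionally on the first breast cancer through a constant
#' hazard in time since the first diagnosis.
#'
#' The `mode` controls how multiple cancers per individual enter the
#' product:
#' \describe{
#'   \item{`all_relevant`}{every modelled cancer is an independent
#'     process: each diagnosis contributes its density at the diagnosis
#'     age and each undiagnosed process its survival at the censoring
#'     age; CBC enters through the conditional constant-hazard model.}
#'   \item{`first_diagnosis`}{follow-up ends at the first gene-related
#'     diagnosis: that cancer contributes its density, every other
#'     process its survival at that age; later events are discarded.}
#'   \item{`first_diagnosis_plus_cbc`}{as `first_diagnosis`, but when the
#'     first diagnosis is a breast cancer the CBC process is retained and
#'     modelled conditionally to the censoring age.}
#'   \item{`legacy_cbc`}{as `all_relevant`, but a BC + CBC pair is scored
#'     with the historical symmetric two-breast term
#'     `f(t1) f(t2) / (4 sqrt(S(t1) S(t2)))` instead of the conditional
#'     model, reproducing the original independent-breasts behaviour.}
#' }
#'
#' Cancers for which the set carries no curve for this gene are not
#' gene-associated and are ignored entirely; males contribute only through
#' male-applicable processes and are uninformative if there are none.
#'
#' @param ind one-row slice of a `coseg_pedigree` (or a list with the same
#'   fields).
#' @param genotype "carrier" or "noncarrier".
#' @param pset a [pen_set] covering the gene.
#' @param gene gene under analysis.
#' @param mode one of `"all_relevant"`, `"first_diagnosis"`,
#'   `"first_diagnosis_plus_cbc"`, `"legacy_cbc"`.
#' @return A list with `loglik` (finite scalar) and `terms`, a tibble
#'   breaking the contribution down per cancer process.
#' @export
individual_contribution <- function(ind, genotype = c("carrier", "noncarrier"),
                                    pset, gene, mode = MODES) {
  genotype <- match.arg(genotype)
  mode <- match.arg(mode)
  status <- if (genotype == "carrier") "carrier" else "population"
  sex <- ind$sex
  cancers <- modeled_cancers(pset, gene, sex)
  terms <- list()
  add <- function(cancer, kind, age, lt) {
    terms[[length(terms) + 1L]] <<- tibble::tibble(
      cancer = cancer, kind = kind, age = age, log_term = lt)
  }
  ages <- c(BC = ind$bc1_age %||% NA_real_, OC = ind$oc_age %||% NA_real_,
            PANC = ind$panc_age %||% NA_real_)
  ages <- ages[names(ages) %in% cancers]
  cbc_age <- ind$bc2_age %||% NA_real_
  censor <- ind$censor_age
  has_bc <- "BC" %in% names(ages) && !is.na(ages[["BC"]])

  if (!is.na(cbc_age) && !has_bc) {
    stop_coseg(sprintf(
      "%s has a CBC event but BC is not modelled for %s (%s)",
      ind$id, gene, sex))
  }

  curve <- function(cancer) {
    p <- pen_lookup(pset, gene, cancer, sex, status)
    if (is.null(p)) {
      stop_coseg(sprintf("no %s %s curve for %s (sex %s) in penetrance set",
                         status, cancer, gene, sex))
    }
    p
  }
  cbc_mod <- function() {
    m <- cbc_lookup(pset, gene, status)
    if (is.null(m)) {
      stop_coseg(sprintf(
        "no %s CBC hazard for %s in penetrance set", status, gene))
    }
    m
  }

  dx_ages <- ages[!is.na(ages)]
  first_dx <- if (length(dx_ages)) min(dx_ages) else NA_real_

  if (mode %in% c("all_relevant", "legacy_cbc")) {
    for (cn in names(ages)) {
      t_dx <- ages[[cn]]
      if (!is.na(t_dx)) {
        if (cn == "BC" && mode == "legacy_cbc" && !is.na(cbc_age)) {
          add("BC+CBC", "legacy_density", t_dx,
              log(legacy_cbc_contribution(t_dx, cbc_age, pset, gene = gene,
                                          sex = sex, carrier_status = status)))
        } else {
          add(cn, "density", t_dx, pen_log_f(curve(cn), t_dx))
        }
      } else {
        add(cn, "survival", censor, pen_log_S(curve(cn), censor))
      }
    }
    if (has_bc && mode == "all_relevant" && nrow(pset$cbc) > 0L) {
      m <- cbc_mod()
      if (!is.na(cbc_age)) {
        add("CBC", "density", cbc_age, cbc_log_f(m, cbc_age - ages[["BC"]]))
      } else {
        add("CBC", "survival", censor, cbc_log_S(m, censor - ages[["BC"]]))
      }
    }
    if (has_bc && mode == "all_relevant" && nrow(pset$cbc) == 0L &&
        !is.na(cbc_age)) {
      stop_coseg(sprintf("no CBC hazard in penetrance set but %s has a CBC",
                         ind$id))
    }
  } else { # first_diagnosis variants
    if (is.na(first_dx)) {
      for (cn in names(ages)) {
        add(cn, "survival", censor, pen_log_S(curve(cn), censor))
      }
    } else {
      for (cn in names(ages)) {
        t_dx <- ages[[cn]]
        if (!is.na(t_dx) && t_dx <= first_dx) {
          add(cn, "density", t_dx, pen_log_f(curve(cn), t_dx))
        } else {
          add(cn, "survival", first_dx, pen_log_S(curve(cn), first_dx))
        }
      }
      bc_first <- has_bc && ages[["BC"]] <= first_dx
      if (mode == "first_diagnosis_plus_cbc" && bc_first &&
          nrow(pset$cbc) > 0L) {
        m <- cbc_mod()
        if (!is.na(cbc_age)) {
          add("CBC", "density", cbc_age, cbc_log_f(m, cbc_age - ages[["BC"]]))
        } else {
          add("CBC", "survival", censor, cbc_log_S(m, censor - ages[["BC"]]))
        }
      }
    }
  }

  if (length(terms) == 0L) {
    return(list(loglik = 0,
                terms = tibble::tibble(cancer = character(),
                                       kind = character(), age = numeric(),
                                       log_term = numeric())))
  }
  terms <- dplyr::bind_rows(terms)
  ll <- sum(terms$log_term)
  if (!is.finite(ll)) {
    stop_coseg(sprintf(
      "non-finite likelihood contribution for %s (curve saturated?)", ind$id))
  }
  list(loglik = ll, terms = terms)
}

#' Historical symmetric contralateral-breast-cancer term
#'
#' The original survival co-segregation model lacked conditional CBC
#' rates and treated the two breasts as independent processes, replacing
#' the first-BC density by
#' `f(t_bc) f(t_cbc) / (4 sqrt(S(t_bc) S(t_cbc)))`
#' where `f` and `S` come from the (single-breast) BC penetrance curve of
#' the hypothesised genotype. Exposed for reproducing that behaviour via
#' the `legacy_cbc` mode.
#'
#' @param t_bc,t_cbc ages at first and contralateral BC, `t_cbc >= t_bc`.
#' @param pset a [pen_set].
#' @param gene gene under analysis.
#' @param sex "F" (or "M" where male BC is modelled).
#' @param carrier_status "carrier" or "population".
#' @return The probability term (positive scalar).
#' @export
legacy_cbc_contribution <- function(t_bc, t_cbc, pset, gene,
                                    sex = "F",
                                    carrier_status = c("carrier", "population")) {
  carrier_status <- match.arg(carrier_status)
  if (t_cbc < t_bc) stop_coseg("t_cbc must be >= t_bc")
  p <- pen_lookup(pset, gene, "BC", sex, carrier_status)
  if (is.null(p)) {
    stop_coseg(sprintf("no %s BC curve for %s in penetrance set",
                       carrier_status, gene))
  }
  e1 <- pen_curve(p, t_bc)
  e2 <- pen_curve(p, t_cbc)
  if (e1$S <= 0 || e2$S <= 0) {
    stop_coseg("BC survival is zero: penetrance curve saturated")
  }
  e1$f * e2$f / (4 * sqrt(e1$S * e2$S))
}

# per-individual log-likelihood under both genotypes, for a whole pedigree
pedigree_loglik_matrix <- function(ped, pset, gene, mode) {
  n <- nrow(ped)
  ll <- matrix(0, n, 2L, dimnames = list(ped$id, c("carrier", "noncarrier")))
  for (i in seq_len(n)) {
    ind <- as.list(ped[i, ])
    ll[i, 1L] <- individual_contribution(ind, "carrier", pset, gene, mode)$loglik
    ll[i, 2L] <- individual_contribution(ind, "noncarrier", pset, gene, mode)$loglik
  }
  ll
}
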