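# penetrance set with BC, OC and a CBC hazard, for multi-cancer cases
multi_pset <- function(lambda_car = 0.02, lambda_pop = 0.004) {
  pen_set(
    tibble::tibble(
      gene = "BRCA1",
      cancer = rep(c("BC", "OC"), each = 2),
      sex = "F",
      carrier_status = rep(c("carrier", "population"), 2),
      r = c(0.6, 0.1, 0.4, 0.015),
      mu = c(50, 62, 55, 65),
      sigma = c(14, 14, 12, 13)),
    cbc = tibble::tibble(gene = "BRCA1",
                         carrier_status = c("carrier", "population"),
                         rate = c(lambda_car, lambda_pop)),
    population = "custom")
}

ind_row <- function(...) {
  ped <- make_ped(id = "x", proband = TRUE, genotype = "carrier", ...)
  as.list(ped[1, ])
}

curve_of <- function(pset, cancer, status) {
  coseglr:::pen_lookup(pset, "BRCA1", cancer, "F", status)
}

test_that("an individual with unknown age contributes probability one", {
  ps <- multi_pset()
  for (g in c("carrier", "noncarrier")) {
    ctr <- individual_contribution(ind_row(censor_age = 0), g, ps, "BRCA1",
                                   "all_relevant")
    expect_equal(ctr$loglik, 0)
  }
})

test_that("multi-cancer modes follow the survival factorisation", {
  ps <- multi_pset()
  ind <- ind_row(bc1_age = 45, oc_age = 60, censor_age = 60)
  bc <- pen_curve(curve_of(ps, "BC", "carrier"), c(45, 60))
  oc <- pen_curve(curve_of(ps, "OC", "carrier"), c(45, 60))

  # all relevant cancers: f_bc(45) * f_ov(60) * S_cbc(60-45)
  all_rel <- individual_contribution(ind, "carrier", ps, "BRCA1",
                                     "all_relevant")
  expect_equal(all_rel$loglik,
               log(bc$f[1]) + log(oc$f[2]) + (-0.02 * (60 - 45)),
               tolerance = 1e-12)

  # first diagnosis: follow-up ends at 45: f_bc(45) * S_ov(45)
  fd <- individual_contribution(ind, "carrier", ps, "BRCA1",
                                "first_diagnosis")
  expect_equal(fd$loglik, log(bc$f[1]) + log(oc$S[1]), tolerance = 1e-12)
})

test_that("conditional CBC density and survival enter the hybrid mode", {
  ps <- multi_pset(lambda_car = 0.02)
  ind <- ind_row(bc1_age = 40, bc2_age = 48, censor_age = 70)
  got <- individual_contribution(ind, "carrier", ps, "BRCA1",
                                 "first_diagnosis_plus_cbc")
  bc <- pen_curve(curve_of(ps, "BC", "carrier"), 40)
  oc <- pen_curve(curve_of(ps, "OC", "carrier"), 40)
  hand <- log(bc$f) + log(0.02) - 0.02 * 8 + log(oc$S)
  expect_equal(got$loglik, hand, tolerance = 1e-12)

  # BC survivor without CBC: exp(-lambda * (censor - t_bc))
  ind2 <- ind_row(bc1_age = 40, censor_age = 70)
  got2 <- individual_contribution(ind2, "carrier", ps, "BRCA1",
                                  "first_diagnosis_plus_cbc")
  expect_equal(got2$loglik, log(bc$f) - 0.02 * 30 + log(oc$S),
               tolerance = 1e-12)

  # the noncarrier hypothesis uses the population CBC hazard
  got3 <- individual_contribution(ind, "noncarrier", ps, "BRCA1",
                                  "first_diagnosis_plus_cbc")
  bcp <- pen_curve(curve_of(ps, "BC", "population"), 40)
  ocp <- pen_curve(curve_of(ps, "OC", "population"), 40)
  expect_equal(got3$loglik, log(bcp$f) + log(0.004) - 0.004 * 8 + log(ocp$S),
               tolerance = 1e-12)
})

test_that("first-diagnosis contributions ignore later events", {
  ps <- multi_pset()
  base <- ind_row(bc1_age = 45, censor_age = 70)
  mutated <- ind_row(bc1_age = 45, oc_age = 60, bc2_age = 55,
                     censor_age = 70)
  for (g in c("carrier", "noncarrier")) {
    expect_equal(
      individual_contribution(base, g, ps, "BRCA1", "first_diagnosis")$loglik,
      individual_contribution(mutated, g, ps, "BRCA1",
                              "first_diagnosis")$loglik)
  }
})

test_that("unaffected contributions are non-increasing in follow-up age", {
  ps <- multi_pset()
  lls <- vapply(seq(0, 90, by = 5), function(a) {
    individual_contribution(ind_row(censor_age = a), "carrier", ps,
                            "BRCA1", "all_relevant")$loglik
  }, numeric(1))
  expect_true(all(diff(lls) <= 1e-12))
})

test_that("identical carrier and population curves equalise the genotype contributions", {
  ps <- pen_set(
    tibble::tibble(gene = "BRCA1", cancer = "BC", sex = "F",
                   carrier_status = c("carrier", "population"),
                   r = 0.3, mu = 55, sigma = 14),
    population = "custom")
  for (ind in list(ind_row(bc1_age = 45, censor_age = 45),
                   ind_row(censor_age = 70))) {
    expect_equal(
      individual_contribution(ind, "carrier", ps, "BRCA1", "all_relevant")$loglik,
      individual_contribution(ind, "noncarrier", ps, "BRCA1", "all_relevant")$loglik)
  }
})

test_that("males without male-applicable cancers are uninformative", {
  ps <- multi_pset()
  ped <- make_ped(id = "m1", sex = "M", censor_age = 80)
  ind <- as.list(ped[1, ])
  for (g in c("carrier", "noncarrier")) {
    expect_equal(individual_contribution(ind, g, ps, "BRCA1",
                                         "all_relevant")$loglik, 0)
  }
})

test_that("the historical symmetric CBC term matches its closed form", {
  ps <- pen_set(
    tibble::tibble(gene = "BRCA1", cancer = "BC", sex = "F",
                   carrier_status = c("carrier", "population"),
                   r = c(0.6, 0.1), mu = c(55, 62), sigma = c(15, 14)),
    population = "custom")
  e45 <- pen_curve(curve_of(ps, "BC", "carrier"), 45)
  e55 <- pen_curve(curve_of(ps, "BC", "carrier"), 55)
  expect_equal(
    legacy_cbc_contribution(45, 55, ps, "BRCA1"),
    e45$f * e55$f / (4 * sqrt(e45$S * e55$S)))
  # simultaneous bilateral diagnosis collapses to f(t)^2 / (4 S(t))
  expect_equal(legacy_cbc_contribution(45, 45, ps, "BRCA1"),
               e45$f^2 / (4 * e45$S))
  expect_gt(legacy_cbc_contribution(30, 80, ps, "BRCA1"), 0)
  expect_error(legacy_cbc_contribution(55, 45, ps, "BRCA1"), "t_cbc")

  ind <- ind_row(bc1_age = 45, bc2_age = 55, censor_age = 60)
  got <- individual_contribution(ind, "carrier", ps, "BRCA1", "legacy_cbc")
  expect_equal(got$loglik,
               log(e45$f * e55$f / (4 * sqrt(e45$S * e55$S))))
})

test_that("carrier-to-population contribution ratio is larger when all cancers count", {
  ps <- multi_pset()
  ind <- ind_row(bc1_age = 42, oc_age = 55, censor_age = 55)
  ratio <- function(mode) {
    individual_contribution(ind, "carrier", ps, "BRCA1", mode)$loglik -
      individual_contribution(ind, "noncarrier", ps, "BRCA1", mode)$loglik
  }
  expect_gt(ratio("all_relevant"), ratio("first_diagnosis"))
})
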