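test_that("founder prior and transmission follow rare-dominant Mendelian rules", {
  expect_equal(founder_prior(1e-4), 2 * 1e-4 * 0.9999)
  expect_equal(founder_prior(0.005), 2 * 0.005 * 0.995)
  qs <- c(1e-5, 1e-4, 1e-3, 9e-3)
  expect_true(all(diff(founder_prior(qs)) > 0))
  expect_error(founder_prior(0.5), "allele frequency")

  expect_equal(transmission_prob(TRUE, FALSE, TRUE), 0.5)
  expect_equal(transmission_prob(FALSE, FALSE, TRUE), 0)
  expect_equal(transmission_prob(TRUE, TRUE, TRUE), 0.75)
  for (fa in c(TRUE, FALSE)) for (mo in c(TRUE, FALSE)) {
    expect_equal(transmission_prob(fa, mo, TRUE) +
                   transmission_prob(fa, mo, FALSE), 1)
  }
})

trio_ped <- function(child_geno = "carrier", mum_geno = "untested") {
  make_ped(id = c("dad", "mum", "kid"),
           father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mum"),
           sex = c("M", "F", "F"), proband = c(FALSE, FALSE, TRUE),
           genotype = c("untested", mum_geno, child_geno),
           censor_age = c(70, 68, 40))
}

test_that("trio enumeration matches a 2^3 brute force", {
  q <- 1e-4
  cfg <- enumerate_configs(trio_ped(), q = q)
  # brute force over all 8 assignments: a carrier child needs a carrier
  # parent, so 3 assignments match the observed genotypes
  expect_equal(nrow(cfg), 3)
  expect_true(all(vapply(cfg$carriers, function(x) "kid" %in% x, logical(1))))

  pf <- 2 * q * (1 - q)
  prior <- function(dad, mum, kid) {
    p_car <- c(0, 0.5, 0.75)[dad + mum + 1]
    (if (dad) pf else 1 - pf) * (if (mum) pf else 1 - pf) *
      (if (kid) p_car else 1 - p_car)
  }
  norm <- prior(TRUE, FALSE, TRUE) + prior(FALSE, TRUE, TRUE) +
    prior(TRUE, TRUE, TRUE)
  expect_equal(sum(exp(cfg$log_prior)), 1)
  got <- sort(exp(cfg$log_prior))
  want <- sort(c(prior(TRUE, FALSE, TRUE), prior(FALSE, TRUE, TRUE),
                 prior(TRUE, TRUE, TRUE)) / norm)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("impossible observed genotypes are rejected", {
  # both parents observed noncarrier but the proband carries the variant
  ped <- make_ped(id = c("dad", "mum", "kid"),
                  father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mum"),
                  sex = c("M", "F", "F"), proband = c(FALSE, FALSE, TRUE),
                  genotype = c("noncarrier", "noncarrier", "carrier"),
                  censor_age = c(70, 68, 40))
  expect_error(enumerate_configs(ped), "inconsistent with Mendelian")
  expect_error(compute_lr(ped, pset = toy_pset()),
               "inconsistent with Mendelian")
})

test_that("LR is exactly 1 when only the proband is genotyped", {
  ped <- random_small_ped(11)
  ped$genotype <- ifelse(ped$proband, "carrier", "untested")
  res <- compute_lr(ped, pset = toy_pset())
  expect_equal(res$lr, 1)
})

test_that("LR is 1 when carrier and population penetrances coincide", {
  ps <- toy_pset(r_car = 0.1, mu_car = 62, s_car = 14,
                 r_pop = 0.1, mu_pop = 62, s_pop = 14)
  for (seed in c(3, 17)) {
    ped <- random_small_ped(seed)
    expect_lt(abs(compute_lr(ped, pset = ps)$lr - 1), 1e-10)
  }
})

test_that("compute_lr matches the exhaustive brute-force oracle", {
  ps <- toy_pset()
  n_checked <- 0
  for (seed in 1:14) {
    ped <- random_small_ped(seed)
    if (nrow(ped) > 10) next
    ll_car <- oracle_bc_loglik(ped, 0.6, 50, 14)
    ll_non <- oracle_bc_loglik(ped, 0.1, 62, 14)
    want <- oracle_lr(ped, 1e-4, ll_car, ll_non)
    got <- compute_lr(ped, pset = ps, mode = "all_relevant",
                      allele_frequency = 1e-4)$lr
    expect_lt(abs(got - want) / want, 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
})

test_that("the LR is invariant to relabeling and row order", {
  ped <- read_canrisk(
    system.file("extdata", "synthetic_fig1_family.canrisk",
                package = "coseglr"))
  ps <- load_penetrance_set("UK")
  base <- compute_lr(ped, pset = ps)$lr

  shuffled <- ped[c(5, 2, 9, 1, 7, 3, 8, 4, 6), ]
  shuffled <- coseglr:::new_pedigree(shuffled, family_id = "FAM1",
                                     gene = "BRCA1")
  expect_equal(compute_lr(shuffled, pset = ps)$lr, base, tolerance = 1e-12)

  relab <- ped
  map <- setNames(paste0("ID", seq_len(nrow(ped))), ped$id)
  relab$id <- unname(map[relab$id])
  relab$father_id <- unname(map[relab$father_id])
  relab$mother_id <- unname(map[relab$mother_id])
  relab <- coseglr:::new_pedigree(relab, family_id = "FAM1", gene = "BRCA1")
  expect_equal(compute_lr(relab, pset = ps)$lr, base, tolerance = 1e-12)
})

test_that("monozygotic twins share one genotype and one transmission term", {
  ped <- make_ped(id = c("dad", "mum", "t1", "t2"),
                  father_id = c(NA, NA, "dad", "dad"),
                  mother_id = c(NA, NA, "mum", "mum"),
                  sex = c("M", "F", "F", "F"),
                  proband = c(FALSE, FALSE, TRUE, FALSE),
                  mz_twin = c(NA, NA, "tw1", "tw1"),
                  genotype = c("untested", "untested", "carrier", "untested"),
                  censor_age = c(70, 68, 40, 40))
  cfg <- enumerate_configs(ped)
  for (cc in cfg$carriers) {
    expect_equal("t1" %in% cc, "t2" %in% cc)
  }
  # identical to the trio: the co-twin adds no free variable
  trio <- enumerate_configs(trio_ped())
  expect_equal(sort(exp(cfg$log_prior)), sort(exp(trio$log_prior)))
})

test_that("consanguineous pedigrees are rejected with a clear error", {
  ped <- make_ped(id = c("gf", "gm", "s1", "s2", "kid"),
                  father_id = c(NA, NA, "gf", "gf", "s1"),
                  mother_id = c(NA, NA, "gm", "gm", "s2"),
                  sex = c("M", "F", "M", "F", "F"),
                  proband = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                  genotype = c(rep("untested", 4), "carrier"),
                  censor_age = c(80, 80, 50, 50, 20))
  expect_error(compute_lr(ped, pset = toy_pset()), "consanguineous")
})

test_that("oversized pedigrees advise trimming instead of exhausting memory", {
  n <- 30
  ids <- c("f0", "m0", paste0("k", 1:n))
  ped <- make_ped(id = ids,
                  father_id = c(NA, NA, rep("f0", n)),
                  mother_id = c(NA, NA, rep("m0", n)),
                  sex = c("M", "F", rep("F", n)),
                  proband = c(FALSE, FALSE, TRUE, rep(FALSE, n - 1)),
                  genotype = c("untested", "untested", "carrier",
                               rep("untested", n - 1)),
                  censor_age = 40)
  expect_error(compute_lr(ped, pset = toy_pset(), max_configs = 2^20),
               "trim_pedigree")
})

test_that("independent families multiply and settings mismatches warn", {
  expect_equal(combine_families(list(2, 3)), 6)
  expect_equal(combine_families(list(4.2, 1)), 4.2)
  x <- 7.3
  expect_lt(abs(combine_families(list(x, 1 / x)) - 1), 1e-12)
  expect_error(combine_families(list()), "no results")

  ped <- random_small_ped(5)
  r1 <- compute_lr(ped, pset = toy_pset(), mode = "all_relevant")
  r2 <- compute_lr(ped, pset = toy_pset(), mode = "first_diagnosis")
  expect_warning(combine_families(list(r1, r2)), "differing settings")
  expect_equal(suppressWarnings(combine_families(list(r1, r2))),
               r1$lr * r2$lr)
})

test_that("ACMG mapping is config-driven with ties going up", {
  expect_equal(lr_to_acmg(1.0), "no_evidence")
  expect_equal(lr_to_acmg(1e6), "PP1_very_strong")
  expect_equal(lr_to_acmg(2.08), "PP1_supporting") # boundary -> higher band
  expect_equal(lr_to_acmg(0.01), "BS4_strong")
  custom <- tibble::tibble(label = c("low", "high"), lower = c(0, 5))
  expect_equal(lr_to_acmg(4.9, custom), "low")
  expect_equal(lr_to_acmg(5, custom), "high")
  bad <- tibble::tibble(label = c("a", "b"), lower = c(1, 5))
  expect_error(lr_to_acmg(2, bad), "cover")
})

test_that("tidy and glance expose the result tables", {
  ped <- random_small_ped(8)
  res <- compute_lr(ped, pset = toy_pset())
  td <- tidy(res)
  expect_equal(nrow(td), nrow(ped))
  expect_true(all(c("ll_carrier", "ll_noncarrier", "posterior_carrier")
                  %in% names(td)))
  expect_true(all(td$posterior_carrier >= 0 & td$posterior_carrier <= 1))
  expect_gte(td$posterior_carrier[td$proband], 1 - 1e-9)
  gl <- glance(res)
  expect_equal(gl$lr, res$lr)
  expect_equal(gl$mode, "first_diagnosis_plus_cbc")
})
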