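# shared fixtures and the independent brute-force oracle used by the
# enumeration / likelihood-ratio tests

# construct a coseg_pedigree directly from member fields
make_ped <- function(..., family_id = "T", gene = "BRCA1") {
  rows <- tibble::tibble(...)
  defaults <- list(name = rows$id, father_id = NA_character_,
                   mother_id = NA_character_, sex = "F", proband = FALSE,
                   mz_twin = NA_character_, dead = FALSE, censor_age = 0,
                   yob = NA_real_, bc1_age = NA_real_, bc2_age = NA_real_,
                   oc_age = NA_real_, panc_age = NA_real_,
                   genotype = "untested")
  for (nm in names(defaults)) {
    if (!nm %in% names(rows)) rows[[nm]] <- defaults[[nm]]
  }
  coseglr:::new_pedigree(rows, family_id = family_id, gene = gene)
}

# toy single-cancer penetrance set: female BC only, no CBC hazard
toy_pset <- function(r_car = 0.6, mu_car = 50, s_car = 14,
                     r_pop = 0.1, mu_pop = 62, s_pop = 14,
                     gene = "BRCA1", cbc = NULL) {
  pen_set(tibble::tibble(
    gene = gene, cancer = "BC", sex = "F",
    carrier_status = c("carrier", "population"),
    r = c(r_car, r_pop), mu = c(mu_car, mu_pop),
    sigma = c(s_car, s_pop)), cbc = cbc, population = "custom")
}

# --- independent oracle ---------------------------------------------------
# direct formulas for the scaled truncated-normal model, written without
# the package's curve helpers
oracle_log_f <- function(t, r, mu, sigma) {
  log(r) + dnorm(t, mu, sigma, log = TRUE) - log(1 - pnorm(0, mu, sigma))
}
oracle_log_S <- function(t, r, mu, sigma) {
  log(1 - r * (pnorm(t, mu, sigma) - pnorm(0, mu, sigma)) /
        (1 - pnorm(0, mu, sigma)))
}

# per-individual log-likelihood for a female-BC-only analysis
oracle_bc_loglik <- function(ped, r, mu, sigma) {
  vapply(seq_len(nrow(ped)), function(i) {
    if (ped$sex[i] != "F") return(0)
    if (!is.na(ped$bc1_age[i])) {
      oracle_log_f(ped$bc1_age[i], r, mu, sigma)
    } else {
      oracle_log_S(ped$censor_age[i], r, mu, sigma)
    }
  }, numeric(1))
}

# exhaustive 2^n likelihood-ratio computation: plain loops, own Mendelian
# table, natural-scale sums
oracle_lr <- function(ped, q, ll_car, ll_non) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  pf <- 2 * q * (1 - q)
  num_all <- 0; num_cons <- 0; den_all <- 0; den_cons <- 0
  for (code in 0:(2^n - 1)) {
    g <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!g[which(ped$proband)]) next
    prior <- 1
    for (i in seq_len(n)) {
      if (is.na(fa[i])) {
        prior <- prior * if (g[i]) pf else 1 - pf
      } else {
        k <- g[fa[i]] + g[mo[i]]
        p_car <- c(0, 0.5, 0.75)[k + 1]
        prior <- prior * if (g[i]) p_car else 1 - p_car
      }
    }
    if (prior == 0) next
    lik <- exp(sum(ifelse(g, ll_car, ll_non)))
    cons <- TRUE
    for (i in seq_len(n)) {
      if (ped$genotype[i] == "carrier" && !g[i]) cons <- FALSE
      if (ped$genotype[i] == "noncarrier" && g[i]) cons <- FALSE
    }
    num_all <- num_all + prior * lik
    den_all <- den_all + prior
    if (cons) {
      num_cons <- num_cons + prior * lik
      den_cons <- den_cons + prior
    }
  }
  (num_cons / num_all) / (den_cons / den_all)
}

# small random pedigree via the package generator (topology only is
# reused; the oracle recomputes everything else)
random_small_ped <- function(seed, model = "pathogenic", pset = toy_pset()) {
  spec <- sim_spec(pset = pset, model = model, n_children = 2,
                   sibship_lambda = 1, genotype_prob = 0.7, seed = seed)
  simulate_pedigree(spec)
}
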