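#' Specification for simulating a test pedigree
#'
#' Bundles the generator settings used by [simulate_pedigree()]: a
#' three-generation nuclear topology (a founder couple, their children
#' with married-in spouses, and grandchildren), the true penetrance
#' curves, whether phenotypes are generated under the pathogenic model
#' (carriers follow carrier curves) or the benign model (everyone follows
#' population curves, so genotype and phenotype are independent), and the
#' observation process (genotyping probability, censoring-age range).
#'
#' @param gene gene label for the generated pedigree.
#' @param pset true [pen_set] used to draw cancer ages.
#' @param model "pathogenic" or "benign".
#' @param allele_frequency founder allele frequency.
#' @param n_children number of generation-2 children of the founder
#'   couple.
#' @param sibship_lambda Poisson mean for generation-3 sibship sizes
#'   (per generation-2 couple), truncated at 3 so the family stays within
#'   the exact-enumeration budget.
#' @param genotype_prob probability that a member's true genotype is
#'   observed (the proband is always observed).
#' @param censor_range range of the uniform censoring-age draw, years.
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(gene = "BRCA1", pset = NULL,
                     model = c("pathogenic", "benign"),
                     allele_frequency = 1e-4,
                     n_children = 2, sibship_lambda = 1.5,
                     genotype_prob = 0.8, censor_range = c(35, 85),
                     seed = NULL) {
  model <- match.arg(model)
  if (allele_frequency <= 0) {
    stop_coseg("cannot condition on a carrier proband with q = 0")
  }
  assert_prob(genotype_prob, "genotype_prob")
  structure(list(gene = gene, pset = pset, model = model,
                 allele_frequency = allele_frequency,
                 n_children = n_children, sibship_lambda = sibship_lambda,
                 genotype_prob = genotype_prob, censor_range = censor_range,
                 seed = seed),
            class = "sim_spec")
}

# draw an age at onset from a scaled truncated-normal curve; NA if the
# lifetime indicator says never affected or onset falls after censoring
draw_onset <- function(params, censor) {
  if (runif(1) >= params$r) return(NA_real_)
  t <- tnorm_quantile(runif(1), params$mu, params$sigma)
  if (t <= censor) t else NA_real_
}

#' Simulate a pedigree with known truth
#'
#' Generates a three-generation family, samples a genotype configuration
#' from the Mendelian prior conditioned on the proband being a carrier
#' (by enumeration, so the conditioning is exact), draws cancer histories
#' from the true penetrance curves — per genotype under the pathogenic
#' model, from the population curves for everyone under the benign model —
#' including contralateral breast cancer from the conditional
#' constant-hazard model, applies censoring, and masks genotypes per the
#' genotyping probability. The result is a regular `coseg_pedigree`,
#' writable with [write_canrisk()].
#'
#' Under the benign model the likelihood ratio computed from such
#' replicates has expectation 1 (it is a likelihood ratio evaluated on
#' data drawn from its denominator model), which is the basis of the
#' null-calibration checks.
#'
#' @param spec a [sim_spec].
#' @return A `coseg_pedigree` with attribute `true_genotype` (named
#'   character vector of the simulated truth).
#' @export
simulate_pedigree <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
  }
  pset <- spec$pset %||% load_penetrance_set("UK", gene = spec$gene)

  # --- topology -------------------------------------------------------
  rows <- list()
  add <- function(id, father = NA_character_, mother = NA_character_,
                  sex = NULL) {
    rows[[id]] <<- list(id = id, father_id = father, mother_id = mother,
                        sex = sex %||% sample(c("F", "M"), 1L))
  }
  add("gm", sex = "F"); add("gf", sex = "M")
  n_kids <- max(1L, spec$n_children)
  gen2 <- character(0)
  for (i in seq_len(n_kids)) {
    kid <- sprintf("c%d", i)
    add(kid, father = "gf", mother = "gm")
    gen2 <- c(gen2, kid)
  }
  gen3 <- character(0)
  for (kid in gen2) {
    n_g3 <- min(rpois(1L, spec$sibship_lambda), 3L)
    if (n_g3 > 0L) {
      sp <- paste0(kid, "sp")
      add(sp, sex = if (rows[[kid]]$sex == "F") "M" else "F")
      for (j in seq_len(n_g3)) {
        gid <- sprintf("%sg%d", kid, j)
        fa <- if (rows[[kid]]$sex == "M") kid else sp
        mo <- if (rows[[kid]]$sex == "F") kid else sp
        add(gid, father = fa, mother = mo)
        gen3 <- c(gen3, gid)
      }
    }
  }
  proband <- if (length(gen3)) gen3[[1L]] else gen2[[1L]]
  rows[[proband]]$sex <- "F"

  ped <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  n <- nrow(ped)
  ped <- tibble::tibble(
    id = ped$id, name = ped$id,
    father_id = ped$father_id, mother_id = ped$mother_id, sex = ped$sex,
    proband = ped$id == proband,
    mz_twin = NA_character_, dead = FALSE,
    censor_age = round(runif(n, spec$censor_range[1], spec$censor_range[2])),
    yob = NA_real_, bc1_age = NA_real_, bc2_age = NA_real_,
    oc_age = NA_real_, panc_age = NA_real_,
    genotype = "untested")
  ped <- new_pedigree(ped, family_id = "SIM", gene = spec$gene)

  # --- genotypes: exact draw from the prior given a carrier proband ---
  cfg <- enumerate_configs_latent(ped, spec$allele_frequency)
  w <- exp(cfg$log_prior - max(cfg$log_prior))
  pick <- sample.int(length(w), 1L, prob = w)
  carriers <- cfg$carriers[[pick]]
  truth <- ifelse(ped$id %in% carriers, "carrier", "noncarrier")
  names(truth) <- ped$id

  # --- phenotypes -----------------------------------------------------
  for (i in seq_len(n)) {
    status <- if (spec$model == "pathogenic" && truth[i] == "carrier") {
      "carrier"
    } else "population"
    cens <- ped$censor_age[i]
    for (cn in modeled_cancers(pset, spec$gene, ped$sex[i])) {
      p <- pen_lookup(pset, spec$gene, cn, ped$sex[i], status)
      t_dx <- draw_onset(p, cens)
      if (!is.na(t_dx)) {
        t_dx <- max(1, round(t_dx))
        col <- c(BC = "bc1_age", OC = "oc_age", PANC = "panc_age")[[cn]]
        ped[[col]][i] <- t_dx
      }
    }
    if (!is.na(ped$bc1_age[i]) && nrow(pset$cbc) > 0L) {
      m <- cbc_lookup(pset, spec$gene, status)
      if (!is.null(m)) {
        wait <- rexp(1L, m$rate)
        if (ped$bc1_age[i] + wait <= cens) {
          ped$bc2_age[i] <- round(ped$bc1_age[i] + wait)
          ped$bc2_age[i] <- max(ped$bc2_age[i], ped$bc1_age[i])
        }
      }
    }
    ev <- c(ped$bc1_age[i], ped$bc2_age[i], ped$oc_age[i], ped$panc_age[i])
    ped$censor_age[i] <- max(cens, ev[!is.na(ev)], 0)
  }

  # --- observation process -------------------------------------------
  seen <- runif(n) < spec$genotype_prob
  seen[ped$proband] <- TRUE
  ped$genotype <- ifelse(seen, truth, "untested")
  attr(ped, "true_genotype") <- truth
  ped
}

# enumeration over all latent genotypes, proband forced carrier but other
# observed genotypes ignored (used for sampling the simulation truth)
enumerate_configs_latent <- function(ped, q) {
  tmp <- ped
  tmp$genotype <- ifelse(tmp$proband, "carrier", "untested")
  enumerate_configs(tmp, q)
}

#' Generate a synthetic incidence-rate table from penetrance parameters
#'
#' Forward model for the penetrance fit: tabulates the model hazard
#' `h(t) = r f0(t) / (1 - r F0(t))` at interval midpoints, optionally with
#' multiplicative log-normal noise. A noiseless table is recovered
#' exactly (up to optimiser tolerance) by [fit_penetrance()].
#'
#' @param params a [pen_params].
#' @param bins vector of interval boundaries, e.g. `seq(20, 90, by = 5)`.
#' @param noise_sd standard deviation of the log-normal multiplicative
#'   noise (0 = noiseless).
#' @param seed optional seed for the noise draw.
#' @return An incidence tibble with columns `age_start`, `age_end`, `rate`.
#' @export
synth_incidence <- function(params, bins = seq(20, 90, by = 5),
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "pen_params"), length(bins) >= 2L)
  bins <- sort(bins)
  mids <- (head(bins, -1) + tail(bins, -1)) / 2
  rate <- pen_curve(params, mids)$h
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) {
        get(".Random.seed", .GlobalEnv)
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    rate <- rate * exp(stats::rnorm(length(rate), 0, noise_sd))
  }
  tibble::tibble(age_start = head(bins, -1), age_end = tail(bins, -1),
                 rate = rate)
}
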