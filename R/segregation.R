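#' Founder carrier prior for a rare dominant variant
#'
#' Under Hardy–Weinberg with allele frequency `q`, a founder is a
#' heterozygous carrier with probability `2q(1-q)`. Homozygous carriers
#' are collapsed into the carrier state: for the rare variants
#' (`q < 0.01`) this model targets, their probability is negligible.
#'
#' @param q variant allele frequency, in (0, 0.01).
#' @return Carrier probability for one founder.
#' @examples
#' founder_prior(1e-4) # 1.9998e-4
#' @export
founder_prior <- function(q) {
  if (!is.numeric(q) || any(q <= 0) || any(q >= 0.01)) {
    stop_coseg("allele frequency q must lie in (0, 0.01)")
  }
  2 * q * (1 - q)
}

#' Mendelian transmission probability of the carrier state
#'
#' Probability that a child is a carrier given the carrier states of its
#' two parents, for a rare dominant variant with carriers treated as
#' heterozygous: no carrier parent gives 0, one gives 1/2, and two carrier
#' parents give 3/4 (the child is a carrier unless it inherits neither
#' allele).
#'
#' @param father_carrier,mother_carrier logical (vectorised).
#' @param child_carrier logical (vectorised); the probability returned is
#'   for this state.
#' @return Transmission probability in \[0, 1\].
#' @export
transmission_prob <- function(father_carrier, mother_carrier, child_carrier) {
  p_car <- c(0, 0.5, 0.75)[father_carrier + mother_carrier + 1L]
  ifelse(child_carrier, p_car, 1 - p_car)
}

# pedigree indices shared by enumeration and LR computation
ped_structure <- function(ped, q) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  if (has_parent_cycle(ped)) {
    stop_coseg("parent links contain a cycle", class = "coseg_validation_error")
  }
  if (has_consanguinity(ped)) {
    stop_coseg(paste("consanguineous mating detected: genotype enumeration",
                     "over inbred pedigrees is not supported"),
               class = "coseg_validation_error")
  }
  founder <- is.na(fa) & is.na(mo)
  # MZ-twin groups share one genotype variable and one transmission term
  grp <- ifelse(is.na(ped$mz_twin), paste0(".solo.", ped$id), ped$mz_twin)
  grp_id <- match(grp, unique(grp))
  primary <- !duplicated(grp_id)
  # transmission is counted once per MZ group (for its primary member)
  trans_members <- which(!founder & primary)
  # a twin group split across founder/non-founder would be malformed
  for (g in unique(grp_id[duplicated(grp_id)])) {
    mem <- which(grp_id == g)
    if (length(unique(founder[mem])) > 1L) {
      stop_coseg("MZ-twin group mixes founders and non-founders")
    }
  }
  obs <- ped$genotype
  proband <- which(ped$proband)
  if (length(proband) != 1L) {
    stop_coseg("pedigree must have exactly one proband",
               class = "coseg_validation_error")
  }
  if (obs[proband] != "carrier") {
    stop_coseg("proband must carry the variant",
               class = "coseg_validation_error")
  }
  list(n = n, fa = fa, mo = mo, founder = founder, grp_id = grp_id,
       primary = primary, trans_members = trans_members,
       free_idx = which(primary), obs = obs, proband = proband,
       p_founder = founder_prior(q))
}

# assignment chunk: logical matrix (configs x members) for free-variable
# codes `codes` (0-based integers over 2^k free variables)
chunk_assignments <- function(codes, st) {
  k <- length(st$free_idx)
  Afree <- matrix(FALSE, length(codes), k)
  for (b in seq_len(k)) {
    Afree[, b] <- bitwAnd(codes, bitwShiftL(1L, b - 1L)) > 0L
  }
  A <- Afree[, st$grp_id, drop = FALSE]
  colnames(A) <- NULL
  A
}

# unnormalised log prior of each row of assignment matrix A
chunk_log_prior <- function(A, st) {
  lp <- rep(0, nrow(A))
  lpf <- log(st$p_founder); lnf <- log1p(-st$p_founder)
  for (j in which(st$founder & st$primary)) {
    lp <- lp + ifelse(A[, j], lpf, lnf)
  }
  for (j in st$trans_members) {
    pr <- transmission_prob(A[, st$fa[j]], A[, st$mo[j]], A[, j])
    lp <- lp + log(pr)
  }
  lp
}

chunk_consistent <- function(A, st) {
  ok <- rep(TRUE, nrow(A))
  for (j in which(st$obs != "untested")) {
    ok <- ok & (A[, j] == (st$obs[j] == "carrier"))
  }
  ok
}

#' Enumerate genotype configurations consistent with a pedigree
#'
#' Walks every assignment of the carrier state to the pedigree members
#' that (i) matches all observed genotypes, including the proband being a
#' carrier, and (ii) has nonzero probability under founder priors and
#' Mendelian transmission. Log priors are normalised over all
#' nonzero-probability configurations in which the proband is a carrier,
#' so that, conditional on the proband's carrier status, the returned and
#' unreturned configurations together sum to one.
#'
#' @param ped a `coseg_pedigree`.
#' @param q variant allele frequency (founder prior `2q(1-q)`).
#' @param max_configs cap on `2^k` over the `k` free genotype variables;
#'   larger pedigrees raise an error advising [trim_pedigree()].
#' @return A tibble with one row per consistent configuration: `config_id`,
#'   `carriers` (list column of carrier ids) and `log_prior`.
#' @export
enumerate_configs <- function(ped, q = 1e-4, max_configs = 2^20) {
  st <- ped_structure(ped, q)
  k <- length(st$free_idx)
  if (2^k > max_configs) {
    stop_coseg(sprintf(
      paste("pedigree has %d free genotype variables (%g configurations,",
            "cap %g); consider trim_pedigree() to drop uninformative",
            "branches"), k, 2^k, max_configs),
      class = "coseg_enumeration_error")
  }
  codes <- seq_len(2^k) - 1L
  A <- chunk_assignments(codes, st)
  lp <- chunk_log_prior(A, st)
  carrier_proband <- A[, st$proband] & is.finite(lp)
  norm <- logsumexp(lp[carrier_proband])
  keep <- carrier_proband & chunk_consistent(A, st)
  if (!any(keep)) {
    stop_coseg("observed genotypes inconsistent with Mendelian transmission",
               class = "coseg_enumeration_error")
  }
  tibble::tibble(
    config_id = seq_len(sum(keep)),
    carriers = lapply(which(keep), function(r) ped$id[A[r, ]]),
    log_prior = lp[keep] - norm
  )
}

#' Co-segregation likelihood ratio of a pedigree
#'
#' Computes the likelihood ratio comparing the probability of the observed
#' family genotypes given the phenotypes under the pathogenic hypothesis
#' (carriers follow carrier penetrance curves, noncarriers the
#' general-population curves) against the benign hypothesis (phenotypes
#' independent of genotype). Both probabilities condition on the proband
#' being a carrier. The numerator is obtained by Bayes inversion over all
#' Mendelian genotype configurations:
#' `P(G_obs | Ph) = sum over consistent configs of P(Ph|c) P(c) / sum over
#' all configs of P(Ph|c) P(c)`; the denominator is the prior mass of the
#' consistent configurations. LR > 1 favours pathogenicity.
#'
#' The enumeration is exact (no peeling approximation) and is evaluated in
#' log space in chunks, so memory stays bounded for pedigrees up to the
#' configuration cap.
#'
#' @param ped a `coseg_pedigree` (see [read_canrisk()]).
#' @param pset a [pen_set]; defaults to the bundled set for `population`.
#' @param gene gene under analysis; defaults to the pedigree's gene
#'   attribute.
#' @param mode multiple-cancer handling; see [individual_contribution()].
#'   Default `"first_diagnosis_plus_cbc"`.
#' @param allele_frequency variant allele frequency for founder priors.
#' @param population bundled penetrance set to load when `pset` is `NULL`.
#' @param max_configs enumeration cap (default `2^26`).
#' @return A `coseg_lr` object with elements `lr`, `log_numerator`,
#'   `log_denominator`, `n_configs`, `settings` and `per_individual`
#'   (tibble of per-member log-likelihood contributions and posterior
#'   carrier probabilities under the pathogenic hypothesis). Supports
#'   [tidy()] and [glance()].
#' @export
compute_lr <- function(ped, pset = NULL, gene = NULL,
                       mode = c("first_diagnosis_plus_cbc", "all_relevant",
                                "first_diagnosis", "legacy_cbc"),
                       allele_frequency = 1e-4, population = "UK",
                       max_configs = 2^26) {
  stopifnot(inherits(ped, "coseg_pedigree"))
  mode <- match.arg(mode)
  gene <- gene %||% attr(ped, "gene")
  if (is.null(pset)) pset <- load_penetrance_set(population, gene = gene)
  st <- ped_structure(ped, allele_frequency)
  k <- length(st$free_idx)
  if (2^k > max_configs) {
    stop_coseg(sprintf(
      paste("pedigree has %d free genotype variables (%g configurations,",
            "cap %g); consider trim_pedigree() to drop uninformative",
            "branches"), k, 2^k, max_configs),
      class = "coseg_enumeration_error")
  }
  ll <- pedigree_loglik_matrix(ped, pset, gene, mode)

  chunk_bits <- min(k, 16L)
  n_chunks <- 2^(k - chunk_bits)
  acc <- list(prior_all = -Inf, prior_cons = -Inf,
              post_all = -Inf, post_cons = -Inf,
              n_cons = 0L, n_all = 0L,
              post_carrier = rep(-Inf, st$n))
  for (ch in seq_len(n_chunks)) {
    codes <- (ch - 1L) * 2L^chunk_bits + seq_len(2L^chunk_bits) - 1L
    A <- chunk_assignments(as.integer(codes), st)
    lp <- chunk_log_prior(A, st)
    base <- A[, st$proband] & is.finite(lp)
    if (!any(base)) next
    ph <- as.vector(A %*% ll[, 1L] + (!A) %*% ll[, 2L])
    cons <- base & chunk_consistent(A, st)
    lpost <- lp + ph
    acc$prior_all <- lse_pair(acc$prior_all, logsumexp(lp[base]))
    acc$post_all <- lse_pair(acc$post_all, logsumexp(lpost[base]))
    acc$prior_cons <- lse_pair(acc$prior_cons, logsumexp(lp[cons]))
    acc$post_cons <- lse_pair(acc$post_cons, logsumexp(lpost[cons]))
    acc$n_cons <- acc$n_cons + sum(cons)
    acc$n_all <- acc$n_all + sum(base)
    for (j in seq_len(st$n)) {
      sel <- base & A[, j]
      if (any(sel)) {
        acc$post_carrier[j] <- lse_pair(acc$post_carrier[j],
                                        logsumexp(lpost[sel]))
      }
    }
  }
  if (acc$n_cons == 0L) {
    stop_coseg("observed genotypes inconsistent with Mendelian transmission",
               class = "coseg_enumeration_error")
  }
  log_num <- acc$post_cons - acc$post_all
  log_den <- acc$prior_cons - acc$prior_all
  per_ind <- tibble::tibble(
    id = ped$id,
    genotype = ped$genotype,
    proband = ped$proband,
    ll_carrier = ll[, 1L],
    ll_noncarrier = ll[, 2L],
    posterior_carrier = exp(acc$post_carrier - acc$post_all)
  )
  structure(
    list(lr = exp(log_num - log_den),
         log_numerator = log_num, log_denominator = log_den,
         n_configs = acc$n_cons, n_configs_total = acc$n_all,
         settings = list(gene = gene, population = pset$population,
                         mode = mode, allele_frequency = allele_frequency,
                         family_id = attr(ped, "family_id")),
         per_individual = per_ind),
    class = "coseg_lr"
  )
}

#' @export
print.coseg_lr <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Co-segregation LR = %.4g\n", x$lr))
  cat(sprintf("  family %s | gene %s | population %s | mode %s | q = %g\n",
              s$family_id, s$gene, s$population, s$mode, s$allele_frequency))
  cat(sprintf("  %d consistent / %d total genotype configurations\n",
              x$n_configs, x$n_configs_total))
  invisible(x)
}

#' Combine likelihood ratios from independent families
#'
#' Families segregating the same variant contribute independent evidence:
#' their likelihood ratios multiply. A warning is raised if the results
#' were produced under differing settings (gene, population, mode or
#' allele frequency).
#'
#' @param results a list of `coseg_lr` objects (or bare positive numbers).
#' @return The combined LR (positive scalar).
#' @export
combine_families <- function(results) {
  if (length(results) == 0L) stop_coseg("no results to combine")
  if (is.numeric(results)) results <- as.list(results)
  lrs <- vapply(results, function(r) {
    if (inherits(r, "coseg_lr")) r$lr else as.numeric(r)
  }, numeric(1))
  if (any(!is.finite(lrs)) || any(lrs <= 0)) {
    stop_coseg("all LRs must be positive and finite")
  }
  keys <- lapply(results, function(r) {
    if (inherits(r, "coseg_lr")) {
      r$settings[c("gene", "population", "mode", "allele_frequency")]
    } else NULL
  })
  keys <- keys[!vapply(keys, is.null, logical(1))]
  if (length(keys) > 1L && !all(vapply(keys, identical, logical(1), keys[[1]]))) {
    rlang::warn("combining families analysed under differing settings")
  }
  exp(sum(log(lrs)))
}

#' Convert a likelihood ratio to an ACMG/AMP co-segregation evidence label
#'
#' Maps an LR onto the configured strength bands for the PP1
#' (co-segregation with disease) and BS4 (lack of segregation) evidence
#' codes. The bands are entirely configuration-driven: a table of labels
#' with lower LR bounds, covering (0, Inf). An LR exactly at a cut-point
#' is assigned to the higher interval.
#'
#' @param lr positive likelihood ratio.
#' @param thresholds a data frame with columns `label` and `lower`
#'   (ascending, first `lower` must be 0), or the path to a YAML file with
#'   a `thresholds` list; defaults to the bundled Tavtigian-style bands.
#' @return The matching label (character scalar).
#' @export
lr_to_acmg <- function(lr, thresholds = NULL) {
  if (!is.numeric(lr) || length(lr) != 1L || !is.finite(lr) || lr <= 0) {
    stop_coseg("`lr` must be a single positive number")
  }
  if (is.null(thresholds)) {
    thresholds <- system.file("extdata", "acmg_thresholds.yaml",
                              package = "coseglr", mustWork = TRUE)
  }
  if (is.character(thresholds)) {
    cfg <- yaml::read_yaml(thresholds)
    thresholds <- dplyr::bind_rows(lapply(cfg$thresholds, tibble::as_tibble))
  }
  thresholds <- tibble::as_tibble(thresholds)
  stopifnot(all(c("label", "lower") %in% names(thresholds)))
  thresholds <- dplyr::arrange(thresholds, .data$lower)
  if (thresholds$lower[1] != 0) {
    stop_coseg("threshold intervals must cover (0, Inf): first lower bound must be 0")
  }
  if (anyDuplicated(thresholds$lower)) {
    stop_coseg("threshold intervals overlap: duplicate lower bounds")
  }
  i <- findInterval(lr, thresholds$lower) # lr == cut-point -> higher interval
  thresholds$label[i]
}
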