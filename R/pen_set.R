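#' Penetrance sets: all curves needed for one analysis
#'
#' A penetrance set bundles, per gene, the age-specific penetrance curves
#' for carriers and for the general population, for every cancer type
#' modelled for that gene, plus the conditional contralateral-breast-cancer
#' (CBC) hazards. The benign hypothesis evaluates every individual with the
#' general-population curves, so for every carrier curve the matching
#' population curve must be present.
#'
#' @param curves tibble with columns `gene`, `cancer` (one of BC, OC,
#'   PANC), `sex` ("F" or "M"), `carrier_status` ("carrier" or
#'   "population"), `r`, `mu`, `sigma`.
#' @param cbc tibble with columns `gene`, `carrier_status`, `rate`
#'   (constant CBC hazard per year since first BC); may be empty or `NULL`
#'   if CBC is not modelled.
#' @param population label: one of "NL", "UK", "US", "legacy-NL", "custom".
#' @param provenance free-text description of where the parameters come from.
#' @return An object of class `pen_set`.
#' @export
pen_set <- function(curves, cbc = NULL, population = "custom",
                    provenance = "") {
  need <- c("gene", "cancer", "sex", "carrier_status", "r", "mu", "sigma")
  if (!all(need %in% names(curves))) {
    stop_coseg(sprintf("`curves` must have columns %s",
                       paste(need, collapse = ", ")))
  }
  curves <- tibble::as_tibble(curves)
  if (!all(curves$cancer %in% setdiff(CANCERS, "CBC"))) {
    stop_coseg("curve `cancer` must be one of BC, OC, PANC (CBC goes in `cbc`)")
  }
  if (!all(curves$carrier_status %in% c("carrier", "population"))) {
    stop_coseg("`carrier_status` must be 'carrier' or 'population'")
  }
  if (!all(curves$sex %in% c("F", "M"))) stop_coseg("`sex` must be 'F' or 'M'")
  if (anyDuplicated(curves[, c("gene", "cancer", "sex", "carrier_status")])) {
    stop_coseg("duplicate (gene, cancer, sex, carrier_status) curve")
  }
  for (i in seq_len(nrow(curves))) {
    pen_params(curves$r[i], curves$mu[i], curves$sigma[i]) # validates ranges
  }
  carr <- dplyr::filter(curves, .data$carrier_status == "carrier")
  for (i in seq_len(nrow(carr))) {
    hit <- dplyr::filter(curves, .data$carrier_status == "population",
                         .data$gene == carr$gene[i],
                         .data$cancer == carr$cancer[i],
                         .data$sex == carr$sex[i])
    if (nrow(hit) == 0L) {
      stop_coseg(sprintf(
        "carrier curve %s/%s/%s has no matching general-population curve",
        carr$gene[i], carr$cancer[i], carr$sex[i]))
    }
  }
  if (is.null(cbc)) {
    cbc <- tibble::tibble(gene = character(), carrier_status = character(),
                          rate = numeric())
  }
  cbc <- tibble::as_tibble(cbc)
  if (nrow(cbc) > 0L) {
    stopifnot(all(c("gene", "carrier_status", "rate") %in% names(cbc)))
    if (any(cbc$rate <= 0)) stop_coseg("CBC rates must be > 0")
    for (g in unique(cbc$gene[cbc$carrier_status == "carrier"])) {
      if (!any(cbc$carrier_status == "population" & cbc$gene == g)) {
        stop_coseg(sprintf(
          "carrier CBC hazard for %s has no matching population hazard", g))
      }
    }
  }
  structure(list(curves = curves, cbc = cbc, population = population,
                 provenance = provenance),
            class = "pen_set")
}

#' @export
print.pen_set <- function(x, ...) {
  cat(sprintf("<pen_set> population %s: %d curves, %d CBC hazards\n",
              x$population, nrow(x$curves), nrow(x$cbc)))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n")
  print(x$curves, n = Inf)
  invisible(x)
}

# curve lookup; NULL if the (gene, cancer, sex, status) curve is absent
pen_lookup <- function(pset, gene, cancer, sex, carrier_status) {
  hit <- which(pset$curves$gene == gene & pset$curves$cancer == cancer &
               pset$curves$sex == sex &
               pset$curves$carrier_status == carrier_status)
  if (length(hit) == 0L) return(NULL)
  row <- pset$curves[hit[1], ]
  pen_params(row$r, row$mu, row$sigma, gene = gene, cancer = cancer,
             sex = sex, carrier_status = carrier_status,
             population = pset$population)
}

cbc_lookup <- function(pset, gene, carrier_status) {
  hit <- which(pset$cbc$gene == gene &
               pset$cbc$carrier_status == carrier_status)
  if (length(hit) == 0L) return(NULL)
  cbc_model(pset$cbc$rate[hit[1]], gene = gene,
            carrier_status = carrier_status)
}

# cancers modelled for a gene and sex in this set (CBC handled separately)
modeled_cancers <- function(pset, gene, sex) {
  cur <- dplyr::filter(pset$curves, .data$gene == !!gene, .data$sex == !!sex)
  unique(cur$cancer)
}

#' Load a bundled or user-supplied penetrance set
#'
#' Bundled sets are shipped as human-readable YAML files, one per reference
#' population (`"NL"`, `"UK"`, `"US"`, and `"legacy-NL"` for the historical
#' high-risk parameters used by the original survival co-segregation
#' model). The bundled files are synthetic illustrative parameter sets
#' assembled from widely cited literature risk figures; their provenance
#' field says so. Users supply their own fitted sets via `source_config`.
#'
#' @param population one of "NL", "UK", "US", "legacy-NL"; ignored when
#'   `source_config` is given.
#' @param gene optional gene; when given, the loaded set is checked to
#'   contain curves for it.
#' @param source_config path to a YAML file with the same layout as the
#'   bundled ones.
#' @return A [pen_set].
#' @export
load_penetrance_set <- function(population = c("UK", "NL", "US", "legacy-NL"),
                                gene = NULL, source_config = NULL) {
  if (is.null(source_config)) {
    avail <- c("UK", "NL", "US", "legacy-NL")
    population <- as.character(population[1])
    if (!population %in% avail) {
      stop_coseg(sprintf("unknown population '%s'; available: %s",
                         population, paste(avail, collapse = ", ")))
    }
    fname <- sprintf("penetrance/synthetic_%s.yaml",
                     gsub("-", "_", population))
    source_config <- system.file("extdata", fname, package = "coseglr",
                                 mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(source_config)
  curves <- dplyr::bind_rows(lapply(cfg$curves, tibble::as_tibble))
  cbc <- if (length(cfg$cbc)) {
    dplyr::bind_rows(lapply(cfg$cbc, tibble::as_tibble))
  } else NULL
  pset <- pen_set(curves, cbc,
                  population = cfg$population %||% "custom",
                  provenance = cfg$provenance %||% "")
  if (!is.null(gene)) {
    if (!gene %in% pset$curves$gene) {
      stop_coseg(sprintf("penetrance set '%s' has no curves for gene %s",
                         pset$population, gene))
    }
  }
  pset
}

#' Write a penetrance set to a YAML config file
#'
#' @param pset a [pen_set].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_penetrance_set <- function(pset, path) {
  stopifnot(inherits(pset, "pen_set"))
  cfg <- list(
    population = pset$population,
    provenance = pset$provenance,
    curves = lapply(seq_len(nrow(pset$curves)),
                    function(i) as.list(pset$curves[i, ])),
    cbc = lapply(seq_len(nrow(pset$cbc)),
                 function(i) as.list(pset$cbc[i, ]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
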