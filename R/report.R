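#' Run a full co-segregation analysis and write result artifacts
#'
#' End-to-end driver behind the command-line front end: reads a CanRisk
#' pedigree, validates it, optionally trims uninformative young branches,
#' computes the likelihood ratio, and writes a machine-readable JSON
#' result plus a plain-text report. Nothing is transmitted or retained
#' anywhere except the requested output directory. Outputs carry no
#' timestamps, so identical inputs give byte-identical files.
#'
#' @param pedigree path to a CanRisk pedigree file.
#' @param gene "BRCA1", "BRCA2" or "PALB2".
#' @param population "UK", "NL", "US", "legacy-NL", or the path of a
#'   custom penetrance YAML config.
#' @param mode multiple-cancer handling; the default
#'   `"first_diagnosis_plus_cbc"` ends follow-up at the first diagnosis
#'   but keeps contralateral breast cancer (note that expert-panel
#'   guidance aligns with plain `"first_diagnosis"`).
#' @param allele_frequency variant allele frequency.
#' @param trim drop unaffected, untested leaf branches younger than 20
#'   before analysis.
#' @param thresholds optional ACMG thresholds config (see [lr_to_acmg()]);
#'   `NULL` uses the bundled bands.
#' @param out_dir output directory; created if absent. Writes
#'   `result.json` and `report.txt`.
#' @return The `coseg_lr` result, invisibly.
#' @export
run_coseg <- function(pedigree, gene = "BRCA1", population = "UK",
                      mode = "first_diagnosis_plus_cbc",
                      allele_frequency = 1e-4, trim = FALSE,
                      thresholds = NULL, out_dir = ".") {
  gene <- match.arg(gene, GENES)
  ped <- read_canrisk(pedigree, gene = gene)
  findings <- validate_pedigree(ped)
  trimmed <- character(0)
  if (trim) {
    ped <- trim_pedigree(ped)
    trimmed <- attr(ped, "trimmed_ids")
  }
  pset <- if (file.exists(population)) {
    load_penetrance_set(source_config = population, gene = gene)
  } else {
    load_penetrance_set(population, gene = gene)
  }
  res <- compute_lr(ped, pset = pset, gene = gene, mode = mode,
                    allele_frequency = allele_frequency)
  acmg <- lr_to_acmg(res$lr, thresholds)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  payload <- list(
    lr = res$lr,
    log_numerator = res$log_numerator,
    log_denominator = res$log_denominator,
    n_configs = res$n_configs,
    acmg = acmg,
    settings = res$settings,
    per_individual = res$per_individual,
    warnings = findings$message[findings$level == "warning"],
    trimmed = trimmed,
    penetrance_provenance = pset$provenance
  )
  jsonlite::write_json(payload, file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(payload, ped), file.path(out_dir, "report.txt"))
  invisible(res)
}

format_report <- function(payload, ped) {
  s <- payload$settings
  fmt_age <- function(x) ifelse(is.na(x), "-", format(x))
  member_rows <- sprintf(
    "  %-10s %-3s %-10s BC:%-4s CBC:%-4s OC:%-4s PANC:%-4s censored:%s",
    ped$id, ped$sex, ped$genotype, fmt_age(ped$bc1_age),
    fmt_age(ped$bc2_age), fmt_age(ped$oc_age), fmt_age(ped$panc_age),
    fmt_age(ped$censor_age))
  c("Co-segregation analysis report",
    "==============================",
    "",
    sprintf("Family:            %s", s$family_id),
    sprintf("Gene:              %s", s$gene),
    sprintf("Population:        %s", s$population),
    sprintf("Multiple cancers:  %s", s$mode),
    sprintf("Allele frequency:  %g", s$allele_frequency),
    "",
    sprintf("Likelihood ratio:  %.6g", payload$lr),
    sprintf("ACMG segregation:  %s", payload$acmg),
    sprintf("Configurations:    %d consistent with observed genotypes",
            payload$n_configs),
    "",
    "Pedigree members:",
    member_rows,
    "",
    if (length(payload$trimmed)) {
      sprintf("Trimmed (uninformative young branches): %s",
              paste(payload$trimmed, collapse = ", "))
    } else "No members trimmed.",
    "",
    if (length(payload$warnings)) {
      c("Warnings:", paste0("  - ", payload$warnings))
    } else "No warnings.",
    "",
    sprintf("Penetrance provenance: %s", payload$penetrance_provenance))
}
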