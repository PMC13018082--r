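#' Read a pedigree from a CanRisk-format file
#'
#' Parses the tabular pedigree exchange format used by the CanRisk /
#' BOADICEA risk tool: a header line beginning `##CanRisk`, a column-header
#' row beginning `##FamID`, then one whitespace-separated row per
#' individual. Structural columns (ids, parent links, sex, proband flag,
#' MZ-twin group, vital status), the censoring age (`Age`), the per-cancer
#' diagnosis-age columns (`BC1`, `BC2`, `OC`, `PAN`; 0 = unaffected) and
#' the test-result column for the gene under analysis are interpreted;
#' risk-factor and pathology columns are preserved verbatim for
#' round-tripping but otherwise ignored.
#'
#' Gene-test entries use CanRisk's `testtype:result` coding: a result of
#' `P` maps to carrier, `N` to noncarrier, `0` to untested. The `BC2`
#' column maps to a contralateral-breast-cancer event. A parent id of `0`
#' means absent; if exactly one parent is named, an untested unaffected
#' placeholder co-parent is synthesised so every non-founder has two
#' parents. Individuals with age 0 (unknown) are censored at 0 and are
#' uninformative for the survival likelihood. Dead individuals are
#' censored at their age at death.
#'
#' @param path_or_text path to a CanRisk file, or the file contents as a
#'   single string (anything containing a newline is treated as contents).
#' @param gene gene whose test-result column defines the genotype:
#'   "BRCA1", "BRCA2" or "PALB2".
#' @return A `coseg_pedigree`: a tibble with one row per individual and
#'   columns `id`, `name`, `father_id`, `mother_id`, `sex`, `proband`,
#'   `mz_twin`, `dead`, `censor_age`, `yob`, `bc1_age`, `bc2_age`,
#'   `oc_age`, `panc_age`, `genotype`; attributes `family_id` and `gene`.
#' @export
read_canrisk <- function(path_or_text, gene = "BRCA1") {
  gene <- match.arg(gene, GENES)
  txt <- if (length(path_or_text) == 1L && !grepl("\n", path_or_text)) {
    if (!file.exists(path_or_text)) {
      stop_coseg(sprintf("pedigree file not found: %s", path_or_text),
                 class = "coseg_input_error")
    }
    readLines(path_or_text, warn = FALSE)
  } else {
    unlist(strsplit(path_or_text, "\n", fixed = TRUE))
  }
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) < 3L || !grepl("^##CanRisk", txt[1])) {
    stop_coseg("not a CanRisk file: first line must begin '##CanRisk'",
               class = "coseg_parse_error")
  }
  hdr_i <- which(grepl("^##", txt) & grepl("FamID", txt))[1]
  if (is.na(hdr_i)) {
    stop_coseg("no column-header row (##FamID ...) found",
               class = "coseg_parse_error")
  }
  cols <- strsplit(sub("^##", "", txt[hdr_i]), "[ \t]+")[[1]]
  rows <- strsplit(trimws(txt[-seq_len(hdr_i)]), "[ \t]+")
  bad <- which(lengths(rows) != length(cols))
  if (length(bad)) {
    stop_coseg(sprintf(
      "malformed row %d: %d fields where %d columns were declared",
      bad[1], lengths(rows)[bad[1]], length(cols)),
      class = "coseg_parse_error")
  }
  raw <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(raw) <- cols

  need <- c("FamID", "IndivID", "FathID", "MothID", "Sex", "Target", "Age")
  miss <- setdiff(need, cols)
  if (length(miss)) {
    stop_coseg(sprintf("missing required column(s): %s",
                       paste(miss, collapse = ", ")),
               class = "coseg_parse_error")
  }
  if (!gene %in% cols) {
    stop_coseg(sprintf("no test-result column for gene %s", gene),
               class = "coseg_parse_error")
  }
  if (anyDuplicated(raw$IndivID)) {
    dup <- raw$IndivID[duplicated(raw$IndivID)][1]
    stop_coseg(sprintf("duplicate individual id '%s'", dup),
               class = "coseg_parse_error")
  }
  if (!all(raw$Sex %in% c("M", "F"))) {
    i <- which(!raw$Sex %in% c("M", "F"))[1]
    stop_coseg(sprintf("row %d (id %s): unknown sex code '%s' in column Sex",
                       i, raw$IndivID[i], raw$Sex[i]),
               class = "coseg_parse_error")
  }

  num_col <- function(col, default = 0) {
    if (!col %in% cols) return(rep(default, nrow(raw)))
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop_coseg(sprintf("row %d (id %s): non-numeric value '%s' in column %s",
                         i, raw$IndivID[i], raw[[col]][i], col),
                 class = "coseg_parse_error")
    }
    v
  }
  age0_na <- function(x) ifelse(x == 0, NA_real_, x)

  parse_geno <- function(x) {
    res <- sub("^[^:]*:", "", x)
    dplyr::case_when(res == "P" ~ "carrier",
                     res == "N" ~ "noncarrier",
                     TRUE ~ "untested")
  }

  ped <- tibble::tibble(
    id = raw$IndivID,
    name = if ("Name" %in% cols) raw$Name else raw$IndivID,
    father_id = ifelse(raw$FathID == "0", NA_character_, raw$FathID),
    mother_id = ifelse(raw$MothID == "0", NA_character_, raw$MothID),
    sex = raw$Sex,
    proband = raw$Target == "1",
    mz_twin = if ("MZtwin" %in% cols) {
      ifelse(raw$MZtwin == "0", NA_character_, raw$MZtwin)
    } else NA_character_,
    dead = if ("Dead" %in% cols) raw$Dead == "1" else FALSE,
    censor_age = num_col("Age"),
    yob = age0_na(num_col("Yob")),
    bc1_age = age0_na(num_col("BC1")),
    bc2_age = age0_na(num_col("BC2")),
    oc_age = age0_na(num_col("OC")),
    panc_age = age0_na(num_col("PAN")),
    genotype = parse_geno(raw[[gene]])
  )

  other_genes <- intersect(setdiff(GENES, gene), cols)
  informative <- other_genes[vapply(other_genes, function(g) {
    any(parse_geno(raw[[g]]) != "untested")
  }, logical(1))]
  if (length(informative)) {
    rlang::warn(sprintf(
      "test results for other gene(s) %s are ignored (analysing %s)",
      paste(informative, collapse = ", "), gene))
  }

  core_used <- c("FamID", "Name", "Target", "IndivID", "FathID", "MothID",
                 "Sex", "MZtwin", "Dead", "Age", "Yob", "BC1", "BC2", "OC",
                 "PAN", gene)
  extra <- raw[, setdiff(cols, core_used), drop = FALSE]
  extra$IndivID <- raw$IndivID

  n_prob <- sum(ped$proband)
  if (n_prob == 0L) {
    stop_coseg("missing proband: no row has Target = 1",
               class = "coseg_parse_error")
  }
  if (n_prob > 1L) {
    stop_coseg("more than one row has Target = 1",
               class = "coseg_parse_error")
  }
  if (ped$genotype[ped$proband] != "carrier") {
    stop_coseg("proband must carry the variant (positive gene-test result)",
               class = "coseg_parse_error")
  }
  for (pid in c(ped$father_id, ped$mother_id)) {
    if (!is.na(pid) && !pid %in% ped$id) {
      stop_coseg(sprintf("parent id '%s' does not match any individual", pid),
                 class = "coseg_parse_error")
    }
  }

  ped <- synthesize_coparents(ped)
  out <- new_pedigree(ped, family_id = raw$FamID[1], gene = gene)
  attr(out, "canrisk_extra") <- extra
  attr(out, "canrisk_version") <- sub("^##", "", txt[1])
  findings <- validate_pedigree(out)
  errs <- findings$message[findings$level == "error"]
  if (length(errs)) {
    stop_coseg(paste0("invalid pedigree:\n  ", paste(errs, collapse = "\n  ")),
               class = "coseg_validation_error")
  }
  out
}

new_pedigree <- function(tbl, family_id, gene) {
  structure(tibble::as_tibble(tbl),
            family_id = family_id, gene = gene,
            class = c("coseg_pedigree", class(tibble::tibble())))
}

# every individual with exactly one named parent gets an untested,
# unaffected placeholder co-parent with unknown age (censor 0)
synthesize_coparents <- function(ped) {
  one <- which(is.na(ped$father_id) != is.na(ped$mother_id))
  for (i in one) {
    if (is.na(ped$father_id[i])) {
      nid <- paste0(ped$mother_id[i], ".partner")
      ped$father_id[i] <- nid
      sex <- "M"
    } else {
      nid <- paste0(ped$father_id[i], ".partner")
      ped$mother_id[i] <- nid
      sex <- "F"
    }
    if (!nid %in% ped$id) {
      ped <- dplyr::bind_rows(ped, tibble::tibble(
        id = nid, name = nid, father_id = NA_character_,
        mother_id = NA_character_, sex = sex, proband = FALSE,
        mz_twin = NA_character_, dead = FALSE, censor_age = 0,
        yob = NA_real_, bc1_age = NA_real_, bc2_age = NA_real_,
        oc_age = NA_real_, panc_age = NA_real_, genotype = "untested"))
    }
  }
  ped
}

#' Write a pedigree in CanRisk format
#'
#' Inverse of [read_canrisk()]: writes the structural, cancer-age and
#' gene-test columns, restoring any unrecognised columns preserved at read
#' time. Round-trips field-for-field with [read_canrisk()].
#'
#' @param ped a `coseg_pedigree`.
#' @param path optional destination; when `NULL` the text is returned.
#' @return The file text as a character vector of lines, invisibly when
#'   written to `path`.
#' @export
write_canrisk <- function(ped, path = NULL) {
  stopifnot(inherits(ped, "coseg_pedigree"))
  gene <- attr(ped, "gene")
  fam <- attr(ped, "family_id") %||% "FAM1"
  a0 <- function(x) ifelse(is.na(x), "0", format(x, trim = TRUE))
  geno_code <- c(carrier = "S:P", noncarrier = "S:N", untested = "0:0")
  base <- tibble::tibble(
    FamID = fam,
    Name = ped$name,
    Target = ifelse(ped$proband, "1", "0"),
    IndivID = ped$id,
    FathID = a0(ped$father_id),
    MothID = a0(ped$mother_id),
    Sex = ped$sex,
    MZtwin = a0(ped$mz_twin),
    Dead = ifelse(ped$dead, "1", "0"),
    Age = a0(ped$censor_age),
    Yob = a0(ped$yob),
    BC1 = a0(ped$bc1_age),
    BC2 = a0(ped$bc2_age),
    OC = a0(ped$oc_age),
    PAN = a0(ped$panc_age))
  base[[gene]] <- geno_code[ped$genotype]
  extra <- attr(ped, "canrisk_extra")
  if (!is.null(extra) && ncol(extra) > 1L) {
    extra <- extra[match(ped$id, extra$IndivID), , drop = FALSE]
    for (col in setdiff(names(extra), "IndivID")) {
      base[[col]] <- ifelse(is.na(extra[[col]]), "0", extra[[col]])
    }
  }
  lines <- c(attr(ped, "canrisk_version") %||% "CanRisk 2.0",
             paste0(names(base), collapse = "\t"))
  lines[1] <- paste0("##", lines[1])
  lines[2] <- paste0("##", lines[2])
  body <- apply(base, 1L, paste, collapse = "\t")
  lines <- c(lines, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Validate a pedigree
#'
#' Structural and phenotypic consistency checks. Findings are returned,
#' never thrown; the input is never modified. Errors make the likelihood
#' undefined (relationship cycles, consanguineous matings, CBC before or
#' without a first BC, ovarian cancer in males, events after the censoring
#' age, sex-inconsistent parent links); warnings flag analyses that are
#' legal but degenerate (no informative genotypes, unknown ages, extreme
#' ages).
#'
#' @param ped a `coseg_pedigree`.
#' @return A tibble of findings with columns `level` ("error"/"warning"),
#'   `code`, `id` (individual concerned, `NA` for family-level findings)
#'   and `message`. Zero rows means a clean pedigree.
#' @export
validate_pedigree <- function(ped) {
  f <- list()
  add <- function(level, code, id, msg) {
    f[[length(f) + 1L]] <<- tibble::tibble(level = level, code = code,
                                           id = id, message = msg)
  }
  idx <- match(ped$father_id, ped$id)
  midx <- match(ped$mother_id, ped$id)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (!is.na(ped$father_id[i]) && is.na(idx[i])) {
      add("error", "missing_parent", id,
          sprintf("father '%s' of %s is not in the pedigree",
                  ped$father_id[i], id))
    }
    if (!is.na(ped$mother_id[i]) && is.na(midx[i])) {
      add("error", "missing_parent", id,
          sprintf("mother '%s' of %s is not in the pedigree",
                  ped$mother_id[i], id))
    }
    if (!is.na(idx[i]) && ped$sex[idx[i]] != "M") {
      add("error", "parent_sex", id, sprintf("father of %s is not male", id))
    }
    if (!is.na(midx[i]) && ped$sex[midx[i]] != "F") {
      add("error", "parent_sex", id, sprintf("mother of %s is not female", id))
    }
    if (is.na(ped$father_id[i]) != is.na(ped$mother_id[i])) {
      add("error", "single_parent", id,
          sprintf("%s has exactly one named parent", id))
    }
    if (ped$sex[i] == "M" && !is.na(ped$oc_age[i])) {
      add("error", "male_oc", id,
          sprintf("%s is male but has an ovarian cancer age", id))
    }
    if (!is.na(ped$bc2_age[i])) {
      if (is.na(ped$bc1_age[i])) {
        add("error", "cbc_without_bc", id,
            sprintf("%s has a CBC age but no first BC age", id))
      } else if (ped$bc2_age[i] < ped$bc1_age[i]) {
        add("error", "cbc_before_bc", id,
            sprintf("CBC precedes BC for %s (%g < %g)", id,
                    ped$bc2_age[i], ped$bc1_age[i]))
      }
    }
    ev <- c(ped$bc1_age[i], ped$bc2_age[i], ped$oc_age[i], ped$panc_age[i])
    ev <- ev[!is.na(ev)]
    if (length(ev) && ped$censor_age[i] < max(ev)) {
      add("error", "censor_before_event", id,
          sprintf("censoring age %g of %s precedes a diagnosis at %g",
                  ped$censor_age[i], id, max(ev)))
    }
    if (any(ev > 130) || ped$censor_age[i] > 130) {
      add("error", "age_range", id, sprintf("age over 130 years for %s", id))
    } else if (ped$censor_age[i] > 100) {
      add("warning", "age_over_100", id,
          sprintf("%s is over 100 years old", id))
    }
    if (ped$censor_age[i] == 0 && length(ev) == 0L) {
      add("warning", "unknown_age", id,
          sprintf("%s has unknown age: survival contribution is 1", id))
    }
  }
  # cycles in the parent graph
  if (has_parent_cycle(ped)) {
    add("error", "cycle", NA_character_,
        "parent links contain a cycle (someone is their own ancestor)")
  } else if (has_consanguinity(ped)) {
    add("error", "consanguinity", NA_character_,
        paste("consanguineous mating detected: genotype enumeration over",
              "inbred pedigrees is not supported"))
  }
  if (sum(ped$proband) != 1L) {
    add("error", "proband", NA_character_, "pedigree must have exactly one proband")
  } else if (ped$genotype[ped$proband] != "carrier") {
    add("error", "proband", NA_character_, "proband must carry the variant")
  }
  informative <- ped$genotype != "untested" & !ped$proband
  if (!any(informative)) {
    add("warning", "uninformative", NA_character_,
        "no relative besides the proband is genotyped: LR will equal 1")
  }
  if (length(f) == 0L) {
    return(tibble::tibble(level = character(), code = character(),
                          id = character(), message = character()))
  }
  dplyr::bind_rows(f)
}

has_parent_cycle <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  state <- integer(n) # 0 unseen, 1 in stack, 2 done
  cyc <- FALSE
  visit <- function(i) {
    if (cyc || is.na(i)) return()
    if (state[i] == 1L) { cyc <<- TRUE; return() }
    if (state[i] == 2L) return()
    state[i] <<- 1L
    visit(fa[i]); visit(mo[i])
    state[i] <<- 2L
  }
  for (i in seq_len(n)) visit(i)
  cyc
}

ancestor_sets <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  anc <- vector("list", n)
  get_anc <- function(i) {
    if (!is.null(anc[[i]])) return(anc[[i]])
    out <- integer(0)
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) out <- union(out, c(p, get_anc(p)))
    }
    anc[[i]] <<- out
    out
  }
  for (i in seq_len(n)) get_anc(i)
  anc
}

# a mating is consanguineous if the two parents share an ancestor
has_consanguinity <- function(ped) {
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  if (has_parent_cycle(ped)) return(FALSE)
  anc <- ancestor_sets(ped)
  for (i in seq_len(nrow(ped))) {
    if (!is.na(fa[i]) && !is.na(mo[i])) {
      af <- c(fa[i], anc[[fa[i]]])
      am <- c(mo[i], anc[[mo[i]]])
      if (length(intersect(af, am))) return(TRUE)
    }
  }
  FALSE
}

#' Trim uninformative young branches from a pedigree
#'
#' Large pedigrees can exceed the genotype-enumeration budget. Branches
#' containing only unaffected, untested individuals younger than
#' `max_untested_age` carry almost no co-segregation information and can
#' be removed; the proband and every genotyped or affected individual are
#' always retained, and no retained member is ever disconnected from its
#' ancestors. The operation is idempotent.
#'
#' @param ped a `coseg_pedigree`.
#' @param max_untested_age leaves younger than this (years) are removable;
#'   default 20.
#' @return A trimmed copy of `ped`, with the removed ids in attribute
#'   `trimmed_ids`.
#' @export
trim_pedigree <- function(ped, max_untested_age = 20) {
  stopifnot(inherits(ped, "coseg_pedigree"))
  keep <- rep(TRUE, nrow(ped))
  affected <- !is.na(ped$bc1_age) | !is.na(ped$oc_age) | !is.na(ped$panc_age)
  had_children <- ped$id %in% c(ped$father_id, ped$mother_id)
  repeat {
    is_parent <- ped$id %in% c(ped$father_id[keep], ped$mother_id[keep])
    removable <- keep & !is_parent & !ped$proband &
      ped$genotype == "untested" & !affected &
      ped$censor_age < max_untested_age
    # founders that lost all their children to trimming and carry nothing
    orphaned_spouse <- keep & !is_parent & had_children & !ped$proband &
      is.na(ped$father_id) & is.na(ped$mother_id) &
      ped$genotype == "untested" & !affected
    drop <- removable | orphaned_spouse
    if (!any(drop)) break
    keep <- keep & !drop
  }
  out <- ped[keep, , drop = FALSE]
  out <- new_pedigree(out, family_id = attr(ped, "family_id"),
                      gene = attr(ped, "gene"))
  attr(out, "canrisk_extra") <- attr(ped, "canrisk_extra")
  attr(out, "canrisk_version") <- attr(ped, "canrisk_version")
  attr(out, "trimmed_ids") <- ped$id[!keep]
  out
}

#' @export
print.coseg_pedigree <- function(x, ...) {
  cat(sprintf("CanRisk pedigree '%s' (%d members, gene %s, proband %s)\n",
              attr(x, "family_id"), nrow(x), attr(x, "gene"),
              x$id[x$proband][1]))
  NextMethod()
}

#' Modify one pedigree member in place
#'
#' Convenience for what-if analyses (e.g. varying the age or genotype of
#' one relative): returns a copy of the pedigree with the named fields of
#' one member replaced. Diagnosis ages set to `NA` remove the event.
#'
#' @param ped a `coseg_pedigree`.
#' @param id member to modify.
#' @param ... fields to set, e.g. `censor_age = 60`, `bc1_age = 45`,
#'   `genotype = "noncarrier"`.
#' @return The modified pedigree.
#' @export
update_member <- function(ped, id, ...) {
  stopifnot(inherits(ped, "coseg_pedigree"))
  i <- match(id, ped$id)
  if (is.na(i)) stop_coseg(sprintf("no member with id '%s'", id))
  vals <- list(...)
  bad <- setdiff(names(vals), names(ped))
  if (length(bad)) stop_coseg(sprintf("unknown field(s): %s",
                                      paste(bad, collapse = ", ")))
  for (nm in names(vals)) ped[[nm]][i] <- vals[[nm]]
  ped
}
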