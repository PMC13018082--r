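fig1_path <- function() {
  system.file("extdata", "synthetic_fig1_family.canrisk", package = "coseglr")
}

canrisk_text <- function(rows,
                         header = "##FamID\tName\tTarget\tIndivID\tFathID\tMothID\tSex\tMZtwin\tDead\tAge\tYob\tBC1\tBC2\tOC\tPAN\tBRCA1") {
  paste(c("##CanRisk 2.0", header, rows), collapse = "\n")
}

test_that("a minimal trio file maps fields to the pedigree", {
  txt <- canrisk_text(c(
    "F1\tdad\t0\tdad\t0\t0\tM\t0\t0\t70\t0\t0\t0\t0\t0\t0:0",
    "F1\tmum\t0\tmum\t0\t0\tF\t0\t0\t68\t0\t45\t0\t0\t0\t0:0",
    "F1\tkid\t1\tkid\tdad\tmum\tF\t0\t0\t40\t0\t0\t0\t0\t0\tS:P"))
  ped <- read_canrisk(txt, gene = "BRCA1")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$id[ped$proband], "kid")
  expect_equal(ped$genotype, c("untested", "untested", "carrier"))
  expect_equal(ped$bc1_age, c(NA, 45, NA))
  expect_equal(attr(ped, "family_id"), "F1")
})

test_that("structural parse errors name the offending row or column", {
  expect_error(read_canrisk("no newline here.canrisk"), "not found")
  expect_error(read_canrisk("plain text\nwithout header\nrows"), "##CanRisk")
  bad_sex <- canrisk_text(
    "F1\ta\t1\ta\t0\t0\tX\t0\t0\t40\t0\t0\t0\t0\t0\tS:P")
  expect_error(read_canrisk(bad_sex), "unknown sex code 'X'")
  dup <- canrisk_text(c(
    "F1\ta\t1\ta\t0\t0\tF\t0\t0\t40\t0\t0\t0\t0\t0\tS:P",
    "F1\ta\t0\ta\t0\t0\tF\t0\t0\t40\t0\t0\t0\t0\t0\t0:0"))
  expect_error(read_canrisk(dup), "duplicate individual id")
  neg <- canrisk_text(
    "F1\ta\t1\ta\t0\t0\tF\t0\t0\t40\t0\t35\t0\t0\t0\tS:N")
  expect_error(read_canrisk(neg), "proband must carry")
  no_target <- canrisk_text(
    "F1\ta\t0\ta\t0\t0\tF\t0\t0\t40\t0\t0\t0\t0\t0\tS:P")
  expect_error(read_canrisk(no_target), "missing proband")
})

test_that("the bundled family file reproduces its member and genotype counts", {
  ped <- read_canrisk(fig1_path(), gene = "BRCA1")
  expect_equal(nrow(ped), 9)
  expect_equal(sum(ped$genotype == "carrier"), 3)
  expect_equal(sum(ped$genotype == "noncarrier"), 2)
  expect_equal(sum(!is.na(ped$bc1_age)), 4)
  expect_equal(ped$censor_age[ped$id == "q"], 81)
  expect_equal(nrow(validate_pedigree(ped)), 0)
})

test_that("write/read round-trip preserves every field", {
  ped <- read_canrisk(fig1_path(), gene = "BRCA1")
  txt <- paste(write_canrisk(ped), collapse = "\n")
  ped2 <- read_canrisk(txt, gene = "BRCA1")
  expect_equal(as.data.frame(ped2), as.data.frame(ped))
  expect_equal(attr(ped2, "family_id"), attr(ped, "family_id"))
})

test_that("a single named parent gets a synthesised placeholder co-parent", {
  txt <- canrisk_text(c(
    "F1\tmum\t0\tmum\t0\t0\tF\t0\t0\t68\t0\t45\t0\t0\t0\tS:P",
    "F1\tkid\t1\tkid\t0\tmum\tF\t0\t0\t40\t0\t0\t0\t0\t0\tS:P"))
  ped <- read_canrisk(txt)
  expect_equal(nrow(ped), 3)
  partner <- ped[ped$id == "mum.partner", ]
  expect_equal(partner$sex, "M")
  expect_equal(partner$genotype, "untested")
  expect_equal(partner$censor_age, 0)
})

test_that("validation findings catch phenotype inconsistencies without mutating", {
  ped <- make_ped(id = c("a", "b"), proband = c(TRUE, FALSE),
                  genotype = c("carrier", "noncarrier"),
                  censor_age = c(50, 60))
  ped_bad <- update_member(ped, "a", bc1_age = 45, bc2_age = 40,
                           censor_age = 50)
  f <- validate_pedigree(ped_bad)
  expect_true(any(grepl("CBC precedes BC", f$message)))

  ped_m <- make_ped(id = c("a", "b"), sex = c("F", "M"),
                    proband = c(TRUE, FALSE),
                    genotype = c("carrier", "noncarrier"),
                    censor_age = c(50, 60), oc_age = c(NA, 55))
  expect_true(any(validate_pedigree(ped_m)$code == "male_oc"))

  solo <- make_ped(id = c("a", "b"), proband = c(TRUE, FALSE),
                   genotype = c("carrier", "untested"),
                   censor_age = c(50, 60))
  f2 <- validate_pedigree(solo)
  expect_true(any(grepl("LR will equal 1", f2$message)))
  expect_false(any(f2$level == "error"))
})

test_that("trimming removes only young uninformative leaves and is idempotent", {
  txt <- canrisk_text(c(
    "F1\tdad\t0\tdad\t0\t0\tM\t0\t0\t70\t0\t0\t0\t0\t0\t0:0",
    "F1\tmum\t0\tmum\t0\t0\tF\t0\t0\t68\t0\t45\t0\t0\t0\tS:P",
    "F1\tpro\t1\tpro\tdad\tmum\tF\t0\t0\t40\t0\t38\t0\t0\t0\tS:P",
    "F1\tsis\t0\tsis\tdad\tmum\tF\t0\t0\t30\t0\t0\t0\t0\t0\t0:0",
    "F1\tson\t0\tson\tdad\tmum\tM\t0\t0\t15\t0\t0\t0\t0\t0\t0:0"))
  ped <- read_canrisk(txt)
  trimmed <- trim_pedigree(ped)
  expect_equal(attr(trimmed, "trimmed_ids"), "son")
  expect_true("sis" %in% trimmed$id) # 30-year-old leaf is retained
  again <- trim_pedigree(trimmed)
  expect_equal(again$id, trimmed$id)

  # young untested unaffected leaves are nearly uninformative for the LR
  lr_full <- compute_lr(ped, pset = toy_pset())$lr
  lr_trim <- compute_lr(trimmed, pset = toy_pset())$lr
  expect_lt(abs(lr_trim - lr_full) / lr_full, 0.01)
})

test_that("update_member edits one member and rejects unknown fields", {
  ped <- read_canrisk(fig1_path())
  p2 <- update_member(ped, "q", bc1_age = 60, censor_age = 60)
  expect_equal(p2$bc1_age[p2$id == "q"], 60)
  expect_equal(ped$bc1_age[ped$id == "q"], NA_real_)
  expect_error(update_member(ped, "zz", censor_age = 1), "no member")
  expect_error(update_member(ped, "q", nonsense = 1), "unknown field")
})
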