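pilot_concordance <- function() {
  concordance_call(pilot_mutations(), pilot_patients(),
                   pilot_major_clonotypes())
}

test_that("concordance reproduces the pilot cohort's verbal calls", {
  cc <- pilot_concordance()
  call_of <- function(pt) unique(cc$concordance[cc$patient_id == pt])
  expect_equal(call_of("pt1"), "clonal_homo_or_hemizygous")  # 0.86 / 0.87
  expect_equal(call_of("pt3"), "clonal_heterozygous")        # 0.27 / 0.65
  expect_equal(call_of("pt2"), "subclonal")                  # 0.21 / 0.95
  expect_equal(call_of("pt8"), "subclonal")
  expect_equal(call_of("pt9"), "subclonal")
  # oligoclonal samples cannot anchor the mutation to a clone
  expect_equal(call_of("pt4"), "indeterminate_oligoclonal")  # gamma 2nd 18.9%
  expect_equal(call_of("pt7"), "indeterminate_oligoclonal")  # delta 2nd 38.9%
})

test_that("concordance labels are monotone in VAF with inclusive boundaries", {
  pts <- tibble::tibble(patient_id = "p", tgd_fraction_pbmc = 1.0)
  majors <- pilot_major_clonotypes()[1, ]
  majors$sample_id <- "p"
  lab <- function(vaf) {
    concordance_call(tibble::tibble(patient_id = "p", gene = "STAT3",
                                    aa_change = "x", vaf = vaf),
                     pts, majors)$concordance
  }
  vafs <- c(0.1, 0.34, 0.35, 0.5, 0.74, 0.75, 0.9)
  labels <- vapply(vafs, lab, character(1))
  expect_equal(labels, c("subclonal", "subclonal", "clonal_heterozygous",
                         "clonal_heterozygous", "clonal_heterozygous",
                         "clonal_homo_or_hemizygous",
                         "clonal_homo_or_hemizygous"))
  ord <- factor(labels, levels = c("subclonal", "clonal_heterozygous",
                                   "clonal_homo_or_hemizygous"))
  expect_true(all(diff(as.integer(ord)) >= 0))
})

test_that("a VAF well above the clone fraction raises an inconsistency warning", {
  pts <- tibble::tibble(patient_id = "p", tgd_fraction_pbmc = 0.3)
  majors <- pilot_major_clonotypes()[1, ]
  majors$sample_id <- "p"
  expect_warning(
    concordance_call(tibble::tibble(patient_id = "p", gene = "STAT3",
                                    aa_change = "x", vaf = 0.45),
                     pts, majors),
    "non-clone")
})

test_that("STAT3/STAT5B mutual exclusivity holds in the pilot and fails when planted", {
  res <- check_mutual_exclusivity(pilot_mutations())
  expect_true(res$exclusive)
  expect_equal(nrow(res$violators), 0)
  planted <- dplyr::bind_rows(
    pilot_mutations(),
    tibble::tibble(patient_id = "pt3", gene = "STAT5B",
                   aa_change = "N642H", vaf = 0.1, phase = "unknown"))
  res2 <- check_mutual_exclusivity(planted)
  expect_false(res2$exclusive)
  expect_equal(res2$violators$patient_id, "pt3")
  expect_true(check_mutual_exclusivity(pilot_mutations()[0, ])$exclusive)
})

test_that("maturation phenotypes are an exact four-combination lookup", {
  df <- tibble::tibble(
    CD28 = c("-", "-", "-", "-", "-", NA),
    CD45RA = c("+", "-", "+", "+", "+", "+"),
    CD45RO = c("-", "+", "+", "+", "-", "-"),
    CD62L = c("-", "-", "-", "+", "+", "-")
  )
  out <- classify_maturation(df)
  expect_equal(out$maturation,
               c("effector", "effector_memory", "transitional",
                 "transitional_62L", "other", "other"))
})

test_that("counts-based association reproduces the cohort's printed p-values", {
  # the CD28 row (0/11 vs 0/14) has a degenerate margin and warns
  expect_warning(
    rep <- associate_feature_counts(cohort_feature_counts(),
                                    force_fisher = TRUE),
    "Degenerate")
  p_of <- function(f) rep$p_value[rep$feature == f]
  expect_equal(round(p_of("CD5"), 3), 0.006)
  expect_equal(round(p_of("CD56"), 3), 0.002)
  expect_equal(round(p_of("CD45RO"), 3), 0.009)
  expect_equal(round(p_of("autoimmune_disease"), 3), 0.025)
  expect_lt(p_of("Vd2+/Vg9+"), 1e-4)
})

test_that("patient-level association excludes unknowns and degenerate rows", {
  pts <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:10),
    course = rep(c("symptomatic", "indolent"), each = 5),
    CD5 = c("-", "-", "-", "-", "+", "+", "+", "+", "+", "+"),
    CD57 = rep("+", 10),                 # all-positive: p must be 1
    CD16 = c("+", NA, "+", "-", "+", "+", "+", NA, "-", "+"),
    NKG2A = rep(NA_character_, 10)       # fully unknown: skipped
  )
  ws <- capture_warnings(rep <- build_association_report(pts))
  expect_match(ws, "NKG2A", all = FALSE)      # fully-unknown feature skipped
  expect_match(ws, "Degenerate", all = FALSE) # all-positive CD57 margin
  expect_false("NKG2A" %in% rep$feature)
  expect_equal(rep$p_value[rep$feature == "CD57"], 1)
  cd16 <- rep[rep$feature == "CD16", ]
  expect_equal(cd16$symptomatic_n, 4)    # one unknown dropped per group
  expect_equal(cd16$indolent_n, 4)
  cd5 <- rep[rep$feature == "CD5", ]
  expect_equal(cd5$method, "fisher_exact")
})

test_that("the diagnostic classifier encodes the phenotype/genotype cascade", {
  pts <- tibble::tribble(
    ~patient_id, ~disease,   ~Vd2, ~Vg9, ~CD56,
    "a", "Tgd_LGLL", "+", "+", "+",
    "b", "Tgd_LGLL", "-", "-", "-",
    "c", "HSTCL",    "-", "-", "+",
    "d", "Tgd_LGLL", NA,  "+", "+",
    "e", "Tgd_LGLL", "+", "+", "-"
  )
  muts <- tibble::tribble(
    ~patient_id, ~gene,
    "a", "STAT5B",
    "b", "STAT3",
    "c", "STAT5B",
    "e", "STAT3"
  )
  out <- diagnostic_classifier(pts, muts)
  expect_equal(out$expected_course,
               c("indolent_expected", "symptomatic_expected", "aggressive",
                 "unclassifiable", "indolent_expected"))
  expect_equal(out$neutropenia_alert, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_true(out$stat5b_cd56_support[out$patient_id == "a"])
  # HSTCL stays aggressive despite the STAT5B/CD56 combination
  expect_false(out$stat5b_cd56_support[out$patient_id == "c"])
  # STAT3 in a Vd2+/Vg9+ clone is conflicting evidence
  expect_true(out$discordant[out$patient_id == "e"])
  expect_false(any(out$discordant[out$patient_id %in% c("a", "b", "c")]))
})
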