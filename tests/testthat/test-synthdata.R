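test_that("segment library is structurally faithful", {
  segs <- gd_segment_library()
  vs <- segs[segs$segment_class == "V", ]
  js <- segs[segs$segment_class == "J", ]
  codon_at <- function(seq, k) substr(seq, (k - 1) * 3 + 1, k * 3)
  v_anchor <- translate_cdr3(mapply(codon_at, vs$sequence, vs$anchor_offset))
  expect_true(all(v_anchor$cdr3_aa == "C"))
  j_anchor <- translate_cdr3(mapply(codon_at, js$sequence, js$anchor_offset))
  expect_true(all(j_anchor$cdr3_aa == "F"))
  # KK-bearing joining segments, as in the natural gamma locus
  for (jj in c("TRGJ1/2", "TRGJP")) {
    seq <- js$sequence[js$name == jj]
    aa <- translate_cdr3(substr(seq, 1, 3 * floor(nchar(seq) / 3)))$cdr3_aa
    expect_true(grepl("KK", aa))
  }
  expect_true(all(segs$chain[segs$segment_class == "D"] == "TRD"))
  expect_true(all(grepl("^[ACGT]+$", segs$sequence)))
})

test_that("rearrangement draws are reproducible and zero-noise draws are germline", {
  a <- simulate_rearrangement(50, "TRG", seed = 99)
  b <- simulate_rearrangement(50, "TRG", seed = 99)
  expect_identical(a, b)
  # degenerate junction parameters: fixed germline junction across seeds
  g1 <- simulate_rearrangement(3, "TRG", v_weights = c(TRGV9 = 1),
                               j_weights = c(TRGJP = 1), trim_p = 1,
                               insert_lambda = 0, seed = 1)
  g2 <- simulate_rearrangement(3, "TRG", v_weights = c(TRGV9 = 1),
                               j_weights = c(TRGJP = 1), trim_p = 1,
                               insert_lambda = 0, seed = 2)
  expect_equal(unique(g1$cdr3_nt), unique(g2$cdr3_nt))
  expect_equal(unique(g1$cdr3_aa), "CALWEVQELGKKIKVF")
})

test_that("default junction model yields about a third productive draws", {
  draws <- simulate_rearrangement(10000, "TRG", seed = 7)
  expect_gt(mean(draws$productive), 0.25)
  expect_lt(mean(draws$productive), 0.45)
  lens <- nchar(draws$cdr3_aa[draws$productive])
  expect_true(stats::median(lens) >= 9 && stats::median(lens) <= 16)
})

test_that("convergent variants are distinct encodings of the same peptide", {
  pl <- plant_public_clonotype("CALWEVRELGKKIKVF", "TRGV9", "TRGJP",
                               n_variants = 3, seed = 5)
  expect_equal(nrow(pl), 3)
  expect_equal(length(unique(pl$cdr3_nt)), 3)
  tr <- translate_cdr3(pl$cdr3_nt)
  expect_true(all(tr$cdr3_aa == "CALWEVRELGKKIKVF"))
  one <- plant_public_clonotype("CAF", "TRGV9", "TRGJP", 1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_error(plant_public_clonotype("CAB", "TRGV9", "TRGJP"),
               "Non-standard")
})

test_that("cohort simulation is deterministic for a fixed seed", {
  a <- simulate_cohort(n_indolent = 2, n_symptomatic = 1, n_hstcl = 1,
                       n_controls = 2, seed = 13, read_depth = 2e4,
                       n_background = 80)
  b <- simulate_cohort(n_indolent = 2, n_symptomatic = 1, n_hstcl = 1,
                       n_controls = 2, seed = 13, read_depth = 2e4,
                       n_background = 80)
  expect_identical(a$repertoires, b$repertoires)
  expect_identical(a$truth$mutations, b$truth$mutations)
})

test_that("cohort presets realize the planted clonal structure", {
  sim <- simulate_cohort(n_indolent = 3, n_symptomatic = 2, n_hstcl = 1,
                         n_controls = 3, seed = 21, read_depth = 3e4,
                         n_background = 120)
  reps <- sim$repertoires
  majors <- call_major_clonotypes(reps)
  arch <- classify_architecture(majors[majors$group == "HSTCL", ])
  expect_true(all(arch$architecture == "monoclonal"))
  # indolent usage is the planted combination, modal on both chains
  ind <- majors[majors$group == "indolent_LGLL", ]
  ug <- compute_vdj_usage(ind, chain = "TRG")
  expect_equal(ug$v_call[which.max(ug$n)], "TRGV9")
  expect_equal(ug$j_call[which.max(ug$n)], "TRGJP")
  ud <- compute_vdj_usage(ind, chain = "TRD")
  expect_equal(ud$v_call[which.max(ud$n)], "TRDV2")
  # symptomatic majors avoid the Vg9-JgP / Vd2 combinations entirely
  sym <- majors[majors$group == "symptomatic_LGLL", ]
  expect_false(any(sym$v_call %in% c("TRGV9", "TRDV2")))
  # controls carry no major clone
  expect_equal(nrow(majors[majors$group == "control", ]), 0)
})

test_that("planted frequencies are recovered within multinomial error", {
  sim <- simulate_cohort(n_indolent = 3, n_symptomatic = 2, n_hstcl = 1,
                         n_controls = 1, seed = 31, read_depth = 1e5,
                         n_background = 120)
  obs <- dplyr::left_join(sim$truth$plants, sim$repertoires,
                          by = c("sample_id", "chain", "cdr3_nt"))
  err <- abs(obs$frequency - obs$target_freq)
  bound <- 4 * sqrt(obs$target_freq * (1 - obs$target_freq) / 1e5)
  expect_true(all(!is.na(obs$frequency)))
  expect_gte(mean(err <= bound), 0.99)
})

test_that("metadata realization follows the configured effect structure", {
  sim <- simulate_cohort(n_indolent = 4, n_symptomatic = 4, n_hstcl = 1,
                         n_controls = 1, seed = 8, read_depth = 2e4,
                         n_background = 80, p_mut_symptomatic = 1,
                         p_mut_indolent = 1)
  md <- simulate_patient_metadata(sim$truth, seed = 9)
  stat3 <- md$mutations$patient_id[md$mutations$gene == "STAT3"]
  expect_gt(length(stat3), 0)
  p3 <- md$patients[md$patients$patient_id %in% stat3, ]
  expect_true(all(p3$CD56 == "-"))          # deterministic default effect
  expect_true(all(p3$neutropenia == "+"))
  ind <- md$patients[md$patients$course == "indolent", ]
  expect_true(all(ind$Vd2 == "+" & ind$Vg9 == "+"))
  expect_error(
    simulate_patient_metadata(sim$truth, effect = list(p_cd56_indolent = 2)),
    "\\[0, 1\\]")
})

test_that("observed VAF converges to the true VAF with depth", {
  sim <- simulate_cohort(n_indolent = 3, n_symptomatic = 0, n_hstcl = 0,
                         n_controls = 1, seed = 15, read_depth = 2e4,
                         n_background = 80, p_mut_indolent = 1)
  md <- simulate_patient_metadata(sim$truth, depth = 1e6, seed = 16)
  truth <- sim$truth$mutations
  cmp <- dplyr::inner_join(md$mutations, truth[, c("patient_id", "true_vaf")],
                           by = "patient_id")
  expect_true(all(abs(cmp$vaf - cmp$true_vaf) <= 0.002))
})
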