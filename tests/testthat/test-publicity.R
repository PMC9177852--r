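test_that("pilot major CDR3 query sets have 19 gamma and 24 delta sequences", {
  m <- pilot_major_clonotypes()
  expect_equal(length(unique(m$cdr3_aa[m$chain == "TRG"])), 19)
  expect_equal(length(unique(m$cdr3_aa[m$chain == "TRD"])), 24)
})

test_that("shared major sequences match the cohort's recurrence pattern", {
  shared <- count_shared_major_sequences(pilot_major_clonotypes())
  expect_equal(
    shared$n_patients[shared$cdr3_aa == "CALWEVRELGKKIKVF"], 3)
  expect_equal(
    shared$n_patients[shared$cdr3_aa == "CALWEVEELGKKIKVF"], 2)
  delta <- shared[shared$chain == "TRD", ]
  expect_true(all(delta$n_patients == 1))  # no delta major recurs
})

test_that("recurrence matrix carries zero cells and sums nt variants", {
  reps <- pilot_with_control()
  majors <- reps[reps$group != "control", ]
  rec <- build_recurrence_matrix(majors, reps, chain = "TRG")
  expect_equal(length(unique(rec$cdr3_aa)), 19)
  expect_equal(nrow(rec), 19 * 12)  # 11 patients + 1 control, every query
  # a sequence present only in its own patient has exactly one nonzero cell
  row <- rec[rec$cdr3_aa == "CATWDRYKKLF", ]
  expect_equal(sum(row$frequency > 0), 1)
  expect_equal(row$sample_id[row$frequency > 0], "pt3")
  # convergent nt variants of one aa sum their frequencies
  two_nt <- tibble::tibble(
    sample_id = "sx", group = "control", chain = "TRG", v_call = "TRGV9",
    d_call = NA_character_, j_call = "TRGJP",
    cdr3_nt = c("TGTGCTTTT", "TGCGCTTTT"), cdr3_aa = "CAF",
    read_count = c(30L, 20L), frequency = c(0.6, 0.4), productive = TRUE)
  q <- two_nt[1, ]; q$sample_id <- "px"; q$group <- "indolent_LGLL"
  rec2 <- build_recurrence_matrix(q, dplyr::bind_rows(two_nt, q), chain = "TRG")
  expect_equal(rec2$frequency[rec2$sample_id == "sx"], 1.0)
})

test_that("publicity labels partition the query set and match definitions", {
  reps <- pilot_with_control()
  majors <- reps[reps$group != "control", ]
  rec <- build_recurrence_matrix(majors, reps, chain = "TRG")
  pub <- classify_publicity(rec)
  expect_equal(sort(unique(pub$cdr3_aa)), sort(unique(majors$cdr3_aa[majors$chain == "TRG"])))
  expect_true(all(table(pub$cdr3_aa) == 1))  # exactly one label each
  # CALERGKLF was planted in the control -> public
  expect_equal(pub$publicity[pub$cdr3_aa == "CALERGKLF"], "public")
  # shared by three patients, absent from the control -> private to disease
  expect_equal(pub$publicity[pub$cdr3_aa == "CALWEVRELGKKIKVF"],
               "private_to_disease")
  # found in exactly one patient, no control -> private to the patient
  expect_equal(pub$publicity[pub$cdr3_aa == "CATWDRYKKLF"],
               "private_to_patient")
  no_ctrl <- build_recurrence_matrix(majors, majors, chain = "TRG")
  expect_error(classify_publicity(no_ctrl), "control")
})

test_that("recurrence equals brute-force string matching on a synthetic cohort", {
  sim <- simulate_cohort(n_indolent = 3, n_symptomatic = 2, n_hstcl = 1,
                         n_controls = 6, seed = 77, read_depth = 3e4,
                         n_background = 120)
  reps <- sim$repertoires
  majors <- call_major_clonotypes(reps)
  majors <- majors[majors$group != "control", ]
  rec <- build_recurrence_matrix(majors[majors$chain == "TRG", ], reps,
                                 chain = "TRG")
  # oracle: nested-loop all-pairs comparison
  queries <- unique(majors$cdr3_aa[majors$chain == "TRG"])
  g <- reps[reps$chain == "TRG", ]
  for (q in queries) {
    for (sid in unique(g$sample_id)) {
      expected <- 0
      sub <- g[g$sample_id == sid, ]
      for (i in seq_len(nrow(sub))) {
        if (!is.na(sub$cdr3_aa[i]) && sub$cdr3_aa[i] == q) {
          expected <- expected + sub$frequency[i]
        }
      }
      got <- rec$frequency[rec$cdr3_aa == q & rec$sample_id == sid]
      expect_equal(got, expected)
    }
  }
})

test_that("publicity recovery on planted cohorts is exact for both chains", {
  sim <- simulate_cohort(seed = 42, n_controls = 8, read_depth = 5e4,
                         n_background = 150)
  reps <- sim$repertoires
  majors <- call_major_clonotypes(reps)
  majors <- majors[majors$group != "control", ]
  for (ch in c("TRG", "TRD")) {
    rec <- build_recurrence_matrix(majors[majors$chain == ch, ], reps,
                                   chain = ch)
    cmp <- dplyr::inner_join(classify_publicity(rec),
                             sim$truth$publicity[sim$truth$publicity$chain == ch, ],
                             by = "cdr3_aa")
    expect_gt(nrow(cmp), 0)
    expect_equal(cmp$publicity, cmp$expected)
  }
})

test_that("enrichment testing flags planted patient-dominant sequences", {
  reps <- pilot_with_control(control_seqs = c("CALERGKLF", "CAAAAF"))
  majors <- reps[reps$group != "control", ]
  rec <- build_recurrence_matrix(majors, reps, chain = "TRG")
  enr <- test_enrichment(rec)
  expect_true(all(enr$p_one_sided > 0 & enr$p_one_sided <= 1))
  top <- enr$cdr3_aa[1]
  # the most enriched sequence is one of the multi-patient dominants
  expect_true(top %in% c("CALWEVRELGKKIKVF", "CALWEVEELGKKIKVF"))
  expect_equal(enr$significant, enr$p_one_sided < 0.05)
})

test_that("clustering distances behave on identical and disjoint repertoires", {
  a <- tiny_clonotypes(); a$frequency <- c(0.6, 0.3, 0.1)
  b <- a; b$sample_id <- "s2"
  c3 <- a; c3$sample_id <- "s3"
  c3$cdr3_aa <- c("WWWW", "YYYY", "HHHH")
  cl <- cluster_repertoires(dplyr::bind_rows(a, b, c3), metric = "jaccard_aa")
  d <- as.matrix(cl$dist)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1)
  clmh <- cluster_repertoires(dplyr::bind_rows(a, b, c3),
                              metric = "morisita_horn")
  expect_equal(as.matrix(clmh$dist)["s1", "s2"], 0)
})

test_that("samples without productive clonotypes are excluded with a warning", {
  a <- tiny_clonotypes(); a$frequency <- c(0.6, 0.3, 0.1)
  b <- a; b$sample_id <- "s2"; b$frequency <- c(0.5, 0.3, 0.2)
  cc <- a; cc$sample_id <- "s3"; cc$frequency <- c(0.2, 0.3, 0.5)
  empty <- a[1, ]; empty$sample_id <- "s4"; empty$cdr3_aa <- NA_character_
  expect_warning(
    cl <- cluster_repertoires(dplyr::bind_rows(a, b, cc, empty)),
    "s4")
  expect_equal(nrow(cl$labels), 3)
})

test_that("catalog screening reports exact matches and tolerates bad rows", {
  m <- pilot_major_clonotypes()
  empty <- screen_catalog(m, tibble::tibble(sequence = character(),
                                            annotation = character()))
  expect_equal(nrow(empty), 0)
  cat1 <- tibble::tibble(sequence = "CALWEVRELGKKIKVF",
                         annotation = "planted match")
  hits <- screen_catalog(m, cat1)
  expect_setequal(hits$sample_id, c("pt7", "pt8", "pt10"))
  disjoint <- tibble::tibble(sequence = c("CAAAAAAF", "CASSLGF"),
                             annotation = c("x", "y"))
  expect_equal(nrow(screen_catalog(m, disjoint)), 0)
  malformed <- tibble::tibble(sequence = c("CALWEVRELGKKIKVF", NA, "bad!"),
                              annotation = "z")
  expect_warning(hits2 <- screen_catalog(m, malformed), "malformed")
  expect_equal(nrow(hits2), 3)
})
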