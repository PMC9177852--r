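#' Relate STAT mutation VAF to clone size and zygosity
#'
#' For each mutation call, computes the clonality ratio
#' `rho = vaf / clone_fraction`, where the clone fraction is the
#' flow-determined T gamma/delta fraction of PBMC — the substrate of the
#' mutation assay. Labels follow the expectation that a heterozygous
#' mutation carried by every leukemic cell gives `rho` near 0.5 and a
#' homozygous or hemizygous one `rho` near 1:
#' `clonal_homo_or_hemizygous` when `rho >= rho_clonal` (default 0.75),
#' `clonal_heterozygous` when `rho_het <= rho < rho_clonal` (default 0.35),
#' `subclonal` below. Both boundaries are inclusive at the lower edge. An
#' oligoclonality gate overrides the ratio: when the second-largest major
#' clonotype on either chain reaches `oligo_gate` (default 10%), the
#' mutation cannot be assigned to a clone and the call is
#' `indeterminate_oligoclonal`. A VAF exceeding the clone fraction by more
#' than 0.10 triggers an inconsistency warning (possible non-clone
#' origin).
#'
#' @param mutations Tibble with `patient_id`, `gene`, `aa_change`, `vaf`.
#' @param patients Tibble with `patient_id` and `tgd_fraction_pbmc`.
#' @param majors Major-clonotype tibble (both chains) whose `sample_id`
#'   matches `patient_id`.
#' @param rho_clonal,rho_het Label boundaries on `rho`.
#' @param oligo_gate Second-major frequency at or above which the call is
#'   indeterminate.
#' @return The mutation tibble with added `clone_fraction`, `rho`,
#'   `second_major`, `concordance` columns.
#' @export
concordance_call <- function(mutations, patients, majors,
                             rho_clonal = 0.75, rho_het = 0.35,
                             oligo_gate = 0.10) {
  check_clonotypes(majors)
  if (!all(c("patient_id", "vaf") %in% names(mutations))) {
    abort("`mutations` needs patient_id and vaf columns.")
  }
  second <- majors %>%
    dplyr::group_by(.data$sample_id, .data$chain) %>%
    dplyr::summarise(second_major = sort(.data$frequency, decreasing = TRUE)[2],
                     .groups = "drop") %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(second_major = max(.data$second_major, 0, na.rm = TRUE),
                     .groups = "drop")
  out <- mutations %>%
    dplyr::left_join(patients[c("patient_id", "tgd_fraction_pbmc")],
                     by = "patient_id") %>%
    dplyr::left_join(second, by = c(patient_id = "sample_id")) %>%
    dplyr::mutate(
      clone_fraction = .data$tgd_fraction_pbmc,
      second_major = dplyr::coalesce(.data$second_major, 0),
      rho = .data$vaf / .data$clone_fraction,
      concordance = dplyr::case_when(
        .data$second_major >= oligo_gate ~ "indeterminate_oligoclonal",
        .data$rho >= rho_clonal ~ "clonal_homo_or_hemizygous",
        .data$rho >= rho_het ~ "clonal_heterozygous",
        TRUE ~ "subclonal"
      )
    ) %>%
    dplyr::select(-"tgd_fraction_pbmc")
  high <- out$vaf > out$clone_fraction + 0.10
  if (any(high, na.rm = TRUE)) {
    warn(sprintf(
      "VAF exceeds clone fraction by > 0.10 for: %s (possible non-clone origin).",
      paste(unique(out$patient_id[high]), collapse = ", ")))
  }
  out
}

#' Check mutual exclusivity of STAT3 and STAT5B mutations
#'
#' @param mutations Tibble with `patient_id` and `gene`.
#' @return A list: `exclusive` (logical — no patient carries mutations in
#'   both genes) and `violators` (tibble of offending patients with their
#'   gene sets).
#' @export
check_mutual_exclusivity <- function(mutations) {
  if (nrow(mutations) == 0) {
    return(list(exclusive = TRUE,
                violators = tibble::tibble(patient_id = character(),
                                           genes = character())))
  }
  per_patient <- mutations %>%
    dplyr::distinct(.data$patient_id, .data$gene) %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(n_genes = dplyr::n(),
                     genes = paste(sort(.data$gene), collapse = "+"),
                     .groups = "drop")
  violators <- per_patient %>%
    dplyr::filter(.data$n_genes > 1) %>%
    dplyr::select("patient_id", "genes")
  list(exclusive = nrow(violators) == 0, violators = violators)
}

#' Label T-cell maturation phenotypes
#'
#' Exact lookup of the four CD28/CD45RA/CD45RO/CD62L combinations observed
#' in gamma/delta LGL clones: effector (CD28-RA+RO-62L-), effector memory
#' (CD28-RA-RO+62L-), transitional (CD28-RA+RO+62L-) and transitional with
#' retained CD62L (CD28-RA+RO+62L+). Any other combination, including one
#' with an unknown marker, is `other`.
#'
#' @param patients Tibble with tri-state (`"+"`, `"-"`, `NA`) columns
#'   `CD28`, `CD45RA`, `CD45RO`, `CD62L`.
#' @return The tibble with an added `maturation` column.
#' @export
classify_maturation <- function(patients) {
  need <- c("CD28", "CD45RA", "CD45RO", "CD62L")
  missing <- setdiff(need, names(patients))
  if (length(missing)) {
    abort(sprintf("Missing maturation marker column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  key <- paste(patients$CD28, patients$CD45RA, patients$CD45RO,
               patients$CD62L, sep = "")
  lookup <- c("-+--" = "effector", "--+-" = "effector_memory",
              "-++-" = "transitional", "-+++" = "transitional_62L")
  patients$maturation <- unname(lookup[key])
  patients$maturation[is.na(patients$maturation)] <- "other"
  patients
}

#' Build a symptomatic-versus-indolent association report
#'
#' For each feature column, cross-tabulates feature positivity against the
#' clinical course of the LGLL patients (HSTCL and controls are excluded
#' from testing, as in the source cohort layout), picks Fisher's exact or
#' the chi-square test by the expected-count rule (or forces Fisher), and
#' reports the two-sided p-value. Patients with an unknown value for a
#' feature are excluded from that row's denominators; a feature with no
#' known values is skipped with a warning.
#'
#' @param patients Tibble with a `course` column (`"symptomatic"` /
#'   `"indolent"`) and tri-state feature columns.
#' @param features Character vector of feature column names; defaults to
#'   every tri-state column.
#' @param force_fisher Always use Fisher's exact test?
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble: one row per feature with counts, test, `p_value` and
#'   `significant`.
#' @export
build_association_report <- function(patients, features = NULL,
                                     force_fisher = FALSE, alpha = 0.05) {
  if (!"course" %in% names(patients)) abort("`patients` needs a 'course' column.")
  pts <- patients[patients$course %in% c("symptomatic", "indolent"), ]
  if (length(unique(pts$course)) < 2) {
    abort("Need both symptomatic and indolent patients.")
  }
  if (is.null(features)) {
    is_tri <- vapply(pts, function(col) {
      is.character(col) && all(col %in% c("+", "-", NA_character_))
    }, logical(1))
    features <- setdiff(names(pts)[is_tri], c("patient_id", "disease", "course"))
  }
  rows <- purrr::map(features, function(f) {
    v <- pts[[f]]
    known <- !is.na(v)
    if (!any(known)) {
      warn(sprintf("Feature '%s' has no known values; skipped.", f))
      return(NULL)
    }
    s <- pts$course == "symptomatic" & known
    i <- pts$course == "indolent" & known
    tab <- counts_to_table(sum(v[s] == "+"), sum(s), sum(v[i] == "+"), sum(i))
    res <- test_2x2(tab, force_fisher = force_fisher)
    tibble::tibble(
      feature = f,
      symptomatic_pos = sum(v[s] == "+"), symptomatic_n = sum(s),
      indolent_pos = sum(v[i] == "+"), indolent_n = sum(i),
      method = res$method, statistic = res$statistic,
      p_value = res$p_value, significant = res$p_value < alpha
    )
  })
  dplyr::bind_rows(rows)
}

#' Association tests from tabulated feature counts
#'
#' Same testing machinery as [build_association_report()] but starting
#' from already-tabulated per-feature counts (as in
#' [cohort_feature_counts()]) rather than patient-level records.
#'
#' @param counts Tibble with `feature`, `symptomatic_pos`,
#'   `symptomatic_n`, `indolent_pos`, `indolent_n`.
#' @param force_fisher Always use Fisher's exact test?
#' @param alpha Significance level.
#' @return A tibble with one test result row per feature.
#' @export
associate_feature_counts <- function(counts, force_fisher = FALSE,
                                     alpha = 0.05) {
  need <- c("feature", "symptomatic_pos", "symptomatic_n",
            "indolent_pos", "indolent_n")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    abort(sprintf("Missing column(s): %s", paste(missing, collapse = ", ")))
  }
  counts %>%
    dplyr::rowwise() %>%
    dplyr::mutate(res = list(test_2x2(
      counts_to_table(.data$symptomatic_pos, .data$symptomatic_n,
                      .data$indolent_pos, .data$indolent_n),
      force_fisher = force_fisher))) %>%
    dplyr::ungroup() %>%
    tidyr::unnest("res") %>%
    dplyr::mutate(significant = .data$p_value < alpha)
}

#' Expected clinical course from phenotype and genotype
#'
#' Encodes the combined diagnostic reading of a gamma/delta
#' lymphoproliferation: HSTCL is flagged aggressive regardless of
#' genotype; otherwise Vd2+/Vg9+ clones are expected to run an indolent
#' course and Vd2-negative clones (Vd1+ or Vd1-/Vd2-) a symptomatic one.
#' A STAT3 mutation adds a neutropenia alert (STAT3-mutated patients are
#' consistently neutropenic); a STAT5B mutation together with CD56
#' positivity in LGLL reinforces the indolent expectation. Evidence
#' pointing both ways (a STAT3 mutation in a Vd2+/Vg9+ clone, or
#' STAT5B/CD56 support in a Vd2-negative one) is flagged discordant. A
#' patient with unknown Vd2 status is unclassifiable.
#'
#' @param patients Tibble with `patient_id`, `disease` and tri-state
#'   `Vd2`, `Vg9`, `CD56` columns.
#' @param mutations Optional tibble with `patient_id`, `gene`.
#' @return A tibble: `patient_id`, `expected_course` (one of
#'   `indolent_expected`, `symptomatic_expected`, `aggressive`,
#'   `unclassifiable`), `neutropenia_alert`, `stat5b_cd56_support`,
#'   `discordant`.
#' @export
diagnostic_classifier <- function(patients, mutations = NULL) {
  need <- c("patient_id", "disease", "Vd2", "Vg9", "CD56")
  missing <- setdiff(need, names(patients))
  if (length(missing)) {
    abort(sprintf("Missing column(s): %s", paste(missing, collapse = ", ")))
  }
  genes <- if (is.null(mutations) || nrow(mutations) == 0) {
    tibble::tibble(patient_id = character(), has_stat3 = logical(),
                   has_stat5b = logical())
  } else {
    mutations %>%
      dplyr::group_by(.data$patient_id) %>%
      dplyr::summarise(has_stat3 = any(.data$gene == "STAT3"),
                       has_stat5b = any(.data$gene == "STAT5B"),
                       .groups = "drop")
  }
  patients %>%
    dplyr::left_join(genes, by = "patient_id") %>%
    dplyr::mutate(
      has_stat3 = dplyr::coalesce(.data$has_stat3, FALSE),
      has_stat5b = dplyr::coalesce(.data$has_stat5b, FALSE),
      expected_course = dplyr::case_when(
        .data$disease == "HSTCL" ~ "aggressive",
        is.na(.data$Vd2) ~ "unclassifiable",
        .data$Vd2 == "+" & !is.na(.data$Vg9) & .data$Vg9 == "+" ~
          "indolent_expected",
        .data$Vd2 == "-" ~ "symptomatic_expected",
        TRUE ~ "unclassifiable"
      ),
      neutropenia_alert = .data$has_stat3,
      stat5b_cd56_support = .data$has_stat5b & !is.na(.data$CD56) &
        .data$CD56 == "+" & .data$disease == "Tgd_LGLL",
      discordant = (.data$expected_course == "indolent_expected" &
                      .data$has_stat3) |
        (.data$expected_course == "symptomatic_expected" &
           .data$stat5b_cd56_support)
    ) %>%
    dplyr::select("patient_id", "expected_course", "neutropenia_alert",
                  "stat5b_cd56_support", "discordant")
}
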