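#' Build a CDR3 recurrence matrix
#'
#' Takes the pooled major clonotypes of the patients as the query set
#' (distinct CDR3 amino-acid sequences) and records, for every sample in
#' the cohort (patients and healthy controls), the frequency of each query
#' sequence in that sample's full productive repertoire. Matching is exact
#' amino-acid identity against any clonotype of the sample — gene segments
#' are not required to match — and frequencies of distinct nucleotide
#' variants encoding the same amino-acid sequence are summed (convergent
#' recombination). Absence is an explicit zero cell.
#'
#' @param majors Major-clonotype tibble of the patients (one chain).
#' @param repertoires Full productive clonotype tibble of all samples,
#'   patients and controls, same chain.
#' @param chain Chain to analyze; inferred when `majors` has a single one.
#' @return A long tibble of class `tcrgd_recurrence` with columns
#'   `cdr3_aa`, `sample_id`, `group`, `frequency` — one row per query
#'   sequence and sample.
#' @export
build_recurrence_matrix <- function(majors, repertoires, chain = NULL) {
  check_clonotypes(majors)
  check_clonotypes(repertoires)
  chain <- chain %||% unique(majors$chain)
  if (length(chain) != 1) {
    abort("`majors` spans several chains; pass `chain` explicitly.")
  }
  queries <- sort(unique(majors$cdr3_aa[majors$chain == chain &
                                          !is.na(majors$cdr3_aa)]))
  if (!length(queries)) abort("Empty query set: no major CDR3 sequences.")
  reps <- repertoires[repertoires$chain == chain, ]
  samples <- dplyr::distinct(reps, .data$sample_id, .data$group)
  hits <- reps %>%
    dplyr::filter(.data$cdr3_aa %in% queries) %>%
    dplyr::group_by(.data$sample_id, .data$cdr3_aa) %>%
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop")
  out <- tidyr::expand_grid(cdr3_aa = queries, sample_id = samples$sample_id) %>%
    dplyr::left_join(samples, by = "sample_id") %>%
    dplyr::left_join(hits, by = c("sample_id", "cdr3_aa")) %>%
    dplyr::mutate(frequency = dplyr::coalesce(.data$frequency, 0))
  out <- tibble::new_tibble(out, chain = chain,
                            class = "tcrgd_recurrence")
  out
}

#' Widen a recurrence matrix
#'
#' @param recurrence Output of [build_recurrence_matrix()].
#' @return A wide tibble, rows = query sequences, columns = samples.
#' @export
recurrence_wide <- function(recurrence) {
  tidyr::pivot_wider(tibble::as_tibble(recurrence)[
    c("cdr3_aa", "sample_id", "frequency")],
    names_from = "sample_id", values_from = "frequency")
}

#' Classify query clonotypes as public or private
#'
#' A sequence present in at least one healthy control is public; one
#' absent from all controls but present in two or more patients is private
#' to the disease; one found in exactly one patient and no control is
#' private to the patient. The three labels partition the query set.
#'
#' @param recurrence Output of [build_recurrence_matrix()]; must contain at
#'   least one control sample.
#' @return A tibble with `cdr3_aa`, `n_patients`, `n_controls`,
#'   `publicity`.
#' @export
classify_publicity <- function(recurrence) {
  rec <- tibble::as_tibble(recurrence)
  if (!any(rec$group == "control")) {
    abort("Publicity calls require at least one control sample.")
  }
  rec %>%
    dplyr::group_by(.data$cdr3_aa) %>%
    dplyr::summarise(
      n_patients = sum(.data$frequency > 0 & .data$group != "control"),
      n_controls = sum(.data$frequency > 0 & .data$group == "control"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(publicity = dplyr::case_when(
      .data$n_controls >= 1 ~ "public",
      .data$n_patients >= 2 ~ "private_to_disease",
      TRUE ~ "private_to_patient"
    ))
}

#' Count patients sharing each major CDR3 sequence
#'
#' Counts patients (not clonotype entries) whose major-clonotype set
#' contains each amino-acid sequence, per chain.
#'
#' @param majors Major-clonotype tibble.
#' @return A tibble with `chain`, `cdr3_aa`, `n_patients`, descending.
#' @export
count_shared_major_sequences <- function(majors) {
  check_clonotypes(majors)
  majors %>%
    dplyr::distinct(.data$chain, .data$cdr3_aa, .data$sample_id) %>%
    dplyr::count(.data$chain, .data$cdr3_aa, name = "n_patients") %>%
    dplyr::arrange(.data$chain, dplyr::desc(.data$n_patients), .data$cdr3_aa)
}

#' Test per-clonotype frequency enrichment in patients versus controls
#'
#' For each query sequence of a recurrence matrix, compares its frequencies
#' in patient repertoires against control repertoires with the one-sided
#' two-sample rank-sum test (alternative: patients stochastically greater).
#' Samples lacking the clonotype contribute an explicit zero, so presence /
#' absence influences the ranks. P-values are reported raw, as in the
#' underlying study design; apply [stats::p.adjust()] downstream if a
#' multiplicity correction is wanted.
#'
#' @param recurrence Output of [build_recurrence_matrix()].
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with `cdr3_aa`, `u_statistic`, `p_one_sided`,
#'   `significant`, ordered by p-value.
#' @export
test_enrichment <- function(recurrence, alpha = 0.05) {
  rec <- tibble::as_tibble(recurrence)
  if (!any(rec$group == "control")) abort("No control samples to compare against.")
  rec %>%
    dplyr::group_by(.data$cdr3_aa) %>%
    dplyr::summarise(
      res = list(rank_sum_test(.data$frequency[.data$group != "control"],
                               .data$frequency[.data$group == "control"],
                               alternative = "greater")),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res") %>%
    dplyr::transmute(.data$cdr3_aa, u_statistic = .data$statistic,
                     p_one_sided = .data$p_value,
                     significant = .data$p_value < alpha) %>%
    dplyr::arrange(.data$p_one_sided, .data$cdr3_aa)
}

#' Cluster repertoires by clonotype overlap
#'
#' Builds per-sample CDR3 amino-acid frequency vectors, computes a
#' pairwise distance matrix (Morisita-Horn on frequencies by default, or
#' binary Jaccard on presence/absence), and clusters samples by
#' average-linkage agglomeration. The two-group cut of the tree is
#' reported alongside the dendrogram.
#'
#' @param repertoires Productive clonotype tibble, single chain (or pass
#'   `chain`). Samples with no productive clonotypes are excluded with a
#'   warning.
#' @param metric `"morisita_horn"` or `"jaccard_aa"`.
#' @param chain Optional chain filter.
#' @param k Number of clusters for the cut (default 2).
#' @return An object of class `tcrgd_clusters`: list with `hclust`,
#'   `labels` (tibble `sample_id`, `group`, `cluster`), `metric`, `dist`.
#' @export
cluster_repertoires <- function(repertoires,
                                metric = c("morisita_horn", "jaccard_aa"),
                                chain = NULL, k = 2) {
  metric <- match.arg(metric)
  check_clonotypes(repertoires)
  if (!is.null(chain)) repertoires <- repertoires[repertoires$chain == chain, ]
  if (length(unique(repertoires$chain)) > 1) {
    abort("Repertoires span several chains; pass `chain`.")
  }
  usable <- repertoires %>%
    dplyr::filter(!is.na(.data$cdr3_aa), !is.na(.data$frequency))
  dropped <- setdiff(unique(repertoires$sample_id), unique(usable$sample_id))
  if (length(dropped)) {
    warn(sprintf("Excluding %d sample(s) with no productive clonotypes: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  mat <- usable %>%
    dplyr::group_by(.data$sample_id, .data$cdr3_aa) %>%
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "cdr3_aa", values_from = "frequency",
                       values_fill = 0)
  if (nrow(mat) < 3) abort("Need at least three non-empty repertoires.")
  ids <- mat$sample_id
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- ids
  d <- switch(metric,
    morisita_horn = vegan::vegdist(m, method = "horn"),
    jaccard_aa = vegan::vegdist(m, method = "jaccard", binary = TRUE)
  )
  hc <- stats::hclust(d, method = "average")
  cut <- stats::cutree(hc, k = k)
  groups <- usable %>%
    dplyr::distinct(.data$sample_id, .data$group)
  labels <- tibble::tibble(sample_id = ids, cluster = unname(cut[ids])) %>%
    dplyr::left_join(groups, by = "sample_id") %>%
    dplyr::select("sample_id", "group", "cluster")
  structure(list(hclust = hc, labels = labels, metric = metric, dist = d),
            class = "tcrgd_clusters")
}

#' @export
print.tcrgd_clusters <- function(x, ...) {
  cat(sprintf("Repertoire clustering (%s, average linkage): %d samples\n",
              x$metric, nrow(x$labels)))
  print(table(x$labels$group, x$labels$cluster))
  invisible(x)
}

#' @export
plot.tcrgd_clusters <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = sprintf("%s, average linkage", x$metric), ...)
}

#' Tidy repertoire-cluster labels
#'
#' @param x A `tcrgd_clusters` object.
#' @param ... Unused.
#' @return The per-sample label tibble (`sample_id`, `group`, `cluster`).
#' @method tidy tcrgd_clusters
#' @export
tidy.tcrgd_clusters <- function(x, ...) x$labels

#' @rdname tidy.tcrgd_clusters
#' @return For `glance()`: one row with `n_samples`, `metric`, and
#'   `separates_patients_controls` — whether the two-group cut puts all
#'   patient samples in one cluster and all controls in the other.
#' @method glance tcrgd_clusters
#' @export
glance.tcrgd_clusters <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$labels), metric = x$metric,
    separates_patients_controls = separates_groups(x)
  )
}

#' Does the two-group cut separate patients from controls?
#'
#' @param x A `tcrgd_clusters` object.
#' @return Logical.
#' @export
separates_groups <- function(x) {
  stopifnot(inherits(x, "tcrgd_clusters"))
  lab <- x$labels
  is_control <- lab$group == "control"
  length(unique(lab$cluster[is_control])) == 1 &&
    length(unique(lab$cluster[!is_control])) == 1 &&
    lab$cluster[is_control][1] != lab$cluster[!is_control][1]
}

#' Screen major clonotypes against an annotated CDR3 catalog
#'
#' Exact amino-acid identity screen of the cohort's major clonotypes
#' against a user-supplied catalog of CDR3 sequences with annotations
#' (e.g. pathogen-associated clonotypes from the literature). Catalog rows
#' without a usable sequence are skipped with a warning. An empty result
#' is the report that no overlap exists.
#'
#' @param majors Major-clonotype tibble.
#' @param catalog Data frame with columns `sequence` and `annotation`, or a
#'   path to a two-column TSV.
#' @return A tibble of matches: `sample_id`, `chain`, `cdr3_aa`,
#'   `frequency`, `annotation`.
#' @export
screen_catalog <- function(majors, catalog) {
  check_clonotypes(majors)
  if (is.character(catalog) && length(catalog) == 1) {
    catalog <- readr::read_tsv(catalog, col_types = readr::cols(.default = "c"),
                               progress = FALSE)
  }
  if (!all(c("sequence", "annotation") %in% names(catalog))) {
    abort("Catalog needs 'sequence' and 'annotation' columns.")
  }
  bad <- is.na(catalog$sequence) | catalog$sequence == "" |
    grepl("[^A-Z]", catalog$sequence)
  if (any(bad)) {
    warn(sprintf("Skipping %d malformed catalog row(s).", sum(bad)))
    catalog <- catalog[!bad, ]
  }
  majors %>%
    dplyr::inner_join(
      tibble::as_tibble(catalog[c("sequence", "annotation")]),
      by = c(cdr3_aa = "sequence"), relationship = "many-to-many") %>%
    dplyr::select("sample_id", "chain", "cdr3_aa", "frequency", "annotation") %>%
    dplyr::arrange(.data$cdr3_aa, .data$sample_id)
}
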