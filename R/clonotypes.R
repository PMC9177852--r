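#' Translate CDR3 nucleotide sequences
#'
#' Standard-genetic-code translation with a productivity verdict per
#' sequence: `"productive"` (in frame, no stop), `"out_of_frame"` (length
#' not divisible by 3), or `"stop_codon"`. Out-of-frame sequences get `NA`
#' amino acids; stop-containing translations are returned with `*`.
#'
#' @param cdr3_nt Character vector of nucleotide sequences over ACGT.
#' @return A tibble with columns `cdr3_nt`, `cdr3_aa`, `verdict`.
#' @export
#' @examples
#' translate_cdr3(c("TGTGCC", "TGTGC", "TGTTAA"))
translate_cdr3 <- function(cdr3_nt) {
  cdr3_nt <- toupper(cdr3_nt)
  ok <- !is.na(cdr3_nt)
  if (any(grepl("[^ACGT]", cdr3_nt[ok]))) {
    abort("CDR3 nucleotide sequences may contain only A, C, G, T.")
  }
  aa <- rep(NA_character_, length(cdr3_nt))
  verdict <- rep(NA_character_, length(cdr3_nt))
  in_frame <- ok & nchar(cdr3_nt) %% 3 == 0 & nchar(cdr3_nt) > 0
  verdict[ok & !in_frame] <- "out_of_frame"
  if (any(in_frame)) {
    aa[in_frame] <- as.character(
      Biostrings::translate(Biostrings::DNAStringSet(cdr3_nt[in_frame]),
                            no.init.codon = TRUE)
    )
    has_stop <- in_frame & grepl("*", aa, fixed = TRUE)
    verdict[has_stop] <- "stop_codon"
    verdict[in_frame & !has_stop] <- "productive"
  }
  tibble::tibble(cdr3_nt = cdr3_nt, cdr3_aa = aa, verdict = verdict)
}

#' Call major clonotypes
#'
#' A major clonotype has a frequency of at least `threshold` (default 5%,
#' boundary inclusive) of productive reads in its sample and chain. Entries
#' are returned sorted by descending frequency within each (sample, chain),
#' ties broken by CDR3 amino-acid lexicographic order, with a `rank`
#' column; rank 1 is the dominant clone.
#'
#' @param df A productive-filtered, normalized clonotype tibble.
#' @param threshold Frequency cutoff in (0, 1].
#' @return The major-clonotype tibble with an added `rank` column.
#' @export
call_major_clonotypes <- function(df, threshold = 0.05) {
  check_clonotypes(df)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single fraction in (0, 1].")
  }
  df %>%
    dplyr::filter(!is.na(.data$frequency), .data$frequency >= threshold) %>%
    dplyr::group_by(.data$sample_id, .data$chain) %>%
    dplyr::arrange(dplyr::desc(.data$frequency), .data$cdr3_aa,
                   .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$sample_id, .data$chain, .data$rank)
}

#' Classify per-sample clonal architecture
#'
#' Counts major clonotypes per chain and labels each sample by the maximum
#' per-chain count: 1 is monoclonal, 2 biclonal, 3 or more oligoclonal. A
#' sample with no major clonotype on either chain is labelled polyclonal
#' (the expected state of healthy-donor repertoires).
#'
#' @param majors Output of [call_major_clonotypes()], both chains pooled.
#' @return A tibble with `sample_id`, `n_major_gamma`, `n_major_delta`,
#'   `architecture`.
#' @export
classify_architecture <- function(majors) {
  check_clonotypes(majors)
  wide <- majors %>%
    dplyr::count(.data$sample_id, .data$chain) %>%
    tidyr::pivot_wider(names_from = "chain", values_from = "n",
                       values_fill = 0L)
  if (!"TRG" %in% names(wide)) wide$TRG <- 0L
  if (!"TRD" %in% names(wide)) wide$TRD <- 0L
  wide %>%
    dplyr::mutate(n_major_gamma = .data$TRG, n_major_delta = .data$TRD) %>%
    dplyr::transmute(
      .data$sample_id, .data$n_major_gamma, .data$n_major_delta,
      architecture = dplyr::case_when(
        pmax(.data$n_major_gamma, .data$n_major_delta) == 0 ~ "polyclonal",
        pmax(.data$n_major_gamma, .data$n_major_delta) == 1 ~ "monoclonal",
        pmax(.data$n_major_gamma, .data$n_major_delta) == 2 ~ "biclonal",
        TRUE ~ "oligoclonal"
      )
    ) %>%
    dplyr::arrange(.data$sample_id)
}

#' Tabulate combinatorial V-(D)-J usage of major clonotypes
#'
#' Counts each major-clonotype entry once (occurrence counting, not
#' distinct sequences) per V–J (TRG) or V–D–J (TRD) combination. The
#' per-chain denominator is the total number of entries counted, so counts
#' sum to the denominator within each chain. Missing D calls on TRD are
#' reported as `"none"`.
#'
#' @param majors A major-clonotype tibble.
#' @param group Optional subject-group filter (e.g. `"indolent_LGLL"`).
#' @param chain Optional chain filter (`"TRG"` or `"TRD"`).
#' @return A tibble with `chain`, `v_call`, `d_call`, `j_call`, `n`,
#'   `denominator`.
#' @export
compute_vdj_usage <- function(majors, group = NULL, chain = NULL) {
  check_clonotypes(majors)
  if (!is.null(group)) majors <- majors[majors$group %in% group, ]
  if (!is.null(chain)) majors <- majors[majors$chain %in% chain, ]
  if (nrow(majors) == 0) {
    return(tibble::tibble(chain = character(), v_call = character(),
                          d_call = character(), j_call = character(),
                          n = integer(), denominator = integer()))
  }
  majors %>%
    dplyr::mutate(d_call = dplyr::if_else(
      .data$chain == "TRD" & is.na(.data$d_call), "none", .data$d_call)) %>%
    dplyr::count(.data$chain, .data$v_call, .data$d_call, .data$j_call) %>%
    dplyr::group_by(.data$chain) %>%
    dplyr::mutate(denominator = sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$chain, dplyr::desc(.data$n))
}

#' Scan CDR3 amino-acid sequences for the KK dipeptide motif
#'
#' The adjacent double-lysine motif is encoded by the TRGJ1/TRGJ2 and TRGJP
#' joining segments and has been implicated in phosphoantigen recognition
#' by Vgamma9/Vdelta2 T cells.
#'
#' @param cdr3_aa Character vector of amino-acid sequences.
#' @return Logical vector: does `"KK"` occur as a substring?
#' @export
scan_kk_motif <- function(cdr3_aa) {
  if (length(cdr3_aa) == 0 || any(!nzchar(cdr3_aa), na.rm = TRUE)) {
    abort("`cdr3_aa` must contain non-empty sequences.")
  }
  grepl("KK", cdr3_aa, fixed = TRUE)
}
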