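#' Read a clonotype table
#'
#' Ingests per-sample clonotype tables in one of three dialects and returns
#' a tidy clonotype tibble, one row per rearrangement. Gene names are
#' normalized to gene-level IMGT style (allele suffixes such as `*01`
#' stripped). Rows whose read count cannot be parsed as a non-negative
#' integer are rejected; the rejected rows (with their line numbers) are
#' attached as the `"rejected"` attribute and reported with a warning.
#'
#' Dialects:
#' * `"internal"` — the package's own tab-separated format as written by
#'   [write_clonotype_table()]; carries `sample_id`, `chain` and `group`
#'   explicitly.
#' * `"airr"` — AIRR Rearrangement TSV with at least `v_call`, `d_call`,
#'   `j_call`, `junction`, `junction_aa`, `duplicate_count`, `productive`.
#' * `"mixcr"` — MiXCR export TSV with at least `cloneCount`,
#'   `allVHitsWithScore`, `allDHitsWithScore`, `allJHitsWithScore`,
#'   `nSeqCDR3`, `aaSeqCDR3`. Multi-hit gene fields resolve to the
#'   top-scoring hit, ties broken lexicographically.
#'
#' For the `airr` and `mixcr` dialects the sample id is taken from a
#' `sample_id` column when present, otherwise from the file name; the chain
#' is taken from the V (or J) gene-name prefix.
#'
#' @param path Path to a TSV file.
#' @param dialect One of `"internal"`, `"airr"`, `"mixcr"`.
#' @param sample_id Optional sample id overriding the default.
#' @param group Optional subject-group label (`"control"`,
#'   `"indolent_LGLL"`, `"symptomatic_LGLL"`, `"HSTCL"`).
#' @return A clonotype tibble with normalized frequencies (fractions of
#'   productive reads per sample and chain).
#' @export
read_clonotype_table <- function(path, dialect = c("internal", "airr", "mixcr"),
                                 sample_id = NULL, group = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(sprintf("Empty clonotype table: %s", path))

  required <- switch(dialect,
    internal = c("sample_id", "chain", "v_call", "d_call", "j_call",
                 "cdr3_nt", "cdr3_aa", "read_count", "productive"),
    airr = c("v_call", "d_call", "j_call", "junction", "junction_aa",
             "duplicate_count", "productive"),
    mixcr = c("cloneCount", "allVHitsWithScore", "allDHitsWithScore",
              "allJHitsWithScore", "nSeqCDR3", "aaSeqCDR3")
  )
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("Dialect '%s' requires missing column(s): %s",
                  dialect, paste(missing, collapse = ", ")))
  }

  default_id <- sample_id %||%
    (if ("sample_id" %in% names(raw)) NULL else
       sub("\\.(tsv|txt)$", "", basename(path)))

  df <- switch(dialect,
    internal = tibble::tibble(
      sample_id = raw$sample_id,
      group = if ("group" %in% names(raw)) raw$group else group,
      chain = raw$chain,
      v_call = strip_allele(raw$v_call),
      d_call = strip_allele(raw$d_call),
      j_call = strip_allele(raw$j_call),
      cdr3_nt = raw$cdr3_nt,
      cdr3_aa = raw$cdr3_aa,
      count_raw = raw$read_count,
      productive = toupper(raw$productive) %in% c("T", "TRUE", "1")
    ),
    airr = tibble::tibble(
      sample_id = sample_id %||%
        (if ("sample_id" %in% names(raw)) raw$sample_id else default_id),
      group = group,
      v_call = strip_allele(raw$v_call),
      d_call = strip_allele(raw$d_call),
      j_call = strip_allele(raw$j_call),
      cdr3_nt = raw$junction,
      cdr3_aa = raw$junction_aa,
      count_raw = raw$duplicate_count,
      productive = toupper(raw$productive) %in% c("T", "TRUE", "1")
    ),
    mixcr = tibble::tibble(
      sample_id = sample_id %||%
        (if ("sample_id" %in% names(raw)) raw$sample_id else default_id),
      group = group,
      v_call = resolve_mixcr_hits(raw$allVHitsWithScore),
      d_call = resolve_mixcr_hits(raw$allDHitsWithScore),
      j_call = resolve_mixcr_hits(raw$allJHitsWithScore),
      cdr3_nt = raw$nSeqCDR3,
      cdr3_aa = raw$aaSeqCDR3,
      count_raw = raw$cloneCount
    )
  )
  if (!"chain" %in% names(df)) {
    df$chain <- chain_of(dplyr::coalesce(df$v_call, df$j_call))
  }
  if (!"productive" %in% names(df)) {
    df$productive <- translate_cdr3(df$cdr3_nt)$verdict == "productive"
  }
  df$d_call[df$d_call %in% c("", ".", "NA")] <- NA_character_

  count <- suppressWarnings(as.numeric(df$count_raw))
  bad <- is.na(count) | count < 0 | count != floor(count)
  if (any(bad)) {
    rejected <- tibble::tibble(line = which(bad) + 1L,
                               read_count = df$count_raw[bad])
    warn(sprintf("Rejected %d row(s) with unparseable read counts (lines %s).",
                 sum(bad), paste(rejected$line, collapse = ", ")))
  } else {
    rejected <- tibble::tibble(line = integer(), read_count = character())
  }
  df <- df[!bad, ]
  df$read_count <- as.integer(count[!bad])
  df$count_raw <- NULL
  df$frequency <- NA_real_
  df <- df[, clonotype_cols]
  check_clonotypes(df)
  out <- normalize_frequencies(df)
  attr(out, "rejected") <- rejected
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "TRGV9*00(1250.5),TRGV4*00(900)" -> "TRGV9" (top score, ties lexicographic)
resolve_mixcr_hits <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || s == "") return(NA_character_)
    hits <- strsplit(s, ",", fixed = TRUE)[[1]]
    name <- strip_allele(sub("\\(.*$", "", hits))
    score <- suppressWarnings(as.numeric(sub("^.*\\(([^)]*)\\)$", "\\1", hits)))
    score[is.na(score)] <- -Inf
    ord <- order(-score, name)
    name[ord[1]]
  }, character(1), USE.NAMES = FALSE)
}

chain_of <- function(gene) {
  out <- rep(NA_character_, length(gene))
  out[startsWith(gene, "TRG")] <- "TRG"
  out[startsWith(gene, "TRD")] <- "TRD"
  out
}

#' Write a clonotype table in the internal dialect
#'
#' Tab-separated, UTF-8, fixed header. Reading the file back with
#' [read_clonotype_table()] reproduces counts exactly and frequencies to
#' within 1e-9.
#'
#' @param df A clonotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(df, path) {
  check_clonotypes(df)
  readr::write_tsv(df[, clonotype_cols], path, progress = FALSE)
  invisible(path)
}

#' Normalize clonotype frequencies
#'
#' Recomputes `frequency` as `read_count / sum(read_count)` over the
#' productive clonotypes of each (sample, chain); unproductive reads never
#' enter denominators and unproductive rows get `NA` frequency.
#'
#' @param df A clonotype tibble with `read_count` and `productive`.
#' @return The tibble with a recomputed `frequency` column.
#' @export
normalize_frequencies <- function(df) {
  check_clonotypes(df)
  if (any(df$read_count < 0, na.rm = TRUE)) abort("Negative read counts.")
  df %>%
    dplyr::group_by(.data$sample_id, .data$chain) %>%
    dplyr::mutate(
      frequency = {
        tot <- sum(.data$read_count[.data$productive])
        if (any(.data$productive) && (is.na(tot) || tot == 0)) {
          abort(sprintf(
            "All-zero productive read counts in sample '%s' (%s).",
            dplyr::cur_group()$sample_id, dplyr::cur_group()$chain))
        }
        ifelse(.data$productive, .data$read_count / tot, NA_real_)
      }
    ) %>%
    dplyr::ungroup()
}

#' Restrict a repertoire to productive rearrangements
#'
#' Keeps clonotypes that are in frame, free of stop codons and (when a
#' segment library is supplied) use only functional V and J genes — open
#' reading frame and pseudogene segments are excluded. Frequencies are
#' re-normalized over the retained reads. Productivity is taken from the
#' `cdr3_nt` translation when available, otherwise from the `productive`
#' flag; a clonotype with neither is an error. The operation is idempotent.
#'
#' @param df A clonotype tibble.
#' @param segments Optional segment library (see [gd_segment_library()])
#'   with columns `name` and `functionality`.
#' @return The filtered, re-normalized clonotype tibble.
#' @export
filter_productive <- function(df, segments = NULL) {
  check_clonotypes(df)
  has_nt <- !is.na(df$cdr3_nt) & df$cdr3_nt != ""
  if (!"productive" %in% names(df)) df$productive <- NA
  unresolvable <- !has_nt & is.na(df$productive)
  if (any(unresolvable)) {
    abort(sprintf(
      "%d clonotype(s) lack both cdr3_nt and a productive flag; cannot assess productivity.",
      sum(unresolvable)))
  }
  keep <- df$productive
  if (any(has_nt)) {
    verdict <- translate_cdr3(df$cdr3_nt[has_nt])$verdict
    keep[has_nt] <- verdict == "productive"
  }
  # stop symbol in a supplied aa sequence always disqualifies
  keep[!is.na(df$cdr3_aa) & grepl("*", df$cdr3_aa, fixed = TRUE)] <- FALSE
  if (!is.null(segments)) {
    functional <- segments$name[segments$functionality == "functional"]
    known <- segments$name
    v_bad <- df$v_call %in% setdiff(known, functional)
    j_bad <- df$j_call %in% setdiff(known, functional)
    keep <- keep & !v_bad & !j_bad
  }
  out <- df[keep & !is.na(keep), ]
  out$productive <- TRUE
  normalize_frequencies(out)
}

#' Read patient metadata
#'
#' CSV with one row per patient: `patient_id`, `disease` (one of
#' `Tgd_LGLL`, `HSTCL`, `control`), `course` (`symptomatic`, `indolent`,
#' `not_applicable`), optional `tgd_fraction_pbmc` and `abs_tgd_per_ul`,
#' and any number of marker / clinical-flag columns encoded as `+`, `-`, or
#' `na`. Tri-states are kept as `"+"`, `"-"`, `NA`; unknowns are never
#' imputed.
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per patient.
#' @export
read_patient_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("patient_id", "disease") %in% names(raw))) {
    abort("Patient metadata needs 'patient_id' and 'disease' columns.")
  }
  dup <- raw$patient_id[duplicated(raw$patient_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate patient_id: %s", paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(unique(raw$disease), c("Tgd_LGLL", "HSTCL", "control"))
  if (length(bad)) {
    abort(sprintf("Unknown disease label(s): %s", paste(bad, collapse = ", ")))
  }
  numeric_cols <- intersect(c("tgd_fraction_pbmc", "abs_tgd_per_ul"), names(raw))
  tri_cols <- setdiff(names(raw), c("patient_id", "disease", "course", numeric_cols))
  out <- raw
  for (col in numeric_cols) out[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  for (col in tri_cols) {
    v <- raw[[col]]
    v[!v %in% c("+", "-")] <- NA_character_
    out[[col]] <- v
  }
  out
}

#' Write major-clonotype CDR3 amino-acid sequences as FASTA
#'
#' Record ids follow `sample_id|chain|rank`, rank being the within-sample
#' descending-frequency rank.
#'
#' @param df A clonotype tibble with `cdr3_aa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cdr3_fasta <- function(df, path) {
  check_clonotypes(df)
  df <- df %>%
    dplyr::filter(!is.na(.data$cdr3_aa)) %>%
    dplyr::group_by(.data$sample_id, .data$chain) %>%
    dplyr::arrange(dplyr::desc(.data$frequency), .data$cdr3_aa,
                   .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup()
  seqs <- Biostrings::AAStringSet(df$cdr3_aa)
  names(seqs) <- paste(df$sample_id, df$chain, df$rank, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
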