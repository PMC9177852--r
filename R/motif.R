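AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a CDR3 motif matrix
#'
#' Multiple-aligns a set of CDR3 amino-acid sequences and summarizes the
#' alignment as a position-frequency matrix with per-column information
#' content. The alignment is a deterministic center-star construction: the
#' center is the sequence minimizing the summed pairwise edit distance
#' (ties broken by input order); every other sequence is globally aligned
#' to the center (BLOSUM62, gap open 10, gap extend 1) and the pairwise
#' alignments are merged under the once-a-gap-always-a-gap rule.
#' Per-column residue frequencies are computed over non-gap symbols and
#' information content in bits is `log2(20) - H` with `H` the Shannon
#' entropy of the column.
#'
#' @param cdr3_aa Character vector of at least two amino-acid sequences,
#'   each of length at least 2.
#' @param gap_open,gap_extend Positive gap penalties for the pairwise
#'   global alignments.
#' @return An object of class `tcrgd_motif`: a list with `alignment`
#'   (gap-padded strings of equal length), `pfm` (20 x L matrix of
#'   per-column residue fractions over non-gaps), `bits` (per-column
#'   information content), `n` (number of sequences).
#' @export
#' @examples
#' m <- build_motif_matrix(c("CALWEVEELGKKIKVF", "CALWEVRELGKKIKVF",
#'                           "CALWEDRELGKKIKVF"))
#' tidy(m)
build_motif_matrix <- function(cdr3_aa, gap_open = 10, gap_extend = 1) {
  cdr3_aa <- toupper(cdr3_aa)
  if (length(cdr3_aa) < 2) {
    abort("Need at least two sequences to build an alignment.")
  }
  if (any(is.na(cdr3_aa)) || any(nchar(cdr3_aa) < 2)) {
    abort("All sequences must be non-missing and of length >= 2.")
  }
  if (any(grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), cdr3_aa))) {
    abort("Sequences may contain only the 20 standard amino acids.")
  }

  d <- utils::adist(cdr3_aa)
  center_idx <- which.min(rowSums(d))
  center <- cdr3_aa[center_idx]
  others <- setdiff(seq_along(cdr3_aa), center_idx)

  L <- nchar(center)
  # per-alignment insertions: slot s = gap block after center residue s
  # (slot 0 = before the first residue)
  blosum_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = blosum_env)
  parsed <- lapply(others, function(i) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = cdr3_aa[i], subject = center, type = "global",
      substitutionMatrix = blosum_env$BLOSUM62,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    s_al <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    p_al <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    slot <- cumsum(s_al != "-")
    frags <- vapply(0:L, function(s) {
      paste(p_al[s_al == "-" & slot == s], collapse = "")
    }, character(1))
    res <- p_al[s_al != "-"]
    list(frags = frags, res = res)
  })

  ins <- rep(0L, L + 1)
  for (p in parsed) ins <- pmax(ins, nchar(p$frags))

  weave <- function(frags, res) {
    out <- character(0)
    for (s in 0:L) {
      frag <- frags[s + 1]
      out <- c(out, frag, strrep("-", ins[s + 1] - nchar(frag)))
      if (s < L) out <- c(out, res[s + 1])
    }
    paste(out, collapse = "")
  }
  aligned <- character(length(cdr3_aa))
  aligned[center_idx] <- weave(rep("", L + 1), strsplit(center, "")[[1]])
  for (k in seq_along(others)) {
    aligned[others[k]] <- weave(parsed[[k]]$frags, parsed[[k]]$res)
  }
  stopifnot(length(unique(nchar(aligned))) == 1)

  mat <- do.call(rbind, strsplit(aligned, ""))
  ncol_al <- ncol(mat)
  pfm <- matrix(0, nrow = length(AA_ALPHABET20), ncol = ncol_al,
                dimnames = list(AA_ALPHABET20, NULL))
  bits <- numeric(ncol_al)
  for (j in seq_len(ncol_al)) {
    col <- mat[, j]
    col <- col[col != "-"]
    f <- table(factor(col, levels = AA_ALPHABET20)) / length(col)
    pfm[, j] <- as.numeric(f)
    nz <- pfm[, j][pfm[, j] > 0]
    bits[j] <- log2(20) + sum(nz * log2(nz))
  }
  structure(
    list(alignment = aligned, pfm = pfm, bits = bits, n = length(cdr3_aa)),
    class = "tcrgd_motif"
  )
}

#' @export
print.tcrgd_motif <- function(x, ...) {
  cat(sprintf("CDR3 motif matrix: %d sequences, %d alignment columns\n",
              x$n, length(x$bits)))
  cat(sprintf("Mean information content: %.2f bits/column\n", mean(x$bits)))
  invisible(x)
}

#' Tidy a motif matrix into long format
#'
#' @param x A `tcrgd_motif` object.
#' @param ... Unused.
#' @return A tibble with `position`, `residue`, `frequency`, `bits`
#'   (column information content, repeated within a position).
#' @method tidy tcrgd_motif
#' @export
tidy.tcrgd_motif <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(ncol(x$pfm)), each = nrow(x$pfm)),
    residue = rep(rownames(x$pfm), times = ncol(x$pfm)),
    frequency = as.vector(x$pfm),
    bits = rep(x$bits, each = nrow(x$pfm))
  )
}

#' @rdname tidy.tcrgd_motif
#' @return For `glance()`: a one-row tibble with `n_sequences`,
#'   `n_columns`, `mean_bits`.
#' @method glance tcrgd_motif
#' @export
glance.tcrgd_motif <- function(x, ...) {
  tibble::tibble(n_sequences = x$n, n_columns = length(x$bits),
                 mean_bits = mean(x$bits))
}

#' Plot a motif matrix as a sequence-logo-style letter chart
#'
#' Letters at each alignment position are stacked with heights proportional
#' to their share of the column's information content, the usual
#' information-scaled logo layout.
#'
#' @param object A `tcrgd_motif` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tcrgd_motif
#' @export
autoplot.tcrgd_motif <- function(object, ...) {
  df <- tidy(object) %>%
    dplyr::filter(.data$frequency > 0) %>%
    dplyr::mutate(height = .data$frequency * .data$bits) %>%
    dplyr::group_by(.data$position) %>%
    dplyr::arrange(.data$height, .by_group = TRUE) %>%
    dplyr::mutate(ymax = cumsum(.data$height),
                  ymid = .data$ymax - .data$height / 2) %>%
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid,
                                   label = .data$residue,
                                   size = .data$height)) +
    ggplot2::geom_text(ggplot2::aes(colour = .data$residue),
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 8), guide = "none") +
    ggplot2::labs(x = "Alignment position", y = "Information (bits)") +
    ggplot2::theme_minimal()
}

#' Write a position-frequency matrix as TSV
#'
#' @param x A `tcrgd_motif` object.
#' @param path Output path; rows are residues, columns alignment positions.
#' @return `path`, invisibly.
#' @export
write_motif_pfm <- function(x, path) {
  stopifnot(inherits(x, "tcrgd_motif"))
  df <- tibble::as_tibble(x$pfm, .name_repair = ~ paste0("pos", seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(residue = rownames(x$pfm)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
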