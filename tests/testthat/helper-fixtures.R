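# small in-code fixtures shared across test files

tiny_clonotypes <- function() {
  tibble::tibble(
    sample_id = "s1", group = "control", chain = "TRG",
    v_call = c("TRGV9", "TRGV9", "TRGV2"),
    d_call = NA_character_,
    j_call = c("TRGJP", "TRGJ1/2", "TRGJP2"),
    cdr3_nt = c("TGTGCCCTGTGG", "TGTGCCACCTGG", "TGTGCCACCGGG"),
    cdr3_aa = c("CALW", "CATW", "CATG"),
    read_count = c(60L, 30L, 10L),
    frequency = NA_real_, productive = TRUE
  )
}

write_internal_fixture <- function(df = tiny_clonotypes()) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# patient-level repertoire set built from the bundled pilot majors plus a
# synthetic polyclonal control; used by recurrence/publicity tests
pilot_with_control <- function(control_seqs = c("CALERGKLF", "CAAAAF")) {
  majors <- pilot_major_clonotypes()
  ctrl <- tibble::tibble(
    sample_id = "ctrl1", group = "control", chain = "TRG",
    v_call = "TRGV9", d_call = NA_character_, j_call = "TRGJP",
    cdr3_nt = NA_character_, cdr3_aa = control_seqs,
    read_count = 50L, frequency = 1 / length(control_seqs), productive = TRUE
  )
  dplyr::bind_rows(majors, ctrl)
}
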