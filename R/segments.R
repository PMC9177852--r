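#' Synthetic TRG/TRD gene-segment library
#'
#' A compact, fully synthetic germline segment library for the V(D)J
#' simulator. Sequences are invented but structurally faithful to real
#' gamma/delta loci: every V segment encodes the conserved cysteine at its
#' anchor codon, every J segment the conserved phenylalanine, and the
#' TRGJ1/2 and TRGJP joining segments encode the adjacent double-lysine
#' (KK) motif upstream of the anchor, as their natural counterparts do.
#' `TRGJ1/2` models the TRGJ1/TRGJ2 pair that amplicon assays cannot
#' distinguish. Two non-functional gamma V segments (one ORF, one
#' pseudogene) are included so the functional-gene filter has something to
#' remove. A real IMGT reference can be substituted by supplying any tibble
#' with the same columns.
#'
#' @return A tibble with columns `name`, `chain`, `segment_class`,
#'   `functionality`, `sequence`, `anchor_offset` (1-based codon index of
#'   the conserved C or F within `sequence`; `NA` for D segments).
#' @export
gd_segment_library <- function() {
  tibble::tribble(
    ~name,      ~chain, ~segment_class, ~functionality, ~sequence,                                  ~anchor_offset,
    "TRGV2",    "TRG",  "V", "functional", "CAGCTGTGTGCCACCTGGGATGGC",                   3L,
    "TRGV3",    "TRG",  "V", "functional", "CAGCTGTGTGCCACCTGGGATAGG",                   3L,
    "TRGV4",    "TRG",  "V", "functional", "CAGCTGTGTGCCACCTGG",                         3L,
    "TRGV8",    "TRG",  "V", "functional", "CAGCTGTGTGCCACCTGGGAT",                      3L,
    "TRGV9",    "TRG",  "V", "functional", "CAGCTGTGTGCCCTGTGGGAGGTG",                   3L,
    "TRGV10",   "TRG",  "V", "ORF",        "CAGCTGTGTGCCACCTGG",                         3L,
    "TRGV11",   "TRG",  "V", "pseudogene", "CAGCTGTGTGCCACCTGG",                         3L,
    "TRGJ1/2",  "TRG",  "J", "functional", "TATTATAAGAAACTGTTTGGCAGCGGC",                6L,
    "TRGJP",    "TRG",  "J", "functional", "CAGGAGCTGGGCAAGAAAATCAAGGTGTTTGGCCCCGGC",    10L,
    "TRGJP1",   "TRG",  "J", "functional", "ACCACCGGCTGGTTCAAGATCTTTGGCAAGGGC",          8L,
    "TRGJP2",   "TRG",  "J", "functional", "AGCAGCGATTGGATCAAGACCTTTGGCAAAGGC",          8L,
    "TRDV1",    "TRD",  "V", "functional", "CAGCTGTGTGCCCTGGGCGAG",                      3L,
    "TRDV2",    "TRD",  "V", "functional", "CAGCTGTGTGCCTGTGACACC",                      3L,
    "TRDV5",    "TRD",  "V", "functional", "CAGCTGTGTGCCGCCAGC",                         3L,
    "TRDV8",    "TRD",  "V", "functional", "CAGCTGTGTGCCTAT",                            3L,
    "TRDD2",    "TRD",  "D", "functional", "CCTTCCTAC",                                  NA_integer_,
    "TRDD3",    "TRD",  "D", "functional", "ACTGGGGGATACG",                              NA_integer_,
    "TRDJ1",    "TRD",  "J", "functional", "AACACCGATAAGCTGATCTTTGGCAGCGGC",             7L,
    "TRDJ3",    "TRD",  "J", "functional", "AGCTGGGACACCCGGCAGATGTTCTTTGGCACCGGC",       9L
  )
}

# codon usage table for synonymous resampling (standard code, no stops)
codons_by_aa <- function() {
  codons <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  paste0), c("T", "C", "A", "G"), paste0))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(codons),
                                           no.init.codon = TRUE))
  split(codons, aa)[setdiff(unique(aa), "*")]
}
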