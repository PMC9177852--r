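#' Bundled pilot-cohort major clonotypes
#'
#' Major clonotypes (frequency >= 5% of productive reads, per chain) called
#' by deep TCR sequencing in an 11-sample pilot cohort of gamma/delta
#' lymphoproliferative disease: 2 hepatosplenic T-cell lymphomas (HSTCL),
#' 4 symptomatic and 5 indolent T gamma/delta LGL leukemias. Gene calls are
#' at gene-level granularity; `TRGJ1/2` denotes the TRGJ1/TRGJ2 pair, which
#' amplicon assays cannot distinguish. CDR3 nucleotide sequences are not
#' part of this fixture (`cdr3_nt` is `NA`); frequencies are fractions of
#' productive reads of the same chain.
#'
#' @return A tibble with one row per major clonotype entry and the standard
#'   clonotype columns (`sample_id`, `group`, `chain`, `v_call`, `d_call`,
#'   `j_call`, `cdr3_nt`, `cdr3_aa`, `read_count`, `frequency`,
#'   `productive`).
#' @seealso [pilot_patients()], [pilot_mutations()], [cohort_feature_counts()]
#' @export
#' @examples
#' majors <- pilot_major_clonotypes()
#' dplyr::count(majors, chain)
pilot_major_clonotypes <- function() {
  g <- tibble::tribble(
    ~sample_id, ~v_call,  ~j_call,   ~frequency, ~cdr3_aa,
    "pt1",  "TRGV8", "TRGJ1/2", 0.9738, "CATWDSSYYKKLF",
    "pt2",  "TRGV3", "TRGJ1/2", 0.9820, "CATWDRLHYYKKLF",
    "pt3",  "TRGV3", "TRGJ1/2", 0.8382, "CATWDRYKKLF",
    "pt4",  "TRGV4", "TRGJ1/2", 0.6161, "CATWDGPSMDYYKKLF",
    "pt4",  "TRGV8", "TRGJP1",  0.1889, "CATWDRGGTTGWFKIF",
    "pt4",  "TRGV3", "TRGJP2",  0.0563, "CATWDRPDWIKTF",
    "pt5",  "TRGV2", "TRGJP2",  0.4099, "CATWDGPGSSDWIKTF",
    "pt5",  "TRGV2", "TRGJ1/2", 0.3566, "CATWDGPSYYKKLF",
    "pt5",  "TRGV8", "TRGJ1/2", 0.0885, "CATWDRWYYKKLF",
    "pt6",  "TRGV2", "TRGJ1/2", 0.2511, "CATWDGRVNYYKKLF",
    "pt6",  "TRGV2", "TRGJP2",  0.0918, "CATWDYCSDWIKTF",
    "pt6",  "TRGV4", "TRGJ1/2", 0.0712, "CATWEKGKLLYKKLF",
    "pt6",  "TRGV8", "TRGJP2",  0.0640, "CATWDSSDWIKTF",
    "pt7",  "TRGV9", "TRGJP",   0.3204, "CALWEVEELGKKIKVF",
    "pt7",  "TRGV9", "TRGJ1/2", 0.2605, "CALERGKLF",
    "pt7",  "TRGV9", "TRGJP",   0.2293, "CALWEVRELGKKIKVF",
    "pt8",  "TRGV9", "TRGJP",   0.5565, "CALWEVRELGKKIKVF",
    "pt9",  "TRGV9", "TRGJP",   0.6134, "CALWEDRELGKKIKVF",
    "pt10", "TRGV9", "TRGJP",   0.2075, "CALWEVRELGKKIKVF",
    "pt10", "TRGV9", "TRGJP",   0.1902, "CALWEEELGKKIKVF",
    "pt10", "TRGV9", "TRGJP",   0.1216, "CALWDTELGKKIKVF",
    "pt11", "TRGV9", "TRGJP",   0.3653, "CALWEVEELGKKIKVF"
  )
  g$chain <- "TRG"
  g$d_call <- NA_character_

  d <- tibble::tribble(
    ~sample_id, ~v_call,  ~d_call,  ~j_call,  ~frequency, ~cdr3_aa,
    "pt1",  "TRDV1", "TRDD3", "TRDJ1", 0.9952, "CALALPGIRGYTDKLIF",
    "pt2",  "TRDV1", "TRDD2", "TRDJ1", 0.9505, "CALGDDIHPLPNTDKLIF",
    "pt3",  "TRDV5", "TRDD3", "TRDJ1", 0.9323, "CAASAIGSRGTDKLIF",
    "pt4",  "TRDV1", "TRDD3", "TRDJ1", 0.9298, "CALGEAPLGDTHSDKLIF",
    "pt5",  "TRDV1", "TRDD2", "TRDJ1", 0.5101, "CALGELVGGPFNTDKLIF",
    "pt5",  "TRDV1", "TRDD3", "TRDJ1", 0.3243, "CALGERRGDTFGADKLIF",
    "pt5",  "TRDV1", "TRDD3", "TRDJ1", 0.1497, "CALGEPPPSLGESKLIF",
    "pt6",  "TRDV5", "TRDD3", "TRDJ1", 0.1789, "CAATSSYWGIYTDKLIF",
    "pt6",  "TRDV1", "TRDD2", "TRDJ1", 0.0972, "CALGVLPPGVHKLIF",
    "pt6",  "TRDV1", "TRDD3", "TRDJ1", 0.0901, "CALGPFLPTGGYTDKLIF",
    "pt6",  "TRDV1", "TRDD2", "TRDJ1", 0.0721, "CALGEAAPYQPSYTDKLIF",
    "pt6",  "TRDV8", "TRDD3", "TRDJ1", 0.0668, "CAYRSSTLFPYWGIRPDKLIF",
    "pt7",  "TRDV2", "TRDD3", "TRDJ1", 0.6070, "CACDTLLGDTRSNTDKLIF",
    "pt7",  "TRDV2", "TRDD3", "TRDJ3", 0.3888, "CACDTLLGDTEDSWDTRQMFF",
    "pt8",  "TRDV2", "TRDD3", "TRDJ1", 0.9818, "CACDTVVRGDLNTDKLIF",
    "pt9",  "TRDV2", "TRDD3", "TRDJ1", 0.8250, "CACDTVGLGDTPSTDKLIF",
    "pt9",  "TRDV2", "TRDD3", "TRDJ1", 0.0550, "CACDVLGDTTDKLIF",
    "pt10", "TRDV2", "TRDD3", "TRDJ3", 0.3973, "CACDTSGGHPLSWDTRQMFF",
    "pt10", "TRDV2", "TRDD3", "TRDJ1", 0.3766, "CACDTVGLGENGADKLIF",
    "pt10", "TRDV2", "TRDD3", "TRDJ1", 0.1696, "CACDSILGALRRSPNTDKLIF",
    "pt11", "TRDV2", "TRDD3", "TRDJ1", 0.3919, "CACDTVEGWGIQAGDKLIF",
    "pt11", "TRDV2", "TRDD3", "TRDJ3", 0.3107, "CACDSTGEISWDTRQMFF",
    "pt11", "TRDV2", "TRDD3", "TRDJ1", 0.0725, "CACDTLGDTDKLIF",
    "pt11", "TRDV2", "TRDD3", "TRDJ3", 0.0540, "CACDTVRTGGYAWDTRQMFF"
  )
  d$chain <- "TRD"

  out <- dplyr::bind_rows(g, d)
  groups <- c(
    pt1 = "HSTCL", pt2 = "HSTCL",
    pt3 = "symptomatic_LGLL", pt4 = "symptomatic_LGLL",
    pt5 = "symptomatic_LGLL", pt6 = "symptomatic_LGLL",
    pt7 = "indolent_LGLL", pt8 = "indolent_LGLL", pt9 = "indolent_LGLL",
    pt10 = "indolent_LGLL", pt11 = "indolent_LGLL"
  )
  out$group <- unname(groups[out$sample_id])
  out$cdr3_nt <- NA_character_
  out$read_count <- NA_integer_
  out$productive <- TRUE
  out[, clonotype_cols]
}

#' Bundled pilot-cohort patient records
#'
#' Flow-cytometric and clinical summary of the 11 pilot patients: disease,
#' clinical course, T gamma/delta fraction of PBMC (the substrate of the
#' STAT mutation assay) and the Vd1/Vd2/Vg9 clone phenotype.
#'
#' @return A tibble with one row per patient.
#' @export
pilot_patients <- function() {
  tibble::tribble(
    ~patient_id, ~disease,    ~course,        ~tgd_fraction_pbmc, ~Vd1, ~Vd2, ~Vg9,
    "pt1",  "HSTCL",    "not_applicable", 0.87, "+", "-", "-",
    "pt2",  "HSTCL",    "not_applicable", 0.95, "+", "-", "-",
    "pt3",  "Tgd_LGLL", "symptomatic",    0.65, "-", "-", "-",
    "pt4",  "Tgd_LGLL", "symptomatic",    0.66, "+", "-", "-",
    "pt5",  "Tgd_LGLL", "symptomatic",    0.45, "+", "-", "-",
    "pt6",  "Tgd_LGLL", "symptomatic",    0.26, "+", "-", "-",
    "pt7",  "Tgd_LGLL", "indolent",       0.58, "-", "+", "+",
    "pt8",  "Tgd_LGLL", "indolent",       0.42, "-", "+", "+",
    "pt9",  "Tgd_LGLL", "indolent",       0.83, "-", "+", "+",
    "pt10", "Tgd_LGLL", "indolent",       0.34, "-", "+", "+",
    "pt11", "Tgd_LGLL", "indolent",       0.23, "-", "+", "+"
  )
}

#' Bundled pilot-cohort STAT3/STAT5B mutation calls
#'
#' Somatic STAT3/STAT5B variant calls with variant allele fractions (VAF)
#' measured by targeted amplicon sequencing of PBMC in the pilot cohort.
#' `phase` is "monoallelic" where two co-occurring variants of the same gene
#' were shown to lie on the same allele, otherwise "unknown". Wild-type
#' patients (pt5, pt6, pt10, pt11) carry no rows.
#'
#' @return A tibble with columns `patient_id`, `gene`, `aa_change`, `vaf`,
#'   `phase`.
#' @export
pilot_mutations <- function() {
  tibble::tribble(
    ~patient_id, ~gene,    ~aa_change,      ~vaf,   ~phase,
    "pt1",  "STAT5B", "V712E",         0.8599, "unknown",
    "pt2",  "STAT5B", "N642H",         0.2112, "unknown",
    "pt3",  "STAT3",  "K658R",         0.2679, "monoallelic",
    "pt3",  "STAT3",  "I659_M660insL", 0.2635, "monoallelic",
    "pt4",  "STAT3",  "D661Y",         0.4107, "unknown",
    "pt7",  "STAT5B", "N642H",         0.1755, "unknown",
    "pt7",  "STAT5B", "Q706L",         0.1434, "unknown",
    "pt8",  "STAT5B", "N642H",         0.1074, "monoallelic",
    "pt8",  "STAT5B", "L643M",         0.1041, "monoallelic",
    "pt9",  "STAT5B", "Y665F",         0.1303, "unknown"
  )
}

#' Bundled enlarged-cohort feature counts
#'
#' Per-feature positive counts and denominators for the enlarged cohort
#' (36 T gamma/delta LGLL split into 17 symptomatic and 19 indolent, plus 3
#' HSTCL shown descriptively). Denominators vary by feature because not all
#' markers were determined in all patients; maturation markers (CD28,
#' CD45RA, CD45RO, CD62L) were assessed in a 25-patient subcohort and not
#' in HSTCL. `reported_significant` records which rows the source cohort
#' report flagged at P < 0.05.
#'
#' @return A tibble with one row per feature.
#' @export
cohort_feature_counts <- function() {
  tibble::tribble(
    ~feature, ~symptomatic_pos, ~symptomatic_n, ~indolent_pos, ~indolent_n,
    ~hstcl_pos, ~hstcl_n, ~reported_significant,
    "CD5",                 9L, 17L, 18L, 19L, 0L, 3L, TRUE,
    "CD8",                11L, 17L, 14L, 19L, 1L, 3L, FALSE,
    "HLA-DR",              1L, 17L,  1L, 19L, 0L, 3L, FALSE,
    "CD16",               16L, 17L, 17L, 19L, 3L, 3L, FALSE,
    "CD56",                4L, 17L, 15L, 19L, 3L, 3L, TRUE,
    "CD57",               16L, 17L, 17L, 19L, 0L, 3L, FALSE,
    "CD158",               7L, 16L,  7L, 19L, 3L, 3L, FALSE,
    "CD158a",              0L, 16L,  3L, 19L, 3L, 3L, FALSE,
    "CD158b",              6L, 16L,  5L, 19L, 3L, 3L, FALSE,
    "CD158e",              2L, 16L,  2L, 19L, 2L, 3L, FALSE,
    "NKG2",                6L, 16L, 14L, 19L, 3L, 3L, TRUE,
    "NKG2A",               3L, 16L, 14L, 19L, 0L, 3L, TRUE,
    "NKG2C",               3L, 16L,  0L, 19L, 3L, 3L, FALSE,
    "Vd1+/Vg9-",          11L, 17L,  0L, 19L, 2L, 3L, TRUE,
    "Vd2+/Vg9+",           2L, 17L, 19L, 19L, 0L, 3L, TRUE,
    "Vd1-/Vd2-",           4L, 17L,  0L, 19L, 1L, 3L, FALSE,
    "CD28",                0L, 11L,  0L, 14L, NA_integer_, NA_integer_, FALSE,
    "CD45RA",             10L, 11L, 13L, 14L, NA_integer_, NA_integer_, FALSE,
    "CD45RO",              6L, 11L, 14L, 14L, NA_integer_, NA_integer_, TRUE,
    "CD62L",               0L, 11L,  6L, 14L, NA_integer_, NA_integer_, TRUE,
    "STAT_mutated",        7L, 17L,  3L, 19L, 3L, 3L, FALSE,
    "STAT3_mutated",       7L, 17L,  0L, 19L, 0L, 3L, TRUE,
    "STAT5B_mutated",      0L, 17L,  3L, 19L, 3L, 3L, FALSE,
    "neutropenia",        16L, 17L,  0L, 19L, 1L, 3L, TRUE,
    "anemia",              9L, 17L,  0L, 19L, 2L, 3L, TRUE,
    "thrombocytopenia",    2L, 17L,  0L, 19L, 3L, 3L, FALSE,
    "autoimmune_disease",  8L, 17L,  2L, 19L, 0L, 3L, TRUE,
    "splenomegaly",        4L, 17L,  0L, 19L, 3L, 3L, FALSE,
    "secondary_neoplasia", 5L, 17L,  3L, 19L, 0L, 3L, FALSE,
    "in_therapy",          7L, 17L,  0L, 19L, 3L, 3L, TRUE,
    "deceased",            1L, 17L,  0L, 19L, 2L, 3L, FALSE
  )
}
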