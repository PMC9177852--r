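#' Simulate V(D)J rearrangements
#'
#' Draws `n` rearrangements of one chain from a segment library: V, (D)
#' and J segments are sampled by weight; the 3' end of V, both ends of D
#' and the 5' end of J are trimmed by a capped geometric number of
#' nucleotides (default p = 0.25, cap 10); Poisson-distributed random N
#' nucleotides (default lambda = 4) are inserted at each junction. The
#' CDR3 spans the conserved V cysteine anchor through the conserved J
#' phenylalanine anchor, and productivity is assessed by translation:
#' in frame and stop-free. Roughly a third of draws are productive (frame
#' 1/3 minus stop losses).
#'
#' @param n Number of rearrangements.
#' @param chain `"TRG"` or `"TRD"`.
#' @param segments Segment library tibble (see [gd_segment_library()]).
#' @param v_weights,d_weights,j_weights Optional named weight vectors over
#'   functional segment names; default uniform over functional segments.
#' @param trim_p,trim_cap Geometric trimming parameter and cap (nt).
#' @param insert_lambda Poisson mean of N insertions per junction.
#' @param seed Optional seed; when given the draw is reproducible and the
#'   global RNG state is left untouched.
#' @return A clonotype-shaped tibble (without counts/frequencies):
#'   `chain`, `v_call`, `d_call`, `j_call`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`.
#' @export
simulate_rearrangement <- function(n = 1, chain = c("TRG", "TRD"),
                                   segments = gd_segment_library(),
                                   v_weights = NULL, d_weights = NULL,
                                   j_weights = NULL,
                                   trim_p = 0.25, trim_cap = 10,
                                   insert_lambda = 4, seed = NULL) {
  chain <- match.arg(chain)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_rearrangement(
      n, chain, segments, v_weights, d_weights, j_weights,
      trim_p, trim_cap, insert_lambda, seed = NULL)))
  }
  seg <- segments[segments$chain == chain &
                    segments$functionality == "functional", ]
  pick_set <- function(class, weights) {
    s <- seg[seg$segment_class == class, ]
    if (nrow(s) == 0) {
      if (class == "D" && chain == "TRG") return(NULL)
      abort(sprintf("No functional %s segments for chain %s.", class, chain))
    }
    w <- if (is.null(weights)) stats::setNames(rep(1, nrow(s)), s$name)
    else weights[s$name[s$name %in% names(weights)]]
    w <- w[!is.na(w)]
    if (!length(w) || any(w < 0)) abort("Invalid segment weights.")
    list(seg = s, w = w / sum(w))
  }
  vs <- pick_set("V", v_weights)
  js <- pick_set("J", j_weights)
  ds <- if (chain == "TRD") pick_set("D", d_weights) else NULL

  trim <- function(k) pmin(stats::rgeom(k, trim_p), trim_cap)
  nins <- function(k) stats::rpois(k, insert_lambda)
  rand_nt <- function(len) {
    vapply(len, function(l) paste(sample(c("A", "C", "G", "T"), l,
                                         replace = TRUE), collapse = ""),
           character(1))
  }

  v_names <- sample(names(vs$w), n, replace = TRUE, prob = vs$w)
  j_names <- sample(names(js$w), n, replace = TRUE, prob = js$w)
  v_idx <- match(v_names, vs$seg$name)
  j_idx <- match(j_names, js$seg$name)
  v_full <- substring(vs$seg$sequence[v_idx],
                      (vs$seg$anchor_offset[v_idx] - 1) * 3 + 1)
  j_full <- substr(js$seg$sequence[j_idx], 1,
                   js$seg$anchor_offset[j_idx] * 3)
  v_part <- substr(v_full, 1, pmax(0, nchar(v_full) - trim(n)))
  j_trimn <- trim(n)
  j_part <- substring(j_full, pmin(j_trimn + 1, nchar(j_full) + 1))

  if (chain == "TRD") {
    d_names <- sample(names(ds$w), n, replace = TRUE, prob = ds$w)
    d_full <- ds$seg$sequence[match(d_names, ds$seg$name)]
    d5 <- trim(n); d3 <- trim(n)
    d_part <- substr(d_full, pmin(d5 + 1, nchar(d_full) + 1),
                     pmax(0, nchar(d_full) - d3))
    cdr3 <- paste0(v_part, rand_nt(nins(n)), d_part, rand_nt(nins(n)), j_part)
  } else {
    d_names <- NA_character_
    cdr3 <- paste0(v_part, rand_nt(nins(n)), j_part)
  }
  tr <- translate_cdr3(cdr3)
  tibble::tibble(
    chain = chain, v_call = v_names, d_call = d_names, j_call = j_names,
    cdr3_nt = cdr3,
    cdr3_aa = ifelse(tr$verdict == "productive", tr$cdr3_aa, NA_character_),
    productive = tr$verdict == "productive"
  )
}

# draw until n productive rearrangements are collected
sample_productive <- function(n, chain, segments = gd_segment_library(), ...) {
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    batch <- simulate_rearrangement(max(3 * n, 30), chain, segments, ...)
    out <- dplyr::bind_rows(out, batch[batch$productive, ])
  }
  out[seq_len(n), ]
}

#' Generate convergent nucleotide variants of a CDR3 amino-acid sequence
#'
#' Emulates convergent recombination: returns `n_variants` clonotypes with
#' pairwise-distinct nucleotide sequences, produced by synonymous codon
#' resampling, all translating to `aa_seq`.
#'
#' @param aa_seq Amino-acid sequence over the 20 standard residues.
#' @param v_name,j_name Gene names to attach to the variants.
#' @param n_variants Number of distinct nucleotide encodings.
#' @param d_name Optional D gene name (TRD).
#' @param seed Optional seed for reproducible draws.
#' @return A tibble with `v_call`, `d_call`, `j_call`, `cdr3_nt`,
#'   `cdr3_aa`, `productive`.
#' @export
plant_public_clonotype <- function(aa_seq, v_name, j_name, n_variants = 1,
                                   d_name = NA_character_, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, plant_public_clonotype(
      aa_seq, v_name, j_name, n_variants, d_name, seed = NULL)))
  }
  aa <- strsplit(toupper(aa_seq), "")[[1]]
  tab <- codons_by_aa()
  if (any(!aa %in% names(tab))) {
    abort(sprintf("Non-standard residue(s) in aa_seq: %s",
                  paste(setdiff(aa, names(tab)), collapse = ", ")))
  }
  max_var <- prod(pmin(vapply(tab[aa], length, integer(1)), 1e9))
  if (n_variants > max_var) {
    abort("More variants requested than distinct synonymous encodings exist.")
  }
  nts <- character(0)
  tries <- 0
  while (length(nts) < n_variants && tries < 1000 * n_variants) {
    cand <- paste(vapply(tab[aa], function(cs) sample(cs, 1), character(1)),
                  collapse = "")
    nts <- unique(c(nts, cand))
    tries <- tries + 1
  }
  if (length(nts) < n_variants) abort("Failed to find distinct encodings.")
  tibble::tibble(
    v_call = v_name, d_call = d_name, j_call = j_name,
    cdr3_nt = nts, cdr3_aa = paste(aa, collapse = ""), productive = TRUE
  )
}

#' Simulate a patient + control cohort of TRG/TRD repertoires
#'
#' Generates a cohort with the statistical structure the analysis
#' pipeline assumes: a shared polyclonal background pool (the common
#' healthy repertoire, with geometric or power-law clone sizes and no
#' clone at or above 5%), indolent patients carrying dominant
#' TRGV9-TRGJP / TRDV2-TRDD3-TRDJ1 clones that include convergent public
#' gamma sequences shared across patients (and present in controls via
#' the pool), one gamma sequence planted as private to the disease in two
#' indolent patients, symptomatic patients with diverse Vd2-negative
#' usage, and HSTCL samples with a single dominant TRDV1 clone at about
#' 95%. Clone frequencies are realized by multinomial sampling of
#' `read_depth` reads. The returned truth record carries every plant, the
#' expected publicity label of every planted patient-major sequence, and
#' per-patient mutation truth (gene, zygosity, cancer-cell fraction, true
#' VAF = clone fraction x ccf x 0.5 for heterozygous or x 1 for
#' homozygous).
#'
#' @param n_indolent,n_symptomatic,n_hstcl,n_controls Cohort sizes
#'   (defaults mirror the 11-patient / 23-control study design).
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param read_depth Reads per sample and chain (default 400,000, the
#'   magnitude of the study's median sequencing depth).
#' @param n_background Clonotypes in the shared background pool per chain.
#' @param background_q Geometric decay of background clone sizes (top
#'   background clone has relative weight about `background_q`).
#' @param clone_size_law `"geometric"` or `"power_law"` background sizes.
#' @param n_dominant_range Range of dominant-clone counts per patient
#'   chain (indolent/symptomatic); use `c(1, 1)` for strictly monoclonal
#'   patients.
#' @param p_mut_symptomatic,p_mut_indolent Probability that a symptomatic
#'   (STAT3) or indolent (STAT5B) patient carries a mutation; HSTCL always
#'   carries STAT5B.
#' @param segments Segment library.
#' @return A list with `repertoires` (clonotype tibble, both chains, all
#'   samples) and `truth` (list of tibbles: `samples`, `plants`,
#'   `publicity`, `mutations`).
#' @export
simulate_cohort <- function(n_indolent = 5, n_symptomatic = 4, n_hstcl = 2,
                            n_controls = 23, seed = 1, read_depth = 4e5,
                            n_background = 400, background_q = 0.02,
                            clone_size_law = c("geometric", "power_law"),
                            n_dominant_range = c(1, 3),
                            p_mut_symptomatic = 0.41, p_mut_indolent = 0.16,
                            segments = gd_segment_library()) {
  clone_size_law <- match.arg(clone_size_law)
  withr::with_seed(seed, {
    bg_weights <- function(n) {
      w <- switch(clone_size_law,
        geometric = background_q * (1 - background_q)^(seq_len(n) - 1),
        power_law = seq_len(n)^-1.5
      )
      w / sum(w)
    }
    make_pool <- function(chain) {
      pool <- sample_productive(n_background, chain, segments)
      pool <- pool[!duplicated(pool$cdr3_aa), ]
      pool$weight <- bg_weights(nrow(pool))
      pool
    }
    pool_g <- make_pool("TRG")
    pool_d <- make_pool("TRD")

    # convergent public gamma sequences: dominant in patients AND seeded
    # into the shared pool near its head so every control carries them
    v9jp <- function(n) sample_productive(
      n, "TRG", segments,
      v_weights = c(TRGV9 = 1), j_weights = c(`TRGJP` = 1))
    publics <- v9jp(40)
    publics <- publics[!publics$cdr3_aa %in% pool_g$cdr3_aa, ]
    publics <- publics[!duplicated(publics$cdr3_aa), ][1:3, ]
    for (k in 1:3) {
      slot <- 5 * k  # pool ranks 5/10/15: abundant enough to never drop out
      var <- plant_public_clonotype(publics$cdr3_aa[k], "TRGV9", "TRGJP",
                                    n_variants = 1)
      pool_g[slot, c("v_call", "d_call", "j_call", "cdr3_nt", "cdr3_aa")] <-
        list("TRGV9", NA_character_, "TRGJP", var$cdr3_nt, var$cdr3_aa)
    }
    # one gamma sequence private to the disease (two patients, no control)
    priv <- v9jp(40)
    priv <- priv[!priv$cdr3_aa %in% c(pool_g$cdr3_aa, publics$cdr3_aa), ][1, ]

    unique_clone <- function(chain, v_w, d_w, j_w, taken) {
      repeat {
        cand <- sample_productive(5, chain, segments, v_weights = v_w,
                                  d_weights = d_w, j_weights = j_w)
        cand <- cand[!cand$cdr3_aa %in% taken, ]
        if (nrow(cand)) return(cand[1, ])
      }
    }
    dom_targets <- function(n_dom) {
      mass <- stats::runif(1, 0.5, 0.8)
      raw <- sort(stats::runif(n_dom, 0.5, 1), decreasing = TRUE)
      mass * raw / sum(raw)
    }

    samples <- tibble::tibble(
      sample_id = c(sprintf("ind%02d", seq_len(n_indolent)),
                    sprintf("sym%02d", seq_len(n_symptomatic)),
                    sprintf("hstcl%02d", seq_len(n_hstcl)),
                    sprintf("ctrl%02d", seq_len(n_controls))),
      group = rep(c("indolent_LGLL", "symptomatic_LGLL", "HSTCL", "control"),
                  c(n_indolent, n_symptomatic, n_hstcl, n_controls))
    )

    taken <- c(pool_g$cdr3_aa, pool_d$cdr3_aa, publics$cdr3_aa, priv$cdr3_aa)
    plants <- list()
    plan_patient <- function(sid, group, idx) {
      pg <- NULL; pd <- NULL
      if (group == "HSTCL") {
        g <- unique_clone("TRG", c(TRGV8 = 1), NULL, c(`TRGJ1/2` = 1), taken)
        d <- unique_clone("TRD", c(TRDV1 = 1), c(TRDD3 = 1), c(TRDJ1 = 1), taken)
        pg <- dplyr::mutate(g, target_freq = 0.95)
        pd <- dplyr::mutate(d, target_freq = 0.95)
      } else if (group == "indolent_LGLL") {
        n_dom <- sample(n_dominant_range[1]:n_dominant_range[2], 1)
        tg <- dom_targets(n_dom)
        # dominants are convergent publics shared across patients: every
        # patient's major set is a prefix of the same ordered public list
        # (so dominant sequences recur across patients, as observed), each
        # re-encoded with a patient-specific nucleotide variant
        pg <- purrr::map(seq_len(min(n_dom, 3)), function(k) {
          plant_public_clonotype(publics$cdr3_aa[k], "TRGV9", "TRGJP",
                                 n_variants = 1)
        }) %>% dplyr::bind_rows()
        pg$target_freq <- tg[seq_len(nrow(pg))]
        # two designated patients additionally carry the private-to-disease
        # sequence as a major clone
        if (idx <= 2) {
          pv <- plant_public_clonotype(priv$cdr3_aa, "TRGV9", "TRGJP", 1)
          pv$target_freq <- 0.08
          pg <- dplyr::bind_rows(pg, pv)
        }
        n_dd <- sample(n_dominant_range[1]:n_dominant_range[2], 1)
        td <- dom_targets(n_dd)
        pd <- purrr::map(seq_len(n_dd), function(k) {
          cl <- unique_clone("TRD", c(TRDV2 = 1), c(TRDD3 = 1), c(TRDJ1 = 1),
                             taken)
          taken <<- c(taken, cl$cdr3_aa)
          cl
        }) %>% dplyr::bind_rows()
        pd$target_freq <- td
      } else {  # symptomatic: diverse, Vd2-negative usage
        n_dom <- sample(n_dominant_range[1]:n_dominant_range[2], 1)
        tg <- dom_targets(n_dom)
        pg <- purrr::map(seq_len(n_dom), function(k) {
          cl <- unique_clone("TRG",
                             stats::setNames(rep(1, 4),
                                             c("TRGV2", "TRGV3", "TRGV4", "TRGV8")),
                             NULL, NULL, taken)
          taken <<- c(taken, cl$cdr3_aa)
          cl
        }) %>% dplyr::bind_rows()
        pg$target_freq <- tg
        n_dd <- sample(n_dominant_range[1]:n_dominant_range[2], 1)
        td <- dom_targets(n_dd)
        pd <- purrr::map(seq_len(n_dd), function(k) {
          cl <- unique_clone("TRD",
                             stats::setNames(rep(1, 3),
                                             c("TRDV1", "TRDV5", "TRDV8")),
                             NULL, c(TRDJ1 = 1), taken)
          taken <<- c(taken, cl$cdr3_aa)
          cl
        }) %>% dplyr::bind_rows()
        pd$target_freq <- td
      }
      pg$chain <- "TRG"; pd$chain <- "TRD"
      dplyr::bind_rows(pg, pd) %>%
        dplyr::mutate(sample_id = sid, group = group)
    }

    pts <- samples[samples$group != "control", ]
    idx_in_group <- stats::ave(seq_len(nrow(pts)), pts$group, FUN = seq_along)
    for (i in seq_len(nrow(pts))) {
      plants[[i]] <- plan_patient(pts$sample_id[i], pts$group[i],
                                  idx_in_group[i])
      taken <- c(taken, plants[[i]]$cdr3_aa)
    }
    plants <- dplyr::bind_rows(plants)
    if (nrow(plants) == 0) {
      plants <- tibble::tibble(
        v_call = character(), d_call = character(), j_call = character(),
        cdr3_nt = character(), cdr3_aa = character(), productive = logical(),
        target_freq = numeric(), chain = character(), sample_id = character(),
        group = character())
    }

    realize <- function(sid, group, chain, pool) {
      pl <- plants[plants$sample_id == sid & plants$chain == chain, ]
      dom_mass <- sum(pl$target_freq)
      probs <- c(pl$target_freq, pool$weight * (1 - dom_mass))
      counts <- as.vector(stats::rmultinom(1, read_depth, probs))
      df <- tibble::tibble(
        sample_id = sid, group = group, chain = chain,
        v_call = c(pl$v_call, pool$v_call),
        d_call = c(pl$d_call, pool$d_call),
        j_call = c(pl$j_call, pool$j_call),
        cdr3_nt = c(pl$cdr3_nt, pool$cdr3_nt),
        cdr3_aa = c(pl$cdr3_aa, pool$cdr3_aa),
        read_count = counts, productive = TRUE
      )
      df[df$read_count > 0, ]
    }
    reps <- purrr::map2(samples$sample_id, samples$group, function(sid, grp) {
      dplyr::bind_rows(realize(sid, grp, "TRG", pool_g),
                       realize(sid, grp, "TRD", pool_d))
    }) %>% dplyr::bind_rows()
    reps$frequency <- NA_real_
    reps <- normalize_frequencies(reps[, clonotype_cols])

    publicity_truth <- plants %>%
      dplyr::filter(.data$chain == "TRG" | .data$chain == "TRD") %>%
      dplyr::distinct(.data$chain, .data$cdr3_aa, .data$sample_id) %>%
      dplyr::count(.data$chain, .data$cdr3_aa, name = "n_patients") %>%
      dplyr::mutate(
        in_pool = .data$cdr3_aa %in% c(pool_g$cdr3_aa, pool_d$cdr3_aa),
        expected = dplyr::case_when(
          .data$in_pool ~ "public",
          .data$n_patients >= 2 ~ "private_to_disease",
          TRUE ~ "private_to_patient"
        )
      )

    mutations <- pts %>%
      dplyr::mutate(
        tgd_fraction = stats::runif(dplyr::n(), 0.2, 0.95),
        gene = dplyr::case_when(
          .data$group == "HSTCL" ~ "STAT5B",
          .data$group == "symptomatic_LGLL" &
            stats::runif(dplyr::n()) < p_mut_symptomatic ~ "STAT3",
          .data$group == "indolent_LGLL" &
            stats::runif(dplyr::n()) < p_mut_indolent ~ "STAT5B",
          TRUE ~ NA_character_
        ),
        zygosity = ifelse(stats::runif(dplyr::n()) < 0.7, "het", "hom"),
        ccf = sample(c(1, 1, 1, 0.3), dplyr::n(), replace = TRUE),
        true_vaf = .data$tgd_fraction * .data$ccf *
          ifelse(.data$zygosity == "het", 0.5, 1)
      ) %>%
      dplyr::mutate(
        zygosity = ifelse(is.na(.data$gene), NA_character_, .data$zygosity),
        ccf = ifelse(is.na(.data$gene), NA_real_, .data$ccf),
        true_vaf = ifelse(is.na(.data$gene), NA_real_, .data$true_vaf)
      ) %>%
      dplyr::select("sample_id", "group", "tgd_fraction", "gene",
                    "zygosity", "ccf", "true_vaf") %>%
      dplyr::rename(patient_id = "sample_id")

    list(
      repertoires = reps,
      truth = list(samples = samples, plants = plants,
                   publicity = publicity_truth, mutations = mutations)
    )
  })
}

#' Realize patient metadata and observed mutation calls from cohort truth
#'
#' Draws immunophenotype markers and clinical flags conditional on group
#' (defaults follow the cohort's association structure: indolent clones
#' are always Vd2+/Vg9+ with CD56 positive w.p. 0.79 and CD5 positive
#' w.p. 0.95; symptomatic clones are Vd2-negative w.p. 0.88 and
#' neutropenic w.p. 0.94; STAT3-mutated patients are deterministically
#' CD56-negative and neutropenic; STAT5B-mutated LGLL patients are
#' deterministically CD56-positive), and realizes the observed VAF of
#' each true mutation as a binomial draw at the given sequencing depth.
#'
#' @param truth The `truth` element of [simulate_cohort()] output.
#' @param depth Mutation sequencing depth (default 5000, the magnitude of
#'   the study's median amplicon depth).
#' @param effect Optional list overriding the conditional probabilities:
#'   `p_cd56_indolent`, `p_cd5_indolent`, `p_vd2neg_symptomatic`,
#'   `p_neutropenia_symptomatic`, `p_cd56_symptomatic`,
#'   `p_cd5_symptomatic`, `p_stat3_cd56neg`, `p_stat3_neutropenia`.
#' @param seed Optional seed.
#' @return A list: `patients` (metadata tibble with tri-state markers) and
#'   `mutations` (observed calls: `patient_id`, `gene`, `aa_change`,
#'   `vaf`, `depth`).
#' @export
simulate_patient_metadata <- function(truth, depth = 5000, effect = list(),
                                      seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, simulate_patient_metadata(truth, depth, effect, seed = NULL)))
  }
  p <- utils::modifyList(list(
    p_cd56_indolent = 0.79, p_cd5_indolent = 0.95,
    p_vd2neg_symptomatic = 0.88, p_neutropenia_symptomatic = 0.94,
    p_cd56_symptomatic = 0.24, p_cd5_symptomatic = 0.53,
    p_stat3_cd56neg = 1.0, p_stat3_neutropenia = 1.0
  ), effect)
  bad <- unlist(p) < 0 | unlist(p) > 1
  if (any(bad)) abort("Effect probabilities must lie in [0, 1].")
  tri <- function(yes) ifelse(yes, "+", "-")
  mt <- truth$mutations
  n <- nrow(mt)
  is_ind <- mt$group == "indolent_LGLL"
  is_sym <- mt$group == "symptomatic_LGLL"
  is_hst <- mt$group == "HSTCL"
  vd2 <- ifelse(is_ind, "+",
                ifelse(is_hst, "-",
                       tri(stats::runif(n) >= p$p_vd2neg_symptomatic)))
  vg9 <- ifelse(is_ind, "+", ifelse(vd2 == "+", "+", "-"))
  vd1 <- ifelse(vd2 == "+", "-", tri(stats::runif(n) < 0.73))
  cd56 <- ifelse(is_hst, "+",
                 tri(stats::runif(n) <
                       ifelse(is_ind, p$p_cd56_indolent, p$p_cd56_symptomatic)))
  cd5 <- ifelse(is_hst, "-",
                tri(stats::runif(n) <
                      ifelse(is_ind, p$p_cd5_indolent, p$p_cd5_symptomatic)))
  neutro <- ifelse(is_sym, tri(stats::runif(n) < p$p_neutropenia_symptomatic),
                   "-")
  stat3 <- !is.na(mt$gene) & mt$gene == "STAT3"
  cd56[stat3 & stats::runif(n) < p$p_stat3_cd56neg] <- "-"
  neutro[stat3 & stats::runif(n) < p$p_stat3_neutropenia] <- "+"
  stat5b_lgll <- !is.na(mt$gene) & mt$gene == "STAT5B" & !is_hst
  cd56[stat5b_lgll] <- "+"

  patients <- tibble::tibble(
    patient_id = mt$patient_id,
    disease = ifelse(is_hst, "HSTCL", "Tgd_LGLL"),
    course = dplyr::case_when(is_ind ~ "indolent", is_sym ~ "symptomatic",
                              TRUE ~ "not_applicable"),
    tgd_fraction_pbmc = mt$tgd_fraction,
    Vd1 = vd1, Vd2 = vd2, Vg9 = vg9, CD56 = cd56, CD5 = cd5,
    neutropenia = neutro
  )
  mut <- mt[!is.na(mt$gene), ]
  aa_pool <- list(STAT3 = c("Y640F", "D661Y", "K658R"),
                  STAT5B = c("N642H", "Y665F", "V712E"))
  mutations <- tibble::tibble(
    patient_id = mut$patient_id,
    gene = mut$gene,
    aa_change = vapply(mut$gene, function(g) sample(aa_pool[[g]], 1),
                       character(1)),
    vaf = stats::rbinom(nrow(mut), depth, mut$true_vaf) / depth,
    depth = depth
  )
  list(patients = patients, mutations = mutations)
}
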