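# Synthetic NanoString-style cohorts: negative-binomial counts with stable
# housekeeping genes, a positive-control ladder, low-count negative controls,
# a per-lane efficiency factor (the FFPE degradation stand-in), and planted
# entity signatures calibrated so that the expected reference-fold of each
# planted marker lands inside the hybridization-QC fold range.

#' Configuration for the NanoString cohort generator
#'
#' @param compartment `"supratentorial"` or `"infratentorial"`.
#' @param background_diagnoses named integer vector: diagnosis -> number of
#'   background (non-entity) samples.
#' @param planted_entities named integer vector: entity -> number of planted
#'   samples (0 allowed).
#' @param reference_samples named list: entity -> character vector of sample
#'   ids tagged as reference samples (must be planted samples of that entity).
#'   Default: the first planted sample of each entity with count >= 1.
#' @param marker_fold_range length-2 numeric, linear reference-fold range the
#'   planted markers are calibrated into (default `c(3.9, 92.7)`, the observed
#'   hybridization-QC extremes).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); default 0.05.
#' @param hk_mean_counts scale of housekeeping means (default 1000; the three
#'   genes sit at 2x, 1x and 0.5x this scale).
#' @param marker_base_counts background mean count of endogenous marker probes
#'   in samples not expressing them (default 20, i.e. near-noise).
#' @param neg_mean_counts mean of negative-control counts (default 2).
#' @param glioma_fold linear fold applied to the glioma panel in samples whose
#'   diagnosis is in `glioma_diagnoses` (default 3; set 1 to disable).
#' @param glioma_diagnoses diagnoses treated as glioma-like (default
#'   `c("HGG", "GBM")`).
#' @param dual_glioma named integer vector: entity -> number of its planted
#'   samples (taken from the end, never the references) that additionally
#'   express the glioma panel, emulating dual-signature tumors. Default none.
#' @param lane_sdlog sd (log scale) of the per-lane efficiency factor.
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(compartment,
                          background_diagnoses,
                          planted_entities,
                          reference_samples = NULL,
                          marker_fold_range = c(3.9, 92.7),
                          nb_dispersion = 0.05,
                          hk_mean_counts = 1000,
                          marker_base_counts = 20,
                          neg_mean_counts = 2,
                          glioma_fold = 3,
                          glioma_diagnoses = c("HGG", "GBM"),
                          dual_glioma = NULL,
                          lane_sdlog = 0.15,
                          seed = 1L) {
  compartment <- match.arg(compartment, c("supratentorial", "infratentorial"))
  if (length(background_diagnoses) > 0 &&
      (is.null(names(background_diagnoses)) ||
       any(!nzchar(names(background_diagnoses))))) {
    abort_config("background_diagnoses must be named")
  }
  if (length(planted_entities) > 0 &&
      (is.null(names(planted_entities)) || any(!nzchar(names(planted_entities))))) {
    abort_config("planted_entities must be named")
  }
  if (marker_fold_range[1] < 1 || marker_fold_range[1] > marker_fold_range[2]) {
    abort_config("marker_fold_range must satisfy 1 <= low <= high")
  }
  if (nb_dispersion <= 0) abort_config("nb_dispersion must be > 0")
  planted <- setNames(as.integer(planted_entities), names(planted_entities))
  planted_pos <- planted[planted >= 1]
  ids_for <- function(entity) {
    sprintf("%s_%02d", entity, seq_len(planted_pos[[entity]]))
  }
  if (is.null(reference_samples)) {
    reference_samples <- lapply(names(planted_pos), function(e) ids_for(e)[1])
    names(reference_samples) <- names(planted_pos)
  }
  for (e in names(reference_samples)) {
    if (!e %in% names(planted_pos)) {
      abort_config(paste0("reference sample for unplanted entity: ", e))
    }
    if (!all(reference_samples[[e]] %in% ids_for(e))) {
      abort_config(paste0("reference ids of ", e, " are not planted samples"))
    }
  }
  dual_glioma <- dual_glioma %||% setNames(integer(), character())
  for (e in names(dual_glioma)) {
    n_free <- planted_pos[[e]] %||% 0L
    if (dual_glioma[[e]] > n_free - length(reference_samples[[e]] %||% character())) {
      abort_config(paste0("dual_glioma count too large for entity ", e))
    }
  }
  structure(
    list(
      compartment = compartment,
      background_diagnoses = setNames(
        as.integer(background_diagnoses), names(background_diagnoses)
      ),
      planted_entities = planted,
      reference_samples = reference_samples,
      marker_fold_range = as.numeric(marker_fold_range),
      nb_dispersion = nb_dispersion,
      hk_mean_counts = hk_mean_counts,
      marker_base_counts = marker_base_counts,
      neg_mean_counts = neg_mean_counts,
      glioma_fold = glioma_fold,
      glioma_diagnoses = glioma_diagnoses,
      dual_glioma = dual_glioma,
      lane_sdlog = lane_sdlog,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default cohort compositions
#'
#' Mirror the study's compartment compositions: 92 supratentorial samples
#' (80 background tumors plus 1 EFT-CIC, 3 NB-FOXR2, 4 HGNET-MN1 and
#' 4 HGNET-BCOR, with the per-entity reference samples among them; NB-FOXR2
#' carries two references) and 95 infratentorial samples (93 background plus
#' 2 HGNET-BCOR, one of them the reference) — 187 samples in total.
#'
#' @param seed integer seed (the infratentorial config derives a sub-seed).
#' @return `default_supratentorial_config()` / `default_infratentorial_config()`
#'   return a [cohort_config()]; `default_cohort_configs()` a named list of
#'   both.
#' @export
default_supratentorial_config <- function(seed = 1L) {
  cohort_config(
    compartment = "supratentorial",
    background_diagnoses = c(
      HGG = 25L, PNET = 17L, EPN = 18L, CPC = 9L, ATRT = 7L, ETMR = 2L,
      `CNS-NOS` = 2L
    ),
    planted_entities = c(
      `EFT-CIC` = 1L, `NB-FOXR2` = 3L, `HGNET-MN1` = 4L, `HGNET-BCOR` = 4L
    ),
    reference_samples = list(
      `EFT-CIC` = "EFT-CIC_01",
      `NB-FOXR2` = c("NB-FOXR2_01", "NB-FOXR2_02"),
      `HGNET-MN1` = "HGNET-MN1_01",
      `HGNET-BCOR` = "HGNET-BCOR_01"
    ),
    seed = seed
  )
}

#' @rdname default_supratentorial_config
#' @export
default_infratentorial_config <- function(seed = 1L) {
  cohort_config(
    compartment = "infratentorial",
    background_diagnoses = c(EPN = 50L, MB = 36L, CPC = 4L, ATRT = 3L),
    planted_entities = c(`HGNET-BCOR` = 2L),
    reference_samples = list(`HGNET-BCOR` = "HGNET-BCOR_01"),
    seed = derive_seed(seed, 101L)
  )
}

#' @rdname default_supratentorial_config
#' @export
default_cohort_configs <- function(seed = 1L) {
  list(
    supratentorial = default_supratentorial_config(seed),
    infratentorial = default_infratentorial_config(seed)
  )
}

# Elevation (linear fold over baseline, shared by the m planted samples of an
# entity) whose expected reference-fold -- reference value over the mean of
# ALL remaining samples, other positives included -- equals `target`.
# Attainable targets are bounded by (N-1)/(m-1); drawn targets are clamped to
# 80% of that bound so planted samples stay exchangeable with the reference
# (reference co-clustering is what the calling rule anchors on).
fold_to_elevation <- function(target, n_total, m) {
  if (m <= 1) {
    return(list(elevation = target, fold = target))
  }
  cap <- 0.8 * (n_total - 1) / (m - 1)
  f <- min(target, cap)
  list(
    elevation = f * (n_total - m) / ((n_total - 1) - f * (m - 1)),
    fold = f
  )
}

#' Generate a synthetic NanoString cohort
#'
#' Draws negative-binomial counts for every probe of the CodeSet in every
#' sample. Housekeeping probes have entity-independent means; marker probes
#' of each planted entity are elevated so that the expected reference-fold
#' (see [hybridization_fold()]) of each probe falls inside the configured
#' fold range; one planted sample per entity (or more, if configured) is
#' tagged as a reference. Per-lane efficiency multiplies all probes of a lane
#' and is what the technical normalization removes.
#'
#' @param config a [cohort_config()].
#' @param cs a [codeset()]; every planted entity must have marker probes for
#'   the config's compartment.
#' Sample ids are prefixed with a compartment tag (`ST_`/`IT_`) so merged
#' cohorts have unique ids; config-level reference ids are un-prefixed.
#'
#' @return list of class `ns_cohort` with elements `samples` (list of
#'   [rcc_sample()]), `truth` (tibble: `sample_id`, `compartment`,
#'   `diagnosis`, `entity` (`NA` for background), `reference`, `dual_glioma`),
#'   `planted_folds` (tibble: `entity`, `probe`, `target_fold`, `elevation`),
#'   `codeset`, `config`.
#' @export
simulate_cohort <- function(config, cs = default_codeset()) {
  stopifnot(inherits(config, "cohort_config"), inherits(cs, "codeset"))
  planted_pos <- config$planted_entities[config$planted_entities >= 1]
  for (e in names(planted_pos)) {
    if (!e %in% names(cs$entities)) {
      abort_config(paste0("planted entity not in CodeSet: ", e))
    }
    if (length(entity_panel(cs, e, config$compartment)) == 0) {
      abort_config(paste0(
        "entity ", e, " has no marker probes for compartment ",
        config$compartment
      ))
    }
  }
  # Compartment tag keeps sample ids unique when cohorts are merged.
  tag <- c(supratentorial = "ST", infratentorial = "IT")[[config$compartment]]
  bg_ids <- unlist(lapply(names(config$background_diagnoses), function(d) {
    sprintf("%s_%s_%02d", tag, d, seq_len(config$background_diagnoses[[d]]))
  }), use.names = FALSE) %||% character()
  truth <- bind_rows(
    tibble(
      sample_id = bg_ids,
      diagnosis = rep(names(config$background_diagnoses),
                      config$background_diagnoses),
      entity = NA_character_
    ),
    bind_rows(lapply(names(planted_pos), function(e) {
      tibble(
        sample_id = sprintf("%s_%s_%02d", tag, e, seq_len(planted_pos[[e]])),
        diagnosis = e,
        entity = e
      )
    }))
  )
  truth$compartment <- config$compartment
  truth$reference <- FALSE
  for (e in names(config$reference_samples)) {
    truth$reference[
      truth$sample_id %in% paste0(tag, "_", config$reference_samples[[e]])
    ] <- TRUE
  }
  truth$dual_glioma <- FALSE
  for (e in names(config$dual_glioma)) {
    k <- config$dual_glioma[[e]]
    if (k > 0) {
      cand <- truth$sample_id[!is.na(truth$entity) & truth$entity == e &
                                !truth$reference]
      truth$dual_glioma[truth$sample_id %in% utils::tail(cand, k)] <- TRUE
    }
  }
  truth <- truth[, c("sample_id", "compartment", "diagnosis", "entity",
                     "reference", "dual_glioma")]
  n_total <- nrow(truth)
  if (n_total < 2) abort_config("cohort must contain at least 2 samples")

  classes <- codeset_classes(cs)
  probes <- classes$probe
  base_mu <- numeric(length(probes))
  names(base_mu) <- probes
  base_mu[classes$code_class == "Endogenous"] <- config$marker_base_counts
  hk <- cs$housekeeping
  base_mu[hk] <- config$hk_mean_counts *
    rep_len(c(2, 1, 0.5), length(hk))
  base_mu[names(cs$positive_controls)] <- cs$positive_controls
  base_mu[classes$code_class == "Negative"] <- config$neg_mean_counts

  withr::with_seed(config$seed, {
    # Per-probe target reference-folds for every planted entity's markers
    # (the full marker set of the entity, both compartments' panels: the gene
    # is expressed regardless of which panel reads it out).
    planted_folds <- bind_rows(lapply(names(planted_pos), function(e) {
      pr <- unique(unlist(cs$entities[[e]], use.names = FALSE))
      m <- planted_pos[[e]]
      targets <- runif(length(pr), config$marker_fold_range[1],
                       config$marker_fold_range[2])
      sol <- lapply(targets, fold_to_elevation, n_total = n_total, m = m)
      tibble(
        entity = e, probe = pr,
        target_fold = vapply(sol, `[[`, numeric(1), "fold"),
        elevation = vapply(sol, `[[`, numeric(1), "elevation")
      )
    }))

    mu <- matrix(base_mu, nrow = length(probes), ncol = n_total,
                 dimnames = list(probes, truth$sample_id))
    if (nrow(planted_folds) > 0) {
      for (i in seq_len(nrow(planted_folds))) {
        pf <- planted_folds[i, ]
        cols <- !is.na(truth$entity) & truth$entity == pf$entity
        mu[pf$probe, cols] <- mu[pf$probe, cols] * pf$elevation
      }
    }
    glioma_cols <- truth$diagnosis %in% config$glioma_diagnoses |
      truth$dual_glioma
    if (any(glioma_cols) && config$glioma_fold != 1) {
      mu[cs$glioma_panel, glioma_cols] <-
        mu[cs$glioma_panel, glioma_cols] * config$glioma_fold
    }
    lane_eff <- rlnorm(n_total, meanlog = 0, sdlog = config$lane_sdlog)
    counts <- matrix(
      rnbinom(
        length(mu),
        mu = sweep(mu, 2, lane_eff, `*`),
        size = 1 / config$nb_dispersion
      ),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )
  })

  samples <- lapply(seq_len(n_total), function(j) {
    rcc_sample(
      sample_id = truth$sample_id[j],
      records = tibble(
        code_class = classes$code_class,
        probe = probes,
        accession = paste0("SYN_", probes),
        count = counts[, j]
      ),
      lane_id = j
    )
  })
  structure(
    list(
      samples = samples,
      truth = truth,
      planted_folds = if (nrow(planted_folds) > 0) planted_folds else
        tibble(entity = character(), probe = character(),
               target_fold = numeric(), elevation = numeric()),
      codeset = cs,
      config = config
    ),
    class = "ns_cohort"
  )
}

#' @export
print.ns_cohort <- function(x, ...) {
  cat(
    "<ns_cohort> ", nrow(x$truth), " ", x$config$compartment, " samples (",
    sum(!is.na(x$truth$entity)), " planted entity sample(s), ",
    sum(x$truth$reference), " reference(s))\n",
    sep = ""
  )
  invisible(x)
}

#' Write a cohort to disk
#'
#' One RCC file per lane plus a `truth.tsv` ground-truth table.
#'
#' @param cohort an `ns_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ns_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$samples) {
    write_rcc(s, file.path(dir, paste0(s$sample_id, ".rcc")))
  }
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
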