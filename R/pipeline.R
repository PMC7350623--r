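# End-to-end orchestration: simulate -> discover -> normalize -> classify ->
# evaluate, with a digest manifest for reproducibility.

#' Pipeline configuration
#'
#' @param discovery `NULL` to skip the discovery stage, or a list with
#'   elements `config` (a [discovery_config()]), `target_classes` (character;
#'   default: classes with planted markers) and `params` (a
#'   [discovery_params()]).
#' @param cohorts named list of [cohort_config()] objects, one per
#'   compartment (default [default_cohort_configs()]).
#' @param codeset a [codeset()] or a path to a YAML CodeSet file (the file
#'   must exist — checked before any compute).
#' @param tau z threshold for [call_groups()].
#' @param min_log2_elev absolute elevation threshold for [call_groups()].
#' @param seed master seed, re-derived per stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(discovery = NULL,
                            cohorts = default_cohort_configs(seed),
                            codeset = default_codeset(),
                            tau = 2,
                            min_log2_elev = 1,
                            seed = 1L) {
  structure(
    list(
      discovery = discovery, cohorts = cohorts, codeset = codeset,
      tau = tau, min_log2_elev = min_log2_elev, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Demonstration pipeline configuration
#'
#' A small discovery simulation (three tumor classes, 300 probes, four
#' planted markers for one class) plus the default 187-sample two-compartment
#' detection cohort.
#'
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L) {
  dcfg <- discovery_config(
    classes = c(BCOR = 8L, HGG = 12L, EPN = 12L),
    n_probes = 300L,
    planted_markers = tibble(
      class = "BCOR",
      probe_id = c("P0001", "P0002", "P0003", "P0004"),
      log2_effect = c(5, 4.5, 4, 6)
    ),
    seed = derive_seed(seed, 11L)
  )
  pipeline_config(
    discovery = list(
      config = dcfg,
      target_classes = "BCOR",
      params = discovery_params(seed = derive_seed(seed, 12L))
    ),
    cohorts = default_cohort_configs(derive_seed(seed, 13L)),
    seed = seed
  )
}

write_stage_tsv <- function(tbl, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(tbl, path)
  path
}

#' Run the full diagnostic pipeline
#'
#' Executes the stages in order, fails fast on any stage error (leaving a
#' `<stage>.failed` marker next to the partial outputs), and writes a
#' `manifest.json` with seeds and MD5 digests of every stage output.
#' Identical config and seed give identical digests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cs <- config$codeset
  if (is.character(cs)) {
    if (!file.exists(cs)) {
      abort_config(paste0("CodeSet file does not exist: ", cs))
    }
    cs <- read_codeset(cs)
  }
  stopifnot(inherits(cs, "codeset"))

  outputs <- character()
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      file.create(file.path(out_dir, paste0(name, ".failed")))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    res
  }

  # -- discovery ------------------------------------------------------------
  if (!is.null(config$discovery)) {
    outputs <- c(outputs, stage("discover", function() {
      d <- config$discovery
      sim <- simulate_discovery(d$config)
      paths <- c(
        write_stage_tsv(sim$intensities, out_dir, "discovery_intensities.tsv"),
        write_stage_tsv(sim$labels, out_dir, "discovery_labels.tsv")
      )
      targets <- d$target_classes %||% unique(d$config$planted_markers$class)
      for (cl in targets) {
        md <- discover_markers(sim$intensities, sim$labels, cl,
                               params = d$params %||% discovery_params())
        paths <- c(paths, write_stage_tsv(
          as_tibble(md), out_dir, paste0("markers_", cl, ".tsv")
        ))
      }
      paths
    }))
  }

  # -- simulate detection cohorts ------------------------------------------
  cohorts <- stage("simulate", function() {
    lapply(config$cohorts, simulate_cohort, cs = cs)
  })
  truth <- bind_rows(lapply(cohorts, function(x) x$truth))
  outputs <- c(outputs, stage("write_cohorts", function() {
    paths <- character()
    for (comp in names(cohorts)) {
      d <- file.path(out_dir, paste0("rcc_", comp))
      write_cohort(cohorts[[comp]], d)
      paths <- c(paths, list.files(d, full.names = TRUE))
    }
    paths
  }))

  # -- normalize ------------------------------------------------------------
  all_samples <- unlist(lapply(cohorts, function(x) x$samples),
                        recursive = FALSE)
  norm <- stage("normalize", function() normalize_cohort(all_samples, cs))
  outputs <- c(outputs, stage("write_normalize", function() {
    c(
      write_stage_tsv(norm$log2, out_dir, "normalized_log2.tsv"),
      write_stage_tsv(
        left_join(
          rename(norm$tech_factors, tech_factor = factor, tech_qc = qc),
          rename(norm$bio_factors, bio_factor = factor, bio_qc = qc),
          by = "sample_id"
        ),
        out_dir, "normalization_factors.tsv"
      )
    )
  }))

  # -- classify -------------------------------------------------------------
  calls <- stage("classify", function() {
    classify_cohort(norm, truth, cs, tau = config$tau,
                    min_log2_elev = config$min_log2_elev)
  })
  outputs <- c(outputs, stage("write_classify", function() {
    paths <- write_stage_tsv(calls, out_dir, "calls.tsv")
    for (comp in names(cohorts)) {
      ids <- truth$sample_id[truth$compartment == comp]
      hc <- cluster_samples(norm, cs, comp, samples = ids)
      nwk <- file.path(out_dir, paste0("dendrogram_", comp, ".nwk"))
      writeLines(as_newick(hc), nwk)
      paths <- c(paths, nwk)
    }
    paths
  }))

  # -- evaluate -------------------------------------------------------------
  outputs <- c(outputs, stage("evaluate", function() {
    auc <- bind_rows(lapply(names(cohorts), function(comp) {
      ids <- truth$sample_id[truth$compartment == comp]
      sub <- norm$log2[, c("probe_id", ids)]
      tab <- suppressWarnings(
        auc_table(sub, cs, truth[truth$compartment == comp, ], comp)
      )
      mutate(tab, compartment = comp, .before = 1)
    }))
    write_stage_tsv(auc, out_dir, "auc_table.tsv")
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("cnssig")),
    seed = config$seed,
    cohort_seeds = lapply(config$cohorts, function(x) x$seed),
    timestamp = format(Sys.time(), tz = "UTC"),
    n_samples = nrow(truth),
    n_called = sum(!is.na(calls$called_entity)),
    digests = as.list(setNames(
      unname(tools::md5sum(sort(unique(outputs)))),
      basename(sort(unique(outputs)))
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
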