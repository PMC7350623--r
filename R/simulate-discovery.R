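# Synthetic discovery-stage data: log-normal probe intensities per class with
# planted up-regulated marker probes, emulating probe-set-level microarray
# matrices. log2 intensity ~ Normal(baseline + planted effect, sd), reported
# on the linear scale.

#' Configuration for the discovery-stage generator
#'
#' @param classes named integer vector: class name -> sample count (each >= 2,
#'   t-tests need at least two samples per side).
#' @param n_probes total number of probes.
#' @param planted_markers data frame with columns `class`, `probe_id`,
#'   `log2_effect` (finite, >= 0). Probe ids must be distinct across classes
#'   and drawn from the generated probe set (`P0001`, `P0002`, ...).
#' @param baseline_mean_log2 baseline log2 intensity (default 6, i.e. modest
#'   expression on a typical array scale).
#' @param baseline_sd_log2 per-probe log2 noise sd (default 1; comfortably
#'   above the sqrt(0.25) variance-filter floor so null probes are retained).
#' @param seed integer seed.
#' @return object of class `discovery_config`.
#' @export
discovery_config <- function(classes,
                             n_probes = 1000L,
                             planted_markers = NULL,
                             baseline_mean_log2 = 6,
                             baseline_sd_log2 = 1,
                             seed = 1L) {
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    abort_config("classes must be a named vector of sample counts")
  }
  if (any(classes < 2)) {
    abort_config("all class sample counts must be >= 2 (t-tests need >= 2 per side)")
  }
  if (baseline_sd_log2 <= 0) abort_config("baseline_sd_log2 must be > 0")
  if (n_probes < 1) abort_config("n_probes must be >= 1")
  if (is.null(planted_markers)) {
    planted_markers <- tibble(
      class = character(), probe_id = character(), log2_effect = numeric()
    )
  }
  planted_markers <- as_tibble(planted_markers)
  stopifnot(all(c("class", "probe_id", "log2_effect") %in% names(planted_markers)))
  if (nrow(planted_markers) > 0) {
    if (anyDuplicated(planted_markers$probe_id)) {
      abort_config("planted probe_ids must be distinct across classes")
    }
    if (any(!is.finite(planted_markers$log2_effect)) ||
        any(planted_markers$log2_effect < 0)) {
      abort_config("log2_effect values must be finite and >= 0")
    }
    if (!all(planted_markers$class %in% names(classes))) {
      abort_config("planted_markers refer to unknown classes")
    }
  }
  structure(
    list(
      classes = setNames(as.integer(classes), names(classes)),
      n_probes = as.integer(n_probes),
      planted_markers = planted_markers,
      baseline_mean_log2 = baseline_mean_log2,
      baseline_sd_log2 = baseline_sd_log2,
      seed = as.integer(seed)
    ),
    class = "discovery_config"
  )
}

#' Generate a synthetic discovery-stage expression matrix
#'
#' Draws linear-scale intensities `2^N(baseline + effect, sd)` per probe and
#' sample. A planted marker of class `c` with log2 effect `e` has its expected
#' log2 intensity raised by `e` in class-`c` samples; all other probes are
#' exchangeable across classes. Reproducible under the config seed.
#'
#' @param config a [discovery_config()].
#' @return list of class `discovery_sim` with elements
#'   `intensities` (wide tibble, `probe_id` + one column per sample, linear
#'   scale), `labels` (tibble `sample_id`, `class`) and `config`.
#' @export
simulate_discovery <- function(config) {
  stopifnot(inherits(config, "discovery_config"))
  probes <- sprintf("P%04d", seq_len(config$n_probes))
  bad <- setdiff(config$planted_markers$probe_id, probes)
  if (length(bad) > 0) {
    abort_config(paste0(
      "planted probe_ids outside the probe set: ", paste(bad, collapse = ", ")
    ))
  }
  labels <- tibble(
    sample_id = unlist(lapply(names(config$classes), function(cl) {
      sprintf("%s_%02d", cl, seq_len(config$classes[[cl]]))
    })),
    class = rep(names(config$classes), config$classes)
  )
  n <- nrow(labels)
  withr::with_seed(config$seed, {
    log2x <- matrix(
      rnorm(config$n_probes * n, config$baseline_mean_log2,
            config$baseline_sd_log2),
      nrow = config$n_probes, dimnames = list(probes, labels$sample_id)
    )
    if (nrow(config$planted_markers) > 0) {
      for (i in seq_len(nrow(config$planted_markers))) {
        pm <- config$planted_markers[i, ]
        cols <- labels$class == pm$class
        log2x[pm$probe_id, cols] <- log2x[pm$probe_id, cols] + pm$log2_effect
      }
    }
  })
  structure(
    list(
      intensities = matrix_to_expr(2^log2x),
      labels = labels,
      config = config
    ),
    class = "discovery_sim"
  )
}

#' @export
print.discovery_sim <- function(x, ...) {
  cat(
    "<discovery_sim> ", x$config$n_probes, " probes x ", nrow(x$labels),
    " samples; classes: ",
    paste(names(x$config$classes), x$config$classes, sep = "=", collapse = ", "),
    "; ", nrow(x$config$planted_markers), " planted marker(s)\n",
    sep = ""
  )
  invisible(x)
}
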