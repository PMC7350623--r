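# Broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a marker-discovery result
#'
#' Returns the full per-probe resampling statistics (not just the selected
#' panel), one row per probe tested, with a `selected` flag.
#'
#' @param x a `marker_discovery` object from [discover_markers()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy marker_discovery
#' @export
tidy.marker_discovery <- function(x, ...) {
  stats <- attr(x, "stats")
  stats |>
    as_tibble() |>
    mutate(selected = probe_id %in% x$probe_id)
}

#' Summarize a marker-discovery result
#' @param x a `marker_discovery` object.
#' @param ... unused.
#' @return one-row tibble: probes tested, selected, parameters used.
#' @method glance marker_discovery
#' @export
glance.marker_discovery <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    target_class = attr(x, "stats")$target_class[1],
    n_probes_tested = nrow(attr(x, "stats")),
    n_selected = nrow(x),
    n_reps = p$n_reps,
    fold_threshold = p$fold_threshold,
    top_n = p$top_n
  )
}

#' Tidy group calls
#'
#' Joins the per-sample calls with the long per-entity score table.
#'
#' @param x a `group_calls` object from [call_groups()].
#' @param ... unused.
#' @return a tibble with one row per sample x entity.
#' @method tidy group_calls
#' @export
tidy.group_calls <- function(x, ...) {
  left_join(attr(x, "scores"), as_tibble(x), by = "sample_id")
}

#' Summarize group calls
#' @param x a `group_calls` object.
#' @param ... unused.
#' @return one-row tibble: samples, calls, per-entity call counts nested out.
#' @method glance group_calls
#' @export
glance.group_calls <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    n_called = sum(!is.na(x$called_entity)),
    n_ambiguous = sum(x$ambiguous),
    n_reference = sum(x$reference),
    tau = attr(x, "tau")
  )
}

#' Tidy a probe ROC
#' @param x a `probe_roc` object.
#' @param ... unused.
#' @return tibble of ROC points with the probe id and AUC attached.
#' @method tidy probe_roc
#' @export
tidy.probe_roc <- function(x, ...) {
  mutate(x$points, probe = x$probe, auc = x$auc)
}
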