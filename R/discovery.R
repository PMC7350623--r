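# In-silico marker discovery: quantile normalization, log2 variance
# filtering, the repeated balanced-subsample t statistic, and candidate
# ranking per tumor entity.

#' Marker-discovery parameters
#'
#' @param variance_threshold probes with log2-scale variance strictly below
#'   this are removed (default 0.25).
#' @param n_reps number of balanced subsample repetitions (default 100; 200
#'   was used for the NB-FOXR2 class, whose candidate list was depleted by
#'   down-regulated genes).
#' @param fold_threshold minimum mean linear fold for a candidate (default 10).
#' @param top_n significance-rank cutoff (default 100).
#' @param welch use Welch's t instead of the pooled-variance Student t.
#' @param seed integer seed for the subsample draws.
#' @return object of class `discovery_params`.
#' @export
discovery_params <- function(variance_threshold = 0.25,
                             n_reps = 100L,
                             fold_threshold = 10,
                             top_n = 100L,
                             welch = FALSE,
                             seed = 1L) {
  if (variance_threshold < 0) abort_config("variance_threshold must be >= 0")
  if (n_reps < 1) abort_config("n_reps must be >= 1")
  if (fold_threshold < 1) abort_config("fold_threshold must be >= 1")
  if (top_n < 1) abort_config("top_n must be >= 1")
  structure(
    list(
      variance_threshold = variance_threshold, n_reps = as.integer(n_reps),
      fold_threshold = fold_threshold, top_n = as.integer(top_n),
      welch = isTRUE(welch), seed = as.integer(seed)
    ),
    class = "discovery_params"
  )
}

#' Quantile-normalize an expression table
#'
#' Every sample's sorted value vector is replaced by the across-sample mean of
#' sorted vectors; within-sample ranks are preserved (ties receive the mean of
#' the tied quantiles). Idempotent.
#'
#' @param expr wide tibble: `probe_id` plus one numeric column per sample
#'   (at least 2 samples).
#' @return tibble of the same shape.
#' @export
quantile_normalize <- function(expr) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2) {
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  }
  if (any(is.na(m))) stop("missing values are not supported", call. = FALSE)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  matrix_to_expr(out)
}

#' Log2-transform and variance-filter an expression table
#'
#' Takes log2 of strictly positive linear-scale intensities and removes probes
#' whose across-sample variance on the log2 scale is strictly below
#' `variance_threshold` (a probe at exactly the threshold is retained).
#' Probe order is preserved.
#'
#' @inheritParams quantile_normalize
#' @param variance_threshold strict lower variance cutoff (default 0.25).
#' @return log2-scale tibble restricted to retained probes.
#' @export
log2_variance_filter <- function(expr, variance_threshold = 0.25) {
  m <- expr_to_matrix(expr)
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop(
      "non-positive intensity at probe ", rownames(m)[bad[1]],
      ", sample ", colnames(m)[bad[2]],
      call. = FALSE
    )
  }
  lg <- log2(m)
  v <- apply(lg, 1, var)
  matrix_to_expr(lg[v >= variance_threshold, , drop = FALSE])
}

# Row-wise two-sample t-test on a log2 matrix: columns idx1 vs idx2.
# Pooled-variance Student t by default, Welch optionally. Probes with zero
# variance in both groups get p = 0 when the means differ, 1 when equal
# (avoids NaN propagation).
row_t_test <- function(m, idx1, idx2, welch = FALSE) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  x1 <- m[, idx1, drop = FALSE]
  x2 <- m[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0 | !is.finite(p)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  list(p = p, diff = m1 - m2)
}

#' Resampled balanced-subsample marker statistics
#'
#' The marker statistic of the discovery stage: the target class (n samples)
#' is compared `n_reps` times against an equally sized subset drawn without
#' replacement from the pool of samples with a different diagnosis; per probe,
#' a two-sided t-test p-value and a log2 mean difference are computed for each
#' repetition and averaged. When the pool is smaller than the target class the
#' whole pool is used every repetition (with a warning).
#'
#' @param expr_log2 wide log2-scale tibble (`probe_id` + sample columns).
#' @param labels data frame with columns `sample_id`, `class` covering the
#'   samples of `expr_log2`.
#' @param target_class class name (>= 2 samples; pool must also have >= 2).
#' @param params a [discovery_params()].
#' @return tibble of class `marker_stats` with columns `probe_id`,
#'   `target_class`, `mean_p`, `mean_log2fc`, `mean_linear_fold`, `rank`
#'   (significance rank among all tested probes: ascending `mean_p`, ties by
#'   descending `mean_log2fc`, then `probe_id`).
#' @export
resampled_marker_stats <- function(expr_log2, labels, target_class,
                                   params = discovery_params()) {
  m <- expr_to_matrix(expr_log2)
  labels <- as_tibble(labels)
  stopifnot(all(c("sample_id", "class") %in% names(labels)))
  labels <- labels[match(colnames(m), labels$sample_id), ]
  if (any(is.na(labels$sample_id))) {
    stop("labels must cover every sample column", call. = FALSE)
  }
  idx_t <- which(labels$class == target_class)
  idx_pool <- which(labels$class != target_class)
  if (length(idx_t) < 2) {
    stop("target class needs >= 2 samples", call. = FALSE)
  }
  if (length(idx_pool) < 2) {
    stop("non-target pool needs >= 2 samples", call. = FALSE)
  }
  m_draw <- min(length(idx_t), length(idx_pool))
  if (length(idx_pool) < length(idx_t)) {
    warning(
      "non-target pool smaller than target class; using the whole pool ",
      "in every repetition",
      call. = FALSE
    )
  }
  p_sum <- numeric(nrow(m))
  d_sum <- numeric(nrow(m))
  withr::with_seed(params$seed, {
    for (r in seq_len(params$n_reps)) {
      drawn <- if (m_draw == length(idx_pool)) {
        idx_pool
      } else {
        sample(idx_pool, m_draw)
      }
      tt <- row_t_test(m, idx_t, drawn, welch = params$welch)
      p_sum <- p_sum + tt$p
      d_sum <- d_sum + tt$diff
    }
  })
  out <- tibble(
    probe_id = rownames(m),
    target_class = target_class,
    mean_p = unname(p_sum) / params$n_reps,
    mean_log2fc = unname(d_sum) / params$n_reps,
    mean_linear_fold = 2^(unname(d_sum) / params$n_reps)
  )
  out <- arrange(out, mean_p, desc(mean_log2fc), probe_id)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("marker_stats", class(out))
  out
}

#' Rank and select the candidate marker panel
#'
#' Keeps the `top_n` most significant probes (by the `rank` column of
#' [resampled_marker_stats()]) and, among those, the probes whose mean linear
#' fold is at least `fold_threshold`.
#'
#' @param stats a `marker_stats` tibble for one target class.
#' @param params a [discovery_params()] (uses `top_n`, `fold_threshold`).
#' @return tibble of selected candidates, sorted by `rank`; may be empty.
#' @export
rank_markers <- function(stats, params = discovery_params()) {
  stopifnot(is.data.frame(stats))
  out <- stats |>
    arrange(rank) |>
    head(params$top_n) |>
    filter(mean_linear_fold >= params$fold_threshold)
  class(out) <- setdiff(class(out), "marker_stats")
  as_tibble(out)
}

#' Intersect an internal candidate panel with an external reference list
#'
#' Returns probes present in both lists, annotated with their rank in each.
#' Probes in `forced` are kept even when absent from the internal panel
#' (flagged `"external-only"`), mirroring externally mandated candidates that
#' are carried along to examine their probe performance.
#'
#' @param panel tibble from [rank_markers()] (columns `probe_id`, `rank`).
#' @param external_list character vector of probe ids, ranked (best first).
#' @param forced character vector of probe ids to force-include.
#' @return tibble with `probe_id`, `rank_internal`, `rank_external`,
#'   `provenance` (`"both"` or `"external-only"`).
#' @export
intersect_markers <- function(panel, external_list, forced = character()) {
  stopifnot(is.data.frame(panel))
  ext_rank <- match(panel$probe_id, external_list)
  shared <- tibble(
    probe_id = panel$probe_id,
    rank_internal = panel$rank,
    rank_external = ext_rank,
    provenance = "both"
  ) |>
    filter(!is.na(rank_external))
  extra <- setdiff(forced, shared$probe_id)
  forced_tbl <- tibble(
    probe_id = extra,
    rank_internal = NA_integer_,
    rank_external = match(extra, external_list),
    provenance = "external-only"
  )
  bind_rows(shared, forced_tbl)
}

#' One-call marker discovery for a target class
#'
#' Runs the discovery chain on a linear-scale matrix: optional compartment
#' split, quantile normalization, log2 transform with variance filtering,
#' resampled marker statistics and panel selection.
#'
#' @param expr linear-scale wide tibble (`probe_id` + sample columns).
#' @param labels tibble with `sample_id`, `class` and optionally
#'   `compartment`.
#' @param target_class class to find markers for.
#' @param params a [discovery_params()].
#' @param compartment if given and `labels` has a `compartment` column,
#'   restrict to that compartment before normalization (quantile
#'   normalization is applied separately per compartment).
#' @return object of class `marker_discovery`: the selected panel tibble with
#'   attributes `stats` (full `marker_stats`) and `params`.
#' @export
discover_markers <- function(expr, labels, target_class,
                             params = discovery_params(),
                             compartment = NULL) {
  labels <- as_tibble(labels)
  if (!is.null(compartment)) {
    if (!"compartment" %in% names(labels)) {
      abort_config("labels lack a compartment column")
    }
    labels <- filter(labels, .data$compartment == !!compartment)
    expr <- expr[, c("probe_id", labels$sample_id)]
  }
  normed <- quantile_normalize(expr)
  lg <- log2_variance_filter(normed, params$variance_threshold)
  stats <- resampled_marker_stats(lg, labels, target_class, params)
  panel <- rank_markers(stats, params)
  structure(panel, stats = stats, params = params, class =
              c("marker_discovery", class(panel)))
}
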