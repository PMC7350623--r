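# One-vs-rest ROC/AUC evaluation of individual marker probes.

#' ROC curve for one probe against one entity
#'
#' Scores are the probe's log2 normalized expression; the ROC is a threshold
#' sweep over the unique scores, and the AUC is the trapezoidal area, which
#' with the midrank tie convention equals the Mann-Whitney U statistic
#' divided by `n_pos * n_neg`.
#'
#' @param norm an `ns_normalized` object or a log2-scale wide tibble.
#' @param probe probe name.
#' @param positive_samples sample ids of the positive (entity) class; all
#'   remaining samples are negatives. Both classes must be nonempty.
#' @return object of class `probe_roc`: list with `probe`, `auc`, `points`
#'   (tibble `fpr`, `tpr` sorted by `fpr`, including (0,0) and (1,1)),
#'   `n_pos`, `n_neg`.
#' @export
probe_roc <- function(norm, probe, positive_samples) {
  lg <- if (inherits(norm, "ns_normalized")) norm$log2 else norm
  m <- expr_to_matrix(lg)
  if (!probe %in% rownames(m)) stop("unknown probe: ", probe, call. = FALSE)
  scores <- m[probe, ]
  is_pos <- colnames(m) %in% positive_samples
  if (!any(is_pos) || all(is_pos)) {
    stop("need at least one positive and one negative sample", call. = FALSE)
  }
  r <- pROC::roc(
    response = factor(is_pos, levels = c(FALSE, TRUE)),
    predictor = scores, direction = "<", quiet = TRUE
  )
  points <- tibble(fpr = 1 - r$specificities, tpr = r$sensitivities) |>
    arrange(fpr, tpr)
  structure(
    list(
      probe = probe,
      auc = as.numeric(pROC::auc(r)),
      points = points,
      n_pos = sum(is_pos),
      n_neg = sum(!is_pos)
    ),
    class = "probe_roc"
  )
}

#' @export
print.probe_roc <- function(x, ...) {
  cat(
    "<probe_roc> ", x$probe, ": AUC = ", format(x$auc, digits = 4),
    " (", x$n_pos, " pos / ", x$n_neg, " neg)\n",
    sep = ""
  )
  invisible(x)
}

#' Per-entity, per-probe AUC table
#'
#' One-vs-rest ROC/AUC for every marker probe of every entity of the
#' compartment's panels, with entity membership (from the ground-truth or
#' call table) as the positive class. Entities with zero positive samples
#' are skipped with a warning. Optionally also reports the panel-mean score
#' AUC per entity.
#'
#' @inheritParams probe_roc
#' @param cs a [codeset()]; defaults to the one carried by `norm`.
#' @param truth tibble with `sample_id` and `entity` (`NA` for background)
#'   covering all scored samples.
#' @param compartment compartment whose panels are evaluated.
#' @param panel_mean also add one row per entity using the panel-mean score
#'   (`probe = "<panel mean>"`). Default `FALSE`.
#' @return tibble of class `auc_table`: `entity`, `probe`, `auc`, `n_pos`,
#'   `n_neg`, sorted by entity then descending AUC.
#' @export
auc_table <- function(norm, cs = NULL, truth, compartment,
                      panel_mean = FALSE) {
  if (inherits(norm, "ns_normalized")) cs <- cs %||% norm$codeset
  if (is.null(cs)) abort_config("a codeset is required")
  lg <- if (inherits(norm, "ns_normalized")) norm$log2 else norm
  truth <- as_tibble(truth)
  stopifnot(all(c("sample_id", "entity") %in% names(truth)))
  ids <- sample_ids_of(lg)
  if (!all(ids %in% truth$sample_id)) {
    stop("ground truth must cover all samples", call. = FALSE)
  }
  rows <- lapply(callable_entities(cs, compartment), function(e) {
    pos <- truth$sample_id[!is.na(truth$entity) & truth$entity == e]
    pos <- intersect(pos, ids)
    if (length(pos) == 0) {
      warning("entity ", e, " has zero positive samples; skipped",
              call. = FALSE)
      return(NULL)
    }
    panel <- entity_panel(cs, e, compartment)
    out <- bind_rows(lapply(panel, function(p) {
      r <- probe_roc(lg, p, pos)
      tibble(entity = e, probe = p, auc = r$auc,
             n_pos = r$n_pos, n_neg = r$n_neg)
    }))
    if (panel_mean) {
      m <- expr_to_matrix(lg)
      mean_scores <- colMeans(m[intersect(panel, rownames(m)), , drop = FALSE])
      mean_tbl <- matrix_to_expr(rbind(`<panel mean>` = mean_scores))
      r <- probe_roc(mean_tbl, "<panel mean>", pos)
      out <- bind_rows(out, tibble(
        entity = e, probe = "<panel mean>", auc = r$auc,
        n_pos = r$n_pos, n_neg = r$n_neg
      ))
    }
    out
  })
  out <- bind_rows(rows) |> arrange(entity, desc(auc))
  class(out) <- c("auc_table", class(out))
  out
}
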