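# Two-stage count normalization (technical: positive controls; biological:
# housekeeping genes) plus the reference-fold hybridization QC.

#' Technical (positive-control) normalization
#'
#' Each sample is rescaled by `anchor / geomean(positive controls of the
#' sample)`. With `target` given (the default path via [normalize_cohort()]
#' uses the CodeSet's positive-control design-ladder geomean) the anchor is
#' that constant, which makes the two-stage normalization exactly invariant
#' to any per-sample count rescaling. With `target = NULL` the anchor is the
#' arithmetic mean across samples of the per-sample geometric means (so a
#' sample whose geomean equals the cohort mean gets factor 1, and a
#' single-sample cohort is left untouched).
#'
#' A sample with a zero positive-control count is flagged (`qc = "pos_zero"`),
#' gets factor 1 and a warning.
#'
#' @param counts wide tibble (`probe_id` + sample columns) of counts to scale.
#' @param positive wide tibble of the positive-control counts, same samples.
#' @param target positive number (fixed anchor) or `NULL` (cohort-mean
#'   anchor).
#' @return list: `counts` (scaled tibble), `factors` (tibble `sample_id`,
#'   `factor`, `qc`).
#' @export
technical_normalize <- function(counts, positive, target = NULL) {
  m <- expr_to_matrix(counts)
  pos <- expr_to_matrix(positive)
  stopifnot(identical(colnames(m), colnames(pos)))
  gm <- apply(pos, 2, geomean)
  qc <- rep(NA_character_, ncol(m))
  bad <- gm <= 0 | !is.finite(gm)
  if (any(bad)) {
    warning(
      "zero positive-control count in sample(s): ",
      paste(colnames(m)[bad], collapse = ", "), "; factor 1 applied",
      call. = FALSE
    )
    qc[bad] <- "pos_zero"
  }
  anchor <- if (is.null(target)) mean(gm[!bad]) else target
  f <- ifelse(bad, 1, anchor / gm)
  list(
    counts = matrix_to_expr(sweep(m, 2, f, `*`)),
    factors = tibble(sample_id = colnames(m), factor = unname(f), qc = qc)
  )
}

#' Biological (housekeeping) normalization
#'
#' Same construction as [technical_normalize()] but anchored on housekeeping
#' geometric means; the anchor is the arithmetic mean across samples of the
#' per-sample housekeeping geomeans. A sample with a zero housekeeping count
#' is flagged (`qc = "hk_zero"`) and its geomean is computed from the
#' remaining housekeeping probes.
#'
#' @param counts wide tibble of (technically normalized) counts to scale.
#' @param housekeeping wide tibble of housekeeping counts, same samples and
#'   scaling as `counts`.
#' @return list: `counts`, `factors` (tibble `sample_id`, `factor`, `qc`).
#' @export
housekeeping_normalize <- function(counts, housekeeping) {
  m <- expr_to_matrix(counts)
  hk <- expr_to_matrix(housekeeping)
  stopifnot(identical(colnames(m), colnames(hk)))
  has_zero <- apply(hk, 2, function(x) any(x == 0))
  gm <- apply(hk, 2, geomean, drop_zero = TRUE)
  qc <- ifelse(has_zero, "hk_zero", NA_character_)
  bad <- !is.finite(gm) | gm <= 0
  if (any(bad)) {
    warning(
      "all housekeeping counts zero in sample(s): ",
      paste(colnames(m)[bad], collapse = ", "), "; factor 1 applied",
      call. = FALSE
    )
    qc[bad] <- "hk_all_zero"
  }
  anchor <- mean(gm[!bad])
  f <- ifelse(bad, 1, anchor / gm)
  list(
    counts = matrix_to_expr(sweep(m, 2, f, `*`)),
    factors = tibble(sample_id = colnames(m), factor = unname(f),
                     qc = unname(qc))
  )
}

#' Log2 transform with pseudocount
#'
#' `log2(count + pseudocount)`; with the default pseudocount 1, a zero count
#' maps to 0 and a count of 1 maps to 1.
#'
#' @param counts wide tibble of non-negative values.
#' @param pseudocount added before the log (default 1).
#' @return wide tibble of log2 values.
#' @export
log2_counts <- function(counts, pseudocount = 1) {
  m <- expr_to_matrix(counts)
  stopifnot(all(m >= 0))
  matrix_to_expr(log2(m + pseudocount))
}

#' Normalize a NanoString cohort
#'
#' Assembles the count matrix from RCC lanes, optionally subtracts negative-
#' control background (mean + 2 sd per lane, floored at 0; off by default),
#' applies technical then housekeeping normalization, and returns linear and
#' log2 (pseudocount 1) endogenous values.
#'
#' @param cohort an `ns_cohort` from [simulate_cohort()], or a list of
#'   [rcc_sample()].
#' @param cs a [codeset()]; defaults to the cohort's own.
#' @param background_subtract subtract per-lane negative-control background
#'   (mean + 2 sd, floored at 0) before normalization. Default `FALSE`.
#' @param anchor `"ladder"` (fixed anchor: geomean of the CodeSet's
#'   positive-control design levels; exactly scale-invariant) or
#'   `"cohort_mean"` (arithmetic mean across samples of positive-control
#'   geomeans).
#' @return object of class `ns_normalized`: list with `log2` and `linear`
#'   wide tibbles (endogenous + housekeeping probes), `tech_factors`,
#'   `bio_factors`, `qc` (per-sample flags tibble) and `codeset`.
#' @export
normalize_cohort <- function(cohort, cs = NULL,
                             background_subtract = FALSE,
                             anchor = c("ladder", "cohort_mean")) {
  anchor <- match.arg(anchor)
  if (inherits(cohort, "ns_cohort")) {
    samples <- cohort$samples
    cs <- cs %||% cohort$codeset
  } else {
    samples <- cohort
    if (is.null(cs)) abort_config("a codeset is required")
  }
  parts <- assemble_counts(samples, cs)
  endo <- parts$endogenous
  hk <- parts$housekeeping
  if (background_subtract) {
    neg <- expr_to_matrix(parts$negative)
    cutoff <- apply(neg, 2, function(x) mean(x) + 2 * sd(x))
    subtract <- function(tbl) {
      m <- sweep(expr_to_matrix(tbl), 2, cutoff, `-`)
      matrix_to_expr(pmax(m, 0))
    }
    endo <- subtract(endo)
    hk <- subtract(hk)
  }
  target <- if (anchor == "ladder") geomean(cs$positive_controls) else NULL
  both <- bind_rows(endo, hk)
  tech <- technical_normalize(both, parts$positive, target = target)
  hk_scaled <- tech$counts |> filter(probe_id %in% cs$housekeeping)
  bio <- housekeeping_normalize(tech$counts, hk_scaled)
  qc <- tibble(
    sample_id = parts$sample_ids,
    tech_qc = tech$factors$qc,
    bio_qc = bio$factors$qc
  )
  structure(
    list(
      linear = bio$counts,
      log2 = log2_counts(bio$counts),
      tech_factors = tech$factors,
      bio_factors = bio$factors,
      qc = qc,
      codeset = cs
    ),
    class = "ns_normalized"
  )
}

#' @export
print.ns_normalized <- function(x, ...) {
  cat(
    "<ns_normalized> ", nrow(x$linear), " probes x ",
    length(sample_ids_of(x$linear)), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' Reference-fold hybridization QC for one probe
#'
#' Good hybridization requires the probe's normalized linear-scale expression
#' in the known-positive reference sample to exceed the arithmetic mean of
#' all remaining samples: `fold = reference / mean(others)`, pass iff
#' `fold > 1`. A zero mean of the remaining samples makes the fold undefined
#' (`NA`, QC-indeterminate, not a pass).
#'
#' @param norm an `ns_normalized` object (or a linear-scale wide tibble).
#' @param probe probe name.
#' @param reference_sample sample id of the reference.
#' @return tibble: `probe`, `reference_sample`, `fold`, `pass`.
#' @export
hybridization_fold <- function(norm, probe, reference_sample) {
  lin <- if (inherits(norm, "ns_normalized")) norm$linear else norm
  m <- expr_to_matrix(lin)
  if (ncol(m) < 2) stop("reference-fold QC needs >= 2 samples", call. = FALSE)
  if (!probe %in% rownames(m)) stop("unknown probe: ", probe, call. = FALSE)
  if (!reference_sample %in% colnames(m)) {
    stop("unknown reference sample: ", reference_sample, call. = FALSE)
  }
  ref <- m[probe, reference_sample]
  rest <- mean(m[probe, setdiff(colnames(m), reference_sample)])
  fold <- if (rest == 0) NA_real_ else ref / rest
  tibble(
    probe = probe,
    reference_sample = reference_sample,
    fold = fold,
    pass = if (is.na(fold)) NA else fold > 1
  )
}

#' Hybridization QC over a cohort's entity panels
#'
#' Computes [hybridization_fold()] for every marker probe of every entity
#' that has a reference sample, using the first reference of each entity.
#'
#' @param norm an `ns_normalized` object.
#' @param cs a [codeset()].
#' @param references named list: entity -> reference sample id(s).
#' @param compartment compartment whose panels are assessed.
#' @return tibble: `entity`, `probe`, `reference_sample`, `fold`, `pass`.
#' @export
hybridization_qc <- function(norm, cs, references, compartment) {
  rows <- lapply(names(references), function(e) {
    panel <- entity_panel(cs, e, compartment)
    if (length(panel) == 0) return(NULL)
    bind_rows(lapply(panel, function(p) {
      hybridization_fold(norm, p, references[[e]][1])
    })) |>
      mutate(entity = e, .before = 1)
  })
  bind_rows(rows)
}
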