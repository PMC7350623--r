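# Reference-anchored diagnosis: average-linkage clustering of normalized
# marker expression, per-entity signature scores, the explicit group-calling
# rule, and the glioma-contrast re-analysis.

# Restrict a log2 table to the marker probes visible in a compartment
# (entity panels + glioma panel), samples x probes matrix.
marker_matrix <- function(norm, cs, compartment, samples = NULL) {
  lg <- if (inherits(norm, "ns_normalized")) norm$log2 else norm
  probes <- unique(c(
    unlist(lapply(
      names(cs$entities), entity_panel, cs = cs, compartment = compartment
    ), use.names = FALSE),
    cs$glioma_panel
  ))
  probes <- intersect(lg$probe_id, probes)
  m <- t(expr_to_matrix(lg)[probes, , drop = FALSE])
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  m
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerative UPGMA (average linkage) over pairwise Euclidean distances of
#' the samples' log2 marker-probe vectors (entity panels plus glioma panel of
#' the given compartment).
#'
#' @param norm an `ns_normalized` object (or a log2-scale wide tibble).
#' @param cs a [codeset()]; defaults to the one carried by `norm`.
#' @param compartment compartment whose panels define the probe space.
#' @param samples optional character vector restricting/ordering the samples.
#' @return an [stats::hclust] object (class `c("ns_dendrogram", "hclust")`)
#'   with the probe set stored in attribute `probes`.
#' @export
cluster_samples <- function(norm, cs = NULL, compartment, samples = NULL) {
  if (inherits(norm, "ns_normalized")) cs <- cs %||% norm$codeset
  if (is.null(cs)) abort_config("a codeset is required")
  m <- marker_matrix(norm, cs, compartment, samples)
  if (nrow(m) < 2) stop("clustering needs >= 2 samples", call. = FALSE)
  hc <- hclust(dist(m), method = "average")
  attr(hc, "probes") <- colnames(m)
  class(hc) <- c("ns_dendrogram", "hclust")
  hc
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from merge heights (ultrametric tree).
#'
#' @param hc an [stats::hclust] (e.g. from [cluster_samples()]).
#' @return single Newick string.
#' @export
as_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  class(hc) <- "hclust"
  ape::write.tree(ape::as.phylo(hc))
}

# Height at which each leaf first merges into the tree.
leaf_merge_heights <- function(hc) {
  n <- length(hc$labels)
  h <- numeric(n)
  for (i in seq_along(hc$height)) {
    for (leaf in hc$merge[i, ]) {
      if (leaf < 0 && h[-leaf] == 0) h[-leaf] <- hc$height[i]
    }
  }
  setNames(h, hc$labels)
}

#' Per-entity signature scores
#'
#' For each entity, the raw score of a sample is the mean of its log2
#' normalized values over the entity's marker panel; `z` standardizes the raw
#' score across the cohort (all z set to 0 when the cohort sd is 0), and
#' `elevation` is the raw score minus the cohort median raw score (an
#' absolute log2 elevation over the non-expressing background, which the
#' calling rule thresholds in addition to `z`; a cohort-z alone can exceed
#' any threshold on pure noise).
#'
#' @inheritParams cluster_samples
#' @param entities entities to score (default: all entities callable in the
#'   compartment).
#' @return tibble: `sample_id`, `entity`, `score`, `z`, `elevation`.
#' @export
signature_scores <- function(norm, cs = NULL, compartment, entities = NULL) {
  if (inherits(norm, "ns_normalized")) cs <- cs %||% norm$codeset
  if (is.null(cs)) abort_config("a codeset is required")
  lg <- if (inherits(norm, "ns_normalized")) norm$log2 else norm
  m <- expr_to_matrix(lg)
  entities <- entities %||% callable_entities(cs, compartment)
  for (e in entities) {
    if (length(intersect(entity_panel(cs, e, compartment), rownames(m))) == 0) {
      abort_config(paste0(
        "entity ", e, " has no measured marker probes in ", compartment
      ))
    }
  }
  bind_rows(lapply(entities, function(e) {
    panel <- intersect(entity_panel(cs, e, compartment), rownames(m))
    s <- colMeans(m[panel, , drop = FALSE])
    sd_s <- sd(s)
    tibble(
      sample_id = colnames(m),
      entity = e,
      score = unname(s),
      z = if (sd_s > 0) unname((s - mean(s)) / sd_s) else 0,
      elevation = unname(s - median(s))
    )
  }))
}

#' Call entity membership for every sample
#'
#' A sample is called entity `g` iff (i) its signature z-score for `g` is at
#' least `tau`, (ii) its absolute log2 elevation over the cohort median score
#' is at least `min_log2_elev`, (iii) `g` is the arg-max entity among those
#' passing (a tie between two entities yields no call and an ambiguity flag),
#' and (iv) when `g` has a reference sample in the cohort, the sample falls
#' in the same cluster as a reference of `g` when the dendrogram is cut into
#' `k = (number of entities with references) + 1` clusters. Every reference
#' sample must be called its own entity, otherwise a
#' classification-integrity error is raised.
#'
#' @inheritParams cluster_samples
#' @param references named list: entity -> reference sample id(s) present in
#'   the cohort. Entities without a reference are callable by score alone
#'   (flagged lower-confidence in `co_cluster`).
#' @param tau z-score threshold (default 2).
#' @param min_log2_elev absolute log2-elevation threshold (default 1, i.e. at
#'   least a 2-fold mean marker elevation over the cohort median).
#' @param entities entities to consider; they must be callable in the
#'   compartment (a nonempty panel), else a configuration error is raised.
#' @return object of class `group_calls`: tibble with `sample_id`,
#'   `called_entity` (`NA` when no call), `max_z`, `ambiguous`, `co_cluster`
#'   (`NA` for entities without references), `reference`; the long score
#'   table and the dendrogram are attached as attributes `scores` and
#'   `dendrogram`.
#' @export
call_groups <- function(norm, cs = NULL, references = list(), compartment,
                        tau = 2, min_log2_elev = 1, entities = NULL,
                        samples = NULL) {
  if (inherits(norm, "ns_normalized")) cs <- cs %||% norm$codeset
  if (is.null(cs)) abort_config("a codeset is required")
  entities <- entities %||% callable_entities(cs, compartment)
  not_callable <- setdiff(entities, callable_entities(cs, compartment))
  if (length(not_callable) > 0) {
    abort_config(paste0(
      "entity not callable in ", compartment, ": ",
      paste(not_callable, collapse = ", ")
    ))
  }
  scores <- signature_scores(norm, cs, compartment, entities)
  if (!is.null(samples)) scores <- filter(scores, sample_id %in% samples)
  ids <- unique(scores$sample_id)

  hc <- cluster_samples(norm, cs, compartment, samples = ids)
  ref_entities <- intersect(names(references), entities)
  ref_entities <- ref_entities[vapply(
    ref_entities, function(e) any(references[[e]] %in% ids), logical(1)
  )]
  k <- length(ref_entities) + 1L
  groups <- cutree(structure(hc, class = "hclust"), k = min(k, length(ids)))

  call_one <- function(id) {
    sc <- scores[scores$sample_id == id, ]
    pass <- sc$z >= tau & sc$elevation >= min_log2_elev
    if (!any(pass)) {
      return(tibble(
        sample_id = id, called_entity = NA_character_,
        max_z = max(sc$z), ambiguous = FALSE, co_cluster = NA
      ))
    }
    cand <- sc[pass, ]
    top <- cand[order(-cand$z), ]
    if (nrow(top) > 1 && isTRUE(all.equal(top$z[1], top$z[2]))) {
      return(tibble(
        sample_id = id, called_entity = NA_character_,
        max_z = top$z[1], ambiguous = TRUE, co_cluster = NA
      ))
    }
    g <- top$entity[1]
    if (g %in% ref_entities) {
      refs <- intersect(references[[g]], ids)
      co <- groups[id] %in% groups[refs]
      if (!co) {
        return(tibble(
          sample_id = id, called_entity = NA_character_,
          max_z = top$z[1], ambiguous = FALSE, co_cluster = FALSE
        ))
      }
      tibble(
        sample_id = id, called_entity = g, max_z = top$z[1],
        ambiguous = FALSE, co_cluster = TRUE
      )
    } else {
      tibble(
        sample_id = id, called_entity = g, max_z = top$z[1],
        ambiguous = FALSE, co_cluster = NA
      )
    }
  }
  calls <- bind_rows(lapply(ids, call_one))
  calls$reference <- FALSE
  for (e in names(references)) {
    refs <- intersect(references[[e]], ids)
    calls$reference[calls$sample_id %in% refs] <- TRUE
    miscalled <- refs[!(calls$called_entity[match(refs, calls$sample_id)] %in% e)]
    if (length(miscalled) > 0) {
      stop(
        "classification-integrity error: reference sample(s) not called ",
        "their own entity: ", paste(miscalled, collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    calls,
    scores = scores, dendrogram = hc, tau = tau,
    class = c("group_calls", class(calls))
  )
}

#' Classify a multi-compartment cohort
#'
#' Runs [call_groups()] separately per compartment (marker panels are always
#' analyzed separately in supra- and infratentorial locations) and binds the
#' calls.
#'
#' @param norm an `ns_normalized` object covering all samples.
#' @param truth_or_samples tibble with `sample_id`, `compartment` and
#'   optionally `entity`/`reference` (e.g. the `truth` of an `ns_cohort`), or
#'   a named list: compartment -> sample ids.
#' @param references named list of named lists:
#'   compartment -> (entity -> reference ids). When `truth_or_samples` has
#'   `reference` and `entity` columns the references are taken from there.
#' @inheritParams call_groups
#' @return tibble of calls with a `compartment` column.
#' @export
classify_cohort <- function(norm, truth_or_samples, cs = NULL,
                            references = NULL, tau = 2, min_log2_elev = 1) {
  if (inherits(norm, "ns_normalized")) cs <- cs %||% norm$codeset
  if (is.data.frame(truth_or_samples)) {
    sheet <- as_tibble(truth_or_samples)
    split_ids <- split(sheet$sample_id, sheet$compartment)
    if (is.null(references) &&
        all(c("entity", "reference") %in% names(sheet))) {
      references <- lapply(split_ids, function(ids) {
        refs <- sheet[sheet$sample_id %in% ids & sheet$reference &
                        !is.na(sheet$entity), ]
        split(refs$sample_id, refs$entity)
      })
    }
  } else {
    split_ids <- truth_or_samples
  }
  references <- references %||%
    setNames(
      rep(list(list()), length(split_ids)), names(split_ids)
    )
  bind_rows(lapply(names(split_ids), function(comp) {
    calls <- call_groups(
      norm, cs,
      references = references[[comp]] %||% list(),
      compartment = comp, tau = tau, min_log2_elev = min_log2_elev,
      samples = split_ids[[comp]]
    )
    calls <- as_tibble(calls)
    calls$compartment <- comp
    calls
  }))
}

#' Glioma-contrast re-analysis
#'
#' Re-analyzes a (typically glioma-dominated) cohort against two panels: the
#' HGNET-BCOR marker panel and the glioma panel (GFAP/OLIG2/PMP2). Panel
#' positivity is absolute: a sample is positive for a panel when its mean
#' log2 panel score exceeds the panel's cohort 10th-percentile floor by at
#' least `min_log2_elev` (cohort z-scores are uninformative here because
#' glioma-high samples are the majority). Labels: `dual` (both panels),
#' `signature` (entity panel only), `glioma` (glioma panel only), `outlier`
#' (neither panel and the sample's first dendrogram merge height — its
#' nearest-neighbor height — exceeds the 95th percentile of the cohort's
#' first-merge heights), otherwise `none`.
#'
#' @inheritParams cluster_samples
#' @param entity the contrasted entity (default `"HGNET-BCOR"`).
#' @param min_log2_elev absolute log2 elevation over the panel floor
#'   (default 1).
#' @param outlier_quantile merge-height quantile for outlier detection
#'   (default 0.95).
#' @return tibble: `sample_id`, `score_entity`, `score_glioma`, `label`.
#' @export
glioma_contrast <- function(norm, cs = NULL, compartment = "supratentorial",
                            entity = "HGNET-BCOR", min_log2_elev = 1,
                            outlier_quantile = 0.95, samples = NULL) {
  if (inherits(norm, "ns_normalized")) cs <- cs %||% norm$codeset
  if (is.null(cs)) abort_config("a codeset is required")
  lg <- if (inherits(norm, "ns_normalized")) norm$log2 else norm
  m <- expr_to_matrix(lg)
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  panel_e <- intersect(entity_panel(cs, entity, compartment), rownames(m))
  panel_g <- intersect(cs$glioma_panel, rownames(m))
  if (length(panel_e) == 0 || length(panel_g) == 0) {
    abort_config("both the entity panel and the glioma panel must be measured")
  }
  s_e <- colMeans(m[panel_e, , drop = FALSE])
  s_g <- colMeans(m[panel_g, , drop = FALSE])
  pos_e <- s_e - quantile(s_e, 0.1) >= min_log2_elev
  pos_g <- s_g - quantile(s_g, 0.1) >= min_log2_elev

  sub <- matrix_to_expr(m[c(panel_e, panel_g), , drop = FALSE])
  hc <- cluster_samples(sub, cs, compartment)
  first_h <- leaf_merge_heights(hc)
  # Outlier cut on the same per-sample statistic (first-merge heights): the
  # quantile over all merge heights is dominated by the few top-level
  # cluster joins and by the outlier's own merge.
  h_cut <- quantile(first_h, outlier_quantile)

  label <- dplyr::case_when(
    pos_e & pos_g ~ "dual",
    pos_e ~ "signature",
    pos_g ~ "glioma",
    first_h[colnames(m)] > h_cut ~ "outlier",
    TRUE ~ "none"
  )
  tibble(
    sample_id = colnames(m),
    score_entity = unname(s_e),
    score_glioma = unname(s_g),
    label = unname(label)
  )
}
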