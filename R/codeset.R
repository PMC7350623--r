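#' Construct a CodeSet probe-panel definition
#'
#' A CodeSet describes the custom probe panel hybridized in an nCounter run:
#' per-entity marker probes (split by brain compartment, since entity panels
#' differ between supratentorial and infratentorial tumors), housekeeping
#' genes used for biological normalization, a glioma contrast panel, and the
#' synthetic positive/negative control probes.
#'
#' @param name codeset name.
#' @param entities named list, one element per entity; each element is a list
#'   with character vectors `supratentorial` and/or `infratentorial` giving
#'   the marker probe names used in that compartment. An entity absent from a
#'   compartment (empty vector) is not callable there.
#' @param housekeeping character vector of housekeeping probe names.
#' @param glioma_panel character vector of glioma marker probes.
#' @param positive_controls named numeric vector: probe name -> design count
#'   level of the synthetic positive-control ladder. The geometric mean of
#'   these design levels is the default anchor of [technical_normalize()].
#' @param negative_controls character vector of negative-control probe names.
#' @return an object of class `codeset`.
#' @seealso [default_codeset()] for the four-entity diagnostic panel.
#' @export
codeset <- function(name,
                    entities,
                    housekeeping = c("ACTB", "GAPDH", "LDHA"),
                    glioma_panel = c("GFAP", "OLIG2", "PMP2"),
                    positive_controls = default_positive_ladder(),
                    negative_controls = paste0("NEG_", LETTERS[1:6])) {
  stopifnot(is.list(entities), length(entities) > 0, !is.null(names(entities)))
  entities <- lapply(entities, function(e) {
    list(
      supratentorial = as.character(e$supratentorial %||% character()),
      infratentorial = as.character(e$infratentorial %||% character())
    )
  })
  if (length(housekeeping) == 0) abort_config("housekeeping list must be nonempty")
  empty <- vapply(
    entities,
    function(e) length(e$supratentorial) + length(e$infratentorial) == 0,
    logical(1)
  )
  if (any(empty)) {
    abort_config(paste0(
      "every entity needs at least one marker probe in some compartment; ",
      "offending: ", paste(names(entities)[empty], collapse = ", ")
    ))
  }
  marker_probes <- unique(unlist(lapply(entities, unlist), use.names = FALSE))
  all_probes <- c(
    marker_probes, glioma_panel, housekeeping,
    names(positive_controls), negative_controls
  )
  dup <- unique(all_probes[duplicated(all_probes)])
  if (length(dup) > 0) {
    abort_config(paste0(
      "probe names must be unique across categories; duplicated: ",
      paste(dup, collapse = ", ")
    ))
  }
  structure(
    list(
      name = name,
      entities = entities,
      housekeeping = as.character(housekeeping),
      glioma_panel = as.character(glioma_panel),
      positive_controls = positive_controls,
      negative_controls = as.character(negative_controls)
    ),
    class = "codeset"
  )
}

#' Synthetic positive-control ladder design levels
#'
#' Six-probe geometric ladder (factor 4) of design count levels, mirroring the
#' spike-in layout of nCounter positive controls.
#'
#' @return named numeric vector.
#' @export
default_positive_ladder <- function() {
  setNames(16384 / 4^(0:5), paste0("POS_", LETTERS[1:6]))
}

#' Diagnostic CodeSet for the four rare CNS tumor entities
#'
#' The per-entity panels reflect the published compartment-specific probe
#' selection: CNS HGNET-BCOR and CNS HGNET-MN1 are detectable in both
#' compartments (with reduced infratentorial panels), CNS NB-FOXR2 and CNS
#' EFT-CIC only supratentorially. Supratentorial panel sizes are 6 (HGNET-BCOR),
#' 6 (HGNET-MN1), 4 (NB-FOXR2) and 6 (EFT-CIC).
#'
#' @return a [codeset()] object.
#' @export
default_codeset <- function() {
  codeset(
    name = "cns_four_entity_panel",
    entities = list(
      `HGNET-BCOR` = list(
        supratentorial = c("BCOR", "EMX1", "PRDM6", "SHISA8", "MNX1", "MMP15"),
        infratentorial = c("BCOR", "SHISA8", "MNX1", "MMP15", "RTN4RL1")
      ),
      `HGNET-MN1` = list(
        supratentorial = c("BEND2", "MUM1", "SHOX", "APCDD1L", "FAM3B", "ECHS1"),
        infratentorial = c("BEND2", "SHOX", "APCDD1L")
      ),
      `NB-FOXR2` = list(
        supratentorial = c("FOXR2", "DNAH2", "SOX10", "FAM163A"),
        infratentorial = character()
      ),
      `EFT-CIC` = list(
        supratentorial = c("MYO1D", "CES1", "SCARA5", "CAMK1G", "SHC4", "ETV4"),
        infratentorial = character()
      )
    )
  )
}

#' Marker probes of one entity in one compartment
#' @param cs a [codeset()].
#' @param entity entity name.
#' @param compartment `"supratentorial"` or `"infratentorial"`.
#' @return character vector of probe names (possibly empty).
#' @export
entity_panel <- function(cs, entity, compartment) {
  stopifnot(inherits(cs, "codeset"))
  compartment <- match.arg(compartment, c("supratentorial", "infratentorial"))
  if (!entity %in% names(cs$entities)) {
    abort_config(paste0("unknown entity: ", entity))
  }
  cs$entities[[entity]][[compartment]]
}

#' Entities callable in a compartment
#' @inheritParams entity_panel
#' @return character vector of entity names with a nonempty panel there.
#' @export
callable_entities <- function(cs, compartment) {
  compartment <- match.arg(compartment, c("supratentorial", "infratentorial"))
  names(cs$entities)[vapply(
    cs$entities, function(e) length(e[[compartment]]) > 0, logical(1)
  )]
}

# All endogenous probes (entity markers + glioma panel), cohort-wide.
endogenous_probes <- function(cs) {
  unique(c(unlist(lapply(cs$entities, unlist), use.names = FALSE), cs$glioma_panel))
}

# Probe -> CodeClass lookup used by the generator and matrix assembly.
codeset_classes <- function(cs) {
  tibble(
    probe = c(
      endogenous_probes(cs), cs$housekeeping,
      names(cs$positive_controls), cs$negative_controls
    ),
    code_class = c(
      rep("Endogenous", length(endogenous_probes(cs))),
      rep("Housekeeping", length(cs$housekeeping)),
      rep("Positive", length(cs$positive_controls)),
      rep("Negative", length(cs$negative_controls))
    )
  )
}

#' @export
print.codeset <- function(x, ...) {
  cat("<codeset> ", x$name, "\n", sep = "")
  for (e in names(x$entities)) {
    cat(
      "  ", e, ": supra [",
      paste(x$entities[[e]]$supratentorial, collapse = ", "),
      "] | infra [",
      paste(x$entities[[e]]$infratentorial, collapse = ", "), "]\n",
      sep = ""
    )
  }
  cat("  housekeeping:", paste(x$housekeeping, collapse = ", "), "\n")
  cat("  glioma panel:", paste(x$glioma_panel, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a CodeSet as YAML
#' @param cs a [codeset()].
#' @param path file path.
#' @return `read_codeset()` returns a [codeset()]; `write_codeset()` the path,
#'   invisibly.
#' @export
write_codeset <- function(cs, path) {
  stopifnot(inherits(cs, "codeset"))
  yaml::write_yaml(
    list(
      name = cs$name,
      entities = cs$entities,
      housekeeping = cs$housekeeping,
      glioma_panel = cs$glioma_panel,
      positive_controls = as.list(cs$positive_controls),
      negative_controls = cs$negative_controls
    ),
    path
  )
  invisible(path)
}

#' @rdname write_codeset
#' @export
read_codeset <- function(path) {
  y <- yaml::read_yaml(path)
  codeset(
    name = y$name,
    entities = y$entities,
    housekeeping = unlist(y$housekeeping),
    glioma_panel = unlist(y$glioma_panel),
    positive_controls = unlist(y$positive_controls),
    negative_controls = unlist(y$negative_controls)
  )
}
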