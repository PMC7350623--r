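# Internal helpers shared across modules.

#' Geometric mean
#'
#' @param x numeric vector, strictly positive values contribute; zeros are
#'   dropped when `drop_zero = TRUE` (used for degraded housekeeping lanes).
#' @param drop_zero drop zero entries instead of propagating them.
#' @return a single number; `NA` if nothing positive remains.
#' @keywords internal
geomean <- function(x, drop_zero = FALSE) {
  if (drop_zero) x <- x[x > 0]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) return(0)
  exp(mean(log(x)))
}

# Wide expression tibble (probe_id + one numeric column per sample) -> matrix.
expr_to_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "probe_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "probe_id")])
  if (!is.numeric(m)) stop("expression columns must be numeric", call. = FALSE)
  rownames(m) <- tbl$probe_id
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(probe_id = rownames(m), .before = 1L)
}

sample_ids_of <- function(tbl) setdiff(names(tbl), "probe_id")

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

abort_config <- function(msg) stop("configuration error: ", msg, call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x
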