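# RCC lane files: the sectioned text dialect used to exchange nCounter counts.
# Fixed bit-exactly here (tag-delimited sections, Code_Summary CSV body,
# version header 1.7) so generated fixtures are diffable goldens.

#' Construct one RCC lane
#'
#' @param sample_id sample identifier (stored in `Sample_Attributes/ID`).
#' @param records data frame with columns `code_class`
#'   (Endogenous/Housekeeping/Positive/Negative), `probe`, `accession`,
#'   `count` (non-negative integers).
#' @param lane_id lane number.
#' @param binding_density placeholder lane metric.
#' @return an object of class `rcc_sample`.
#' @export
rcc_sample <- function(sample_id, records, lane_id = 1L, binding_density = 0.5) {
  records <- as_tibble(records)
  stopifnot(all(c("code_class", "probe", "accession", "count") %in% names(records)))
  if (nrow(records) > 0) {
    if (any(is.na(records$count)) ||
        any(records$count < 0) ||
        any(records$count != round(records$count))) {
      stop("RCC counts must be non-negative integers", call. = FALSE)
    }
    dup <- unique(records$probe[duplicated(records$probe)])
    if (length(dup) > 0) {
      stop(
        "duplicate probe name(s) in RCC records: ", paste(dup, collapse = ", "),
        call. = FALSE
      )
    }
  }
  records$count <- as.integer(records$count)
  structure(
    list(
      sample_id = as.character(sample_id),
      lane_id = as.integer(lane_id),
      binding_density = binding_density,
      records = records
    ),
    class = "rcc_sample"
  )
}

#' @export
print.rcc_sample <- function(x, ...) {
  cat(
    "<rcc_sample> ", x$sample_id, " (lane ", x$lane_id, ", ",
    nrow(x$records), " probes)\n",
    sep = ""
  )
  invisible(x)
}

# Minimal CSV field quoting/unquoting for Code_Summary rows.
csv_quote <- function(x) {
  needs <- grepl('[",]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

csv_split <- function(line) {
  scan(
    text = line, what = character(), sep = ",", quote = '"',
    quiet = TRUE, strip.white = FALSE
  )
}

#' Write an RCC lane file
#'
#' Emits the sectioned RCC dialect: `<Header>`, `<Sample_Attributes>`,
#' `<Lane_Attributes>` and a `<Code_Summary>` CSV body with columns
#' `CodeClass,Name,Accession,Count`. Field order is fixed for diffability.
#'
#' @param sample an [rcc_sample()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(sample, path) {
  stopifnot(inherits(sample, "rcc_sample"))
  r <- sample$records
  body <- if (nrow(r) == 0) {
    character()
  } else {
    paste(
      csv_quote(r$code_class), csv_quote(r$probe),
      csv_quote(r$accession), r$count,
      sep = ","
    )
  }
  lines <- c(
    "<Header>",
    "FileVersion,1.7",
    "SoftwareVersion,cnssig",
    "</Header>",
    "",
    "<Sample_Attributes>",
    paste0("ID,", csv_quote(sample$sample_id)),
    "Owner,",
    "Comments,",
    "Date,1970-01-01",
    "</Sample_Attributes>",
    "",
    "<Lane_Attributes>",
    paste0("ID,", sample$lane_id),
    paste0("BindingDensity,", format(sample$binding_density, trim = TRUE)),
    "</Lane_Attributes>",
    "",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    body,
    "</Code_Summary>",
    ""
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an RCC lane file
#'
#' Parses the dialect written by [write_rcc()]. Malformed input (missing
#' section closers, non-integer counts, duplicate probes) raises a parse
#' error naming the offending line.
#'
#' @param path RCC file path.
#' @return an [rcc_sample()].
#' @export
read_rcc <- function(path) {
  if (!file.exists(path)) stop("no such RCC file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parse_err <- function(i, msg) {
    stop(
      "RCC parse error at ", basename(path), ":", i, " - ", msg,
      call. = FALSE
    )
  }
  section_bounds <- function(tag) {
    open <- which(lines == paste0("<", tag, ">"))
    close <- which(lines == paste0("</", tag, ">"))
    if (length(open) != 1) {
      parse_err(1L, paste0("missing or duplicated section <", tag, ">"))
    }
    if (length(close) != 1 || close < open) {
      parse_err(open, paste0("section <", tag, "> is not closed by </", tag, ">"))
    }
    c(open, close)
  }
  kv <- function(tag) {
    b <- section_bounds(tag)
    rows <- lines[(b[1] + 1):(b[2] - 1)]
    rows <- rows[nzchar(rows)]
    keys <- sub(",.*$", "", rows)
    vals <- sub("^[^,]*,", "", rows)
    setNames(as.list(vals), keys)
  }
  header <- kv("Header")
  if (is.null(header$FileVersion)) parse_err(1L, "Header lacks FileVersion")
  sa <- kv("Sample_Attributes")
  la <- kv("Lane_Attributes")
  b <- section_bounds("Code_Summary")
  rows_idx <- seq(b[1] + 1, b[2] - 1)
  rows <- lines[rows_idx]
  keep <- nzchar(rows)
  rows <- rows[keep]
  rows_idx <- rows_idx[keep]
  if (length(rows) == 0 || rows[1] != "CodeClass,Name,Accession,Count") {
    parse_err(b[1] + 1, "Code_Summary must start with its column header")
  }
  rows <- rows[-1]
  rows_idx <- rows_idx[-1]
  rec <- lapply(seq_along(rows), function(i) {
    f <- csv_split(rows[i])
    if (length(f) != 4) parse_err(rows_idx[i], "expected 4 CSV fields")
    cnt <- suppressWarnings(as.numeric(f[4]))
    if (is.na(cnt) || cnt != round(cnt) || cnt < 0) {
      parse_err(rows_idx[i], paste0("count is not a non-negative integer: ", f[4]))
    }
    tibble(
      code_class = f[1], probe = f[2], accession = f[3],
      count = as.integer(cnt)
    )
  })
  records <- if (length(rec) == 0) {
    tibble(
      code_class = character(), probe = character(),
      accession = character(), count = integer()
    )
  } else {
    bind_rows(rec)
  }
  dup <- unique(records$probe[duplicated(records$probe)])
  if (length(dup) > 0) {
    parse_err(b[1], paste0("duplicate probe name(s): ", paste(dup, collapse = ", ")))
  }
  rcc_sample(
    sample_id = sa$ID %||% basename(path),
    records = records,
    lane_id = as.integer(la$ID %||% 1L),
    binding_density = as.numeric(la$BindingDensity %||% NA_real_)
  )
}

#' Read every RCC file in a directory
#' @param dir directory containing `*.rcc`/`*.RCC` files.
#' @return list of [rcc_sample()], ordered by file name.
#' @export
read_rcc_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.rcc$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(paths) == 0) stop("no RCC files found in ", dir, call. = FALSE)
  lapply(paths, read_rcc)
}

#' Assemble a counts table from RCC lanes
#'
#' Builds wide tibbles (`probe_id` + one column per sample, in input order)
#' for each CodeClass partition. All lanes must share the same probe set.
#'
#' @param samples list of [rcc_sample()].
#' @param cs a [codeset()]; probes are partitioned by its categories.
#' @return list with wide tibbles `endogenous`, `housekeeping`, `positive`,
#'   `negative`, and `sample_ids`.
#' @export
assemble_counts <- function(samples, cs) {
  stopifnot(length(samples) >= 1, inherits(cs, "codeset"))
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids across lanes", call. = FALSE)
  ref_probes <- samples[[1]]$records$probe
  for (s in samples) {
    miss <- setdiff(ref_probes, s$records$probe)
    extra <- setdiff(s$records$probe, ref_probes)
    if (length(miss) + length(extra) > 0) {
      stop(
        "probe-set mismatch in sample ", s$sample_id, ": missing [",
        paste(miss, collapse = ", "), "] extra [",
        paste(extra, collapse = ", "), "]",
        call. = FALSE
      )
    }
  }
  counts <- vapply(
    samples,
    function(s) s$records$count[match(ref_probes, s$records$probe)],
    numeric(length(ref_probes))
  )
  counts <- matrix(counts, nrow = length(ref_probes),
                   dimnames = list(ref_probes, ids))
  classes <- codeset_classes(cs)
  part <- function(class) {
    probes <- intersect(ref_probes, classes$probe[classes$code_class == class])
    matrix_to_expr(counts[probes, , drop = FALSE])
  }
  list(
    endogenous = part("Endogenous"),
    housekeeping = part("Housekeeping"),
    positive = part("Positive"),
    negative = part("Negative"),
    sample_ids = ids
  )
}
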