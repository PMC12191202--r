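# Structured lesion records: the bridge between report text and geometry.
# One record describes one lesion the radiologist called out -- its class
# (primary tumor vs lymph node), laterality, PET slice, anatomic region or
# LN level, size and SUV.

lesion_classes <- c("primary", "node")
lateralities <- c("left", "right", "bilateral", "midline", "unknown")

#' Anatomic-region and LN-level vocabularies
#'
#' The primary-tumor regions distinguished in head-and-neck reports and the
#' standard lymph-node level labels the package recognises.
#' @export
hn_regions <- c("nasopharyngeal", "oropharynx", "hypopharynx",
                "tongue_base", "carotid_space", "other")

#' @rdname hn_regions
#' @export
hn_ln_levels <- c("1b", "2a", "2b", "3", "4a", "4b", "5a", "5b")

#' Create a lesion record
#'
#' @param case_id Case identifier.
#' @param lesion_class `"primary"` or `"node"`.
#' @param laterality `"left"`, `"right"`, `"bilateral"`, `"midline"` or
#'   `"unknown"`.
#' @param slice_number Optional positive integer PET slice number; records
#'   without one are matched by anatomic region / LN level instead.
#' @param anatomic_region Optional region from [hn_regions] (primaries).
#' @param ln_level Optional level from [hn_ln_levels] (nodes).
#' @param size_mm,suv_bw Optional positive scalars.
#' @param grouped `TRUE` for "clusters" / "several nodes" descriptions; a
#'   grouped record may match several contour instances but counts as one
#'   reported lesion.
#' @return One-row data.frame of class `lesion_record` columns.
#' @export
lesion_record <- function(case_id = "", lesion_class, laterality = "unknown",
                          slice_number = NA, anatomic_region = NA,
                          ln_level = NA, size_mm = NA, suv_bw = NA,
                          grouped = FALSE) {
  lesion_class <- match.arg(lesion_class, lesion_classes)
  laterality <- match.arg(laterality, lateralities)
  rec <- data.frame(
    case_id = as.character(case_id),
    lesion_class = lesion_class,
    laterality = laterality,
    slice_number = as.integer(slice_number),
    anatomic_region = as.character(anatomic_region),
    ln_level = as.character(ln_level),
    size_mm = as.numeric(size_mm),
    suv_bw = as.numeric(suv_bw),
    grouped = isTRUE(grouped),
    stringsAsFactors = FALSE
  )
  msgs <- validate_records(rec, strict = TRUE)
  if (length(msgs)) stop("invalid lesion record: ", paste(msgs, collapse = "; "))
  rec
}

record_columns <- c("case_id", "lesion_class", "laterality", "slice_number",
                    "anatomic_region", "ln_level", "size_mm", "suv_bw",
                    "grouped")

#' Bind lesion records into one table
#' @param ... One-row [lesion_record()] data.frames (or record tables).
#' @export
lesion_records <- function(...) {
  recs <- list(...)
  if (!length(recs)) return(empty_records())
  do.call(rbind, recs)
}

empty_records <- function() {
  data.frame(case_id = character(), lesion_class = character(),
             laterality = character(), slice_number = integer(),
             anatomic_region = character(), ln_level = character(),
             size_mm = numeric(), suv_bw = numeric(), grouped = logical(),
             stringsAsFactors = FALSE)
}

#' Validate a table of lesion records
#'
#' Flags structural violations and the known extraction failure modes:
#' primaries carrying an LN level, nodes with neither level nor
#' region+laterality, levels outside the head-and-neck vocabulary (e.g.
#' axillary nodes leaking in), non-positive slice/size/SUV, and duplicate
#' (class, slice) pairs -- the signature of one primary tumor split into
#' several records.
#'
#' @param records A record table.
#' @param strict Also flag missing class/laterality values (used by the
#'   constructor).
#' @return Character vector of violation messages; empty when clean.
#' @export
validate_records <- function(records, strict = FALSE) {
  msgs <- character()
  if (!nrow(records)) return(msgs)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    who <- sprintf("record %d (%s)", i, r$lesion_class)
    if (!r$lesion_class %in% lesion_classes) {
      msgs <- c(msgs, sprintf("%s: unknown class", who))
      next
    }
    if (!r$laterality %in% lateralities) {
      msgs <- c(msgs, sprintf("%s: unknown laterality '%s'", who, r$laterality))
    }
    if (r$lesion_class == "primary") {
      if (!is.na(r$ln_level)) {
        msgs <- c(msgs, sprintf("%s: primary tumor carries LN level '%s'",
                                who, r$ln_level))
      }
      if (strict && is.na(r$anatomic_region)) {
        msgs <- c(msgs, sprintf("%s: primary without anatomic region", who))
      }
      if (!is.na(r$anatomic_region) && !r$anatomic_region %in% hn_regions) {
        msgs <- c(msgs, sprintf("%s: unknown anatomic region '%s'", who,
                                r$anatomic_region))
      }
    } else {
      if (!is.na(r$ln_level) && !r$ln_level %in% hn_ln_levels) {
        msgs <- c(msgs, sprintf(
          "%s: LN level '%s' outside the head-and-neck vocabulary", who,
          r$ln_level))
      }
      # construction (strict) accepts slice-located nodes; the reporting
      # pass flags any node lacking level and region as unlocatable for
      # scenario-2 matching
      if (is.na(r$ln_level) &&
          (is.na(r$anatomic_region) || r$laterality == "unknown") &&
          (!strict || is.na(r$slice_number))) {
        msgs <- c(msgs, sprintf(
          "%s: node without LN level or (laterality + region)", who))
      }
    }
    for (f in c("slice_number", "size_mm", "suv_bw")) {
      if (!is.na(r[[f]]) && r[[f]] <= 0) {
        msgs <- c(msgs, sprintf("%s: %s must be positive", who, f))
      }
    }
  }
  dup <- records[!is.na(records$slice_number), c("lesion_class", "slice_number")]
  if (nrow(dup)) {
    d <- duplicated(dup)
    for (i in which(d)) {
      msgs <- c(msgs, sprintf(
        "duplicate (%s, slice %d) pair: possible split of one lesion",
        dup$lesion_class[i], dup$slice_number[i]))
    }
  }
  msgs
}

# ---- fixture-v1 dialect -----------------------------------------------------
# A deterministic plain-text stand-in for LLM output so the pipeline is
# testable offline.  One lesion per line, 6 or 7 semicolon fields:
#   class;laterality;slice;region_or_level;size_mm;suv_bw[;grouped]
# Empty fields mean "not reported"; '#' starts a comment line.  This dialect
# is this package's own and is not a clinical format.

#' Parse a structured fixture-dialect report
#'
#' @param text Report text in the `fixture-v1` dialect (see Details).
#' @param case_id Case id stamped on every record.
#' @param dialect Only `"fixture-v1"` is defined.
#' @return A record table, one row per lesion line.
#' @details Each non-comment line is
#'   `class;laterality;slice;region_or_level;size_mm;suv_bw[;grouped]`.
#'   The fourth field is an anatomic region for primaries and an LN level
#'   for nodes.
#' @export
parse_structured_report <- function(text, case_id = "", dialect = "fixture-v1") {
  if (!identical(dialect, "fixture-v1")) stop("unknown dialect: ", dialect)
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  out <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, ";", fixed = TRUE)[[1]]
    f <- c(trimws(f), rep("", max(0, 7 - length(f))))
    if (length(f) > 7 || !f[1] %in% lesion_classes) {
      stop(sprintf("fixture-v1 parse error at line %d: '%s'", ln, line))
    }
    blank <- function(x) if (x == "") NA else x
    rec <- try(lesion_record(
      case_id = case_id,
      lesion_class = f[1],
      laterality = if (f[2] == "") "unknown" else f[2],
      slice_number = if (f[3] == "") NA else as.integer(f[3]),
      anatomic_region = if (f[1] == "primary") blank(f[4]) else NA,
      ln_level = if (f[1] == "node") blank(f[4]) else NA,
      size_mm = if (f[5] == "") NA else as.numeric(f[5]),
      suv_bw = if (f[6] == "") NA else as.numeric(f[6]),
      grouped = identical(f[7], "grouped")
    ), silent = TRUE)
    if (inherits(rec, "try-error")) {
      stop(sprintf("fixture-v1 parse error at line %d: %s", ln,
                   attr(rec, "condition")$message))
    }
    out[[length(out) + 1]] <- rec
  }
  if (!length(out)) empty_records() else do.call(rbind, out)
}

#' Render records back to the fixture dialect
#'
#' Inverse of [parse_structured_report()]: parsing the rendered text
#' reproduces the records exactly.
#'
#' @param records A record table.
#' @return A single string, one lesion per line.
#' @export
render_report_text <- function(records) {
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    region <- if (r$lesion_class == "primary") r$anatomic_region else r$ln_level
    paste(c(r$lesion_class, r$laterality,
            if (is.na(r$slice_number)) "" else r$slice_number,
            if (is.na(region)) "" else region,
            fmt_num(r$size_mm), fmt_num(r$suv_bw),
            if (r$grouped) "grouped" else ""), collapse = ";")
  }, character(1))
  paste(lines, collapse = "\n")
}

# ---- canonical JSON / CSV serialisation ------------------------------------

#' Read and write lesion-record tables
#'
#' JSON is the canonical on-disk form; CSV (one record per row, fixed
#' header) is provided for spreadsheets.
#'
#' @param records A record table.
#' @param path File path (`.json` or `.csv` decides the format).
#' @return `read_records()` returns a record table.
#' @export
write_records <- function(records, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(records, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(records, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  }
  if (!length(df) || !nrow(df)) return(empty_records())
  for (col in record_columns) if (is.null(df[[col]])) df[[col]] <- NA
  out <- empty_records()
  for (i in seq_len(nrow(df))) {
    out <- rbind(out, lesion_record(
      case_id = df$case_id[i] %||% "",
      lesion_class = df$lesion_class[i],
      laterality = if (is.na(df$laterality[i])) "unknown" else df$laterality[i],
      slice_number = df$slice_number[i],
      anatomic_region = df$anatomic_region[i],
      ln_level = as.character(df$ln_level[i]),
      size_mm = df$size_mm[i],
      suv_bw = df$suv_bw[i],
      grouped = isTRUE(df$grouped[i])
    ))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
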