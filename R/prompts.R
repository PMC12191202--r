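# LLM report-extraction adapter.  A backend is any object exposing one
# text -> text method; live GPT-4 / Llama-style backends plug in behind the
# same contract, while tests and offline runs use the mock backend with
# canned output.  The prompts instruct the model to tabulate every lesion in
# the report; the second prompt additionally anchors the decision on the
# Impression paragraph, which summarises the non-benign findings and guards
# against benign high-uptake regions (e.g. a goiter) being tabulated.

prompt1_text <- paste(
  "Generate a table for HN, extract slice number, tumor size (if none,",
  "leave empty), SUV value, tumor anatomic region, tumor type, whether the",
  "tumor is primary or a lymph node tumor, if multiple tumors, list each",
  "tumor at different rows. For primary tumors, the anatomic region is",
  "nasopharyngeal, oropharynx, hypopharynx, tongue base, and carotid space;",
  "extract detailed left, right, or bilateral tumors. For lymph nodes,",
  "provide the detailed lymph node level as anatomic region")

prompt2_text <- paste(
  prompt1_text,
  ". Use the impression paragraph to help determine if the tumor in the",
  "findings paragraph is primary or a lymph node tumor")

# The model's output format is pinned by this suffix; unknown columns in
# the reply are ignored at parse time.
output_format_suffix <- paste(
  "Answer only with a markdown table with the columns:",
  "| lesion_class | laterality | slice_number | region_or_level |",
  "size_mm | suv_bw | grouped |.",
  "lesion_class is 'primary' or 'node'; grouped is 'yes' for clusters or",
  "several nodes, else 'no'; leave unknown cells empty.")

#' Prompt templates for report extraction
#'
#' Two instruction templates: `prompt1` asks for a lesion table directly;
#' `prompt2` additionally directs the model to use the Impression paragraph
#' to decide whether a finding is a primary tumor or a lymph node, which
#' suppresses benign findings.  Templates are immutable package resources.
#'
#' @param id `"prompt1"` or `"prompt2"`.
#' @return An object of class `prompt_template` with fields `id`, `text`.
#' @export
prompt_template <- function(id = c("prompt2", "prompt1")) {
  id <- match.arg(id)
  structure(list(id = id,
                 text = if (id == "prompt1") prompt1_text else prompt2_text),
            class = "prompt_template")
}

#' Render a full prompt for one report
#'
#' Concatenates the instruction template, the pinned output-format suffix
#' and the report text.  For `prompt2` a report without an Impression
#' section triggers a warning but rendering proceeds.
#'
#' @param template A [prompt_template()].
#' @param report_text Free-text radiology report (Findings + Impression).
#' @return A single prompt string.
#' @export
render_prompt <- function(template, report_text) {
  stopifnot(inherits(template, "prompt_template"))
  if (!nzchar(trimws(paste(report_text, collapse = "\n")))) {
    warning("empty report text; rendering prompt alone")
    report_text <- ""
  } else if (template$id == "prompt2" &&
             !grepl("impression", report_text, ignore.case = TRUE)) {
    warning("report has no Impression section; prompt2 may underperform")
  }
  paste(template$text, output_format_suffix, "\nReport:\n", report_text)
}

#' Extraction backends
#'
#' A backend is a list with fields `id` (text) and `complete`
#' (`function(prompt_text) -> text`).  `mock_backend()` ignores the prompt
#' and replies with canned text, giving deterministic offline runs and
#' recorded-transcript replay.
#'
#' @param reply Canned model reply (e.g. a markdown lesion table).
#' @param id Backend identifier stored in transcripts.
#' @export
mock_backend <- function(reply, id = "mock") {
  list(id = id, complete = function(prompt_text) reply)
}

#' Parse a markdown lesion table into records
#'
#' Reads the first markdown table in `text`, maps its header to the
#' canonical record fields (case-insensitively; unknown columns ignored)
#' and builds one [lesion_record()] per data row.
#'
#' @param text Model reply text.
#' @param case_id Case id stamped on the records.
#' @return A record table.
#' @export
parse_markdown_table <- function(text, case_id = "") {
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  tab <- grep("^\\s*\\|.*\\|\\s*$", lines)
  if (length(tab) < 2) stop("extraction table malformed: no markdown table found")
  cells <- lapply(lines[tab], function(l) {
    parts <- strsplit(l, "|", fixed = TRUE)[[1]]
    trimws(parts[-1])  # drop text before the leading pipe
  })
  header <- tolower(cells[[1]])
  rows <- cells[-1]
  rows <- rows[!vapply(rows, function(r) all(grepl("^[-: ]*$", r)), TRUE)]
  col_of <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, header)
      if (length(hit)) return(hit[1])
    }
    NA_integer_
  }
  cols <- list(
    class = col_of(c("class", "type")),
    laterality = col_of("later"),
    slice = col_of("slice"),
    region = col_of(c("region", "level", "anatomic")),
    size = col_of("size"),
    suv = col_of("suv"),
    grouped = col_of("group")
  )
  if (is.na(cols$class)) stop("extraction table malformed: no lesion class column")
  get <- function(r, j) {
    if (is.na(j) || j > length(r)) return(NA_character_)
    v <- r[[j]]
    if (v == "" || tolower(v) %in% c("na", "n/a", "-", "none")) NA_character_ else v
  }
  num <- function(x) if (is.na(x)) NA_real_ else suppressWarnings(as.numeric(gsub("[^0-9.]+", "", x)))
  out <- empty_records()
  for (r in rows) {
    cls <- tolower(get(r, cols$class) %||% "")
    cls <- if (grepl("prim", cls)) "primary" else if (grepl("node|lymph|ln", cls)) "node" else cls
    if (!cls %in% lesion_classes) {
      stop("extraction table malformed: unrecognised lesion class '",
           get(r, cols$class), "'")
    }
    lat <- tolower(get(r, cols$laterality) %||% "unknown")
    if (is.na(lat) || !lat %in% lateralities) lat <- "unknown"
    region <- get(r, cols$region)
    region_norm <- if (is.na(region)) NA else {
      rn <- tolower(gsub("[ -]", "_", region))
      if (rn %in% hn_regions || rn %in% hn_ln_levels) rn else region
    }
    grp <- tolower(get(r, cols$grouped) %||% "no")
    sl <- num(get(r, cols$slice))
    out <- rbind(out, lesion_record(
      case_id = case_id, lesion_class = cls, laterality = lat,
      slice_number = if (is.na(sl)) NA else as.integer(round(sl)),
      anatomic_region = if (cls == "primary") region_norm else NA,
      ln_level = if (cls == "node") region_norm else NA,
      size_mm = num(get(r, cols$size)), suv_bw = num(get(r, cols$suv)),
      grouped = !is.na(grp) && grepl("^(y|yes|true|1)$", grp)
    ))
  }
  out
}

#' Run LLM extraction on one report
#'
#' Renders the prompt, calls the backend once, parses the reply table and
#' returns the full transcript for audit.  The result is a pure function of
#' the report, the prompt and the backend reply, so a stored transcript
#' replays to identical records.
#'
#' @param report_text Free-text radiology report.
#' @param prompt_id `"prompt1"` or `"prompt2"` (default).
#' @param backend A backend, e.g. [mock_backend()].
#' @param case_id Case id stamped on the records.
#' @return An `extraction_transcript`: list with `report_text`, `prompt_id`,
#'   `raw_model_output`, `records`, `backend_id`.
#' @export
llm_extract <- function(report_text, prompt_id = "prompt2", backend,
                        case_id = "") {
  template <- prompt_template(prompt_id)
  prompt <- render_prompt(template, report_text)
  raw <- backend$complete(prompt)
  records <- tryCatch(parse_markdown_table(raw, case_id = case_id),
    error = function(e) {
      e2 <- simpleError(conditionMessage(e))
      e2$raw_model_output <- raw
      stop(e2)
    })
  structure(list(report_text = report_text, prompt_id = prompt_id,
                 raw_model_output = raw, records = records,
                 backend_id = backend$id),
            class = "extraction_transcript")
}

#' Replay a stored extraction transcript
#'
#' Re-parses the recorded raw model output; the result must equal the
#' stored records (losslessness invariant).
#'
#' @param transcript An `extraction_transcript` (or its JSON path).
#' @export
replay_transcript <- function(transcript) {
  if (is.character(transcript)) {
    transcript <- jsonlite::fromJSON(transcript, simplifyDataFrame = TRUE)
  }
  case_id <- if (nrow(transcript$records)) transcript$records$case_id[1] else ""
  parse_markdown_table(transcript$raw_model_output, case_id = case_id)
}
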