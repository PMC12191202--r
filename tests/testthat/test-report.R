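# Lesion records, the fixture dialect, validation and the extraction adapter.

test_that("fixture dialect parses single lesion lines", {
  r <- parse_structured_report("node;left;23;2a;12;5.4")
  expect_equal(r$lesion_class, "node")
  expect_equal(r$ln_level, "2a")
  expect_equal(r$slice_number, 23L)
  expect_equal(r$size_mm, 12)
  expect_equal(r$suv_bw, 5.4)
  expect_false(r$grouped)

  r2 <- parse_structured_report("primary;right;18;nasopharyngeal;;8.1")
  expect_equal(r2$lesion_class, "primary")
  expect_equal(r2$anatomic_region, "nasopharyngeal")
  expect_true(is.na(r2$size_mm))

  r3 <- parse_structured_report("node;bilateral;;3;;;grouped")
  expect_true(r3$grouped)
  expect_true(is.na(r3$slice_number))

  expect_error(parse_structured_report("banana;left;1;2a;;"), "line 1")
  expect_error(parse_structured_report("node;left;1;2a;;\nnode;;;;"),
               "line 2")
})

test_that("render/parse round-trips arbitrary valid record tables", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    recs <- do.call(rbind, lapply(seq_len(n), function(i) {
      cls <- sample(c("primary", "node"), 1)
      lesion_record(
        case_id = "", lesion_class = cls,
        laterality = sample(c("left", "right", "bilateral"), 1),
        slice_number = if (runif(1) < 0.5) sample(1:64, 1) else NA,
        anatomic_region = if (cls == "primary") sample(hn_regions[1:5], 1) else NA,
        ln_level = if (cls == "node") sample(hn_ln_levels, 1) else NA,
        size_mm = if (runif(1) < 0.5) round(runif(1, 5, 30), 1) else NA,
        suv_bw = if (runif(1) < 0.5) round(runif(1, 1, 12), 2) else NA,
        grouped = cls == "node" && runif(1) < 0.3)
    }))
    back <- parse_structured_report(render_report_text(recs))
    expect_equal(back, recs, ignore_attr = TRUE)
  }
})

test_that("validation flags the known extraction failure modes", {
  clean <- rbind(
    lesion_record(lesion_class = "primary", laterality = "right",
                  anatomic_region = "oropharynx", slice_number = 18),
    lesion_record(lesion_class = "node", laterality = "left", ln_level = "2a",
                  slice_number = 30))
  expect_length(validate_records(clean), 0)

  split_primary <- rbind(clean[1, ], clean[1, ])
  expect_match(validate_records(split_primary), "duplicate", all = FALSE)

  non_hn <- clean
  non_hn$ln_level[2] <- "axillary"
  expect_match(validate_records(non_hn), "vocabulary", all = FALSE)

  orphan <- clean
  orphan$ln_level[2] <- NA
  orphan$anatomic_region[2] <- NA
  expect_match(validate_records(orphan), "node without", all = FALSE)

  confused <- clean
  confused$ln_level[1] <- "2a"
  expect_match(validate_records(confused), "primary tumor carries", all = FALSE)
})

test_that("prompt rendering carries the instruction phrases and warns on gaps", {
  p1 <- render_prompt(prompt_template("prompt1"), "Findings: x. Impression: y.")
  expect_match(p1, "Generate a table for HN", fixed = TRUE)
  expect_false(grepl("impression paragraph", p1))
  p2 <- render_prompt(prompt_template("prompt2"), "Findings: x. Impression: y.")
  expect_match(p2, "Use the impression paragraph to help determine", fixed = TRUE)
  expect_warning(render_prompt(prompt_template("prompt2"), "Findings only."),
                 "Impression")
  expect_warning(render_prompt(prompt_template("prompt1"), ""), "empty report")
})

test_that("llm_extract parses mock-backend tables and rejects prose", {
  tbl <- paste(
    "| lesion_class | laterality | slice_number | region_or_level | size_mm | suv_bw | grouped |",
    "|---|---|---|---|---|---|---|",
    "| primary | right | 18 | nasopharyngeal |  | 8.1 | no |",
    "| node | left | 23 | 2a | 12 | 5.4 | no |",
    sep = "\n")
  tr <- llm_extract("Findings: two lesions. Impression: as above.",
                    backend = mock_backend(tbl), case_id = "c1")
  expect_s3_class(tr, "extraction_transcript")
  expect_equal(nrow(tr$records), 2)
  expect_equal(tr$records$lesion_class, c("primary", "node"))
  expect_equal(tr$records$ln_level, c(NA, "2a"))
  expect_equal(tr$records$case_id, c("c1", "c1"))

  expect_error(
    llm_extract("Findings: x. Impression: y.",
                backend = mock_backend("No table here, just prose.")),
    "malformed")

  # replay reproduces the stored records exactly
  expect_equal(replay_transcript(tr), tr$records)
})

test_that("a report mirroring the clinical structure extracts a nasopharyngeal primary", {
  recs <- rbind(
    lesion_record(case_id = "appx", lesion_class = "primary",
                  laterality = "right", anatomic_region = "nasopharyngeal",
                  slice_number = 41, suv_bw = 9.3),
    lesion_record(case_id = "appx", lesion_class = "node", laterality = "right",
                  ln_level = "2a", slice_number = 48, size_mm = 14, suv_bw = 6.1))
  prose <- render_prose_report(recs)
  expect_match(prose, "Findings:")
  expect_match(prose, "Impression:")
  tr <- llm_extract(prose, backend = mock_backend(records_to_markdown(recs)),
                    case_id = "appx")
  expect_equal(tr$records$anatomic_region[1], "nasopharyngeal")
  expect_equal(tr$records, recs, ignore_attr = TRUE)
})

test_that("record tables round-trip through JSON and CSV", {
  recs <- rbind(
    lesion_record(case_id = "a", lesion_class = "primary", laterality = "left",
                  anatomic_region = "tongue_base", slice_number = 12),
    lesion_record(case_id = "a", lesion_class = "node", laterality = "right",
                  ln_level = "4a", suv_bw = 3.3, grouped = TRUE))
  for (ext in c("json", "csv")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_records(recs, f)
    expect_equal(read_records(f), recs, ignore_attr = TRUE)
    unlink(f)
  }
})
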