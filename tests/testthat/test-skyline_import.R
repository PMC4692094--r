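test_that("parse_report reads the dialect and applies the null convention", {
  rows <- parse_report(tiny_report_csv())
  expect_s3_class(rows, "srm_report")
  expect_equal(nrow(rows), 6)
  expect_true(all(rows$isotope_label_type == "light"))

  # header-only file: empty report
  hdr <- sub("\n.*", "\n", tiny_report_csv())
  expect_equal(nrow(parse_report(hdr)), 0)

  # blank and #N/A numeric cells become NA; the rows are retained
  csv <- tiny_report_csv()
  lines <- strsplit(csv, "\n")[[1]]
  lines[2] <- sub("14.2,100", ",#N/A", lines[2], fixed = TRUE)
  rows2 <- parse_report(paste0(paste(lines, collapse = "\n"), "\n"))
  expect_equal(nrow(rows2), 6)
  expect_true(is.na(rows2$retention_time[1]))
  expect_true(is.na(rows2$area[1]))
})

test_that("parse_report header matching ignores case, spaces and order", {
  csv <- tiny_report_csv()
  lines <- strsplit(csv, "\n")[[1]]
  lines[1] <- paste("protein name,peptide modified sequence,PRECURSORMZ",
                    "Precursor Charge,product mz,PRODUCT CHARGE,fragmention",
                    "isotopelabeltype,replicate name,file name",
                    "retention time,AREA,background,HEIGHT,FWHM", sep = ",")
  rows <- parse_report(paste0(paste(lines, collapse = "\n"), "\n"))
  expect_equal(rows$precursor_mz[1], 523.77)
})

test_that("parse_report reports missing columns and bad cells precisely", {
  csv <- tiny_report_csv()
  lines <- strsplit(csv, "\n")[[1]]
  drop8 <- vapply(strsplit(lines, ","), function(f)
    paste(f[-8], collapse = ","), character(1))
  no_label <- paste0(paste(drop8, collapse = "\n"), "\n")
  expect_error(parse_report(no_label), "IsotopeLabelType")

  bad <- sub("523.77", "not-a-number", csv, fixed = TRUE)
  expect_error(parse_report(bad), "row 1")
  badlab <- sub("light", "medium", csv, fixed = TRUE)
  expect_error(parse_report(badlab), "light")
})

test_that("detect_label_mode follows the IsotopeLabelType column", {
  expect_equal(detect_label_mode(parse_report(tiny_report_csv("light"))),
               "LABEL_FREE")
  expect_equal(detect_label_mode(
    parse_report(tiny_report_csv(c("light", "heavy")))), "MS1_LABEL_BASED")
  expect_equal(detect_label_mode(parse_report(tiny_report_csv("heavy"))),
               "MS1_LABEL_BASED")
  hdr_only <- parse_report(sub("\n.*", "\n", tiny_report_csv()))
  expect_error(detect_label_mode(hdr_only), "empty")
})

test_that("label-free conversion: 2 assays, 6 features, 1 peptide, no ratios", {
  doc <- build_document(parse_report(tiny_report_csv("light")))
  expect_length(doc$assays, 2)
  expect_equal(sum(vapply(doc$feature_lists,
                          function(fl) length(fl$features), integer(1))), 6)
  expect_length(doc$peptides, 1)
  expect_length(doc$ratio_definitions, 0)
  expect_null(doc$ratio_quant_layer)
})

test_that("labeled conversion: 4 assays, 12 features, 1 peptide, ratios present", {
  doc <- build_document(parse_report(tiny_report_csv(c("light", "heavy"))))
  expect_length(doc$assays, 4)
  expect_equal(sum(vapply(doc$feature_lists,
                          function(fl) length(fl$features), integer(1))), 12)
  expect_length(doc$peptides, 1)
  expect_length(doc$ratio_definitions, 2)  # one per replicate
  expect_false(is.null(doc$ratio_quant_layer))
})

test_that("every converter feature layer has the four fixed columns", {
  for (doc in list(build_document(parse_report(tiny_report_csv())),
                   labeled_doc(seed = 11))) {
    for (fl in doc$feature_lists) {
      cols <- fl$quant_layers[[1]]$columns
      expect_length(cols, 4)
      expect_equal(vapply(cols, function(c) c$datatype$name, character(1)),
                   c("XIC area", "XIC background", "peak intensity",
                     "full width at half-maximum"))
    }
  }
})

test_that("feature count equals the number of distinct transition keys", {
  exp <- generate_srm_experiment(synth_spec(seed = 12, labeled = TRUE))
  rows <- parse_report(exp$report_csv)
  doc <- build_document(rows)
  # independent set construction over the raw rows
  keys <- unique(paste(rows$replicate_name, rows$peptide_modified_sequence,
                       rows$precursor_charge, rows$fragment_ion,
                       rows$product_charge, rows$isotope_label_type))
  expect_equal(sum(vapply(doc$feature_lists,
                          function(fl) length(fl$features), integer(1))),
               length(keys))
})

test_that("every measurement tuple lands exactly once in the matrices", {
  exp <- generate_srm_experiment(synth_spec(seed = 13, noise_sigma = 0.4))
  rows <- parse_report(exp$report_csv)
  doc <- build_document(rows)
  emitted <- list()
  for (fl in doc$feature_lists)
    for (r in names(fl$quant_layers[[1]]$rows))
      emitted[[r]] <- fl$quant_layers[[1]]$rows[[r]]
  expect_length(emitted, nrow(rows))
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  want <- lapply(seq_len(nrow(rows)), function(i)
    zero_na(c(rows$area[i], rows$background[i], rows$height[i], rows$fwhm[i])))
  got <- lapply(emitted, unname)
  expect_setequal(
    vapply(want, paste, character(1), collapse = "|"),
    vapply(got, paste, character(1), collapse = "|"))
})

test_that("absent areas become 0 and keep the matrix rectangular", {
  csv <- tiny_report_csv()
  lines <- strsplit(csv, "\n")[[1]]
  lines[2] <- sub("14.2,100", "14.2,", lines[2], fixed = TRUE)
  doc <- build_document(parse_report(paste0(paste(lines, collapse = "\n"), "\n")))
  ql <- doc$feature_lists[[1]]$quant_layers[[1]]
  expect_true(all(vapply(ql$rows, length, integer(1)) == 4))
  expect_equal(ql$rows[["ft_1"]][1], 0)
})

test_that("duplicate transition rows are rejected as ambiguous features", {
  csv <- tiny_report_csv()
  lines <- strsplit(csv, "\n")[[1]]
  dup <- paste0(paste(c(lines, lines[2]), collapse = "\n"), "\n")
  expect_error(build_document(parse_report(dup)), "ambiguous feature")
})

test_that("converter output always validates clean", {
  for (seed in 21:24) {
    doc <- if (seed %% 2) labeled_doc(seed = seed, sigma = 0.2)
           else labelfree_doc(seed = seed, sigma = 0.2)
    expect_length(error_findings(validate_document(doc)), 0)
  }
})

test_that("row order permutation changes no aggregated value", {
  exp <- generate_srm_experiment(synth_spec(seed = 31, noise_sigma = 0.3))
  rows <- parse_report(exp$report_csv)
  set.seed(1)
  shuffled <- rows[sample(nrow(rows)), , drop = FALSE]
  da <- build_document(rows)
  db <- build_document(shuffled)
  # ids depend on discovery order; align assays by name, peptides by key
  an <- vapply(da$assays, `[[`, character(1), "name")
  bn <- vapply(db$assays, `[[`, character(1), "name")
  bkey <- vapply(db$peptides, function(p) paste(p$sequence, p$charge),
                 character(1))
  la <- da$peptide_quant_layers[[1]]
  lb <- db$peptide_quant_layers[[1]]
  for (pa in da$peptides) {
    pb <- db$peptides[[match(paste(pa$sequence, pa$charge), bkey)]]
    expect_equal(la$rows[[pa$id]], lb$rows[[pb$id]][match(an, bn)])
  }
})

test_that("modified sequences split into sequence plus canonical descriptor", {
  doc <- build_document(parse_report(
    sub("ELVISK", "C[+57.0]PEPR", tiny_report_csv(), fixed = TRUE)))
  expect_equal(doc$peptides[[1]]$sequence, "CPEPR")
  expect_equal(doc$peptides[[1]]$modifications, "1:+57.0")
})
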