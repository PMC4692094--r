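test_that("cv_param enforces its invariants", {
  expect_error(cv_param(""), "non-empty")
  expect_error(cv_param("charge state", accession = "notanaccession"),
               "PREFIX:digits")
  p <- cv_term("charge state", value = 2)
  expect_equal(p$accession, "MS:1000041")
  expect_identical(p$value, "2")
  # accession-less terms are legal and match by exact name
  q <- cv_param("fragment ion", value = "y7")
  expect_null(q$accession)
})

test_that("new_document carries the technique terms implied by its mode", {
  lf <- new_document("LABEL_FREE")
  nm <- vapply(lf$analysis_summary$technique_terms, `[[`, character(1), "name")
  expect_true("SRM quantitation analysis" %in% nm)
  expect_true("LC-MS label-free quantitation analysis" %in% nm)
  expect_length(lf$ratio_definitions, 0)

  lb <- new_document("MS1_LABEL_BASED")
  nm <- vapply(lb$analysis_summary$technique_terms, `[[`, character(1), "name")
  expect_true("MS1 label-based analysis" %in% nm)
})

test_that("transition_feature requires the three product descriptors once each", {
  pp <- list(cv_term("isolation window target m/z", value = "624.31"),
             cv_term("local retention time", value = "14.2"),
             cv_term("charge state", value = "1"))
  ft <- transition_feature("ft_1", 523.77, 2, pp)
  expect_null(ft$precursor_rt)

  expect_error(transition_feature("ft_2", 523.77, 2, pp[-1]),
               "isolation window target m/z")
  expect_error(transition_feature("ft_3", 523.77, 2, c(pp, pp[3])),
               "charge state")
  expect_error(transition_feature("ft_4", -1, 2, pp), "precursor_mz")
  expect_error(transition_feature("ft_5", 523.77, 0, pp), "precursor_charge")
  bad <- pp
  bad[[1]] <- cv_term("isolation window target m/z", value = "-5")
  expect_error(transition_feature("ft_6", 523.77, 2, bad), "m/z must be > 0")
})

test_that("feature_quant_layer rejects ragged rows and bad column indices", {
  cols <- list(quant_column(0, cv_term("XIC area")),
               quant_column(1, cv_term("XIC background")))
  expect_error(
    feature_quant_layer("fql_1", cols, list(ft_1 = c(1, 2, 3))),
    "3 values but the layer defines 2 columns")
  expect_error(
    feature_quant_layer("fql_1", rev(cols), list(ft_1 = c(1, 2))),
    "consecutive from 0")
  ok <- feature_quant_layer("fql_1", cols, list(ft_1 = c(1, 2)))
  expect_length(ok$rows$ft_1, 2)
})

test_that("peptide_consensus checks its sequence alphabet", {
  expect_error(peptide_consensus("pep_1", "pept1de", charge = 2), "uppercase")
  expect_silent(peptide_consensus("pep_1", "ELVISK", charge = 2))
})

test_that("mod_descriptor is canonical under input order", {
  expect_identical(mod_descriptor(), "")
  a <- mod_descriptor(c(7, 2), c("Oxidation", "Carbamidomethyl"))
  b <- mod_descriptor(c(2, 7), c("Carbamidomethyl", "Oxidation"))
  expect_identical(a, b)
  expect_identical(a, "2:Carbamidomethyl;7:Oxidation")
})

test_that("ratio_definition rejects identical numerator and denominator", {
  expect_error(ratio_definition("r1", "assay_1", "assay_1"), "distinct")
})

test_that("reference graph of pipeline-built documents is closed", {
  for (doc in list(labeled_doc(seed = 3), labelfree_doc(seed = 4))) {
    expect_length(resolve_references(doc), 0)
    # independent graph walk: every evidence feature id occurs in a list
    all_ids <- unlist(lapply(doc$feature_lists, function(fl)
      vapply(fl$features, `[[`, character(1), "id")))
    ev_ids <- unlist(lapply(doc$peptides, function(p)
      lapply(p$evidence, `[[`, "feature_refs")))
    expect_true(all(ev_ids %in% all_ids))
    expect_false(anyDuplicated(all_ids) > 0)
  }
})

test_that("resolve_references flags seeded dangling references", {
  doc <- labelfree_doc(seed = 5)
  broken <- mutate_rule(doc, "R6")  # drop a feature still in evidence
  f <- resolve_references(broken)
  expect_length(f, 1)
  expect_equal(f[[1]]$severity, "ERROR")
  expect_match(f[[1]]$message, "unknown feature")

  doc2 <- doc
  gone <- doc2$assays[[1]]$id
  doc2$assays <- doc2$assays[-1]
  f2 <- resolve_references(doc2)
  expect_gte(length(f2), 1)
  expect_true(any(grepl(gone, vapply(f2, `[[`, character(1), "message"))))
  expect_true(any(grepl("AssayQuantLayer",
                        vapply(f2, `[[`, character(1), "element_path"))))
})

test_that("a feature claimed by two peptide consensus objects is flagged", {
  doc <- labelfree_doc(seed = 6)
  fr <- doc$peptides[[1]]$evidence[[1]]$feature_refs[1]
  doc$peptides[[2]]$evidence[[1]]$feature_refs <-
    c(doc$peptides[[2]]$evidence[[1]]$feature_refs, fr)
  f <- resolve_references(doc)
  expect_true(any(grepl("already referenced",
                        vapply(f, `[[`, character(1), "message"))))
})
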