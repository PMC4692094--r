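# one peptide, areas 100/200/300 in each assay (tiny_report_csv)

test_that("peptide aggregation implements SUM, MEAN and WEIGHTED_MEAN", {
  doc <- build_document(parse_report(tiny_report_csv()))
  sum_l <- aggregate_peptides(doc, aggregation_spec("SUM"))
  expect_equal(unname(sum_l$rows[["pep_1"]]), c(600, 600))
  expect_equal(sum_l$datatype$name, "summed XIC area")

  mean_l <- aggregate_peptides(doc, aggregation_spec("MEAN"))
  expect_equal(unname(mean_l$rows[["pep_1"]]), c(200, 200))

  # hand-computed oracle: sum(w*x)/sum(w) with w = x = {100,200,300}
  wm <- (100^2 + 200^2 + 300^2) / (100 + 200 + 300)
  wm_l <- aggregate_peptides(doc, aggregation_spec("WEIGHTED_MEAN"))
  expect_equal(unname(wm_l$rows[["pep_1"]]), rep(wm, 2), tolerance = 1e-6)
})

test_that("a single transition aggregates to itself under any method", {
  doc <- build_document(parse_report(
    generate_srm_experiment(synth_spec(
      n_proteins = 1, peptides_per_protein = 1, transitions_per_peptide = 1,
      n_replicates = 1, labeled = FALSE, noise_sigma = 0, base_area = 777,
      seed = 2))$report_csv))
  for (m in c("SUM", "MEAN", "WEIGHTED_MEAN"))
    expect_equal(unname(aggregate_peptides(
      doc, aggregation_spec(m))$rows[[1]]), 777)
})

test_that("peptides without features in an assay quantify as 0", {
  # drop the r2 rows of the peptide -> its r2 cell must be 0
  csv <- tiny_report_csv()
  lines <- strsplit(csv, "\n")[[1]]
  one_rep <- grepl("^r2,|,r2,", lines)
  extra <- sub("ELVISK", "MKLNPK", lines[c(5:7)], fixed = TRUE)
  doc <- build_document(parse_report(
    paste0(paste(c(lines, extra), collapse = "\n"), "\n")))
  layer <- doc$peptide_quant_layers[[1]]
  # MKLNPK only measured in r2: its r1 cell is 0
  pep2 <- doc$peptides[[2]]
  expect_equal(pep2$sequence, "MKLNPK")
  expect_equal(unname(layer$rows[[pep2$id]]), c(0, 600))
})

test_that("all-zero weights yield 0 with a recorded warning", {
  csv <- tiny_report_csv(areas = c(0, 0, 0))
  doc0 <- build_document(parse_report(csv),
                         spec = aggregation_spec("SUM"))
  wl <- aggregate_peptides(doc0, aggregation_spec("WEIGHTED_MEAN"))
  expect_equal(unname(wl$rows[["pep_1"]]), c(0, 0))
  expect_gte(length(wl$warnings), 1)
  expect_match(wl$warnings[1], "weights zero")
})

test_that("light/heavy ratios divide peptide-layer values per replicate", {
  csv <- tiny_report_csv(c("light", "heavy"))
  # make heavy areas half the light ones -> ratio 2
  lines <- strsplit(csv, "\n")[[1]]
  heavy <- grepl(",heavy,", lines)
  for (i in which(heavy))
    lines[i] <- sub(",(100|200|300),",
                    paste0(",", as.numeric(sub(".*,(100|200|300),.*", "\\1",
                                               lines[i])) / 2, ","), lines[i])
  doc <- build_document(parse_report(paste0(paste(lines, collapse = "\n"), "\n")))
  rql <- doc$ratio_quant_layer
  expect_equal(unname(rql$rows[["pep_1"]]), c(2, 2))
  # definitions: numerator is the light assay of the replicate
  for (rd in doc$ratio_definitions) {
    num <- Filter(function(a) a$id == rd$numerator_ref, doc$assays)[[1]]
    den <- Filter(function(a) a$id == rd$denominator_ref, doc$assays)[[1]]
    expect_equal(num$label, "LIGHT")
    expect_equal(den$label, "HEAVY")
    expect_equal(num$raw_file_ref, den$raw_file_ref)
  }
})

test_that("zero light gives ratio 0; zero heavy gives NaN with a warning", {
  doc <- build_document(parse_report(tiny_report_csv(c("light", "heavy"))))
  layer <- doc$peptide_quant_layers[[1]]
  lights <- which(vapply(doc$assays, `[[`, character(1), "label")[
    match(layer$assay_refs, vapply(doc$assays, `[[`, character(1), "id"))]
    == "LIGHT")
  z <- layer
  z$rows[["pep_1"]][lights] <- 0
  r <- compute_peptide_ratios(doc, z)
  expect_equal(unname(r$layer$rows[["pep_1"]]), c(0, 0))

  z2 <- layer
  z2$rows[["pep_1"]][-lights] <- 0
  r2 <- compute_peptide_ratios(doc, z2)
  expect_true(all(is.nan(r2$layer$rows[["pep_1"]])))
  expect_match(r2$layer$warnings[1], "NaN")
})

test_that("ratio computation refuses label-free documents", {
  doc <- build_document(parse_report(tiny_report_csv()))
  expect_error(compute_peptide_ratios(doc, doc$peptide_quant_layers[[1]]),
               "label-free")
})

test_that("flip reverses orientation of definitions and values", {
  doc <- labeled_doc(seed = 41)
  layer <- doc$peptide_quant_layers[[1]]
  fwd <- compute_peptide_ratios(doc, layer)
  rev <- compute_peptide_ratios(doc, layer, flip = TRUE)
  for (p in names(fwd$layer$rows))
    expect_equal(rev$layer$rows[[p]], 1 / fwd$layer$rows[[p]],
                 tolerance = 1e-6)
})

test_that("noise-free labeled data recovers the true ratio exactly", {
  exp <- generate_srm_experiment(synth_spec(noise_sigma = 0, true_ratio = 2.5,
                                            seed = 42))
  doc <- build_document(parse_report(exp$report_csv))
  for (v in doc$ratio_quant_layer$rows)
    expect_equal(unname(v), rep(2.5, length(v)), tolerance = 1e-6)
})

test_that("median ratio under log-normal noise stays within 3*sigma/sqrt(n)", {
  sigma <- 0.2; ntrans <- 5; r <- 2
  meds <- vapply(1:8, function(s) {
    doc <- labeled_doc(seed = 300 + s, sigma = sigma,
                       transitions_per_peptide = ntrans)
    median(unlist(doc$ratio_quant_layer$rows))
  }, numeric(1))
  expect_true(all(abs(meds - r) <= 3 * sigma / sqrt(ntrans)))
})

test_that("protein aggregation follows its method and the peptide mapping", {
  doc <- labelfree_doc(seed = 51, sigma = 0.3)
  pl <- doc$peptide_quant_layers[[1]]
  prot_sum <- aggregate_proteins(doc, pl, aggregation_spec())
  # brute-force oracle: column-wise sums over the protein's peptides
  for (pr in doc$proteins) {
    m <- do.call(rbind, pl$rows[pr$peptide_refs])
    expect_equal(unname(prot_sum$rows[[pr$id]]), unname(colSums(m)))
  }
  prot_mean <- aggregate_proteins(doc, pl, aggregation_spec(
    protein_method = "MEAN"))
  for (pr in doc$proteins) {
    m <- do.call(rbind, pl$rows[pr$peptide_refs])
    expect_equal(unname(prot_mean$rows[[pr$id]]), unname(colMeans(m)))
  }
})

test_that("single-peptide proteins inherit that peptide's values", {
  doc <- build_document(parse_report(tiny_report_csv()))
  prot <- aggregate_proteins(doc, doc$peptide_quant_layers[[1]],
                             aggregation_spec(protein_method = "MEAN"))
  expect_equal(prot$rows[["prot_1"]],
               doc$peptide_quant_layers[[1]]$rows[["pep_1"]])
})

test_that("proteins with no quantified peptides are excluded with a warning", {
  doc <- build_document(parse_report(tiny_report_csv()))
  doc$proteins[[2]] <- list(id = "prot_2", accession = "PROT_B",
                            peptide_refs = character())
  prot <- aggregate_proteins(doc, doc$peptide_quant_layers[[1]])
  expect_false("prot_2" %in% names(prot$rows))
  expect_match(prot$warnings[1], "no quantified peptides")
})

test_that("SUM conserves total signal from features through proteins", {
  doc <- labelfree_doc(seed = 61, sigma = 0.25)
  pl <- aggregate_peptides(doc, aggregation_spec("SUM"))
  prl <- aggregate_proteins(doc, pl, aggregation_spec("SUM"))
  pep_tot <- Reduce(`+`, pl$rows)
  prot_tot <- Reduce(`+`, prl$rows)
  expect_equal(prot_tot, pep_tot, tolerance = 1e-9)
  # per assay, the peptide totals equal total XIC area in that assay
  aid <- pl$assay_refs
  area_tot <- setNames(numeric(length(aid)), aid)
  for (p in doc$peptides)
    for (ev in p$evidence) {
      for (fl in doc$feature_lists)
        for (fr in intersect(ev$feature_refs,
                             names(fl$quant_layers[[1]]$rows)))
          area_tot[ev$assay_ref] <- area_tot[ev$assay_ref] +
            fl$quant_layers[[1]]$rows[[fr]][1]
    }
  expect_equal(unname(pep_tot), unname(area_tot[aid]), tolerance = 1e-6)
})
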