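# Shared fixtures: everything is generated in code at test time.

# A small labeled document built through the full import pipeline.
labeled_doc <- function(seed = 1, sigma = 0, ...) {
  exp <- generate_srm_experiment(synth_spec(labeled = TRUE,
                                            noise_sigma = sigma,
                                            seed = seed, ...))
  build_document(parse_report(exp$report_csv))
}

labelfree_doc <- function(seed = 1, sigma = 0, ...) {
  exp <- generate_srm_experiment(synth_spec(labeled = FALSE,
                                            noise_sigma = sigma,
                                            seed = seed, ...))
  build_document(parse_report(exp$report_csv))
}

# Hand-written tiny report CSV: 2 replicates x 1 peptide x 3 transitions.
tiny_report_csv <- function(labels = "light",
                            areas = c(100, 200, 300)) {
  hdr <- paste("ProteinName,PeptideModifiedSequence,PrecursorMz,PrecursorCharge",
               "ProductMz,ProductCharge,FragmentIon,IsotopeLabelType",
               "ReplicateName,FileName,RetentionTime,Area,Background,Height,Fwhm",
               sep = ",")
  rows <- character()
  for (rep in c("r1", "r2"))
    for (lab in labels)
      for (t in 1:3)
        rows <- c(rows, paste(
          "PROT_A", "ELVISK", "523.77", "2",
          300 + 100 * t, "1", paste0("y", 3 + t), lab,
          rep, paste0(rep, ".raw"), "14.2", areas[t], "1", "10", "0.1",
          sep = ","))
  paste0(paste(c(hdr, rows), collapse = "\n"), "\n")
}

find_term_idx <- function(terms, name) {
  for (i in seq_along(terms)) if (terms[[i]]$name == name) return(i)
  stop("term not found: ", name)
}

drop_product_param <- function(doc, term) {
  pp <- doc$feature_lists[[1]]$features[[1]]$product_params
  keep <- vapply(pp, function(p) p$name != term, logical(1))
  doc$feature_lists[[1]]$features[[1]]$product_params <- pp[keep]
  doc
}

# Single-rule mutations of a valid document; each is designed to trip
# exactly the named rule (reference-destroying ones may co-fire R6).
mutate_rule <- function(doc, rule) {
  switch(rule,
    R1 = {
      i <- find_term_idx(doc$analysis_summary$technique_terms,
                         "SRM quantitation analysis")
      doc$analysis_summary$technique_terms <-
        doc$analysis_summary$technique_terms[-i]
      doc
    },
    R2 = {
      terms <- doc$analysis_summary$technique_terms
      mode_names <- c("LC-MS label-free quantitation analysis",
                      "MS1 label-based analysis")
      keep <- vapply(terms, function(p) !p$name %in% mode_names, logical(1))
      doc$analysis_summary$technique_terms <- terms[keep]
      doc
    },
    R3 = drop_product_param(doc, "isolation window target m/z"),
    R4 = drop_product_param(doc, "local retention time"),
    R5 = {
      ql <- doc$feature_lists[[1]]$quant_layers[[1]]
      r1 <- names(ql$rows)[1]
      doc$feature_lists[[1]]$quant_layers[[1]]$rows[[r1]] <-
        c(ql$rows[[r1]], 99)
      doc
    },
    R6 = {
      # delete a feature and its matrix row; only peptide evidence dangles
      ft <- doc$feature_lists[[1]]$features[[1]]
      doc$feature_lists[[1]]$features <-
        doc$feature_lists[[1]]$features[-1]
      doc$feature_lists[[1]]$quant_layers[[1]]$rows[[ft$id]] <- NULL
      doc
    },
    R7 = {
      stopifnot(doc$analysis_summary$label_mode == "LABEL_FREE")
      aids <- vapply(doc$assays, `[[`, character(1), "id")
      doc$ratio_definitions <- list(ratio_definition("ratio_x",
                                                     aids[1], aids[2]))
      doc
    },
    R8 = {
      stopifnot(length(doc$ratio_definitions) > 0)
      doc$ratio_definitions[[1]]$denominator_ref <-
        doc$ratio_definitions[[1]]$numerator_ref
      doc
    },
    stop("unknown rule ", rule))
}

error_findings <- function(findings)
  Filter(function(f) f$severity == "ERROR", findings)

finding_rules <- function(findings)
  vapply(findings, `[[`, character(1), "rule_id")
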