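#' The SRM semantic rule registry
#'
#' A closed registry of ten rules: the SRM-specific controlled-vocabulary
#' rules (technique terms, required product descriptors, the label-mode /
#' ratio contract) plus the general structural rules SRM inherits (matrix
#' shape and reference closure). R1-R8 are ERRORs: a file failing any of
#' them is not a valid SRM mzQuantML file. R9-R10 are advisory WARNINGs.
#'
#' @return A named list of rules; each rule has `rule_id`, `severity`,
#'   `description`, and a `check(doc)` function returning findings.
#' @export
srm_rules <- function() .srm_rule_registry

# helper: iterate every feature with its path
each_feature <- function(doc, fn) {
  out <- list()
  for (fl in doc$feature_lists)
    for (ft in fl$features) {
      f <- fn(ft, paste0("FeatureList/", fl$id, "/Feature/", ft$id))
      if (!is.null(f)) out <- c(out, f)
    }
  out
}

.rule <- function(rule_id, severity, description, check)
  list(rule_id = rule_id, severity = severity, description = description,
       check = check)

.srm_rule_registry <- list(
  R1 = .rule("R1", "ERROR",
    "AnalysisSummary is present and carries 'SRM quantitation analysis'",
    function(doc) {
      terms <- doc$analysis_summary$technique_terms
      if (is.null(doc$analysis_summary) ||
          is.null(cv_find(terms, "SRM quantitation analysis")))
        list(srm_finding("R1", "ERROR", "AnalysisSummary",
          "missing 'SRM quantitation analysis' technique term"))
    }),
  R2 = .rule("R2", "ERROR",
    "AnalysisSummary carries exactly one of the two label-mode terms",
    function(doc) {
      terms <- doc$analysis_summary$technique_terms
      n <- (!is.null(cv_find(terms, "LC-MS label-free quantitation analysis"))) +
           (!is.null(cv_find(terms, "MS1 label-based analysis")))
      if (n != 1L)
        list(srm_finding("R2", "ERROR", "AnalysisSummary",
          paste0("expected exactly one label-mode term, found ", n)))
    }),
  R3 = .rule("R3", "ERROR",
    "every Feature carries 'isolation window target m/z'",
    function(doc) each_feature(doc, function(ft, path) {
      if (cv_count(ft$product_params, "isolation window target m/z") == 0L)
        list(srm_finding("R3", "ERROR", path,
          paste0("feature '", ft$id,
                 "' lacks 'isolation window target m/z'")))
    })),
  R4 = .rule("R4", "ERROR",
    "every Feature carries 'local retention time' and 'charge state'",
    function(doc) each_feature(doc, function(ft, path) {
      out <- list()
      for (term in c("local retention time", "charge state"))
        if (cv_count(ft$product_params, term) == 0L)
          out <- c(out, list(srm_finding("R4", "ERROR", path,
            paste0("feature '", ft$id, "' lacks '", term, "'"))))
      out
    })),
  R5 = .rule("R5", "ERROR",
    "every FeatureQuantLayer row length equals its column count",
    function(doc) {
      out <- list()
      for (fl in doc$feature_lists)
        for (ql in fl$quant_layers) {
          nc <- length(ql$columns)
          for (r in names(ql$rows))
            if (length(ql$rows[[r]]) != nc)
              out <- c(out, list(srm_finding("R5", "ERROR",
                paste0("FeatureList/", fl$id, "/FeatureQuantLayer/", ql$id),
                paste0("row '", r, "' has ", length(ql$rows[[r]]),
                       " values for ", nc, " columns"))))
        }
      out
    }),
  R6 = .rule("R6", "ERROR",
    "all cross-references resolve (no dangling ids)",
    function(doc) resolve_references(doc)),
  R7 = .rule("R7", "ERROR",
    "label-free documents contain no RatioList or RatioQuantLayer",
    function(doc) {
      if (!identical(doc$analysis_summary$label_mode, "LABEL_FREE"))
        return(NULL)
      out <- list()
      if (length(doc$ratio_definitions))
        out <- c(out, list(srm_finding("R7", "ERROR", "RatioList",
          "label-free document carries a RatioList")))
      if (!is.null(doc$ratio_quant_layer))
        out <- c(out, list(srm_finding("R7", "ERROR",
          "PeptideConsensusList/RatioQuantLayer",
          "label-free document carries a RatioQuantLayer")))
      out
    }),
  R8 = .rule("R8", "ERROR",
    "each Ratio's numerator and denominator are distinct same-kind references",
    function(doc) {
      out <- list()
      for (rd in doc$ratio_definitions)
        if (identical(rd$numerator_ref, rd$denominator_ref))
          out <- c(out, list(srm_finding("R8", "ERROR",
            paste0("RatioList/", rd$id),
            paste0("ratio '", rd$id,
                   "' has identical numerator and denominator '",
                   rd$numerator_ref, "'"))))
      out
    }),
  R9 = .rule("R9", "WARNING",
    "a peptide AssayQuantLayer is present when features exist",
    function(doc) {
      n_feat <- sum(vapply(doc$feature_lists,
                           function(fl) length(fl$features), integer(1)))
      if (n_feat > 0 && !length(doc$peptide_quant_layers))
        list(srm_finding("R9", "WARNING", "PeptideConsensusList",
          "features present but no peptide-level AssayQuantLayer"))
    }),
  R10 = .rule("R10", "WARNING",
    "peptides quantified nonzero in an assay reference a feature in it",
    function(doc) {
      out <- list()
      for (ql in doc$peptide_quant_layers)
        for (r in names(ql$rows)) {
          pep <- NULL
          for (p in doc$peptides) if (p$id == r) pep <- p
          if (is.null(pep)) next  # dangling row: R6 territory
          ev_assays <- vapply(pep$evidence, `[[`, character(1), "assay_ref")
          hot <- which(ql$rows[[r]] != 0)
          for (j in hot)
            if (!ql$assay_refs[j] %in% ev_assays)
              out <- c(out, list(srm_finding("R10", "WARNING",
                paste0("PeptideConsensusList/", r),
                paste0("peptide '", r, "' quantified nonzero in assay '",
                       ql$assay_refs[j], "' without feature evidence"))))
        }
      out
    })
)

#' Classify a document's technique and label mode
#'
#' Mirrors how the validator decides what rule set applies: a document is
#' an SRM file iff its analysis summary carries the SRM technique term,
#' and its label mode comes from whichever of the two mode terms is
#' present (`"UNKNOWN"` when neither is).
#'
#' @param doc An `srm_document`.
#' @return A list with `is_srm` (logical) and `label_mode` (`"LABEL_FREE"`,
#'   `"MS1_LABEL_BASED"` or `"UNKNOWN"`).
#' @export
classify <- function(doc) {
  terms <- doc$analysis_summary$technique_terms
  mode <-
    if (!is.null(cv_find(terms, "MS1 label-based analysis"))) "MS1_LABEL_BASED"
    else if (!is.null(cv_find(terms, "LC-MS label-free quantitation analysis"))) "LABEL_FREE"
    else "UNKNOWN"
  list(is_srm = !is.null(cv_find(terms, "SRM quantitation analysis")),
       label_mode = mode)
}

#' Validate an SRM document against the semantic rule registry
#'
#' Applies rules R1-R10 of [srm_rules()] in order and returns all findings,
#' in rule order then document order. An empty list means the document is
#' a valid SRM mzQuantML file; ERROR findings mean it is not, WARNING
#' findings are advisory. Structural parse problems (malformed XML, ragged
#' matrices) are reported by [read_mzq()] instead.
#'
#' @param doc An `srm_document`.
#' @return List of [srm_finding()]s.
#' @export
#' @examples
#' doc <- new_document("LABEL_FREE")
#' validate_document(doc)  # empty: an empty document is valid
validate_document <- function(doc) {
  stopifnot(inherits(doc, "srm_document"))
  out <- list()
  for (rule in .srm_rule_registry) {
    f <- rule$check(doc)
    if (length(f)) out <- c(out, f)
  }
  out
}

#' Render findings as a tab-separated report
#'
#' @param findings List of [srm_finding()]s.
#' @return A character vector, one line per finding (with a header), of
#'   `rule_id`, `severity`, `element_path`, `message`.
#' @export
findings_report <- function(findings) {
  c("rule_id\tseverity\telement_path\tmessage",
    vapply(findings, format, character(1)))
}

n_errors <- function(findings)
  sum(vapply(findings, function(f) f$severity == "ERROR", logical(1)))
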