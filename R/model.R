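#' Construct a controlled-vocabulary parameter
#'
#' A `cv_param` is an annotation attached to an mzQuantML element: a term
#' name, usually with a PSI-MS accession, and optionally a value and a unit.
#'
#' @param name Term name; must be a non-empty string.
#' @param accession Optional accession of the form `PREFIX:digits`
#'   (e.g. `"MS:1000827"`).
#' @param value Optional value string (numbers are passed as strings).
#' @param unit_name Optional unit name.
#' @return An object of class `cv_param`.
#' @export
#' @examples
#' cv_param("isolation window target m/z", "MS:1000827", value = "624.31")
cv_param <- function(name, accession = NULL, value = NULL, unit_name = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("cv_param: 'name' must be a non-empty string", call. = FALSE)
  if (!is.null(accession)) {
    if (!is.character(accession) || length(accession) != 1L ||
        !grepl("^[A-Za-z]+:[0-9]+$", accession))
      stop("cv_param: accession must match PREFIX:digits, got ",
           deparse(accession), call. = FALSE)
  }
  if (!is.null(value)) value <- as.character(value)
  structure(list(name = name, accession = accession, value = value,
                 unit_name = unit_name),
            class = "cv_param")
}

#' @export
format.cv_param <- function(x, ...) {
  s <- if (is.null(x$accession)) x$name else sprintf("[%s] %s", x$accession, x$name)
  if (!is.null(x$value)) s <- paste0(s, " = ", x$value)
  if (!is.null(x$unit_name)) s <- paste0(s, " ", x$unit_name)
  s
}

#' @export
print.cv_param <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# ---------------------------------------------------------------------------

.label_modes <- c("LABEL_FREE", "MS1_LABEL_BASED")
.mode_term <- c(LABEL_FREE = "LC-MS label-free quantitation analysis",
                MS1_LABEL_BASED = "MS1 label-based analysis")

#' Construct an AnalysisSummary
#'
#' The analysis summary declares the quantitation technique of the file.
#' For the SRM dialect it must carry the term \dQuote{SRM quantitation
#' analysis} plus exactly one of the two label-mode terms, consistent with
#' `label_mode`.
#'
#' @param label_mode `"LABEL_FREE"` or `"MS1_LABEL_BASED"`.
#' @param technique_terms List of [cv_param()]s; defaults to the two terms
#'   implied by `label_mode`.
#' @return An object of class `analysis_summary`.
#' @export
analysis_summary <- function(label_mode,
                             technique_terms = list(
                               cv_term("SRM quantitation analysis"),
                               cv_term(.mode_term[[label_mode]]))) {
  label_mode <- match.arg(label_mode, .label_modes)
  if (is.null(cv_find(technique_terms, "SRM quantitation analysis")))
    stop("analysis_summary: missing 'SRM quantitation analysis' term",
         call. = FALSE)
  if (is.null(cv_find(technique_terms, .mode_term[[label_mode]])))
    stop("analysis_summary: technique terms inconsistent with label_mode ",
         label_mode, call. = FALSE)
  structure(list(technique_terms = technique_terms, label_mode = label_mode),
            class = "analysis_summary")
}

#' Construct a transition feature
#'
#' One quantified SRM transition in one run. Precursor (MS1) properties are
#' carried as attributes (`rt`, `mz`, `charge`); the product (MS2) side is
#' carried as CV parameters, of which \dQuote{isolation window target m/z},
#' \dQuote{local retention time} and \dQuote{charge state} are mandatory and
#' must each occur exactly once.
#'
#' @param id Feature identifier.
#' @param precursor_mz Precursor m/z in Th; must be positive.
#' @param precursor_charge Precursor charge; integer >= 1.
#' @param product_params List of [cv_param()]s describing the product ion.
#' @param precursor_rt Optional precursor retention time in minutes. An
#'   absent value is serialized as the literal `"null"`; it is never a
#'   sentinel number.
#' @return An object of class `transition_feature`.
#' @export
transition_feature <- function(id, precursor_mz, precursor_charge,
                               product_params, precursor_rt = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(precursor_mz) || precursor_mz <= 0)
    stop("transition_feature ", id, ": precursor_mz must be > 0", call. = FALSE)
  precursor_charge <- as.integer(precursor_charge)
  if (is.na(precursor_charge) || precursor_charge < 1L)
    stop("transition_feature ", id, ": precursor_charge must be >= 1",
         call. = FALSE)
  for (req in c("isolation window target m/z", "local retention time",
                "charge state")) {
    n <- cv_count(product_params, req)
    if (n != 1L)
      stop("transition_feature ", id, ": product_params must carry exactly ",
           "one '", req, "' (found ", n, ")", call. = FALSE)
  }
  tmz <- as.numeric(cv_find(product_params, "isolation window target m/z")$value)
  if (!is.finite(tmz) || tmz <= 0)
    stop("transition_feature ", id, ": product target m/z must be > 0",
         call. = FALSE)
  pz <- as.integer(cv_find(product_params, "charge state")$value)
  if (is.na(pz) || pz < 1L)
    stop("transition_feature ", id, ": product charge must be >= 1",
         call. = FALSE)
  if (!is.null(precursor_rt)) precursor_rt <- canon_num(precursor_rt)
  structure(list(id = id, precursor_rt = precursor_rt,
                 precursor_mz = canon_num(precursor_mz),
                 precursor_charge = precursor_charge,
                 product_params = product_params),
            class = "transition_feature")
}

#' Construct a quant-layer column definition
#'
#' @param column_index 0-based column position.
#' @param datatype [cv_param()] naming the measurement type.
#' @return An object of class `quant_column`.
#' @export
quant_column <- function(column_index, datatype) {
  stopifnot(inherits(datatype, "cv_param"))
  column_index <- as.integer(column_index)
  stopifnot(!is.na(column_index), column_index >= 0L)
  structure(list(column_index = column_index, datatype = datatype),
            class = "quant_column")
}

#' Construct a FeatureQuantLayer
#'
#' A matrix of per-feature measurements. Unlike assay- or ratio-level
#' layers, a feature layer may define several column data types (e.g. XIC
#' area, background, height, peak width). Every row must have exactly as
#' many values as there are columns; this matrix-shape rule is enforced at
#' construction time.
#'
#' @param id Layer identifier.
#' @param columns List of [quant_column()]s with consecutive indices from 0.
#' @param rows Named list: feature id -> numeric vector of values.
#' @return An object of class `feature_quant_layer`.
#' @export
feature_quant_layer <- function(id, columns, rows) {
  stopifnot(is.character(id), length(id) == 1L)
  idx <- vapply(columns, function(c) c$column_index, integer(1))
  if (!identical(idx, seq_along(columns) - 1L))
    stop("feature_quant_layer ", id,
         ": column indices must be consecutive from 0", call. = FALSE)
  if (length(rows) && (is.null(names(rows)) || any(!nzchar(names(rows)))))
    stop("feature_quant_layer ", id, ": rows must be named by feature id",
         call. = FALSE)
  nc <- length(columns)
  for (fr in names(rows)) {
    v <- rows[[fr]]
    if (!is.numeric(v) || length(v) != nc)
      stop("feature_quant_layer ", id, ": row '", fr, "' has ", length(v),
           " values but the layer defines ", nc, " columns", call. = FALSE)
    rows[[fr]] <- canon_num(v)
  }
  structure(list(id = id, columns = columns, rows = rows),
            class = "feature_quant_layer")
}

#' Construct an Assay
#'
#' One measured sample channel. In labeled SRM, the light and heavy
#' channels of a replicate are distinct assays referencing the same
#' raw-files group.
#'
#' @param id Assay identifier.
#' @param name Display name.
#' @param raw_file_ref Id of the raw-files group the assay was acquired in.
#' @param label `"LIGHT"` or `"HEAVY"`.
#' @param label_param Optional [cv_param()] describing the label chemistry;
#'   a default is chosen from `label`.
#' @return An object of class `srm_assay`.
#' @export
srm_assay <- function(id, name, raw_file_ref, label = c("LIGHT", "HEAVY"),
                      label_param = NULL) {
  label <- match.arg(label)
  if (is.null(label_param))
    label_param <- if (label == "LIGHT") cv_term("unlabeled sample")
                   else cv_param("isotope labeled sample")
  structure(list(id = id, name = name, raw_file_ref = raw_file_ref,
                 label = label, label_param = label_param),
            class = "srm_assay")
}

#' Construct a PeptideConsensus
#'
#' The peptide-level object: a modified peptide sequence at one precursor
#' charge, with evidence references to every transition feature that
#' contributed to its quantification, keyed by assay and isotope label.
#' One consensus spans both isotope channels of a labeled experiment.
#'
#' @param id Identifier.
#' @param sequence Uppercase amino-acid sequence.
#' @param modifications Canonical modification descriptor string (empty for
#'   unmodified peptides); see [mod_descriptor()].
#' @param charge Precursor charge; integer >= 1.
#' @param evidence List of entries `list(assay_ref=, label=, feature_refs=)`.
#' @return An object of class `peptide_consensus`.
#' @export
peptide_consensus <- function(id, sequence, modifications = "", charge,
                              evidence = list()) {
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence))
    stop("peptide_consensus ", id,
         ": sequence must be uppercase amino acids, got '", sequence, "'",
         call. = FALSE)
  charge <- as.integer(charge)
  stopifnot(!is.na(charge), charge >= 1L)
  structure(list(id = id, sequence = sequence, modifications = modifications,
                 charge = charge, evidence = evidence),
            class = "peptide_consensus")
}

#' Canonical modification descriptor
#'
#' Two report rows denote the same peptide consensus iff their plain
#' sequence, this descriptor, and the precursor charge agree. The
#' descriptor is the sorted list of `[position,name]` pairs rendered as
#' `pos1:name1;pos2:name2`, so it is insensitive to input order.
#'
#' @param positions Integer vector of modified residue positions.
#' @param names Character vector of modification names, parallel to
#'   `positions`.
#' @return A single string; `""` when there are no modifications.
#' @export
mod_descriptor <- function(positions = integer(), names = character()) {
  stopifnot(length(positions) == length(names))
  if (!length(positions)) return("")
  o <- order(positions, names)
  paste(sprintf("%d:%s", as.integer(positions[o]), names[o]), collapse = ";")
}

#' Construct an AssayQuantLayer
#'
#' A single-datatype matrix of peptide- or protein-level values, one column
#' per assay in declared assay order.
#'
#' @param id Identifier.
#' @param datatype [cv_param()]; exactly one datatype per layer.
#' @param object_level `"PEPTIDE"` or `"PROTEIN"`.
#' @param assay_refs Character vector of assay ids (the column order).
#' @param rows Named list: object id -> numeric vector, one value per assay.
#' @param warnings Optional character vector of warnings attached during
#'   aggregation.
#' @return An object of class `assay_quant_layer`.
#' @export
assay_quant_layer <- function(id, datatype, object_level = c("PEPTIDE", "PROTEIN"),
                              assay_refs, rows, warnings = character()) {
  object_level <- match.arg(object_level)
  stopifnot(inherits(datatype, "cv_param"), is.character(assay_refs))
  na <- length(assay_refs)
  for (r in names(rows)) {
    if (!is.numeric(rows[[r]]) || length(rows[[r]]) != na)
      stop("assay_quant_layer ", id, ": row '", r, "' has ",
           length(rows[[r]]), " values but the layer references ", na,
           " assays", call. = FALSE)
    rows[[r]] <- canon_num(rows[[r]])
  }
  structure(list(id = id, datatype = datatype, object_level = object_level,
                 assay_refs = assay_refs, rows = rows, warnings = warnings),
            class = "assay_quant_layer")
}

#' Construct a RatioDefinition
#'
#' @param id Identifier.
#' @param numerator_ref,denominator_ref Distinct references of the same
#'   kind (both assays, or both study variables).
#' @param ref_kind `"assay"` or `"study_variable"`.
#' @return An object of class `ratio_definition`.
#' @export
ratio_definition <- function(id, numerator_ref, denominator_ref,
                             ref_kind = "assay") {
  if (identical(numerator_ref, denominator_ref))
    stop("ratio_definition ", id,
         ": numerator and denominator must be distinct", call. = FALSE)
  structure(list(id = id, numerator_ref = numerator_ref,
                 denominator_ref = denominator_ref, ref_kind = ref_kind),
            class = "ratio_definition")
}

#' Construct a RatioQuantLayer
#'
#' Peptide-level ratio matrix: one column per ratio definition.
#'
#' @param id Identifier.
#' @param datatype [cv_param()] describing the ratio values.
#' @param ratio_refs Character vector of ratio-definition ids.
#' @param rows Named list: peptide id -> numeric vector (one value per
#'   ratio; `NaN` marks an undefined ratio).
#' @param warnings Optional character vector.
#' @return An object of class `ratio_quant_layer`.
#' @export
ratio_quant_layer <- function(id, datatype, ratio_refs, rows,
                              warnings = character()) {
  nr <- length(ratio_refs)
  for (r in names(rows)) {
    if (length(rows[[r]]) != nr)
      stop("ratio_quant_layer ", id, ": row '", r, "' has ",
           length(rows[[r]]), " values for ", nr, " ratios", call. = FALSE)
    rows[[r]] <- canon_num(rows[[r]])
  }
  structure(list(id = id, datatype = datatype, ratio_refs = ratio_refs,
                 rows = rows, warnings = warnings),
            class = "ratio_quant_layer")
}

#' Construct a validator finding
#'
#' @param rule_id Rule identifier (`"R1"` ... `"R10"`).
#' @param severity `"ERROR"` or `"WARNING"`.
#' @param element_path Slash-separated path with element ids.
#' @param message Human-readable description.
#' @return An object of class `srm_finding`.
#' @export
srm_finding <- function(rule_id, severity = c("ERROR", "WARNING"),
                        element_path, message) {
  severity <- match.arg(severity)
  structure(list(rule_id = rule_id, severity = severity,
                 element_path = element_path, message = message),
            class = "srm_finding")
}

#' @export
format.srm_finding <- function(x, ...) {
  sprintf("%s\t%s\t%s\t%s", x$rule_id, x$severity, x$element_path, x$message)
}

#' @export
print.srm_finding <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# ---------------------------------------------------------------------------

#' Create an empty SRM mzQuantML document
#'
#' Returns a document whose analysis summary carries the SRM technique term
#' plus the mode term implied by `label_mode`, with all lists empty. A
#' label-free document never carries ratio definitions or a ratio layer.
#'
#' @param label_mode `"LABEL_FREE"` or `"MS1_LABEL_BASED"`.
#' @return An object of class `srm_document`.
#' @export
#' @examples
#' doc <- new_document("LABEL_FREE")
#' length(doc$ratio_definitions)  # 0
new_document <- function(label_mode = c("LABEL_FREE", "MS1_LABEL_BASED")) {
  label_mode <- match.arg(label_mode)
  structure(list(
    analysis_summary = analysis_summary(label_mode),
    raw_file_groups = list(),   # each: list(id, raw_files = list(list(id, location)))
    software = list(),          # each: list(id, name, version, params)
    data_processing = list(),   # each: list(order, software_ref, method_params)
    assays = list(),
    ratio_definitions = list(),
    proteins = list(),          # each: list(id, accession, peptide_refs)
    protein_quant_layers = list(),
    peptides = list(),
    peptide_quant_layers = list(),
    ratio_quant_layer = NULL,
    feature_lists = list(),     # each: list(id, raw_file_group_ref, features, quant_layers)
    extras = list()
  ), class = "srm_document")
}

# Gather all transition features of a document into one named list.
doc_features <- function(doc) {
  out <- list()
  for (fl in doc$feature_lists)
    for (ft in fl$features) {
      if (!is.null(out[[ft$id]]))
        stop("duplicate feature id '", ft$id, "' in document", call. = FALSE)
      out[[ft$id]] <- ft
    }
  out
}

doc_assay_ids <- function(doc) vapply(doc$assays, `[[`, character(1), "id")

#' Check the reference graph of a document
#'
#' Walks every cross-reference in the document (assay to raw-files group,
#' quant-layer row to feature, peptide evidence to feature and assay,
#' protein to peptide, ratio definition to assay, ratio layer to ratio
#' definition) and returns one ERROR finding per dangling reference. An
#' empty list means the reference graph is closed. A feature referenced by
#' more than one peptide consensus is also reported.
#'
#' @param doc An `srm_document`.
#' @return List of [srm_finding()]s (possibly empty).
#' @export
resolve_references <- function(doc) {
  stopifnot(inherits(doc, "srm_document"))
  findings <- list()
  bad <- function(path, msg)
    findings[[length(findings) + 1L]] <<-
      srm_finding("R6", "ERROR", path, msg)

  group_ids <- vapply(doc$raw_file_groups, `[[`, character(1), "id")
  assay_ids <- doc_assay_ids(doc)
  feats <- tryCatch(doc_features(doc), error = function(e) NULL)
  if (is.null(feats)) {
    bad("FeatureList", "duplicate feature id")
    feat_ids <- character()
  } else feat_ids <- names(feats)
  pep_ids <- vapply(doc$peptides, `[[`, character(1), "id")
  ratio_ids <- vapply(doc$ratio_definitions, `[[`, character(1), "id")

  for (a in doc$assays)
    if (!a$raw_file_ref %in% group_ids)
      bad(paste0("AssayList/", a$id),
          paste0("assay '", a$id, "' references unknown raw-files group '",
                 a$raw_file_ref, "'"))

  for (fl in doc$feature_lists) {
    if (!fl$raw_file_group_ref %in% group_ids)
      bad(paste0("FeatureList/", fl$id),
          paste0("feature list '", fl$id,
                 "' references unknown raw-files group '",
                 fl$raw_file_group_ref, "'"))
    local_ids <- vapply(fl$features, `[[`, character(1), "id")
    for (ql in fl$quant_layers)
      for (fr in names(ql$rows))
        if (!fr %in% local_ids)
          bad(paste0("FeatureList/", fl$id, "/FeatureQuantLayer/", ql$id),
              paste0("row references unknown feature '", fr, "'"))
  }

  seen_feature_owner <- character()
  for (p in doc$peptides) {
    for (ev in p$evidence) {
      if (!ev$assay_ref %in% assay_ids)
        bad(paste0("PeptideConsensusList/", p$id),
            paste0("evidence references unknown assay '", ev$assay_ref, "'"))
      for (fr in ev$feature_refs) {
        if (!fr %in% feat_ids)
          bad(paste0("PeptideConsensusList/", p$id),
              paste0("evidence references unknown feature '", fr, "'"))
        else if (!is.na(seen_feature_owner[fr]) &&
                 nzchar(seen_feature_owner[fr]) &&
                 seen_feature_owner[fr] != p$id)
          bad(paste0("PeptideConsensusList/", p$id),
              paste0("feature '", fr, "' already referenced by peptide '",
                     seen_feature_owner[fr], "'"))
        else seen_feature_owner[fr] <- p$id
      }
    }
  }

  check_aql <- function(ql, context, object_ids, object_what) {
    for (ar in ql$assay_refs)
      if (!ar %in% assay_ids)
        bad(paste0(context, "/AssayQuantLayer/", ql$id),
            paste0("layer '", ql$id, "' references unknown assay '", ar, "'"))
    for (r in names(ql$rows))
      if (!r %in% object_ids)
        bad(paste0(context, "/AssayQuantLayer/", ql$id),
            paste0("row references unknown ", object_what, " '", r, "'"))
  }
  for (ql in doc$peptide_quant_layers)
    check_aql(ql, "PeptideConsensusList", pep_ids, "peptide")
  for (ql in doc$protein_quant_layers)
    check_aql(ql, "ProteinList",
              vapply(doc$proteins, `[[`, character(1), "id"), "protein")

  for (pr in doc$proteins)
    for (pref in pr$peptide_refs)
      if (!pref %in% pep_ids)
        bad(paste0("ProteinList/", pr$id),
            paste0("protein '", pr$id, "' references unknown peptide '",
                   pref, "'"))

  for (rd in doc$ratio_definitions)
    for (ref in c(rd$numerator_ref, rd$denominator_ref))
      if (!ref %in% assay_ids)
        bad(paste0("RatioList/", rd$id),
            paste0("ratio '", rd$id, "' references unknown assay '", ref, "'"))

  if (!is.null(doc$ratio_quant_layer)) {
    rql <- doc$ratio_quant_layer
    for (rr in rql$ratio_refs)
      if (!rr %in% ratio_ids)
        bad(paste0("PeptideConsensusList/RatioQuantLayer/", rql$id),
            paste0("layer references unknown ratio '", rr, "'"))
    for (r in names(rql$rows))
      if (!r %in% pep_ids)
        bad(paste0("PeptideConsensusList/RatioQuantLayer/", rql$id),
            paste0("row references unknown peptide '", r, "'"))
  }

  for (dp in doc$data_processing)
    if (!is.null(dp$software_ref) &&
        !dp$software_ref %in% vapply(doc$software, `[[`, character(1), "id"))
      bad(paste0("DataProcessingList/order=", dp$order),
          paste0("processing step references unknown software '",
                 dp$software_ref, "'"))

  findings
}

#' @export
print.srm_document <- function(x, ...) {
  feats <- tryCatch(length(doc_features(x)), error = function(e) NA_integer_)
  cat("SRM mzQuantML document\n")
  cat("  label mode:      ", x$analysis_summary$label_mode, "\n", sep = "")
  cat("  raw-file groups: ", length(x$raw_file_groups), "\n", sep = "")
  cat("  assays:          ", length(x$assays), "\n", sep = "")
  cat("  features:        ", feats, "\n", sep = "")
  cat("  peptides:        ", length(x$peptides), "\n", sep = "")
  cat("  proteins:        ", length(x$proteins), "\n", sep = "")
  cat("  ratio defs:      ", length(x$ratio_definitions), "\n", sep = "")
  invisible(x)
}
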