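#' Aggregation settings for peptide- and protein-level quantification
#'
#' SRM software derives a peptide-level value by combining the quantified
#' transitions of that peptide — a sum, mean or weighted mean — and may in
#' turn aggregate peptide values to the protein level. The default is the
#' plain sum of XIC areas at both levels.
#'
#' @param peptide_method `"SUM"`, `"MEAN"` or `"WEIGHTED_MEAN"`.
#' @param protein_method `"SUM"` or `"MEAN"`.
#' @param weight_column CV term name of the feature column used as weights;
#'   only meaningful (and only allowed) with `WEIGHTED_MEAN`.
#' @return An object of class `aggregation_spec`.
#' @export
aggregation_spec <- function(peptide_method = c("SUM", "MEAN", "WEIGHTED_MEAN"),
                             protein_method = c("SUM", "MEAN"),
                             weight_column = NULL) {
  peptide_method <- match.arg(peptide_method)
  protein_method <- match.arg(protein_method)
  if (peptide_method == "WEIGHTED_MEAN") {
    if (is.null(weight_column)) weight_column <- "XIC area"
  } else if (!is.null(weight_column)) {
    stop("aggregation_spec: weight_column is only used with WEIGHTED_MEAN",
         call. = FALSE)
  }
  structure(list(peptide_method = peptide_method,
                 protein_method = protein_method,
                 weight_column = weight_column),
            class = "aggregation_spec")
}

# Per-feature value lookup for one CV-termed column across all feature
# quant layers of the document. Returns a named numeric vector.
feature_column_values <- function(doc, term = "XIC area") {
  out <- numeric()
  for (fl in doc$feature_lists)
    for (ql in fl$quant_layers) {
      ci <- NA_integer_
      for (col in ql$columns)
        if (cv_same_term(col$datatype, term)) ci <- col$column_index + 1L
      if (is.na(ci)) next
      for (fr in names(ql$rows)) out[[fr]] <- ql$rows[[fr]][ci]
    }
  out
}

apply_method <- function(method, x, w = NULL) {
  if (!length(x)) return(0)
  switch(method,
    SUM = sum(x),
    MEAN = mean(x),
    WEIGHTED_MEAN = if (sum(w) == 0) 0 else sum(w * x) / sum(w))
}

.method_datatype <- function(method)
  cv_param(name = switch(method,
    SUM = "summed XIC area",
    MEAN = "mean XIC area",
    WEIGHTED_MEAN = "weighted mean XIC area"))

#' Aggregate transition features to a peptide-level quant layer
#'
#' For each peptide consensus and each assay, combines the XIC-area cells
#' of the features the peptide claims as evidence in that assay (and that
#' assay's isotope label), using the method in `spec`. A peptide with no
#' feature in an assay gets value 0, keeping the matrix rectangular. The
#' layer's datatype term records the method used.
#'
#' @param doc An `srm_document` with feature quant layers carrying an
#'   \dQuote{XIC area} column.
#' @param spec An [aggregation_spec()]; the default sums XIC areas.
#' @return An `assay_quant_layer` at PEPTIDE level, with columns in the
#'   document's assay order. `WEIGHTED_MEAN` cells whose weights are all
#'   zero get value 0 and a warning recorded in the layer's `warnings`.
#' @export
#' @examples
#' exp <- generate_srm_experiment(synth_spec(seed = 1))
#' doc <- build_document(parse_report(exp$report_csv))
#' aggregate_peptides(doc)$rows[[1]]
aggregate_peptides <- function(doc, spec = aggregation_spec()) {
  stopifnot(inherits(doc, "srm_document"), inherits(spec, "aggregation_spec"))
  areas <- feature_column_values(doc, "XIC area")
  if (!length(areas))
    stop("aggregate_peptides: document has no 'XIC area' feature column",
         call. = FALSE)
  weights <- if (spec$peptide_method == "WEIGHTED_MEAN")
    feature_column_values(doc, spec$weight_column) else NULL
  assay_ids <- doc_assay_ids(doc)
  warns <- character()
  rows <- list()
  for (p in doc$peptides) {
    v <- numeric(length(assay_ids))
    for (j in seq_along(assay_ids)) {
      frs <- character()
      for (ev in p$evidence)
        if (ev$assay_ref == assay_ids[j]) frs <- c(frs, ev$feature_refs)
      x <- unname(areas[frs])
      w <- if (is.null(weights)) NULL else unname(weights[frs])
      if (spec$peptide_method == "WEIGHTED_MEAN" && length(x) && sum(w) == 0)
        warns <- c(warns, paste0("peptide '", p$id, "' assay '", assay_ids[j],
                                 "': all weights zero; value set to 0"))
      v[j] <- apply_method(spec$peptide_method, x, w)
    }
    rows[[p$id]] <- v
  }
  assay_quant_layer("pep_aql_1", .method_datatype(spec$peptide_method),
                    "PEPTIDE", assay_ids, rows, warnings = warns)
}

#' Compute light/heavy peptide ratios for a labeled experiment
#'
#' For each replicate (raw-files group) with a light and a heavy assay, one
#' ratio is defined with the light assay as numerator and the heavy assay
#' as denominator, and evaluated per peptide on the values of the supplied
#' peptide-level layer. A zero heavy value yields `NaN` with a warning; a
#' zero light value over a nonzero heavy value is a plain 0.
#'
#' @param doc A labeled (`MS1_LABEL_BASED`) `srm_document`.
#' @param layer Peptide-level `assay_quant_layer`, e.g. from
#'   [aggregate_peptides()].
#' @param flip Divide heavy by light instead (numerator and denominator
#'   swapped in the definitions too).
#' @return A list with `definitions` (list of [ratio_definition()]) and
#'   `layer` (a `ratio_quant_layer`).
#' @export
compute_peptide_ratios <- function(doc, layer, flip = FALSE) {
  stopifnot(inherits(doc, "srm_document"), inherits(layer, "assay_quant_layer"))
  if (doc$analysis_summary$label_mode != "MS1_LABEL_BASED")
    stop("compute_peptide_ratios: label-free files carry no RatioList",
         call. = FALSE)
  # pair light/heavy assays through their shared raw-files group
  groups <- vapply(doc$raw_file_groups, `[[`, character(1), "id")
  defs <- list(); num_ids <- character(); den_ids <- character()
  for (g in groups) {
    light <- heavy <- NULL
    for (a in doc$assays)
      if (a$raw_file_ref == g) {
        if (a$label == "LIGHT") light <- a$id else heavy <- a$id
      }
    if (is.null(light) || is.null(heavy))
      stop("compute_peptide_ratios: replicate group '", g,
           "' lacks a light/heavy assay pair", call. = FALSE)
    if (flip) { tmp <- light; light <- heavy; heavy <- tmp }
    defs[[length(defs) + 1L]] <-
      ratio_definition(paste0("ratio_", length(defs) + 1L), light, heavy)
    num_ids <- c(num_ids, light); den_ids <- c(den_ids, heavy)
  }
  ni <- match(num_ids, layer$assay_refs)
  di <- match(den_ids, layer$assay_refs)
  warns <- character()
  rows <- list()
  for (r in names(layer$rows)) {
    num <- layer$rows[[r]][ni]
    den <- layer$rows[[r]][di]
    v <- ifelse(den == 0, NaN, num / den)
    if (any(den == 0))
      warns <- c(warns, paste0("peptide '", r,
                               "': zero denominator; ratio recorded as NaN"))
    rows[[r]] <- v
  }
  rql <- ratio_quant_layer("pep_rql_1",
    cv_param(if (flip) "heavy/light peptide ratio"
             else "light/heavy peptide ratio"),
    vapply(defs, `[[`, character(1), "id"), rows, warnings = warns)
  list(definitions = defs, layer = rql)
}

#' Aggregate peptide values to a protein-level quant layer
#'
#' Applies the protein method of `spec` per protein per assay over the
#' values of its peptides in `peptide_layer`. Proteins are emitted in
#' first-appearance order of the document's protein list; a protein with
#' no resolvable peptide rows is excluded with a warning.
#'
#' @param doc An `srm_document` with a protein list mapping proteins to
#'   peptides.
#' @param peptide_layer Peptide-level `assay_quant_layer`.
#' @param spec An [aggregation_spec()].
#' @return An `assay_quant_layer` at PROTEIN level.
#' @export
aggregate_proteins <- function(doc, peptide_layer, spec = aggregation_spec()) {
  stopifnot(inherits(peptide_layer, "assay_quant_layer"))
  if (!length(doc$proteins))
    stop("aggregate_proteins: document has no protein list", call. = FALSE)
  warns <- character()
  rows <- list()
  for (pr in doc$proteins) {
    prefs <- intersect(pr$peptide_refs, names(peptide_layer$rows))
    if (!length(prefs)) {
      warns <- c(warns, paste0("protein '", pr$id,
                               "' has no quantified peptides; excluded"))
      next
    }
    m <- do.call(rbind, peptide_layer$rows[prefs])
    rows[[pr$id]] <- apply(m, 2L, function(col)
      apply_method(spec$protein_method, col))
  }
  assay_quant_layer("prot_aql_1", .method_datatype(spec$protein_method),
                    "PROTEIN", peptide_layer$assay_refs, rows,
                    warnings = warns)
}
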