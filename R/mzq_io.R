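#' Serialization options for mzQuantML output
#'
#' @param pretty_print Indent the XML output. The rendering is deterministic
#'   either way: the same document always yields the same bytes.
#' @param schema_location Optional path to the official mzQuantML XSD; when
#'   supplied, [write_mzq()] additionally validates its output against it.
#'   The package's own structural checks always run regardless.
#' @return An object of class `serialization_options`.
#' @export
serialization_options <- function(pretty_print = TRUE, schema_location = NULL) {
  structure(list(pretty_print = isTRUE(pretty_print),
                 schema_location = schema_location),
            class = "serialization_options")
}

.mzq_ns <- "http://psidev.info/psi/pi/mzQuantML/1.0.0"

# Fixed decimal rendering: '.' separator, up to 6 fractional digits, no
# exponent for |x| in [1e-4, 1e7). NaN marks an undefined value (e.g. a
# ratio with zero denominator) and survives the round trip. Model
# constructors store values canonicalized onto this grid (canon_num), so
# serialization is lossless and round-trip comparison needs no tolerance.
fmt_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.nan(v)) return("NaN")
    if (is.na(v)) return("NaN")
    if (!is.finite(v)) return(if (v > 0) "INF" else "-INF")
    if (v == 0) return("0")
    av <- abs(v)
    if (av >= 1e-4 && av < 1e7) {
      s <- formatC(v, format = "f", digits = 6, mode = "double")
      s <- sub("0+$", "", s)
      sub("\\.$", "", s)
    } else {
      # rare outside the fixed-point window; exponent form, C locale
      formatC(v, format = "e", digits = 6)
    }
  }, character(1))
}

# Project numbers onto the serialization grid (<= 6 fractional digits in
# the fixed-point window); fixed point of the write/parse cycle.
canon_num <- function(x) parse_num(fmt_num(x))

parse_num <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == "NaN"] <- NaN
  out[s == "INF"] <- Inf
  out[s == "-INF"] <- -Inf
  if (anyNA(out) && any(is.na(out) & s != "NaN"))
    stop("unparseable numeric value '", s[which(is.na(out) & s != "NaN")[1]],
         "'", call. = FALSE)
  out
}

# --- writing ----------------------------------------------------------------

add_param <- function(parent, p) {
  if (is.null(p$accession)) {
    n <- xml2::xml_add_child(parent, "userParam", name = p$name)
  } else {
    n <- xml2::xml_add_child(parent, "cvParam", cvRef = "PSI-MS",
                             accession = p$accession, name = p$name)
  }
  if (!is.null(p$value)) xml2::xml_set_attr(n, "value", p$value)
  if (!is.null(p$unit_name)) xml2::xml_set_attr(n, "unitName", p$unit_name)
  invisible(n)
}

add_assay_quant_layer <- function(parent, ql, tag = "AssayQuantLayer") {
  node <- xml2::xml_add_child(parent, tag, id = ql$id)
  dt <- xml2::xml_add_child(node, "DataType")
  add_param(dt, ql$datatype)
  refs <- if (tag == "RatioQuantLayer") ql$ratio_refs else ql$assay_refs
  xml2::xml_add_child(node, "ColumnIndex", paste(refs, collapse = " "))
  dm <- xml2::xml_add_child(node, "DataMatrix")
  for (r in names(ql$rows))
    xml2::xml_add_child(dm, "Row", paste(fmt_num(ql$rows[[r]]), collapse = " "),
                        object_ref = r)
  invisible(node)
}

#' Serialize an SRM document to mzQuantML XML
#'
#' Emits elements in schema order (CvList, AnalysisSummary, InputFiles,
#' SoftwareList, DataProcessingList, AssayList, RatioList when present,
#' ProteinList, PeptideConsensusList, FeatureList). Feature elements carry
#' `rt`/`mz`/`charge` attributes for the precursor and CV parameters for
#' the product ion; an absent precursor retention time is written as the
#' literal attribute value `"null"`. Serialization is refused with a
#' diagnostic listing the dangling references when the document's reference
#' graph is not closed. Unknown elements retained by [read_mzq()] are
#' re-emitted after the AssayList.
#'
#' @param doc An `srm_document`.
#' @param options A [serialization_options()] object.
#' @return A UTF-8 string containing the XML document.
#' @seealso [read_mzq()], [write_mzq_file()]
#' @export
write_mzq <- function(doc, options = serialization_options()) {
  stopifnot(inherits(doc, "srm_document"))
  danglers <- resolve_references(doc)
  if (length(danglers))
    stop("write_mzq: unresolved references:\n",
         paste(vapply(danglers, function(f) f$message, character(1)),
               collapse = "\n"), call. = FALSE)

  root <- xml2::xml_new_root("MzQuantML", xmlns = .mzq_ns,
                             id = "mzq_doc", version = "1.0.1")

  cvl <- xml2::xml_add_child(root, "CvList")
  xml2::xml_add_child(cvl, "Cv", id = "PSI-MS",
    fullName = "PSI-MS controlled vocabulary",
    uri = "http://psidev.cvs.sourceforge.net/viewvc/psidev/psi/psi-ms/mzML/controlledVocabulary/psi-ms.obo")

  asum <- xml2::xml_add_child(root, "AnalysisSummary")
  for (p in doc$analysis_summary$technique_terms) add_param(asum, p)

  inf <- xml2::xml_add_child(root, "InputFiles")
  for (g in doc$raw_file_groups) {
    gn <- xml2::xml_add_child(inf, "RawFilesGroup", id = g$id)
    for (rf in g$raw_files)
      xml2::xml_add_child(gn, "RawFile", id = rf$id, location = rf$location)
  }

  if (length(doc$software)) {
    sl <- xml2::xml_add_child(root, "SoftwareList")
    for (sw in doc$software) {
      sn <- xml2::xml_add_child(sl, "Software", id = sw$id, version = sw$version)
      for (p in sw$params) add_param(sn, p)
    }
  }

  if (length(doc$data_processing)) {
    dpl <- xml2::xml_add_child(root, "DataProcessingList")
    for (i in seq_along(doc$data_processing)) {
      dp <- doc$data_processing[[i]]
      dn <- xml2::xml_add_child(dpl, "DataProcessing",
                                id = paste0("dp_", i),
                                order = as.character(dp$order))
      if (!is.null(dp$software_ref))
        xml2::xml_set_attr(dn, "software_ref", dp$software_ref)
      pm <- xml2::xml_add_child(dn, "ProcessingMethod", order = "1")
      for (p in dp$method_params) add_param(pm, p)
    }
  }

  al <- xml2::xml_add_child(root, "AssayList", id = "assay_list")
  for (a in doc$assays) {
    an <- xml2::xml_add_child(al, "Assay", id = a$id, name = a$name,
                              rawFilesGroup_ref = a$raw_file_ref)
    lb <- xml2::xml_add_child(an, "Label")
    md <- xml2::xml_add_child(lb, "Modification")
    add_param(md, a$label_param)
  }

  for (ex in doc$extras) {
    node <- xml2::read_xml(ex$xml)
    xml2::xml_add_child(root, node)
  }

  if (length(doc$ratio_definitions)) {
    rl <- xml2::xml_add_child(root, "RatioList")
    for (rd in doc$ratio_definitions)
      xml2::xml_add_child(rl, "Ratio", id = rd$id,
                          numerator_ref = rd$numerator_ref,
                          denominator_ref = rd$denominator_ref)
  }

  if (length(doc$proteins)) {
    pl <- xml2::xml_add_child(root, "ProteinList", id = "protein_list")
    for (pr in doc$proteins) {
      pn <- xml2::xml_add_child(pl, "Protein", id = pr$id,
                                accession = pr$accession)
      xml2::xml_add_child(pn, "PeptideConsensus_refs",
                          paste(pr$peptide_refs, collapse = " "))
    }
    for (ql in doc$protein_quant_layers) add_assay_quant_layer(pl, ql)
  }

  if (length(doc$peptides) || length(doc$peptide_quant_layers)) {
    pcl <- xml2::xml_add_child(root, "PeptideConsensusList",
                               id = "peptide_list", finalResult = "true")
    for (p in doc$peptides) {
      pn <- xml2::xml_add_child(pcl, "PeptideConsensus", id = p$id,
                                charge = as.character(p$charge))
      xml2::xml_add_child(pn, "PeptideSequence", p$sequence)
      if (nzchar(p$modifications))
        add_param(pn, cv_param("modification descriptor",
                               value = p$modifications))
      for (ev in p$evidence)
        for (fr in ev$feature_refs)
          xml2::xml_add_child(pn, "EvidenceRef", feature_ref = fr,
                              assay_refs = ev$assay_ref)
    }
    for (ql in doc$peptide_quant_layers) add_assay_quant_layer(pcl, ql)
    if (!is.null(doc$ratio_quant_layer))
      add_assay_quant_layer(pcl, doc$ratio_quant_layer, "RatioQuantLayer")
  }

  for (fl in doc$feature_lists) {
    fn <- xml2::xml_add_child(root, "FeatureList", id = fl$id,
                              rawFilesGroup_ref = fl$raw_file_group_ref)
    for (ft in fl$features) {
      rt <- if (is.null(ft$precursor_rt)) "null" else fmt_num(ft$precursor_rt)
      ftn <- xml2::xml_add_child(fn, "Feature", id = ft$id, rt = rt,
                                 mz = fmt_num(ft$precursor_mz),
                                 charge = as.character(ft$precursor_charge))
      for (p in ft$product_params) add_param(ftn, p)
    }
    for (ql in fl$quant_layers) {
      qn <- xml2::xml_add_child(fn, "FeatureQuantLayer", id = ql$id)
      cd <- xml2::xml_add_child(qn, "ColumnDefinition")
      for (col in ql$columns) {
        cn <- xml2::xml_add_child(cd, "Column",
                                  index = as.character(col$column_index))
        dt <- xml2::xml_add_child(cn, "DataType")
        add_param(dt, col$datatype)
      }
      dm <- xml2::xml_add_child(qn, "DataMatrix")
      for (r in names(ql$rows))
        xml2::xml_add_child(dm, "Row",
                            paste(fmt_num(ql$rows[[r]]), collapse = " "),
                            object_ref = r)
    }
  }

  xmldoc <- xml2::xml_root(root)
  if (!is.null(options$schema_location)) {
    schema <- xml2::read_xml(options$schema_location)
    ok <- xml2::xml_validate(xmldoc, schema)
    if (!ok)
      stop("write_mzq: output failed XSD validation: ",
           paste(attr(ok, "errors"), collapse = "; "), call. = FALSE)
  }
  fmt <- if (options$pretty_print) "format" else "as_xml"
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  xml2::write_xml(xmldoc, con, options = fmt)
  rawToChar(rawConnectionValue(con))
}

#' Write an SRM document to an mzQuantML file
#'
#' @inheritParams write_mzq
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzq_file <- function(doc, path, options = serialization_options()) {
  txt <- write_mzq(doc, options)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

# --- reading ----------------------------------------------------------------

node_params <- function(node) {
  out <- list()
  for (ch in xml2::xml_children(node)) {
    nm <- xml2::xml_name(ch)
    if (nm %in% c("cvParam", "userParam")) {
      at <- function(a) {
        v <- xml2::xml_attr(ch, a)
        if (is.na(v)) NULL else v
      }
      out[[length(out) + 1L]] <-
        cv_param(name = xml2::xml_attr(ch, "name"),
                 accession = if (nm == "cvParam") at("accession") else NULL,
                 value = at("value"), unit_name = at("unitName"))
    }
  }
  out
}

attr_or <- function(node, a, default = NULL) {
  v <- xml2::xml_attr(node, a)
  if (is.na(v)) default else v
}

read_data_matrix <- function(node, layer_id, ncol = NULL) {
  rows <- list()
  for (rn in xml2::xml_find_all(node, "./DataMatrix/Row")) {
    ref <- xml2::xml_attr(rn, "object_ref")
    vals <- parse_num(strsplit(trimws(xml2::xml_text(rn)), "\\s+")[[1]])
    if (!is.null(ncol) && length(vals) != ncol)
      stop("layer '", layer_id, "': row '", ref, "' has ", length(vals),
           " values but the layer defines ", ncol, " columns", call. = FALSE)
    rows[[ref]] <- vals
  }
  rows
}

read_assay_quant_layer <- function(node, object_level) {
  id <- xml2::xml_attr(node, "id")
  dtn <- xml2::xml_find_first(node, "./DataType")
  datatype <- node_params(dtn)[[1]]
  refs <- strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(node, "./ColumnIndex"))), "\\s+")[[1]]
  rows <- read_data_matrix(node, id, ncol = length(refs))
  if (xml2::xml_name(node) == "RatioQuantLayer")
    ratio_quant_layer(id, datatype, refs, rows)
  else
    assay_quant_layer(id, datatype, object_level, refs, rows)
}

#' Parse mzQuantML XML into an SRM document
#'
#' Inverse of [write_mzq()]: every id, attribute, CV parameter, matrix value
#' and reference present in the input is present in the result. Top-level
#' elements outside the SRM dialect (e.g. a StudyVariableList) are retained
#' verbatim in `doc$extras` so that [write_mzq()] can re-emit them.
#'
#' Malformed XML raises a parse error (with the line number reported by the
#' XML parser); a DataMatrix row whose length differs from its layer's
#' column count, or a missing AnalysisSummary, raises a structural error.
#' Semantic problems (wrong CV terms, dangling references) are not raised
#' here — they are the validator's job, see [validate_document()].
#'
#' @param xml A string of XML, a file path, or a raw vector.
#' @return An `srm_document`.
#' @export
read_mzq <- function(xml) {
  x <- xml2::read_xml(xml)
  xml2::xml_ns_strip(x)
  if (xml2::xml_name(x) != "MzQuantML")
    stop("read_mzq: root element is '", xml2::xml_name(x),
         "', expected 'MzQuantML'", call. = FALSE)

  asum_node <- xml2::xml_find_first(x, "./AnalysisSummary")
  if (inherits(asum_node, "xml_missing"))
    stop("read_mzq: missing AnalysisSummary (compulsory element)",
         call. = FALSE)
  terms <- node_params(asum_node)
  label_mode <-
    if (!is.null(cv_find(terms, "MS1 label-based analysis"))) "MS1_LABEL_BASED"
    else if (!is.null(cv_find(terms, "LC-MS label-free quantitation analysis"))) "LABEL_FREE"
    else "UNKNOWN"
  # lax construction: foreign files may violate the summary invariants,
  # which the validator reports as findings rather than an exception here
  doc <- new_document("LABEL_FREE")
  doc$analysis_summary <- structure(
    list(technique_terms = terms, label_mode = label_mode),
    class = "analysis_summary")

  for (gn in xml2::xml_find_all(x, "./InputFiles/RawFilesGroup")) {
    rfs <- lapply(xml2::xml_find_all(gn, "./RawFile"), function(rf)
      list(id = xml2::xml_attr(rf, "id"),
           location = xml2::xml_attr(rf, "location")))
    doc$raw_file_groups[[length(doc$raw_file_groups) + 1L]] <-
      list(id = xml2::xml_attr(gn, "id"), raw_files = rfs)
  }

  for (sn in xml2::xml_find_all(x, "./SoftwareList/Software"))
    doc$software[[length(doc$software) + 1L]] <-
      list(id = xml2::xml_attr(sn, "id"),
           version = attr_or(sn, "version", ""),
           params = node_params(sn))

  for (dn in xml2::xml_find_all(x, "./DataProcessingList/DataProcessing")) {
    pm <- xml2::xml_find_first(dn, "./ProcessingMethod")
    doc$data_processing[[length(doc$data_processing) + 1L]] <-
      list(order = as.integer(xml2::xml_attr(dn, "order")),
           software_ref = attr_or(dn, "software_ref"),
           method_params = if (inherits(pm, "xml_missing")) list()
                           else node_params(pm))
  }

  for (an in xml2::xml_find_all(x, "./AssayList/Assay")) {
    lp <- xml2::xml_find_first(an, "./Label/Modification")
    label_param <- if (inherits(lp, "xml_missing")) NULL
                   else node_params(lp)[[1]]
    label <- if (!is.null(label_param) &&
                 cv_same_term(label_param, "unlabeled sample")) "LIGHT"
             else if (!is.null(label_param)) "HEAVY" else "LIGHT"
    doc$assays[[length(doc$assays) + 1L]] <-
      srm_assay(xml2::xml_attr(an, "id"), attr_or(an, "name", ""),
                attr_or(an, "rawFilesGroup_ref", ""),
                label = label, label_param = label_param)
  }

  for (rn in xml2::xml_find_all(x, "./RatioList/Ratio"))
    doc$ratio_definitions[[length(doc$ratio_definitions) + 1L]] <-
      structure(list(id = xml2::xml_attr(rn, "id"),
                     numerator_ref = xml2::xml_attr(rn, "numerator_ref"),
                     denominator_ref = xml2::xml_attr(rn, "denominator_ref"),
                     ref_kind = "assay"),
                class = "ratio_definition")

  for (pn in xml2::xml_find_all(x, "./ProteinList/Protein")) {
    refs_txt <- xml2::xml_text(
      xml2::xml_find_first(pn, "./PeptideConsensus_refs"))
    refs <- if (is.na(refs_txt) || !nzchar(trimws(refs_txt))) character()
            else strsplit(trimws(refs_txt), "\\s+")[[1]]
    doc$proteins[[length(doc$proteins) + 1L]] <-
      list(id = xml2::xml_attr(pn, "id"),
           accession = attr_or(pn, "accession", ""),
           peptide_refs = refs)
  }
  for (qn in xml2::xml_find_all(x, "./ProteinList/AssayQuantLayer"))
    doc$protein_quant_layers[[length(doc$protein_quant_layers) + 1L]] <-
      read_assay_quant_layer(qn, "PROTEIN")

  for (pn in xml2::xml_find_all(x, "./PeptideConsensusList/PeptideConsensus")) {
    seqs <- xml2::xml_text(xml2::xml_find_first(pn, "./PeptideSequence"))
    mods <- ""
    for (p in node_params(pn))
      if (identical(p$name, "modification descriptor")) mods <- p$value
    # evidence grouped by assay; label comes from the assay declaration
    ev <- list()
    for (en in xml2::xml_find_all(pn, "./EvidenceRef")) {
      aref <- xml2::xml_attr(en, "assay_refs")
      fref <- xml2::xml_attr(en, "feature_ref")
      hit <- FALSE
      for (i in seq_along(ev))
        if (ev[[i]]$assay_ref == aref) {
          ev[[i]]$feature_refs <- c(ev[[i]]$feature_refs, fref)
          hit <- TRUE
          break
        }
      if (!hit) {
        lbl <- "LIGHT"
        for (a in doc$assays) if (a$id == aref) lbl <- a$label
        ev[[length(ev) + 1L]] <- list(assay_ref = aref, label = lbl,
                                      feature_refs = fref)
      }
    }
    doc$peptides[[length(doc$peptides) + 1L]] <-
      peptide_consensus(xml2::xml_attr(pn, "id"), seqs, mods,
                        as.integer(xml2::xml_attr(pn, "charge")), ev)
  }
  for (qn in xml2::xml_find_all(x, "./PeptideConsensusList/AssayQuantLayer"))
    doc$peptide_quant_layers[[length(doc$peptide_quant_layers) + 1L]] <-
      read_assay_quant_layer(qn, "PEPTIDE")
  rqn <- xml2::xml_find_first(x, "./PeptideConsensusList/RatioQuantLayer")
  if (!inherits(rqn, "xml_missing"))
    doc$ratio_quant_layer <- read_assay_quant_layer(rqn, "PEPTIDE")

  for (fn in xml2::xml_find_all(x, "./FeatureList")) {
    feats <- list()
    for (ftn in xml2::xml_find_all(fn, "./Feature")) {
      rt <- xml2::xml_attr(ftn, "rt")
      # lax construction: the CV-term invariants (exactly one target m/z,
      # local RT, charge state) are semantic rules R3/R4, reported by the
      # validator on parsed documents rather than enforced here
      feats[[length(feats) + 1L]] <- structure(list(
        id = xml2::xml_attr(ftn, "id"),
        precursor_rt = if (identical(rt, "null")) NULL else parse_num(rt),
        precursor_mz = parse_num(xml2::xml_attr(ftn, "mz")),
        precursor_charge = as.integer(xml2::xml_attr(ftn, "charge")),
        product_params = node_params(ftn)), class = "transition_feature")
    }
    qls <- list()
    for (qn in xml2::xml_find_all(fn, "./FeatureQuantLayer")) {
      qid <- xml2::xml_attr(qn, "id")
      cols <- lapply(xml2::xml_find_all(qn, "./ColumnDefinition/Column"),
        function(cn) quant_column(
          as.integer(xml2::xml_attr(cn, "index")),
          node_params(xml2::xml_find_first(cn, "./DataType"))[[1]]))
      rows <- read_data_matrix(qn, qid, ncol = length(cols))
      qls[[length(qls) + 1L]] <- feature_quant_layer(qid, cols, rows)
    }
    doc$feature_lists[[length(doc$feature_lists) + 1L]] <-
      list(id = xml2::xml_attr(fn, "id"),
           raw_file_group_ref = attr_or(fn, "rawFilesGroup_ref", ""),
           features = feats, quant_layers = qls)
  }

  known <- c("CvList", "AnalysisSummary", "InputFiles", "SoftwareList",
             "DataProcessingList", "AssayList", "RatioList", "ProteinList",
             "PeptideConsensusList", "FeatureList")
  for (ch in xml2::xml_children(x))
    if (!xml2::xml_name(ch) %in% known)
      doc$extras[[length(doc$extras) + 1L]] <-
        list(name = xml2::xml_name(ch), xml = as.character(ch))

  doc
}

# --- semantic comparison ----------------------------------------------------

#' Compare two SRM documents semantically
#'
#' Field-by-field equality over everything that carries meaning: summary
#' terms, ids, attributes, CV parameters, matrix values (NaN equals NaN)
#' and references. Lexical differences that do not change meaning (e.g.
#' whitespace in the source XML) are ignored by construction since both
#' sides are parsed documents.
#'
#' @param a,b `srm_document` objects.
#' @return `TRUE` or `FALSE`.
#' @export
mzq_semantic_equal <- function(a, b) {
  norm <- function(d) {
    d$extras <- lapply(d$extras, function(e) e["name"])
    # drop aggregation warnings: advisory, not document content
    d$peptide_quant_layers <- lapply(d$peptide_quant_layers,
      function(q) { q$warnings <- NULL; q })
    d$protein_quant_layers <- lapply(d$protein_quant_layers,
      function(q) { q$warnings <- NULL; q })
    if (!is.null(d$ratio_quant_layer)) d$ratio_quant_layer$warnings <- NULL
    d
  }
  isTRUE(all.equal(norm(a), norm(b), tolerance = 0))
}
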