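#' @keywords internal
#' @name cv-table
#' @title Internal controlled-vocabulary table
#'
#' The SRM dialect of mzQuantML uses a small, closed set of PSI-MS
#' controlled-vocabulary terms. This table maps the term names used by the
#' package to their accessions. Matching elsewhere (validator, quantifier)
#' is by accession first, falling back to exact name, so documents written
#' by other tools that use the same accessions are recognised even if their
#' spelling of the name differs.
NULL

.mzq_cv_table <- list(
  "SRM quantitation analysis"              = "MS:1001838",
  "LC-MS label-free quantitation analysis" = "MS:1001834",
  "MS1 label-based analysis"               = "MS:1002018",
  "local retention time"                   = "MS:1000895",
  "isolation window target m/z"            = "MS:1000827",
  "isolation window lower offset"          = "MS:1000828",
  "isolation window upper offset"          = "MS:1000829",
  "charge state"                           = "MS:1000041",
  "XIC area"                               = "MS:1001858",
  "XIC background"                         = "MS:1001859",
  "peak intensity"                         = "MS:1000042",
  "full width at half-maximum"             = "MS:1000086",
  "unlabeled sample"                       = "MS:1002038",
  "Skyline"                                = "MS:1000922"
)

#' Look up the accession of a dialect CV term
#'
#' @param name Exact term name.
#' @return The accession string, or `NULL` when the name is not in the
#'   dialect table (terms without a published accession are carried by
#'   name only).
#' @keywords internal
cv_accession <- function(name) {
  acc <- .mzq_cv_table[[name]]
  if (is.null(acc)) NULL else acc
}

#' Construct a CV parameter for a known dialect term
#'
#' Convenience wrapper around [cv_param()] that fills in the accession from
#' the internal dialect table.
#'
#' @param name Term name (must not be empty).
#' @param value Optional value string.
#' @param unit_name Optional unit name (e.g. `"minute"`).
#' @return A `cv_param` object.
#' @export
#' @examples
#' cv_term("charge state", value = "2")
cv_term <- function(name, value = NULL, unit_name = NULL) {
  cv_param(name = name, accession = cv_accession(name),
           value = value, unit_name = unit_name)
}

# TRUE when two cv_params denote the same term: accession match wins,
# exact-name match is the fallback for accession-less terms.
cv_same_term <- function(p, name) {
  acc <- cv_accession(name)
  if (!is.null(acc) && !is.null(p$accession)) return(identical(p$accession, acc))
  identical(p$name, name)
}

# Find the first param matching a dialect term name; NULL if absent.
cv_find <- function(params, name) {
  for (p in params) if (cv_same_term(p, name)) return(p)
  NULL
}

cv_count <- function(params, name) {
  sum(vapply(params, cv_same_term, logical(1), name = name))
}
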