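#' Sib-pair datasets
#'
#' A `sib_pair` bundles the germline variant tables of one affected patient
#' and their unaffected full sibling, plus (optionally) the patient's tumor
#' variant table. A cohort is a plain list of `sib_pair` objects with unique
#' `case_id`s.
#'
#' @param case_id case identifier (e.g. `"case1"`).
#' @param affected,unaffected germline variant tables ([variant_table]) of
#'   the affected and unaffected sib.
#' @param tumor tumor-tissue variant table of the affected patient, or `NULL`.
#' @return an object of class `sib_pair`.
#' @export
sib_pair <- function(case_id, affected, unaffected, tumor = NULL) {
  stopifnot(is.character(case_id), length(case_id) == 1)
  validate_variant_table(affected)
  validate_variant_table(unaffected)
  if (!is.null(tumor)) validate_variant_table(tumor)
  structure(
    list(case_id = case_id, affected = affected,
         unaffected = unaffected, tumor = tumor),
    class = "sib_pair"
  )
}

#' @export
print.sib_pair <- function(x, ...) {
  cat(sprintf(
    "<sib_pair %s>  affected: %d variants | unaffected: %d | tumor: %s\n",
    x$case_id, nrow(x$affected), nrow(x$unaffected),
    if (is.null(x$tumor)) "absent" else paste0(nrow(x$tumor), " variants")
  ))
  invisible(x)
}

validate_cohort <- function(cohort) {
  if (!is.list(cohort) || !all(vapply(cohort, inherits, logical(1), "sib_pair"))) {
    stop("cohort must be a list of sib_pair objects")
  }
  ids <- vapply(cohort, function(p) p$case_id, character(1))
  if (anyDuplicated(ids) > 0) stop("duplicate case_id in cohort")
  invisible(cohort)
}
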