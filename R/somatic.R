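#' Extract somatic variants by blood-vs-tumor subtraction
#'
#' A tumor variant is called somatic when its key is absent from the matched
#' blood (germline) table or explicitly homozygous-reference there. This is
#' table subtraction, not probabilistic calling: presence in tumor exome,
#' absence from blood.
#'
#' @param blood germline variant table of the patient.
#' @param tumor tumor-tissue variant table of the same patient.
#' @return the somatic subset of `tumor`.
#' @export
call_somatic <- function(blood, tumor) {
  id_b <- attr(blood, "case_id"); id_t <- attr(tumor, "case_id")
  if (!is.null(id_b) && !is.null(id_t) && !identical(id_b, id_t)) {
    stop("call_somatic: blood and tumor tables come from different cases (",
         id_b, " vs ", id_t, ")")
  }
  if (nrow(tumor) == 0) return(tumor)
  idx <- match(variant_key(tumor), variant_key(blood))
  absent <- is.na(idx)
  hom_ref_blood <- !absent & !is.na(blood$gt[idx]) & blood$gt[idx] == "hom_ref"
  tumor[absent | hom_ref_blood, , drop = FALSE]
}

#' Tally somatic variants by mutation class
#'
#' @param somatic a variant table of somatic calls.
#' @return a `somatic_tally`: list with `total`, `coding` (exonic
#'   consequences), `missense` (nonsynonymous SNVs), `frameshift_indel` and
#'   `nonsense` counts.
#' @export
tally_somatic <- function(somatic) {
  cons <- somatic$consequence
  coding <- !is.na(cons) & cons %in% EXONIC_CONSEQUENCES
  out <- list(
    total = nrow(somatic),
    coding = sum(coding),
    missense = sum(coding & cons == "nonsynonymous_snv"),
    frameshift_indel = sum(coding & cons == "frameshift_indel"),
    nonsense = sum(coding & cons == "nonsense")
  )
  structure(out, class = "somatic_tally")
}

#' @export
print.somatic_tally <- function(x, ...) {
  cat(sprintf(
    "<somatic_tally> total %d | coding %d (missense %d, frameshift indel %d, nonsense %d)\n",
    x$total, x$coding, x$missense, x$frameshift_indel, x$nonsense
  ))
  invisible(x)
}

#' Write a somatic tally as JSON
#'
#' @param tally a `somatic_tally` from [tally_somatic()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_somatic_tally <- function(tally, path) {
  jsonlite::write_json(unclass(tally), path, auto_unbox = TRUE)
  invisible(path)
}

#' Detect loss of heterozygosity at candidate loci
#'
#' A candidate locus shows LOH when it is heterozygous in the patient's blood
#' and homozygous for the alternate allele in tumor tissue. Tumor
#' homozygosity is satisfied by the recorded genotype state `hom_alt` or,
#' when allele depths are present, by a tumor alternate-allele fraction of at
#' least `min_hom_af` (default 0.8, tolerating some normal-cell
#' contamination). Candidates absent from the tumor table are reported with
#' tumor state `missing` and `is_loh = FALSE`.
#'
#' @param candidates germline (blood) candidate variant table with genotypes.
#' @param tumor tumor variant table of the same patient.
#' @param min_hom_af allele-fraction threshold for calling tumor
#'   homozygosity; must lie in (0.5, 1].
#' @return a tibble with columns `key`, `gene`, `blood_state`, `tumor_state`,
#'   `tumor_alt_fraction`, `is_loh`.
#' @export
detect_loh <- function(candidates, tumor, min_hom_af = 0.8) {
  if (min_hom_af <= 0.5 || min_hom_af > 1) {
    stop("min_hom_af must lie in (0.5, 1]")
  }
  if (nrow(candidates) == 0) {
    return(tibble::tibble(
      key = character(0), gene = character(0), blood_state = character(0),
      tumor_state = character(0), tumor_alt_fraction = numeric(0),
      is_loh = logical(0)
    ))
  }
  keys <- variant_key(candidates)
  idx <- match(keys, variant_key(tumor))
  tumor_state <- ifelse(is.na(idx), "missing", tumor$gt[idx])
  tumor_state[is.na(tumor_state)] <- "missing"
  af <- rep(NA_real_, length(keys))
  have <- !is.na(idx)
  af[have] <- allele_fraction(tumor[idx[have], , drop = FALSE])
  hom_tumor <- tumor_state == "hom_alt" | (!is.na(af) & af >= min_hom_af)
  blood_het <- !is.na(candidates$gt) & candidates$gt == "het"
  tibble::tibble(
    key = keys,
    gene = candidates$gene,
    blood_state = candidates$gt,
    tumor_state = tumor_state,
    tumor_alt_fraction = af,
    is_loh = blood_het & hom_tumor & !is.na(idx)
  )
}

#' Write LOH calls as TSV
#'
#' @param loh a tibble from [detect_loh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loh <- function(loh, path) {
  readr::write_tsv(loh, path)
  invisible(path)
}
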