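#' Prioritization cascade configuration
#'
#' Thresholds and inputs for the six-stage germline prioritization cascade:
#' coverage, exonic/rare, benign & in-house exclusion, deleteriousness,
#' sib discordance, cancer-gene panel.
#'
#' @param min_depth minimum total read depth (coverage stage), default 10.
#' @param max_maf maximum population minor allele frequency, default 0.01.
#' @param keep_absent_maf keep variants with unreported MAF, default `TRUE`
#'   ("rare or not reported").
#' @param cadd_min minimum CADD scaled score for the score-based
#'   deleteriousness path, default 20.
#' @param require_metasvm_d require a MetaSVM "D" call in addition to CADD on
#'   the score-based path, default `TRUE`.
#' @param deleterious_rule how scores and consequence combine:
#'   `"truncating_or_scores"` (default) retains truncating variants
#'   (frameshift indels, nonsense) unconditionally and requires the score
#'   rule for other exonic variants; `"cadd_and_svm"` requires the score rule
#'   for every variant; `"cadd_or_svm"` retains a variant passing either
#'   score. Synonymous variants are never retained.
#' @param direction `"affected_only"` (default) keeps variants private to the
#'   affected sib; `"unaffected_only"` is the symmetric protective screen.
#' @param inhouse_db character vector of variant keys (see [variant_key()])
#'   observed in an in-house database; excluded at the benign stage.
#' @param cancer_genes character vector of cancer-predisposition gene symbols
#'   (case-insensitive); required by the panel stage.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10, max_maf = 0.01, keep_absent_maf = TRUE,
                          cadd_min = 20, require_metasvm_d = TRUE,
                          deleterious_rule = c("truncating_or_scores",
                                               "cadd_and_svm", "cadd_or_svm"),
                          direction = c("affected_only", "unaffected_only"),
                          inhouse_db = character(0),
                          cancer_genes = character(0)) {
  deleterious_rule <- match.arg(deleterious_rule)
  direction <- match.arg(direction)
  if (max_maf < 0 || max_maf > 1) stop("max_maf must be in [0,1]")
  if (min_depth < 0) stop("min_depth must be >= 0")
  structure(
    list(
      min_depth = min_depth, max_maf = max_maf,
      keep_absent_maf = keep_absent_maf, cadd_min = cadd_min,
      require_metasvm_d = require_metasvm_d,
      deleterious_rule = deleterious_rule, direction = direction,
      inhouse_db = inhouse_db, cancer_genes = cancer_genes
    ),
    class = "filter_config"
  )
}

#' Coverage filter
#'
#' Retains variants with total read depth at or above `cfg$min_depth`
#' (boundary inclusive). Records with missing depth are treated as failing
#' unless `min_depth` is 0.
#'
#' @param variants a variant table.
#' @param cfg a [filter_config()].
#' @return the retained subset.
#' @export
filter_coverage <- function(variants, cfg) {
  if (cfg$min_depth == 0) return(variants)
  variants[!is.na(variants$depth) & variants$depth >= cfg$min_depth, , drop = FALSE]
}

#' Exonic / rare filter
#'
#' Retains exonic consequences (nonsynonymous SNVs, frameshift indels,
#' nonsense, synonymous, other exonic) whose MAF is at most `cfg$max_maf`, or
#' unreported when `cfg$keep_absent_maf` is set.
#'
#' @inheritParams filter_coverage
#' @return the retained subset.
#' @export
filter_exonic_rare <- function(variants, cfg) {
  exonic <- !is.na(variants$consequence) &
    variants$consequence %in% EXONIC_CONSEQUENCES
  rare <- ifelse(is.na(variants$maf), cfg$keep_absent_maf,
                 variants$maf <= cfg$max_maf)
  variants[exonic & rare, , drop = FALSE]
}

#' Benign / in-house exclusion filter
#'
#' Removes variants annotated as clinically benign or likely benign, and any
#' variant whose key appears in the in-house database `cfg$inhouse_db`.
#'
#' @inheritParams filter_coverage
#' @return the retained subset.
#' @export
filter_benign_and_inhouse <- function(variants, cfg) {
  benign <- !is.na(variants$clinsig) &
    variants$clinsig %in% c("benign", "likely_benign")
  inhouse <- variant_key(variants) %in% cfg$inhouse_db
  variants[!benign & !inhouse, , drop = FALSE]
}

deleterious_mask <- function(variants, cfg) {
  truncating <- !is.na(variants$consequence) &
    variants$consequence %in% TRUNCATING_CONSEQUENCES
  synonymous <- !is.na(variants$consequence) & variants$consequence == "synonymous"
  cadd_pass <- !is.na(variants$cadd_phred) & variants$cadd_phred >= cfg$cadd_min
  svm_pass <- !is.na(variants$metasvm) & variants$metasvm == "D"
  score_pass <- switch(cfg$deleterious_rule,
    truncating_or_scores = ,
    cadd_and_svm = if (cfg$require_metasvm_d) cadd_pass & svm_pass else cadd_pass,
    cadd_or_svm = cadd_pass | svm_pass
  )
  keep <- switch(cfg$deleterious_rule,
    truncating_or_scores = truncating | score_pass,
    cadd_and_svm = score_pass,
    cadd_or_svm = truncating | score_pass
  )
  keep & !synonymous
}

#' Deleteriousness filter
#'
#' Under the default `truncating_or_scores` rule, truncating variants
#' (frameshift indels and nonsense, for which missense deleteriousness scores
#' are undefined) are retained unconditionally, and any other exonic variant
#' must reach the CADD cutoff and (by default) carry a MetaSVM "D" call.
#' Synonymous variants are never retained. The retained set partitions into
#' truncating and non-truncating ("nonsynonymous") classes, both reported in
#' the cascade trace.
#'
#' @inheritParams filter_coverage
#' @return the retained subset, with attribute `partition` giving the
#'   truncating / nonsynonymous split.
#' @export
filter_deleterious <- function(variants, cfg) {
  keep <- deleterious_mask(variants, cfg)
  out <- variants[keep, , drop = FALSE]
  truncating <- !is.na(out$consequence) & out$consequence %in% TRUNCATING_CONSEQUENCES
  attr(out, "partition") <- c(
    truncating = sum(truncating),
    nonsynonymous = sum(!truncating)
  )
  out
}

#' Sib-discordance filter
#'
#' With direction `affected_only` (default), retains the affected sib's
#' variants whose key is absent from the unaffected sib's table or explicitly
#' homozygous-reference there (with adequate depth when depth is recorded).
#' Absence of the key counts as homozygous reference: exome variant tables do
#' not carry reference blocks. Direction `unaffected_only` is the symmetric
#' protective screen.
#'
#' @param pair a [sib_pair()].
#' @param cfg a [filter_config()].
#' @param variants optionally, an already-filtered subset of the source sib's
#'   table to screen (defaults to the full table).
#' @return the retained subset of the source sib's variants.
#' @export
filter_discordant <- function(pair, cfg, variants = NULL) {
  source_tab <- if (cfg$direction == "affected_only") pair$affected else pair$unaffected
  other_tab <- if (cfg$direction == "affected_only") pair$unaffected else pair$affected
  if (is.null(other_tab)) stop("sib-discordance filter requires both sib tables")
  if (is.null(variants)) variants <- source_tab
  if (nrow(variants) == 0) return(variants)
  other_keys <- variant_key(other_tab)
  keys <- variant_key(variants)
  idx <- match(keys, other_keys)
  absent <- is.na(idx)
  hom_ref_there <- !absent &
    !is.na(other_tab$gt[idx]) & other_tab$gt[idx] == "hom_ref" &
    (is.na(other_tab$depth[idx]) | other_tab$depth[idx] >= cfg$min_depth)
  variants[absent | hom_ref_there, , drop = FALSE]
}

#' Cancer-gene panel filter
#'
#' Retains variants whose gene symbol is in the configured
#' cancer-predisposition panel (case-insensitive match).
#'
#' @inheritParams filter_coverage
#' @return the retained subset.
#' @export
filter_cancer_genes <- function(variants, cfg) {
  if (length(cfg$cancer_genes) == 0) {
    stop("cancer-gene panel stage enabled with an empty panel")
  }
  keep <- !is.na(variants$gene) &
    toupper(variants$gene) %in% toupper(cfg$cancer_genes)
  variants[keep, , drop = FALSE]
}

#' Run the full prioritization cascade on one sib pair
#'
#' Applies, in order: coverage, exonic/rare, benign & in-house exclusion,
#' deleteriousness, sib discordance, cancer-gene panel. Returns the candidate
#' variants in deterministic (chrom, pos, alt) order together with a
#' per-stage audit trace.
#'
#' @param pair a [sib_pair()].
#' @param cfg a [filter_config()]; the panel must be non-empty.
#' @return a list with elements `candidates` (variant table) and `trace`
#'   (tibble with columns `stage`, `n_in`, `n_out`, `removed` (list of keys),
#'   `n_truncating`, `n_nonsynonymous`).
#' @export
run_cascade <- function(pair, cfg) {
  if (length(cfg$cancer_genes) == 0) {
    stop("run_cascade: filter_config has an empty cancer-gene panel")
  }
  source_tab <- if (cfg$direction == "affected_only") pair$affected else pair$unaffected
  stages <- list(
    coverage = function(v) filter_coverage(v, cfg),
    exonic_rare = function(v) filter_exonic_rare(v, cfg),
    benign_inhouse = function(v) filter_benign_and_inhouse(v, cfg),
    deleterious = function(v) filter_deleterious(v, cfg),
    discordant = function(v) filter_discordant(pair, cfg, variants = v),
    cancer_panel = function(v) filter_cancer_genes(v, cfg)
  )
  cur <- source_tab
  trace <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    nm <- names(stages)[i]
    nxt <- stages[[i]](cur)
    part <- attr(nxt, "partition")
    trace[[i]] <- tibble::tibble(
      stage = nm,
      n_in = nrow(cur),
      n_out = nrow(nxt),
      removed = list(setdiff(variant_key(cur), variant_key(nxt))),
      n_truncating = if (!is.null(part)) part[["truncating"]] else NA_integer_,
      n_nonsynonymous = if (!is.null(part)) part[["nonsynonymous"]] else NA_integer_
    )
    cur <- nxt
  }
  ord <- order(cur$chrom, cur$pos, cur$alt)
  cur <- cur[ord, , drop = FALSE]
  attr(cur, "partition") <- NULL
  list(candidates = cur, trace = dplyr::bind_rows(trace))
}

#' Run the cascade over a cohort and pool candidates
#'
#' Runs [run_cascade()] on every pair and pools candidates over the cohort as
#' distinct (variant key, case) assignments. A variant is "shared" when the
#' same key is a candidate in two or more cases.
#'
#' @param cohort list of [sib_pair()] objects.
#' @param cfg a [filter_config()].
#' @return a list with `per_case` (tibble of candidate rows with a `case_id`
#'   column), `pooled` (variant table of distinct candidate keys),
#'   `shared_keys` (keys in >= 2 cases), and `traces` (named list of per-pair
#'   traces).
#' @export
run_cohort_cascade <- function(cohort, cfg) {
  validate_cohort(cohort)
  res <- lapply(cohort, run_cascade, cfg = cfg)
  names(res) <- vapply(cohort, function(p) p$case_id, character(1))
  per_case <- dplyr::bind_rows(lapply(names(res), function(id) {
    cand <- res[[id]]$candidates
    if (nrow(cand) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(case_id = id), cand)
  }))
  if (is.null(per_case) || nrow(per_case) == 0) {
    per_case <- dplyr::bind_cols(
      tibble::tibble(case_id = character(0)),
      as_variant_table(tibble::tibble(chrom = character(0), pos = integer(0),
                                      ref = "A", alt = "T")[0, ])
    )
  }
  keys <- variant_key(per_case)
  pooled <- per_case[!duplicated(keys), setdiff(names(per_case), "case_id"),
                     drop = FALSE]
  shared <- unique(keys[duplicated(keys)])
  list(
    per_case = per_case,
    pooled = pooled,
    shared_keys = shared,
    traces = lapply(res, `[[`, "trace")
  )
}

#' Export a cascade trace
#'
#' Writes the per-stage audit trail as JSON (stages with removed keys) or TSV
#' (counts only).
#'
#' @param trace a trace tibble from [run_cascade()].
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(trace[, c("stage", "n_in", "n_out",
                               "n_truncating", "n_nonsynonymous")], path)
  } else {
    jsonlite::write_json(
      lapply(seq_len(nrow(trace)), function(i) {
        list(
          stage = trace$stage[i], n_in = trace$n_in[i], n_out = trace$n_out[i],
          removed = trace$removed[[i]],
          n_truncating = trace$n_truncating[i],
          n_nonsynonymous = trace$n_nonsynonymous[i]
        )
      }),
      path, auto_unbox = TRUE, null = "null", na = "null"
    )
  }
  invisible(path)
}
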