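#' Run the end-to-end signature pipeline
#'
#' Executes the full analysis on a cohort: germline prioritization cascade
#' per pair, pooling over the cohort, blood-vs-tumor somatic extraction and
#' tallying, LOH detection at candidate loci, expression-class integration,
#' and (when an edge list is available) candidate-network construction. The
#' result is a per-patient signature report with cohort-level summaries.
#'
#' @param cohort list of [sib_pair()]s; alternatively pass `fixture = TRUE`
#'   to run on the packaged worked example, or a [simulation_config()] via
#'   `simulate` to run on a synthetic cohort.
#' @param profiles expression profiles (significance may be unfilled; it is
#'   computed here).
#' @param cfg a [filter_config()] with a non-empty cancer-gene panel.
#' @param th a [de_thresholds()].
#' @param retain_genes RNA-effect retain-list passed to
#'   [integrate_candidates()].
#' @param edges optional interaction edge tibble for the network stage.
#' @param fixture if `TRUE`, ignore the other data arguments and run on
#'   [load_paper_fixture()].
#' @param simulate optional [simulation_config()]; generates a synthetic
#'   cohort and runs on it (the truth record is attached to the result).
#' @param sig_method significance method for [compute_significance()].
#' @param min_hom_af LOH allele-fraction threshold, see [detect_loh()].
#' @param out_dir optional directory; when given, writes `report.tsv`,
#'   `report.json`, `trace.json`, `loh.tsv` and `log.txt` there.
#' @return an object of class `pipeline_result`: list with `report` (a
#'   `signature_report` whose `variants` tibble carries `loh`), `summary`
#'   (named list of cohort counts), `cascade` (the [run_cohort_cascade()]
#'   result), `loh` (pooled LOH calls), `somatic_tallies` (per case),
#'   `network` (or `NULL`), `profiles` (with significance filled), and
#'   `truth` when simulated.
#' @export
run_pipeline <- function(cohort = NULL, profiles = NULL, cfg = NULL,
                         th = de_thresholds(), retain_genes = character(0),
                         edges = NULL, fixture = FALSE, simulate = NULL,
                         sig_method = "log_t", min_hom_af = 0.8,
                         out_dir = NULL) {
  truth <- NULL
  if (fixture) {
    fx <- load_paper_fixture()
    cohort <- fx$cohort
    profiles <- fx$profiles
    edges <- fx$edges
    retain_genes <- fx$retain_genes
    if (is.null(cfg)) cfg <- filter_config(cancer_genes = fx$panel)
  } else if (!is.null(simulate)) {
    sim <- simulate_cohort(simulate)
    cohort <- sim$cohort
    profiles <- sim$profiles
    truth <- sim$truth
    if (is.null(cfg)) cfg <- filter_config(cancer_genes = simulate$panel_genes)
  }
  if (is.null(cohort)) stop("run_pipeline: no cohort given")
  if (is.null(cfg) || length(cfg$cancer_genes) == 0) {
    stop("run_pipeline: filter_config with a non-empty cancer-gene panel is required")
  }
  validate_cohort(cohort)

  cascade <- run_cohort_cascade(cohort, cfg)

  loh_rows <- list(); tallies <- list()
  for (pair in cohort) {
    if (is.null(pair$tumor)) next
    cand <- cascade$per_case[cascade$per_case$case_id == pair$case_id, ,
                             drop = FALSE]
    loh <- detect_loh(cand[setdiff(names(cand), "case_id")], pair$tumor,
                      min_hom_af = min_hom_af)
    if (nrow(loh) > 0) {
      loh <- dplyr::bind_cols(tibble::tibble(case_id = pair$case_id), loh)
    }
    loh_rows[[pair$case_id]] <- loh
    tallies[[pair$case_id]] <- tally_somatic(call_somatic(pair$affected, pair$tumor))
  }
  loh_all <- dplyr::bind_rows(loh_rows)

  report <- NULL
  if (!is.null(profiles)) {
    if (anyNA(profiles$p_t_vs_n)) {
      profiles <- compute_significance(profiles, method = sig_method,
                                       pseudocount = th$pseudocount)
    }
    report <- integrate_candidates(cascade$per_case, profiles, th,
                                   retain_genes = retain_genes)
    loh_flag <- if (nrow(loh_all) > 0) {
      loh_all$key[loh_all$is_loh]
    } else character(0)
    report$variants$loh <- report$variants$key %in% loh_flag
  }

  network <- NULL
  if (!is.null(edges) && nrow(cascade$per_case) > 0) {
    by_case <- split(cascade$per_case$gene, cascade$per_case$case_id)
    network <- build_candidate_network(by_case, edges)
  }

  per_case_counts <- if (!is.null(report)) report$per_case else NULL
  summary <- list(
    n_candidates = nrow(cascade$pooled),
    n_shared = length(cascade$shared_keys),
    class_counts = if (!is.null(report)) as.list(report$class_counts) else NULL,
    n_functional = if (!is.null(report)) report$n_functional else NULL,
    rna_panel_size = if (!is.null(report)) report$rna_panel_size else NULL,
    n_loh = if (nrow(loh_all) > 0) sum(loh_all$is_loh) else 0L,
    per_case = per_case_counts,
    candidates_per_case_mean = if (!is.null(per_case_counts)) mean(per_case_counts$n_candidates) else NULL,
    candidates_per_case_range = if (!is.null(per_case_counts)) range(per_case_counts$n_candidates) else NULL,
    functional_per_case_mean = if (!is.null(per_case_counts)) mean(per_case_counts$n_functional) else NULL,
    functional_per_case_range = if (!is.null(per_case_counts)) range(per_case_counts$n_functional) else NULL
  )

  result <- structure(
    list(report = report, summary = summary, cascade = cascade, loh = loh_all,
         somatic_tallies = tallies, network = network, profiles = profiles,
         truth = truth, config = cfg, thresholds = th),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  candidates: %d distinct (%d shared by >= 2 cases)\n",
              s$n_candidates, s$n_shared))
  if (!is.null(s$class_counts)) {
    cat(sprintf("  expression classes: TUMOR_DOWN %d, TUMOR_UP %d, BOTH_DOWN %d, NO_CHANGE %d\n",
                s$class_counts$TUMOR_DOWN, s$class_counts$TUMOR_UP,
                s$class_counts$BOTH_DOWN, s$class_counts$NO_CHANGE))
    cat(sprintf("  functional: %d | RNA-effect panel: %d | LOH: %d\n",
                s$n_functional, s$rna_panel_size, s$n_loh))
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$report)) {
    readr::write_tsv(result$report$variants, file.path(out_dir, "report.tsv"))
    jsonlite::write_json(
      pipeline_report_json(result),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  traces <- lapply(result$cascade$traces, function(tr) {
    lapply(seq_len(nrow(tr)), function(i) list(
      stage = tr$stage[i], n_in = tr$n_in[i], n_out = tr$n_out[i],
      removed = tr$removed[[i]]
    ))
  })
  jsonlite::write_json(traces, file.path(out_dir, "trace.json"),
                       auto_unbox = TRUE, null = "null")
  if (nrow(result$loh) > 0) write_loh(result$loh, file.path(out_dir, "loh.tsv"))
  log_lines <- c(
    paste0("oligosig ", as.character(utils::packageVersion("oligosig"))),
    paste0("R ", R.version.string),
    paste0("run time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("min_depth=", result$config$min_depth,
           " max_maf=", result$config$max_maf,
           " cadd_min=", result$config$cadd_min,
           " deleterious_rule=", result$config$deleterious_rule),
    paste0("min_fold=", result$thresholds$min_fold,
           " alpha=", result$thresholds$alpha,
           " pseudocount=", result$thresholds$pseudocount)
  )
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

pipeline_report_json <- function(result) {
  s <- result$summary
  list(
    summary = list(
      n_candidates = s$n_candidates,
      n_shared = s$n_shared,
      class_counts = s$class_counts,
      n_functional = s$n_functional,
      rna_panel_size = s$rna_panel_size,
      n_loh = s$n_loh
    ),
    per_case = if (!is.null(s$per_case)) s$per_case else list(),
    variants = result$report$variants
  )
}

#' Validate a pipeline report JSON file against the shipped schema
#'
#' A light structural check: verifies the presence and types of the fields
#' declared in `inst/extdata/report_schema.json` and that the summary counts
#' are re-derivable from the per-variant table.
#'
#' @param path path to a `report.json` written by [run_pipeline()].
#' @return `TRUE` invisibly; errors with a message on the first violation.
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report_schema.json", package = "oligosig",
                mustWork = TRUE)
  )
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in names(schema$required_summary_fields)) {
    if (is.null(rep$summary[[field]])) {
      stop("report.json: missing summary field ", field)
    }
  }
  v <- rep$variants
  if (is.null(v)) stop("report.json: missing variants table")
  for (col in schema$required_variant_columns) {
    if (is.null(v[[col]])) stop("report.json: variants lack column ", col)
  }
  if (length(unique(v$key)) != rep$summary$n_candidates) {
    stop("report.json: n_candidates does not match the variant table")
  }
  dup <- unique(v$key[duplicated(v$key)])
  if (length(dup) != rep$summary$n_shared) {
    stop("report.json: n_shared does not match the variant table")
  }
  pooled <- v[!duplicated(v$key), , drop = FALSE]
  if (sum(pooled$functional) != rep$summary$n_functional) {
    stop("report.json: n_functional does not match the variant table")
  }
  if (sum(pooled$rna_panel) != rep$summary$rna_panel_size) {
    stop("report.json: rna_panel_size does not match the variant table")
  }
  invisible(TRUE)
}
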