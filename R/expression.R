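#' Differential-expression thresholds
#'
#' @param min_fold minimum linear fold change (default 2; must be > 1).
#' @param alpha significance level (default 0.05).
#' @param pseudocount FPKM offset used before taking ratios and logs
#'   (default 0.1), avoiding infinite fold changes at zero expression.
#' @return an object of class `de_thresholds`.
#' @export
de_thresholds <- function(min_fold = 2, alpha = 0.05, pseudocount = 0.1) {
  if (min_fold <= 1) stop("min_fold must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  structure(list(min_fold = min_fold, alpha = alpha, pseudocount = pseudocount),
            class = "de_thresholds")
}

EXPRESSION_CLASSES <- c("TUMOR_DOWN", "TUMOR_UP", "BOTH_DOWN", "NO_CHANGE")

# One-sample location test of a single log2 FPKM observation against the
# control-group distribution. With controls c_1..c_k (log2 scale, mean m,
# sd s), the statistic for a new observation x is
#   t = (x - m) / (s * sqrt(1 + 1/k)),  df = k - 1
# (the prediction-interval form of the one-sample t test). The T-vs-N
# comparison treats both as single observations with the C-calibrated
# variance: t = (x_t - x_n) / (s * sqrt(2)), df = k - 1. With a degenerate
# control spread (s = 0) the p-value is 0 for any non-zero difference and 1
# otherwise, which makes noise-free simulations exactly recoverable.
log_t_p <- function(diff, s, k, scale) {
  if (is.na(s)) return(NA_real_)
  if (s == 0) return(ifelse(diff == 0, 1, 0))
  tt <- diff / (s * scale)
  2 * pt(-abs(tt), df = k - 1)
}

# Rank-based exchangeability p-values. For a single observation x against
# controls c: pool x with the controls and report the fraction of pool
# members whose absolute deviation from the pool mean is at least that of x.
# For T vs N, the observed |log2 T - log2 N| is compared against all ordered
# control pairs' |c_i - c_j| with an add-one correction.
perm_p_one <- function(x, cvals) {
  pool <- c(x, cvals)
  dev <- abs(pool - mean(pool))
  mean(dev >= dev[1] - 1e-12)
}

perm_p_pair <- function(x, y, cvals) {
  obs <- abs(x - y)
  pairs <- abs(outer(cvals, cvals, "-"))
  pairs <- pairs[upper.tri(pairs)]
  (1 + sum(pairs >= obs - 1e-12)) / (1 + length(pairs))
}

#' Compute significance of tumor/normal FPKM against the control group
#'
#' Fills the `p_t_vs_c`, `p_n_vs_c` and `p_t_vs_n` columns of an
#' expression-profile tibble. All tests are carried out on
#' `log2(FPKM + pseudocount)`. With `method = "log_t"`, the tumor and normal
#' values are each tested against the control-normal group by a one-sample
#' location test (prediction-interval t form, df = controls - 1), and the
#' tumor-vs-normal comparison uses the same control-calibrated variance. With
#' `method = "permutation"`, rank-based exchangeability p-values are used
#' instead (exactly 1 when the observation equals every control).
#'
#' @param profiles expression-profile tibble (see [read_expression_table()]).
#' @param method `"log_t"` (default) or `"permutation"`.
#' @param pseudocount FPKM offset before the log transform (default 0.1).
#' @param c_samples optional named list of per-gene control FPKM vectors
#'   overriding the `fpkm_c` list-column.
#' @return `profiles` with the three p-value columns filled (all in \[0,1\]).
#' @export
compute_significance <- function(profiles, method = c("log_t", "permutation"),
                                 pseudocount = 0.1, c_samples = NULL) {
  method <- match.arg(method)
  if (nrow(profiles) == 0) return(profiles)
  for (i in seq_len(nrow(profiles))) {
    cvals <- if (!is.null(c_samples)) c_samples[[profiles$gene[i]]] else profiles$fpkm_c[[i]]
    if (is.null(cvals) || length(cvals) < 2) {
      stop("compute_significance: gene ", profiles$gene[i],
           " has fewer than 2 control samples")
    }
    lc <- log2(cvals + pseudocount)
    lt <- log2(profiles$fpkm_t[i] + pseudocount)
    ln <- log2(profiles$fpkm_n[i] + pseudocount)
    if (method == "log_t") {
      k <- length(lc); m <- mean(lc); s <- sd(lc)
      profiles$p_t_vs_c[i] <- log_t_p(lt - m, s, k, sqrt(1 + 1 / k))
      profiles$p_n_vs_c[i] <- log_t_p(ln - m, s, k, sqrt(1 + 1 / k))
      profiles$p_t_vs_n[i] <- log_t_p(lt - ln, s, k, sqrt(2))
    } else {
      profiles$p_t_vs_c[i] <- perm_p_one(lt, lc)
      profiles$p_n_vs_c[i] <- perm_p_one(ln, lc)
      profiles$p_t_vs_n[i] <- perm_p_pair(lt, ln, lc)
    }
  }
  profiles
}

#' Classify candidate genes by their T/N/C expression pattern
#'
#' Assigns exactly one class per profiled gene, checked in this order:
#' \describe{
#'   \item{BOTH_DOWN}{tumor and matched normal each at most
#'     `fpkm_c_mean / min_fold`, with both significant against the control
#'     group — transcript instability in the carrier, checked first because a
#'     depressed normal makes the tumor-vs-normal comparison uninformative.}
#'   \item{TUMOR_DOWN}{tumor at most `fpkm_n / min_fold` with significant
#'     T-vs-N — a putative second hit in a tumor suppressor.}
#'   \item{TUMOR_UP}{tumor at least `fpkm_n * min_fold` with significant
#'     T-vs-N — a likely oncogene.}
#'   \item{NO_CHANGE}{anything else.}
#' }
#' Fold comparisons are on pseudocount-offset FPKM.
#'
#' @param profiles expression-profile tibble with significance filled (see
#'   [compute_significance()]).
#' @param th a [de_thresholds()].
#' @return character vector of classes, one per profile row.
#' @export
classify_expression <- function(profiles, th = de_thresholds()) {
  if (nrow(profiles) == 0) return(character(0))
  if (anyNA(profiles$p_t_vs_n) || anyNA(profiles$p_t_vs_c) || anyNA(profiles$p_n_vs_c)) {
    stop("classify_expression: significance not computed; run compute_significance() first")
  }
  pc <- th$pseudocount
  t_ <- profiles$fpkm_t + pc
  n_ <- profiles$fpkm_n + pc
  c_ <- profiles$fpkm_c_mean + pc
  both_down <- t_ <= c_ / th$min_fold & n_ <= c_ / th$min_fold &
    profiles$p_t_vs_c <= th$alpha & profiles$p_n_vs_c <= th$alpha
  tumor_down <- t_ <= n_ / th$min_fold & profiles$p_t_vs_n <= th$alpha
  tumor_up <- t_ >= n_ * th$min_fold & profiles$p_t_vs_n <= th$alpha
  ifelse(both_down, "BOTH_DOWN",
         ifelse(tumor_down, "TUMOR_DOWN",
                ifelse(tumor_up, "TUMOR_UP", "NO_CHANGE")))
}

#' Integrate germline candidates with expression classes
#'
#' Joins each candidate variant to its gene's expression profile and assigns
#' the expression class. A candidate is "functional" when its class is not
#' `NO_CHANGE`. Genes in `retain_genes` (e.g. a truncated putative tumor
#' suppressor retained by judgment despite unchanged mRNA) are additionally
#' flagged for the RNA-effect panel. Candidates whose gene has no profile are
#' reported as unprofiled (class `NA`, not functional).
#'
#' @param candidates candidate variant tibble; may carry a `case_id` column
#'   (as produced by [run_cohort_cascade()]`$per_case`) for per-case counts.
#' @param profiles expression-profile tibble with significance filled.
#' @param th a [de_thresholds()].
#' @param retain_genes character vector of gene symbols kept on the RNA-effect
#'   panel irrespective of class (opt-in list, empty by default).
#' @return an object of class `signature_report`: list with `variants` (one
#'   row per (case, variant) with `class`, `functional`, `rna_panel`),
#'   `class_counts` (pooled over distinct variant keys, named by class),
#'   `n_functional`, `rna_panel_size`, `unprofiled` (gene symbols), and
#'   `per_case` (tibble of per-case candidate/functional counts, when case
#'   ids are available).
#' @export
integrate_candidates <- function(candidates, profiles, th = de_thresholds(),
                                 retain_genes = character(0)) {
  has_case <- "case_id" %in% names(candidates)
  cls <- classify_expression(profiles, th)
  prof_idx <- match(toupper(candidates$gene), toupper(profiles$gene))
  variant_class <- cls[prof_idx]
  keys <- variant_key(candidates)
  functional <- !is.na(variant_class) & variant_class != "NO_CHANGE"
  rna_panel <- functional | toupper(candidates$gene) %in% toupper(retain_genes)
  variants <- tibble::tibble(
    case_id = if (has_case) candidates$case_id else NA_character_,
    key = keys,
    gene = candidates$gene,
    consequence = candidates$consequence,
    class = variant_class,
    functional = functional,
    rna_panel = rna_panel
  )
  pooled <- variants[!duplicated(variants$key), , drop = FALSE]
  class_counts <- setNames(integer(length(EXPRESSION_CLASSES)), EXPRESSION_CLASSES)
  tab <- table(factor(pooled$class, levels = EXPRESSION_CLASSES))
  class_counts[names(tab)] <- as.integer(tab)
  per_case <- NULL
  if (has_case) {
    per_case <- dplyr::summarise(
      dplyr::group_by(variants, .data$case_id),
      n_candidates = dplyr::n(),
      n_functional = sum(.data$functional),
      n_rna_panel = sum(.data$rna_panel),
      .groups = "drop"
    )
  }
  structure(
    list(
      variants = variants,
      class_counts = class_counts,
      n_functional = sum(pooled$functional),
      rna_panel_size = sum(pooled$rna_panel),
      unprofiled = unique(pooled$gene[is.na(pooled$class)]),
      per_case = per_case
    ),
    class = "signature_report"
  )
}

#' Genome-wide differential-expression summary
#'
#' Splits profiled genes into significantly upregulated (tumor at least
#' `min_fold` times the matched normal, T-vs-N p at most `alpha`) and
#' significantly downregulated (symmetric) lists; the two lists are disjoint.
#'
#' @param profiles expression-profile tibble with significance filled.
#' @param th a [de_thresholds()].
#' @return list with character vectors `up` and `down` (sorted by p, then
#'   symbol).
#' @export
de_summary <- function(profiles, th = de_thresholds()) {
  if (nrow(profiles) == 0) return(list(up = character(0), down = character(0)))
  if (anyNA(profiles$p_t_vs_n)) {
    stop("de_summary: significance not computed")
  }
  pc <- th$pseudocount
  t_ <- profiles$fpkm_t + pc
  n_ <- profiles$fpkm_n + pc
  sig <- profiles$p_t_vs_n <= th$alpha
  up <- sig & t_ >= n_ * th$min_fold
  down <- sig & t_ <= n_ / th$min_fold
  ord <- order(profiles$p_t_vs_n, profiles$gene)
  list(
    up = profiles$gene[ord][up[ord]],
    down = profiles$gene[ord][down[ord]]
  )
}

#' Filter fusion candidates to cancer-specific events
#'
#' Retains fusions with at least `min_span` spanning reads in tumor and fewer
#' than `min_span` in the matched normal tissue (fusions also supported in
#' normal tissue are not cancer-specific).
#'
#' @param fusions a fusion-candidate tibble (see [fusion_candidates()]).
#' @param min_span spanning-read support threshold (default 10).
#' @return the retained subset.
#' @export
filter_cancer_fusions <- function(fusions, min_span = 10) {
  fusions[fusions$spanning_reads_tumor >= min_span &
            fusions$spanning_reads_normal < min_span, , drop = FALSE]
}

#' @export
print.signature_report <- function(x, ...) {
  cat("<signature_report>\n")
  cat(sprintf("  candidate rows: %d (%d distinct variants)\n",
              nrow(x$variants), length(unique(x$variants$key))))
  cat(sprintf("  classes: TUMOR_DOWN %d, TUMOR_UP %d, BOTH_DOWN %d, NO_CHANGE %d\n",
              x$class_counts[["TUMOR_DOWN"]], x$class_counts[["TUMOR_UP"]],
              x$class_counts[["BOTH_DOWN"]], x$class_counts[["NO_CHANGE"]]))
  cat(sprintf("  functional: %d | RNA-effect panel: %d\n",
              x$n_functional, x$rna_panel_size))
  if (length(x$unprofiled) > 0) {
    cat("  unprofiled genes:", paste(x$unprofiled, collapse = ", "), "\n")
  }
  invisible(x)
}
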