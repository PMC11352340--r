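profile_row <- function(gene, t, n, cvals) {
  tibble::tibble(
    gene = gene, fpkm_t = t, fpkm_n = n, fpkm_c = list(cvals),
    fpkm_c_mean = mean(cvals),
    p_t_vs_n = NA_real_, p_n_vs_c = NA_real_, p_t_vs_c = NA_real_
  )
}

test_that("log-t significance matches the closed-form t computed by hand", {
  cvals <- c(18, 19, 20, 21, 22)
  prof <- compute_significance(profile_row("g", 0.1, 20, cvals))
  # independent recomputation of the prediction-form one-sample t
  lc <- log2(cvals + 0.1)
  tt <- (log2(0.2) - mean(lc)) / (sd(lc) * sqrt(1 + 1 / 5))
  expect_equal(prof$p_t_vs_c, 2 * stats::pt(-abs(tt), df = 4))
  expect_lt(prof$p_t_vs_c, 0.05)
  # a tumor value equal to a control-group member is unremarkable
  prof2 <- compute_significance(profile_row("g", 20, 20, cvals))
  expect_gt(prof2$p_t_vs_c, 0.5)
})

test_that("permutation p-value is 1 when the observation equals every control", {
  prof <- compute_significance(profile_row("g", 20, 20, rep(20, 5)),
                               method = "permutation")
  expect_equal(prof$p_t_vs_c, 1)
  expect_equal(prof$p_n_vs_c, 1)
  expect_equal(prof$p_t_vs_n, 1)
})

test_that("permutation p-values are super-uniform under the null", {
  withr::with_seed(2024, {
    n_genes <- 2000
    k <- 19
    rows <- lapply(seq_len(n_genes), function(i) {
      vals <- 2^rnorm(k + 2, 4, 0.5)   # iid: tumor, normal, k controls
      profile_row(paste0("g", i), vals[1], vals[2], vals[-(1:2)])
    })
    prof <- compute_significance(dplyr::bind_rows(rows), method = "permutation")
    frac <- mean(prof$p_t_vs_c < 0.05)
    se <- sqrt(0.05 * 0.95 / n_genes)
    expect_lte(frac, 0.05 + 3 * se)
  })
})

test_that("significance requires at least two controls and errors name the gene", {
  expect_error(compute_significance(profile_row("ABC", 1, 2, 5)), "ABC")
})

test_that("classification follows the documented rule with BOTH_DOWN precedence", {
  th <- de_thresholds()
  cvals_hi <- c(18, 19, 20, 21, 22)
  cvals_lo <- c(2.7, 2.85, 3, 3.15, 3.3)
  prof <- compute_significance(dplyr::bind_rows(
    profile_row("second_hit", 2, 20, cvals_hi),     # down in tumor only
    profile_row("oncogene", 30, 3, cvals_lo),       # up in tumor
    profile_row("unstable", 1, 1.2, cvals_hi),      # down in both vs controls
    profile_row("quiet", 19, 20, cvals_hi)          # no change
  ))
  expect_equal(classify_expression(prof, th),
               c("TUMOR_DOWN", "TUMOR_UP", "BOTH_DOWN", "NO_CHANGE"))
  # classification is total: one class per gene, always
  expect_true(all(classify_expression(prof, th) %in%
                    c("TUMOR_DOWN", "TUMOR_UP", "BOTH_DOWN", "NO_CHANGE")))
  # unfilled significance is a hard error
  expect_error(classify_expression(profile_row("g", 1, 2, c(3, 4))),
               "significance")
})

test_that("classification is invariant to rescaling a gene's FPKM values", {
  withr::with_seed(7, {
    for (i in 1:20) {
      # values well above the 0.1 pseudocount, as the invariance requires
      t <- runif(1, 5, 50); n <- runif(1, 5, 50)
      cvals <- runif(5, 5, 50)
      base <- compute_significance(profile_row("g", t, n, cvals))
      scaled <- compute_significance(profile_row("g", t * 100, n * 100, cvals * 100))
      expect_equal(classify_expression(base), classify_expression(scaled))
    }
  })
})

test_that("integration joins candidates to classes and counts per case", {
  fx <- load_paper_fixture()
  cfg <- filter_config(cancer_genes = fx$panel)
  cc <- run_cohort_cascade(fx$cohort, cfg)
  prof <- compute_significance(fx$profiles)
  rep <- integrate_candidates(cc$per_case, prof, de_thresholds(),
                              retain_genes = fx$retain_genes)
  expect_equal(sum(rep$class_counts), 40L)   # classes partition the candidates
  expect_equal(rep$n_functional,
               sum(rep$class_counts[c("TUMOR_DOWN", "TUMOR_UP", "BOTH_DOWN")]))
  expect_equal(rep$rna_panel_size, rep$n_functional + 1L)  # + retained URI1
  expect_equal(rep$per_case$n_candidates, c(6L, 14L, 13L, 10L))
  expect_equal(rep$per_case$n_functional, c(3L, 7L, 6L, 1L))
  # case 4's RNA-effect rows are IQGAP2 plus the retained URI1
  expect_equal(rep$per_case$n_rna_panel, c(3L, 7L, 6L, 2L))
  expect_length(rep$unprofiled, 0)
  # a candidate without a profile is reported as unprofiled, not classified
  orphan <- dplyr::bind_cols(tibble::tibble(case_id = "case1"),
                             vt(vt_row(gene = "NOPROFILE")))
  rep2 <- integrate_candidates(orphan, prof, de_thresholds())
  expect_equal(rep2$unprofiled, "NOPROFILE")
  expect_false(rep2$variants$functional)
})

test_that("genome-wide DE summary recovers planted directions and stays disjoint", {
  expect_equal(
    de_summary(compute_significance(dplyr::bind_rows(
      profile_row("up", 25, 10, c(9, 10, 11, 10, 10)),
      profile_row("weak", 19, 10, c(9, 10, 11, 10, 10))
    ))),
    list(up = "up", down = character(0))
  )
  sim <- simulate_cohort(small_sim_config(seed = 13, n_de_up = 30,
                                          n_de_down = 25, n_null_genes = 200,
                                          sigma = 0))
  prof <- compute_significance(sim$profiles)
  de <- de_summary(prof)
  truth <- sim$truth$de_direction
  expect_true(all(names(truth)[truth == "up"] %in% de$up))
  expect_true(all(names(truth)[truth == "down"] %in% de$down))
  expect_length(intersect(de$up, de$down), 0)
  expect_false(any(names(truth)[truth == "none"] %in% c(de$up, de$down)))
})

test_that("cancer-specific fusion filtering applies both spanning-read rules", {
  fus <- fusion_candidates(
    gene5 = c("A", "B", "C"), gene3 = c("X", "Y", "Z"),
    spanning_reads_tumor = c(12L, 12L, 8L),
    spanning_reads_normal = c(0L, 11L, 0L)
  )
  kept <- filter_cancer_fusions(fus, min_span = 10)
  expect_equal(kept$gene5, "A")
  expect_error(fusion_candidates("A", "A", 1L, 0L), "differ")
})
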