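test_that("somatic calling is blood-vs-tumor table subtraction", {
  blood <- vt(vt_row(pos = 1), vt_row(pos = 2, gt = "hom_ref"))
  tumor <- vt(vt_row(pos = 1), vt_row(pos = 2), vt_row(pos = 3))
  som <- call_somatic(blood, tumor)
  # tumor-only and hom-ref-in-blood are somatic; het in both is germline
  expect_setequal(som$pos, c(2L, 3L))
  expect_equal(nrow(call_somatic(blood, tumor[0, ])), 0L)

  # somatic and germline-in-tumor partition the tumor table
  germline_in_tumor <- tumor[!variant_key(tumor) %in% variant_key(som), ]
  expect_equal(nrow(som) + nrow(germline_in_tumor), nrow(tumor))
  expect_length(intersect(variant_key(som), variant_key(germline_in_tumor)), 0)

  bt <- blood; attr(bt, "case_id") <- "case1"
  tt <- tumor; attr(tt, "case_id") <- "case2"
  expect_error(call_somatic(bt, tt), "different cases")
})

test_that("somatic tallies count by consequence class", {
  withr::with_seed(11, {
    tab <- random_variant_table(300, paste0("P", 1:5))
    tab$consequence <- sample(
      c("nonsynonymous_snv", "frameshift_indel", "nonsense", "noncoding"),
      300, replace = TRUE
    )
    tally <- tally_somatic(as_variant_table(tab))
    expect_equal(tally$total, 300L)
    expect_equal(tally$missense, sum(tab$consequence == "nonsynonymous_snv"))
    expect_equal(tally$frameshift_indel, sum(tab$consequence == "frameshift_indel"))
    expect_equal(tally$nonsense, sum(tab$consequence == "nonsense"))
    expect_equal(tally$coding, 300L - sum(tab$consequence == "noncoding"))
    expect_lte(tally$missense + tally$frameshift_indel + tally$nonsense,
               tally$coding)
  })
  empty <- tally_somatic(vt(vt_row())[0, ])
  expect_equal(empty$total, 0L)
  expect_equal(empty$coding, 0L)
})

test_that("planted somatic class counts are recovered exactly from the truth", {
  sim <- simulate_cohort(small_sim_config(seed = 5))
  pair <- sim$cohort[[1]]
  som <- call_somatic(pair$affected, pair$tumor)
  truth <- sim$truth$somatic[sim$truth$somatic$case_id == "case1", ]
  expect_setequal(variant_key(som), truth$key)
  tally <- tally_somatic(som)
  expect_equal(tally$missense, sum(truth$consequence == "nonsynonymous_snv"))
  expect_equal(tally$frameshift_indel, sum(truth$consequence == "frameshift_indel"))
  expect_equal(tally$nonsense, sum(truth$consequence == "nonsense"))
})

test_that("LOH detection follows the het-blood / hom-tumor rule", {
  cand <- vt(
    vt_row(pos = 1, alt_depth = 12L, ref_depth = 13L, depth = 25L),      # AF 0.48 blood
    vt_row(pos = 2),
    vt_row(pos = 3),
    vt_row(pos = 4, gt = "hom_alt"),
    vt_row(pos = 5)
  )
  tumor <- vt(
    vt_row(pos = 1, gt = "het", alt_depth = 19L, ref_depth = 1L, depth = 20L),  # AF 0.95
    vt_row(pos = 2, gt = "het", alt_depth = 10L, ref_depth = 10L, depth = 20L), # AF 0.50
    vt_row(pos = 3, gt = "hom_alt", alt_depth = NA, ref_depth = NA, depth = NA),
    vt_row(pos = 4, gt = "hom_alt")
  )
  loh <- detect_loh(cand, tumor, min_hom_af = 0.8)
  expect_equal(loh$is_loh, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(loh$tumor_state[5], "missing")
  expect_true(is.na(loh$tumor_alt_fraction[5]))
  expect_equal(loh$tumor_alt_fraction[1], 0.95)
  expect_error(detect_loh(cand, tumor, min_hom_af = 0.5), "min_hom_af")
  expect_error(detect_loh(cand, tumor, min_hom_af = 1.2), "min_hom_af")
})

test_that("LOH recovery on synthetic tumors matches the planted conversions at purity 1", {
  sim <- simulate_cohort(small_sim_config(seed = 31, n_loh = 5))
  cfg <- filter_config(cancer_genes = sim$config$panel_genes)
  cc <- run_cohort_cascade(sim$cohort, cfg)
  called <- character(0)
  for (pair in sim$cohort) {
    cand <- cc$per_case[cc$per_case$case_id == pair$case_id, -1]
    loh <- detect_loh(cand, pair$tumor)
    called <- c(called, loh$key[loh$is_loh])
  }
  expect_setequal(called, sim$truth$loh_keys)
})

test_that("detected LOH fraction decreases as tumor purity falls", {
  frac_at <- function(purity) {
    sim <- simulate_cohort(small_sim_config(seed = 77, n_loh = 4,
                                            tumor_purity = purity))
    cfg <- filter_config(cancer_genes = sim$config$panel_genes)
    cc <- run_cohort_cascade(sim$cohort, cfg)
    called <- 0
    for (pair in sim$cohort) {
      cand <- cc$per_case[cc$per_case$case_id == pair$case_id, -1]
      called <- called + sum(detect_loh(cand, pair$tumor)$is_loh)
    }
    called / length(sim$truth$loh_keys)
  }
  fr <- vapply(c(1, 0.8, 0.5), frac_at, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[1], 1)
})

test_that("fixture candidates are all in the tumor, het unless planted LOH", {
  fx <- load_paper_fixture()
  cfg <- filter_config(cancer_genes = fx$panel)
  cc <- run_cohort_cascade(fx$cohort, cfg)
  for (pair in fx$cohort) {
    cand <- cc$per_case[cc$per_case$case_id == pair$case_id, -1]
    keys <- variant_key(cand)
    idx <- match(keys, variant_key(pair$tumor))
    expect_false(anyNA(idx))
    expect_true(all(pair$tumor$gt[idx] %in% c("het", "hom_alt")))
  }
})
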