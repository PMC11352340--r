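cfg0 <- filter_config(cancer_genes = c("GENE1", "GENE2"))

test_that("coverage filter applies an inclusive depth threshold", {
  tab <- vt(vt_row(pos = 1, depth = 9L, alt_depth = 4L, ref_depth = 5L),
            vt_row(pos = 2, depth = 10L, alt_depth = 5L, ref_depth = 5L))
  kept <- filter_coverage(tab, cfg0)
  expect_equal(kept$pos, 2L)
  # min_depth 0 is the identity
  cfg_id <- filter_config(min_depth = 0, cancer_genes = "GENE1")
  expect_equal(filter_coverage(tab, cfg_id), tab)
})

test_that("exonic/rare filter keeps rare or unreported MAF, exonic only", {
  tab <- vt(
    vt_row(pos = 1, maf = 0.02),
    vt_row(pos = 2, maf = NA),
    vt_row(pos = 3, maf = 0.01),
    vt_row(pos = 4, maf = 0.001, consequence = "noncoding")
  )
  kept <- filter_exonic_rare(tab, cfg0)
  expect_setequal(kept$pos, c(2L, 3L))
  cfg_strict <- filter_config(keep_absent_maf = FALSE, cancer_genes = "GENE1")
  expect_equal(filter_exonic_rare(tab, cfg_strict)$pos, 3L)
})

test_that("benign and in-house variants are excluded", {
  tab <- vt(
    vt_row(pos = 1, clinsig = "likely_benign"),
    vt_row(pos = 2, clinsig = "benign"),
    vt_row(pos = 3, clinsig = NA),
    vt_row(pos = 4, clinsig = "other")
  )
  cfg_db <- filter_config(inhouse_db = "1:4:C:T", cancer_genes = "GENE1")
  kept <- filter_benign_and_inhouse(tab, cfg_db)
  expect_equal(kept$pos, 3L)
})

test_that("deleteriousness rule retains truncating unconditionally and scores otherwise", {
  tab <- vt(
    vt_row(pos = 1, consequence = "nonsense", cadd_phred = NA, metasvm = NA),
    vt_row(pos = 2, consequence = "frameshift_indel", cadd_phred = NA, metasvm = NA),
    vt_row(pos = 3, cadd_phred = 25, metasvm = "D"),
    vt_row(pos = 4, cadd_phred = 25, metasvm = "T"),
    vt_row(pos = 5, cadd_phred = 15, metasvm = "D"),
    vt_row(pos = 6, consequence = "synonymous", cadd_phred = 30, metasvm = "D")
  )
  kept <- filter_deleterious(tab, cfg0)
  expect_setequal(kept$pos, c(1L, 2L, 3L))
  expect_equal(attr(kept, "partition"),
               c(truncating = 2L, nonsynonymous = 1L))
  # partition is disjoint and exhaustive
  expect_equal(sum(attr(kept, "partition")), nrow(kept))

  cfg_or <- filter_config(deleterious_rule = "cadd_or_svm", cancer_genes = "GENE1")
  expect_setequal(filter_deleterious(tab, cfg_or)$pos, c(1L, 2L, 3L, 4L, 5L))
  cfg_and <- filter_config(deleterious_rule = "cadd_and_svm", cancer_genes = "GENE1")
  expect_setequal(filter_deleterious(tab, cfg_and)$pos, 3L)
})

test_that("sib discordance keeps affected-exclusive variants, both directions", {
  affected <- vt(
    vt_row(pos = 1),                       # absent in sib -> kept
    vt_row(pos = 2),                       # het in sib -> removed
    vt_row(pos = 3),                       # hom_ref in sib, covered -> kept
    vt_row(pos = 4)                        # hom_ref in sib, low depth -> removed
  )
  unaffected <- vt(
    vt_row(pos = 2),
    vt_row(pos = 3, gt = "hom_ref", alt_depth = 0L, ref_depth = 20L),
    vt_row(pos = 4, gt = "hom_ref", alt_depth = 0L, ref_depth = 5L, depth = 5L),
    vt_row(pos = 9)                        # private to unaffected
  )
  pair <- sib_pair("caseX", affected, unaffected)
  kept <- filter_discordant(pair, cfg0)
  expect_setequal(kept$pos, c(1L, 3L))
  cfg_rev <- filter_config(direction = "unaffected_only", cancer_genes = "GENE1")
  expect_equal(filter_discordant(pair, cfg_rev)$pos, 9L)
})

test_that("panel filter is case-insensitive and rejects an empty panel", {
  tab <- vt(vt_row(pos = 1, gene = "men1"), vt_row(pos = 2, gene = "XYZ"))
  cfg <- filter_config(cancer_genes = "MEN1")
  expect_equal(filter_cancer_genes(tab, cfg)$gene, "men1")
  expect_error(filter_cancer_genes(tab, filter_config()), "empty panel")
  expect_equal(nrow(filter_cancer_genes(tab[0, ], cfg)), 0L)
})

test_that("cascade equals a brute-force single-pass predicate conjunction", {
  # oracle: direct conjunction of all stage predicates, evaluated per row
  brute_force <- function(pair, cfg) {
    v <- pair$affected
    exonic <- !is.na(v$consequence) & v$consequence %in%
      c("nonsynonymous_snv", "frameshift_indel", "nonsense", "synonymous", "other_exonic")
    rare <- ifelse(is.na(v$maf), cfg$keep_absent_maf, v$maf <= cfg$max_maf)
    not_benign <- !(!is.na(v$clinsig) & v$clinsig %in% c("benign", "likely_benign"))
    truncating <- v$consequence %in% c("frameshift_indel", "nonsense")
    scores <- !is.na(v$cadd_phred) & v$cadd_phred >= cfg$cadd_min &
      !is.na(v$metasvm) & v$metasvm == "D"
    deleterious <- (truncating | scores) & v$consequence != "synonymous"
    u <- pair$unaffected
    idx <- match(variant_key(v), variant_key(u))
    discordant <- is.na(idx) |
      (!is.na(u$gt[idx]) & u$gt[idx] == "hom_ref" &
         (is.na(u$depth[idx]) | u$depth[idx] >= cfg$min_depth))
    in_panel <- toupper(v$gene) %in% toupper(cfg$cancer_genes)
    covered <- !is.na(v$depth) & v$depth >= cfg$min_depth
    sort(variant_key(v)[covered & exonic & rare & not_benign & deleterious &
                          discordant & in_panel])
  }
  withr::with_seed(123, {
    panel <- paste0("PNL", 1:20)
    cfg <- filter_config(cancer_genes = panel)
    for (rep in 1:5) {
      n <- sample(c(50, 400, 1000), 1)
      aff <- as_variant_table(random_variant_table(n, panel))
      # sib table: some genuinely shared variants plus its own private ones
      # (private positions offset into a disjoint range to keep keys unique)
      shared_idx <- sample.int(n, n %/% 4)
      una_priv <- random_variant_table(n, panel)
      una_priv$pos <- una_priv$pos + 2000000L
      una <- as_variant_table(dplyr::bind_rows(aff[shared_idx, ], una_priv))
      pair <- sib_pair("p", aff, una)
      res <- run_cascade(pair, cfg)
      expect_equal(sort(variant_key(res$candidates)), brute_force(pair, cfg))
    }
  })
})

test_that("commuting early stages can be reordered without changing the result", {
  withr::with_seed(99, {
    panel <- paste0("PNL", 1:20)
    cfg <- filter_config(cancer_genes = panel)
    tab <- as_variant_table(random_variant_table(500, panel))
    a <- filter_benign_and_inhouse(filter_exonic_rare(filter_coverage(tab, cfg), cfg), cfg)
    b <- filter_coverage(filter_exonic_rare(filter_benign_and_inhouse(tab, cfg), cfg), cfg)
    expect_setequal(variant_key(a), variant_key(b))
  })
})

test_that("the cascade trace is a monotone funnel with bookkeeping intact", {
  fx <- load_paper_fixture()
  cfg <- filter_config(cancer_genes = fx$panel)
  res <- run_cascade(fx$cohort[[2]], cfg)
  tr <- res$trace
  expect_equal(tr$stage, c("coverage", "exonic_rare", "benign_inhouse",
                           "deleterious", "discordant", "cancer_panel"))
  expect_true(all(tr$n_out <= tr$n_in))
  expect_equal(tr$n_in[-1], tr$n_out[-nrow(tr)])
  expect_equal(tr$n_in - tr$n_out, lengths(tr$removed))
  # deleterious partition reported in the trace
  del <- tr[tr$stage == "deleterious", ]
  expect_equal(del$n_truncating + del$n_nonsynonymous, del$n_out)
  # deterministic candidate order
  expect_equal(order(res$candidates$chrom, res$candidates$pos,
                     res$candidates$alt),
               seq_len(nrow(res$candidates)))
})

test_that("cascade on a cohort without planted private variants yields none", {
  tab <- vt(vt_row(pos = 1), vt_row(pos = 2, gene = "GENE2"))
  pair <- sib_pair("c1", tab, tab)  # everything shared
  res <- run_cohort_cascade(list(pair), cfg0)
  expect_equal(nrow(res$pooled), 0L)
  expect_equal(res$shared_keys, character(0))
})

test_that("trace export writes JSON and TSV", {
  fx <- load_paper_fixture()
  cfg <- filter_config(cancer_genes = fx$panel)
  tr <- run_cascade(fx$cohort[[1]], cfg)$trace
  j <- withr::local_tempfile(fileext = ".json")
  t <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, j, "json")
  write_trace(tr, t, "tsv")
  parsed <- jsonlite::read_json(j)
  expect_equal(length(parsed), 6L)
  expect_equal(parsed[[1]]$stage, "coverage")
  expect_equal(nrow(readr::read_tsv(t, show_col_types = FALSE)), 6L)
})
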