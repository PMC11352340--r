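#' Simulation configuration for synthetic sib-pair cohorts
#'
#' The generator emulates the statistical structure the analysis assumes:
#' sibs sharing about half of their heterozygous germline variants, a small
#' planted set of private rare deleterious variants in cancer-panel genes in
#' each affected sib, tumor tables carrying every germline variant plus
#' somatic mutations in realistic class proportions, planted het-to-hom LOH
#' conversions, and log-normal FPKM with planted fold-change effects per
#' expression class. Planted variants are constructed with annotation margins
#' well clear of every default threshold and background variants are
#' constructed to violate at least one, so recovery against the returned
#' truth record is exact by design.
#'
#' @param n_pairs number of sib pairs (default 4).
#' @param seed integer seed; all randomness derives from it.
#' @param n_background_variants background germline variants per pair
#'   (default 5000).
#' @param sib_share_prob probability a background variant is carried by both
#'   sibs (default 0.5; unshared variants go to one sib at random).
#' @param n_private_deleterious planted signature size per case: a fixed
#'   integer, or `NULL` to draw Poisson with mean `private_mean`.
#' @param private_mean Poisson mean for the planted signature size
#'   (default 10).
#' @param somatic_class_weights relative proportions of missense /
#'   frameshift-indel / nonsense among coding somatic mutations
#'   (default 1092:374:43).
#' @param somatic_noncoding_frac fraction of somatic mutations outside coding
#'   regions (default 0.41).
#' @param n_somatic somatic mutations per tumor (default 2568).
#' @param n_loh planted het-to-hom LOH conversions per cohort (default 9);
#'   must not exceed the total planted signature size.
#' @param tumor_purity tumor cell fraction used only to scale the expected
#'   LOH allele fraction (default 1).
#' @param planted_fold linear fold change planted for non-null expression
#'   classes (default 4).
#' @param n_controls control-normal group size (default 5).
#' @param sigma log2-scale FPKM noise standard deviation (default 0.25; 0
#'   disables noise).
#' @param expr_class_weights sampling weights of the planted expression class
#'   for signature genes (default 8:3:5:24 for
#'   TUMOR_DOWN/TUMOR_UP/BOTH_DOWN/NO_CHANGE).
#' @param n_de_up,n_de_down,n_null_genes additional genome-wide genes with
#'   planted up/down/no differential expression (defaults 50/40/910).
#' @param panel_genes cancer-panel gene symbols the planted signature is
#'   drawn from (default 100 synthetic symbols `CPG001`...).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 4, seed = 1,
                              n_background_variants = 5000,
                              sib_share_prob = 0.5,
                              n_private_deleterious = 10,
                              private_mean = 10,
                              somatic_class_weights = c(missense = 1092,
                                                        frameshift_indel = 374,
                                                        nonsense = 43),
                              somatic_noncoding_frac = 0.41,
                              n_somatic = 2568,
                              n_loh = 9,
                              tumor_purity = 1,
                              planted_fold = 4,
                              n_controls = 5,
                              sigma = 0.25,
                              expr_class_weights = c(TUMOR_DOWN = 8, TUMOR_UP = 3,
                                                     BOTH_DOWN = 5, NO_CHANGE = 24),
                              n_de_up = 50, n_de_down = 40, n_null_genes = 910,
                              panel_genes = sprintf("CPG%03d", 1:100)) {
  stopifnot(n_pairs >= 1, n_background_variants >= 0,
            sib_share_prob >= 0, sib_share_prob <= 1,
            all(somatic_class_weights > 0),
            somatic_noncoding_frac >= 0, somatic_noncoding_frac < 1,
            n_somatic >= 0, n_loh >= 0,
            tumor_purity > 0, tumor_purity <= 1,
            planted_fold > 1, n_controls >= 2, sigma >= 0,
            all(expr_class_weights >= 0), length(panel_genes) >= 1)
  if (!is.null(n_private_deleterious) && n_private_deleterious < 0) {
    stop("n_private_deleterious must be >= 0")
  }
  if (!is.null(n_private_deleterious) &&
      n_loh > n_private_deleterious * n_pairs) {
    stop("n_loh exceeds the total planted signature size")
  }
  structure(as.list(environment()), class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a sib-pair cohort with planted ground truth
#'
#' Deterministic given `cfg$seed`. See [simulation_config()] for what is
#' emulated. The returned truth record carries every planted fact the other
#' modules can be tested against: signature keys per case, somatic keys and
#' classes per case, LOH keys, and per-gene expression class / DE direction.
#'
#' @param cfg a [simulation_config()].
#' @return list with `cohort` (list of [sib_pair()]), `profiles` (expression
#'   profiles, significance unfilled), `truth` (list: `signature` tibble with
#'   `case_id`, `key`, `gene`; `background` tibble with `key`, `shared`,
#'   `carrier`; `somatic` tibble with `case_id`, `key`, `consequence`;
#'   `loh_keys`; `expression_class` named vector; `de_direction` named
#'   vector), and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  n_sig <- if (is.null(cfg$n_private_deleterious)) {
    pmax(1L, rpois(cfg$n_pairs, cfg$private_mean))
  } else {
    rep(as.integer(cfg$n_private_deleterious), cfg$n_pairs)
  }
  if (cfg$n_loh > sum(n_sig)) {
    stop("n_loh exceeds the planted signature size (", sum(n_sig), ")")
  }
  case_ids <- sprintf("case%d", seq_len(cfg$n_pairs))
  bg_gene_pool <- sprintf("BG%04d", 1:2000)

  sig_rows <- list(); bg_truth <- list()
  pairs_data <- vector("list", cfg$n_pairs)
  for (p in seq_len(cfg$n_pairs)) {
    planted <- make_planted(cfg, p, n_sig[p])
    bg <- make_background(cfg, p, bg_gene_pool)
    affected <- as_variant_table(dplyr::bind_rows(
      planted, bg$tab[bg$carrier %in% c("both", "affected"), , drop = FALSE]
    ))
    unaffected <- as_variant_table(
      bg$tab[bg$carrier %in% c("both", "unaffected"), , drop = FALSE]
    )
    sig_rows[[p]] <- tibble::tibble(
      case_id = case_ids[p],
      key = variant_key(planted),
      gene = planted$gene
    )
    bg_truth[[p]] <- tibble::tibble(
      case_id = case_ids[p],
      key = variant_key(bg$tab),
      shared = bg$carrier == "both",
      carrier = bg$carrier
    )
    pairs_data[[p]] <- list(affected = affected, unaffected = unaffected)
  }
  signature <- dplyr::bind_rows(sig_rows)

  # cohort-wide LOH draw over planted signature variants
  loh_keys <- if (cfg$n_loh > 0) {
    sample(signature$key, cfg$n_loh)
  } else character(0)

  somatic_rows <- list()
  cohort <- vector("list", cfg$n_pairs)
  for (p in seq_len(cfg$n_pairs)) {
    germ <- pairs_data[[p]]$affected
    is_loh <- variant_key(germ) %in% loh_keys
    # with normal-cell contamination the expected LOH allele fraction is
    # purity * 1 + (1 - purity) * 0.5; the recorded genotype state mimics a
    # caller that labels hom_alt only at allele fractions >= 0.9
    loh_af <- cfg$tumor_purity * 1 + (1 - cfg$tumor_purity) * 0.5
    tum_germ <- germ
    tum_germ$gt <- ifelse(is_loh & loh_af >= 0.9, "hom_alt", "het")
    dp <- tum_germ$depth
    alt <- ifelse(is_loh, round(dp * loh_af), round(dp * 0.5))
    tum_germ$alt_depth <- as.integer(alt)
    tum_germ$ref_depth <- as.integer(dp - alt)
    som <- make_somatic(cfg, p, bg_gene_pool)
    somatic_rows[[p]] <- tibble::tibble(
      case_id = case_ids[p],
      key = variant_key(som),
      consequence = som$consequence
    )
    tumor <- as_variant_table(dplyr::bind_rows(tum_germ, som))
    cohort[[p]] <- sib_pair(case_ids[p], pairs_data[[p]]$affected,
                            pairs_data[[p]]$unaffected, tumor)
  }

  expr <- make_expression(cfg, unique(signature$gene))
  truth <- list(
    signature = signature,
    background = dplyr::bind_rows(bg_truth),
    somatic = dplyr::bind_rows(somatic_rows),
    loh_keys = loh_keys,
    expression_class = expr$class,
    de_direction = expr$de_direction
  )
  list(cohort = cohort, profiles = expr$profiles, truth = truth, config = cfg)
}

# Planted signature variants for pair p: rare (or unreported), high CADD,
# MetaSVM D, mixed consequence classes, heterozygous, well covered; every
# default threshold is passed with margin.
make_planted <- function(cfg, p, n) {
  if (n == 0) {
    return(as_variant_table(tibble::tibble(
      chrom = character(0), pos = integer(0), ref = character(0), alt = character(0)
    )))
  }
  genes <- sample(cfg$panel_genes, n, replace = n > length(cfg$panel_genes))
  cons <- sample(c("nonsynonymous_snv", "frameshift_indel", "nonsense"),
                 n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  dp <- sample(30:60, n, replace = TRUE)
  ad <- as.integer(round(dp * runif(n, 0.4, 0.6)))
  tibble::tibble(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = 5000000L + p * 100000L + seq_len(n),
    ref = ref, alt = unname(alt), gene = genes, consequence = cons,
    maf = ifelse(runif(n) < 0.3, NA_real_, runif(n, 0, 0.005)),
    cadd_phred = ifelse(cons == "nonsynonymous_snv", runif(n, 25, 40), NA_real_),
    metasvm = ifelse(cons == "nonsynonymous_snv", "D", NA_character_),
    clinsig = NA_character_,
    gt = "het", alt_depth = ad, ref_depth = dp - ad, depth = dp
  )
}

# Background variants for pair p. Each is shared by both sibs with
# probability sib_share_prob, otherwise carried by one sib at random, and is
# constructed to fail at least one cascade stage: off-panel genes fail the
# panel stage, and a sampled violation mode additionally exercises the
# earlier stages (a fifth of the violating variants sit in panel genes so
# that failure happens before the panel stage).
make_background <- function(cfg, p, bg_gene_pool) {
  n <- cfg$n_background_variants
  if (n == 0) {
    return(list(tab = as_variant_table(tibble::tibble(
      chrom = character(0), pos = integer(0), ref = character(0), alt = character(0)
    )), carrier = character(0)))
  }
  shared <- runif(n) < cfg$sib_share_prob
  carrier <- ifelse(shared, "both",
                    ifelse(runif(n) < 0.5, "affected", "unaffected"))
  mode <- sample(c("common_maf", "benign", "low_score", "synonymous",
                   "noncoding", "low_depth", "off_panel_only"),
                 n, replace = TRUE,
                 prob = c(0.15, 0.1, 0.2, 0.15, 0.1, 0.1, 0.2))
  in_panel <- mode != "off_panel_only" & runif(n) < 0.2
  gene <- ifelse(in_panel,
                 sample(cfg$panel_genes, n, replace = TRUE),
                 sample(bg_gene_pool, n, replace = TRUE))
  cons <- rep("nonsynonymous_snv", n)
  cons[mode == "synonymous"] <- "synonymous"
  cons[mode == "noncoding"] <- "noncoding"
  maf <- runif(n, 0, 0.005)
  maf[mode == "common_maf"] <- runif(sum(mode == "common_maf"), 0.02, 0.5)
  cadd <- runif(n, 25, 40)
  cadd[mode == "low_score"] <- runif(sum(mode == "low_score"), 0, 15)
  svm <- rep("D", n)
  svm[mode == "low_score"] <- "T"
  clinsig <- rep(NA_character_, n)
  clinsig[mode == "benign"] <- sample(c("benign", "likely_benign"),
                                      sum(mode == "benign"), replace = TRUE)
  dp <- sample(25:60, n, replace = TRUE)
  dp[mode == "low_depth"] <- sample(1:8, sum(mode == "low_depth"), replace = TRUE)
  ad <- as.integer(round(dp * 0.5))
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  tab <- tibble::tibble(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = 10000000L + p * 1000000L + seq_len(n),
    ref = ref, alt = unname(alt), gene = gene, consequence = cons,
    maf = maf, cadd_phred = cadd, metasvm = svm, clinsig = clinsig,
    gt = "het", alt_depth = ad, ref_depth = dp - ad, depth = dp
  )
  list(tab = tab, carrier = carrier)
}

# Somatic mutations for tumor p: a noncoding fraction plus coding classes in
# the configured proportions; keys are disjoint from all germline ranges.
make_somatic <- function(cfg, p, bg_gene_pool) {
  n <- cfg$n_somatic
  if (n == 0) {
    return(tibble::tibble(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), gene = character(0), consequence = character(0),
      maf = numeric(0), cadd_phred = numeric(0), metasvm = character(0),
      clinsig = character(0), gt = character(0), alt_depth = integer(0),
      ref_depth = integer(0), depth = integer(0)
    ))
  }
  noncoding <- runif(n) < cfg$somatic_noncoding_frac
  w <- cfg$somatic_class_weights / sum(cfg$somatic_class_weights)
  coding_class <- sample(c("nonsynonymous_snv", "frameshift_indel", "nonsense"),
                         n, replace = TRUE, prob = w)
  cons <- ifelse(noncoding, "noncoding", coding_class)
  dp <- sample(20:80, n, replace = TRUE)
  af <- runif(n, 0.1, 0.6)
  ad <- as.integer(round(dp * af))
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  tibble::tibble(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = 100000000L + p * 1000000L + seq_len(n),
    ref = ref, alt = unname(alt),
    gene = sample(bg_gene_pool, n, replace = TRUE),
    consequence = cons,
    maf = NA_real_, cadd_phred = NA_real_, metasvm = NA_character_,
    clinsig = NA_character_, gt = "het",
    alt_depth = ad, ref_depth = dp - ad, depth = dp
  )
}

# FPKM profiles: log-normal noise around class-specific means. Signature
# genes carry a planted class sampled with expr_class_weights; additional
# genes carry planted genome-wide DE (up/down) or none.
make_expression <- function(cfg, signature_genes) {
  classes <- sample(names(cfg$expr_class_weights),
                    length(signature_genes), replace = TRUE,
                    prob = cfg$expr_class_weights / sum(cfg$expr_class_weights))
  names(classes) <- signature_genes
  de_up <- if (cfg$n_de_up > 0) sprintf("DEU%04d", seq_len(cfg$n_de_up)) else character(0)
  de_down <- if (cfg$n_de_down > 0) sprintf("DED%04d", seq_len(cfg$n_de_down)) else character(0)
  nulls <- if (cfg$n_null_genes > 0) sprintf("NUL%04d", seq_len(cfg$n_null_genes)) else character(0)
  de_direction <- c(
    setNames(rep("up", length(de_up)), de_up),
    setNames(rep("down", length(de_down)), de_down),
    setNames(rep("none", length(nulls)), nulls)
  )
  genes <- c(signature_genes, de_up, de_down, nulls)
  n <- length(genes)
  mu <- 2^runif(n, 3, 6)
  fold <- cfg$planted_fold
  t_mu <- mu; n_mu <- mu
  cl <- c(classes, setNames(rep(NA_character_, n - length(classes)),
                            genes[-seq_along(classes)]))
  for (i in seq_len(n)) {
    g <- genes[i]
    eff <- if (!is.na(cl[i])) cl[i] else switch(de_direction[[g]] %||% "none",
                                                up = "TUMOR_UP",
                                                down = "TUMOR_DOWN",
                                                none = "NO_CHANGE")
    if (i <= length(classes)) eff <- classes[i]
    if (eff == "TUMOR_DOWN") t_mu[i] <- mu[i] / fold
    if (eff == "TUMOR_UP") t_mu[i] <- mu[i] * fold
    if (eff == "BOTH_DOWN") { t_mu[i] <- mu[i] / fold; n_mu[i] <- mu[i] / fold }
  }
  noisy <- function(m, k = 1) 2^rnorm(k, log2(m), cfg$sigma)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cvals <- vapply(seq_len(cfg$n_controls), function(j) noisy(mu[i]), numeric(1))
    rows[[i]] <- tibble::tibble(
      gene = genes[i],
      fpkm_t = noisy(t_mu[i]),
      fpkm_n = noisy(n_mu[i]),
      fpkm_c = list(cvals),
      fpkm_c_mean = mean(cvals),
      p_t_vs_n = NA_real_, p_n_vs_c = NA_real_, p_t_vs_c = NA_real_
    )
  }
  list(
    profiles = dplyr::bind_rows(rows),
    class = classes,
    de_direction = de_direction
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write the expression profiles in the long TSV format
#'
#' Inverse of [read_expression_table()]: emits one row per (gene, sample)
#' with roles `T`, `N` and `C1..Ck`.
#'
#' @param profiles expression-profile tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(profiles, path) {
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    cvals <- profiles$fpkm_c[[i]]
    tibble::tibble(
      gene = profiles$gene[i],
      sample = c("T", "N", paste0("C", seq_along(cvals))),
      role = c("T", "N", rep("C", length(cvals))),
      fpkm = c(profiles$fpkm_t[i], profiles$fpkm_n[i], cvals)
    )
  })
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits, per subject, the germline variant tables in both the TSV and VCF
#' dialects, plus one tumor table per case, the expression table, the truth
#' record as JSON, and a manifest with MD5 checksums.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return tibble manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.tsv`.
#' @export
emit_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (pair in sim$cohort) {
    id <- pair$case_id
    for (role in c("affected", "unaffected", "tumor")) {
      tab <- pair[[role]]
      if (is.null(tab)) next
      tsv <- file.path(dir, sprintf("%s_%s.tsv", id, role))
      vcf <- file.path(dir, sprintf("%s_%s.vcf", id, role))
      write_variant_table(tab, tsv, dialect = "tsv")
      write_variant_table(tab, vcf, dialect = "vcf",
                          sample_name = paste0(id, "_", role))
      written <- c(written, tsv, vcf)
    }
  }
  expr_path <- file.path(dir, "expression.tsv")
  write_expression_table(sim$profiles, expr_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(
      signature = sim$truth$signature,
      loh_keys = sim$truth$loh_keys,
      somatic = sim$truth$somatic,
      expression_class = as.list(sim$truth$expression_class),
      de_direction = as.list(sim$truth$de_direction)
    ),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  written <- c(written, expr_path, truth_path)
  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
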