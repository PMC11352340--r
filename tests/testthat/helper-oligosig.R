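# Shared test fixtures, built in code.

# A minimal variant-table row with passing annotations; override any field.
vt_row <- function(chrom = "1", pos = 100L, ref = "C", alt = "T",
                   gene = "GENE1", consequence = "nonsynonymous_snv",
                   maf = 0.001, cadd_phred = 30, metasvm = "D",
                   clinsig = NA_character_, gt = "het",
                   alt_depth = 10L, ref_depth = 10L, depth = 20L) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
    consequence = consequence, maf = maf, cadd_phred = cadd_phred,
    metasvm = metasvm, clinsig = clinsig, gt = gt,
    alt_depth = as.integer(alt_depth), ref_depth = as.integer(ref_depth),
    depth = as.integer(depth)
  )
}

vt <- function(...) as_variant_table(dplyr::bind_rows(...))

# Small, fast simulation settings for unit tests.
small_sim_config <- function(seed = 42, ...) {
  args <- list(
    n_pairs = 2, seed = seed, n_background_variants = 200,
    n_somatic = 150, n_loh = 4, n_de_up = 10, n_de_down = 10,
    n_null_genes = 40
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# Random annotated variant table for property tests (deterministic given a
# pre-set RNG state); covers passing and failing values of every filter.
random_variant_table <- function(n, panel) {
  bases <- c("A", "C", "G", "T")
  dp <- sample(5:40, n, replace = TRUE)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tibble::tibble(
    chrom = as.character(sample(1:5, n, replace = TRUE)),
    pos = sample.int(1e6, n),
    ref = ref, alt = unname(alt),
    gene = sample(c(panel, paste0("OFF", 1:10)), n, replace = TRUE),
    consequence = sample(c("nonsynonymous_snv", "frameshift_indel", "nonsense",
                           "synonymous", "other_exonic", "noncoding"),
                         n, replace = TRUE),
    maf = ifelse(runif(n) < 0.3, NA_real_, runif(n)^3),
    cadd_phred = ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 45)),
    metasvm = sample(c("D", "T", NA_character_), n, replace = TRUE),
    clinsig = sample(c("benign", "likely_benign", "other", NA_character_),
                     n, replace = TRUE),
    gt = sample(c("het", "hom_alt"), n, replace = TRUE),
    alt_depth = as.integer(dp %/% 2), ref_depth = as.integer(dp - dp %/% 2),
    depth = as.integer(dp)
  )
}
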