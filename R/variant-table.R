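#' @title Variant tables
#' @description
#' A variant table is a tibble with one row per (subject, site, alt allele)
#' holding an annotated variant call. Missing annotations are `NA` ("absent"),
#' never 0: an unreported population frequency must remain distinguishable
#' from a rare one.
#'
#' Columns:
#' \describe{
#'   \item{chrom}{chromosome name (character)}
#'   \item{pos}{1-based position (integer, VCF convention)}
#'   \item{ref, alt}{reference / alternate allele (character, `ref != alt`)}
#'   \item{gene}{gene symbol}
#'   \item{consequence}{one of `nonsynonymous_snv`, `frameshift_indel`,
#'     `nonsense`, `synonymous`, `other_exonic`, `noncoding`}
#'   \item{maf}{population minor allele frequency in \[0,1\] or `NA`}
#'   \item{cadd_phred}{CADD scaled deleteriousness score (>= 0) or `NA`}
#'   \item{metasvm}{MetaSVM call, `"D"` (damaging), `"T"` (tolerated) or `NA`}
#'   \item{clinsig}{`"benign"`, `"likely_benign"`, `"other"` or `NA`}
#'   \item{gt}{genotype state: `hom_ref`, `het`, `hom_alt`, `missing`}
#'   \item{alt_depth, ref_depth}{reads supporting alt / ref (integer >= 0)}
#'   \item{depth}{total read depth (integer >= 0, `alt_depth + ref_depth <= depth`)}
#' }
#' @name variant_table
NULL

CONSEQUENCE_LEVELS <- c(
  "nonsynonymous_snv", "frameshift_indel", "nonsense",
  "synonymous", "other_exonic", "noncoding"
)
EXONIC_CONSEQUENCES <- c(
  "nonsynonymous_snv", "frameshift_indel", "nonsense",
  "synonymous", "other_exonic"
)
TRUNCATING_CONSEQUENCES <- c("frameshift_indel", "nonsense")
GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

VARIANT_COLUMNS <- c(
  "chrom", "pos", "ref", "alt", "gene", "consequence", "maf", "cadd_phred",
  "metasvm", "clinsig", "gt", "alt_depth", "ref_depth", "depth"
)

#' Construct a variant table
#'
#' Coerces a data frame to the canonical variant-table column set and types,
#' left-normalizes indel alleles, and validates the invariants documented in
#' [variant_table].
#'
#' @param x data frame with at least the coordinate, allele and genotype
#'   columns; missing annotation columns are filled with `NA`.
#' @param normalize left-normalize indel representations (trim shared allele
#'   suffix, then shared prefix beyond the anchor base, adjusting `pos`).
#' @return a validated tibble (see [variant_table]).
#' @export
as_variant_table <- function(x, normalize = TRUE) {
  x <- tibble::as_tibble(x)
  for (col in VARIANT_COLUMNS) {
    if (!col %in% names(x)) {
      x[[col]] <- NA
    }
  }
  x <- x[VARIANT_COLUMNS]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$ref <- toupper(as.character(x$ref))
  x$alt <- toupper(as.character(x$alt))
  x$gene <- as.character(x$gene)
  x$consequence <- as.character(x$consequence)
  x$maf <- as.numeric(x$maf)
  x$cadd_phred <- as.numeric(x$cadd_phred)
  x$metasvm <- as.character(x$metasvm)
  x$clinsig <- as.character(x$clinsig)
  x$gt <- as.character(x$gt)
  x$alt_depth <- as.integer(x$alt_depth)
  x$ref_depth <- as.integer(x$ref_depth)
  x$depth <- as.integer(x$depth)
  if (normalize && nrow(x) > 0) {
    norm <- normalize_alleles(x$pos, x$ref, x$alt)
    x$pos <- norm$pos
    x$ref <- norm$ref
    x$alt <- norm$alt
  }
  validate_variant_table(x)
  x
}

#' Validate a variant table
#'
#' Checks the [variant_table] invariants: positive positions, `ref != alt`,
#' frequencies in \[0,1\], known consequence/genotype/annotation vocabularies,
#' allele depths summing to at most the total depth, and at most one row per
#' variant key.
#'
#' @param x a variant table.
#' @return `x`, invisibly; errors on the first violated invariant.
#' @export
validate_variant_table <- function(x) {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) {
    return(invisible(x))
  }
  if (anyNA(x$pos) || any(x$pos < 1)) stop("variant table: pos must be >= 1")
  if (any(is.na(x$ref) | is.na(x$alt) | x$ref == x$alt)) {
    stop("variant table: ref and alt must be present and distinct")
  }
  bad_maf <- !is.na(x$maf) & (x$maf < 0 | x$maf > 1)
  if (any(bad_maf)) stop("variant table: maf outside [0,1]")
  bad_cadd <- !is.na(x$cadd_phred) & x$cadd_phred < 0
  if (any(bad_cadd)) stop("variant table: cadd_phred must be >= 0")
  if (!all(is.na(x$consequence) | x$consequence %in% CONSEQUENCE_LEVELS)) {
    stop("variant table: unknown consequence value")
  }
  if (!all(is.na(x$metasvm) | x$metasvm %in% c("D", "T"))) {
    stop("variant table: metasvm must be D, T or NA")
  }
  if (!all(is.na(x$clinsig) | x$clinsig %in% c("benign", "likely_benign", "other"))) {
    stop("variant table: clinsig must be benign, likely_benign, other or NA")
  }
  if (!all(is.na(x$gt) | x$gt %in% GT_LEVELS)) {
    stop("variant table: unknown genotype state")
  }
  ad_known <- !is.na(x$alt_depth) & !is.na(x$ref_depth) & !is.na(x$depth)
  if (any(ad_known & (x$alt_depth + x$ref_depth > x$depth))) {
    stop("variant table: alt_depth + ref_depth exceeds depth")
  }
  if (any(ad_known & (x$alt_depth < 0 | x$ref_depth < 0))) {
    stop("variant table: negative allele depth")
  }
  if (anyDuplicated(variant_key(x)) > 0) {
    stop("variant table: duplicated variant key (chrom, pos, ref, alt)")
  }
  invisible(x)
}

#' Variant keys
#'
#' The identity of a variant is its `(chrom, pos, ref, alt)` tuple, rendered
#' as `"chrom:pos:ref:alt"`. Keys are how tables from different subjects are
#' matched (sib discordance, somatic subtraction, LOH lookup).
#'
#' @param x a variant table.
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(x) {
  if (nrow(x) == 0) return(character(0))
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Allele fraction of the alternate allele
#'
#' Defined only when `alt_depth + ref_depth > 0`; `NA` otherwise.
#'
#' @param x a variant table.
#' @return numeric vector in \[0,1\] (or `NA`).
#' @export
allele_fraction <- function(x) {
  denom <- x$alt_depth + x$ref_depth
  ifelse(!is.na(denom) & denom > 0, x$alt_depth / denom, NA_real_)
}

# Left-normalization: trim shared trailing bases while both alleles keep at
# least one base, then shared leading bases beyond the anchor, shifting pos.
normalize_alleles <- function(pos, ref, alt) {
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    if (is.na(r) || is.na(a) || (nchar(r) == 1L && nchar(a) == 1L)) next
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Default VCF INFO key mapping for annotations
#'
#' Annotation INFO keys are not standardized across annotators, so the VCF
#' reader takes a mapping from canonical column names to INFO keys. These are
#' the defaults, matching the dialect written by [write_variant_table()].
#'
#' @return named character vector mapping canonical names to INFO keys.
#' @export
default_vcf_keys <- function() {
  c(
    gene = "GENE", consequence = "CONSEQ", maf = "MAF",
    cadd_phred = "CADD_PHRED", metasvm = "METASVM", clinsig = "CLNSIG"
  )
}

#' Read a variant table from VCF or TSV
#'
#' For `dialect = "vcf"` a single-sample VCF 4.x file is read (via
#' \pkg{vcfR}); annotations are pulled from INFO fields named by `keys`,
#' genotype state from the sample `GT`, allele depths from `AD`, total depth
#' from `DP`. Multi-allelic sites are decomposed into one record per alt
#' allele. For `dialect = "tsv"` the documented tab-separated dialect with a
#' header row carrying the [variant_table] column names is read; missing
#' values are encoded as `.` or empty.
#'
#' @param path file path.
#' @param dialect `"vcf"` or `"tsv"`; default guesses from the extension.
#' @param keys INFO key mapping for VCF annotations, see [default_vcf_keys()].
#' @return a validated variant table.
#' @export
read_variant_table <- function(path, dialect = c("auto", "vcf", "tsv"),
                               keys = default_vcf_keys()) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
    vcf = read_variant_vcf(path, keys),
    tsv = read_variant_tsv(path)
  )
}

read_variant_tsv <- function(path) {
  # base read.delim: its double parsing is correctly rounded, so the TSV
  # dialect round-trips doubles exactly
  x <- utils::read.delim(
    path,
    na.strings = c("", ".", "NA"),
    colClasses = c(
      chrom = "character", pos = "integer", ref = "character",
      alt = "character", gene = "character", consequence = "character",
      maf = "numeric", cadd_phred = "numeric", metasvm = "character",
      clinsig = "character", gt = "character", alt_depth = "integer",
      ref_depth = "integer", depth = "integer"
    ),
    stringsAsFactors = FALSE
  )
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(VARIANT_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("malformed variant TSV ", path, ": missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  as_variant_table(x)
}

read_variant_vcf <- function(path, keys = default_vcf_keys()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(as_variant_table(tibble::tibble(
      chrom = character(0), pos = integer(0), ref = character(0), alt = character(0)
    )))
  }
  gt_raw <- if (ncol(vcf@gt) >= 2) {
    vcfR::extract.gt(vcf, element = "GT")[, 1]
  } else rep(NA_character_, nrow(fix))
  ad_raw <- if (ncol(vcf@gt) >= 2) {
    vcfR::extract.gt(vcf, element = "AD")[, 1]
  } else rep(NA_character_, nrow(fix))
  dp_raw <- if (ncol(vcf@gt) >= 2) {
    suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1]))
  } else rep(NA_integer_, nrow(fix))

  info_get <- function(key) {
    if (is.na(key)) return(rep(NA_character_, nrow(fix)))
    vals <- vcfR::extract.info(vcf, element = key)
    as.character(vals)
  }
  gene <- info_get(keys[["gene"]])
  conseq <- info_get(keys[["consequence"]])
  maf <- suppressWarnings(as.numeric(info_get(keys[["maf"]])))
  cadd <- suppressWarnings(as.numeric(info_get(keys[["cadd_phred"]])))
  metasvm <- info_get(keys[["metasvm"]])
  clinsig <- info_get(keys[["clinsig"]])

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad <- if (!is.na(ad_raw[i])) {
      suppressWarnings(as.integer(strsplit(ad_raw[i], ",", fixed = TRUE)[[1]]))
    } else NULL
    gt_alleles <- if (!is.na(gt_raw[i])) {
      strsplit(gt_raw[i], "[/|]")[[1]]
    } else NULL
    sub <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      state <- NA_character_
      if (!is.null(gt_alleles)) {
        if (any(gt_alleles == ".")) {
          state <- "missing"
        } else {
          n_alt <- sum(gt_alleles == as.character(j))
          state <- if (n_alt == 2) "hom_alt" else if (n_alt == 1) "het" else "hom_ref"
        }
      }
      sub[[j]] <- tibble::tibble(
        chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i],
        alt = alts[j],
        gene = gene[i],
        consequence = conseq[i],
        maf = maf[i],
        cadd_phred = cadd[i],
        metasvm = metasvm[i],
        clinsig = clinsig[i],
        gt = state,
        alt_depth = if (!is.null(ad) && length(ad) >= j + 1) ad[j + 1] else NA_integer_,
        ref_depth = if (!is.null(ad) && length(ad) >= 1) ad[1] else NA_integer_,
        depth = dp_raw[i]
      )
    }
    rows[[i]] <- dplyr::bind_rows(sub)
  }
  as_variant_table(dplyr::bind_rows(rows))
}

#' Write a variant table
#'
#' `dialect = "tsv"` writes the documented TSV dialect (missing values as
#' `.`), which round-trips through [read_variant_table()] preserving every
#' populated field. `dialect = "vcf"` writes a minimal single-sample VCF 4.2
#' with annotations in INFO fields named by [default_vcf_keys()] and genotype
#' as `GT:AD:DP`.
#'
#' @param x a variant table.
#' @param path output file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample_name sample column name used for the VCF dialect.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path, dialect = c("tsv", "vcf"),
                                sample_name = "SAMPLE") {
  dialect <- match.arg(dialect)
  validate_variant_table(x)
  if (dialect == "tsv") {
    out <- x
    fmt <- function(v) {
      s <- if (is.double(v)) sprintf("%.17g", v) else as.character(v)
      ifelse(is.na(v), ".", s)
    }
    out[] <- lapply(out, fmt)
    readr::write_tsv(out, path)
    return(invisible(path))
  }
  keys <- default_vcf_keys()
  info_field <- function(key, v) {
    s <- if (is.double(v)) sprintf("%.17g", v) else as.character(v)
    ifelse(is.na(v), NA, paste0(key, "=", s))
  }
  info <- apply(cbind(
    info_field(keys[["gene"]], x$gene),
    info_field(keys[["consequence"]], x$consequence),
    info_field(keys[["maf"]], x$maf),
    info_field(keys[["cadd_phred"]], x$cadd_phred),
    info_field(keys[["metasvm"]], x$metasvm),
    info_field(keys[["clinsig"]], x$clinsig)
  ), 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) "." else paste(r, collapse = ";")
  })
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  gt <- ifelse(is.na(x$gt), "./.", gt_code[x$gt])
  ad <- ifelse(is.na(x$ref_depth) | is.na(x$alt_depth), ".",
               paste(x$ref_depth, x$alt_depth, sep = ","))
  dp <- ifelse(is.na(x$depth), ".", as.character(x$depth))
  body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", info,
                "GT:AD:DP", paste(gt, ad, dp, sep = ":"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oligosig",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", keys[["gene"]]),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence class\">", keys[["consequence"]]),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Population minor allele frequency\">", keys[["maf"]]),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"CADD scaled score\">", keys[["cadd_phred"]]),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"MetaSVM call (D/T)\">", keys[["metasvm"]]),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Clinical significance\">", keys[["clinsig"]]),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
  writeLines(c(header, body), path)
  invisible(path)
}
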