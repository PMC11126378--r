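# Multi-sample VCF and sidecar readers/writers.

#' Read a multi-sample VCF into a cohort genotype table
#'
#' Parses GT fields of a VCF v4.2 (via \pkg{vcfR}), restricts records to a
#' window around the index variant, splits multi-allelic records, and maps
#' genotypes to zygosity codes. Missingness is coverage-aware: a `./.` call is
#' `MISSING` for an `EXOME` sample (unless a callable-regions file covers the
#' position, in which case it is callably `HOM_REF`) and `HOM_REF` for a
#' `GENOME` sample, where absence of a call is definite reference evidence.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF with GT fields for
#'   all declared samples.
#' @param index One-row variant `data.frame` ([genomic_variant()]): the index
#'   variant.
#' @param sample_meta Roles sidecar ([sample_roles()] or [read_roles()]):
#'   `sample_id` and `coverage_class` per sample; every sample must appear in
#'   the VCF header.
#' @param window_bp Half-window: records farther than this from the index are
#'   dropped (default 5,000,000 bp on each side).
#' @param callable_bed Optional named list (by sample id) of BED file paths
#'   (0-based half-open) giving each exome sample's callable intervals.
#' @return A [cohort_table()] object.
#' @export
read_cohort_vcf <- function(path, index, sample_meta,
                            window_bp = 5e6, callable_bed = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF has no records: ", path, call. = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  missing_samples <- setdiff(sample_meta$sample_id, colnames(gt_raw))
  if (length(missing_samples) > 0L) {
    stop("sample in sidecar absent from VCF header: ", missing_samples[1L],
         call. = FALSE)
  }
  gt_raw <- gt_raw[, sample_meta$sample_id, drop = FALSE]
  fix$POS <- as.integer(fix$POS)
  fix$CHROM <- canonical_chrom(fix$CHROM)
  chrom0 <- canonical_chrom(index$chrom[1L])
  for (ch in unique(fix$CHROM)) {
    p <- fix$POS[fix$CHROM == ch]
    if (is.unsorted(p)) stop("unsorted VCF: positions decrease on chr", ch,
                             call. = FALSE)
  }
  keep <- fix$CHROM == chrom0 & abs(fix$POS - index$pos) <= window_bp
  if (!any(keep)) stop("no VCF records in the analysis window", call. = FALSE)
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]

  variants <- list()
  genos <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    split <- normalize_variant(fix$CHROM[i], fix$POS[i], fix$REF[i], alts,
                               vid = ifelse(fix$ID[i] %in% c(".", NA), NA, fix$ID[i]))
    for (k in seq_along(alts)) {
      variants[[length(variants) + 1L]] <- split[k, , drop = FALSE]
      genos[[length(genos) + 1L]] <- vapply(gt_raw[i, ], gt_to_zygosity,
                                            character(1L), alt_index = k)
    }
  }
  variants <- do.call(rbind, variants)
  geno <- do.call(rbind, genos)
  colnames(geno) <- sample_meta$sample_id

  # coverage-aware missingness
  for (j in seq_len(nrow(sample_meta))) {
    sid <- sample_meta$sample_id[j]
    miss <- geno[, sid] == "MISSING"
    if (!any(miss)) next
    if (sample_meta$coverage_class[j] == "GENOME") {
      geno[miss, sid] <- "HOM_REF"
    } else if (!is.null(callable_bed) && !is.null(callable_bed[[sid]])) {
      iv <- read_callable_bed(callable_bed[[sid]], chrom = chrom0)
      callable <- vapply(variants$pos, function(p) {
        any(p > iv$start & p <= iv$end)
      }, logical(1L))
      geno[miss & callable, sid] <- "HOM_REF"
    }
  }
  cohort_table(variants, sample_meta, geno, index)
}

# Map one GT string to a zygosity code for the alt allele with 1-based VCF
# index alt_index; other alt alleles count as reference for this record.
gt_to_zygosity <- function(gt, alt_index = 1L) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("MISSING")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("MISSING")
  n_alt <- sum(alleles == as.character(alt_index))
  c("HOM_REF", "HET", "HOM_ALT")[n_alt + 1L]
}

zygosity_to_gt <- function(z) {
  c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")[z]
}

#' Write a cohort genotype table as a VCF v4.2 text file
#'
#' Emits a minimal GT-only multi-sample VCF. Reading the file back with
#' [read_cohort_vcf()] reproduces the genotype matrix up to the documented
#' coverage-aware missingness mapping (a `GENOME` sample's `MISSING` becomes
#' `HOM_REF`); a read - write - read cycle is a fixed point.
#'
#' @param table A [cohort_table()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(table, path) {
  stopifnot(inherits(table, "cohort_gt"))
  v <- table$variants
  gt <- apply(table$genotypes, 2L, zygosity_to_gt)
  if (nrow(v) == 1L) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, table$samples$sample_id))
  header <- c("##fileformat=VCFv4.2",
              "##source=founderseg",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", table$samples$sample_id), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], ifelse(is.na(v$vid[i]), ".", v$vid[i]),
            v$ref[i], v$alt[i], ".", ".", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a roles sidecar TSV
#'
#' Expected columns: `sample_id`, `coverage_class`, and optionally
#' `carrier_class` (usually derived from the index genotypes instead, see
#' [derive_roles()]).
#'
#' @param path Path to the TSV.
#' @return Roles `data.frame` as from [sample_roles()].
#' @export
read_roles <- function(path) {
  if (!file.exists(path)) stop("roles file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "coverage_class")
  if (!all(need %in% names(d))) {
    stop("roles sidecar must have columns sample_id and coverage_class",
         call. = FALSE)
  }
  cc <- if ("carrier_class" %in% names(d)) d$carrier_class else NA_character_
  sample_roles(d$sample_id, carrier_class = cc, coverage_class = d$coverage_class)
}

#' Write a roles sidecar TSV
#' @param roles Roles `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roles <- function(roles, path) {
  utils::write.table(roles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a BED (0-based half-open) restricted to one chromosome.
read_callable_bed <- function(path, chrom = NULL) {
  if (!file.exists(path)) stop("BED not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  d$chrom <- canonical_chrom(d$chrom)
  if (!is.null(chrom)) d <- d[d$chrom == canonical_chrom(chrom), , drop = FALSE]
  d[, c("chrom", "start", "end")]
}
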