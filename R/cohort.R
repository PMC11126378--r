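# CohortGenotypeTable: variants x samples zygosity matrix with an index variant.

#' Construct a cohort genotype table
#'
#' A position-sorted variants-by-samples zygosity matrix on a single
#' chromosome, together with the carrier roles and the index variant around
#' which haplotype sharing is assessed.
#'
#' @param variants `data.frame` of variant records as returned by
#'   [genomic_variant()] (columns `chrom`, `pos`, `ref`, `alt`, `vid`). All
#'   records must lie on the index variant's chromosome. Rows are sorted by
#'   position; several records may share a position (split multi-allelics).
#' @param samples Roles `data.frame` from [sample_roles()]; `carrier_class`
#'   may be `NA` and filled in later with [derive_roles()].
#' @param genotypes Character matrix of zygosity codes (see [ZYGOSITY]) with
#'   one row per variant and one column per sample.
#' @param index_variant One-row variant `data.frame`: the index variant. Must
#'   be present in `variants`, and no sample may be `MISSING` or `HOM_REF`
#'   at it.
#' @return An object of class `cohort_gt`.
#' @export
cohort_table <- function(variants, samples, genotypes, index_variant) {
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  genotypes <- as.matrix(genotypes)
  if (nrow(variants) == 0L) stop("cohort has no variants", call. = FALSE)
  if (nrow(genotypes) != nrow(variants) || ncol(genotypes) != nrow(samples)) {
    stop("genotype matrix dimensions do not match variants x samples", call. = FALSE)
  }
  if (!all(genotypes %in% ZYGOSITY)) {
    stop("unknown zygosity code in genotype matrix", call. = FALSE)
  }
  colnames(genotypes) <- samples$sample_id
  if (length(unique(variants$chrom)) != 1L) {
    stop("all variants must lie on one chromosome", call. = FALSE)
  }
  if (canonical_chrom(index_variant$chrom[1L]) != variants$chrom[1L]) {
    stop("index variant is not on the cohort chromosome", call. = FALSE)
  }
  ord <- order(variants$pos)
  variants <- variants[ord, , drop = FALSE]
  genotypes <- genotypes[ord, , drop = FALSE]
  key <- variant_key(variants)
  if (anyDuplicated(key)) stop("duplicate (pos, ref, alt) variant records", call. = FALSE)
  rownames(variants) <- NULL
  rownames(genotypes) <- key
  obj <- structure(list(variants = variants, samples = samples,
                        genotypes = genotypes,
                        index_variant = index_variant[1L, , drop = FALSE]),
                   class = "cohort_gt")
  ii <- index_row(obj)
  if (is.na(ii)) stop("index variant is absent from the variant list", call. = FALSE)
  gt <- stats::setNames(genotypes[ii, ], colnames(genotypes))
  if (any(gt %in% c("MISSING", "HOM_REF"))) {
    bad <- colnames(genotypes)[gt %in% c("MISSING", "HOM_REF")][1L]
    stop(sprintf("sample %s is %s at the index variant", bad, gt[[bad]]),
         call. = FALSE)
  }
  obj
}

variant_key <- function(v) paste(v$pos, v$ref, v$alt, sep = ":")

index_row <- function(table) {
  iv <- table$index_variant
  m <- which(table$variants$pos == iv$pos & table$variants$ref == iv$ref &
               table$variants$alt == iv$alt)
  if (length(m) == 0L) NA_integer_ else m[1L]
}

index_genotypes <- function(table) {
  stats::setNames(table$genotypes[index_row(table), ],
                  colnames(table$genotypes))
}

#' Restrict a cohort table to a subset of samples
#'
#' @param table A [cohort_table()] object.
#' @param sample_ids Character vector of sample ids to keep (order respected).
#' @return A `cohort_gt` over the chosen samples.
#' @export
subset_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "cohort_gt"))
  miss <- setdiff(sample_ids, table$samples$sample_id)
  if (length(miss) > 0L) stop("unknown sample id: ", miss[1L], call. = FALSE)
  keep <- match(sample_ids, table$samples$sample_id)
  cohort_table(table$variants, table$samples[keep, , drop = FALSE],
               table$genotypes[, keep, drop = FALSE], table$index_variant)
}

#' @export
print.cohort_gt <- function(x, ...) {
  iv <- x$index_variant
  cat(sprintf("Cohort genotype table: %d variants x %d samples on chr%s\n",
              nrow(x$variants), nrow(x$samples), x$variants$chrom[1L]))
  cat(sprintf("  index variant: %s:%d %s>%s\n", iv$chrom, iv$pos, iv$ref, iv$alt))
  zyg <- index_genotypes(x)
  cat("  index zygosity:", paste(sprintf("%s=%s", names(zyg), zyg), collapse = ", "),
      "\n")
  invisible(x)
}
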