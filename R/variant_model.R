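# Domain types: variants, zygosity, carrier roles.

#' Zygosity codes
#'
#' Genotype states used throughout the package. `MISSING` is distinct from
#' `HOM_REF`: `MISSING` means the position was not callable for that sample
#' (e.g. outside exome capture), whereas `HOM_REF` means callably reference.
#'
#' @format Character vector of the four zygosity codes.
#' @export
ZYGOSITY <- c("HOM_REF", "HET", "HOM_ALT", "MISSING")

#' Carrier classes at the index variant
#' @format Character vector of the two carrier classes.
#' @export
CARRIER_CLASSES <- c("HOMOZYGOUS_CARRIER", "HETEROZYGOUS_CARRIER")

#' Coverage classes
#' @format Character vector of the two coverage classes.
#' @export
COVERAGE_CLASSES <- c("GENOME", "EXOME")

#' Construct a genomic variant record
#'
#' One normalized small variant on a 1-based GRCh38 coordinate. Indels are
#' represented with an anchor base and are expected to be left-aligned
#' (see [normalize_variant()]). Chromosome names are canonicalized to the
#' un-prefixed form (`"chr1"` becomes `"1"`).
#'
#' @param chrom Chromosome name, with or without a `"chr"` prefix.
#' @param pos 1-based position of the first reference base.
#' @param ref,alt Reference and alternate allele strings over `{A,C,G,T}`.
#' @param vid Optional variant identifier (dbSNP rs or internal).
#' @return A one-row `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `vid`.
#' @examples
#' genomic_variant("chr1", 21839005, "G", "A", vid = "rs1294413650")
#' @export
genomic_variant <- function(chrom, pos, ref, alt, vid = NA_character_) {
  chrom <- canonical_chrom(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (is.na(pos) || pos < 1L) {
    stop("variant position must be an integer >= 1", call. = FALSE)
  }
  if (!is_acgt(ref) || !is_acgt(alt)) {
    stop(sprintf("malformed alleles at %s:%d (%s>%s): alleles must be non-empty ACGT strings",
                 chrom, pos, ref, alt), call. = FALSE)
  }
  if (identical(ref, alt)) {
    stop(sprintf("ref and alt are identical at %s:%d", chrom, pos), call. = FALSE)
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vid = as.character(vid), stringsAsFactors = FALSE)
}

canonical_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

is_acgt <- function(x) {
  length(x) == 1L && !is.na(x) && nzchar(x) && grepl("^[ACGT]+$", x)
}

#' Normalize a possibly multi-allelic variant record
#'
#' Splits a record with several alternate alleles into one biallelic record
#' per alt, then parsimony-trims and (when reference context is supplied)
#' left-aligns each, following the VCF normalization convention: shared
#' trailing bases are removed (extending to the left through the reference
#' when an allele would empty), then shared leading bases are removed.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position of the first reference base.
#' @param ref Reference allele string.
#' @param alts Character vector of one or more alternate alleles.
#' @param vid Optional identifier carried onto every split record.
#' @param ref_seq Optional reference sequence context as a single string;
#'   required for left-alignment of indels across repeat runs.
#' @param ref_start 1-based genomic position of the first base of `ref_seq`.
#' @return A `data.frame` of normalized biallelic records, one row per alt,
#'   in the input alt order.
#' @examples
#' normalize_variant("1", 100, "A", c("G", "T"))
#' @export
normalize_variant <- function(chrom, pos, ref, alts, vid = NA_character_,
                              ref_seq = NULL, ref_start = 1L) {
  if (length(alts) < 1L) stop("record has no alt allele", call. = FALSE)
  out <- lapply(alts, function(alt) {
    if (!is_acgt(toupper(ref)) || !is_acgt(toupper(alt))) {
      stop(sprintf("malformed alleles in record %s:%s (%s>%s)",
                   chrom, pos, ref, alt), call. = FALSE)
    }
    n <- left_align_allele(as.integer(pos), toupper(ref), toupper(alt),
                           ref_seq = ref_seq, ref_start = as.integer(ref_start))
    genomic_variant(chrom, n$pos, n$ref, n$alt, vid = vid)
  })
  do.call(rbind, out)
}

# Trim + left-align one ref/alt pair. Without ref_seq only parsimony trimming
# is performed (no shifting through repeats).
left_align_allele <- function(pos, ref, alt, ref_seq = NULL, ref_start = 1L) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    shifted <- FALSE
    # drop shared trailing base; if an allele would empty, prepend the
    # reference base preceding pos (requires context)
    while (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)]) {
      if (length(r) == 1L || length(a) == 1L) {
        if (is.null(ref_seq)) break
        i <- pos - 1L - ref_start + 1L
        if (i < 1L || i > nchar(ref_seq)) break
        b <- toupper(substr(ref_seq, i, i))
        r <- c(b, r[-length(r)])
        a <- c(b, a[-length(a)])
        pos <- pos - 1L
        shifted <- TRUE
      } else {
        r <- r[-length(r)]
        a <- a[-length(a)]
      }
    }
    if (!shifted) break
  }
  # drop shared leading bases while both alleles keep an anchor
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Construct sample roles
#'
#' @param sample_id Character vector of sample identifiers.
#' @param carrier_class Carrier class at the index variant
#'   (`"HOMOZYGOUS_CARRIER"` or `"HETEROZYGOUS_CARRIER"`), or `NA` if not yet
#'   derived (see [derive_roles()]).
#' @param coverage_class `"GENOME"` or `"EXOME"` per sample.
#' @return A `data.frame` with columns `sample_id`, `carrier_class`,
#'   `coverage_class`.
#' @export
sample_roles <- function(sample_id, carrier_class = NA_character_,
                         coverage_class = "GENOME") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids", call. = FALSE)
  carrier_class <- rep_len(as.character(carrier_class), length(sample_id))
  coverage_class <- rep_len(as.character(coverage_class), length(sample_id))
  bad <- !is.na(carrier_class) & !carrier_class %in% CARRIER_CLASSES
  if (any(bad)) stop("unknown carrier class: ", carrier_class[bad][1L], call. = FALSE)
  if (!all(coverage_class %in% COVERAGE_CLASSES)) {
    stop("coverage class must be GENOME or EXOME", call. = FALSE)
  }
  data.frame(sample_id = sample_id, carrier_class = carrier_class,
             coverage_class = coverage_class, stringsAsFactors = FALSE)
}

#' Derive carrier roles from zygosity at the index variant
#'
#' Assigns each sample's carrier class from its observed zygosity at the
#' cohort's index variant: `HOM_ALT` samples are homozygous carriers, `HET`
#' samples heterozygous carriers. A sample that is `HOM_REF` or `MISSING` at
#' the index is not a carrier and raises an error naming the sample.
#'
#' @param table A [cohort_table()] object.
#' @return The table's roles `data.frame` with `carrier_class` filled in.
#' @export
derive_roles <- function(table) {
  stopifnot(inherits(table, "cohort_gt"))
  gt <- index_genotypes(table)
  bad <- names(gt)[!gt %in% c("HOM_ALT", "HET")]
  if (length(bad) > 0L) {
    stop(sprintf("sample %s is %s at the index variant and is not a carrier",
                 bad[1L], gt[[bad[1L]]]), call. = FALSE)
  }
  roles <- table$samples
  roles$carrier_class <- ifelse(gt[roles$sample_id] == "HOM_ALT",
                                "HOMOZYGOUS_CARRIER", "HETEROZYGOUS_CARRIER")
  roles
}
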