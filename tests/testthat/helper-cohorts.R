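# Test cohort builders.

ZYG3 <- c("HOM_REF", "HET", "HOM_ALT")

# A random cohort with a valid (consistent) index site and arbitrary genotype
# patterns elsewhere, including MISSING.
random_cohort <- function(n_markers = 100, n_hom = 2, n_het = 3, seed = 1,
                          p_missing = 0.15) {
  set.seed(seed)
  n <- n_hom + n_het
  ids <- sprintf("R%02d", seq_len(n))
  roles <- sample_roles(ids,
                        carrier_class = rep(c("HOMOZYGOUS_CARRIER",
                                              "HETEROZYGOUS_CARRIER"),
                                            c(n_hom, n_het)),
                        coverage_class = "GENOME")
  pos <- sort(sample.int(n_markers * 50L, n_markers))
  i0 <- sample.int(n_markers, 1L)
  geno <- matrix(sample(c(ZYG3, "MISSING"), n_markers * n,
                        prob = c((1 - p_missing) / 3, (1 - p_missing) / 3,
                                 (1 - p_missing) / 3, p_missing),
                        replace = TRUE),
                 nrow = n_markers, dimnames = list(NULL, ids))
  geno[i0, ] <- rep(c("HOM_ALT", "HET"), c(n_hom, n_het))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_markers, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  variants <- do.call(rbind, lapply(seq_len(n_markers), function(i) {
    genomic_variant("1", pos[i], ref[i], alt[i])
  }))
  index <- variants[i0, , drop = FALSE]
  list(table = cohort_table(variants, roles, geno, index), roles = roles)
}

# A tiny hand-built cohort from an explicit zygosity matrix (rows = positions).
build_cohort <- function(pos, geno, roles, index_pos) {
  geno <- as.matrix(geno)
  colnames(geno) <- roles$sample_id
  bases <- c("A", "C", "G", "T")
  variants <- do.call(rbind, lapply(seq_along(pos), function(i) {
    genomic_variant("1", pos[i], "A", "G")
  }))
  index <- variants[match(index_pos, pos), , drop = FALSE]
  cohort_table(variants, roles, geno, index)
}

five_sample_roles <- function() {
  sample_roles(c("P02", "P03", "P04", "P06", "P07"),
               carrier_class = c("HOMOZYGOUS_CARRIER", "HOMOZYGOUS_CARRIER",
                                 "HETEROZYGOUS_CARRIER", "HETEROZYGOUS_CARRIER",
                                 "HETEROZYGOUS_CARRIER"),
               coverage_class = c("GENOME", rep("EXOME", 4)))
}

fixture_cohort <- function() {
  idx <- genomic_variant("1", 21839005, "G", "A")
  roles <- read_roles(fs_extdata("ddrd_roles.tsv"))
  read_cohort_vcf(fs_extdata("ddrd_cohort.vcf"), idx, roles)
}

# The interval a segment is known to live in: delimited by its flanking
# breakers (window edge when absent). This is the quantity incremental
# narrowing shrinks monotonically; the outermost-consistent-site endpoints can
# move outward *within* it as added samples turn uninformative sites
# consistent.
seg_bounds <- function(seg) {
  c(if (is.null(seg$p_breaker)) -Inf else seg$p_breaker$position,
    if (is.null(seg$q_breaker)) Inf else seg$q_breaker$position)
}

random_segment <- function(seed) {
  set.seed(seed)
  start <- sample.int(1e6, 1L)
  end <- start + sample.int(1e5, 1L)
  mk_breaker <- function(p) {
    if (stats::runif(1) < 0.3) NULL
    else list(position = p, sample_id = sample(LETTERS, 1),
              reason = sample(c("HET_IN_HOMOZYGOUS_CARRIER",
                                "ABSENT_IN_HETEROZYGOUS_CARRIER",
                                "HOMOZYGOUS_CONFLICT"), 1))
  }
  structure(list(chrom = "1", start = start, end = end,
                 length_bp = segment_length(start, end),
                 p_breaker = mk_breaker(start - sample.int(1000, 1L)),
                 q_breaker = mk_breaker(end + sample.int(1000, 1L)),
                 supporting_sites = sort(sample(start:end, sample.int(10, 1L))),
                 window = c(start - 5000L, end + 5000L),
                 index_pos = start),
            class = "shared_segment")
}
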