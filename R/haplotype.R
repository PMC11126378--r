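# Founder-segment detection: zygosity-constrained consistency rules, outward
# scan with breaker-delimited margins, incremental narrowing.

#' Classify one site against the shared-haplotype consistency rules
#'
#' Evaluates the rule table, in order:
#' \enumerate{
#'   \item any homozygous carrier `HET` -> `BREAKER` (`HET_IN_HOMOZYGOUS_CARRIER`);
#'   \item two homozygous carriers callably homozygous for different alleles
#'     (one `HOM_ALT`, one `HOM_REF`) -> `BREAKER` (`HOMOZYGOUS_CONFLICT`);
#'   \item the site is *haplotype-defining* iff at least one homozygous
#'     carrier is `HOM_ALT`; if so and any heterozygous carrier is callably
#'     `HOM_REF` -> `BREAKER` (`ABSENT_IN_HETEROZYGOUS_CARRIER`);
#'   \item if haplotype-defining and every non-`MISSING` genotype is
#'     compatible (`HOM_ALT` in homozygous carriers; `HET` or `HOM_ALT` in
#'     heterozygous carriers, under the unphased-heterozygote assumption that
#'     the alt allele rides on the founder allele) -> `CONSISTENT`;
#'   \item otherwise `UNINFORMATIVE` (in particular at sites where the
#'     homozygous carriers are callably reference: the founder haplotype
#'     carries the reference allele there, and alt alleles in heterozygous
#'     carriers may lie on their other chromosome).
#' }
#' One homozygous carrier with `HOM_ALT` suffices to make a site defining when
#' the others are `MISSING` (exome gaps must not erase evidence).
#'
#' @param genotypes Named character vector of zygosity codes, one per sample.
#' @param roles Roles `data.frame` ([sample_roles()]) with `carrier_class` set.
#' @return A list with `status` (`"CONSISTENT"`, `"BREAKER"` or
#'   `"UNINFORMATIVE"`) and, for breakers, `evidence = list(sample_id, reason)`.
#' @export
classify_site <- function(genotypes, roles) {
  if (nrow(roles) == 0L) stop("roles are empty", call. = FALSE)
  if (any(is.na(roles$carrier_class))) {
    stop("carrier_class is not set; run derive_roles() first", call. = FALSE)
  }
  g <- genotypes[roles$sample_id]
  if (anyNA(g)) stop("genotypes missing for a sample in roles", call. = FALSE)
  hom <- roles$sample_id[roles$carrier_class == "HOMOZYGOUS_CARRIER"]
  het <- roles$sample_id[roles$carrier_class == "HETEROZYGOUS_CARRIER"]

  # (a) heterozygosity in a homozygous carrier breaks the shared segment
  hit <- hom[g[hom] == "HET"]
  if (length(hit) > 0L) {
    return(site_status("BREAKER", hit[1L], "HET_IN_HOMOZYGOUS_CARRIER"))
  }
  # (b) callable homozygous carriers disagreeing on the allele
  if (any(g[hom] == "HOM_ALT") && any(g[hom] == "HOM_REF")) {
    hit <- hom[g[hom] == "HOM_REF"][1L]
    return(site_status("BREAKER", hit, "HOMOZYGOUS_CONFLICT"))
  }
  defining <- any(g[hom] == "HOM_ALT")
  # (c) a haplotype-defining allele absent from a callable heterozygous carrier
  if (defining) {
    hit <- het[g[het] == "HOM_REF"]
    if (length(hit) > 0L) {
      return(site_status("BREAKER", hit[1L], "ABSENT_IN_HETEROZYGOUS_CARRIER"))
    }
    # (d) all remaining non-MISSING genotypes are compatible by construction
    return(site_status("CONSISTENT"))
  }
  # (e) not haplotype-defining
  site_status("UNINFORMATIVE")
}

site_status <- function(status, sample_id = NA_character_, reason = NA_character_) {
  list(status = status,
       evidence = if (status == "BREAKER") list(sample_id = sample_id, reason = reason))
}

#' Classify every site of a cohort table
#'
#' @inheritParams detect_segment
#' @return `data.frame` with one row per variant: `pos`, `status`,
#'   `breaker_sample`, `breaker_reason`.
#' @export
classify_sites <- function(table, roles = NULL) {
  stopifnot(inherits(table, "cohort_gt"))
  if (is.null(roles)) roles <- effective_roles(table)
  n <- nrow(table$variants)
  status <- character(n)
  bsample <- rep(NA_character_, n)
  breason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- classify_site(stats::setNames(table$genotypes[i, ],
                                       colnames(table$genotypes)), roles)
    status[i] <- s$status
    if (s$status == "BREAKER") {
      bsample[i] <- s$evidence$sample_id
      breason[i] <- s$evidence$reason
    }
  }
  data.frame(pos = table$variants$pos, status = status,
             breaker_sample = bsample, breaker_reason = breason,
             stringsAsFactors = FALSE)
}

effective_roles <- function(table) {
  roles <- table$samples
  if (any(is.na(roles$carrier_class))) roles <- derive_roles(table)
  roles
}

#' Detect the maximal shared founder segment around the index variant
#'
#' Classifies every site with [classify_site()] and scans outward from the
#' index variant in position order on each side. Uninformative sites are
#' skipped; extension stops at the first breaker per side (recorded as
#' `p_breaker`/`q_breaker`) or at the window edge. The segment endpoints are
#' the outermost consistent sites reached, so flanking breakers lie strictly
#' outside the reported interval. When several records share a position, a
#' breaker at that position wins over a consistent record (conservative
#' truncation).
#'
#' @param table A [cohort_table()] object.
#' @param roles Optional roles `data.frame`; defaults to the table's samples
#'   (with carrier classes derived from the index variant if unset).
#' @param max_uninformative_gap_bp Maximum base-pair gap of uninformative or
#'   absent markers the scan may jump across while extending (default
#'   unlimited; exome data has long uninformative gaps by construction).
#' @return A `shared_segment` object with fields `chrom`, `start`, `end`,
#'   `length_bp`, `p_breaker`, `q_breaker`, `supporting_sites`, `window`,
#'   `index_pos`.
#' @examples
#' fx <- fs_extdata("ddrd_cohort.vcf")
#' roles <- read_roles(fs_extdata("ddrd_roles.tsv"))
#' idx <- genomic_variant("1", 21839005, "G", "A")
#' tab <- read_cohort_vcf(fx, index = idx, sample_meta = roles)
#' detect_segment(tab)
#' @export
detect_segment <- function(table, roles = NULL, max_uninformative_gap_bp = Inf) {
  stopifnot(inherits(table, "cohort_gt"))
  if (is.null(roles)) roles <- effective_roles(table)
  cls <- classify_sites(table, roles)
  # collapse records sharing a position: breaker wins, then consistent
  pos <- sort(unique(cls$pos))
  pstat <- vapply(pos, function(p) {
    st <- cls$status[cls$pos == p]
    if (any(st == "BREAKER")) "BREAKER"
    else if (any(st == "CONSISTENT")) "CONSISTENT"
    else "UNINFORMATIVE"
  }, character(1L))
  idx_pos <- table$index_variant$pos
  i0 <- match(idx_pos, pos)
  if (pstat[i0] != "CONSISTENT") {
    stop(sprintf("index variant classifies %s; malformed cohort", pstat[i0]),
         call. = FALSE)
  }

  scan_side <- function(idx_seq) {
    bound <- idx_pos
    breaker <- NULL
    for (i in idx_seq) {
      if (pstat[i] == "BREAKER") {
        j <- which(cls$pos == pos[i] & cls$status == "BREAKER")[1L]
        breaker <- list(position = pos[i],
                        sample_id = cls$breaker_sample[j],
                        reason = cls$breaker_reason[j])
        break
      }
      if (pstat[i] == "CONSISTENT") {
        if (abs(pos[i] - bound) > max_uninformative_gap_bp) break
        bound <- pos[i]
      }
    }
    list(bound = bound, breaker = breaker)
  }

  left <- scan_side(rev(seq_len(i0 - 1L)))
  right <- scan_side(seq.int(i0 + 1L, length.out = length(pos) - i0))
  start <- left$bound
  end <- right$bound
  supporting <- pos[pstat == "CONSISTENT" & pos >= start & pos <= end]
  seg <- structure(list(chrom = table$variants$chrom[1L],
                        start = start, end = end,
                        length_bp = segment_length(start, end),
                        p_breaker = left$breaker, q_breaker = right$breaker,
                        supporting_sites = supporting,
                        window = c(min(pos), max(pos)),
                        index_pos = idx_pos),
                   class = "shared_segment")
  # post-hoc guard: no breaker inside the reported segment
  inside <- cls$pos >= seg$start & cls$pos <= seg$end
  if (any(cls$status[inside] == "BREAKER")) {
    stop("internal error: breaker site inside the reported segment", call. = FALSE)
  }
  seg
}

#' Narrow the shared segment incrementally over a sample order
#'
#' Reproduces stepwise narrowing: the segment is detected over growing sample
#' subsets in the given order. Each added sample can only add breaker
#' evidence, so the breaker-delimited interval shrinks monotonically (the
#' outermost-consistent-site endpoints may still move outward *within* that
#' interval as added samples turn uninformative sites into supporting ones).
#' Intermediate subsets that contain no homozygous carrier cannot
#' define the haplotype and record `NULL` (no constraint yet). The final
#' segment always equals joint [detect_segment()] over all samples, whatever
#' the order.
#'
#' @inheritParams detect_segment
#' @param order Character vector: a permutation of the table's sample ids.
#' @return The final `shared_segment`, with the per-step segments in
#'   `attr(, "steps")` (a list named by the sample added at each step).
#' @export
narrow_incrementally <- function(table, roles = NULL, order = NULL,
                                 max_uninformative_gap_bp = Inf) {
  stopifnot(inherits(table, "cohort_gt"))
  if (is.null(roles)) roles <- effective_roles(table)
  if (is.null(order)) order <- roles$sample_id
  if (!setequal(order, roles$sample_id) || length(order) != nrow(roles)) {
    stop("order must be a permutation of the cohort sample ids", call. = FALSE)
  }
  steps <- vector("list", length(order))
  names(steps) <- order
  seg <- NULL
  for (k in seq_along(order)) {
    ids <- order[seq_len(k)]
    sub <- subset_samples(table, ids)
    sub_roles <- roles[match(ids, roles$sample_id), , drop = FALSE]
    if (!any(sub_roles$carrier_class == "HOMOZYGOUS_CARRIER")) {
      steps[[k]] <- NULL  # no homozygous carrier yet: haplotype undefined
      next
    }
    seg <- detect_segment(sub, sub_roles,
                          max_uninformative_gap_bp = max_uninformative_gap_bp)
    steps[[k]] <- seg
  }
  if (is.null(seg)) stop("no homozygous carrier in the cohort", call. = FALSE)
  attr(seg, "steps") <- steps
  seg
}

#' Length of a closed genomic interval
#'
#' Inclusive arithmetic: both endpoints count, so `segment_length(x, x)` is 1.
#'
#' @param start,end 1-based interval endpoints, `start <= end`.
#' @return Integer `end - start + 1`.
#' @examples
#' segment_length(21775527, 21861499)  # 85973
#' @export
segment_length <- function(start, end) {
  if (any(start > end)) stop("start exceeds end", call. = FALSE)
  as.integer(end - start + 1)
}

#' @export
print.shared_segment <- function(x, ...) {
  cat(sprintf("Shared founder segment chr%s:%d-%d (%d bp)\n",
              x$chrom, x$start, x$end, x$length_bp))
  fmt_breaker <- function(b, side) {
    if (is.null(b)) sprintf("  %s margin: window edge reached\n", side)
    else sprintf("  %s breaker: %d (%s in %s)\n", side, b$position, b$reason,
                 b$sample_id)
  }
  cat(fmt_breaker(x$p_breaker, "p-side"))
  cat(fmt_breaker(x$q_breaker, "q-side"))
  cat(sprintf("  supporting sites: %d; index at %d\n",
              length(x$supporting_sites), x$index_pos))
  invisible(x)
}
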