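# Synthetic founder-cohort simulator: a planted ancestral segment descends to
# N carriers, truncated per founder copy by recombination; background
# polymorphism, genotype error and exome-capture missingness on top.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the detector targets: a five-sample
#' cohort (two homozygous, three heterozygous carriers of the index allele),
#' markers collated across 5,000,000 bp on both sides of the index, and
#' whole-genome coverage for the first homozygous carrier with exome coverage
#' for the rest.
#'
#' @param chrom Chromosome name (default `"1"`).
#' @param index_pos,index_ref,index_alt Index variant (defaults
#'   `21839005 G>A`).
#' @param window_bp Half-window in bp on each side of the index (default
#'   5e6, i.e. a 10,000,001-bp closed analysis window).
#' @param n_hom_carriers,n_het_carriers Carrier counts (defaults 2 and 3).
#' @param generations_to_founder Meioses separating each carrier from the
#'   founder (scalar or one value per carrier; default 10).
#' @param recomb_rate_per_bp_per_meiosis Recombination rate (default 1e-8,
#'   ~1 cM/Mb).
#' @param marker_density_per_bp Expected marker density (default 1e-3, one
#'   marker per kb: the scale of sites at which a haplotype differs from the
#'   reference).
#' @param background_af_alpha,background_af_beta Beta parameters for
#'   background allele frequencies (default Beta(0.2, 2), skewed to rare).
#' @param exome_fraction Fraction of markers callable in `EXOME` samples
#'   (default 0.2); the index variant is always callable.
#' @param genotype_error_rate Per-genotype error probability (default 0);
#'   errors never touch the index genotype (confirmed calls in practice).
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom = "1", index_pos = 21839005L, index_ref = "G",
                       index_alt = "A", window_bp = 5e6,
                       n_hom_carriers = 2L, n_het_carriers = 3L,
                       generations_to_founder = 10L,
                       recomb_rate_per_bp_per_meiosis = 1e-8,
                       marker_density_per_bp = 1e-3,
                       background_af_alpha = 0.2, background_af_beta = 2,
                       exome_fraction = 0.2, genotype_error_rate = 0,
                       seed = 1L) {
  n_samples <- n_hom_carriers + n_het_carriers
  if (n_samples < 1L) stop("need at least one carrier", call. = FALSE)
  stopifnot(window_bp > 0, marker_density_per_bp > 0,
            recomb_rate_per_bp_per_meiosis >= 0,
            exome_fraction >= 0, exome_fraction <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            all(generations_to_founder >= 0))
  structure(list(chrom = canonical_chrom(chrom), index_pos = as.integer(index_pos),
                 index_ref = index_ref, index_alt = index_alt,
                 window_bp = window_bp,
                 n_hom_carriers = as.integer(n_hom_carriers),
                 n_het_carriers = as.integer(n_het_carriers),
                 generations_to_founder = rep_len(generations_to_founder, n_samples),
                 recomb_rate_per_bp_per_meiosis = recomb_rate_per_bp_per_meiosis,
                 marker_density_per_bp = marker_density_per_bp,
                 background_af_alpha = background_af_alpha,
                 background_af_beta = background_af_beta,
                 exome_fraction = exome_fraction,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic sub-seed so that draws for one phase/sample do not shift when
# other phases change (poor man's counter-based stream).
sub_seed <- function(master, tag) {
  as.integer((as.double(master) * 1021 + tag * 7919) %% 2147483587)
}

#' Simulate a founder cohort with ground truth
#'
#' The planted ancestral haplotype carries the alternate allele at every
#' simulated marker: markers emulate the cohort-ascertained variant sites
#' that display a founder haplotype, so every in-segment marker is potentially
#' informative and detection resolution is set by marker spacing. Each founder
#' copy (two per homozygous carrier, one per heterozygous carrier) retains the
#' ancestral alleles on a contiguous interval around the index, truncated on
#' each side at an `Exponential(generations x recomb_rate)` distance (Haldane,
#' no interference). Outside retained intervals and on non-founder
#' chromosomes, alleles are drawn per marker from the background allele
#' frequency. Genotype errors and exome masking are applied last.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (a [cohort_table()]), `roles`, and `truth`
#'   (class `synthetic_truth`): per-copy retained intervals, the continuous
#'   true shared interval (their intersection, clamped to the window), its
#'   closure to the outermost markers inside, and the marker positions.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_hom <- config$n_hom_carriers
  n_het <- config$n_het_carriers
  n_samples <- n_hom + n_het
  lo <- config$index_pos - config$window_bp
  hi <- config$index_pos + config$window_bp

  # phase 1: marker positions, alleles, background AFs
  set.seed(sub_seed(config$seed, 1L))
  n_markers <- stats::rpois(1L, config$marker_density_per_bp * (hi - lo + 1))
  if (n_markers == 0L) stop("zero markers in window; raise marker_density_per_bp",
                            call. = FALSE)
  pos <- sort(unique(round(stats::runif(n_markers, lo, hi))))
  pos <- union(pos, config$index_pos)
  pos <- sort(pos)
  m <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  i0 <- match(config$index_pos, pos)
  ref[i0] <- config$index_ref
  alt[i0] <- config$index_alt
  af <- stats::rbeta(m, config$background_af_alpha, config$background_af_beta)
  callable <- stats::runif(m) < config$exome_fraction
  callable[i0] <- TRUE

  sample_id <- sprintf("S%02d", seq_len(n_samples))
  carrier <- rep(c("HOMOZYGOUS_CARRIER", "HETEROZYGOUS_CARRIER"),
                 c(n_hom, n_het))
  coverage <- c("GENOME", rep("EXOME", n_samples - 1L))
  roles <- sample_roles(sample_id, carrier_class = carrier,
                        coverage_class = coverage)

  # phase 2: founder-copy truncation intervals per sample
  copies_per_sample <- ifelse(carrier == "HOMOZYGOUS_CARRIER", 2L, 1L)
  retained <- list()
  for (s in seq_len(n_samples)) {
    set.seed(sub_seed(config$seed, 100L + s))
    rate <- config$generations_to_founder[s] * config$recomb_rate_per_bp_per_meiosis
    for (cp in seq_len(copies_per_sample[s])) {
      if (rate > 0) {
        l <- config$index_pos - stats::rexp(1L, rate)
        r <- config$index_pos + stats::rexp(1L, rate)
      } else {
        l <- -Inf; r <- Inf
      }
      retained[[length(retained) + 1L]] <-
        list(sample_id = sample_id[s], copy = cp, start = l, end = r)
    }
  }

  # phase 3: chromosome alleles and zygosity per sample
  geno <- matrix("HOM_REF", nrow = m, ncol = n_samples,
                 dimnames = list(NULL, sample_id))
  ri <- 0L
  for (s in seq_len(n_samples)) {
    set.seed(sub_seed(config$seed, 200L + s))
    n_copies <- copies_per_sample[s]
    alt_count <- integer(m)
    for (cp in seq_len(n_copies)) {
      ri <- ri + 1L
      inside <- pos >= retained[[ri]]$start & pos <= retained[[ri]]$end
      chrom_alt <- ifelse(inside, TRUE, stats::runif(m) < af)
      alt_count <- alt_count + chrom_alt
    }
    for (bg in seq_len(2L - n_copies)) {
      chrom_alt <- stats::runif(m) < af
      chrom_alt[i0] <- FALSE  # the non-founder chromosome is ref at the index
      alt_count <- alt_count + chrom_alt
    }
    geno[, s] <- c("HOM_REF", "HET", "HOM_ALT")[alt_count + 1L]
  }

  geno_clean <- geno  # pre-error, pre-masking snapshot for the truth record

  # phase 4: genotype error, then exome masking
  if (config$genotype_error_rate > 0) {
    set.seed(sub_seed(config$seed, 300L))
    for (s in seq_len(n_samples)) {
      hit <- which(stats::runif(m) < config$genotype_error_rate)
      hit <- setdiff(hit, i0)
      for (i in hit) {
        geno[i, s] <- sample(setdiff(c("HOM_REF", "HET", "HOM_ALT"), geno[i, s]), 1L)
      }
    }
  }
  exome <- which(coverage == "EXOME")
  if (length(exome) > 0L) geno[!callable, exome] <- "MISSING"

  variants <- do.call(rbind, lapply(seq_len(m), function(i) {
    genomic_variant(config$chrom, pos[i], ref[i], alt[i])
  }))
  index <- genomic_variant(config$chrom, config$index_pos, config$index_ref,
                           config$index_alt)
  table <- cohort_table(variants, roles, geno, index)

  starts <- vapply(retained, `[[`, numeric(1L), "start")
  ends <- vapply(retained, `[[`, numeric(1L), "end")
  true_start <- max(c(starts, lo))
  true_end <- min(c(ends, hi))
  inside <- pos >= true_start & pos <= true_end

  # Detectability envelope: markers outside the true identity-by-descent
  # interval can still be compatible with sharing when a truncated founder
  # copy carries the ancestral allele by chance (identity-by-state). An
  # errorless detector with full coverage can extend across such markers but
  # can never cross the first genuinely incompatible genotype pattern, found
  # here on the noise-free, unmasked genotypes.
  incompatible <- vapply(seq_len(m), function(i) {
    classify_site(stats::setNames(geno_clean[i, ], sample_id),
                  roles)$status == "BREAKER"
  }, logical(1L))
  left_out <- which(pos < true_start & incompatible)
  right_out <- which(pos > true_end & incompatible)
  envelope_start <- if (length(left_out)) max(pos[left_out]) else -Inf
  envelope_end <- if (length(right_out)) min(pos[right_out]) else Inf

  truth <- structure(list(retained = retained,
                          true_start = true_start, true_end = true_end,
                          closure_start = if (any(inside)) min(pos[inside]) else NA_integer_,
                          closure_end = if (any(inside)) max(pos[inside]) else NA_integer_,
                          envelope_start = envelope_start,
                          envelope_end = envelope_end,
                          marker_pos = pos, callable = callable,
                          geno_clean = geno_clean,
                          window = c(lo, hi)),
                     class = "synthetic_truth")
  list(table = table, roles = roles, truth = truth)
}

#' Check a detected segment against the simulator's ground truth
#'
#' Containment requires the detected segment to stay strictly inside the
#' truth's detectability envelope: the interval delimited by the first marker
#' on each side whose noise-free genotype pattern is genuinely incompatible
#' with founder sharing. (Markers just outside the true identity-by-descent
#' interval can mimic sharing by identity-by-state, so the envelope, not the
#' raw breakpoint, is the attainable bound.) The boundary error is
#' the distance between the true recombination breakpoint and its point
#' estimate, taken as the midpoint of the uncertainty gap between the detected
#' endpoint and the flanking breaker (or window edge) - the true breakpoint
#' is known only to lie in that gap.
#'
#' @param segment A `shared_segment` from [detect_segment()].
#' @param truth A `synthetic_truth` from [simulate_cohort()].
#' @return A list with `containment_ok`, `boundary_error_p`,
#'   `boundary_error_q`, `boundary_error_bp` (their mean), `true_length`,
#'   `detected_length`.
#' @export
compare_to_truth <- function(segment, truth) {
  stopifnot(inherits(segment, "shared_segment"), inherits(truth, "synthetic_truth"))
  ok_left <- segment$start > truth$envelope_start
  ok_right <- segment$end < truth$envelope_end
  gap_p <- if (!is.null(segment$p_breaker)) segment$p_breaker$position else truth$window[1L]
  gap_q <- if (!is.null(segment$q_breaker)) segment$q_breaker$position else truth$window[2L]
  est_p <- (segment$start + gap_p) / 2
  est_q <- (segment$end + gap_q) / 2
  err_p <- abs(est_p - max(truth$true_start, truth$window[1L]))
  err_q <- abs(est_q - min(truth$true_end, truth$window[2L]))
  list(containment_ok = ok_left && ok_right,
       boundary_error_p = err_p, boundary_error_q = err_q,
       boundary_error_bp = (err_p + err_q) / 2,
       true_length = min(truth$true_end, truth$window[2L]) -
         max(truth$true_start, truth$window[1L]) + 1,
       detected_length = segment$length_bp)
}

#' Parameter-recovery study over simulated cohorts
#'
#' Simulates, detects and compares against ground truth over replicates of one
#' or more configurations.
#'
#' @param configs A [sim_config()] or a (possibly named) list of them.
#' @param n_reps Replicates per configuration; replicate `r` uses seed
#'   `config$seed + r`.
#' @return `data.frame` with one row per (config, rep): detected and true
#'   lengths, boundary error, mean inter-marker spacing, containment flag.
#' @export
recovery_study <- function(configs, n_reps = 20L) {
  if (inherits(configs, "sim_config")) configs <- list(config = configs)
  if (is.null(names(configs))) names(configs) <- sprintf("config%d", seq_along(configs))
  rows <- list()
  for (cname in names(configs)) {
    cfg <- configs[[cname]]
    for (r in seq_len(n_reps)) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r
      sim <- simulate_cohort(cfg_r)
      seg <- detect_segment(sim$table, sim$roles)
      cmp <- compare_to_truth(seg, sim$truth)
      pos <- sim$truth$marker_pos
      spacing <- if (length(pos) > 1L) (max(pos) - min(pos)) / (length(pos) - 1L) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        config = cname, rep = r, seed = cfg_r$seed,
        true_length = cmp$true_length, detected_length = cmp$detected_length,
        boundary_error_bp = cmp$boundary_error_bp,
        mean_marker_spacing = spacing,
        containment_ok = cmp$containment_ok,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
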