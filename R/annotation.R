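# Catalog and cohort statistics: allele frequencies, score summaries,
# protein-domain localization.

#' Allele frequency from allele counts
#'
#' Computes `ac/an` and reports it to a number of significant figures
#' (significant-figure rounding, not decimal places, matching the scientific
#' notation in which minor allele frequencies are conventionally quoted).
#'
#' @param ac Alternate allele count (integer, `>= 0`).
#' @param an Total allele number (integer, `> 0`).
#' @param sig_figs Significant figures for the reported value (default 2).
#' @return A list with `exact` (the unrounded ratio) and `frequency` (rounded
#'   to `sig_figs` significant figures).
#' @examples
#' allele_frequency(17, 298038)$frequency  # 5.7e-05
#' allele_frequency(10, 28258)$frequency   # 3.5e-04
#' @export
allele_frequency <- function(ac, an, sig_figs = 2L) {
  ac <- as.numeric(ac); an <- as.numeric(an)
  if (is.na(an) || an <= 0) stop("allele number must be positive", call. = FALSE)
  if (is.na(ac) || ac < 0) stop("allele count must be non-negative", call. = FALSE)
  if (ac > an) stop("allele count exceeds allele number", call. = FALSE)
  exact <- ac / an
  list(exact = exact, frequency = signif(exact, sig_figs),
       ac = ac, an = an, sig_figs = as.integer(sig_figs))
}

#' Mean and sample standard deviation of pathogenicity scores
#'
#' The standard deviation uses the sample (n-1) denominator. Rounded values
#' use 3 decimals, the convention for reporting predictor scores.
#'
#' @param scores Numeric vector of scores in `[0, 1]`, length `>= 2`.
#' @return A list with `mean`, `sd` (unrounded) and `mean_3`, `sd_3` (rounded
#'   to 3 decimals), plus `n`.
#' @examples
#' sjs <- c(0.965, 0.595, 0.335, 0.515, 0.966, 0.741, 0.286, 0.428, 0.489,
#'          0.571, 0.690)
#' score_summary(sjs)[c("mean_3", "sd_3")]  # 0.598, 0.227
#' @export
score_summary <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no scores supplied", call. = FALSE)
  if (length(scores) < 2L) {
    stop("at least two scores are needed for a standard deviation", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]", call. = FALSE)
  m <- mean(scores)
  s <- stats::sd(scores)
  list(mean = m, sd = s, mean_3 = round(m, 3L), sd_3 = round(s, 3L),
       n = length(scores))
}

#' Construct a protein-domain map
#'
#' Closed codon intervals on the protein coordinate of the reference isoform.
#' Intervals may not overlap.
#'
#' @param label Character vector of domain labels.
#' @param codon_start,codon_end Integer vectors of closed interval endpoints.
#' @return A `data.frame` of class `domain_map`, sorted by `codon_start`.
#' @export
domain_map <- function(label, codon_start, codon_end) {
  codon_start <- as.integer(codon_start)
  codon_end <- as.integer(codon_end)
  if (any(is.na(codon_start) | is.na(codon_end)) || any(codon_start < 1L)) {
    stop("codon ranges must be positive integers", call. = FALSE)
  }
  if (any(codon_start > codon_end)) {
    stop("codon_start exceeds codon_end", call. = FALSE)
  }
  d <- data.frame(domain_label = as.character(label), codon_start = codon_start,
                  codon_end = codon_end, stringsAsFactors = FALSE)
  d <- d[order(d$codon_start), , drop = FALSE]
  if (nrow(d) > 1L && any(d$codon_start[-1L] <= d$codon_end[-nrow(d)])) {
    stop("domain intervals overlap", call. = FALSE)
  }
  rownames(d) <- NULL
  class(d) <- c("domain_map", "data.frame")
  d
}

#' Read a domain map config (TSV: label, start codon, end codon)
#' @param path Path to the TSV.
#' @return A [domain_map()] object.
#' @export
read_domain_map <- function(path) {
  if (!file.exists(path)) stop("domain map not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain_label", "codon_start", "codon_end")
  if (!all(need %in% names(d))) {
    stop("domain map must have columns domain_label, codon_start, codon_end",
         call. = FALSE)
  }
  domain_map(d$domain_label, d$codon_start, d$codon_end)
}

#' Locate a codon in a domain map
#'
#' @param codon Integer codon number (`>= 1`).
#' @param map A [domain_map()].
#' @return The label of the unique closed interval containing the codon, or
#'   `NA_character_` when none does.
#' @examples
#' m <- domain_map("Domain IV", 1695, 3655)
#' locate_in_domain(3324, m)  # "Domain IV"
#' locate_in_domain(3661, m)  # NA
#' @export
locate_in_domain <- function(codon, map) {
  stopifnot(inherits(map, "domain_map"))
  codon <- as.integer(codon)
  if (is.na(codon) || codon < 1L) stop("codon must be >= 1", call. = FALSE)
  hit <- which(map$codon_start <= codon & codon <= map$codon_end)
  if (length(hit) == 0L) NA_character_ else map$domain_label[hit[1L]]
}

#' Count a disease's missense variants inside a named domain
#'
#' Counts catalog records with the given disease label, consequence
#' `MISSENSE`, and codon inside the named domain's closed codon interval.
#' Variants annotated at domain interfaces are counted only if their codon
#' falls inside the queried interval.
#'
#' @param catalog Catalog `data.frame` ([read_catalog()]).
#' @param disease Disease label (`"SJS"`, `"DDSH"` or `"DDRD"`).
#' @param map A [domain_map()].
#' @param domain_label Name of the domain to query (must be in the map).
#' @return Integer count.
#' @export
count_missense_in_domain <- function(catalog, disease, map, domain_label) {
  stopifnot(inherits(map, "domain_map"))
  if (!domain_label %in% map$domain_label) {
    stop("unknown domain label: ", domain_label, call. = FALSE)
  }
  rows <- catalog[catalog$disease == disease &
                    catalog$consequence == "MISSENSE" &
                    !is.na(catalog$codon), , drop = FALSE]
  if (nrow(rows) == 0L) return(0L)
  hits <- vapply(rows$codon, function(cd) {
    lbl <- locate_in_domain(cd, map)
    !is.na(lbl) && lbl == domain_label
  }, logical(1L))
  sum(hits)
}

#' Count catalog records per disease
#'
#' Counts distinct variants (unique `hgvs_c`) per disease label, so a catalog
#' listing one variant in several patients counts it once.
#'
#' @param catalog Catalog `data.frame`.
#' @param distinct Count distinct `hgvs_c` per disease (default) rather than
#'   raw rows.
#' @return Named integer vector, one element per disease present.
#' @export
catalog_counts <- function(catalog, distinct = TRUE) {
  if (nrow(catalog) == 0L) return(stats::setNames(integer(0), character(0)))
  split_c <- split(catalog$hgvs_c, catalog$disease)
  out <- vapply(split_c, function(x) {
    if (distinct) length(unique(x)) else length(x)
  }, integer(1L))
  out[order(names(out))]
}
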