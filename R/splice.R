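# Splice-donor disruption reasoning: enumerate candidate cryptic 5' splice
# sites around a disrupted authentic donor and classify the predicted
# transcript outcome. The donor-site scoring model itself is injected.

#' Construct a donor context
#'
#' Reference sequence spanning an authentic 5' splice site (donor) plus a
#' search window. The donor convention is 3 exonic + 6 intronic bases; the
#' first two intronic bases of the authentic donor must be the invariant
#' `GT` dinucleotide in the reference.
#'
#' @param sequence Reference nucleotide string over `{A,C,G,T}`.
#' @param authentic_offset 1-based index within `sequence` of the first
#'   intronic base (the `G` of the authentic `GT`).
#' @param exon_length_bp Length in bp of the exon upstream of the donor
#'   (decides the reading-frame consequence of skipping it); may be `NA`.
#' @param strand `"+"` or `"-"`; sequences are supplied already in
#'   donor-strand orientation.
#' @param name Optional context name (e.g. the disrupting variant's HGVS).
#' @return An object of class `donor_context`.
#' @export
donor_context <- function(sequence, authentic_offset, exon_length_bp = NA_integer_,
                          strand = "+", name = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("donor context sequence must be over {A,C,G,T}", call. = FALSE)
  }
  authentic_offset <- as.integer(authentic_offset)
  if (is.na(authentic_offset) || authentic_offset < 1L ||
      authentic_offset + 1L > nchar(sequence)) {
    stop("authentic_offset out of range", call. = FALSE)
  }
  if (substr(sequence, authentic_offset, authentic_offset + 1L) != "GT") {
    stop("reference bases at the authentic donor are not GT", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be + or -", call. = FALSE)
  structure(list(sequence = sequence, authentic_offset = authentic_offset,
                 exon_length_bp = as.integer(exon_length_bp), strand = strand,
                 name = as.character(name)),
            class = "donor_context")
}

#' Enumerate candidate cryptic donor sites around the authentic donor
#'
#' Scans `+/- window_bp` around the authentic donor for `GT` dinucleotides
#' (the disrupted authentic site itself is excluded) and returns each with its
#' 9-mer donor window (3 exonic + 6 intronic bases). Candidates whose 9-mer
#' would run off the sequence are dropped.
#'
#' @param ctx A [donor_context()].
#' @param window_bp Search half-window in bp (default 40, covering the
#'   candidate offsets observed in practice).
#' @return `data.frame` with columns `offset` (signed, relative to the
#'   authentic donor) and `ninemer`.
#' @export
enumerate_candidate_donors <- function(ctx, window_bp = 40L) {
  stopifnot(inherits(ctx, "donor_context"))
  n <- nchar(ctx$sequence)
  a <- ctx$authentic_offset
  if (a - window_bp < 1L || a + window_bp + 1L > n) {
    stop("search window exceeds the context sequence", call. = FALSE)
  }
  lo <- a - window_bp
  hi <- a + window_bp
  offs <- integer(0)
  nine <- character(0)
  for (p in lo:hi) {
    if (p == a) next
    if (substr(ctx$sequence, p, p + 1L) != "GT") next
    if (p - 3L < 1L || p + 5L > n) next
    offs <- c(offs, p - a)
    nine <- c(nine, substr(ctx$sequence, p - 3L, p + 5L))
  }
  data.frame(offset = offs, ninemer = nine, stringsAsFactors = FALSE)
}

#' Donor scorer backed by a 9-mer lookup table
#'
#' The donor-site scoring model is injected: any deterministic function
#' mapping a 9-mer (3 exonic + 6 intronic bases) to a real score, higher =
#' stronger donor, satisfies the contract. This constructor wraps a two-column
#' table (`ninemer`, `score`), the plug-in format the package ships for its
#' fixtures; a full maximum-entropy donor model can be plugged in the same
#' way.
#'
#' @param table `data.frame` with columns `ninemer` and `score`, or a path to
#'   such a TSV.
#' @return A function `(ninemers) -> scores` that errors on 9-mers absent
#'   from the table.
#' @export
lookup_scorer <- function(table) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("ninemer", "score") %in% names(table)))
  tab <- stats::setNames(as.numeric(table$score), toupper(table$ninemer))
  function(ninemers) {
    ninemers <- toupper(ninemers)
    unknown <- setdiff(ninemers, names(tab))
    if (length(unknown) > 0L) {
      stop("no score for donor 9-mer ", unknown[1L], call. = FALSE)
    }
    unname(tab[ninemers])
  }
}

#' Classify the predicted outcome of a disrupted donor
#'
#' A cryptic 5' splice site is called activated when the best-scoring
#' candidate reaches `max(floor, authentic_score - margin)`; otherwise the
#' upstream exon is predicted to be skipped, frameshifting when its length is
#' not a multiple of 3. Outcomes are predictions (no transcript data is
#' consulted).
#'
#' @param candidates `data.frame` from [enumerate_candidate_donors()] with an
#'   added `score` column (or which will be scored with `scorer`).
#' @param authentic_score Donor score of the intact authentic site.
#' @param exon_length_bp Length of the upstream exon in bp; required when no
#'   candidate qualifies.
#' @param margin Score units a candidate may fall below the authentic score
#'   and still count as a plausible cryptic donor (default 3.0).
#' @param floor Absolute minimum score for a plausible donor (default 0.0).
#' @param scorer Optional scorer function applied when `candidates` lacks a
#'   `score` column.
#' @return An object of class `splice_outcome` with fields `outcome`
#'   (`"CRYPTIC_ACTIVATION"`, `"EXON_SKIP_FRAMESHIFT"` or
#'   `"EXON_SKIP_INFRAME"`), `best_offset`, `best_score`, `authentic_score`,
#'   `exon_length_bp`, `margin`, `floor`.
#' @export
classify_outcome <- function(candidates, authentic_score, exon_length_bp = NA,
                             margin = 3.0, floor = 0.0, scorer = NULL) {
  stopifnot(is.data.frame(candidates))
  if (margin <= 0) stop("margin must be positive", call. = FALSE)
  if (!"score" %in% names(candidates)) {
    if (is.null(scorer)) stop("candidates carry no scores and no scorer given",
                              call. = FALSE)
    candidates$score <- if (nrow(candidates)) scorer(candidates$ninemer) else numeric(0)
  }
  exon_length_bp <- as.integer(exon_length_bp)
  best_offset <- NA_integer_
  best_score <- -Inf
  if (nrow(candidates) > 0L) {
    b <- which.max(candidates$score)
    best_offset <- candidates$offset[b]
    best_score <- candidates$score[b]
  }
  threshold <- max(floor, authentic_score - margin)
  if (nrow(candidates) > 0L && best_score >= threshold) {
    outcome <- "CRYPTIC_ACTIVATION"
  } else {
    if (is.na(exon_length_bp)) {
      stop("no qualifying candidate and no upstream exon length supplied",
           call. = FALSE)
    }
    outcome <- if (exon_length_bp %% 3L != 0L) "EXON_SKIP_FRAMESHIFT"
               else "EXON_SKIP_INFRAME"
  }
  structure(list(outcome = outcome, best_offset = best_offset,
                 best_score = if (is.finite(best_score)) best_score else NA_real_,
                 authentic_score = authentic_score,
                 exon_length_bp = exon_length_bp,
                 margin = margin, floor = floor),
            class = "splice_outcome")
}

#' Predict the splice outcome for a donor context end-to-end
#'
#' Convenience wrapper: enumerates candidates, scores them, and classifies.
#'
#' @param ctx A [donor_context()].
#' @param scorer Scorer function (e.g. [lookup_scorer()]).
#' @param authentic_score Score of the intact authentic donor.
#' @param window_bp Candidate search half-window.
#' @inheritParams classify_outcome
#' @return A `splice_outcome`.
#' @export
predict_splice_outcome <- function(ctx, scorer, authentic_score,
                                   window_bp = 40L, margin = 3.0, floor = 0.0) {
  cand <- enumerate_candidate_donors(ctx, window_bp = window_bp)
  classify_outcome(cand, authentic_score,
                   exon_length_bp = ctx$exon_length_bp,
                   margin = margin, floor = floor, scorer = scorer)
}

#' @export
print.splice_outcome <- function(x, ...) {
  cat(sprintf("Predicted splice outcome: %s\n", x$outcome))
  if (!is.na(x$best_offset)) {
    cat(sprintf("  best candidate donor: offset %+d, score %.2f (authentic %.2f)\n",
                x$best_offset, x$best_score, x$authentic_score))
  } else {
    cat(sprintf("  no candidate GT in window (authentic score %.2f)\n",
                x$authentic_score))
  }
  if (!is.na(x$exon_length_bp)) {
    cat(sprintf("  upstream exon: %d bp (mod 3 = %d)\n", x$exon_length_bp,
                x$exon_length_bp %% 3L))
  }
  invisible(x)
}

#' Packaged donor-context fixtures for the two HSPG2 splice variants
#'
#' Builds the two donor contexts analysed in the package examples:
#' `c.7006+1G>A` (intron 54 donor; one candidate GT 6 nt downstream; upstream
#' exon 136 bp; authentic score 9.40, candidate -6.23) and `c.11562+2T>G`
#' (intron 84 donor; candidate GTs 20 bp upstream and 33 bp downstream;
#' upstream exon 110 bp; authentic score 6.54, candidates -11.07 and -11.54).
#' The context sequences are synthetic: constructed strings carrying GT
#' dinucleotides at exactly the reported candidate offsets (true intronic
#' sequence is not redistributed with the package); the bundled lookup scorer
#' maps their 9-mers to the published MaxEntScan:5ss values.
#'
#' @return A list with elements `contexts` (named list of [donor_context()]s),
#'   `scorer` (a [lookup_scorer()]), and `authentic_scores` (named numeric).
#' @export
hspg2_donor_fixtures <- function() {
  ctx_tab <- utils::read.delim(fs_extdata("synthetic_splice_contexts.tsv"),
                               stringsAsFactors = FALSE)
  contexts <- lapply(seq_len(nrow(ctx_tab)), function(i) {
    donor_context(ctx_tab$sequence[i], ctx_tab$authentic_offset[i],
                  exon_length_bp = ctx_tab$exon_length_bp[i],
                  name = ctx_tab$name[i])
  })
  names(contexts) <- ctx_tab$name
  list(contexts = contexts,
       scorer = lookup_scorer(fs_extdata("synthetic_donor_scores.tsv")),
       authentic_scores = stats::setNames(ctx_tab$authentic_score, ctx_tab$name))
}
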