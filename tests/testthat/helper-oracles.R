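# Independent oracles used by the tests. Written from scratch against the
# definitions (not against the package's code paths).

# -- site status oracle: direct transcription of the rule table ---------------
oracle_status <- function(g, roles) {
  hom <- roles$sample_id[roles$carrier_class == "HOMOZYGOUS_CARRIER"]
  het <- roles$sample_id[roles$carrier_class == "HETEROZYGOUS_CARRIER"]
  gh <- g[hom]
  gt <- g[het]
  if ("HET" %in% gh) return("BREAKER")
  if ("HOM_ALT" %in% gh && "HOM_REF" %in% gh) return("BREAKER")
  if ("HOM_ALT" %in% gh) {
    if ("HOM_REF" %in% gt) return("BREAKER")
    return("CONSISTENT")
  }
  "UNINFORMATIVE"
}

# -- exhaustive contiguous-window oracle for segment detection ----------------
# Tests every contiguous site window containing the index whose sites are all
# CONSISTENT-or-UNINFORMATIVE and that is flanked by BREAKER/edge; returns the
# maximal one, trimmed to its outermost CONSISTENT sites.
oracle_segment <- function(table, roles) {
  st <- vapply(seq_len(nrow(table$variants)), function(i) {
    oracle_status(table$genotypes[i, ], roles)
  }, character(1))
  pos <- table$variants$pos
  i0 <- which(pos == table$index_variant$pos &
                table$variants$ref == table$index_variant$ref &
                table$variants$alt == table$index_variant$alt)
  n <- length(pos)
  best <- NULL
  for (i in seq_len(i0)) {
    for (j in i0:n) {
      if (any(st[i:j] == "BREAKER")) next
      if (i > 1L && st[i - 1L] != "BREAKER") next
      if (j < n && st[j + 1L] != "BREAKER") next
      cons <- which(st[i:j] == "CONSISTENT") + i - 1L
      cand <- c(pos[min(cons)], pos[max(cons)])
      if (is.null(best) || (cand[2] - cand[1]) > (best[2] - best[1])) best <- cand
    }
  }
  best
}

# -- brute-force indel left alignment -----------------------------------------
apply_variant <- function(ref_seq, pos, ref, alt, ref_start = 1L) {
  i <- pos - ref_start + 1L
  stopifnot(substr(ref_seq, i, i + nchar(ref) - 1L) == ref)
  paste0(substr(ref_seq, 1L, i - 1L), alt,
         substr(ref_seq, i + nchar(ref), nchar(ref_seq)))
}

# Enumerates every representation (pos', ref', alt') whose application to the
# reference yields the same edited sequence, keeps the parsimony-trimmed ones,
# and returns the leftmost (then shortest). Anchor convention: alleles stay
# non-empty.
oracle_leftalign <- function(ref_seq, pos, ref, alt, ref_start = 1L) {
  edited <- apply_variant(ref_seq, pos, ref, alt, ref_start)
  n_ref <- nchar(ref_seq)
  n_ed <- nchar(edited)
  reps <- list()
  p_max <- min(pos - ref_start + 1L + nchar(ref), n_ref)
  for (p in seq_len(p_max)) {
    for (lr in 1L:min(8L, n_ref - p + 1L)) {
      la <- lr + (n_ed - n_ref)
      if (la < 1L) next
      r <- substr(ref_seq, p, p + lr - 1L)
      a <- substr(edited, p, p + la - 1L)
      if (substr(ref_seq, 1L, p - 1L) != substr(edited, 1L, p - 1L)) next
      if (substr(ref_seq, p + lr, n_ref) != substr(edited, p + la, n_ed)) next
      if (r == a) next
      trimmed <- !(nchar(r) > 1L && nchar(a) > 1L &&
                     (substr(r, 1L, 1L) == substr(a, 1L, 1L) ||
                        substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))))
      if (trimmed) reps[[length(reps) + 1L]] <- list(pos = p + ref_start - 1L,
                                                     ref = r, alt = a)
    }
  }
  stopifnot(length(reps) > 0L)
  ord <- order(vapply(reps, `[[`, numeric(1), "pos"),
               vapply(reps, function(x) nchar(x$ref), numeric(1)))
  reps[[ord[1L]]]
}

# -- two-pass textbook mean/SD ------------------------------------------------
oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)))
}

# -- naive full-scan candidate donor enumeration ------------------------------
oracle_candidates <- function(sequence, authentic_offset, window_bp) {
  out <- data.frame(offset = integer(0), ninemer = character(0))
  for (p in seq_len(nchar(sequence) - 1L)) {
    if (p == authentic_offset) next
    if (abs(p - authentic_offset) > window_bp) next
    if (substr(sequence, p, p + 1L) != "GT") next
    if (p - 3L < 1L || p + 5L > nchar(sequence)) next
    out <- rbind(out, data.frame(offset = p - authentic_offset,
                                 ninemer = substr(sequence, p - 3L, p + 5L)))
  }
  out
}
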