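test_that("classify_site implements the consistency rule table", {
  roles <- five_sample_roles()
  g <- function(...) stats::setNames(c(...), roles$sample_id)

  # shared pattern: hom carriers HOM_ALT, het carriers HET
  s <- classify_site(g("HOM_ALT", "HOM_ALT", "HET", "HET", "HET"), roles)
  expect_equal(s$status, "CONSISTENT")

  # heterozygosity in a homozygous carrier delimits the segment
  s <- classify_site(g("HET", "MISSING", "MISSING", "MISSING", "MISSING"), roles)
  expect_equal(s$status, "BREAKER")
  expect_equal(s$evidence, list(sample_id = "P02",
                                reason = "HET_IN_HOMOZYGOUS_CARRIER"))

  # a defining allele absent from a callable heterozygous carrier
  s <- classify_site(g("HOM_ALT", "HOM_ALT", "HET", "HOM_REF", "HET"), roles)
  expect_equal(s$status, "BREAKER")
  expect_equal(s$evidence, list(sample_id = "P06",
                                reason = "ABSENT_IN_HETEROZYGOUS_CARRIER"))

  # homozygous carriers callably homozygous for different alleles
  s <- classify_site(g("HOM_ALT", "HOM_REF", "HET", "HET", "HET"), roles)
  expect_equal(s$status, "BREAKER")
  expect_equal(s$evidence$reason, "HOMOZYGOUS_CONFLICT")

  # one HOM_ALT homozygous carrier suffices when the other is MISSING
  s <- classify_site(g("HOM_ALT", "MISSING", "MISSING", "MISSING", "MISSING"),
                     roles)
  expect_equal(s$status, "CONSISTENT")

  # hom carriers callably reference: uninformative, never a breaker
  s <- classify_site(g("HOM_REF", "HOM_REF", "HET", "HOM_REF", "HET"), roles)
  expect_equal(s$status, "UNINFORMATIVE")

  # het carrier HOM_ALT is compatible (both chromosomes may carry the allele)
  s <- classify_site(g("HOM_ALT", "HOM_ALT", "HOM_ALT", "HET", "HET"), roles)
  expect_equal(s$status, "CONSISTENT")

  expect_error(classify_site(g("HOM_ALT", "HOM_ALT", "HET", "HET", "HET"),
                             roles[0, ]), "empty")
})

test_that("classify_site agrees with an independent rule transcription", {
  for (seed in 1:10) {
    rc <- random_cohort(n_markers = 60, seed = seed)
    for (i in seq_len(nrow(rc$table$variants))) {
      g <- rc$table$genotypes[i, ]
      expect_equal(classify_site(g, rc$roles)$status, oracle_status(g, rc$roles),
                   info = sprintf("seed %d site %d", seed, i))
    }
  }
})

test_that("the packaged fixture yields the expected founder segment", {
  tab <- fixture_cohort()
  t0 <- proc.time()["elapsed"]
  seg <- detect_segment(tab)
  expect_lt(proc.time()["elapsed"] - t0, 1)
  expect_equal(seg$start, 21775527L)
  expect_equal(seg$end, 21861499L)
  expect_equal(seg$length_bp, 85973L)
  expect_equal(seg$p_breaker$position, 21773254L)
  expect_equal(seg$p_breaker$sample_id, "DDRD_P02")
  expect_equal(seg$p_breaker$reason, "HET_IN_HOMOZYGOUS_CARRIER")
  expect_equal(seg$q_breaker$position, 21862954L)
  expect_equal(seg$q_breaker$sample_id, "DDRD_P06")
  expect_equal(seg$q_breaker$reason, "ABSENT_IN_HETEROZYGOUS_CARRIER")
  expect_true(all(seg$supporting_sites >= seg$start &
                    seg$supporting_sites <= seg$end))
  expect_true(seg$start <= 21839005 && 21839005 <= seg$end)
})

test_that("immediate breakers on both sides reduce the segment to the index", {
  roles <- five_sample_roles()
  geno <- rbind(c("HET", "HOM_ALT", "HET", "HET", "HET"),
                c("HOM_ALT", "HOM_ALT", "HET", "HET", "HET"),
                c("HOM_ALT", "HOM_ALT", "HET", "HOM_REF", "HET"))
  tab <- build_cohort(c(100L, 200L, 300L), geno, roles, 200L)
  seg <- detect_segment(tab)
  expect_equal(c(seg$start, seg$end, seg$length_bp), c(200L, 200L, 1L))
})

test_that("an index that does not classify CONSISTENT is a malformed cohort", {
  roles <- five_sample_roles()
  roles$carrier_class <- rep("HETEROZYGOUS_CARRIER", 5)  # no homozygous carrier
  geno <- rbind(rep("HET", 5), rep("HET", 5))
  tab <- build_cohort(c(100L, 200L), geno, roles, 100L)
  expect_error(detect_segment(tab, roles), "UNINFORMATIVE")
})

test_that("detect_segment equals the exhaustive contiguous-window oracle", {
  for (seed in 1:25) {
    rc <- random_cohort(n_markers = sample(20:300, 1), seed = seed)
    seg <- detect_segment(rc$table, rc$roles)
    expect_equal(c(seg$start, seg$end), oracle_segment(rc$table, rc$roles),
                 info = paste("cohort seed", seed))
  }
})

test_that("narrowing is monotone and its final segment is order-independent", {
  for (seed in 1:12) {
    rc <- random_cohort(n_markers = 120, seed = seed)
    joint <- detect_segment(rc$table, rc$roles)
    set.seed(seed)
    for (perm in 1:3) {
      ord <- sample(rc$roles$sample_id)
      seg <- narrow_incrementally(rc$table, rc$roles, order = ord)
      expect_equal(c(seg$start, seg$end), c(joint$start, joint$end),
                   info = sprintf("seed %d perm %s", seed,
                                  paste(ord, collapse = ",")))
      steps <- Filter(Negate(is.null), attr(seg, "steps"))
      if (length(steps) > 1L) {
        for (k in 2:length(steps)) {
          b_now <- seg_bounds(steps[[k]])
          b_prev <- seg_bounds(steps[[k - 1L]])
          expect_gte(b_now[1], b_prev[1])
          expect_lte(b_now[2], b_prev[2])
          # and the endpoints always stay inside the previous step's bounds
          expect_gt(steps[[k]]$start, b_prev[1])
          expect_lt(steps[[k]]$end, b_prev[2])
        }
      }
    }
  }
})

test_that("subset monotonicity: more samples never widen the breaker interval", {
  for (seed in 13:20) {
    rc <- random_cohort(n_markers = 100, n_hom = 2, n_het = 3, seed = seed)
    full <- detect_segment(rc$table, rc$roles)
    ids <- rc$roles$sample_id[c(1, 3)]  # one hom + one het carrier
    sub <- detect_segment(subset_samples(rc$table, ids),
                          rc$roles[match(ids, rc$roles$sample_id), ])
    expect_gte(seg_bounds(full)[1], seg_bounds(sub)[1])
    expect_lte(seg_bounds(full)[2], seg_bounds(sub)[2])
    # the full cohort's segment lives inside the subset's breaker interval
    expect_gt(full$start, seg_bounds(sub)[1])
    expect_lt(full$end, seg_bounds(sub)[2])
  }
})

test_that("a single homozygous carrier reduces to run-of-homozygosity detection", {
  for (seed in 21:28) {
    set.seed(seed)
    n <- 80
    pos <- sort(sample.int(4000, n))
    z <- sample(c("HOM_REF", "HET", "HOM_ALT"), n, replace = TRUE)
    i0 <- sample.int(n, 1)
    z[i0] <- "HOM_ALT"
    roles <- sample_roles("solo", carrier_class = "HOMOZYGOUS_CARRIER")
    tab <- build_cohort(pos, matrix(z, ncol = 1), roles, pos[i0])
    seg <- detect_segment(tab)
    # independent ROH computation: HET sites flanking the index delimit the
    # run; endpoints are the outermost HOM_ALT sites inside it
    hets <- which(z == "HET")
    lo <- max(c(0L, hets[hets < i0]))
    hi <- min(c(n + 1L, hets[hets > i0]))
    run <- (lo + 1L):(hi - 1L)
    alts <- run[z[run] == "HOM_ALT"]
    expect_equal(c(seg$start, seg$end), c(pos[min(alts)], pos[max(alts)]),
                 info = paste("seed", seed))
  }
})

test_that("a breaker wins over a consistent record at the same position", {
  roles <- five_sample_roles()
  geno <- rbind(c("HOM_ALT", "HOM_ALT", "HET", "HET", "HET"),
                c("HOM_ALT", "HOM_ALT", "HET", "HET", "HET"),
                c("HET", "HOM_ALT", "HET", "HET", "HET"),      # breaker at 300
                c("HOM_ALT", "HOM_ALT", "HET", "HET", "HET"))  # consistent at 300
  variants <- rbind(genomic_variant("1", 100, "A", "G"),
                    genomic_variant("1", 200, "A", "G"),
                    genomic_variant("1", 300, "A", "G"),
                    genomic_variant("1", 300, "A", "T"))
  colnames(geno) <- roles$sample_id
  tab <- cohort_table(variants, roles, geno, variants[2, ])
  seg <- detect_segment(tab)
  expect_equal(c(seg$start, seg$end), c(100L, 200L))
  expect_equal(seg$q_breaker$position, 300L)
})

test_that("max_uninformative_gap_bp bounds the scan's jumps", {
  roles <- five_sample_roles()
  cons <- c("HOM_ALT", "HOM_ALT", "HET", "HET", "HET")
  unin <- c("HOM_REF", "HOM_REF", "HET", "HOM_REF", "HET")
  geno <- rbind(cons, unin, cons, cons)
  tab <- build_cohort(c(100L, 5000L, 10000L, 10100L), geno, roles, 10000L)
  free <- detect_segment(tab)
  expect_equal(c(free$start, free$end), c(100L, 10100L))
  capped <- detect_segment(tab, max_uninformative_gap_bp = 2000)
  expect_equal(c(capped$start, capped$end), c(10000L, 10100L))
})

test_that("segment_length uses closed-interval arithmetic", {
  expect_equal(segment_length(21775527, 21861499), 85973L)
  expect_equal(segment_length(5, 5), 1L)
  expect_error(segment_length(10, 9), "exceeds")
  # brute-force position count on small intervals
  for (s in c(1L, 7L, 100L)) {
    for (e in s + c(0L, 1L, 13L)) {
      expect_equal(segment_length(s, e), length(s:e))
    }
  }
})
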