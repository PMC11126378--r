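test_that("the packaged cohort VCF reads with coverage-aware missingness", {
  tab <- fixture_cohort()
  expect_s3_class(tab, "cohort_gt")
  expect_equal(nrow(tab$variants), 19L)
  expect_equal(unname(index_zyg <- tab$genotypes["21839005:G:A", ]),
               c("HOM_ALT", "HOM_ALT", "HET", "HET", "HET"))
  # ./. in an exome sample stays MISSING; 0/0 in the genome sample is HOM_REF
  expect_equal(unname(tab$genotypes["21773254:T:C", "DDRD_P03"]), "MISSING")
  expect_equal(unname(tab$genotypes["21773254:T:C", "DDRD_P02"]), "HET")
  expect_equal(unname(tab$genotypes["21774210:G:A", "DDRD_P02"]), "HOM_REF")
  # the ACACAC insertion is carried as a left-anchored indel record
  expect_true("21815500:A:AACACAC" %in% rownames(tab$genotypes))
})

test_that("multi-allelic records are split into biallelic rows", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "A", "B"), collapse = "\t"),
               paste(c("1", "100", ".", "A", "G", ".", ".", ".", "GT", "1/1", "0/1"),
                     collapse = "\t"),
               paste(c("1", "200", ".", "C", "G,T", ".", ".", ".", "GT", "1/2", "0/2"),
                     collapse = "\t")), f)
  roles <- sample_roles(c("A", "B"), coverage_class = "GENOME")
  idx <- genomic_variant("1", 100, "A", "G")
  tab <- read_cohort_vcf(f, idx, roles, window_bp = 1000)
  expect_equal(rownames(tab$genotypes), c("100:A:G", "200:C:G", "200:C:T"))
  # sample A is 1/2 at 200: HET for each decomposed allele
  expect_equal(unname(tab$genotypes["200:C:G", ]), c("HET", "HOM_REF"))
  expect_equal(unname(tab$genotypes["200:C:T", ]), c("HET", "HET"))
})

test_that("VCF validation: unknown samples and unsorted files are rejected", {
  roles <- sample_roles(c("DDRD_P02", "GHOST"), coverage_class = "GENOME")
  idx <- genomic_variant("1", 21839005, "G", "A")
  expect_error(read_cohort_vcf(fs_extdata("ddrd_cohort.vcf"), idx, roles),
               "GHOST")

  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "A"), collapse = "\t"),
               paste(c("1", "200", ".", "A", "G", ".", ".", ".", "GT", "0/1"),
                     collapse = "\t"),
               paste(c("1", "100", ".", "C", "T", ".", ".", ".", "GT", "1/1"),
                     collapse = "\t")), f)
  expect_error(read_cohort_vcf(f, genomic_variant("1", 100, "C", "T"),
                               sample_roles("A"), window_bp = 1000),
               "unsorted")
})

test_that("a callable-regions BED turns exome no-calls into HOM_REF", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "A", "B"), collapse = "\t"),
               paste(c("1", "100", ".", "A", "G", ".", ".", ".", "GT", "1/1", "1/1"),
                     collapse = "\t"),
               paste(c("1", "150", ".", "C", "T", ".", ".", ".", "GT", "0/1", "./."),
                     collapse = "\t"),
               paste(c("1", "300", ".", "G", "A", ".", ".", ".", "GT", "0/1", "./."),
                     collapse = "\t")), f)
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t140\t200", bed)  # covers 150 (0-based half-open), not 300
  roles <- sample_roles(c("A", "B"), coverage_class = c("GENOME", "EXOME"))
  idx <- genomic_variant("1", 100, "A", "G")
  tab <- read_cohort_vcf(f, idx, roles, window_bp = 1000,
                         callable_bed = list(B = bed))
  expect_equal(unname(tab$genotypes[, "B"]), c("HOM_ALT", "HOM_REF", "MISSING"))
})

test_that("VCF read -> write -> read is a fixed point on the genotype matrix", {
  tab <- fixture_cohort()
  f <- tempfile(fileext = ".vcf")
  write_cohort_vcf(tab, f)
  roles <- read_roles(fs_extdata("ddrd_roles.tsv"))
  back <- read_cohort_vcf(f, tab$index_variant, roles)
  expect_identical(back$genotypes, tab$genotypes)
  expect_identical(back$variants[c("chrom", "pos", "ref", "alt")],
                   tab$variants[c("chrom", "pos", "ref", "alt")])
})

test_that("the packaged catalog loads with its documented partitions", {
  cat52 <- read_catalog(fs_extdata("hspg2_known_variants.tsv"))
  expect_equal(nrow(cat52), 52L)
  expect_equal(sum(cat52$disease == "SJS"), 44L)
  expect_equal(sum(cat52$disease == "DDSH"), 8L)
  # only coordinates the source lists under two tables recur across fixtures
  ddrd <- read_catalog(fs_extdata("ddrd_variants.tsv"))
  shared <- intersect(unique(ddrd$hgvs_c), unique(cat52$hgvs_c))
  expect_setequal(shared, c("c.9970G>A", "c.7006+1G>A"))
})

test_that("catalog validation rejects bad scores, labels and headers", {
  f <- tempfile(fileext = ".tsv")
  hdr <- paste(c("disease", "coordinate_grch38", "hgvs_c", "hgvs_p",
                 "consequence", "codon", "domain_label", "dbsnp", "hgmd",
                 "inmerf", "cadd", "dann"), collapse = "\t")
  writeLines(c(hdr, paste(c("SJS", "1", "c.1A>G", "p.M1V", "MISSENSE", "1", "",
                            "", "", "1.2", "", ""), collapse = "\t")), f)
  expect_error(read_catalog(f), "outside \\[0,1\\]")
  writeLines(c(hdr, paste(c("XYZ", "1", "c.1A>G", "", "SPLICING", "", "", "",
                            "", "", "", ""), collapse = "\t")), f)
  expect_error(read_catalog(f), "disease")
  writeLines(hdr, f)
  expect_equal(nrow(read_catalog(f)), 0L)
  writeLines("disease\thgvs_c", f)
  expect_error(read_catalog(f), "lacks column")
})

test_that("panel filtering keeps only panel genes, preserving order", {
  panel <- read_gene_panel(fs_extdata("skeletal_dysplasia_panel.txt"))
  expect_equal(length(panel), 62L)
  expect_true("HSPG2" %in% panel)
  ann <- data.frame(gene = c("HSPG2", "TTN", "BRCA1", "HSPG2", "COL2A1"),
                    pos = 1:5)
  kept <- filter_by_panel(ann, panel)
  expect_equal(kept$gene, c("HSPG2", "HSPG2", "COL2A1"))
  expect_equal(kept$pos, c(1L, 4L, 5L))
  expect_equal(nrow(filter_by_panel(ann[0, ], panel)), 0L)
  expect_equal(filter_by_panel(ann, unique(ann$gene)), ann)
})

test_that("segment reports round-trip bit-exactly, including random segments", {
  tab <- fixture_cohort()
  seg <- detect_segment(tab)
  f <- tempfile(fileext = ".tsv")
  write_segment_report(seg, f)
  back <- read_segment_report(f)
  expect_equal(back$start, 21775527L)
  expect_equal(back$end, 21861499L)
  expect_equal(back$length_bp, 85973L)
  expect_equal(back$p_breaker, seg$p_breaker)
  expect_equal(back$q_breaker, seg$q_breaker)
  expect_equal(back$supporting_sites, seg$supporting_sites)

  for (s in 1:20) {
    rs <- random_segment(s)
    write_segment_report(rs, f)
    back <- read_segment_report(f)
    expect_equal(back[c("start", "end", "length_bp", "p_breaker", "q_breaker",
                        "supporting_sites")],
                 unclass(rs)[c("start", "end", "length_bp", "p_breaker",
                               "q_breaker", "supporting_sites")],
                 info = paste("segment seed", s))
  }

  solo <- random_segment(99)
  solo$end <- solo$start
  solo$length_bp <- 1L
  solo$supporting_sites <- solo$start
  write_segment_report(solo, f)
  expect_equal(read_segment_report(f)$length_bp, 1L)
})
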