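# Variant catalog, gene panel, domain map and segment report I/O.

CATALOG_DISEASES <- c("SJS", "DDSH", "DDRD")
CATALOG_CONSEQUENCES <- c("MISSENSE", "NONSENSE", "FRAMESHIFT", "SPLICING",
                          "INFRAME", "OTHER")

#' Read a variant catalog TSV
#'
#' Reads the packaged catalog of published pathogenic *HSPG2* variants (or a
#' user table with the same schema). Required columns: `disease`,
#' `coordinate_grch38`, `hgvs_c`, `hgvs_p`, `consequence`, `codon`,
#' `domain_label`, `dbsnp`, `inmerf`, `cadd`, `dann`; optional extras (e.g.
#' `patient`, `zygosity`, `hgmd`) are carried through. Pathogenicity scores
#' are probabilities: 1.000 is most pathogenic and 0.000 least, and any score
#' outside `[0, 1]` is rejected. Missense records must carry a codon.
#'
#' @param path Path to the TSV.
#' @return `data.frame` of catalog records.
#' @examples
#' cat52 <- read_catalog(fs_extdata("hspg2_known_variants.tsv"))
#' nrow(cat52)  # 52
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", "na", ""))
  need <- c("disease", "coordinate_grch38", "hgvs_c", "hgvs_p", "consequence",
            "codon", "domain_label", "dbsnp", "inmerf", "cadd", "dann")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("catalog header lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) == 0L) return(d)
  bad <- !d$disease %in% CATALOG_DISEASES
  if (any(bad)) stop("unknown disease label: ", d$disease[bad][1L], call. = FALSE)
  bad <- !d$consequence %in% CATALOG_CONSEQUENCES
  if (any(bad)) stop("unknown consequence: ", d$consequence[bad][1L], call. = FALSE)
  for (col in c("inmerf", "cadd", "dann")) {
    x <- d[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      stop(sprintf("%s score outside [0,1] in row %d", col,
                   which(!is.na(x) & (x < 0 | x > 1))[1L]), call. = FALSE)
    }
  }
  if (any(d$consequence == "MISSENSE" & is.na(d$codon))) {
    stop("missense record without a codon", call. = FALSE)
  }
  d
}

#' Read a gene panel
#'
#' One gene symbol per line; lines starting with `#` are comments.
#'
#' @param path Path to the panel file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop("panel not found: ", path, call. = FALSE)
  x <- readLines(path)
  x <- trimws(x[!grepl("^\\s*#", x)])
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop("gene panel is empty", call. = FALSE)
  unique(x)
}

#' Filter gene-annotated variants by a panel
#'
#' Keeps only rows whose `gene` is in the panel; order is preserved and an
#' empty result is allowed.
#'
#' @param annotations `data.frame` with a `gene` column (plus variant fields).
#' @param panel Character vector of gene symbols ([read_gene_panel()]).
#' @return The filtered `data.frame`.
#' @export
filter_by_panel <- function(annotations, panel) {
  stopifnot(is.data.frame(annotations))
  if (!"gene" %in% names(annotations)) {
    stop("annotations must carry a gene column", call. = FALSE)
  }
  annotations[annotations$gene %in% panel, , drop = FALSE]
}

#' Write a shared-segment report
#'
#' Writes a one-row TSV with the segment endpoints, length, breaker evidence
#' and supporting-site count, plus a human-readable `.txt` companion. Numbers
#' are plain integers (no thousands separators) so the TSV round-trips
#' bit-exactly through [read_segment_report()].
#'
#' @param segment A `shared_segment` from [detect_segment()].
#' @param path Output TSV path; the text companion gets extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_segment_report <- function(segment, path) {
  stopifnot(inherits(segment, "shared_segment"))
  fmt_b <- function(b, field) {
    if (is.null(b)) NA else switch(field, position = b$position,
                                   sample = b$sample_id, reason = b$reason)
  }
  row <- data.frame(chrom = segment$chrom, start = segment$start,
                    end = segment$end, length_bp = segment$length_bp,
                    index_pos = segment$index_pos,
                    p_breaker_pos = fmt_b(segment$p_breaker, "position"),
                    p_breaker_sample = fmt_b(segment$p_breaker, "sample"),
                    p_breaker_reason = fmt_b(segment$p_breaker, "reason"),
                    q_breaker_pos = fmt_b(segment$q_breaker, "position"),
                    q_breaker_sample = fmt_b(segment$q_breaker, "sample"),
                    q_breaker_reason = fmt_b(segment$q_breaker, "reason"),
                    n_supporting = length(segment$supporting_sites),
                    supporting_sites = paste(segment$supporting_sites, collapse = ","),
                    window_start = segment$window[1L],
                    window_end = segment$window[2L],
                    stringsAsFactors = FALSE)
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- paste0(tools::file_path_sans_ext(path), ".txt")
  writeLines(utils::capture.output(print(segment)), txt)
  invisible(path)
}

#' Read a shared-segment report TSV back into a `shared_segment`
#'
#' @param path Path written by [write_segment_report()].
#' @return A `shared_segment` object equal (endpoints, length, breakers,
#'   supporting sites) to the one written.
#' @export
read_segment_report <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        supporting_sites = "character",
                                        p_breaker_sample = "character",
                                        p_breaker_reason = "character",
                                        q_breaker_sample = "character",
                                        q_breaker_reason = "character"))
  parse_b <- function(pos, sample, reason) {
    if (is.na(pos)) NULL else list(position = as.integer(pos),
                                   sample_id = sample, reason = reason)
  }
  supporting <- if (is.na(d$supporting_sites) || !nzchar(d$supporting_sites)) {
    integer(0)
  } else {
    as.integer(strsplit(d$supporting_sites, ",", fixed = TRUE)[[1]])
  }
  structure(list(chrom = as.character(d$chrom), start = as.integer(d$start),
                 end = as.integer(d$end), length_bp = as.integer(d$length_bp),
                 p_breaker = parse_b(d$p_breaker_pos, d$p_breaker_sample,
                                     d$p_breaker_reason),
                 q_breaker = parse_b(d$q_breaker_pos, d$q_breaker_sample,
                                     d$q_breaker_reason),
                 supporting_sites = supporting,
                 window = c(as.integer(d$window_start), as.integer(d$window_end)),
                 index_pos = as.integer(d$index_pos)),
            class = "shared_segment")
}

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return Absolute path (or a character vector of file names).
#' @export
fs_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "founderseg")))
  }
  p <- system.file("extdata", file, package = "founderseg")
  if (!nzchar(p)) stop("no packaged fixture named ", file, call. = FALSE)
  p
}
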