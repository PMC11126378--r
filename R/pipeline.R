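# End-to-end pipeline: (simulate |) detect -> annotate -> splice -> report.

#' Build a pipeline configuration
#'
#' Either from arguments or from a YAML file (`pipeline_config(yaml = path)`);
#' arguments override YAML keys.
#'
#' @param vcf,roles Paths to the cohort VCF and roles sidecar (detect mode).
#' @param index Index variant as `"chrom:pos:ref:alt"` (e.g.
#'   `"chr1:21839005:G:A"`) or a one-row variant `data.frame`.
#' @param catalog Path to the variant catalog TSV (annotate stage; optional).
#' @param domain_map Path to the domain map TSV (optional).
#' @param panel Path to a gene panel file (optional, recorded in the log).
#' @param splice_contexts,donor_scores Paths to a donor-context TSV and a
#'   9-mer score table (optional; the packaged synthetic fixtures are used
#'   when both are `NULL` and `splice = TRUE`).
#' @param out_dir Output directory for the report bundle.
#' @param window_bp Analysis half-window (default 5e6).
#' @param splice_margin,splice_floor Cryptic-activation thresholds.
#' @param splice Run the splice stage (default `TRUE` when contexts are
#'   available).
#' @param simulate A [sim_config()] to generate the cohort instead of reading
#'   `vcf`/`roles` (simulate mode).
#' @param seed Seed recorded in the log and used in simulate mode.
#' @param yaml Optional YAML file with any of the above keys.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, roles = NULL, index = NULL,
                            catalog = NULL, domain_map = NULL, panel = NULL,
                            splice_contexts = NULL, donor_scores = NULL,
                            out_dir = tempfile("founderseg_run_"),
                            window_bp = 5e6, splice_margin = 3.0,
                            splice_floor = 0.0, splice = TRUE,
                            simulate = NULL, seed = 1L, yaml = NULL) {
  cfg <- list(vcf = vcf, roles = roles, index = index, catalog = catalog,
              domain_map = domain_map, panel = panel,
              splice_contexts = splice_contexts, donor_scores = donor_scores,
              out_dir = out_dir, window_bp = window_bp,
              splice_margin = splice_margin, splice_floor = splice_floor,
              splice = splice, simulate = simulate, seed = as.integer(seed))
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    for (k in names(y)) if (is.null(cfg[[k]]) ||
                            identical(cfg[[k]], formals(pipeline_config)[[k]])) cfg[[k]] <- y[[k]]
  }
  if (is.null(cfg$simulate)) {
    for (p in c("vcf", "roles")) {
      if (is.null(cfg[[p]])) stop("pipeline config lacks path: ", p, call. = FALSE)
      if (!file.exists(cfg[[p]])) {
        stop(sprintf("pipeline config: %s file does not exist: %s", p, cfg[[p]]),
             call. = FALSE)
      }
    }
    if (is.null(cfg$index)) stop("pipeline config lacks the index variant", call. = FALSE)
  }
  if (cfg$window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

parse_index_spec <- function(index) {
  if (is.data.frame(index)) return(index)
  parts <- strsplit(index, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop("index spec must be chrom:pos:ref:alt, got ", index, call. = FALSE)
  }
  genomic_variant(parts[1L], as.integer(parts[2L]), parts[3L], parts[4L])
}

#' Run the analysis pipeline
#'
#' Stages: load (or simulate) the cohort; detect the shared founder segment
#' and write a segment report; summarize the variant catalog (per-disease
#' counts, missense score summary, domain-IV localization) when a catalog is
#' configured; classify splice-donor outcomes when contexts are configured;
#' write a run log with per-stage counts and a config hash. Outputs are
#' deterministic given inputs (plus the seed in simulate mode); timestamps are
#' confined to the log.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `segment`, `annotation` summary,
#'   `splice` outcomes and output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("founderseg %s", as.character(utils::packageVersion("founderseg"))),
                 sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("config hash: %s", config_hash(config)),
                 sprintf("seed: %d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # stage 1: cohort
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      cfg <- config$simulate
      cfg$seed <- config$seed
      simulate_cohort(cfg)
    })
    table <- sim$table
    roles <- sim$roles
    write_cohort_vcf(table, file.path(config$out_dir, "simulated_cohort.vcf"))
    log_lines <- c(log_lines, sprintf("simulate: %d markers x %d samples",
                                      nrow(table$variants), nrow(roles)))
  } else {
    table <- stage("load", {
      roles <- read_roles(config$roles)
      read_cohort_vcf(config$vcf, parse_index_spec(config$index), roles,
                      window_bp = config$window_bp)
    })
    roles <- derive_roles(table)
    log_lines <- c(log_lines, sprintf("load: %d variants x %d samples in window",
                                      nrow(table$variants), nrow(roles)))
  }

  # stage 2: founder segment
  segment <- stage("detect", detect_segment(table, roles))
  seg_path <- file.path(config$out_dir, "segment_report.tsv")
  write_segment_report(segment, seg_path)
  log_lines <- c(log_lines,
                 sprintf("detect: segment chr%s:%d-%d (%d bp), %d supporting sites",
                         segment$chrom, segment$start, segment$end,
                         segment$length_bp, length(segment$supporting_sites)))

  # stage 3: catalog annotation summary
  annotation <- NULL
  if (!is.null(config$catalog)) {
    annotation <- stage("annotate", {
      cat_tab <- read_catalog(config$catalog)
      counts <- catalog_counts(cat_tab)
      rows <- data.frame(statistic = sprintf("n_variants_%s", names(counts)),
                         value = as.numeric(counts), stringsAsFactors = FALSE)
      sjs_mis <- cat_tab[cat_tab$disease == "SJS" &
                           cat_tab$consequence == "MISSENSE", ]
      if (nrow(sjs_mis) >= 2L) {
        ss <- score_summary(sjs_mis$inmerf)
        rows <- rbind(rows,
                      data.frame(statistic = c("sjs_missense_n",
                                               "sjs_missense_inmerf_mean",
                                               "sjs_missense_inmerf_sd"),
                                 value = c(ss$n, ss$mean_3, ss$sd_3)))
      }
      if (!is.null(config$domain_map)) {
        dm <- read_domain_map(config$domain_map)
        for (lbl in dm$domain_label) {
          rows <- rbind(rows, data.frame(
            statistic = sprintf("sjs_missense_in_%s", gsub("\\s+", "_", lbl)),
            value = count_missense_in_domain(cat_tab, "SJS", dm, lbl)))
        }
      }
      rows
    })
    utils::write.table(annotation, file.path(config$out_dir, "annotation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("annotate: %d summary statistics",
                                      nrow(annotation)))
  }

  # stage 4: splice outcomes
  splice_tab <- NULL
  if (isTRUE(config$splice)) {
    splice_tab <- stage("splice", {
      if (is.null(config$splice_contexts) || is.null(config$donor_scores)) {
        fx <- hspg2_donor_fixtures()
        contexts <- fx$contexts
        scorer <- fx$scorer
        auth <- fx$authentic_scores
      } else {
        ctx_tab <- utils::read.delim(config$splice_contexts, stringsAsFactors = FALSE)
        contexts <- lapply(seq_len(nrow(ctx_tab)), function(i) {
          donor_context(ctx_tab$sequence[i], ctx_tab$authentic_offset[i],
                        exon_length_bp = ctx_tab$exon_length_bp[i],
                        name = ctx_tab$name[i])
        })
        names(contexts) <- ctx_tab$name
        scorer <- lookup_scorer(config$donor_scores)
        auth <- stats::setNames(ctx_tab$authentic_score, ctx_tab$name)
      }
      do.call(rbind, lapply(names(contexts), function(nm) {
        o <- predict_splice_outcome(contexts[[nm]], scorer, auth[[nm]],
                                    margin = config$splice_margin,
                                    floor = config$splice_floor)
        data.frame(variant = nm, predicted_outcome = o$outcome,
                   authentic_score = o$authentic_score,
                   best_candidate_offset = o$best_offset,
                   best_candidate_score = o$best_score,
                   exon_length_bp = o$exon_length_bp, stringsAsFactors = FALSE)
      }))
    })
    utils::write.table(splice_tab, file.path(config$out_dir, "splice_outcomes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, sprintf("splice: %d contexts classified",
                                      nrow(splice_tab)))
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(segment = segment, annotation = annotation, splice = splice_tab,
                 paths = list(out_dir = config$out_dir, segment = seg_path)))
}

config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(x)), f)
  unname(tools::md5sum(f))
}
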