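# End-to-end orchestration: configuration, stage composition, report.

#' Build a pipeline configuration
#'
#' Collects every stage parameter with its standard default: 3' adapter
#' trimming (min overlap 8, <= 1 mismatch), inclusive 16-35 nt length
#' filter, <= 2 annotation mismatches, 70 nt candidate flanks, fold-change
#' threshold 1.5, isomiR bounds (5' <= 3, 3' <= 4, <= 2 non-templated nt),
#' hairpin rules (stem score >= 25, loop 3-20 nt, >= 60% mature pairing),
#' 5 kb RCGTG promoter scan, and >= 3-source target consensus. The
#' configuration serializes round-trip through YAML.
#'
#' @param fastq Named list/vector with `normoxic` and `hypoxic` FASTQ
#'   paths (optional when simulating in memory).
#' @param reference Path to a reference bundle directory written by
#'   [write_reference_bundle()] (in-memory bundles may be passed directly
#'   to [run_pipeline()]).
#' @param outdir Output directory.
#' @param seed Master seed recorded in the run log.
#' @param adapter,min_overlap,adapter_mismatches Trimming parameters.
#' @param min_len,max_len Length filter bounds.
#' @param max_mismatches Annotation mismatch bound (non-mature stages).
#' @param flank Candidate precursor flank (nt).
#' @param de_threshold,de_metric,pseudocount Differential-call parameters.
#' @param isomir_shift5,isomir_shift3,isomir_nta isomiR grouping bounds.
#' @param hairpin_min_score,hairpin_loop_min,hairpin_loop_max,
#'   hairpin_min_paired Hairpin filter parameters.
#' @param hre_span,hre_pattern Promoter scan parameters.
#' @param min_support,prediction_sets Target-consensus parameters
#'   (`prediction_sets`: named file paths, optional).
#' @param cluster_max_gap Cluster chaining distance (nt).
#' @return A `hypoxamir_config` list.
#' @export
pipeline_config <- function(fastq = NULL, reference = NULL, outdir = NULL,
                            seed = 1L,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_overlap = 8L, adapter_mismatches = 1L,
                            min_len = 16L, max_len = 35L,
                            max_mismatches = 2L, flank = 70L,
                            de_threshold = 1.5, de_metric = "tpm",
                            pseudocount = 1L,
                            isomir_shift5 = 3L, isomir_shift3 = 4L,
                            isomir_nta = 2L,
                            hairpin_min_score = 25L,
                            hairpin_loop_min = 3L, hairpin_loop_max = 20L,
                            hairpin_min_paired = 0.6,
                            hre_span = 5000L, hre_pattern = "RCGTG",
                            min_support = 3L, prediction_sets = NULL,
                            cluster_max_gap = 10000L) {
  cfg <- list(
    fastq = fastq, reference = reference, outdir = outdir,
    seed = as.integer(seed), adapter = adapter,
    min_overlap = as.integer(min_overlap),
    adapter_mismatches = as.integer(adapter_mismatches),
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    max_mismatches = as.integer(max_mismatches), flank = as.integer(flank),
    de_threshold = de_threshold, de_metric = de_metric,
    pseudocount = as.integer(pseudocount),
    isomir_shift5 = as.integer(isomir_shift5),
    isomir_shift3 = as.integer(isomir_shift3),
    isomir_nta = as.integer(isomir_nta),
    hairpin_min_score = as.integer(hairpin_min_score),
    hairpin_loop_min = as.integer(hairpin_loop_min),
    hairpin_loop_max = as.integer(hairpin_loop_max),
    hairpin_min_paired = hairpin_min_paired,
    hre_span = as.integer(hre_span), hre_pattern = hre_pattern,
    min_support = as.integer(min_support),
    prediction_sets = prediction_sets,
    cluster_max_gap = as.integer(cluster_max_gap))
  class(cfg) <- c("hypoxamir_config", "list")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks parameter sanity before any compute; aborts with a
#' `hypoxamir_config_error` on violation.
#'
#' @param cfg A `hypoxamir_config`.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "hypoxamir_config_error")
  if (cfg$min_len > cfg$max_len) fail("min_len must be <= max_len")
  if (cfg$min_len <= 0L) fail("length bounds must be positive")
  if (cfg$min_overlap < 1L) fail("min_overlap must be >= 1")
  if (cfg$max_mismatches < 0L) fail("max_mismatches must be >= 0")
  if (cfg$de_threshold <= 1) fail("de_threshold must exceed 1")
  if (!cfg$de_metric %in% c("tpm", "rpkm")) fail("de_metric: tpm or rpkm")
  if (cfg$flank < 0L) fail("flank must be >= 0")
  if (cfg$hre_span < 1L) fail("hre_span must be >= 1")
  if (cfg$hairpin_loop_min > cfg$hairpin_loop_max) {
    fail("hairpin loop bounds out of order")
  }
  invisible(cfg)
}

#' Read and write pipeline configurations (YAML)
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` a `hypoxamir_config`;
#'   `write_pipeline_config()` the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param cfg A `hypoxamir_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a reference bundle directory
#'
#' Counterpart of [write_reference_bundle()]: reads the FASTA databases,
#' the precursor/exon GFF3 files and the cluster/HRE TSVs back into an
#' `srna_reference`.
#'
#' @param dir Bundle directory.
#' @return An `srna_reference` list.
#' @export
read_reference_bundle <- function(dir) {
  rfa <- function(p) {
    x <- Biostrings::readDNAStringSet(p)
    setNames(as.character(x), sub(" .*", "", names(x)))
  }
  genome <- rfa(file.path(dir, "genome.fa"))
  ncrna <- rfa(file.path(dir, "ncrna.fa"))
  gff <- function(p) {
    if (!file.exists(p)) return(NULL)
    as.data.frame(rtracklayer::import(p, format = "gff3"))
  }
  pg <- gff(file.path(dir, "precursors.gff3"))
  precursors <- tibble(
    name = pg$ID, mirna = pg$mirna,
    seq = unname(ncrna[pg$ID]),
    contig = as.character(pg$seqnames), start = pg$start, end = pg$end,
    strand = as.character(pg$strand), arm = pg$arm,
    mat_start = as.integer(pg$mat_start), mat_end = as.integer(pg$mat_end))
  eg <- gff(file.path(dir, "exons.gff3"))
  exons <- if (is.null(eg)) {
    tibble(exon_id = character(), contig = character(),
           start = integer(), end = integer(), strand = character())
  } else {
    tibble(exon_id = eg$ID, contig = as.character(eg$seqnames),
           start = eg$start, end = eg$end, strand = as.character(eg$strand))
  }
  rtsv <- function(p) {
    if (!file.exists(p)) return(NULL)
    as_tibble(utils::read.delim(p, stringsAsFactors = FALSE))
  }
  structure(list(
    genome = genome,
    exons = exons,
    mature = rfa(file.path(dir, "mature.fa")),
    precursors = precursors,
    other_ncrna = ncrna,
    pirnas = rfa(file.path(dir, "pirna.fa")),
    rna_db = rfa(file.path(dir, "rna_db.fa")),
    clusters = rtsv(file.path(dir, "clusters.tsv")) %||%
      tibble(cluster = character(), mirna = character()),
    hairpins = tibble(),
    hres = rtsv(file.path(dir, "planted_hres.tsv")) %||% tibble(),
    params = list(promoter_span = 5000L)
  ), class = "srna_reference")
}

#' Run the full small-RNA analysis pipeline
#'
#' Composes preprocessing, elimination annotation, quantification and
#' differential calling, cluster co-regulation, isomiR cataloguing,
#' novel-miRNA prediction, promoter HRE scanning and (when prediction
#' sets are configured) target consensus, for a normoxic/hypoxic library
#' pair. Re-running with an identical configuration reproduces the
#' outputs byte for byte.
#'
#' @param config A `hypoxamir_config` from [pipeline_config()].
#' @param reference Optional in-memory `srna_reference` overriding
#'   `config$reference`.
#' @param libraries Optional named list of preprocessed `tag_library`
#'   objects (`normoxic`, `hypoxic`) to skip FASTQ reading.
#' @return A `hypoxamir_run` list with per-stage tibbles (`tags`,
#'   `annotation`, `expression`, `differential`, `coregulation`,
#'   `isomirs`, `isomir_summary`, `novel`, `hre`, `targets`, `summary`);
#'   supports [tidy()], [glance()] and [autoplot()].
#' @export
run_pipeline <- function(config, reference = NULL, libraries = NULL) {
  validate_config(config)
  ref <- reference %||% config$reference
  if (is.character(ref)) ref <- read_reference_bundle(ref)
  if (!inherits(ref, "srna_reference")) abort("a reference bundle is required")
  conds <- c("normoxic", "hypoxic")

  # --- preprocess ---------------------------------------------------------
  if (is.null(libraries)) {
    if (is.null(config$fastq)) abort("config$fastq or `libraries` required")
    libraries <- lapply(conds, function(cond) {
      preprocess_fastq(config$fastq[[cond]], adapter = config$adapter,
                       min_overlap = config$min_overlap,
                       max_mismatches = config$adapter_mismatches,
                       min_len = config$min_len, max_len = config$max_len,
                       sample_id = cond, condition = cond)
    })
    names(libraries) <- conds
  }

  # --- annotate -----------------------------------------------------------
  annotation <- lapply(libraries, eliminate_hierarchy, ref = ref,
                       max_mismatches = config$max_mismatches)

  # --- quantify + differential -------------------------------------------
  expression <- lapply(annotation, mirna_expression, mature_set = ref$mature)
  de <- call_differential(expression$normoxic, expression$hypoxic,
                          threshold = config$de_threshold,
                          metric = config$de_metric,
                          pseudocount = config$pseudocount)
  clusters <- if (nrow(ref$clusters %||% tibble()) > 0) {
    ref$clusters
  } else {
    mirna_clusters(ref$precursors, config$cluster_max_gap)
  }
  coreg <- cluster_coregulation(de, clusters)

  # --- isomiRs ------------------------------------------------------------
  all_tags <- dplyr::bind_rows(lapply(conds, function(cond) {
    tibble(tag = libraries[[cond]]$tag, count = libraries[[cond]]$count,
           condition = cond)
  }))
  isomirs <- dplyr::bind_rows(lapply(names(ref$mature), function(mn) {
    p <- ref$precursors[ref$precursors$mirna == mn, ]
    grp <- group_isomirs(all_tags, p$seq, ref$mature[[mn]],
                         max_shift5 = config$isomir_shift5,
                         max_shift3 = config$isomir_shift3,
                         max_nta = config$isomir_nta,
                         exclude = ref$mature[names(ref$mature) != mn])
    if (nrow(grp) > 0) grp$mirna <- mn
    grp
  }))
  isomir_summary <- isomir_condition_summary(isomirs)

  # --- novel miRNAs -------------------------------------------------------
  candidates <- lapply(annotation, extract_genomic_candidates,
                       genome = ref$genome, flank = config$flank)
  novel <- predict_novel(candidates, libraries,
                         min_score = config$hairpin_min_score,
                         loop_range = c(config$hairpin_loop_min,
                                        config$hairpin_loop_max),
                         min_paired_frac = config$hairpin_min_paired)

  # --- promoter HREs of up-regulated miRNAs ------------------------------
  up <- de$mirna[de$direction == "up"]
  hre <- if (length(up) > 0) {
    loci <- ref$precursors[ref$precursors$mirna %in% up, ]
    scan_hre(extract_upstream(loci, ref$genome, span = config$hre_span),
             pattern = config$hre_pattern)
  } else {
    scan_hre(extract_upstream(ref$precursors[0, ], ref$genome))
  }

  # --- target consensus ---------------------------------------------------
  targets <- if (!is.null(config$prediction_sets)) {
    consensus_targets(read_prediction_sets(unlist(config$prediction_sets)),
                      min_support = config$min_support)
  } else {
    tibble(gene = character(), support = integer(), sources = character())
  }

  # --- summary ------------------------------------------------------------
  class_tbl <- dplyr::bind_rows(lapply(conds, function(cond) {
    annotation[[cond]] |>
      dplyr::group_by(class = .data$class) |>
      dplyr::summarise(reads = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(condition = cond,
                    pct = 100 * .data$reads / sum(.data$reads))
  }))
  stats <- dplyr::bind_rows(lapply(conds, function(cond) {
    st <- attr(libraries[[cond]], "stats") %||%
      tibble(reads_in = NA_integer_, no_adapter = NA_integer_,
             length_fail = NA_integer_,
             reads_kept = total_clone_count(libraries[[cond]]))
    st$condition <- cond
    st
  }))
  run <- structure(list(
    tags = libraries, annotation = annotation, expression = expression,
    differential = de, clusters = clusters, coregulation = coreg,
    isomirs = isomirs, isomir_summary = isomir_summary, novel = novel,
    hre = hre, targets = targets,
    summary = list(classes = class_tbl, preprocess = stats),
    config = config
  ), class = "hypoxamir_run")

  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

# Write all stage tables; fixed column order, 4-decimal floats.
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    df <- as.data.frame(df)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], round, 4L)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  for (cond in names(run$tags)) {
    write_tag_library(run$tags[[cond]],
                      tsv = file.path(outdir, paste0("tags_", cond, ".tsv")),
                      fasta = file.path(outdir, paste0("tags_", cond, ".fa")))
    write_annotation(run$annotation[[cond]],
                     file.path(outdir, paste0("annotation_", cond, ".tsv")))
    wt(run$expression[[cond]], paste0("expression_", cond, ".tsv"))
  }
  wt(run$differential, "differential.tsv")
  wt(run$coregulation, "cluster_coregulation.tsv")
  wt(run$isomirs, "isomirs.tsv")
  wt(run$isomir_summary, "isomir_summary.tsv")
  wt(run$novel, "novel_mirnas.tsv")
  write_hre_hits(run$hre, tsv = file.path(outdir, "hre_hits.tsv"),
                 bed = file.path(outdir, "hre_hits.bed"))
  wt(run$targets, "targets.tsv")
  wt(run$summary$classes, "summary_classes.tsv")
  wt(run$summary$preprocess, "summary_preprocess.tsv")
  log <- unclass(run$config)
  log <- log[!vapply(log, is.null, logical(1))]
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  invisible(outdir)
}

#' @export
print.hypoxamir_run <- function(x, ...) {
  g <- glance(x)
  cat("# hypoxamiR pipeline run\n")
  cat(sprintf("#   reads kept: %s normoxic, %s hypoxic\n",
              fmt_num(g$reads_normoxic), fmt_num(g$reads_hypoxic)))
  cat(sprintf("#   miRNA read fraction: %.1f%% / %.1f%%\n",
              g$mirna_pct_normoxic, g$mirna_pct_hypoxic))
  cat(sprintf("#   differential: %d up, %d down (threshold %.2g)\n",
              g$n_up, g$n_down, x$config$de_threshold))
  cat(sprintf("#   novel miRNAs: %d; HRE-bearing promoters: %d; isomiR species: %d\n",
              g$n_novel, g$n_hre_mirnas, g$n_isomir_species))
  invisible(x)
}

#' Tidy a pipeline run
#'
#' @param x A `hypoxamir_run`.
#' @param table Which stage table to return: `"differential"`,
#'   `"expression"`, `"annotation"`, `"isomirs"`, `"isomir_summary"`,
#'   `"novel"`, `"hre"`, `"targets"`, `"coregulation"`, `"classes"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy hypoxamir_run
#' @export
tidy.hypoxamir_run <- function(x, table = "differential", ...) {
  switch(table,
    differential = x$differential,
    expression = dplyr::bind_rows(lapply(names(x$expression), function(cn) {
      dplyr::mutate(x$expression[[cn]], condition = cn)
    })),
    annotation = dplyr::bind_rows(lapply(names(x$annotation), function(cn) {
      dplyr::mutate(as_tibble(x$annotation[[cn]]), condition = cn)
    })),
    isomirs = x$isomirs,
    isomir_summary = x$isomir_summary,
    novel = as_tibble(x$novel),
    hre = as_tibble(x$hre),
    targets = x$targets,
    coregulation = x$coregulation,
    classes = x$summary$classes,
    abort(sprintf("unknown table '%s'", table)))
}

#' One-row summary of a pipeline run
#'
#' @param x A `hypoxamir_run`.
#' @param ... Unused.
#' @return One-row tibble with library sizes, miRNA read percentages,
#'   differential/novel/HRE/isomiR totals.
#' @method glance hypoxamir_run
#' @export
glance.hypoxamir_run <- function(x, ...) {
  cls <- x$summary$classes
  pct <- function(cond) {
    v <- cls$pct[cls$condition == cond & cls$class == "mature_miRNA"]
    if (length(v) == 0) 0 else v
  }
  tibble(
    reads_normoxic = total_clone_count(x$tags$normoxic),
    reads_hypoxic = total_clone_count(x$tags$hypoxic),
    tags_normoxic = nrow(x$tags$normoxic),
    tags_hypoxic = nrow(x$tags$hypoxic),
    mirna_pct_normoxic = pct("normoxic"),
    mirna_pct_hypoxic = pct("hypoxic"),
    n_up = sum(x$differential$direction == "up"),
    n_down = sum(x$differential$direction == "down"),
    n_novel = nrow(x$novel),
    n_hre_mirnas = dplyr::n_distinct(x$hre$mirna),
    n_isomir_species = nrow(x$isomirs))
}
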