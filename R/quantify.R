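# Normalization and differential expression.
#
# TPM ("transcript parts per million"): read count divided by the total
# clone count of the sample, times 10^6. RPKM (as used for mature miRNAs
# here): TPM divided by the nucleotide length of the mature miRNA, so
# RPKM * length = TPM exactly. Differential expression is a fold-change
# call with the minimum threshold 1.5 (strict inequality).

#' TPM normalization
#'
#' @param count Read count(s), `0 <= count <= total_clone_count`.
#' @param total_clone_count Total reads in the library (> 0).
#' @return `count / total_clone_count * 1e6`.
#' @export
#' @examples
#' normalize_tpm(396, 7297894)
normalize_tpm <- function(count, total_clone_count) {
  if (any(total_clone_count <= 0)) {
    abort("total clone count must be > 0 (undefined library)",
          class = "hypoxamir_undefined_library")
  }
  if (any(count < 0) || any(count > total_clone_count)) {
    abort("counts must lie in [0, total_clone_count]")
  }
  count / total_clone_count * 1e6
}

#' RPKM normalization (TPM per nucleotide of mature length)
#'
#' @param tpm TPM value(s).
#' @param length Mature miRNA length(s) in nt (>= 1).
#' @return `tpm / length`.
#' @export
normalize_rpkm <- function(tpm, length) {
  if (any(length < 1)) abort("mature length must be >= 1")
  tpm / length
}

#' Fold change between conditions on the TPM scale
#'
#' `FC = TPM(count_h + s, total_h) / TPM(count_n + s, total_n)`, where the
#' pseudocount `s` is added to both raw counts only when either of them is
#' zero, keeping folds finite for condition-specific miRNAs without biasing
#' abundant ones. Swapping conditions yields `1/FC`.
#'
#' @param count_h,total_h Hypoxic count and library total clone count.
#' @param count_n,total_n Normoxic count and library total clone count.
#' @param pseudocount Pseudocount `s` (default 1 raw read).
#' @return Numeric fold change(s), hypoxic over normoxic.
#' @export
#' @examples
#' compute_fold_change(7252, 5256222, 396, 7297894)  # ~25
compute_fold_change <- function(count_h, total_h, count_n, total_n,
                                pseudocount = 1L) {
  s <- ifelse(count_h == 0 | count_n == 0, pseudocount, 0)
  th <- (count_h + s) / total_h * 1e6
  tn <- (count_n + s) / total_n * 1e6
  th / tn
}

#' Mature miRNA expression table for one library
#'
#' Sums exact-mature tag counts per miRNA (zero for undetected miRNAs) and
#' attaches TPM and RPKM. TPM uses the library's total clone count, so the
#' sum of TPM over the complete tag set of a library is 10^6.
#'
#' @param anno An `annotation_table` (or a `tag_library` plus
#'   `mature_set`).
#' @param mature_set Named mature sequences (lengths taken from these).
#' @param total_clone_count Library total; defaults to the annotation's
#'   attribute.
#' @return Tibble: `mirna`, `length`, `count`, `tpm`, `rpkm`.
#' @export
mirna_expression <- function(anno, mature_set,
                             total_clone_count = NULL) {
  total <- total_clone_count %||% attr(anno, "total_clone_count")
  if (is.null(total)) abort("total_clone_count is required")
  hits <- anno[anno$class == "mature_miRNA", c("ref", "count")]
  counts <- setNames(rep(0L, length(mature_set)), names(mature_set))
  if (nrow(hits) > 0) {
    agg <- tapply(hits$count, hits$ref, sum)
    counts[names(agg)] <- as.integer(agg)
  }
  out <- tibble(
    mirna = names(mature_set),
    length = nchar(mature_set),
    count = unname(counts),
    tpm = normalize_tpm(unname(counts), total))
  out$rpkm <- normalize_rpkm(out$tpm, out$length)
  attr(out, "total_clone_count") <- total
  attr(out, "condition") <- attr(anno, "condition")
  out
}

#' Call differentially expressed miRNAs by fold change
#'
#' Pairs a normoxic and a hypoxic expression table, computes the
#' pseudocounted fold change (hypoxic/normoxic) on the TPM (default) or
#' RPKM scale, and labels each miRNA `up` (FC > threshold), `down`
#' (FC < 1/threshold) or `unchanged`. Equality with the threshold is
#' `unchanged` (strict inequality).
#'
#' @param expr_n,expr_h Expression tables from [mirna_expression()]
#'   (normoxic and hypoxic).
#' @param threshold Minimum fold change (default 1.5).
#' @param metric `"tpm"` or `"rpkm"`; for equal mature lengths both give
#'   identical calls.
#' @param pseudocount Passed to [compute_fold_change()].
#' @return A `hypoxamir_de` tibble sorted by `|log2 fc|` descending:
#'   `mirna`, `count_n`, `count_h`, `tpm_n`, `tpm_h`, `fc`, `log2_fc`,
#'   `direction`, `threshold`.
#' @export
call_differential <- function(expr_n, expr_h, threshold = 1.5,
                              metric = c("tpm", "rpkm"), pseudocount = 1L) {
  metric <- match.arg(metric)
  stopifnot(identical(expr_n$mirna, expr_h$mirna))
  tot_n <- attr(expr_n, "total_clone_count")
  tot_h <- attr(expr_h, "total_clone_count")
  # the per-nt RPKM scaling cancels in the hypoxic/normoxic ratio (the
  # mature length is condition-independent), so both metrics give the same
  # folds; the argument is kept so callers can state which scale they used
  fc <- compute_fold_change(expr_h$count, tot_h, expr_n$count, tot_n,
                            pseudocount)
  out <- tibble(
    mirna = expr_n$mirna,
    count_n = expr_n$count, count_h = expr_h$count,
    tpm_n = expr_n$tpm, tpm_h = expr_h$tpm,
    fc = fc, log2_fc = log2(fc),
    direction = dplyr::case_when(
      fc > threshold ~ "up",
      fc < 1 / threshold ~ "down",
      .default = "unchanged"),
    threshold = threshold) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2_fc)), .data$mirna)
  class(out) <- c("hypoxamir_de", class(out))
  out
}

#' Derive genomic miRNA clusters from precursor loci
#'
#' Chains precursors on the same contig and strand whose starts lie within
#' `max_gap` of the previous member (default 10 kb, the usual miRNA cluster
#' convention); singleton groups are dropped.
#'
#' @param precursors Tibble with `mirna`, `contig`, `start`, `end`,
#'   `strand`.
#' @param max_gap Maximum start-to-start distance within a cluster (nt).
#' @return Tibble: `cluster`, `mirna`.
#' @export
mirna_clusters <- function(precursors, max_gap = 10000L) {
  pr <- dplyr::arrange(precursors, .data$contig, .data$strand, .data$start)
  grp <- cumsum(
    c(TRUE, pr$contig[-1] != pr$contig[-nrow(pr)] |
        pr$strand[-1] != pr$strand[-nrow(pr)] |
        pr$start[-1] - pr$start[-nrow(pr)] > max_gap))
  out <- tibble(grp = grp, mirna = pr$mirna) |>
    dplyr::group_by(.data$grp) |>
    dplyr::filter(dplyr::n() > 1L) |>
    dplyr::ungroup()
  tibble(cluster = sprintf("cluster_%d", match(out$grp, unique(out$grp))),
         mirna = out$mirna)
}

#' Cluster co-regulation summary
#'
#' For each cluster: members found in the differential table, number up and
#' down, and a co-regulation flag (at least one regulated member and all
#' regulated members share the same direction). miRNAs listed in the
#' cluster map but absent from the table are skipped with a warning.
#'
#' @param de A `hypoxamir_de` table from [call_differential()].
#' @param clusters Tibble with columns `cluster`, `mirna`.
#' @return Tibble: `cluster`, `members`, `n_members`, `n_up`, `n_down`,
#'   `co_regulated`, `direction`.
#' @export
cluster_coregulation <- function(de, clusters) {
  missing <- setdiff(clusters$mirna, de$mirna)
  if (length(missing) > 0) {
    warn(sprintf("cluster members absent from the expression table: %s",
                 paste(missing, collapse = ", ")))
    clusters <- clusters[!clusters$mirna %in% missing, , drop = FALSE]
  }
  dplyr::left_join(clusters, de[, c("mirna", "direction")], by = "mirna") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      members = paste(.data$mirna, collapse = ","),
      n_members = dplyr::n(),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      co_regulated = (.data$n_up + .data$n_down > 0) &
        (.data$n_up == 0 | .data$n_down == 0),
      direction = dplyr::case_when(
        !.data$co_regulated ~ "mixed_or_none",
        .data$n_up > 0 ~ "up",
        .default = "down"),
      .groups = "drop")
}

#' Pearson product-moment correlation
#'
#' A validated wrapper: requires equal lengths of at least 3 and nonzero
#' variance in both vectors, then returns the standard product-moment `r`.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (length(x) < 3L) abort("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for zero-variance input",
          class = "hypoxamir_zero_variance")
  }
  cor(x, y, method = "pearson")
}
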