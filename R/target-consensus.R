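# Target prediction: canonical seed-match site discovery and the
# >= 3-of-N consensus combiner over multiple prediction sources.

#' Find canonical seed-match sites in a 3' UTR
#'
#' Scans the UTR for the reverse complement of the miRNA seed (positions
#' 2-7, the 6mer core) and classifies each occurrence by the canonical
#' taxonomy: an additional match to position 8 immediately 5' of the core
#' in the UTR gives 7mer-m8, an adenine immediately 3' of the core
#' (opposite miRNA position 1) gives 7mer-A1, both give 8mer, neither
#' gives 6mer. Types are mutually exclusive per locus with priority
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer.
#'
#' @param utr 3' UTR sequence (DNA, 5'->3'). Shorter than 6 nt yields an
#'   empty result.
#' @param mirna Mature miRNA sequence (RNA or DNA), length >= 8.
#' @return Tibble: `site_type`, `start` (1-based UTR position of the
#'   site), `site_seq` (the matched UTR subsequence including the m8/A1
#'   positions where applicable), sorted by `start`.
#' @export
#' @examples
#' find_seed_sites("AAACACTGTGCAA", "UCACAGUGAACC")  # 7mer-m8 site
find_seed_sites <- function(utr, mirna) {
  mirna <- toupper(rna_to_dna(mirna))
  if (nchar(mirna) < 8L) abort("miRNA must be at least 8 nt")
  utr <- toupper(rna_to_dna(utr))
  empty <- tibble(site_type = character(), start = integer(),
                  site_seq = character())
  if (nchar(utr) < 6L) return(empty)
  core <- revcomp(substr(mirna, 2L, 7L))           # 6mer match
  m8c <- chartr("ACGT", "TGCA", substr(mirna, 8L, 8L))  # base pairing nt 8
  hits <- gregexpr(core, utr, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(empty)
  rows <- lapply(as.integer(hits), function(p) {
    has_m8 <- p > 1L && substr(utr, p - 1L, p - 1L) == m8c
    has_a1 <- p + 6L <= nchar(utr) && substr(utr, p + 6L, p + 6L) == "A"
    if (has_m8 && has_a1) {
      tibble(site_type = "8mer", start = p - 1L,
             site_seq = substr(utr, p - 1L, p + 6L))
    } else if (has_m8) {
      tibble(site_type = "7mer-m8", start = p - 1L,
             site_seq = substr(utr, p - 1L, p + 5L))
    } else if (has_a1) {
      tibble(site_type = "7mer-A1", start = p,
             site_seq = substr(utr, p, p + 6L))
    } else {
      tibble(site_type = "6mer", start = p,
             site_seq = substr(utr, p, p + 5L))
    }
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$start)
}

#' Combine target predictions by source consensus
#'
#' Keeps genes predicted by at least `min_support` of the supplied
#' prediction sources (the rule applied to the 11 external programs in
#' hypoxamiR target screens; the built-in seed matcher can serve as one
#' source).
#'
#' @param prediction_sets Either a named list of character vectors of gene
#'   ids (one per source) or a two-column data frame `source`, `gene`.
#' @param min_support Minimum number of supporting sources (default 3).
#' @return Tibble: `gene`, `support`, `sources` (comma-separated), sorted
#'   by support descending then gene id. Permuting the input sources
#'   leaves the result identical.
#' @export
#' @examples
#' consensus_targets(list(p1 = c("A", "B", "C"), p2 = c("A", "B"),
#'                        p3 = c("A", "C"), p4 = "A"), min_support = 3)
consensus_targets <- function(prediction_sets, min_support = 3L) {
  if (is.data.frame(prediction_sets)) {
    stopifnot(all(c("source", "gene") %in% names(prediction_sets)))
    df <- as_tibble(prediction_sets)[, c("source", "gene")]
  } else {
    if (is.null(names(prediction_sets)) ||
        any(!nzchar(names(prediction_sets)))) {
      names(prediction_sets) <- sprintf("source_%d",
                                        seq_along(prediction_sets))
    }
    df <- dplyr::bind_rows(lapply(names(prediction_sets), function(s) {
      tibble(source = s, gene = unique(as.character(prediction_sets[[s]])))
    }))
  }
  n_sources <- dplyr::n_distinct(df$source)
  if (min_support > n_sources) {
    abort(sprintf("min_support (%d) exceeds the number of sources (%d)",
                  min_support, n_sources),
          class = "hypoxamir_config_error")
  }
  df |>
    dplyr::distinct(.data$source, .data$gene) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(support = dplyr::n(),
                     sources = paste(sort(.data$source), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$gene)
}

#' Read prediction sets from files
#'
#' Each file is either one gene id per line, or a two-column TSV
#' `source`, `gene` (combined across files).
#'
#' @param paths Named character vector of file paths; names become source
#'   names for one-gene-per-line files.
#' @return A two-column tibble `source`, `gene`.
#' @export
read_prediction_sets <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  dplyr::bind_rows(lapply(names(paths), function(nm) {
    first <- readLines(paths[[nm]], n = 1L)
    if (grepl("\t", first)) {
      df <- utils::read.delim(paths[[nm]], stringsAsFactors = FALSE)
      tibble(source = as.character(df[[1]]), gene = as.character(df[[2]]))
    } else {
      tibble(source = nm, gene = readLines(paths[[nm]]))
    }
  }))
}
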