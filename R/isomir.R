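# isomiR cataloguing: group 5'/3' end variants of a mature miRNA around
# its precursor anchor, pick the representative (highest read count), and
# summarize per-condition isomiR diversity.

#' Group end-variant tags into an isomiR family
#'
#' A tag joins the family of a precursor-anchored mature miRNA if the
#' maximal prefix of the tag that matches the precursor aligns with a 5'
#' offset of at most `max_shift5` from the anchor start, the templated 3'
#' end lies within `max_shift3` of the anchor end, and any unmatched 3'
#' suffix (non-templated addition) is at most `max_nta` nt. Offsets are
#' recorded relative to the anchor (positive = shifted 3'-ward). The
#' representative is the variant with the highest total count, ties broken
#' lexicographically.
#'
#' Tags equal to another miRNA's exact mature sequence can be excluded via
#' `exclude` (exact annotation wins over isomiR membership).
#'
#' @param tags A `tag_library`, or a tibble with columns `tag`, `count`
#'   and optionally `condition` (bind several libraries to catalogue
#'   per-condition counts).
#' @param precursor Precursor (or candidate window) sequence.
#' @param anchor Mature anchor sequence; must be a substring of
#'   `precursor`.
#' @param max_shift5,max_shift3 Maximum |5'| and |3'| templated offsets.
#' @param max_nta Maximum non-templated 3' suffix length.
#' @param exclude Character vector of sequences to exclude (e.g. other
#'   miRNAs' matures).
#' @return An `isomir_group` tibble: `sequence`, `offset5`, `offset3`,
#'   `nta`, one `count_<condition>` column per condition, `total`,
#'   `is_representative`; sorted by total desc then sequence.
#' @export
group_isomirs <- function(tags, precursor, anchor,
                          max_shift5 = 3L, max_shift3 = 4L, max_nta = 2L,
                          exclude = NULL) {
  precursor <- toupper(rna_to_dna(precursor))
  anchor <- toupper(rna_to_dna(anchor))
  a_start <- as.integer(regexpr(anchor, precursor, fixed = TRUE))
  if (a_start < 1L) {
    abort("anchor is not a substring of the precursor",
          class = "hypoxamir_reference_error")
  }
  a_end <- a_start + nchar(anchor) - 1L

  df <- as_tibble(tags)[, intersect(c("tag", "count", "condition"),
                                    names(tags))]
  if (!"condition" %in% names(df)) {
    df$condition <- attr(tags, "condition") %||% "all"
  }
  conds <- unique(df$condition)
  df$seq_dna <- toupper(rna_to_dna(df$tag))
  if (!is.null(exclude)) {
    df <- df[!df$seq_dna %in% setdiff(toupper(rna_to_dna(exclude)), anchor), ,
             drop = FALSE]
  }

  # per distinct sequence: maximal precursor-matching prefix and its
  # best-aligned start (smallest |5' offset|, ties to the smaller offset)
  uniq <- unique(df$seq_dna)
  placed <- lapply(uniq, function(sq) {
    L <- nchar(sq)
    for (k in L:max(1L, L - max_nta)) {
      pre <- substr(sq, 1L, k)
      hits <- gregexpr(pre, precursor, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      off5 <- as.integer(hits) - a_start
      best <- order(abs(off5), off5)[1]
      off3 <- (as.integer(hits[best]) + k - 1L) - a_end
      if (abs(off5[best]) <= max_shift5 && abs(off3) <= max_shift3) {
        return(tibble(seq_dna = sq, offset5 = off5[best],
                      offset3 = off3, nta = substr(sq, k + 1L, L)))
      }
      return(NULL)  # prefix found but misaligned: not this family
    }
    NULL
  })
  placed <- dplyr::bind_rows(placed)
  if (nrow(placed) == 0L) {
    out <- tibble(sequence = character(), offset5 = integer(),
                  offset3 = integer(), nta = character())
    for (cn in conds) out[[paste0("count_", cn)]] <- integer()
    out$total <- integer()
    out$is_representative <- logical()
    class(out) <- c("isomir_group", class(out))
    attr(out, "anchor") <- anchor
    return(out)
  }

  counts <- df |>
    dplyr::inner_join(placed, by = "seq_dna") |>
    dplyr::group_by(.data$seq_dna, .data$offset5, .data$offset3,
                    .data$nta, .data$condition) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "count",
                       names_prefix = "count_", values_fill = 0L)
  cnt_cols <- paste0("count_", conds)
  for (cc in setdiff(cnt_cols, names(counts))) counts[[cc]] <- 0L
  counts$total <- as.integer(rowSums(counts[, cnt_cols, drop = FALSE]))
  out <- counts |>
    dplyr::rename(sequence = "seq_dna") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$sequence) |>
    dplyr::mutate(is_representative = dplyr::row_number() == 1L)
  out <- out[, c("sequence", "offset5", "offset3", "nta", cnt_cols,
                 "total", "is_representative")]
  class(out) <- c("isomir_group", class(out))
  attr(out, "anchor") <- anchor
  out
}

#' Per-condition isomiR diversity summary
#'
#' Counts, per condition, the distinct isomiR species expressed (count
#' >= 1), the singletons (count exactly 1) and the total reads.
#'
#' @param groups An `isomir_group` tibble, or a list of them (e.g. one per
#'   precursor) which is bound first.
#' @return Tibble: `condition`, `species`, `singletons`, `reads`.
#' @export
isomir_condition_summary <- function(groups) {
  if (!is.data.frame(groups)) groups <- dplyr::bind_rows(groups)
  cnt_cols <- grep("^count_", names(groups), value = TRUE)
  long <- tidyr::pivot_longer(
    as_tibble(groups)[, c("sequence", cnt_cols)],
    dplyr::all_of(cnt_cols),
    names_to = "condition", names_prefix = "count_", values_to = "count")
  long |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(species = sum(.data$count >= 1L),
                     singletons = sum(.data$count == 1L),
                     reads = sum(.data$count), .groups = "drop")
}
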