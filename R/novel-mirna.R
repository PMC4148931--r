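# Novel miRNA discovery: fold candidate windows, test hairpin geometry,
# and emit predictions with stem-placement verdicts.

#' Evaluate a candidate precursor window
#'
#' Applies the precursor rules to a folded window: the stem must score at
#' least `min_score` in total pair weight, the hairpin must be a single
#' stem-loop with a terminal loop of 3-20 nt (bulges and internal loops
#' are allowed, multiloops are not), the mature interval must not
#' intersect the terminal loop, and at least `min_paired_frac` of mature
#' positions must be paired.
#'
#' With the default `scope = "mature_stem"`, the rules are applied to the
#' maximal simple stem-loop containing the mature (walking outward from
#' the mature's terminal loop until a multiloop branch point), so extra
#' hairpins folded by the random flanks of a tag +/- 70 nt window do not
#' veto a genuine precursor. `scope = "global"` applies the single-loop
#' rule to the whole structure, which is appropriate when the window is a
#' trimmed precursor rather than a flanked candidate.
#'
#' @param struct An `rna_structure` from [fold_hairpin()], or a sequence
#'   to fold.
#' @param mature_start,mature_end 1-based mature interval in the window.
#' @param min_score Minimum stem pair-weight score.
#' @param loop_range Allowed terminal loop length (nt).
#' @param min_paired_frac Minimum fraction of paired mature positions.
#' @param scope `"mature_stem"` or `"global"` (see Details).
#' @return One-row tibble: `passes`, `reasons` (comma-separated; empty
#'   when passing), `arm` (`"5p"`, `"3p"` or `"none"`), `stem_score`,
#'   `loop_length`, `mature_paired_frac`.
#' @export
evaluate_precursor <- function(struct, mature_start, mature_end,
                               min_score = 25L, loop_range = c(3L, 20L),
                               min_paired_frac = 0.6,
                               scope = c("mature_stem", "global")) {
  scope <- match.arg(scope)
  if (is.character(struct)) struct <- fold_hairpin(struct)
  n <- nchar(struct$seq)
  stopifnot(mature_start >= 1L, mature_end <= n, mature_start <= mature_end)
  mat <- mature_start:mature_end
  paired_frac <- mean(struct$partner[mat] > 0L)
  loops <- struct$loops
  reasons <- character(0)
  arm <- "none"
  stem_score <- struct$score
  loop_len <- NA_integer_

  in_loop <- nrow(loops) > 0 &&
    any(loops$start <= mature_end & loops$end >= mature_start)
  if (in_loop) reasons <- c(reasons, "mature_in_loop")

  if (scope == "global") {
    if (nrow(loops) != 1L) {
      reasons <- c(reasons,
                   if (nrow(loops) == 0L) "no_hairpin" else "multi_loop")
    }
    if (nrow(loops) >= 1L) {
      loop_len <- loops$length[1L]
      if (nrow(loops) == 1L &&
          (loop_len < loop_range[1] || loop_len > loop_range[2])) {
        reasons <- c(reasons, "loop_span")
      }
      if (!in_loop && nrow(loops) == 1L) {
        arm <- if (mature_end < loops$start[1L]) "5p" else
          if (mature_start > loops$end[1L]) "3p" else "none"
      }
    }
    if (stem_score < min_score) reasons <- c(reasons, "low_pair_score")
  } else {
    regions <- stem_loop_regions(struct)
    hit <- which(regions$start <= mature_start & regions$end >= mature_end)
    if (length(hit) == 0L) {
      if (!in_loop) reasons <- c(reasons, "multi_loop")
      if (struct$score < min_score) reasons <- c(reasons, "low_pair_score")
    } else {
      reg <- regions[hit[1L], ]
      stem_score <- reg$stem_score
      loop_len <- reg$loop_length
      if (loop_len < loop_range[1] || loop_len > loop_range[2]) {
        reasons <- c(reasons, "loop_span")
      }
      if (stem_score < min_score) reasons <- c(reasons, "low_pair_score")
      if (!in_loop) {
        arm <- if (mature_end < reg$loop_start) "5p" else
          if (mature_start > reg$loop_end) "3p" else "none"
      }
    }
  }
  if (paired_frac < min_paired_frac) {
    reasons <- c(reasons, "mature_unpaired")
  }
  tibble(passes = length(reasons) == 0L,
         reasons = paste(reasons, collapse = ","),
         arm = arm, stem_score = as.integer(stem_score),
         loop_length = loop_len, mature_paired_frac = paired_frac)
}

#' Scan a candidate window for a passing precursor fold
#'
#' A candidate window (tag +/- 70 nt) carries random flanking sequence on
#' the far side of the true hairpin, and under base-pair maximization the
#' flanks fold into their own small stem-loops. Rather than judging one
#' global fold, the scan folds a grid of subwindows (the tag padded by
#' `pads` nt on each side), applies [evaluate_precursor()] to each, and
#' returns the best verdict (a passing one if any subwindow passes).
#'
#' @param window Oriented candidate window sequence.
#' @param tag_offset Bases preceding the tag in the window.
#' @param tag_len Tag length (nt).
#' @param pads Candidate paddings (nt) tried on each side of the tag.
#' @param hairpin_penalty Hairpin-initiation penalty used for the scan
#'   folds (see [fold_hairpin()]).
#' @inheritParams evaluate_precursor
#' @return One-row tibble as [evaluate_precursor()], plus `pad5`, `pad3`.
#' @export
scan_precursor_window <- function(window, tag_offset, tag_len,
                                  pads = c(10L, 40L, 70L),
                                  min_score = 25L, loop_range = c(3L, 20L),
                                  min_paired_frac = 0.6,
                                  hairpin_penalty = 8L) {
  L <- nchar(window)
  best <- NULL
  for (p5 in pads) {
    for (p3 in pads) {
      s <- max(tag_offset + 1L - p5, 1L)
      e <- min(tag_offset + tag_len + p3, L)
      ms <- tag_offset + 1L - s + 1L
      st <- fold_hairpin(substr(window, s, e),
                         hairpin_penalty = hairpin_penalty)
      v <- evaluate_precursor(st, ms, ms + tag_len - 1L,
                              min_score = min_score, loop_range = loop_range,
                              min_paired_frac = min_paired_frac)
      v$pad5 <- p5
      v$pad3 <- p3
      if (v$passes) return(v)
      # remember the highest-scoring failure for the reject log
      if (is.null(best) || v$stem_score > best$stem_score) best <- v
    }
  }
  best
}

#' Predict novel miRNAs from candidate precursor windows
#'
#' Folds each candidate window from [extract_genomic_candidates()],
#' applies [evaluate_precursor()] with the expressed tag as the mature
#' interval, and emits one record per passing window with per-condition
#' read counts and the isomiR variants found around the tag. Windows
#' identical in coordinates are merged, keeping the most abundant tag as
#' the mature. Failing candidates are kept in the `rejected` attribute
#' with their reasons.
#'
#' @param candidates Candidate tibble(s) from
#'   [extract_genomic_candidates()]; pass a list or pre-bound tibble to
#'   combine conditions.
#' @param libraries Named list of `tag_library` objects (names or
#'   `condition` attributes label the count columns).
#' @param min_score,loop_range,min_paired_frac Passed to
#'   [scan_precursor_window()].
#' @param high_count_min Read-count tier threshold (default > 10 reads).
#' @return A `novel_mirna` tibble: `id`, `contig`, `start`, `end`,
#'   `strand`, `mature`, `stem_score`, `arm`, one `count_<condition>`
#'   column per library, `total_count`, `in_all_conditions`,
#'   `high_count`, `n_isomirs`. `attr(, "rejected")` holds the reject log.
#' @export
predict_novel <- function(candidates, libraries,
                          min_score = 25L, loop_range = c(3L, 20L),
                          min_paired_frac = 0.6,
                          high_count_min = 10L) {
  if (is.data.frame(candidates)) candidates <- list(candidates)
  cand <- dplyr::bind_rows(candidates)
  conds <- vapply(seq_along(libraries), function(i) {
    attr(libraries[[i]], "condition") %||% names(libraries)[i] %||%
      paste0("lib", i)
  }, character(1))
  empty <- tibble(id = character(), contig = character(), start = integer(),
                  end = integer(), strand = character(), mature = character(),
                  stem_score = integer(), arm = character())
  for (cn in conds) empty[[paste0("count_", cn)]] <- integer()
  empty$total_count <- integer()
  empty$in_all_conditions <- logical()
  empty$high_count <- logical()
  empty$n_isomirs <- integer()
  if (nrow(cand) == 0L) {
    attr(empty, "rejected") <- tibble(tag = character(),
                                      contig = character(),
                                      start = integer(), end = integer(),
                                      reasons = character())
    class(empty) <- c("novel_mirna", class(empty))
    return(empty)
  }
  # merge identical windows, keep the most abundant tag as the mature
  cand <- cand |>
    dplyr::group_by(.data$contig, .data$win_start, .data$win_end,
                    .data$strand) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$tag, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  count_of <- function(lib, tg) {
    k <- match(tg, lib$tag)
    if (is.na(k)) 0L else lib$count[k]
  }

  rows <- list(); rejected <- list()
  for (r in seq_len(nrow(cand))) {
    cd <- cand[r, ]
    verdict <- scan_precursor_window(cd$window, cd$tag_offset,
                                     nchar(cd$tag),
                                     min_score = min_score,
                                     loop_range = loop_range,
                                     min_paired_frac = min_paired_frac)
    if (!verdict$passes) {
      rejected[[length(rejected) + 1L]] <- tibble(
        tag = cd$tag, contig = cd$contig, start = cd$win_start,
        end = cd$win_end, reasons = verdict$reasons)
      next
    }
    counts <- vapply(libraries, count_of, integer(1), tg = cd$tag)
    tags <- dplyr::bind_rows(lapply(seq_along(libraries), function(i) {
      tibble(tag = libraries[[i]]$tag, count = libraries[[i]]$count,
             condition = conds[i])
    }))
    grp <- group_isomirs(tags, cd$window, cd$tag)
    row <- tibble(contig = cd$contig, start = cd$win_start,
                  end = cd$win_end, strand = cd$strand, mature = cd$tag,
                  stem_score = verdict$stem_score, arm = verdict$arm)
    for (i in seq_along(conds)) {
      row[[paste0("count_", conds[i])]] <- unname(counts[i])
    }
    row$total_count <- sum(counts)
    row$in_all_conditions <- all(counts > 0L)
    row$high_count <- sum(counts) > high_count_min
    row$n_isomirs <- nrow(grp)
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows) > 0) {
    dplyr::bind_rows(rows) |>
      dplyr::arrange(dplyr::desc(.data$total_count), .data$contig,
                     .data$start) |>
      dplyr::mutate(id = sprintf("novel_%d", dplyr::row_number()),
                    .before = 1L)
  } else {
    empty
  }
  attr(out, "rejected") <- if (length(rejected) > 0) {
    dplyr::bind_rows(rejected)
  } else {
    tibble(tag = character(), contig = character(), start = integer(),
           end = integer(), reasons = character())
  }
  class(out) <- c("novel_mirna", class(out))
  out
}
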