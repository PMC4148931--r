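# RNA secondary structure by weighted base-pair maximization.
#
# The folder maximizes total pair weight (GC = 3, AU = 2, GU = 1) over all
# nested (pseudoknot-free) structures with a minimum hairpin loop of 3
# unpaired bases, via the classic interval dynamic program with a
# deterministic traceback. It deliberately trades thermodynamic accuracy
# for an exactly testable optimum: the hairpin/stem geometry decisions the
# novel-miRNA filter needs (is there a single clean stem-loop, is the
# mature on the stem) are preserved.

#' Fold a sequence by weighted base-pair maximization
#'
#' @param seq A single RNA/DNA string over A, C, G, U/T.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @param hairpin_penalty Score charged per terminal loop (hairpin
#'   initiation); 0 (the default) is pure pair-weight maximization, a
#'   positive value suppresses helices that do not pay for the loop they
#'   open (the novel-miRNA window scan uses 8).
#' @return An `rna_structure` list: `seq` (RNA alphabet), `structure`
#'   (dot-bracket), `score` (total pair weight), `partner` (1-based pairing
#'   partner per position, 0 if unpaired), `pairs` (tibble `i`, `j`,
#'   `weight`), `loops` (tibble of terminal loops: closing pair `i`, `j`,
#'   loop interval `start`, `end`, `length`).
#' @export
#' @examples
#' fold_hairpin("GGGAAACCC")$structure  # "(((...)))"
fold_hairpin <- function(seq, min_loop = 3L, hairpin_penalty = 0L) {
  stopifnot(length(seq) == 1L, nchar(seq) >= 1L)
  rna <- toupper(dna_to_rna(seq))
  res <- .fold_nussinov(rna, as.integer(min_loop),
                        as.integer(hairpin_penalty))
  partner <- res$partner
  n <- nchar(rna)
  i <- which(partner > seq_len(n))
  pairs <- tibble(i = i, j = partner[i])
  if (nrow(pairs) > 0) {
    b1 <- substring(rna, pairs$i, pairs$i)
    b2 <- substring(rna, pairs$j, pairs$j)
    key <- paste0(pmin(b1, b2), pmax(b1, b2))
    pairs$weight <- c(CG = 3L, AU = 2L, GU = 1L)[key]
  } else {
    pairs$weight <- integer(0)
  }
  structure(list(
    seq = rna, structure = res$structure, score = res$score,
    partner = partner, pairs = pairs,
    loops = terminal_loops_from_pairs(pairs, partner)
  ), class = "rna_structure")
}

# Terminal (hairpin) loops: pairs (i, j) with every inner position unpaired.
terminal_loops_from_pairs <- function(pairs, partner) {
  if (nrow(pairs) == 0L) {
    return(tibble(i = integer(), j = integer(), start = integer(),
                  end = integer(), length = integer()))
  }
  inner_unpaired <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$i[r]; j <- pairs$j[r]
    j - i > 1L && all(partner[(i + 1L):(j - 1L)] == 0L)
  }, logical(1))
  lp <- pairs[inner_unpaired, c("i", "j")]
  tibble(i = lp$i, j = lp$j, start = lp$i + 1L, end = lp$j - 1L,
         length = lp$j - lp$i - 1L)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  cat(sprintf("# score %d, %d pairs, %d terminal loop(s)\n",
              x$score, nrow(x$pairs), nrow(x$loops)))
  invisible(x)
}

# For each terminal loop, the maximal simple stem-loop region around it:
# all pairs that enclose the loop and enclose no other terminal loop
# (walking out of the stem stops at a multiloop branch point). Returns a
# tibble with one row per loop: region bounds, stem pair score.
stem_loop_regions <- function(struct) {
  loops <- struct$loops
  pairs <- struct$pairs
  if (nrow(loops) == 0L) {
    return(tibble(loop = integer(), start = integer(), end = integer(),
                  loop_start = integer(), loop_end = integer(),
                  loop_length = integer(), stem_score = integer()))
  }
  n_enclosed <- function(i, j) sum(loops$i >= i & loops$j <= j)
  out <- lapply(seq_len(nrow(loops)), function(t) {
    li <- loops$i[t]; lj <- loops$j[t]
    encl <- pairs$i <= li & pairs$j >= lj
    simple <- encl & vapply(seq_len(nrow(pairs)), function(r) {
      !encl[r] || n_enclosed(pairs$i[r], pairs$j[r]) == 1L
    }, logical(1))
    stem <- pairs[simple, ]
    tibble(loop = t, start = min(stem$i), end = max(stem$j),
           loop_start = loops$start[t], loop_end = loops$end[t],
           loop_length = loops$length[t],
           stem_score = sum(stem$weight))
  })
  dplyr::bind_rows(out)
}
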