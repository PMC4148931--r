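# Hierarchical elimination annotation.
#
# Tags are matched against reference classes in a fixed stage order; the
# first matching stage claims the tag:
#   mature miRNA (exact) -> ncRNA -> piRNA -> rRNA/mRNA -> exon ->
#   intergenic/intronic -> unassigned.
# Matching is ungapped substring alignment (Hamming mismatches only, up to
# `max_mismatches`, default 2), forward strand for transcript databases and
# both strands for the genome. Coordinates are 1-based inclusive internally
# (GFF3-compatible on output).

ANNOT_CLASSES <- c("mature_miRNA", "ncRNA", "piRNA", "rna_db",
                   "exon", "intergenic_intronic", "unassigned")

#' Exact matching of tags to mature miRNAs
#'
#' Assigns a tag if and only if its sequence equals a mature miRNA sequence
#' exactly (U/T-insensitive); no mismatch is allowed at this stage. Tags
#' matching several identical mature entries are assigned to the first in
#' lexicographic name order, with all hits recorded.
#'
#' @param lib A `tag_library` (or tibble with `tag`, `count`).
#' @param mature_set Named character vector of mature miRNA sequences.
#' @return Tibble: `tag`, `count`, `class`, `ref`, `mismatches`,
#'   `all_refs`; rows only for assigned tags.
#' @export
match_exact_mature <- function(lib, mature_set) {
  if (length(mature_set) == 0L) abort("`mature_set` must be non-empty")
  mat <- toupper(rna_to_dna(mature_set))
  mat <- mat[order(names(mat))]
  tags <- toupper(rna_to_dna(lib$tag))
  hits <- lapply(tags, function(tg) names(mat)[mat == tg])
  idx <- lengths(hits) > 0L
  tibble(
    tag = lib$tag[idx],
    count = lib$count[idx],
    class = "mature_miRNA",
    ref = vapply(hits[idx], `[`, character(1), 1L),
    mismatches = 0L,
    all_refs = vapply(hits[idx], paste, character(1), collapse = ",")
  )
}

# Concatenated-subject matcher shared by the transcript and genomic
# stages. Subjects are joined with an N5 spacer (N never matches and, at
# <= 2 mismatches, cannot be bridged), so one search per tag covers the
# whole database. Exact hits are found first with a fixed-string search;
# only tags without an exact hit pay for the mismatch-tolerant scan.
# Preference: fewer mismatches, then subject order, then leftmost.
build_subject_concat <- function(seqs) {
  spacer <- strrep("N", 5L)
  lens <- nchar(seqs)
  offsets <- cumsum(c(0L, utils::head(lens + 5L, -1L)))
  list(concat = paste(seqs, collapse = spacer),
       names = names(seqs), offsets = offsets, lens = lens)
}

locate_in_concat <- function(sc, pos, width) {
  k <- findInterval(pos, sc$offsets + 1L)
  within <- pos - sc$offsets[k]
  ok <- within + width - 1L <= sc$lens[k]
  list(subject = sc$names[k], pos = within, ok = ok)
}

match_concat <- function(tags, sc, max_mismatches) {
  out <- tibble(subject = rep(NA_character_, length(tags)),
                pos = NA_integer_, mismatches = NA_integer_)
  if (length(tags) == 0L || nchar(sc$concat) == 0L) return(out)
  # exact pass (leftmost hit in concatenation order)
  hit <- vapply(tags, function(tg) {
    as.integer(regexpr(tg, sc$concat, fixed = TRUE))
  }, integer(1), USE.NAMES = FALSE)
  exact <- hit > 0L
  if (any(exact)) {
    loc <- locate_in_concat(sc, hit[exact], nchar(tags[exact]))
    out$subject[exact] <- loc$subject
    out$pos[exact] <- loc$pos
    out$mismatches[exact] <- 0L
  }
  # mismatch-tolerant pass for the rest
  if (max_mismatches > 0L && any(!exact)) {
    subj <- Biostrings::DNAString(sc$concat)
    for (i in which(!exact)) {
      pat <- Biostrings::DNAString(tags[i])
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches)
      if (length(m) == 0L) next
      sts <- BiocGenerics::start(m)
      # mismatch matching can report overhanging (out-of-bounds) starts
      sts <- sts[sts >= 1L & sts + length(pat) - 1L <= length(subj)]
      if (length(sts) == 0L) next
      mms <- Biostrings::neditStartingAt(pat, subj, starting.at = sts)
      loc <- locate_in_concat(sc, sts, length(pat))
      keep <- loc$ok  # drop windows bridging a spacer
      if (!any(keep)) next
      k <- which(keep)[order(mms[keep], sts[keep])[1L]]
      out$subject[i] <- loc$subject[k]
      out$pos[i] <- loc$pos[k]
      out$mismatches[i] <- mms[k]
    }
  }
  out
}

# Best ungapped substring match of each tag against a named set of
# transcript sequences (forward strand, lexicographic subject order).
match_transcript_db <- function(tags, db, max_mismatches) {
  db <- db[order(names(db))]
  sc <- build_subject_concat(toupper(rna_to_dna(db)))
  m <- match_concat(tags, sc, max_mismatches)
  tibble(ref = m$subject, mismatches = m$mismatches)
}

# Best genomic match of each tag (both strands). Preference: fewer
# mismatches, then contig name, then "+" before "-", then leftmost.
match_genome <- function(tags, genome, max_mismatches) {
  contigs <- sort(names(genome))
  fwd <- setNames(toupper(genome[contigs]), paste0(contigs, "/+"))
  rev <- setNames(revcomp(fwd), paste0(contigs, "/-"))
  # interleave so that, per contig, "+" precedes "-"
  seqs <- as.vector(rbind(fwd, rev))
  names(seqs) <- as.vector(rbind(names(fwd), names(rev)))
  sc <- build_subject_concat(seqs)
  m <- match_concat(tags, sc, max_mismatches)
  got <- !is.na(m$subject)
  contig <- sub("/.$", "", m$subject)
  strand <- sub("^.*/", "", m$subject)
  w <- nchar(tags)
  clen <- nchar(genome)[contig]
  st <- ifelse(strand == "+", m$pos, clen - (m$pos + w - 1L) + 1L)
  tibble(contig = ifelse(got, contig, NA_character_),
         start = as.integer(ifelse(got, st, NA)),
         end = as.integer(ifelse(got, st + w - 1L, NA)),
         strand = ifelse(got, strand, NA_character_),
         mismatches = m$mismatches)
}

#' Hierarchical elimination annotation of a tag library
#'
#' Runs the fixed stage order mature (0 mismatches, exact) -> ncRNA ->
#' piRNA -> rRNA/mRNA -> genome, where genomic hits overlapping an exon
#' interval are class `exon` and all others `intergenic_intronic`. The
#' first matching stage wins; tags matching nothing are `unassigned`.
#'
#' @param lib A `tag_library`.
#' @param ref An `srna_reference` (or any list with `mature`,
#'   `other_ncrna`, `pirnas`, `rna_db`, `genome`, `exons`).
#' @param max_mismatches Maximum Hamming mismatches for the non-mature
#'   stages (default 2; the mature stage always requires 0).
#' @return An `annotation_table` tibble: `tag`, `count`, `class`, `ref`,
#'   `mismatches`, `contig`, `start`, `end`, `strand`. Every input tag
#'   appears exactly once.
#' @export
eliminate_hierarchy <- function(lib, ref, max_mismatches = 2L) {
  for (field in c("mature", "other_ncrna", "pirnas", "rna_db", "genome")) {
    if (is.null(ref[[field]])) {
      abort(sprintf("reference bundle is missing stage '%s'", field),
            class = "hypoxamir_config_error")
    }
  }
  tags <- toupper(rna_to_dna(lib$tag))
  n <- length(tags)
  res <- tibble(
    tag = lib$tag, count = lib$count,
    class = rep("unassigned", n), ref = NA_character_,
    mismatches = NA_integer_, contig = NA_character_,
    start = NA_integer_, end = NA_integer_, strand = NA_character_)

  open <- rep(TRUE, n)

  # stage 1: exact mature
  mm0 <- match_exact_mature(lib, ref$mature)
  hit <- match(mm0$tag, res$tag)
  res$class[hit] <- "mature_miRNA"
  res$ref[hit] <- mm0$ref
  res$mismatches[hit] <- 0L
  open[hit] <- FALSE

  # stages 2-4: transcript databases, forward strand
  for (stage in list(list(cls = "ncRNA", db = ref$other_ncrna),
                     list(cls = "piRNA", db = ref$pirnas),
                     list(cls = "rna_db", db = ref$rna_db))) {
    if (!any(open) || length(stage$db) == 0L) next
    idx <- which(open)
    m <- match_transcript_db(tags[idx], stage$db, max_mismatches)
    got <- !is.na(m$ref)
    res$class[idx[got]] <- stage$cls
    res$ref[idx[got]] <- m$ref[got]
    res$mismatches[idx[got]] <- m$mismatches[got]
    open[idx[got]] <- FALSE
  }

  # stages 5-6: genome, both strands; exon overlap decides the class
  if (any(open)) {
    idx <- which(open)
    g <- match_genome(tags[idx], ref$genome, max_mismatches)
    got <- !is.na(g$contig)
    if (any(got)) {
      hit_gr <- GenomicRanges::GRanges(
        g$contig[got], IRanges::IRanges(g$start[got], g$end[got]))
      if (!is.null(ref$exons) && nrow(ref$exons) > 0) {
        ex_gr <- GenomicRanges::GRanges(
          ref$exons$contig,
          IRanges::IRanges(ref$exons$start, ref$exons$end))
        ov <- GenomicRanges::findOverlaps(hit_gr, ex_gr, select = "first")
      } else {
        ov <- rep(NA_integer_, length(hit_gr))
      }
      cls <- ifelse(is.na(ov), "intergenic_intronic", "exon")
      refname <- ifelse(is.na(ov), g$contig[got], ref$exons$exon_id[ov])
      res$class[idx[got]] <- cls
      res$ref[idx[got]] <- refname
      res$mismatches[idx[got]] <- g$mismatches[got]
      res$contig[idx[got]] <- g$contig[got]
      res$start[idx[got]] <- g$start[got]
      res$end[idx[got]] <- g$end[got]
      res$strand[idx[got]] <- g$strand[got]
    }
  }

  class(res) <- c("annotation_table", class(res))
  attr(res, "sample_id") <- attr(lib, "sample_id")
  attr(res, "condition") <- attr(lib, "condition")
  attr(res, "total_clone_count") <- total_clone_count(lib)
  res
}

#' Extract candidate precursor windows around intergenic/intronic tags
#'
#' For each intergenic/intronic tag (by default only exact genomic
#' matches), extracts the genomic window covering the tag plus `flank`
#' nucleotides on either side, strand-oriented and truncated at contig
#' ends. These windows serve as potential precursor miRNAs.
#'
#' @param anno An `annotation_table` from [eliminate_hierarchy()].
#' @param genome Named character vector of contig sequences.
#' @param flank Flanking nucleotides on each side (default 70).
#' @param exact_only Keep only 0-mismatch genomic matches (default TRUE).
#' @return Tibble: `tag`, `count`, `contig`, `win_start`, `win_end`,
#'   `strand`, `window` (oriented sequence), `tag_offset` (bases preceding
#'   the tag within the oriented window).
#' @export
extract_genomic_candidates <- function(anno, genome, flank = 70L,
                                       exact_only = TRUE) {
  cand <- anno[anno$class == "intergenic_intronic", , drop = FALSE]
  if (exact_only) cand <- cand[cand$mismatches == 0L, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(tibble(tag = character(), count = integer(), contig = character(),
                  win_start = integer(), win_end = integer(),
                  strand = character(), window = character(),
                  tag_offset = integer()))
  }
  clen <- nchar(genome)
  ws <- pmax(cand$start - flank, 1L)
  we <- pmin(cand$end + flank, clen[cand$contig])
  win <- substr(genome[cand$contig], ws, we)
  minus <- cand$strand == "-"
  win[minus] <- revcomp(win[minus])
  # offset of the tag within the oriented window
  off <- ifelse(minus, we - cand$end, cand$start - ws)
  tibble(tag = cand$tag, count = cand$count, contig = cand$contig,
         win_start = as.integer(ws), win_end = as.integer(we),
         strand = cand$strand, window = unname(win),
         tag_offset = as.integer(off))
}

#' Write an annotation table as TSV
#'
#' @param anno An `annotation_table`.
#' @param path Output path.
#' @return `anno`, invisibly.
#' @export
write_annotation <- function(anno, path) {
  cols <- c("tag", "count", "class", "ref", "mismatches",
            "contig", "start", "end", "strand")
  utils::write.table(as.data.frame(anno)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(anno)
}
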