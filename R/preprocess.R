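# Preprocessing: 3' adapter trimming, length filtering, tag collapsing.
#
# A "tag" is a unique insert sequence carried with its read count; the total
# clone count of a library is the sum of all tag counts and is the TPM
# denominator downstream.

#' Trim the 3' sequencing adapter from reads
#'
#' Finds the leftmost window at which a prefix of the adapter of length at
#' least `min_overlap` matches the read with at most `max_mismatches`
#' Hamming mismatches, and returns the read prefix preceding it. Reads in
#' which no such match exists get `NA` (the no-adapter marker); downstream
#' preprocessing discards them, since a valid insert must be adapter-ligated.
#' Empty reads trim to the empty string.
#'
#' @param reads Character vector of read sequences (DNA).
#' @param adapter Adapter sequence, default the small-RNA 3' adapter
#'   `TGGAATTCTCGGGTGCCAAGG`.
#' @param min_overlap Minimum read/adapter overlap to accept a match.
#' @param max_mismatches Maximum mismatches tolerated within the overlap.
#' @return Character vector: trimmed inserts, `""` for adapter-leading or
#'   empty reads, `NA` where no adapter was found.
#' @export
#' @examples
#' trim_adapter3("ACGTACGTTGGAATTCTCGG", "TGGAATTCTCGG", min_overlap = 8)
trim_adapter3 <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                          min_overlap = 8L, max_mismatches = 1L) {
  stopifnot(is.character(reads), length(adapter) == 1L)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) abort("`min_overlap` must be >= 1")
  la <- nchar(adapter)
  if (la < min_overlap) abort("adapter shorter than `min_overlap`")
  n <- length(reads)
  if (n == 0L) return(character(0))
  reads <- toupper(reads)
  len <- nchar(reads)
  out <- rep(NA_character_, n)
  out[len == 0L] <- ""
  maxlen <- max(len)
  if (maxlen == 0L) return(out)
  # character matrix, "" past each read's end
  M <- vapply(seq_len(maxlen), function(i) substring(reads, i, i),
              character(n))
  if (n == 1L) M <- matrix(M, nrow = 1L)
  ad <- strsplit(toupper(adapter), "")[[1]]
  cut <- rep(NA_integer_, n)
  for (p in seq_len(maxlen)) {
    ov <- pmin(len - p + 1L, la)
    todo <- is.na(cut) & ov >= min_overlap
    if (!any(todo)) next
    mm <- integer(n)
    for (j in seq_len(min(la, maxlen - p + 1L))) {
      col <- M[, p + j - 1L]
      mm <- mm + (col != ad[j] & col != "")
    }
    hit <- todo & mm <= max_mismatches
    cut[hit] <- p
  }
  found <- !is.na(cut)
  out[found] <- substr(reads[found], 1L, cut[found] - 1L)
  out
}

#' Filter sequences by length
#'
#' Retains sequences whose length lies in `[min_len, max_len]` inclusive,
#' preserving input order. The default range 16-35 nt is the standard small
#' RNA insert window applied after adapter removal.
#'
#' @param seqs Character vector of sequences.
#' @param min_len,max_len Inclusive length bounds.
#' @return The retained subset of `seqs`, in input order.
#' @export
length_filter <- function(seqs, min_len = 16L, max_len = 35L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len <= 0L || max_len <= 0L) abort("length bounds must be positive")
  if (min_len > max_len) abort("`min_len` must be <= `max_len`")
  n <- nchar(seqs)
  seqs[n >= min_len & n <= max_len]
}

#' Collapse reads into a tag library
#'
#' Collapses a stream of identical-insert reads into unique tags with read
#' counts. The result is a tibble with class `tag_library` carrying
#' `sample_id`, `condition` and `total_clone_count` attributes;
#' `total_clone_count` equals the number of input reads.
#'
#' @param seqs Character vector of insert sequences (non-empty strings).
#' @param sample_id Sample label.
#' @param condition Condition label, e.g. `"normoxic"` or `"hypoxic"`.
#' @return A `tag_library` tibble with columns `tag`, `count`, sorted by
#'   count (desc) then tag.
#' @export
collapse_reads <- function(seqs, sample_id = "sample", condition = "normoxic") {
  if (any(!nzchar(seqs))) abort("all sequences must be non-empty")
  if (length(seqs) == 0L) {
    return(new_tag_library(tibble(tag = character(), count = integer()),
                           sample_id, condition, total = 0L))
  }
  tab <- table(seqs)
  out <- tibble(tag = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$tag)
  new_tag_library(out, sample_id, condition, total = length(seqs))
}

new_tag_library <- function(df, sample_id, condition, total) {
  out <- as_tibble(df)
  attr(out, "sample_id") <- sample_id
  attr(out, "condition") <- condition
  attr(out, "total_clone_count") <- as.integer(total)
  class(out) <- c("tag_library", class(out))
  out
}

#' Total clone count of a tag library
#'
#' @param lib A `tag_library`.
#' @return Integer: total reads collapsed into the library.
#' @export
total_clone_count <- function(lib) {
  tc <- attr(lib, "total_clone_count")
  if (is.null(tc)) sum(lib$count) else tc
}

#' Preprocess raw reads into a tag library
#'
#' Runs adapter trimming, then the inclusive 16-35 nt length filter, then
#' collapsing. Per-step read counts are recorded in the `stats` attribute so
#' that read conservation (input = no-adapter + length-filtered + kept) can
#' be audited.
#'
#' @param reads Character vector of raw read sequences.
#' @inheritParams trim_adapter3
#' @inheritParams length_filter
#' @inheritParams collapse_reads
#' @return A `tag_library`; `attr(, "stats")` holds a one-row tibble with
#'   columns `reads_in`, `no_adapter`, `length_fail`, `reads_kept`.
#' @export
preprocess_reads <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_overlap = 8L, max_mismatches = 1L,
                             min_len = 16L, max_len = 35L,
                             sample_id = "sample", condition = "normoxic") {
  trimmed <- trim_adapter3(reads, adapter, min_overlap, max_mismatches)
  with_adapter <- trimmed[!is.na(trimmed)]
  kept <- length_filter(with_adapter, min_len, max_len)
  lib <- collapse_reads(kept, sample_id, condition)
  attr(lib, "stats") <- tibble(
    reads_in    = length(reads),
    no_adapter  = sum(is.na(trimmed)),
    length_fail = length(with_adapter) - length(kept),
    reads_kept  = length(kept)
  )
  lib
}

#' Preprocess a FASTQ file into a tag library
#'
#' @param path Path to a FASTQ file (Phred+33).
#' @inheritParams preprocess_reads
#' @return A `tag_library`, as [preprocess_reads()].
#' @export
preprocess_fastq <- function(path, adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_overlap = 8L, max_mismatches = 1L,
                             min_len = 16L, max_len = 35L,
                             sample_id = NULL, condition = "normoxic") {
  reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  preprocess_reads(unname(reads), adapter, min_overlap, max_mismatches,
                   min_len, max_len, sample_id, condition)
}

#' Write a tag library to disk
#'
#' Writes the collapsed tags both as TSV (`tag`, `count`) and, optionally,
#' as FASTA with `>tag_<i>_x<count>` headers.
#'
#' @param lib A `tag_library`.
#' @param tsv,fasta Output paths (`NULL` to skip either).
#' @return `lib`, invisibly.
#' @export
write_tag_library <- function(lib, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(as.data.frame(lib)[, c("tag", "count")], tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(lib$tag)
    names(seqs) <- sprintf("tag_%d_x%d", seq_len(nrow(lib)), lib$count)
    Biostrings::writeXStringSet(seqs, fasta)
  }
  invisible(lib)
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("# Tag library '%s' (%s): %s unique tags, %s reads\n",
              attr(x, "sample_id") %||% "?", attr(x, "condition") %||% "?",
              fmt_num(nrow(x)), fmt_num(total_clone_count(x))))
  NextMethod()
}
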