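# Promoter extraction and hypoxia response element (HRE) scanning.
#
# The HRE is scanned as the HIF-binding core consensus RCGTG (R = A/G) on
# either strand of the 5 kb region upstream of the precursor 5' end; the
# pattern is configurable as any IUPAC string. Offsets are reported
# negative, -1 being the base immediately upstream of the precursor.

#' Extract the upstream promoter region of precursor loci
#'
#' For a plus-strand precursor at `[start, end]` the promoter is
#' `[start - span, start - 1]`; for a minus-strand precursor it is the
#' reverse complement of `[end + 1, end + span]`. Regions are truncated at
#' contig bounds. Promoter position `p` (1-based, oriented) maps to the
#' signed offset `p - span_actual - 1`.
#'
#' @param loci Tibble with columns `mirna` (or `name`), `contig`, `start`,
#'   `end`, `strand`.
#' @param genome Named character vector of contig sequences.
#' @param span Upstream span in nt (default 5000).
#' @return Tibble: `mirna`, `contig`, `strand`, `prom_start`, `prom_end`
#'   (genomic, 1-based), `span_actual`, `promoter` (oriented sequence).
#' @export
extract_upstream <- function(loci, genome, span = 5000L) {
  loci <- as_tibble(loci)
  if (!"mirna" %in% names(loci) && "name" %in% names(loci)) {
    loci$mirna <- loci$name
  }
  clen <- nchar(genome)
  bad <- loci$start < 1L | loci$end > clen[loci$contig] |
    is.na(clen[loci$contig])
  if (any(bad)) {
    abort(sprintf("locus off contig: %s",
                  paste(loci$mirna[bad], collapse = ", ")))
  }
  plus <- loci$strand == "+"
  ps <- ifelse(plus, pmax(loci$start - span, 1L), loci$end + 1L)
  pe <- ifelse(plus, loci$start - 1L,
               pmin(loci$end + span, clen[loci$contig]))
  len <- pmax(pe - ps + 1L, 0L)
  prom <- ifelse(len > 0L, substr(genome[loci$contig], ps, pe), "")
  prom[!plus & len > 0L] <- revcomp(prom[!plus & len > 0L])
  tibble(mirna = loci$mirna, contig = loci$contig, strand = loci$strand,
         prom_start = as.integer(ifelse(len > 0L, ps, NA)),
         prom_end = as.integer(ifelse(len > 0L, pe, NA)),
         span_actual = as.integer(len), promoter = unname(prom))
}

scan_one_promoter <- function(promoter, pattern) {
  S <- nchar(promoter)
  w <- nchar(pattern)
  if (S < w) {
    return(tibble(offset = integer(), strand = character(),
                  motif = character()))
  }
  subj <- Biostrings::DNAString(promoter)
  pat <- Biostrings::DNAString(pattern)
  hits <- list()
  for (sd in c("+", "-")) {
    p <- if (sd == "+") pat else Biostrings::reverseComplement(pat)
    m <- Biostrings::matchPattern(p, subj, fixed = FALSE)
    if (length(m) == 0L) next
    found <- as.character(m)
    if (sd == "-") found <- revcomp(found)
    hits[[sd]] <- tibble(offset = BiocGenerics::start(m) - S - 1L,
                         strand = sd, motif = found)
  }
  if (length(hits) == 0L) {
    return(tibble(offset = integer(), strand = character(),
                  motif = character()))
  }
  dplyr::bind_rows(hits) |> dplyr::arrange(.data$offset, .data$strand)
}

#' Scan promoter sequences for hypoxia response elements
#'
#' Reports every match of the motif pattern and of its reverse complement
#' (overlapping matches allowed), each with the signed offset of the match
#' start from the precursor 5' end and the motif-conforming strand
#' sequence, in deterministic ascending-offset order.
#'
#' @param promoters Output of [extract_upstream()], or a single promoter
#'   sequence string.
#' @param pattern IUPAC DNA motif (default the HIF core consensus
#'   `"RCGTG"`).
#' @return An `hre_hits` tibble: `mirna`, `offset`, `strand`, `motif`, and
#'   (when genomic promoter coordinates are available) `gstart`, the
#'   1-based genomic start of the matched window.
#' @export
#' @examples
#' scan_hre("AAACGTGAA")  # one forward hit at offset -7
scan_hre <- function(promoters, pattern = "RCGTG") {
  if (is.character(promoters)) {
    promoters <- tibble(mirna = NA_character_, contig = NA_character_,
                        strand = NA_character_, prom_start = NA_integer_,
                        prom_end = NA_integer_,
                        span_actual = nchar(promoters),
                        promoter = promoters)
  }
  out <- lapply(seq_len(nrow(promoters)), function(r) {
    pr <- promoters[r, ]
    h <- scan_one_promoter(pr$promoter, pattern)
    if (nrow(h) == 0L) return(NULL)
    h$mirna <- pr$mirna
    S <- pr$span_actual
    if (!is.na(pr$prom_start)) {
      h$gstart <- if (pr$strand %in% "-") {
        pr$prom_end - (h$offset + S + 1L) + 1L - (nchar(pattern) - 1L)
      } else {
        pr$prom_start + (h$offset + S + 1L) - 1L
      }
    } else {
      h$gstart <- NA_integer_
    }
    h[, c("mirna", "offset", "strand", "motif", "gstart")]
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble(mirna = character(), offset = integer(),
                  strand = character(), motif = character(),
                  gstart = integer())
  }
  class(out) <- c("hre_hits", class(out))
  attr(out, "pattern") <- pattern
  out
}

#' Write HRE hits as TSV and BED
#'
#' @param hits An `hre_hits` tibble with genomic coordinates.
#' @param tsv,bed Output paths (`NULL` to skip).
#' @return `hits`, invisibly.
#' @export
write_hre_hits <- function(hits, tsv = NULL, bed = NULL, contig = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(
      as.data.frame(hits)[, c("mirna", "offset", "strand", "motif")],
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    ok <- !is.na(hits$gstart)
    w <- nchar(attr(hits, "pattern") %||% "RCGTG")
    bed_df <- data.frame(
      chrom = contig %||% "chr", chromStart = hits$gstart[ok] - 1L,
      chromEnd = hits$gstart[ok] - 1L + w,
      name = sprintf("%s_HRE_%d", hits$mirna[ok], hits$offset[ok]),
      score = 0L, strand = hits$strand[ok])
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(hits)
}
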