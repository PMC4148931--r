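# Shared sequence helpers. All sequences are handled as uppercase character
# vectors; DNA on disk, U<->T conversion is lossless and internal.

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTG")
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' Convert between RNA and DNA alphabets
#'
#' @param x Character vector of sequences.
#' @return `rna_to_dna()` replaces U/u with T/t; `dna_to_rna()` the reverse.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

random_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Count Hamming mismatches between equal-length strings (vectorized over a).
hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a sequence while preserving its dinucleotide composition via a
#' random Eulerian-path walk on the dinucleotide transition graph (the
#' Altschul-Erickson construction, implemented as a randomized edge walk with
#' restart on dead ends). Used to build null sequences for hairpin-filter
#' specificity checks.
#'
#' @param seq A single DNA/RNA string (length >= 2).
#' @return A shuffled string with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  first <- chars[1]
  last <- chars[n]
  # multiset of edges first->second for every adjacent pair
  edges <- split(chars[-1], chars[-n])
  for (tries in seq_len(200)) {
    pool <- lapply(edges, sample)
    path <- character(n)
    path[1] <- first
    ok <- TRUE
    for (i in 2:n) {
      avail <- pool[[path[i - 1]]]
      if (is.null(avail) || length(avail) == 0L) { ok <- FALSE; break }
      path[i] <- avail[1]
      pool[[path[i - 1]]] <- avail[-1]
    }
    if (ok && all(lengths(pool) == 0L) && path[n] == last) {
      return(paste(path, collapse = ""))
    }
  }
  # degenerate composition: fall back to the original sequence
  seq
}

# Deterministic derived seeds, kept within 32-bit integer range.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + 97003 * offset) %% 2147483629)
}

fmt_num <- function(x) formatC(x, format = "fg", big.mark = ",")
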