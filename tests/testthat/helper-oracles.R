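# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (exhaustive enumeration, sliding windows)
# and share no code with the implementation paths they check.

# --- folding: exhaustive enumeration over all nested structures ----------
pair_weight_oracle <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) 3L
  else if (p %in% c("AU", "UA")) 2L
  else if (p %in% c("GU", "UG")) 1L
  else 0L
}

# All nested pair sets of s[i..j] with minimum loop `min_loop`, as lists
# of c(i, k) pairs; memoized per interval.
enumerate_structures <- function(s, min_loop = 3L) {
  n <- length(s)
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- gen(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pair_weight_oracle(s[i], s[k]) == 0L) next
      for (L in gen(i + 1L, k - 1L)) {
        for (R in gen(k + 1L, j)) {
          out[[length(out) + 1L]] <- c(list(c(i, k)), L, R)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  gen(1L, n)
}

# Score one structure: total pair weight minus `q` per terminal loop.
score_structure_oracle <- function(s, pairs, q = 0L) {
  if (length(pairs) == 0L) return(0L)
  m <- do.call(rbind, pairs)
  paired <- as.vector(m)
  sc <- 0L
  for (r in seq_len(nrow(m))) {
    sc <- sc + pair_weight_oracle(s[m[r, 1L]], s[m[r, 2L]])
    inner <- if (m[r, 2L] - m[r, 1L] > 1L) {
      (m[r, 1L] + 1L):(m[r, 2L] - 1L)
    } else integer(0)
    if (!any(inner %in% paired)) sc <- sc - q
  }
  sc
}

best_fold_score_oracle <- function(seq, min_loop = 3L, q = 0L) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  structs <- enumerate_structures(s, min_loop)
  max(0L, max(vapply(structs, function(p) {
    score_structure_oracle(s, p, q)
  }, integer(1))))
}

# --- matching: brute-force Hamming sliding window ------------------------
# Minimum Hamming distance of `tag` over every window of `subject`
# (forward strand); Inf if the tag is longer than the subject.
min_hamming_oracle <- function(tag, subject) {
  tl <- nchar(tag); sl <- nchar(subject)
  if (tl > sl) return(Inf)
  tg <- utf8ToInt(tag)
  best <- Inf
  for (p in 1:(sl - tl + 1L)) {
    d <- sum(utf8ToInt(substr(subject, p, p + tl - 1L)) != tg)
    if (d < best) best <- d
  }
  best
}

# --- motif scan: sliding window over an expanded IUPAC pattern -----------
scan_motif_oracle <- function(promoter, pattern = "RCGTG") {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"))
  pat <- strsplit(pattern, "")[[1]]
  matches_at <- function(seqchars, p) {
    all(vapply(seq_along(pat), function(k) {
      seqchars[p + k - 1L] %in% expand[[pat[k]]]
    }, logical(1)))
  }
  ch <- strsplit(promoter, "")[[1]]
  rc <- strsplit(hypoxamir::revcomp(promoter), "")[[1]]
  S <- length(ch); w <- length(pat)
  hits <- list()
  if (S >= w) {
    for (p in 1:(S - w + 1L)) {
      if (matches_at(ch, p)) {
        hits[[length(hits) + 1L]] <- c(offset = p - S - 1L, strand = 1L)
      }
      if (matches_at(rc, p)) {
        # map the reverse-complement window back to forward coordinates
        fwd_start <- S - (p + w - 1L) + 1L
        hits[[length(hits) + 1L]] <- c(offset = fwd_start - S - 1L,
                                       strand = 2L)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(offset = integer(), strand = character()))
  }
  df <- as.data.frame(do.call(rbind, hits))
  df$strand <- c("+", "-")[df$strand]
  df[order(df$offset, df$strand), ]
}

# --- shared synthetic setup ----------------------------------------------
# Full default study conditions (error-free), used by planted-truth tests.
sim_setup <- function(seed, ...) {
  ref <- build_toy_reference(seed = seed)
  prof <- simulation_profile(ref, error_rate = 0, seed = seed, ...)
  sim <- simulate_srna_libraries(ref, prof)
  libs <- lapply(c(normoxic = "normoxic", hypoxic = "hypoxic"),
                 function(cond) {
    rd <- sim$reads[sim$reads$condition == cond, ]
    preprocess_reads(rd$read, adapter = prof$adapter, condition = cond,
                     sample_id = cond)
  })
  list(ref = ref, prof = prof, sim = sim, libs = libs)
}
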