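# Folding, hairpin verdicts, and novel-miRNA prediction.

test_that("simple folds match hand-derived structures", {
  st <- fold_hairpin("GGGAAACCC")
  expect_identical(st$structure, "(((...)))")
  expect_identical(st$score, 9L)
  st <- fold_hairpin("AAAAAAAAAA")
  expect_identical(st$structure, "..........")
  expect_identical(st$score, 0L)
  expect_error(fold_hairpin("ACGTN"), "invalid base")
})

test_that("structures are balanced, nested, with loops of at least 3", {
  set.seed(61)
  for (i in 1:30) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(20:60, 1),
                       replace = TRUE), collapse = "")
    st <- fold_hairpin(sq)
    db <- strsplit(st$structure, "")[[1]]
    expect_identical(sum(db == "("), sum(db == ")"))
    if (nrow(st$pairs) > 0) {
      expect_true(all(st$pairs$j - st$pairs$i - 1 >= 3))
      # nestedness: no two pairs interleave
      for (r in seq_len(nrow(st$pairs))) {
        i <- st$pairs$i[r]; j <- st$pairs$j[r]
        crossing <- st$pairs$i < i & st$pairs$j > i & st$pairs$j < j
        expect_false(any(crossing))
      }
      # partner vector is an involution consistent with the brackets
      expect_identical(st$partner[st$pairs$i], st$pairs$j)
      expect_identical(st$partner[st$pairs$j], st$pairs$i)
    }
  }
})

test_that("DP scores equal exhaustive enumeration on short sequences", {
  set.seed(62)
  for (i in 1:30) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(8:14, 1),
                       replace = TRUE), collapse = "")
    expect_identical(fold_hairpin(sq)$score,
                     best_fold_score_oracle(sq), label = sq)
  }
})

test_that("the hairpin-initiation penalty matches enumeration too", {
  set.seed(63)
  for (i in 1:20) {
    sq <- paste(sample(c("A", "C", "G", "U"), sample(8:13, 1),
                       replace = TRUE), collapse = "")
    for (q in c(2L, 8L)) {
      expect_identical(fold_hairpin(sq, hairpin_penalty = q)$score,
                       best_fold_score_oracle(sq, q = q),
                       label = paste(sq, q))
    }
  }
})

test_that("a perfect stem with the mature on the 5' arm passes", {
  arm <- "GCGGCAUCCGAUCGUUACCGUGCAGCCCCC"
  hp <- paste0(arm, "AAAAAAA", revcomp(chartr("U", "T", arm)))
  v <- evaluate_precursor(fold_hairpin(hp), 3, 24, scope = "global")
  expect_true(v$passes)
  expect_identical(v$arm, "5p")
  expect_identical(v$reasons, "")
})

test_that("a mature centered on the terminal loop is rejected", {
  arm <- "GCGGCAUCCGAUCGUUACCGUGCAGCCCCC"
  hp <- paste0(arm, "AAAAAAA", revcomp(chartr("U", "T", arm)))
  st <- fold_hairpin(hp)
  # the loop sits at positions 31-37; centre a 22-mer on it
  v <- evaluate_precursor(st, 24, 45, scope = "global")
  expect_false(v$passes)
  expect_match(v$reasons, "mature_in_loop")
})

test_that("weak stems fail with a low-pair-score reason", {
  v <- evaluate_precursor(fold_hairpin("GGGCAAAAGCCC"), 1, 3,
                          scope = "global")
  expect_false(v$passes)
  expect_match(v$reasons, "low_pair_score")
})

test_that("planted hairpins pass and their shuffles fail (global rules)", {
  set.seed(64)
  pass_true <- pass_shuf <- logical(0)
  for (i in 1:10) {
    ref <- build_toy_reference(seed = 700 + i)
    for (r in 1:2) {
      h <- ref$hairpins[r, ]
      v <- evaluate_precursor(fold_hairpin(h$seq), h$mat_start, h$mat_end,
                              scope = "global")
      pass_true <- c(pass_true, v$passes)
      v2 <- evaluate_precursor(fold_hairpin(shuffle_dinucleotide(h$seq)),
                               h$mat_start, h$mat_end, scope = "global")
      pass_shuf <- c(pass_shuf, v2$passes)
    }
  }
  expect_gte(mean(pass_true), 0.9)
  expect_gte(mean(!pass_shuf), 0.8)
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  set.seed(65)
  for (i in 1:10) {
    sq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
    sh <- shuffle_dinucleotide(sq)
    dinuc <- function(s) {
      ch <- strsplit(s, "")[[1]]
      sort(paste0(ch[-length(ch)], ch[-1]))
    }
    expect_identical(dinuc(sh), dinuc(sq))
  }
})

test_that("prediction is empty without candidates and logs rejects", {
  setup <- sim_setup(25)
  empty <- predict_novel(
    extract_genomic_candidates(
      eliminate_hierarchy(collapse_reads("ACGTACGTACGTACGTACGTAC"),
                          setup$ref)[0, ],
      setup$ref$genome),
    setup$libs)
  expect_identical(nrow(empty), 0L)
  expect_s3_class(attr(empty, "rejected"), "data.frame")
})

test_that("the planted intergenic hairpins are predicted end to end", {
  setup <- sim_setup(26)
  annos <- lapply(setup$libs, eliminate_hierarchy, ref = setup$ref)
  cand <- lapply(annos, extract_genomic_candidates,
                 genome = setup$ref$genome)
  nov <- predict_novel(cand, setup$libs)
  expect_identical(nrow(nov), 2L)
  expect_true(all(startsWith(nov$id, "novel_")))
  # predicted loci coincide with the planted hairpin loci
  for (r in seq_len(nrow(setup$ref$hairpins))) {
    h <- setup$ref$hairpins[r, ]
    hit <- nov[nov$start <= h$start & nov$end >= h$end &
                 nov$strand == h$strand, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$mature, h$mature_seq)
    expect_true(hit$in_all_conditions)
    expect_true(hit$high_count)
  }
  # the mature is a substring of the emitted window
  anno_all <- dplyr::bind_rows(cand)
  for (r in seq_len(nrow(nov))) {
    w <- anno_all$window[anno_all$tag == nov$mature[r]][1]
    expect_true(grepl(nov$mature[r], w, fixed = TRUE))
  }
})

test_that("raising min_score never increases predictions", {
  setup <- sim_setup(27)
  annos <- lapply(setup$libs, eliminate_hierarchy, ref = setup$ref)
  cand <- lapply(annos, extract_genomic_candidates,
                 genome = setup$ref$genome)
  n_pred <- vapply(c(10L, 25L, 60L, 90L), function(ms) {
    nrow(predict_novel(cand, setup$libs, min_score = ms))
  }, integer(1))
  expect_true(all(diff(n_pred) <= 0))
})
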