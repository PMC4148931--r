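# Hierarchical elimination annotation.

# A small bespoke reference exercising every stage.
make_mini_ref <- function(seed = 11) {
  set.seed(seed)
  genome <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  list(
    genome = c(chrM = genome),
    exons = tibble::tibble(exon_id = "exon_1", contig = "chrM",
                           start = 2001L, end = 2400L, strand = "+"),
    mature = c(`mir-x` = "ACGTACGTACGTACGTACGTAC"),
    other_ncrna = c(nc_1 = paste0("GG", substr(genome, 101, 160), "TT")),
    pirnas = c(pi_1 = "TTTTGGGGCCCCAAAATTTTGGGGCCCCAA"),
    rna_db = c(rna_1 = paste(rep("ACGGT", 40), collapse = "")))
}

test_that("exact mature matching is U/T-insensitive and exact-only", {
  lib <- collapse_reads(c("ACGTACGTACGTACGTACGTAC",
                          "ACGTACGTACGTACGTACGTAA"))
  got <- match_exact_mature(lib, c(`mir-x` = "ACGUACGUACGUACGUACGUAC"))
  expect_identical(got$tag, "ACGTACGTACGTACGTACGTAC")
  expect_identical(got$ref, "mir-x")
  expect_identical(got$mismatches, 0L)
  # the 1-mismatch neighbour is not assigned at this stage
  expect_false("ACGTACGTACGTACGTACGTAA" %in% got$tag)
})

test_that("error-free simulated miRNA tags are fully assigned", {
  setup <- sim_setup(21)
  anno <- eliminate_hierarchy(setup$libs$normoxic, setup$ref)
  mat_tags <- anno[anno$tag %in% setup$ref$mature, ]
  expect_true(all(mat_tags$class == "mature_miRNA"))
  # each assigned to the miRNA that generated it
  expect_identical(mat_tags$ref,
                   names(setup$ref$mature)[match(mat_tags$tag,
                                                 setup$ref$mature)])
})

test_that("earlier stages claim tags before later ones", {
  ref <- make_mini_ref()
  # plant the piRNA sequence inside the exon region too
  g <- ref$genome[["chrM"]]
  ref$genome[["chrM"]] <- paste0(substr(g, 1, 2100),
                                 ref$pirnas[["pi_1"]],
                                 substr(g, 2131, nchar(g)))
  lib <- collapse_reads(ref$pirnas[["pi_1"]])
  anno <- eliminate_hierarchy(lib, ref)
  expect_identical(anno$class, "piRNA")
})

test_that("transcript matches tolerate up to two mismatches", {
  ref <- make_mini_ref()
  sub <- substr(ref$other_ncrna[["nc_1"]], 10, 35)
  ch <- strsplit(sub, "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  ch[5] <- flip(ch[5]); ch[15] <- flip(ch[15])
  mutated2 <- paste(ch, collapse = "")
  ch[20] <- flip(ch[20])
  mutated3 <- paste(ch, collapse = "")
  anno <- eliminate_hierarchy(collapse_reads(c(mutated2, mutated3)), ref,
                              max_mismatches = 2)
  got <- setNames(anno$class, anno$tag)
  expect_identical(got[[mutated2]], "ncRNA")
  expect_identical(anno$mismatches[anno$tag == mutated2], 2L)
  expect_false(got[[mutated3]] == "ncRNA")
})

test_that("every tag is classified exactly once (partition)", {
  setup <- sim_setup(22)
  lib <- setup$libs$hypoxic
  anno <- eliminate_hierarchy(lib, setup$ref)
  expect_identical(nrow(anno), nrow(lib))
  expect_identical(sort(anno$tag), sort(lib$tag))
  expect_identical(sum(anno$count), total_clone_count(lib))
  expect_true(all(anno$class %in% c(
    "mature_miRNA", "ncRNA", "piRNA", "rna_db", "exon",
    "intergenic_intronic", "unassigned")))
})

test_that("per-class read counts equal the planted ground truth", {
  setup <- sim_setup(23)
  for (cond in c("normoxic", "hypoxic")) {
    anno <- eliminate_hierarchy(setup$libs[[cond]], setup$ref)
    got <- tapply(anno$count, anno$class, sum)
    truth <- setup$sim$truth$classes
    truth <- truth[truth$condition == cond, ]
    oracle <- tapply(truth$count, truth$class, sum)[truth$class]
    expect_identical(as.numeric(got[truth$class]), as.numeric(oracle))
  }
})

test_that("raising the mismatch bound never unassigns tags", {
  ref <- make_mini_ref(12)
  set.seed(31)
  # fuzzed tags: mutated copies of database and genome windows + noise
  mk_mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  }
  tags <- unique(c(
    vapply(1:30, function(i) {
      src <- sample(c(ref$other_ncrna, ref$pirnas, ref$rna_db,
                      substr(ref$genome[[1]], 500, 560)), 1)
      st <- sample(nchar(src) - 22, 1)
      mk_mut(substr(src, st, st + 21), sample(0:3, 1))
    }, character(1)),
    vapply(1:10, function(i) {
      paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")
    }, character(1))))
  lib <- collapse_reads(tags)
  assigned <- vapply(0:2, function(mm) {
    anno <- eliminate_hierarchy(lib, ref, max_mismatches = mm)
    sum(anno$class != "unassigned")
  }, integer(1))
  expect_true(all(diff(assigned) >= 0))
})

test_that("assignments agree with a brute-force Hamming oracle", {
  ref <- make_mini_ref(13)
  set.seed(32)
  tags <- vapply(1:25, function(i) {
    if (i <= 15) {
      src <- sample(c(unname(ref$other_ncrna), unname(ref$rna_db),
                      substr(ref$genome[[1]], 100, 220)), 1)
      st <- sample(nchar(src) - 20, 1)
      s <- substr(src, st, st + 19)
      ch <- strsplit(s, "")[[1]]
      p <- sample(20, 1)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    } else {
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    }
  }, character(1))
  lib <- collapse_reads(unique(tags))
  anno <- eliminate_hierarchy(lib, ref, max_mismatches = 2)
  for (r in seq_len(nrow(anno))) {
    tg <- anno$tag[r]
    # oracle: first stage (fixed order) whose best window distance <= 2
    dists <- c(
      mature = if (tg %in% ref$mature) 0 else Inf,
      ncRNA = min(vapply(ref$other_ncrna, min_hamming_oracle,
                         numeric(1), tag = tg)),
      piRNA = min(vapply(ref$pirnas, min_hamming_oracle, numeric(1),
                         tag = tg)),
      rna_db = min(vapply(ref$rna_db, min_hamming_oracle, numeric(1),
                          tag = tg)),
      genome = min(min_hamming_oracle(tg, ref$genome[[1]]),
                   min_hamming_oracle(tg, revcomp(ref$genome[[1]]))))
    hit <- which(dists <= 2)
    expected <- if (length(hit) == 0) "unassigned" else names(hit)[1]
    got <- anno$class[r]
    if (expected == "genome") {
      expect_true(got %in% c("exon", "intergenic_intronic"), label = tg)
      expect_identical(anno$mismatches[r], as.integer(dists[["genome"]]))
    } else {
      expect_identical(got, sub("mature", "mature_miRNA", expected),
                       label = tg)
    }
  }
})

test_that("candidate windows carry the tag at the recorded offset", {
  ref <- make_mini_ref(14)
  g <- ref$genome[[1]]
  tag_mid <- substr(g, 1001, 1022)      # 22 nt, mid-contig, intergenic
  tag_edge <- substr(g, 11, 32)         # 10 nt from the contig start
  lib <- collapse_reads(c(tag_mid, tag_edge))
  anno <- eliminate_hierarchy(lib, ref)
  cand <- extract_genomic_candidates(anno, ref$genome, flank = 70)
  cm <- cand[cand$tag == tag_mid, ]
  expect_identical(nchar(cm$window), 162L)
  expect_identical(cm$tag_offset, 70L)
  expect_identical(substr(cm$window, 71, 92), tag_mid)
  ce <- cand[cand$tag == tag_edge, ]
  expect_identical(ce$tag_offset, 10L)
  expect_identical(ce$win_start, 1L)
})

test_that("minus-strand windows are reverse-complemented correctly", {
  ref <- make_mini_ref(15)
  g <- ref$genome[[1]]
  tag_rc <- revcomp(substr(g, 1501, 1522))  # matches the minus strand
  anno <- eliminate_hierarchy(collapse_reads(tag_rc), ref)
  expect_identical(anno$strand, "-")
  expect_identical(anno$start, 1501L)
  cand <- extract_genomic_candidates(anno, ref$genome, flank = 70)
  # oriented window equals the revcomp oracle of the plus-strand slice
  expect_identical(cand$window, revcomp(substr(g, 1431, 1592)))
  expect_identical(substr(cand$window, cand$tag_offset + 1,
                          cand$tag_offset + 22), tag_rc)
})
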