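# TPM/RPKM normalization, fold change, differential calls, clusters,
# correlation.

test_that("TPM follows count / total x 10^6", {
  expect_identical(normalize_tpm(0, 1000), 0)
  # the in-study worked example: 396 reads in a 7,297,894-read library
  expect_equal(normalize_tpm(396, 7297894), 54.26, tolerance = 0.01 / 54.26)
  expect_identical(normalize_tpm(5000, 5000), 1e6)
  expect_error(normalize_tpm(1, 0), class = "hypoxamir_undefined_library")
  expect_error(normalize_tpm(11, 10))
})

test_that("RPKM is TPM per nucleotide and inverts exactly", {
  expect_identical(normalize_rpkm(0, 22), 0)
  expect_equal(normalize_rpkm(54.26, 22), 2.466, tolerance = 1e-3)
  set.seed(41)
  tpm <- runif(100, 0, 1e5)
  len <- sample(16:27, 100, replace = TRUE)
  expect_equal(normalize_rpkm(tpm, len) * len, tpm)
  expect_error(normalize_rpkm(1, 0))
})

test_that("TPM sums to one million over a library's full tag set", {
  set.seed(42)
  for (i in 1:5) {
    counts <- sample(1:500, 50, replace = TRUE)
    total <- sum(counts)
    expect_equal(sum(normalize_tpm(counts, total)), 1e6)
  }
})

test_that("fold change reproduces the 25-fold miR-210-3p example", {
  fc <- compute_fold_change(7252, 5256222, 396, 7297894)
  expect_identical(round(fc), 25)
  expect_equal(fc, 25.43, tolerance = 0.01)
})

test_that("fold change is symmetric and pseudocounted only at zero", {
  expect_identical(compute_fold_change(50, 1e6, 50, 1e6), 1)
  expect_equal(compute_fold_change(0, 1e6, 100, 1e6, pseudocount = 1),
               1 / 101)
  set.seed(43)
  ch <- sample(0:100, 50, replace = TRUE)
  cn <- sample(0:100, 50, replace = TRUE)
  fc <- compute_fold_change(ch, 2e6, cn, 3e6)
  fc_swapped <- compute_fold_change(cn, 3e6, ch, 2e6)
  expect_equal(fc * fc_swapped, rep(1, 50))
  # nonzero pairs are not pseudocounted
  nz <- ch > 0 & cn > 0
  expect_equal(fc[nz], (ch[nz] / 2e6) / (cn[nz] / 3e6))
})

test_that("differential calls use strict threshold inequalities", {
  mats <- setNames(c("AAAAGGGGCCCCTTTTAAAAGG", "CCCCGGGGAAAATTTTCCCCGG",
                     "GGGGAAAATTTTCCCCGGGGAA"), c("m1", "m2", "m3"))
  mk <- function(counts, cond) {
    anno <- tibble::tibble(tag = unname(mats), count = counts,
                           class = "mature_miRNA", ref = names(mats))
    attr(anno, "total_clone_count") <- 1000000L
    attr(anno, "condition") <- cond
    mirna_expression(anno, mats)
  }
  # equal totals: FC is the raw count ratio; 1.6 -> up, 1.5 -> unchanged,
  # 0.5 -> down
  de <- call_differential(mk(c(10L, 10L, 10L), "normoxic"),
                          mk(c(16L, 15L, 5L), "hypoxic"))
  got <- setNames(de$direction, de$mirna)
  expect_identical(got[["m1"]], "up")
  expect_identical(got[["m2"]], "unchanged")
  expect_identical(got[["m3"]], "down")
  # sorted by |log2 FC| descending
  expect_identical(de$mirna[1], "m3")
  # swapping the conditions flips every direction
  de_sw <- call_differential(mk(c(16L, 15L, 5L), "hypoxic"),
                             mk(c(10L, 10L, 10L), "normoxic"))
  expect_equal(unname(setNames(de_sw$fc, de_sw$mirna)[de$mirna]),
               1 / de$fc)
  flip <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(flip[de$direction]),
                   unname(setNames(de_sw$direction, de_sw$mirna)[de$mirna]))
})

test_that("cluster co-regulation summarizes directions correctly", {
  de <- tibble::tibble(
    mirna = c("a", "b", "c", "d", "e"),
    direction = c("up", "up", "up", "down", "unchanged"))
  clusters <- tibble::tibble(
    cluster = c("c1", "c1", "c2", "c2", "c3", "c3"),
    mirna = c("a", "b", "c", "d", "e", "zz"))
  expect_warning(out <- cluster_coregulation(de, clusters), "zz")
  got <- setNames(out$co_regulated, out$cluster)
  expect_true(got[["c1"]])            # both up
  expect_false(got[["c2"]])           # one up, one down
  expect_false(got[["c3"]])           # no regulated member left
  expect_identical(out$n_members[out$cluster == "c3"], 1L)
})

test_that("random cluster summaries match a brute-force recount", {
  set.seed(44)
  for (i in 1:10) {
    mirnas <- paste0("m", 1:20)
    de <- tibble::tibble(
      mirna = mirnas,
      direction = sample(c("up", "down", "unchanged"), 20, replace = TRUE))
    clusters <- tibble::tibble(
      cluster = paste0("c", sample(1:5, 12, replace = TRUE)),
      mirna = sample(mirnas, 12))
    out <- cluster_coregulation(de, clusters)
    for (r in seq_len(nrow(out))) {
      members <- clusters$mirna[clusters$cluster == out$cluster[r]]
      dirs <- de$direction[match(members, de$mirna)]
      expect_identical(out$n_up[r], sum(dirs == "up"))
      expect_identical(out$n_down[r], sum(dirs == "down"))
      expect_identical(
        out$co_regulated[r],
        (sum(dirs != "unchanged") > 0) &&
          (all(dirs[dirs != "unchanged"] == "up") ||
             all(dirs[dirs != "unchanged"] == "down")))
    }
  }
})

test_that("precursor loci chain into clusters within 10 kb", {
  pr <- tibble::tibble(
    mirna = c("a", "b", "c", "d", "e"),
    contig = "chr1",
    start = c(1000L, 5000L, 9000L, 50000L, 58000L),
    end = c(1080L, 5080L, 9080L, 50080L, 58080L),
    strand = c("+", "+", "+", "+", "-"))
  cl <- mirna_clusters(pr, max_gap = 10000L)
  # a, b, c chain; d and e differ in strand so stay apart (singletons drop)
  expect_identical(sort(cl$mirna), c("a", "b", "c"))
  expect_identical(dplyr::n_distinct(cl$cluster), 1L)
})

test_that("pearson correlation matches the textbook formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  set.seed(45)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_correlation(x, y), oracle)
  }
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "hypoxamir_zero_variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  expect_error(pearson_correlation(1:5, 1:4), "equal length")
})
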