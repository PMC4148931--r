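# isomiR grouping and per-condition diversity summaries.

# toy precursor with the anchor placed away from both ends
PREC <- "GGCTAGCTAGGACGTACGTACGTACGTACGTACCTTGACCAGTT"
ANCHOR <- "ACGTACGTACGTACGTACGTAC"  # at positions 12-33

test_that("the unshifted tag gets offsets (0, 0) and no suffix", {
  grp <- group_isomirs(collapse_reads(ANCHOR), PREC, ANCHOR)
  expect_identical(nrow(grp), 1L)
  expect_identical(grp$offset5, 0L)
  expect_identical(grp$offset3, 0L)
  expect_identical(grp$nta, "")
  expect_true(grp$is_representative)
})

test_that("constructed end shifts are recovered as offsets", {
  # drop the first base, extend one templated base at the 3' end: (+1, +1)
  shifted <- substr(PREC, 13, 34)
  grp <- group_isomirs(collapse_reads(shifted), PREC, ANCHOR)
  expect_identical(grp$offset5, 1L)
  expect_identical(grp$offset3, 1L)
  expect_identical(grp$nta, "")
  # non-templated 3' addition: the suffix is recorded, offsets untouched
  # (the precursor continues with C at position 34, so add a G)
  nta_tag <- paste0(ANCHOR, "G")
  grp <- group_isomirs(collapse_reads(nta_tag), PREC, ANCHOR)
  expect_identical(grp$offset3, 0L)
  expect_identical(grp$nta, "G")
})

test_that("tags outside the isomiR bounds are excluded", {
  # 5' offset of +4 exceeds the default bound of 3
  far <- substr(PREC, 16, 37)
  grp <- group_isomirs(collapse_reads(far), PREC, ANCHOR)
  expect_identical(nrow(grp), 0L)
  # a 3-nt non-templated suffix exceeds the default max_nta of 2
  long_nta <- paste0(ANCHOR, "GGG")
  grp <- group_isomirs(collapse_reads(long_nta), PREC, ANCHOR)
  expect_identical(nrow(grp), 0L)
  # another miRNA's exact mature is excluded when listed
  grp <- group_isomirs(collapse_reads(ANCHOR), PREC, ANCHOR,
                       exclude = c(other = ANCHOR))
  expect_identical(nrow(grp), 1L)  # own anchor is never excluded
})

test_that("an anchor missing from the precursor is a reference error", {
  expect_error(group_isomirs(collapse_reads("ACGT"), PREC,
                             "TTTTTTTTTTTTTTTTTTTTTT"),
               class = "hypoxamir_reference_error")
})

test_that("the representative has maximal count with lexicographic ties", {
  shifted <- substr(PREC, 13, 34)
  tags <- tibble::tibble(tag = c(ANCHOR, shifted),
                         count = c(5L, 9L), condition = "all")
  grp <- group_isomirs(tags, PREC, ANCHOR)
  expect_identical(grp$sequence[grp$is_representative], shifted)
  tags$count <- c(7L, 7L)  # tie: lexicographically smaller sequence wins
  grp <- group_isomirs(tags, PREC, ANCHOR)
  expect_identical(grp$sequence[grp$is_representative],
                   min(c(ANCHOR, shifted)))
  # conservation: group counts sum to the counts of the assigned tags
  expect_identical(sum(grp$total), 14L)
})

test_that("recovered isomiR counts equal the planted ground truth", {
  setup <- sim_setup(24)
  all_tags <- dplyr::bind_rows(lapply(c("normoxic", "hypoxic"),
                                      function(cond) {
    tibble::tibble(tag = setup$libs[[cond]]$tag,
                   count = setup$libs[[cond]]$count, condition = cond)
  }))
  truth <- setup$sim$truth$variants
  for (mn in names(setup$ref$mature)[c(1, 5, 8)]) {
    p <- setup$ref$precursors[setup$ref$precursors$mirna == mn, ]
    grp <- group_isomirs(all_tags, p$seq, setup$ref$mature[[mn]],
                         exclude = setup$ref$mature)
    for (cond in c("normoxic", "hypoxic")) {
      tr <- truth[truth$mirna == mn & truth$condition == cond, ]
      got <- setNames(grp[[paste0("count_", cond)]], grp$sequence)
      exp <- setNames(tr$count, tr$sequence)
      expect_identical(got[names(exp)], exp)
      expect_identical(sum(got), sum(exp))
    }
  }
})

test_that("condition summaries count species, singletons and reads", {
  grp <- tibble::tibble(sequence = "X", count_hypoxic = 1L,
                        count_normoxic = 0L)
  s <- isomir_condition_summary(grp)
  expect_identical(s$species[s$condition == "hypoxic"], 1L)
  expect_identical(s$singletons[s$condition == "hypoxic"], 1L)
  expect_identical(s$species[s$condition == "normoxic"], 0L)

  grp <- tibble::tibble(sequence = c("A", "B", "C"),
                        count_normoxic = c(5L, 1L, 1L),
                        count_hypoxic = c(0L, 2L, 0L))
  s <- isomir_condition_summary(grp)
  expect_identical(s$species[s$condition == "normoxic"], 3L)
  expect_identical(s$singletons[s$condition == "normoxic"], 2L)
  expect_identical(s$reads[s$condition == "normoxic"], 7L)
})

test_that("random summaries equal a brute-force recount and permute", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    grp <- tibble::tibble(
      sequence = paste0("s", seq_len(n)),
      count_normoxic = rpois(n, 2),
      count_hypoxic = rpois(n, 3))
    s <- isomir_condition_summary(grp)
    for (cond in c("normoxic", "hypoxic")) {
      cnt <- grp[[paste0("count_", cond)]]
      expect_identical(s$species[s$condition == cond], sum(cnt >= 1))
      expect_identical(s$singletons[s$condition == cond], sum(cnt == 1))
      expect_identical(s$reads[s$condition == cond], sum(cnt))
    }
    # relabeling conditions permutes rows only
    swapped <- grp
    names(swapped)[2:3] <- names(grp)[3:2]
    s2 <- isomir_condition_summary(swapped)
    expect_identical(
      s[s$condition == "normoxic", -1],
      s2[s2$condition == "hypoxic", -1])
  }
})
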