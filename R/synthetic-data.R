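# Synthetic reference bundle and two-condition small-RNA library simulator.
#
# The generator plants full ground truth: per-miRNA baseline abundance and
# hypoxia fold multipliers (including one strongly induced miR-210-like
# species), isomiR end heterogeneity with non-templated 3' additions,
# background piRNA / rRNA-mRNA / exon fragments, intergenic hairpins not
# present in any database (novel-miRNA positives), and RCGTG hypoxia
# response elements planted at known offsets within 5 kb upstream of the
# induced precursors.

#' Build a seeded toy reference bundle
#'
#' Constructs a single-contig genome hosting miRNA precursor loci (two of
#' them clustered groups), planted intergenic hairpins, exon intervals, and
#' RCGTG motifs upstream of the hypoxia-induced precursors, together with
#' the transcript databases used by the elimination hierarchy: mature
#' miRNAs, an ncRNA set that (as in real ncRNA collections) includes the
#' precursor sequences, piRNAs, and an rRNA/mRNA database.
#'
#' Every mature sequence is a substring of its precursor; every precursor
#' occurs at its genomic coordinates (strand-aware); HRE offsets lie in
#' `[-promoter_span, -1]` relative to the precursor 5' end.
#'
#' @param seed Integer master seed; the same seed reproduces the bundle
#'   byte-for-byte.
#' @param contig_length Length (nt) of the simulated contig.
#' @param n_mirnas Number of miRNAs (>= 6 recommended; >= 1 required).
#' @param mature_len Mature miRNA length (nt).
#' @param arm_len,loop_len Precursor stem arm and terminal loop lengths.
#' @param cluster_sizes Integer vector; the first `sum(cluster_sizes)`
#'   miRNAs are laid out as genomic clusters (members 1.6 kb apart).
#' @param n_hairpins Planted intergenic hairpins (novel-miRNA positives).
#' @param n_pirnas,n_ncrna,n_rna_db Sizes of the background databases.
#' @param n_exons Exon intervals placed between loci.
#' @param promoter_span Upstream span (nt) available for HRE planting.
#' @param hre_mirnas Names of miRNAs receiving planted HREs; default the
#'   hypoxia-induced set of [simulation_profile()] (first five miRNAs).
#' @return An `srna_reference` list: `genome`, `exons`, `mature`,
#'   `precursors`, `other_ncrna`, `pirnas`, `rna_db`, `clusters`,
#'   `hairpins`, `hres`, `params`.
#' @export
build_toy_reference <- function(seed = 1L,
                                contig_length = 150000L,
                                n_mirnas = 12L,
                                mature_len = 22L,
                                arm_len = 30L,
                                loop_len = 8L,
                                cluster_sizes = c(3L, 2L),
                                n_hairpins = 2L,
                                n_pirnas = 20L,
                                n_ncrna = 8L,
                                n_rna_db = 6L,
                                n_exons = 6L,
                                promoter_span = 5000L,
                                hre_mirnas = NULL) {
  stopifnot(n_mirnas >= 1L, n_hairpins >= 0L, mature_len >= 16L,
            arm_len > mature_len / 2, sum(cluster_sizes) <= n_mirnas)
  set.seed(derive_seed(seed, 0L))
  contig <- "chr_s1"
  prec_len <- 2L * arm_len + loop_len

  mirna_names <- sprintf("mir-s%02d", seq_len(n_mirnas))
  if (is.null(hre_mirnas)) hre_mirnas <- mirna_names[seq_len(min(5L, n_mirnas))]

  # --- layout: cluster blocks, then singletons, then hairpins -------------
  gap_within <- 1600L   # start-to-start inside a cluster
  gap_between <- 12000L # keeps unrelated loci > 10 kb apart
  blocks <- list()
  i <- 1L
  for (k in seq_along(cluster_sizes)) {
    blocks[[length(blocks) + 1L]] <- list(
      kind = "cluster", members = mirna_names[i:(i + cluster_sizes[k] - 1L)],
      strand = "+", cluster = sprintf("cluster_%d", k))
    i <- i + cluster_sizes[k]
  }
  singles <- if (i <= n_mirnas) mirna_names[i:n_mirnas] else character(0)
  for (j in seq_along(singles)) {
    blocks[[length(blocks) + 1L]] <- list(
      kind = "single", members = singles[j],
      strand = if (j %% 2L == 1L) "+" else "-")
  }
  for (h in seq_len(n_hairpins)) {
    blocks[[length(blocks) + 1L]] <- list(
      kind = "hairpin", members = sprintf("hairpin_%d", h),
      strand = if (h %% 2L == 1L) "+" else "-")
  }

  cursor <- promoter_span + 3000L
  loci <- list()
  for (b in blocks) {
    starts <- cursor + (seq_along(b$members) - 1L) * gap_within
    for (m in seq_along(b$members)) {
      loci[[length(loci) + 1L]] <- tibble(
        name = b$members[m], kind = b$kind, strand = b$strand,
        start = starts[m], end = starts[m] + prec_len - 1L,
        cluster = if (b$kind == "cluster") b$cluster else NA_character_)
    }
    cursor <- max(starts) + prec_len + gap_between
  }
  loci <- dplyr::bind_rows(loci)
  required <- max(loci$end) + 2000L
  if (contig_length < required) {
    abort(sprintf(
      "contig too short to host requested features: need >= %d nt, got %d",
      required, contig_length), class = "hypoxamir_sizing_error")
  }

  genome <- random_dna(1L, contig_length)

  # --- precursor sequences (stem-loop with 2 stem mutations) --------------
  make_precursor <- function(arm) {
    # All-A loop with an all-C clamp on the loop-proximal 5' arm (G on
    # the 3' arm head): loop adenines find no pairing partner anywhere
    # near the loop (A only pairs U; the arm heads are C/G), so the
    # planted stem-loop is the unambiguous base-pair-maximization
    # optimum with exactly one terminal loop.
    arm5 <- paste0(random_dna(1L, arm_len - 5L), strrep("C", 5L))
    loop <- strrep("A", loop_len)
    arm3 <- strsplit(revcomp(arm5), "")[[1]]
    # two stem mutations, kept out of the loop-proximal clamp
    for (p in sample(6:arm_len, 2L)) {
      arm3[p] <- sample(setdiff(c("A", "C", "G", "T"), arm3[p]), 1L)
    }
    seq <- paste0(arm5, loop, paste(arm3, collapse = ""))
    if (arm == "5p") ms <- 3L else ms <- arm_len + loop_len + 3L
    list(seq = seq, mat_start = ms, mat_end = ms + mature_len - 1L, arm = arm)
  }

  splice_in <- function(genome, start, piece) {
    paste0(substr(genome, 1L, start - 1L), piece,
           substr(genome, start + nchar(piece), nchar(genome)))
  }

  prec_rows <- list()
  mature <- character(0)
  hp_rows <- list()
  for (r in seq_len(nrow(loci))) {
    loc <- loci[r, ]
    arm <- if (r %% 2L == 1L) "5p" else "3p"
    pc <- make_precursor(arm)
    piece <- if (loc$strand == "+") pc$seq else revcomp(pc$seq)
    genome <- splice_in(genome, loc$start, piece)
    mat_seq <- substr(pc$seq, pc$mat_start, pc$mat_end)
    if (loc$strand == "+") {
      g_ms <- loc$start + pc$mat_start - 1L
      g_me <- loc$start + pc$mat_end - 1L
    } else {
      g_me <- loc$end - pc$mat_start + 1L
      g_ms <- loc$end - pc$mat_end + 1L
    }
    row <- tibble(name = paste0("pre-", loc$name), mirna = loc$name,
                  seq = pc$seq, contig = contig, start = loc$start,
                  end = loc$end, strand = loc$strand, arm = pc$arm,
                  mat_start = pc$mat_start, mat_end = pc$mat_end,
                  mat_gstart = g_ms, mat_gend = g_me)
    if (loc$kind == "hairpin") {
      row$mature_seq <- mat_seq
      hp_rows[[length(hp_rows) + 1L]] <- row
    } else {
      prec_rows[[length(prec_rows) + 1L]] <- row
      mature[loc$name] <- mat_seq
    }
  }
  precursors <- dplyr::bind_rows(prec_rows)
  hairpins <- dplyr::bind_rows(hp_rows)

  clusters <- loci |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::transmute(cluster = .data$cluster, mirna = .data$name)

  # --- exons in the middles of inter-block gaps ---------------------------
  block_bounds <- loci |>
    dplyr::group_by(grp = cumsum(!duplicated(dplyr::if_else(
      is.na(.data$cluster), .data$name, .data$cluster)))) |>
    dplyr::summarise(bstart = min(.data$start), bend = max(.data$end),
                     .groups = "drop")
  exon_rows <- list()
  for (g in seq_len(min(n_exons, nrow(block_bounds) - 1L))) {
    mid <- (block_bounds$bend[g] + block_bounds$bstart[g + 1L]) %/% 2L
    elen <- sample(300:700, 1L)
    exon_rows[[g]] <- tibble(
      exon_id = sprintf("exon_%d", g), contig = contig,
      start = mid - elen %/% 2L, end = mid - elen %/% 2L + elen - 1L,
      strand = sample(c("+", "-"), 1L))
  }
  exons <- dplyr::bind_rows(exon_rows)

  # --- transcript databases ----------------------------------------------
  other_ncrna <- c(
    setNames(precursors$seq, precursors$name),
    setNames(random_dna(n_ncrna, sample(60:200, n_ncrna, replace = TRUE)),
             sprintf("ncrna_%d", seq_len(n_ncrna))))
  pirnas <- setNames(random_dna(n_pirnas, sample(26:31, n_pirnas, TRUE)),
                     sprintf("pirna_%d", seq_len(n_pirnas)))
  rna_db <- setNames(random_dna(n_rna_db, sample(200:500, n_rna_db, TRUE)),
                     sprintf("rna_%d", seq_len(n_rna_db)))

  # --- plant HREs upstream of induced precursors --------------------------
  hre_rows <- list()
  offset_grid <- seq(-promoter_span + 100L, -50L, by = 13L)
  occupied <- dplyr::bind_rows(
    loci[, c("start", "end")],
    tibble(start = integer(), end = integer()))
  for (mn in intersect(hre_mirnas, precursors$mirna)) {
    p <- precursors[precursors$mirna == mn, ]
    # candidate motif windows must not overwrite a locus (clustered
    # precursors sit inside each other's promoters) or an earlier motif
    gstart_of <- function(o) {
      if (p$strand == "+") p$start + o else p$end - o - 4L
    }
    free <- vapply(offset_grid, function(o) {
      g <- gstart_of(o)
      g >= 1L && g + 4L <= contig_length &&
        !any(occupied$start <= g + 4L & occupied$end >= g)
    }, logical(1))
    offs <- sort(sample(offset_grid[free], sample(1:3, 1L)))
    for (o in offs) {
      motif <- sample(c("ACGTG", "GCGTG"), 1L)
      gstart <- gstart_of(o)
      genome <- splice_in(
        genome, gstart, if (p$strand == "+") motif else revcomp(motif))
      occupied <- dplyr::bind_rows(occupied,
                                   tibble(start = gstart, end = gstart + 4L))
      hre_rows[[length(hre_rows) + 1L]] <- tibble(
        mirna = mn, offset = o, motif = motif, contig = contig,
        gstart = gstart)
    }
  }
  hres <- dplyr::bind_rows(hre_rows)
  if (nrow(hres) == 0L) {
    hres <- tibble(mirna = character(), offset = integer(),
                   motif = character(), contig = character(),
                   gstart = integer())
  }

  ref <- structure(list(
    genome = setNames(genome, contig),
    exons = exons,
    mature = mature,
    precursors = precursors,
    other_ncrna = other_ncrna,
    pirnas = pirnas,
    rna_db = rna_db,
    clusters = clusters,
    hairpins = hairpins,
    hres = hres,
    params = list(seed = seed, contig_length = contig_length,
                  mature_len = mature_len, arm_len = arm_len,
                  loop_len = loop_len, promoter_span = promoter_span)
  ), class = "srna_reference")
  validate_reference(ref)
  ref
}

#' Validate reference-bundle invariants
#'
#' Checks that every mature sequence occurs in its precursor, every
#' precursor (and planted hairpin) occurs at its genomic coordinates
#' strand-aware, and every planted HRE offset lies in
#' `[-promoter_span, -1]`.
#'
#' @param ref An `srna_reference`.
#' @return `ref`, invisibly; aborts on violation.
#' @export
validate_reference <- function(ref) {
  pr <- ref$precursors
  for (r in seq_len(nrow(pr))) {
    p <- pr[r, ]
    mat <- ref$mature[[p$mirna]]
    if (!grepl(mat, p$seq, fixed = TRUE)) {
      abort(sprintf("mature %s not found in its precursor", p$mirna))
    }
    slice <- substr(ref$genome[[p$contig]], p$start, p$end)
    if (p$strand == "-") slice <- revcomp(slice)
    if (slice != p$seq) {
      abort(sprintf("precursor %s does not match its genomic locus", p$name))
    }
  }
  for (r in seq_len(nrow(ref$hairpins))) {
    h <- ref$hairpins[r, ]
    slice <- substr(ref$genome[[h$contig]], h$start, h$end)
    if (h$strand == "-") slice <- revcomp(slice)
    if (slice != h$seq) abort(sprintf("hairpin %s locus mismatch", h$name))
  }
  span <- ref$params$promoter_span
  if (nrow(ref$hres) > 0 &&
      any(ref$hres$offset < -span | ref$hres$offset > -1L)) {
    abort("planted HRE offset outside [-span, -1]")
  }
  invisible(ref)
}

#' Define a simulation profile
#'
#' Encodes the two-condition study design: per-miRNA baseline mean counts
#' and hypoxia fold multipliers, negative-binomial overdispersion, the
#' isomiR end-variant distribution, sequencing error rate, adapter and read
#' length, and background class fractions.
#'
#' Default design over the reference's miRNAs (in order): the first four
#' are hypoxia-induced 4-fold (baseline 50), the fifth is a strongly
#' induced miR-210-like species (25-fold from baseline 20), the sixth and
#' seventh are repressed 4-fold (baseline 600, multiplier 0.25), and the
#' remainder are unchanged at baseline 150. Up- and down-regulation are
#' approximately mass-balanced so that the total clone count, and hence
#' the TPM scale, stays comparable across conditions (TPM measures
#' relative abundance; a composition-shifted library would distort every
#' fold). Counts are drawn negative-binomially with variance
#' `(1 + dispersion) * mean` (size = mean/dispersion), so
#' `dispersion = 0` is Poisson.
#'
#' @param ref An `srna_reference`.
#' @param baseline_mean Named numeric, baseline (normoxic) mean read count
#'   per miRNA; `NULL` for the default design.
#' @param fold Named numeric, hypoxic fold multiplier per miRNA (> 0);
#'   `NULL` for the default design.
#' @param dispersion Overdispersion relative to Poisson (>= 0).
#' @param p_representative Probability mass of the unshifted mature form
#'   among a miRNA's reads; the rest is spread uniformly over 5' shifts
#'   `shift5` x 3' shifts `shift3` (excluding the (0,0) cell).
#' @param shift5,shift3 Allowed templated 5'/3' end shifts (nt).
#' @param nta_rate Per-read probability of one non-templated 3' addition.
#' @param nta_bases Bases used for non-templated additions (DNA alphabet).
#' @param error_rate Per-base substitution error rate.
#' @param adapter 3' adapter ligated to every insert.
#' @param read_length Sequencing read length (nt).
#' @param background_frac Named fractions (of total reads) for classes
#'   `pirna`, `rna_db`, `exon`.
#' @param hairpin_mean Mean read count per planted hairpin per condition.
#' @param seed Master seed; per-library streams are derived at fixed
#'   offsets from it.
#' @return A `simulation_profile` list.
#' @export
simulation_profile <- function(ref,
                               baseline_mean = NULL,
                               fold = NULL,
                               dispersion = 0.05,
                               p_representative = 0.6,
                               shift5 = -1:1,
                               shift3 = -2:2,
                               nta_rate = 0.15,
                               nta_bases = c("A", "T"),
                               error_rate = 0.001,
                               adapter = "TGGAATTCTCGGGTGCCAAGG",
                               read_length = 50L,
                               background_frac = c(pirna = 0.05,
                                                   rna_db = 0.08,
                                                   exon = 0.05),
                               hairpin_mean = 60,
                               seed = 1L) {
  mirnas <- names(ref$mature)
  n <- length(mirnas)
  if (is.null(baseline_mean)) {
    baseline_mean <- setNames(rep(150, n), mirnas)
    baseline_mean[seq_len(min(4L, n))] <- 50
    if (n >= 5L) baseline_mean[5L] <- 20
    if (n >= 7L) baseline_mean[6:7] <- 600
  }
  if (is.null(fold)) {
    fold <- setNames(rep(1, n), mirnas)
    fold[seq_len(min(4L, n))] <- 4
    if (n >= 5L) fold[5L] <- 25
    if (n >= 7L) fold[6:7] <- 0.25
  }
  bad <- setdiff(c(names(baseline_mean), names(fold)), mirnas)
  if (length(bad) > 0) {
    abort(sprintf("profile references miRNAs absent from the reference: %s",
                  paste(bad, collapse = ", ")),
          class = "hypoxamir_reference_error")
  }
  rates <- c(p_representative, nta_rate, error_rate, background_frac)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (any(fold <= 0)) abort("fold multipliers must be > 0")
  if (dispersion < 0) abort("dispersion must be >= 0")
  structure(list(
    baseline_mean = baseline_mean, fold = fold, dispersion = dispersion,
    p_representative = p_representative, shift5 = shift5, shift3 = shift3,
    nta_rate = nta_rate, nta_bases = nta_bases, error_rate = error_rate,
    adapter = adapter, read_length = as.integer(read_length),
    background_frac = background_frac, hairpin_mean = hairpin_mean,
    seed = as.integer(seed)
  ), class = "simulation_profile")
}

rnb <- function(n, mu, phi) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    if (phi <= 0) {
      out[pos] <- rpois(sum(pos), mu[pos])
    } else {
      out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / phi)
    }
  }
  out
}

#' Simulate two-condition small-RNA sequencing libraries
#'
#' Draws per-miRNA read counts (negative binomial), spreads them over
#' isomiR end variants, adds non-templated 3' additions, planted-hairpin
#' reads and piRNA / rRNA-mRNA / exon background fragments, ligates the 3'
#' adapter, truncates to the read length, applies substitution errors, and
#' returns reads plus the full ground truth. With `dir` set, writes
#' `normoxic.fastq`, `hypoxic.fastq` (Phred+33, constant quality) and
#' ground-truth TSVs.
#'
#' @param ref An `srna_reference`.
#' @param profile A [simulation_profile()].
#' @param dir Output directory, or `NULL` to stay in memory.
#' @return An `srna_simulation` list: `reads` (tibble: condition, id,
#'   insert, read), `truth` (list of tibbles `mirnas`, `variants`,
#'   `classes`, `hairpins`), `profile`, and `files` when written.
#' @export
simulate_srna_libraries <- function(ref, profile, dir = NULL) {
  stopifnot(inherits(ref, "srna_reference"),
            inherits(profile, "simulation_profile"))
  bad <- setdiff(names(profile$baseline_mean), names(ref$mature))
  if (length(bad) > 0) {
    abort(sprintf("profile references miRNAs absent from the reference: %s",
                  paste(bad, collapse = ", ")),
          class = "hypoxamir_reference_error")
  }
  conds <- c("normoxic", "hypoxic")
  all_reads <- list(); all_var <- list(); all_mir <- list()
  all_cls <- list(); all_hp <- list()

  # isomiR variant grid: representative (0,0) plus remaining cells
  grid <- expand.grid(d5 = profile$shift5, d3 = profile$shift3)
  grid <- grid[!(grid$d5 == 0 & grid$d3 == 0), ]
  probs <- c(profile$p_representative,
             rep((1 - profile$p_representative) / nrow(grid), nrow(grid)))

  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    set.seed(derive_seed(profile$seed, ci))
    inserts <- character(0); counts <- integer(0); cls <- character(0)

    # --- miRNA-derived reads with isomiR structure ------------------------
    var_rows <- list(); mir_rows <- list()
    for (mn in names(profile$baseline_mean)) {
      mu <- profile$baseline_mean[[mn]] *
        if (cond == "hypoxic") profile$fold[[mn]] else 1
      N <- rnb(1L, mu, profile$dispersion)
      p <- ref$precursors[ref$precursors$mirna == mn, ]
      vc <- as.integer(rmultinom(1L, N, probs))
      d5s <- c(0L, grid$d5); d3s <- c(0L, grid$d3)
      seq_count <- list()
      for (v in which(vc > 0L)) {
        tmpl <- substr(p$seq, p$mat_start + d5s[v], p$mat_end + d3s[v])
        n_nta <- rbinom(1L, vc[v], profile$nta_rate)
        forms <- c(tmpl)
        fcnt <- c(vc[v] - n_nta)
        if (n_nta > 0L) {
          add <- table(sample(profile$nta_bases, n_nta, replace = TRUE))
          forms <- c(forms, paste0(tmpl, names(add)))
          fcnt <- c(fcnt, as.integer(add))
        }
        for (f in which(fcnt > 0L)) {
          seq_count[[forms[f]]] <- (seq_count[[forms[f]]] %||% 0L) + fcnt[f]
        }
      }
      if (length(seq_count) > 0L) {
        vr <- tibble(mirna = mn, condition = cond,
                     sequence = names(seq_count),
                     count = as.integer(unlist(seq_count)))
        var_rows[[mn]] <- vr
        inserts <- c(inserts, vr$sequence)
        counts <- c(counts, vr$count)
        is_mat <- vr$sequence %in% ref$mature
        cls <- c(cls, ifelse(is_mat, "mature_miRNA", "ncRNA"))
        exact <- sum(vr$count[vr$sequence == ref$mature[[mn]]])
      } else {
        exact <- 0L
      }
      mir_rows[[mn]] <- tibble(
        mirna = mn, condition = cond, mean = mu,
        fold = profile$fold[[mn]], total_count = N, exact_count = exact)
    }
    all_var[[cond]] <- dplyr::bind_rows(var_rows)
    all_mir[[cond]] <- dplyr::bind_rows(mir_rows)

    # --- planted hairpin (novel-miRNA) reads ------------------------------
    hp_rows <- list()
    for (r in seq_len(nrow(ref$hairpins))) {
      h <- ref$hairpins[r, ]
      N <- rnb(1L, profile$hairpin_mean, profile$dispersion)
      if (N > 0L) {
        inserts <- c(inserts, h$mature_seq)
        counts <- c(counts, N)
        cls <- c(cls, "intergenic_intronic")
      }
      hp_rows[[r]] <- tibble(name = h$name, condition = cond, count = N,
                             mature_seq = h$mature_seq)
    }
    all_hp[[cond]] <- dplyr::bind_rows(hp_rows)

    # --- background classes ----------------------------------------------
    # background mass anchored to the baseline miRNA total, identical in
    # expectation across conditions (rRNA/piRNA content does not track
    # the hypoxic induction of specific miRNAs)
    E <- sum(profile$baseline_mean)
    bf <- profile$background_frac
    scale <- 1 - sum(bf)
    # piRNA: full-length piRNA reads
    if (!is.na(bf["pirna"]) && bf["pirna"] > 0 && length(ref$pirnas) > 0) {
      mu_each <- bf[["pirna"]] / scale * E / length(ref$pirnas)
      pc <- rnb(length(ref$pirnas), rep(mu_each, length(ref$pirnas)),
                profile$dispersion)
      keep <- pc > 0L
      inserts <- c(inserts, unname(ref$pirnas[keep]))
      counts <- c(counts, pc[keep])
      cls <- c(cls, rep("piRNA", sum(keep)))
    }
    # rRNA/mRNA fragments: random slices of rna_db entries
    if (!is.na(bf["rna_db"]) && bf["rna_db"] > 0 && length(ref$rna_db) > 0) {
      n_frag <- rnb(1L, bf[["rna_db"]] / scale * E, profile$dispersion)
      if (n_frag > 0L) {
        src <- sample(length(ref$rna_db), n_frag, replace = TRUE)
        flen <- sample(18:28, n_frag, replace = TRUE)
        fs <- vapply(seq_len(n_frag), function(i) {
          s <- ref$rna_db[[src[i]]]
          st <- sample(nchar(s) - flen[i] + 1L, 1L)
          substr(s, st, st + flen[i] - 1L)
        }, character(1))
        inserts <- c(inserts, fs)
        counts <- c(counts, rep(1L, n_frag))
        cls <- c(cls, rep("rna_db", n_frag))
      }
    }
    # exon fragments: slices of exon genome intervals
    if (!is.na(bf["exon"]) && bf["exon"] > 0 && nrow(ref$exons) > 0) {
      n_frag <- rnb(1L, bf[["exon"]] / scale * E, profile$dispersion)
      if (n_frag > 0L) {
        ei <- sample(nrow(ref$exons), n_frag, replace = TRUE)
        flen <- sample(18:28, n_frag, replace = TRUE)
        fs <- vapply(seq_len(n_frag), function(i) {
          ex <- ref$exons[ei[i], ]
          st <- sample(seq(ex$start, ex$end - flen[i] + 1L), 1L)
          substr(ref$genome[[ex$contig]], st, st + flen[i] - 1L)
        }, character(1))
        inserts <- c(inserts, fs)
        counts <- c(counts, rep(1L, n_frag))
        cls <- c(cls, rep("exon", n_frag))
      }
    }

    all_cls[[cond]] <- tibble(condition = cond, class = cls, count = counts) |>
      dplyr::group_by(.data$condition, .data$class) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")

    # --- assemble reads ---------------------------------------------------
    rep_insert <- rep(inserts, counts)
    nr <- length(rep_insert)
    filler <- "ATCTCGTATGCCGTCTTCTGCTTG"
    tails <- paste0(profile$adapter,
                    strrep(filler, ceiling(profile$read_length /
                                             nchar(filler)) + 1L))
    reads <- substr(paste0(rep_insert, tails), 1L, profile$read_length)
    if (profile$error_rate > 0 && nr > 0L) {
      nerr <- rbinom(nr, nchar(reads), profile$error_rate)
      for (i in which(nerr > 0L)) {
        ch <- strsplit(reads[i], "")[[1]]
        pos <- sample(length(ch), nerr[i])
        for (p in pos) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        }
        reads[i] <- paste(ch, collapse = "")
      }
    }
    all_reads[[cond]] <- tibble(
      condition = cond,
      id = sprintf("%s_%06d", substr(cond, 1L, 3L), seq_len(nr)),
      insert = rep_insert, read = reads)
  }

  sim <- structure(list(
    reads = dplyr::bind_rows(all_reads),
    truth = list(mirnas = dplyr::bind_rows(all_mir),
                 variants = dplyr::bind_rows(all_var),
                 classes = dplyr::bind_rows(all_cls),
                 hairpins = dplyr::bind_rows(all_hp)),
    profile = profile
  ), class = "srna_simulation")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(normoxic = file.path(dir, "normoxic.fastq"),
               hypoxic = file.path(dir, "hypoxic.fastq"))
    for (cond in conds) {
      rd <- sim$reads[sim$reads$condition == cond, ]
      write_fastq(setNames(rd$read, rd$id), files[[cond]])
    }
    utils::write.table(sim$truth$mirnas, file.path(dir, "truth_mirnas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$classes, file.path(dir, "truth_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sim$files <- files
  }
  sim
}

# Phred+33 FASTQ with constant quality "I"
write_fastq <- function(seqs, path) {
  if (length(seqs) == 0L) { file.create(path); return(invisible(path)) }
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a reference bundle to disk
#'
#' Emits the bundle as plain-text standard formats: genome and database
#' FASTAs, precursor/exon/hairpin GFF3 (1-based inclusive), and cluster and
#' planted-HRE TSVs.
#'
#' @param ref An `srna_reference`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_reference_bundle <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wfa <- function(x, path) {
    s <- Biostrings::DNAStringSet(unname(x)); names(s) <- names(x)
    Biostrings::writeXStringSet(s, path)
  }
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    mature = file.path(dir, "mature.fa"),
    ncrna = file.path(dir, "ncrna.fa"),
    pirna = file.path(dir, "pirna.fa"),
    rna_db = file.path(dir, "rna_db.fa"),
    precursors = file.path(dir, "precursors.gff3"),
    exons = file.path(dir, "exons.gff3"),
    hairpins = file.path(dir, "hairpins.gff3"),
    clusters = file.path(dir, "clusters.tsv"),
    hres = file.path(dir, "planted_hres.tsv"))
  wfa(ref$genome, paths[["genome"]])
  wfa(ref$mature, paths[["mature"]])
  wfa(ref$other_ncrna, paths[["ncrna"]])
  wfa(ref$pirnas, paths[["pirna"]])
  wfa(ref$rna_db, paths[["rna_db"]])
  gr_of <- function(df, type, id_col) {
    gr <- GenomicRanges::GRanges(
      seqnames = df$contig,
      ranges = IRanges::IRanges(df$start, df$end),
      strand = df$strand)
    gr$type <- type
    gr$ID <- df[[id_col]]
    gr
  }
  pr <- gr_of(ref$precursors, "miRNA_primary_transcript", "name")
  pr$mirna <- ref$precursors$mirna
  pr$arm <- ref$precursors$arm
  pr$mat_start <- ref$precursors$mat_start
  pr$mat_end <- ref$precursors$mat_end
  rtracklayer::export(pr, paths[["precursors"]], format = "gff3")
  rtracklayer::export(gr_of(ref$exons, "exon", "exon_id"),
                      paths[["exons"]], format = "gff3")
  if (nrow(ref$hairpins) > 0) {
    rtracklayer::export(gr_of(ref$hairpins, "hairpin", "name"),
                        paths[["hairpins"]], format = "gff3")
  }
  utils::write.table(ref$clusters, paths[["clusters"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ref$hres, paths[["hres"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @export
print.srna_reference <- function(x, ...) {
  cat(sprintf(paste0(
    "# Synthetic small-RNA reference: %d contig(s) (%s nt), %d miRNAs,\n",
    "#   %d clusters, %d planted hairpins, %d planted HREs\n"),
    length(x$genome), fmt_num(sum(nchar(x$genome))), length(x$mature),
    dplyr::n_distinct(x$clusters$cluster), nrow(x$hairpins), nrow(x$hres)))
  invisible(x)
}
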