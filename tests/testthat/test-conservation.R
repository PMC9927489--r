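rand_seq <- function(n) paste(sample(dutstl:::AA20, n, TRUE), collapse = "")

test_that("length filtering keeps the inclusive 125-225 band", {
  set.seed(51)
  lens <- c(100, 125, 150, 225, 230)
  s <- sequence_set(paste0("s", seq_along(lens)),
                    vapply(lens, rand_seq, character(1)))
  lf <- length_filter(s)
  expect_equal(length(lf$sequences), 3)
  expect_equal(lf$removed, 2)
  expect_equal(nchar(lf$sequences$seqs), c(125, 150, 225))
  expect_equal(lf$sequences$ids, c("s2", "s3", "s4"))  # order preserved

  empty <- length_filter(sequence_set(character(), character()))
  expect_equal(length(empty$sequences), 0)
  expect_equal(empty$removed, 0)

  # idempotent
  lf2 <- length_filter(lf$sequences)
  expect_equal(lf2$removed, 0)
  expect_equal(lf2$sequences$seqs, lf$sequences$seqs)
})

test_that("length filtering matches generator ground truth", {
  fam <- make_sequence_family(family_spec(n = 500, seed = 52))
  lf <- length_filter(fam$unaligned)
  expect_equal(length(lf$sequences), fam$truth$in_range)
  expect_equal(lf$removed, 500 - fam$truth$in_range)
})

test_that("mode detection finds planted bimodality and matches the rule oracle", {
  set.seed(53)
  m <- length_modes(sequence_set(paste0("s", 1:50),
                                 vapply(rep(150, 50), rand_seq,
                                        character(1))))
  expect_equal(nrow(m), 1)
  expect_lte(abs(m$location - 150), 2.5)

  fam <- make_sequence_family(family_spec(n = 1000, outlier_frac = 0,
                                          seed = 54))
  modes <- length_modes(fam$unaligned)
  expect_gte(nrow(modes), 2)
  top2 <- sort(modes$location[1:2])
  expect_lte(abs(top2[1] - 150), 5)
  expect_lte(abs(top2[2] - 190), 5)

  # uniform lengths: whatever the histogram rule says, we agree with the
  # independently coded rule
  for (seed in 1:5) {
    set.seed(seed)
    lens <- sample(125:225, 400, replace = TRUE)
    su <- sequence_set(paste0("u", 1:400),
                       vapply(lens, rand_seq, character(1)))
    got <- length_modes(su)
    expect_equal(got$location, as.numeric(length_modes_oracle(lens)))
  }
})

test_that("greedy clustering follows the identity rule", {
  a <- rand_seq(100)
  s2 <- sequence_set(c("x", "y"), c(a, a))
  cl <- cluster_representatives(s2)
  expect_equal(length(cl$representatives), 1)
  expect_equal(unique(cl$assignment$representative), "x")

  # 90 matches over 100 columns at threshold 0.95 -> two clusters
  set.seed(55)
  chars <- strsplit(a, "")[[1]]
  idx <- sample(100, 10)
  chars[idx] <- vapply(chars[idx], function(ch)
    sample(setdiff(dutstl:::AA20, ch), 1), character(1))
  b <- paste(chars, collapse = "")
  expect_equal(pairwise_identity(a, b)$identity, 0.90, tolerance = 1e-9)
  cl2 <- cluster_representatives(sequence_set(c("x", "y"), c(a, b)), 0.95)
  expect_equal(length(cl2$representatives), 2)
  cl3 <- cluster_representatives(sequence_set(c("x", "y"), c(a, b)), 0.85)
  expect_equal(length(cl3$representatives), 1)
})

test_that("greedy clustering equals a brute-force oracle under the same order", {
  set.seed(56)
  base <- lapply(1:6, function(i) strsplit(rand_seq(80), "")[[1]])
  seqs <- vapply(1:30, function(i) {
    ch <- base[[sample(6, 1)]]
    nmut <- sample(0:6, 1)
    if (nmut > 0) {
      at <- sample(80, nmut)
      ch[at] <- vapply(ch[at], function(x)
        sample(setdiff(dutstl:::AA20, x), 1), character(1))
    }
    paste(ch, collapse = "")
  }, character(1))
  s <- sequence_set(paste0("s", 1:30), seqs)
  got <- cluster_representatives(s, 0.95)

  # independent greedy re-implementation (same stated order and rule)
  ord <- order(-nchar(seqs), seq_along(seqs))
  reps <- integer()
  for (i in ord) {
    hit <- FALSE
    for (r in reps) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[i]), Biostrings::AAString(seqs[r]),
        substitutionMatrix = "BLOSUM62", gapOpening = 10,
        gapExtension = 0.5, type = "global")
      pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
      ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
      ident <- sum(pa == ps & pa != "-") / length(pa)
      if (ident >= 0.95) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, i)
  }
  expect_equal(got$representatives, paste0("s", reps))
  expect_true(all(got$assignment$representative %in% got$representatives))
})

test_that("cluster count is non-increasing as the threshold relaxes", {
  fam <- make_sequence_family(family_spec(n = 20, seed = 57))
  s <- fam$unaligned
  counts <- vapply(c(1.0, 0.9, 0.7, 0.5), function(th)
    length(cluster_representatives(s, th)$representatives), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gappyout trimming removes empty columns, obeys the slope rule, and is idempotent", {
  msa_from <- function(mat) sequence_set(paste0("s", seq_len(nrow(mat))),
                                         apply(mat, 1, paste, collapse = ""),
                                         aligned = TRUE)
  # no gaps: unchanged
  set.seed(58)
  clean <- matrix(sample(dutstl:::AA20, 10 * 20, TRUE), 10, 20)
  tr <- gappyout_trim(msa_from(clean))
  expect_equal(length(tr$removed_columns), 0)
  expect_equal(tr$msa$seqs, msa_from(clean)$seqs)

  # an all-gap column is always removed
  one_empty <- clean
  one_empty[, 7] <- "-"
  tr2 <- gappyout_trim(msa_from(one_empty))
  expect_true(7 %in% tr2$removed_columns)

  # constructed gap-fraction pattern vs the exhaustive slope-rule oracle
  fracs <- c(0, 0, 0, 0.1, 0.1, 0.2, 0.2, 0.8, 0.8, 0.9, 0.9, 1,
             0, 0, 0.1, 0.2, 0.8, 0.9, 1, 0)
  n <- 10
  mat <- vapply(fracs, function(f) {
    col <- sample(dutstl:::AA20, n, TRUE)
    col[seq_len(round(f * n))] <- "-"
    col
  }, character(n))
  tr3 <- gappyout_trim(msa_from(mat))
  expect_equal(tr3$removed_columns, gappyout_oracle(mat))
  expect_true(all(colMeans(mat[, tr3$removed_columns] == "-") >= 0.8))

  # idempotence + oracle agreement on generated alignments
  for (seed in 1:10) {
    fam <- make_sequence_family(family_spec(n = 60, seed = seed))
    tr <- gappyout_trim(fam$aligned)
    expect_equal(tr$removed_columns,
                 gappyout_oracle(dutstl:::msa_matrix(fam$aligned)))
    again <- gappyout_trim(tr$msa)
    expect_equal(length(again$removed_columns), 0)
    # gap-free columns never removed
    gap_free <- which(colMeans(
      dutstl:::msa_matrix(fam$aligned) == "-") == 0)
    expect_false(any(gap_free %in% tr$removed_columns))
  }
})

test_that("logo information matches its closed form and limits", {
  g_col <- sequence_set(paste0("s", 1:1000), rep("G", 1000), aligned = TRUE)
  prof <- logo_profile(g_col)
  expect_equal(unname(prof$freq["G", 1]), 1)
  expect_equal(prof$information[1], log2(20) - 19 / (2 * log(2) * 1000),
               tolerance = 1e-12)
  expect_gt(prof$information[1], 4.3)

  unif <- sequence_set(paste0("s", 1:2000),
                       rep(dutstl:::AA20, 100), aligned = TRUE)
  expect_lt(logo_profile(unif)$information[1], 0.05)

  # counts {A:6, V:3, L:1}: independent arithmetic
  col <- c(rep("A", 6), rep("V", 3), "L")
  prof3 <- logo_profile(sequence_set(paste0("s", 1:10), col, aligned = TRUE))
  p <- c(0.6, 0.3, 0.1)
  h <- -sum(p * log2(p))
  expect_equal(unname(prof3$freq["A", 1]), 0.6)
  expect_equal(prof3$information[1],
               max(0, log2(20) - h - 19 / (2 * log(2) * 10)),
               tolerance = 1e-12)

  # column of gaps only
  gappy <- sequence_set(c("a", "b", "c"), c("A-", "C-", "D-"),
                        aligned = TRUE)
  prof4 <- logo_profile(gappy)
  expect_equal(prof4$information[2], 0)
  expect_equal(prof4$occupancy[2], 0)
  expect_true(all(prof4$information >= 0 &
                  prof4$information <= log2(20)))

  # permutation invariance
  fam <- make_sequence_family(family_spec(n = 50, seed = 59))
  p1 <- logo_profile(fam$aligned)
  set.seed(1)
  perm <- sample(50)
  p2 <- logo_profile(sequence_set(fam$aligned$ids[perm],
                                  fam$aligned$seqs[perm], aligned = TRUE))
  expect_equal(p1$freq, p2$freq)
  expect_equal(p1$information, p2$information)
})

test_that("motif conservation recovers planted levels and skips decoys", {
  fam <- make_sequence_family(family_spec(n = 300, seed = 60))
  cols <- split(fam$truth$motifs$aln_column, fam$truth$motifs$motif)
  mc <- motif_conservation(fam$aligned, cols)
  planted <- fam$truth$motifs[order(fam$truth$motifs$motif,
                                    fam$truth$motifs$aln_column), ]
  mc <- mc[order(mc$motif, mc$column), ]
  expect_equal(mc$modal, planted$residue)
  expect_true(all(abs(mc$frequency - planted$level) < 0.08))
  expect_true(all(mc$conserved))

  # background (decoy) columns are not flagged at the 0.5 threshold
  decoys <- setdiff(seq_len(nchar(fam$aligned$seqs[1]))[1:50],
                    c(fam$truth$motifs$aln_column, fam$truth$gap_columns))
  md <- motif_conservation(fam$aligned, list(decoy = decoys[1:8]))
  expect_false(any(md$conserved))

  expect_equal(nrow(motif_conservation(fam$aligned, list())), 0)
  expect_error(motif_conservation(fam$aligned, cols, reference_row = "no"),
               "not in alignment")
  mref <- motif_conservation(fam$aligned, cols,
                             reference_row = fam$aligned$ids[1])
  expect_true("reference" %in% names(mref))
})

test_that("FASTA round trips preserve sequence sets", {
  fam <- make_sequence_family(family_spec(n = 20, seed = 61))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam$unaligned, f1)
  back <- read_fasta(f1)
  expect_equal(back$ids, fam$unaligned$ids)
  expect_equal(back$seqs, fam$unaligned$seqs)
  expect_false(back$aligned)

  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam$aligned, f2)
  back2 <- read_fasta(f2)
  expect_true(back2$aligned)
  expect_equal(back2$seqs, fam$aligned$seqs)
})
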