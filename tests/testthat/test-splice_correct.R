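test_that("one-hot encoding maps bases to unit vectors and N to zero", {
  m <- encode_window(paste0("A", strrep("N", 20)))
  expect_equal(m[1, ], c(1, 0, 0, 0))
  expect_equal(rowSums(m[2:21, ]), rep(0, 20))
  expect_equal(encode_window(strrep("N", 21)), matrix(0, 21, 4))
  w <- encode_window(paste0(strrep("C", 10), "G", strrep("T", 10)))
  expect_equal(w[11, ], c(0, 0, 1, 0))
  expect_equal(unname(colSums(w)), c(0, 10, 1, 10))
  expect_error(encode_window("ACGT"), "21")
  expect_error(encode_window(paste0("X", strrep("A", 20))), "outside")
})

test_that("splice-site windows carry the stated exon/intron composition", {
  # chromosome: 30 exon A's, intron = GTAAGT + 20 C's + TTTTTTT + CAG, 30 G's
  seqP <- paste0(strrep("A", 30), "GTAAGT", strrep("C", 20), "TTTTTTT",
                 "CAG", strrep("G", 30))
  g <- genome_ref(c(chr = seqP))
  donor <- 31L; acceptor <- 66L
  w <- splice_site_window(g, "chr", "+", donor, acceptor, "donor", 10L)
  expect_identical(w$label, 10L)
  expect_identical(substr(w$seq, 1, 10), strrep("A", 10))
  expect_identical(substr(w$seq, 11, 12), "GT")
  a <- splice_site_window(g, "chr", "+", donor, acceptor, "acceptor", 4L)
  expect_identical(a$label, 17L)
  expect_identical(substr(a$seq, 16, 17), "AG")
  expect_identical(substr(a$seq, 18, 21), strrep("G", 4))
  # minus strand: windows are reverse-complemented into transcript orientation
  gm <- genome_ref(c(chr = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seqP)))))
  len <- nchar(seqP)
  dm <- len - acceptor + 1L; am <- len - donor + 1L
  wm <- splice_site_window(gm, "chr", "-", dm, am, "donor", 10L)
  expect_identical(wm$seq, w$seq)
  # N padding at the chromosome edge
  we <- splice_site_window(g, "chr", "+", 2L, 66L, "donor", 10L)
  expect_identical(substr(we$seq, 1, 9), strrep("N", 9))
})

test_that("training-set construction samples, labels, and splits reproducibly", {
  ts <- build_training_set(tw$db, tw$genome, seed = 5)
  n_total <- nrow(ts$train) + nrow(ts$validation)
  expect_identical(n_total, 2L * nrow(tw$db$junction_set))
  expect_identical(nrow(ts$validation),
                   as.integer(max(1, round(0.1 * n_total))))
  expect_true(all(ts$train$label >= 1 & ts$train$label <= 20))
  expect_true(all(nchar(ts$train$seq) == 21))
  ts2 <- build_training_set(tw$db, tw$genome, seed = 5)
  expect_identical(ts, ts2)
  empty_db <- isoform_db(tibble::tibble(
    chrom = "chr1", start = 1L, end = 50L, strand = "+",
    gene_id = "g", isoform_id = "t"))
  expect_error(build_training_set(empty_db, tw$genome), "no junctions")
})

test_that("model training is seeded-deterministic and outputs distributions", {
  ts <- build_training_set(tw$db, tw$genome, seed = 5)
  small <- ts$train[1:60, ]
  m1 <- train_model(small, epochs = 3, seed = 11)
  m2 <- train_model(small, epochs = 3, seed = 11)
  expect_equal(m1$final_loss, m2$final_loss)
  expect_equal(m1$dense$W, m2$dense$W)
  probs <- predict(m1, ts$validation$seq[1:8])
  expect_equal(rowSums(probs), rep(1, 8), tolerance = 1e-9)
  expect_error(train_model(small[0, ]), "empty")
})

test_that("model checkpoints round-trip through the JSON format", {
  ts <- build_training_set(tw$db, tw$genome, seed = 5)
  m <- train_model(ts$train[1:40, ], epochs = 2, seed = 3)
  ck <- withr::local_tempfile(fileext = ".json")
  save_splice_model(m, ck)
  m2 <- load_splice_model(ck)
  expect_equal(predict(m, ts$validation$seq[1:5]),
               predict(m2, ts$validation$seq[1:5]), tolerance = 1e-12)
})

test_that("wobble candidates preserve base correspondence; known junctions win", {
  # junction already annotated is returned unchanged by the fallback
  j <- tw$db$junction_set[1, ]
  adj <- adjust_junction(NULL, tw$genome, tw$db, j$chrom, j$strand,
                         j$donor, j$acceptor)
  expect_identical(adj$shift, 0L)
  expect_error(adjust_junction(NULL, tw$genome, tw$db, j$chrom, j$strand,
                               j$donor, j$acceptor, radius = -1), "radius")

  # engineered wobble: exon ends ...GG, intron GTAAGT...CAG, next exon
  # starts with C; shifting by -1 preserves the sequence (G repeats) and
  # only the true placement is annotated
  left <- paste0(strrep("A", 28), "GG")
  intr <- paste0("GTAAGT", strrep("C", 15), "TTTTTTT", "CAG")
  right <- paste0("C", strrep("A", 29))
  g2 <- genome_ref(c(chr = paste0(left, intr, right)))
  donor <- 31L; acceptor <- 61L
  db2 <- isoform_db(tibble::tibble(
    chrom = "chr", start = c(1L, acceptor + 1L), end = c(donor - 1L, 90L),
    strand = "+", gene_id = "g", isoform_id = "t"))
  shifts <- isokit:::wobble_shifts(g2, "chr", donor, acceptor, 15L)
  expect_setequal(shifts, c(-1L, 0L))
  # start from a corrupted placement one base left of truth
  adj2 <- adjust_junction(NULL, g2, db2, "chr", "+", donor - 1L,
                          acceptor - 1L)
  expect_identical(adj2$donor, donor)
  expect_identical(adj2$acceptor, acceptor)
})

test_that("fallback mode prefers canonical motifs when nothing is annotated", {
  # same engineered wobble but an annotation elsewhere: the canonical
  # GT-AG placement among the equal-sequence shifts is chosen
  left <- paste0(strrep("A", 28), "GG")
  intr <- paste0("GTAAGT", strrep("C", 15), "TTTTTTT", "CAG")
  right <- paste0("C", strrep("A", 29))
  g2 <- genome_ref(c(chr = paste0(left, intr, right)))
  donor <- 31L; acceptor <- 61L
  db_far <- isoform_db(tibble::tibble(
    chrom = "chr", start = c(70L, 80L), end = c(75L, 85L),
    strand = "+", gene_id = "g", isoform_id = "t"))
  m0 <- junction_motif(g2, "chr", "+", donor, acceptor)
  expect_true(m0$canonical)
  m_shift <- junction_motif(g2, "chr", "+", donor - 1L, acceptor - 1L)
  expect_false(m_shift$canonical)
  adj <- adjust_junction(NULL, g2, db_far, "chr", "+", donor - 1L,
                         acceptor - 1L)
  expect_identical(adj$donor, donor)
})

test_that("correction restores shifted junctions and never changes their count", {
  alns <- assemble_truth(tsim$reads, tsim$truth_maps)
  corr <- corrupt_junctions(alns, tw$genome, max_shift = 5L, seed = 13L)
  expect_gt(corr$n_shifted, 0L)
  fixed <- purrr::map(corr$alignments, function(a)
    correct_alignment(NULL, tw$genome, tw$db, a))
  for (id in names(alns)) {
    expect_identical(nrow(fixed[[id]]$junctions),
                     nrow(alns[[id]]$junctions))
    expect_identical(unique(fixed[[id]]$segments$chrom),
                     unique(alns[[id]]$segments$chrom))
  }
  truth_k <- unlist(purrr::map(alns, function(a)
    isokit:::junction_key(a$junctions$chrom, a$junctions$donor,
                          a$junctions$acceptor)))
  fixed_k <- unlist(purrr::map(fixed, function(a)
    isokit:::junction_key(a$junctions$chrom, a$junctions$donor,
                          a$junctions$acceptor)))
  corrupt_k <- unlist(purrr::map(corr$alignments, function(a)
    isokit:::junction_key(a$junctions$chrom, a$junctions$donor,
                          a$junctions$acceptor)))
  expect_gt(mean(fixed_k == truth_k), mean(corrupt_k == truth_k))
  # with annotation guidance every ambiguity-preserving shift is reverted
  expect_identical(unname(fixed_k), unname(truth_k))
})

test_that("monoexonic alignments pass through correction unchanged", {
  iso1 <- tw$db$isoforms[tw$db$isoforms$n_exons >= 2, ][1, ]
  rd <- read_from_intervals(tw, "mono1", iso1$chrom,
                            iso1$exons[[1]][1, ], iso1$strand)
  aln <- assemble_alignment(rd$read, rd$map, rd$map, strand = iso1$strand)
  expect_identical(correct_alignment(NULL, tw$genome, tw$db, aln), aln)
})
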