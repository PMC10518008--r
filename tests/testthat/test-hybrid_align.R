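test_that("window slicing matches the closed-form count and anchors the last window", {
  w <- slice_windows(strrep("A", 1000), h = 250, t = 100)
  expect_identical(nrow(w), 9L)
  expect_identical(w$start[9], 751L)
  expect_identical(w$end[9], 1000L)
  expect_true(all(nchar(w$seq) == 250L))

  w2 <- slice_windows(strrep("A", 250), h = 250, t = 100)
  expect_identical(nrow(w2), 1L)
  expect_identical(w2$end, 250L)

  w3 <- slice_windows(strrep("C", 300), h = 250, t = 100)
  expect_identical(nrow(w3), 2L)
  expect_identical(w3$start[2], 51L)
  expect_identical(w3$end[2], 300L)

  expect_error(slice_windows("ACGT", h = 0), "positive")
  expect_error(slice_windows("ACGT", h = 10, t = 0), "positive")
})

test_that("position matrix pools, deduplicates, and weights candidates", {
  long <- tibble::tibble(read_pos = 1:3, chrom = "chr1", gpos = c(500L, 501L, 502L))
  short <- tibble::tibble(read_pos = c(1L, 2L), chrom = "chr1",
                          gpos = c(500L, 700L))
  pm <- build_position_matrix(long, short, 4L)
  expect_identical(pm$n, c(1L, 2L, 1L, 0L))       # agreement dedups; pos 4 unmapped
  expect_equal(pm$w, c(1, 0.5, 1, 0))
  expect_error(build_position_matrix(long, short, 2L), "beyond")
})

test_that("block partition applies the 10-bp multi-block rule", {
  mk <- function(n_per_pos) {
    rows <- purrr::map(seq_along(n_per_pos), function(i) {
      n <- n_per_pos[i]
      if (n == 0L) return(NULL)
      tibble::tibble(read_pos = i, chrom = "chr1",
                     gpos = 1000L * i + seq_len(n))
    })
    build_position_matrix(dplyr::bind_rows(rows),
                          tibble::tibble(read_pos = integer(),
                                         chrom = character(),
                                         gpos = integer()),
                          length(n_per_pos))
  }
  b1 <- partition_blocks(mk(rep(1L, 20)))
  expect_identical(nrow(b1), 1L)
  expect_identical(b1$resolve, "unique")

  b2 <- partition_blocks(mk(c(rep(1L, 50), rep(2L, 8), rep(1L, 42))))
  expect_identical(b2$resolve, c("unique", "long", "unique"))

  b3 <- partition_blocks(mk(c(rep(1L, 5), rep(3L, 30), rep(1L, 5))))
  expect_identical(b3$resolve[2], "algorithm")
})

test_that("run enumeration reproduces the hand-executed greedy example", {
  df <- tibble::tibble(
    read_pos = c(1L, 1L, 2L, 2L, 3L, 3L),
    chrom = "chr1",
    gpos = c(100L, 200L, 101L, 201L, 102L, 300L)
  )
  pm <- build_position_matrix(df, df[0, ], 3L)
  runs <- enumerate_local_alignments(pm, 1L, 3L)
  expect_identical(nrow(runs), 3L)
  expect_equal(runs$gstart, c(100L, 200L, 300L))
  expect_equal(runs$gend, c(102L, 201L, 300L))
  expect_equal(runs$q, c(1.5, 1.0, 0.5))
  # every candidate ends up in some run
  expect_identical(sum(runs$read_end - runs$read_start + 1L), 6L)
})

test_that("runs never merge across chromosomes and singletons work", {
  df <- tibble::tibble(read_pos = 1:2, chrom = c("chr1", "chr2"),
                       gpos = c(100L, 101L))
  pm <- build_position_matrix(df, df[0, ], 2L)
  runs <- enumerate_local_alignments(pm, 1L, 2L)
  expect_identical(nrow(runs), 2L)

  df2 <- tibble::tibble(read_pos = 1:4, chrom = "chr1", gpos = 100:103)
  pm2 <- build_position_matrix(df2, df2[0, ], 4L)
  runs2 <- enumerate_local_alignments(pm2, 1L, 4L)
  expect_identical(nrow(runs2), 1L)
  expect_equal(runs2$q, sum(pm2$w))
})

test_that("combination selection follows the printed score on worked cases", {
  # single alignment: chosen trivially
  one <- tibble::tibble(tau = 1L, read_start = 1L, read_end = 5L,
                        chrom = "chr1", gstart = 100L, gend = 104L, q = 3)
  expect_identical(select_combination(one)$indices, 1L)
  expect_error(select_combination(one[0, ]), "no local alignments")

  # the greedy-example runs with same-chromosome anchors adjacent to 100-102:
  # exhaustive scoring of all 7 subsets picks {100-102}
  runs <- tibble::tibble(
    tau = 1:3, read_start = c(1L, 1L, 3L), read_end = c(3L, 2L, 3L),
    chrom = "chr1", gstart = c(100L, 200L, 300L), gend = c(102L, 201L, 300L),
    q = c(1.5, 1.0, 0.5)
  )
  up <- list(chrom = "chr1", gpos = 99L)
  down <- list(chrom = "chr1", gpos = 103L)
  best <- select_combination(runs, up, down)
  expect_identical(best$indices, 1L)
  oracle <- brute_force_combination(runs, up, down)
  expect_equal(best$score, oracle$score)

  # equal-quality distant-chromosome run is rejected through the 1000 constant
  runs2 <- tibble::tibble(
    tau = 1:3, read_start = c(1L, 11L, 1L), read_end = c(10L, 20L, 20L),
    chrom = c("chr1", "chr1", "chr9"),
    gstart = c(100L, 500L, 7000L), gend = c(109L, 509L, 7019L),
    q = c(5, 5, 10)
  )
  best2 <- select_combination(runs2, list(chrom = "chr1", gpos = 90L),
                              list(chrom = "chr1", gpos = 600L))
  expect_setequal(best2$indices, c(1L, 2L))
})

test_that("combination selection equals the brute-force oracle on random instances", {
  set.seed(1234)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    alns <- random_alignment_instance(n)
    up <- random_anchor(); down <- random_anchor()
    got <- select_combination(alns, up, down)
    want <- brute_force_combination(alns, up, down)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("adding a candidate position never removes an existing run's coverage", {
  set.seed(99)
  for (i in 1:50) {
    L <- sample(5:12, 1)
    rows <- purrr::map(1:L, function(p) {
      k <- sample(0:2, 1)
      if (k == 0) return(NULL)
      tibble::tibble(read_pos = p, chrom = "chr1",
                     gpos = sample(1:40, k))
    })
    df <- dplyr::bind_rows(rows)
    if (nrow(df) == 0) next
    pm1 <- build_position_matrix(df, df[0, ], L)
    r1 <- enumerate_local_alignments(pm1, 1L, L)
    extra <- tibble::tibble(read_pos = sample(1:L, 1), chrom = "chr1",
                            gpos = sample(41:60, 1))
    pm2 <- build_position_matrix(dplyr::bind_rows(df, extra), df[0, ], L)
    r2 <- enumerate_local_alignments(pm2, 1L, L)
    for (j in seq_len(nrow(r1))) {
      contained <- any(r2$chrom == r1$chrom[j] &
                         r2$gstart <= r1$gstart[j] & r2$gend >= r1$gend[j])
      expect_true(contained)
    }
  }
})

test_that("assembly is deterministic and complete on noise-free reads", {
  alns <- assemble_truth(tsim$reads, tsim$truth_maps)
  alns2 <- assemble_truth(tsim$reads, tsim$truth_maps)
  expect_identical(alns, alns2)

  got <- dplyr::bind_rows(purrr::imap(alns, function(a, id)
    dplyr::mutate(alignment_junctions(a), read_id = id)))
  truth <- tsim$truth_junctions
  gk <- paste(got$read_id, got$chrom, got$donor, got$acceptor)
  tk <- paste(truth$read_id, truth$chrom, truth$donor, truth$acceptor)
  expect_setequal(gk, tk)   # 100% of truth junctions, nothing else
})

test_that("short-read windows rescue an exon merged by the long-read mapping", {
  # read from a 2-exon region; the long-read mapping wrongly continues across
  # the intron, absorbing the second exon with the small indel breaks such a
  # forced alignment carries, while the window mappings place it correctly.
  # The per-alignment penalty of the combination score discards the
  # fragmented merged placement in favour of the single consistent run.
  g <- tw$db$isoforms[tw$db$isoforms$n_exons >= 2L, ][1, ]
  ex <- g$exons[[1]][1:2, ]
  rd <- read_from_intervals(tw, "merge1", g$chrom, ex, g$strand)
  L <- nchar(rd$read$seq)
  len1 <- ex$end[1] - ex$start[1] + 1L
  len2 <- L - len1
  jump <- 2L * (seq_len(len2) > len2 %/% 3) +
    2L * (seq_len(len2) > 2L * (len2 %/% 3))
  wrong_long <- tibble::tibble(
    read_pos = seq_len(L), chrom = g$chrom,
    gpos = c(ex$start[1] + seq_len(len1) - 1L,
             ex$end[1] + seq_len(len2) + jump)
  )
  aln <- assemble_alignment(rd$read, wrong_long, rd$map,
                            strand = g$strand)
  expect_identical(nrow(aln$junctions), 1L)
  expect_identical(aln$junctions$donor, ex$end[1] + 1L)
  expect_identical(aln$junctions$acceptor, ex$start[2] - 1L)
})

test_that("reads spanning two chromosomes keep both segments", {
  i1 <- tw$db$isoforms[tw$db$isoforms$chrom == "chr1", ][1, ]
  i2 <- tw$db$isoforms[tw$db$isoforms$chrom == "chr2", ][1, ]
  ex1 <- i1$exons[[1]][1, ]; ex2 <- i2$exons[[1]][1, ]
  r1 <- read_from_intervals(tw, "fus1", i1$chrom, ex1)
  r2 <- read_from_intervals(tw, "fus1", i2$chrom, ex2)
  m2 <- r2$map
  m2$read_pos <- m2$read_pos + nrow(r1$map)
  read <- tibble::tibble(read_id = "fus1",
                         seq = paste0(r1$read$seq, r2$read$seq),
                         ccs_count = 2L)
  full_map <- dplyr::bind_rows(r1$map, m2)
  aln <- assemble_alignment(read, full_map, full_map)
  expect_identical(sort(unique(aln$segments$chrom)), c("chr1", "chr2"))
  expect_identical(nrow(aln$junctions), 0L)   # breakpoint, not a junction
})

test_that("a read with no mapping is reported unmapped, not an error", {
  empty <- tibble::tibble(read_pos = integer(), chrom = character(),
                          gpos = integer())
  aln <- assemble_alignment(tibble::tibble(read_id = "x", seq = "ACGTACGT"),
                            empty, empty)
  expect_false(aln$mapped)
})
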