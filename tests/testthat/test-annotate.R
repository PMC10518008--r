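# hand-built single-chromosome reference for score arithmetic
score_db <- isoform_db(tibble::tibble(
  chrom = "chr1", start = 101L, end = 1000L, strand = "+",
  gene_id = "gA", isoform_id = "gA.t1"
))
mk_aln <- function(id, segs, junctions = NULL, strand = "+") {
  segs$read_start <- cumsum(c(1L, head(segs$gend - segs$gstart + 1L, -1)))
  segs$read_end <- segs$read_start + (segs$gend - segs$gstart)
  if (is.null(junctions)) {
    junctions <- tibble::tibble(chrom = character(), strand = character(),
                                donor = integer(), acceptor = integer())
  }
  structure(list(read_id = id, mapped = TRUE, strand = strand,
                 segments = segs, junctions = junctions),
            class = "spliced_alignment")
}

test_that("overlap score follows the printed formula and argmax", {
  aln <- mk_aln("t", tibble::tibble(chrom = "chr1", gstart = 101L,
                                    gend = 1000L))
  bm <- best_match(aln, score_db)
  expect_identical(bm$l_ti, 900L)
  expect_identical(bm$l_t, 0L)
  expect_identical(bm$l_i, 0L)
  expect_equal(bm$score, 900)

  aln2 <- mk_aln("t2", tibble::tibble(chrom = "chr1", gstart = 201L,
                                      gend = 1100L))
  bm2 <- best_match(aln2, score_db)
  expect_identical(bm2$l_ti, 800L)
  expect_identical(bm2$l_t, 100L)
  expect_identical(bm2$l_i, 100L)
  expect_equal(bm2$score, 800 - 0.5 * 100 - 0.5 * 100)

  # two candidates: the higher score wins
  db2 <- isoform_db(tibble::tibble(
    chrom = "chr1", start = c(101L, 301L), end = c(1000L, 600L),
    strand = "+", gene_id = c("gA", "gB"),
    isoform_id = c("gA.t1", "gB.t1")))
  bm3 <- best_match(aln, db2)
  expect_identical(bm3$isoform_id, "gA.t1")
  expect_null(best_match(mk_aln("x", tibble::tibble(
    chrom = "chr1", gstart = 5000L, gend = 5100L)), score_db))
})

test_that("full-length, truncated, skip, and shifted reads hit their classes", {
  # a gene with >= 3 exons and a single annotated isoform
  iso <- tw$db$isoforms |>
    dplyr::group_by(gene_id) |>
    dplyr::filter(dplyr::n() == 1, n_exons >= 3) |>
    dplyr::ungroup() |>
    dplyr::slice(1)
  ex <- iso$exons[[1]]

  full <- read_from_intervals(tw, "full", iso$chrom, ex, iso$strand)
  a_full <- assemble_alignment(full$read, full$map, full$map,
                               strand = iso$strand)
  expect_identical(classify(a_full, tw$db)$class, "FSM")

  # 5' truncation past the end window, junction-preserving -> ISM
  trunc_iv <- ex
  trunc_iv$start[1] <- trunc_iv$end[1] - 5L
  if (ex$end[1] - ex$start[1] + 1L < 107L) trunc_iv <- trunc_iv[-1, ]
  tr <- read_from_intervals(tw, "tr", iso$chrom, trunc_iv, iso$strand)
  a_tr <- assemble_alignment(tr$read, tr$map, tr$map, strand = iso$strand)
  cls_tr <- classify(a_tr, tw$db)
  expect_identical(cls_tr$class, "ISM")
  expect_identical(cls_tr$best_match, iso$isoform_id)

  # internal exon skip with known boundaries -> NIC
  skip <- read_from_intervals(tw, "skip", iso$chrom, ex[-2, ], iso$strand)
  a_skip <- assemble_alignment(skip$read, skip$map, skip$map,
                               strand = iso$strand)
  expect_identical(classify(a_skip, tw$db)$class, "NIC")

  # novel mid-exon donor -> NNC
  shift_iv <- ex
  shift_iv$end[1] <- shift_iv$end[1] - 7L
  sh <- read_from_intervals(tw, "sh", iso$chrom, shift_iv, iso$strand)
  a_sh <- assemble_alignment(sh$read, sh$map, sh$map, strand = iso$strand)
  expect_identical(classify(a_sh, tw$db)$class, "NNC")

  # small end offsets stay inside the 100-bp FSM window
  near <- ex
  near$start[1] <- near$start[1] + 50L
  nr <- read_from_intervals(tw, "nr", iso$chrom, near, iso$strand)
  a_nr <- assemble_alignment(nr$read, nr$map, nr$map, strand = iso$strand)
  expect_identical(classify(a_nr, tw$db)$class, "FSM")
})

test_that("monoexonic and intergenic rules assign Genic/ISM/FSM/Intergenic", {
  iso <- tw$db$isoforms[tw$db$isoforms$n_exons >= 3, ][1, ]
  ex <- iso$exons[[1]]

  # matches one internal exon exactly -> monoexonic ISM
  exact <- read_from_intervals(tw, "ex1", iso$chrom, ex[2, ], iso$strand)
  a_ex <- assemble_alignment(exact$read, exact$map, exact$map,
                             strand = iso$strand)
  expect_identical(classify(a_ex, tw$db)$class, "ISM")

  # inside the gene but matching no reference structure -> Genic
  part <- ex[2, ]
  part$start <- part$start + 11L
  gen <- read_from_intervals(tw, "gen1", iso$chrom, part, iso$strand)
  a_gen <- assemble_alignment(gen$read, gen$map, gen$map,
                              strand = iso$strand)
  expect_identical(classify(a_gen, tw$db)$class, "Genic")

  # monoexonic reference matched within 100 bp at both ends -> FSM
  mono_db <- isoform_db(tibble::tibble(
    chrom = "chr1", start = 101L, end = 700L, strand = "+",
    gene_id = "gM", isoform_id = "gM.t1"))
  g_mono <- genome_ref(c(chr1 = strrep("A", 1000)))
  a_mono <- mk_aln("m", tibble::tibble(chrom = "chr1", gstart = 151L,
                                       gend = 680L))
  expect_identical(classify(a_mono, mono_db)$class, "FSM")

  # outside every gene -> Intergenic
  gene_rows <- tw$db$genes[tw$db$genes$chrom == "chr1", ]
  gap_start <- max(gene_rows$end) + 50L
  inter <- mk_aln("i", tibble::tibble(chrom = "chr1", gstart = gap_start,
                                      gend = gap_start + 80L))
  expect_identical(classify(inter, tw$db)$class, "Intergenic")
})

test_that("cross-gene reads with enough mapped bases on each side are fusions", {
  g1 <- tw$db$isoforms[tw$db$isoforms$chrom == "chr1", ][1, ]
  g2 <- tw$db$isoforms[tw$db$isoforms$chrom == "chr2", ][1, ]
  ex1 <- g1$exons[[1]][1, ]; ex2 <- g2$exons[[1]][1, ]
  r1 <- read_from_intervals(tw, "f", g1$chrom, ex1)
  r2 <- read_from_intervals(tw, "f", g2$chrom, ex2)
  m2 <- r2$map; m2$read_pos <- m2$read_pos + nrow(r1$map)
  read <- tibble::tibble(read_id = "f", seq = paste0(r1$read$seq, r2$read$seq),
                         ccs_count = 3L)
  mp <- dplyr::bind_rows(r1$map, m2)
  aln <- assemble_alignment(read, mp, mp)
  rec <- classify(aln, tw$db)
  expect_identical(rec$class, "Fusion")
  expect_setequal(rec$gene_ids[[1]], c(g1$gene_id, g2$gene_id))
  det <- rec$fusion[[1]]
  expect_identical(det$gene5, g1$gene_id)
  expect_identical(det$bp5, ex1$end)
  expect_identical(det$bp3, ex2$start)

  # too few bases on the second side: not a fusion
  ex2b <- ex2; ex2b$end <- ex2b$start + 9L
  r2b <- read_from_intervals(tw, "f2", g2$chrom, ex2b)
  m2b <- r2b$map; m2b$read_pos <- m2b$read_pos + nrow(r1$map)
  readb <- tibble::tibble(read_id = "f2",
                          seq = paste0(r1$read$seq, r2b$read$seq),
                          ccs_count = 3L)
  mpb <- dplyr::bind_rows(r1$map, m2b)
  alnb <- assemble_alignment(readb, mpb, mpb)
  expect_false(identical(classify(alnb, tw$db)$class, "Fusion"))
})

test_that("classification is total and junction novelty labels are correct", {
  alns <- assemble_truth(tsim$reads, tsim$truth_maps)
  ann <- annotate_alignments(alns, tw$db)
  expect_identical(nrow(ann), nrow(tsim$reads))
  expect_false(any(is.na(ann$class)))
  expect_true(all(ann$class == "FSM"))   # error-free full-length reads

  j <- tw$db$junction_set[1:3, ]
  lab <- label_junction_novelty(j, tw$db, tw$genome)
  expect_true(all(lab$known))
  expect_true(all(lab$canonical))
  novel <- j[1, ]
  novel$donor <- novel$donor + 4L
  lab2 <- label_junction_novelty(novel, tw$db)
  expect_false(lab2$known)
})
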