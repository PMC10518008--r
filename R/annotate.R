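#' Default annotation parameters
#'
#' @param theta1,theta2 Overlap-score penalties on isoform-only and
#'   transcript-only exonic bases (default 0.5 each).
#' @param fsm_end_window FSM end-agreement window in bp (default 100).
#' @param fusion_min_seg Minimal mapped bases per fusion side (default 20).
#' @return Named list.
#' @export
annotate_params <- function(theta1 = 0.5, theta2 = 0.5,
                            fsm_end_window = 100L, fusion_min_seg = 20L) {
  as.list(environment())
}

# total overlap (bp) between two sets of closed intervals on one chromosome
interval_overlap <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) return(0L)
  ir1 <- IRanges::reduce(IRanges::IRanges(s1, e1))
  ir2 <- IRanges::reduce(IRanges::IRanges(s2, e2))
  sum(IRanges::width(IRanges::intersect(ir1, ir2)))
}

# isoform ids whose genomic span overlaps any exon block of the alignment
overlapping_isoforms <- function(aln, db) {
  if (!aln$mapped || nrow(aln$segments) == 0L) return(character(0))
  q <- GenomicRanges::GRanges(aln$segments$chrom,
                              IRanges::IRanges(aln$segments$gstart,
                                               aln$segments$gend))
  hits <- GenomicRanges::findOverlaps(q, db$ranges)
  unique(names(db$ranges)[S4Vectors::subjectHits(hits)])
}

#' Best-matching reference isoform of a spliced alignment
#'
#' Scores every overlapping reference isoform as
#' `L_TI - theta1 * L_I - theta2 * L_T`, where `L_TI` is the exonic overlap
#' of transcript and isoform, `L_T` the transcript exonic bases not covered
#' by the isoform, and `L_I` the isoform exonic bases not covered by the
#' transcript; returns the argmax.
#'
#' @param aln A `spliced_alignment`.
#' @param db An `isoform_db`.
#' @param params From [annotate_params()].
#' @return One-row tibble (`isoform_id`, `gene_id`, `score`, `l_ti`, `l_t`,
#'   `l_i`) or `NULL` when no isoform overlaps.
#' @export
best_match <- function(aln, db, params = annotate_params()) {
  cands <- overlapping_isoforms(aln, db)
  if (length(cands) == 0L) return(NULL)
  segs <- aln$segments
  t_len <- sum(segs$gend - segs$gstart + 1L)
  rows <- purrr::map(cands, function(id) {
    i <- match(id, db$isoforms$isoform_id)
    ex <- db$isoforms$exons[[i]]
    ch <- db$isoforms$chrom[i]
    s <- segs[segs$chrom == ch, , drop = FALSE]
    l_ti <- interval_overlap(s$gstart, s$gend, ex$start, ex$end)
    i_len <- sum(ex$end - ex$start + 1L)
    tibble(isoform_id = id, gene_id = db$isoforms$gene_id[i],
           l_ti = l_ti, l_t = t_len - l_ti, l_i = i_len - l_ti)
  }) |> bind_rows() |>
    mutate(score = .data$l_ti - params$theta1 * .data$l_i -
             params$theta2 * .data$l_t) |>
    arrange(desc(.data$score), desc(.data$l_ti), .data$isoform_id)
  rows[1, c("isoform_id", "gene_id", "score", "l_ti", "l_t", "l_i")]
}

# is `sub` a consecutive subsequence of `full`?
is_consecutive_subchain <- function(sub, full) {
  n <- length(sub); m <- length(full)
  if (n == 0L || n > m) return(FALSE)
  for (s in seq_len(m - n + 1L)) {
    if (identical(sub, full[s:(s + n - 1L)])) return(TRUE)
  }
  FALSE
}

# does any read exon block fully span an annotated intron of the isoform?
has_intron_retention <- function(segs, db, isoform_id) {
  j <- db$junctions[db$junctions$isoform_id == isoform_id, , drop = FALSE]
  if (nrow(j) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(j)), function(i) {
    any(segs$chrom == j$chrom[i] & segs$gstart <= j$donor[i] - 1L &
          segs$gend >= j$acceptor[i] + 1L)
  }, TRUE))
}

# fusion-side analysis: assign each exon block its unambiguous gene, collect
# per-gene mapped lengths, and locate a cross-gene transition
fusion_sides <- function(aln, db, min_seg) {
  segs <- aln$segments
  q <- GenomicRanges::GRanges(segs$chrom,
                              IRanges::IRanges(segs$gstart, segs$gend))
  g <- GenomicRanges::GRanges(db$genes$chrom,
                              IRanges::IRanges(db$genes$start, db$genes$end))
  hits <- GenomicRanges::findOverlaps(q, g)
  block_gene <- rep(NA_character_, nrow(segs))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (b in seq_len(nrow(segs))) {
    gs <- unique(db$genes$gene_id[sh[qh == b]])
    if (length(gs) == 1L) block_gene[b] <- gs
  }
  lens <- segs$gend - segs$gstart + 1L
  gene_len <- tapply(lens[!is.na(block_gene)], block_gene[!is.na(block_gene)],
                     sum)
  big <- names(gene_len)[gene_len >= min_seg]
  trans <- which(!is.na(block_gene[-nrow(segs)]) &
                   !is.na(block_gene[-1]) &
                   block_gene[-nrow(segs)] != block_gene[-1] &
                   block_gene[-nrow(segs)] %in% big &
                   block_gene[-1] %in% big)
  if (length(trans) == 0L) return(NULL)
  i <- trans[1]
  list(
    gene5 = block_gene[i], gene3 = block_gene[i + 1L],
    genes = unique(stats::na.omit(block_gene)),
    detail = tibble(
      gene5 = block_gene[i], gene3 = block_gene[i + 1L],
      chrom5 = segs$chrom[i], bp5 = segs$gend[i], strand5 = aln$strand,
      chrom3 = segs$chrom[i + 1L], bp3 = segs$gstart[i + 1L],
      strand3 = aln$strand
    )
  )
}

#' Classify a spliced alignment into one of the seven transcript classes
#'
#' Classes: FSM (all junctions match the best-match isoform, both ends within
#' the end window, no intron retention), ISM (junction chain matches a
#' consecutive sub-chain), NIC (only known donors/acceptors in a novel
#' combination, including retention of known introns), NNC (at least one
#' novel donor or acceptor), Fusion (a novel junction or breakpoint joining
#' two distinct genes with enough mapped bases on each side), Genic
#' (monoexonic inside a gene without a reference match), and Intergenic (no
#' overlap with any annotated isoform).
#'
#' @param aln A `spliced_alignment` (after correction).
#' @param db An `isoform_db`.
#' @param params From [annotate_params()].
#' @return A one-row annotation tibble; see [annotate_alignments()].
#' @export
classify <- function(aln, db, params = annotate_params()) {
  base <- tibble(
    read_id = aln$read_id, class = NA_character_,
    best_match = NA_character_, gene_ids = list(character(0)),
    n_junctions = if (aln$mapped) nrow(aln$junctions) else NA_integer_,
    n_novel_junctions = NA_integer_,
    junctions = list(if (aln$mapped) aln$junctions else tibble()),
    segments = list(if (aln$mapped) aln$segments else tibble()),
    strand = aln$strand, fusion = list(NULL)
  )
  if (!aln$mapped) {
    base$class <- "Unmapped"
    return(base)
  }
  jk <- junction_key(aln$junctions$chrom, aln$junctions$donor,
                     aln$junctions$acceptor)
  known <- jk %in% db$junction_keys
  base$n_novel_junctions <- sum(!known)

  over <- overlapping_isoforms(aln, db)
  if (length(over) == 0L) {
    base$class <- "Intergenic"
    return(base)
  }

  # fusion precedence: a novel junction/breakpoint joining two genes
  fs <- fusion_sides(aln, db, params$fusion_min_seg)
  has_breakpoint <- nrow(aln$segments) > length(jk) + 1L
  if (!is.null(fs) && (any(!known) || has_breakpoint)) {
    base$class <- "Fusion"
    base$gene_ids <- list(fs$genes)
    base$fusion <- list(fs$detail)
    return(base)
  }

  bm <- best_match(aln, db, params)
  base$best_match <- bm$isoform_id
  base$gene_ids <- list(bm$gene_id)
  segs <- aln$segments
  t_start <- min(segs$gstart); t_end <- max(segs$gend)
  iref <- match(bm$isoform_id, db$isoforms$isoform_id)

  if (nrow(aln$junctions) == 0L) {
    # monoexonic rules
    if (db$isoforms$n_exons[iref] == 1L &&
        abs(t_start - db$isoforms$start[iref]) <= params$fsm_end_window &&
        abs(t_end - db$isoforms$end[iref]) <= params$fsm_end_window) {
      base$class <- "FSM"
      return(base)
    }
    for (id in over) {
      i <- match(id, db$isoforms$isoform_id)
      if (db$isoforms$n_exons[i] < 2L) next
      ex <- db$isoforms$exons[[i]]
      if (any(ex$start == t_start & ex$end == t_end)) {
        base$class <- "ISM"
        base$best_match <- id
        base$gene_ids <- list(db$isoforms$gene_id[i])
        return(base)
      }
    }
    base$class <- "Genic"
    return(base)
  }

  ref_j <- db$junctions[db$junctions$isoform_id == bm$isoform_id, ,
                        drop = FALSE]
  ref_keys <- junction_key(ref_j$chrom, ref_j$donor, ref_j$acceptor)
  retention <- has_intron_retention(segs, db, bm$isoform_id)
  full <- length(jk) == length(ref_keys) && identical(jk, ref_keys)
  ends_ok <- abs(t_start - db$isoforms$start[iref]) <= params$fsm_end_window &&
    abs(t_end - db$isoforms$end[iref]) <= params$fsm_end_window

  if (!retention && full && ends_ok) {
    base$class <- "FSM"
    return(base)
  }
  if (!retention && is_consecutive_subchain(jk, ref_keys)) {
    base$class <- "ISM"
    return(base)
  }
  donors_known <- paste(aln$junctions$chrom, aln$junctions$donor,
                        sep = ":") %in% db$donor_keys
  acceptors_known <- paste(aln$junctions$chrom, aln$junctions$acceptor,
                           sep = ":") %in% db$acceptor_keys
  base$class <- if (all(known | (donors_known & acceptors_known))) "NIC"
  else "NNC"
  base
}

#' Annotate a set of spliced alignments
#'
#' Classifies every alignment and returns one row per read.
#'
#' @param alignments List of `spliced_alignment` objects.
#' @param db An `isoform_db`.
#' @param params From [annotate_params()].
#' @return Tibble with columns `read_id`, `class`, `best_match`, `gene_ids`
#'   (list), `n_junctions`, `n_novel_junctions`, `junctions` (list),
#'   `segments` (list), `strand`, `fusion` (list; per-side breakpoints for
#'   Fusion records).
#' @export
annotate_alignments <- function(alignments, db, params = annotate_params()) {
  bind_rows(purrr::map(alignments, classify, db = db, params = params))
}

#' Label junction novelty and canonical status
#'
#' @param junctions Tibble (`chrom`, `strand`, `donor`, `acceptor`).
#' @param db An `isoform_db`.
#' @param genome Optional `genome_ref` for motif/canonical columns.
#' @param canonical_set Canonical motif set.
#' @return Input with `known` (and, given a genome, `motif`/`canonical`)
#'   columns added.
#' @export
label_junction_novelty <- function(junctions, db, genome = NULL,
                                   canonical_set = .default_canonical) {
  out <- junctions |>
    mutate(known = junction_key(.data$chrom, .data$donor, .data$acceptor)
           %in% db$junction_keys)
  if (!is.null(genome) && nrow(out) > 0L) {
    res <- purrr::pmap(
      list(out$chrom, out$strand, out$donor, out$acceptor),
      function(ch, st, d, a) junction_motif(genome, ch, st, d, a,
                                            canonical_set)
    )
    out$motif <- map_chr(res, "motif")
    out$canonical <- map_lgl(res, "canonical")
  }
  out
}

#' Write the annotation table as TSV
#'
#' @param annotations From [annotate_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  flat <- annotations |>
    mutate(genes = map_chr(.data$gene_ids, paste, collapse = ",")) |>
    select("read_id", "class", "best_match", "genes", "n_junctions",
           "n_novel_junctions", "strand")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
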