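#' Evaluate code under a fixed RNG seed, restoring the RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# intron in transcription orientation: extended donor consensus GTAAGT, then
# random interior, then a polypyrimidine tract and the acceptor CAG.  Real
# splice sites carry U1/U2 consensus well beyond the bare dinucleotides; the
# extended motifs make boundary placement learnable, as it is in real genomes.
make_intron <- function(len, strand) {
  stopifnot(len >= 20L)
  tract <- paste(sample(c("C", "T"), 7L, replace = TRUE), collapse = "")
  s <- paste0("GTAAGT", random_dna(len - 16L), tract, "CAG")
  if (identical(strand, "-")) revcomp(s) else s
}

#' Synthetic world configuration
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes (genes distributed round-robin).
#' @param n_exons_range Exons per gene (uniform integer range).
#' @param exon_len_range,intron_len_range Exon/intron lengths in bp.
#' @param isoforms_per_gene_max Maximal isoforms per gene; extra isoforms are
#'   exon-skip variants sharing junction subsets with the full-length model.
#' @param intergenic_range Intergenic gap lengths in bp.
#' @param p_minus Probability a gene lies on the minus strand.
#' @return Named list of generator settings.
#' @export
world_config <- function(n_genes = 50L, n_chroms = 2L,
                         n_exons_range = c(2L, 12L),
                         exon_len_range = c(80L, 300L),
                         intron_len_range = c(60L, 400L),
                         isoforms_per_gene_max = 3L,
                         intergenic_range = c(200L, 1000L),
                         p_minus = 0.5) {
  as.list(environment())
}

#' Generate a synthetic genome, annotation, and truth tables
#'
#' Builds a multi-gene genome with canonical GT-AG introns carrying extended
#' splice-site consensus (donor `GTAAGT`, polypyrimidine tract + `CAG`
#' acceptor), a multi-isoform annotation in which additional isoforms are
#' exon-skip variants sharing junction subsets, and per-isoform transcript
#' sequences. Deterministic under `seed`.
#'
#' @param config From [world_config()].
#' @param seed Integer seed.
#' @return A `synthetic_world`: list with `genome` (`genome_ref`), `db`
#'   (`isoform_db`), `isoform_seq` (named character, genome-forward oriented
#'   exon concatenation), `config`, `seed`.
#' @export
make_world <- function(config = world_config(), seed = 1L) {
  with_seed(seed, {
    chrom_parts <- setNames(vector("list", config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
    chrom_len <- setNames(integer(config$n_chroms), names(chrom_parts))
    exon_rows <- list()
    for (g in seq_len(config$n_genes)) {
      chrom <- names(chrom_parts)[(g - 1L) %% config$n_chroms + 1L]
      strand <- if (runif(1) < config$p_minus) "-" else "+"
      n_ex <- sample(config$n_exons_range[1]:config$n_exons_range[2], 1L)
      ex_len <- sample(config$exon_len_range[1]:config$exon_len_range[2],
                       n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) {
        sample(config$intron_len_range[1]:config$intron_len_range[2],
               n_ex - 1L, replace = TRUE)
      } else integer(0)
      gap <- sample(config$intergenic_range[1]:config$intergenic_range[2], 1L)
      chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], random_dna(gap))
      chrom_len[chrom] <- chrom_len[chrom] + gap
      gene_id <- sprintf("G%04d", g)
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- chrom_len[chrom] + 1L
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        ends[e] <- pos + ex_len[e] - 1L
        chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], random_dna(ex_len[e]))
        pos <- ends[e] + 1L
        if (e < n_ex) {
          chrom_parts[[chrom]] <- c(chrom_parts[[chrom]],
                                    make_intron(in_len[e], strand))
          pos <- pos + in_len[e]
        }
      }
      chrom_len[chrom] <- pos - 1L

      # isoform 1: full model; extras: internal exon-skip variants
      iso_sets <- list(seq_len(n_ex))
      if (n_ex >= 3L && config$isoforms_per_gene_max > 1L) {
        n_extra <- sample(0:(config$isoforms_per_gene_max - 1L), 1L)
        skippable <- 2:(n_ex - 1L)
        n_extra <- min(n_extra, length(skippable))
        if (n_extra > 0L) {
          for (sk in sample(skippable, n_extra)) {
            iso_sets <- c(iso_sets, list(setdiff(seq_len(n_ex), sk)))
          }
        }
      }
      for (v in seq_along(iso_sets)) {
        keep <- iso_sets[[v]]
        exon_rows[[length(exon_rows) + 1L]] <- tibble(
          chrom = chrom, start = starts[keep], end = ends[keep],
          strand = strand, gene_id = gene_id,
          isoform_id = sprintf("%s.I%d", gene_id, v)
        )
      }
    }
    for (chrom in names(chrom_parts)) {
      tail_gap <- sample(config$intergenic_range[1]:config$intergenic_range[2], 1L)
      chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], random_dna(tail_gap))
    }
    genome <- genome_ref(vapply(chrom_parts, paste, "", collapse = ""))
    db <- isoform_db(bind_rows(exon_rows))
    iso_seq <- vapply(seq_len(nrow(db$isoforms)), function(i) {
      ex <- db$isoforms$exons[[i]]
      paste(vapply(seq_len(nrow(ex)), function(e)
        genome_seq(genome, db$isoforms$chrom[i], ex$start[e], ex$end[e]), ""),
        collapse = "")
    }, "")
    names(iso_seq) <- db$isoforms$isoform_id
    structure(list(genome = genome, db = db, isoform_seq = iso_seq,
                   config = config, seed = seed),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$db$genes), " genes, ",
      nrow(x$db$isoforms), " isoforms on ", length(x$genome$seq),
      " chromosome(s) (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# per-base truth mapping of an isoform's genome-forward oriented sequence
isoform_truth_map <- function(db, isoform_id) {
  i <- match(isoform_id, db$isoforms$isoform_id)
  ex <- db$isoforms$exons[[i]]
  gpos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE),
                 use.names = FALSE)
  tibble(read_pos = seq_along(gpos), chrom = db$isoforms$chrom[i],
         gpos = as.integer(gpos))
}

# apply substitution/indel corruption to (seq, truth map); insertions add
# unmapped bases, deletions remove read bases (leaving a genomic gap)
corrupt_read <- function(seq, map, sub_rate, indel_rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  gpos <- rep(NA_integer_, length(bases))
  chrom <- rep(NA_character_, length(bases))
  gpos[map$read_pos] <- map$gpos
  chrom[map$read_pos] <- map$chrom
  n <- length(bases)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    for (i in hit) bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  if (indel_rate > 0) {
    hit <- sort(which(runif(n) < indel_rate), decreasing = TRUE)
    for (i in hit) {
      w <- sample(1:3, 1L)
      if (runif(1) < 0.5) {  # insertion after i
        ins <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
        bases <- append(bases, ins, after = i)
        gpos <- append(gpos, rep(NA_integer_, w), after = i)
        chrom <- append(chrom, rep(NA_character_, w), after = i)
      } else {               # deletion starting at i
        del <- i:min(length(bases), i + w - 1L)
        bases <- bases[-del]; gpos <- gpos[-del]; chrom <- chrom[-del]
      }
    }
  }
  keep <- !is.na(gpos)
  list(seq = paste(bases, collapse = ""),
       map = tibble(read_pos = which(keep), chrom = chrom[keep],
                    gpos = gpos[keep]))
}

#' Simulate long reads with truth alignments from a synthetic world
#'
#' Emits full-length and (optionally) 5'-truncated junction-preserving reads
#' from the world's isoforms, with per-read CCS support counts, optional
#' substitution/indel corruption, and per-base truth mappings. Read sequences
#' are in genome-forward orientation (the orientation an aligner reports);
#' the source strand is recorded per read.
#'
#' @param world A `synthetic_world`.
#' @param reads_per_isoform Reads simulated per isoform (integer, or a named
#'   vector over isoform ids for a non-uniform expression profile).
#' @param truncate_frac Fraction of multi-exon reads 5'-truncated to ISM.
#' @param sub_rate,indel_rate Per-base corruption rates.
#' @param ccs_range Range of per-read CCS support counts.
#' @param seed Integer seed.
#' @return List with `reads` (tibble: `read_id`, `seq`, `ccs_count`,
#'   `isoform_id`, `gene_id`, `strand`, `truth_class`), `truth_maps` (named
#'   list of per-base mapping tibbles), `truth_junctions` (tibble of the
#'   junctions each read should produce).
#' @export
simulate_reads <- function(world, reads_per_isoform = 2L, truncate_frac = 0,
                           sub_rate = 0, indel_rate = 0,
                           ccs_range = c(2L, 5L), seed = 1L) {
  db <- world$db
  with_seed(seed, {
    profile <- if (length(reads_per_isoform) == 1L && is.null(names(reads_per_isoform))) {
      setNames(rep(as.integer(reads_per_isoform), nrow(db$isoforms)),
               db$isoforms$isoform_id)
    } else reads_per_isoform
    reads <- list(); truth_maps <- list(); truth_junc <- list()
    rid <- 0L
    for (iso in names(profile)) {
      i <- match(iso, db$isoforms$isoform_id)
      full_map <- isoform_truth_map(db, iso)
      full_seq <- world$isoform_seq[[iso]]
      ex <- db$isoforms$exons[[i]]
      jt <- exons_to_junctions(ex, db$isoforms$chrom[i], db$isoforms$strand[i],
                               db$isoforms$gene_id[i], iso)
      for (r in seq_len(profile[[iso]])) {
        rid <- rid + 1L
        read_id <- sprintf("read%05d", rid)
        truncate <- nrow(ex) >= 3L && runif(1) < truncate_frac
        if (truncate) {
          # drop leading exons and part of the first kept exon; keep >= 1
          # junction; trimmed length forced beyond the 100-bp end window
          j <- sample(2:(nrow(ex) - 1L), 1L)
          off <- sample(seq_len(ex$end[j] - ex$start[j]), 1L)
          cut_gpos <- ex$start[j] + off - 1L
          keep_from <- which(full_map$gpos >= cut_gpos)[1]
          if (full_map$read_pos[keep_from] <= 100L) {
            keep_from <- which(full_map$read_pos > 100L)[1]
          }
          map <- full_map[keep_from:nrow(full_map), , drop = FALSE]
          map$read_pos <- seq_len(nrow(map))
          seqr <- substr(full_seq, keep_from, nchar(full_seq))
          cls <- "ISM"
          jr <- jt[jt$donor > map$gpos[1], , drop = FALSE]
        } else {
          map <- full_map; seqr <- full_seq; cls <- "FSM"; jr <- jt
        }
        if (sub_rate > 0 || indel_rate > 0) {
          cr <- corrupt_read(seqr, map, sub_rate, indel_rate)
          seqr <- cr$seq; map <- cr$map
        }
        reads[[rid]] <- tibble(
          read_id = read_id, seq = seqr,
          ccs_count = sample(ccs_range[1]:ccs_range[2], 1L),
          isoform_id = iso, gene_id = db$isoforms$gene_id[i],
          strand = db$isoforms$strand[i], truth_class = cls
        )
        truth_maps[[read_id]] <- map
        if (nrow(jr) > 0L) {
          truth_junc[[read_id]] <- mutate(jr, read_id = read_id)
        }
      }
    }
    list(reads = bind_rows(reads), truth_maps = truth_maps,
         truth_junctions = bind_rows(truth_junc))
  })
}

#' Simulate spliced RNA-seq short reads spanning junctions
#'
#' Emits junction-spanning short-read records (one row per spanning read,
#' giving the spliced gap it supports), emulating a spliced short-read
#' aligner's output on RNA-seq from the same sample.
#'
#' @param world A `synthetic_world`.
#' @param junctions Tibble of junctions to cover (default: all annotated).
#' @param reads_per_junction Range of spanning-read counts per junction.
#' @param seed Integer seed.
#' @return Tibble: `read_id`, `chrom`, `donor`, `acceptor`.
#' @export
simulate_rnaseq_support <- function(world, junctions = NULL,
                                    reads_per_junction = c(2L, 10L),
                                    seed = 1L) {
  if (is.null(junctions)) junctions <- world$db$junction_set
  with_seed(seed, {
    n <- sample(reads_per_junction[1]:reads_per_junction[2],
                nrow(junctions), replace = TRUE)
    idx <- rep(seq_len(nrow(junctions)), n)
    tibble(read_id = sprintf("sr%06d", seq_along(idx)),
           chrom = junctions$chrom[idx],
           donor = junctions$donor[idx],
           acceptor = junctions$acceptor[idx])
  })
}

#' Per-junction short-read support
#'
#' Counts the spanning reads whose spliced gap exactly matches each junction;
#' a junction is supported when the count reaches `min_reads` or the junction
#' is present in the reference database.
#'
#' @param short_read_alignments Tibble (`chrom`, `donor`, `acceptor`), one
#'   row per spanning read.
#' @param junctions Tibble of junctions to score (`chrom`, `donor`,
#'   `acceptor`).
#' @param db Optional `isoform_db` for the reference-database clause.
#' @param min_reads Support threshold (default 2).
#' @return `junctions` with `support` and `supported` columns added.
#' @export
junction_support <- function(short_read_alignments, junctions, db = NULL,
                             min_reads = 2L) {
  jk <- junction_key(junctions$chrom, junctions$donor, junctions$acceptor)
  sk <- junction_key(short_read_alignments$chrom,
                     short_read_alignments$donor,
                     short_read_alignments$acceptor)
  counts <- table(sk)
  support <- as.integer(counts[jk])
  support[is.na(support)] <- 0L
  in_db <- if (is.null(db)) rep(FALSE, length(jk)) else jk %in% db$junction_keys
  junctions |>
    mutate(support = support, supported = support >= min_reads | in_db)
}

#' Randomly delete a percentage of genes from an annotation
#'
#' Removes all isoforms of the selected genes; the deleted genes' junctions
#' form the positive set of the sensitivity/precision protocol.
#'
#' @param db An `isoform_db`.
#' @param x_percent Percentage of genes to delete (0 < X < 100).
#' @param seed Integer seed.
#' @return List: `db` (reduced), `deleted_genes`, `deleted_junctions`.
#' @export
delete_annotation <- function(db, x_percent, seed = 1L) {
  if (x_percent <= 0 || x_percent >= 100) {
    abort("x_percent must be strictly between 0 and 100")
  }
  with_seed(seed, {
    genes <- db$genes$gene_id
    n_del <- max(1L, round(length(genes) * x_percent / 100))
    deleted <- sample(genes, n_del)
    keep_iso <- db$isoforms[!db$isoforms$gene_id %in% deleted, , drop = FALSE]
    if (nrow(keep_iso) == 0L) abort("deletion removed every gene")
    exon_df <- purrr::pmap(
      list(keep_iso$exons, keep_iso$chrom, keep_iso$strand,
           keep_iso$gene_id, keep_iso$isoform_id),
      function(ex, ch, st, g, id) mutate(ex, chrom = ch, strand = st,
                                         gene_id = g, isoform_id = id)
    ) |> bind_rows()
    deleted_j <- db$junctions |>
      filter(.data$gene_id %in% deleted) |>
      distinct(.data$chrom, .data$donor, .data$acceptor, .keep_all = TRUE) |>
      select("chrom", "strand", "donor", "acceptor")
    list(db = isoform_db(exon_df), deleted_genes = deleted,
         deleted_junctions = deleted_j)
  })
}

#' Junction-recovery sensitivity and precision
#'
#' Positives are the junctions of the deleted genes; TP are reported
#' junctions in the positive set, FP reported junctions outside it, FN
#' positives never reported. Sensitivity = TP/(TP+FN); precision = TP/(TP+FP).
#'
#' @param reported Tibble of reported junctions (`chrom`, `donor`,
#'   `acceptor`), typically the distinct novel junctions of a run against the
#'   reduced annotation.
#' @param positives Tibble of positive junctions (same columns).
#' @return One-row tibble: `tp`, `fp`, `fn`, `sensitivity`, `precision`.
#' @export
sensitivity_precision <- function(reported, positives) {
  rk <- unique(junction_key(reported$chrom, reported$donor,
                            reported$acceptor))
  pk <- unique(junction_key(positives$chrom, positives$donor,
                            positives$acceptor))
  tp <- length(intersect(rk, pk))
  fp <- length(setdiff(rk, pk))
  fn <- length(setdiff(pk, rk))
  if (length(pk) == 0L) {
    warn("empty positive set: sensitivity undefined")
    sens <- NaN
  } else sens <- tp / (tp + fn)
  prec <- if (tp + fp == 0L) NaN else tp / (tp + fp)
  tibble(tp = tp, fp = fp, fn = fn, sensitivity = sens, precision = prec)
}

#' Fusion-simulation configuration
#'
#' @param n_datasets Number of simulated datasets.
#' @param n_fusions Fusions per dataset.
#' @param n_background Non-fusion background transcripts per dataset.
#' @param support_range Supporting reads per fusion (uniform integer range).
#' @param ccs_range Per-read CCS support counts.
#' @param sub_rate,indel_rate Corruption rates for fusion reads.
#' @param min_segment Minimal transcript bases kept on each fusion side.
#' @return Named list of settings.
#' @export
fusion_sim_config <- function(n_datasets = 10L, n_fusions = 300L,
                              n_background = 2000L, support_range = c(1L, 5L),
                              ccs_range = c(1L, 5L), sub_rate = 0.005,
                              indel_rate = 0.002, min_segment = 50L) {
  as.list(environment())
}

#' Simulate gene-fusion datasets
#'
#' Per dataset: fusion sequences are built by sampling distinct partner
#' genes, placing random breakpoints inside one transcript of each partner,
#' and concatenating the flanking sequences; SNPs and short indels are added
#' at the configured rates; each fusion receives a uniform 1..5 supporting
#' reads. Background non-fusion transcripts are sampled from genes not used
#' as fusion partners in the dataset.
#'
#' @param world A `synthetic_world` (needs at least 2 genes).
#' @param config From [fusion_sim_config()].
#' @param seed Integer seed.
#' @return List of datasets; each has `reads`, `truth_maps`, and
#'   `truth_fusions` (tibble: `fusion_id`, `gene5`, `gene3`, `chrom5`, `bp5`,
#'   `chrom3`, `bp3`, `n_support`).
#' @export
simulate_fusions <- function(world, config = fusion_sim_config(), seed = 1L) {
  db <- world$db
  if (nrow(db$genes) < 2L) abort("fusion simulation needs at least 2 genes")
  with_seed(seed, {
    purrr::map(seq_len(config$n_datasets), function(ds) {
      reads <- list(); truth_maps <- list(); fus <- list()
      rid <- 0L
      partner_genes <- character(0)
      for (f in seq_len(config$n_fusions)) {
        gpair <- sample(db$genes$gene_id, 2L)
        partner_genes <- union(partner_genes, gpair)
        iso5 <- sample(db$isoforms$isoform_id[db$isoforms$gene_id == gpair[1]], 1L)
        iso3 <- sample(db$isoforms$isoform_id[db$isoforms$gene_id == gpair[2]], 1L)
        m5 <- isoform_truth_map(db, iso5)
        m3 <- isoform_truth_map(db, iso3)
        len5 <- nrow(m5); len3 <- nrow(m3)
        ms <- config$min_segment
        cut5 <- sample(ms:max(ms, len5 - ms), 1L)
        cut3 <- sample(ms:max(ms, len3 - ms), 1L)
        seq5 <- substr(world$isoform_seq[[iso5]], 1L, cut5)
        seq3 <- substr(world$isoform_seq[[iso3]], cut3, len3)
        map5 <- m5[seq_len(cut5), , drop = FALSE]
        map3 <- m3[cut3:len3, , drop = FALSE]
        map3$read_pos <- cut5 + seq_len(nrow(map3))
        fseq <- paste0(seq5, seq3)
        fmap <- bind_rows(map5, map3)
        n_sup <- sample(config$support_range[1]:config$support_range[2], 1L)
        for (s in seq_len(n_sup)) {
          rid <- rid + 1L
          read_id <- sprintf("ds%02d_fus%04d_r%d", ds, f, s)
          seqr <- fseq; mapr <- fmap
          if (config$sub_rate > 0 || config$indel_rate > 0) {
            cr <- corrupt_read(seqr, mapr, config$sub_rate, config$indel_rate)
            seqr <- cr$seq; mapr <- cr$map
          }
          reads[[rid]] <- tibble(
            read_id = read_id, seq = seqr,
            ccs_count = sample(config$ccs_range[1]:config$ccs_range[2], 1L),
            isoform_id = NA_character_, gene_id = NA_character_,
            strand = "+", truth_class = "Fusion"
          )
          truth_maps[[read_id]] <- mapr
        }
        fus[[f]] <- tibble(
          fusion_id = sprintf("fus%04d", f),
          gene5 = gpair[1], gene3 = gpair[2],
          chrom5 = map5$chrom[1], bp5 = map5$gpos[nrow(map5)],
          chrom3 = map3$chrom[1], bp3 = map3$gpos[1],
          n_support = n_sup
        )
      }
      bg_iso <- db$isoforms$isoform_id[!db$isoforms$gene_id %in% partner_genes]
      if (length(bg_iso) > 0L && config$n_background > 0L) {
        picks <- sample(bg_iso, config$n_background, replace = TRUE)
        for (iso in picks) {
          rid <- rid + 1L
          read_id <- sprintf("ds%02d_bg%05d", ds, rid)
          reads[[rid]] <- tibble(
            read_id = read_id, seq = world$isoform_seq[[iso]],
            ccs_count = sample(config$ccs_range[1]:config$ccs_range[2], 1L),
            isoform_id = iso,
            gene_id = db$isoforms$gene_id[match(iso, db$isoforms$isoform_id)],
            strand = db$isoforms$strand[match(iso, db$isoforms$isoform_id)],
            truth_class = "background"
          )
          truth_maps[[read_id]] <- isoform_truth_map(db, iso)
        }
      }
      list(reads = bind_rows(reads), truth_maps = truth_maps,
           truth_fusions = bind_rows(fus))
    })
  })
}

#' Corrupt alignments with ambiguity-preserving junction shifts
#'
#' Randomly shifts each junction of each alignment within `max_shift` bp,
#' restricted to wobble placements that leave the read-to-genome base
#' correspondence unchanged (the only shifts a mapper can plausibly make
#' without creating mismatches). Junctions with no wobble freedom are left
#' untouched. Used by the correction-benefit protocol.
#'
#' @param alignments List of `spliced_alignment` objects.
#' @param genome A `genome_ref`.
#' @param max_shift Maximal absolute shift in bp (default 5).
#' @param seed Integer seed.
#' @return List with `alignments` (corrupted) and `n_shifted`.
#' @export
corrupt_junctions <- function(alignments, genome, max_shift = 5L, seed = 1L) {
  n_shifted <- 0L
  out <- with_seed(seed, {
    purrr::map(alignments, function(aln) {
      if (!aln$mapped || nrow(aln$junctions) == 0L) return(aln)
      segs <- aln$segments
      jn <- aln$junctions
      for (j in seq_len(nrow(jn))) {
        shifts <- wobble_shifts(genome, jn$chrom[j], jn$donor[j],
                                jn$acceptor[j], max_shift)
        shifts <- setdiff(shifts, 0L)
        if (length(shifts) == 0L) next
        d <- if (length(shifts) == 1L) shifts else sample(shifts, 1L)
        left <- which(segs$chrom == jn$chrom[j] &
                        segs$gend == jn$donor[j] - 1L)
        right <- which(segs$chrom == jn$chrom[j] &
                         segs$gstart == jn$acceptor[j] + 1L)
        if (length(left) != 1L || length(right) != 1L) next
        segs$gend[left] <- segs$gend[left] + d
        segs$read_end[left] <- segs$read_end[left] + d
        segs$gstart[right] <- segs$gstart[right] + d
        segs$read_start[right] <- segs$read_start[right] + d
        jn$donor[j] <- jn$donor[j] + d
        jn$acceptor[j] <- jn$acceptor[j] + d
        n_shifted <<- n_shifted + 1L
      }
      aln$segments <- segs
      aln$junctions <- jn
      aln
    })
  })
  list(alignments = out, n_shifted = n_shifted)
}
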