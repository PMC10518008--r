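#' Read alignment records into per-base mapping tables
#'
#' Reads a SAM or BAM file and projects every aligned base (CIGAR `M`
#' operations) onto the reference, returning one row per aligned base. Window
#' short-read names of the form `readID|offset` (see
#' [write_window_fasta()]) are translated back to parent-read coordinates.
#' Reverse-strand records are projected back onto the original (forward) read
#' orientation.
#'
#' @param path SAM or BAM file.
#' @param window_names If `TRUE`, parse `readID|offset` names and report
#'   positions in parent-read coordinates.
#' @param include_secondary Keep secondary records (flag 0x100); default TRUE.
#' @return Tibble with columns `read_id`, `read_pos`, `chrom`, `gpos`,
#'   `rev` (logical: record was reverse-strand).
#' @export
read_base_mappings <- function(path, window_names = FALSE,
                               include_secondary = TRUE) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag"), flag = flags)
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  if (length(ga) == 0L) {
    return(tibble(read_id = character(), read_pos = integer(),
                  chrom = character(), gpos = integer(), rev = logical()))
  }
  meta <- S4Vectors::mcols(ga)
  keep <- rep(TRUE, length(ga))
  if (!include_secondary) keep <- bitwAnd(meta$flag, 256L) == 0L
  ga <- ga[keep]; meta <- meta[keep, , drop = FALSE]

  cig <- GenomicAlignments::cigar(ga)
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "M")
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = GenomicRanges::start(ga), ops = "M")
  chroms <- as.character(GenomicRanges::seqnames(ga))
  qlen <- GenomicAlignments::qwidth(ga)
  is_rev <- bitwAnd(meta$flag, 16L) != 0L

  rows <- vector("list", length(ga))
  for (i in seq_along(ga)) {
    qs <- IRanges::start(qr[[i]]); qe <- IRanges::end(qr[[i]])
    rs <- IRanges::start(rr[[i]])
    qpos <- unlist(mapply(seq.int, qs, qe, SIMPLIFY = FALSE), use.names = FALSE)
    gpos <- unlist(mapply(function(a, b, r) r + seq.int(a, b) - a,
                          qs, qe, rs, SIMPLIFY = FALSE), use.names = FALSE)
    if (is_rev[i]) qpos <- qlen[i] - qpos + 1L
    rows[[i]] <- tibble(read_id = meta$qname[i], read_pos = qpos,
                        chrom = chroms[i], gpos = as.integer(gpos),
                        rev = is_rev[i])
  }
  out <- bind_rows(rows)
  if (window_names && nrow(out) > 0L) {
    parts <- strsplit(out$read_id, "|", fixed = TRUE)
    offs <- as.integer(map_chr(parts, function(p) p[length(p)]))
    out$read_id <- map_chr(parts, function(p)
      paste(p[-length(p)], collapse = "|"))
    out$read_pos <- out$read_pos + offs - 1L
  }
  out
}

# build a CIGAR + record fields from one read's per-base forward-orientation
# mapping; one record per chromosome segment (first primary, rest supplementary)
mapping_to_sam_records <- function(read_id, seq, map_df, min_intron = 20L) {
  L <- nchar(seq)
  g <- rep(NA_integer_, L); ch <- rep(NA_character_, L)
  if (nrow(map_df) > 0L) {
    g[map_df$read_pos] <- map_df$gpos
    ch[map_df$read_pos] <- map_df$chrom
  }
  mapped <- which(!is.na(g))
  if (length(mapped) == 0L) {
    return(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", read_id, seq))
  }
  # chromosome segments
  seg_brk <- which(ch[mapped][-1] != ch[mapped][-length(mapped)])
  seg_start <- c(1L, seg_brk + 1L); seg_end <- c(seg_brk, length(mapped))
  recs <- character(0)
  for (s in seq_along(seg_start)) {
    idx <- mapped[seg_start[s]:seg_end[s]]
    cig <- character(0)
    if (idx[1] > 1L) cig <- c(cig, paste0(idx[1] - 1L, "S"))
    i <- 1L
    while (i <= length(idx)) {
      j <- i
      while (j < length(idx) && idx[j + 1L] == idx[j] + 1L &&
             g[idx[j + 1L]] == g[idx[j]] + 1L) j <- j + 1L
      cig <- c(cig, paste0(j - i + 1L, "M"))
      if (j < length(idx)) {
        rgap <- idx[j + 1L] - idx[j] - 1L
        ggap <- g[idx[j + 1L]] - g[idx[j]] - 1L
        if (rgap > 0L) cig <- c(cig, paste0(rgap, "I"))
        if (ggap > 0L) {
          cig <- c(cig, paste0(ggap, if (ggap >= min_intron) "N" else "D"))
        }
      }
      i <- j + 1L
    }
    if (idx[length(idx)] < L) cig <- c(cig, paste0(L - idx[length(idx)], "S"))
    flag <- if (s == 1L) 0L else 2048L
    recs <- c(recs, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                            read_id, flag, ch[idx[1]], g[idx[1]],
                            paste(cig, collapse = ""), seq))
  }
  recs
}

#' Write per-base mappings as a SAM file
#'
#' Serializes forward-orientation per-base mappings (e.g. simulator truth
#' mappings) as SAM records; genomic gaps of at least `min_intron` bp become
#' `N` operations, shorter ones `D`, interior unmapped read bases `I`, and
#' flanking unmapped bases soft clips. Reads spanning several chromosomes
#' emit one record per chromosome segment (supplementary after the first).
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param mappings Tibble (`read_id`, `read_pos`, `chrom`, `gpos`).
#' @param genome A `genome_ref` (for the SAM header).
#' @param path Output path ending in `.sam`.
#' @param min_intron Minimal genomic gap written as an `N` operation.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, mappings, genome, path, min_intron = 20L) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome$lengths),
                   genome$lengths))
  maps <- split(mappings, mappings$read_id)
  body <- purrr::pmap(list(reads$read_id, reads$seq), function(id, s) {
    m <- maps[[id]]
    if (is.null(m)) m <- tibble(read_pos = integer(), chrom = character(),
                                gpos = integer())
    mapping_to_sam_records(id, s, m, min_intron)
  })
  writeLines(c(hdr, unlist(body)), path)
  invisible(path)
}

#' Write spliced alignments as BED12
#'
#' Each chromosome segment of each alignment becomes one BED12 line with exon
#' blocks as blockStarts/blockSizes (0-based half-open output coordinates).
#'
#' @param alignments List of `spliced_alignment` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(alignments, path) {
  lines <- purrr::map(alignments, function(aln) {
    if (!aln$mapped) return(character(0))
    segs <- aln$segments
    out <- character(0)
    for (ch in unique(segs$chrom)) {
      s <- segs[segs$chrom == ch, , drop = FALSE]
      chrom_start <- min(s$gstart) - 1L          # to 0-based
      chrom_end <- max(s$gend)
      sizes <- s$gend - s$gstart + 1L
      starts <- s$gstart - 1L - chrom_start
      out <- c(out, sprintf(
        "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
        ch, chrom_start, chrom_end, aln$read_id, aln$strand,
        chrom_start, chrom_end, nrow(s),
        paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(starts, collapse = ","), ",")))
    }
    out
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Write the per-read junction report
#'
#' One line per (read, junction): `read_id`, `chrom`, `strand`, `donor`,
#' `acceptor`. Junctions supported by several reads appear once per read.
#'
#' @param alignments List of `spliced_alignment` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_file <- function(alignments, path) {
  rows <- purrr::map(alignments, function(aln) {
    j <- aln$junctions
    if (!aln$mapped || nrow(j) == 0L) return(character(0))
    sprintf("%s\t%s\t%s\t%d\t%d", aln$read_id, j$chrom, j$strand,
            j$donor, j$acceptor)
  })
  writeLines(unlist(rows), path)
  invisible(path)
}
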