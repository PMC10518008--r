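#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-record) FASTA file into a `genome_ref` object.
#' Sequences are case-folded to uppercase and validated to contain only
#' A/C/G/T/N.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `genome_ref` object: a list with `seq` (named character vector of
#'   chromosome sequences) and `lengths` (named integer vector).
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) abort(paste0("malformed FASTA '", fasta_path, "': ",
                                     conditionMessage(e))),
    # Biostrings silently drops invalid letters; treat that as malformed
    warning = function(w) abort(paste0("malformed FASTA '", fasta_path,
                                       "': ", conditionMessage(w)))
  )
  if (length(set) == 0L) abort(paste0("empty FASTA: ", fasta_path))
  # keep only the first whitespace-delimited token of each header
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate chromosome name(s): ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGTN characters in chromosome(s): ",
                 paste(nm[bad], collapse = ", ")))
  }
  genome_ref(seqs)
}

#' Construct a genome reference from named sequences
#'
#' @param seqs Named character vector of uppercase chromosome sequences.
#' @return A `genome_ref` object.
#' @export
genome_ref <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs <- toupper(seqs)
  structure(
    list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
    class = "genome_ref"
  )
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("<genome_ref> ", length(x$seq), " chromosome(s), ",
      format(sum(x$lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Extract genomic sequence
#'
#' @param genome A `genome_ref`.
#' @param chrom Chromosome name.
#' @param start,end 1-based closed interval.
#' @return Character scalar; regions outside the chromosome are N-padded.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  len <- genome$lengths[[chrom]]
  if (is.null(len)) abort(paste0("unknown chromosome: ", chrom))
  if (end < start) return("")
  s <- max(1L, start); e <- min(len, end)
  core <- if (s > e) "" else substr(genome$seq[[chrom]], s, e)
  left <- if (start < 1L) strrep("N", 1L - start) else ""
  right <- if (end > len) strrep("N", end - len) else ""
  paste0(left, core, right)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE))
}

.default_canonical <- c("GT-AG", "GC-AG", "AT-AC")

#' Splice-junction motif and canonical status
#'
#' Reports the intron-boundary dinucleotides of a junction in transcription
#' orientation (minus-strand junctions are reverse-complemented), e.g.
#' `"GT-AG"`, together with a canonical flag.
#'
#' Junction coordinates follow the package convention: `donor` is the first
#' intronic base and `acceptor` the last intronic base, both in genome
#' coordinates (`donor < acceptor` regardless of strand).
#'
#' @param genome A `genome_ref`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param donor,acceptor First/last intronic base (1-based genome coords).
#' @param canonical_set Character vector of motifs counted as canonical.
#' @return A list with `motif` (e.g. `"GT-AG"`) and `canonical` (logical).
#' @export
junction_motif <- function(genome, chrom, strand, donor, acceptor,
                           canonical_set = .default_canonical) {
  len <- genome$lengths[[chrom]]
  if (is.null(len)) abort(paste0("unknown chromosome: ", chrom))
  if (donor < 1L || acceptor > len || acceptor - donor < 3L) {
    abort("junction out of chromosome bounds or intron shorter than 4 bp")
  }
  d2 <- substr(genome$seq[[chrom]], donor, donor + 1L)
  a2 <- substr(genome$seq[[chrom]], acceptor - 1L, acceptor)
  motif <- if (identical(strand, "-")) {
    paste0(revcomp(a2), "-", revcomp(d2))
  } else {
    paste0(d2, "-", a2)
  }
  list(motif = motif, canonical = motif %in% canonical_set)
}

junction_key <- function(chrom, donor, acceptor) {
  paste(chrom, donor, acceptor, sep = ":")
}

# derive the junction tibble of one isoform from its coordinate-sorted exons
exons_to_junctions <- function(exons, chrom, strand, gene_id, isoform_id) {
  k <- nrow(exons)
  if (k < 2L) {
    return(tibble(isoform_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  donor = integer(), acceptor = integer()))
  }
  tibble(
    isoform_id = isoform_id, gene_id = gene_id, chrom = chrom, strand = strand,
    donor = exons$end[-k] + 1L,
    acceptor = exons$start[-1] - 1L
  )
}

#' Load a transcript annotation from GTF
#'
#' Parses an Ensembl-dialect GTF (requires `gene_id` and `transcript_id`
#' attributes on exon features) into an `isoform_db`: isoform models with
#' derived splice junctions, a gene index, and an interval index for overlap
#' queries.
#'
#' @param gtf_path Path to a GTF file.
#' @param genome Optional `genome_ref`; when given, exon coordinates are
#'   validated against chromosome lengths.
#' @return An `isoform_db` object.
#' @export
load_annotation <- function(gtf_path, genome = NULL) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) abort(paste0("no exon features in GTF: ", gtf_path))
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(ex$gene_id),
    isoform_id = as.character(ex$transcript_id)
  )
  if (anyNA(df$gene_id) || anyNA(df$isoform_id)) {
    abort("GTF exon features must carry gene_id and transcript_id")
  }
  if (!is.null(genome)) {
    lens <- genome$lengths[df$chrom]
    if (anyNA(lens) || any(df$end > lens) || any(df$start < 1L)) {
      abort("exon outside chromosome bounds")
    }
  }
  isoform_db(df)
}

#' Build an isoform database from an exon table
#'
#' @param exon_df Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `isoform_id` (one row per exon, 1-based closed coords).
#' @return An `isoform_db` object with per-isoform junctions, a deduplicated
#'   junction set, donor/acceptor site sets, and a `GRanges` interval index.
#' @export
isoform_db <- function(exon_df) {
  exon_df <- as_tibble(exon_df) |> arrange(.data$isoform_id, .data$start)
  if (any(exon_df$end < exon_df$start)) abort("exon with end < start")
  split_ex <- split(exon_df, exon_df$isoform_id)
  iso <- purrr::map(split_ex, function(d) {
    if (length(unique(d$chrom)) != 1L || length(unique(d$strand)) != 1L) {
      abort(paste0("isoform ", d$isoform_id[1],
                   " spans multiple chromosomes or strands"))
    }
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)])) {
      abort(paste0("overlapping or unsorted exons in isoform ",
                   d$isoform_id[1]))
    }
    tibble(
      isoform_id = d$isoform_id[1], gene_id = d$gene_id[1],
      chrom = d$chrom[1], strand = d$strand[1],
      start = min(d$start), end = max(d$end), n_exons = nrow(d),
      exons = list(tibble(start = d$start, end = d$end))
    )
  }) |> bind_rows()

  juncs <- purrr::pmap(
    list(iso$exons, iso$chrom, iso$strand, iso$gene_id, iso$isoform_id),
    function(ex, ch, st, g, id) exons_to_junctions(ex, ch, st, g, id)
  ) |> bind_rows()

  junction_set <- juncs |>
    distinct(.data$chrom, .data$donor, .data$acceptor, .keep_all = TRUE) |>
    select("chrom", "strand", "donor", "acceptor")

  genes <- iso |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              n_isoforms = n(), .groups = "drop")

  ranges <- GenomicRanges::GRanges(
    seqnames = iso$chrom,
    ranges = IRanges::IRanges(start = iso$start, end = iso$end)
  )
  names(ranges) <- iso$isoform_id

  structure(
    list(
      isoforms = iso,
      junctions = juncs,
      junction_set = junction_set,
      junction_keys = junction_key(junction_set$chrom, junction_set$donor,
                                   junction_set$acceptor),
      donor_keys = unique(paste(juncs$chrom, juncs$donor, sep = ":")),
      acceptor_keys = unique(paste(juncs$chrom, juncs$acceptor, sep = ":")),
      genes = genes,
      ranges = ranges
    ),
    class = "isoform_db"
  )
}

#' @export
print.isoform_db <- function(x, ...) {
  cat("<isoform_db> ", nrow(x$genes), " gene(s), ", nrow(x$isoforms),
      " isoform(s), ", nrow(x$junction_set), " distinct junction(s)\n",
      sep = "")
  invisible(x)
}

#' Write an isoform database to GTF
#'
#' Emits transcript and exon features in the Ensembl dialect; round-trips
#' through [load_annotation()].
#'
#' @param db An `isoform_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(db, path) {
  iso <- db$isoforms
  rows <- purrr::pmap(
    list(iso$exons, iso$chrom, iso$strand, iso$gene_id, iso$isoform_id),
    function(ex, ch, st, g, id) {
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', g, id)
      tx <- sprintf("%s\tisokit\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                    ch, min(ex$start), max(ex$end), st, attr_str)
      exl <- sprintf("%s\tisokit\texon\t%d\t%d\t.\t%s\t.\t%s",
                     ch, ex$start, ex$end, st, attr_str)
      c(tx, exl)
    }
  )
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Write a genome reference to FASTA
#'
#' @param genome A `genome_ref`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' All distinct junctions of an isoform database
#'
#' @param db An `isoform_db`.
#' @param genome Optional `genome_ref`; when supplied, motif and canonical
#'   columns are added.
#' @param canonical_set Canonical motif set (see [junction_motif()]).
#' @return Tibble with one row per distinct junction.
#' @export
db_junctions <- function(db, genome = NULL,
                         canonical_set = .default_canonical) {
  js <- db$junction_set
  if (!is.null(genome) && nrow(js) > 0L) {
    res <- purrr::pmap(
      list(js$chrom, js$strand, js$donor, js$acceptor),
      function(ch, st, d, a) junction_motif(genome, ch, st, d, a,
                                            canonical_set)
    )
    js$motif <- map_chr(res, "motif")
    js$canonical <- map_lgl(res, "canonical")
  }
  js
}
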