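#' Pipeline configuration
#'
#' Collects the stage inputs and every numeric default of the toolkit:
#' window length 250, step 100, combination tuning constants (2, 2, 1, 1),
#' cross-chromosome distance 1000, overlap penalties 0.5/0.5, DIU thresholds
#' Q = 4 and P = 5%, minimal CCS support 2, FSM end window 100 bp, minimal
#' fusion segment 20 bp.
#'
#' @param genome A `genome_ref` or path to a genome FASTA.
#' @param annotation An `isoform_db` or path to a GTF.
#' @param reads Tibble (`read_id`, `seq`, `ccs_count`) or path to a reads
#'   FASTA whose headers carry `ccs=<n>`.
#' @param long_maps,short_maps Per-base mapping tibbles (`read_id`,
#'   `read_pos`, `chrom`, `gpos`) or paths to SAM/BAM files (window reads
#'   named `readID|offset`).
#' @param model A `splice_model`, a checkpoint path, or `NULL`.
#' @param use_cnn Apply the model (`TRUE`) or the deterministic fallback.
#' @param align,annot Parameter lists from [align_params()] /
#'   [annotate_params()].
#' @param min_ccs,radius,bp_tol,Q,P Stage thresholds (see module docs).
#' @param sample_id Sample label.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (only stochastic stages consume it).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, reads, long_maps,
                            short_maps = NULL, model = NULL, use_cnn = TRUE,
                            align = align_params(),
                            annot = annotate_params(), min_ccs = 2L,
                            radius = 15L, bp_tol = 10L, Q = 4, P = 0.05,
                            sample_id = "sample", out_dir = "isokit_out",
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_inputs <- function(config) {
  g <- config$genome
  if (is.character(g)) g <- load_genome(g)
  db <- config$annotation
  if (is.character(db)) db <- load_annotation(db, g)
  reads <- config$reads
  if (is.character(reads)) reads <- read_reads_fasta(reads)
  lm <- config$long_maps
  if (is.character(lm)) lm <- read_base_mappings(lm)
  sm <- config$short_maps
  if (is.character(sm)) sm <- read_base_mappings(sm, window_names = TRUE)
  if (is.null(sm)) sm <- tibble(read_id = character(), read_pos = integer(),
                                chrom = character(), gpos = integer())
  model <- config$model
  if (is.character(model)) model <- load_splice_model(model)
  list(genome = g, db = db, reads = reads, long_maps = lm, short_maps = sm,
       model = model)
}

#' Run the full analysis pipeline
#'
#' CCS filtering, hybrid alignment assembly, splice-site correction (CNN or
#' deterministic fallback), seven-class annotation, expression
#' quantification, and fusion calling; writes the corrected alignments
#' (BED12), the per-read junction report, gene and transcript expression
#' tables, and the gene-fusion file, plus a manifest with content hashes.
#'
#' @param config From [pipeline_config()].
#' @return List with `alignments`, `annotations`, `expression`, `fusions`,
#'   `files` (output paths), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- resolve_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  reads <- filter_ccs(inp$reads, config$min_ccs)
  if (nrow(reads) == 0L) abort("no reads retained by the CCS filter")
  message("isokit: ", nrow(reads), " reads after CCS filter (>= ",
          config$min_ccs, ")")

  lm_by <- split(inp$long_maps, inp$long_maps$read_id)
  sm_by <- split(inp$short_maps, inp$short_maps$read_id)
  empty_map <- tibble(read_pos = integer(), chrom = character(),
                      gpos = integer())
  alignments <- purrr::map(seq_len(nrow(reads)), function(i) {
    id <- reads$read_id[i]
    lm <- lm_by[[id]] %||% empty_map
    sm <- sm_by[[id]] %||% empty_map
    strand <- if ("strand" %in% names(reads)) reads$strand[i] else "+"
    assemble_alignment(reads[i, ], lm[, c("read_pos", "chrom", "gpos")],
                       sm[, c("read_pos", "chrom", "gpos")],
                       params = config$align, strand = strand)
  })
  names(alignments) <- reads$read_id
  n_mapped <- sum(map_lgl(alignments, "mapped"))
  message("isokit: ", n_mapped, "/", length(alignments), " reads assembled")

  model <- if (isTRUE(config$use_cnn)) inp$model else NULL
  alignments <- purrr::map(alignments, function(a)
    correct_alignment(model, inp$genome, inp$db, a, radius = config$radius))
  message("isokit: splice correction done (",
          if (is.null(model)) "fallback" else "CNN", " mode)")

  annotations <- annotate_alignments(alignments, inp$db, config$annot)
  mapped_annot <- annotations[annotations$class != "Unmapped", , drop = FALSE]
  expr <- expression_table(mapped_annot, inp$db, config$sample_id,
                           total = nrow(reads))
  fusions <- call_fusions(mapped_annot, reads, bp_tol = config$bp_tol)

  files <- c(
    bed = file.path(config$out_dir, "alignments.bed"),
    junctions = file.path(config$out_dir, "junctions.txt"),
    annotation = file.path(config$out_dir, "annotation.tsv"),
    gene_expr = file.path(config$out_dir, "gene_expression.tsv"),
    tx_expr = file.path(config$out_dir, "transcript_expression.tsv"),
    fusion = file.path(config$out_dir, "fusions.tsv")
  )
  write_bed12(alignments, files[["bed"]])
  write_junction_file(alignments, files[["junctions"]])
  write_annotation_tsv(annotations, files[["annotation"]])
  write_expression_tsv(filter(expr, .data$feature_type == "gene"),
                       files[["gene_expr"]])
  write_expression_tsv(filter(expr, .data$feature_type != "gene"),
                       files[["tx_expr"]])
  write_fusion_tsv(fusions, files[["fusion"]])
  manifest <- file.path(config$out_dir, "manifest.tsv")
  write.table(
    tibble(file = basename(files), md5 = unname(tools::md5sum(files))),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE
  )
  message("isokit: outputs written to ", config$out_dir)
  invisible(list(alignments = alignments, annotations = annotations,
                 expression = expr, fusions = fusions,
                 files = c(files, manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write polished-transcript FASTA with CCS counts
#'
#' Headers carry the CCS support as `>read_id ccs=<n>` (missing annotations
#' default to 1).
#'
#' @param path FASTA path.
#' @return Tibble (`read_id`, `seq`, `ccs_count`).
#' @export
read_reads_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  hdr <- names(set)
  ccs <- suppressWarnings(as.integer(sub(".*ccs=(\\d+).*", "\\1", hdr)))
  ccs[is.na(ccs)] <- 1L
  tibble(read_id = sub("\\s.*$", "", hdr),
         seq = as.character(set), ccs_count = ccs)
}

#' @rdname read_reads_fasta
#' @param reads Tibble (`read_id`, `seq`, `ccs_count`).
#' @export
write_reads_fasta <- function(reads, path) {
  lines <- as.vector(rbind(
    sprintf(">%s ccs=%d", reads$read_id, reads$ccs_count), reads$seq))
  writeLines(lines, path)
  invisible(path)
}
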