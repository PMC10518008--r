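#' Extract the 21-bp window of one splice site
#'
#' Windows are taken in transcription orientation with `n_exonic` exonic
#' bases followed (donor) or preceded (acceptor) by intronic sequence; the
#' true boundary offset (the label the model predicts) is `n_exonic` for
#' donor windows and `21 - n_exonic` for acceptor windows. Sequence beyond
#' chromosome ends is N-padded.
#'
#' @param genome A `genome_ref`.
#' @param chrom,strand,donor,acceptor Junction coordinates (see
#'   [junction_motif()]).
#' @param side `"donor"` or `"acceptor"` (transcription orientation).
#' @param n_exonic Number of exonic bases in the window (1-10 at training
#'   time, 10 at scoring time).
#' @return List with `seq` (21 bases) and `label` (boundary offset).
#' @export
splice_site_window <- function(genome, chrom, strand, donor, acceptor,
                               side = c("donor", "acceptor"),
                               n_exonic = 10L) {
  side <- match.arg(side)
  n <- n_exonic
  if (identical(strand, "-")) {
    s <- if (side == "donor") {
      genome_seq(genome, chrom, acceptor - (21L - n) + 1L, acceptor + n)
    } else {
      genome_seq(genome, chrom, donor - n, donor + (21L - n) - 1L)
    }
    s <- revcomp(s)
  } else {
    s <- if (side == "donor") {
      genome_seq(genome, chrom, donor - n, donor + (21L - n) - 1L)
    } else {
      genome_seq(genome, chrom, acceptor - (21L - n) + 1L, acceptor + n)
    }
  }
  list(seq = s, label = if (side == "donor") n else 21L - n)
}

#' Build a labeled splice-window training set from an annotation
#'
#' For every distinct annotated junction, one donor-side and one
#' acceptor-side 21-bp window is sampled with the exonic length N drawn
#' uniformly from 1..10; the label is the boundary offset within the window.
#' Windows are split 90/10 into training and validation sets under the seed.
#'
#' @param db An `isoform_db` with at least one junction.
#' @param genome A `genome_ref`.
#' @param seed Integer seed (N sampling and the split).
#' @param val_frac Validation fraction (default 0.1).
#' @return List with tibbles `train` and `validation` (`seq`, `label`,
#'   `side`).
#' @export
build_training_set <- function(db, genome, seed = 1L, val_frac = 0.1) {
  js <- db$junction_set
  if (nrow(js) == 0L) abort("annotation has no junctions")
  with_seed(seed, {
    rows <- vector("list", 2L * nrow(js))
    for (i in seq_len(nrow(js))) {
      for (side in c("donor", "acceptor")) {
        n <- sample(1:10, 1L)
        w <- splice_site_window(genome, js$chrom[i], js$strand[i],
                                js$donor[i], js$acceptor[i], side, n)
        rows[[2L * (i - 1L) + (side == "acceptor") + 1L]] <-
          tibble(seq = w$seq, label = w$label, side = side)
      }
    }
    all <- bind_rows(rows)
    n_val <- max(1L, round(nrow(all) * val_frac))
    val_idx <- sample.int(nrow(all), n_val)
    list(train = all[-val_idx, , drop = FALSE],
         validation = all[val_idx, , drop = FALSE])
  })
}

# enumerate sequence-preserving ("wobble") shifts of a junction: shifting the
# boundary by d keeps the read-to-genome base identity iff the bases entering
# the exon on one side equal the bases leaving it on the other
wobble_shifts <- function(genome, chrom, donor, acceptor, radius) {
  len <- genome$lengths[[chrom]]
  valid <- 0L
  for (d in seq_len(radius)) {
    if (acceptor + d > len) break
    if (genome_seq(genome, chrom, donor + d - 1L, donor + d - 1L) !=
        genome_seq(genome, chrom, acceptor + d, acceptor + d)) break
    valid <- c(valid, d)
  }
  for (d in seq_len(radius)) {
    if (donor - d < 1L) break
    if (genome_seq(genome, chrom, donor - d, donor - d) !=
        genome_seq(genome, chrom, acceptor - d + 1L, acceptor - d + 1L)) break
    valid <- c(valid, -d)
  }
  sort(valid)
}

#' Locally adjust one splice junction
#'
#' Enumerates the candidate placements within `radius` bp that leave the
#' transcript-to-genome base correspondence unchanged (junction wobble where
#' flanking sequence repeats). With a model, candidates are scored by the
#' product of the donor-window and acceptor-window boundary probabilities and
#' the argmax is returned, ties broken by annotated-junction match, then
#' canonical motif, then leftmost placement. Without a model (the
#' deterministic fallback mode), candidates are ranked by annotated-junction
#' match, then canonical motif, then the original placement.
#'
#' @param model A `splice_model`, or `NULL` for the fallback mode.
#' @param genome A `genome_ref`.
#' @param db An `isoform_db` (annotated-junction lookup).
#' @param chrom,strand,donor,acceptor The junction to adjust.
#' @param radius Search radius in bp (default 15).
#' @param canonical_set Canonical motif set.
#' @return One-row tibble: `chrom`, `strand`, `donor`, `acceptor`, `shift`.
#' @export
adjust_junction <- function(model, genome, db, chrom, strand, donor,
                            acceptor, radius = 15L,
                            canonical_set = .default_canonical) {
  if (radius < 0L) abort("radius must be non-negative")
  shifts <- wobble_shifts(genome, chrom, donor, acceptor, radius)
  cand <- tibble(shift = shifts, donor = donor + shifts,
                 acceptor = acceptor + shifts)
  cand$known <- junction_key(chrom, cand$donor, cand$acceptor) %in%
    db$junction_keys
  cand$canonical <- map_lgl(seq_len(nrow(cand)), function(i) {
    tryCatch(junction_motif(genome, chrom, strand, cand$donor[i],
                            cand$acceptor[i], canonical_set)$canonical,
             error = function(e) FALSE)
  })
  if (is.null(model)) {
    ord <- order(-cand$known, -cand$canonical, cand$shift != 0L, cand$donor)
  } else {
    dw <- map_chr(seq_len(nrow(cand)), function(i)
      splice_site_window(genome, chrom, strand, cand$donor[i],
                         cand$acceptor[i], "donor", 10L)$seq)
    aw <- map_chr(seq_len(nrow(cand)), function(i)
      splice_site_window(genome, chrom, strand, cand$donor[i],
                         cand$acceptor[i], "acceptor", 10L)$seq)
    pd <- predict(model, dw)[, 10L]
    pa <- predict(model, aw)[, 11L]
    score <- pd * pa
    ord <- order(-score, -cand$known, -cand$canonical, cand$donor)
  }
  best <- cand[ord[1], , drop = FALSE]
  tibble(chrom = chrom, strand = strand, donor = best$donor,
         acceptor = best$acceptor, shift = best$shift)
}

#' Correct every junction of a spliced alignment
#'
#' Applies [adjust_junction()] to each junction and updates the flanking exon
#' blocks consistently (read-to-genome base assignment near the boundary
#' moves with the junction; the junction count never changes).
#'
#' @param model A `splice_model` or `NULL` (deterministic fallback).
#' @param genome A `genome_ref`.
#' @param db An `isoform_db`.
#' @param aln A `spliced_alignment`.
#' @param radius Search radius in bp.
#' @param canonical_set Canonical motif set.
#' @return The corrected `spliced_alignment`.
#' @export
correct_alignment <- function(model, genome, db, aln, radius = 15L,
                              canonical_set = .default_canonical) {
  if (!aln$mapped || nrow(aln$junctions) == 0L) return(aln)
  segs <- aln$segments
  jn <- aln$junctions
  for (j in seq_len(nrow(jn))) {
    left <- which(segs$chrom == jn$chrom[j] & segs$gend == jn$donor[j] - 1L)
    right <- which(segs$chrom == jn$chrom[j] &
                     segs$gstart == jn$acceptor[j] + 1L)
    adj <- adjust_junction(model, genome, db, jn$chrom[j], jn$strand[j],
                           jn$donor[j], jn$acceptor[j], radius,
                           canonical_set)
    if (adj$shift != 0L && length(left) == 1L && length(right) == 1L) {
      segs$gend[left] <- adj$donor - 1L
      segs$read_end[left] <- segs$read_end[left] + adj$shift
      segs$gstart[right] <- adj$acceptor + 1L
      segs$read_start[right] <- segs$read_start[right] + adj$shift
    }
    jn$donor[j] <- adj$donor
    jn$acceptor[j] <- adj$acceptor
  }
  aln$segments <- segs
  aln$junctions <- jn
  aln
}

#' Save / load a splice model
#'
#' Model weights and architecture metadata are serialized as plain JSON so
#' checkpoints stay text-only and portable.
#'
#' @param model A `splice_model`.
#' @param path Checkpoint path (`.json`).
#' @return `path` invisibly (`save_splice_model`); a `splice_model`
#'   (`load_splice_model`).
#' @export
save_splice_model <- function(model, path) {
  payload <- list(
    format = "isokit-splice-model-1",
    channels = model$channels, n_classes = model$n_classes,
    conv = lapply(model$conv, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)),
    bn = model$bn,
    dense = list(W = as.vector(model$dense$W), dim = dim(model$dense$W),
                 b = model$dense$b)
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_splice_model
#' @export
load_splice_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(p$format, "isokit-splice-model-1")) {
    abort("unrecognized splice-model checkpoint format")
  }
  num <- function(x) as.numeric(unlist(x))
  model <- list(
    conv = lapply(p$conv, function(l)
      list(W = matrix(num(l$W), l$dim[[1]], l$dim[[2]]), b = num(l$b))),
    bn = lapply(p$bn, function(l) lapply(l, num)),
    dense = list(W = matrix(num(p$dense$W), p$dense$dim[[1]],
                            p$dense$dim[[2]]),
                 b = num(p$dense$b)),
    channels = p$channels, n_classes = p$n_classes
  )
  structure(model, class = "splice_model")
}
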