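#' Call gene fusions from annotated reads
#'
#' Groups Fusion-class reads by ordered gene pair and breakpoint pair (within
#' `bp_tol` bp on both sides; opposite 5'/3' orientations stay separate
#' calls) and records the supporting transcripts with their CCS counts.
#'
#' @param annotations From [annotate_alignments()].
#' @param reads Optional tibble with `read_id` and `ccs_count` to attach CCS
#'   support (1 assumed when absent).
#' @param bp_tol Breakpoint grouping tolerance in bp (default 10).
#' @return Tibble of calls: `gene5`, `gene3`, `chrom5`, `bp5`, `strand5`,
#'   `chrom3`, `bp3`, `strand3`, `n_supporting`, `max_ccs`, `supporters`
#'   (list), `ccs` (list).
#' @export
call_fusions <- function(annotations, reads = NULL, bp_tol = 10L) {
  fus <- annotations[annotations$class == "Fusion", , drop = FALSE]
  empty <- tibble(gene5 = character(), gene3 = character(),
                  chrom5 = character(), bp5 = integer(),
                  strand5 = character(), chrom3 = character(),
                  bp3 = integer(), strand3 = character(),
                  n_supporting = integer(), max_ccs = integer(),
                  supporters = list(), ccs = list())
  if (nrow(fus) == 0L) return(empty)
  ccs_of <- function(id) {
    if (is.null(reads)) return(1L)
    v <- reads$ccs_count[match(id, reads$read_id)]
    if (is.na(v)) 1L else as.integer(v)
  }
  calls <- list()
  for (r in seq_len(nrow(fus))) {
    d <- fus$fusion[[r]]
    if (is.null(d)) next
    placed <- FALSE
    for (ci in seq_along(calls)) {
      cl <- calls[[ci]]
      if (cl$gene5 == d$gene5 && cl$gene3 == d$gene3 &&
          cl$chrom5 == d$chrom5 && cl$chrom3 == d$chrom3 &&
          abs(cl$bp5 - d$bp5) <= bp_tol && abs(cl$bp3 - d$bp3) <= bp_tol) {
        cl$supporters <- c(cl$supporters, fus$read_id[r])
        cl$ccs <- c(cl$ccs, ccs_of(fus$read_id[r]))
        calls[[ci]] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      calls[[length(calls) + 1L]] <- list(
        gene5 = d$gene5, gene3 = d$gene3,
        chrom5 = d$chrom5, bp5 = d$bp5, strand5 = d$strand5,
        chrom3 = d$chrom3, bp3 = d$bp3, strand3 = d$strand3,
        supporters = fus$read_id[r], ccs = ccs_of(fus$read_id[r])
      )
    }
  }
  bind_rows(purrr::map(calls, function(cl) {
    tibble(gene5 = cl$gene5, gene3 = cl$gene3,
           chrom5 = cl$chrom5, bp5 = cl$bp5, strand5 = cl$strand5,
           chrom3 = cl$chrom3, bp3 = cl$bp3, strand3 = cl$strand3,
           n_supporting = length(cl$supporters),
           max_ccs = max(cl$ccs),
           supporters = list(cl$supporters), ccs = list(cl$ccs))
  }))
}

#' Filter tumor fusion calls to somatic candidates
#'
#' Keeps a tumor call iff it has at least one supporting transcript backed by
#' a CCS cluster of size two or more, then removes calls for which the
#' matched normal contains one or more supporting CCS reads of the same
#' fusion (same gene pair, breakpoints within tolerance). With no normal
#' available, candidates are returned flagged unfiltered.
#'
#' @param tumor_calls From [call_fusions()] on the tumor sample.
#' @param normal_annotations Annotations of the matched normal (or `NULL`).
#' @param bp_tol Breakpoint matching tolerance in bp (default 10).
#' @return `tumor_calls` with a logical `somatic` column (NA when
#'   unfiltered), restricted to retained calls.
#' @export
somatic_filter <- function(tumor_calls, normal_annotations, bp_tol = 10L) {
  if (nrow(tumor_calls) == 0L) {
    return(mutate(tumor_calls, somatic = logical(0)))
  }
  if (is.null(normal_annotations)) {
    return(mutate(tumor_calls, somatic = NA))
  }
  keep <- map_lgl(tumor_calls$ccs, function(v) any(v >= 2L))
  out <- tumor_calls[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(mutate(out, somatic = logical(0)))
  normal_fus <- normal_annotations[normal_annotations$class == "Fusion", ,
                                   drop = FALSE]
  germline <- map_lgl(seq_len(nrow(out)), function(i) {
    any(map_lgl(normal_fus$fusion, function(d) {
      !is.null(d) && d$gene5 == out$gene5[i] && d$gene3 == out$gene3[i] &&
        d$chrom5 == out$chrom5[i] && d$chrom3 == out$chrom3[i] &&
        abs(d$bp5 - out$bp5[i]) <= bp_tol &&
        abs(d$bp3 - out$bp3[i]) <= bp_tol
    }))
  })
  out <- out[!germline, , drop = FALSE]
  mutate(out, somatic = TRUE)
}

#' Write fusion calls as TSV
#'
#' @param calls From [call_fusions()] / [somatic_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fusion_tsv <- function(calls, path) {
  flat <- calls |>
    mutate(breakpoint5 = paste0(.data$chrom5, ":", .data$bp5),
           breakpoint3 = paste0(.data$chrom3, ":", .data$bp3)) |>
    select(dplyr::any_of(c("gene5", "gene3", "breakpoint5", "breakpoint3",
                           "strand5", "strand3", "n_supporting", "max_ccs",
                           "somatic")))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
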