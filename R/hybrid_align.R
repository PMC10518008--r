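#' Default assembly parameters
#'
#' Numeric defaults of the hybrid alignment assembly: window length `h` (250),
#' step `t` (100), combination-score tuning constants `mu` (2, 2, 1, 1),
#' cross-chromosome anchor distance (1000), maximal multiply-mapped block
#' resolved by the long-read mapping alone (10 bp), minimal intron length
#' (20 bp), and the exhaustive-search bound on the number of local alignments
#' (12; larger instances fall back to dynamic programming).
#'
#' @return Named list of parameters.
#' @export
align_params <- function(h = 250L, t = 100L, mu = c(2, 2, 1, 1),
                         xchrom_dist = 1000, max_multi_resolve = 10L,
                         min_intron = 20L, exact_max = 12L) {
  stopifnot(length(mu) == 4, h >= t, t >= 1)
  list(h = as.integer(h), t = as.integer(t), mu = as.numeric(mu),
       xchrom_dist = xchrom_dist, max_multi_resolve = max_multi_resolve,
       min_intron = as.integer(min_intron), exact_max = as.integer(exact_max))
}

#' Slice a long read into overlapping windows
#'
#' A read of length L is scanned with sliding windows of length `h` and step
#' `t`; the window count is `ceiling((L - h + t) / t)` and the last window is
#' anchored to the read end. Reads no longer than `h` yield a single window
#' equal to the read.
#'
#' @param seq Read sequence (character scalar).
#' @param h Window length in bp (default 250).
#' @param t Step size in bp (default 100).
#' @return Tibble with columns `window`, `start`, `end`, `seq` (read-local
#'   1-based coordinates).
#' @export
slice_windows <- function(seq, h = 250L, t = 100L) {
  if (h < 1L || t < 1L) abort("window length and step must be positive")
  h <- as.integer(h); t <- as.integer(t)
  L <- nchar(seq)
  if (L < 1L) abort("empty read")
  if (L <= h) {
    return(tibble(window = 1L, start = 1L, end = L, seq = seq))
  }
  n <- as.integer(ceiling((L - h + t) / t))
  starts <- 1L + (seq_len(n) - 1L) * t
  starts[n] <- L - h + 1L
  ends <- pmin(starts + h - 1L, L)
  tibble(window = seq_len(n), start = starts, end = ends,
         seq = substring(seq, starts, ends))
}

#' Write sliced windows as FASTA for an external spliced aligner
#'
#' Window read names encode the parent read and the 1-based read offset as
#' `readID|offset`, which [read_base_mappings()] uses to project aligned
#' window bases back onto read coordinates.
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param path Output FASTA path.
#' @inheritParams slice_windows
#' @return `path`, invisibly.
#' @export
write_window_fasta <- function(reads, path, h = 250L, t = 100L) {
  lines <- purrr::pmap(list(reads$read_id, reads$seq), function(id, s) {
    w <- slice_windows(s, h, t)
    as.vector(rbind(sprintf(">%s|%d", id, w$start), w$seq))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Build the per-nucleotide candidate position matrix
#'
#' Combines the long-read mapping and all window short-read mappings of one
#' read into, for each read position, the deduplicated sorted set of candidate
#' genome positions. Each candidate of a position with `n` candidates carries
#' weight `1/n`; positions with no mapping anywhere are flagged unmapped.
#'
#' @param long_map Tibble with columns `read_pos`, `chrom`, `gpos` (per-base
#'   projection of the long-read mapping; may have zero rows).
#' @param short_maps Tibble in the same shape, pooled over windows.
#' @param read_len Length of the read (bp).
#' @return A `position_matrix` object.
#' @export
build_position_matrix <- function(long_map, short_maps, read_len) {
  df <- bind_rows(long_map, short_maps)
  if (nrow(df) > 0L && (max(df$read_pos) > read_len || min(df$read_pos) < 1L)) {
    abort("mapping references read coordinates beyond the read length")
  }
  df <- df |>
    distinct(.data$read_pos, .data$chrom, .data$gpos) |>
    arrange(.data$read_pos, .data$chrom, .data$gpos)
  n <- tabulate(df$read_pos, nbins = read_len)
  idx <- split(seq_len(nrow(df)), factor(df$read_pos, levels = seq_len(read_len)))
  structure(
    list(df = df, idx = idx, n = n, L = read_len,
         w = ifelse(n > 0L, 1 / n, 0)),
    class = "position_matrix"
  )
}

#' @export
print.position_matrix <- function(x, ...) {
  cat("<position_matrix> read length ", x$L, "; unique ", sum(x$n == 1L),
      ", multi ", sum(x$n > 1L), ", unmapped ", sum(x$n == 0L), "\n", sep = "")
  invisible(x)
}

#' Partition a read into uniquely- and multiply-mapped blocks
#'
#' Maximal runs of uniquely mapped positions (exactly one candidate) versus
#' multiply mapped ones (zero or several candidates). Multiply-mapped blocks
#' no longer than `max_multi_resolve` bp are resolved by the long-read
#' mapping; longer ones are flagged for run enumeration and combination
#' selection.
#'
#' @param pm A `position_matrix`.
#' @param max_multi_resolve Block-length cutoff (default 10 bp).
#' @return Tibble with columns `start`, `end`, `kind` (`"unique"`/`"multi"`),
#'   `resolve` (`"unique"`, `"long"`, or `"algorithm"`).
#' @export
partition_blocks <- function(pm, max_multi_resolve = 10L) {
  uniq <- pm$n == 1L
  r <- rle(uniq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(
    start = starts, end = ends,
    kind = ifelse(r$values, "unique", "multi"),
    resolve = ifelse(r$values, "unique",
                     ifelse(r$lengths <= max_multi_resolve, "long",
                            "algorithm"))
  )
}

#' Enumerate maximal consecutive local alignments of a multiply-mapped block
#'
#' Greedy run construction: repeatedly seed a run at the first candidate not
#' yet consumed (scanning read positions left to right, candidates in sorted
#' order), then extend while the next read position has a candidate exactly
#' one base downstream on the same chromosome. Each run's quality is the sum
#' of the weights (`1/n_i`) of its members. Terminates with every candidate in
#' some run.
#'
#' @param pm A `position_matrix`.
#' @param block_start,block_end Read interval of the block (1-based closed).
#' @return Tibble of local alignments: `tau`, `read_start`, `read_end`,
#'   `chrom`, `gstart`, `gend`, `q`.
#' @export
enumerate_local_alignments <- function(pm, block_start, block_end) {
  pos <- block_start:block_end
  cand <- lapply(pos, function(i) pm$df[pm$idx[[i]], , drop = FALSE])
  used <- lapply(cand, function(d) rep(FALSE, nrow(d)))
  m <- length(pos)
  out <- list()
  tau <- 0L
  repeat {
    seed <- NULL
    for (i in seq_len(m)) {
      j <- which(!used[[i]])
      if (length(j) > 0L) { seed <- c(i, j[1]); break }
    }
    if (is.null(seed)) break
    i <- seed[1]; j <- seed[2]
    used[[i]][j] <- TRUE
    ch <- cand[[i]]$chrom[j]
    g0 <- cand[[i]]$gpos[j]
    g <- g0
    q <- pm$w[pos[i]]
    k <- i
    while (k < m) {
      nxt <- which(cand[[k + 1L]]$chrom == ch & cand[[k + 1L]]$gpos == g + 1L)
      if (length(nxt) == 0L) break
      k <- k + 1L
      used[[k]][nxt[1]] <- TRUE
      g <- g + 1L
      q <- q + pm$w[pos[k]]
    }
    tau <- tau + 1L
    out[[tau]] <- tibble(tau = tau, read_start = pos[i], read_end = pos[k],
                         chrom = ch, gstart = g0, gend = g, q = q)
  }
  if (tau == 0L) {
    return(tibble(tau = integer(), read_start = integer(),
                  read_end = integer(), chrom = character(),
                  gstart = integer(), gend = integer(), q = numeric()))
  }
  bind_rows(out)
}

anchor_distance <- function(aln_chrom, aln_gpos, anchor, upstream,
                            xchrom_dist) {
  if (is.null(anchor)) return(0)
  if (!identical(aln_chrom, anchor$chrom)) return(xchrom_dist)
  gap <- if (upstream) aln_gpos - anchor$gpos - 1L else anchor$gpos - aln_gpos - 1L
  if (gap < 0L) return(xchrom_dist)
  log10(1 + gap)
}

score_combination <- function(alns, idx, anchor_up, anchor_down, mu,
                              xchrom_dist) {
  sub <- alns[idx, , drop = FALSE]
  k <- nrow(sub)
  qsum <- sum(sub$q)
  ov <- 0
  if (k > 1L) {
    for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
      ov <- ov + max(0L, min(sub$read_end[a], sub$read_end[b]) -
                       max(sub$read_start[a], sub$read_start[b]) + 1L)
    }
  }
  first <- which.min(sub$read_start)
  last <- which.max(sub$read_end)
  d1 <- anchor_distance(sub$chrom[first], sub$gstart[first], anchor_up,
                        TRUE, xchrom_dist)
  d2 <- anchor_distance(sub$chrom[last], sub$gend[last], anchor_down,
                        FALSE, xchrom_dist)
  list(score = qsum - mu[1] * ov - mu[2] * k - mu[3] * d1 - mu[4] * d2,
       k = k, overlap = ov, d1 = d1, d2 = d2, q_sum = qsum)
}

#' Select the best combination of local alignments
#'
#' Maximizes `sum(Q) - mu1*O - mu2*k - mu3*D1 - mu4*D2` over combinations of
#' local alignments, where `O` is the total pairwise read-coordinate overlap
#' among chosen alignments, `k` their number, and `D1`/`D2` the distances of
#' the combination to its flanking uniquely-mapped anchors
#' (`log10(1 + genomic gap)` for same-chromosome, correctly ordered
#' placements; the cross-chromosome constant otherwise). The search is
#' exhaustive over all non-empty subsets up to `exact_max` alignments and
#' switches to dynamic programming over read-sorted alignments beyond that
#' (where `O` is accumulated over consecutive chosen pairs). Ties are broken
#' toward fewer alignments, then the leftmost genome start.
#'
#' @param alns Tibble of local alignments from
#'   [enumerate_local_alignments()].
#' @param anchor_up,anchor_down Optional flanking anchors, each a list with
#'   `chrom` and `gpos`, or `NULL` at read edges.
#' @param params Parameters from [align_params()].
#' @return List with `indices` (rows of `alns` chosen), `score`, `k`,
#'   `overlap`, `d1`, `d2`, `q_sum`.
#' @export
select_combination <- function(alns, anchor_up = NULL, anchor_down = NULL,
                               params = align_params()) {
  n <- nrow(alns)
  if (n == 0L) abort("no local alignments to combine")
  mu <- params$mu
  xd <- params$xchrom_dist
  if (n <= params$exact_max) {
    best <- NULL
    for (mask in seq_len(2^n - 1L)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
      sc <- score_combination(alns, idx, anchor_up, anchor_down, mu, xd)
      if (is.null(best) || sc$score > best$score + 1e-9 ||
          (abs(sc$score - best$score) <= 1e-9 &&
           (sc$k < best$k ||
            (sc$k == best$k &&
             min(alns$gstart[idx]) < min(alns$gstart[best$indices]))))) {
        best <- c(sc, list(indices = idx))
      }
    }
    return(best)
  }
  # DP regime: alignments sorted by read start; overlap term accumulated over
  # consecutive chosen pairs.
  ord <- order(alns$read_start, alns$gstart)
  a <- alns[ord, , drop = FALSE]
  dp <- numeric(n); parent <- integer(n)
  for (j in seq_len(n)) {
    d1 <- anchor_distance(a$chrom[j], a$gstart[j], anchor_up, TRUE, xd)
    dp[j] <- a$q[j] - mu[2] - mu[3] * d1
    parent[j] <- 0L
    if (j > 1L) for (i in 1:(j - 1L)) {
      ov <- max(0L, min(a$read_end[i], a$read_end[j]) -
                  max(a$read_start[i], a$read_start[j]) + 1L)
      cand <- dp[i] + a$q[j] - mu[2] - mu[1] * ov
      if (cand > dp[j] + 1e-9) { dp[j] <- cand; parent[j] <- i }
    }
  }
  final <- dp - mu[4] * vapply(seq_len(n), function(j)
    anchor_distance(a$chrom[j], a$gend[j], anchor_down, FALSE, xd), 0)
  j <- which.max(final)
  idx_sorted <- integer(0)
  while (j > 0L) { idx_sorted <- c(j, idx_sorted); j <- parent[j] }
  idx <- ord[idx_sorted]
  c(score_combination(alns, idx, anchor_up, anchor_down, mu, xd),
    list(indices = idx))
}

#' Assemble long- and short-read mappings into a spliced alignment
#'
#' Full assembly of one read: build the candidate position matrix, partition
#' into uniquely/multiply mapped blocks, resolve short ambiguous blocks by the
#' long-read mapping, resolve long ambiguous blocks by local-alignment
#' enumeration and combination selection, then derive exon blocks and the
#' junction chain (genomic gaps of at least `min_intron` bp between
#' consecutive exon blocks).
#'
#' @param read A list or one-row tibble with `read_id` and `seq`.
#' @param long_map,short_maps Per-base mapping tibbles (`read_pos`, `chrom`,
#'   `gpos`); see [read_base_mappings()].
#' @param params Parameters from [align_params()].
#' @param strand Strand to record on the alignment (`"+"` by default;
#'   typically the aligner's reported strand).
#' @return A `spliced_alignment` object, or one with `mapped = FALSE` when no
#'   base has any candidate position.
#' @export
assemble_alignment <- function(read, long_map, short_maps,
                               params = align_params(), strand = "+") {
  L <- nchar(read$seq)
  pm <- build_position_matrix(long_map, short_maps, L)
  if (all(pm$n == 0L)) {
    return(structure(list(read_id = read$read_id, mapped = FALSE,
                          strand = strand,
                          segments = tibble(), junctions = tibble()),
                     class = "spliced_alignment"))
  }
  fchrom <- rep(NA_character_, L)
  fgpos <- rep(NA_integer_, L)

  # long-read mapping as per-base vectors
  lchrom <- rep(NA_character_, L)
  lgpos <- rep(NA_integer_, L)
  if (nrow(long_map) > 0L) {
    lchrom[long_map$read_pos] <- long_map$chrom
    lgpos[long_map$read_pos] <- long_map$gpos
  }

  # unique positions take their single candidate
  uniq_pos <- which(pm$n == 1L)
  if (length(uniq_pos) > 0L) {
    row1 <- match(uniq_pos, pm$df$read_pos)
    fchrom[uniq_pos] <- pm$df$chrom[row1]
    fgpos[uniq_pos] <- pm$df$gpos[row1]
  }

  blocks <- partition_blocks(pm, params$max_multi_resolve)
  for (b in seq_len(nrow(blocks))) {
    if (blocks$resolve[b] == "unique") next
    s <- blocks$start[b]; e <- blocks$end[b]
    if (blocks$resolve[b] == "long") {
      fchrom[s:e] <- lchrom[s:e]
      fgpos[s:e] <- lgpos[s:e]
      next
    }
    runs <- enumerate_local_alignments(pm, s, e)
    if (nrow(runs) == 0L) next
    up <- NULL
    prev <- which(!is.na(fgpos[seq_len(s - 1L)]))
    if (s > 1L && length(prev) > 0L) {
      p <- max(prev)
      up <- list(chrom = fchrom[p], gpos = fgpos[p])
    }
    down <- NULL
    if (e < L) {
      nxt <- e + which(!is.na(lgpos[(e + 1L):L]) | pm$n[(e + 1L):L] == 1L)
      if (length(nxt) > 0L) {
        p <- nxt[1]
        if (pm$n[p] == 1L) {
          r <- match(p, pm$df$read_pos)
          down <- list(chrom = pm$df$chrom[r], gpos = pm$df$gpos[r])
        } else {
          down <- list(chrom = lchrom[p], gpos = lgpos[p])
        }
      }
    }
    comb <- select_combination(runs, up, down, params)
    chosen <- runs[comb$indices, , drop = FALSE] |> arrange(.data$read_start)
    for (r in seq_len(nrow(chosen))) {
      span <- chosen$read_start[r]:chosen$read_end[r]
      fill <- span[is.na(fgpos[span])]
      if (length(fill) > 0L) {
        fchrom[fill] <- chosen$chrom[r]
        fgpos[fill] <- chosen$gstart[r] + (fill - chosen$read_start[r])
      }
    }
  }

  base_mapping_to_alignment(read$read_id, fchrom, fgpos, strand,
                            params$min_intron)
}

# turn per-base (chrom, gpos) vectors into exon blocks + junction chain
base_mapping_to_alignment <- function(read_id, fchrom, fgpos, strand,
                                      min_intron) {
  mapped <- which(!is.na(fgpos))
  if (length(mapped) == 0L) {
    return(structure(list(read_id = read_id, mapped = FALSE, strand = strand,
                          segments = tibble(), junctions = tibble()),
                     class = "spliced_alignment"))
  }
  ch <- fchrom[mapped]; g <- fgpos[mapped]
  m <- length(mapped)
  # break between consecutive mapped bases when the chromosome changes, the
  # genome coordinate is non-increasing, or the genomic gap reaches an intron
  brk <- if (m > 1L) {
    which(ch[-1] != ch[-m] | g[-1] <= g[-m] |
            (g[-1] - g[-m] - 1L) >= min_intron)
  } else integer(0)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, m)
  segments <- tibble(
    chrom = ch[starts],
    gstart = g[starts], gend = g[ends],
    read_start = mapped[starts], read_end = mapped[ends]
  )
  k <- nrow(segments)
  junctions <- tibble(chrom = character(), strand = character(),
                      donor = integer(), acceptor = integer())
  if (k > 1L) {
    same <- segments$chrom[-k] == segments$chrom[-1] &
      segments$gstart[-1] > segments$gend[-k]
    gap <- segments$gstart[-1] - segments$gend[-k] - 1L
    jn <- which(same & gap >= min_intron)
    if (length(jn) > 0L) {
      junctions <- tibble(
        chrom = segments$chrom[jn], strand = strand,
        donor = segments$gend[jn] + 1L,
        acceptor = segments$gstart[jn + 1L] - 1L
      )
    }
  }
  structure(list(read_id = read_id, mapped = TRUE, strand = strand,
                 segments = segments, junctions = junctions),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  if (!x$mapped) {
    cat("<spliced_alignment> ", x$read_id, ": unmapped\n", sep = "")
    return(invisible(x))
  }
  cat("<spliced_alignment> ", x$read_id, ": ", nrow(x$segments),
      " exon block(s), ", nrow(x$junctions), " junction(s) on ",
      paste(unique(x$segments$chrom), collapse = ","), " (", x$strand, ")\n",
      sep = "")
  invisible(x)
}

#' Junction table of a spliced alignment
#'
#' @param aln A `spliced_alignment`.
#' @return Tibble of junctions (`chrom`, `strand`, `donor`, `acceptor`).
#' @export
alignment_junctions <- function(aln) {
  aln$junctions
}
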