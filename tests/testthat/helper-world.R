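# Shared fixtures: one small synthetic world + error-free reads, built once
# per test run.  Individual tests construct their own bespoke inputs where
# the scenario calls for it.

tw <- make_world(world_config(n_genes = 12L), seed = 42L)
tsim <- simulate_reads(tw, reads_per_isoform = 1L, truncate_frac = 0,
                       seed = 7L)

# assemble every read of a simulation from its truth mappings (truth serves
# as both the long-read and the window short-read mapping)
assemble_truth <- function(reads, truth_maps, params = align_params()) {
  alns <- lapply(seq_len(nrow(reads)), function(i) {
    m <- truth_maps[[reads$read_id[i]]]
    assemble_alignment(reads[i, ], m, m, params = params,
                       strand = reads$strand[i])
  })
  names(alns) <- reads$read_id
  alns
}

# build a read (seq + truth map) from arbitrary genomic intervals
read_from_intervals <- function(world, read_id, chrom, intervals,
                                strand = "+") {
  seqs <- vapply(seq_len(nrow(intervals)), function(i)
    genome_seq(world$genome, chrom, intervals$start[i], intervals$end[i]), "")
  gpos <- unlist(mapply(seq.int, intervals$start, intervals$end,
                        SIMPLIFY = FALSE))
  list(
    read = tibble::tibble(read_id = read_id, seq = paste(seqs, collapse = ""),
                          ccs_count = 2L, strand = strand),
    map = tibble::tibble(read_pos = seq_along(gpos), chrom = chrom,
                         gpos = as.integer(gpos))
  )
}

# independent brute-force oracle for combination selection: enumerates every
# non-empty subset and scores it directly from the definition
brute_force_combination <- function(alns, anchor_up, anchor_down,
                                    params = align_params()) {
  mu <- params$mu; xd <- params$xchrom_dist
  dist1 <- function(ch, g, anchor) {
    if (is.null(anchor)) return(0)
    if (ch != anchor$chrom) return(xd)
    gap <- g - anchor$gpos - 1
    if (gap < 0) xd else log10(1 + gap)
  }
  dist2 <- function(ch, g, anchor) {
    if (is.null(anchor)) return(0)
    if (ch != anchor$chrom) return(xd)
    gap <- anchor$gpos - g - 1
    if (gap < 0) xd else log10(1 + gap)
  }
  n <- nrow(alns)
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- alns[idx, , drop = FALSE]
    k <- nrow(sub)
    ov <- 0
    if (k > 1) for (a in 1:(k - 1)) for (b in (a + 1):k) {
      ov <- ov + max(0, min(sub$read_end[a], sub$read_end[b]) -
                       max(sub$read_start[a], sub$read_start[b]) + 1)
    }
    fi <- which.min(sub$read_start); la <- which.max(sub$read_end)
    sc <- sum(sub$q) - mu[1] * ov - mu[2] * k -
      mu[3] * dist1(sub$chrom[fi], sub$gstart[fi], anchor_up) -
      mu[4] * dist2(sub$chrom[la], sub$gend[la], anchor_down)
    if (is.null(best) || sc > best$score + 1e-9) {
      best <- list(score = sc, indices = idx)
    }
  }
  best
}

# random local-alignment instances for the oracle property
random_alignment_instance <- function(n_alns, n_chroms = 2L) {
  tibble::tibble(
    tau = seq_len(n_alns),
    read_start = sample(1:40, n_alns, replace = TRUE),
    chrom = sample(paste0("chr", seq_len(n_chroms)), n_alns, replace = TRUE),
    gstart = sample(1:5000, n_alns, replace = TRUE),
    q = round(runif(n_alns, 0.2, 6), 3)
  ) |>
    dplyr::mutate(read_end = .data$read_start +
                    sample(1:30, n_alns, replace = TRUE),
                  gend = .data$gstart + (.data$read_end - .data$read_start))
}

random_anchor <- function(n_chroms = 2L) {
  if (runif(1) < 0.3) return(NULL)
  list(chrom = sample(paste0("chr", seq_len(n_chroms)), 1),
       gpos = sample(1:5000, 1))
}

# two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration
fisher_2x2_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided exact binomial p by enumeration of equally-or-less-likely outcomes
binom_two_sided_oracle <- function(x, n, p) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}
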