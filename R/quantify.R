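#' Filter transcripts by CCS support
#'
#' Following the Iso-seq protocol, only polished transcripts supported by at
#' least `min_ccs` circular consensus sequences are analysed.
#'
#' @param reads Tibble with a `ccs_count` column.
#' @param min_ccs Minimal CCS support (default 2).
#' @return The retained rows.
#' @export
filter_ccs <- function(reads, min_ccs = 2L) {
  filter(reads, .data$ccs_count >= min_ccs)
}

#' Transcripts-per-hundred-thousand normalization
#'
#' @param count Observed transcript count(s).
#' @param total Total transcript count of the sample (after CCS filtering).
#' @return `count * 100000 / total`.
#' @export
tpt <- function(count, total) {
  if (any(total <= 0)) abort("total transcript count must be positive")
  count * 1e5 / total
}

# ordered junction-chain key of one annotation row
chain_keys <- function(junctions) {
  if (nrow(junctions) == 0L) return(character(0))
  junction_key(junctions$chrom, junctions$donor, junctions$acceptor)
}

# per-isoform ordered junction chains of the reference
db_chains <- function(db) {
  split(junction_key(db$junctions$chrom, db$junctions$donor,
                     db$junctions$acceptor),
        db$junctions$isoform_id)
}

#' Count reads uniquely annotated to known isoforms
#'
#' An FSM/ISM read counts for a known isoform iff its junction chain matches
#' consecutive junctions of only that isoform; reads whose chain matches
#' several isoforms are excluded from expression. Monoexonic FSM/ISM reads
#' count for their recorded best match. Gene counts are the sums over their
#' known isoforms.
#'
#' @param annotations From [annotate_alignments()].
#' @param db An `isoform_db`.
#' @return List with tibbles `isoforms` (`isoform_id`, `gene_id`, `count`)
#'   covering every known isoform, and `genes` (`gene_id`, `count`).
#' @export
count_known <- function(annotations, db) {
  chains <- db_chains(db)
  counts <- setNames(integer(nrow(db$isoforms)), db$isoforms$isoform_id)
  km <- annotations[annotations$class %in% c("FSM", "ISM"), , drop = FALSE]
  for (r in seq_len(nrow(km))) {
    ck <- chain_keys(km$junctions[[r]])
    if (length(ck) == 0L) {
      hit <- km$best_match[r]
    } else {
      hit <- names(chains)[vapply(chains, function(full)
        is_consecutive_subchain(ck, full), TRUE)]
    }
    if (length(hit) == 1L && !is.na(hit)) counts[hit] <- counts[hit] + 1L
  }
  iso <- tibble(isoform_id = names(counts),
                gene_id = db$isoforms$gene_id[match(names(counts),
                                                    db$isoforms$isoform_id)],
                count = as.integer(counts))
  genes <- iso |>
    group_by(.data$gene_id) |>
    summarise(count = sum(.data$count), .groups = "drop")
  list(isoforms = iso, genes = genes)
}

#' Cluster novel isoforms by their splice junctions
#'
#' Two novel reads of the same class (NIC or NNC) cluster together when one's
#' junction chain matches consecutive junctions of the other. Reads are
#' processed in descending junction-count order (greedy, deterministic);
#' the cluster id is derived from the seed read's chain so that identical
#' novel isoforms receive identical feature ids across samples.
#'
#' @param annotations From [annotate_alignments()].
#' @return Tibble: `feature_id`, `class`, `gene_id`, `count`.
#' @export
cluster_novel <- function(annotations) {
  nov <- annotations[annotations$class %in% c("NIC", "NNC"), , drop = FALSE]
  if (nrow(nov) == 0L) {
    return(tibble(feature_id = character(), class = character(),
                  gene_id = character(), count = integer()))
  }
  out <- list()
  for (cls in c("NIC", "NNC")) {
    sub <- nov[nov$class == cls, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub <- sub[order(-sub$n_junctions, sub$read_id), , drop = FALSE]
    reps <- list(); members <- integer(0); rep_gene <- character(0)
    for (r in seq_len(nrow(sub))) {
      ck <- chain_keys(sub$junctions[[r]])
      placed <- FALSE
      for (ci in seq_along(reps)) {
        if (is_consecutive_subchain(ck, reps[[ci]])) {
          members[ci] <- members[ci] + 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps[[length(reps) + 1L]] <- ck
        members <- c(members, 1L)
        g <- sub$gene_ids[[r]]
        rep_gene <- c(rep_gene, if (length(g) > 0L) g[1] else NA_character_)
      }
    }
    out[[cls]] <- tibble(
      feature_id = paste0(cls, ":", map_chr(reps, paste, collapse = "|")),
      class = cls, gene_id = rep_gene, count = members
    )
  }
  bind_rows(out)
}

#' Build the expression table of one sample
#'
#' Combines unique known-isoform counts, novel-cluster counts, and gene
#' counts, normalized as transcripts per hundred thousand (TPT) against the
#' sample's total transcript count (every retained transcript counted once).
#'
#' @param annotations From [annotate_alignments()] (CCS-filtered reads).
#' @param db An `isoform_db`.
#' @param sample_id Sample label stored in the table.
#' @param total Total transcript count; defaults to `nrow(annotations)`.
#' @return Tibble: `feature_id`, `feature_type` (`isoform`, `novel_cluster`,
#'   `gene`), `class`, `gene_id`, `count`, `tpt`, `sample`, `total`.
#' @export
expression_table <- function(annotations, db, sample_id = "sample",
                             total = nrow(annotations)) {
  known <- count_known(annotations, db)
  novel <- cluster_novel(annotations)
  iso_tab <- known$isoforms |>
    mutate(feature_id = .data$isoform_id, feature_type = "isoform",
           class = "known") |>
    select("feature_id", "feature_type", "class", "gene_id", "count")
  nov_tab <- novel |>
    mutate(feature_type = "novel_cluster") |>
    select("feature_id", "feature_type", "class", "gene_id", "count")
  gene_tab <- known$genes |>
    mutate(feature_id = .data$gene_id, feature_type = "gene",
           class = "gene") |>
    select("feature_id", "feature_type", "class", "gene_id", "count")
  bind_rows(iso_tab, nov_tab, gene_tab) |>
    mutate(tpt = tpt(.data$count, total), sample = sample_id, total = total)
}

#' Exact two-sided binomial test for differential isoform expression
#'
#' Tests `count1` of `count1 + count2` against the success probability
#' implied by the two samples' totals.
#'
#' @param count1,count2 Observed transcript counts in the two samples.
#' @param total1,total2 Total transcript counts of the two samples.
#' @return Two-sided p-value.
#' @export
diff_isoform_binomial <- function(count1, count2, total1, total2) {
  if (total1 <= 0 || total2 <= 0) abort("totals must be positive")
  n <- count1 + count2
  if (n == 0) return(1)
  binom.test(count1, n, p = total1 / (total1 + total2))$p.value
}

#' Gene-level differential expression by exact binomial test
#'
#' Applies [diff_isoform_binomial()] to gene counts of two samples with BH
#' adjustment. (This package's DEG method; a per-gene count-based exact
#' test.)
#'
#' @param expr1,expr2 Expression tables from [expression_table()].
#' @return Tibble: `gene_id`, `count1`, `count2`, `p_value`, `q_value`.
#' @export
deg_binomial <- function(expr1, expr2) {
  g1 <- filter(expr1, .data$feature_type == "gene")
  g2 <- filter(expr2, .data$feature_type == "gene")
  tab <- dplyr::full_join(
    select(g1, "gene_id", count1 = "count"),
    select(g2, "gene_id", count2 = "count"), by = "gene_id"
  ) |>
    mutate(count1 = ifelse(is.na(.data$count1), 0L, .data$count1),
           count2 = ifelse(is.na(.data$count2), 0L, .data$count2))
  t1 <- expr1$total[1]; t2 <- expr2$total[1]
  tab$p_value <- map_dbl(seq_len(nrow(tab)), function(i)
    diff_isoform_binomial(tab$count1[i], tab$count2[i], t1, t2))
  tab$q_value <- p.adjust(tab$p_value, method = "BH")
  tab
}

#' Low-expression filter of the differential-isoform-usage test
#'
#' A gene passes iff both condition-wise TPT sums reach `Q`, every isoform's
#' combined TPT reaches `Q`, and every isoform's share of the gene's combined
#' TPT reaches `P`.
#'
#' @param e1,e2 Per-isoform TPT vectors of the gene under the two conditions.
#' @param Q Minimal TPT (default 4).
#' @param P Minimal isoform fraction (default 0.05).
#' @return Logical.
#' @export
diu_filter <- function(e1, e2, Q = 4, P = 0.05) {
  if (length(e1) != length(e2) || length(e1) < 2L) return(FALSE)
  tot <- sum(e1) + sum(e2)
  sum(e1) >= Q && sum(e2) >= Q &&
    all(e1 + e2 >= Q) && all((e1 + e2) / tot >= P)
}

fisher_m_by_2 <- function(counts) {
  if (any(colSums(counts) == 0L) || any(rowSums(counts) == 0L)) return(1)
  p <- tryCatch(
    fisher.test(counts, workspace = 2e7)$p.value,
    error = function(e)
      fisher.test(counts, simulate.p.value = TRUE, B = 1e5)$p.value
  )
  min(1, p)   # the exact network algorithm can overshoot 1 by an ulp
}

#' Differential isoform usage between two samples
#'
#' For each gene with at least two isoform-level features (known isoforms
#' and novel clusters), builds the isoform-by-condition contingency table,
#' applies the low-expression filter on TPT, runs Fisher's exact test on the
#' observed counts, and adjusts p-values by Benjamini-Hochberg across tested
#' genes.
#'
#' @param expr1,expr2 Expression tables from [expression_table()].
#' @param Q,P Filter thresholds (defaults 4 and 5%).
#' @return A `diu_result`: tibble (`gene_id`, `m`, `p_value`, `q_value`,
#'   `table` list-column of count matrices) with `tidy()`/`glance()`
#'   methods.
#' @export
diu_test <- function(expr1, expr2, Q = 4, P = 0.05) {
  iso1 <- filter(expr1, .data$feature_type %in% c("isoform", "novel_cluster"))
  iso2 <- filter(expr2, .data$feature_type %in% c("isoform", "novel_cluster"))
  tab <- dplyr::full_join(
    select(iso1, "feature_id", "gene_id", count1 = "count", tpt1 = "tpt"),
    select(iso2, "feature_id", "gene_id", count2 = "count", tpt2 = "tpt"),
    by = c("feature_id", "gene_id")
  ) |>
    mutate(across(c("count1", "count2", "tpt1", "tpt2"),
                  ~ ifelse(is.na(.x), 0, .x)))
  res <- tab |>
    group_by(.data$gene_id) |>
    dplyr::group_map(function(d, key) {
      if (!diu_filter(d$tpt1, d$tpt2, Q, P)) return(NULL)
      cm <- matrix(c(d$count1, d$count2), ncol = 2,
                   dimnames = list(d$feature_id, c("cond1", "cond2")))
      tibble(gene_id = key$gene_id, m = nrow(d),
             p_value = fisher_m_by_2(cm), table = list(cm))
    }) |>
    bind_rows()
  if (nrow(res) == 0L) {
    res <- tibble(gene_id = character(), m = integer(), p_value = numeric(),
                  table = list())
  }
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res <- res[, c("gene_id", "m", "p_value", "q_value", "table")]
  structure(res, class = c("diu_result", class(tibble())))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-isoform-usage result
#'
#' @param x A `diu_result`.
#' @param ... Unused.
#' @return Tibble with one row per tested gene.
#' @export
tidy.diu_result <- function(x, ...) {
  as_tibble(x[, c("gene_id", "m", "p_value", "q_value")])
}

#' One-row summary of a differential-isoform-usage result
#'
#' @param x A `diu_result`.
#' @param fdr Significance threshold on q-values (default 0.05).
#' @param ... Unused.
#' @return Tibble: `n_tested`, `n_significant`, `fdr`.
#' @export
glance.diu_result <- function(x, fdr = 0.05, ...) {
  tibble(n_tested = nrow(x),
         n_significant = sum(x$q_value < fdr),
         fdr = fdr)
}

#' Write expression / DIU tables as TSV
#'
#' @param x An expression table or `diu_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  flat <- if (inherits(x, "diu_result")) tidy(x) else x
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
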