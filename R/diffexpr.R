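#' Tumour-versus-normal differential expression for one cancer type
#'
#' Per-gene two-group comparison on the log2(TPM+1)-like scale between the
#' tumour and normal samples of one cancer type. The fold change is the
#' difference of group means on the log2 scale
#' (`log2FC = mean(tumour) - mean(normal)`); a gene is called `up` when
#' `log2FC >= log2(fc_threshold)` and `p <= alpha`, `down` symmetrically,
#' otherwise `none`. Raw p-values drive the calls; a Benjamini-Hochberg FDR
#' column is emitted alongside for transparency.
#'
#' @param expr an [expression_matrix()].
#' @param cancer cancer-type label; both groups must have >= 2 samples.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param alpha significance level (default 0.05).
#' @param test `"welch"` (default, Welch two-sample t) or `"wilcoxon"`.
#' @return data frame (`deg_table`) with columns `gene`, `mean_high`,
#'   `mean_low`, `log2_fold_change`, `p_value`, `fdr`, `direction`.
#' @export
tumour_vs_normal <- function(expr, cancer, fc_threshold = 2, alpha = 0.05,
                             test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(inherits(expr, "expression_matrix"))
  ann <- expr$annotations
  tum <- ann$sample[ann$cancer_type == cancer & ann$sample_type == "tumour"]
  nor <- ann$sample[ann$cancer_type == cancer & ann$sample_type == "normal"]
  if (length(tum) < 2 || length(nor) < 2) {
    stop(sprintf(
      "cancer '%s' needs >= 2 tumour and >= 2 normal samples (got %d / %d)",
      cancer, length(tum), length(nor)), call. = FALSE)
  }
  two_group_deg(expr$values[, tum, drop = FALSE],
                expr$values[, nor, drop = FALSE],
                fc_threshold, alpha, test)
}

#' Anchor-stratified differential expression
#'
#' Splits the tumour samples of one cancer type by the expression of an
#' anchor gene — strictly above the `high_cut` percentile versus strictly
#' below the `low_cut` percentile, middle excluded — and runs the same
#' per-gene two-group comparison as [tumour_vs_normal()] between the
#' anchor-high and anchor-low groups. The anchor itself is excluded from the
#' output.
#'
#' @inheritParams tumour_vs_normal
#' @param anchor anchor gene symbol (must be present and non-constant).
#' @param high_cut,low_cut percentile cutoffs of the split (defaults
#'   0.75 / 0.25).
#' @return a `deg_table` as in [tumour_vs_normal()] (`mean_high` /
#'   `mean_low` are the anchor-high / anchor-low group means), without the
#'   anchor gene.
#' @export
anchor_stratified_deg <- function(expr, anchor, cancer, high_cut = 0.75,
                                  low_cut = 0.25, fc_threshold = 2,
                                  alpha = 0.05,
                                  test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(inherits(expr, "expression_matrix"))
  if (!anchor %in% rownames(expr$values)) {
    stop(sprintf("anchor gene '%s' not present in the expression matrix",
                 anchor), call. = FALSE)
  }
  ann <- expr$annotations
  tum <- ann$sample[ann$cancer_type == cancer & ann$sample_type == "tumour"]
  if (length(tum) < 4) {
    stop(sprintf("cancer '%s' needs >= 4 tumour samples", cancer),
         call. = FALSE)
  }
  g <- assign_groups(stats::setNames(expr$values[anchor, tum], tum),
                     high_cut, low_cut)
  high <- names(g)[g == "high"]
  low <- names(g)[g == "low"]
  if (length(high) < 2 || length(low) < 2) {
    stop("anchor split leaves fewer than 2 samples in a group",
         call. = FALSE)
  }
  vals <- expr$values[setdiff(rownames(expr$values), anchor), , drop = FALSE]
  two_group_deg(vals[, high, drop = FALSE], vals[, low, drop = FALSE],
                fc_threshold, alpha, test)
}

# vectorised two-group DEG on log2-scale matrices (groups in columns)
two_group_deg <- function(a, b, fc_threshold, alpha, test) {
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  lfc <- mean_a - mean_b
  if (test == "welch") {
    p <- welch_p(a, b)
  } else {
    p <- vapply(seq_len(nrow(a)), function(i) {
      if (all(a[i, ] == a[i, 1]) && all(b[i, ] == b[i, 1]) &&
          a[i, 1] == b[i, 1]) return(1)
      stats::wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value
    }, numeric(1))
  }
  out <- data.frame(gene = rownames(a),
                    mean_high = mean_a, mean_low = mean_b,
                    log2_fold_change = lfc, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$direction <- deg_direction(out$log2_fold_change, out$p_value,
                                 fc_threshold, alpha)
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

# row-wise Welch t-test p-values; degenerate rows: equal constant groups
# give p = 1, unequal constant groups give p = 0
welch_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1, stats::var)
  vb <- apply(b, 1, stats::var)
  d <- rowMeans(a) - rowMeans(b)
  se2 <- va / na + vb / nb
  p <- rep(NA_real_, nrow(a))
  degen <- se2 == 0
  p[degen & d == 0] <- 1
  p[degen & d != 0] <- 0
  ok <- !degen
  tt <- d[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  p
}

# pure direction rule of the DEG table
deg_direction <- function(log2_fold_change, p_value, fc_threshold, alpha) {
  cut <- log2(fc_threshold)
  ifelse(log2_fold_change >= cut & p_value <= alpha, "up",
         ifelse(log2_fold_change <= -cut & p_value <= alpha, "down", "none"))
}

#' Filter a copy-number shortlist for concordant expression
#'
#' Retains amplified genes whose expression direction is `up` and deleted
#' genes whose direction is `down`; all others are dropped. Shortlist genes
#' absent from the DEG table are dropped with a warning.
#'
#' @param shortlist a `gene_shortlist` from [top_fraction()].
#' @param deg a `deg_table` from [tumour_vs_normal()].
#' @return the retained rows of `shortlist`, with the DEG table's
#'   `log2_fold_change` and `p_value` attached.
#' @export
concordance_filter <- function(shortlist, deg) {
  idx <- match(shortlist$gene, deg$gene)
  missing <- shortlist$gene[is.na(idx)]
  if (length(missing)) {
    warning("shortlist gene(s) absent from the DEG table, dropped: ",
            paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(idx) &
    ((shortlist$direction == "amplified" & deg$direction[idx] == "up") |
       (shortlist$direction == "deleted" & deg$direction[idx] == "down"))
  out <- shortlist[keep, , drop = FALSE]
  out$log2_fold_change <- deg$log2_fold_change[idx[keep]]
  out$p_value <- deg$p_value[idx[keep]]
  rownames(out) <- NULL
  out
}

#' Select the largest-fold-change fraction of DEG calls
#'
#' Among genes called `up`, selects the top `ceiling(fraction * n_up)` by
#' log2 fold change descending, ties at the boundary included; symmetric
#' for `down` genes (most negative fold change first).
#'
#' @param deg a `deg_table`.
#' @param fraction fraction of each direction's calls to keep, in (0, 1].
#' @return list with character vectors `up` and `down`.
#' @export
top_fraction_deg <- function(deg, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  pick <- function(tab, decreasing) {
    if (!nrow(tab)) return(character(0))
    k <- ceiling(fraction * nrow(tab))
    mag <- if (decreasing) tab$log2_fold_change else -tab$log2_fold_change
    ord <- order(-mag, tab$gene)
    boundary <- mag[ord][k]
    tab$gene[mag >= boundary][order(-mag[mag >= boundary],
                                    tab$gene[mag >= boundary])]
  }
  list(up = pick(deg[deg$direction == "up", , drop = FALSE], TRUE),
       down = pick(deg[deg$direction == "down", , drop = FALSE], FALSE))
}

#' Genes recurring across per-cancer gene sets
#'
#' Counts, for every gene, the number of supplied per-cancer sets containing
#' it and keeps genes present in at least `min_cancers` sets.
#'
#' @param gene_sets list of character vectors, one per cancer.
#' @param min_cancers minimum number of sets a gene must appear in
#'   (default 3).
#' @return data frame with columns `gene` and `n_cancers`, sorted by count
#'   descending then gene symbol.
#' @export
cross_cancer_overlap <- function(gene_sets, min_cancers = 3) {
  stopifnot(length(gene_sets) >= min_cancers)
  counts <- table(unlist(lapply(gene_sets, unique), use.names = FALSE))
  keep <- counts[counts >= min_cancers]
  out <- data.frame(gene = names(keep), n_cancers = as.integer(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_cancers, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
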