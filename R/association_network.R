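#' Spearman correlation of genes with an anchor gene
#'
#' Rank correlation of each listed gene with the anchor across the tumour
#' samples, with a two-sided p-value. Genes with constant expression have no
#' defined correlation and are reported not-evaluable.
#'
#' @param expr an [expression_matrix()].
#' @param anchor anchor gene symbol.
#' @param genes gene symbols to correlate with the anchor.
#' @param cancer optional cancer-type label to restrict the tumour samples.
#' @return data frame with columns `gene`, `rho`, `p_value`, `n`,
#'   `evaluable`.
#' @export
spearman_anchor <- function(expr, anchor, genes, cancer = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  ann <- expr$annotations
  keep <- ann$sample_type == "tumour"
  if (!is.null(cancer)) keep <- keep & ann$cancer_type == cancer
  samples <- ann$sample[keep]
  if (length(samples) < 5) {
    stop("need >= 5 tumour samples for correlation analysis", call. = FALSE)
  }
  x <- expr$values[anchor, samples]
  rows <- lapply(genes, function(g) {
    y <- expr$values[g, samples]
    if (length(unique(y)) == 1 || length(unique(x)) == 1) {
      return(data.frame(gene = g, rho = NA_real_, p_value = NA_real_,
                        n = length(samples), evaluable = FALSE))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(gene = g, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(samples), evaluable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of expression across tumour stages
#'
#' Tests whether a gene's tumour expression differs across collapsed stage
#' groups (I-IV). Stage groups with fewer than 2 samples are dropped; at
#' least two groups must remain.
#'
#' @param expr an [expression_matrix()].
#' @param gene gene symbol.
#' @param clinical a [clinical_table()] supplying per-sample stages.
#' @param cancer optional cancer-type label to restrict the samples.
#' @return list with elements `F`, `p`, `n`, `n_groups`.
#' @export
stage_anova <- function(expr, gene, clinical, cancer = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  clin <- as.data.frame(clinical)
  if (!is.null(cancer)) clin <- clin[clin$cancer_type == cancer, ]
  clin <- clin[!is.na(clin$stage) & clin$sample %in% colnames(expr$values), ]
  values <- expr$values[gene, clin$sample]
  stage <- clin$stage
  counts <- table(stage)
  keep <- stage %in% names(counts)[counts >= 2]
  values <- values[keep]; stage <- stage[keep]
  if (length(unique(stage)) < 2) {
    stop("stage ANOVA needs >= 2 stage groups with >= 2 samples each",
         call. = FALSE)
  }
  fit <- stats::anova(stats::lm(values ~ factor(stage)))
  list(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
       n = length(values), n_groups = length(unique(stage)))
}

#' Co-occurrence test for the alterations of two genes
#'
#' Builds the 2x2 table of joint alteration status across samples, computes
#' the odds ratio with the Haldane-Anscombe +0.5 correction applied when any
#' cell is zero (so the log2 odds ratio is always finite), and tests
#' association with the two-sided Fisher exact test.
#'
#' @param alterations_a,alterations_b binary (0/1) per-sample alteration
#'   calls, same length and sample order. See [alteration_calls()] for
#'   deriving these from GISTIC calls.
#' @param gene_a,gene_b optional gene symbols carried into the result.
#' @return one-row data frame (`cooccurrence_result`) with columns `gene_a`,
#'   `gene_b`, `both_altered`, `a_only`, `b_only`, `neither`,
#'   `log2_odds_ratio`, `p_value`.
#' @examples
#' a <- rep(c(1, 0), each = 50)
#' b <- rep(c(1, 0, 1, 0), c(25, 25, 25, 25))
#' cooccurrence_test(a, b)  # independent: log2 OR = 0, p = 1
#' @export
cooccurrence_test <- function(alterations_a, alterations_b,
                              gene_a = "gene_a", gene_b = "gene_b") {
  stopifnot(length(alterations_a) == length(alterations_b),
            length(alterations_a) >= 1,
            all(alterations_a %in% c(0, 1)),
            all(alterations_b %in% c(0, 1)))
  n11 <- sum(alterations_a == 1 & alterations_b == 1)
  n10 <- sum(alterations_a == 1 & alterations_b == 0)
  n01 <- sum(alterations_a == 0 & alterations_b == 1)
  n00 <- sum(alterations_a == 0 & alterations_b == 0)
  cells <- c(n11, n10, n01, n00)
  adj <- if (any(cells == 0)) cells + 0.5 else cells
  log2_or <- log2((adj[1] * adj[4]) / (adj[2] * adj[3]))
  p <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
  data.frame(gene_a = gene_a, gene_b = gene_b,
             both_altered = n11, a_only = n10, b_only = n01, neither = n00,
             log2_odds_ratio = log2_or, p_value = p,
             stringsAsFactors = FALSE)
}

#' Binary alteration calls from GISTIC codes
#'
#' @param calls integer GISTIC calls in \{-2..2\} (one gene, all samples).
#' @param alter_on `"deep"` counts only the extreme codes -2/+2 as altered
#'   (default); `"any"` counts every non-zero call.
#' @param mutated optional logical vector: samples carrying a mutation are
#'   altered regardless of copy number.
#' @return integer 0/1 vector.
#' @export
alteration_calls <- function(calls, alter_on = c("deep", "any"),
                             mutated = NULL) {
  alter_on <- match.arg(alter_on)
  out <- if (alter_on == "deep") abs(calls) == 2 else calls != 0
  if (!is.null(mutated)) out <- out | as.logical(mutated)
  as.integer(out)
}

#' Degree-based hub ranking within a candidate-induced subgraph
#'
#' Computes node degree in the subgraph induced by the candidate genes and
#' returns candidates with degree at least `min_degree`, sorted by degree
#' descending with alphabetical tie-break — the cytoHubba "Degree" hub
#' criterion.
#'
#' @param network an [edge_list()].
#' @param candidates gene symbols defining the induced subgraph.
#' @param min_degree minimum degree to qualify as a hub (default 1).
#' @return data frame with columns `node`, `degree`, `rank` (competition
#'   ranking by degree).
#' @export
hub_rank <- function(network, candidates, min_degree = 1) {
  stopifnot(nrow(network) >= 1)
  sub <- network[network$node_a %in% candidates &
                   network$node_b %in% candidates, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = unique(candidates))
  deg <- igraph::degree(g)
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[out$degree >= min_degree, , drop = FALSE]
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  out$rank <- as.integer(rank(-out$degree, ties.method = "min"))
  rownames(out) <- NULL
  out
}

#' Four-criteria validation intersection
#'
#' Exact intersection of the genes passing the survival, stage, correlation
#' and co-occurrence screens, with a per-gene audit table of pass flags over
#' the union of all candidates.
#'
#' @param survival_pass,stage_pass,correlation_pass,cooccurrence_pass
#'   character vectors of genes passing each criterion.
#' @return list with `genes` (the alphabetical four-way intersection) and
#'   `audit` (data frame of per-gene pass flags).
#' @export
criteria_intersect <- function(survival_pass, stage_pass, correlation_pass,
                               cooccurrence_pass) {
  universe <- sort(unique(c(survival_pass, stage_pass, correlation_pass,
                            cooccurrence_pass)))
  audit <- data.frame(gene = universe,
                      survival = universe %in% survival_pass,
                      stage = universe %in% stage_pass,
                      correlation = universe %in% correlation_pass,
                      cooccurrence = universe %in% cooccurrence_pass,
                      stringsAsFactors = FALSE)
  list(genes = audit$gene[audit$survival & audit$stage & audit$correlation &
                            audit$cooccurrence],
       audit = audit)
}
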