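#' Competition-rank scores from breadth percentages
#'
#' Sorts genes by value (breadth percentage) descending and scores each gene
#' by its 1-based position: the top gene scores 1, the next 2, and so on.
#' Tied values share the minimal position of their tie block and the next
#' distinct value resumes at its actual position (competition ranking, e.g.
#' 90/70/70/50 scores 1/2/2/4).
#'
#' @param values named numeric vector (per-gene breadth percentages).
#' @return named integer vector of scores, in the input's gene order.
#' @export
rank_scores <- function(values) {
  stopifnot(length(values) >= 1)
  out <- as.integer(rank(-values, ties.method = "min"))
  names(out) <- names(values)
  out
}

#' Combine expression and survival rank scores into the final gene score
#'
#' Adds each gene's expression-rank score and survival-rank score; the
#' resulting table is sorted ascending by total (ties broken
#' alphabetically), so a low total marks a gene ranked high in both
#' breadth graphs. Upregulated and downregulated genes should be scored in
#' separate tables, never mixed.
#'
#' @param expr_scores,surv_scores named integer vectors over the same gene
#'   universe (from [rank_scores()]).
#' @return data frame (`gene_score`) with columns `gene`,
#'   `expression_rank_score`, `survival_rank_score`, `total_score`.
#' @export
combined_score <- function(expr_scores, surv_scores) {
  only <- c(setdiff(names(expr_scores), names(surv_scores)),
            setdiff(names(surv_scores), names(expr_scores)))
  if (length(only)) {
    stop("gene(s) present in only one score vector: ",
         paste(sort(unique(only)), collapse = ", "), call. = FALSE)
  }
  genes <- names(expr_scores)
  out <- data.frame(gene = genes,
                    expression_rank_score = as.integer(expr_scores),
                    survival_rank_score =
                      as.integer(surv_scores[genes]),
                    stringsAsFactors = FALSE)
  out$total_score <- out$expression_rank_score + out$survival_rank_score
  out <- out[order(out$total_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_score", "data.frame")
  out
}

#' Intersect the pan-cancer shortlist with recurrent individual-cancer hits
#'
#' The final selection of the screen: pan-shortlisted genes that are also
#' shortlisted and survival-significant in at least `min_cancers`
#' individual cancer types.
#'
#' @param pan_genes character vector of pan-cancer shortlisted genes.
#' @param per_cancer_hits named list mapping gene symbol to the character
#'   vector of cancers where it was individually shortlisted and
#'   survival-significant.
#' @param min_cancers minimum number of supporting cancers (default 2).
#' @return data frame with columns `gene`, `n_cancers`, `cancers`
#'   (comma-separated), sorted by support descending then gene symbol.
#' @export
pan_individual_intersect <- function(pan_genes, per_cancer_hits,
                                     min_cancers = 2) {
  hits <- vapply(pan_genes, function(g) {
    length(unique(per_cancer_hits[[g]]))
  }, integer(1))
  keep <- hits >= min_cancers
  out <- data.frame(
    gene = pan_genes[keep],
    n_cancers = hits[keep],
    cancers = vapply(pan_genes[keep], function(g) {
      paste(sort(unique(per_cancer_hits[[g]])), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_cancers, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
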