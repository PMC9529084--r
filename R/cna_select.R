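#' Count deep alteration events per gene
#'
#' Counts, for every gene, the samples carrying the extreme GISTIC codes:
#' -2 (deep deletion) and +2 (high-level amplification). Shallow calls
#' (+/-1) contribute to neither count.
#'
#' @param matrix a [gistic_matrix()].
#' @return data frame with columns `gene`, `n_deep_deletion`,
#'   `n_amplification`, `n_samples`, one row per gene in matrix order.
#' @examples
#' m <- gistic_matrix(matrix(c(-2L, -2L, 0L, 2L, 1L), 1, 5,
#'        dimnames = list("CTHRC1", paste0("S", 1:5))))
#' count_alterations(m)  # 2 deep deletions, 1 amplification
#' @export
count_alterations <- function(matrix) {
  stopifnot(inherits(matrix, "gistic_matrix"))
  data.frame(gene = rownames(matrix),
             n_deep_deletion = as.integer(rowSums(matrix == -2L)),
             n_amplification = as.integer(rowSums(matrix == 2L)),
             n_samples = ncol(matrix),
             stringsAsFactors = FALSE)
}

#' Select the most-altered fraction of genes in one direction
#'
#' Sorts genes by their deep-event count in the requested direction and
#' selects the top `ceiling(fraction * n_genes)`; genes tied with the
#' boundary count are all included, so the result may exceed the nominal
#' cut. Genes with zero events in the direction are never selected
#' (selection is among altered genes). With a 1027-gene universe and
#' fraction 0.05 the nominal cut is 52 genes per direction.
#'
#' @param counts result of [count_alterations()].
#' @param fraction fraction of the gene universe to select, in (0, 1].
#' @param direction `"amplified"` (ranks by `n_amplification`) or
#'   `"deleted"` (ranks by `n_deep_deletion`).
#' @param source provenance tag carried into the shortlist: `"pan"` or a
#'   cancer-type label.
#' @return data frame (`gene_shortlist`) with columns `gene`, `direction`,
#'   `count`, `n_samples`, `source`, sorted by count descending then gene
#'   symbol.
#' @export
top_fraction <- function(counts, fraction, direction = c("amplified",
                                                         "deleted"),
                         source = "pan") {
  direction <- match.arg(direction)
  stopifnot(fraction > 0, fraction <= 1)
  cnt <- if (direction == "amplified") counts$n_amplification else
    counts$n_deep_deletion
  n_genes <- nrow(counts)
  k <- ceiling(fraction * n_genes)
  ord <- order(-cnt, counts$gene)
  shortlist_empty <- function() {
    data.frame(gene = character(0), direction = character(0),
               count = integer(0), n_samples = integer(0),
               source = character(0), stringsAsFactors = FALSE)
  }
  if (all(cnt == 0)) {
    warning(sprintf("no %s deep events in source '%s'; empty shortlist",
                    direction, source), call. = FALSE)
    return(shortlist_empty())
  }
  boundary <- cnt[ord][min(k, n_genes)]
  keep <- cnt >= max(boundary, 1L) & cnt >= 1L
  out <- data.frame(gene = counts$gene[keep],
                    direction = direction,
                    count = as.integer(cnt[keep]),
                    n_samples = counts$n_samples[keep],
                    source = source,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
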