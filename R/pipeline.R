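#' Run the full matrisome prioritisation screen on a multi-cancer cohort
#'
#' Executes the complete screen on a cohort of per-cancer GISTIC matrices,
#' a pooled expression matrix and a clinical table:
#'
#' 1. **Per cancer**: deep-event counting, top-fraction shortlisting in both
#'    directions, tumour-versus-normal differential expression, the
#'    concordance filter (amplified genes must be up, deleted genes down),
#'    and a 75/25 percentile log-rank survival screen of the concordant
#'    genes. A gene "hits" a cancer when it survives all three stages there.
#' 2. **Pan-cancer**: the per-cancer GISTIC matrices are pooled, the top
#'    fraction per direction is selected, and each shortlisted gene is
#'    classified up/down/none by majority vote over its significant
#'    per-cancer DEG calls. Concordant genes get an expression breadth (the
#'    percentage of cancers with a significant concordant call) and a
#'    survival breadth (percentage of cancers where the gene's 75/25 split
#'    is log-rank significant); competition ranks of the two breadths are
#'    summed into the final score, separately for up- and downregulated
#'    genes.
#' 3. **Final selection**: pan-shortlisted concordant genes hitting at least
#'    `min_cancers_individual` individual cancers.
#'
#' @param cohort list with elements `gistic` (named list of
#'   [gistic_matrix()] per cancer), `expression` (an
#'   [expression_matrix()]), `clinical` (a [clinical_table()]), as produced
#'   by [simulate_cohort()] or assembled from the readers.
#' @param config a [pipeline_config()].
#' @return list of class `matriscreen_result` with elements
#'   `per_cancer_shortlists`, `per_cancer_deg`, `per_cancer_hits` (named
#'   list gene -> supporting cancers), `pan_shortlist`, `pan_concordant`,
#'   `breadth` (per-gene expression/survival breadth percentages),
#'   `scores` (list with `up` and `down` [combined_score()] tables), and
#'   `final` (the [pan_individual_intersect()] table).
#' @export
run_prioritization <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cancers <- names(cohort$gistic)
  n_cancers <- length(cancers)
  denom <- if (is.null(config$n_cancers_denominator)) n_cancers else
    config$n_cancers_denominator
  expr <- cohort$expression
  clin <- as.data.frame(cohort$clinical)

  # ---- per-cancer DEG tables and copy-number shortlists
  per_deg <- list()
  per_short <- list()
  for (cancer in cancers) {
    per_deg[[cancer]] <- tumour_vs_normal(expr, cancer,
                                          config$fold_change_threshold,
                                          config$alpha, config$deg_test)
    counts <- count_alterations(cohort$gistic[[cancer]])
    per_short[[cancer]] <- suppressWarnings(rbind(
      top_fraction(counts, config$top_fraction, "amplified", cancer),
      top_fraction(counts, config$top_fraction, "deleted", cancer)))
  }

  # ---- survival screen helper: 75/25 split of one gene in one cancer
  surv_p <- function(gene, cancer) {
    tum <- expr$annotations$sample[
      expr$annotations$cancer_type == cancer &
        expr$annotations$sample_type == "tumour"]
    tum <- intersect(tum, clin$sample)
    values <- stats::setNames(expr$values[gene, tum], tum)
    if (length(unique(values)) == 1 || length(values) < 4) return(NA_real_)
    g <- assign_groups(values, config$high_cutoff, config$low_cutoff)
    if (!any(g == "high") || !any(g == "low")) return(NA_real_)
    idx <- match(names(g), clin$sample)
    res <- suppressWarnings(
      logrank_test(clin$time_days[idx], clin$event[idx], g))
    res$p
  }

  # ---- per-cancer hits: shortlisted + concordant + survival-significant
  per_hits <- list()
  for (cancer in cancers) {
    conc <- suppressWarnings(
      concordance_filter(per_short[[cancer]], per_deg[[cancer]]))
    for (gene in unique(conc$gene)) {
      p <- surv_p(gene, cancer)
      if (!is.na(p) && p < config$alpha) {
        per_hits[[gene]] <- c(per_hits[[gene]], cancer)
      }
    }
  }

  # ---- pan-cancer shortlist on the pooled call matrix
  pooled <- gistic_matrix(do.call(cbind, lapply(cohort$gistic, unclass)))
  pan_counts <- count_alterations(pooled)
  pan_short <- suppressWarnings(rbind(
    top_fraction(pan_counts, config$top_fraction, "amplified", "pan"),
    top_fraction(pan_counts, config$top_fraction, "deleted", "pan")))

  # pan expression classification: majority vote over significant
  # per-cancer calls
  call_counts <- function(gene) {
    calls <- vapply(cancers, function(cn) {
      tab <- per_deg[[cn]]
      d <- tab$direction[tab$gene == gene]
      if (!length(d)) "none" else d
    }, character(1))
    c(up = sum(calls == "up"), down = sum(calls == "down"))
  }
  pan_rows <- list()
  for (i in seq_len(nrow(pan_short))) {
    gene <- pan_short$gene[i]
    cc <- call_counts(gene)
    pan_dir <- if (cc["up"] > cc["down"] && cc["up"] >= 1) "up"
      else if (cc["down"] > cc["up"] && cc["down"] >= 1) "down"
      else "none"
    concordant <- (pan_short$direction[i] == "amplified" && pan_dir == "up") ||
      (pan_short$direction[i] == "deleted" && pan_dir == "down")
    if (!concordant) next
    n_expr <- unname(if (pan_dir == "up") cc["up"] else cc["down"])
    n_surv <- sum(vapply(cancers, function(cn) {
      p <- surv_p(gene, cn)
      !is.na(p) && p < config$alpha
    }, logical(1)))
    pan_rows[[gene]] <- data.frame(
      gene = gene, direction = pan_short$direction[i],
      expression_direction = pan_dir,
      expression_breadth = percent_affected(n_expr, denom),
      survival_breadth = percent_affected(n_surv, denom),
      stringsAsFactors = FALSE)
  }
  breadth <- if (length(pan_rows)) {
    do.call(rbind, c(pan_rows, make.row.names = FALSE))
  } else {
    data.frame(gene = character(0), direction = character(0),
               expression_direction = character(0),
               expression_breadth = numeric(0),
               survival_breadth = numeric(0))
  }

  # ---- rank-sum scores, separately for up- and downregulated genes
  score_table <- function(dir) {
    sub <- breadth[breadth$expression_direction == dir, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    combined_score(
      rank_scores(stats::setNames(sub$expression_breadth, sub$gene)),
      rank_scores(stats::setNames(sub$survival_breadth, sub$gene)))
  }
  scores <- list(up = score_table("up"), down = score_table("down"))

  final <- pan_individual_intersect(breadth$gene, per_hits,
                                    config$min_cancers_individual)

  structure(list(per_cancer_shortlists = per_short,
                 per_cancer_deg = per_deg,
                 per_cancer_hits = per_hits,
                 pan_shortlist = pan_short,
                 pan_concordant = breadth$gene,
                 breadth = breadth,
                 scores = scores,
                 final = final,
                 config = config),
            class = "matriscreen_result")
}

#' @export
print.matriscreen_result <- function(x, ...) {
  cat(sprintf(
    "matriscreen result: %d cancers; pan shortlist %d genes, %d concordant; final selection: %s\n",
    length(x$per_cancer_shortlists), nrow(x$pan_shortlist),
    length(x$pan_concordant),
    if (nrow(x$final)) paste(x$final$gene, collapse = ", ") else "(none)"))
  invisible(x)
}
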