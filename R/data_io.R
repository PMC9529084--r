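#' Read a GISTIC-thresholded copy-number matrix (Xena genomicMatrix TSV)
#'
#' The file is tab-separated with a header row `sample<TAB>id1<TAB>id2...`
#' naming the sample columns; each following row is a gene symbol followed
#' by one integer call in \{-2, -1, 0, 1, 2\} per sample. Row and column
#' order are preserved. Missing cells are rejected (no imputation).
#'
#' @param path path to the TSV file.
#' @return a [gistic_matrix()].
#' @export
read_gistic_matrix <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2) {
    stop("GISTIC matrix file needs an identifier column plus at least one sample column",
         call. = FALSE)
  }
  # an all-missing column parses as logical NA; keep it numeric so the
  # missing-value check reports it as such rather than as non-numeric
  df[-1] <- lapply(df[-1], function(col) {
    if (is.logical(col) && all(is.na(col))) as.numeric(col) else col
  })
  numeric_col <- vapply(df[-1], is.numeric, logical(1))
  if (!all(numeric_col)) {
    stop(sprintf("non-numeric GISTIC call(s) in sample column '%s'",
                 colnames(df)[-1][!numeric_col][1]), call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  gistic_matrix(values, gene_ids = as.character(df[[1]]),
                sample_ids = colnames(df)[-1])
}

#' Write a GISTIC matrix in the genomicMatrix TSV dialect
#'
#' @param x a [gistic_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gistic_matrix <- function(x, path) {
  write_matrix_tsv(unclass(x), path)
}

#' Read an expression matrix with its sample annotation table
#'
#' The matrix file uses the same tab-separated genomicMatrix dialect as
#' [read_gistic_matrix()]; the annotation file is a TSV with named header
#' columns `sample`, `cancer_type`, `sample_type` mapping every sample to a
#' cancer-type label and a tumour/normal flag. Samples present in the matrix
#' but absent from the annotations are an error.
#'
#' @param path path to the expression TSV.
#' @param annotation_path path to the annotation TSV.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, annotation_path) {
  df <- read_tsv_strict(path)
  numeric_col <- vapply(df[-1], is.numeric, logical(1))
  if (!all(numeric_col)) {
    stop(sprintf("non-numeric expression value(s) in sample column '%s'",
                 colnames(df)[-1][!numeric_col][1]), call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  ann <- read_tsv_strict(annotation_path)
  expression_matrix(values, ann)
}

#' Write an expression matrix and its annotations
#'
#' @param x an [expression_matrix()].
#' @param path output path for the value matrix.
#' @param annotation_path output path for the annotation table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, annotation_path) {
  write_matrix_tsv(x$values, path)
  utils::write.table(x$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with named header columns `sample`, `cancer_type`, `time_days`,
#' `event`, `stage`, `race`, `gender`. Missing stage/race/gender entries use
#' the literal token `NA` (never an empty string).
#'
#' @param path path to the TSV file.
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  clinical_table(read_tsv_strict(path, na = "NA"))
}

#' Write a clinical table
#'
#' @param x a [clinical_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines are ignored; order is preserved; duplicates are removed
#' keeping the first occurrence, with a warning.
#'
#' @param path path to the text file.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  if (!length(lines)) {
    stop(sprintf("gene list '%s' is empty", path), call. = FALSE)
  }
  dup <- unique(lines[duplicated(lines)])
  if (length(dup)) {
    warning("dropping duplicate gene symbol(s): ",
            paste(dup, collapse = ", "), call. = FALSE)
    lines <- lines[!duplicated(lines)]
  }
  lines
}

#' Write a gene list (one symbol per line)
#'
#' @param genes character vector of gene symbols.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read an interaction edge list with confidence filtering
#'
#' Three tab-separated columns: nodeA, nodeB, score. Scores are accepted on
#' either the \[0, 1\] scale or the STRING-style \[0, 1000\] integer scale;
#' if any score exceeds 1 the whole file is taken to be on the 0-1000 scale
#' and divided by 1000. Self-loops are removed, reciprocal duplicates are
#' collapsed (keeping the highest confidence), and edges below
#' `min_confidence` are dropped.
#'
#' @param path path to the TSV file (no header).
#' @param min_confidence minimum confidence to retain an edge; default 0.4,
#'   the STRING "medium confidence" cutoff.
#' @return an [edge_list()].
#' @export
read_edge_list <- function(path, min_confidence = 0.4) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) {
    stop("edge list file needs 3 tab-separated columns: nodeA, nodeB, score",
         call. = FALSE)
  }
  score <- df[[3]]
  if (!is.numeric(score) || anyNA(score)) {
    stop("edge scores must be numeric", call. = FALSE)
  }
  if (any(score < 0) || any(score > 1000)) {
    stop("edge scores must lie in [0, 1] or in [0, 1000]", call. = FALSE)
  }
  if (any(score > 1)) score <- score / 1000
  keep <- df[[1]] != df[[2]]
  edges <- data.frame(node_a = as.character(df[[1]][keep]),
                      node_b = as.character(df[[2]][keep]),
                      confidence = score[keep],
                      stringsAsFactors = FALSE)
  # collapse reciprocal duplicates, keeping the highest-confidence record
  key <- edge_key(edges$node_a, edges$node_b)
  edges <- edges[order(key, -edges$confidence), , drop = FALSE]
  edges <- edges[!duplicated(edge_key(edges$node_a, edges$node_b)), ,
                 drop = FALSE]
  edges <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  edge_list(edges)
}

#' Write an edge list as a 3-column TSV
#'
#' @param x an [edge_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration with the screen's default thresholds
#'
#' Collects the tunable thresholds of the prioritisation screen: the
#' top-altered fraction selected from the copy-number stage, the percentile
#' cutoffs of the high/low expression split, the fold-change and significance
#' thresholds of the differential-expression calls, the cross-cancer overlap
#' minima, and the breadth denominator used by the percentage-affected
#' statistic.
#'
#' @param top_fraction fraction of the gene universe selected per direction
#'   in the copy-number stage (default 0.05).
#' @param high_cutoff,low_cutoff percentiles of the anchor-expression split:
#'   samples strictly above the `high_cutoff` percentile are "high", strictly
#'   below the `low_cutoff` percentile "low", the middle excluded (defaults
#'   0.75 / 0.25).
#' @param fold_change_threshold linear fold-change threshold for calling a
#'   gene differentially expressed (default 2; applied as |log2FC| >= 1).
#' @param alpha significance level for every screen (default 0.05).
#' @param min_cancers_overlap minimum cancers for the cross-cancer DEG
#'   overlap (default 3).
#' @param min_cancers_individual minimum individual cancers for the final
#'   pan/individual intersection (default 2).
#' @param min_hub_degree minimum degree for a node to count as a hub
#'   (default 1).
#' @param n_cancers_denominator denominator of the percentage-affected
#'   breadth statistic (default 30, the number of cancer types screened);
#'   `NULL` lets the pipeline use the number of cancers actually supplied.
#' @param edge_confidence_min minimum interaction confidence (default 0.4).
#' @param deg_test two-group test for differential expression: `"welch"`
#'   (default) or `"wilcoxon"`.
#' @param seed optional integer seed recorded with the configuration.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(top_fraction = 0.05,
                            high_cutoff = 0.75,
                            low_cutoff = 0.25,
                            fold_change_threshold = 2,
                            alpha = 0.05,
                            min_cancers_overlap = 3,
                            min_cancers_individual = 2,
                            min_hub_degree = 1,
                            n_cancers_denominator = 30,
                            edge_confidence_min = 0.4,
                            deg_test = c("welch", "wilcoxon"),
                            seed = NULL) {
  deg_test <- match.arg(deg_test)
  stopifnot(top_fraction > 0, top_fraction <= 1,
            low_cutoff >= 0, low_cutoff <= high_cutoff, high_cutoff <= 1,
            fold_change_threshold > 1,
            alpha > 0, alpha < 1,
            min_cancers_overlap >= 1, min_cancers_individual >= 1,
            min_hub_degree >= 0, edge_confidence_min >= 0,
            edge_confidence_min <= 1)
  if (!is.null(n_cancers_denominator)) {
    stopifnot(n_cancers_denominator >= 1)
  }
  structure(list(top_fraction = top_fraction,
                 high_cutoff = high_cutoff,
                 low_cutoff = low_cutoff,
                 fold_change_threshold = fold_change_threshold,
                 alpha = alpha,
                 min_cancers_overlap = min_cancers_overlap,
                 min_cancers_individual = min_cancers_individual,
                 min_hub_degree = min_hub_degree,
                 n_cancers_denominator = n_cancers_denominator,
                 edge_confidence_min = edge_confidence_min,
                 deg_test = deg_test,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; omitted keys take their defaults from
#' [pipeline_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

# strict TSV reader: errors on ragged rows, keeps column names verbatim
read_tsv_strict <- function(path, na = c("NA")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = na, fill = FALSE,
                          blank.lines.skip = TRUE)
  df
}

write_matrix_tsv <- function(values, path) {
  header <- paste(c("sample", colnames(values)), collapse = "\t")
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], format(values[i, ], trim = TRUE,
                                        digits = 15, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
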