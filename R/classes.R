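#' Construct a validated GISTIC call matrix
#'
#' A `gistic_matrix` is an integer gene-by-sample matrix of thresholded
#' copy-number calls in \{-2, -1, 0, 1, 2\}: -2 deep deletion, -1 shallow
#' deletion, 0 neutral, +1/+2 low/high-level gain. Only the extreme codes
#' (-2, +2) are counted as alteration events downstream.
#'
#' @param values integer matrix, genes in rows, samples in columns.
#' @param gene_ids unique gene symbols; defaults to `rownames(values)`.
#' @param sample_ids unique sample identifiers; defaults to
#'   `colnames(values)`.
#' @return an integer matrix of class `gistic_matrix` with gene row names
#'   and sample column names.
#' @examples
#' gistic_matrix(matrix(c(2L, 0L, -2L, 1L), 2, 2,
#'                      dimnames = list(c("CTHRC1", "POSTN"), c("S1", "S2"))))
#' @export
gistic_matrix <- function(values, gene_ids = rownames(values),
                          sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gistic_matrix requires gene and sample identifiers", call. = FALSE)
  }
  check_unique_ids(gene_ids, "gene")
  check_unique_ids(sample_ids, "sample")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop("value grid dimensions do not match the identifier lists",
         call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "missing GISTIC call at gene '%s', sample '%s': missing calls are rejected, no imputation is performed",
      gene_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  if (!is.numeric(values) || any(values != round(values))) {
    stop("GISTIC calls must be integers in {-2, -1, 0, 1, 2}", call. = FALSE)
  }
  bad <- which(!(values %in% (-2L:2L)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "GISTIC call %s at gene '%s', sample '%s' is outside {-2, -1, 0, 1, 2}",
      format(values[bad[1]]), gene_ids[idx[1]], sample_ids[idx[2]]),
      call. = FALSE)
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("gistic_matrix", class(values))
  values
}

#' Construct a validated expression matrix with sample annotations
#'
#' Holds gene-by-sample expression values on a log2(TPM+1)-like scale
#' (non-negative, finite) together with the per-sample cancer-type label and
#' tumour/normal flag that downstream two-group comparisons rely on.
#'
#' @param values non-negative numeric matrix, genes in rows, samples in
#'   columns.
#' @param annotations data frame with columns `sample`, `cancer_type`,
#'   `sample_type` (each sample flagged `"tumour"` or `"normal"`). Every
#'   matrix column must be annotated.
#' @return a list of class `expression_matrix` with elements `values` and
#'   `annotations` (annotations reordered to the column order of `values`).
#' @export
expression_matrix <- function(values, annotations) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene row names and sample column names",
         call. = FALSE)
  }
  check_unique_ids(rownames(values), "gene")
  check_unique_ids(colnames(values), "sample")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  annotations <- as.data.frame(annotations)
  needed <- c("sample", "cancer_type", "sample_type")
  if (!all(needed %in% names(annotations))) {
    stop("annotations need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  missing_ann <- setdiff(colnames(values), annotations$sample)
  if (length(missing_ann)) {
    stop("samples missing from annotations: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  }
  annotations <- annotations[match(colnames(values), annotations$sample), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  if (!all(annotations$sample_type %in% c("tumour", "normal"))) {
    stop("sample_type must be 'tumour' or 'normal'", call. = FALSE)
  }
  structure(list(values = values, annotations = annotations),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$annotations$sample_type)
  cat(sprintf(
    "expression_matrix: %d genes x %d samples (%d tumour, %d normal), %d cancer type(s)\n",
    nrow(x$values), ncol(x$values),
    if ("tumour" %in% names(tab)) tab[["tumour"]] else 0L,
    if ("normal" %in% names(tab)) tab[["normal"]] else 0L,
    length(unique(x$annotations$cancer_type))))
  invisible(x)
}

# closed vocabulary for collapsed tumour stages
STAGE_LEVELS <- c("I", "II", "III", "IV")

#' Construct a validated clinical table
#'
#' Per-sample follow-up data: survival time in days, event indicator
#' (1 = death observed, 0 = censored), collapsed tumour stage and optional
#' race/gender labels. Missing stage/race/gender are encoded as `NA`, never
#' as empty strings.
#'
#' @param data data frame with columns `sample`, `cancer_type`, `time_days`,
#'   `event`, and optionally `stage`, `race`, `gender`.
#' @return data frame of class `clinical_table`.
#' @seealso [collapse_stage()] for the sub-stage collapsing rule.
#' @export
clinical_table <- function(data) {
  data <- as.data.frame(data)
  needed <- c("sample", "cancer_type", "time_days", "event")
  if (!all(needed %in% names(data))) {
    stop("clinical table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("stage", "race", "gender")) {
    if (!col %in% names(data)) data[[col]] <- NA_character_
    data[[col]] <- as.character(data[[col]])
    data[[col]][!is.na(data[[col]]) & data[[col]] == ""] <- NA_character_
  }
  check_unique_ids(data$sample, "sample")
  if (anyNA(data$time_days) || any(data$time_days < 0)) {
    stop("time_days must be non-negative and non-missing", call. = FALSE)
  }
  if (!all(data$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (death observed)", call. = FALSE)
  }
  data$event <- as.integer(data$event)
  data$stage <- collapse_stage(data$stage)
  rownames(data) <- NULL
  class(data) <- c("clinical_table", "data.frame")
  data
}

#' Collapse tumour sub-stages to their parent stage
#'
#' Maps labels such as `"Stage IIIA"`, `"iiib"` or `"IV"` to the closed
#' vocabulary I/II/III/IV. Unrecognised labels raise an error; `NA` is kept.
#'
#' @param stage character vector of stage labels.
#' @return character vector over \{I, II, III, IV, NA\}.
#' @export
collapse_stage <- function(stage) {
  out <- toupper(trimws(as.character(stage)))
  out <- sub("^STAGE\\s*", "", out)
  out <- sub("^(IV|III|II|I).*$", "\\1", out)
  bad <- !is.na(out) & !(out %in% STAGE_LEVELS)
  if (any(bad)) {
    stop("unrecognised stage label(s): ",
         paste(unique(stage[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Construct a validated undirected edge list
#'
#' Interaction edges with confidence scores in \[0, 1\]. Self-loops are
#' forbidden and each unordered node pair appears at most once.
#'
#' @param edges data frame with columns `node_a`, `node_b`, `confidence`.
#' @return data frame of class `edge_list`.
#' @export
edge_list <- function(edges) {
  edges <- as.data.frame(edges)
  needed <- c("node_a", "node_b", "confidence")
  if (!all(needed %in% names(edges))) {
    stop("edge list needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (any(edges$node_a == edges$node_b)) {
    stop("edge list contains self-loops", call. = FALSE)
  }
  if (anyNA(edges$confidence) ||
      any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidence must lie in [0, 1]", call. = FALSE)
  }
  key <- edge_key(edges$node_a, edges$node_b)
  if (anyDuplicated(key)) {
    stop("edge list contains duplicate (unordered) node pairs", call. = FALSE)
  }
  rownames(edges) <- NULL
  class(edges) <- c("edge_list", "data.frame")
  edges
}

# canonical unordered-pair key
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(ids == "")) {
    stop(sprintf("%s identifiers must be non-empty", what), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}
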