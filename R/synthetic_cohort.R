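#' Configuration for the multi-cancer cohort simulator
#'
#' Describes a synthetic pan-cancer study: several cancer types, each with
#' tumour and normal samples, a gene universe with a handful of planted
#' driver genes, and the effect channels the prioritisation screen is built
#' to detect. Per driver the simulator plants: an elevated deep-amplification
#' and/or deep-deletion probability, an additive tumour expression shift (in
#' log2 units), a copy-number coupling `cna_coupling` (log2 units per GISTIC
#' step), a proportional-hazards effect `log_hazard_ratio` per unit
#' expression z-score, and a per-stage expression trend. Pairs of genes can
#' additionally be given co-occurring alterations at a target odds ratio.
#'
#' @param n_cancers number of cancer types.
#' @param n_tumour,n_normal samples of each kind per cancer type.
#' @param n_genes size of the gene universe (symbols `G0001`, `G0002`, ...).
#' @param drivers data frame with one row per planted driver: columns
#'   `gene`, `cancers` (comma-separated cancer labels, or `"all"`),
#'   `amp_prob`, `del_prob`, `expression_shift`, `cna_coupling`,
#'   `log_hazard_ratio`, `stage_trend`. `NULL` means no drivers (a null
#'   cohort).
#' @param cooccurring_pairs data frame with columns `gene_a`, `gene_b`,
#'   `odds_ratio`, `p_a`, `p_b`: pairs given jointly distributed deep
#'   alterations at the target odds ratio (pan-cohort, overriding their
#'   independent calls).
#' @param background_deep_prob per-gene probability of a background deep
#'   event (split evenly between -2 and +2); default 0.02.
#' @param background_shallow_prob probability of a background shallow (+/-1)
#'   call; default 0.10. Shallow calls never count as alteration events, so
#'   this exercises the deep-events-only counting rule.
#' @param baseline_mean_range range of per-gene baseline expression means on
#'   the log2(TPM+1)-like scale; default c(2, 8).
#' @param noise_sd residual expression standard deviation (log2 units);
#'   default 0.8.
#' @param baseline_hazard baseline event rate per day; default 1/1000.
#' @param censoring_rate target fraction of censored samples; default 0.3.
#' @param stage_probs sampling probabilities of stages I-IV for tumour
#'   samples.
#' @param n_background_edges random non-driver edges in the simulated
#'   interaction network; default 30.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including the seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cancers = 5,
                       n_tumour = 100,
                       n_normal = 40,
                       n_genes = 150,
                       drivers = NULL,
                       cooccurring_pairs = NULL,
                       background_deep_prob = 0.02,
                       background_shallow_prob = 0.10,
                       baseline_mean_range = c(2, 8),
                       noise_sd = 0.8,
                       baseline_hazard = 1 / 1000,
                       censoring_rate = 0.3,
                       stage_probs = c(0.3, 0.3, 0.25, 0.15),
                       n_background_edges = 30,
                       seed = 1L) {
  stopifnot(n_cancers >= 1, n_tumour >= 4, n_normal >= 2, n_genes >= 2,
            background_deep_prob >= 0, background_deep_prob <= 1,
            background_shallow_prob >= 0, background_shallow_prob <= 1,
            noise_sd > 0, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1,
            length(stage_probs) == 4, all(stage_probs >= 0))
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(drivers)) {
    drivers <- as.data.frame(drivers)
    needed <- c("gene", "cancers", "amp_prob", "del_prob",
                "expression_shift", "cna_coupling", "log_hazard_ratio",
                "stage_trend")
    miss <- setdiff(needed, names(drivers))
    if (length(miss)) {
      stop("driver table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    absent <- setdiff(drivers$gene, genes)
    if (length(absent)) {
      stop("driver gene(s) absent from the gene universe: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    stopifnot(all(drivers$amp_prob >= 0 & drivers$amp_prob <= 1),
              all(drivers$del_prob >= 0 & drivers$del_prob <= 1))
  }
  if (!is.null(cooccurring_pairs)) {
    cooccurring_pairs <- as.data.frame(cooccurring_pairs)
    stopifnot(all(c("gene_a", "gene_b", "odds_ratio", "p_a", "p_b") %in%
                    names(cooccurring_pairs)),
              all(cooccurring_pairs$odds_ratio > 0))
    absent <- setdiff(c(cooccurring_pairs$gene_a, cooccurring_pairs$gene_b),
                      genes)
    if (length(absent)) {
      stop("co-occurring pair gene(s) absent from the gene universe: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_cancers = n_cancers, n_tumour = n_tumour,
                 n_normal = n_normal, n_genes = n_genes, genes = genes,
                 cancer_labels = sprintf("CAN%02d", seq_len(n_cancers)),
                 drivers = drivers, cooccurring_pairs = cooccurring_pairs,
                 background_deep_prob = background_deep_prob,
                 background_shallow_prob = background_shallow_prob,
                 baseline_mean_range = baseline_mean_range,
                 noise_sd = noise_sd, baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate, stage_probs = stage_probs,
                 n_background_edges = n_background_edges,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-cancer cohort with planted ground truth
#'
#' Generates, per cancer type, a GISTIC call matrix over tumour samples, an
#' expression matrix over tumour and normal samples, a clinical table with
#' exponential survival times under a proportional-hazards model driven by
#' driver-gene expression, and a pan-cohort interaction edge list containing
#' a clique over the planted drivers plus random background edges.
#'
#' Generative model, all on the log2(TPM+1)-like scale: normal samples draw
#' `baseline + N(0, noise_sd)`; tumour samples draw
#' `baseline + cna_coupling * call + expression_shift + stage_trend * (stage - 1)
#' + N(0, noise_sd)`, floored at zero. The hazard for a tumour sample is
#' `baseline_hazard * exp(sum_d gamma_d * z_d)` over drivers `d`, where
#' `z_d` is the within-cancer z-score of the driver's expression; censoring
#' is independent uniform over a study window sized to hit the target
#' censoring fraction.
#'
#' @param config a [sim_config()].
#' @return list with elements `gistic` (named list of [gistic_matrix()], one
#'   per cancer), `expression` (a pooled [expression_matrix()]),
#'   `clinical` (a [clinical_table()] over tumour samples), `edges`
#'   (an [edge_list()]), and `truth` (realized per-driver alteration
#'   frequencies, shifts, hazard ratios and per-pair odds ratios).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- config$genes
  baseline <- stats::runif(config$n_genes, config$baseline_mean_range[1],
                           config$baseline_mean_range[2])
  names(baseline) <- genes

  driver_effect <- function(gene, cancer) {
    d <- config$drivers
    if (is.null(d)) return(NULL)
    row <- d[d$gene == gene, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    in_cancer <- row$cancers == "all" |
      vapply(strsplit(row$cancers, ","), function(v) cancer %in% trimws(v),
             logical(1))
    if (!any(in_cancer)) return(NULL)
    row[which(in_cancer)[1], ]
  }

  gistic <- list()
  expr_cols <- list()
  ann_rows <- list()
  clin_rows <- list()
  truth_drivers <- list()

  for (cancer in config$cancer_labels) {
    tum_ids <- sprintf("%s-T%03d", cancer, seq_len(config$n_tumour))
    norm_ids <- sprintf("%s-N%03d", cancer, seq_len(config$n_normal))

    # --- copy-number calls over tumour samples
    calls <- matrix(0L, config$n_genes, config$n_tumour,
                    dimnames = list(genes, tum_ids))
    for (g in seq_along(genes)) {
      eff <- driver_effect(genes[g], cancer)
      p_amp <- if (is.null(eff)) config$background_deep_prob / 2 else eff$amp_prob
      p_del <- if (is.null(eff)) config$background_deep_prob / 2 else eff$del_prob
      u <- stats::runif(config$n_tumour)
      v <- calls[g, ]
      v[u < p_amp] <- 2L
      v[u >= p_amp & u < p_amp + p_del] <- -2L
      # background shallow +/-1 calls on top of neutral samples
      w <- stats::runif(config$n_tumour)
      shallow <- v == 0L & w < config$background_shallow_prob
      v[shallow] <- ifelse(stats::runif(sum(shallow)) < 0.5, 1L, -1L)
      calls[g, ] <- v
    }
    gistic[[cancer]] <- gistic_matrix(calls)

    # --- stages
    stage_idx <- sample.int(4, config$n_tumour, replace = TRUE,
                            prob = config$stage_probs)
    stage <- STAGE_LEVELS[stage_idx]

    # --- expression
    tum_expr <- matrix(stats::rnorm(config$n_genes * config$n_tumour,
                                    sd = config$noise_sd),
                       config$n_genes, config$n_tumour,
                       dimnames = list(genes, tum_ids)) + baseline
    norm_expr <- matrix(stats::rnorm(config$n_genes * config$n_normal,
                                     sd = config$noise_sd),
                        config$n_genes, config$n_normal,
                        dimnames = list(genes, norm_ids)) + baseline
    loghr <- numeric(0)
    for (g in seq_along(genes)) {
      eff <- driver_effect(genes[g], cancer)
      if (is.null(eff)) next
      tum_expr[g, ] <- tum_expr[g, ] +
        eff$cna_coupling * calls[g, ] +
        eff$expression_shift +
        eff$stage_trend * (stage_idx - 1)
      if (eff$log_hazard_ratio != 0) {
        loghr[genes[g]] <- eff$log_hazard_ratio
      }
      truth_drivers[[paste(cancer, genes[g])]] <- data.frame(
        cancer_type = cancer, gene = genes[g],
        amp_freq = mean(calls[g, ] == 2L),
        del_freq = mean(calls[g, ] == -2L),
        expression_shift = eff$expression_shift,
        hazard_ratio = exp(eff$log_hazard_ratio),
        stage_trend = eff$stage_trend)
    }
    tum_expr <- pmax(tum_expr, 0)
    norm_expr <- pmax(norm_expr, 0)

    # --- survival: hazard scales with driver expression z-scores
    log_rel_hazard <- rep(0, config$n_tumour)
    for (g in names(loghr)) {
      z <- as.numeric(scale(tum_expr[g, ]))
      if (anyNA(z)) z <- rep(0, config$n_tumour)  # constant expression
      log_rel_hazard <- log_rel_hazard + loghr[[g]] * z
    }
    rate <- config$baseline_hazard * exp(log_rel_hazard)
    t_event <- stats::rexp(config$n_tumour, rate = rate)
    window <- censoring_window(config$baseline_hazard, config$censoring_rate)
    t_cens <- if (is.finite(window)) {
      stats::runif(config$n_tumour, 0, window)
    } else {
      rep(Inf, config$n_tumour)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    expr_cols[[cancer]] <- cbind(tum_expr, norm_expr)
    ann_rows[[cancer]] <- data.frame(
      sample = c(tum_ids, norm_ids),
      cancer_type = cancer,
      sample_type = rep(c("tumour", "normal"),
                        c(config$n_tumour, config$n_normal)))
    clin_rows[[cancer]] <- data.frame(
      sample = tum_ids, cancer_type = cancer,
      time_days = round(time, 3), event = event, stage = stage,
      race = sample(c("white", "black", "asian"), config$n_tumour,
                    replace = TRUE, prob = c(0.6, 0.25, 0.15)),
      gender = sample(c("male", "female"), config$n_tumour, replace = TRUE))
  }

  # --- pan-cohort co-occurring alteration pairs (override independent calls)
  truth_pairs <- NULL
  if (!is.null(config$cooccurring_pairs)) {
    all_tumour <- unlist(lapply(gistic, colnames), use.names = FALSE)
    n_all <- length(all_tumour)
    rows <- list()
    for (i in seq_len(nrow(config$cooccurring_pairs))) {
      pr <- config$cooccurring_pairs[i, ]
      ab <- simulate_cooccurrence_pair(n_all, pr$p_a, pr$p_b, pr$odds_ratio)
      offset <- 0L
      for (cancer in config$cancer_labels) {
        idx <- offset + seq_len(ncol(gistic[[cancer]]))
        m <- unclass(gistic[[cancer]])
        m[pr$gene_a, ] <- ifelse(ab$a[idx] == 1L, 2L, 0L)
        m[pr$gene_b, ] <- ifelse(ab$b[idx] == 1L, 2L, 0L)
        gistic[[cancer]] <- gistic_matrix(m)
        offset <- offset + ncol(m)
      }
      tab <- table(factor(ab$a, 0:1), factor(ab$b, 0:1))
      rows[[i]] <- data.frame(gene_a = pr$gene_a, gene_b = pr$gene_b,
                              target_odds_ratio = pr$odds_ratio,
                              realized_p_a = mean(ab$a),
                              realized_p_b = mean(ab$b),
                              both_altered = tab["1", "1"])
    }
    truth_pairs <- do.call(rbind, rows)
  }

  # --- interaction network: driver clique + random background edges
  driver_genes <- if (is.null(config$drivers)) character(0) else
    unique(config$drivers$gene)
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      confidence = numeric(0))
  if (length(driver_genes) >= 2) {
    cmb <- utils::combn(sort(driver_genes), 2)
    edges <- rbind(edges, data.frame(node_a = cmb[1, ], node_b = cmb[2, ],
                                     confidence = 0.9))
  }
  pool <- setdiff(genes, driver_genes)
  n_bg <- min(config$n_background_edges, choose(length(pool), 2))
  if (n_bg > 0) {
    seen <- character(0)
    bg <- list()
    while (length(bg) < n_bg) {
      pair <- sort(sample(pool, 2))
      key <- paste(pair, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      bg[[length(bg) + 1L]] <- data.frame(node_a = pair[1], node_b = pair[2],
                                          confidence = stats::runif(1, 0.4, 1))
    }
    edges <- rbind(edges, do.call(rbind, bg))
  }

  ann <- do.call(rbind, ann_rows)
  rownames(ann) <- NULL
  list(gistic = gistic,
       expression = expression_matrix(do.call(cbind, expr_cols), ann),
       clinical = clinical_table(do.call(rbind, clin_rows)),
       edges = edge_list(edges),
       truth = list(
         drivers = if (length(truth_drivers))
           do.call(rbind, c(truth_drivers, make.row.names = FALSE)) else NULL,
         pairs = truth_pairs,
         driver_genes = driver_genes))
}

#' Simulate a pair of binary alteration vectors with a target odds ratio
#'
#' Draws `n` i.i.d. samples from the 2x2 joint distribution whose marginals
#' are `p_a`, `p_b` and whose odds ratio equals `odds_ratio`. The
#' joint-positive cell probability is the unique admissible root of the
#' quadratic `(OR-1) p11^2 - ((OR-1)(p_a+p_b) + 1) p11 + OR p_a p_b = 0`.
#'
#' @param n number of samples.
#' @param p_a,p_b marginal alteration probabilities, in (0, 1).
#' @param odds_ratio target odds ratio, > 0.
#' @param seed optional seed; if `NULL` the current RNG state is used.
#' @return list with integer vectors `a`, `b` (0/1 of length `n`) and the
#'   exact joint cell probabilities `p11`, `p10`, `p01`, `p00`.
#' @export
simulate_cooccurrence_pair <- function(n, p_a, p_b, odds_ratio, seed = NULL) {
  stopifnot(n >= 1, p_a > 0, p_a < 1, p_b > 0, p_b < 1, odds_ratio > 0)
  if (!is.null(seed)) set.seed(seed)
  p11 <- joint_positive_cell(p_a, p_b, odds_ratio)
  p10 <- p_a - p11
  p01 <- p_b - p11
  p00 <- 1 - p11 - p10 - p01
  cells <- c(p11, p10, p01, p00)
  if (any(cells < -1e-12)) {
    stop("no admissible joint distribution for the requested marginals and odds ratio",
         call. = FALSE)
  }
  cells <- pmax(cells, 0)
  draw <- sample.int(4, n, replace = TRUE, prob = cells)
  list(a = as.integer(draw %in% c(1L, 2L)),
       b = as.integer(draw %in% c(1L, 3L)),
       p11 = p11, p10 = p10, p01 = p01, p00 = p00)
}

# unique admissible root of the 2x2 joint-positive cell quadratic
joint_positive_cell <- function(p_a, p_b, odds_ratio) {
  if (abs(odds_ratio - 1) < 1e-12) return(p_a * p_b)
  a <- odds_ratio - 1
  b <- -((odds_ratio - 1) * (p_a + p_b) + 1)
  c0 <- odds_ratio * p_a * p_b
  disc <- b^2 - 4 * a * c0
  if (disc < 0) {
    stop("no admissible joint distribution for the requested marginals and odds ratio",
         call. = FALSE)
  }
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
  if (!any(ok)) {
    stop("no admissible joint distribution for the requested marginals and odds ratio",
         call. = FALSE)
  }
  min(max(roots[ok][1], lo), hi)
}

# study-window length b such that exponential(rate) survival censored by
# Uniform(0, b) yields the target censoring fraction:
# P(C < T) = E[exp(-rate * C)] = (1 - exp(-rate*b)) / (rate*b)
censoring_window <- function(rate, target) {
  if (target <= 0) return(Inf)
  f <- function(b) (1 - exp(-rate * b)) / (rate * b) - target
  stats::uniroot(f, lower = 1e-8 / rate, upper = 1e9 / rate,
                 tol = 1e-10 / rate)$root
}

#' Write a simulated cohort to disk in the package's file dialects
#'
#' One GISTIC TSV per cancer, a pooled expression TSV plus annotation TSV, a
#' clinical TSV, an edge-list TSV and a `truth.json` ground-truth summary.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cancer in names(cohort$gistic)) {
    write_gistic_matrix(cohort$gistic[[cancer]],
                        file.path(dir, paste0("gistic_", cancer, ".tsv")))
  }
  write_expression_matrix(cohort$expression,
                          file.path(dir, "expression.tsv"),
                          file.path(dir, "annotations.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_edge_list(cohort$edges, file.path(dir, "edges.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
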