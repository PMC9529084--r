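make_tumour_expr <- function(values) {
  ids <- sprintf("T%03d", seq_len(ncol(values)))
  colnames(values) <- ids
  expression_matrix(values,
                    data.frame(sample = ids, cancer_type = "BRCA",
                               sample_type = "tumour"))
}

test_that("Spearman correlation handles monotone, identity and degenerate cases", {
  set.seed(501)
  n <- 30
  anchor <- sort(abs(rnorm(n, 5, 2)))
  vals <- rbind(ANCHOR = anchor,
                MONO = anchor^2 + 1,          # strictly increasing transform
                CONST = rep(4, n))
  expr <- make_tumour_expr(vals)
  res <- spearman_anchor(expr, "ANCHOR", c("MONO", "ANCHOR", "CONST"))
  expect_equal(res$rho[res$gene == "MONO"], 1)
  expect_equal(res$rho[res$gene == "ANCHOR"], 1)
  expect_lt(res$p_value[res$gene == "ANCHOR"], 1e-6)
  expect_false(res$evaluable[res$gene == "CONST"])
})

test_that("Spearman rho equals the exhaustive rank formula on small vectors", {
  set.seed(502)
  for (rep in 1:20) {
    x <- sample(100, 6)   # distinct values, classical formula applies
    y <- sample(100, 6)
    vals <- rbind(ANCHOR = x, GENE = y, PAD1 = runif(6), PAD2 = runif(6))
    expr <- make_tumour_expr(vals)
    res <- spearman_anchor(expr, "ANCHOR", "GENE")
    expect_equal(res$rho, spearman_oracle(x, y), tolerance = 1e-9)
  }
})

test_that("stage ANOVA reproduces its closed-form identities", {
  clin <- clinical_table(data.frame(
    sample = sprintf("T%03d", 1:6), cancer_type = "BRCA",
    time_days = 100, event = 0,
    stage = rep(c("I", "II"), each = 3)))
  # equal group values: F = 0, p = 1
  expr <- make_tumour_expr(matrix(rep(c(1, 2, 3), 2), 1, 6,
                                  dimnames = list("G1", NULL)))
  res <- stage_anova(expr, "G1", clin)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(503)
  v <- rnorm(6, mean = rep(c(0, 2), each = 3))
  expr <- make_tumour_expr(matrix(pmax(v, 0), 1, 6,
                                  dimnames = list("G1", NULL)))
  res <- stage_anova(expr, "G1", clin)
  tt <- t.test(expr$values[1, 1:3], expr$values[1, 4:6], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)

  # single usable group is an error
  clin1 <- clinical_table(data.frame(
    sample = sprintf("T%03d", 1:6), cancer_type = "BRCA",
    time_days = 100, event = 0, stage = c(rep("I", 5), "II")))
  expect_error(stage_anova(expr, "G1", clin1), ">= 2 stage groups")
})

test_that("a planted per-stage trend is detected with high power", {
  detected <- vapply(1:40, function(seed) {
    set.seed(600 + seed)
    stage <- rep(c("I", "II", "III", "IV"), each = 30)
    v <- pmax(5 + 0.5 * (match(stage, c("I", "II", "III", "IV")) - 1) +
                rnorm(120, sd = 0.8), 0)
    expr <- make_tumour_expr(matrix(v, 1, 120, dimnames = list("G1", NULL)))
    clin <- clinical_table(data.frame(
      sample = colnames(expr$values), cancer_type = "BRCA",
      time_days = 100, event = 0, stage = stage))
    stage_anova(expr, "G1", clin)$p < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("co-occurrence statistics follow the stated continuity correction", {
  # perfectly balanced independence table
  a <- rep(c(1, 1, 0, 0), each = 25)
  b <- rep(c(1, 0, 1, 0), each = 25)
  res <- cooccurrence_test(a, b)
  expect_equal(res$log2_odds_ratio, 0)
  expect_equal(res$p_value, 1)
  expect_identical(c(res$both_altered, res$a_only, res$b_only, res$neither),
                   c(25L, 25L, 25L, 25L))

  # zero cells: Haldane-Anscombe correction keeps the log2 OR finite
  a <- rep(c(1, 0), each = 10)
  res <- cooccurrence_test(a, a)
  expect_equal(res$log2_odds_ratio, log2((10.5 * 10.5) / (0.5 * 0.5)),
               tolerance = 1e-12)
  expect_true(is.finite(res$log2_odds_ratio))
})

test_that("co-occurrence test is symmetric and matches the enumeration oracle", {
  set.seed(504)
  for (rep in 1:30) {
    n <- sample(10:40, 1)
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    b <- rbinom(n, 1, runif(1, 0.2, 0.8))
    res <- cooccurrence_test(a, b)
    expect_equal(res$p_value,
                 fisher_oracle(res$both_altered, res$a_only, res$b_only,
                               res$neither),
                 tolerance = 1e-9)
    # symmetry in the two genes
    swapped <- cooccurrence_test(b, a)
    expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
    expect_equal(swapped$log2_odds_ratio, res$log2_odds_ratio,
                 tolerance = 1e-12)
  }
})

test_that("hub ranking follows degree within the candidate-induced subgraph", {
  star <- edge_list(data.frame(node_a = "HUB",
                               node_b = paste0("L", 1:5),
                               confidence = 0.9))
  hubs <- hub_rank(star, c("HUB", paste0("L", 1:5), "ISOLATED"), 1)
  expect_identical(hubs$node[1], "HUB")
  expect_identical(hubs$degree[1], 5L)
  expect_identical(hubs$rank[1], 1L)
  expect_false("ISOLATED" %in% hubs$node)
  expect_true(all(hubs$degree[-1] == 1L))

  # degrees equal a brute-force adjacency recount on random graphs
  set.seed(505)
  for (rep in 1:10) {
    nodes <- sprintf("N%02d", 1:30)
    pairs <- t(combn(nodes, 2))
    pick <- sample(nrow(pairs), 60)
    net <- edge_list(data.frame(node_a = pairs[pick, 1],
                                node_b = pairs[pick, 2],
                                confidence = runif(60, 0.4, 1)))
    candidates <- sample(nodes, 20)
    hubs <- hub_rank(net, candidates, 0)
    oracle <- degree_oracle(net, candidates)
    expect_identical(setNames(hubs$degree, hubs$node)[candidates],
                     setNames(as.integer(oracle), candidates))
  }
})

test_that("the four-criteria intersection is an exact set conjunction", {
  res <- criteria_intersect(c("A", "B"), c("A", "B"), c("A", "B"),
                            c("A", "B"))
  expect_identical(res$genes, c("A", "B"))

  res <- criteria_intersect(c("A", "B"), character(0), c("A"), c("A"))
  expect_identical(res$genes, character(0))

  set.seed(506)
  for (rep in 1:15) {
    sets <- replicate(4, sample(LETTERS[1:8], sample(2:6, 1)),
                      simplify = FALSE)
    res <- criteria_intersect(sets[[1]], sets[[2]], sets[[3]], sets[[4]])
    expected <- sort(Reduce(intersect, sets))
    expect_identical(res$genes, expected)
    # audit flags are faithful
    for (g in res$audit$gene) {
      expect_identical(res$audit$survival[res$audit$gene == g],
                       g %in% sets[[1]])
    }
  }
})

test_that("alteration calls respect the deep/any distinction and mutations", {
  calls <- c(-2L, -1L, 0L, 1L, 2L)
  expect_identical(alteration_calls(calls, "deep"), c(1L, 0L, 0L, 0L, 1L))
  expect_identical(alteration_calls(calls, "any"), c(1L, 1L, 0L, 1L, 1L))
  expect_identical(alteration_calls(calls, "deep",
                                    mutated = c(FALSE, TRUE, FALSE, FALSE,
                                                FALSE)),
                   c(1L, 1L, 0L, 0L, 1L))
})

test_that("hub ranking recovers the simulator's planted driver clique", {
  drivers <- data.frame(
    gene = sprintf("G%04d", 1:6), cancers = "all",
    amp_prob = 0.2, del_prob = 0, expression_shift = 1,
    cna_coupling = 0.3, log_hazard_ratio = 0, stage_trend = 0)
  recovered <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_cancers = 1, n_tumour = 20, n_normal = 5,
                      n_genes = 40, drivers = drivers,
                      n_background_edges = 10, seed = 700 + seed)
    cohort <- simulate_cohort(cfg)
    hubs <- hub_rank(cohort$edges, cfg$genes, 1)
    clique <- drivers$gene
    clique_min <- min(hubs$degree[hubs$node %in% clique])
    background_max <- max(c(0L, hubs$degree[!hubs$node %in% clique]))
    all(clique %in% hubs$node) && clique_min > background_max
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})
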