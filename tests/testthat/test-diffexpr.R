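make_expr <- function(tum, nor, cancer = "BRCA") {
  genes <- rownames(tum)
  tum_ids <- sprintf("T%03d", seq_len(ncol(tum)))
  nor_ids <- sprintf("N%03d", seq_len(ncol(nor)))
  colnames(tum) <- tum_ids; colnames(nor) <- nor_ids
  ann <- data.frame(sample = c(tum_ids, nor_ids), cancer_type = cancer,
                    sample_type = rep(c("tumour", "normal"),
                                      c(ncol(tum), ncol(nor))))
  expression_matrix(cbind(tum, nor), ann)
}

test_that("a planted log2 shift is called up with high confidence", {
  set.seed(201)
  genes <- c("SHIFTED", "FLAT")
  tum <- matrix(rnorm(60, mean = 5, sd = 0.5), 2, 30,
                dimnames = list(genes, NULL))
  nor <- matrix(rnorm(60, mean = 5, sd = 0.5), 2, 30,
                dimnames = list(genes, NULL))
  tum["SHIFTED", ] <- tum["SHIFTED", ] + 1.5
  deg <- tumour_vs_normal(make_expr(tum, nor), "BRCA")
  expect_identical(deg$direction[deg$gene == "SHIFTED"], "up")
  expect_lt(deg$p_value[deg$gene == "SHIFTED"], 0.001)
  expect_identical(deg$direction[deg$gene == "FLAT"], "none")
})

test_that("identical constant groups give zero fold change and p = 1", {
  tum <- matrix(3, 1, 5, dimnames = list("G1", NULL))
  nor <- matrix(3, 1, 5, dimnames = list("G1", NULL))
  deg <- tumour_vs_normal(make_expr(tum, nor), "BRCA")
  expect_equal(deg$log2_fold_change, 0)
  expect_equal(deg$p_value, 1)
  expect_identical(deg$direction, "none")
})

test_that("group swap negates every fold change and mirrors the calls", {
  set.seed(202)
  tum <- matrix(abs(rnorm(200, 5, 2)), 10, 20,
                dimnames = list(sprintf("G%02d", 1:10), NULL))
  nor <- matrix(abs(rnorm(100, 5, 2)), 10, 10,
                dimnames = list(sprintf("G%02d", 1:10), NULL))
  fwd <- tumour_vs_normal(make_expr(tum, nor), "BRCA")
  rev <- tumour_vs_normal(make_expr(nor, tum), "BRCA")
  expect_equal(rev$log2_fold_change, -fwd$log2_fold_change)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
  expect_identical(rev$direction[fwd$direction == "up"],
                   rep("down", sum(fwd$direction == "up")))
  expect_identical(rev$direction[fwd$direction == "down"],
                   rep("up", sum(fwd$direction == "down")))
})

test_that("fewer than two samples in a group is an error", {
  tum <- matrix(1:2, 1, 2, dimnames = list("G1", NULL))
  nor <- matrix(1, 1, 1, dimnames = list("G1", NULL))
  expect_error(tumour_vs_normal(make_expr(tum, nor), "BRCA"), ">= 2")
})

test_that("direction is a pure function of fold change, p and thresholds", {
  set.seed(203)
  for (rep in 1:200) {
    lfc <- runif(1, -3, 3)
    p <- runif(1)
    dir <- matriscreen:::deg_direction(lfc, p, 2, 0.05)
    expected <- if (lfc >= 1 && p <= 0.05) "up"
      else if (lfc <= -1 && p <= 0.05) "down" else "none"
    expect_identical(dir, expected)
  }
})

test_that("the concordance filter keeps exactly the direction-consistent genes", {
  shortlist <- data.frame(
    gene = c("A", "B", "C", "D"),
    direction = c("amplified", "amplified", "deleted", "deleted"),
    count = c(10L, 8L, 6L, 4L), n_samples = 100L, source = "pan")
  deg <- data.frame(
    gene = c("A", "B", "C", "D"),
    mean_high = 0, mean_low = 0,
    log2_fold_change = c(1.5, -2.0, -1.2, 0.1),
    p_value = c(0.01, 0.001, 0.02, 0.5), fdr = NA,
    direction = c("up", "down", "down", "none"))
  kept <- concordance_filter(shortlist, deg)
  expect_setequal(kept$gene, c("A", "C"))  # B discordant, D no change

  # genes missing from the DEG table are dropped with a warning
  expect_warning(kept <- concordance_filter(
    rbind(shortlist,
          data.frame(gene = "E", direction = "amplified", count = 2L,
                     n_samples = 100L, source = "pan")), deg), "E")
  expect_false("E" %in% kept$gene)
})

test_that("concordance filtering equals a brute-force rule evaluation on fuzzed inputs", {
  set.seed(204)
  for (rep in 1:20) {
    n <- 30
    shortlist <- data.frame(
      gene = sprintf("G%02d", 1:n),
      direction = sample(c("amplified", "deleted"), n, TRUE),
      count = sample(1:20, n, TRUE), n_samples = 100L, source = "pan")
    deg <- data.frame(
      gene = sprintf("G%02d", 1:n), mean_high = 0, mean_low = 0,
      log2_fold_change = runif(n, -3, 3), p_value = runif(n), fdr = NA,
      direction = sample(c("up", "down", "none"), n, TRUE))
    kept <- concordance_filter(shortlist, deg)
    expected <- character(0)
    for (i in 1:n) {
      d <- deg$direction[deg$gene == shortlist$gene[i]]
      if ((shortlist$direction[i] == "amplified" && d == "up") ||
          (shortlist$direction[i] == "deleted" && d == "down")) {
        expected <- c(expected, shortlist$gene[i])
      }
    }
    expect_setequal(kept$gene, expected)
  }
})

test_that("anchor stratification recovers co-regulated genes and excludes the anchor", {
  set.seed(205)
  n <- 80
  factor_score <- rnorm(n)
  anchor <- 5 + 1.5 * factor_score + rnorm(n, sd = 0.3)
  partner <- 5 + 1.5 * factor_score + rnorm(n, sd = 0.3)
  noise <- rnorm(n, 5, 0.5)
  tum <- rbind(ANCHOR = anchor, PARTNER = partner, NOISE = noise)
  tum <- pmax(tum, 0)
  nor <- matrix(5, 3, 4, dimnames = list(rownames(tum), NULL))
  expr <- make_expr(tum, nor)
  deg <- anchor_stratified_deg(expr, "ANCHOR", "BRCA")
  expect_false("ANCHOR" %in% deg$gene)
  expect_identical(deg$direction[deg$gene == "PARTNER"], "up")
  expect_identical(deg$direction[deg$gene == "NOISE"], "none")

  const <- tum; const["ANCHOR", ] <- 5
  expect_error(anchor_stratified_deg(make_expr(const, nor), "ANCHOR",
                                     "BRCA"), "constant|fewer")
})

test_that("top-fraction DEG selection equals a brute-force sort-and-cut", {
  set.seed(206)
  for (rep in 1:20) {
    n <- 50
    deg <- data.frame(gene = sprintf("G%02d", 1:n),
                      mean_high = 0, mean_low = 0,
                      log2_fold_change = round(runif(n, -4, 4), 1),
                      p_value = runif(n, 0, 0.1), fdr = NA)
    deg$direction <- matriscreen:::deg_direction(deg$log2_fold_change,
                                                 deg$p_value, 2, 0.05)
    sel <- top_fraction_deg(deg, 0.1)

    up <- deg[deg$direction == "up", ]
    expected_up <- character(0)
    if (nrow(up)) {
      k <- ceiling(0.1 * nrow(up))
      cut <- sort(up$log2_fold_change, decreasing = TRUE)[k]
      expected_up <- up$gene[up$log2_fold_change >= cut]
    }
    expect_setequal(sel$up, expected_up)

    dn <- deg[deg$direction == "down", ]
    expected_dn <- character(0)
    if (nrow(dn)) {
      k <- ceiling(0.1 * nrow(dn))
      cut <- sort(dn$log2_fold_change)[k]
      expected_dn <- dn$gene[dn$log2_fold_change <= cut]
    }
    expect_setequal(sel$down, expected_dn)
  }
  expect_identical(top_fraction_deg(
    data.frame(gene = "A", mean_high = 0, mean_low = 0,
               log2_fold_change = 0.1, p_value = 0.5, fdr = NA,
               direction = "none"), 0.05)$up, character(0))
})

test_that("cross-cancer overlap counts set membership correctly", {
  expect_identical(nrow(cross_cancer_overlap(
    list(c("A"), c("B"), c("C"), c("D")), 3)), 0L)

  ov <- cross_cancer_overlap(list(c("A", "B"), c("A", "C"), "A", "B"), 3)
  expect_identical(ov$gene, "A")
  expect_identical(ov$n_cancers, 3L)

  # brute-force membership count on fuzzed sets
  set.seed(207)
  for (rep in 1:10) {
    sets <- replicate(6, sample(LETTERS[1:10], sample(3:8, 1)),
                      simplify = FALSE)
    ov <- cross_cancer_overlap(sets, 3)
    for (g in LETTERS[1:10]) {
      n <- sum(vapply(sets, function(s) g %in% s, logical(1)))
      expect_identical(g %in% ov$gene, n >= 3)
      if (n >= 3) expect_identical(ov$n_cancers[ov$gene == g], n)
    }
  }
})
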