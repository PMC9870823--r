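test_that("exact rank-sum p-values match full enumeration on the worked case", {
  # x entirely below y: most extreme of the C(6,3)=20 orderings, p = 2/20
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$method, "exact")
  expect_equal(w$statistic, 6)
  expect_equal(w$p_value, 0.1)
  expect_equal(oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)
})

test_that("degenerate comparisons return p = 1 and are flagged", {
  w <- wilcoxon_rank_sum(1, 1)
  expect_true(w$degenerate)
  expect_equal(w$p_value, 1)
  w2 <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2))
  expect_true(w2$degenerate)
  expect_equal(w2$p_value, 1)
})

test_that("exact path equals exhaustive permutation enumeration on random cases", {
  set.seed(55)
  for (i in 1:100) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    vals <- sample(1000L, nx + ny)   # no ties by construction
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    w <- wilcoxon_rank_sum(x, y)
    expect_equal(w$method, "exact")
    expect_equal(w$p_value, oracle_wilcoxon_exact(x, y))
    # independent cross-check against the reference implementation
    expect_equal(w$p_value, stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("ties fall through to the tie-corrected normal approximation", {
  x <- c(0.1, 0.2, 0.2, 0.5); y <- c(0.2, 0.6, 0.7)
  w <- wilcoxon_rank_sum(x, y)
  expect_equal(w$method, "normal_approx")
  expect_true(w$ties)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Bonferroni adjustment is the capped product and dominates raw p", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(c(0.1, 0.2), 1), "n_tests")
  expect_error(bonferroni(0), "0, 1")
  set.seed(2)
  p <- runif(20, 1e-6, 1)
  adj <- bonferroni(p, 25)
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), seq_len(20))  # monotone in p
})

test_that("per-patient frequencies use patient-level denominators, missing not zero", {
  cell_table <- data.frame(
    cell_id = sprintf("c%02d", 1:30),
    patient = rep(c("P1", "P2"), each = 15L),
    lineage = "CD8",
    expanded = c(rep(TRUE, 10), rep(FALSE, 5), rep(FALSE, 15)))
  feats <- data.frame(cell_id = cell_table$cell_id,
                      CD57 = c(rep(c(TRUE, FALSE), c(4, 6)),
                               rep(FALSE, 5), rep(TRUE, 15)))
  fr <- per_patient_marker_freq(cell_table, feats)
  get <- function(p, g) fr$frequency[fr$patient == p & fr$group == g &
                                       fr$feature == "CD57"]
  expect_equal(get("P1", "expanded"), 0.4)
  expect_equal(get("P1", "non_expanded"), 0)
  expect_true(is.na(get("P2", "expanded")))   # no expanded cells: missing
  expect_equal(get("P2", "non_expanded"), 1)
  # compartment filter: CD4 cells never enter
  cell_table$lineage[1:5] <- "CD4"
  fr2 <- per_patient_marker_freq(cell_table, feats)
  expect_equal(fr2$denominator[fr2$patient == "P1" &
                                 fr2$group == "expanded"], 5L)
})

test_that("group comparison assembles tests, adjustment and exclusions", {
  set.seed(10)
  rows <- list()
  for (p in sprintf("P%d", 1:9)) {
    rows[[length(rows) + 1L]] <- data.frame(
      patient = p, group = c("expanded", "non_expanded"),
      feature = "CD57",
      numerator = NA, denominator = 10,
      frequency = c(runif(1, 0.5, 0.9), runif(1, 0.0, 0.2)))
    rows[[length(rows) + 1L]] <- data.frame(
      patient = p, group = c("expanded", "non_expanded"),
      feature = "PD1",
      numerator = NA, denominator = 10,
      frequency = runif(2, 0.1, 0.2))
  }
  fr <- do.call(rbind, rows)
  cmp <- compare_groups(fr, n_tests = 13)
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$n_tests, c(13, 13))
  cd57 <- cmp[cmp$feature == "CD57", ]
  expect_equal(cd57$p_adjusted, min(1, 13 * cd57$p_raw))
  expect_true(cd57$significant)
  expect_false(cmp$significant[cmp$feature == "PD1"])
})

test_that("PCA satisfies orthonormality, completeness and reconstruction", {
  set.seed(7)
  n <- 150L
  cell_table <- data.frame(cell_id = sprintf("c%03d", 1:n),
                           M1 = rlnorm(n, 5, 1), M2 = rlnorm(n, 4, 0.5),
                           M3 = rlnorm(n, 6, 0.8),
                           diff_state = sample(c("N", "CM", "EM", "E"), n,
                                               replace = TRUE))
  pca <- run_pca(cell_table, markers = c("M1", "M2", "M3"))
  L <- pca$loadings
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-8)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  # round trip: scores %*% t(loadings) reconstructs the scaled matrix
  raw <- asinh(as.matrix(cell_table[, c("M1", "M2", "M3")]) / pca$cofactor)
  ind <- sapply(c("N", "CM", "EM", "E"),
                function(s) as.numeric(cell_table$diff_state == s))
  colnames(ind) <- paste0("state_", c("N", "CM", "EM", "E"))
  scaled <- scale(cbind(raw, ind)[, pca$features], center = pca$center,
                  scale = pca$scale)
  expect_lt(max(abs(pca$scores %*% t(L) - scaled)), 1e-8)
})

test_that("rank-1 data put all variance on component 1; constants are dropped", {
  n <- 60L
  base <- asinh(seq_len(n) / 150)   # collinear in transformed feature space
  cell_table <- data.frame(cell_id = sprintf("c%03d", 1:n),
                           M1 = 150 * sinh(base),
                           M2 = 150 * sinh(2 * base),
                           M3 = 150 * sinh(0.5 * base),
                           FLAT = 1)
  expect_warning(
    pca <- run_pca(cell_table, markers = c("M1", "M2", "M3", "FLAT"),
                   state_encoding = "none"),
    "zero-variance")
  expect_equal(pca$dropped, "FLAT")
  expect_equal(pca$var_explained[1], 1, tolerance = 1e-8)
})

test_that("cohort summary equals an independent recount of the truth", {
  truth <- generate_cohort(small_config())
  tc <- truth$cells
  ct <- assign_clonotypes(truth_chain_table(truth))
  cs <- clone_statistics(ct, tc)
  summ <- summarize_cohort(
    data.frame(cell_id = tc$cell_id, patient = tc$patient,
               lineage = tc$lineage, diff_state = tc$diff_state),
    cs)
  # recount directly from ground truth
  expect_equal(summ$totals$n_cells, nrow(tc))
  expect_equal(summ$totals$median_cells_per_patient,
               stats::median(as.integer(table(tc$patient))))
  expect_equal(summ$totals$n_expanded_clones, nrow(truth$clones))
  per_pt <- as.integer(table(factor(truth$clones$patient,
                                    levels = sort(unique(tc$patient)))))
  expect_equal(summ$totals$median_clones_per_patient,
               stats::median(per_pt))
  expect_equal(summ$totals$range_clones_per_patient, range(per_pt))
  expect_equal(summ$totals$pct_expanded_clones_cd8,
               100 * mean(truth$clones$lineage == "CD8"))
  p1 <- summ$per_patient[1, ]
  sel <- tc$patient == p1$patient
  expect_equal(p1$frac_cd8, mean(tc$lineage[sel] == "CD8"))
  expect_equal(p1$frac_N, mean(tc$diff_state[sel] == "N"))
})

test_that("simple median examples", {
  cell_table <- data.frame(cell_id = as.character(1:60),
                           patient = rep(c("A", "B", "C"), c(10, 20, 30)),
                           lineage = "CD8", diff_state = "N")
  ct <- assign_clonotypes(data.frame(
    cell_id = cell_table$cell_id, patient = cell_table$patient,
    beta_aa = paste0("B", 1:60), alpha1_aa = paste0("A", 1:60),
    alpha2_aa = NA_character_))
  summ <- summarize_cohort(cell_table, clone_statistics(ct, cell_table))
  expect_equal(summ$totals$n_cells, 60L)
  expect_equal(summ$totals$median_cells_per_patient, 20L)
})
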