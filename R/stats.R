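# Comparative statistics: per-patient frequencies, exact Wilcoxon rank-sum,
# Bonferroni correction, PCA of phenotypes, cohort summaries.
#
# The test unit is the patient: frequencies of positive cells are computed
# per patient within expanded and non-expanded compartments, and the
# two-sample comparison runs on those per-patient values. Cell-level
# testing is deliberately not offered (cells of one patient are not
# independent; testing them inflates significance).

#' Per-patient marker/state/gene frequencies by expansion group
#'
#' For each patient and feature, the fraction of positive cells among
#' expanded-clone members and among non-expanded cells, within the chosen
#' compartment (CD8+ by default). A patient with an empty group yields a
#' missing record (excluded from that feature's test), never a zero.
#'
#' @param cell_table data.frame with `cell_id`, `patient`, `lineage`, and
#'   `expanded` (logical: member of an expanded clonotype).
#' @param features data.frame `cell_id` + logical feature columns (marker
#'   positivity, differentiation-state indicators, or gene calls).
#' @param compartment lineage filter (default "CD8"; NULL for all cells).
#' @return data.frame: `patient`, `group` (expanded | non_expanded),
#'   `feature`, `numerator`, `denominator`, `frequency`.
#' @export
per_patient_marker_freq <- function(cell_table, features,
                                    compartment = "CD8") {
  ct <- cell_table
  if (!is.null(compartment)) {
    ct <- ct[!is.na(ct$lineage) & ct$lineage == compartment, , drop = FALSE]
  }
  fcols <- setdiff(names(features), "cell_id")
  fi <- match(ct$cell_id, features$cell_id)
  rows <- list()
  for (p in unique(ct$patient)) {
    for (g in c("expanded", "non_expanded")) {
      sel <- ct$patient == p &
        (if (g == "expanded") ct$expanded else !ct$expanded)
      idx <- fi[which(sel)]
      idx <- idx[!is.na(idx)]
      for (f in fcols) {
        vals <- features[[f]][idx]
        vals <- vals[!is.na(vals)]
        d <- length(vals)
        rows[[length(rows) + 1L]] <- data.frame(
          patient = p, group = g, feature = f,
          numerator = if (d > 0L) sum(vals) else NA_integer_,
          denominator = d,
          frequency = if (d > 0L) sum(vals) / d else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exact null distribution of the rank-sum W of the smaller-indexed group:
# number of ways to choose nx of ranks 1..N summing to each value
ranksum_null_counts <- function(nx, N) {
  maxs <- sum((N - nx + 1L):N)
  # counts[k + 1, s + 1] = ways to pick k distinct ranks from those seen so
  # far with sum s
  counts <- matrix(0, nx + 1L, maxs + 1L)
  counts[1L, 1L] <- 1
  for (r in seq_len(N)) {
    kmax <- min(r, nx)
    for (k in kmax:1L) {
      smax <- maxs - r
      counts[k + 1L, (r + 1L):(maxs + 1L)] <-
        counts[k + 1L, (r + 1L):(maxs + 1L)] +
        counts[k, 1L:(smax + 1L)]
    }
  }
  counts[nx + 1L, ]
}

#' Two-sided Wilcoxon rank-sum test
#'
#' The statistic is the rank sum W of `x` in the pooled sample. With no
#' ties and both group sizes at most `exact_max`, the two-sided p-value is
#' computed by exact enumeration of the null distribution of W over all
#' choose(nx+ny, nx) rank assignments (p = 2 * min tail, capped at 1).
#' Otherwise mid-ranks with the tie-corrected normal approximation and
#' continuity correction are used. If every pooled value is identical the
#' comparison is degenerate and p = 1 by convention.
#'
#' @param x,y numeric vectors (finite, length >= 1).
#' @param mode "exact_if_small" (default), "exact" (refuses ties by falling
#'   through to the approximation, flagged), or "approx".
#' @param exact_max largest per-group size for the exact path (default 10).
#' @return list: `statistic` (rank sum of x), `p_value`, `method`
#'   ("exact" | "normal_approx"), `ties`, `degenerate`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("exact_if_small", "exact",
                                             "approx"),
                              exact_max = 10L) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L || !all(is.finite(c(x, y)))) {
    stop("x and y must be non-empty and finite")
  }
  pooled <- c(x, y)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(pooled) > 0L
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = W, p_value = 1, method = "degenerate",
                ties = TRUE, degenerate = TRUE))
  }
  use_exact <- switch(mode,
                      approx = FALSE,
                      exact = !ties,
                      exact_if_small = !ties && max(nx, ny) <= exact_max)
  if (use_exact) {
    cnt <- ranksum_null_counts(nx, N)
    total <- sum(cnt)
    lo <- sum(cnt[seq_len(W + 1L)])           # P(W <= w), sums are 0-indexed
    hi <- sum(cnt[(W + 1L):length(cnt)])      # P(W >= w)
    p <- min(1, 2 * min(lo, hi) / total)
    return(list(statistic = W, p_value = p, method = "exact", ties = FALSE,
                degenerate = FALSE))
  }
  # mid-rank normal approximation with tie correction + continuity correction
  mu <- nx * (N + 1) / 2
  tie_tab <- table(pooled)
  sig2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sig2 <= 0) {
    return(list(statistic = W, p_value = 1, method = "degenerate",
                ties = ties, degenerate = TRUE))
  }
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = W, p_value = p, method = "normal_approx", ties = ties,
       degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p p-values in (0, 1].
#' @param n_tests family size; must be at least `length(p)`.
#' @return adjusted p-values `pmin(1, n_tests * p)`.
#' @export
bonferroni <- function(p, n_tests = length(p)) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  if (n_tests < length(p)) stop("n_tests must be >= number of p-values")
  pmin(1, n_tests * p)
}

#' Compare expanded vs non-expanded per-patient frequencies across features
#'
#' One Wilcoxon rank-sum test per feature on the per-patient frequency
#' vectors, Bonferroni-corrected within the family. Patients missing either
#' group for a feature are excluded from that feature's test and counted.
#'
#' @param freq output of [per_patient_marker_freq()].
#' @param n_tests Bonferroni family size (default: number of features in
#'   `freq`). Made explicit because the family definition changes the
#'   correction.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param paired use the same-patient pairing (signed-rank style exclusion
#'   is NOT applied; the unpaired rank-sum test is the default, matching
#'   the named test).
#' @return data.frame (class `comparison_result`): `feature`,
#'   `n_expanded`, `n_non_expanded`, `n_excluded_patients`,
#'   `median_expanded`, `median_non_expanded`, `statistic`, `method`,
#'   `p_raw`, `p_adjusted`, `n_tests`, `significant`.
#' @export
compare_groups <- function(freq, n_tests = NULL, alpha = 0.05,
                           paired = FALSE) {
  feats <- unique(freq$feature)
  if (is.null(n_tests)) n_tests <- length(feats)
  rows <- list()
  for (f in feats) {
    sub <- freq[freq$feature == f, , drop = FALSE]
    wide <- merge(
      sub[sub$group == "expanded", c("patient", "frequency")],
      sub[sub$group == "non_expanded", c("patient", "frequency")],
      by = "patient", suffixes = c("_ex", "_ne"), all = TRUE)
    complete <- !is.na(wide$frequency_ex) & !is.na(wide$frequency_ne)
    x <- wide$frequency_ex[if (paired) complete else
      !is.na(wide$frequency_ex)]
    y <- wide$frequency_ne[if (paired) complete else
      !is.na(wide$frequency_ne)]
    excl <- sum(!complete)
    if (length(x) == 0L || length(y) == 0L) {
      rows[[f]] <- data.frame(feature = f, n_expanded = length(x),
                              n_non_expanded = length(y),
                              n_excluded_patients = excl,
                              median_expanded = NA_real_,
                              median_non_expanded = NA_real_,
                              statistic = NA_real_, method = "not_testable",
                              p_raw = NA_real_, p_adjusted = NA_real_,
                              n_tests = n_tests, significant = FALSE)
      next
    }
    w <- wilcoxon_rank_sum(x, y)
    rows[[f]] <- data.frame(feature = f, n_expanded = length(x),
                            n_non_expanded = length(y),
                            n_excluded_patients = excl,
                            median_expanded = stats::median(x),
                            median_non_expanded = stats::median(y),
                            statistic = w$statistic, method = w$method,
                            p_raw = w$p_value, p_adjusted = NA_real_,
                            n_tests = n_tests, significant = FALSE)
  }
  out <- do.call(rbind, rows)
  testable <- !is.na(out$p_raw)
  out$p_adjusted[testable] <- bonferroni(out$p_raw[testable], n_tests)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Principal component analysis of per-cell phenotypes
#'
#' Marker intensities are arcsinh-transformed (`asinh(x / cofactor)`, flow
#' cytometry convention), differentiation state is encoded as four 0/1
#' indicator features (or one ordinal feature), then every feature is
#' centered and scaled to unit variance and decomposed by singular values.
#' Zero-variance features are dropped with a warning and recorded.
#'
#' @param cell_table data.frame with `cell_id`, marker intensity columns,
#'   and optionally `diff_state`.
#' @param markers marker column names to include.
#' @param cofactor arcsinh cofactor (default 150).
#' @param state_encoding "indicator" (default), "ordinal" (N < CM < EM < E),
#'   or "none".
#' @return object of class `phenotype_pca`: `scores`, `loadings`
#'   (orthonormal columns), `sdev`, `var_explained`, `center`, `scale`,
#'   `features`, `dropped`, `cofactor`, `cell_id`.
#' @export
run_pca <- function(cell_table, markers, cofactor = 150,
                    state_encoding = c("indicator", "ordinal", "none")) {
  state_encoding <- match.arg(state_encoding)
  missing <- setdiff(markers, names(cell_table))
  if (length(missing) > 0L) {
    stop("marker column(s) absent: ", paste(missing, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(cell_table))
  mat <- asinh(as.matrix(cell_table[, markers, drop = FALSE]) / cofactor)
  colnames(mat) <- markers
  if (state_encoding != "none" && "diff_state" %in% names(cell_table)) {
    st <- cell_table$diff_state
    keep <- keep & !is.na(st)
    if (state_encoding == "indicator") {
      for (s in c("N", "CM", "EM", "E")) {
        mat <- cbind(mat, as.numeric(st == s))
        colnames(mat)[ncol(mat)] <- paste0("state_", s)
      }
    } else {
      mat <- cbind(mat, state_ord = match(st, c("N", "CM", "EM", "E")))
    }
  }
  keep <- keep & stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2L) stop("need at least 2 complete cells for PCA")
  v <- apply(mat, 2L, stats::var)
  dropped <- colnames(mat)[v == 0]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    mat <- mat[, v > 0, drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("need at least 2 non-constant features for PCA")
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  out <- list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
              var_explained = pc$sdev^2 / sum(pc$sdev^2),
              center = pc$center, scale = pc$scale,
              features = colnames(mat), dropped = dropped,
              cofactor = cofactor, cell_id = cell_table$cell_id[keep])
  class(out) <- "phenotype_pca"
  out
}

#' @export
print.phenotype_pca <- function(x, ...) {
  cat("Phenotype PCA:", length(x$cell_id), "cells,", length(x$features),
      "features\n")
  ve <- utils::head(x$var_explained, 3)
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cohort-level summary
#'
#' @param cell_table merged cell table with `patient`, `lineage`,
#'   `diff_state`, `expanded`.
#' @param clone_stats output of [clone_statistics()].
#' @return list of class `cohort_summary`: `totals` (cells, patients,
#'   median cells/patient; expanded clones with median and range; percent
#'   of expanded clones CD8), `clone_sizes` (size frequency table),
#'   `per_patient` (cells, CD4/CD8 fractions, differentiation fractions).
#' @export
summarize_cohort <- function(cell_table, clone_stats) {
  pts <- sort(unique(cell_table$patient))
  cells_per_patient <- vapply(pts, function(p)
    sum(cell_table$patient == p), integer(1))
  ex <- clone_stats$clonotypes[clone_stats$clonotypes$expanded, ,
                               drop = FALSE]
  clones_per_patient <- vapply(pts, function(p) sum(ex$patient == p),
                               integer(1))
  totals <- list(
    n_patients = length(pts),
    n_cells = nrow(cell_table),
    median_cells_per_patient = stats::median(cells_per_patient),
    n_expanded_clones = nrow(ex),
    median_clones_per_patient = stats::median(clones_per_patient),
    range_clones_per_patient = range(clones_per_patient),
    pct_expanded_clones_cd8 = if (nrow(ex) > 0L)
      100 * mean(ex$lineage == "CD8") else NA_real_)

  per_patient <- data.frame(patient = pts, n_cells = cells_per_patient,
                            n_expanded_clones = clones_per_patient)
  per_patient$frac_cd8 <- vapply(pts, function(p) {
    l <- cell_table$lineage[cell_table$patient == p]
    mean(l == "CD8", na.rm = TRUE)
  }, numeric(1))
  for (s in c("N", "CM", "EM", "E")) {
    per_patient[[paste0("frac_", s)]] <- vapply(pts, function(p) {
      st <- cell_table$diff_state[cell_table$patient == p]
      st <- st[!is.na(st)]
      if (length(st) == 0L) NA_real_ else mean(st == s)
    }, numeric(1))
  }
  out <- list(totals = totals,
              clone_sizes = as.data.frame(table(size = ex$size),
                                          stringsAsFactors = FALSE),
              per_patient = per_patient)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Cohort: %d cells from %d patients (median %s cells/patient)\n",
              t$n_cells, t$n_patients,
              format(t$median_cells_per_patient)))
  cat(sprintf("Expanded clones: %d (median %s/patient, range %d-%d); %.0f%% CD8+\n",
              t$n_expanded_clones, format(t$median_clones_per_patient),
              t$range_clones_per_patient[1], t$range_clones_per_patient[2],
              t$pct_expanded_clones_cd8))
  invisible(x)
}
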