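# Synthetic cohort generator.
#
# Emulates the experimental design the analysis assumes: ~9 patients, ~370
# index-sorted T cells each, sort gates tuned to deposit approximately equal
# numbers of CD4+ and CD8+ cells, few expanded clones per patient (median 4,
# range 1-18), expanded clones predominantly CD8+ (probability 0.89),
# subset-specific marker positivity (CD57 enriched on expanded cells), and
# plate/well-barcoded amplicon reads with a dispersed per-transcript count
# model. Every stochastic choice is recorded as ground truth so the pipeline
# can be validated end to end.

MARKER_PANEL_NAMES <- c("CD3", "CD4", "CD8", "CD45RA", "CCR7", "PD1",
                        "CTLA4", "TIM3", "BTLA", "CD57", "CD28", "CD25",
                        "CD39")
GENE_PANEL_NAMES <- c("IFNG", "TNF", "IL2", "IL10", "IL17A", "TGFB1",
                      "TBX21", "GATA3", "FOXP3", "RORC", "EOMES", "GZMB")
SIM_GROUPS <- c("cd8_expanded", "cd8_nonexpanded", "cd4_expanded",
                "cd4_nonexpanded")

#' Default 13-marker intensity panel
#'
#' Log-normal location/scale per marker for the negative and positive
#' populations on the raw fluorescence scale, plus the fixed gate threshold
#' between them. Default separation is > 6 SD on the log scale, i.e. the
#' mixtures are effectively non-overlapping (decades apart, as for well
#' compensated bright fluorochromes); tighten `sdlog` to study gate error.
#'
#' @return data.frame with columns `marker`, `neg_meanlog`, `pos_meanlog`,
#'   `sdlog`, `gate`.
#' @export
default_marker_panel <- function() {
  pos <- c(7.8, 7.5, 7.6, 7.2, 6.9, 7.0, 6.8, 6.9, 7.1, 7.3, 7.4, 6.8, 6.7)
  neg <- c(3.2, 3.0, 2.9, 3.1, 2.8, 3.0, 2.9, 3.0, 3.1, 2.9, 3.0, 2.8, 2.9)
  data.frame(marker = MARKER_PANEL_NAMES, neg_meanlog = neg,
             pos_meanlog = pos, sdlog = 0.35, gate = exp((neg + pos) / 2))
}

#' Default marker positivity rates per simulation group
#'
#' Rates for the non-structural markers, per group (expanded/non-expanded x
#' CD8/CD4). Anchored to the reported cohort-level medians: checkpoint
#' molecules (PD-1, CTLA-4, TIM-3) rare and somewhat higher on CD8- cells,
#' BTLA and CD28 on the majority of cells, CD25 mostly on CD4, CD39 low,
#' and CD57 enriched on expanded CD8 cells (0.5 vs 0.1).
#'
#' @return data.frame with columns `marker` and one rate column per group.
#' @export
default_positivity_rates <- function() {
  tab <- rbind(
    PD1   = c(0.12, 0.08, 0.16, 0.15),
    CTLA4 = c(0.06, 0.05, 0.12, 0.12),
    TIM3  = c(0.07, 0.05, 0.08, 0.08),
    BTLA  = c(0.60, 0.65, 0.75, 0.75),
    CD57  = c(0.50, 0.10, 0.10, 0.05),
    CD28  = c(0.80, 0.92, 0.95, 0.95),
    CD25  = c(0.05, 0.05, 0.20, 0.20),
    CD39  = c(0.03, 0.03, 0.05, 0.05))
  out <- data.frame(marker = rownames(tab), tab, row.names = NULL)
  names(out)[-1] <- SIM_GROUPS
  out
}

#' Default differentiation-state probabilities per simulation group
#'
#' CD8 cells roughly even across naive/CM/EM with few effectors; CD4 (CD8-)
#' cells dominated by CM/EM; expanded cells shifted away from naive toward
#' EM/E differentiation.
#'
#' @return data.frame with columns `group`, `N`, `CM`, `EM`, `E`.
#' @export
default_diff_state_probs <- function() {
  data.frame(group = SIM_GROUPS,
             N  = c(0.04, 0.30, 0.10, 0.15),
             CM = c(0.21, 0.30, 0.40, 0.45),
             EM = c(0.45, 0.30, 0.40, 0.35),
             E  = c(0.30, 0.10, 0.10, 0.05))
}

#' Default cytokine / transcription-factor count model
#'
#' Per-gene expression probabilities per group and the dispersed (negative
#' binomial) emission model. Expressed transcripts emit strictly more than
#' 10 reads, non-expressed at most 10, so the downstream `> 10` threshold
#' recovers truth exactly at zero sequencing error.
#'
#' @return list with `rates` (data.frame gene x group), `expressed_mu`,
#'   `expressed_size`, `background_mu`, `background_size`.
#' @export
default_gene_count_model <- function() {
  tab <- rbind(
    IFNG  = c(0.35, 0.20, 0.15, 0.15),
    TNF   = c(0.40, 0.35, 0.35, 0.35),
    IL2   = c(0.15, 0.20, 0.30, 0.30),
    IL10  = c(0.05, 0.05, 0.10, 0.10),
    IL17A = c(0.02, 0.02, 0.08, 0.08),
    TGFB1 = c(0.30, 0.30, 0.35, 0.35),
    TBX21 = c(0.45, 0.30, 0.20, 0.20),
    GATA3 = c(0.10, 0.10, 0.40, 0.40),
    FOXP3 = c(0.03, 0.03, 0.15, 0.15),
    RORC  = c(0.05, 0.05, 0.12, 0.12),
    EOMES = c(0.40, 0.25, 0.10, 0.10),
    GZMB  = c(0.45, 0.25, 0.08, 0.08))
  rates <- data.frame(gene = rownames(tab), tab, row.names = NULL)
  names(rates)[-1] <- SIM_GROUPS
  list(rates = rates, expressed_mu = 40, expressed_size = 3,
       background_mu = 1, background_size = 0.6)
}

#' Simulation configuration
#'
#' Defaults encode the cohort regime the generator emulates. Sequencing and
#' barcode error rates default to zero (the validation regime); set them
#' positive to study robustness.
#'
#' @param n_patients number of patients.
#' @param cells_per_patient sorted cells per patient.
#' @param cd8_sort_fraction target CD8+ fraction of the sort (gates adjusted
#'   toward equal CD4/CD8 deposits).
#' @param clones_per_patient distribution spec for the number of expanded
#'   clones per patient: list(dist = "truncgeom", prob, min, max) or
#'   list(dist = "fixed", value). The truncated-geometric default
#'   (p = 0.17 on 1..18) has median 4.
#' @param clone_size_spec distribution over cells per expanded clone:
#'   list(min_size, prob) for `min_size + geometric(prob)`; sizes >= 2.
#' @param expanded_cd8_prob probability an expanded clone is CD8+.
#' @param marker_panel see [default_marker_panel()].
#' @param positivity_rates see [default_positivity_rates()].
#' @param diff_state_probs see [default_diff_state_probs()].
#' @param gene_count_model see [default_gene_count_model()].
#' @param reads_per_chain list(min, mu, size): reads per chain are
#'   `min + NegBin(mu, size)`.
#' @param dual_alpha_prob probability a cell (or clone) carries a second,
#'   subdominant alpha chain.
#' @param seq_error_rate per-base substitution probability on read inserts.
#' @param barcode_mismatch_rate probability a read's barcode region receives
#'   a single random substitution (correctable at the default tolerance).
#' @param rng_seed integer master seed; all randomness derives from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 9L,
                       cells_per_patient = 370L,
                       cd8_sort_fraction = 0.5,
                       clones_per_patient = list(dist = "truncgeom",
                                                 prob = 0.17, min = 1L,
                                                 max = 18L),
                       clone_size_spec = list(min_size = 2L, prob = 0.45),
                       expanded_cd8_prob = 0.89,
                       marker_panel = default_marker_panel(),
                       positivity_rates = default_positivity_rates(),
                       diff_state_probs = default_diff_state_probs(),
                       gene_count_model = default_gene_count_model(),
                       reads_per_chain = list(min = 2L, mu = 16, size = 10),
                       dual_alpha_prob = 0.10,
                       seq_error_rate = 0,
                       barcode_mismatch_rate = 0,
                       rng_seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cells_per_patient = as.integer(cells_per_patient),
              cd8_sort_fraction = cd8_sort_fraction,
              clones_per_patient = clones_per_patient,
              clone_size_spec = clone_size_spec,
              expanded_cd8_prob = expanded_cd8_prob,
              marker_panel = marker_panel,
              positivity_rates = positivity_rates,
              diff_state_probs = diff_state_probs,
              gene_count_model = gene_count_model,
              reads_per_chain = reads_per_chain,
              dual_alpha_prob = dual_alpha_prob,
              seq_error_rate = seq_error_rate,
              barcode_mismatch_rate = barcode_mismatch_rate,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$cd8_sort_fraction, cfg$expanded_cd8_prob,
             cfg$dual_alpha_prob, cfg$seq_error_rate,
             cfg$barcode_mismatch_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_patients < 1L || cfg$cells_per_patient < 1L) {
    stop("n_patients and cells_per_patient must be >= 1")
  }
  css <- cfg$clone_size_spec
  min_clone <- if (identical(css$dist, "fixed")) css$value else css$min_size
  if (min_clone < 2L) stop("expanded clone sizes must be >= 2")
  dsp <- cfg$diff_state_probs
  sums <- rowSums(dsp[, c("N", "CM", "EM", "E")])
  if (any(abs(sums - 1) > 1e-8)) {
    stop("diff_state_probs must sum to 1 within each group")
  }
  rates <- as.matrix(cfg$positivity_rates[, SIM_GROUPS])
  if (any(rates < 0 | rates > 1)) stop("positivity rates must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration:\n")
  cat(sprintf("  %d patients x %d cells (CD8 sort fraction %.2f)\n",
              x$n_patients, x$cells_per_patient, x$cd8_sort_fraction))
  cat(sprintf("  expanded clones/patient: %s; P(clone CD8+) = %.2f\n",
              if (identical(x$clones_per_patient$dist, "fixed"))
                sprintf("fixed %d", x$clones_per_patient$value)
              else sprintf("truncated geometric p=%.2f on [%d, %d]",
                           x$clones_per_patient$prob,
                           x$clones_per_patient$min, x$clones_per_patient$max),
              x$expanded_cd8_prob))
  cat(sprintf("  seq error %.4g, barcode corruption %.4g, seed %d\n",
              x$seq_error_rate, x$barcode_mismatch_rate, x$rng_seed))
  invisible(x)
}

sim_group <- function(lineage, expanded) {
  paste0(ifelse(lineage == "CD8", "cd8_", "cd4_"),
         ifelse(expanded, "expanded", "nonexpanded"))
}

draw_n_clones <- function(spec, n) {
  if (identical(spec$dist, "fixed")) return(rep(as.integer(spec$value), n))
  if (identical(spec$dist, "truncgeom")) {
    k <- spec$min + stats::rgeom(n, spec$prob)
    return(pmin(as.integer(k), as.integer(spec$max)))
  }
  stop("unknown clones_per_patient dist: ", spec$dist)
}

draw_clone_sizes <- function(spec, n) {
  if (identical(spec$dist, "fixed")) return(rep(as.integer(spec$value), n))
  as.integer(spec$min_size + stats::rgeom(n, spec$prob))
}

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

# Batch of random CDR3-bearing chains for one locus: junction starts with
# the V anchor codon (Cys), ends with the J anchor codon (Phe/Trp),
# 9-17 aa total, middle codons drawn from the sense codons.
draw_chains <- function(ref, locus, n) {
  vsub <- ref[ref$locus == locus & ref$type == "V", , drop = FALSE]
  jsub <- ref[ref$locus == locus & ref$type == "J", , drop = FALSE]
  vi <- sample.int(nrow(vsub), n, replace = TRUE)
  ji <- sample.int(nrow(jsub), n, replace = TRUE)
  mid_n <- sample(9:17, n, replace = TRUE) - 2L
  codons <- sample(SENSE_CODONS, sum(mid_n), replace = TRUE)
  mids <- vapply(split(codons, factor(rep(seq_len(n), mid_n),
                                      levels = seq_len(n))),
                 paste, character(1), collapse = "")
  nt <- paste0(substr(vsub$sequence[vi], vsub$anchor_index[vi] + 1L,
                      vsub$anchor_index[vi] + 3L),
               mids,
               substr(jsub$sequence[ji], jsub$anchor_index[ji] + 1L,
                      jsub$anchor_index[ji] + 3L))
  data.frame(v = vsub$segment[vi], j = jsub$segment[ji], nt = nt,
             aa = translate_nt(nt))
}

# n full alpha/beta chain sets (one per clone or singleton), with a second
# subdominant alpha where dual[i] is TRUE. Amino-acid (beta, alpha) pairs
# are unique within the batch and against `seen` keys.
draw_chain_sets <- function(ref, dual, seen = character(0)) {
  n <- length(dual)
  b <- draw_chains(ref, "TRB", n)
  a <- draw_chains(ref, "TRA", n)
  a2 <- draw_chains(ref, "TRA", n)
  for (i in 1:100) {
    key <- paste(b$aa, a$aa)
    bad <- which(duplicated(key) | key %in% seen)
    if (length(bad) == 0L) break
    b[bad, ] <- draw_chains(ref, "TRB", length(bad))
    a[bad, ] <- draw_chains(ref, "TRA", length(bad))
  }
  out <- data.frame(beta_v = b$v, beta_j = b$j, cdr3b_nt = b$nt,
                    cdr3b_aa = b$aa,
                    alpha_v = a$v, alpha_j = a$j, cdr3a_nt = a$nt,
                    cdr3a_aa = a$aa,
                    alpha2_v = a2$v, alpha2_j = a2$j, cdr3a2_nt = a2$nt,
                    cdr3a2_aa = a2$aa)
  out[!dual, c("alpha2_v", "alpha2_j", "cdr3a2_nt", "cdr3a2_aa")] <-
    NA_character_
  out
}

#' Generate a synthetic cohort ground truth
#'
#' Draws, per patient, the number of expanded clones, their sizes and
#' lineages, assigns clone membership among the sorted cells (all remaining
#' cells are singletons with unique CDR3 pairs), then draws differentiation
#' states, marker intensities/positivity and per-gene expression flags and
#' emission counts from the group-specific models.
#'
#' @param config a [sim_config()].
#' @param reference optional `segment_reference`; generated from the config
#'   seed when NULL.
#' @param gene_reference optional gene amplicon reference; generated when
#'   NULL.
#' @return object of class `cohort_truth`: list with `cells`, `clones`,
#'   `marker_intensity`, `marker_positive`, `genes`, `gates`,
#'   `plate_manifest`, `reference`, `gene_reference`, `config`.
#' @export
generate_cohort <- function(config, reference = NULL, gene_reference = NULL) {
  validate_sim_config(config)
  if (is.null(reference)) {
    reference <- generate_reference(10L, 6L, seed = config$rng_seed)
  }
  if (is.null(gene_reference)) {
    gene_reference <- generate_gene_reference(
      config$gene_count_model$rates$gene, seed = config$rng_seed)
  }
  set.seed(child_seed(config$rng_seed, 10L))

  patients <- sprintf("PT%02d", seq_len(config$n_patients))
  wells <- plate_wells()
  seen_junctions <- character(0)
  cell_rows <- list(); clone_rows <- list()

  for (p in patients) {
    n_cells <- config$cells_per_patient
    n_cd8 <- round(n_cells * config$cd8_sort_fraction)
    lineage <- c(rep("CD8", n_cd8), rep("CD4", n_cells - n_cd8))
    lineage <- sample(lineage)  # shuffle across wells/plates

    n_clones <- draw_n_clones(config$clones_per_patient, 1L)
    sizes <- draw_clone_sizes(config$clone_size_spec, n_clones)
    if (sum(sizes) > n_cells) {
      stop("infeasible config: expanded-clone cells (", sum(sizes),
           ") exceed cells_per_patient (", n_cells, ") for ", p)
    }
    clone_lineage <- ifelse(stats::runif(n_clones) < config$expanded_cd8_prob,
                            "CD8", "CD4")
    for (lin in c("CD8", "CD4")) {
      need <- sum(sizes[clone_lineage == lin])
      if (need > sum(lineage == lin)) {
        stop("infeasible config: ", lin, " clone cells (", need,
             ") exceed sorted ", lin, " cells for ", p)
      }
    }

    clone_id <- rep(NA_character_, n_cells)
    if (n_clones > 0L) {
      for (k in seq_len(n_clones)) {
        free <- which(is.na(clone_id) & lineage == clone_lineage[k])
        members <- sample(free, sizes[k])
        clone_id[members] <- sprintf("%s_clone%02d", p, k)
      }
    }

    # chain sets: one per clone, one per singleton; amino-acid pairs unique
    # across the whole cohort unless configured otherwise
    expanded <- !is.na(clone_id)
    n_singleton <- sum(!expanded)
    dual <- stats::runif(n_clones + n_singleton) < config$dual_alpha_prob
    sets <- draw_chain_sets(reference, dual, seen = seen_junctions)
    seen_junctions <- c(seen_junctions, paste(sets$cdr3b_aa, sets$cdr3a_aa))

    # row index into `sets` per cell: clones use rows 1..n_clones
    clone_ids <- if (n_clones > 0L) {
      sprintf("%s_clone%02d", p, seq_len(n_clones))
    } else {
      character(0)
    }
    set_idx <- integer(n_cells)
    set_idx[expanded] <- match(clone_id[expanded], clone_ids)
    set_idx[!expanded] <- n_clones + seq_len(n_singleton)

    plate <- sprintf("%s-p%d", p, (seq_len(n_cells) - 1L) %/% 96L + 1L)
    well <- wells[(seq_len(n_cells) - 1L) %% 96L + 1L]
    grp <- sim_group(lineage, expanded)

    dsp <- config$diff_state_probs
    diff_state <- character(n_cells)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      pr <- as.numeric(dsp[dsp$group == g, c("N", "CM", "EM", "E")])
      diff_state[idx] <- sample(c("N", "CM", "EM", "E"), length(idx),
                                replace = TRUE, prob = pr)
    }

    cell_rows[[p]] <- data.frame(
      cell_id = paste0(plate, ":", well),
      patient = p, plate = plate, well = well,
      lineage = lineage, clone_id = clone_id, expanded = expanded,
      diff_state = diff_state,
      sets[set_idx, , drop = FALSE],
      row.names = NULL)

    if (n_clones > 0L) {
      clone_rows[[p]] <- data.frame(
        patient = p, clone_id = clone_ids,
        size = sizes, lineage = clone_lineage,
        cdr3b_aa = sets$cdr3b_aa[seq_len(n_clones)],
        cdr3a_aa = sets$cdr3a_aa[seq_len(n_clones)],
        row.names = NULL)
    }
  }

  cells <- do.call(rbind, cell_rows)
  rownames(cells) <- NULL
  clones <- if (length(clone_rows)) do.call(rbind, clone_rows) else
    data.frame(patient = character(0), clone_id = character(0),
               size = integer(0), lineage = character(0),
               cdr3b_aa = character(0), cdr3a_aa = character(0))
  rownames(clones) <- NULL

  mk <- draw_markers(cells, config)
  genes <- draw_genes(cells, config)

  truth <- list(cells = cells, clones = clones,
                marker_intensity = mk$intensity,
                marker_positive = mk$positive,
                genes = genes,
                gates = data.frame(marker = config$marker_panel$marker,
                                   threshold = config$marker_panel$gate),
                plate_manifest = unique(cells[, c("plate", "patient")]),
                reference = reference, gene_reference = gene_reference,
                config = config)
  class(truth) <- "cohort_truth"
  truth
}

# Structural markers follow identity deterministically (CD3 always positive,
# CD4/CD8 by lineage, CD45RA/CCR7 by differentiation state); the remaining
# markers follow the per-group positivity rates. Intensities are log-normal
# draws from the matching population, rounded to 2 decimals (the positivity
# flag is re-derived from the rounded value so index CSVs round-trip).
draw_markers <- function(cells, config) {
  n <- nrow(cells)
  panel <- config$marker_panel
  rates <- config$positivity_rates
  grp <- sim_group(cells$lineage, cells$expanded)
  pos <- matrix(NA, n, nrow(panel), dimnames = list(NULL, panel$marker))
  for (m in panel$marker) {
    pos[, m] <- switch(m,
      CD3 = rep(TRUE, n),
      CD4 = cells$lineage == "CD4",
      CD8 = cells$lineage == "CD8",
      CD45RA = cells$diff_state %in% c("N", "E"),
      CCR7 = cells$diff_state %in% c("N", "CM"),
      {
        r <- rates[rates$marker == m, SIM_GROUPS]
        stats::runif(n) < as.numeric(r[match(grp, SIM_GROUPS)])
      })
  }
  inten <- matrix(NA_real_, n, nrow(panel),
                  dimnames = list(NULL, panel$marker))
  for (j in seq_len(nrow(panel))) {
    mu <- ifelse(pos[, j], panel$pos_meanlog[j], panel$neg_meanlog[j])
    inten[, j] <- round(stats::rlnorm(n, mu, panel$sdlog[j]), 2L)
    pos[, j] <- inten[, j] > panel$gate[j]
  }
  list(intensity = data.frame(cell_id = cells$cell_id, inten,
                              check.names = FALSE),
       positive = data.frame(cell_id = cells$cell_id, pos,
                             check.names = FALSE))
}

draw_genes <- function(cells, config) {
  gm <- config$gene_count_model
  grp <- sim_group(cells$lineage, cells$expanded)
  out <- vector("list", nrow(gm$rates))
  for (g in seq_len(nrow(gm$rates))) {
    r <- as.numeric(gm$rates[g, SIM_GROUPS])[match(grp, SIM_GROUPS)]
    expressed <- stats::runif(nrow(cells)) < r
    count <- integer(nrow(cells))
    ne <- sum(expressed)
    count[expressed] <- 11L + stats::rnbinom(ne, mu = gm$expressed_mu,
                                             size = gm$expressed_size)
    count[!expressed] <- pmin(stats::rnbinom(nrow(cells) - ne,
                                             mu = gm$background_mu,
                                             size = gm$background_size), 10L)
    out[[g]] <- data.frame(cell_id = cells$cell_id,
                           gene = gm$rates$gene[g],
                           expressed = expressed, count = count)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$cell_id, res$gene), ]
  rownames(res) <- NULL
  res
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("Synthetic cohort:", length(unique(x$cells$patient)), "patients,",
      nrow(x$cells), "cells,", nrow(x$clones), "expanded clones\n")
  invisible(x)
}

# Apply random substitutions at per-base rate to a character vector.
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs)
  k <- stats::rbinom(length(seqs), len, rate)
  idx <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(len[i], k[i])
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

# Full amplicon insert for one chain: V (ending in its anchor codon) +
# junction middle + J (starting at its anchor codon).
chain_insert <- function(v, j, cdr3_nt, reference) {
  vrow <- reference[match(v, reference$segment), ]
  jrow <- reference[match(j, reference$segment), ]
  paste0(vrow$sequence, substr(cdr3_nt, 4L, nchar(cdr3_nt) - 3L),
         jrow$sequence)
}

#' Synthesize barcoded paired-end reads from a cohort truth
#'
#' Each cell's chains and expressed/background transcripts emit reads
#' carrying the cell's plate and well barcodes on read 1
#' (plate + well + insert; gene-specific priming is modelled as the insert
#' beginning at the target's 5' end). Read 2 is the insert's reverse
#' complement. Substitution errors are applied to the insert at
#' `seq_error_rate`; with probability `barcode_mismatch_rate` the barcode
#' region receives one random substitution. Cells carrying a second alpha
#' chain emit it at roughly half the dominant alpha's read count, so read
#' support always identifies the dominant chain.
#'
#' @param truth a `cohort_truth`.
#' @param config the matching [sim_config()].
#' @param scheme a `barcode_scheme` covering all plates in the truth.
#' @return data.frame with columns `id`, `seq1`, `seq2` (one row per read
#'   pair), in shuffled order.
#' @export
synthesize_reads <- function(truth, config, scheme) {
  missing_plate <- setdiff(truth$cells$plate, names(scheme$plate))
  if (length(missing_plate) > 0L) {
    stop("barcode scheme lacks plates: ", paste(missing_plate, collapse = ", "))
  }
  set.seed(child_seed(config$rng_seed, 11L))
  cells <- truth$cells
  rpc <- config$reads_per_chain
  draw_reads <- function(n) as.integer(rpc$min + stats::rnbinom(n, mu = rpc$mu,
                                                                size = rpc$size))

  n <- nrow(cells)
  beta_n <- draw_reads(n)
  alpha_n <- draw_reads(n)
  has_a2 <- !is.na(cells$cdr3a2_nt)
  alpha_n[has_a2] <- pmax(alpha_n[has_a2], 4L)  # keep dominance strict
  alpha2_n <- ifelse(has_a2, pmax(2L, alpha_n %/% 2L), 0L)

  emit <- list(
    data.frame(cell = seq_len(n),
               insert = chain_insert(cells$beta_v, cells$beta_j,
                                     cells$cdr3b_nt, truth$reference),
               n_reads = beta_n),
    data.frame(cell = seq_len(n),
               insert = chain_insert(cells$alpha_v, cells$alpha_j,
                                     cells$cdr3a_nt, truth$reference),
               n_reads = alpha_n))
  if (any(has_a2)) {
    emit[[3]] <- data.frame(
      cell = which(has_a2),
      insert = chain_insert(cells$alpha2_v[has_a2], cells$alpha2_j[has_a2],
                            cells$cdr3a2_nt[has_a2], truth$reference),
      n_reads = alpha2_n[has_a2])
  }
  g <- truth$genes[truth$genes$count > 0L, , drop = FALSE]
  if (nrow(g) > 0L) {
    emit[[length(emit) + 1L]] <- data.frame(
      cell = match(g$cell_id, cells$cell_id),
      insert = truth$gene_reference$sequence[
        match(g$gene, truth$gene_reference$gene)],
      n_reads = g$count)
  }
  emit <- do.call(rbind, emit)

  cell_idx <- rep(emit$cell, emit$n_reads)
  insert1 <- mutate_seqs(rep(emit$insert, emit$n_reads),
                         config$seq_error_rate)
  insert2 <- mutate_seqs(revcomp(rep(emit$insert, emit$n_reads)),
                         config$seq_error_rate)
  bc <- paste0(scheme$plate[cells$plate[cell_idx]],
               scheme$well[cells$well[cell_idx]])
  if (config$barcode_mismatch_rate > 0) {
    hit <- stats::runif(length(bc)) < config$barcode_mismatch_rate
    bc[hit] <- vapply(bc[hit], function(b) {
      p <- sample.int(nchar(b), 1L)
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(b, p, p)), 1L)
      b
    }, character(1), USE.NAMES = FALSE)
  }
  ord <- sample.int(length(bc))
  data.frame(id = sprintf("read%07d", seq_along(bc)),
             seq1 = paste0(bc, insert1)[ord],
             seq2 = insert2[ord], row.names = NULL)
}

#' Write per-plate FACS index-sort CSV exports
#'
#' One CSV per plate, one row per sorted well, with the plate id, well
#' coordinate, sort-gate label and raw-scale intensities for every panel
#' marker (RFC-4180, header row).
#'
#' @param truth a `cohort_truth`.
#' @param dir output directory.
#' @param decorate when TRUE, marker columns get fluorochrome-style
#'   decorated names (e.g. "FL1-A :: CD3") to exercise header mapping.
#' @return invisibly, the written paths.
#' @export
write_index_csv <- function(truth, dir, decorate = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- truth$cells
  inten <- truth$marker_intensity
  markers <- setdiff(names(inten), "cell_id")
  paths <- character(0)
  for (pl in unique(cells$plate)) {
    rows <- which(cells$plate == pl)
    df <- data.frame(Plate = pl, Well = cells$well[rows],
                     SortGate = ifelse(cells$lineage[rows] == "CD8",
                                       "CD8+", "CD8-"),
                     inten[match(cells$cell_id[rows], inten$cell_id),
                           markers, drop = FALSE],
                     check.names = FALSE)
    if (decorate) {
      names(df)[-(1:3)] <- sprintf("FL%d-A :: %s", seq_along(markers),
                                   markers)
    }
    path <- file.path(dir, paste0(pl, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Simulate a full cohort run to disk
#'
#' Writes everything a pipeline run consumes: segment and gene references,
#' barcode scheme, plate manifest, gate table, paired-end FASTQ (gzip),
#' per-plate index CSVs, and the ground-truth tables.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created).
#' @return the `cohort_truth`, invisibly.
#' @export
simulate_cohort <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_cohort(config)
  scheme <- make_barcode_scheme(unique(truth$cells$plate),
                                seed = config$rng_seed)
  reads <- synthesize_reads(truth, config, scheme)

  dir.create(file.path(outdir, "reference"), showWarnings = FALSE)
  write_reference(truth$reference,
                  file.path(outdir, "reference", "segments.fasta"),
                  file.path(outdir, "reference", "anchors.tsv"))
  write_gene_reference(truth$gene_reference,
                       file.path(outdir, "reference", "genes.fasta"))
  write_scheme(scheme, file.path(outdir, "barcodes.tsv"))
  utils::write.table(truth$plate_manifest, file.path(outdir, "plates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$gates, file.path(outdir, "gates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fastq(reads$id, reads$seq1, file.path(outdir, "reads_R1.fastq.gz"))
  write_fastq(reads$id, reads$seq2, file.path(outdir, "reads_R2.fastq.gz"))
  write_index_csv(truth, file.path(outdir, "index"))

  tdir <- file.path(outdir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(tdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(truth$cells, "cells.tsv")
  wt(truth$clones, "clones.tsv")
  wt(truth$genes, "genes.tsv")
  wt(truth$marker_positive, "marker_positive.tsv")
  invisible(truth)
}
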