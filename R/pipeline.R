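# End-to-end pipeline over the on-disk artifacts a run produces:
# demultiplex -> annotate -> expression/marker calls -> index integration ->
# clonotyping -> comparisons.

# Pivot retained chain calls to one row per cell (dominant beta, dominant
# and secondary alpha).
chains_to_cells <- function(chains, chain_sets) {
  pick <- function(locus, rank, col) {
    sub <- chains[chains$locus == locus & chains$chain_rank == rank, ,
                  drop = FALSE]
    sub[[col]][match(chain_sets$cell_id, sub$cell_id)]
  }
  data.frame(cell_id = chain_sets$cell_id,
             beta_v = pick("TRB", 1L, "v_call"),
             beta_j = pick("TRB", 1L, "j_call"),
             beta_aa = pick("TRB", 1L, "cdr3_aa"),
             beta_nt = pick("TRB", 1L, "cdr3_nt"),
             alpha1_v = pick("TRA", 1L, "v_call"),
             alpha1_j = pick("TRA", 1L, "j_call"),
             alpha1_aa = pick("TRA", 1L, "cdr3_aa"),
             alpha1_nt = pick("TRA", 1L, "cdr3_nt"),
             alpha2_aa = pick("TRA", 2L, "cdr3_aa"),
             row.names = NULL)
}

#' Run the full analysis pipeline on a simulated (or equivalent) run
#' directory
#'
#' Expects the layout written by [simulate_cohort()]: `reference/`
#' (segments.fasta, anchors.tsv, genes.fasta), `barcodes.tsv`,
#' `plates.tsv`, `gates.tsv`, `reads_R1.fastq.gz`, `reads_R2.fastq.gz`,
#' and `index/*.csv`. Stages: demultiplexing, V/J + CDR3 annotation with
#' per-well collapse, gene expression calls (> 10 reads), index CSV
#' integration, marker gating, differentiation-state classification,
#' clonotype assignment and expansion statistics, per-patient expanded vs
#' non-expanded marker comparisons (Wilcoxon + Bonferroni), and a cohort
#' summary.
#'
#' @param dir run directory.
#' @param policy clonotype pairing policy (see [assign_clonotypes()]).
#' @param expression_threshold read-count threshold for gene expression
#'   (default 10, exclusive).
#' @param min_reads,min_fraction chain-support thresholds
#'   (see [collapse_well()]).
#' @param compare_family feature family for the comparison step: "markers"
#'   (default), "states", "genes", or "none".
#' @return list of class `pipeline_result` with elements `demux_summary`,
#'   `annotation`, `cells` (the merged per-cell analysis table),
#'   `clonotypes`, `clone_stats`, `comparisons`, `summary`.
#' @export
run_pipeline <- function(dir, policy = "paired_strict",
                         expression_threshold = 10L, min_reads = 2L,
                         min_fraction = 0.10,
                         compare_family = c("markers", "states", "genes",
                                            "none")) {
  compare_family <- match.arg(compare_family)
  reference <- read_reference(file.path(dir, "reference", "segments.fasta"),
                              file.path(dir, "reference", "anchors.tsv"))
  gene_ref <- read_gene_reference(file.path(dir, "reference", "genes.fasta"))
  scheme <- read_scheme(file.path(dir, "barcodes.tsv"))
  manifest <- utils::read.delim(file.path(dir, "plates.tsv"),
                                stringsAsFactors = FALSE)
  gates <- utils::read.delim(file.path(dir, "gates.tsv"),
                             stringsAsFactors = FALSE)

  dm <- demultiplex(file.path(dir, "reads_R1.fastq.gz"),
                    file.path(dir, "reads_R2.fastq.gz"), scheme)
  ann <- annotate_cells(dm, reference, gene_ref, min_reads = min_reads,
                        min_fraction = min_fraction)

  index_files <- list.files(file.path(dir, "index"), pattern = "\\.csv$",
                            full.names = TRUE)
  events <- do.call(rbind, lapply(index_files, read_index_csv,
                                  panel = gates$marker))
  merged <- merge_cells(events, ann$chain_sets, manifest)

  marker_calls <- call_marker_positive(
    data.frame(cell_id = merged$cell_id,
               merged[, gates$marker, drop = FALSE], check.names = FALSE),
    gates)
  gene_calls <- call_gene_expression(ann$gene_counts,
                                     threshold = expression_threshold,
                                     cells = merged$cell_id,
                                     genes = gene_ref$gene)

  cells <- merged[, c("cell_id", "patient", "plate", "well", "provenance",
                      "sort_gate", "n_alpha", "n_beta", "qc")]
  cells$lineage <- ifelse(merged$provenance == "sequencing_only",
                          NA_character_, call_lineage(marker_calls$CD8))
  cells$diff_state <- classify_differentiation(marker_calls$CD45RA,
                                               marker_calls$CCR7)

  chain_cells <- chains_to_cells(ann$chains, ann$chain_sets)
  ci <- match(cells$cell_id, chain_cells$cell_id)
  for (cn in setdiff(names(chain_cells), "cell_id")) {
    cells[[cn]] <- chain_cells[[cn]][ci]
  }

  analysis <- cells[cells$provenance == "matched", , drop = FALSE]
  ct <- assign_clonotypes(analysis, policy = policy)
  cs <- clone_statistics(ct, analysis)
  ex_ids <- cs$clonotypes$clonotype_id[cs$clonotypes$expanded]
  cells$clonotype_id <- ct$cell_assignments$clonotype_id[
    match(cells$cell_id, ct$cell_assignments$cell_id)]
  cells$expanded <- !is.na(cells$clonotype_id) &
    cells$clonotype_id %in% ex_ids

  mi <- match(cells$cell_id, marker_calls$cell_id)
  for (m in gates$marker) cells[[paste0(m, "_pos")]] <- marker_calls[[m]][mi]
  gi <- match(cells$cell_id, gene_calls$cell_id)
  for (g in gene_ref$gene) cells[[paste0(g, "_expr")]] <- gene_calls[[g]][gi]

  comparisons <- NULL
  if (compare_family != "none") {
    feats <- switch(compare_family,
      markers = {
        f <- data.frame(cell_id = marker_calls$cell_id,
                        marker_calls[, setdiff(gates$marker,
                                               c("CD3", "CD4", "CD8")),
                                     drop = FALSE], check.names = FALSE)
        f
      },
      states = {
        st <- cells$diff_state[match(marker_calls$cell_id, cells$cell_id)]
        data.frame(cell_id = marker_calls$cell_id,
                   N = st == "N", CM = st == "CM", EM = st == "EM",
                   E = st == "E")
      },
      genes = gene_calls)
    comparisons <- compare_groups(
      per_patient_marker_freq(cells[cells$provenance == "matched", ],
                              feats, compartment = "CD8"))
  }

  summary <- summarize_cohort(cells[cells$provenance == "matched", ], cs)
  out <- list(demux_summary = dm$summary, annotation = ann, cells = cells,
              clonotypes = ct, clone_stats = cs, comparisons = comparisons,
              summary = summary)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$summary)
  s <- x$demux_summary
  cat(sprintf("Reads: %d total, %d assigned (%.1f%%)\n", s[["total"]],
              s[["assigned"]], 100 * s[["assigned"]] / max(1, s[["total"]])))
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons$feature[x$comparisons$significant]
    cat("Significant after Bonferroni:",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
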