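# Binary expression and phenotype calls.
#
# Two strict-inequality thresholds drive everything: a transcript is
# expressed when its per-cell read count is strictly greater than 10, and a
# marker is positive when its index-sort intensity is strictly greater than
# its gate. Checkpoint gates can be derived from non-T-cell background
# events (a high quantile of background intensity), mirroring manual gating
# on populations known to be negative.

#' Call gene expression from per-cell read counts
#'
#' Expressed means strictly more than `threshold` reads per cell; missing
#' (cell, gene) combinations count as zero reads.
#'
#' @param counts data.frame with columns `cell_id`, `gene`, `count`
#'   (non-negative integers; at most one row per cell-gene pair).
#' @param threshold read-count threshold (default 10; exclusive boundary).
#' @param cells optional cell ids to force into the output (rows of all
#'   zeros when unobserved).
#' @param genes optional gene names to force into the output.
#' @return data.frame: `cell_id`, one logical column per gene.
#' @export
call_gene_expression <- function(counts, threshold = 10L, cells = NULL,
                                 genes = NULL) {
  if (any(counts$count < 0)) stop("negative read counts")
  if (anyDuplicated(paste(counts$cell_id, counts$gene, sep = "\r"))) {
    stop("more than one row per (cell, gene)")
  }
  cells <- sort(unique(c(counts$cell_id, cells)))
  genes <- sort(unique(c(counts$gene, genes)))
  mat <- matrix(FALSE, length(cells), length(genes),
                dimnames = list(NULL, genes))
  i <- match(counts$cell_id, cells)
  j <- match(counts$gene, genes)
  mat[cbind(i, j)] <- counts$count > threshold
  data.frame(cell_id = cells, mat, check.names = FALSE)
}

#' Call marker positivity from index-sort intensities
#'
#' Positive means intensity strictly greater than the marker's gate.
#'
#' @param intensities data.frame: `cell_id` plus one numeric column per
#'   marker (raw scale).
#' @param gates data.frame with columns `marker`, `threshold`, and
#'   optionally `provenance` (recorded per call set; defaults "fixed").
#' @return data.frame: `cell_id`, one logical column per gated marker;
#'   attribute `gate_provenance` carries the provenance per marker.
#' @export
call_marker_positive <- function(intensities, gates) {
  missing <- setdiff(gates$marker, names(intensities))
  if (length(missing) > 0L) {
    stop("missing marker column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(gates$provenance)) gates$provenance <- "fixed"
  out <- data.frame(cell_id = intensities$cell_id)
  for (k in seq_len(nrow(gates))) {
    m <- gates$marker[k]
    out[[m]] <- intensities[[m]] > gates$threshold[k]
  }
  attr(out, "gate_provenance") <- stats::setNames(gates$provenance,
                                                  gates$marker)
  out
}

#' Derive a gate threshold from non-T-cell background events
#'
#' Operationalizes gating "based on expression on non-T cells": the gate is
#' a high quantile of the background intensity distribution, so that almost
#' all background events fall below it.
#'
#' @param background numeric vector of background intensities (>= 100
#'   events required).
#' @param quantile which upper quantile to use (default 0.995).
#' @return the gate threshold (type-7 sample quantile; `quantile = 1`
#'   returns the maximum).
#' @export
estimate_gate_from_background <- function(background, quantile = 0.995) {
  if (length(background) < 100L) {
    stop("need >= 100 background events to derive a gate; supply a fixed ",
         "gate instead")
  }
  if (quantile < 0 || quantile > 1) stop("quantile must lie in [0, 1]")
  unname(stats::quantile(background, quantile, type = 7))
}

#' Classify T cell differentiation state from CD45RA and CCR7 calls
#'
#' CD45RA+CCR7+ is naive (N), CD45RA-CCR7+ central memory (CM),
#' CD45RA-CCR7- effector memory (EM), CD45RA+CCR7- effector (E). Missing
#' calls yield NA (excluded downstream).
#'
#' @param cd45ra,ccr7 logical vectors.
#' @return character vector of states ("N", "CM", "EM", "E", or NA).
#' @export
classify_differentiation <- function(cd45ra, ccr7) {
  stopifnot(length(cd45ra) == length(ccr7))
  out <- ifelse(cd45ra & ccr7, "N",
                ifelse(!cd45ra & ccr7, "CM",
                       ifelse(!cd45ra & !ccr7, "EM", "E")))
  out[is.na(cd45ra) | is.na(ccr7)] <- NA_character_
  out
}

#' CD4/CD8 lineage from marker calls
#'
#' CD8 positivity defines the CD8+ compartment; everything else is labeled
#' "CD4" by default, matching the convention of reporting the CD8-negative
#' compartment as CD4. With `require_cd4 = TRUE`, CD8-negative cells must
#' be CD4-positive to be labeled CD4; CD8-CD4- (or double-positive) cells
#' become "ambiguous".
#'
#' @param cd8 logical vector of CD8 calls.
#' @param cd4 logical vector of CD4 calls (only used when `require_cd4`).
#' @param require_cd4 see above.
#' @return character vector: "CD8", "CD4", or "ambiguous".
#' @export
call_lineage <- function(cd8, cd4 = NULL, require_cd4 = FALSE) {
  if (!require_cd4) {
    return(ifelse(cd8, "CD8", "CD4"))
  }
  stopifnot(!is.null(cd4))
  ifelse(cd8 & !cd4, "CD8", ifelse(cd4 & !cd8, "CD4", "ambiguous"))
}
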