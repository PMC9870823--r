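# FACS index-sort CSV parsing and integration with sequencing data.
#
# Sorter exports vary in header dialect (fluorochrome/channel decorations
# around the marker name), so marker resolution goes through an explicit
# mapping: a column matches a panel marker either by exact name or via a
# user-supplied dictionary. Nothing is guessed.

#' Read a FACS index-sort CSV export
#'
#' One row per sorted well. Well coordinates are normalized ("a01" ->
#' "A1"); a duplicate well is a hard failure. Marker columns are resolved
#' to canonical panel names either directly or through `marker_map`.
#'
#' @param path CSV path (RFC-4180, header row).
#' @param panel character vector of canonical marker names that must all be
#'   resolvable.
#' @param marker_map optional named character vector mapping CSV column
#'   names to canonical marker names.
#' @param plate_col,well_col,gate_col column names for plate id, well
#'   coordinate and sort-gate label (gate optional).
#' @return data.frame of index events: `plate`, `well`, `sort_gate`, one
#'   intensity column per panel marker.
#' @export
read_index_csv <- function(path, panel, marker_map = NULL,
                           plate_col = "Plate", well_col = "Well",
                           gate_col = "SortGate") {
  if (!file.exists(path)) stop("index CSV not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c(plate_col, well_col) %in% names(df))) {
    stop("index CSV must have columns '", plate_col, "' and '", well_col, "'")
  }
  resolved <- stats::setNames(names(df), names(df))
  if (!is.null(marker_map)) {
    hit <- names(df) %in% names(marker_map)
    resolved[hit] <- marker_map[names(df)[hit]]
  }
  missing <- setdiff(panel, resolved)
  if (length(missing) > 0L) {
    stop("unmappable marker column(s) for: ",
         paste(missing, collapse = ", "),
         "; available columns: ", paste(names(df), collapse = ", "))
  }
  out <- data.frame(plate = as.character(df[[plate_col]]),
                    well = normalize_well(df[[well_col]]),
                    sort_gate = if (gate_col %in% names(df))
                      as.character(df[[gate_col]]) else NA_character_)
  for (m in panel) {
    out[[m]] <- as.numeric(df[[names(resolved)[match(m, resolved)]]])
  }
  dup <- duplicated(paste(out$plate, out$well))
  if (any(dup)) {
    stop("duplicate index event(s) for well(s): ",
         paste(unique(paste(out$plate[dup], out$well[dup])), collapse = ", "))
  }
  out
}

#' Merge index events with sequencing-derived per-cell data
#'
#' Full outer join on (plate, well) with provenance flags; the join is
#' lossless (every input row appears exactly once). Patient identity is
#' carried at plate level via `plate_manifest`; a plate mapped to two
#' patients is a hard failure.
#'
#' @param events index events (possibly several plates,
#'   [read_index_csv()] output rbind-ed).
#' @param chain_sets per-well chain-set table from [annotate_cells()]
#'   (`cell_id`, `plate`, `well`, `n_alpha`, `n_beta`, `qc`).
#' @param plate_manifest data.frame `plate`, `patient`.
#' @return data.frame with one row per (plate, well) seen on either side:
#'   `cell_id`, `patient`, `plate`, `well`, `provenance` (matched |
#'   index_only | sequencing_only), index columns, chain-set columns.
#' @export
merge_cells <- function(events, chain_sets, plate_manifest) {
  if (anyDuplicated(plate_manifest$plate)) {
    dup <- plate_manifest$plate[duplicated(plate_manifest$plate)]
    stop("conflicting patient assignment for plate(s): ",
         paste(unique(dup), collapse = ", "))
  }
  ek <- paste(events$plate, events$well)
  sk <- paste(chain_sets$plate, chain_sets$well)
  if (anyDuplicated(ek)) stop("duplicate index events")
  if (anyDuplicated(sk)) stop("duplicate sequenced wells")
  keys <- union(ek, sk)
  ei <- match(keys, ek)
  si <- match(keys, sk)
  plate <- ifelse(is.na(ei), chain_sets$plate[si], events$plate[ei])
  well <- ifelse(is.na(ei), chain_sets$well[si], events$well[ei])
  out <- data.frame(cell_id = paste0(plate, ":", well),
                    patient = plate_manifest$patient[
                      match(plate, plate_manifest$plate)],
                    plate = plate, well = well,
                    provenance = ifelse(is.na(ei), "sequencing_only",
                                        ifelse(is.na(si), "index_only",
                                               "matched")))
  for (cn in setdiff(names(events), c("plate", "well"))) {
    out[[cn]] <- events[[cn]][ei]
  }
  for (cn in setdiff(names(chain_sets),
                     c("cell_id", "plate", "well"))) {
    out[[cn]] <- chain_sets[[cn]][si]
  }
  out
}

#' Arrange cells and features into a heatmap bundle
#'
#' Columns (cells) are ordered so that members of one clonotype are
#' adjacent: expanded clones first (by size descending, then clone key),
#' then singleton/unkeyed cells by cell id. Rows are a fixed feature
#' schema: the clone-identity band, then marker features, then gene
#' features. The arrangement is deterministic and invariant to input row
#' order.
#'
#' @param cell_table merged cell table (must contain `cell_id`).
#' @param ct a `clonotype_result`.
#' @param marker_values data.frame `cell_id` + numeric marker columns
#'   (e.g. arcsinh intensities).
#' @param gene_calls data.frame `cell_id` + logical gene columns.
#' @return list of class `heatmap_bundle`: `matrix` (features x cells),
#'   `cell_order`, `feature_order`, `clone_blocks` (data.frame clone id,
#'   first/last column), `clone_band` (clone index per column, 0 for
#'   singletons).
#' @export
build_heatmap_bundle <- function(cell_table, ct, marker_values, gene_calls) {
  ca <- ct$cell_assignments
  clon <- ct$clonotypes
  cells <- sort(unique(cell_table$cell_id))
  cid <- ca$clonotype_id[match(cells, ca$cell_id)]
  size <- clon$size[match(cid, clon$clonotype_id)]
  key <- clon$clone_key[match(cid, clon$clonotype_id)]
  expanded <- !is.na(size) & size >= 2L

  ord <- order(!expanded,                      # expanded clones first
               -ifelse(expanded, size, 0L),    # by size desc
               ifelse(expanded, key, ""),      # then clone key
               cells)                          # then cell id
  cells <- cells[ord]
  cid <- cid[ord]; expanded <- expanded[ord]

  band <- integer(length(cells))
  ex_ids <- unique(cid[expanded])
  band[expanded] <- match(cid[expanded], ex_ids)

  markers <- setdiff(names(marker_values), "cell_id")
  genes <- setdiff(names(gene_calls), "cell_id")
  nm <- c("clone", markers, genes)
  mat <- matrix(NA_real_, length(nm), length(cells),
                dimnames = list(nm, cells))
  mat["clone", ] <- band
  mi <- match(cells, marker_values$cell_id)
  for (m in markers) mat[m, ] <- marker_values[[m]][mi]
  gi <- match(cells, gene_calls$cell_id)
  for (g in genes) mat[g, ] <- as.numeric(gene_calls[[g]][gi])

  blocks <- if (length(ex_ids) > 0L) {
    data.frame(clonotype_id = ex_ids,
               first = vapply(seq_along(ex_ids),
                              function(k) min(which(band == k)), integer(1)),
               last = vapply(seq_along(ex_ids),
                             function(k) max(which(band == k)), integer(1)))
  } else {
    data.frame(clonotype_id = character(0), first = integer(0),
               last = integer(0))
  }
  out <- list(matrix = mat, cell_order = cells, feature_order = nm,
              clone_blocks = blocks, clone_band = band)
  class(out) <- "heatmap_bundle"
  out
}

#' Write a heatmap bundle as matrix TSV plus JSON sidecar
#' @param bundle a `heatmap_bundle`.
#' @param dir output directory.
#' @return invisibly `dir`.
#' @export
write_heatmap_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(feature = rownames(bundle$matrix),
                                bundle$matrix, check.names = FALSE),
                     file.path(dir, "heatmap_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(cell_order = bundle$cell_order,
         feature_order = bundle$feature_order,
         clone_blocks = bundle$clone_blocks),
    file.path(dir, "heatmap_sidecar.json"), auto_unbox = FALSE)
  invisible(dir)
}
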