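# Clonotype calling and clonal-expansion statistics.
#
# A clonotype is a class of cells within one patient sharing identical
# TCRalpha/beta CDR3 amino-acid sequences; a clone is expanded if at least
# two cells share the identity. Clones are never merged across patients
# even when sequences coincide. Three pairing policies are offered because
# the treatment of cells with incomplete chain recovery is a genuine
# analysis choice:
#   paired_strict    key = (beta CDR3 aa, dominant alpha CDR3 aa); cells
#                    without both productive chains are unkeyed (default)
#   beta_only        key = beta CDR3 aa
#   paired_any_alpha cells match when beta is identical and ANY retained
#                    alpha is shared (transitive closure via union-find)

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Group cells into clonotypes by CDR3 amino-acid identity
#'
#' @param cells data.frame with one row per cell: columns `cell_id`,
#'   `patient`, `beta_aa` (productive beta CDR3 aa or NA), `alpha1_aa`
#'   (dominant alpha or NA), `alpha2_aa` (secondary alpha or NA). Optional
#'   `beta_v`, `beta_j`, `alpha1_v`, `alpha1_j` when `use_vj = TRUE`.
#' @param policy pairing policy, see above.
#' @param use_vj include V/J gene identity in the key (default FALSE: the
#'   clone definition is CDR3 amino-acid identity only).
#' @return list of class `clonotype_result`: `clonotypes` (patient,
#'   clonotype_id, clone_key, size, expanded, member_cell_ids
#'   semicolon-joined), `cell_assignments` (cell_id, patient, clonotype_id
#'   or NA, keyed flag), `policy`.
#' @export
assign_clonotypes <- function(cells,
                              policy = c("paired_strict", "beta_only",
                                         "paired_any_alpha"),
                              use_vj = FALSE) {
  policy <- match.arg(policy)
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell ids: ",
         paste(unique(cells$cell_id[duplicated(cells$cell_id)]),
               collapse = ", "))
  }
  has_beta <- !is.na(cells$beta_aa)
  has_alpha <- !is.na(cells$alpha1_aa)
  keyed <- switch(policy,
                  paired_strict = has_beta & has_alpha,
                  beta_only = has_beta,
                  paired_any_alpha = has_beta & has_alpha)
  vj <- function(chain) {
    if (!use_vj) return(rep("", nrow(cells)))
    paste0("|", cells[[paste0(chain, "_v")]], "|",
           cells[[paste0(chain, "_j")]])
  }

  assign_id <- rep(NA_character_, nrow(cells))
  for (p in unique(cells$patient)) {
    sel <- which(cells$patient == p & keyed)
    if (length(sel) == 0L) next
    if (policy == "paired_any_alpha") {
      # union-find within identical-beta groups over shared alphas
      beta_key <- paste0(cells$beta_aa[sel], vj("beta")[sel])
      parent <- uf_new(length(sel))
      for (bk in unique(beta_key)) {
        grp <- which(beta_key == bk)
        if (length(grp) < 2L) next
        for (i in grp[-1]) {
          for (j in grp[grp < i]) {
            ai <- stats::na.omit(c(cells$alpha1_aa[sel[i]],
                                   cells$alpha2_aa[sel[i]]))
            aj <- stats::na.omit(c(cells$alpha1_aa[sel[j]],
                                   cells$alpha2_aa[sel[j]]))
            if (length(intersect(ai, aj)) > 0L) {
              parent <- uf_union(parent, i, j)
            }
          }
        }
      }
      root <- vapply(seq_along(sel), function(i) uf_find(parent, i),
                     integer(1))
      assign_id[sel] <- paste0(p, "#", root)
    } else {
      key <- switch(policy,
        paired_strict = paste0(cells$beta_aa[sel], vj("beta")[sel], "+",
                               cells$alpha1_aa[sel], vj("alpha1")[sel]),
        beta_only = paste0(cells$beta_aa[sel], vj("beta")[sel]))
      assign_id[sel] <- paste0(p, "#", key)
    }
  }

  keyed_idx <- which(!is.na(assign_id))
  ids <- unique(assign_id[keyed_idx])
  clon <- data.frame(
    clonotype_id = sprintf("CT%05d", seq_along(ids)),
    raw = ids,
    patient = cells$patient[match(ids, assign_id)])
  clon$size <- as.integer(table(assign_id)[clon$raw])
  clon$expanded <- clon$size >= 2L
  clon$member_cell_ids <- vapply(clon$raw, function(r) {
    paste(cells$cell_id[which(assign_id == r)], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  # human-readable key: representative cell's CDR3s
  rep_cell <- match(clon$raw, assign_id)
  clon$clone_key <- paste0(cells$beta_aa[rep_cell], "+",
                           ifelse(is.na(cells$alpha1_aa[rep_cell]), "",
                                  cells$alpha1_aa[rep_cell]))
  clon$raw <- NULL

  cell_assignments <- data.frame(
    cell_id = cells$cell_id, patient = cells$patient,
    clonotype_id = clon$clonotype_id[match(assign_id,
                                           ids)][seq_len(nrow(cells))],
    keyed = !is.na(assign_id))
  cell_assignments$clonotype_id[is.na(assign_id)] <- NA_character_

  out <- list(clonotypes = clon[, c("patient", "clonotype_id", "clone_key",
                                    "size", "expanded", "member_cell_ids")],
              cell_assignments = cell_assignments, policy = policy)
  class(out) <- "clonotype_result"
  out
}

#' @export
print.clonotype_result <- function(x, ...) {
  cat("Clonotypes (policy ", x$policy, "): ", nrow(x$clonotypes),
      " clonotypes, ", sum(x$clonotypes$expanded), " expanded\n", sep = "")
  invisible(x)
}

#' Clone lineage, frequencies and per-patient expansion summaries
#'
#' Clone lineage is the strict majority of member lineages (`mixed` on a
#' tie). For CD8 clones, `frequency_within_cd8` is clone size divided by
#' the patient's keyed CD8+ cells - the denominator is cells contributing
#' to clonotyping (sequenced T cells), not all sorted cells. Patients with
#' zero keyed CD8 cells get missing (NA) frequencies, not zero.
#'
#' @param ct a `clonotype_result`.
#' @param cells data.frame with `cell_id` and `lineage` ("CD4"/"CD8").
#' @return list: `clonotypes` (input table plus `lineage` and
#'   `frequency_within_cd8`), `per_patient` (patient, n_keyed_cells,
#'   n_keyed_cd8, n_expanded_clones, n_expanded_cd8_clones,
#'   expanded_cell_freq_cd8, max_clone_freq_cd8).
#' @export
clone_statistics <- function(ct, cells) {
  clon <- ct$clonotypes
  lin <- cells$lineage[match(ct$cell_assignments$cell_id, cells$cell_id)]
  ca <- ct$cell_assignments
  ca$lineage <- lin

  keyed_cd8 <- tapply(ca$keyed & ca$lineage == "CD8", ca$patient, sum)

  memb <- split(ca$lineage, ca$clonotype_id)
  clon$lineage <- vapply(clon$clonotype_id, function(cid) {
    members <- memb[[cid]]
    n8 <- sum(members == "CD8", na.rm = TRUE)
    n4 <- sum(members == "CD4", na.rm = TRUE)
    if (n8 > n4) "CD8" else if (n4 > n8) "CD4" else "mixed"
  }, character(1), USE.NAMES = FALSE)
  denom <- as.numeric(keyed_cd8[clon$patient])
  clon$frequency_within_cd8 <- ifelse(clon$lineage == "CD8" & denom > 0,
                                      clon$size / denom, NA_real_)

  pts <- sort(unique(ca$patient))
  per_patient <- data.frame(patient = pts)
  per_patient$n_keyed_cells <- as.integer(tapply(ca$keyed, ca$patient,
                                                 sum)[pts])
  per_patient$n_keyed_cd8 <- as.integer(keyed_cd8[pts])
  ex <- clon[clon$expanded, , drop = FALSE]
  per_patient$n_expanded_clones <- vapply(pts, function(p)
    sum(ex$patient == p), integer(1))
  per_patient$n_expanded_cd8_clones <- vapply(pts, function(p)
    sum(ex$patient == p & ex$lineage == "CD8"), integer(1))
  per_patient$expanded_cell_freq_cd8 <- vapply(pts, function(p) {
    d <- as.numeric(keyed_cd8[p])
    if (is.na(d) || d == 0) return(NA_real_)
    sum(ex$size[ex$patient == p & ex$lineage == "CD8"]) / d
  }, numeric(1))
  per_patient$max_clone_freq_cd8 <- vapply(pts, function(p) {
    f <- ex$frequency_within_cd8[ex$patient == p & ex$lineage == "CD8"]
    if (length(f) == 0L || all(is.na(f))) NA_real_ else max(f, na.rm = TRUE)
  }, numeric(1))

  list(clonotypes = clon, per_patient = per_patient)
}
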