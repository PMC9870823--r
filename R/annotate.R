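# V/J annotation, CDR3 extraction and per-well consensus chain calls.
#
# Segment assignment is by minimum edit distance under semi-global
# alignment (segment fully aligned within the read). The CDR3 is extracted
# by mapping the reference anchor positions (V cysteine, J Phe/Trp) through
# the alignment, spanning both anchor codons inclusively, and translated in
# the V reading frame. Exact prefix/suffix matches short-circuit the
# alignment; at zero sequencing error everything takes that path.

# edit-distance scoring: match 0, mismatch -1, gap -1 => score == -distance
edit_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters <- c("A", "C", "G", "T", "N")
      m <- matrix(-1, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 0
      m["N", ] <- -1; m[, "N"] <- -1
      mat <<- m
    }
    mat
  }
})

# Semi-global (pattern-global) alignment of each pattern against one
# subject; returns edit distances and subject start/end of the best hits.
semiglobal_dist <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = edit_submat(),
    gapOpening = 0, gapExtension = 1)
  list(dist = -Biostrings::score(aln),
       start = Biostrings::start(Biostrings::subject(aln)),
       end = Biostrings::end(Biostrings::subject(aln)),
       aln = aln)
}

#' Assign the best V and J segment to a read insert
#'
#' Scores every reference segment by minimum edit distance under
#' semi-global alignment; the call's locus is the locus of the best V, and
#' the best J of that locus completes the call. Distance margins to the
#' second-best segment are reported.
#'
#' @param insert nucleotide string (barcode-trimmed read 1).
#' @param reference a `segment_reference`.
#' @param max_edit_frac maximum edit distance as a fraction of segment
#'   length (default 0.10); reads with no segment within tolerance are
#'   unannotated.
#' @return list with `annotated` (logical), and when annotated: `locus`,
#'   `v_call`, `j_call`, `v_dist`, `j_dist`, `v_margin`, `j_margin`.
#' @export
align_segments <- function(insert, reference, max_edit_frac = 0.10) {
  stopifnot(nchar(insert) > 0L)
  vs <- reference[reference$type == "V", , drop = FALSE]
  js <- reference[reference$type == "J", , drop = FALSE]
  unann <- list(annotated = FALSE)
  if (nchar(insert) < max(nchar(vs$sequence))) return(unann)

  dv <- semiglobal_dist(vs$sequence, insert)$dist
  best_v <- which.min(dv)
  if (dv[best_v] > max_edit_frac * nchar(vs$sequence[best_v])) return(unann)
  locus <- vs$locus[best_v]

  jl <- js[js$locus == locus, , drop = FALSE]
  dj <- semiglobal_dist(jl$sequence, insert)$dist
  best_j <- which.min(dj)
  if (dj[best_j] > max_edit_frac * nchar(jl$sequence[best_j])) return(unann)

  list(annotated = TRUE, locus = locus,
       v_call = vs$segment[best_v], j_call = jl$segment[best_j],
       v_dist = dv[best_v], j_dist = dj[best_j],
       v_margin = if (length(dv) > 1L) min(dv[-best_v]) - dv[best_v] else NA,
       j_margin = if (length(dj) > 1L) min(dj[-best_j]) - dj[best_j] else NA)
}

# Map a 1-based pattern position to the subject coordinate through a
# pairwise alignment (pattern globally aligned). NA when the position falls
# in a deletion.
map_pattern_pos <- function(aln, ppos) {
  pg <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sg <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  soff <- Biostrings::start(Biostrings::subject(aln)) - 1L
  pc <- 0L; sc <- 0L
  for (k in seq_along(pg)) {
    if (pg[k] != "-") pc <- pc + 1L
    if (sg[k] != "-") sc <- sc + 1L
    if (pc == ppos && pg[k] != "-") {
      if (sg[k] == "-") return(NA_integer_)
      return(soff + sc)
    }
  }
  NA_integer_
}

# Locate the read position (1-based) of a segment's anchor codon start.
locate_anchor <- function(insert, seg_row) {
  seq <- seg_row$sequence
  anchor1 <- seg_row$anchor_index + 1L
  if (seg_row$type == "V" && startsWith(insert, seq)) return(anchor1)
  if (seg_row$type == "J" && endsWith(insert, seq)) {
    return(nchar(insert) - nchar(seq) + anchor1)
  }
  sg <- semiglobal_dist(seq, insert)
  map_pattern_pos(sg$aln[1L], anchor1)
}

#' Extract the CDR3 from an annotated read insert
#'
#' The CDR3 spans from the V anchor codon (conserved Cys, inclusive) to the
#' J anchor codon (Phe/Trp of the FGXG motif, inclusive), located by
#' mapping the reference anchor positions through the alignment, and is
#' translated in the V reading frame. Junctions that are out of frame,
#' contain a stop codon or an ambiguous base, or whose anchor residues do
#' not translate to C / F/W are flagged unproductive (and are excluded from
#' clonotyping downstream).
#'
#' @param insert nucleotide string.
#' @param v_call,j_call assigned segment names.
#' @param reference a `segment_reference`.
#' @return list with `cdr3_nt`, `cdr3_aa`, `productive`, `reason` (NA when
#'   productive; otherwise one of "anchors_unlocatable", "out_of_frame",
#'   "stop_codon", "ambiguous_base", "anchor_mismatch").
#' @export
extract_cdr3 <- function(insert, v_call, j_call, reference) {
  vrow <- reference[match(v_call, reference$segment), , drop = FALSE]
  jrow <- reference[match(j_call, reference$segment), , drop = FALSE]
  if (nrow(vrow) != 1L || nrow(jrow) != 1L || anyNA(vrow$segment) ||
      anyNA(jrow$segment)) {
    stop("v_call/j_call not found in reference")
  }
  fail <- function(reason) list(cdr3_nt = NA_character_,
                                cdr3_aa = NA_character_,
                                productive = FALSE, reason = reason)
  vpos <- locate_anchor(insert, vrow)
  jpos <- locate_anchor(insert, jrow)
  if (is.na(vpos) || is.na(jpos) || jpos + 2L > nchar(insert) ||
      jpos <= vpos) {
    return(fail("anchors_unlocatable"))
  }
  nt <- substr(insert, vpos, jpos + 2L)
  if (nchar(nt) %% 3L != 0L) {
    return(c(list(cdr3_nt = nt, cdr3_aa = NA_character_,
                  productive = FALSE, reason = "out_of_frame")))
  }
  if (!grepl("^[ACGT]+$", nt)) {
    return(c(list(cdr3_nt = nt, cdr3_aa = NA_character_,
                  productive = FALSE, reason = "ambiguous_base")))
  }
  aa <- translate_nt(nt)
  out <- list(cdr3_nt = nt, cdr3_aa = aa, productive = TRUE,
              reason = NA_character_)
  if (grepl("\\*", aa)) {
    out$productive <- FALSE; out$reason <- "stop_codon"
  } else if (substr(aa, 1L, 1L) != "C" ||
             !substr(aa, nchar(aa), nchar(aa)) %in% c("F", "W")) {
    out$productive <- FALSE; out$reason <- "anchor_mismatch"
  }
  out
}

#' Collapse annotated reads of one well into consensus chain calls
#'
#' Reads are grouped by (locus, V, J, CDR3 nt); groups supported by at
#' least `min_reads` reads and at least `min_fraction` of the well's reads
#' for that locus are candidates. Among productive candidates, the top 1
#' beta and top 2 alpha groups by read count are retained (ties broken by
#' CDR3 nt lexicographic order). QC flags record missing/multiple chains
#' and dropped unproductive groups.
#'
#' @param reads data.frame with one row per annotated TCR read (or
#'   pre-aggregated group) for one well: columns `locus`, `v_call`,
#'   `j_call`, `cdr3_nt`, `cdr3_aa`, `productive`, and optionally `n_reads`
#'   (default 1 per row).
#' @param min_reads minimum supporting reads per group (default 2).
#' @param min_fraction minimum fraction of the well's locus reads
#'   (default 0.10).
#' @return list with `calls` (data.frame of retained ChainCalls: locus,
#'   v_call, j_call, cdr3_nt, cdr3_aa, supporting_reads,
#'   fraction_of_locus_reads, chain_rank) and `qc` (character vector of
#'   flags among no_beta, no_alpha, multiple_beta, unproductive_dropped,
#'   low_support, empty).
#' @export
collapse_well <- function(reads, min_reads = 2L, min_fraction = 0.10) {
  empty_calls <- data.frame(locus = character(0), v_call = character(0),
                            j_call = character(0), cdr3_nt = character(0),
                            cdr3_aa = character(0),
                            supporting_reads = integer(0),
                            fraction_of_locus_reads = numeric(0),
                            chain_rank = integer(0))
  if (is.null(reads) || nrow(reads) == 0L) {
    return(list(calls = empty_calls, qc = "empty"))
  }
  if (is.null(reads$n_reads)) reads$n_reads <- 1L
  key <- paste(reads$locus, reads$v_call, reads$j_call, reads$cdr3_nt,
               sep = "\r")
  grp <- stats::aggregate(list(supporting_reads = reads$n_reads),
                          by = list(key = key), FUN = sum)
  first <- match(grp$key, key)
  grp$locus <- reads$locus[first]
  grp$v_call <- reads$v_call[first]
  grp$j_call <- reads$j_call[first]
  grp$cdr3_nt <- reads$cdr3_nt[first]
  grp$cdr3_aa <- reads$cdr3_aa[first]
  grp$productive <- reads$productive[first]
  locus_tot <- tapply(grp$supporting_reads, grp$locus, sum)
  grp$fraction_of_locus_reads <-
    grp$supporting_reads / as.numeric(locus_tot[grp$locus])

  pass <- grp$supporting_reads >= min_reads &
    grp$fraction_of_locus_reads >= min_fraction
  qc <- character(0)
  if (any(!pass)) qc <- c(qc, "low_support")
  cand <- grp[pass, , drop = FALSE]
  if (any(!cand$productive)) qc <- c(qc, "unproductive_dropped")
  cand <- cand[cand$productive, , drop = FALSE]
  # deterministic: read count desc, then cdr3_nt lexicographic
  cand <- cand[order(-cand$supporting_reads, cand$cdr3_nt), , drop = FALSE]

  beta <- cand[cand$locus == "TRB", , drop = FALSE]
  alpha <- cand[cand$locus == "TRA", , drop = FALSE]
  if (nrow(beta) == 0L) qc <- c(qc, "no_beta")
  if (nrow(beta) > 1L) qc <- c(qc, "multiple_beta")
  if (nrow(alpha) == 0L) qc <- c(qc, "no_alpha")
  keep <- rbind(utils::head(beta, 1L), utils::head(alpha, 2L))
  if (nrow(keep) > 0L) {
    keep$chain_rank <- stats::ave(seq_len(nrow(keep)), keep$locus,
                                  FUN = seq_along)
  } else {
    keep$chain_rank <- integer(0)
  }
  cols <- c("locus", "v_call", "j_call", "cdr3_nt", "cdr3_aa",
            "supporting_reads", "fraction_of_locus_reads", "chain_rank")
  rownames(keep) <- NULL
  list(calls = keep[, cols, drop = FALSE],
       qc = if (length(qc)) unique(qc) else "ok")
}

# Classify the distinct insert sequences of a run: gene amplicon, TCR chain
# or unannotated. Exact dictionary / prefix+suffix matches first; edit
# distance fallbacks otherwise.
classify_inserts <- function(inserts, reference, gene_reference,
                             max_edit_frac = 0.10) {
  n <- length(inserts)
  out <- data.frame(insert = inserts, kind = "unannotated",
                    gene = NA_character_, locus = NA_character_,
                    v_call = NA_character_, j_call = NA_character_,
                    cdr3_nt = NA_character_, cdr3_aa = NA_character_,
                    productive = NA, reason = NA_character_)
  # tier 1a: exact gene amplicon
  gi <- match(inserts, gene_reference$sequence)
  is_gene <- !is.na(gi)
  out$kind[is_gene] <- "gene"
  out$gene[is_gene] <- gene_reference$gene[gi[is_gene]]

  # tier 1b: exact V prefix + J suffix
  todo <- which(!is_gene)
  if (length(todo) > 0L) {
    vs <- reference[reference$type == "V", , drop = FALSE]
    js <- reference[reference$type == "J", , drop = FALSE]
    v_hit <- rep(NA_integer_, n); j_hit <- rep(NA_integer_, n)
    for (i in seq_len(nrow(vs))) {
      hit <- todo[startsWith(inserts[todo], vs$sequence[i])]
      v_hit[hit] <- i
    }
    for (i in seq_len(nrow(js))) {
      hit <- todo[endsWith(inserts[todo], js$sequence[i])]
      j_hit[hit] <- ifelse(is.na(v_hit[hit]), j_hit[hit],
                           ifelse(vs$locus[v_hit[hit]] == js$locus[i], i,
                                  j_hit[hit]))
    }
    exact_tcr <- todo[!is.na(v_hit[todo]) & !is.na(j_hit[todo])]
    for (i in exact_tcr) {
      out$kind[i] <- "tcr"
      out$locus[i] <- vs$locus[v_hit[i]]
      out$v_call[i] <- vs$segment[v_hit[i]]
      out$j_call[i] <- js$segment[j_hit[i]]
    }
    # tier 2: edit-distance fallback
    rest <- setdiff(todo, exact_tcr)
    for (i in rest) {
      dg <- utils::adist(inserts[i], gene_reference$sequence)
      if (min(dg) <= max_edit_frac * nchar(gene_reference$sequence[
            which.min(dg)])) {
        out$kind[i] <- "gene"
        out$gene[i] <- gene_reference$gene[which.min(dg)]
        next
      }
      al <- align_segments(inserts[i], reference, max_edit_frac)
      if (isTRUE(al$annotated)) {
        out$kind[i] <- "tcr"
        out$locus[i] <- al$locus
        out$v_call[i] <- al$v_call
        out$j_call[i] <- al$j_call
      }
    }
  }
  # CDR3 extraction for all TCR inserts
  tcr <- which(out$kind == "tcr")
  for (i in tcr) {
    cd <- extract_cdr3(inserts[i], out$v_call[i], out$j_call[i], reference)
    out$cdr3_nt[i] <- cd$cdr3_nt
    out$cdr3_aa[i] <- cd$cdr3_aa
    out$productive[i] <- cd$productive
    out$reason[i] <- cd$reason
  }
  out
}

#' Annotate a demultiplexed run: chain calls and gene counts per cell
#'
#' Classifies every distinct insert (gene amplicon vs TCR chain), extracts
#' CDR3s, and collapses reads per well into consensus chain calls. Gene
#' read counts are summed per (cell, gene).
#'
#' @param dm a `demux_result` (or its `assignments` data.frame).
#' @param reference a `segment_reference`.
#' @param gene_reference gene amplicon reference data.frame.
#' @param min_reads,min_fraction chain-group support thresholds, see
#'   [collapse_well()].
#' @param max_edit_frac segment assignment tolerance, see
#'   [align_segments()].
#' @return list of class `annotation_result`: `chain_sets` (one row per
#'   well: cell_id, plate, well, qc), `chains` (retained chain calls with
#'   cell ids), `gene_counts` (cell_id, gene, count), `rearrangements`
#'   (AIRR-style table, includes unretained groups with `retained = FALSE`).
#' @export
annotate_cells <- function(dm, reference, gene_reference, min_reads = 2L,
                           min_fraction = 0.10, max_edit_frac = 0.10) {
  asg <- if (inherits(dm, "demux_result")) dm$assignments else dm
  a <- asg[asg$status == "assigned", , drop = FALSE]
  if (nrow(a) == 0L) {
    stop("no assigned reads to annotate")
  }
  cls <- classify_inserts(unique(a$insert), reference, gene_reference,
                          max_edit_frac)
  idx <- match(a$insert, cls$insert)
  a$cell_id <- paste0(a$plate, ":", a$well)

  # gene counts
  gsel <- cls$kind[idx] == "gene"
  gene_counts <- if (any(gsel)) {
    gc <- stats::aggregate(
      list(count = rep.int(1L, sum(gsel))),
      by = list(cell_id = a$cell_id[gsel], gene = cls$gene[idx[gsel]]),
      FUN = sum)
    gc[order(gc$cell_id, gc$gene), ]
  } else {
    data.frame(cell_id = character(0), gene = character(0),
               count = integer(0))
  }
  rownames(gene_counts) <- NULL

  # chain calls per well: aggregate read groups once, then collapse per cell
  tsel <- cls$kind[idx] == "tcr"
  tcr <- data.frame(cell_id = a$cell_id[tsel],
                    cls[idx[tsel], c("locus", "v_call", "j_call", "cdr3_nt",
                                     "cdr3_aa", "productive")],
                    row.names = NULL)
  if (nrow(tcr) > 0L) {
    gkey <- paste(tcr$cell_id, tcr$locus, tcr$v_call, tcr$j_call,
                  tcr$cdr3_nt, sep = "\r")
    agg <- stats::aggregate(list(n_reads = rep.int(1L, nrow(tcr))),
                            by = list(gkey = gkey), FUN = sum)
    first <- match(agg$gkey, gkey)
    tcr <- data.frame(tcr[first, , drop = FALSE], n_reads = agg$n_reads,
                      row.names = NULL)
  } else {
    tcr$n_reads <- integer(0)
  }
  by_cell <- split(tcr, tcr$cell_id)
  all_cells <- unique(a[, c("cell_id", "plate", "well")])
  chain_rows <- list(); set_rows <- list()
  for (k in seq_len(nrow(all_cells))) {
    cid <- all_cells$cell_id[k]
    cw <- collapse_well(by_cell[[cid]], min_reads = min_reads,
                        min_fraction = min_fraction)
    set_rows[[k]] <- data.frame(cell_id = cid, plate = all_cells$plate[k],
                                well = all_cells$well[k],
                                n_alpha = sum(cw$calls$locus == "TRA"),
                                n_beta = sum(cw$calls$locus == "TRB"),
                                qc = paste(cw$qc, collapse = ";"))
    if (nrow(cw$calls) > 0L) {
      chain_rows[[k]] <- data.frame(cell_id = cid, cw$calls)
    }
  }
  chain_sets <- do.call(rbind, set_rows)
  chains <- if (length(chain_rows)) do.call(rbind, chain_rows) else
    data.frame(cell_id = character(0), locus = character(0),
               v_call = character(0), j_call = character(0),
               cdr3_nt = character(0), cdr3_aa = character(0),
               supporting_reads = integer(0),
               fraction_of_locus_reads = numeric(0), chain_rank = integer(0))
  rownames(chain_sets) <- rownames(chains) <- NULL

  out <- list(chain_sets = chain_sets, chains = chains,
              gene_counts = gene_counts,
              rearrangements = airr_rearrangements(chains))
  class(out) <- "annotation_result"
  out
}

#' AIRR Rearrangement-style table from chain calls
#'
#' @param chains chain-call data.frame as produced by [annotate_cells()].
#' @return data.frame with AIRR-named columns: `cell_id`, `locus`,
#'   `v_call`, `j_call`, `junction`, `junction_aa`, `duplicate_count`,
#'   `productive`.
#' @export
airr_rearrangements <- function(chains) {
  data.frame(cell_id = chains$cell_id, locus = chains$locus,
             v_call = chains$v_call, j_call = chains$j_call,
             junction = chains$cdr3_nt, junction_aa = chains$cdr3_aa,
             duplicate_count = chains$supporting_reads,
             productive = rep(TRUE, nrow(chains)))
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("Annotation:", nrow(x$chain_sets), "wells,",
      nrow(x$chains), "retained chain calls,",
      length(unique(x$gene_counts$gene)), "genes counted\n")
  invisible(x)
}
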