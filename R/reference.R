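# Synthetic V/J segment and gene-amplicon references with CDR3 anchors.
#
# The CDR3 is delimited by conserved residues: the cysteine near the 3' end
# of the V segment and the phenylalanine/tryptophan of the J segment's FGXG
# motif. References carry these anchor positions explicitly (0-based offset
# of the anchor codon within the segment) so that CDR3 extraction is
# anchor-mapped rather than motif-scanned.

V_SEGMENT_LEN <- 60L
J_SEGMENT_LEN <- 48L
MIN_SEGMENT_DIST <- 5L

#' Generate a synthetic V/J segment reference
#'
#' Produces random, mutually distinguishable TRA/TRB V and J segments. Every
#' V segment ends in a cysteine codon (its CDR3 anchor, the last codon);
#' every J segment begins with a Phe/Trp codon followed by a glycine-rich
#' FGXG-like motif (anchor at offset 0). All segments are pairwise
#' separated by edit distance >= 5 so that annotation is unambiguous.
#'
#' @param n_v_per_locus number of V segments per locus (TRA and TRB).
#' @param n_j_per_locus number of J segments per locus.
#' @param seed integer seed; the same seed reproduces the reference exactly.
#' @return data.frame of class `segment_reference` with columns `segment`,
#'   `locus`, `type` ("V"/"J"), `sequence`, `anchor_index` (0-based).
#' @export
generate_reference <- function(n_v_per_locus, n_j_per_locus, seed = 1L) {
  stopifnot(n_v_per_locus >= 1L, n_j_per_locus >= 1L)
  set.seed(child_seed(seed, 1L))
  seqs <- character(0)

  draw_distinct <- function(make) {
    for (i in 1:1000) {
      s <- make()
      if (length(seqs) == 0L ||
          min(utils::adist(s, seqs)) >= MIN_SEGMENT_DIST) {
        seqs <<- c(seqs, s)
        return(s)
      }
    }
    stop("could not generate mutually distinguishable segments")
  }
  rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

  make_v <- function() {
    # random body ending in a Cys codon
    paste0(rand_nt(V_SEGMENT_LEN - 3L), sample(c("TGT", "TGC"), 1L))
  }
  make_j <- function() {
    # F/W anchor, then an FGXG-like glycine motif, then random tail
    paste0(sample(c("TTT", "TTC", "TGG"), 1L), "GGA", rand_nt(3L), "GGT",
           rand_nt(J_SEGMENT_LEN - 12L))
  }

  rows <- list()
  for (locus in c("TRA", "TRB")) {
    for (i in seq_len(n_v_per_locus)) {
      rows[[length(rows) + 1L]] <- data.frame(
        segment = sprintf("%sV%d", locus, i), locus = locus, type = "V",
        sequence = draw_distinct(make_v),
        anchor_index = V_SEGMENT_LEN - 3L)
    }
    for (i in seq_len(n_j_per_locus)) {
      rows[[length(rows) + 1L]] <- data.frame(
        segment = sprintf("%sJ%d", locus, i), locus = locus, type = "J",
        sequence = draw_distinct(make_j),
        anchor_index = 0L)
    }
  }
  ref <- do.call(rbind, rows)
  class(ref) <- c("segment_reference", "data.frame")
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  needed <- c("segment", "locus", "type", "sequence", "anchor_index")
  if (!all(needed %in% names(ref))) {
    stop("segment reference must have columns: ", paste(needed, collapse = ", "))
  }
  len <- nchar(ref$sequence)
  if (any(ref$anchor_index < 0L | ref$anchor_index + 3L > len)) {
    stop("anchor index outside segment sequence")
  }
  codon <- substr(ref$sequence, ref$anchor_index + 1L, ref$anchor_index + 3L)
  aa <- translate_nt(codon)
  bad_v <- ref$type == "V" & aa != "C"
  bad_j <- ref$type == "J" & !aa %in% c("F", "W")
  if (any(bad_v | bad_j)) {
    stop("anchor codon does not translate to the conserved residue for: ",
         paste(ref$segment[bad_v | bad_j], collapse = ", "))
  }
  invisible(ref)
}

#' Write a segment reference as FASTA plus anchor sidecar
#'
#' @param ref a `segment_reference` data.frame.
#' @param fasta_path output FASTA path.
#' @param anchors_path output tab-separated sidecar (segment, locus, type,
#'   anchor_index; 0-based).
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta_path, anchors_path) {
  ss <- Biostrings::DNAStringSet(ref$sequence)
  names(ss) <- ref$segment
  Biostrings::writeXStringSet(ss, fasta_path)
  utils::write.table(ref[, c("segment", "locus", "type", "anchor_index")],
                     anchors_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, anchors_path))
}

#' Read a segment reference written by [write_reference()]
#' @param fasta_path FASTA of segment sequences.
#' @param anchors_path anchor sidecar TSV.
#' @return a `segment_reference` data.frame.
#' @export
read_reference <- function(fasta_path, anchors_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  anchors <- utils::read.delim(anchors_path, stringsAsFactors = FALSE)
  idx <- match(anchors$segment, names(ss))
  if (anyNA(idx)) stop("anchor sidecar names a segment absent from the FASTA")
  ref <- data.frame(segment = anchors$segment, locus = anchors$locus,
                    type = anchors$type,
                    sequence = unname(as.character(ss)[idx]),
                    anchor_index = as.integer(anchors$anchor_index))
  rownames(ref) <- NULL
  class(ref) <- c("segment_reference", "data.frame")
  validate_reference(ref)
  ref
}

GENE_AMPLICON_LEN <- 150L

#' Generate synthetic cytokine / transcription-factor amplicon references
#'
#' One random amplicon per gene, pairwise well separated (edit distance
#' >= 20) so that read classification is unambiguous.
#'
#' @param genes character vector of gene names.
#' @param seed integer seed.
#' @param length amplicon length in nt.
#' @return data.frame with columns `gene`, `sequence`.
#' @export
generate_gene_reference <- function(genes, seed = 1L,
                                    length = GENE_AMPLICON_LEN) {
  set.seed(child_seed(seed, 2L))
  seqs <- character(0)
  for (g in genes) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      if (length(seqs) == 0L || min(utils::adist(s, seqs)) >= 20L) break
    }
    seqs <- c(seqs, s)
  }
  data.frame(gene = genes, sequence = seqs)
}

#' Write / read a gene amplicon reference (FASTA)
#' @param gene_ref data.frame from [generate_gene_reference()].
#' @param path FASTA path.
#' @return invisibly `path` (writer); the data.frame (reader).
#' @export
write_gene_reference <- function(gene_ref, path) {
  ss <- Biostrings::DNAStringSet(gene_ref$sequence)
  names(ss) <- gene_ref$gene
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_gene_reference
#' @export
read_gene_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- data.frame(gene = names(ss), sequence = unname(as.character(ss)))
  rownames(out) <- NULL
  out
}
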