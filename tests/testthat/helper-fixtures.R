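# Small deterministic fixtures built in code.

tiny_reference <- function() generate_reference(2L, 2L, seed = 5L)

# hand-built reference with fully controlled sequences/anchors; the two
# loci use unrelated bodies so segments stay mutually distinguishable
manual_reference <- function() {
  va_body <- "ATGGCTGCTACTGAAGCTGAT"
  vb_body <- "CCTCCACGACGATTGGTTCGA"
  ja_tail <- "GGAGCTGGTACTAAAGTTGTT"
  jb_tail <- "GGTTATGGACCGTCTCAACAA"
  ref <- data.frame(
    segment = c("TRAV1", "TRAJ1", "TRBV1", "TRBJ1"),
    locus = c("TRA", "TRA", "TRB", "TRB"),
    type = c("V", "J", "V", "J"),
    sequence = c(paste0(va_body, "TGT"),
                 paste0("TTC", ja_tail),
                 paste0(vb_body, "TGT"),
                 paste0("TGG", jb_tail)),
    anchor_index = c(nchar(va_body), 0L, nchar(vb_body), 0L))
  class(ref) <- c("segment_reference", "data.frame")
  ref
}

small_config <- function(...) {
  sim_config(n_patients = 2L, cells_per_patient = 150L, rng_seed = 11L, ...)
}

chain_insert_for_test <- function(v, j, cdr3_nt, reference) {
  indexclone:::chain_insert(v, j, cdr3_nt, reference)
}

# per-cell truth table in the shape assign_clonotypes() expects
truth_chain_table <- function(truth) {
  tc <- truth$cells
  data.frame(cell_id = tc$cell_id, patient = tc$patient,
             beta_aa = tc$cdr3b_aa, alpha1_aa = tc$cdr3a_aa,
             alpha2_aa = tc$cdr3a2_aa)
}

# true partition labels (clone id, or a unique label per singleton)
truth_partition <- function(truth, ids) {
  m <- match(ids, truth$cells$cell_id)
  ifelse(is.na(truth$cells$clone_id[m]), paste0("s_", ids),
         truth$cells$clone_id[m])
}
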