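# brute-force semi-global edit distance: minimum Levenshtein distance of
# the segment against any substring of the read
oracle_semiglobal <- function(segment, read) {
  n <- nchar(read)
  best <- Inf
  for (i in seq_len(n)) {
    for (j in i:n) {
      best <- min(best, utils::adist(segment, substr(read, i, j)))
    }
  }
  best
}

ref <- manual_reference()
v_of <- function(s) ref$sequence[ref$segment == s]

test_that("exact V+junction+J constructs annotate with distance 0", {
  insert <- paste0(v_of("TRBV1"), "GCCAGCAGT", v_of("TRBJ1"))
  al <- align_segments(insert, ref)
  expect_true(al$annotated)
  expect_equal(al$locus, "TRB")
  expect_equal(al$v_call, "TRBV1")
  expect_equal(al$j_call, "TRBJ1")
  expect_equal(al$v_dist, 0)
  expect_equal(al$j_dist, 0)
})

test_that("substitutions shift the edit distance exactly as the brute force says", {
  insert <- paste0(v_of("TRAV1"), "GGTACT", v_of("TRAJ1"))
  mutated <- insert
  substr(mutated, 2L, 2L) <- "C"   # TRAV1 starts ATG...
  substr(mutated, 5L, 5L) <- "A"
  al <- align_segments(mutated, ref)
  expect_true(al$annotated)
  expect_equal(al$v_call, "TRAV1")
  expect_equal(al$v_dist, 2)
  expect_equal(al$v_dist, oracle_semiglobal(v_of("TRAV1"), mutated))
  # and the brute force confirms no other V does better
  for (s in ref$segment[ref$type == "V" & ref$segment != "TRAV1"]) {
    expect_gt(oracle_semiglobal(v_of(s), mutated), al$v_dist)
  }
})

test_that("random sequences are rejected as unannotated", {
  bigref <- tiny_reference()
  set.seed(12)
  for (i in 1:100) {
    rand <- paste(sample(c("A", "C", "G", "T"), 120L, replace = TRUE),
                  collapse = "")
    expect_false(align_segments(rand, bigref)$annotated)
  }
})

test_that("CDR3 extraction spans both anchors and translates correctly", {
  # junction TGT GCC AGC AGT TTC -> CASSF (manual codon-table translation)
  insert <- paste0(v_of("TRAV1"), "GCCAGCAGT", v_of("TRAJ1"))
  cd <- extract_cdr3(insert, "TRAV1", "TRAJ1", ref)
  expect_true(cd$productive)
  expect_equal(cd$cdr3_nt, "TGTGCCAGCAGTTTC")
  expect_equal(cd$cdr3_aa, "CASSF")
  expect_equal(oracle_translate(cd$cdr3_nt), cd$cdr3_aa)
})

test_that("frame, stop-codon and anchor violations are flagged unproductive", {
  out_of_frame <- paste0(v_of("TRAV1"), "GCCA", v_of("TRAJ1"))
  cd1 <- extract_cdr3(out_of_frame, "TRAV1", "TRAJ1", ref)
  expect_false(cd1$productive)
  expect_equal(cd1$reason, "out_of_frame")

  with_stop <- paste0(v_of("TRAV1"), "TAAGCCAGC", v_of("TRAJ1"))
  cd2 <- extract_cdr3(with_stop, "TRAV1", "TRAJ1", ref)
  expect_false(cd2$productive)
  expect_equal(cd2$reason, "stop_codon")

  # mutate the V anchor cysteine codon away -> anchor mismatch
  broken <- paste0(v_of("TRAV1"), "GCCAGCAGT", v_of("TRAJ1"))
  vlen <- nchar(v_of("TRAV1"))
  substr(broken, vlen - 2L, vlen) <- "GGG"
  cd3 <- extract_cdr3(broken, "TRAV1", "TRAJ1", ref)
  expect_false(cd3$productive)
})

test_that("anchor mapping survives substitutions near the junction", {
  insert <- paste0(v_of("TRBV1"), "GCCAGCAGT", v_of("TRBJ1"))
  mutated <- insert
  substr(mutated, 4L, 4L) <- "A"  # error inside V, away from anchor
  cd <- extract_cdr3(mutated, "TRBV1", "TRBJ1", ref)
  expect_true(cd$productive)
  expect_equal(cd$cdr3_aa, "CASSW")  # TRBJ1 anchor is TGG = W
})

test_that("well collapse applies support thresholds, ranks and tie-breaks", {
  row <- function(locus, nt, n, productive = TRUE) {
    data.frame(locus = locus, v_call = "V", j_call = "J", cdr3_nt = nt,
               cdr3_aa = "X", productive = productive, n_reads = n)
  }
  # 18 vs 2 beta reads: both pass (fraction 0.9 / 0.1) but only top-1 kept
  cw <- collapse_well(rbind(row("TRB", "AAA", 18L), row("TRB", "CCC", 2L)))
  expect_equal(nrow(cw$calls), 1L)
  expect_equal(cw$calls$cdr3_nt, "AAA")
  expect_equal(cw$calls$supporting_reads, 18L)
  expect_true("multiple_beta" %in% strsplit(cw$qc, ";")[[1]] ||
                "multiple_beta" %in% cw$qc)

  # three alpha groups 10/9/1: top two retained, third fails min_reads too
  cw2 <- collapse_well(rbind(row("TRA", "AAA", 10L), row("TRA", "CCC", 9L),
                             row("TRA", "GGG", 1L)))
  expect_equal(sort(cw2$calls$supporting_reads), c(9L, 10L))
  expect_equal(cw2$calls$chain_rank[order(-cw2$calls$supporting_reads)],
               c(1L, 2L))

  # beta only: alpha flagged missing
  cw3 <- collapse_well(row("TRB", "AAA", 20L))
  expect_equal(cw3$calls$locus, "TRB")
  expect_true("no_alpha" %in% cw3$qc)

  # tie on read count: cdr3_nt lexicographic wins
  cw4 <- collapse_well(rbind(row("TRB", "TTT", 5L), row("TRB", "AAA", 5L)))
  expect_equal(cw4$calls$cdr3_nt, "AAA")

  # unproductive groups are excluded but flagged
  cw5 <- collapse_well(rbind(row("TRB", "AAA", 10L, productive = FALSE)))
  expect_equal(nrow(cw5$calls), 0L)
  expect_true("unproductive_dropped" %in% cw5$qc)
})

test_that("raising min_reads never increases retained calls (monotonicity)", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    reads <- data.frame(locus = sample(c("TRA", "TRB"), k, replace = TRUE),
                        v_call = "V", j_call = "J",
                        cdr3_nt = replicate(k, paste(
                          sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                          collapse = "")),
                        cdr3_aa = "X", productive = TRUE,
                        n_reads = sample(1:20, k, replace = TRUE))
    n_prev <- Inf
    for (mr in c(1L, 2L, 5L, 10L, 25L)) {
      n_now <- nrow(collapse_well(reads, min_reads = mr)$calls)
      expect_lte(n_now, n_prev)
      n_prev <- n_now
    }
  }
})

test_that("zero-error cohort annotation recovers every cell's chains", {
  cfg <- sim_config(n_patients = 1L, cells_per_patient = 50L,
                    clones_per_patient = list(dist = "fixed", value = 3L),
                    rng_seed = 19L)
  truth <- generate_cohort(cfg)
  scheme <- make_barcode_scheme(unique(truth$cells$plate), seed = 19L)
  reads <- synthesize_reads(truth, cfg, scheme)
  dm <- demultiplex(data.frame(id = reads$id, seq = reads$seq1),
                    data.frame(id = reads$id, seq = reads$seq2), scheme)
  ann <- annotate_cells(dm, truth$reference, truth$gene_reference)
  tc <- truth$cells
  ch <- ann$chains
  for (i in seq_len(nrow(tc))) {
    b <- ch[ch$cell_id == tc$cell_id[i] & ch$locus == "TRB" &
              ch$chain_rank == 1L, ]
    a <- ch[ch$cell_id == tc$cell_id[i] & ch$locus == "TRA" &
              ch$chain_rank == 1L, ]
    expect_equal(b$cdr3_aa, tc$cdr3b_aa[i])
    expect_equal(b$v_call, tc$beta_v[i])
    expect_equal(b$j_call, tc$beta_j[i])
    expect_equal(a$cdr3_aa, tc$cdr3a_aa[i])
  }
  # translation correctness on every retained call
  expect_true(all(vapply(seq_len(nrow(ch)), function(k)
    oracle_translate(ch$cdr3_nt[k]) == ch$cdr3_aa[k], logical(1))))
  # gene counts equal the emission counts exactly at zero error
  g <- truth$genes[truth$genes$count > 0, ]
  gc <- ann$gene_counts
  key <- paste(gc$cell_id, gc$gene)
  expect_setequal(key, paste(g$cell_id, g$gene))
  expect_equal(gc$count[match(paste(g$cell_id, g$gene), key)], g$count)
})

test_that("AIRR rearrangement export carries the schema columns", {
  chains <- data.frame(cell_id = "P1:A1", locus = "TRB", v_call = "TRBV1",
                       j_call = "TRBJ1", cdr3_nt = "TGTTTC",
                       cdr3_aa = "CF", supporting_reads = 7L,
                       fraction_of_locus_reads = 1, chain_rank = 1L)
  air <- airr_rearrangements(chains)
  expect_named(air, c("cell_id", "locus", "v_call", "j_call", "junction",
                      "junction_aa", "duplicate_count", "productive"))
  expect_equal(air$duplicate_count, 7L)
  expect_true(air$productive)
})
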