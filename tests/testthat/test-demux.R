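scheme96 <- make_barcode_scheme(c("P1", "P2"), seed = 6L)

test_that("exact and single-mismatch barcodes decode; ties are rejected", {
  bc <- function(pl, wl) paste0(scheme96$plate[pl], scheme96$well[wl])
  insert <- "ACGTACGTACGT"
  # exact
  r <- parse_barcodes(paste0(bc("P1", "B7"), insert), scheme96)
  expect_equal(r$status, "assigned")
  expect_equal(c(r$plate, r$well), c("P1", "B7"))
  expect_equal(c(r$plate_mm, r$well_mm), c(0L, 0L))
  expect_equal(r$insert, insert)
  # one substitution in the well barcode
  wbc <- scheme96$well[["B7"]]
  substr(wbc, 3L, 3L) <- setdiff(c("A", "C", "G", "T"),
                                 substr(wbc, 3L, 3L))[1]
  r1 <- parse_barcodes(paste0(scheme96$plate[["P1"]], wbc, insert), scheme96)
  expect_equal(r1$status, "assigned")
  expect_equal(c(r1$plate_mm, r1$well_mm), c(0L, 1L))
  expect_equal(r1$well, "B7")
  # equidistant (1,1) between two well codes -> ambiguous; scheme built by
  # hand because a distance-3 scheme cannot produce this case
  tie_scheme <- structure(
    list(plate = c(P1 = "AAAACCCC"),
         well = c(W1 = "AAAAAAAA", W2 = "AAAAAATT"),
         plate_len = 8L, well_len = 8L, max_mismatches = 1L),
    class = "barcode_scheme")
  q <- "AAAAAAAT"
  expect_equal(unname(sort(oracle_hamming(q, tie_scheme$well))), c(1L, 1L))
  rt <- parse_barcodes(paste0("AAAACCCC", q, insert), tie_scheme)
  expect_equal(rt$status, "ambiguous")
  # truncated and invalid inputs get their own reason codes
  expect_equal(parse_barcodes("ACGT", scheme96)$status, "truncated")
  expect_equal(parse_barcodes(paste0("XXXXXXXX", scheme96$well[["A1"]],
                                     insert), scheme96)$status,
               "invalid_base")
})

test_that("decoding agrees with a brute-force Hamming scan", {
  set.seed(33)
  codes <- scheme96$well
  for (i in 1:200) {
    q <- paste(sample(c("A", "C", "G", "T", "N"), 8L, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    d <- oracle_hamming(q, codes)
    r <- parse_barcodes(paste0(scheme96$plate[["P1"]], q, "ACGT"), scheme96)
    best <- min(d)
    if (best <= 1L && sum(d == best) == 1L) {
      expect_equal(r$well, names(codes)[which.min(d)])
      expect_equal(r$well_mm, best)
    } else {
      expect_true(is.na(r$well))
    }
  }
})

test_that("zero-error synthetic run demultiplexes perfectly against truth", {
  cfg <- sim_config(n_patients = 1L, cells_per_patient = 60L, rng_seed = 2L)
  truth <- generate_cohort(cfg)
  scheme <- make_barcode_scheme(unique(truth$cells$plate), seed = 2L)
  reads <- synthesize_reads(truth, cfg, scheme)
  dm <- demultiplex(data.frame(id = reads$id, seq = reads$seq1),
                    data.frame(id = reads$id, seq = reads$seq2), scheme)
  expect_equal(unname(dm$summary[["assigned"]]), nrow(reads))
  # per-well read counts equal the truth emission totals
  a <- dm$assignments
  got <- table(paste0(a$plate, ":", a$well))
  g <- truth$genes[truth$genes$count > 0, ]
  chain_reads <- nrow(reads) - sum(g$count)
  per_cell_genes <- tapply(g$count, g$cell_id, sum)
  expected_total <- sum(g$count) + chain_reads
  expect_equal(sum(got), expected_total)
  for (cid in names(per_cell_genes)) {
    expect_gte(got[[cid]], per_cell_genes[[cid]])
  }
})

test_that("reads are conserved and order-invariant through demultiplexing", {
  cfg <- sim_config(n_patients = 1L, cells_per_patient = 30L,
                    barcode_mismatch_rate = 0.2, rng_seed = 14L)
  truth <- generate_cohort(cfg)
  scheme <- make_barcode_scheme(unique(truth$cells$plate), seed = 14L)
  reads <- synthesize_reads(truth, cfg, scheme)
  # push some reads beyond tolerance
  reads$seq1[1:50] <- paste0(strrep("N", 16L),
                             substr(reads$seq1[1:50], 17L,
                                    nchar(reads$seq1[1:50])))
  dm <- demultiplex(data.frame(id = reads$id, seq = reads$seq1),
                    data.frame(id = reads$id, seq = reads$seq2), scheme)
  s <- dm$summary
  expect_equal(unname(s[["total"]]),
               unname(s[["assigned"]] + s[["no_match"]] + s[["ambiguous"]] +
                        s[["truncated"]] + s[["invalid_base"]]))
  expect_equal(unname(s[["total"]]), nrow(reads))
  # permutation invariance of per-bin multisets
  set.seed(1)
  perm <- sample.int(nrow(reads))
  dm2 <- demultiplex(data.frame(id = reads$id[perm], seq = reads$seq1[perm]),
                     data.frame(id = reads$id[perm], seq = reads$seq2[perm]),
                     scheme)
  key <- function(d) {
    a <- d$assignments[d$assignments$status == "assigned", ]
    sort(paste(a$plate, a$well, a$insert))
  }
  expect_identical(key(dm), key(dm2))
  expect_identical(dm$summary, dm2$summary)
})

test_that("corruption beyond tolerance leaves ~95% assigned (binomial regime)", {
  scheme <- scheme96
  set.seed(77)
  n <- 10000L
  wells <- sample(names(scheme$well), n, replace = TRUE)
  seq1 <- paste0(scheme$plate[["P1"]], scheme$well[wells], "ACGTACGT")
  corrupt <- stats::runif(n) < 0.05
  # replace the well barcode with Ns: beyond any mismatch tolerance
  seq1[corrupt] <- paste0(scheme$plate[["P1"]], strrep("N", 8L), "ACGTACGT")
  r <- parse_barcodes(seq1, scheme)
  frac <- mean(r$status == "assigned")
  se <- sqrt(0.95 * 0.05 / n)
  expect_lt(abs(frac - 0.95), 3 * se)
  expect_true(all(r$status[corrupt] != "assigned"))
})

test_that("empty input and desynchronized mates are handled", {
  empty <- data.frame(id = character(0), seq = character(0))
  dm <- demultiplex(empty, empty, scheme96)
  expect_equal(unname(dm$summary[["total"]]), 0L)
  expect_equal(nrow(dm$assignments), 0L)
  r1 <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACGT"))
  r2 <- data.frame(id = c("a", "c"), seq = c("ACGT", "ACGT"))
  expect_error(demultiplex(r1, r2, scheme96), "desynchronized.*'b'")
})

test_that("per-well bins are written with trimmed read 1", {
  cfg <- sim_config(n_patients = 1L, cells_per_patient = 20L,
                    clones_per_patient = list(dist = "fixed", value = 2L),
                    rng_seed = 9L)
  truth <- generate_cohort(cfg)
  scheme <- make_barcode_scheme(unique(truth$cells$plate), seed = 9L)
  reads <- synthesize_reads(truth, cfg, scheme)
  dm <- demultiplex(data.frame(id = reads$id, seq = reads$seq1),
                    data.frame(id = reads$id, seq = reads$seq2), scheme)
  d <- withr::local_tempdir()
  write_demux_bins(dm, d)
  cell <- truth$cells[3L, ]
  f <- file.path(d, cell$plate, paste0(cell$well, "_R1.fastq.gz"))
  expect_true(file.exists(f))
  binned <- read_fastq(f)
  a <- dm$assignments
  expect_setequal(binned$seq,
                  a$insert[a$plate == cell$plate & a$well == cell$well])
})
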