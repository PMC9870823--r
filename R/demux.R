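# Plate/well barcode schemes and read demultiplexing.
#
# Nested-PCR constructs carry a plate barcode then a well barcode at the 5'
# end of read 1, at fixed offsets. Decoding is unique-nearest within a
# mismatch tolerance: a read is assigned only if exactly one barcode lies
# within `max_mismatches` and every other barcode is strictly farther.
# Ambiguous reads are never force-assigned - a misassigned well corrupts a
# single-cell identity, which is worse than dropping the read.

#' Construct a plate/well barcode scheme
#'
#' Barcodes are generated greedily at pairwise Hamming distance
#' >= 2*max_mismatches + 1 within each set, which guarantees that
#' `max_mismatches`-error decoding is unambiguous.
#'
#' @param plate_ids character vector of plate identifiers.
#' @param wells character vector of well coordinates (default: full 96-well
#'   layout).
#' @param bc_length barcode length in nt (default 8).
#' @param max_mismatches per-barcode mismatch tolerance (default 1).
#' @param seed integer seed.
#' @return object of class `barcode_scheme`: list with named character
#'   vectors `plate` and `well`, plus `plate_len`, `well_len`,
#'   `max_mismatches`.
#' @export
make_barcode_scheme <- function(plate_ids, wells = plate_wells(),
                                bc_length = 8L, max_mismatches = 1L,
                                seed = 1L) {
  set.seed(child_seed(seed, 3L))
  min_dist <- 2L * max_mismatches + 1L
  gen_set <- function(n) {
    codes <- character(0)
    tries <- 0L
    while (length(codes) < n) {
      s <- paste(sample(c("A", "C", "G", "T"), bc_length, replace = TRUE),
                 collapse = "")
      if (length(codes) == 0L ||
          min(hamming_to_codes(s, codes)) >= min_dist) {
        codes <- c(codes, s)
      }
      tries <- tries + 1L
      if (tries > 200L * n) stop("cannot satisfy barcode distance constraint")
    }
    codes
  }
  scheme <- list(plate = stats::setNames(gen_set(length(plate_ids)), plate_ids),
                 well = stats::setNames(gen_set(length(wells)), wells),
                 plate_len = as.integer(bc_length),
                 well_len = as.integer(bc_length),
                 max_mismatches = as.integer(max_mismatches))
  class(scheme) <- "barcode_scheme"
  validate_scheme(scheme)
  scheme
}

validate_scheme <- function(scheme) {
  min_dist <- 2L * scheme$max_mismatches + 1L
  for (set in c("plate", "well")) {
    codes <- scheme[[set]]
    if (length(unique(nchar(codes))) != 1L) {
      stop(set, " barcodes must share one length")
    }
    if (length(codes) > 1L) {
      d <- hamming_to_codes(codes, codes)
      diag(d) <- NA_integer_
      if (min(d, na.rm = TRUE) < min_dist) {
        stop(set, " barcodes violate pairwise Hamming distance >= ", min_dist)
      }
    }
  }
  invisible(scheme)
}

#' Write / read a barcode scheme as TSV
#' @param scheme a `barcode_scheme`.
#' @param path TSV path (columns kind, id, barcode).
#' @param max_mismatches tolerance to attach on read (default 1).
#' @return invisibly `path` (writer); a `barcode_scheme` (reader).
#' @export
write_scheme <- function(scheme, path) {
  df <- rbind(
    data.frame(kind = "plate", id = names(scheme$plate),
               barcode = unname(scheme$plate)),
    data.frame(kind = "well", id = names(scheme$well),
               barcode = unname(scheme$well)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path, max_mismatches = 1L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  scheme <- list(
    plate = stats::setNames(df$barcode[df$kind == "plate"],
                            df$id[df$kind == "plate"]),
    well = stats::setNames(df$barcode[df$kind == "well"],
                           df$id[df$kind == "well"]),
    plate_len = nchar(df$barcode[df$kind == "plate"][1]),
    well_len = nchar(df$barcode[df$kind == "well"][1]),
    max_mismatches = as.integer(max_mismatches))
  class(scheme) <- "barcode_scheme"
  validate_scheme(scheme)
  scheme
}

# Decode one barcode region against one code set. Returns list of vectors:
# id (NA when unassigned), mismatches, status (assigned|no_match|ambiguous).
decode_one <- function(region, codes, max_mm) {
  n <- length(region)
  id <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  status <- rep("no_match", n)
  # fast path: exact dictionary hit (unique-nearest is automatic because the
  # scheme guarantees pairwise distance > max_mm + 0)
  hit <- match(region, codes)
  exact <- !is.na(hit)
  id[exact] <- names(codes)[hit[exact]]
  mm[exact] <- 0L
  status[exact] <- "assigned"
  rest <- which(!exact)
  if (length(rest) > 0L) {
    d <- hamming_to_codes(region[rest], codes)
    best <- apply(d, 1L, min)
    nbest <- rowSums(d == best)
    best_j <- apply(d, 1L, which.min)
    ok <- best <= max_mm & nbest == 1L
    amb <- best <= max_mm & nbest > 1L
    id[rest[ok]] <- names(codes)[best_j[ok]]
    mm[rest[ok]] <- best[ok]
    status[rest[ok]] <- "assigned"
    status[rest[amb]] <- "ambiguous"
    mm[rest] <- ifelse(status[rest] == "assigned", mm[rest], best)
  }
  list(id = id, mismatches = mm, status = status)
}

#' Decode plate and well barcodes from read-1 sequences
#'
#' Barcodes sit at fixed offsets: plate barcode first, well barcode
#' immediately after. A read is assigned iff both barcodes decode uniquely
#' within the scheme's mismatch tolerance; otherwise the reason is one of
#' `truncated` (read shorter than the barcode region), `invalid_base`
#' (characters outside ACGTN), `no_match`, `ambiguous`. N bases count as
#' mismatches.
#'
#' @param read1_seq character vector of read-1 sequences.
#' @param scheme a `barcode_scheme`.
#' @param read_id optional read identifiers carried into the result.
#' @return data.frame with columns `read_id`, `plate`, `well`, `plate_mm`,
#'   `well_mm`, `status` ("assigned" or a reason code), and `insert` (read 1
#'   with the barcode region trimmed; NA when unassigned).
#' @export
parse_barcodes <- function(read1_seq, scheme, read_id = NULL) {
  n <- length(read1_seq)
  if (is.null(read_id)) read_id <- as.character(seq_len(n))
  region_len <- scheme$plate_len + scheme$well_len
  status <- rep(NA_character_, n)
  plate <- well <- rep(NA_character_, n)
  pmm <- wmm <- rep(NA_integer_, n)

  truncated <- nchar(read1_seq) < region_len
  status[truncated] <- "truncated"
  head_seq <- substr(read1_seq, 1L, region_len)
  invalid <- !truncated & !grepl("^[ACGTN]*$", head_seq)
  status[invalid] <- "invalid_base"

  todo <- which(!truncated & !invalid)
  if (length(todo) > 0L) {
    p <- decode_one(substr(read1_seq[todo], 1L, scheme$plate_len),
                    scheme$plate, scheme$max_mismatches)
    w <- decode_one(substr(read1_seq[todo], scheme$plate_len + 1L, region_len),
                    scheme$well, scheme$max_mismatches)
    plate[todo] <- p$id
    well[todo] <- w$id
    pmm[todo] <- p$mismatches
    wmm[todo] <- w$mismatches
    st <- ifelse(p$status == "assigned" & w$status == "assigned", "assigned",
                 ifelse(p$status == "no_match" | w$status == "no_match",
                        "no_match", "ambiguous"))
    status[todo] <- st
  }
  assigned <- status == "assigned"
  plate[!assigned] <- NA_character_
  well[!assigned] <- NA_character_
  insert <- ifelse(assigned, substr(read1_seq, region_len + 1L,
                                    nchar(read1_seq)), NA_character_)
  data.frame(read_id = read_id, plate = plate, well = well,
             plate_mm = pmm, well_mm = wmm, status = status,
             insert = insert, row.names = NULL)
}

#' Demultiplex a paired-end run into per-well read bins
#'
#' @param r1 path to read-1 FASTQ (gzip ok) or a data.frame with columns
#'   `id`, `seq` as returned by [read_fastq()].
#' @param r2 matching read-2 input; mates must be order-synchronized (a
#'   mismatching id is a hard failure naming the read).
#' @param scheme a `barcode_scheme`.
#' @return object of class `demux_result`: list with `assignments` (one row
#'   per read pair: read_id, plate, well, status, insert, seq2) and
#'   `summary` (total, assigned, and per-reason unassigned counts).
#' @export
demultiplex <- function(r1, r2, scheme) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (nrow(r1) != nrow(r2)) stop("read-1 and read-2 files differ in length")
  desync <- which(r1$id != r2$id)
  if (length(desync) > 0L) {
    stop("desynchronized mates at record ", desync[1],
         ": '", r1$id[desync[1]], "' vs '", r2$id[desync[1]], "'")
  }
  asg <- parse_barcodes(r1$seq, scheme, read_id = r1$id)
  asg$seq2 <- r2$seq
  reasons <- c("no_match", "ambiguous", "truncated", "invalid_base")
  summary <- c(total = nrow(asg), assigned = sum(asg$status == "assigned"),
               stats::setNames(vapply(reasons,
                                      function(r) sum(asg$status == r),
                                      integer(1)), reasons))
  out <- list(assignments = asg, summary = summary)
  class(out) <- "demux_result"
  out
}

#' @export
print.demux_result <- function(x, ...) {
  s <- x$summary
  cat("Demultiplexing of", s[["total"]], "read pairs:",
      s[["assigned"]], "assigned",
      sprintf("(%.1f%%)", 100 * s[["assigned"]] / max(1, s[["total"]])), "\n")
  un <- s[setdiff(names(s), c("total", "assigned"))]
  un <- un[un > 0]
  if (length(un)) cat("  unassigned:",
                      paste(names(un), un, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write per-well FASTQ bins from a demultiplexing result
#'
#' Creates `<outdir>/<plate>/<well>_R1.fastq.gz` and `..._R2.fastq.gz` for
#' every well that received reads, with the barcode region trimmed from
#' read 1, plus a tab-separated `summary.tsv`.
#'
#' @param dm a `demux_result`.
#' @param outdir output directory.
#' @return invisibly `outdir`.
#' @export
write_demux_bins <- function(dm, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  a <- dm$assignments[dm$assignments$status == "assigned", , drop = FALSE]
  for (pl in unique(a$plate)) {
    pdir <- file.path(outdir, pl)
    dir.create(pdir, showWarnings = FALSE)
    ap <- a[a$plate == pl, , drop = FALSE]
    for (wl in unique(ap$well)) {
      aw <- ap[ap$well == wl, , drop = FALSE]
      write_fastq(aw$read_id, aw$insert,
                  file.path(pdir, paste0(wl, "_R1.fastq.gz")))
      write_fastq(aw$read_id, aw$seq2,
                  file.path(pdir, paste0(wl, "_R2.fastq.gz")))
    }
  }
  utils::write.table(data.frame(metric = names(dm$summary),
                                count = as.integer(dm$summary)),
                     file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
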