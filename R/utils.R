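# Shared helpers: well coordinates, Hamming distances, FASTQ i/o, translation.

#' Normalize a 96-well coordinate
#'
#' Accepts coordinates case-insensitively and with or without a zero-padded
#' column ("a01", "A01", "A1" all map to "A1"). Rows A-H, columns 1-12.
#'
#' @param x character vector of well coordinates.
#' @return character vector of normalized coordinates ("A1".."H12").
#' @export
normalize_well <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-H])0?([1-9][0-2]?)$", x))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("invalid 96-well coordinate(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  row <- vapply(m, `[`, character(1), 2L)
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  if (any(col < 1L | col > 12L)) stop("well column out of range 1-12")
  paste0(row, col)
}

#' All wells of a 96-well plate in row-major order
#' @return character vector "A1","A2",...,"H12".
#' @export
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

# Hamming distances between each query string and each code string.
# All strings must share one fixed length; returns an integer matrix
# length(queries) x length(codes). N never matches anything (counts as
# mismatch even against N).
hamming_to_codes <- function(queries, codes) {
  n <- unique(nchar(c(queries, codes)))
  if (length(n) != 1L) stop("hamming_to_codes: strings must have equal length")
  qm <- matrix(unlist(strsplit(queries, "", fixed = TRUE), use.names = FALSE),
               ncol = n, byrow = TRUE)
  out <- matrix(0L, nrow = length(queries), ncol = length(codes))
  for (j in seq_along(codes)) {
    cj <- strsplit(codes[j], "", fixed = TRUE)[[1]]
    d <- qm != rep(cj, each = nrow(qm))
    # N on either side is a mismatch, even N vs N
    d <- d | qm == "N" | rep(cj == "N", each = nrow(qm))
    out[, j] <- as.integer(rowSums(d))
  }
  out
}

# Reverse complement for plain character vectors (delegates to Biostrings).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate in-frame nucleotide strings to amino acids. Sequences containing
# characters other than ACGT, or with length not divisible by 3, yield NA.
translate_nt <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nchar(x) %% 3L == 0L & nchar(x) > 0L & grepl("^[ACGT]+$", x)
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(x[ok]),
                                no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

#' Write reads to a gzip FASTQ file
#'
#' All records receive the fixed quality string "I" (Phred+33 Q40), matching
#' the simulator's error model where per-base qualities carry no information.
#'
#' @param ids read identifiers (without the leading `@`).
#' @param seqs nucleotide sequences.
#' @param path output path; compressed with gzip when it ends in ".gz".
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  n <- length(ids)
  qual <- strrep("I", nchar(seqs))
  rec <- character(4L * n)
  if (n > 0L) {
    rec[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
    rec[seq(2L, by = 4L, length.out = n)] <- seqs
    rec[seq(3L, by = 4L, length.out = n)] <- "+"
    rec[seq(4L, by = 4L, length.out = n)] <- qual
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path, plain or gzip.
#' @return data.frame with columns `id` (header up to first whitespace) and
#'   `seq`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(id = character(0), seq = character(0)))
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss), row.names = NULL)
}

# Deterministic child seed derived from a base seed (kept < 2^31).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2011 + as.numeric(k) * 7919) %% 2147483629)
}
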