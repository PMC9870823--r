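# Independent oracles used across tests. These are deliberately naive,
# self-contained reimplementations (hand-coded codon table, brute-force
# scans, exhaustive enumeration) kept separate from the package code paths
# they check.

# standard genetic code, hand-coded
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt) {
  stopifnot(nchar(nt) %% 3 == 0)
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  paste(ORACLE_CODONS[codons], collapse = "")
}

# brute-force Hamming distance of one query against each code
oracle_hamming <- function(query, codes) {
  q <- strsplit(query, "")[[1]]
  vapply(strsplit(codes, ""), function(cc) {
    sum(q != cc | q == "N" | cc == "N")
  }, integer(1))
}

# exhaustive two-sided rank-sum p-value over all rank assignments (no ties)
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  W <- sum(rank(c(x, y))[seq_len(nx)])
  all_w <- apply(utils::combn(N, nx), 2, sum)
  min(1, 2 * min(mean(all_w <= W), mean(all_w >= W)))
}

# brute-force partition of cells into clonotypes by pairwise identity +
# transitive closure (union-find free: repeated merging)
oracle_partition <- function(ids, match_fun) {
  groups <- as.list(seq_along(ids))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (is.null(groups[[i]])) next
      for (j in seq_along(groups)) {
        if (j <= i || is.null(groups[[j]])) next
        pairs <- expand.grid(a = groups[[i]], b = groups[[j]])
        if (any(mapply(match_fun, pairs$a, pairs$b))) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups <- Filter(Negate(is.null), groups)
  out <- integer(length(ids))
  for (g in seq_along(groups)) out[groups[[g]]] <- g
  out
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  x <- sum(choose(tab, 2))
  ra <- sum(choose(rowSums(tab), 2)); cb <- sum(choose(colSums(tab), 2))
  e <- ra * cb / choose(n, 2)
  (x - e) / ((ra + cb) / 2 - e)
}
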