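# Fixtures built in code; nothing binary, nothing read from disk.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# one handcrafted AAindex1 record: I rows 0.1..1.0 / 1.1..2.0
toy_aaindex_text <- function(acc = "TOY000101", na_slot = NULL) {
  v <- sprintf("%.1f", seq(0.1, 2.0, by = 0.1))
  if (!is.null(na_slot)) v[na_slot] <- "NA"
  paste(c(paste("H", acc),
          "D toy linear scale",
          "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
          paste0("   ", paste(v[1:10], collapse = "  ")),
          paste0("   ", paste(v[11:20], collapse = "  ")),
          "//"), collapse = "\n")
}

toy_scale <- function(acc = "TOY000101", values = seq(0.1, 2.0, by = 0.1),
                      class = "other") {
  aa_scale(acc, stats::setNames(values, AA20), char_class = class)
}

# spec-style toy alignment: ref "A-CD", family "AXCD", "-YC-"
toy_alignment <- function() {
  aa_alignment(c("ref", "f1", "f2"), c("A-CD", "AXCD", "-YC-"), "ref")
}

random_alignment <- function(n_fam, L, seed, gap_frac = 0.1) {
  set.seed(seed)
  ref <- paste(sample(AA20, L, TRUE), collapse = "")
  fam <- vapply(seq_len(n_fam), function(i) {
    ch <- sample(AA20, L, TRUE)
    ch[runif(L) < gap_frac] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  aa_alignment(c("ref", sprintf("f%02d", seq_len(n_fam))), c(ref, fam), "ref")
}

random_scale <- function(acc, seed, class = "other") {
  set.seed(seed)
  toy_scale(acc, rnorm(20), class)
}

# minimal Clustal rendition of an alignment (dialect as emitted by common
# aligners: header, blank lines, name-padded block, conservation line)
write_clustal <- function(aln, path) {
  pad <- formatC(aln$ids, width = 16, flag = "-")
  writeLines(c("CLUSTAL format alignment",
               "", "",
               paste0(pad, aln$seqs),
               strrep(" ", 16)), path)
  invisible(path)
}

write_fasta <- function(aln, path) {
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), path)
  invisible(path)
}

# CA-only PDB text at given coordinates (list/matrix of xyz rows)
toy_pdb_text <- function(xyz, resnames = NULL, chain = "A",
                         occ = NULL, alt = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  if (is.null(occ)) occ <- rep(1, n)
  if (is.null(alt)) alt <- rep(" ", n)
  c(sprintf("ATOM  %5d  CA %s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
            seq_len(n), alt, resnames, chain, seq_len(n),
            xyz[, 1], xyz[, 2], xyz[, 3], occ),
    "END")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
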