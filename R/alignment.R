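#' Construct an alignment object
#'
#' In-memory constructor for a protein multiple sequence alignment
#' containing the reference protein and its family. Sequences are
#' uppercased, `.` gap characters are normalized to `-`, and any letter
#' outside the 20 standard residues plus `X` and `-` is mapped to `X`
#' with a warning.
#'
#' @param ids Character vector of record identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param ref_id Identifier of the reference protein; must occur exactly
#'   once among `ids`.
#' @return An object of class `aa_alignment`: list with `ids`, `seqs`,
#'   `ref_id`.
#' @export
aa_alignment <- function(ids, seqs, ref_id) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop_input("ids and seqs differ in length (%d vs %d)", length(ids), length(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  allowed <- c(AAINDEX_ORDER, "X", "-")
  n_bad <- 0L
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    bad <- !(ch %in% allowed)
    if (any(bad)) { n_bad <<- n_bad + sum(bad); ch[bad] <- "X" }
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  if (n_bad > 0L)
    warning(sprintf("%d non-standard residue letter(s) mapped to 'X'", n_bad))
  len <- nchar(seqs)
  if (length(unique(len)) > 1L) {
    off <- ids[len != stats::median(len)]
    stop_input("ragged alignment: sequence length differs for %s",
               paste(off, collapse = ", "))
  }
  if (sum(ids == ref_id) != 1L)
    stop_input("reference id '%s' occurs %d times in alignment (need exactly 1)",
               ref_id, sum(ids == ref_id))
  structure(list(ids = ids, seqs = seqs, ref_id = ref_id), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<%s> %d records x %d columns, reference '%s'\n",
              class(x)[1L], length(x$ids), nchar(x$seqs[1L]), x$ref_id))
  invisible(x)
}

#' Read a family alignment
#'
#' Reads an aligned FASTA or Clustal (.aln) file and normalizes it (see
#' [aa_alignment()]). Alignment is accepted as input; famdev does not run
#' an aligner.
#'
#' @param path Path to the alignment file.
#' @param ref_id Identifier of the reference protein.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, ref_id, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("alignment file not found: %s", path)
  if (format == "fasta") {
    ss <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop_input("failed to parse FASTA %s: %s",
                                                  path, conditionMessage(e)))
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else {
    m <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "clustal"),
                  error = function(e) stop_input("failed to parse Clustal %s: %s",
                                                 path, conditionMessage(e)))
    ss <- Biostrings::unmasked(m)
    ids <- names(ss)
    seqs <- as.character(ss)
  }
  aa_alignment(ids, seqs, ref_id)
}

#' Crop an alignment to the reference window
#'
#' Retains exactly the columns in which the reference sequence is non-gap
#' (family residues aligned outside the reference window are cropped off;
#' family gaps inside retained columns are preserved). Positions are
#' numbered 1..L to match conventional residue numbering of the reference.
#'
#' @param aln An `aa_alignment` (or an already-cropped alignment, in which
#'   case the operation is the identity).
#' @return An object of class `aa_cropped` (also an `aa_alignment`):
#'   fields `ids`, `seqs`, `ref_id`, `positions` (1..L) and `colmap`
#'   (0-based original column index per retained position).
#' @export
crop_to_reference <- function(aln) {
  ref <- aln$seqs[aln$ids == aln$ref_id]
  refc <- strsplit(ref, "")[[1L]]
  keep <- which(refc != "-")
  if (length(keep) == 0L) stop_input("reference '%s' is all gaps", aln$ref_id)
  M <- do.call(rbind, strsplit(aln$seqs, ""))
  seqs <- apply(M[, keep, drop = FALSE], 1L, paste, collapse = "")
  structure(list(ids = aln$ids, seqs = seqs, ref_id = aln$ref_id,
                 positions = seq_along(keep), colmap = keep - 1L),
            class = c("aa_cropped", "aa_alignment"))
}

#' Reference sequence of a cropped alignment
#'
#' @param ca An `aa_cropped` alignment.
#' @return Ungapped reference sequence (character scalar).
#' @export
reference_sequence <- function(ca) {
  ca$seqs[ca$ids == ca$ref_id]
}

#' Family residues at one reference position
#'
#' Returns the residue letters of the family (reference excluded unless
#' requested) at a reference position of the cropped alignment.
#'
#' @param ca An `aa_cropped` alignment.
#' @param r Reference position (1-based).
#' @param filter If `TRUE` (default), drop gaps (`-`) and unknowns (`X`).
#' @param include_reference Include the reference's own residue.
#' @return Character vector of residue letters, in record order.
#' @export
column_residues <- function(ca, r, filter = TRUE, include_reference = FALSE) {
  L <- nchar(ca$seqs[1L])
  if (!(is.numeric(r) && length(r) == 1L && r >= 1 && r <= L))
    stop_input("position r=%s out of range 1..%d", toString(r), L)
  keep <- if (include_reference) rep(TRUE, length(ca$ids)) else ca$ids != ca$ref_id
  ch <- substring(ca$seqs[keep], r, r)
  if (filter) ch <- ch[!ch %in% c("-", "X")]
  ch
}

#' Write a cropped alignment as aligned FASTA
#'
#' @param ca An `aa_cropped` alignment (any `aa_alignment` is accepted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(ca, path) {
  writeLines(paste0(">", ca$ids, "\n", ca$seqs), path)
  invisible(path)
}

# N x L character matrix of the family block (reference excluded unless
# include_reference); internal workhorse for vectorized column statistics.
family_matrix <- function(ca, include_reference = FALSE) {
  keep <- if (include_reference) rep(TRUE, length(ca$ids)) else ca$ids != ca$ref_id
  do.call(rbind, strsplit(ca$seqs[keep], ""))
}
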