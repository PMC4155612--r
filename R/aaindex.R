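#' Construct an amino-acid index scale
#'
#' An index scale assigns one numeric value to each of the 20 standard
#' amino acids, quantifying a biophysical property (hydrophobicity, helix
#' propensity, ...). Values are stored in the canonical AAindex residue
#' order (`A R N D C Q E G H I L K M F P S T W Y V`); `NA` marks a missing
#' entry.
#'
#' @param accession Accession string (e.g. `"KYTJ820101"`).
#' @param values Numeric vector of length 20. Either named by one-letter
#'   residue code (any order) or unnamed in canonical AAindex order.
#' @param description Free-text description.
#' @param char_class One of [char_classes()].
#' @return An object of class `aa_scale`: a list with fields `accession`,
#'   `description`, `char_class` and `values` (named numeric, length 20).
#' @export
#' @examples
#' s <- aa_scale("TOY000101", stats::setNames(1:20, famdev:::AAINDEX_ORDER))
#' s$values[["A"]]
aa_scale <- function(accession, values, description = "", char_class = "other") {
  if (length(values) != 20L)
    stop_input("scale %s: expected 20 residue values, got %d", accession, length(values))
  if (!is.null(names(values))) {
    if (!setequal(names(values), AAINDEX_ORDER))
      stop_input("scale %s: value names are not the 20 standard residues", accession)
    values <- values[AAINDEX_ORDER]
  } else {
    names(values) <- AAINDEX_ORDER
  }
  if (all(is.na(values)))
    stop_input("scale %s: all 20 values missing", accession)
  if (!char_class %in% CHAR_CLASSES)
    stop_input("scale %s: unknown characteristic class '%s'", accession, char_class)
  structure(list(accession = as.character(accession),
                 description = as.character(description),
                 char_class = char_class,
                 values = stats::setNames(as.numeric(values), AAINDEX_ORDER)),
            class = "aa_scale")
}

#' @export
print.aa_scale <- function(x, ...) {
  cat(sprintf("<aa_scale> %s [%s] %s\n", x$accession, x$char_class, x$description))
  print(round(x$values, 4))
  invisible(x)
}

#' Parse AAindex1 flat-file text
#'
#' Parses the GenomeNet AAindex1 dialect: records terminated by `//`, with
#' an `H` line (accession), `D` line(s) (description) and an `I` section
#' whose header lists residue pairs and which is followed by two rows of
#' ten values in the order `A R N D C Q E G H I / L K M F P S T W Y V`.
#' The token `NA` denotes a missing value.
#'
#' @param text Character vector: lines, or a single string with newlines.
#' @return List of [aa_scale] objects (class defaults to `"other"` until
#'   [assign_classes()] is applied). Empty input yields an empty list.
#' @seealso [read_aaindex1()], [format_aaindex1()]
#' @export
parse_aaindex1 <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) return(list())
  ends <- grepl("^//", lines)
  rec_id <- cumsum(c(0L, utils::head(as.integer(ends), -1L)))
  recs <- split(lines[!ends], rec_id[!ends])
  out <- list()
  for (rec in recs) {
    if (all(!nzchar(trimws(rec)))) next
    acc_line <- grep("^H ", rec, value = TRUE)
    acc <- if (length(acc_line)) trimws(sub("^H ", "", acc_line[1L])) else "<no accession>"
    d_i <- grep("^D ", rec)
    desc <- ""
    if (length(d_i)) {
      j <- d_i[1L]
      desc <- trimws(sub("^D ", "", rec[j]))
      # continuation lines are indented (no tag letter)
      while (j + 1L <= length(rec) && grepl("^\\s+\\S", rec[j + 1L])) {
        j <- j + 1L
        desc <- paste(desc, trimws(rec[j]))
      }
    }
    i_i <- grep("^I( |$)", rec)
    if (!length(i_i))
      stop_input("AAindex record %s: no I section", acc)
    j <- i_i[1L] + 1L
    rows <- character()
    while (j <= length(rec) && !grepl("^[A-Z] ", rec[j])) {
      rows <- c(rows, rec[j]); j <- j + 1L
    }
    tok <- unlist(strsplit(trimws(rows), "\\s+"))
    tok <- tok[nzchar(tok)]
    if (length(tok) != 20L)
      stop_input("AAindex record %s: malformed I section (expected 20 numeric tokens, got %d)",
                 acc, length(tok))
    vals <- suppressWarnings(ifelse(tok == "NA", NA_real_, as.numeric(tok)))
    bad <- which(!is.na(tok) & tok != "NA" & is.na(vals))
    if (length(bad))
      stop_input("AAindex record %s: non-numeric token '%s' in I section", acc, tok[bad[1L]])
    if (all(is.na(vals)))
      stop_input("AAindex record %s: all 20 values missing", acc)
    out[[length(out) + 1L]] <- aa_scale(acc, stats::setNames(vals, AAINDEX_ORDER), desc)
  }
  out
}

#' Read an AAindex1 flat file
#'
#' @param path Path to an AAindex1 file.
#' @return List of [aa_scale] objects.
#' @export
read_aaindex1 <- function(path) {
  if (!file.exists(path)) stop_input("AAindex file not found: %s", path)
  parse_aaindex1(readLines(path, warn = FALSE))
}

#' Format index scales as AAindex1 flat-file text
#'
#' Inverse of [parse_aaindex1()]: values are written at full precision so a
#' format/parse round trip reproduces them exactly; `NA` is written for
#' missing entries.
#'
#' @param scales A single [aa_scale] or a list of them.
#' @return Character scalar of AAindex1 text.
#' @export
format_aaindex1 <- function(scales) {
  if (inherits(scales, "aa_scale")) scales <- list(scales)
  fmt1 <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  blocks <- vapply(scales, function(s) {
    v <- fmt1(s$values)
    paste(c(paste("H", s$accession),
            paste("D", s$description),
            "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
            paste0("   ", paste(v[1:10], collapse = " ")),
            paste0("   ", paste(v[11:20], collapse = " ")),
            "//"), collapse = "\n")
  }, character(1L))
  paste0(paste(blocks, collapse = "\n"), "\n")
}

#' Read a class-assignment table
#'
#' Two-column tab-separated file with header `accession<TAB>class` mapping
#' AAindex accessions to the six characteristic classes.
#'
#' @param path Path to the TSV.
#' @return Named character vector (accession -> class), usable as the
#'   `cmap` argument of [assign_classes()].
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop_input("class map file not found: %s", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("accession", "class") %in% names(d)))
    stop_input("class map %s: expected header 'accession<TAB>class'", path)
  stats::setNames(as.character(d$class), as.character(d$accession))
}

#' Packaged default class map
#'
#' A hand-curated assignment of well-known AAindex accessions to the six
#' characteristic classes. Best-effort: the historical clustering of the
#' full database is not redistributable, so arbitrary accessions absent
#' from this table fall to the catch-all class `other` (see
#' [assign_classes()]); [build_class_map()] offers a broader
#' description-keyword reconstruction.
#'
#' @return Named character vector (accession -> class).
#' @export
default_class_map <- function() {
  read_class_map(system.file("extdata", "default_classes.tsv", package = "famdev"))
}

#' Assign characteristic classes to scales
#'
#' Accessions present in `cmap` receive that class; accessions absent from
#' it fall to the catch-all class `other` (so arbitrary AAindex snapshots
#' load without a complete table).
#'
#' @param scales List of [aa_scale] objects.
#' @param cmap Named character vector (accession -> class), e.g. from
#'   [read_class_map()] or [default_class_map()].
#' @return The scales with `char_class` fields updated.
#' @export
assign_classes <- function(scales, cmap) {
  bad <- setdiff(unique(cmap), CHAR_CLASSES)
  if (length(bad))
    stop_input("class map contains unknown class label(s): %s",
               paste(bad, collapse = ", "))
  lapply(scales, function(s) {
    s$char_class <- if (s$accession %in% names(cmap)) unname(cmap[[s$accession]]) else "other"
    s
  })
}

#' Build a class map from scale descriptions
#'
#' Keyword-based reconstruction of the six-class grouping from free-text
#' index descriptions. Precedence: hydrophobicity terms, then beta-sheet
#' terms, then helix/turn/coil terms, then composition, then generic
#' physicochemical terms; anything unmatched is `other` (which by design
#' also catches e.g. surface-exposure scales).
#'
#' @param scales List of [aa_scale] objects (their `description` fields
#'   are classified).
#' @return Named character vector (accession -> class).
#' @export
build_class_map <- function(scales) {
  cls <- vapply(scales, function(s) classify_description(s$description), character(1L))
  stats::setNames(cls, vapply(scales, `[[`, character(1L), "accession"))
}

classify_description <- function(d) {
  d <- tolower(d)
  if (grepl("hydrophob|hydropath|transfer free energy|partition|solvation|solvent", d))
    return("hydrophobicity")
  if (grepl("beta|sheet|strand", d)) return("beta_propensity")
  if (grepl("helix|turn|coil|alpha", d)) return("alpha_turn_propensity")
  if (grepl("composition|weight|number of atoms", d)) return("composition")
  if (grepl("volume|bulk|polar|charge|pk|isoelectric|refract|flexib|size", d))
    return("physicochemical")
  "other"
}

#' Standardize an index scale
#'
#' Centers and rescales the non-missing values to mean 0 and standard
#' deviation 1, using the population convention (divisor n): the 20
#' residue types are the complete population a scale describes, not a
#' sample. Missing values are preserved. Standardization makes loadings of
#' different scales comparable before principal-component summarisation.
#'
#' @param scale An [aa_scale].
#' @return The standardized [aa_scale].
#' @export
standardize_scale <- function(scale) {
  v <- scale$values
  ok <- !is.na(v)
  if (sum(ok) < 2L)
    stop_input("scale %s: fewer than 2 non-missing values", scale$accession)
  m <- mean(v[ok])
  s <- sqrt(mean((v[ok] - m)^2))
  if (s == 0)
    stop_input("constant scale: %s has zero spread", scale$accession)
  scale$values[ok] <- (v[ok] - m) / s
  scale
}
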