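#' Synthetic index scales with dominant first principal axis
#'
#' Generates random index scales for each of the six characteristic
#' classes. Scales within a class share a latent class prototype with
#' within-class correlation `rho` (default 0.7), so the first principal
#' axis dominates — emulating real index classes, where many published
#' scales measure variations of one underlying property. Deterministic
#' given `seed`.
#'
#' @param n_per_class Scales per class (>= 2).
#' @param seed Integer seed.
#' @param rho Within-class correlation of scale values (default 0.7).
#' @return List of `6 * n_per_class` [aa_scale]s with classes assigned.
#' @export
synth_scales <- function(n_per_class = 5L, seed = 1L, rho = 0.7) {
  if (n_per_class < 2L) stop_input("n_per_class must be >= 2")
  set.seed(seed)
  codes <- c(alpha_turn_propensity = "AT", beta_propensity = "BP",
             hydrophobicity = "HY", composition = "CO",
             physicochemical = "PH", other = "OT")
  out <- list()
  for (cls in CHAR_CLASSES) {
    z <- stats::rnorm(20L)
    for (i in seq_len(n_per_class)) {
      v <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(20L)
      out[[length(out) + 1L]] <-
        aa_scale(sprintf("SYN%s%03d", codes[[cls]], i),
                 stats::setNames(v, AAINDEX_ORDER),
                 description = sprintf("synthetic %s scale %d", cls, i),
                 char_class = cls)
    }
  }
  out
}

#' Specification of a synthetic protein family
#'
#' Defaults emulate a mid-sized enzyme study: a 248-residue reference, a family
#' of 200 aligned homologues, and a 7-residue anomalous region at
#' positions 150-156. `conservation` gives the per-position substitution
#' probability; by default it is drawn uniformly on \[0.05, 0.5\] (from
#' near-conserved to typically variable columns) from `seed`.
#'
#' @param L Reference length.
#' @param N Family size (>= 2).
#' @param conservation Numeric length-L vector of per-position
#'   substitution probabilities in \[0,1\], or `NULL` to draw the default.
#' @param anomaly_start,anomaly_end Implanted anomalous interval (1-based,
#'   inclusive, within 1..L).
#' @param seed Integer seed.
#' @return List of class `family_spec`.
#' @export
family_spec <- function(L = 248L, N = 200L, conservation = NULL,
                        anomaly_start = 150L, anomaly_end = 156L, seed = 7L) {
  L <- as.integer(L); N <- as.integer(N)
  if (N < 2L) stop_input("family size N must be >= 2")
  if (anomaly_start < 1L || anomaly_end > L || anomaly_start > anomaly_end)
    stop_input("anomaly interval %d:%d outside 1..%d", anomaly_start, anomaly_end, L)
  if (!is.null(conservation)) {
    if (length(conservation) != L || any(conservation < 0 | conservation > 1))
      stop_input("conservation must be length L with values in [0,1]")
  }
  structure(list(L = L, N = N, conservation = conservation,
                 anomaly_start = as.integer(anomaly_start),
                 anomaly_end = as.integer(anomaly_end),
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic family alignment with an implanted anomaly
#'
#' Draws a consensus sequence uniformly over the 20 residues; each family
#' sequence substitutes each position with its conservation-dependent
#' probability (substitutions uniform over the other 19 letters). The
#' reference equals the consensus except inside the anomaly interval,
#' where each residue is greedily chosen to maximize the summed absolute
#' deviation of its standardized index values from the family column
#' means, over one designated scale per characteristic class — implanting
#' a multi-characteristic biophysical anomaly. Extra columns in which the
#' reference is gapped (family insertions, rate 2%) are interleaved to
#' exercise cropping; reference numbering is unaffected.
#'
#' @param spec A [family_spec()].
#' @param scales Index scales used for implantation (default
#'   `synth_scales(5, spec$seed)`); the first scale of each class is the
#'   designated implantation scale.
#' @return List: `alignment` (an [aa_alignment()], reference id `"REF"`),
#'   `truth` (list with `anomaly_positions`, `consensus`, `conservation`,
#'   `gap_columns` — 1-based column indices in the uncropped alignment).
#' @export
synth_family <- function(spec, scales = NULL) {
  set.seed(spec$seed)
  if (is.null(scales)) scales <- synth_scales(5L, spec$seed)
  L <- spec$L; N <- spec$N
  p <- spec$conservation
  if (is.null(p)) p <- stats::runif(L, 0.05, 0.5)
  consensus <- sample(AAINDEX_ORDER, L, replace = TRUE)
  fam <- matrix(rep(consensus, each = N), nrow = N)
  mut <- matrix(stats::runif(N * L), nrow = N) < matrix(rep(p, each = N), nrow = N)
  for (r in which(colSums(mut) > 0L)) {
    rows <- which(mut[, r])
    fam[rows, r] <- sample(setdiff(AAINDEX_ORDER, consensus[r]),
                           length(rows), replace = TRUE)
  }
  # designated implantation scale: first of each class, standardized
  desig <- lapply(CHAR_CLASSES, function(cls) {
    grp <- Filter(function(s) s$char_class == cls, scales)
    if (length(grp)) standardize_scale(grp[[1L]]) else NULL
  })
  desig <- Filter(Negate(is.null), desig)
  ref <- consensus
  anom <- spec$anomaly_start:spec$anomaly_end
  for (r in anom) {
    colmeans <- vapply(desig, function(s) mean(s$values[fam[, r]]), numeric(1L))
    dev <- vapply(AAINDEX_ORDER, function(a) {
      sum(abs(vapply(desig, function(s) s$values[[a]], numeric(1L)) - colmeans))
    }, numeric(1L))
    ref[r] <- AAINDEX_ORDER[which.max(dev)]
  }
  # family-insertion columns (reference gapped) at rate 2%
  n_gap <- max(1L, round(0.02 * L))
  gap_after <- sort(sample(0:L, n_gap))
  cols <- vector("list", L + n_gap)
  gap_cols <- integer(0)
  ci <- 0L
  add <- function(refch, famch) {
    ci <<- ci + 1L
    cols[[ci]] <<- c(refch, famch)
  }
  for (g in gap_after[gap_after == 0L])
    { add("-", sample(AAINDEX_ORDER, N, replace = TRUE)); gap_cols <- c(gap_cols, ci) }
  for (r in seq_len(L)) {
    add(ref[r], fam[, r])
    for (g in gap_after[gap_after == r])
      { add("-", sample(AAINDEX_ORDER, N, replace = TRUE)); gap_cols <- c(gap_cols, ci) }
  }
  M <- do.call(cbind, cols)
  seqs <- apply(M, 1L, paste, collapse = "")
  aln <- aa_alignment(c("REF", sprintf("FAM%04d", seq_len(N))), seqs, "REF")
  list(alignment = aln,
       truth = list(anomaly_positions = anom, consensus = paste(consensus, collapse = ""),
                    conservation = p, gap_columns = gap_cols))
}

#' Generate a synthetic C-alpha trace in PDB format
#'
#' Self-avoiding random walk with fixed 3.8 Angstrom steps (the
#' consecutive C-alpha convention) and a minimum pairwise separation of
#' 3.0 Angstrom enforced by rejection. Output is valid PDB text: CA-only
#' ATOM records, single chain A, residue numbers 1..L. Byte-identical
#' given the same arguments and seed.
#'
#' @param L Number of residues (>= 2).
#' @param seed Integer seed.
#' @param seq Optional residue sequence (string, length L) for the residue
#'   names; random by default.
#' @param step Consecutive C-alpha distance (default 3.8 Angstrom).
#' @param min_sep Minimum pairwise separation (default 3.0 Angstrom).
#' @return Character vector of PDB lines.
#' @export
synth_pdb <- function(L, seed = 1L, seq = NULL, step = 3.8, min_sep = 3.0) {
  L <- as.integer(L)
  if (L < 2L) stop_input("synth_pdb needs L >= 2")
  set.seed(seed)
  if (is.null(seq)) seq <- paste(sample(AAINDEX_ORDER, L, replace = TRUE),
                                 collapse = "")
  ch <- strsplit(toupper(seq), "")[[1L]]
  if (length(ch) != L) stop_input("seq length %d != L = %d", length(ch), L)
  for (restart in seq_len(50L)) {
    xyz <- matrix(NA_real_, L, 3L)
    xyz[1L, ] <- 0
    ok <- TRUE
    for (i in 2:L) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        u <- stats::rnorm(3L)
        u <- u / sqrt(sum(u * u))
        cand <- xyz[i - 1L, ] + step * u
        if (i > 2L) {
          d2 <- rowSums((xyz[1:(i - 2L), , drop = FALSE] -
                           matrix(cand, i - 2L, 3L, byrow = TRUE))^2)
          if (min(d2) < min_sep^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop_input("self-avoiding walk failed after bounded retries; reseed")
  res3 <- vapply(ch, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || nchar(r) != 3L) "UNK" else r
  }, character(1L), USE.NAMES = FALSE)
  lines <- sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   seq_len(L), res3, seq_len(L), xyz[, 1L], xyz[, 2L], xyz[, 3L])
  c(lines, sprintf("TER   %5d      %3s A%4d", L + 1L, res3[L], L), "END")
}
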