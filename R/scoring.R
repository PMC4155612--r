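#' Index profile of the reference sequence
#'
#' Maps each residue of the ungapped reference sequence through an index
#' scale: the per-position value that enters the c-score numerator.
#' `X` residues, and residues whose scale entry is missing, yield `NA`.
#'
#' @param ref_seq Ungapped reference sequence (string over the 20 standard
#'   letters plus `X`).
#' @param scale An [aa_scale] (or [pc1_scale()] result).
#' @return List of class `index_profile`: `characteristic_id`, `values`
#'   (numeric, length = nchar(ref_seq)).
#' @export
profile_reference <- function(ref_seq, scale) {
  ch <- strsplit(toupper(ref_seq), "")[[1L]]
  bad <- setdiff(unique(ch), c(AAINDEX_ORDER, "X"))
  if (length(bad))
    stop_input("reference sequence contains non-residue letter(s): %s",
               paste(bad, collapse = ", "))
  vals <- unname(scale$values[ch])  # 'X' has no entry -> NA
  structure(list(characteristic_id = scale$accession, values = as.numeric(vals)),
            class = "index_profile")
}

#' Per-column family statistics under an index scale
#'
#' For each reference position, maps the family residues through the scale
#' (gaps, `X`, and residues with missing scale entries are excluded) and
#' computes the mean and population standard deviation (divisor n) of the
#' remaining values: the family terms of the c-score. Positions with a
#' single contributing residue carry a mean but no sd; empty columns carry
#' neither.
#'
#' @param ca An `aa_cropped` alignment.
#' @param scale An [aa_scale].
#' @param include_reference Include the reference residue in the family
#'   statistics (default `FALSE`: the reference is what the family is
#'   contrasted against, and including it shrinks deviations).
#' @return List of class `fam_stats`: `characteristic_id`, `mean`, `sd`,
#'   `n` (each length L).
#' @export
family_column_stats <- function(ca, scale, include_reference = FALSE) {
  M <- family_matrix(ca, include_reference)
  if (nrow(M) < 1L) stop_input("cropped alignment has no family records")
  V <- matrix(scale$values[M], nrow = nrow(M))
  n <- colSums(!is.na(V))
  mu <- suppressWarnings(colMeans(V, na.rm = TRUE))
  ex2 <- suppressWarnings(colMeans(V * V, na.rm = TRUE))
  s <- sqrt(pmax(ex2 - mu * mu, 0))
  mu[n == 0L] <- NA_real_
  s[n < 2L] <- NA_real_
  structure(list(characteristic_id = scale$accession,
                 mean = as.numeric(mu), sd = as.numeric(s), n = as.integer(n)),
            class = "fam_stats")
}

#' c-scores for one characteristic
#'
#' The c-score at position r is the reference index value minus the family
#' mean, divided by the family standard deviation — a conservation-weighted
#' deviation: the same absolute difference scores higher in a conserved
#' column than in a variable one.
#'
#' Perfectly conserved columns have sd 0, which the raw ratio cannot
#' handle; the divisor is therefore floored at
#' `sigma_floor_frac * median(positive sd)` (positions where the floor was
#' applied are flagged). If no position has positive sd the floor falls
#' back to `sigma_floor_frac * 1` (scales standardized to unit spread make
#' 1 the natural sd unit).
#'
#' @param profile An [profile_reference()] result.
#' @param stats A [family_column_stats()] result for the same
#'   characteristic and length.
#' @param sigma_floor_frac Floor fraction f (default 0.01).
#' @return List of class `c_score_row`: `characteristic_id`, `scores`
#'   (numeric length L, `NA` where inputs missing), `sigma_floored`
#'   (logical length L).
#' @export
c_scores <- function(profile, stats, sigma_floor_frac = 0.01) {
  if (length(profile$values) != length(stats$mean))
    stop_input("profile and family stats differ in length (%d vs %d)",
               length(profile$values), length(stats$mean))
  sdv <- stats$sd
  if (all(is.na(sdv))) stop_input("no family variance information (all sd missing)")
  pos <- sdv[!is.na(sdv) & sdv > 0]
  med <- if (length(pos)) stats::median(pos) else 1
  floorv <- sigma_floor_frac * med
  sig_eff <- pmax(sdv, floorv)
  flo <- !is.na(sdv) & sdv < floorv
  sc <- (profile$values - stats$mean) / sig_eff
  structure(list(characteristic_id = profile$characteristic_id,
                 scores = as.numeric(sc), sigma_floored = flo),
            class = "c_score_row")
}

#' Representative scale of a characteristic class by principal components
#'
#' Treats each (standardized) index scale of a class as a point in the
#' 20-dimensional residue space and extracts the first principal axis of
#' the class's second-moment matrix. The unit-norm loading vector is the
#' class's representative scale: one value per amino acid, usable wherever
#' a single index is. Because input scales are standardized to mean 0
#' across residues, no further centering is applied — a class of k
#' identical scales is exactly rank 1 (variance explained 1).
#'
#' Sign convention: the axis is oriented to correlate positively with the
#' elementwise mean of the input scales; if that correlation is exactly
#' zero, the largest-magnitude loading is made positive.
#'
#' @param scales List of standardized [aa_scale]s sharing a class. Scales
#'   with missing values are dropped with a warning; at least 2 usable
#'   scales are required.
#' @return Object of classes `pc_scale` and `aa_scale`: fields of
#'   [aa_scale] (with `values` = loadings) plus `loadings`,
#'   `variance_explained` and `n_indices_used`.
#' @export
pc1_scale <- function(scales) {
  ok <- vapply(scales, function(s) !anyNA(s$values), logical(1L))
  if (any(!ok)) {
    dropped <- vapply(scales[!ok], `[[`, character(1L), "accession")
    warning(sprintf("dropping %d scale(s) with missing values from PCA: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  scales <- scales[ok]
  if (length(scales) < 2L)
    stop_input("pc1_scale needs >= 2 usable scales, got %d", length(scales))
  cls <- scales[[1L]]$char_class
  X <- do.call(rbind, lapply(scales, `[[`, "values"))
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  ev[ev < ev[1L] * 1e-12] <- 0   # clamp numerical noise so rank-1 gives exactly 1
  ve <- ev[1L] / sum(ev)
  w <- e$vectors[, 1L]
  ip <- sum(w * colMeans(X))
  if (ip < 0) w <- -w
  else if (ip == 0 && w[which.max(abs(w))] < 0) w <- -w
  w <- w / sqrt(sum(w * w))
  out <- aa_scale(paste0("PC1_", cls), stats::setNames(w, AAINDEX_ORDER),
                  description = sprintf("first principal axis of %d %s scales",
                                        nrow(X), cls),
                  char_class = cls)
  out$loadings <- out$values
  out$variance_explained <- ve
  out$n_indices_used <- nrow(X)
  class(out) <- c("pc_scale", "aa_scale")
  out
}

#' Conservation row for one characteristic
#'
#' Per-position family variability under one characteristic: the raw
#' statistic is the family standard deviation of the index values (the
#' c-score denominator), min-max normalized to \[0, 1\] for display —
#' 0 = fully conserved (bright), 1 = most variable (dark). A row with
#' constant sd renders as fully conserved (all 0).
#'
#' @param stats A [family_column_stats()] result with at least one finite sd.
#' @return List of class `conservation_row`: `characteristic_id`, `raw`,
#'   `display`.
#' @export
conservation_row <- function(stats) {
  raw <- stats$sd
  fin <- !is.na(raw)
  if (!any(fin)) stop_input("conservation_row: no finite sd values")
  rng <- range(raw[fin])
  disp <- rep(NA_real_, length(raw))
  disp[fin] <- if (rng[2L] > rng[1L]) (raw[fin] - rng[1L]) / (rng[2L] - rng[1L]) else 0
  structure(list(characteristic_id = stats$characteristic_id,
                 raw = as.numeric(raw), display = disp),
            class = "conservation_row")
}

#' Histogram of c-scores, capped at +/-3
#'
#' Equal-width bins on \[-3, 3\]; scores beyond the cap are counted in the
#' edge bins (and tallied separately) so extreme outliers do not stretch
#' the axis yet no data is silently dropped. Bins are half-open \[lo, hi)
#' except the last, which is closed.
#'
#' @param row A `c_score_row` (or bare numeric vector of scores).
#' @param n_bins Number of bins (default 40).
#' @param cap Cap in score units (default 3).
#' @return List of class `score_histogram`: `characteristic_id`,
#'   `bin_edges` (length n_bins+1), `counts` (length n_bins),
#'   `n_clamped_low`, `n_clamped_high`.
#' @export
score_histogram <- function(row, n_bins = 40L, cap = 3) {
  if (n_bins < 1L) stop_input("n_bins must be >= 1")
  id <- if (is.list(row)) row$characteristic_id else NA_character_
  x <- if (is.list(row)) row$scores else row
  x <- x[is.finite(x)]
  lo <- sum(x < -cap); hi <- sum(x > cap)
  xc <- pmin(pmax(x, -cap), cap)
  width <- 2 * cap / n_bins
  idx <- pmin(floor((xc + cap) / width) + 1L, n_bins)
  structure(list(characteristic_id = id,
                 bin_edges = seq(-cap, cap, length.out = n_bins + 1L),
                 counts = tabulate(idx, nbins = n_bins),
                 n_clamped_low = as.integer(lo), n_clamped_high = as.integer(hi)),
            class = "score_histogram")
}

#' Filter c-scores to a closed range
#'
#' Mirrors range-brushing on a score histogram: positions whose score lies
#' in \[lo, hi\] are selected.
#'
#' @param row A `c_score_row` or numeric vector of scores.
#' @param lo,hi Closed interval bounds, `lo <= hi`.
#' @return Logical mask over positions; `FALSE` where the score is missing.
#' @export
filter_scores <- function(row, lo, hi) {
  if (lo > hi) stop_input("filter bounds out of order: lo %g > hi %g", lo, hi)
  x <- if (is.list(row)) row$scores else row
  is.finite(x) & x >= lo & x <= hi
}

#' Build the c-score matrix for an alignment
#'
#' High-level driver: scores every characteristic against the cropped
#' alignment. In `pc1` mode the supplied scales are standardized, grouped
#' by characteristic class (fixed display order), and each class with at
#' least two usable scales is collapsed to its [pc1_scale()]
#' representative; in `indices` mode the named accessions are scored
#' directly.
#'
#' @param ca An `aa_cropped` alignment.
#' @param scales List of [aa_scale]s (classes already assigned).
#' @param mode `"pc1"` or `"indices"`.
#' @param indices Character vector of accessions (required in `indices`
#'   mode).
#' @param sigma_floor_frac Passed to [c_scores()].
#' @param include_reference Passed to [family_column_stats()].
#' @return Object of class `c_score_matrix`: `characteristics` (ids, in
#'   display order), `classes`, `scores` (#characteristics x L matrix),
#'   `sigma_floored` (same shape), `stats` (list of `fam_stats`),
#'   `scales_used` (the scales scored, e.g. `pc_scale`s), `ref_id`, `L`.
#' @export
build_score_matrix <- function(ca, scales, mode = c("pc1", "indices"),
                               indices = NULL, sigma_floor_frac = 0.01,
                               include_reference = FALSE) {
  mode <- match.arg(mode)
  if (mode == "pc1") {
    std <- list()
    for (s in scales) {
      st <- tryCatch(standardize_scale(s), error = function(e) NULL)
      if (!is.null(st)) std[[length(std) + 1L]] <- st
      else warning(sprintf("dropping unusable scale %s", s$accession))
    }
    use <- list()
    for (cls in CHAR_CLASSES) {
      grp <- Filter(function(s) s$char_class == cls, std)
      grp <- Filter(function(s) !anyNA(s$values), grp)
      if (length(grp) >= 2L) use[[length(use) + 1L]] <- pc1_scale(grp)
      else warning(sprintf("class %s has %d usable scale(s); skipped", cls, length(grp)))
    }
    if (!length(use)) stop_input("no characteristic class has >= 2 usable scales")
  } else {
    if (is.null(indices) || !length(indices))
      stop_input("indices mode requires a vector of accessions")
    accs <- vapply(scales, `[[`, character(1L), "accession")
    miss <- setdiff(indices, accs)
    if (length(miss))
      stop_input("accession(s) not found: %s", paste(miss, collapse = ", "))
    use <- scales[match(indices, accs)]
  }
  ref <- reference_sequence(ca)
  L <- nchar(ref)
  k <- length(use)
  sc <- matrix(NA_real_, k, L)
  fl <- matrix(FALSE, k, L)
  st_list <- vector("list", k)
  for (i in seq_len(k)) {
    pr <- profile_reference(ref, use[[i]])
    st <- family_column_stats(ca, use[[i]], include_reference)
    row <- c_scores(pr, st, sigma_floor_frac)
    sc[i, ] <- row$scores
    fl[i, ] <- row$sigma_floored
    st_list[[i]] <- st
  }
  ids <- vapply(use, `[[`, character(1L), "accession")
  rownames(sc) <- ids; rownames(fl) <- ids
  structure(list(characteristics = ids,
                 classes = vapply(use, `[[`, character(1L), "char_class"),
                 scores = sc, sigma_floored = fl, stats = st_list,
                 scales_used = use, ref_id = ca$ref_id, L = L),
            class = "c_score_matrix")
}

#' @export
print.c_score_matrix <- function(x, ...) {
  cat(sprintf("<c_score_matrix> %d characteristic(s) x %d positions (ref '%s')\n",
              length(x$characteristics), x$L, x$ref_id))
  cat(" characteristics:", paste(x$characteristics, collapse = ", "), "\n")
  invisible(x)
}

#' Stacked-bar layout of a c-score matrix
#'
#' Per position, partitions the characteristics by score sign (zeros and
#' missing values omitted): positive scores stack above the sequence,
#' negative below. Segment magnitudes are `|score|` clamped at the display
#' cap (3, matching the histogram cap); the raw score is preserved
#' alongside. Segment order is the fixed characteristic order.
#'
#' @param m A `c_score_matrix`.
#' @param cap Display cap (default 3).
#' @return List of class `stack_layout`: element r is a list with
#'   `positive` and `negative` data frames (`characteristic`, `magnitude`,
#'   `raw`).
#' @export
stack_layout <- function(m, cap = 3) {
  out <- vector("list", m$L)
  for (r in seq_len(m$L)) {
    s <- m$scores[, r]
    mk <- function(sel) {
      data.frame(characteristic = m$characteristics[sel],
                 magnitude = pmin(abs(s[sel]), cap),
                 raw = s[sel], row.names = NULL,
                 stringsAsFactors = FALSE)
    }
    out[[r]] <- list(positive = mk(which(is.finite(s) & s > 0)),
                     negative = mk(which(is.finite(s) & s < 0)))
  }
  structure(out, class = "stack_layout")
}

#' Rank positions by cumulative deviation
#'
#' Sum of `|c-score|` across characteristics per position — the stacked-bar
#' total height, and the natural single-number ranking of candidate
#' anomalous residues.
#'
#' @param m A `c_score_matrix`.
#' @return Numeric vector length L (named by position).
#' @export
total_deviation <- function(m) {
  tot <- colSums(abs(m$scores), na.rm = TRUE)
  stats::setNames(tot, seq_len(m$L))
}
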