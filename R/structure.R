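#' Extract C-alpha coordinates from a PDB file
#'
#' One entry per residue, taking the CA atom of ATOM records (HETATM
#' ignored; multi-model files use the first model). Alternate locations
#' are resolved to the highest occupancy, ties to the first occurrence.
#' Residues lacking a CA atom simply do not appear. Three-letter residue
#' names outside the 20 standard amino acids become `X`.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier, or `"AUTO"` (default) for the first
#'   chain encountered.
#' @return Object of class `calpha_set`: `chain_id`, `resno` (PDB residue
#'   numbers), `letters` (one-letter codes), `xyz` (L x 3 matrix, Angstrom).
#' @export
parse_pdb_calpha <- function(path, chain = "AUTO") {
  if (!file.exists(path)) stop_input("PDB file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop_input("failed to parse PDB %s: %s",
                                   path, conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) stop_input("no C-alpha ATOM records in %s", path)
  if (identical(chain, "AUTO")) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L)
    stop_input("no C-alpha atoms in chain '%s'", chain)
  # altloc resolution: per residue keep highest occupancy, ties first seen
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(ix) ix[which.max(occ[ix])]), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  ord <- order(at$resno)
  at <- at[ord, , drop = FALSE]
  letters <- suppressWarnings(bio3d::aa321(at$resid))
  letters[is.na(letters) | !letters %in% AAINDEX_ORDER] <- "X"
  structure(list(chain_id = chain,
                 resno = as.integer(at$resno),
                 letters = as.character(letters),
                 xyz = cbind(x = at$x, y = at$y, z = at$z)),
            class = "calpha_set")
}

#' @export
print.calpha_set <- function(x, ...) {
  cat(sprintf("<calpha_set> chain %s, %d C-alpha atoms (resno %d..%d)\n",
              x$chain_id, length(x$resno), min(x$resno), max(x$resno)))
  invisible(x)
}

#' Map structure residues onto reference positions
#'
#' Aligns the structure's residue-letter string against the ungapped
#' reference sequence without gaps: the structure sequence is slid along
#' the reference and the offset maximizing the number of identities is
#' chosen (ties to the smallest offset). The auto mapping is accepted only
#' if identity over the overlap is at least `min_identity`; otherwise an
#' error reports the best offset and identity so the user can pass
#' `offset` explicitly (which bypasses the check).
#'
#' @param cs A `calpha_set`.
#' @param ref_seq Ungapped reference sequence.
#' @param offset `"auto"` (default) or an integer: structure entry i maps
#'   to reference position `offset + i`.
#' @param min_identity Acceptance threshold for auto mapping (default 0.95).
#' @return Object of class `structure_map`: integer vector length L, entry
#'   r is the index into the `calpha_set` or `NA` if unmapped; attributes
#'   `offset` and `identity`.
#' @export
map_structure <- function(cs, ref_seq, offset = "auto", min_identity = 0.95) {
  refc <- strsplit(toupper(ref_seq), "")[[1L]]
  L <- length(refc)
  p <- cs$letters
  n <- length(p)
  score_at <- function(o) {
    i <- max(1L, 1L - o):min(n, L - o)
    if (length(i) < 1L || i[1L] > i[length(i)]) return(c(0L, 0L))
    m <- sum(p[i] == refc[o + i] & p[i] != "X" & refc[o + i] != "X")
    c(m, length(i))
  }
  if (identical(offset, "auto")) {
    offs <- (1L - n):(L - 1L)
    sc <- vapply(offs, score_at, integer(2L))
    # degenerate overlaps (a couple of residues hanging off either end) can
    # be 100% identical by chance; require at least half the shorter
    # sequence to overlap before trusting the identity
    min_ov <- max(1L, min(n, L) %/% 2L)
    elig <- sc[2L, ] >= min_ov
    best <- which(elig)[which.max(sc[1L, elig])]
    o <- offs[best]
    ident <- sc[1L, best] / sc[2L, best]
    if (!is.finite(ident) || ident < min_identity)
      stop_mapping(paste0("structure-to-reference mapping failed: best identity ",
                          "%.1f%% at offset %d (threshold %.0f%%); ",
                          "pass an explicit offset to override"),
                   100 * ident, o, 100 * min_identity)
  } else {
    o <- as.integer(offset)
    sc <- score_at(o)
    ident <- if (sc[2L] > 0L) sc[1L] / sc[2L] else NA_real_
    if (sc[2L] == 0L)
      stop_mapping("offset %d leaves no overlap with the reference", o)
  }
  map <- rep(NA_integer_, L)
  i <- max(1L, 1L - o):min(n, L - o)
  map[o + i] <- i
  structure(map, class = "structure_map", offset = o, identity = ident)
}

#' Pairwise C-alpha distance matrix over reference positions
#'
#' Euclidean distances in Angstrom between the C-alpha atoms of mapped
#' reference positions; `NA` where either endpoint is unmapped.
#'
#' @param cs A `calpha_set`.
#' @param sm A `structure_map` over L reference positions.
#' @return Symmetric L x L numeric matrix (Angstrom), zero diagonal on
#'   mapped positions.
#' @export
distance_matrix <- function(cs, sm) {
  mapped <- which(!is.na(sm))
  if (length(mapped) < 2L)
    stop_mapping("need >= 2 mapped positions to compute distances, got %d",
                 length(mapped))
  L <- length(sm)
  D <- matrix(NA_real_, L, L)
  D[mapped, mapped] <- as.matrix(stats::dist(cs$xyz[unclass(sm)[mapped], , drop = FALSE]))
  D
}

#' Focus region
#'
#' A contiguous window of reference positions examined in detail;
#' at most 15 residues so per-residue detail stays readable.
#'
#' @param start,end 1-based inclusive reference positions.
#' @return List of class `focus_region`: `start`, `end`.
#' @export
focus_region <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop_input("invalid focus region %s:%s", start, end)
  if (end - start + 1L > 15L)
    stop_input("focus region %d:%d exceeds the 15-residue limit", start, end)
  structure(list(start = start, end = end), class = "focus_region")
}

#' Distance of every residue to a focus region
#'
#' For each non-focus residue, the minimum C-alpha distance to any residue
#' of the focus region (the residue's distance to the region's sphere of
#' influence). Unmapped residues carry `NA`; focus residues are excluded
#' from the result.
#'
#' @param dm Distance matrix from [distance_matrix()].
#' @param f A [focus_region()] (or length-2 integer vector).
#' @return Named numeric vector over non-focus positions (names are
#'   reference positions).
#' @export
focus_distances <- function(dm, f) {
  if (!inherits(f, "focus_region")) f <- focus_region(f[1L], f[2L])
  L <- nrow(dm)
  if (f$end > L) stop_input("focus region %d:%d outside 1..%d", f$start, f$end, L)
  idx <- f$start:f$end
  sub <- dm[, idx, drop = FALSE]
  if (all(is.na(sub)))
    stop_mapping("focus region %d:%d is entirely unmapped", f$start, f$end)
  fd <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
  fd[!is.finite(fd)] <- NA_real_
  keep <- setdiff(seq_len(L), idx)
  stats::setNames(fd[keep], keep)
}

#' Histogram of focus distances
#'
#' Distribution of all residues' distances to the focus region, used to
#' choose the proximity threshold. Half-open bins `[k*w, (k+1)*w)` starting
#' at 0; the top edge is the smallest multiple of `w` strictly above the
#' maximum distance, so every finite distance is counted.
#'
#' @param fd Focus distances from [focus_distances()].
#' @param bin_width Bin width in Angstrom (default 2).
#' @return List of class `proximity_histogram`: `bin_edges`, `counts`.
#' @export
proximity_histogram <- function(fd, bin_width = 2) {
  x <- fd[is.finite(fd)]
  if (!length(x)) stop_input("no finite focus distances to histogram")
  n_bins <- floor(max(x) / bin_width) + 1L
  idx <- floor(x / bin_width) + 1L
  structure(list(bin_edges = seq(0, n_bins * bin_width, by = bin_width),
                 counts = tabulate(idx, nbins = n_bins)),
            class = "proximity_histogram")
}

#' Bundle proximate residues into chords
#'
#' Residues whose focus distance lies in `[d_lo, d_hi]` qualify; maximal
#' runs of consecutive reference positions are bundled into one chord each
#' (one arch per proximate region instead of one arc per residue). Each
#' bundle carries the minimum member distance and a brightness rank
#' (0 = closest bundle = darkest).
#'
#' @param fd Focus distances from [focus_distances()].
#' @param d_lo,d_hi Distance range in Angstrom, `d_lo <= d_hi`
#'   (defaults 0 and 8, a conventional C-alpha contact cutoff).
#' @param min_seq_separation Optionally drop qualifying residues within
#'   this many sequence positions of the focus region (default 0: sequence
#'   neighbours are kept).
#' @param focus Needed only when `min_seq_separation > 0`: the
#'   [focus_region()].
#' @return Data frame with columns `target_start`, `target_end`,
#'   `min_distance`, `brightness_rank`, sorted by `target_start`.
#' @export
bundle_chords <- function(fd, d_lo = 0, d_hi = 8, min_seq_separation = 0L,
                          focus = NULL) {
  if (d_lo > d_hi) stop_input("chord range out of order: %g > %g", d_lo, d_hi)
  pos <- as.integer(names(fd))
  q <- pos[is.finite(fd) & fd >= d_lo & fd <= d_hi]
  if (min_seq_separation > 0L) {
    if (is.null(focus)) stop_input("min_seq_separation requires a focus region")
    sep <- pmax(focus$start - q, q - focus$end, 0L)
    q <- q[sep >= min_seq_separation]
  }
  if (!length(q))
    return(data.frame(target_start = integer(), target_end = integer(),
                      min_distance = numeric(), brightness_rank = integer()))
  q <- sort(q)
  run <- cumsum(c(1L, as.integer(diff(q) != 1L)))
  d_by_pos <- fd[as.character(q)]
  starts <- tapply(q, run, min)
  endsv <- tapply(q, run, max)
  mind <- tapply(d_by_pos, run, min)
  out <- data.frame(target_start = as.integer(starts),
                    target_end = as.integer(endsv),
                    min_distance = as.numeric(mind),
                    brightness_rank = NA_integer_)
  ord <- order(out$min_distance, out$target_start)
  out$brightness_rank[ord] <- seq_len(nrow(out)) - 1L
  out[order(out$target_start), , drop = FALSE]
}
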