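#' Run the full deviation analysis
#'
#' End-to-end driver: read (or accept) the family alignment, crop it to
#' the reference window, load and classify index scales, compute the
#' c-score matrix (PC1 representatives by default), conservation rows and
#' histograms, optionally link a PDB structure (focus distances, proximity
#' histogram, bundled chords), and assemble the visualization bundle.
#'
#' @param msa Path to an alignment file, or an `aa_alignment`.
#' @param ref_id Reference identifier (required when `msa` is a path).
#' @param scales Path to an AAindex1 file, or a list of [aa_scale]s.
#' @param class_map Path to a class TSV, a named character vector, `NULL`
#'   (packaged default map, then description keywords for accessions it
#'   does not cover), or `FALSE` to keep classes already on the scales.
#' @param msa_format `"fasta"` or `"clustal"`.
#' @param mode `"pc1"` or `"indices"`.
#' @param indices Accessions to score in `indices` mode.
#' @param pdb Optional path to a PDB file (or a `calpha_set`).
#' @param chain Chain id or `"AUTO"`.
#' @param offset `"auto"` or integer, see [map_structure()].
#' @param focus Optional focus region: a [focus_region()] or
#'   `c(start, end)`. Required for chords/proximity output.
#' @param d_lo,d_hi Chord distance range (Angstrom).
#' @param bin_width Proximity histogram bin width (Angstrom).
#' @param sigma_floor_frac,include_reference See [c_scores()] and
#'   [family_column_stats()].
#' @param filters Optional list of `list(characteristic_id, lo, hi)`.
#' @param out Optional path for the JSON bundle.
#' @param plot Optional path for the overview PNG.
#' @return The `viz_bundle`, invisibly. The attribute `"score_matrix"`
#'   carries the underlying `c_score_matrix`.
#' @export
run_deviation_analysis <- function(msa, ref_id = NULL, scales,
                                   class_map = NULL,
                                   msa_format = c("fasta", "clustal"),
                                   mode = c("pc1", "indices"), indices = NULL,
                                   pdb = NULL, chain = "AUTO", offset = "auto",
                                   focus = NULL, d_lo = 0, d_hi = 8,
                                   bin_width = 2, sigma_floor_frac = 0.01,
                                   include_reference = FALSE,
                                   filters = list(), out = NULL, plot = NULL) {
  msa_format <- match.arg(msa_format)
  mode <- match.arg(mode)
  aln <- if (inherits(msa, "aa_alignment")) msa else {
    if (is.null(ref_id)) stop_input("ref_id is required when msa is a file path")
    read_alignment(msa, ref_id, msa_format)
  }
  ca <- if (inherits(aln, "aa_cropped")) aln else crop_to_reference(aln)
  if (is.character(scales) && length(scales) == 1L) scales <- read_aaindex1(scales)
  if (!isFALSE(class_map)) {
    cmap <- if (is.null(class_map)) {
      dm <- tryCatch(default_class_map(), error = function(e) character())
      kw <- build_class_map(scales)
      c(dm, kw[setdiff(names(kw), names(dm))])
    } else if (is.character(class_map) && length(class_map) == 1L &&
               is.null(names(class_map))) {
      read_class_map(class_map)
    } else class_map
    scales <- assign_classes(scales, cmap)
  }
  m <- build_score_matrix(ca, scales, mode = mode, indices = indices,
                          sigma_floor_frac = sigma_floor_frac,
                          include_reference = include_reference)
  chords <- prox <- fr <- NULL
  if (!is.null(focus)) {
    fr <- if (inherits(focus, "focus_region")) focus else focus_region(focus[1L], focus[2L])
  }
  if (!is.null(pdb)) {
    if (is.null(fr))
      stop_input("a focus region is required to compute chords from a structure")
    cs <- if (inherits(pdb, "calpha_set")) pdb else parse_pdb_calpha(pdb, chain)
    sm <- map_structure(cs, reference_sequence(ca), offset)
    dm <- distance_matrix(cs, sm)
    fd <- focus_distances(dm, fr)
    prox <- proximity_histogram(fd, bin_width)
    chords <- bundle_chords(fd, d_lo, d_hi)
  }
  bundle <- assemble_viz_bundle(m, ca, mode = mode, focus = fr,
                                chords = chords,
                                d_range = if (is.null(chords)) NULL else c(d_lo, d_hi),
                                prox = prox, filters = filters)
  if (!is.null(out)) export_viz_bundle(bundle, out)
  if (!is.null(plot)) plot_overview(bundle, plot)
  attr(bundle, "score_matrix") <- m
  invisible(bundle)
}
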