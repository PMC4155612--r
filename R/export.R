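#' Assemble the visualization bundle
#'
#' Collects every computed artifact into one self-describing list — the
#' contract a front-end (or notebook) consumes: score histograms,
#' per-position stacked bars, conservation rows, proximity chords and
#' histogram, focus metadata and active filters. Characteristic order is
#' identical across histograms, stacks and conservation rows (histogram
#' left-to-right corresponds to heat-map top-to-bottom).
#'
#' @param m A `c_score_matrix` from [build_score_matrix()].
#' @param ca The `aa_cropped` alignment the scores were computed over.
#' @param mode Scoring mode recorded in `meta` (`"pc1"` or `"indices"`).
#' @param focus Optional [focus_region()].
#' @param chords Optional data frame from [bundle_chords()].
#' @param d_range Length-2 numeric: the active chord threshold range
#'   (required when `chords` given).
#' @param prox Optional `proximity_histogram`.
#' @param filters Optional list of filters, each
#'   `list(characteristic_id=, lo=, hi=)`.
#' @return List of class `viz_bundle`.
#' @export
assemble_viz_bundle <- function(m, ca, mode = "pc1", focus = NULL,
                                chords = NULL, d_range = NULL, prox = NULL,
                                filters = list()) {
  if (m$L != nchar(reference_sequence(ca)))
    stop_mapping("length mismatch between score matrix (L=%d) and alignment (L=%d)",
                 m$L, nchar(reference_sequence(ca)))
  hists <- lapply(seq_along(m$characteristics), function(i) {
    h <- score_histogram(list(characteristic_id = m$characteristics[i],
                              scores = m$scores[i, ]))
    h[c("characteristic_id", "bin_edges", "counts",
        "n_clamped_low", "n_clamped_high")]
  })
  cons <- lapply(m$stats, function(st) {
    cr <- conservation_row(st)
    list(characteristic_id = cr$characteristic_id, raw = cr$raw,
         display = cr$display)
  })
  # keep conservation ids aligned with score rows (fam_stats carry the
  # underlying accession for pc1 rows)
  for (i in seq_along(cons)) cons[[i]]$characteristic_id <- m$characteristics[i]
  sl <- stack_layout(m)
  stacks <- lapply(seq_len(m$L), function(r) {
    list(position = r,
         positive = sl[[r]]$positive,
         negative = sl[[r]]$negative)
  })
  if (!is.null(chords) && is.null(d_range))
    stop_mapping("chords supplied without their active threshold range")
  bundle <- list(
    meta = list(reference_id = m$ref_id,
                reference_sequence = reference_sequence(ca),
                L = m$L,
                characteristics = m$characteristics,
                classes = m$classes,
                mode = mode,
                position_base = 1L,
                distance_unit = "angstrom",
                generator = paste("famdev", as.character(utils::packageVersion("famdev")))),
    histograms = hists,
    stacks = stacks,
    conservation = cons,
    chords = if (is.null(chords)) NULL else
      list(d_lo = d_range[1L], d_hi = d_range[2L], bundles = chords),
    proximity_histogram = if (is.null(prox)) NULL else
      list(bin_edges = prox$bin_edges, counts = prox$counts),
    focus = if (is.null(focus)) NULL else list(start = focus$start, end = focus$end),
    filters = filters)
  class(bundle) <- "viz_bundle"
  validate_bundle(bundle)
  bundle
}

#' Validate a visualization bundle
#'
#' Structural validation of the bundle contract (the same constraints the
#' shipped JSON Schema document, `inst/schema/vizbundle.schema.json`,
#' expresses): required fields, consistent characteristic order across
#' histograms/stacks/conservation, display values in \[0,1\], count sums,
#' sorted disjoint chords.
#'
#' @param b A `viz_bundle` (or a list parsed back from its JSON).
#' @return `TRUE`, invisibly; errors describe the first violation.
#' @export
validate_bundle <- function(b) {
  # accept both the native form (lists of records) and the JSON-parsed form
  # (records simplified to data frames)
  as_rowlist <- function(x) {
    if (is.data.frame(x))
      lapply(seq_len(nrow(x)), function(i)
        lapply(x, function(col) if (is.list(col)) col[[i]] else col[i]))
    else x
  }
  need <- c("meta", "histograms", "stacks", "conservation", "filters")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop_mapping("bundle missing field(s): %s", paste(miss, collapse = ", "))
  meta_need <- c("reference_id", "L", "characteristics", "mode",
                 "position_base", "distance_unit")
  miss <- setdiff(meta_need, names(b$meta))
  if (length(miss))
    stop_mapping("bundle meta missing field(s): %s", paste(miss, collapse = ", "))
  if (b$meta$position_base != 1L) stop_mapping("position_base must be 1")
  chars <- as.character(b$meta$characteristics)
  hists <- as_rowlist(b$histograms)
  cons <- as_rowlist(b$conservation)
  stacks <- as_rowlist(b$stacks)
  hid <- vapply(hists, function(h) as.character(h$characteristic_id), character(1L))
  cid <- vapply(cons, function(x) as.character(x$characteristic_id), character(1L))
  if (!identical(hid, chars))
    stop_mapping("characteristic order differs between meta and histograms")
  if (!identical(cid, chars))
    stop_mapping("characteristic order differs between meta and conservation rows")
  if (length(stacks) != b$meta$L)
    stop_mapping("stacks length %d != L = %d", length(stacks), b$meta$L)
  for (h in hists) {
    if (length(h$bin_edges) != length(h$counts) + 1L)
      stop_mapping("histogram %s: %d edges for %d counts", h$characteristic_id,
                   length(h$bin_edges), length(h$counts))
    if (any(h$counts < 0)) stop_mapping("histogram %s: negative count", h$characteristic_id)
  }
  for (x in cons) {
    d <- unlist(x$display)
    d <- d[!is.na(d)]
    if (length(d) && (min(d) < 0 || max(d) > 1))
      stop_mapping("conservation row %s: display outside [0,1]", x$characteristic_id)
    if (length(unlist(x$raw)) != b$meta$L)
      stop_mapping("conservation row %s: length != L", x$characteristic_id)
  }
  if (!is.null(b$chords) && length(b$chords)) {
    bd <- b$chords$bundles
    if (!is.data.frame(bd))
      bd <- do.call(rbind, lapply(bd, as.data.frame))
    if (!is.null(bd) && nrow(bd)) {
      if (is.unsorted(bd$target_start, strictly = TRUE))
        stop_mapping("chord bundles not sorted by target_start")
      if (any(bd$target_end < bd$target_start))
        stop_mapping("chord bundle with end < start")
      if (nrow(bd) > 1L &&
          any(utils::head(bd$target_end, -1L) >= utils::tail(bd$target_start, -1L)))
        stop_mapping("chord bundles overlap")
    }
  }
  invisible(TRUE)
}

#' Export a bundle as JSON
#'
#' Numbers are serialized with 6 significant digits; missing values as
#' `null`.
#'
#' @param bundle A `viz_bundle` from [assemble_viz_bundle()].
#' @param path Optional output path; when given the JSON is written there.
#' @return The JSON text (character scalar), invisibly when `path` given.
#' @export
export_viz_bundle <- function(bundle, path = NULL) {
  validate_bundle(bundle)
  json <- jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE, digits = I(6),
                           na = "null", null = "null", dataframe = "rows")
  if (!is.null(path)) {
    writeLines(as.character(json), path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Read a bundle back from JSON
#'
#' @param path Path to a JSON file written by [export_viz_bundle()].
#' @return Parsed list (class `viz_bundle`).
#' @export
read_viz_bundle <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  class(b) <- "viz_bundle"
  b
}

char_palette <- function(ids) {
  stats::setNames(grDevices::hcl(h = seq(15, 375, length.out = length(ids) + 1L)[seq_along(ids)],
                                 c = 70, l = 55), ids)
}

#' Static overview plot of a bundle
#'
#' Deterministic PNG rendition of the bundle: score histograms (one per
#' characteristic, shared y-axis), the context sequence with stacked
#' c-score bars above (positive) and below (negative) the axis, the
#' conservation heat map (one row per characteristic, bright = conserved),
#' and — when a focus region is present — a focus panel with one residue
#' glyph per focus position.
#'
#' @param bundle A `viz_bundle`.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return Invisibly, a list with `path` and `focus_glyphs` (number of
#'   residue glyphs drawn in the focus panel; 0 without a focus region).
#' @export
plot_overview <- function(bundle, path, width = 1200, height = 900) {
  validate_bundle(bundle)
  chars <- as.character(bundle$meta$characteristics)
  k <- length(chars)
  L <- bundle$meta$L
  pal <- char_palette(chars)
  has_focus <- !is.null(bundle$focus) && length(bundle$focus)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  nrow_lay <- if (has_focus) 4L else 3L
  lay <- rbind(seq_len(k),
               matrix(k + 1L, 1L, k),
               matrix(k + 2L, 1L, k))
  if (has_focus) lay <- rbind(lay, matrix(k + 3L, 1L, k))
  graphics::layout(lay, heights = c(1.2, 2, 1, if (has_focus) 1))
  op <- graphics::par(mar = c(2.5, 2.5, 2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  ymax <- max(1L, unlist(lapply(bundle$histograms, function(h) max(unlist(h$counts)))))
  for (h in bundle$histograms) {
    graphics::barplot(as.numeric(unlist(h$counts)), space = 0, border = NA,
                      col = pal[[as.character(h$characteristic_id)]],
                      ylim = c(0, ymax), main = h$characteristic_id,
                      cex.main = 0.9)
  }
  # stacked c-score bars around the sequence axis
  pos_tot <- neg_tot <- numeric(L)
  graphics::plot.new()
  stacks <- bundle$stacks
  up <- lapply(stacks, `[[`, "positive")
  dn <- lapply(stacks, `[[`, "negative")
  tot <- function(x) {
    df <- as.data.frame(x)
    if (!nrow(df)) 0 else sum(as.numeric(df$magnitude))
  }
  pos_tot <- vapply(up, tot, numeric(1L))
  neg_tot <- vapply(dn, tot, numeric(1L))
  ylim <- max(c(pos_tot, neg_tot, 1))
  graphics::plot.window(xlim = c(0.5, L + 0.5), ylim = c(-ylim, ylim))
  graphics::abline(h = 0)
  for (r in seq_len(L)) {
    draw_stack <- function(df, sign) {
      df <- as.data.frame(df)
      if (!nrow(df)) return()
      y0 <- 0
      for (j in seq_len(nrow(df))) {
        m <- as.numeric(df$magnitude[j])
        graphics::rect(r - 0.45, sign * y0, r + 0.45, sign * (y0 + m),
                       col = pal[[as.character(df$characteristic[j])]], border = NA)
        y0 <- y0 + m
      }
    }
    draw_stack(up[[r]], +1); draw_stack(dn[[r]], -1)
  }
  graphics::axis(1)
  graphics::title(main = sprintf("c-scores along %s (stacked |c|, + above / - below)",
                                 bundle$meta$reference_id), cex.main = 0.9)
  # conservation heat map: one row per characteristic, top row = first
  disp <- do.call(rbind, lapply(bundle$conservation, function(x) as.numeric(unlist(x$display))))
  img <- t(disp)[, rev(seq_len(k)), drop = FALSE]
  graphics::image(x = seq_len(L), y = seq_len(k), z = img,
                  col = grDevices::grey(seq(1, 0.1, length.out = 64)),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1)
  graphics::axis(2, at = seq_len(k), labels = rev(chars), las = 2, cex.axis = 0.6)
  graphics::title(main = "conservation (dark = variable)", cex.main = 0.9)
  n_glyphs <- 0L
  if (has_focus) {
    fs <- as.integer(bundle$focus$start); fe <- as.integer(bundle$focus$end)
    idx <- fs:fe
    ch <- strsplit(as.character(bundle$meta$reference_sequence), "")[[1L]][idx]
    graphics::plot.new()
    graphics::plot.window(xlim = c(0.5, length(idx) + 0.5), ylim = c(0, 1))
    graphics::text(seq_along(idx), 0.5, ch, cex = 2)
    graphics::axis(1, at = seq_along(idx), labels = idx, cex.axis = 0.8)
    graphics::title(main = sprintf("focus region %d:%d", fs, fe), cex.main = 0.9)
    n_glyphs <- length(idx)
  }
  invisible(list(path = path, focus_glyphs = n_glyphs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
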