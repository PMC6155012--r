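# Pixel-as-event imaging-mass-cytometry pipeline: tile stitching, low-
# intensity cleanup, pixels-to-events conversion, two-stage pixel
# classification into B cell subsets, subset masks and spatial summaries.
#
# Coordinate convention: 0-based, row-major, origin top-left; x = column,
# y = row.

#' Stitch image tiles into a mosaic
#'
#' Places each tile at its integer (row, col) offset (0-based).  Where tiles
#' overlap, the later tile in the list overwrites the earlier one.
#'
#' @param tiles List of H x W x C arrays with identical channel names.
#' @param offsets Integer matrix or list of `c(row, col)` offsets, one per
#'   tile.
#' @param shape Optional declared `c(height, width)` mosaic bounds; tiles
#'   placed outside raise an error.  Default: tight bounding box.
#' @return Mosaic array with the shared channel names.
#' @export
stitch_tiles <- function(tiles, offsets, shape = NULL) {
  stopifnot(length(tiles) >= 1, length(offsets) == length(tiles) ||
              (is.matrix(offsets) && nrow(offsets) == length(tiles)))
  if (is.matrix(offsets)) offsets <- lapply(seq_len(nrow(offsets)), function(i) offsets[i, ])
  ch <- dimnames(tiles[[1]])[[3]]
  for (t in tiles) {
    if (!identical(dimnames(t)[[3]], ch)) stopf("tiles have mismatched channel sets")
  }
  ext <- t(vapply(seq_along(tiles), function(i) {
    off <- as.integer(offsets[[i]])
    c(off[1] + dim(tiles[[i]])[1], off[2] + dim(tiles[[i]])[2])
  }, integer(2)))
  if (is.null(shape)) shape <- c(max(ext[, 1]), max(ext[, 2]))
  if (any(ext[, 1] > shape[1]) || any(ext[, 2] > shape[2]) ||
      any(vapply(offsets, function(o) any(o < 0), logical(1)))) {
    stopf("tile placement outside declared mosaic bounds")
  }
  mosaic <- array(0, dim = c(shape[1], shape[2], length(ch)),
                  dimnames = list(NULL, NULL, ch))
  for (i in seq_along(tiles)) {
    off <- as.integer(offsets[[i]])
    d <- dim(tiles[[i]])
    mosaic[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), ] <- tiles[[i]]
  }
  mosaic
}

#' Zero out low-intensity pixels per channel
#'
#' Intensities strictly below the channel threshold are set to 0; values at
#' or above the threshold are unchanged.
#'
#' @param image H x W x C array with channel names.
#' @param thresholds Named non-negative per-channel thresholds; channels not
#'   named are left untouched.
#' @return The cleaned image.
#' @export
denoise_threshold <- function(image, thresholds) {
  ch <- dimnames(image)[[3]]
  bad <- setdiff(names(thresholds), ch)
  if (length(bad)) stopf("unknown channel in thresholds: %s", bad[1])
  stopifnot(all(thresholds >= 0))
  for (m in names(thresholds)) {
    plane <- image[, , m]
    plane[plane < thresholds[[m]]] <- 0
    image[, , m] <- plane
  }
  image
}

#' Convert image pixels to a pixel-event table
#'
#' One event per retained pixel, with channel intensities as marker columns
#' and pixel coordinates stored on a linear scale as `x` (column, 0-based)
#' and `y` (row, 0-based).
#'
#' @param image H x W x C array with channel names.
#' @param roi Optional logical H x W mask of pixels to retain.
#' @return Pixel-event data frame (also carries `event_id`).
#' @export
pixels_to_events <- function(image, roi = NULL) {
  d <- dim(image)
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(roi), d[1:2]))
  if (!any(roi)) stopf("empty ROI")
  idx <- which(roi)
  rows <- ((idx - 1L) %% d[1]) + 1L
  cols <- ((idx - 1L) %/% d[1]) + 1L
  ch <- dimnames(image)[[3]]
  mat <- matrix(image, nrow = d[1] * d[2])[idx, , drop = FALSE]
  colnames(mat) <- ch
  out <- as.data.frame(mat, check.names = FALSE)
  out$x <- cols - 1L
  out$y <- rows - 1L
  out$event_id <- sprintf("px_%d_%d", out$y, out$x)
  out
}

#' Reconstruct channel planes from a pixel-event table
#'
#' Inverse of [pixels_to_events()] within the ROI; pixels outside the events
#' are zero.
#'
#' @param events Pixel-event data frame.
#' @param shape `c(height, width)`.
#' @return H x W x C array.
#' @export
events_to_image <- function(events, shape) {
  ch <- setdiff(marker_names(events), character(0))
  img <- array(0, dim = c(shape[1], shape[2], length(ch)),
               dimnames = list(NULL, NULL, ch))
  lin <- events$y + 1L + events$x * shape[1]
  for (j in seq_along(ch)) {
    plane <- img[, , j]
    plane[lin] <- events[[ch[j]]]
    img[, , j] <- plane
  }
  img
}

#' Subset bubble rules for the imaging panel
#'
#' As [default_bubble_rules()] but restricted to the nine imaging B cell
#' markers; the class-switched memory rule is CD27+ IgM- IgD- (isotype
#' channels are not in the imaging panel).
#'
#' @param threshold Per-marker cut (scalar or named vector).
#' @return Ordered rule list.
#' @export
imc_bubble_rules <- function(threshold = 1.9) {
  rule <- function(name, pos, neg = character(0)) list(name = name, pos = pos, neg = neg)
  rules <- list(
    rule("gc",        pos = c("CD19", "CD20", "CD10", "CD38"), neg = "IgD"),
    rule("precursor", pos = c("CD19", "CD20", "IgM", "IgD", "CD45RB"),
                      neg = c("CD27", "CD10")),
    rule("mz",        pos = c("CD19", "CD20", "CD27", "IgM", "IgD"), neg = "CD10"),
    rule("igm_only",  pos = c("CD19", "CD20", "CD27", "IgM"), neg = c("IgD", "CD10")),
    rule("csm",       pos = c("CD19", "CD20", "CD27"),
                      neg = c("IgM", "IgD", "CD10")),
    rule("naive",     pos = c("CD19", "CD20", "IgM", "IgD"),
                      neg = c("CD27", "CD10", "CD45RB"))
  )
  attr(rules, "threshold") <- threshold
  rules
}

#' Classify pixels into B cell subsets
#'
#' Two-stage scheme: stage 1 embeds and clusters all pixels on all panel
#' channels and keeps the nodes whose CD19 and CD20 medians exceed the
#' stage-1 thresholds; stage 2 embeds and clusters the retained pixels on
#' the nine B cell markers and assigns nodes to subset bubbles by rule.
#' Pixels in nodes matching no rule are labelled `"other"` and are excluded
#' from downstream masks.
#'
#' @param events Pixel-event table from [pixels_to_events()].
#' @param seed Integer seed.
#' @param stage1_k,stage2_k Node counts for the two clustering passes.
#' @param cd19_threshold,cd20_threshold Stage-1 node-median cuts.
#' @param rules Stage-2 bubble rules ([imc_bubble_rules()]).
#' @param b_markers Stage-2 marker list.
#' @return Character vector of per-pixel labels aligned with `events`
#'   (subset names, or `"other"` for unclassified/non-B pixels).
#' @export
classify_pixels <- function(events, seed = NULL, stage1_k = 40, stage2_k = 60,
                            cd19_threshold = 1.9, cd20_threshold = 1.9,
                            rules = imc_bubble_rules(),
                            b_markers = c("CD10", "CD19", "CD20", "CD24", "CD27",
                                          "CD38", "CD45RB", "IgM", "IgD")) {
  mk <- marker_names(events)
  need <- unique(c("CD19", "CD20", b_markers))
  missing <- setdiff(need, mk)
  if (length(missing)) stopf("missing channel: %s", missing[1])

  co1 <- embed_2d(events, markers = mk, method = "pca")
  g1 <- cluster_nodes(co1, events, k = min(stage1_k, nrow(events)),
                      seed = stage_seed(seed %||% 0, "imc"))
  bnodes <- which(g1$medians[, "CD19"] >= cd19_threshold &
                  g1$medians[, "CD20"] >= cd20_threshold)
  if (!length(bnodes)) stopf("no CD19+CD20+ nodes found")
  sel <- g1$membership %in% bnodes

  labels <- rep("other", nrow(events))
  bev <- events[sel, , drop = FALSE]
  co2 <- embed_2d(bev, markers = b_markers, method = "pca")
  g2 <- cluster_nodes(co2, bev, k = min(stage2_k, nrow(bev)),
                      seed = stage_seed((seed %||% 0) + 1L, "imc"))
  bub <- assign_bubbles(g2, rules = rules)
  labels[sel] <- event_subsets(g2, bub)
  labels
}

#' Binary subset masks from pixel labels
#'
#' One mask per subset label (excluding `"other"`); masks are pairwise
#' disjoint because each pixel carries one label.  A pseudocolour composite
#' (integer-coded subset per pixel, 0 = unclassified) is returned alongside.
#'
#' @param events Pixel-event table (provides coordinates).
#' @param labels Per-pixel labels from [classify_pixels()].
#' @param shape `c(height, width)` of the source image.
#' @return List: `masks` (named list of logical matrices), `composite`
#'   (integer matrix), `key` (subset name per composite code).
#' @export
masks_from_labels <- function(events, labels, shape) {
  stopifnot(length(labels) == nrow(events))
  subsets <- setdiff(sort(unique(labels)), "other")
  lin <- events$y + 1L + events$x * shape[1]
  composite <- matrix(0L, shape[1], shape[2])
  masks <- list()
  for (i in seq_along(subsets)) {
    m <- matrix(FALSE, shape[1], shape[2])
    m[lin[labels == subsets[i]]] <- TRUE
    masks[[subsets[i]]] <- m
    composite[m] <- i
  }
  list(masks = masks, composite = composite, key = subsets)
}

#' Rank-concordance of pixel and suspension subset profiles
#'
#' For each held-out marker, computes the Spearman rank correlation between
#' the per-subset median profiles of the pixel (imaging) and suspension
#' arms, over the shared subsets.  The concordance flag is set when the
#' subset rank order agrees exactly (rho == 1).
#'
#' @param pixel_profiles,suspension_profiles Numeric matrices, subsets x
#'   markers (rownames = subset names).
#' @param markers Held-out markers to compare, default CD45RB and CD24.
#' @return Data frame: `marker`, `rho`, `concordant`, `n_subsets`.
#' @export
validate_against_suspension <- function(pixel_profiles, suspension_profiles,
                                        markers = c("CD45RB", "CD24")) {
  shared <- intersect(rownames(pixel_profiles), rownames(suspension_profiles))
  if (!length(shared)) stopf("no shared subsets between the two arms")
  out <- lapply(markers, function(m) {
    rho <- stats::cor(pixel_profiles[shared, m], suspension_profiles[shared, m],
                      method = "spearman")
    data.frame(marker = m, rho = rho, concordant = isTRUE(all.equal(rho, 1)),
               n_subsets = length(shared), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Euclidean distance of every pixel to the nearest TRUE pixel of `ref`
# (0 inside ref).  EBImage::distmap treats zero pixels as background.
distance_to_mask <- function(ref) {
  if (!any(ref)) stopf("empty reference mask")
  as.matrix(EBImage::distmap(1 - ref, metric = "euclidean"))
}

#' Spatial summary of subset masks against reference masks
#'
#' For every (subset, reference) pair, summarises the Euclidean distances
#' from subset pixels to the reference mask (distance 0 inside the
#' reference; otherwise distance to its nearest pixel, i.e. its boundary).
#'
#' @param masks Named list of logical subset masks.
#' @param reference_masks Named list of logical reference masks (e.g. GC,
#'   epithelium).
#' @return Data frame: `subset`, `reference`, `n_pixels`, `mean`, `median`,
#'   `q25`, `q75`.
#' @export
spatial_summary <- function(masks, reference_masks) {
  out <- list()
  for (rn in names(reference_masks)) {
    dm <- distance_to_mask(reference_masks[[rn]])
    for (sn in names(masks)) {
      m <- masks[[sn]]
      stopifnot(identical(dim(m), dim(reference_masks[[rn]])))
      d <- dm[m]
      out[[length(out) + 1L]] <- data.frame(
        subset = sn, reference = rn, n_pixels = sum(m),
        mean = if (length(d)) mean(d) else NA_real_,
        median = if (length(d)) stats::median(d) else NA_real_,
        q25 = if (length(d)) unname(stats::quantile(d, 0.25)) else NA_real_,
        q75 = if (length(d)) unname(stats::quantile(d, 0.75)) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write a multichannel image as TIFF with a channel sidecar
#'
#' One 32-bit page per channel; each channel is scaled into `[0, 1]` by its
#' recorded maximum so the sidecar (`<path>.channels.tsv`) allows a lossless
#' float round trip via [read_multichannel_tiff()].
#'
#' @param image H x W x C array with channel names.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(image, path) {
  ch <- dimnames(image)[[3]]
  scales <- vapply(seq_along(ch), function(j) max(image[, , j], 1e-12), numeric(1))
  pages <- lapply(seq_along(ch), function(j) image[, , j] / scales[j])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  utils::write.table(
    data.frame(channel = ch, scale = scales),
    paste0(path, ".channels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multichannel TIFF written by [write_multichannel_tiff()]
#'
#' @param path TIFF path (sidecar `<path>.channels.tsv` must exist).
#' @return H x W x C array with channel names.
#' @export
read_multichannel_tiff <- function(path) {
  side <- utils::read.delim(paste0(path, ".channels.tsv"), stringsAsFactors = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == nrow(side))
  img <- array(0, dim = c(dim(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, side$channel))
  for (j in seq_along(pages)) img[, , j] <- pages[[j]] * side$scale[j]
  img
}
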