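# Synthetic zoned-tissue image generator for the pixel-as-event imaging
# pipeline.  Zones carry subset archetypes; truth masks are the zone masks.

#' Default imaging channel set
#'
#' The nine B cell classification markers plus CD3 (T cells) and cytokeratin
#' (epithelium), matching the tissue-imaging panel used for pixel
#' classification.
#'
#' @return Character vector of channel names.
#' @export
imc_channels <- function() {
  c("CD19", "CD20", "CD10", "CD24", "CD27", "CD38", "CD45RB", "IgM", "IgD",
    "CD3", "cytokeratin")
}

#' Construct a tissue zone
#'
#' @param name Zone label.
#' @param mask Logical H x W matrix of zone membership.
#' @param loc,scale Named per-channel location/scale parameters (arcsinh
#'   scale), as in [subset_archetype()].
#' @return A `tissue_zone` list.
#' @export
tissue_zone <- function(name, mask, loc, scale = 0.45) {
  stopifnot(is.character(name), is.matrix(mask), is.logical(mask))
  if (length(scale) == 1L) scale <- stats::setNames(rep(scale, length(loc)), names(loc))
  structure(list(name = name, mask = mask, loc = loc, scale = scale[names(loc)]),
            class = "tissue_zone")
}

#' Construct a tissue geometry
#'
#' Validates that zones are pairwise disjoint and lie within the image shape.
#'
#' @param shape Integer `c(height, width)` in pixels.
#' @param zones List of [tissue_zone()] objects.
#' @param background_noise Standard deviation of additive background noise
#'   applied to every pixel (0 disables it).
#' @param pixel_pitch Micrometres per pixel (default 1, i.e. 1000 nm spots).
#' @return A `tissue_geometry` list.
#' @export
tissue_geometry <- function(shape, zones, background_noise = 0.15,
                            pixel_pitch = 1.0) {
  stopifnot(length(shape) == 2L, all(shape >= 1), background_noise >= 0)
  occupancy <- matrix(0L, shape[1], shape[2])
  for (z in zones) {
    stopifnot(inherits(z, "tissue_zone"))
    if (!identical(dim(z$mask), as.integer(shape))) {
      stopf("zone '%s' mask does not match image shape", z$name)
    }
    occupancy <- occupancy + z$mask
  }
  if (any(occupancy > 1L)) stopf("tissue zones overlap")
  structure(
    list(shape = as.integer(shape), zones = zones,
         background_noise = background_noise, pixel_pitch = pixel_pitch),
    class = "tissue_geometry"
  )
}

disc_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

annulus_mask <- function(shape, center, r_inner, r_outer) {
  disc_mask(shape, center, r_outer) & !disc_mask(shape, center, r_inner)
}

band_mask <- function(shape, rows = NULL, cols = NULL) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(rows)) m[rows, ] <- TRUE
  if (!is.null(cols)) m[, cols] <- TRUE
  m
}

#' Default zoned tissue geometry
#'
#' Emulates organised gut lymphoid tissue: an epithelial band along the top
#' edge; a class-switched memory band along the tissue periphery (including
#' the sub-epithelial space); a germinal-centre disc with a marginal-zone
#' annulus immediately around it (sharing its boundary) and a naive annulus
#' outside that; and a separate T cell zone.  The marginal-zone annulus is
#' therefore adjacent to the GC and interior to the memory band, while the
#' memory band is nearer the epithelium than the marginal zone is.
#'
#' @param shape Image shape in pixels, default 512 x 512; the zone layout
#'   scales with the image, so each dimension must be at least 128.
#' @param background_noise Additive background noise SD, default 0.15.
#' @return A [tissue_geometry()] object with zones `epithelium`, `memory`,
#'   `gc`, `mz`, `naive`, `tzone`.
#' @export
default_tissue_geometry <- function(shape = c(512L, 512L),
                                    background_noise = 0.15) {
  shape <- as.integer(shape)
  if (min(shape) < 128L) stopf("default geometry needs each dimension >= 128")
  ch <- imc_channels()
  neg <- stats::setNames(rep(0.3, length(ch)), ch)

  zloc <- function(...) {
    loc <- neg
    ov <- c(...)
    loc[names(ov)] <- ov
    loc
  }
  b <- c(CD19 = 3.5, CD20 = 3.5)

  h <- shape[1]; w <- shape[2]
  # scale the canonical 512 x 512 layout to the requested shape
  sc <- min(h, w) / 512
  ctr <- round(c(0.64 * h, 0.59 * w))
  tctr <- round(c(0.64 * h, 0.25 * w))
  epi_rows <- seq_len(max(4L, round(24 * sc)))
  ring <- max(8L, round(36 * sc))

  epithelium <- band_mask(shape, rows = epi_rows)
  border <- band_mask(shape, rows = c(seq_len(round(60 * sc)), (h - ring + 1L):h),
                      cols = c(seq_len(ring), (w - ring + 1L):w))
  memory <- border & !epithelium
  gc_m <- disc_mask(shape, ctr, 55 * sc)
  mz_m <- annulus_mask(shape, ctr, 55 * sc, 80 * sc)
  nv_m <- annulus_mask(shape, ctr, 80 * sc, 115 * sc)
  tz_m <- disc_mask(shape, tctr, 50 * sc) & !(gc_m | mz_m | nv_m | border)

  zones <- list(
    tissue_zone("epithelium", epithelium,
                zloc(cytokeratin = 4.0)),
    tissue_zone("memory", memory,
                zloc(b, CD27 = 3.5, CD45RB = 2.6, CD24 = 1.8)),
    tissue_zone("gc", gc_m,
                zloc(b, CD10 = 3.5, CD38 = 4.0, CD27 = 2.4, IgM = 1.6)),
    tissue_zone("mz", mz_m,
                zloc(b, CD27 = 3.5, IgM = 3.6, IgD = 2.8, CD45RB = 3.5,
                     CD24 = 3.2)),
    tissue_zone("naive", nv_m,
                zloc(b, IgM = 2.6, IgD = 3.8, CD24 = 2.2, CD38 = 2.2)),
    tissue_zone("tzone", tz_m,
                zloc(CD3 = 4.0))
  )
  tissue_geometry(shape, zones, background_noise = background_noise)
}

#' Simulate a multichannel tissue image with truth masks
#'
#' Every pixel inside a zone draws its channel vector from the zone's
#' location-scale archetype (truncated at zero); unzoned pixels carry only
#' background.  Additive background noise is applied to all pixels.  Truth
#' masks reproduce zone membership exactly.
#'
#' @param geometry A [tissue_geometry()].
#' @param seed Integer seed; deterministic given seed.
#' @return List with `image` (H x W x C array, channel names on the third
#'   dimension), `truth_masks` (named list of logical H x W matrices) and
#'   `geometry`.
#' @export
sim_imc_image <- function(geometry, seed = NULL) {
  stopifnot(inherits(geometry, "tissue_geometry"))
  ch <- names(geometry$zones[[1]]$loc)
  h <- geometry$shape[1]; w <- geometry$shape[2]
  with_seed(seed, {
    img <- array(0, dim = c(h, w, length(ch)), dimnames = list(NULL, NULL, ch))
    masks <- list()
    for (z in geometry$zones) {
      n <- sum(z$mask)
      masks[[z$name]] <- z$mask
      if (!n) next
      for (j in seq_along(ch)) {
        plane <- img[, , j]
        plane[z$mask] <- pmax(stats::rnorm(n, z$loc[ch[j]], z$scale[ch[j]]), 0)
        img[, , j] <- plane
      }
    }
    if (geometry$background_noise > 0) {
      img <- img + abs(stats::rnorm(length(img), 0, geometry$background_noise))
    }
    list(image = img, truth_masks = masks, geometry = geometry)
  })
}
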