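#' Radial region geometry for spot assignment
#'
#' The three-ring scheme bands the cytoplasm by signed distance from the
#' nuclear boundary (negative = inside the nucleus): a perinuclear band from
#' -7 to +7 micrometres (the MTOC, the destination of dynein-driven cargo,
#' sits at the nuclear periphery, so the band reaches inside the nuclear
#' outline), an intermediate band (7, 14], and an outer band (14, 35] chosen
#' to cover the largest cytoplasmic extent of the assay cell line. Upper band
#' edges are exclusive (half-open) so assignment at an exact boundary is
#' deterministic. The two-zone scheme splits the cell into an inner region
#' (nucleus plus perinuclear zone, a configured fraction of cell area) and a
#' peripheral remainder; it is used for the early-endosome localization
#' ratio.
#'
#' @param scheme `"three_ring"` or `"two_zone"`.
#' @param peri_in,peri_out,inter_out,outer_out Band edges in micrometres of
#'   signed distance from the nuclear boundary.
#' @param inner_area_frac For the two-zone scheme: fraction of total cell
#'   area covered by the inner region.
#' @return An object of class `region_geometry`.
#' @export
region_geometry <- function(scheme = c("three_ring", "two_zone"),
                            peri_in = -7, peri_out = 7,
                            inter_out = 14, outer_out = 35,
                            inner_area_frac = 0.5) {
  scheme <- match.arg(scheme)
  stopifnot(peri_in < peri_out, peri_out < inter_out, inter_out < outer_out,
            inner_area_frac > 0, inner_area_frac < 1)
  structure(list(
    scheme = scheme,
    bands_um = c(peri_in = peri_in, peri_out = peri_out,
                 inter_out = inter_out, outer_out = outer_out),
    inner_area_frac = inner_area_frac
  ), class = "region_geometry")
}

#' Spot-detection parameters
#'
#' Two knobs dominate spot detection: `detection_sensitivity`, the minimum
#' blob response for a peak to count as a spot, and `splitting_um`, the
#' minimum separation below which adjacent peaks are merged into the stronger
#' one. The expected spot radius range sets the scales of the multi-scale
#' blob filter.
#'
#' @param detection_sensitivity Threshold on the scale-normalized
#'   Laplacian-of-Gaussian response (image intensity units).
#' @param splitting_um Minimum peak separation in micrometres.
#' @param radius_range_um Length-2 vector: expected spot radius range (um).
#' @param background_subtraction Apply rolling-window (top-hat) background
#'   subtraction before filtering (used for the RFP channel).
#' @param background_radius_um Rolling-window radius; defaults to three times
#'   the maximum spot radius.
#' @return An object of class `spot_params`.
#' @export
spot_params <- function(detection_sensitivity = 0.15,
                        splitting_um = 3,
                        radius_range_um = c(1, 3),
                        background_subtraction = FALSE,
                        background_radius_um = 3 * max(radius_range_um)) {
  stopifnot(length(radius_range_um) == 2, all(radius_range_um > 0),
            radius_range_um[1] <= radius_range_um[2],
            splitting_um >= 0, detection_sensitivity > 0)
  structure(as.list(environment()), class = "spot_params")
}

log_kernel <- function(sigma) {
  k <- max(3L, ceiling(3 * sigma))
  x <- -k:k
  g <- outer(x, x, function(i, j) {
    r2 <- i^2 + j^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  g <- g - mean(g)   # zero-DC so flat background gives zero response
  # scale-normalized: -sigma^2 * laplacian(Gaussian); response to a matched
  # Gaussian blob of amplitude A is ~A/2 independent of sigma
  -g / (2 * pi)
}

tophat_background <- function(img, radius_px) {
  brush <- EBImage::makeBrush(2 * max(1L, round(radius_px)) + 1L, shape = "disc")
  EBImage::opening(img, brush)
}

#' Detect spots with a multi-scale Laplacian-of-Gaussian filter
#'
#' Convolves the image with scale-normalized LoG kernels over the configured
#' radius range, takes the per-pixel maximum response across scales, keeps
#' local maxima whose response exceeds `detection_sensitivity`, merges peaks
#' closer than `splitting_um` into the stronger peak, and discards detections
#' outside the cell mask.
#'
#' @param img Numeric matrix (single-channel image).
#' @param mask Optional logical/numeric matrix; detections outside it are
#'   dropped. NULL keeps all in-image detections.
#' @param params A [spot_params()].
#' @param um_per_px Pixel size in micrometres.
#' @return data.frame with columns `x`, `y` (pixel coordinates, matrix row =
#'   x convention), `response`, `sigma_px`.
#' @export
detect_spots <- function(img, mask = NULL, params = spot_params(),
                         um_per_px = 1) {
  r_px <- params$radius_range_um / um_per_px
  if (r_px[2] < 1) stop("spot radius range below one pixel at ", um_per_px,
                        " um/px; detection is ill-posed")
  if (isTRUE(params$background_subtraction)) {
    img <- img - tophat_background(img, params$background_radius_um / um_per_px)
  }
  sigmas <- unique(seq(r_px[1], r_px[2], length.out = 3)) / sqrt(2)
  sigmas <- pmax(sigmas, 0.6)
  resp <- NULL
  for (s in sigmas) {
    r <- as.matrix(EBImage::filter2(as.matrix(img), log_kernel(s)))
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }

  # 3x3 local maxima above threshold
  nr <- nrow(resp); nc <- ncol(resp)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- resp
  is_max <- resp >= params$detection_sensitivity
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & resp >= pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0),
                      sigma_px = numeric(0)))
  spots <- data.frame(x = idx[, 1], y = idx[, 2],
                      response = resp[idx], sigma_px = NA_real_)
  spots <- spots[order(-spots$response, spots$x, spots$y), , drop = FALSE]

  # merge peaks closer than the splitting distance, keeping the stronger
  min_sep <- params$splitting_um / um_per_px
  if (min_sep > 0 && nrow(spots) > 1) {
    keep <- logical(nrow(spots))
    kx <- ky <- numeric(0)
    for (i in seq_len(nrow(spots))) {
      if (length(kx) == 0 ||
          all((kx - spots$x[i])^2 + (ky - spots$y[i])^2 >= min_sep^2)) {
        keep[i] <- TRUE
        kx <- c(kx, spots$x[i]); ky <- c(ky, spots$y[i])
      }
    }
    spots <- spots[keep, , drop = FALSE]
  }
  if (!is.null(mask)) {
    m <- as.matrix(mask)
    inside <- m[cbind(spots$x, spots$y)] > 0
    spots <- spots[inside, , drop = FALSE]
  }
  rownames(spots) <- NULL
  spots
}

#' Signed distance of pixels from the nuclear boundary
#'
#' Positive outside the nucleus, negative inside, in pixels.
#' @param nucleus_mask Logical/numeric matrix marking the nucleus.
#' @return Numeric matrix of signed distances (pixels).
#' @export
signed_distance_from_nucleus <- function(nucleus_mask) {
  m <- as.matrix(nucleus_mask) > 0
  outside <- as.matrix(EBImage::distmap(1 - m))
  inside <- as.matrix(EBImage::distmap(m * 1))
  outside - inside
}

#' Assign detected spots to radial regions
#'
#' Each spot inside the cell mask is assigned to exactly one band of the
#' three-ring scheme by its signed distance from the nuclear boundary; spots
#' beyond the outer band (or deeper inside the nucleus than the perinuclear
#' band reaches) are counted as out-of-range, so region counts always sum to
#' the number of spots supplied.
#'
#' @param spots data.frame from [detect_spots()] (columns `x`, `y`).
#' @param nucleus_mask,cell_mask Masks for this cell.
#' @param geometry A [region_geometry()].
#' @param um_per_px Pixel size.
#' @return Named integer vector: `perinuclear`, `intermediate`, `outer`,
#'   `out_of_range`.
#' @export
assign_spots_to_regions <- function(spots, nucleus_mask, cell_mask,
                                    geometry = region_geometry(),
                                    um_per_px = 1) {
  counts <- c(perinuclear = 0L, intermediate = 0L, outer = 0L, out_of_range = 0L)
  if (nrow(spots) == 0) return(counts)
  d <- signed_distance_from_nucleus(nucleus_mask)
  d_um <- d[cbind(round(spots$x), round(spots$y))] * um_per_px
  lab <- bin_radial_um(d_um, geometry)
  tab <- table(factor(lab, levels = names(counts)))
  counts[] <- as.integer(tab)
  counts
}

#' Perinuclear/peripheral localization ratio
#'
#' The ratio of spot counts in the inner (perinuclear) region to the
#' peripheral region; values below one indicate cargo dispersion. When the
#' peripheral count is zero, a pseudocount of 1 is added to both terms to
#' keep the ratio finite and monotone; otherwise the plain ratio is
#' returned. Downstream statistics use `log = TRUE` because log ratios are
#' close to normally distributed.
#'
#' @param inner,peripheral Non-negative spot counts (vectorized).
#' @param log Return the natural log of the ratio.
#' @return Numeric ratio (or log ratio).
#' @export
localization_ratio <- function(inner, peripheral, log = FALSE) {
  if (any(inner < 0) || any(peripheral < 0)) stop("spot counts must be >= 0")
  zero <- peripheral == 0
  ratio <- ifelse(zero, (inner + 1) / (peripheral + 1), inner / peripheral)
  if (log) base::log(pmax(ratio, .Machine$double.eps)) else ratio
}

#' Count MTOC puncta in a gamma-tubulin image
#'
#' Runs [detect_spots()] with an MTOC-scale parameter set restricted to one
#' cell mask and returns the punctum count. Downstream analysis summarizes
#' the counts as the per-well proportions of cells with 0, 1, or more than
#' one punctum.
#'
#' @param img Gamma-tubulin channel matrix.
#' @param cell_mask Mask of the cell.
#' @param params A [spot_params()]; the default uses a tight radius range and
#'   a higher sensitivity suited to bright centrosomal puncta.
#' @param um_per_px Pixel size.
#' @return Integer punctum count.
#' @export
count_mtoc_puncta <- function(img, cell_mask,
                              params = spot_params(detection_sensitivity = 0.1,
                                                   splitting_um = 1.5,
                                                   radius_range_um = c(0.8, 2)),
                              um_per_px = 1) {
  nrow(detect_spots(img, cell_mask, params, um_per_px))
}
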