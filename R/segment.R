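#' Segment nuclei from a Hoechst image
#'
#' Nuclei are detected by their strong Hoechst signal: the image is smoothed,
#' thresholded (Otsu by default, on the image's own histogram), small debris
#' removed, and touching nuclei split by watershed on the distance map. The
#' procedure is fully deterministic given the input.
#'
#' @param img Hoechst channel as a numeric matrix.
#' @param um_per_px Pixel size (micrometres per pixel).
#' @param min_area_um2 Objects smaller than this are discarded as debris.
#' @param smooth_sigma_px Gaussian smoothing sigma.
#' @param threshold Absolute intensity threshold; NULL uses Otsu.
#' @return Integer label matrix (0 = background), one label per nucleus.
#' @export
segment_nuclei <- function(img, um_per_px = 1, min_area_um2 = 50,
                           smooth_sigma_px = 1.5, threshold = NULL) {
  img <- as.matrix(img)
  if (all(img <= 0)) return(matrix(0L, nrow(img), ncol(img)))
  sm <- as.matrix(EBImage::gblur(img, sigma = smooth_sigma_px))
  if (is.null(threshold)) {
    rng <- range(sm)
    if (diff(rng) < .Machine$double.eps) return(matrix(0L, nrow(img), ncol(img)))
    threshold <- EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)),
                               range = c(0, 1)) * diff(rng) + rng[1]
  }
  mask <- sm > threshold
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask * 1)
  labels <- EBImage::watershed(dm, tolerance = 1, ext = 2)
  labels <- as.matrix(labels)
  # refine each object at half its own peak intensity: the half-maximum
  # contour tracks the true nuclear outline far better than the global cut
  for (l in seq_len(max(labels))) {
    obj <- labels == l
    if (!any(obj)) next
    local_thr <- 0.5 * stats::quantile(sm[obj], 0.95, names = FALSE)
    if (local_thr > threshold) labels[obj & sm <= local_thr] <- 0L
  }
  # drop debris below the minimum area, then relabel compactly
  min_px <- min_area_um2 / um_per_px^2
  tab <- tabulate(labels[labels > 0])
  drop <- which(tab < min_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel(labels)
}

relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(matrix(0L, nrow(labels), ncol(labels)))
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- match(labels[labels > 0], u)
  out
}

#' Segment cytoplasm around segmented nuclei
#'
#' Grows one cell region per nucleus by Voronoi-style propagation of the
#' nucleus seeds through the cytoplasmic signal (an alpha-tubulin stain, or
#' the weak Hoechst cytoplasmic background when no tubulin channel was
#' acquired). Cells whose boundary touches the image edge are flagged so they
#' can be excluded downstream. A nucleus with no surrounding signal falls
#' back to a dilated copy of the nucleus, with a logged note.
#'
#' @param context_img Cytoplasmic-context channel (matrix).
#' @param nuclei Label matrix from [segment_nuclei()].
#' @param threshold Absolute intensity threshold defining the cytoplasmic
#'   extent; NULL picks a low quantile of the positive signal.
#' @param fallback_dilate_px Dilation radius for nuclei without signal.
#' @return List: `cells` (label matrix, labels matching `nuclei`),
#'   `border_flag` (named logical per label).
#' @export
segment_cytoplasm <- function(context_img, nuclei, threshold = NULL,
                              fallback_dilate_px = 5) {
  nuclei <- as.matrix(nuclei)
  n_lab <- max(nuclei)
  if (n_lab == 0) {
    return(list(cells = matrix(0L, nrow(nuclei), ncol(nuclei)),
                border_flag = setNames(logical(0), character(0))))
  }
  ctx <- as.matrix(context_img)
  if (is.null(threshold)) {
    # half the bright-signal level: the cytoplasmic disc edge sits where the
    # signal falls to half its plateau
    pos <- ctx[ctx > 1e-3]
    threshold <- if (length(pos)) 0.5 * stats::quantile(pos, 0.95, names = FALSE)
                 else Inf
  }
  mask <- (ctx > threshold) | nuclei > 0
  cells <- as.matrix(EBImage::propagate(EBImage::Image(ctx), seeds = nuclei,
                                        mask = mask, lambda = 1e-4))
  # any nucleus whose cell never grew beyond itself: dilate it instead
  for (l in seq_len(n_lab)) {
    cell_px <- sum(cells == l)
    nuc_px <- sum(nuclei == l)
    if (cell_px <= nuc_px) {
      cs_log("nucleus %d has no surrounding signal; using dilated nucleus", l)
      brush <- EBImage::makeBrush(2 * fallback_dilate_px + 1, shape = "disc")
      dil <- as.matrix(EBImage::dilate(nuclei == l, brush))
      cells[dil > 0 & cells == 0] <- l
    }
  }
  border <- vapply(seq_len(n_lab), function(l) {
    any(cells[1, ] == l) || any(cells[nrow(cells), ] == l) ||
      any(cells[, 1] == l) || any(cells[, ncol(cells)] == l)
  }, logical(1))
  list(cells = cells, border_flag = setNames(border, seq_len(n_lab)))
}
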