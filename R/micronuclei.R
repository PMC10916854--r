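#' Detect micronuclei in the cytoplasm of one cell
#'
#' A micronucleus is a small Hoechst-positive chromatin body outside the main
#' nucleus, a marker of chromosome segregation errors. Candidate regions are
#' connected components of supra-background Hoechst signal inside the cell
#' but outside the (slightly dilated) nucleus; components are kept when their
#' mean intensity is at least `intensity_factor` times the local cytoplasmic
#' background and their area lies within `[area_min_um2, area_max]`, where
#' the upper bound is capped at a fraction of the nucleus area so that a
#' second full nucleus is rejected (with a logged note) rather than counted.
#'
#' @param hoechst Hoechst channel matrix.
#' @param nucleus_mask,cell_mask Masks for the cell under consideration.
#' @param um_per_px Pixel size.
#' @param intensity_factor Minimum mean intensity relative to the local
#'   cytoplasmic background (median Hoechst in the cytoplasm).
#' @param area_min_um2 Minimum micronucleus area.
#' @param area_max_frac Maximum area as a fraction of the nucleus area
#'   (must stay below 0.25).
#' @param exclusion_px Pixels around the nucleus boundary excluded so the
#'   nucleus' own intensity skirt (which sits above the cytoplasmic
#'   background just outside the segmented outline) is never counted.
#' @return List: `count`, and `features` (data.frame with one row per
#'   micronucleus: `x`, `y`, `area_um2`, `mean_intensity`,
#'   `dist_to_nucleus_um`).
#' @export
detect_micronuclei <- function(hoechst, nucleus_mask, cell_mask,
                               um_per_px = 1, intensity_factor = 2,
                               area_min_um2 = 1, area_max_frac = 0.25,
                               exclusion_px = 4) {
  hoechst <- as.matrix(hoechst)
  nuc <- as.matrix(nucleus_mask) > 0
  cell <- as.matrix(cell_mask) > 0
  empty <- list(count = 0L,
                features = data.frame(x = numeric(0), y = numeric(0),
                                      area_um2 = numeric(0),
                                      mean_intensity = numeric(0),
                                      dist_to_nucleus_um = numeric(0)))
  cyto <- cell & !nuc
  if (!any(cyto)) return(empty)
  brush <- EBImage::makeBrush(2 * exclusion_px + 1, shape = "disc")
  nuc_dil <- as.matrix(EBImage::dilate(nuc * 1, brush)) > 0
  search <- cell & !nuc_dil
  bg <- stats::median(hoechst[cyto])
  cand <- search & (hoechst > intensity_factor * max(bg, .Machine$double.eps))
  if (!any(cand)) return(empty)
  labels <- as.matrix(EBImage::bwlabel(cand * 1))
  nuc_area <- sum(nuc)
  a_min_px <- area_min_um2 / um_per_px^2
  a_max_px <- min(area_max_frac, 0.25) * nuc_area
  dist_map <- as.matrix(EBImage::distmap((!nuc) * 1))
  rows <- list()
  for (l in seq_len(max(labels))) {
    px <- which(labels == l, arr.ind = TRUE)
    area <- nrow(px)
    mean_int <- mean(hoechst[px])
    if (area < a_min_px) next
    if (area > a_max_px) {
      cs_log("candidate blob of %d px exceeds micronucleus size cap; rejected", area)
      next
    }
    if (mean_int < intensity_factor * bg) next
    cx <- mean(px[, 1]); cy <- mean(px[, 2])
    rows[[length(rows) + 1L]] <- data.frame(
      x = cx, y = cy, area_um2 = area * um_per_px^2,
      mean_intensity = mean_int,
      dist_to_nucleus_um = dist_map[round(cx), round(cy)] * um_per_px
    )
  }
  if (!length(rows)) return(empty)
  feats <- do.call(rbind, rows)
  list(count = nrow(feats), features = feats)
}
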