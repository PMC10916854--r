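#' Quantify one well's images into per-cell records
#'
#' The image-path counterpart of the simulated feature table: segments
#' nuclei and cytoplasm, flags border cells, detects spots per channel
#' within each cell, assigns them to radial regions, counts micronuclei and
#' MTOC puncta, and extracts intensity/texture/shape features. Channel names
#' follow [render_well_images()]: `hoechst` (required), `tubulin` (or the
#' Hoechst background is used as cytoplasmic context), spot channels among
#' `gfp`, `rfp`, `eea1`, `tgn46`, and `gamma_tubulin` for MTOC counting.
#'
#' @param images Named list of channel matrices.
#' @param um_per_px Pixel size.
#' @param spot_params_by_channel Named list of [spot_params()] per spot
#'   channel; unlisted channels use defaults (the RFP channel defaults to
#'   background subtraction on).
#' @param geometry [region_geometry()].
#' @param drop_border Exclude cells touching the image boundary.
#' @param with_texture Attach texture/morphology feature columns (slower).
#' @return data.frame, one row per analyzed cell; attribute
#'   `"provenance"` records the detection parameters used.
#' @export
quantify_well <- function(images, um_per_px = 1,
                          spot_params_by_channel = list(),
                          geometry = region_geometry(),
                          drop_border = TRUE,
                          with_texture = FALSE) {
  stopifnot("hoechst" %in% names(images))
  hoechst <- as.matrix(images$hoechst)
  nuclei <- segment_nuclei(hoechst, um_per_px = um_per_px)
  context <- if ("tubulin" %in% names(images)) as.matrix(images$tubulin) else hoechst
  seg <- segment_cytoplasm(context, nuclei)
  cells <- seg$cells
  n_lab <- max(nuclei)
  if (n_lab == 0) {
    return(structure(data.frame(), provenance = list(um_per_px = um_per_px)))
  }
  spot_channels <- intersect(names(images), CHANNELS)
  params <- lapply(setNames(spot_channels, spot_channels), function(ch) {
    p <- spot_params_by_channel[[ch]]
    if (is.null(p)) p <- spot_params(background_subtraction = identical(ch, "rfp"))
    p
  })
  # detect spots once per channel over the whole field, then assign per cell
  field_spots <- lapply(spot_channels, function(ch)
    detect_spots(as.matrix(images[[ch]]), mask = cells > 0,
                 params = params[[ch]], um_per_px = um_per_px))
  names(field_spots) <- spot_channels
  sd_full <- signed_distance_from_nucleus(nuclei > 0)

  rows <- list()
  for (l in seq_len(n_lab)) {
    nuc <- nuclei == l
    cell <- cells == l
    border <- isTRUE(seg$border_flag[[as.character(l)]])
    if (drop_border && border) next
    area_px <- sum(nuc)
    per <- mask_perimeter(nuc)
    px <- which(nuc, arr.ind = TRUE)
    rec <- data.frame(
      cell_id = l, border = border,
      nucleus_area = area_px * um_per_px^2,
      nucleus_roundness = if (per > 0) min(1, 4 * pi * area_px / per^2) else 0,
      hoechst_int = sum(hoechst[nuc])
    )
    for (ch in spot_channels) {
      sp <- field_spots[[ch]]
      own <- sp[cells[cbind(round(sp$x), round(sp$y))] == l, , drop = FALSE]
      d_um <- sd_full[cbind(round(own$x), round(own$y))] * um_per_px
      lab <- bin_radial_um(d_um, geometry)
      rec[[paste0(ch, "_total")]] <- nrow(own)
      rec[[paste0(ch, "_perinuclear")]] <- sum(lab == "perinuclear")
      rec[[paste0(ch, "_intermediate")]] <- sum(lab == "intermediate")
      rec[[paste0(ch, "_outer")]] <- sum(lab == "outer")
      rec[[paste0(ch, "_oor")]] <- sum(lab == "out_of_range")
      rec[[paste0(ch, "_int")]] <- mean(as.matrix(images[[ch]])[cell])
    }
    if ("eea1" %in% spot_channels) {
      sp <- field_spots$eea1
      own <- sp[cells[cbind(round(sp$x), round(sp$y))] == l, , drop = FALSE]
      d_um <- sd_full[cbind(round(own$x), round(own$y))] * um_per_px
      cut_um <- inner_zone_cut(cell, nuc, geometry, um_per_px, sd_full)
      rec$eea1_inner <- sum(d_um <= cut_um)
      rec$eea1_peripheral <- nrow(own) - rec$eea1_inner
    }
    mn <- detect_micronuclei(hoechst, nuc, cell, um_per_px = um_per_px)
    rec$micronucleus_count <- mn$count
    rec$mtoc_count <- if ("gamma_tubulin" %in% names(images))
      count_mtoc_puncta(as.matrix(images$gamma_tubulin), cell,
                        um_per_px = um_per_px) else NA_integer_
    if (with_texture) {
      tx <- extract_texture_morphology(hoechst, nuc, um_per_px)
      rec <- cbind(rec, as.data.frame(as.list(setNames(tx, paste0("nuc.", names(tx))))))
    }
    rows[[length(rows) + 1L]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  structure(out, provenance = list(
    um_per_px = um_per_px, geometry = unclass(geometry),
    spot_params = lapply(params, unclass)
  ))
}

# distance cut (um) such that the inner zone (nucleus + perinuclear area)
# covers the configured fraction of the cell area
inner_zone_cut <- function(cell_mask, nucleus_mask, geometry, um_per_px,
                           sd_full = NULL) {
  if (is.null(sd_full)) sd_full <- signed_distance_from_nucleus(nucleus_mask)
  d_cell <- sd_full[cell_mask]
  stats::quantile(d_cell, geometry$inner_area_frac, names = FALSE) * um_per_px
}
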