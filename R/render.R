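# add a Gaussian peak to an image in place (local window for speed)
add_gaussian <- function(img, x, y, amp, sigma) {
  w <- ceiling(4 * sigma)
  xs <- max(1, round(x) - w):min(nrow(img), round(x) + w)
  ys <- max(1, round(y) - w):min(ncol(img), round(y) + w)
  if (!length(xs) || !length(ys)) return(img)
  gx <- exp(-((xs - x)^2) / (2 * sigma^2))
  gy <- exp(-((ys - y)^2) / (2 * sigma^2))
  img[xs, ys] <- img[xs, ys] + amp * outer(gx, gy)
  img
}

# smooth-edged disc indicator centred at (x, y)
add_disc <- function(img, x, y, radius, amp, edge = 1) {
  w <- ceiling(radius + 4 * edge)
  xs <- max(1, round(x) - w):min(nrow(img), round(x) + w)
  ys <- max(1, round(y) - w):min(ncol(img), round(y) + w)
  r <- sqrt(outer((xs - x)^2, (ys - y)^2, `+`))
  img[xs, ys] <- img[xs, ys] + amp / (1 + exp((r - radius) / edge))
  img
}

#' Render multi-channel well images from a cell table
#'
#' Converts the per-cell records of one well into synthetic microscopy
#' images plus pixel-level ground truth, for benchmarking the image
#' quantification stage. Cells are placed on a jittered grid of
#' non-overlapping tiles (a configured density cap errors out rather than
#' rendering untestable overlaps). Nuclei are smooth bright discs in the
#' Hoechst channel (with a weak cytoplasmic background), the cytoplasm is a
#' diffuse disc in the tubulin channel, spots are 2-D Gaussian peaks at
#' radial positions drawn from each cell's generative mixture, micronuclei
#' are small bright Hoechst discs outside the nucleus, and MTOC puncta are
#' bright peaks near the nuclear boundary in the gamma-tubulin channel.
#' Additive Gaussian noise is applied at `noise_sd` (0 = noise-free).
#'
#' @param cells Cell table for one well (rows from
#'   [sample_cell_population()]).
#' @param config The [sim_config()] used to generate the cells.
#' @param channels Channels to render, a subset of `hoechst`, `tubulin`,
#'   `gfp`, `rfp`, `eea1`, `tgn46`, `gamma_tubulin`.
#' @param noise_sd Gaussian noise sigma; defaults to the config's value.
#' @param image_px Optional image side length; error if the cells cannot be
#'   placed without overlap.
#' @param min_sep_um Minimum separation between rendered spots of one cell
#'   and channel. Two point sources closer than the optical splitting
#'   distance are indistinguishable from a single blob, so the rendered
#'   ground truth keeps planted spots resolvable; positions are rejection
#'   resampled (radial distribution preserved up to the rejection).
#' @param seed Integer seed for spot placement and noise.
#' @return List with `images` (named list of matrices), `truth` (nucleus and
#'   cell label matrices, per-channel spot coordinates with radial distances
#'   and region labels, micronucleus and MTOC coordinates, cell centres),
#'   and `um_per_px`.
#' @export
render_well_images <- function(cells, config = sim_config(),
                               channels = c("hoechst", "tubulin", "gfp",
                                            "rfp", "eea1", "gamma_tubulin"),
                               noise_sd = config$noise_sd,
                               image_px = NULL, min_sep_um = 5, seed = 1) {
  set.seed(seed)
  upp <- config$um_per_px
  n <- nrow(cells)
  r_cell_max <- (config$nucleus_radius_um + config$cytoplasm_radius_um) / upp
  tile <- ceiling(2 * r_cell_max + 16)
  g <- max(1, ceiling(sqrt(n)))
  need <- g * tile
  if (is.null(image_px)) image_px <- need
  if (need > image_px)
    stop("cell density too high: ", n, " cells need ", need,
         " px but image is ", image_px, " px; segmentation would be untestable")

  imgs <- lapply(channels, function(ch) matrix(0, image_px, image_px))
  names(imgs) <- channels
  nuc_lab <- matrix(0L, image_px, image_px)
  cell_lab <- matrix(0L, image_px, image_px)
  spot_rows <- list(); mn_rows <- list(); mtoc_rows <- list()
  centers <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                        r_nucleus_px = numeric(0), r_cell_px = numeric(0))
  geom <- region_geometry()

  for (i in seq_len(n)) {
    gi <- (i - 1) %/% g; gj <- (i - 1) %% g
    cx <- gi * tile + tile / 2 + stats::runif(1, -2, 2)
    cy <- gj * tile + tile / 2 + stats::runif(1, -2, 2)
    r_nuc <- sqrt(cells$nucleus_area[i] / pi) / upp
    r_cell <- r_nuc + config$cytoplasm_radius_um / upp
    centers <- rbind(centers, data.frame(cell_id = i, x = cx, y = cy,
                                         r_nucleus_px = r_nuc,
                                         r_cell_px = r_cell))
    # label masks (hard discs = ground truth)
    xs <- max(1, floor(cx - r_cell)):min(image_px, ceiling(cx + r_cell))
    ys <- max(1, floor(cy - r_cell)):min(image_px, ceiling(cy + r_cell))
    rr <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`))
    nb <- nuc_lab[xs, ys]; cb <- cell_lab[xs, ys]
    nb[rr <= r_nuc] <- i; cb[rr <= r_cell] <- i
    nuc_lab[xs, ys] <- nb; cell_lab[xs, ys] <- cb

    dens <- cells$hoechst_int[i] / cells$nucleus_area[i]
    if ("hoechst" %in% channels) {
      imgs$hoechst <- add_disc(imgs$hoechst, cx, cy, r_nuc, amp = dens, edge = 1)
      imgs$hoechst <- add_disc(imgs$hoechst, cx, cy, r_cell, amp = 0.06, edge = 2)
      if (cells$micronucleus_count[i] > 0) {
        px <- py <- numeric(0)
        for (k in seq_len(cells$micronucleus_count[i])) {
          for (try in 1:60) {
            d_mn <- stats::runif(1, 7, min(16, config$cytoplasm_radius_um - 3)) / upp
            th <- stats::runif(1, 0, 2 * pi)
            mx <- cx + (r_nuc + d_mn) * cos(th); my <- cy + (r_nuc + d_mn) * sin(th)
            if (!length(px) || all((px - mx)^2 + (py - my)^2 >= (6 / upp)^2)) break
          }
          px <- c(px, mx); py <- c(py, my)
          imgs$hoechst <- add_disc(imgs$hoechst, mx, my, 1.4 / upp,
                                   amp = dens * 1.1, edge = 0.5)
          mn_rows[[length(mn_rows) + 1L]] <- data.frame(cell_id = i, x = mx, y = my)
        }
      }
    }
    if ("tubulin" %in% channels)
      imgs$tubulin <- add_disc(imgs$tubulin, cx, cy, r_cell, amp = 0.4, edge = 2)
    if ("gamma_tubulin" %in% channels && cells$mtoc_count[i] > 0) {
      n_mt <- cells$mtoc_count[i]
      th0 <- stats::runif(1, 0, 2 * pi)
      for (k in seq_len(n_mt)) {
        th <- th0 + (k - 1) * 2 * pi / max(1, n_mt)
        d_mt <- stats::runif(1, 0.5, 2) / upp
        mx <- cx + (r_nuc + d_mt) * cos(th); my <- cy + (r_nuc + d_mt) * sin(th)
        imgs$gamma_tubulin <- add_gaussian(imgs$gamma_tubulin, mx, my, 0.9, 1.2 / upp)
        mtoc_rows[[length(mtoc_rows) + 1L]] <- data.frame(cell_id = i, x = mx, y = my)
      }
    }
    for (ch in intersect(CHANNELS, channels)) {
      n_sp <- cells[[paste0(ch, "_total")]][i]
      if (n_sp == 0) next
      pi_c <- cells[[paste0("truth_pi_", ch)]][i]
      sx <- sy <- d <- numeric(n_sp)
      min_sep_px <- min_sep_um / upp
      for (k in seq_len(n_sp)) {
        for (try in 1:60) {
          dk <- if (stats::runif(1) < pi_c)
            stats::rexp(1, rate = 1 / config$lambda_um)
          else stats::runif(1, 0, config$cytoplasm_radius_um)
          dk <- min(dk, config$cytoplasm_radius_um - 0.5)
          thk <- stats::runif(1, 0, 2 * pi)
          xk <- cx + (r_nuc + dk / upp) * cos(thk)
          yk <- cy + (r_nuc + dk / upp) * sin(thk)
          if (k == 1 || all((sx[seq_len(k - 1)] - xk)^2 +
                              (sy[seq_len(k - 1)] - yk)^2 >= min_sep_px^2))
            break
        }
        sx[k] <- xk; sy[k] <- yk; d[k] <- dk
      }
      for (k in seq_len(n_sp))
        imgs[[ch]] <- add_gaussian(imgs[[ch]], sx[k], sy[k], 0.6, 1.2 / upp)
      spot_rows[[length(spot_rows) + 1L]] <- data.frame(
        channel = ch, cell_id = i, x = sx, y = sy, d_um = d,
        region = bin_radial_um(d, geom))
    }
  }
  if (noise_sd > 0)
    imgs <- lapply(imgs, function(m)
      pmax(m + stats::rnorm(length(m), 0, noise_sd), 0))

  list(
    images = imgs,
    truth = list(
      nuclei = nuc_lab, cells = cell_lab, centers = centers,
      spots = if (length(spot_rows)) do.call(rbind, spot_rows) else
        data.frame(channel = character(0), cell_id = integer(0), x = numeric(0),
                   y = numeric(0), d_um = numeric(0), region = character(0)),
      micronuclei = if (length(mn_rows)) do.call(rbind, mn_rows) else
        data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0)),
      mtoc = if (length(mtoc_rows)) do.call(rbind, mtoc_rows) else
        data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0))
    ),
    um_per_px = upp
  )
}
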