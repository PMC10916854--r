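CHANNELS <- c("gfp", "rfp", "eea1", "tgn46")

# effective clustered fraction per channel after applying an effect
effective_pi <- function(pi0, effect_class, effect_size) {
  es <- clamp01(effect_size)
  pis <- rep(pi0, length(CHANNELS))
  names(pis) <- CHANNELS
  switch(effect_class,
    dispersion_all = pis[] <- pi0 * (1 - es),
    dispersion_PEX_only = pis[c("gfp", "rfp")] <- pi0 * (1 - es),
    dispersion_EEA1_only = pis["eea1"] <- pi0 * (1 - es),
    hyperclustering_EEA1 = pis["eea1"] <- pi0 + (1 - pi0) * es,
    NULL
  )
  pis
}

# three-ring band edges in micrometres of signed distance from the nuclear
# boundary (negative = inside the nucleus); upper edges are exclusive except
# that the perinuclear band is closed on both sides of zero
bin_radial_um <- function(d, geometry = region_geometry()) {
  b <- geometry$bands_um
  cut_lab <- character(length(d))
  cut_lab[d >= b[["peri_in"]] & d <= b[["peri_out"]]] <- "perinuclear"
  cut_lab[d > b[["peri_out"]] & d <= b[["inter_out"]]] <- "intermediate"
  cut_lab[d > b[["inter_out"]] & d <= b[["outer_out"]]] <- "outer"
  cut_lab[cut_lab == ""] <- "out_of_range"
  cut_lab
}

#' Sample a per-cell feature population for one well
#'
#' Draws the cell population of a single well from the generative model: cell
#' count Poisson around the configured mean (scaled by any viability effect),
#' per-cell spot counts negative binomial, and spot radial positions from a
#' two-component mixture of an exponential decay from the nuclear boundary
#' (clustered, fraction `pi_clustered`) and a uniform distribution over the
#' cytoplasm. Dispersion effects lower the clustered fraction,
#' hyperclustering raises it; micronucleus counts are Poisson and MTOC counts
#' multinomial over {0, 1, >1}. Degenerate effect sizes clamp to [0, 1] with
#' a logged note rather than erroring.
#'
#' @param well A list or one-row data.frame with `plate_id`, `row`, `col`,
#'   `role` (and `gene` for library wells).
#' @param effect A list with `effect_class`, `effect_size` and optionally
#'   `viability_mult`; control roles use their built-in effects when `effect`
#'   is NULL.
#' @param config A [sim_config()].
#' @param seed Optional integer; when given, seeds the RNG before drawing so
#'   the well is reproducible in isolation.
#' @return data.frame with one row per cell: morphology, intensities,
#'   micronucleus and MTOC counts, and per-channel spot counts by radial
#'   region (`*_perinuclear`, `*_intermediate`, `*_outer`, `*_oor`, `*_total`)
#'   plus the two-zone early-endosome split (`eea1_inner`, `eea1_peripheral`).
#'   Columns prefixed `truth_` carry generative ground truth.
#' @export
sample_cell_population <- function(well, effect = NULL, config = sim_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effect)) {
    effect <- control_effect(well$role)
  }
  viab_mult <- effect$viability_mult %||% 1
  es <- clamp01(effect$effect_size %||% 0)
  if (identical(effect$effect_class, "lethal")) {
    viab_mult <- viab_mult * max(0.05, 1 - 0.95 * es)
  }

  n <- stats::rpois(1, config$cells_per_well_mean * viab_mult)

  viable_frac <- config$viable_frac *
    if (identical(effect$effect_class, "lethal")) 0.6 else 1
  apoptotic <- stats::runif(n) > viable_frac
  rep_neg <- stats::runif(n) > config$reporter_pos_frac

  r_nuc <- config$nucleus_radius_um
  area_mu <- pi * r_nuc^2
  area <- ifelse(apoptotic,
                 pmax(10, stats::rnorm(n, 0.35 * area_mu, 12)),
                 pmax(30, stats::rnorm(n, area_mu, config$nucleus_area_sd)))
  roundness <- ifelse(apoptotic,
                      stats::runif(n, 0.30, 0.65),
                      pmin(1, 0.97 - abs(stats::rnorm(n, 0, 0.02))))
  dens <- ifelse(apoptotic, stats::rnorm(n, 1.6, 0.15), stats::rnorm(n, 1, 0.1))
  hoechst_int <- pmax(0, area * dens)

  meas <- function(x) x * exp(stats::rnorm(n, 0, config$noise_sd))
  gfp_int <- meas(ifelse(rep_neg, stats::rlnorm(n, log(20), 0.4),
                         stats::rlnorm(n, log(500), 0.3)))
  rfp_int <- meas(ifelse(rep_neg, stats::rlnorm(n, log(15), 0.4),
                         stats::rlnorm(n, log(400), 0.3)))

  mn_rate <- config$micronucleus_rate *
    if (identical(effect$effect_class, "micronucleus")) 1 + 9 * es else 1
  micronucleus_count <- stats::rpois(n, mn_rate)

  p <- config$mtoc_probs
  if (identical(effect$effect_class, "mtoc_gain")) {
    shift <- 0.8 * es * p[2]; p <- c(p[1], p[2] - shift, p[3] + shift)
  } else if (identical(effect$effect_class, "mtoc_loss")) {
    shift <- 0.8 * es * p[2]; p <- c(p[1] + shift, p[2] - shift, p[3])
  }
  mtoc_cat <- if (n > 0) sample.int(3, n, replace = TRUE, prob = p) else integer(0)
  mtoc_count <- ifelse(mtoc_cat == 3, 2L + stats::rbinom(n, 2, 0.4), mtoc_cat - 1L)

  pis <- effective_pi(config$pi_clustered, effect$effect_class %||% "none", es)
  geom <- region_geometry()
  r_cell <- r_nuc + config$cytoplasm_radius_um
  d_inner_cut <- sqrt(geom$inner_area_frac) * r_cell - r_nuc

  out <- data.frame(
    plate_id = rep(well$plate_id, n), row = rep(well$row, n),
    col = rep(well$col, n),
    role = rep(well$role, n), gene = rep(well$gene %||% "", n),
    field = (seq_len(n) - 1L) %% config$fields_per_well + 1L,
    cell_id = seq_len(n),
    nucleus_area = area, nucleus_roundness = roundness,
    hoechst_int = hoechst_int, gfp_int = gfp_int, rfp_int = rfp_int,
    micronucleus_count = micronucleus_count, mtoc_count = mtoc_count,
    truth_apoptotic = apoptotic, truth_reporter_neg = rep_neg,
    stringsAsFactors = FALSE
  )

  for (ch in CHANNELS) {
    pi_cell <- stats::plogis(stats::qlogis(pmin(pmax(pis[[ch]], 1e-4), 1 - 1e-4)) +
                             stats::rnorm(n, 0, 0.2))
    tot <- stats::rnbinom(n, mu = config$spot_mean, size = config$spot_dispersion)
    peri <- inter <- outer <- oor <- inner <- integer(n)
    for (i in seq_len(n)) {
      if (tot[i] == 0) next
      clustered <- stats::runif(tot[i]) < pi_cell[i]
      d <- numeric(tot[i])
      d[clustered] <- stats::rexp(sum(clustered), rate = 1 / config$lambda_um)
      d[!clustered] <- stats::runif(sum(!clustered), 0, config$cytoplasm_radius_um)
      lab <- bin_radial_um(d, geom)
      peri[i] <- sum(lab == "perinuclear")
      inter[i] <- sum(lab == "intermediate")
      outer[i] <- sum(lab == "outer")
      oor[i] <- sum(lab == "out_of_range")
      inner[i] <- sum(d <= d_inner_cut)
    }
    out[[paste0(ch, "_total")]] <- tot
    out[[paste0(ch, "_perinuclear")]] <- peri
    out[[paste0(ch, "_intermediate")]] <- inter
    out[[paste0(ch, "_outer")]] <- outer
    out[[paste0(ch, "_oor")]] <- oor
    out[[paste0("truth_pi_", ch)]] <- pi_cell
    if (ch == "eea1") {
      out$eea1_inner <- inner
      out$eea1_peripheral <- tot - inner
    }
  }
  out
}

#' Simulate a full arrayed screen at the cell level
#'
#' Runs [sample_cell_population()] for every well of a layout, resolving each
#' library gene's planted effect from the ground-truth table and each control
#' role's built-in effect. Every well draws from its own RNG stream keyed by
#' (plate, row, col, seed), so outputs are reproducible per well and in full.
#'
#' @param layout Plate layout from [generate_plate_layout()].
#' @param truth Ground-truth table from [ground_truth()]; NULL for an all-null
#'   library.
#' @param config A [sim_config()]; its `seed` drives all draws.
#' @return A list of class `synthetic_screen` with elements `cells` (one row
#'   per cell), `truth`, `well_truth` (realized per-well cell counts),
#'   `layout`, and `config`.
#' @export
simulate_screen <- function(layout, truth = NULL, config = sim_config()) {
  errs <- validate_plate_layout(layout)
  if (length(errs)) stop("invalid layout: ", paste(errs, collapse = "; "))
  lib_genes <- unique(layout$gene[layout$role == "LIBRARY"])
  if (is.null(truth)) truth <- ground_truth(lib_genes)
  missing_genes <- setdiff(lib_genes, truth$gene_id)
  if (length(missing_genes))
    stop("ground truth missing genes: ", paste(head(missing_genes, 5), collapse = ", "))

  plate_index <- match(layout$plate_id, unique(layout$plate_id))
  pieces <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    eff <- if (w$role == "LIBRARY") {
      tr <- truth[truth$gene_id == w$gene, ]
      list(effect_class = tr$effect_class, effect_size = tr$effect_size)
    } else NULL
    pieces[[i]] <- sample_cell_population(
      w, effect = eff, config = config,
      seed = well_seed(config$seed, plate_index[i], w$row, w$col)
    )
  }
  cells <- do.call(rbind, pieces)
  rownames(cells) <- NULL
  well_truth <- data.frame(layout,
                           n_cells = vapply(pieces, nrow, integer(1)))
  structure(list(cells = cells, truth = truth, well_truth = well_truth,
                 layout = layout, config = config),
            class = "synthetic_screen")
}

#' Simulate well-level endpoint scores directly
#'
#' A lighter companion to [simulate_screen()] that draws per-well endpoint
#' values on the well scale, skipping the cell level. Null wells (NTC and
#' unaffected library genes) draw from Normal(0, `well_sd`) on each cargo
#' endpoint; planted dispersion effects shift the affected endpoints by
#' `-effect_sd * effect_size` well-SD units (hyperclustering shifts
#' positive). Viability is drawn as an analyzed-cell count with near-total
#' loss for lethal genes and the editing control, and a partial loss for the
#' positive control. This is the scale on which SD-threshold hit calling
#' operates, so threshold logic can be exercised with exactly known planted
#' shifts.
#'
#' @param layout Plate layout.
#' @param truth Ground-truth table from [ground_truth()].
#' @param effect_sd Planted shift in units of the well-level SD.
#' @param well_sd Well-to-well SD of null wells on cargo endpoints.
#' @param seed Integer seed.
#' @return data.frame: the layout plus columns `pex_score`, `eea1_score`,
#'   `tgn46_score`, `mn_score`, `viability` (cell count).
#' @export
simulate_endpoint_scores <- function(layout, truth = NULL, effect_sd = 4,
                                     well_sd = 1, seed = 1) {
  lib_genes <- unique(layout$gene[layout$role == "LIBRARY"])
  if (is.null(truth)) truth <- ground_truth(lib_genes)
  set.seed(well_seed(seed, 0L, 0L, 0L))
  n <- nrow(layout)
  out <- layout
  tr <- truth[match(layout$gene, truth$gene_id), ]
  cls <- ifelse(layout$role == "LIBRARY", tr$effect_class, "none")
  es <- ifelse(layout$role == "LIBRARY", tr$effect_size, 0)
  es <- clamp01(es)

  shift <- function(classes) ifelse(cls %in% classes, -effect_sd * es * well_sd, 0)
  pex_mu <- shift(c("dispersion_all", "dispersion_PEX_only"))
  eea1_mu <- shift(c("dispersion_all", "dispersion_EEA1_only")) +
    ifelse(cls == "hyperclustering_EEA1", effect_sd * es * well_sd, 0)
  tgn_mu <- shift("dispersion_all")
  pex_mu[layout$role %in% c("POS_LIS1", "NOCODAZOLE")] <- -8 * well_sd
  eea1_mu[layout$role %in% c("POS_LIS1", "NOCODAZOLE")] <- -8 * well_sd
  tgn_mu[layout$role %in% c("POS_LIS1", "NOCODAZOLE")] <- -8 * well_sd

  mn_mu <- ifelse(cls == "micronucleus", effect_sd * es * well_sd, 0)

  viab_mu <- rep(300, n)
  viab_mu[layout$role == "POS_LIS1"] <- 210
  viab_mu[layout$role == "EDIT_PLK1" | cls == "lethal"] <- 20

  out$pex_score <- stats::rnorm(n, pex_mu, well_sd)
  out$eea1_score <- stats::rnorm(n, eea1_mu, well_sd)
  out$tgn46_score <- stats::rnorm(n, tgn_mu, well_sd)
  out$mn_score <- stats::rnorm(n, mn_mu, well_sd)
  out$viability <- pmax(0, stats::rnorm(n, viab_mu, ifelse(viab_mu < 50, 10, 20)))
  out
}
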