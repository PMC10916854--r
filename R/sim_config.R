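#' Simulation configuration for synthetic screens
#'
#' Collects the generative parameters of the synthetic-screen model. The
#' defaults describe a healthy screening plate: a few hundred analyzed cells
#' per well imaged over four fields, negative-binomial spot counts per cell,
#' and a radial spot mixture in which a fraction `pi_clustered` of spots decays
#' exponentially from the nuclear boundary (perinuclear clustering driven by
#' dynein) while the remainder is spread uniformly through the cytoplasm.
#'
#' @param cells_per_well_mean Mean analyzed cells per well (Poisson).
#' @param fields_per_well Fields of view per well (bookkeeping only; cells are
#'   assigned to fields round-robin).
#' @param spot_mean Mean spots per cell per channel.
#' @param spot_dispersion Negative-binomial size parameter; smaller values give
#'   more overdispersed per-cell spot counts.
#' @param pi_clustered Baseline fraction of spots in the perinuclear-clustered
#'   mixture component (0-1).
#' @param lambda_um Decay length (micrometres) of the clustered component,
#'   measured outward from the nuclear boundary.
#' @param cytoplasm_radius_um Radial extent of the cytoplasm beyond the
#'   nuclear boundary (micrometres); the uniform component lives on
#'   (0, cytoplasm_radius_um].
#' @param nucleus_radius_um Mean nuclear radius (micrometres).
#' @param nucleus_area_sd Standard deviation of nuclear area (square
#'   micrometres) among viable cells.
#' @param viable_frac Fraction of cells with normal (non-apoptotic,
#'   non-mitotic) nuclear morphology.
#' @param reporter_pos_frac Fraction of cells positive for both GFP and RFP
#'   reporters.
#' @param micronucleus_rate Baseline per-cell micronucleus rate (Poisson).
#' @param mtoc_probs Length-3 probability vector for cells with 0, 1, or >1
#'   gamma-tubulin puncta.
#' @param noise_sd Additive Gaussian noise applied to continuous per-cell
#'   features and to rendered images.
#' @param um_per_px Pixel size used when rendering images.
#' @param seed Mandatory integer seed; all draws are keyed to it per well.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(cells_per_well_mean = 300,
                       fields_per_well = 4,
                       spot_mean = 30,
                       spot_dispersion = 10,
                       pi_clustered = 0.7,
                       lambda_um = 3,
                       cytoplasm_radius_um = 30,
                       nucleus_radius_um = 7,
                       nucleus_area_sd = 25,
                       viable_frac = 0.95,
                       reporter_pos_frac = 0.9,
                       micronucleus_rate = 0.05,
                       mtoc_probs = c(0.05, 0.85, 0.10),
                       noise_sd = 0.05,
                       um_per_px = 1,
                       seed = 1) {
  stopifnot(
    cells_per_well_mean > 0, fields_per_well >= 1,
    spot_mean > 0, spot_dispersion > 0,
    pi_clustered >= 0, pi_clustered <= 1,
    lambda_um > 0, cytoplasm_radius_um > 0, nucleus_radius_um > 0,
    viable_frac >= 0, viable_frac <= 1,
    reporter_pos_frac >= 0, reporter_pos_frac <= 1,
    micronucleus_rate >= 0,
    length(mtoc_probs) == 3, abs(sum(mtoc_probs) - 1) < 1e-8,
    noise_sd >= 0, um_per_px > 0,
    is.numeric(seed), length(seed) == 1
  )
  structure(as.list(environment()), class = "sim_config")
}

#' Specify a planted effect for one gene
#'
#' Effect classes correspond to the phenotype categories the screen scores:
#' cargo dispersion (all cargoes, peroxisome reporters only, or early
#' endosomes only), excessive perinuclear hyperclustering of early endosomes,
#' lethality, micronucleus induction, and loss or gain of MTOC number.
#' `effect_size` is a dimensionless multiplier in `[0, 1]` scaling how far the
#' affected generative parameter is pushed toward its extreme (values above 1
#' are clamped with a logged warning).
#'
#' @param gene_id Gene identifier.
#' @param effect_class One of `none`, `dispersion_all`, `dispersion_PEX_only`,
#'   `dispersion_EEA1_only`, `hyperclustering_EEA1`, `lethal`, `micronucleus`,
#'   `mtoc_loss`, `mtoc_gain`.
#' @param effect_size Non-negative effect multiplier (ignored for `none`).
#' @param module_id Optional co-functional module label.
#' @return A one-row data.frame (class `effect_spec`).
#' @export
effect_spec <- function(gene_id, effect_class = "none", effect_size = 1,
                        module_id = NA_character_) {
  classes <- c("none", "dispersion_all", "dispersion_PEX_only",
               "dispersion_EEA1_only", "hyperclustering_EEA1", "lethal",
               "micronucleus", "mtoc_loss", "mtoc_gain")
  effect_class <- match.arg(effect_class, classes)
  if (effect_size < 0) stop("effect_size must be >= 0")
  structure(
    data.frame(gene_id = gene_id, effect_class = effect_class,
               effect_size = effect_size, module_id = module_id,
               stringsAsFactors = FALSE),
    class = c("effect_spec", "data.frame")
  )
}

#' Build a ground-truth table covering every library gene
#'
#' Genes not named in `effects` are assigned `effect_class = "none"`. The
#' result covers each library gene exactly once.
#'
#' @param library_genes Character vector of library gene ids.
#' @param effects A data.frame of effect specs (rows as from [effect_spec()]),
#'   or NULL for an all-null library.
#' @return data.frame with columns `gene_id`, `effect_class`, `effect_size`,
#'   `module_id`.
#' @export
ground_truth <- function(library_genes, effects = NULL) {
  gt <- data.frame(gene_id = unique(library_genes),
                   effect_class = "none", effect_size = 0,
                   module_id = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(effects) && nrow(effects)) {
    dup <- effects$gene_id[duplicated(effects$gene_id)]
    if (length(dup)) stop("duplicate effect specs for: ", paste(dup, collapse = ", "))
    unknown <- setdiff(effects$gene_id, gt$gene_id)
    if (length(unknown)) stop("effects name genes absent from the library: ",
                              paste(head(unknown, 5), collapse = ", "))
    i <- match(effects$gene_id, gt$gene_id)
    gt$effect_class[i] <- effects$effect_class
    gt$effect_size[i] <- effects$effect_size
    gt$module_id[i] <- effects$module_id
  }
  gt
}

# built-in control phenotypes: the positive control disperses all cargoes with
# a partial viability cost; the editing control is near-fully lethal
control_effect <- function(role) {
  switch(role,
    POS_LIS1 = list(effect_class = "dispersion_all", effect_size = 0.8,
                    viability_mult = 0.7),
    EDIT_PLK1 = list(effect_class = "lethal", effect_size = 1,
                     viability_mult = 1),
    NOCODAZOLE = list(effect_class = "dispersion_all", effect_size = 0.9,
                      viability_mult = 1),
    list(effect_class = "none", effect_size = 0, viability_mult = 1)
  )
}

clamp01 <- function(x, what = "effect_size") {
  if (any(x > 1 | x < 0)) {
    cs_log("%s clamped to [0, 1]", what)
    x <- pmin(pmax(x, 0), 1)
  }
  x
}
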