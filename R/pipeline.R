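#' Analyze a simulated or quantified screen end to end
#'
#' Runs the analysis stages on a cell table: well aggregation with viability
#' and reporter gating, per-plate rZ normalization, two-point viability
#' normalization (NTC 0, editing control 100), gene-level aggregation by
#' median per crRNA pool, confound exclusion, SD-threshold hit calling on
#' the cargo endpoints, micronucleus and MTOC calls, and phenotypic
#' fingerprint clustering.
#'
#' @param screen A `synthetic_screen` (from [simulate_screen()]) or a list
#'   with `cells` and `layout`.
#' @param k_cargo SD multiplier for cargo hit calling.
#' @param k_lethal,k_area,k_roundness Confound-exclusion multipliers.
#' @param k_mtoc MTOC categorization multiplier.
#' @param n_clusters Flat clusters for hierarchical fingerprint clustering.
#' @param kmeans_k K for cargo-signature K-means (clamped to the number of
#'   scorable genes).
#' @param seed Seed for the clustering stage.
#' @param min_cells Low-count threshold for well QC.
#' @return List of class `screen_analysis`: `profiles`, `rz`,
#'   `control_stats`, `gene_scores`, `exclusions`, `hits`, `mtoc`,
#'   `fingerprints`, `reduction`, `clusters_hier`, `clusters_kmeans`.
#' @export
analyze_screen <- function(screen, k_cargo = 2.5, k_lethal = 2.5,
                           k_area = 4, k_roundness = 3.5, k_mtoc = 2.5,
                           n_clusters = 8, kmeans_k = 14, seed = 1,
                           min_cells = 50) {
  cells <- screen$cells
  profiles <- aggregate_wells(cells, min_cells = min_cells)
  norm <- normalize_profiles(profiles, on_zero_mad = "drop")
  rz <- norm$rz
  essential <- c("pex_locratio", "eea1_locratio", "tgn46_locratio",
                 "nucleus_area", "nucleus_roundness")
  if (any(essential %in% norm$dropped_features))
    stop("no NTC spread for essential feature(s): ",
         paste(intersect(essential, norm$dropped_features), collapse = ", "))
  has_mn <- !"micronucleus_rate" %in% norm$dropped_features
  has_mtoc <- !any(c("mtoc_p0", "mtoc_p1", "mtoc_p2plus") %in%
                     norm$dropped_features)

  # two-point viability (NTC -> 0, editing control -> 100; higher = more loss)
  viab <- rep(NA_real_, nrow(profiles))
  for (p in unique(profiles$plate_id)) {
    on <- profiles$plate_id == p
    med_ntc <- stats::median(profiles$n_viable[on & profiles$role == "NTC"])
    med_pos <- stats::median(profiles$n_viable[on & profiles$role == "EDIT_PLK1"])
    if (!is.finite(med_pos) || med_pos == med_ntc)
      stop("no viability window on plate ", p)
    viab[on] <- two_point_normalize(profiles$n_viable[on], med_ntc, med_pos,
                                    pos_target = 100)
  }
  rz$viability_tp <- viab

  lib <- rz$role == "LIBRARY" & !rz$excluded
  is_ntc <- rz$role == "NTC" & !rz$excluded
  is_lis1 <- rz$role == "POS_LIS1" & !rz$excluded

  gene_of <- rz$gene[lib]
  agg <- function(col) aggregate_crRNA(rz[[col]][lib], gene_of)
  genes <- sort(unique(gene_of))
  agg_or_na <- function(col) {
    if (col %in% names(rz)) agg(col)[genes] else rep(NA_real_, length(genes))
  }
  gene_scores <- data.frame(
    gene = genes,
    pex = agg("pex_locratio")[genes],
    eea1 = agg("eea1_locratio")[genes],
    tgn46 = agg("tgn46_locratio")[genes],
    area = agg("nucleus_area")[genes],
    roundness = agg("nucleus_roundness")[genes],
    micronucleus = agg_or_na("micronucleus_rate"),
    viability = agg("viability_tp")[genes],
    mtoc_p0 = agg_or_na("mtoc_p0"),
    mtoc_p1 = agg_or_na("mtoc_p1"),
    mtoc_p2plus = agg_or_na("mtoc_p2plus"),
    row.names = NULL
  )

  ctrl <- is_ntc | is_lis1
  exclusions <- exclude_confounded(
    gene_scores,
    ctrl_area = rz$nucleus_area[ctrl],
    ctrl_roundness = rz$nucleus_roundness[ctrl],
    crlis1_viability = rz$viability_tp[is_lis1],
    k_area = k_area, k_roundness = k_roundness, k_lethal = k_lethal
  )

  endpoints <- c(pex = "pex", eea1 = "eea1", tgn46 = "tgn46")
  ref_ntc <- list(pex = rz$pex_locratio[is_ntc],
                  eea1 = rz$eea1_locratio[is_ntc],
                  tgn46 = rz$tgn46_locratio[is_ntc])
  hits <- data.frame(gene = gene_scores$gene, excluded = exclusions$excluded)
  for (ep in names(endpoints)) {
    rule <- threshold_rule(ep, reference = "NTC", k = k_cargo,
                           side = "two_sided", scale = "rz")
    flag <- call_cargo_hits(setNames(gene_scores[[ep]], gene_scores$gene),
                            ref_ntc[[ep]], rule)
    hits[[paste0("hit_", ep)]] <- as.logical(flag) & !exclusions$excluded
  }
  hits$hit_any_cargo <- hits$hit_pex | hits$hit_eea1 | hits$hit_tgn46
  hits$lethal <- as.logical(call_lethal(gene_scores$viability,
                                        rz$viability_tp[is_lis1], k = k_lethal))
  hits$micronucleus <- if (has_mn) {
    as.logical(call_micronucleus_hits(
      gene_scores$micronucleus, rz$micronucleus_rate[is_lis1], k = k_mtoc)) &
      !exclusions$excluded
  } else FALSE

  if (has_mtoc) {
    # MTOC categorization: raw proportions aggregated by mean (sum preserved)
    raw_prof <- profiles[match(interaction(rz$plate_id, rz$row, rz$col),
                               interaction(profiles$plate_id, profiles$row,
                                           profiles$col)), ]
    praw <- stats::aggregate(
      raw_prof[lib, c("mtoc_p0", "mtoc_p1", "mtoc_p2plus")],
      by = list(gene = gene_of), FUN = mean)
    praw <- praw[match(genes, praw$gene), ]
    mtoc <- categorize_mtoc(
      prop_raw = praw[, -1],
      prop_rz = gene_scores[, c("mtoc_p0", "mtoc_p1", "mtoc_p2plus")],
      ntc_rz = rz[is_ntc, c("mtoc_p0", "mtoc_p1", "mtoc_p2plus")],
      crlis1_rz = rz[is_lis1, c("mtoc_p0", "mtoc_p1", "mtoc_p2plus")],
      k = k_mtoc)
    mtoc <- cbind(gene = genes, mtoc)
  } else {
    mtoc <- data.frame(gene = genes, category = "normal",
                       p1_decreased = FALSE, stronger_than_lis1 = FALSE)
  }

  # phenotypic fingerprints over scorable (non-excluded) genes
  fp <- build_fingerprints(rz[lib, , drop = FALSE])
  scorable <- setdiff(genes[!exclusions$excluded], character(0))
  fp <- fp[rownames(fp) %in% scorable, , drop = FALSE]
  crlis1_prof <- as.matrix(rz[is_lis1, colnames(fp), drop = FALSE])
  red <- reduce_features(fp, crlis1_prof)
  fp_red <- fp[, red$retained, drop = FALSE]
  ch <- hierarchical_cluster(fp_red, k = min(n_clusters, nrow(fp_red)))
  km <- kmeans_cargo_clusters(
    as.matrix(gene_scores[match(rownames(fp_red), gene_scores$gene),
                          c("pex", "eea1", "tgn46")]),
    K = min(kmeans_k, nrow(fp_red)), seed = seed)
  names(km$labels) <- rownames(fp_red)

  structure(list(
    profiles = profiles, rz = rz, control_stats = norm$control_stats,
    gene_scores = gene_scores, exclusions = exclusions, hits = hits,
    mtoc = mtoc, fingerprints = fp_red, reduction = red,
    clusters_hier = ch, clusters_kmeans = km,
    params = list(k_cargo = k_cargo, k_lethal = k_lethal, k_area = k_area,
                  k_roundness = k_roundness, k_mtoc = k_mtoc, seed = seed)
  ), class = "screen_analysis")
}

#' Validate a per-cell feature table
#'
#' Checks the column dictionary and the spot-count conservation invariant
#' (region counts sum to the channel total).
#'
#' @param cells Cell table.
#' @return Invisibly, a character vector of errors (empty when valid).
#' @export
validate_cell_table <- function(cells) {
  errs <- character()
  need <- c("plate_id", "row", "col", "role", "nucleus_area",
            "nucleus_roundness", "hoechst_int")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    errs <- c(errs, paste0("missing columns: ", paste(miss, collapse = ", ")))
  for (ch in CHANNELS) {
    cols <- paste0(ch, c("_total", "_perinuclear", "_intermediate", "_outer",
                         "_oor"))
    if (all(cols %in% names(cells))) {
      tot <- cells[[cols[1]]]
      s <- cells[[cols[2]]] + cells[[cols[3]]] + cells[[cols[4]]] +
        cells[[cols[5]]]
      if (any(tot != s))
        errs <- c(errs, paste0(ch, ": region counts do not sum to total"))
      if (any(tot < 0)) errs <- c(errs, paste0(ch, ": negative counts"))
    }
  }
  invisible(errs)
}

#' Build a pipeline run configuration
#'
#' @param mode `"simulate"`, `"analyze"` or `"full"`.
#' @param out_dir Output directory for the run.
#' @param seed Global seed (mandatory; fanned out per stage and per well).
#' @param n_plates,control_design,library_genes Layout parameters.
#' @param effects Planted-effect data.frame (as from [effect_spec()] rows).
#' @param sim Named list of [sim_config()] overrides.
#' @param analysis Named list of [analyze_screen()] overrides.
#' @param cells_csv For `mode = "analyze"`: path to an existing cell table.
#' @param layout_csv For `mode = "analyze"`: path to its layout.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(mode = "full", out_dir = tempfile("screen_run_"),
                       seed = NULL, n_plates = 1,
                       control_design = c(NTC = 38, POS_LIS1 = 13,
                                          EDIT_PLK1 = 13),
                       library_genes = paste0("gene_", sprintf("%03d", 1:80)),
                       effects = NULL, sim = list(), analysis = list(),
                       cells_csv = NULL, layout_csv = NULL) {
  if (!mode %in% c("simulate", "analyze", "full"))
    stop("config error at 'mode': must be simulate, analyze or full")
  if (mode %in% c("simulate", "full") && is.null(seed))
    stop("config error at 'seed': a seed is mandatory for mode '", mode, "'")
  if (mode == "analyze" && (is.null(cells_csv) || is.null(layout_csv)))
    stop("config error at 'cells_csv'/'layout_csv': required for mode 'analyze'")
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$control_design)) y$control_design <- unlist(y$control_design)
  if (!is.null(y$library_genes)) y$library_genes <- as.character(y$library_genes)
  if (!is.null(y$effects)) y$effects <- as.data.frame(y$effects)
  do.call(run_config, y)
}

#' Run the screen pipeline
#'
#' Executes the configured stages in order and writes per-stage CSV outputs
#' plus a provenance manifest (package version, seed, parameters, input and
#' output content hashes) to the run directory. Outputs are deterministic:
#' two runs with the same configuration and seed produce byte-identical
#' tables.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return Invisibly, the output directory. Side effects: `layout.csv`,
#'   `cells.csv`, `truth.csv` (simulate), `well_profiles.csv`,
#'   `gene_scores.csv`, `hit_table.csv`, `mtoc_categories.csv`,
#'   `cluster_assignments.csv`, `fingerprints.csv`, `dendrogram.newick`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  inputs <- character(0)

  if (config$mode %in% c("simulate", "full")) {
    layout <- generate_plate_layout(config$n_plates, config$control_design,
                                    config$library_genes, seed = config$seed)
    truth <- ground_truth(unique(layout$gene[layout$role == "LIBRARY"]),
                          config$effects)
    sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
    cfg <- do.call(sim_config, sim_args)
    screen <- simulate_screen(layout, truth, cfg)
    utils::write.csv(layout, out("layout.csv"), row.names = FALSE)
    utils::write.csv(truth, out("truth.csv"), row.names = FALSE)
    utils::write.csv(screen$cells, out("cells.csv"), row.names = FALSE)
  } else {
    layout <- utils::read.csv(config$layout_csv, stringsAsFactors = FALSE)
    cells <- utils::read.csv(config$cells_csv, stringsAsFactors = FALSE)
    errs <- c(validate_plate_layout(layout), validate_cell_table(cells))
    if (length(errs)) stop("invalid inputs: ", paste(errs, collapse = "; "))
    screen <- list(cells = cells, layout = layout)
    inputs <- c(config$layout_csv, config$cells_csv)
  }

  if (config$mode %in% c("analyze", "full")) {
    an_args <- utils::modifyList(list(screen = screen,
                                      seed = config$seed %||% 1),
                                 config$analysis)
    res <- do.call(analyze_screen, an_args)
    utils::write.csv(res$profiles, out("well_profiles.csv"), row.names = FALSE)
    utils::write.csv(res$gene_scores, out("gene_scores.csv"), row.names = FALSE)
    hit_tab <- merge(res$hits, res$exclusions[, c("gene", "rule")], by = "gene")
    utils::write.csv(hit_tab, out("hit_table.csv"), row.names = FALSE)
    utils::write.csv(res$mtoc, out("mtoc_categories.csv"), row.names = FALSE)
    cl <- rbind(
      data.frame(gene = names(res$clusters_hier$labels), method = "hierarchical",
                 label = as.integer(res$clusters_hier$labels)),
      data.frame(gene = names(res$clusters_kmeans$labels), method = "kmeans",
                 label = as.integer(res$clusters_kmeans$labels))
    )
    utils::write.csv(cl, out("cluster_assignments.csv"), row.names = FALSE)
    utils::write.csv(data.frame(gene = rownames(res$fingerprints),
                                res$fingerprints, check.names = FALSE),
                     out("fingerprints.csv"), row.names = FALSE)
    if (!is.null(res$clusters_hier$tree))
      write_dendrogram(res$clusters_hier, out("dendrogram.newick"))
  }

  files <- list.files(config$out_dir, pattern = "\\.(csv|newick)$",
                      full.names = TRUE)
  manifest <- list(
    package = "cargoscreen",
    version = as.character(utils::packageVersion("cargoscreen")),
    mode = config$mode, seed = config$seed,
    parameters = list(n_plates = config$n_plates,
                      control_design = as.list(config$control_design),
                      sim = config$sim, analysis = config$analysis),
    input_hashes = as.list(tools::md5sum(inputs)),
    output_hashes = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
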