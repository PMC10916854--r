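WELL_FEATURES <- c("nucleus_area", "nucleus_roundness", "hoechst_int",
                   "micronucleus_rate", "mtoc_p0", "mtoc_p1", "mtoc_p2plus",
                   "gfp_total", "rfp_total", "eea1_total", "tgn46_total",
                   "gfp_locratio", "rfp_locratio", "eea1_locratio",
                   "tgn46_locratio", "pex_locratio")

#' Aggregate per-cell records to well-level profiles
#'
#' Applies the viability gate (calibrated from the screen's own NTC cells
#' when no calibration is supplied) and, for the reporter channels, the
#' GFP/RFP positivity gate, then averages per-cell features within each well.
#' Cargo localization is summarized as the mean per-cell log localization
#' ratio: perinuclear versus intermediate-plus-outer counts for GFP, RFP and
#' TGN46, and the two-zone inner versus peripheral counts for EEA1;
#' `pex_locratio` averages the GFP and RFP ratios. Wells with no viable cell
#' are emitted as NaN profiles with `excluded = TRUE`; wells below
#' `min_cells` viable cells are flagged `low_count` (they are still scored
#' but are left out of control statistics downstream).
#'
#' @param cells Cell table (rows from [sample_cell_population()] or the image
#'   quantification path).
#' @param calibration Optional [viability_calibration()].
#' @param min_cells Low-count flag threshold (viable cells per well).
#' @return data.frame, one row per well: keys, `n_cells`, `n_viable`,
#'   `n_reporter_pos`, the feature columns, `low_count`, `excluded`.
#' @export
aggregate_wells <- function(cells, calibration = NULL, min_cells = 50) {
  if (is.null(calibration)) {
    calibration <- viability_calibration(cells[cells$role == "NTC", ])
  }
  viable <- gate_viable(cells, calibration)
  rep_pos <- gate_reporter_positive(cells, cells[cells$role == "NTC" & viable, ])
  key <- interaction(cells$plate_id, cells$row, cells$col, drop = TRUE)
  wells <- split(seq_len(nrow(cells)), key)
  rows <- lapply(wells, function(ix) {
    v <- ix[viable[ix]]
    keys <- intersect(c("plate_id", "row", "col", "role", "gene", "crrna_pool"),
                      names(cells))
    w1 <- cells[ix[1], keys, drop = FALSE]
    if (!("crrna_pool" %in% keys)) w1$crrna_pool <- NA_character_
    prof <- setNames(rep(NaN, length(WELL_FEATURES)), WELL_FEATURES)
    if (length(v)) {
      cv <- cells[v, ]
      rp <- rep_pos[v]
      prof["nucleus_area"] <- mean(cv$nucleus_area)
      prof["nucleus_roundness"] <- mean(cv$nucleus_roundness)
      prof["hoechst_int"] <- mean(cv$hoechst_int)
      prof["micronucleus_rate"] <- mean(cv$micronucleus_count)
      prof["mtoc_p0"] <- mean(cv$mtoc_count == 0)
      prof["mtoc_p1"] <- mean(cv$mtoc_count == 1)
      prof["mtoc_p2plus"] <- mean(cv$mtoc_count > 1)
      for (ch in c("gfp", "rfp")) {
        sel <- if (any(rp)) cv[rp, , drop = FALSE] else cv
        prof[paste0(ch, "_total")] <- mean(sel[[paste0(ch, "_total")]])
        prof[paste0(ch, "_locratio")] <- mean(localization_ratio(
          sel[[paste0(ch, "_perinuclear")]],
          sel[[paste0(ch, "_intermediate")]] + sel[[paste0(ch, "_outer")]],
          log = TRUE))
      }
      prof["tgn46_total"] <- mean(cv$tgn46_total)
      prof["tgn46_locratio"] <- mean(localization_ratio(
        cv$tgn46_perinuclear, cv$tgn46_intermediate + cv$tgn46_outer,
        log = TRUE))
      prof["eea1_total"] <- mean(cv$eea1_total)
      prof["eea1_locratio"] <- mean(localization_ratio(
        cv$eea1_inner, cv$eea1_peripheral, log = TRUE))
      prof["pex_locratio"] <- mean(c(prof["gfp_locratio"], prof["rfp_locratio"]))
    }
    cbind(w1,
          data.frame(n_cells = length(ix), n_viable = length(v),
                     n_reporter_pos = sum(rep_pos[ix] & viable[ix])),
          as.data.frame(as.list(prof)),
          data.frame(low_count = length(v) < min_cells,
                     excluded = length(v) == 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$plate_id, out$row, out$col), ]
}

#' Robust Z-score against the plate's NTC reference
#'
#' `rZ = (x - median_NTC) / (1.4826 * MAD_NTC)`, the robust analogue of a
#' Z-score, with the 1.4826 normal-consistency constant so that rZ is on a
#' standard-deviation scale for Gaussian data. Normalization is per plate and
#' per feature.
#'
#' @param x Well value(s).
#' @param ntc_values NTC reference values for the same plate and feature, or
#'   a list with `median` and `mad` (raw, unscaled MAD).
#' @param feature,plate Optional names used in the error message when the
#'   reference MAD is zero.
#' @return rZ value(s).
#' @export
rz_normalize <- function(x, ntc_values, feature = "feature", plate = "plate") {
  if (is.list(ntc_values)) {
    med <- ntc_values$median; md <- ntc_values$mad
  } else {
    med <- stats::median(ntc_values, na.rm = TRUE)
    md <- stats::mad(ntc_values, constant = 1, na.rm = TRUE)
  }
  if (!is.finite(md) || md == 0)
    stop("NTC MAD is zero for ", feature, " on ", plate,
         "; rZ is undefined")
  (x - med) / (1.4826 * md)
}

#' Two-point normalization between the NTC and a positive control
#'
#' Linearly rescales a raw well value so the NTC median maps to 0 and the
#' positive-control median maps to `pos_target` (-100 for the crLIS1-anchored
#' cargo endpoints, +100 for the crPLK1-anchored lethality endpoint).
#'
#' @param x Well value(s).
#' @param med_ntc,med_pos Plate medians of the NTC and positive control.
#' @param pos_target Signed value the positive-control median maps to.
#' @return Scaled score(s).
#' @export
two_point_normalize <- function(x, med_ntc, med_pos, pos_target = -100) {
  if (med_pos == med_ntc)
    stop("control medians are equal; no assay window for two-point normalization")
  pos_target * (x - med_ntc) / (med_pos - med_ntc)
}

#' Robust Z-prime assay window
#'
#' `rZ' = 1 - 3 * (1.4826*MAD_pos + 1.4826*MAD_neg) / |median_pos -
#' median_neg|`: the robust (median/MAD) analogue of the Z'-factor. 1 is a
#' perfect window; values above ~0.1 per feature qualify a feature for the
#' composite endpoints.
#'
#' @param pos_values,neg_values Control well values (>= 3 each).
#' @return rZ' (scalar). Equal medians return `-Inf` with a warning.
#' @export
robust_z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 3 || length(neg_values) < 3)
    stop("robust_z_prime needs >= 3 values per control group")
  mp <- stats::median(pos_values); mn <- stats::median(neg_values)
  if (mp == mn) {
    warning("control medians are equal; assay window undefined")
    return(-Inf)
  }
  sp <- 1.4826 * stats::mad(pos_values, constant = 1)
  sn <- 1.4826 * stats::mad(neg_values, constant = 1)
  1 - 3 * (sp + sn) / abs(mp - mn)
}

#' Median aggregation of well scores per crRNA pool
#'
#' @param scores Numeric well scores.
#' @param pool crRNA pool (or gene) identifier per score.
#' @return Named numeric vector of pool medians.
#' @export
aggregate_crRNA <- function(scores, pool) {
  if (!length(scores)) stop("no well scores to aggregate")
  vapply(split(scores, pool), stats::median, numeric(1), na.rm = TRUE)
}

#' Replicate concordance of per-crRNA endpoint scores
#'
#' Coefficient of determination of the least-squares fit between two
#' independent replicate runs, computed on matched crRNA identifiers.
#' Endpoints with R-squared below `min_r2` are flagged unusable for hit
#' calling.
#'
#' @param rep1,rep2 Named numeric vectors of per-crRNA scores.
#' @param min_r2 Usability threshold.
#' @return List: `r_squared`, `n`, `usable`.
#' @export
replicate_concordance <- function(rep1, rep2, min_r2 = 0.2) {
  ids <- intersect(names(rep1), names(rep2))
  if (length(ids) < 3) stop("need >= 3 matched crRNA pairs; got ", length(ids))
  # for a simple least-squares fit, R^2 is the squared Pearson correlation
  r2 <- stats::cor(rep1[ids], rep2[ids])^2
  list(r_squared = r2, n = length(ids), usable = r2 >= min_r2)
}
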