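#' Fit a linear-discriminant composite endpoint
#'
#' Builds a single screening readout from several individual features, the
#' way morphology endpoints are built when no single feature separates the
#' phenotype: candidate features are first filtered to those with an
#' individual robust Z-prime of at least `rz_prime_min` between the two
#' control classes, then a two-class Fisher discriminant is fitted,
#' `w proportional to Sw^-1 (mu_pos - mu_neg)` with a ridge term
#' `eps = 1e-6 * trace(Sw) / p` on the pooled within-class scatter for
#' invertibility. The projection is affinely rescaled so the NTC median maps
#' to 0 and the positive-control median to `pos_target` (the two-point
#' convention). A single surviving feature passes through with weight 1
#' before rescaling.
#'
#' @param x Numeric matrix or data.frame of well profiles (rows = wells).
#' @param labels Factor/character per row: `"NTC"` or `"positive"` (other
#'   rows are ignored for training).
#' @param candidate_features Column names to consider.
#' @param rz_prime_min Per-feature rZ' required to enter the discriminant.
#' @param pos_target Value the positive-control median maps to.
#' @param name Endpoint name.
#' @return Object of class `composite_endpoint`: `features`, `weights`,
#'   `offset`, `scale`, and `training` metadata (per-feature rZ', class
#'   sizes).
#' @export
fit_lda_endpoint <- function(x, labels, candidate_features,
                             rz_prime_min = 0.1, pos_target = -100,
                             name = "composite") {
  x <- as.data.frame(x)
  stopifnot(all(candidate_features %in% names(x)))
  is_ntc <- labels == "NTC"
  is_pos <- labels == "positive"
  if (sum(is_ntc) < 3 || sum(is_pos) < 3)
    stop("need >= 3 wells per training class")
  rzp <- vapply(candidate_features, function(f)
    robust_z_prime(x[[f]][is_pos], x[[f]][is_ntc]), numeric(1))
  keep <- candidate_features[rzp >= rz_prime_min]
  if (!length(keep))
    stop("no candidate feature reaches rZ' >= ", rz_prime_min,
         "; composite endpoint unbuildable")
  xm <- as.matrix(x[, keep, drop = FALSE])
  if (length(keep) == 1) {
    w <- 1
  } else {
    mu_p <- colMeans(xm[is_pos, , drop = FALSE])
    mu_n <- colMeans(xm[is_ntc, , drop = FALSE])
    sw <- stats::cov(xm[is_pos, , drop = FALSE]) * (sum(is_pos) - 1) +
      stats::cov(xm[is_ntc, , drop = FALSE]) * (sum(is_ntc) - 1)
    eps <- 1e-6 * sum(diag(sw)) / ncol(sw)
    w <- solve(sw + diag(eps, ncol(sw)), mu_p - mu_n)
  }
  z <- drop(xm %*% w)
  z_ntc <- stats::median(z[is_ntc]); z_pos <- stats::median(z[is_pos])
  if (z_pos == z_ntc) stop("degenerate projection: control medians coincide")
  scale <- pos_target / (z_pos - z_ntc)
  structure(list(
    name = name, features = keep, weights = setNames(as.numeric(w), keep),
    offset = -z_ntc * scale, scale = scale, pos_target = pos_target,
    training = list(rz_prime = rzp, n_ntc = sum(is_ntc), n_pos = sum(is_pos))
  ), class = "composite_endpoint")
}

#' Apply a composite endpoint to well profiles
#'
#' @param endpoint A [fit_lda_endpoint()] result.
#' @param x data.frame/matrix containing the endpoint's feature columns.
#' @return Numeric score per row (NTC median 0, positive median
#'   `pos_target` on the training data).
#' @export
apply_endpoint <- function(endpoint, x) {
  x <- as.data.frame(x)
  xm <- as.matrix(x[, endpoint$features, drop = FALSE])
  drop(xm %*% endpoint$weights) * endpoint$scale + endpoint$offset
}

#' Per-plate rZ normalization of well-profile features
#'
#' Computes plate-local NTC median/MAD control statistics for each feature
#' and returns the profiles with features replaced by their rZ scores.
#' Low-count and excluded wells contribute nothing to the control statistics
#' but are still scored.
#'
#' @param profiles Well profiles from [aggregate_wells()].
#' @param features Feature columns to normalize (default: all well features
#'   present).
#' @param on_zero_mad `"error"` propagates the [rz_normalize()] error when a
#'   plate's NTC MAD is zero for a feature; `"drop"` removes such features
#'   from the normalized set (recorded in `dropped_features`), which is the
#'   practical choice for sparse readouts like per-cell micronucleus rates
#'   at low cell counts.
#' @return List: `rz` (profiles with rZ-scaled features), `control_stats`
#'   (per plate x feature median/MAD of NTC wells), `dropped_features`.
#' @export
normalize_profiles <- function(profiles,
                               features = intersect(WELL_FEATURES,
                                                    names(profiles)),
                               on_zero_mad = c("error", "drop")) {
  on_zero_mad <- match.arg(on_zero_mad)
  out <- profiles
  stats_rows <- list()
  plates <- unique(profiles$plate_id)
  refs <- lapply(plates, function(p)
    profiles$plate_id == p & profiles$role == "NTC" & !profiles$low_count &
      !profiles$excluded)
  names(refs) <- plates
  for (p in plates) {
    if (sum(refs[[p]]) < 3) stop("plate ", p, " has fewer than 3 usable NTC wells")
  }
  dropped <- character(0)
  if (on_zero_mad == "drop") {
    for (f in features) {
      mads <- vapply(plates, function(p)
        stats::mad(profiles[[f]][refs[[p]]], constant = 1, na.rm = TRUE),
        numeric(1))
      if (any(!is.finite(mads) | mads == 0)) {
        dropped <- c(dropped, f)
        cs_log("feature %s dropped from normalization (zero NTC MAD)", f)
      }
    }
    features <- setdiff(features, dropped)
  }
  for (p in plates) {
    on_plate <- profiles$plate_id == p
    ref <- refs[[p]]
    for (f in features) {
      med <- stats::median(profiles[[f]][ref], na.rm = TRUE)
      md <- stats::mad(profiles[[f]][ref], constant = 1, na.rm = TRUE)
      out[[f]][on_plate] <- rz_normalize(profiles[[f]][on_plate],
                                         list(median = med, mad = md),
                                         feature = f, plate = p)
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(plate_id = p, feature = f, median = med, mad = md)
    }
  }
  out[dropped] <- NULL
  list(rz = out, control_stats = do.call(rbind, stats_rows),
       dropped_features = dropped)
}
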