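#' Calibrate the viability gate from NTC cells
#'
#' The viability gate removes cells with apoptotic or mitotic features or
#' abnormal nuclear morphology. It is calibrated per batch from the
#' non-targeting-control cell population as a quantile envelope on nuclear
#' area, nuclear roundness and integrated Hoechst intensity: cells falling
#' outside the envelope on any gated feature are flagged non-viable.
#'
#' @param ntc_cells data.frame of NTC cells with columns `nucleus_area`,
#'   `nucleus_roundness`, `hoechst_int`.
#' @param lower,upper Envelope quantiles (defaults 0.5% and 99.5%).
#' @return Object of class `viability_calibration`: per-feature lower/upper
#'   bounds plus the parameters used (recorded for provenance).
#' @export
viability_calibration <- function(ntc_cells, lower = 0.005, upper = 0.995) {
  feats <- c("nucleus_area", "nucleus_roundness", "hoechst_int")
  stopifnot(all(feats %in% names(ntc_cells)))
  if (nrow(ntc_cells) < 50)
    stop("viability calibration needs >= 50 NTC cells; got ", nrow(ntc_cells))
  env <- lapply(feats, function(f)
    stats::quantile(ntc_cells[[f]], c(lower, upper), na.rm = TRUE, names = FALSE))
  names(env) <- feats
  structure(list(envelope = env, lower = lower, upper = upper,
                 n_reference = nrow(ntc_cells)),
            class = "viability_calibration")
}

#' Gate cells on nuclear-morphology viability
#'
#' @param cells data.frame with the gated feature columns.
#' @param calibration A [viability_calibration()].
#' @return Logical vector: TRUE for cells inside the envelope on every gated
#'   feature.
#' @export
gate_viable <- function(cells, calibration) {
  stopifnot(inherits(calibration, "viability_calibration"))
  ok <- rep(TRUE, nrow(cells))
  for (f in names(calibration$envelope)) {
    b <- calibration$envelope[[f]]
    ok <- ok & cells[[f]] >= b[1] & cells[[f]] <= b[2]
  }
  ok
}

# 1-D two-class threshold by Otsu's criterion on a histogram of log intensity;
# returns NA when the distribution shows no separable negative mode
bimodal_threshold <- function(x, nbins = 64) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 20) return(NA_real_)
  lx <- log(x)
  h <- hist(lx, breaks = nbins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  thr <- exp(mids[k])
  # require genuinely bimodal structure: both sides populated
  f_lo <- mean(x <= thr)
  if (f_lo < 0.02 || f_lo > 0.98) return(NA_real_)
  exp(mids[k])
}

#' Gate cells on GFP/RFP reporter positivity
#'
#' Cells enter the peroxisome-relocalization analysis only when positive for
#' both the GFP-BICD2N-FRB and PTS-RFP-FKBP reporters. Thresholds are
#' calibrated from the bimodal intensity distributions of NTC wells; when a
#' channel shows no separable negative population the configured absolute
#' fallback threshold is used instead (logged).
#'
#' @param cells data.frame with `gfp_int` and `rfp_int` columns.
#' @param ntc_cells NTC reference cells used for calibration; defaults to
#'   `cells`.
#' @param fallback Named numeric fallback thresholds `c(gfp=, rfp=)`.
#' @return Logical vector: TRUE when both intensities exceed their
#'   thresholds. The thresholds used are attached as attribute
#'   `"thresholds"`.
#' @export
gate_reporter_positive <- function(cells, ntc_cells = cells,
                                   fallback = c(gfp = 100, rfp = 80)) {
  thr <- c(gfp = bimodal_threshold(ntc_cells$gfp_int),
           rfp = bimodal_threshold(ntc_cells$rfp_int))
  for (ch in names(thr)) {
    if (is.na(thr[[ch]])) {
      cs_log("no separable negative population for %s; using fallback threshold", ch)
      thr[[ch]] <- fallback[[ch]]
    }
  }
  flag <- cells$gfp_int > thr[["gfp"]] & cells$rfp_int > thr[["rfp"]]
  attr(flag, "thresholds") <- thr
  flag
}
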