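#' Define an SD-threshold hit-calling rule
#'
#' Hits are wells/genes whose endpoint score exceeds `k` standard deviations
#' of a reference control group. Thresholds are closed (a score exactly at
#' the boundary is a hit) and each rule states the scale its scores live on
#' (`raw`, `rz`, or `two_point`) so calls are auditable.
#'
#' @param endpoint Endpoint name.
#' @param reference `"NTC"`, `"crLIS1"` or `"both"` (pooled controls).
#' @param k Positive SD multiplier (figure-legend defaults: 2 for
#'   spot-number endpoints, 3 for EEA1 endpoints in the primary screen, 2.5
#'   in the secondary screen).
#' @param side `"two_sided"`, `"low_only"` or `"high_only"`.
#' @param scale Data scale annotation.
#' @return Object of class `threshold_rule`.
#' @export
threshold_rule <- function(endpoint, reference = c("NTC", "crLIS1", "both"),
                           k = 2.5,
                           side = c("two_sided", "low_only", "high_only"),
                           scale = c("rz", "raw", "two_point")) {
  stopifnot(k > 0)
  structure(list(endpoint = endpoint, reference = match.arg(reference),
                 k = k, side = match.arg(side), scale = match.arg(scale)),
            class = "threshold_rule")
}

# closed-threshold exceedance of k SDs around the reference mean
sd_exceeds <- function(scores, ref_values, k, side) {
  if (length(ref_values) < 3) stop("reference group has fewer than 3 wells")
  ctr <- mean(ref_values)
  s <- stats::sd(ref_values)
  if (!is.finite(s) || s == 0) stop("reference SD is zero; threshold undefined")
  hi <- scores >= ctr + k * s
  lo <- scores <= ctr - k * s
  out <- switch(side, two_sided = hi | lo, low_only = lo, high_only = hi)
  attr(out, "rule_audit") <- list(center = ctr, sd = s, k = k, side = side)
  out
}

#' Call cargo-localization hits against an SD envelope
#'
#' Applies a [threshold_rule()] to per-gene endpoint scores; both the
#' dispersion (negative) and hyperclustering (positive) directions are
#' retained under the default two-sided rule, since crRNA pools causing
#' excessive perinuclear clustering are genuine phenotypes.
#'
#' @param scores Named numeric vector of per-gene scores on the rule's scale.
#' @param ref_values Scores of the rule's reference wells on the same scale.
#' @param rule A [threshold_rule()].
#' @return Named logical vector; attribute `"rule_audit"` records the
#'   reference center, SD and k used.
#' @export
call_cargo_hits <- function(scores, ref_values, rule = threshold_rule("cargo")) {
  sd_exceeds(scores, ref_values, rule$k, rule$side)
}

#' Call lethal crRNAs on the viability scale
#'
#' Viability is two-point normalized (NTC median 0, editing-control crPLK1
#' median 100, higher = more cell loss); genes exceeding the crLIS1-referenced
#' `k`-SD bound on the high side are lethal.
#'
#' @param scores Named per-gene viability scores (two-point scale).
#' @param crlis1_values crLIS1 control well scores on the same scale.
#' @param k SD multiplier.
#' @return Named logical vector with `"rule_audit"` attribute.
#' @export
call_lethal <- function(scores, crlis1_values, k = 2.5) {
  sd_exceeds(scores, crlis1_values, k, "high_only")
}

#' Call micronucleus-phenotype hits
#'
#' High-side exceedance of the crLIS1-referenced `k`-SD envelope on the
#' micronucleus endpoint.
#'
#' @inheritParams call_lethal
#' @export
call_micronucleus_hits <- function(scores, crlis1_values, k = 2.5) {
  sd_exceeds(scores, crlis1_values, k, "high_only")
}

#' Exclude genes with confounding viability / nuclear-morphology phenotypes
#'
#' Genes with strong effects on cell viability or nuclear morphology are
#' excluded from cargo hit calling because they may affect cargo
#' localization indirectly. The nuclear-morphology envelopes are computed
#' from the pooled NTC and crLIS1 control wells: outside +/- `k_area` SD on
#' nuclear area, or below `-k_roundness` SD on nuclear roundness; the
#' lethality rule is [call_lethal()].
#'
#' @param gene_scores data.frame with columns `gene`, `area`, `roundness`
#'   (rZ scale) and `viability` (two-point scale).
#' @param ctrl_area,ctrl_roundness Pooled NTC + crLIS1 control well values on
#'   the same scales.
#' @param crlis1_viability crLIS1 viability scores (two-point scale).
#' @param k_area,k_roundness,k_lethal SD multipliers.
#' @return data.frame: `gene`, per-rule flags (`excl_area`,
#'   `excl_roundness`, `excl_lethal`), `excluded`, and `rule` naming the
#'   triggering rule(s).
#' @export
exclude_confounded <- function(gene_scores, ctrl_area, ctrl_roundness,
                               crlis1_viability,
                               k_area = 4, k_roundness = 3.5, k_lethal = 2.5) {
  stopifnot(all(c("gene", "area", "roundness", "viability") %in%
                  names(gene_scores)))
  a <- sd_exceeds(gene_scores$area, ctrl_area, k_area, "two_sided")
  r <- sd_exceeds(gene_scores$roundness, ctrl_roundness, k_roundness, "low_only")
  l <- call_lethal(gene_scores$viability, crlis1_viability, k_lethal)
  rule <- apply(cbind(area = a, roundness = r, lethal = l), 1, function(z)
    paste(names(z)[z], collapse = "+"))
  data.frame(gene = gene_scores$gene,
             excl_area = as.logical(a), excl_roundness = as.logical(r),
             excl_lethal = as.logical(l),
             excluded = a | r | l, rule = rule,
             stringsAsFactors = FALSE)
}

#' Categorize MTOC phenotypes from gamma-tubulin punctum proportions
#'
#' Genes whose rZ-normalized proportion of cells with exactly one punctum
#' falls below the NTC-referenced `-k` SD cut are split by which abnormal
#' class rises: an increased proportion of cells with more than one punctum
#' (above `+k` SD) is `mtoc_gain`, an increased proportion with no punctum
#' is `mtoc_loss`. An auxiliary flag marks genes whose one-punctum loss is
#' stronger than the crLIS1 reference envelope.
#'
#' @param prop_raw data.frame/matrix of raw per-gene proportions (columns
#'   p0, p1, p2plus); must sum to 1 within 1e-6 per gene.
#' @param prop_rz Matching rZ-normalized proportions.
#' @param ntc_rz rZ proportions of NTC reference wells (3 columns).
#' @param crlis1_rz rZ proportions of crLIS1 wells (for the auxiliary flag);
#'   NULL skips the flag.
#' @param k SD multiplier.
#' @return data.frame: `category` in {normal, mtoc_loss, mtoc_gain},
#'   `p1_decreased`, `stronger_than_lis1`.
#' @export
categorize_mtoc <- function(prop_raw, prop_rz, ntc_rz, crlis1_rz = NULL,
                            k = 2.5) {
  prop_raw <- as.matrix(prop_raw); prop_rz <- as.matrix(prop_rz)
  ntc_rz <- as.matrix(ntc_rz)
  if (any(abs(rowSums(prop_raw) - 1) > 1e-6))
    stop("MTOC punctum proportions must sum to 1 per gene")
  dec1 <- as.logical(sd_exceeds(prop_rz[, 2], ntc_rz[, 2], k, "low_only"))
  up2 <- as.logical(sd_exceeds(prop_rz[, 3], ntc_rz[, 3], k, "high_only"))
  up0 <- as.logical(sd_exceeds(prop_rz[, 1], ntc_rz[, 1], k, "high_only"))
  cat <- rep("normal", nrow(prop_rz))
  cat[dec1 & up2] <- "mtoc_gain"
  cat[dec1 & up0 & !up2] <- "mtoc_loss"
  strong <- rep(FALSE, nrow(prop_rz))
  if (!is.null(crlis1_rz)) {
    crlis1_rz <- as.matrix(crlis1_rz)
    strong <- as.logical(sd_exceeds(prop_rz[, 2], crlis1_rz[, 2], k, "low_only"))
  }
  data.frame(category = cat, p1_decreased = dec1,
             stronger_than_lis1 = strong, stringsAsFactors = FALSE)
}

#' Confirmation-rate percentage
#'
#' `100 * n_confirmed / n_total`, rounded half-up to the requested decimals —
#' the convention used when reporting validation rates (e.g. 19 of 22 hits
#' confirmed is 86.4%).
#'
#' @param n_confirmed,n_total Counts, `0 <= n_confirmed <= n_total`,
#'   `n_total > 0`.
#' @param decimals Decimal places.
#' @return Percentage.
#' @export
summarize_confirmation <- function(n_confirmed, n_total, decimals = 1) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_confirmed < 0 | n_confirmed > n_total))
    stop("n_confirmed must lie in [0, n_total]")
  round_half_up(100 * n_confirmed / n_total, decimals)
}
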