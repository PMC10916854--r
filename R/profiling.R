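#' Build per-crRNA phenotypic fingerprints
#'
#' A fingerprint is the vector of median rZ feature values over all wells of
#' one crRNA pool (gene). All fingerprints share one feature registry (the
#' column order), which downstream reduction and clustering rely on.
#'
#' @param rz_profiles rZ-normalized well profiles (from
#'   [normalize_profiles()]).
#' @param features Feature registry (character, in order).
#' @param by Column naming the grouping unit (default `"gene"`; control wells
#'   with empty gene ids are dropped unless grouped by `"crrna_pool"`).
#' @return Numeric matrix, rows = genes (sorted lexicographically), columns
#'   = feature registry.
#' @export
build_fingerprints <- function(rz_profiles,
                               features = intersect(WELL_FEATURES,
                                                    names(rz_profiles)),
                               by = "gene") {
  keep <- nzchar(rz_profiles[[by]]) & !is.na(rz_profiles[[by]])
  df <- rz_profiles[keep, , drop = FALSE]
  ids <- sort(unique(df[[by]]))
  fp <- matrix(NA_real_, length(ids), length(features),
               dimnames = list(ids, features))
  for (i in seq_along(ids)) {
    sub <- df[df[[by]] == ids[i], features, drop = FALSE]
    fp[i, ] <- vapply(sub, stats::median, numeric(1), na.rm = TRUE)
  }
  fp[is.na(fp)] <- 0  # impute features unavailable for a gene
  fp
}

#' Reduce the fingerprint feature registry
#'
#' Two-step reduction mirroring standard morphological-profiling practice:
#' (1) drop features that are highly variable among replicate positive
#' control (crLIS1) profiles scattered across plates (SD at or above
#' `sd_cut` on the rZ scale) since their variation is technical, then
#' (2) drop redundant features by a greedy scan in registry order, removing
#' any feature whose squared Pearson correlation with an already-retained
#' feature is at or above `r2_cut` (first kept wins). The scan order and the
#' reason for each drop are recorded.
#'
#' @param fingerprints Gene x feature matrix (rZ scale).
#' @param crlis1_profiles Matrix of crLIS1 replicate profiles (rows =
#'   replicate wells/plates, columns = same registry), >= 3 rows.
#' @param sd_cut Variability cut on crLIS1 replicate SD.
#' @param r2_cut Squared-correlation redundancy cut.
#' @return List: `retained` (character registry), `dropped` (data.frame
#'   feature/reason/detail).
#' @export
reduce_features <- function(fingerprints, crlis1_profiles, sd_cut = 3,
                            r2_cut = 0.8) {
  feats <- colnames(fingerprints)
  stopifnot(!is.null(feats), identical(feats, colnames(crlis1_profiles)))
  if (nrow(crlis1_profiles) < 3)
    stop("need >= 3 crLIS1 replicate profiles")
  dropped <- list()
  sds <- apply(crlis1_profiles, 2, stats::sd)
  var_drop <- feats[sds >= sd_cut]
  for (f in var_drop)
    dropped[[f]] <- data.frame(feature = f, reason = "variable",
                               detail = sprintf("crLIS1 SD=%.3f", sds[[f]]))
  surviving <- setdiff(feats, var_drop)
  retained <- character(0)
  for (f in surviving) {
    if (!length(retained)) { retained <- f; next }
    r2 <- suppressWarnings(
      stats::cor(fingerprints[, f], fingerprints[, retained, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    if (any(r2 >= r2_cut)) {
      partner <- retained[which(r2 >= r2_cut)[1]]
      dropped[[f]] <- data.frame(feature = f, reason = "redundant",
                                 detail = sprintf("R2=%.3f with %s",
                                                  max(r2), partner))
    } else retained <- c(retained, f)
  }
  if (!length(retained)) stop("feature reduction dropped every feature")
  list(retained = retained,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(feature = character(0), reason = character(0),
                    detail = character(0)))
}

# per-feature min-max scaling across genes; constant features map to 0
minmax_scale <- function(x) {
  apply(x, 2, function(v) {
    r <- range(v)
    if (diff(r) < .Machine$double.eps) rep(0, length(v)) else (v - r[1]) / diff(r)
  })
}

#' Hierarchical clustering of phenotypic fingerprints
#'
#' Fingerprints are min-max scaled per feature across genes, pairwise
#' distances computed as `1 - Pearson r` (Spearman available), and the tree
#' built by complete linkage. Rows are ordered lexicographically by gene id
#' before linkage so ties break deterministically. Genes with zero-variance
#' fingerprints (correlation undefined) are flagged and attached as
#' singleton clusters rather than entering the tree.
#'
#' @param fingerprints Gene x feature matrix.
#' @param k Number of flat clusters to cut (NULL: no flat labels).
#' @param linkage Linkage method (default `"complete"`).
#' @param distance `"pearson"` or `"spearman"`.
#' @param scale Min-max scale features before distances.
#' @return List of class `cluster_result`: `method`, `labels` (named), `tree`
#'   (hclust or NULL), `flagged` (zero-variance genes), `params`.
#' @export
hierarchical_cluster <- function(fingerprints, k = NULL, linkage = "complete",
                                 distance = c("pearson", "spearman"),
                                 scale = TRUE) {
  distance <- match.arg(distance)
  x <- fingerprints[order(rownames(fingerprints)), , drop = FALSE]
  if (scale) {
    sc <- minmax_scale(x)
    rownames(sc) <- rownames(x)
    x <- sc
  }
  v <- apply(x, 1, stats::sd)
  flagged <- rownames(x)[v < .Machine$double.eps]
  ok <- setdiff(rownames(x), flagged)
  tree <- NULL
  labels <- setNames(integer(0), character(0))
  if (length(ok) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(x[ok, , drop = FALSE]),
                                       method = distance))
    tree <- stats::hclust(d, method = linkage)
    if (!is.null(k)) {
      kk <- min(k, length(ok))
      labels <- stats::cutree(tree, k = kk)
    } else labels <- setNames(rep(1L, length(ok)), ok)
  } else if (length(ok) == 1) {
    labels <- setNames(1L, ok)
  }
  if (length(flagged)) {
    extra <- setNames(seq_along(flagged) + max(labels, 0L), flagged)
    labels <- c(labels, extra)
  }
  structure(list(method = "hierarchical", labels = labels, tree = tree,
                 flagged = flagged,
                 params = list(linkage = linkage, distance = distance,
                               scale = scale, k = k)),
            class = "cluster_result")
}

#' K-means grouping of cargo-signature vectors
#'
#' Groups genes by their mean effect on the localization of the three cargo
#' classes (peroxisomes as the GFP/RFP average, early endosomes, the
#' trans-Golgi network) using Lloyd-iterated K-means with Euclidean distance
#' and multiple seeded restarts (best inertia kept). The default K of 14
#' matches the granularity at which cargo signatures separate into
#' interpretable groups.
#'
#' @param x Gene x endpoint matrix (typically 3 columns: pex, eea1, tgn46
#'   mean rZ).
#' @param K Number of clusters (>= 1).
#' @param seed Integer seed (restarts are deterministic given it).
#' @param n_init Number of restarts.
#' @return `cluster_result`: `labels` in 1..K, `centers`, `params`.
#' @export
kmeans_cargo_clusters <- function(x, K = 14, seed = 1, n_init = 10) {
  x <- as.matrix(x)
  if (K > nrow(x)) stop("K = ", K, " exceeds the number of genes (", nrow(x), ")")
  set.seed(seed)
  if (K == 1) {
    ctr <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
    return(structure(list(method = "kmeans",
                          labels = setNames(rep(1L, nrow(x)), rownames(x)),
                          centers = ctr,
                          params = list(K = 1, seed = seed, n_init = n_init)),
                     class = "cluster_result"))
  }
  km <- stats::kmeans(x, centers = K, nstart = n_init, iter.max = 100)
  structure(list(method = "kmeans",
                 labels = setNames(km$cluster, rownames(x)),
                 centers = km$centers, inertia = km$tot.withinss,
                 params = list(K = K, seed = seed, n_init = n_init)),
            class = "cluster_result")
}

#' Two-dimensional embedding of fingerprints for visualization
#'
#' Projects reduced fingerprints to 2-D for visual inspection of phenotypic
#' neighbourhoods; coordinates are used for display only, never for hit
#' calling. The default is principal-coordinates analysis of the
#' correlation-distance matrix (deterministic); `"nmds"` runs non-metric
#' multidimensional scaling on the same distances with a fixed seed.
#'
#' @param fingerprints Gene x feature matrix (reduced, scaled).
#' @param method `"pcoa"` or `"nmds"`.
#' @param seed Integer seed (used by `"nmds"`).
#' @return data.frame: `gene`, `dim1`, `dim2`.
#' @export
embed_fingerprints <- function(fingerprints, method = c("pcoa", "nmds"),
                               seed = 1) {
  method <- match.arg(method)
  x <- as.matrix(fingerprints)
  n <- nrow(x)
  if (n == 1)
    return(data.frame(gene = rownames(x), dim1 = 0, dim2 = 0))
  if (ncol(x) >= 2) {
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[!is.finite(cc)] <- 0
    d <- stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(x)
  }
  if (method == "nmds") {
    if (!requireNamespace("vegan", quietly = TRUE))
      stop("method 'nmds' needs the vegan package")
    set.seed(seed)
    coords <- vegan::monoMDS(d, k = 2)$points
  } else {
    coords <- stats::cmdscale(d, k = 2)
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
  }
  data.frame(gene = rownames(x), dim1 = coords[, 1], dim2 = coords[, 2])
}

#' Export a clustered fingerprint heatmap and its ordered matrix
#'
#' Writes a heatmap whose row order is the dendrogram leaf order of a
#' hierarchical `cluster_result`, with per-feature min-max scaling so each
#' feature spans [0, 1], plus the ordered scaled matrix as CSV for
#' machine-readable reuse.
#'
#' @param fingerprints Gene x feature matrix (rZ scale).
#' @param cluster_result A [hierarchical_cluster()] result with a tree.
#' @param file PNG path for the heatmap (NULL skips the figure).
#' @param matrix_file CSV path for the ordered scaled matrix (NULL skips).
#' @return Invisibly, the ordered scaled matrix.
#' @export
export_heatmap <- function(fingerprints, cluster_result, file = NULL,
                           matrix_file = NULL) {
  stopifnot(inherits(cluster_result, "cluster_result"),
            !is.null(cluster_result$tree))
  tree <- cluster_result$tree
  ord <- tree$labels[tree$order]
  sc <- minmax_scale(fingerprints)
  rownames(sc) <- rownames(fingerprints)
  extra <- setdiff(rownames(sc), ord)
  mat <- sc[c(ord, extra), , drop = FALSE]
  if (!is.null(matrix_file)) {
    utils::write.csv(data.frame(gene = rownames(mat), mat,
                                check.names = FALSE),
                     matrix_file, row.names = FALSE)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    pheatmap::pheatmap(fingerprints[c(ord, extra), , drop = FALSE],
                       cluster_rows = FALSE, cluster_cols = FALSE,
                       scale = "none")
    grDevices::dev.off()
  }
  invisible(mat)
}

#' Write a dendrogram as Newick text
#'
#' @param cluster_result A hierarchical [hierarchical_cluster()] result.
#' @param file Output path.
#' @return Invisibly, the `phylo` object written.
#' @export
write_dendrogram <- function(cluster_result, file) {
  stopifnot(!is.null(cluster_result$tree))
  phy <- ape::as.phylo(cluster_result$tree)
  ape::write.tree(phy, file = file)
  invisible(phy)
}
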