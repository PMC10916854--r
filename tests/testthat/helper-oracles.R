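# shared fixtures and independent oracles for the test suite

ntc_well <- function() list(plate_id = "p1", row = 1, col = 1,
                            role = "NTC", gene = "")

# greedy nearest matching of detected spots to ground-truth coordinates
match_spots <- function(det, tru, tol = 2) {
  if (nrow(tru) == 0 || nrow(det) == 0)
    return(c(recall = as.numeric(nrow(tru) == 0),
             precision = as.numeric(nrow(det) == 0)))
  used <- rep(FALSE, nrow(tru)); tp <- 0
  for (i in seq_len(nrow(det))) {
    dd <- sqrt((tru$x - det$x[i])^2 + (tru$y - det$y[i])^2)
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) && dd[j] <= tol) { used[j] <- TRUE; tp <- tp + 1 }
  }
  c(recall = tp / nrow(tru), precision = tp / nrow(det))
}

# naive O(n^3) agglomerative linkage oracle returning flat labels at k
# clusters; supports complete linkage on an arbitrary distance matrix
naive_linkage_labels <- function(dmat, k) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- max(dmat[clusters[[a]], clusters[[b]]])
      if (d < best_d) { best_d <- d; best <- c(a, b) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# two partitions identical up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# fingerprints with planted co-functional modules: each module shares an
# effect direction with the stated module:noise separation
planted_module_fingerprints <- function(n_modules = 6, genes_per_module = 8,
                                        n_features = 20, separation = 3,
                                        seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_modules * n_features, 0, separation),
                    n_modules, n_features)
  fp <- matrix(NA_real_, n_modules * genes_per_module, n_features)
  labels <- integer(nrow(fp))
  for (m in seq_len(n_modules)) {
    idx <- (m - 1) * genes_per_module + seq_len(genes_per_module)
    fp[idx, ] <- matrix(rep(centers[m, ], each = genes_per_module),
                        genes_per_module) +
      rnorm(genes_per_module * n_features)
    labels[idx] <- m
  }
  rownames(fp) <- sprintf("gene_%02d", seq_len(nrow(fp)))
  colnames(fp) <- sprintf("f%02d", seq_len(n_features))
  list(fingerprints = fp, labels = labels)
}

# adjusted Rand index (closed form over the contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# small synthetic screen reused across analysis tests (cached per session)
small_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- generate_plate_layout(1, library_genes = paste0("g", 1:20),
                                   seed = 42)
      eff <- rbind(effect_spec("g1", "dispersion_all", 0.9),
                   effect_spec("g2", "lethal", 1),
                   effect_spec("g3", "micronucleus", 1),
                   effect_spec("g4", "hyperclustering_EEA1", 0.9),
                   effect_spec("g5", "mtoc_gain", 1))
      tr <- ground_truth(paste0("g", 1:20), eff)
      cfg <- sim_config(cells_per_well_mean = 60, seed = 42)
      cache <<- simulate_screen(lay, tr, cfg)
    }
    cache
  }
})
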