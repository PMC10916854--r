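test_that("well aggregation is an arithmetic mean over gated cells", {
  scr <- small_screen()
  prof <- aggregate_wells(scr$cells, min_cells = 20)
  expect_true(all(prof$n_viable <= prof$n_cells))
  # brute-force oracle: recompute one well's mean by direct summation
  cal <- viability_calibration(scr$cells[scr$cells$role == "NTC", ])
  w <- prof[prof$role == "NTC", ][1, ]
  sel <- scr$cells$plate_id == w$plate_id & scr$cells$row == w$row &
    scr$cells$col == w$col
  v <- sel & gate_viable(scr$cells, cal)
  expect_equal(w$nucleus_area, sum(scr$cells$nucleus_area[v]) / sum(v),
               tolerance = 1e-12)
  expect_equal(w$n_viable, sum(v))
})

test_that("wells with no viable cells are excluded with NaN profiles", {
  cells <- small_screen()$cells
  # fabricate a well of only pyknotic mimics
  bad <- cells[cells$role == "NTC", ][1:30, ]
  bad$row <- 99  # fake position, distinct well key is all that matters
  bad$role <- "LIBRARY"; bad$gene <- "dead_gene"
  bad$nucleus_area <- 1
  mixed <- rbind(cells, bad)
  prof <- aggregate_wells(mixed, min_cells = 20)
  w <- prof[prof$row == 99, ]
  expect_true(w$excluded)
  expect_true(is.nan(w$nucleus_area))
})

test_that("rZ matches the hand-computed median/MAD oracle", {
  ntc <- c(1, 2, 3, 4, 5)  # median 3, raw MAD 1
  expect_equal(rz_normalize(3, ntc), 0)
  expect_equal(rz_normalize(3 + 1.4826, ntc), 1)
  # antisymmetry about the reference median
  x <- 4.7
  expect_equal(rz_normalize(x, ntc), -rz_normalize(2 * 3 - x, ntc))
  expect_error(rz_normalize(1, c(2, 2, 2, 2)), "MAD is zero")
})

test_that("rZ is invariant under joint affine transforms", {
  set.seed(3)
  ntc <- rnorm(38); x <- rnorm(10)
  a <- 3.7; b <- -11
  expect_equal(rz_normalize(a * x + b, a * ntc + b), rz_normalize(x, ntc),
               tolerance = 1e-12)
})

test_that("two-point normalization anchors the control medians", {
  expect_equal(two_point_normalize(5, med_ntc = 5, med_pos = 1), 0)
  expect_equal(two_point_normalize(1, med_ntc = 5, med_pos = 1), -100)
  expect_equal(two_point_normalize(3, med_ntc = 5, med_pos = 1), -50)
  expect_equal(two_point_normalize(2, med_ntc = 5, med_pos = 1,
                                   pos_target = 100), 75)
  expect_error(two_point_normalize(1, 2, 2), "window")
})

test_that("robust Z-prime matches the hand-computed oracle", {
  expect_equal(robust_z_prime(c(11, 12, 13, 14, 15), c(1, 2, 3, 4, 5)),
               1 - 3 * (1.4826 + 1.4826) / 10)
  expect_equal(robust_z_prime(c(11, 12, 13, 14, 15), c(1, 2, 3, 4, 5)),
               0.11044)
  # zero spread attains the upper bound of 1
  expect_equal(robust_z_prime(c(7, 7, 7), c(2, 2, 2)), 1)
  # symmetric in the two groups
  expect_equal(robust_z_prime(c(1, 2, 3), c(9, 10, 11)),
               robust_z_prime(c(9, 10, 11), c(1, 2, 3)))
  expect_warning(out <- robust_z_prime(c(1, 2, 3), c(3, 2, 1)), "undefined")
  expect_identical(out, -Inf)
  expect_error(robust_z_prime(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("rZ' is jointly affine-invariant and grows with control separation", {
  set.seed(8)
  pos <- rnorm(13, 5); neg <- rnorm(38)
  expect_equal(robust_z_prime(2 * pos + 3, 2 * neg + 3),
               robust_z_prime(pos, neg), tolerance = 1e-12)
  seps <- c(2, 4, 8, 16)
  vals <- vapply(seps, function(s) robust_z_prime(neg + s, neg), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("per-plate normalization centres NTC wells at zero", {
  scr <- small_screen()
  prof <- aggregate_wells(scr$cells, min_cells = 20)
  norm <- normalize_profiles(prof)
  for (p in unique(prof$plate_id)) {
    ref <- norm$rz$role == "NTC" & norm$rz$plate_id == p &
      !norm$rz$low_count & !norm$rz$excluded
    for (f in c("nucleus_area", "gfp_locratio")) {
      expect_equal(median(norm$rz[[f]][ref]), 0)
      # robust spread of NTC rZ is ~1 by construction
      expect_lt(abs(1.4826 * mad(norm$rz[[f]][ref], constant = 1) - 1), 0.15)
    }
  }
})

test_that("the LDA endpoint downweights pure-noise features", {
  set.seed(21)
  n <- 200
  x <- data.frame(informative = c(rnorm(n, 0), rnorm(n, -4)),
                  noise = rnorm(2 * n))
  labels <- rep(c("NTC", "positive"), each = n)
  ep <- fit_lda_endpoint(x, labels, c("informative", "noise"),
                         rz_prime_min = -Inf)
  expect_lt(abs(ep$weights[["noise"]]) / abs(ep$weights[["informative"]]), 0.05)
  # projection is anchored: NTC median 0, positive median -100
  z <- apply_endpoint(ep, x)
  expect_equal(median(z[labels == "NTC"]), 0, tolerance = 1e-9)
  expect_equal(median(z[labels == "positive"]), -100, tolerance = 1e-9)
})

test_that("duplicated informative features share the weight after ridge", {
  set.seed(22)
  f <- c(rnorm(100, 0), rnorm(100, -3))
  x <- data.frame(a = f, b = f)
  labels <- rep(c("NTC", "positive"), each = 100)
  ep <- fit_lda_endpoint(x, labels, c("a", "b"), rz_prime_min = -Inf)
  expect_equal(unname(ep$weights["a"]), unname(ep$weights["b"]),
               tolerance = 1e-6)
})

test_that("endpoints with no qualifying feature are unbuildable", {
  set.seed(23)
  x <- data.frame(noise = rnorm(60))
  labels <- rep(c("NTC", "positive"), each = 30)
  expect_error(fit_lda_endpoint(x, labels, "noise"), "unbuildable")
})

test_that("replicate concordance separates identical from independent runs", {
  set.seed(31)
  s1 <- setNames(rnorm(300), paste0("g", 1:300))
  expect_equal(replicate_concordance(s1, s1)$r_squared, 1)
  # independent noise: R^2 stays near zero across seeds
  high <- 0
  for (s in 1:20) {
    set.seed(s)
    a <- setNames(rnorm(300), paste0("g", 1:300))
    b <- setNames(rnorm(300), paste0("g", 1:300))
    if (replicate_concordance(a, b)$r_squared >= 0.05) high <- high + 1
  }
  expect_lte(high, 1)  # >= 95% of seeds below 0.05
  # the usability rule flags weak endpoints
  set.seed(32)
  a <- setNames(rnorm(200), paste0("g", 1:200))
  b <- 0.4 * a + rnorm(200)  # R^2 ~ 0.14
  cc <- replicate_concordance(a, b)
  expect_lt(cc$r_squared, 0.2)
  expect_false(cc$usable)
  expect_error(replicate_concordance(a[1:2], b[1:2]), "3 matched")
})

test_that("crRNA aggregation is the median across wells", {
  expect_equal(unname(aggregate_crRNA(c(-3, -2, -10), rep("a", 3))), -3)
  expect_equal(unname(aggregate_crRNA(5, "a")), 5)
  # sorting oracle on many random pools
  set.seed(41)
  pool <- sample(paste0("p", 1:100), 1000, replace = TRUE)
  x <- rnorm(1000)
  got <- aggregate_crRNA(x, pool)
  for (p in unique(pool)) {
    v <- sort(x[pool == p])
    n <- length(v)
    oracle <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(got[[p]], oracle)
  }
})
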