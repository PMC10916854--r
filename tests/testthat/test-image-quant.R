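# shared rendered fixture: one healthy well, noise-free and noisy variants
rendered_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(cells_per_well_mean = 8, noise_sd = 0, spot_mean = 12,
                        micronucleus_rate = 0.5, viable_frac = 1, seed = 3)
      cells <- sample_cell_population(ntc_well(), config = cfg, seed = 21)
      cache <<- list(
        cfg = cfg, cells = cells,
        clean = render_well_images(cells, cfg, noise_sd = 0, seed = 5),
        noisy = render_well_images(cells, cfg, noise_sd = 0.05, seed = 5)
      )
    }
    cache
  }
})

test_that("blank images yield no nuclei and no cells", {
  blank <- matrix(0, 64, 64)
  nuc <- segment_nuclei(blank)
  expect_equal(max(nuc), 0)
  seg <- segment_cytoplasm(blank, nuc)
  expect_equal(max(seg$cells), 0)
  expect_length(seg$border_flag, 0)
})

test_that("disjoint synthetic nuclei are segmented with high mask overlap", {
  fx <- rendered_fixture()
  nuc <- segment_nuclei(fx$clean$images$hoechst)
  tru <- fx$clean$truth$nuclei
  expect_equal(max(nuc), nrow(fx$cells))
  for (i in seq_len(nrow(fx$cells))) {
    ctr <- fx$clean$truth$centers[i, ]
    lab <- nuc[round(ctr$x), round(ctr$y)]
    expect_gt(lab, 0)
    inter <- sum(nuc == lab & tru == i)
    union <- sum(nuc == lab | tru == i)
    expect_gte(inter / union, 0.9)
  }
})

test_that("touching nuclei joined by a thin neck are split by watershed", {
  img <- matrix(0, 90, 90)
  xy <- expand.grid(x = 1:90, y = 1:90)
  d1 <- sqrt((xy$x - 30)^2 + (xy$y - 45)^2)
  d2 <- sqrt((xy$x - 60)^2 + (xy$y - 45)^2)
  img[d1 <= 10 | d2 <= 10] <- 1
  img[xy$x > 38 & xy$x < 52 & abs(xy$y - 45) <= 2] <- 1  # thin neck
  nuc <- segment_nuclei(img, threshold = 0.5, smooth_sigma_px = 1)
  expect_equal(max(nuc), 2)
})

test_that("cells clipped at the image edge are border-flagged", {
  cfg <- sim_config(seed = 1)
  # render one cell, then crop so its cytoplasm touches the boundary
  cells <- sample_cell_population(ntc_well(),
                                  config = sim_config(cells_per_well_mean = 1,
                                                      viable_frac = 1, seed = 2),
                                  seed = 6)
  cells <- cells[1, , drop = FALSE]
  r <- render_well_images(cells, cfg, noise_sd = 0, seed = 2)
  nuc <- segment_nuclei(r$images$hoechst)
  seg <- segment_cytoplasm(r$images$tubulin, nuc)
  expect_false(any(seg$border_flag))
  ctr <- r$truth$centers[1, ]
  crop <- seq(max(1, round(ctr$x) - 25), min(nrow(r$images$hoechst),
                                             round(ctr$x) + 25))
  nuc2 <- segment_nuclei(r$images$hoechst[crop, ])
  seg2 <- segment_cytoplasm(r$images$tubulin[crop, ], nuc2)
  expect_true(any(seg2$border_flag))
})

test_that("spot detection is exact on well-separated noise-free spots", {
  img <- matrix(0, 120, 120)
  set.seed(4)
  pts <- expand.grid(x = c(15, 45, 75, 105), y = c(20, 60, 100))
  for (i in seq_len(nrow(pts)))
    img <- cargoscreen:::add_gaussian(img, pts$x[i], pts$y[i], 0.6, 1.2)
  det <- detect_spots(img)
  expect_equal(nrow(det), 12)
  m <- match_spots(det, pts, tol = 1)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["precision"]), 1)
})

test_that("the splitting coefficient merges sub-resolution doublets", {
  mk <- function(sep) {
    img <- matrix(0, 60, 60)
    img <- cargoscreen:::add_gaussian(img, 30 - sep / 2, 30, 0.6, 1.2)
    cargoscreen:::add_gaussian(img, 30 + sep / 2, 30, 0.6, 1.2)
  }
  p <- spot_params(splitting_um = 4)
  expect_equal(nrow(detect_spots(mk(3), params = p)), 1)
  expect_equal(nrow(detect_spots(mk(8), params = p)), 2)
})

test_that("blank channels and sub-pixel radius ranges are handled", {
  expect_equal(nrow(detect_spots(matrix(0, 40, 40))), 0)
  expect_error(detect_spots(matrix(0, 40, 40),
                            params = spot_params(radius_range_um = c(0.1, 0.4)),
                            um_per_px = 1), "pixel")
})

test_that("spots are assigned to half-open radial bands by signed distance", {
  # geometry oracle: the band edges themselves
  expect_equal(bin_radial_um(c(0, 10, 14, 14.01, 35, 35.01, -7, -7.5)),
               c("perinuclear", "intermediate", "intermediate", "outer",
                 "outer", "out_of_range", "perinuclear", "out_of_range"))
  # conservation over random spots in a synthetic cell
  nuc <- matrix(0L, 100, 100)
  xy <- expand.grid(x = 1:100, y = 1:100)
  nuc[sqrt((xy$x - 50)^2 + (xy$y - 50)^2) <= 8] <- 1L
  cellm <- matrix(1L, 100, 100)
  set.seed(9)
  spots <- data.frame(x = runif(100, 1, 100), y = runif(100, 1, 100))
  counts <- assign_spots_to_regions(spots, nuc, cellm)
  expect_equal(sum(counts), 100L)
})

test_that("ring assignment is invariant to translation and rotation", {
  nuc <- matrix(0L, 80, 80)
  xy <- expand.grid(x = 1:80, y = 1:80)
  nuc[sqrt((xy$x - 30)^2 + (xy$y - 30)^2) <= 7] <- 1L
  cellm <- matrix(1L, 80, 80)
  set.seed(12)
  spots <- data.frame(x = 30 + round(rnorm(30, 0, 9)),
                      y = 30 + round(rnorm(30, 0, 9)))
  spots$x <- pmin(pmax(spots$x, 1), 80); spots$y <- pmin(pmax(spots$y, 1), 80)
  base <- assign_spots_to_regions(spots, nuc, cellm)
  # translation by (10, 5)
  nuc_t <- matrix(0L, 80, 80)
  nuc_t[sqrt((xy$x - 40)^2 + (xy$y - 35)^2) <= 7] <- 1L
  shifted <- data.frame(x = spots$x + 10, y = spots$y + 5)
  expect_equal(assign_spots_to_regions(shifted, nuc_t, cellm), base)
  # 90-degree rotation of masks and coordinates
  rot <- function(m) t(m)[ncol(m):1, ]
  spots_r <- data.frame(x = 81 - spots$y, y = spots$x)
  expect_equal(assign_spots_to_regions(spots_r, rot(nuc), rot(cellm)), base)
})

test_that("localization ratio follows the zero-denominator pseudocount policy", {
  expect_equal(localization_ratio(10, 10), 1)
  expect_equal(localization_ratio(9, 3), 3)
  expect_equal(localization_ratio(5, 0), 6)
  expect_equal(localization_ratio(6, 2, log = TRUE), log(3))
  expect_error(localization_ratio(-1, 5), ">= 0")
  # scale invariance when the denominator is positive
  expect_equal(localization_ratio(30, 12), localization_ratio(300, 120))
})

test_that("micronuclei are found at their planted positions and size-capped", {
  fx <- rendered_fixture()
  nuc <- segment_nuclei(fx$clean$images$hoechst)
  seg <- segment_cytoplasm(fx$clean$images$tubulin, nuc)
  tru <- fx$clean$truth$micronuclei
  expect_gt(nrow(tru), 0)
  found <- 0
  for (j in seq_len(nrow(tru))) {
    ctr <- fx$clean$truth$centers[tru$cell_id[j], ]
    lab <- nuc[round(ctr$x), round(ctr$y)]
    mn <- detect_micronuclei(fx$clean$images$hoechst, nuc == lab,
                             seg$cells == lab)
    dd <- sqrt((mn$features$x - tru$x[j])^2 + (mn$features$y - tru$y[j])^2)
    if (any(dd <= 1.5)) found <- found + 1
  }
  expect_equal(found, nrow(tru))
  # a blob larger than the size cap is rejected as a second nucleus
  img <- matrix(0, 90, 90)
  xy <- expand.grid(x = 1:90, y = 1:90)
  nuc1 <- matrix(0L, 90, 90)
  nuc1[sqrt((xy$x - 30)^2 + (xy$y - 45)^2) <= 8] <- 1L
  img[nuc1 == 1] <- 1
  img[sqrt((xy$x - 65)^2 + (xy$y - 45)^2) <= 7] <- 1  # near-nucleus-sized blob
  cellm <- matrix(1L, 90, 90)
  expect_equal(detect_micronuclei(img, nuc1, cellm)$count, 0L)
  # no supra-background blob: count 0
  img2 <- matrix(0.05, 90, 90); img2[nuc1 == 1] <- 1
  expect_equal(detect_micronuclei(img2, nuc1, cellm)$count, 0L)
})

test_that("MTOC punctum counts match the planted centrosome numbers", {
  fx <- rendered_fixture()
  nuc <- segment_nuclei(fx$clean$images$hoechst)
  seg <- segment_cytoplasm(fx$clean$images$tubulin, nuc)
  tru_counts <- table(factor(fx$clean$truth$mtoc$cell_id,
                             levels = seq_len(nrow(fx$cells))))
  for (i in seq_len(nrow(fx$cells))) {
    ctr <- fx$clean$truth$centers[i, ]
    lab <- nuc[round(ctr$x), round(ctr$y)]
    cnt <- count_mtoc_puncta(fx$clean$images$gamma_tubulin, seg$cells == lab)
    expect_equal(cnt, as.integer(tru_counts[[i]]))
  }
  expect_equal(count_mtoc_puncta(matrix(0, 50, 50), matrix(1L, 50, 50)), 0L)
})

test_that("spot detection meets recall/precision targets on rendered wells", {
  fx <- rendered_fixture()
  for (ch in c("gfp", "rfp", "eea1")) {
    p <- spot_params(background_subtraction = identical(ch, "rfp"))
    tru <- fx$clean$truth$spots[fx$clean$truth$spots$channel == ch, ]
    m0 <- match_spots(detect_spots(fx$clean$images[[ch]], params = p), tru)
    expect_gte(m0[["recall"]], 0.99)
    expect_gte(m0[["precision"]], 0.99)
    m1 <- match_spots(detect_spots(fx$noisy$images[[ch]], params = p), tru)
    expect_gte(m1[["recall"]], 0.9)
    expect_gte(m1[["precision"]], 0.9)
  }
})

test_that("quantified cell records conserve spot counts across regions", {
  fx <- rendered_fixture()
  q <- quantify_well(fx$clean$images, um_per_px = 1)
  expect_equal(nrow(q), nrow(fx$cells))
  for (ch in c("gfp", "rfp", "eea1")) {
    expect_equal(q[[paste0(ch, "_total")]],
                 q[[paste0(ch, "_perinuclear")]] +
                   q[[paste0(ch, "_intermediate")]] +
                   q[[paste0(ch, "_outer")]] + q[[paste0(ch, "_oor")]])
  }
})

test_that("viability gate recovers planted apoptotic fractions", {
  cfg <- sim_config(cells_per_well_mean = 4000, viable_frac = 0.8, seed = 14)
  cells <- sample_cell_population(ntc_well(), config = cfg, seed = 14)
  # calibrate on a clean reference population, then gate the mixed one
  ref <- sample_cell_population(ntc_well(),
                                config = sim_config(cells_per_well_mean = 2000,
                                                    viable_frac = 1, seed = 15),
                                seed = 15)
  cal <- viability_calibration(ref)
  flag <- gate_viable(cells, cal)
  gated_out <- mean(!flag)
  expect_lt(abs(gated_out - 0.2), 0.05)
  # NTC-median cell is viable; a pyknotic mimic is not
  med <- data.frame(nucleus_area = median(ref$nucleus_area),
                    nucleus_roundness = median(ref$nucleus_roundness),
                    hoechst_int = median(ref$hoechst_int))
  expect_true(gate_viable(med, cal))
  pyk <- med; pyk$nucleus_area <- cal$envelope$nucleus_area[1] - 1
  expect_false(gate_viable(pyk, cal))
  expect_error(viability_calibration(ref[1:20, ]), "50")
})

test_that("reporter gate recovers planted negative fractions", {
  cfg <- sim_config(cells_per_well_mean = 3000, reporter_pos_frac = 0.7,
                    seed = 16)
  cells <- sample_cell_population(ntc_well(), config = cfg, seed = 16)
  flag <- gate_reporter_positive(cells)
  expect_lt(abs(mean(!flag) - 0.3), 0.05)
  zero <- data.frame(gfp_int = 0, rfp_int = 0)
  expect_false(gate_reporter_positive(zero, ntc_cells = cells))
  pos_med <- data.frame(gfp_int = median(cells$gfp_int[flag]),
                        rfp_int = median(cells$rfp_int[flag]))
  expect_true(gate_reporter_positive(pos_med, ntc_cells = cells))
})

test_that("texture/morphology features behave analytically", {
  # uniform region: zero co-occurrence contrast
  m <- matrix(0L, 60, 60); m[20:40, 20:40] <- 1L
  img <- matrix(0.5, 60, 60)
  f <- extract_texture_morphology(img, m)
  expect_equal(unname(f["h.con"]), 0)
  # perfect disc: roundness within 2% of 1 at radius >= 20 px
  xy <- expand.grid(x = 1:101, y = 1:101)
  disc <- matrix(0L, 101, 101)
  disc[sqrt((xy$x - 51)^2 + (xy$y - 51)^2) <= 22] <- 1L
  fr <- extract_texture_morphology(matrix(1, 101, 101), disc)
  expect_lt(abs(fr[["shape.roundness"]] - 1), 0.02)
  # checkerboard strictly rougher than uniform
  chk <- matrix(rep(c(0, 1), length.out = 3600), 60, 60)
  f2 <- extract_texture_morphology(chk, m)
  expect_gt(f2[["h.con"]], f[["h.con"]])
  # empty mask: all-zero vector, flagged
  fe <- extract_texture_morphology(img, matrix(0L, 60, 60))
  expect_true(all(fe == 0))
  expect_true(attr(fe, "imputed"))
})
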