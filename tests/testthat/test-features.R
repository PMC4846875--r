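# Small hand-built segmentation: one 20x20 cell with a 10x10 nucleus.
toy_seg <- function() {
  nuc <- matrix(0L, 40, 40); nuc[16:25, 16:25] <- 1L
  cell <- matrix(0L, 40, 40); cell[11:30, 11:30] <- 1L
  derive_regions(nuc, cell, expand_px = 3, shrink_px = 2)
}

test_that("integrated and mean intensities are exact pixel sums", {
  seg <- toy_seg()
  ch <- matrix(2, 40, 40)
  cat1 <- rbind(descriptor_def("Nucleus_m_mean", "nucleus", "m", "mean"),
                descriptor_def("Nucleus_m_int", "nucleus", "m", "integrated"),
                descriptor_def("Cell_m_int", "cell", "m", "integrated"))
  f <- compute_cell_features(seg, list(m = ch), catalogue = cat1)
  expect_equal(f$Nucleus_m_mean, 2)
  expect_equal(f$Nucleus_m_int, 200)   # 100 px at value 2
  expect_equal(f$Cell_m_int, 800)
})

test_that("the perinuclear/PM ratio divides exact region sums", {
  seg <- toy_seg()
  ch <- matrix(0, 40, 40)
  ch[seg$perinuclear == 1] <- 150 / sum(seg$perinuclear == 1)
  ch[seg$pm == 1] <- 50 / sum(seg$pm == 1)
  cat1 <- descriptor_def("m_ratio_perinuclear_PM", "perinuclear", "m",
                         "ratio_perinuclear_pm")
  f <- compute_cell_features(seg, list(m = ch), catalogue = cat1)
  expect_equal(f$m_ratio_perinuclear_PM, 3)
})

test_that("a zero PM sum flags the ratio as missing", {
  seg <- toy_seg()
  ch <- matrix(0, 40, 40); ch[seg$perinuclear == 1] <- 1
  cat1 <- descriptor_def("m_ratio_perinuclear_PM", "perinuclear", "m",
                         "ratio_perinuclear_pm")
  f <- compute_cell_features(seg, list(m = ch), catalogue = cat1)
  expect_true(is.na(f$m_ratio_perinuclear_PM))
  expect_equal(attr(f, "flagged_cells"), 1L)
})

test_that("integrated intensity is additive over the region partition", {
  fx <- rendered_fixture()
  chans <- fx$img$channels
  cat1 <- rbind(
    descriptor_def("Cell_EGFR_integrated", "cell", "EGFR", "integrated"),
    descriptor_def("Nucleus_EGFR_integrated", "nucleus", "EGFR", "integrated"),
    descriptor_def("Cytoplasm_EGFR_integrated", "cytoplasm", "EGFR",
                   "integrated"))
  f <- compute_cell_features(fx$seg, chans, catalogue = cat1)
  expect_equal(f$Nucleus_EGFR_integrated + f$Cytoplasm_EGFR_integrated,
               f$Cell_EGFR_integrated, tolerance = 1e-12)
})

test_that("object counts come from centroid region membership", {
  fx <- rendered_fixture()
  eo <- detect_endosomes(fx$img$channels$EGFR, fx$seg, tophat_radius = 5,
                         min_intensity = 80)
  cat1 <- rbind(
    descriptor_def("Perinuclear_endosome_EGFR_count", "perinuclear", "EGFR",
                   "object_count"),
    descriptor_def("PM_endosome_EGFR_count", "pm", "EGFR", "object_count"),
    descriptor_def("Cytoplasm_endosome_EGFR_count", "cytoplasm", "EGFR",
                   "object_count"),
    descriptor_def("Nucleus_endosome_EGFR_count", "nucleus", "EGFR",
                   "object_count"))
  f <- compute_cell_features(fx$seg, fx$img$channels,
                             endosomes = list(EGFR = eo), catalogue = cat1)
  total <- f$Perinuclear_endosome_EGFR_count + f$PM_endosome_EGFR_count +
    f$Cytoplasm_endosome_EGFR_count + f$Nucleus_endosome_EGFR_count
  expect_equal(total[fx$label_of_truth], fx$img$truth$cells$n_spots)
})

test_that("counts are invariant to rescaling of other channels", {
  fx <- rendered_fixture()
  eo <- detect_endosomes(fx$img$channels$EGFR, fx$seg, tophat_radius = 5,
                         min_intensity = 80)
  cat1 <- descriptor_def("Cytoplasm_endosome_EGFR_count", "cytoplasm",
                         "EGFR", "object_count")
  f1 <- compute_cell_features(fx$seg, fx$img$channels,
                              endosomes = list(EGFR = eo), catalogue = cat1)
  chans2 <- fx$img$channels
  chans2$pERK <- chans2$pERK * 10
  f2 <- compute_cell_features(fx$seg, chans2,
                              endosomes = list(EGFR = eo), catalogue = cat1)
  expect_identical(f1$Cytoplasm_endosome_EGFR_count,
                   f2$Cytoplasm_endosome_EGFR_count)
})

fake_objects <- function(pixels, cells, dim = c(50, 50),
                         region = rep("pm", length(pixels))) {
  structure(list(
    objects = data.frame(object = seq_along(pixels), cell = cells,
                         region = region,
                         area = lengths(pixels),
                         x = 0, y = 0, integrated = 0,
                         stringsAsFactors = FALSE),
    pixels = pixels, dim = dim, threshold = 0), class = "endosome_objects")
}

test_that("colocalization counting follows the overlap fraction rule", {
  a <- fake_objects(list(1:10, 101:110), cells = c(1L, 1L))
  expect_equal(unname(coloc_count(a, a, 0.5)), 2)        # identical sets
  b <- fake_objects(list(501:510), cells = 1L)
  expect_equal(sum(coloc_count(a, b, 0.5)), 0)           # disjoint sets
  # one A object overlapping B on 30% of its area
  a1 <- fake_objects(list(1:10), cells = 1L)
  b1 <- fake_objects(list(c(8:10, 200:220)), cells = 1L)
  expect_equal(sum(coloc_count(a1, b1, 0.5)), 0)
  expect_equal(unname(coloc_count(a1, b1, 0.25)), 1)
  expect_error(coloc_count(a1, fake_objects(list(1:2), 1L, dim = c(9, 9))),
               "different shape")
})

test_that("rendered colocalized spots are counted per cell", {
  img <- render_cell_image(4, spot_counts = c(2, 3, 1, 2), seed = 21,
                           width = 240, height = 240, cell_radius = c(18, 24),
                           coloc_frac = 1)
  nuc <- segment_nuclei(img$channels$DNA, min_area = 30)
  seg <- derive_regions(nuc, propagate_cells(nuc, img$channels$EGFR))
  ea <- detect_endosomes(img$channels$EGFR, seg, 5, min_intensity = 80)
  eb <- detect_endosomes(img$channels$Tfn, seg, 5, min_intensity = 80)
  # tolerant fraction: the EGFR footprint of a vesicle is wider than its
  # Tfn footprint because it rides on a brighter structural background
  cc <- coloc_count(ea, eb, 0.25)
  tc <- img$truth$cells
  lab <- seg$cell[cbind(round(tc$cx), round(tc$cy))]
  got <- integer(max(seg$cell)); got[as.integer(names(cc))] <- cc
  expect_equal(got[lab], tc$n_spots)   # every spot present in both channels
})

test_that("the perinuclear-vs-PM slope matches closed-form OLS", {
  d <- data.frame(PM_EGFR_mean = c(1, 2, 3, 4),
                  Perinuclear_EGFR_mean = c(3, 5, 7, 9))
  expect_equal(perinuclear_pm_slope(d), 2)              # exact line y = 2x+1
  d2 <- data.frame(PM_EGFR_mean = c(1, 2, 3),
                   Perinuclear_EGFR_mean = c(1, 3, 2))
  expect_equal(perinuclear_pm_slope(d2), 0.5)           # closed form 1/2
  d3 <- data.frame(PM_EGFR_mean = c(2, 2, 2),
                   Perinuclear_EGFR_mean = c(1, 2, 3))
  expect_true(is.na(perinuclear_pm_slope(d3)))          # zero variance in x
  expect_true(is.na(perinuclear_pm_slope(d2[1:2, ])))   # < 3 cells
  d4 <- rbind(cbind(d, batch_id = "b1"), cbind(d2, batch_id = "b2"))
  expect_equal(perinuclear_pm_slope(d4), c(b1 = 2, b2 = 0.5))
})
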