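test_that("nucleus segmentation recovers bright discs", {
  img <- disc_image(120, 120, cbind(c(25, 60, 95), c(30, 80, 30)), r = 8,
                    value = 200, background = 5)
  lab <- segment_nuclei(img, min_area = 50)
  expect_equal(max(lab), 3)
  rendered <- sum(img > 5) / 3
  areas <- tabulate(lab, 3)
  expect_true(all(abs(areas - rendered) / rendered < 0.05))
  expect_true(all(abs(areas - pi * 64) / (pi * 64) < 0.10))
})

test_that("nucleus segmentation handles degenerate inputs", {
  expect_equal(max(segment_nuclei(matrix(0, 40, 40))), 0)
  expect_equal(max(segment_nuclei(matrix(3.3, 40, 40))), 0)
  small <- disc_image(60, 60, cbind(30, 30), r = 3, value = 100)  # ~28 px
  expect_equal(max(segment_nuclei(small, min_area = 50)), 0)
  expect_gt(max(segment_nuclei(small, min_area = 10)), 0)
  bad <- matrix(1, 10, 10); bad[5, 5] <- NaN
  expect_error(segment_nuclei(bad), "NA/NaN")
  # border-touching nuclei removed
  edge <- disc_image(60, 60, cbind(c(2, 30), c(30, 30)), r = 6, value = 100)
  expect_equal(max(segment_nuclei(edge, min_area = 20)), 1)
})

test_that("propagation splits a uniform disc at the perpendicular bisector", {
  img <- disc_image(101, 101, cbind(51, 51), r = 40, value = 100,
                    background = 0)
  seeds <- matrix(0L, 101, 101)
  seeds[51, 45] <- 1L; seeds[51, 56] <- 2L   # odd separation: no tied column
  lab <- propagate_cells(seeds, img)
  a1 <- sum(lab == 1); a2 <- sum(lab == 2)
  expect_equal(a1 + a2, sum(img > 0))
  expect_lt(abs(a1 - a2) / (a1 + a2), 0.02)
})

test_that("a single seed floods the whole foreground", {
  img <- disc_image(80, 80, cbind(40, 40), r = 25, value = 100)
  seeds <- matrix(0L, 80, 80); seeds[40, 40] <- 1L
  lab <- propagate_cells(seeds, img)
  expect_equal(which(lab == 1), which(img > 0))
  # no seeds -> empty labels; shape mismatch -> error
  expect_equal(max(propagate_cells(matrix(0L, 80, 80), img)), 0)
  expect_error(propagate_cells(matrix(0L, 10, 10), img), "shape")
})

test_that("propagation boundaries follow dark ridges of the guide channel", {
  nr <- 41; nc <- 41
  img <- matrix(100, nr, nc)
  img[, 18] <- 5                      # dark ridge off the midline
  seeds <- matrix(0L, nr, nc)
  seeds[21, 5] <- 1L; seeds[21, 37] <- 2L
  lab <- propagate_cells(seeds, img, lambda = 0.01,
                         mask = matrix(TRUE, nr, nc))
  # crossing the ridge costs ~ 2*95*(1-lambda); the boundary sits on it
  expect_true(all(lab[, 1:17] == 1))
  expect_true(all(lab[, 19:41] == 2))
  boundary <- img[cbind(seq_len(nr), 18)]
  expect_lt(mean(boundary), mean(img))
})

test_that("propagation labels and costs match the Dijkstra oracle", {
  set.seed(31)
  for (i in 1:6) {
    nr <- 18; nc <- 18
    img <- matrix(runif(nr * nc, 0, 50), nr, nc)
    img <- (img + img[c(1, 1:(nr - 1)), ] + img[, c(1, 1:(nc - 1))]) / 3
    seeds <- matrix(0L, nr, nc)
    pos <- sample(which(matrix(TRUE, nr, nc)), 3)
    seeds[pos] <- 1:3
    mask <- matrix(TRUE, nr, nc)
    lab <- propagate_cells(seeds, img, lambda = 0.05, mask = mask)
    costs <- oracle_propagation_costs(seeds, img, lambda = 0.05, mask = mask)
    cmat <- simplify2array(costs)       # nr x nc x 3
    for (p in which(lab > 0)) {
      i2 <- (p - 1) %% nr + 1; j2 <- (p - 1) %/% nr + 1
      cs <- cmat[i2, j2, ]
      best <- min(cs)
      expect_lt(cs[lab[p]] - best, 1e-9)   # assigned label attains min cost
    }
  }
})

test_that("derived ring regions match brute-force disc morphology", {
  nuc <- matrix(0L, 40, 40); nuc[16:25, 16:25] <- 1L    # 10x10 square
  cell <- matrix(0L, 40, 40); cell[5:36, 5:36] <- 1L
  seg <- derive_regions(nuc, cell, expand_px = 2, shrink_px = 5)
  dil <- oracle_dilate(nuc > 0, 2)
  expect_equal(sum(seg$perinuclear == 1), sum(dil) - 100)
  expect_equal(which(seg$perinuclear == 1), which(dil & nuc == 0))
  ero <- oracle_erode(cell > 0, 5)
  expect_equal(which(seg$pm == 1), which(cell > 0 & !ero))
  expect_equal(which(seg$cytoplasm == 1), setdiff(which(cell > 0), which(nuc > 0)))
})

test_that("derived regions handle degenerate radii", {
  nuc <- matrix(0L, 30, 30); nuc[13:18, 13:18] <- 1L
  cell <- matrix(0L, 30, 30); cell[9:22, 9:22] <- 1L
  expect_equal(sum(derive_regions(nuc, cell, expand_px = 0)$perinuclear), 0)
  # shrink radius beyond the inradius: the erosion empties, PM = whole cell
  seg <- derive_regions(nuc, cell, shrink_px = 20)
  expect_equal(which(seg$pm == 1), which(cell == 1))
  expect_error(derive_regions(nuc, cell, expand_px = -1), ">= 0")
  bad_nuc <- matrix(0L, 30, 30); bad_nuc[1:3, 1:3] <- 1L
  expect_error(derive_regions(bad_nuc, cell), "inconsistent")
})

test_that("region set identities hold on random blob masks", {
  set.seed(32)
  for (i in 1:5) {
    img <- disc_image(60, 60, cbind(runif(2, 20, 40), runif(2, 20, 40)),
                      r = 12, value = 100)
    nuc_img <- disc_image(60, 60, cbind(c(25, 40), c(25, 40)), r = 4,
                          value = 100)
    nuc <- segment_nuclei(nuc_img, min_area = 10)
    cell <- propagate_cells(nuc, img)
    r_e <- sample(0:6, 1); r_s <- sample(0:6, 1)
    seg <- derive_regions(nuc, cell, expand_px = r_e, shrink_px = r_s)
    for (k in seq_len(max(cell))) {
      expect_identical(which(seg$cytoplasm == k),
                       setdiff(which(seg$cell == k), which(seg$nucleus == k)))
      expect_equal(sum(seg$perinuclear == k & seg$nucleus == k), 0)
      expect_true(all(which(seg$pm == k) %in% which(seg$cell == k)))
      expect_true(all(which(seg$nucleus == k) %in% which(seg$cell == k)))
    }
  }
})

test_that("white top-hat matches the brute-force oracle", {
  set.seed(33)
  img <- matrix(runif(400, 0, 10), 20, 20)
  img[8:10, 8:10] <- img[8:10, 8:10] + 50
  expect_equal(white_tophat(img, 3), oracle_tophat(img, 3), tolerance = 1e-12)
})

test_that("endosome detection finds exactly the rendered spots", {
  # uniform image: zero objects
  expect_equal(nrow(detect_endosomes(matrix(7, 60, 60))$objects), 0)
  # five well-separated Gaussian spots on flat background
  flat <- matrix(5, 150, 150)
  xs <- matrix(rep(1:150, 150), 150); ys <- t(xs)
  pts <- cbind(c(30, 30, 75, 120, 120), c(30, 120, 75, 30, 120))
  for (i in 1:5)
    flat <- flat + 200 * exp(-((xs - pts[i, 1])^2 + (ys - pts[i, 2])^2) / 8)
  eo <- detect_endosomes(flat, tophat_radius = 5)
  expect_equal(nrow(eo$objects), 5)    # recall = precision = 1
  got <- eo$objects[order(eo$objects$y, eo$objects$x), c("x", "y")]
  want <- pts[order(pts[, 2], pts[, 1]), ]
  expect_equal(unname(as.matrix(got)), unname(want), tolerance = 0.1)
  # one broad blob, radius 20 >> tophat radius 5: opening keeps it, 0 objects
  blob <- disc_image(100, 100, cbind(50, 50), r = 20, value = 80,
                     background = 5)
  expect_equal(nrow(detect_endosomes(blob, tophat_radius = 5)$objects), 0)
  expect_error(detect_endosomes(flat, tophat_radius = 0), ">= 1")
})

test_that("per-cell spot counts match the generator on rendered fields", {
  fx <- rendered_fixture()
  eo <- detect_endosomes(fx$img$channels$EGFR, fx$seg, tophat_radius = 5,
                         min_intensity = 80)
  det <- tabulate(eo$objects$cell, max(fx$seg$cell))
  expect_equal(det[fx$label_of_truth], fx$img$truth$cells$n_spots)
  expect_true(all(eo$objects$cell > 0))
})
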