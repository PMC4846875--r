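# Independent brute-force oracles, deliberately naive implementations.

# ECDF-scan signed KS: evaluate both ECDFs at every pooled point.
oracle_signed_ks <- function(treated, control) {
  pts <- sort(unique(c(treated, control)))
  ft <- vapply(pts, function(p) mean(treated <= p), numeric(1))
  fc <- vapply(pts, function(p) mean(control <= p), numeric(1))
  d_plus <- max(c(fc - ft, 0))    # sup F_control - F_treated
  d_minus <- max(c(ft - fc, 0))
  list(d_plus = d_plus, d_minus = d_minus,
       signed_d = if (d_plus >= d_minus) d_plus else -d_minus)
}

# Pixel-enumeration Euclidean disc morphology on binary masks.
oracle_dilate <- function(mask, r) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!nrow(idx)) return(out)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    d2 <- (idx[, 1] - i)^2 + (idx[, 2] - j)^2
    if (min(d2) <= r^2) out[i, j] <- TRUE
  }
  out
}

oracle_erode <- function(mask, r) {
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    if (!mask[i, j]) next
    if (!nrow(bg)) { out[i, j] <- TRUE; next }
    d2 <- (bg[, 1] - i)^2 + (bg[, 2] - j)^2
    if (min(d2) > r^2) out[i, j] <- TRUE
  }
  out
}

# Direct grayscale white top-hat with a Euclidean disc.
oracle_tophat <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  filt <- function(m, f) {
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      vals <- c()
      for (di in -r:r) for (dj in -r:r) {
        if (di^2 + dj^2 > r^2) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
          vals <- c(vals, m[ii, jj])
      }
      out[i, j] <- f(vals)
    }
    out
  }
  opened <- filt(filt(img, min), max)
  pmax(img - opened, 0)
}

# Multi-source Dijkstra shortest accumulated cost per seed label, with the
# same step cost as the propagation: (1-lambda)*|dI| + lambda*step length.
oracle_propagation_costs <- function(nucleus_labels, guide, lambda, mask) {
  labs <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  nr <- nrow(guide); nc <- ncol(guide)
  off <- cbind(dx = c(1, -1, 0, 0, 1, 1, -1, -1),
               dy = c(0, 0, 1, -1, 1, -1, 1, -1))
  sl <- sqrt(off[, 1]^2 + off[, 2]^2)
  out <- list()
  for (L in labs) {
    cost <- matrix(Inf, nr, nc)
    cost[nucleus_labels == L] <- 0
    done <- matrix(FALSE, nr, nc)
    repeat {
      cand <- which(!done & is.finite(cost))
      if (!length(cand)) break
      u <- cand[which.min(cost[cand])]
      done[u] <- TRUE
      ui <- (u - 1) %% nr + 1; uj <- (u - 1) %/% nr + 1
      for (o in seq_len(nrow(off))) {
        vi <- ui + off[o, 1]; vj <- uj + off[o, 2]
        if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
        if (!mask[vi, vj]) next
        w <- (1 - lambda) * abs(guide[ui, uj] - guide[vi, vj]) + lambda * sl[o]
        if (cost[ui, uj] + w < cost[vi, vj]) cost[vi, vj] <- cost[ui, uj] + w
      }
    }
    out[[as.character(L)]] <- cost
  }
  out
}

# Greedy exhaustive Ward merging: evaluates the delta-SSE criterion for
# every cluster pair at every step.
oracle_ward <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  partitions <- list()
  dsse <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; bv <- Inf
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ma <- colMeans(x[a, , drop = FALSE])
        mb <- colMeans(x[b, , drop = FALSE])
        v <- length(a) * length(b) / (length(a) + length(b)) * sum((ma - mb)^2)
        if (v < bv) { bv <- v; best <- c(i, j) }
      }
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
    dsse <- c(dsse, bv)
    partitions[[length(partitions) + 1L]] <- canonical_partition(clusters)
  }
  list(dsse = dsse, partitions = partitions)
}

canonical_partition <- function(clusters) {
  s <- lapply(clusters, sort)
  s[order(vapply(s, `[`, numeric(1), 1))]
}

# Partition sequence implied by an hclust tree (after each merge).
hclust_partitions <- function(hc, n) {
  lapply(seq_len(n - 1), function(s) {
    labs <- stats::cutree(hc, k = n - s)
    canonical_partition(unname(split(seq_len(n), labs)))
  })
}

# Draw a cell image and return it with a truth-cell -> segmentation-label map.
rendered_fixture <- function(seed = 5, n_cells = 6,
                             spot_counts = c(0, 1, 2, 3, 2, 1)) {
  img <- render_cell_image(n_cells, spot_counts = spot_counts, seed = seed,
                           width = 240, height = 240, cell_radius = c(18, 24))
  nuc <- segment_nuclei(img$channels$DNA, min_area = 30)
  cells <- propagate_cells(nuc, img$channels$EGFR)
  seg <- derive_regions(nuc, cells)
  tc <- img$truth$cells
  list(img = img, seg = seg,
       label_of_truth = seg$cell[cbind(round(tc$cx), round(tc$cy))])
}

# A filled disc mask / image helper.
disc_image <- function(nr, nc, centres, r, value = 100, background = 0) {
  img <- matrix(background, nr, nc)
  xs <- matrix(rep(seq_len(nr), nc), nr)
  ys <- matrix(rep(seq_len(nc), each = nr), nr)
  for (k in seq_len(nrow(centres)))
    img[(xs - centres[k, 1])^2 + (ys - centres[k, 2])^2 <= r^2] <- value
  img
}

# Fake z_profile long table for bookkeeping tests.
fake_z_profile <- function(n_desc, times, compounds, reps = 1:2,
                           control = "DMSO", seed = 1) {
  g <- expand.grid(compound = c(compounds, control),
                   descriptor = sprintf("d%03d", seq_len(n_desc)),
                   time_min = times, replicate = reps,
                   stringsAsFactors = FALSE)
  g <- g[order(g$replicate, g$time_min, g$descriptor, g$compound), ]
  set.seed(seed)
  g$signed_d <- runif(nrow(g), -1, 1)
  g$null_std <- 0.05
  g$z <- g$signed_d / g$null_std
  rownames(g) <- NULL
  attr(g, "control") <- control
  class(g) <- c("z_profile", "data.frame")
  g
}
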