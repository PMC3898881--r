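# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use different code paths from the package internals
# (explicit loops, igraph components, textbook formulas).

# Brute-force Jacobian: explicit 3x3 gradient matrix determinant per voxel,
# central differences interior / one-sided borders, computed with plain loops.
oracle_jacobian <- function(disp, voxel_mm) {
  dm <- dim(disp)[1:3]
  out <- array(NA_real_, dm)
  gidx <- function(i, n) {
    if (i == 1) list(lo = 1, hi = 2, den = 1)
    else if (i == n) list(lo = n - 1, hi = n, den = 1)
    else list(lo = i - 1, hi = i + 1, den = 2)
  }
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    D <- matrix(0, 3, 3)
    gi <- gidx(i, dm[1]); gj <- gidx(j, dm[2]); gk <- gidx(k, dm[3])
    for (c3 in 1:3) {
      D[c3, 1] <- (disp[gi$hi, j, k, c3] - disp[gi$lo, j, k, c3]) /
        (gi$den * voxel_mm[1])
      D[c3, 2] <- (disp[i, gj$hi, k, c3] - disp[i, gj$lo, k, c3]) /
        (gj$den * voxel_mm[2])
      D[c3, 3] <- (disp[i, j, gk$hi, c3] - disp[i, j, gk$lo, c3]) /
        (gk$den * voxel_mm[3])
    }
    out[i, j, k] <- det(diag(3) + D)
  }
  out
}

# Brute-force TFCE: explicit connected-component labelling (igraph) at every
# threshold step, direct summation.
oracle_tfce <- function(stat, E = 0.5, H = 2, dh, connectivity = 26) {
  dm <- dim(stat)
  out <- array(0, dm)
  hmax <- max(stat)
  if (hmax <= 0) return(out)
  nsteps <- floor(hmax / dh + 1e-12)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  coords <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                                  k = seq_len(dm[3])))
  lin <- function(m) m[, 1] + dm[1] * (m[, 2] - 1) + dm[1] * dm[2] * (m[, 3] - 1)
  for (s in seq_len(nsteps)) {
    h <- s * dh
    sel <- which(stat >= h)
    if (length(sel) == 0) next
    idmap <- integer(prod(dm)); idmap[sel] <- seq_along(sel)
    edges <- NULL
    cs <- coords[sel, , drop = FALSE]
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(cs, 2, offs[r, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
        nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
      if (!any(ok)) next
      nl <- lin(nb[ok, , drop = FALSE])
      inset <- idmap[nl] > 0
      if (any(inset))
        edges <- rbind(edges, cbind(which(ok)[inset], idmap[nl[inset]]))
    }
    g <- igraph::graph_from_edgelist(
      rbind(edges, cbind(seq_along(sel), seq_along(sel))), directed = FALSE)
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    out[sel] <- out[sel] + sizes^E * h^H * dh
  }
  out
}

# Textbook two-sample equal-variance t per voxel for a labelling g (0/1).
oracle_two_sample_t <- function(Y, g) {
  y1 <- Y[g == 1, , drop = FALSE]; y0 <- Y[g == 0, , drop = FALSE]
  n1 <- nrow(y1); n0 <- nrow(y0)
  m1 <- colMeans(y1); m0 <- colMeans(y0)
  sp2 <- (colSums(sweep(y1, 2, m1)^2) + colSums(sweep(y0, 2, m0)^2)) /
    (n1 + n0 - 2)
  (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# Closed-form OLS slope, explicit loop.
oracle_slope <- function(y, t) {
  tb <- mean(t); yb <- mean(y)
  num <- 0; den <- 0
  for (i in seq_along(t)) {
    num <- num + (t[i] - tb) * (y[i] - yb)
    den <- den + (t[i] - tb)^2
  }
  num / den
}

# Polynomial least squares via lm (independent of the matrix algebra path).
oracle_quadratic <- function(y, t) unname(coef(lm(y ~ t + I(t^2)))[3])

# Small helpers -------------------------------------------------------------

tiny_phantom <- function(seed = 1, noise_sd = 0, bias = 0, n = 24) {
  make_phantom(phantom_spec(grid_shape = rep(n, 3), noise_sd = noise_sd,
                            bias_amplitude = bias, seed = seed))
}

vol_of <- function(arr, vox = c(2, 2, 2)) as_volume(arr, voxel_mm = vox)

ball_mask <- function(dm, centre, radius) {
  g <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1, j = seq_len(dm[2]) - 1,
                             k = seq_len(dm[3]) - 1))
  array(sqrt(rowSums(sweep(g, 2, centre)^2)) <= radius, dm)
}

# Preprocess one subject's visits the way the pipeline does (shared by the
# within-subject and acceptance tests).
preprocess_series <- function(s) {
  lapply(seq_along(s$times), function(vi) {
    img <- s$volumes[[vi]]
    brain <- extract_brain(img)
    thr <- longvbm:::otsu_threshold(img$data[brain$data > 0.5])
    wm <- longvbm:::like_volume(as.numeric(img$data >= thr &
                                             brain$data > 0.5), img)
    filled <- fill_lesions(img, s$lesion_masks[[vi]], wm)
    corr <- suppressMessages(correct_nonuniformity(filled, 2, brain))
    longvbm:::like_volume(corr$data * (brain$data > 0.5), corr)
  })
}
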