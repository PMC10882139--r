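# Independent oracles and small fixture builders used across the suite.
# Deliberately written as plain, slow, per-element code so they share no
# machinery with the package implementations they check.

# brute-force physical-coordinate interpolation of `moving` at the voxel
# centers of `reference` (scalar loop; linear interpolation; fill outside)
oracle_resample <- function(moving, reference, fill = 0) {
  d <- dim(reference$values)
  out <- array(fill, d)
  md <- dim(moving$values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    phys <- reference$origin + (c(i, j, k) - 1) * reference$spacing
    cidx <- (phys - moving$origin) / moving$spacing + 1
    if (any(cidx < 1) || any(cidx > md)) next
    i0 <- min(floor(cidx[1]), md[1] - 1); i0 <- max(i0, 1)
    j0 <- min(floor(cidx[2]), md[2] - 1); j0 <- max(j0, 1)
    k0 <- min(floor(cidx[3]), md[3] - 1); k0 <- max(k0, 1)
    fx <- cidx[1] - i0; fy <- cidx[2] - j0; fz <- cidx[3] - k0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
      acc <- acc + w * moving$values[min(i0 + dx, md[1]),
                                    min(j0 + dy, md[2]),
                                    min(k0 + dz, md[3])]
    }
    out[i, j, k] <- acc
  }
  out
}

# connected components via igraph on the voxel adjacency graph
oracle_components <- function(mask, offsets) {
  d <- dim(mask)
  fg <- which(mask > 0)
  if (!length(fg)) return(list(n = 0L, labels = array(0L, d)))
  pos <- match(seq_len(prod(d)), fg)  # linear index -> fg id or NA
  coords <- arrayInd(fg, d)
  edges <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    cc <- sweep(coords, 2, o, "+")
    ok <- rep(TRUE, nrow(cc))
    for (ax in seq_along(d)) ok <- ok & cc[, ax] >= 1 & cc[, ax] <= d[ax]
    if (!any(ok)) next
    lin <- as.integer((cc[ok, , drop = FALSE] - 1) %*%
                        cumprod(c(1, d[-length(d)]))) + 1L
    nid <- pos[lin]
    src <- which(ok)[!is.na(nid)]
    dst <- nid[!is.na(nid)]
    edges <- c(edges, rbind(src, dst))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)
  lab <- array(0L, d)
  # renumber by smallest linear index for comparability
  first <- tapply(fg, comp$membership, min)
  ord <- rank(first)
  lab[fg] <- as.integer(ord[as.character(comp$membership)])
  list(n = comp$no, labels = lab)
}

offsets_18 <- function() {
  g <- expand.grid(-1:1, -1:1, -1:1)
  g <- g[rowSums(abs(g)) > 0 & rowSums(abs(g)) <= 2, ]
  as.matrix(g)
}

# exact (100th percentile) Hausdorff distance by all-pairs scan over
# boundary-free full foreground point sets, in mm
oracle_hausdorff <- function(a, b, spacing) {
  pa <- which(a > 0, arr.ind = TRUE)
  pb <- which(b > 0, arr.ind = TRUE)
  pa <- sweep(pa, 2, spacing, "*"); pb <- sweep(pb, 2, spacing, "*")
  dmat <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa)))
    dmat[i, ] <- sqrt(colSums((t(pb) - pa[i, ])^2))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# exhaustive two-sided signed-rank p-value by explicit 2^n enumeration
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(NA_real_)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  total <- 2^n
  vals <- numeric(total)
  for (s in 0:(total - 1)) {
    bits <- as.integer(intToBits(s))[1:n]
    vals[s + 1] <- sum(r[bits == 1])
  }
  p_le <- mean(vals <= V + 1e-9)
  p_ge <- mean(vals >= V - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# interior voxels: all 26 neighbors inside the mask
erode26 <- function(m) {
  d <- dim(m)
  er <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- array(0, d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    sh[xs - dx, ys - dy, zs - dz] <- m[xs, ys, zs]
    er <- er * sh
  }
  er
}

# centered sphere phantom on an isotropic-in-plane grid
sphere_case <- function(dims = c(48, 48, 48), spacing = c(2, 2, 3),
                        radius_mm = 14, peak_suv = 8, noise_sd = 0,
                        seed = 1) {
  ctr <- (dims - 1) * spacing / 2
  ph <- generate_phantom(phantom_spec(
    dims = dims, spacing = spacing,
    lesions = list(list(center = ctr, radii = rep(radius_mm, 3),
                        peak_suv = peak_suv)),
    noise = list(kind = if (noise_sd > 0) "gaussian" else "none",
                 sd = noise_sd),
    seed = seed
  ))
  ph
}

ball_mask <- function(dims, spacing, center_mm, radius_mm) {
  d <- dims
  x <- (seq_len(d[1]) - 1) * spacing[1]
  y <- (seq_len(d[2]) - 1) * spacing[2]
  z <- (seq_len(d[3]) - 1) * spacing[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  ((X - center_mm[1])^2 + (Y - center_mm[2])^2 + (Z - center_mm[3])^2 <=
      radius_mm^2) * 1
}

# build a raw_tpdm object directly for post-processing unit tests
mk_raw <- function(values, spacing, n_angles) {
  v <- scalar_volume(values, spacing)
  v$n_angles <- as.integer(n_angles)
  class(v) <- c("raw_tpdm", class(v))
  v
}
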