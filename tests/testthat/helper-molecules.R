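# Shared fixtures built in code.

mk_ring <- function(n, element = "C", order = 1L, hcount = 1L) {
  molecular_graph(rep(element, n), hcounts = hcount,
                  bonds = data.frame(i = seq_len(n),
                                     j = c(seq_len(n)[-1L], 1L),
                                     order = order))
}

benzene_graph <- function() mk_ring(6L, order = 4L)

chain_graph <- function(n, elements = rep("C", n), hcounts = NULL) {
  if (is.null(hcounts)) hcounts <- c(3L, rep(2L, max(n - 2L, 0L)), 3L)[seq_len(n)]
  bonds <- if (n > 1L) data.frame(i = seq_len(n - 1L), j = 2:n, order = 1L)
  molecular_graph(elements, hcounts = hcounts, bonds = bonds)
}

# tramadol-like: ring of 6 + short chain with O and N
druglike_graph <- function() {
  molecular_graph(
    c(rep("C", 6), "C", "O", "N"),
    hcounts = c(rep(1L, 6), 2L, 1L, 2L),
    bonds = data.frame(i = c(1:6, 1L, 7L, 7L),
                       j = c(2:6, 1L, 7L, 8L, 9L),
                       order = c(rep(4L, 6), 1L, 1L, 1L)))
}

hcl_graph <- function() molecular_graph("Cl", charges = 0L, hcounts = 1L)

salt_of <- function(parent, ion = molecular_graph("Cl", charges = -1L)) {
  neighborpref:::graph_union(parent, ion)
}

# simple planar coordinates for an n-ring (bond length 1.5)
ring_coords <- function(n) {
  R <- 1.5 / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(R * cos(ang), R * sin(ang), 0)
}

# independent brute-force fingerprint Tanimoto on raw bit vectors
oracle_tanimoto <- function(bits_a, bits_b) {
  ia <- which(bits_a); ib <- which(bits_b)
  length(intersect(ia, ib)) / length(union(ia, ib))
}

# independent grid-integration oracle for the Gaussian overlap volume
grid_overlap <- function(a, b, spacing = 0.2, padding = 4) {
  all_pts <- rbind(a$centers, b$centers)
  lo <- apply(all_pts, 2L, min) - padding
  hi <- apply(all_pts, 2L, max) + padding
  xs <- seq(lo[1L], hi[1L], by = spacing)
  ys <- seq(lo[2L], hi[2L], by = spacing)
  zs <- seq(lo[3L], hi[3L], by = spacing)
  g <- as.matrix(expand.grid(xs, ys, zs))
  dens <- function(s) {
    d <- rep(0, nrow(g))
    for (k in seq_len(nrow(s$centers))) {
      d2 <- rowSums(sweep(g, 2L, s$centers[k, ])^2)
      d <- d + s$p * exp(-s$alphas[k] * d2)
    }
    d
  }
  sum(dens(a) * dens(b)) * spacing^3
}

random_shape <- function(n_atoms, spread = 1.5) {
  elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
  coords <- matrix(stats::rnorm(3 * n_atoms, sd = spread), n_atoms, 3L)
  build_shape(conformer(coords), radii = unname(neighborpref:::VDW_RADII[elements]))
}

random_rigid_transform <- function(coords) {
  w <- stats::rnorm(3L)
  R <- neighborpref:::rodrigues_matrix(w)
  t <- stats::rnorm(3L, sd = 5)
  sweep(coords %*% t(R), 2L, t, "+")
}

# a small record with one conformer from a graph with planar template coords
record_from_graph <- function(cid, graph, coords, n_conf = 1L, noise = 0,
                              annotations = character()) {
  confs <- lapply(seq_len(n_conf), function(k) {
    conformer(coords + matrix(stats::rnorm(length(coords), sd = noise),
                              nrow(coords), 3L), id = k)
  })
  compound_record(cid, graph, confs, annotations)
}
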