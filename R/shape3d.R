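# Gaussian-shape-overlay 3-D similarity: shape volumes, shape-Tanimoto,
# pharmacophore color features and color-Tanimoto, combo-Tanimoto, and the
# shape-optimized rigid-body superposition.
#
# Parameterization: each heavy atom contributes a spherical Gaussian
# p * exp(-alpha * r^2) with p = 2*sqrt(2) and alpha = kappa / sigma^2,
# kappa = 2.41798793102, so that the Gaussian integrates to the hard-sphere
# volume (4/3) * pi * sigma^3 of its van der Waals radius sigma. Overlap
# volumes use the first-order (pairwise-sum) approximation, i.e. the L2
# inner product of the summed densities; higher-order inclusion-exclusion
# terms are not included.

GAUSS_P <- 2 * sqrt(2)
GAUSS_KAPPA <- 2.41798793102
COLOR_RADIUS <- 1.0
COLOR_TYPES <- c("donor", "acceptor", "cation", "anion", "hydrophobe", "ring")

#' Build a Gaussian shape from a conformer
#'
#' Hydrogen rows (element "H") are excluded: shapes are built from heavy
#' atoms only.
#'
#' @param conf a `conformer`.
#' @param elements character vector of element symbols aligned with the
#'   conformer rows (used for the vdW radius lookup and to drop hydrogens).
#' @param radii optional explicit per-atom radii overriding the lookup.
#' @return an object of class `gaussian_shape` with fields `centers`,
#'   `alphas`, `p` and `vself`.
#' @export
build_shape <- function(conf, elements = NULL, radii = NULL) {
  stopifnot(inherits(conf, "conformer"))
  coords <- conf$coords
  if (is.null(radii)) {
    if (is.null(elements)) stop("either elements or radii must be given")
    stopifnot(length(elements) == nrow(coords))
    keep <- elements != "H"
    coords <- coords[keep, , drop = FALSE]
    radii <- unname(VDW_RADII[elements[keep]])
    if (anyNA(radii)) stop("no vdW radius for element(s): ",
                           paste(unique(elements[keep][is.na(radii)]),
                                 collapse = ", "))
  } else {
    stopifnot(length(radii) == nrow(coords), all(radii > 0))
  }
  if (nrow(coords) == 0L) stop("conformer has no heavy atoms")
  alphas <- GAUSS_KAPPA / radii^2
  shape <- structure(list(centers = coords, alphas = alphas, p = GAUSS_P,
                          vself = NA_real_), class = "gaussian_shape")
  shape$vself <- overlap_volume(shape, shape)
  shape
}

#' @export
print.gaussian_shape <- function(x, ...) {
  cat(sprintf("<gaussian_shape> %d atoms, self-overlap %.3f A^3\n",
              nrow(x$centers), x$vself))
  invisible(x)
}

#' Construct a rigid pose
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return an object of class `pose3d`.
#' @export
pose3d <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(R = rotation, t = as.numeric(translation)), class = "pose3d")
}

#' @rdname pose3d
#' @export
identity_pose <- function() pose3d()

#' Invert a pose
#' @param pose a `pose3d`.
#' @return the inverse `pose3d`.
#' @export
pose_inverse <- function(pose) {
  pose3d(t(pose$R), -as.numeric(t(pose$R) %*% pose$t))
}

apply_pose <- function(coords, pose) {
  sweep(coords %*% t(pose$R), 2L, pose$t, "+")
}

# unit quaternion (w, x, y, z) from a rotation matrix, for pose dumps
rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Overlap volume between two Gaussian shapes
#'
#' First-order pairwise Gaussian overlap; `pose` is applied to shape `b`.
#'
#' @param a,b `gaussian_shape` objects.
#' @param pose a `pose3d` applied to `b` (default identity).
#' @return overlap volume in cubic Angstrom.
#' @export
overlap_volume <- function(a, b, pose = identity_pose()) {
  bx <- apply_pose(b$centers, pose)
  cpp_overlap(a$centers, a$alphas, bx, b$alphas, a$p * b$p)
}

#' Shape-Tanimoto at a fixed pose
#'
#' ST = V_AB / (V_AA + V_BB - V_AB), clipped to [0, 1] against
#' floating-point overshoot.
#'
#' @inheritParams overlap_volume
#' @return similarity in [0, 1].
#' @export
shape_tanimoto <- function(a, b, pose = identity_pose()) {
  vab <- overlap_volume(a, b, pose)
  st <- vab / (a$vself + b$vself - vab)
  min(max(st, 0), 1)
}

#' Assign pharmacophore color atoms
#'
#' Applies the documented typing rule table to a graph/conformer pair:
#' \itemize{
#'   \item donor: N or O bearing at least one hydrogen, at the atom position;
#'   \item acceptor: N or O with formal charge <= 0 and fewer than four
#'     substituents (heavy neighbours plus hydrogens), at the atom position;
#'   \item cation: any atom with formal charge > 0;
#'   \item anion: any atom with formal charge < 0;
#'   \item hydrophobe: carbons with no heteroatom neighbour, merged per
#'     contiguous group at the group centroid;
#'   \item ring: centroid of each basis ring.
#' }
#' All color atoms have radius 1 Angstrom. Feature-less molecules yield an
#' empty set.
#'
#' @param graph a single-component `molecular_graph`.
#' @param conf the matching `conformer`.
#' @return data frame with columns type, x, y, z, radius.
#' @export
assign_color_atoms <- function(graph, conf) {
  stopifnot(nrow(conf$coords) == n_atoms(graph))
  at <- graph$atoms
  xyz <- conf$coords
  out <- list()
  add <- function(type, pos) {
    out[[length(out) + 1L]] <<- data.frame(
      type = type, x = pos[1], y = pos[2], z = pos[3], radius = COLOR_RADIUS,
      stringsAsFactors = FALSE)
  }
  b <- graph$bonds
  deg <- tabulate(c(b$i, b$j), nbins = n_atoms(graph))
  nbr <- function(k) c(b$j[b$i == k], b$i[b$j == k])
  for (k in seq_len(n_atoms(graph))) {
    el <- at$element[k]
    if (el %in% c("N", "O")) {
      if (at$hcount[k] >= 1L) add("donor", xyz[k, ])
      if (at$charge[k] <= 0L && deg[k] + at$hcount[k] < 4L) {
        add("acceptor", xyz[k, ])
      }
    }
    if (at$charge[k] > 0L) add("cation", xyz[k, ])
    if (at$charge[k] < 0L) add("anion", xyz[k, ])
  }
  # hydrophobes: contiguous carbon groups without heteroatom neighbours
  hydro <- which(at$element == "C" & vapply(seq_len(n_atoms(graph)),
    function(k) all(at$element[nbr(k)] %in% c("C", "H")), logical(1)))
  if (length(hydro) > 0L) {
    keep <- b$i %in% hydro & b$j %in% hydro
    gg <- igraph::graph_from_data_frame(
      d = data.frame(i = match(b$i[keep], hydro), j = match(b$j[keep], hydro)),
      directed = FALSE,
      vertices = data.frame(name = seq_along(hydro)))
    mem <- igraph::components(gg)$membership
    for (gidx in unique(mem)) {
      members <- hydro[mem == gidx]
      add("hydrophobe", colMeans(xyz[members, , drop = FALSE]))
    }
  }
  for (ring in ring_atom_sets(graph)) {
    add("ring", colMeans(xyz[ring, , drop = FALSE]))
  }
  if (length(out) == 0L) {
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

color_shape <- function(colors) {
  list(centers = as.matrix(colors[, c("x", "y", "z")]),
       alphas = GAUSS_KAPPA / colors$radius^2)
}

#' Color-Tanimoto at a fixed pose
#'
#' Tanimoto-style ratio over same-type color-atom Gaussian overlaps summed
#' across the six feature types; cross-type overlap is zero by construction.
#' Returns 0 with attribute `degenerate = TRUE` when both feature sets are
#' empty.
#'
#' @param a_colors,b_colors color-atom data frames from
#'   [assign_color_atoms()].
#' @param pose a `pose3d` applied to `b_colors` (default identity).
#' @return similarity in [0, 1].
#' @export
color_tanimoto <- function(a_colors, b_colors, pose = identity_pose()) {
  if (nrow(a_colors) == 0L && nrow(b_colors) == 0L) {
    return(structure(0, degenerate = TRUE))
  }
  p2 <- GAUSS_P^2
  vaa <- vbb <- vab <- 0
  bxyz <- if (nrow(b_colors) > 0L) {
    apply_pose(as.matrix(b_colors[, c("x", "y", "z")]), pose)
  } else matrix(numeric(), 0L, 3L)
  for (f in COLOR_TYPES) {
    ai <- which(a_colors$type == f)
    bi <- which(b_colors$type == f)
    if (length(ai) > 0L) {
      axyz <- as.matrix(a_colors[ai, c("x", "y", "z")])
      aal <- GAUSS_KAPPA / a_colors$radius[ai]^2
      vaa <- vaa + cpp_overlap(axyz, aal, axyz, aal, p2)
    }
    if (length(bi) > 0L) {
      bal <- GAUSS_KAPPA / b_colors$radius[bi]^2
      vbb <- vbb + cpp_overlap(bxyz[bi, , drop = FALSE], bal,
                               bxyz[bi, , drop = FALSE], bal, p2)
    }
    if (length(ai) > 0L && length(bi) > 0L) {
      axyz <- as.matrix(a_colors[ai, c("x", "y", "z")])
      aal <- GAUSS_KAPPA / a_colors$radius[ai]^2
      bal <- GAUSS_KAPPA / b_colors$radius[bi]^2
      vab <- vab + cpp_overlap(axyz, aal, bxyz[bi, , drop = FALSE], bal, p2)
    }
  }
  denom <- vaa + vbb - vab
  if (denom <= 0) return(structure(0, degenerate = TRUE))
  min(max(vab / denom, 0), 1)
}

#' Combo-Tanimoto
#'
#' The sum ST + CT, ranging 0 to 2 without normalization.
#'
#' @param st shape-Tanimoto in [0, 1].
#' @param ct color-Tanimoto in [0, 1].
#' @return combo score in [0, 2].
#' @export
combo_tanimoto <- function(st, ct) {
  if (st < 0 || st > 1 || ct < 0 || ct > 1) {
    stop("st and ct must lie in [0, 1]")
  }
  st + ct
}

# Gaussian-mass weighted centroid and principal frame of a shape.
principal_frame <- function(shape) {
  w <- shape$p * (pi / shape$alphas)^1.5
  ctr <- colSums(shape$centers * w) / sum(w)
  xc <- sweep(shape$centers, 2L, ctr)
  M <- crossprod(xc * w, xc)
  ev <- eigen(M, symmetric = TRUE)
  V <- ev$vectors
  if (det(V) < 0) V[, 3L] <- -V[, 3L]
  list(center = ctr, axes = V, centered = xc %*% V)
}

#' Shape-optimized superposition and similarity scores
#'
#' Maximizes the Gaussian overlap volume between two shapes over rigid
#' poses, starting from the four proper axis-flip combinations of the
#' Gaussian-weighted principal-frame alignment, each refined by a local
#' optimizer (relative overlap tolerance 1e-6, at most 200 iterations;
#' deterministic, no randomness). CT and ComboT are evaluated at the same
#' shape-optimized pose.
#'
#' @param a,b lists with fields `shape` (a `gaussian_shape`) and optionally
#'   `colors` (a color-atom data frame); a bare `gaussian_shape` is also
#'   accepted (empty color set).
#' @return list of class `similarity3d` with fields `st`, `ct`, `combo`,
#'   `pose` (mapping b's original frame onto a's), `conformer_pair` and
#'   `converged`.
#' @export
optimize_st <- function(a, b) {
  wrap <- function(x) {
    if (inherits(x, "gaussian_shape")) {
      list(shape = x, colors = assign_color_atoms_empty())
    } else x
  }
  a <- wrap(a); b <- wrap(b)
  pa <- principal_frame(a$shape)
  pb <- principal_frame(b$shape)
  p2 <- a$shape$p * b$shape$p
  best <- cpp_optimize_overlap4(pa$centered, a$shape$alphas, pb$centered,
                                b$shape$alphas, p2, 200L, 1e-6)
  # pose mapping b's original coordinates into a's original frame
  Rpose <- pa$axes %*% best$R %*% t(pb$axes)
  tpose <- as.numeric(-Rpose %*% pb$center + pa$axes %*% best$t + pa$center)
  # guard against accumulated round-off in the rotation
  sv <- svd(Rpose)
  Rpose <- sv$u %*% t(sv$v)
  pose <- pose3d(Rpose, tpose)
  st <- min(max(best$V / (a$shape$vself + b$shape$vself - best$V), 0), 1)
  ct <- as.numeric(color_tanimoto(a$colors, b$colors, pose))
  structure(list(st = st, ct = ct, combo = st + ct, pose = pose,
                 conformer_pair = c(NA_integer_, NA_integer_),
                 converged = isTRUE(best$converged)),
            class = "similarity3d")
}

assign_color_atoms_empty <- function() {
  data.frame(type = character(), x = numeric(), y = numeric(),
             z = numeric(), radius = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.similarity3d <- function(x, ...) {
  cat(sprintf("<similarity3d> ST %.4f  CT %.4f  ComboT %.4f\n",
              x$st, x$ct, x$combo))
  invisible(x)
}

# Upper bound on the optimum ST from self-overlap volumes alone
# (Cauchy-Schwarz: V_AB <= sqrt(V_AA * V_BB) at any pose).
st_upper_bound <- function(vself_a, vself_b) {
  s <- sqrt(vself_a * vself_b)
  s / (vself_a + vself_b - s)
}

# --- cached fast path used by the neighboring loop -------------------------
# Conformer entries carry the precomputed principal frame, a color matrix
# (centres, alphas, integer type codes) and the summed same-type color
# self-overlap, so the per-pair work reduces to one C++ optimization plus,
# only for ST-qualifying pairs, the cross color overlaps.

color_matrix <- function(colors) {
  list(centers = as.matrix(colors[, c("x", "y", "z"), drop = FALSE]),
       alphas = GAUSS_KAPPA / colors$radius^2,
       type = match(colors$type, COLOR_TYPES),
       n = nrow(colors))
}

color_self_total <- function(cm) {
  p2 <- GAUSS_P^2
  total <- 0
  for (f in unique(cm$type)) {
    sel <- cm$type == f
    total <- total + cpp_overlap(cm$centers[sel, , drop = FALSE],
                                 cm$alphas[sel],
                                 cm$centers[sel, , drop = FALSE],
                                 cm$alphas[sel], p2)
  }
  total
}

# CT between two precomputed color matrices, with b's centres already posed
color_tanimoto_cm <- function(cma, cmb, b_centers_posed) {
  if (cma$n == 0L && cmb$n == 0L) return(structure(0, degenerate = TRUE))
  p2 <- GAUSS_P^2
  vab <- 0
  for (f in intersect(unique(cma$type), unique(cmb$type))) {
    sa <- cma$type == f; sb <- cmb$type == f
    vab <- vab + cpp_overlap(cma$centers[sa, , drop = FALSE], cma$alphas[sa],
                             b_centers_posed[sb, , drop = FALSE],
                             cmb$alphas[sb], p2)
  }
  denom <- cma$self + cmb$self - vab
  if (denom <= 0) return(structure(0, degenerate = TRUE))
  min(max(vab / denom, 0), 1)
}

# best rigid superposition between two cached conformer entries; returns the
# similarity only when both thresholds are met (NULL otherwise, with the CT
# evaluation skipped whenever ST already fails)
pair_similarity_fast <- function(ea, eb, st_min = -Inf, ct_min = -Inf) {
  best <- cpp_optimize_overlap4(ea$pf$centered, ea$shape$alphas,
                                eb$pf$centered, eb$shape$alphas,
                                ea$shape$p * eb$shape$p, 200L, 1e-6)
  st <- min(max(best$V / (ea$shape$vself + eb$shape$vself - best$V), 0), 1)
  if (st < st_min) return(NULL)
  Rpose <- ea$pf$axes %*% best$R %*% t(eb$pf$axes)
  tpose <- as.numeric(-Rpose %*% eb$pf$center + ea$pf$axes %*% best$t +
                        ea$pf$center)
  bc <- if (eb$cm$n > 0L) {
    sweep(eb$cm$centers %*% t(Rpose), 2L, tpose, "+")
  } else eb$cm$centers
  ct <- as.numeric(color_tanimoto_cm(ea$cm, eb$cm, bc))
  if (ct < ct_min) return(NULL)
  list(st = st, ct = ct, combo = st + ct)
}

#' Diverse conformer ordering
#'
#' Greedy maximin ordering on the (1 - ST) distance: the first conformer of
#' the input keeps its place; each subsequent pick maximizes the minimum
#' (1 - ST) distance to the conformers already chosen, ties broken by
#' conformer id.
#'
#' @param conformers list of `conformer` objects.
#' @param elements element symbols aligned with conformer rows (for shapes).
#' @return the reordered list of conformers.
#' @export
diverse_order <- function(conformers, elements) {
  n <- length(conformers)
  if (n == 0L) stop("at least one conformer required")
  if (n == 1L) return(conformers)
  shapes <- lapply(conformers, build_shape, elements = elements)
  frames <- lapply(shapes, principal_frame)
  ids <- vapply(conformers, function(cf) cf$id, integer(1))
  st <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- cpp_optimize_overlap4(frames[[i]]$centered, shapes[[i]]$alphas,
                                 frames[[j]]$centered, shapes[[j]]$alphas,
                                 shapes[[i]]$p * shapes[[j]]$p, 200L, 1e-6)$V
      st[i, j] <- st[j, i] <-
        min(max(v / (shapes[[i]]$vself + shapes[[j]]$vself - v), 0), 1)
    }
  }
  dist <- 1 - st
  chosen <- 1L
  remaining <- setdiff(seq_len(n), chosen)
  while (length(remaining) > 0L) {
    mind <- vapply(remaining, function(k) min(dist[k, chosen]), numeric(1))
    # maximize min distance; ties broken by conformer id
    best <- remaining[order(-mind, ids[remaining])][1L]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  conformers[chosen]
}
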