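# Seeded generator of compound populations with planted 2-D/3-D similarity
# cluster structure, salt forms, and nested annotation subsets.
#
# Populations are unions of clusters of three kinds:
#   * "common": members share one graph and one template geometry (plus
#     coordinate noise), so every within-cluster pair is both a 2-D and a
#     3-D neighbour;
#   * "2d_only": members share one graph (fingerprint Tanimoto 1) but each
#     member gets its own divergent random fold, so no within-cluster pair
#     is a 3-D neighbour;
#   * "3d_only": members share one skeleton geometry but carry different
#     heteroatom/bond-order decorations at fixed feature slots, so
#     fingerprints fall below the 2-D threshold while shape and feature
#     layout stay nearly identical.
# Scenario = mixing weight over cluster kinds: identical -> all common;
# disjoint -> no common (alternating 2d_only/3d_only); overlapping/mixed ->
# intermediate weights.
#
# Cluster templates sit on a geometric size ladder (heavy-atom counts
# spaced by a factor of about 1.35) so that cross-cluster pairs are neither
# 2-D nor 3-D neighbours. Geometry is template-based (rings as regular
# polygons, zig-zag chains, terminal decorations) with Gaussian coordinate
# noise; chains are kept short enough that every generated structure stays
# conformer-eligible (<= 15 rotatable bonds, <= 50 heavy atoms).

#' Scenario configuration for the synthetic population generator
#'
#' @param scenario one of "identical", "overlapping", "disjoint", "mixed".
#' @param n_compounds number of parent compounds to generate.
#' @param n_clusters number of planted clusters (2 to 8).
#' @param conformers_per_compound conformers generated per compound.
#' @param geometric_noise Gaussian coordinate noise sigma in Angstrom.
#' @param decoration_rate probability that a member of a "common" or
#'   "2d_only" cluster receives one extra terminal heteroatom (a key flip
#'   loosening exact 2-D identity); 0 keeps clusters fingerprint-identical.
#' @param salt_fraction fraction of compounds that additionally emit a
#'   multi-component salt form.
#' @param mixing_weight fraction of clusters of kind "common"; defaults by
#'   scenario (identical 1, overlapping 0.7, mixed 0.4, disjoint 0).
#' @param subset_fractions named fractions for the mesh, protein3d,
#'   pharmact and drug annotation subsets (pharmact must not exceed mesh).
#' @param drug_enrichment cluster-enrichment weight (> 1 makes the drug
#'   subset preferentially absorb whole clusters).
#' @param seed mandatory integer seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("identical", "overlapping",
                                         "disjoint", "mixed"),
                            n_compounds = 60L, n_clusters = 6L,
                            conformers_per_compound = 5L,
                            geometric_noise = 0.1, decoration_rate = 0,
                            salt_fraction = 0, mixing_weight = NULL,
                            subset_fractions = c(mesh = 0.5, protein3d = 0.3,
                                                 pharmact = 0.25, drug = 0.2),
                            drug_enrichment = 3, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(mixing_weight)) {
    mixing_weight <- switch(scenario, identical = 1, overlapping = 0.7,
                            mixed = 0.4, disjoint = 0)
  }
  if (n_clusters < 2L || n_clusters > 8L) {
    stop("n_clusters must be between 2 and 8")
  }
  if (n_clusters > n_compounds) stop("more clusters than compounds")
  sf <- subset_fractions
  if (any(sf < 0 | sf > 1)) stop("subset fractions must lie in [0, 1]")
  if (sf[["pharmact"]] > sf[["mesh"]]) {
    stop("pharmact fraction must not exceed mesh fraction (nesting)")
  }
  if (salt_fraction < 0 || salt_fraction > 1 ||
      decoration_rate < 0 || decoration_rate > 1 ||
      mixing_weight < 0 || mixing_weight > 1) {
    stop("fractions must lie in [0, 1]")
  }
  structure(list(scenario = scenario, n_compounds = as.integer(n_compounds),
                 n_clusters = as.integer(n_clusters),
                 conformers_per_compound = as.integer(conformers_per_compound),
                 geometric_noise = geometric_noise,
                 decoration_rate = decoration_rate,
                 salt_fraction = salt_fraction,
                 mixing_weight = mixing_weight,
                 subset_fractions = sf,
                 drug_enrichment = drug_enrichment,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# single global seed fans out to per-stage child seeds
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 1000003) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Heavy-atom budget ladders: (ring, chain, terminals) per within-kind
# cluster index. "common" clusters (shared graph AND shared geometry) sit on
# a steep size ladder so cross-cluster pairs are neither 2-D nor 3-D
# neighbours. "2d_only" clusters use long flexible chains whose per-member
# random folds diverge in shape. "3d_only" clusters use compact rigid
# scaffolds with fixed feature slots.
SCAFFOLD_PLANS <- list(
  common = list(
    c(5L, 2L, 0L),   #  7 atoms
    c(6L, 3L, 1L),   # 10
    c(6L, 4L, 4L),   # 14
    c(7L, 5L, 7L),   # 19
    c(7L, 6L, 12L),  # 25
    c(8L, 7L, 18L),  # 33
    c(9L, 8L, 24L),  # 41
    c(10L, 8L, 30L)),# 48
  "2d_only" = list(
    c(3L, 10L, 0L),  # 13
    c(4L, 12L, 1L),  # 17
    c(5L, 13L, 6L),  # 24
    c(6L, 14L, 14L)),# 34
  "3d_only" = list(
    c(6L, 4L, 0L),   # 10
    c(7L, 5L, 5L),   # 17
    c(9L, 6L, 14L),  # 29
    c(10L, 7L, 26L)))# 43

# cluster-level signature element (no pharmacophore features of its own)
# breaking the near-nesting of fingerprints between clusters of different
# sizes; indexed by within-kind cluster position
SIGNATURE_ELEMENTS <- c("C", "S", "P", "Si", "F", "Cl", "Br", "I")

# members of one 3d_only cluster carry pairwise-distinct decorations drawn
# from a 3 x 3 variant grid, capping those clusters at 9 members
MAX_3D_CLUSTER <- 9L

# Deterministic scaffold: ring (regular polygon, bond length 1.5 A) fused to
# a zig-zag chain carrying terminal decorations. Heteroatom slots depend on
# the cluster kind. Returns graph, template coordinates and slot indices.
build_scaffold <- function(g, kind, kind_index) {
  plans <- SCAFFOLD_PLANS[[kind]]
  if (kind_index > length(plans)) {
    stop("too many clusters of kind '", kind, "' (at most ",
         length(plans), ")")
  }
  plan <- plans[[kind_index]]
  r <- plan[1L]; cl <- plan[2L]; tn <- plan[3L]
  n <- r + cl + tn
  ring_idx <- seq_len(r)
  chain_idx <- r + seq_len(cl)
  elements <- rep("C", n)
  hcount <- rep(1L, n)
  # ring bonds (incl. closure) + ring-chain attachment
  bonds <- data.frame(i = ring_idx, j = c(ring_idx[-1L], ring_idx[1L]),
                      order = 1L)
  if (cl > 0L) {
    bonds <- rbind(bonds, data.frame(i = r, j = r + 1L, order = 1L))
  }
  if (cl > 1L) {
    bonds <- rbind(bonds, data.frame(i = chain_idx[-cl], j = chain_idx[-1L],
                                     order = 1L))
  }
  # terminal decorations: up to two per backbone atom, outward from chain end
  backbone <- c(rev(chain_idx), rev(ring_idx))
  hosts <- rep(backbone, each = 2L)[seq_len(tn)]
  if (tn > 0L) {
    bonds <- rbind(bonds, data.frame(i = hosts, j = r + cl + seq_len(tn),
                                     order = 1L))
  }
  # template geometry
  coords <- matrix(0, n, 3L)
  Rring <- 1.5 / (2 * sin(pi / r))
  ang <- 2 * pi * (ring_idx - 1L) / r
  coords[ring_idx, ] <- cbind(Rring * cos(ang), Rring * sin(ang), 0)
  if (cl > 0L) {
    # chain leaves ring atom r along +x with a cluster-specific kink
    base <- coords[r, ]
    kink <- 0.25 + 0.1 * g
    for (k in seq_len(cl)) {
      coords[r + k, ] <- base + c(1.35 * k, 0.6 * sin(kink * k),
                                  0.5 * ((k %% 2L) * 2L - 1L))
    }
  }
  if (tn > 0L) {
    slot <- integer(n) # decorations placed alternately above/below host
    for (t in seq_len(tn)) {
      h <- hosts[t]
      slot[h] <- slot[h] + 1L
      dirz <- if (slot[h] == 1L) 1.4 else -1.4
      coords[r + cl + t, ] <- coords[h, ] + c(0.5 * slot[h], 0.5, dirz)
    }
  }
  # heteroatom slots
  hetero_slots <- list()
  if (kind == "3d_only") {
    # two adjacent chain positions and two adjacent ring positions
    hetero_slots <- list(chain = chain_idx[c(2L, 3L)],
                         ring = ring_idx[c(2L, 3L)])
    # cluster signature: feature-less element at ring position 5 and an
    # aromatic ring for every second cluster
    elements[ring_idx[5L]] <- SIGNATURE_ELEMENTS[kind_index]
    if (kind_index %% 2L == 0L) {
      bonds$order[seq_len(r)] <- 4L
    }
  } else if (kind == "2d_only") {
    # cluster signature on the first chain atom
    elements[chain_idx[1L]] <- SIGNATURE_ELEMENTS[kind_index + 1L]
    if (g %% 3L == 1L && cl >= 2L) {
      elements[chain_idx[2L]] <- "O"
    } else if (g %% 3L == 2L) {
      elements[ring_idx[2L]] <- "N"
    }
  } else {
    # give each cluster a distinct fixed heteroatom pattern for extra
    # fingerprint separation between clusters
    if (g %% 3L == 1L && cl >= 2L) {
      elements[chain_idx[2L]] <- "O"
    } else if (g %% 3L == 2L) {
      elements[ring_idx[2L]] <- "N"
    } # g %% 3 == 0: all-carbon
  }
  list(graph_elements = elements, hcount = hcount, bonds = bonds,
       coords = coords, ring_idx = ring_idx, chain_idx = chain_idx,
       hetero_slots = hetero_slots, n = n)
}

scaffold_graph <- function(sc) {
  molecular_graph(sc$graph_elements, charges = 0L, hcounts = sc$hcount,
                  bonds = sc$bonds)
}

# decoration variants for "3d_only" clusters: heteroatom identities on the
# two adjacent slot pairs (unordered {N,O} multisets: NN, NO, OO per pair)
# -> 9 distinct graphs, all with donor+acceptor features at identical
# positions so within-cluster CT stays near 1 while fingerprints diverge.
variant_graph <- function(sc, v) {
  pairs <- list(c("N", "N"), c("N", "O"), c("O", "O"))
  combos <- expand.grid(chain = 1:3, ring = 1:3)
  if (v > nrow(combos)) stop("3d_only cluster size exceeds ", nrow(combos),
                             " decoration variants")
  cb <- combos[v, ]
  el <- sc$graph_elements
  el[sc$hetero_slots$chain] <- pairs[[cb$chain]]
  el[sc$hetero_slots$ring] <- pairs[[cb$ring]]
  # per-variant feature-less marker element on the fourth chain atom widens
  # the fingerprint distance between variants without moving any color atom
  variant_palette <- c("C", "F", "Si", "P", "S", "Cl", "Br", "I", "C")
  el[sc$chain_idx[4L]] <- variant_palette[v]
  hc <- sc$hcount
  hc[c(sc$hetero_slots$chain, sc$hetero_slots$ring)] <- 1L
  molecular_graph(el, charges = 0L, hcounts = hc, bonds = sc$bonds)
}

# divergent per-member geometry for "2d_only" clusters: ring kept as a
# polygon in a random orientation, chain re-grown as a random kinked walk,
# terminals offset from their hosts in random directions
random_fold <- function(sc) {
  n <- sc$n
  coords <- matrix(0, n, 3L)
  r <- length(sc$ring_idx); cl <- length(sc$chain_idx)
  Rring <- 1.5 / (2 * sin(pi / r))
  ang <- 2 * pi * (seq_len(r) - 1L) / r
  ring_flat <- cbind(Rring * cos(ang), Rring * sin(ang), 0)
  rot <- random_rotation()
  coords[sc$ring_idx, ] <- ring_flat %*% t(rot)
  if (cl > 0L) {
    pos <- coords[r, ]
    dir <- rot %*% c(1, 0, 0)
    for (k in seq_len(cl)) {
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      theta <- stats::runif(1, pi / 4, 2 * pi / 3)
      dir <- rotate_about(dir, axis, theta)
      pos <- pos + 1.5 * as.numeric(dir)
      coords[r + k, ] <- pos
    }
  }
  tn <- n - r - cl
  if (tn > 0L) {
    backbone <- c(rev(sc$chain_idx), rev(sc$ring_idx))
    hosts <- rep(backbone, each = 2L)[seq_len(tn)]
    for (t in seq_len(tn)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      coords[r + cl + t, ] <- coords[hosts[t], ] + 1.5 * u
    }
  }
  coords
}

random_rotation <- function() {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  theta <- stats::runif(1, 0, 2 * pi)
  rodrigues_matrix(axis * theta)
}

rodrigues_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-14) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotate_about <- function(v, axis, theta) {
  rodrigues_matrix(axis * theta) %*% as.numeric(v)
}

cluster_kinds <- function(config) {
  k <- config$n_clusters
  n_common <- round(config$mixing_weight * k)
  kinds <- rep("common", k)
  if (n_common < k) {
    rest <- k - n_common
    kinds[(n_common + 1L):k] <- rep(c("2d_only", "3d_only"),
                                    length.out = rest)
  }
  kinds
}

#' Generate a synthetic compound population
#'
#' Builds a series "A" dataset of `n_compounds` compounds in `n_clusters`
#' planted clusters whose 2-D/3-D similarity structure follows the
#' configured scenario, assigns nested annotation subsets, and (for
#' `salt_fraction > 0`) appends multi-component salt forms. Deterministic
#' given the config seed.
#'
#' @param config a `scenario_config`.
#' @return a `compound_dataset` (series "A") with attribute `clusters`
#'   (data frame: cid, cluster, kind).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_compounds
  k <- config$n_clusters
  sizes <- rep(n %/% k, k)
  if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  kinds <- cluster_kinds(config)
  # 3d_only clusters are capped by their decoration-variant space; excess
  # members are redistributed to the other clusters
  is3d <- kinds == "3d_only"
  excess <- sum(pmax(sizes[is3d] - MAX_3D_CLUSTER, 0L))
  sizes[is3d] <- pmin(sizes[is3d], MAX_3D_CLUSTER)
  if (excess > 0L) {
    host <- which(!is3d)
    if (length(host) == 0L) {
      stop("population too large: all clusters are 3d_only and capped at ",
           MAX_3D_CLUSTER, " members")
    }
    add <- rep(excess %/% length(host), length(host))
    if (excess %% length(host) > 0L) {
      add[seq_len(excess %% length(host))] <-
        add[seq_len(excess %% length(host))] + 1L
    }
    sizes[host] <- sizes[host] + add
  }
  kind_index <- stats::ave(seq_len(k), kinds, FUN = seq_along)
  records <- list()
  clusters <- list()
  cid <- 0L
  with_seed(child_seed(config$seed, 1L), {
    for (g in seq_len(k)) {
      sc <- build_scaffold(g, kinds[g], kind_index[g])
      base_graph <- if (kinds[g] == "3d_only") NULL else scaffold_graph(sc)
      for (m in seq_len(sizes[g])) {
        cid <- cid + 1L
        graph <- switch(kinds[g],
          common = base_graph,
          "2d_only" = base_graph,
          "3d_only" = variant_graph(sc, m))
        coords0 <- switch(kinds[g],
          common = sc$coords,
          "3d_only" = sc$coords,
          "2d_only" = random_fold(sc))
        if (config$decoration_rate > 0 && kinds[g] != "3d_only" &&
            stats::runif(1) < config$decoration_rate) {
          host <- sample(sc$n, 1L)
          graph <- decorate_graph(graph, host)
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          coords0 <- rbind(coords0, coords0[host, ] + 1.5 * u)
        }
        confs <- lapply(seq_len(config$conformers_per_compound), function(ci) {
          noise <- matrix(stats::rnorm(length(coords0),
                                       sd = config$geometric_noise),
                          nrow(coords0), 3L)
          conformer(coords0 + noise, id = ci)
        })
        records[[cid]] <- compound_record(cid, graph, confs)
        clusters[[cid]] <- data.frame(cid = cid, cluster = g, kind = kinds[g])
      }
    }
  })
  dataset <- compound_dataset(paste0("synthetic-", config$scenario), "A",
                              records)
  attr(dataset, "clusters") <- do.call(rbind, clusters)
  dataset <- assign_subsets(dataset, config)
  if (config$salt_fraction > 0) {
    dataset <- append_salt_forms(dataset, config)
  }
  attr(dataset, "config") <- config
  dataset
}

decorate_graph <- function(graph, host) {
  at <- graph$atoms
  molecular_graph(c(at$element, "O"), c(at$charge, 0L), c(at$hcount, 1L),
                  bonds = rbind(graph$bonds[, c("i", "j", "order")],
                                data.frame(i = host, j = nrow(at) + 1L,
                                           order = 1L)))
}

#' Assign nested annotation subsets
#'
#' Samples mesh, protein3d, pharmact and drug labels at the configured
#' fractions with pharmact nested inside mesh. The drug subset samples
#' cluster-preferentially: compounds whose cluster already holds a drug
#' member are `drug_enrichment` times as likely to be drawn next, mimicking
#' analogue-series enrichment of curated drug sets.
#'
#' @param dataset a `compound_dataset` with a `clusters` attribute.
#' @param config a `scenario_config`.
#' @return the dataset with per-record annotation labels replaced.
#' @export
assign_subsets <- function(dataset, config) {
  sf <- config$subset_fractions
  cids <- dataset_cids(dataset)
  n <- length(cids)
  cl_map <- attr(dataset, "clusters")
  cluster_of <- if (!is.null(cl_map)) {
    cl_map$cluster[match(cids, cl_map$cid)]
  } else rep(1L, n)
  labels <- with_seed(child_seed(config$seed, 2L), {
    mesh <- sort(sample(n, round(sf[["mesh"]] * n)))
    pharm <- if (length(mesh) > 0L) {
      sort(sample(mesh, min(length(mesh), round(sf[["pharmact"]] * n))))
    } else integer()
    prot <- sort(sample(n, round(sf[["protein3d"]] * n)))
    n_drug <- round(sf[["drug"]] * n)
    drug <- integer()
    while (length(drug) < n_drug) {
      avail <- setdiff(seq_len(n), drug)
      w <- ifelse(cluster_of[avail] %in% cluster_of[drug],
                  config$drug_enrichment, 1)
      drug <- c(drug, avail[sample.int(length(avail), 1L, prob = w)])
    }
    list(mesh = mesh, pharmact = pharm, protein3d = prot, drug = sort(drug))
  })
  records <- dataset$records
  for (idx in seq_len(n)) {
    ann <- c("mesh"[idx %in% labels$mesh],
             "pharmact"[idx %in% labels$pharmact],
             "protein3d"[idx %in% labels$protein3d],
             "drug"[idx %in% labels$drug])
    records[[idx]]$annotations <- sort(ann)
  }
  out <- compound_dataset(dataset$name, dataset$series, records)
  attr(out, "clusters") <- cl_map
  out
}

#' Default counter-ion library for salt-form generation
#'
#' Small ions of at most three heavy atoms used to build multi-component
#' salt/mixture records.
#'
#' @return named list of `molecular_graph` objects.
#' @export
default_counter_ions <- function() {
  list(
    chloride = molecular_graph("Cl", charges = -1L, hcounts = 0L),
    bromide = molecular_graph("Br", charges = -1L, hcounts = 0L),
    ammonium = molecular_graph("N", charges = 1L, hcounts = 4L),
    sodium = molecular_graph("Na", charges = 1L, hcounts = 0L),
    nitrite = molecular_graph(c("N", "O", "O"), charges = c(0L, 0L, -1L),
                              hcounts = 0L,
                              bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L),
                                                 order = c(2L, 1L)))
  )
}

#' Generate salt/mixture forms of a parent record
#'
#' Emits multi-component variants (parent graph plus one small counter-ion)
#' with fresh cids and copied annotations. Salt forms carry no conformers,
#' reproducing the 2-D neighboring bias of salt records.
#'
#' @param record a single-component `compound_record`.
#' @param counter_ions named list of counter-ion graphs.
#' @param n_forms number of salt forms to emit (distinct ions, cycled).
#' @param seed integer seed choosing the ions.
#' @param next_cid first cid to assign to the new records.
#' @return list of multi-component `compound_record` objects.
#' @export
make_salt_forms <- function(record, counter_ions = default_counter_ions(),
                            n_forms = 1L, seed, next_cid) {
  if (length(enumerate_components(record$graph)) != 1L) {
    stop("salt forms are generated from single-component records")
  }
  picks <- with_seed(seed, sample(length(counter_ions),
                                  n_forms, replace = n_forms > length(counter_ions)))
  lapply(seq_len(n_forms), function(f) {
    ion <- counter_ions[[picks[f]]]
    compound_record(next_cid + f - 1L, graph_union(record$graph, ion),
                    conformers = list(), annotations = record$annotations)
  })
}

graph_union <- function(g1, g2) {
  off <- n_atoms(g1)
  b2 <- g2$bonds
  if (nrow(b2) > 0L) { b2$i <- b2$i + off; b2$j <- b2$j + off }
  molecular_graph(c(g1$atoms$element, g2$atoms$element),
                  c(g1$atoms$charge, g2$atoms$charge),
                  c(g1$atoms$hcount, g2$atoms$hcount),
                  bonds = rbind(g1$bonds[, c("i", "j", "order")], b2[, c("i", "j", "order")]))
}

append_salt_forms <- function(dataset, config) {
  cids <- dataset_cids(dataset)
  n <- length(cids)
  n_salt <- round(config$salt_fraction * n)
  if (n_salt == 0L) return(dataset)
  cl_map <- attr(dataset, "clusters")
  records <- dataset$records
  with_seed(child_seed(config$seed, 3L), {
    hosts <- sort(sample(n, n_salt))
    next_cid <- max(cids) + 1L
    for (h in hosts) {
      salt <- make_salt_forms(records[[h]],
                              seed = stats::runif(1) * 1e6,
                              next_cid = next_cid)[[1L]]
      records[[length(records) + 1L]] <- salt
      if (!is.null(cl_map)) {
        cl_map <- rbind(cl_map,
                        data.frame(cid = salt$cid,
                                   cluster = cl_map$cluster[match(cids[h], cl_map$cid)],
                                   kind = "salt"))
      }
      next_cid <- next_cid + 1L
    }
  })
  out <- compound_dataset(dataset$name, "A", records)
  attr(out, "clusters") <- cl_map
  out
}
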