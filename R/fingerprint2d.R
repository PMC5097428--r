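# Substructure-key binary fingerprints and 2-D Tanimoto scoring.
#
# The built-in key catalog is a documented, versioned, simplified analogue of
# the classic substructure-key classes (element counts at thresholds, ring
# counts by size, bonded-element pairs by bond order, atom-environment keys).
# The bit vector reserves 881 positions to mirror the classic sectioning; the
# defined keys occupy a leading prefix and the remaining positions are always
# zero. It is NOT bit-compatible with any external fingerprint system;
# externally computed fingerprints may be imported instead (see
# read_fingerprints()).

FP_LENGTH <- 881L
CATALOG_VERSION <- "npref-simple-1"

FP_HEAVY_ELEMENTS <- c("C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
FP_COUNT_THRESHOLDS <- c(1L, 2L, 3L, 4L, 8L, 16L)
FP_H_THRESHOLDS <- c(1L, 2L, 4L, 8L, 16L, 32L)
FP_RING_SIZES <- 3:10
FP_ORDER_NAMES <- c("1" = "single", "2" = "double", "3" = "triple",
                    "4" = "aromatic")

fp_element_pairs <- function() {
  pairs <- t(utils::combn(FP_HEAVY_ELEMENTS, 2L))
  pairs <- rbind(pairs, cbind(FP_HEAVY_ELEMENTS, FP_HEAVY_ELEMENTS))
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' The built-in substructure key catalog
#'
#' Returns the ordered key definitions of the built-in catalog as a data
#' frame with columns `bit` and `key`. The catalog is deterministic and
#' stereo-blind by construction.
#'
#' @return data frame describing each defined bit.
#' @export
key_catalog <- function() {
  keys <- character()
  for (e in FP_HEAVY_ELEMENTS) {
    keys <- c(keys, sprintf("count:%s>=%d", e, FP_COUNT_THRESHOLDS))
  }
  keys <- c(keys, sprintf("count:H>=%d", FP_H_THRESHOLDS))
  for (s in FP_RING_SIZES) {
    keys <- c(keys, sprintf("ring:%d>=1", s), sprintf("ring:%d>=2", s))
  }
  pairs <- fp_element_pairs()
  for (k in seq_len(nrow(pairs))) {
    keys <- c(keys, sprintf("bond:%s-%s:%s", pairs[k, 1L], pairs[k, 2L],
                            FP_ORDER_NAMES))
  }
  # ring-system composition: element present in a ring; element pair bonded
  # within a ring (any order)
  keys <- c(keys, sprintf("inring:%s", FP_HEAVY_ELEMENTS))
  keys <- c(keys, sprintf("ringbond:%s-%s", pairs[, 1L], pairs[, 2L]))
  for (e in FP_HEAVY_ELEMENTS) {
    keys <- c(keys, sprintf("env:%s:deg>=%d", e, 1:4),
              sprintf("env:%s:hasH", e),
              sprintf("env:%s:charge>0", e),
              sprintf("env:%s:charge<0", e))
  }
  data.frame(bit = seq_along(keys), key = keys, stringsAsFactors = FALSE)
}

# Ring sizes from a cycle-space basis (fundamental cycles of a spanning
# forest, each closed through shortest tree paths): adequate for the simple
# mono- and bicyclic scaffolds this package generates and analyses.
ring_sizes <- function(graph) {
  vapply(ring_atom_sets(graph), length, integer(1))
}

# Returns a list of atom-index vectors, one per basis ring.
ring_atom_sets <- function(graph) {
  b <- graph$bonds
  if (nrow(b) == 0L) return(list())
  g <- as_igraph(graph)
  gmst <- igraph::mst(g)
  mst_ends <- igraph::as_edgelist(gmst, names = TRUE)
  mst_keys <- paste(pmin(as.integer(mst_ends[, 1]), as.integer(mst_ends[, 2])),
                    pmax(as.integer(mst_ends[, 1]), as.integer(mst_ends[, 2])))
  in_mst <- paste(b$i, b$j) %in% mst_keys
  rings <- list()
  for (eid in which(!in_mst)) {
    path <- suppressWarnings(
      igraph::shortest_paths(gmst, from = as.character(b$i[eid]),
                             to = as.character(b$j[eid]),
                             output = "vpath")$vpath[[1]]
    )
    if (length(path) < 3L) next
    rings[[length(rings) + 1L]] <- as.integer(igraph::V(gmst)$name[as.integer(path)])
  }
  rings
}

#' Compute the substructure-key fingerprint of a molecular graph
#'
#' Deterministic and stereo-blind: stereo flags on bonds are ignored, so
#' stereoisomers with identical connectivity yield bit-identical
#' fingerprints.
#'
#' @param graph a single-component `molecular_graph`.
#' @return an object of class `fingerprint` (logical bit vector plus
#'   `length` and `catalog_version` fields).
#' @export
compute_keys <- function(graph) {
  if (length(enumerate_components(graph)) > 1L) {
    stop("multi-component graph: fingerprint the parent component instead")
  }
  bits <- logical(FP_LENGTH)
  pos <- 0L
  el <- graph$atoms$element
  for (e in FP_HEAVY_ELEMENTS) {
    cnt <- sum(el == e)
    bits[pos + seq_along(FP_COUNT_THRESHOLDS)] <- cnt >= FP_COUNT_THRESHOLDS
    pos <- pos + length(FP_COUNT_THRESHOLDS)
  }
  nh <- sum(graph$atoms$hcount) + sum(el == "H")
  bits[pos + seq_along(FP_H_THRESHOLDS)] <- nh >= FP_H_THRESHOLDS
  pos <- pos + length(FP_H_THRESHOLDS)
  rs <- ring_sizes(graph)
  for (s in FP_RING_SIZES) {
    bits[pos + 1L] <- sum(rs == s) >= 1L
    bits[pos + 2L] <- sum(rs == s) >= 2L
    pos <- pos + 2L
  }
  pairs <- fp_element_pairs()
  b <- graph$bonds
  if (nrow(b) > 0L) {
    e1 <- el[b$i]; e2 <- el[b$j]
    blo <- pmin(e1, e2); bhi <- pmax(e1, e2)
    seen <- unique(paste(blo, bhi, b$order, sep = ":"))
  } else seen <- character()
  for (k in seq_len(nrow(pairs))) {
    for (o in 1:4) {
      bits[pos + 1L] <- paste(pairs[k, 1L], pairs[k, 2L], o, sep = ":") %in% seen
      pos <- pos + 1L
    }
  }
  ring_atoms <- unique(unlist(ring_atom_sets(graph)))
  for (e in FP_HEAVY_ELEMENTS) {
    bits[pos + 1L] <- e %in% el[ring_atoms]
    pos <- pos + 1L
  }
  ring_bond_seen <- character()
  if (nrow(b) > 0L && length(ring_atoms) > 0L) {
    g <- as_igraph(graph)
    bridge_ids <- as.integer(igraph::bridges(g))
    inring_bond <- setdiff(seq_len(nrow(b)), bridge_ids)
    if (length(inring_bond) > 0L) {
      r1 <- el[b$i[inring_bond]]; r2 <- el[b$j[inring_bond]]
      ring_bond_seen <- unique(paste(pmin(r1, r2), pmax(r1, r2)))
    }
  }
  for (k in seq_len(nrow(pairs))) {
    bits[pos + 1L] <- paste(pairs[k, 1L], pairs[k, 2L]) %in% ring_bond_seen
    pos <- pos + 1L
  }
  deg <- tabulate(c(b$i, b$j), nbins = n_atoms(graph))
  for (e in FP_HEAVY_ELEMENTS) {
    sel <- el == e
    dmax <- if (any(sel)) max(deg[sel]) else 0L
    bits[pos + 1:4] <- dmax >= 1:4
    pos <- pos + 4L
    bits[pos + 1L] <- any(sel & graph$atoms$hcount >= 1L); pos <- pos + 1L
    bits[pos + 1L] <- any(sel & graph$atoms$charge > 0L); pos <- pos + 1L
    bits[pos + 1L] <- any(sel & graph$atoms$charge < 0L); pos <- pos + 1L
  }
  fingerprint(bits)
}

#' Construct a fingerprint object
#'
#' @param bits logical vector of length at most 881 (padded with zeros).
#' @param catalog_version catalog identifier; fingerprints are comparable
#'   only within one catalog version and length.
#' @return an object of class `fingerprint`.
#' @export
fingerprint <- function(bits, catalog_version = CATALOG_VERSION) {
  bits <- as.logical(bits)
  if (length(bits) < FP_LENGTH) {
    bits <- c(bits, logical(FP_LENGTH - length(bits)))
  }
  structure(list(bits = bits, length = length(bits),
                 catalog_version = catalog_version),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d/%d bits set (catalog %s)\n",
              sum(x$bits), x$length, x$catalog_version))
  invisible(x)
}

#' 2-D Tanimoto similarity of two fingerprints
#'
#' Computes N_AB / (N_A + N_B - N_AB) where N_A and N_B are the set-bit
#' counts and N_AB the common-bit count. When both fingerprints are empty the
#' score is 0 with attribute `degenerate = TRUE` (an empty-key structure
#' should not neighbour everything).
#'
#' @param a,b `fingerprint` objects from the same catalog.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$catalog_version != b$catalog_version || a$length != b$length) {
    stop("fingerprints are from different catalogs and are not comparable")
  }
  na <- sum(a$bits); nb <- sum(b$bits)
  if (na == 0L && nb == 0L) {
    return(structure(0, degenerate = TRUE))
  }
  nab <- sum(a$bits & b$bits)
  nab / (na + nb - nab)
}

fp_to_hex <- function(fp) {
  bits <- fp$bits
  pad <- (8L - length(bits) %% 8L) %% 8L
  bits <- c(bits, logical(pad))
  paste(vapply(seq_len(length(bits) / 8L), function(k) {
    byte <- sum(bits[(k - 1L) * 8L + 1:8] * 2L^(7:0))
    sprintf("%02x", byte)
  }, character(1)), collapse = "")
}

hex_to_fp <- function(hex, length = FP_LENGTH,
                      catalog_version = CATALOG_VERSION) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2),
                            seq(2, nchar(hex), 2)), 16L)
  bits <- as.logical(unlist(lapply(bytes, function(b) bitwAnd(b, 2L^(7:0)) > 0L)))
  fingerprint(bits[seq_len(length)], catalog_version)
}

#' Write fingerprints to a hex-encoded TSV file
#'
#' @param fps named list of `fingerprint` objects (names = cids).
#' @param path output file.
#' @export
write_fingerprints <- function(fps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# catalog_version=%s length=%d",
                     fps[[1]]$catalog_version, fps[[1]]$length), con)
  writeLines("cid\thex", con)
  for (cid in names(fps)) {
    writeLines(paste(cid, fp_to_hex(fps[[cid]]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read fingerprints from a hex-encoded TSV file
#'
#' @param path input file as written by [write_fingerprints()].
#' @return named list of `fingerprint` objects.
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  ver <- CATALOG_VERSION; len <- FP_LENGTH
  if (length(meta) > 0L) {
    m <- regmatches(meta[1], regexec("catalog_version=(\\S+) length=(\\d+)",
                                     meta[1]))[[1]]
    if (length(m) == 3L) { ver <- m[2]; len <- as.integer(m[3]) }
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1L] # header row
  body <- body[nzchar(body)]
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    out[[f[1]]] <- hex_to_fp(f[2], len, ver)
  }
  out
}
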