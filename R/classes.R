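#' @useDynLib neighborpref, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Element symbols accepted by the data model. Covers the organic set plus the
# common counter-ion elements so that salt forms can be represented.
PERIODIC_SYMBOLS <- c(
  "H", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si", "P", "S", "Cl",
  "K", "Ca", "Br", "I", "Li", "Zn", "Fe"
)

# Elements allowed for 3-D conformer generation (PubChem3D convention).
ORGANIC_ELEMENTS <- c("H", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")

# van der Waals radii (Angstrom) used for shape Gaussians; heavy atoms only.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, F = 1.47, Si = 2.10, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98,
  B = 1.92, Na = 2.27, Mg = 1.73, Al = 1.84, K = 2.75, Ca = 2.31,
  Li = 1.82, Zn = 1.39, Fe = 2.00
)

#' Construct a molecular graph
#'
#' A molecular graph stores heavy atoms explicitly; hydrogens are carried as
#' per-atom implicit counts (`hcount`). Bond atom indices are 1-based. Bond
#' order 4 denotes an aromatic bond (SDF V2000 convention). Stereo flags may
#' be attached per bond but are ignored by all 2-D keys.
#'
#' @param elements character vector of element symbols (heavy atoms; "H" is
#'   permitted for completeness but excluded from heavy-atom counts and
#'   shapes).
#' @param charges integer vector of formal charges (recycled if length 1).
#' @param hcounts integer vector of implicit hydrogen counts (recycled).
#' @param bonds data frame or matrix with columns i, j, order; may be empty.
#' @param stereo optional integer vector of per-bond stereo markers.
#' @return an object of class `molecular_graph`.
#' @export
molecular_graph <- function(elements, charges = 0L, hcounts = 0L,
                            bonds = NULL, stereo = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  bad <- setdiff(unique(elements), PERIODIC_SYMBOLS)
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  charges <- as.integer(rep_len(charges, n))
  hcounts <- as.integer(rep_len(hcounts, n))
  if (any(hcounts < 0L)) stop("hydrogen counts must be >= 0")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("i", "j", "order")
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop("bond indices out of range")
    }
    if (!all(bonds$order %in% 1:4)) stop("bond order must be 1, 2, 3 or 4")
    lo <- pmin(bonds$i, bonds$j); hi <- pmax(bonds$i, bonds$j)
    if (anyDuplicated(paste(lo, hi))) stop("duplicate bonds")
    bonds$i <- lo; bonds$j <- hi
    rownames(bonds) <- NULL
  }
  if (!is.null(stereo)) {
    stopifnot(length(stereo) == nrow(bonds))
    bonds$stereo <- as.integer(stereo)
  }
  structure(
    list(
      atoms = data.frame(element = elements, charge = charges,
                         hcount = hcounts, stringsAsFactors = FALSE),
      bonds = bonds
    ),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %d atoms, %d bonds, formula %s\n",
              n_atoms(x), nrow(x$bonds), molecular_formula(x)))
  invisible(x)
}

n_atoms <- function(graph) nrow(graph$atoms)

#' Heavy-atom count of a molecular graph
#' @param graph a `molecular_graph`.
#' @return integer count of non-hydrogen atoms.
#' @export
heavy_atom_count <- function(graph) sum(graph$atoms$element != "H")

molecular_formula <- function(graph) {
  tab <- table(graph$atoms$element)
  nh <- sum(graph$atoms$hcount) + sum(graph$atoms$element == "H")
  els <- sort(names(tab))
  parts <- sprintf("%s%d", els, as.integer(tab[els]))
  if (nh > 0L) parts <- c(parts, sprintf("H%d", nh))
  paste(parts, collapse = "")
}

#' Construct a conformer
#'
#' Coordinates are given for every atom of the owning graph, in the graph's
#' atom order (rows align with atom indices). Hydrogen rows, if present, are
#' dropped when a shape is built.
#'
#' @param coords numeric matrix with 3 columns (x, y, z in Angstrom).
#' @param id integer conformer identifier, unique within a compound.
#' @return an object of class `conformer`.
#' @export
conformer <- function(coords, id = 1L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  structure(list(coords = coords, id = as.integer(id)), class = "conformer")
}

#' Construct a compound record
#'
#' @param cid positive integer compound identifier.
#' @param graph the compound's `molecular_graph` (possibly multi-component).
#' @param conformers list of `conformer` objects (possibly empty).
#' @param annotations character vector of labels drawn from
#'   `c("mesh", "protein3d", "pharmact", "drug")`.
#' @return an object of class `compound_record`.
#' @export
compound_record <- function(cid, graph, conformers = list(),
                            annotations = character()) {
  cid <- as.integer(cid)
  if (is.na(cid) || cid < 1L) stop("cid must be a positive integer")
  stopifnot(inherits(graph, "molecular_graph"))
  annotations <- sort(unique(as.character(annotations)))
  bad <- setdiff(annotations, c("mesh", "protein3d", "pharmact", "drug"))
  if (length(bad) > 0L) stop("unknown annotation label(s): ",
                             paste(bad, collapse = ", "))
  for (cf in conformers) {
    stopifnot(inherits(cf, "conformer"))
    if (nrow(cf$coords) != n_atoms(graph)) {
      stop("conformer row count must equal the graph's atom count")
    }
  }
  structure(list(cid = cid, graph = graph, conformers = conformers,
                 annotations = annotations),
            class = "compound_record")
}

#' Construct a compound dataset
#'
#' A named set of compound records defining the confines of neighboring.
#' Series "B" datasets additionally require every record to be
#' single-component, conformer-eligible and to carry at least one conformer.
#'
#' @param name dataset name.
#' @param series `"A"` or `"B"`.
#' @param records list of `compound_record` objects with unique cids.
#' @return an object of class `compound_dataset`.
#' @export
compound_dataset <- function(name, series, records) {
  series <- match.arg(series, c("A", "B"))
  cids <- vapply(records, function(r) r$cid, integer(1))
  if (anyDuplicated(cids)) stop("cids must be unique within a dataset")
  if (series == "B") {
    for (r in records) {
      if (length(r$conformers) == 0L) {
        stop("series B record cid ", r$cid, " has no conformers")
      }
      el <- is_conformer_eligible(r$graph)
      if (!el$eligible) {
        stop("series B record cid ", r$cid, " is not conformer-eligible: ",
             paste(el$reasons, collapse = ", "))
      }
    }
  }
  structure(list(name = as.character(name), series = series,
                 records = records),
            class = "compound_dataset")
}

#' @export
print.compound_dataset <- function(x, ...) {
  cat(sprintf("<compound_dataset> '%s' (series %s): %d records\n",
              x$name, x$series, length(x$records)))
  invisible(x)
}

dataset_cids <- function(dataset) {
  vapply(dataset$records, function(r) r$cid, integer(1))
}

dataset_record <- function(dataset, cid) {
  for (r in dataset$records) if (r$cid == cid) return(r)
  stop("cid ", cid, " not in dataset")
}
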