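# Covalent-unit handling, parent-compound selection, conformer-eligibility
# filtering and the Series A -> Series B dataset transformation.

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = if (nrow(graph$bonds) > 0L) graph$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(graph)))
  )
}

#' Enumerate covalent units (connected components)
#'
#' Splits a possibly multi-component structure into its covalent units,
#' ordered by their first atom's index in the input graph. Atom provenance is
#' preserved in the `atom_indices` attribute of each component. The
#' deduplicated multiset of unique units (uniqueness by canonical form,
#' stereo-blind) is attached as attribute `unique_units`.
#'
#' @param graph a `molecular_graph`.
#' @return list of single-component `molecular_graph` objects; attribute
#'   `unique_units` holds the distinct components.
#' @export
enumerate_components <- function(graph) {
  if (n_atoms(graph) == 0L) {
    out <- list()
    attr(out, "unique_units") <- list()
    return(out)
  }
  comp <- igraph::components(as_igraph(graph))$membership
  # order components by first atom index
  first_idx <- vapply(seq_len(max(comp)),
                      function(k) min(which(comp == k)), integer(1))
  order_k <- order(first_idx)
  out <- vector("list", length(order_k))
  for (pos in seq_along(order_k)) {
    k <- order_k[pos]
    idx <- unname(which(comp == k))
    sub <- subgraph_by_atoms(graph, idx)
    attr(sub, "atom_indices") <- idx
    out[[pos]] <- sub
  }
  keys <- vapply(out, canonical_form, character(1))
  attr(out, "unique_units") <- out[!duplicated(keys)]
  out
}

subgraph_by_atoms <- function(graph, idx) {
  idx <- sort(idx)
  remap <- integer(n_atoms(graph))
  remap[idx] <- seq_along(idx)
  b <- graph$bonds
  keep <- b$i %in% idx & b$j %in% idx
  b <- b[keep, , drop = FALSE]
  molecular_graph(
    elements = graph$atoms$element[idx],
    charges = graph$atoms$charge[idx],
    hcounts = graph$atoms$hcount[idx],
    bonds = if (nrow(b) > 0L)
      data.frame(i = remap[b$i], j = remap[b$j], order = b$order) else NULL,
    stereo = if (nrow(b) > 0L && !is.null(b$stereo)) b$stereo else NULL
  )
}

#' Canonical form of a molecular graph
#'
#' A deterministic serialization of the labelled graph (element, formal
#' charge, hydrogen count, bond orders), invariant under atom reordering and
#' blind to stereo flags. Two graphs have equal canonical forms iff they are
#' isomorphic as labelled graphs. Canonical labelling is computed with
#' igraph's BLISS backend; bond orders are encoded by subdividing each bond
#' with a colour-coded auxiliary vertex.
#'
#' @param graph a `molecular_graph`.
#' @return a character scalar.
#' @export
canonical_form <- function(graph) {
  n <- n_atoms(graph)
  if (n == 0L) return("")
  lab <- paste(graph$atoms$element, graph$atoms$charge, graph$atoms$hcount,
               sep = "/")
  atom_color <- as.integer(factor(lab, levels = sort(unique(lab)))) - 1L
  nb <- nrow(graph$bonds)
  if (nb == 0L) {
    # no edges: canonical form is the sorted atom label multiset
    return(paste(sort(lab), collapse = ";"))
  }
  # vertices 1..n atoms, n+1..n+nb bond vertices
  ncol_atom <- max(atom_color) + 1L
  colors <- c(atom_color, ncol_atom + graph$bonds$order - 1L)
  edges <- rbind(cbind(graph$bonds$i, n + seq_len(nb)),
                 cbind(graph$bonds$j, n + seq_len(nb)))
  g <- igraph::make_graph(t(edges), n = n + nb, directed = FALSE)
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  # canonical atom order: atoms sorted by their canonical label
  atom_rank <- perm[seq_len(n)]
  ord <- order(atom_rank)
  pos <- integer(n); pos[ord] <- seq_len(n)
  b_i <- pos[graph$bonds$i]; b_j <- pos[graph$bonds$j]
  lo <- pmin(b_i, b_j); hi <- pmax(b_i, b_j)
  bond_str <- sprintf("%d-%d:%d", lo, hi, graph$bonds$order)
  paste(paste(lab[ord], collapse = ";"),
        paste(sort(bond_str), collapse = ";"), sep = "|")
}

#' Neutralize protonation state
#'
#' Adjusts formal charges of protonatable/deprotonatable N, O and S atoms
#' towards net-neutrality, adding or removing implicit hydrogens accordingly:
#' a positively charged N/O/S carrying at least one hydrogen is deprotonated
#' (charge-1, hcount-1, repeated while applicable); a negatively charged
#' N/O/S is protonated (charge+1, hcount+1). Other charged centres (e.g.
#' quaternary ammonium, metals) are left untouched.
#'
#' @param graph a `molecular_graph`.
#' @return the neutralized `molecular_graph`.
#' @export
neutralize <- function(graph) {
  at <- graph$atoms
  for (k in seq_len(nrow(at))) {
    if (!at$element[k] %in% c("N", "O", "S")) next
    while (at$charge[k] > 0L && at$hcount[k] > 0L) {
      at$charge[k] <- at$charge[k] - 1L
      at$hcount[k] <- at$hcount[k] - 1L
    }
    while (at$charge[k] < 0L) {
      at$charge[k] <- at$charge[k] + 1L
      at$hcount[k] <- at$hcount[k] + 1L
    }
  }
  molecular_graph(at$element, at$charge, at$hcount,
                  bonds = if (nrow(graph$bonds) > 0L) graph$bonds else NULL,
                  stereo = graph$bonds$stereo)
}

#' Select the parent compound of a (possibly multi-component) structure
#'
#' The parent is the carbon-containing covalent unit whose heavy-atom count
#' is at least 70 percent of the summed heavy-atom counts of all unique
#' covalent units. The returned component is neutralized. Returns `NULL`
#' when no component qualifies. A connected carbon-containing graph is its
#' own parent.
#'
#' @param graph a `molecular_graph`.
#' @param min_fraction heavy-atom fraction threshold (default 0.70).
#' @return a single-component `molecular_graph`, or `NULL`.
#' @export
select_parent <- function(graph, min_fraction = 0.70) {
  comps <- enumerate_components(graph)
  if (length(comps) == 0L) return(NULL)
  uniq <- attr(comps, "unique_units")
  total <- sum(vapply(uniq, heavy_atom_count, integer(1)))
  if (total == 0L) return(NULL)
  for (comp in comps) {
    if (!"C" %in% comp$atoms$element) next
    if (heavy_atom_count(comp) >= min_fraction * total) {
      out <- neutralize(comp)
      attr(out, "atom_indices") <- attr(comp, "atom_indices")
      return(out)
    }
  }
  NULL
}

#' Count rotatable bonds
#'
#' A bond is rotatable when it is a single (order 1), non-ring bond and both
#' endpoint atoms have at least one additional heavy-atom neighbour. Amide
#' bonds are not excluded. Ring membership is determined by bridge detection:
#' a bond lies in a ring iff it is not a bridge.
#'
#' @param graph a single-component `molecular_graph`.
#' @return integer count.
#' @export
count_rotatable_bonds <- function(graph) {
  comps <- enumerate_components(graph)
  if (length(comps) > 1L) {
    stop("graph has multiple components; select a component first")
  }
  b <- graph$bonds
  if (nrow(b) == 0L) return(0L)
  g <- as_igraph(graph)
  bridge_ids <- igraph::bridges(g)
  is_bridge <- logical(nrow(b))
  is_bridge[as.integer(bridge_ids)] <- TRUE
  deg <- tabulate(c(b$i, b$j), nbins = n_atoms(graph))
  sum(b$order == 1L & is_bridge & deg[b$i] >= 2L & deg[b$j] >= 2L)
}

#' Test 3-D conformer eligibility
#'
#' A structure is eligible for conformer generation when it is a single
#' covalent unit, comprised of organic elements only, not too flexible
#' (at most `max_rotatable` rotatable bonds) and not too large (at most
#' `max_heavy` non-hydrogen atoms).
#'
#' @param graph a `molecular_graph`.
#' @param max_rotatable rotatable-bond cap (default 15).
#' @param max_heavy heavy-atom cap (default 50).
#' @param organic_elements allowed element set.
#' @return list with `eligible` (logical) and `reasons` (character vector of
#'   failed-rule labels among `multi_component`, `non_organic_element`,
#'   `too_flexible`, `too_large`).
#' @export
is_conformer_eligible <- function(graph, max_rotatable = 15L,
                                  max_heavy = 50L,
                                  organic_elements = ORGANIC_ELEMENTS) {
  reasons <- character()
  comps <- enumerate_components(graph)
  if (length(comps) > 1L) reasons <- c(reasons, "multi_component")
  if (!all(graph$atoms$element %in% organic_elements)) {
    reasons <- c(reasons, "non_organic_element")
  }
  if (length(comps) == 1L) {
    if (count_rotatable_bonds(graph) > max_rotatable) {
      reasons <- c(reasons, "too_flexible")
    }
  }
  if (heavy_atom_count(graph) > max_heavy) reasons <- c(reasons, "too_large")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Build a Series B dataset from a Series A dataset
#'
#' Maps every record to its parent compound (the record itself when already
#' single-component), deduplicates by canonical form merging annotation
#' labels by union, and drops entries that fail conformer eligibility or lack
#' conformers. The cid of a collapsed family is the cid of the first record
#' (in cid order) whose own structure equals the parent; if no member is the
#' parent itself, the lowest member cid is used.
#'
#' @param dataset a series "A" `compound_dataset`.
#' @param name optional output dataset name (default `<name>-B`).
#' @return a series "B" `compound_dataset`.
#' @export
build_series_b <- function(dataset, name = NULL) {
  stopifnot(inherits(dataset, "compound_dataset"))
  if (dataset$series != "A") stop("input must be a series A dataset")
  if (is.null(name)) name <- paste0(dataset$name, "-B")

  # map each record to its parent structure
  entries <- list()
  ord <- order(dataset_cids(dataset))
  for (r in dataset$records[ord]) {
    comps <- enumerate_components(r$graph)
    if (length(comps) == 1L) {
      parent <- r$graph
      is_self <- TRUE
    } else {
      parent <- select_parent(r$graph)
      if (is.null(parent)) next
      is_self <- FALSE
    }
    key <- canonical_form(parent)
    if (is.null(entries[[key]])) {
      entries[[key]] <- list(graph = parent, cid = r$cid, is_self = is_self,
                             annotations = r$annotations,
                             conformers = if (is_self) r$conformers else list())
    } else {
      e <- entries[[key]]
      e$annotations <- union(e$annotations, r$annotations)
      # prefer the cid (and conformers) of a record that IS the parent
      if (is_self && !e$is_self) {
        e$cid <- r$cid
        e$is_self <- TRUE
        e$conformers <- r$conformers
      }
      entries[[key]] <- e
    }
  }

  records <- list()
  for (e in entries) {
    if (!is_conformer_eligible(e$graph)$eligible) next
    if (length(e$conformers) == 0L) next
    records[[length(records) + 1L]] <-
      compound_record(e$cid, e$graph, e$conformers, e$annotations)
  }
  records <- records[order(vapply(records, function(r) r$cid, integer(1)))]
  compound_dataset(name, "B", records)
}
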