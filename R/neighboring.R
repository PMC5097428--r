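# Construction of 2-D and 3-D neighbor-pair sets within a dataset.

record_fingerprint <- function(record) {
  comps <- enumerate_components(record$graph)
  if (length(comps) == 1L) return(compute_keys(record$graph))
  # Series A convention for multi-component records: fingerprint the parent
  # if defined, else the largest component (flagged).
  parent <- select_parent(record$graph)
  target <- if (!is.null(parent)) parent else {
    comps[[which.max(vapply(comps, heavy_atom_count, integer(1)))]]
  }
  fp <- compute_keys(target)
  attr(fp, "from_component") <- TRUE
  fp
}

#' 2-D fingerprints for every record of a dataset
#'
#' Multi-component records are fingerprinted on their parent component if
#' defined, else their largest component (the raw-series convention that
#' reproduces the 2-D salt-form bias).
#'
#' @param dataset a `compound_dataset`.
#' @return named list of `fingerprint` objects keyed by cid.
#' @export
dataset_fingerprints <- function(dataset) {
  fps <- lapply(dataset$records, record_fingerprint)
  names(fps) <- as.character(dataset_cids(dataset))
  fps
}

#' 2-D neighbor pairs of a dataset
#'
#' All unordered record pairs whose fingerprint Tanimoto similarity is at
#' least `threshold` (inclusive). Neighboring is confined to the dataset.
#'
#' @param dataset a `compound_dataset`.
#' @param threshold inclusive 2-D Tanimoto threshold (default 0.9).
#' @param fingerprints optional precomputed named fingerprint list.
#' @return data frame with columns cid_lo, cid_hi, tanimoto_2d.
#' @export
neighbors_2d <- function(dataset, threshold = 0.9, fingerprints = NULL) {
  if (is.null(fingerprints)) fingerprints <- dataset_fingerprints(dataset)
  cids <- dataset_cids(dataset)
  n <- length(cids)
  if (n < 2L) {
    return(data.frame(cid_lo = integer(), cid_hi = integer(),
                      tanimoto_2d = numeric()))
  }
  # bit matrix for vectorized pair counts
  B <- vapply(as.character(cids), function(k) fingerprints[[k]]$bits,
              logical(fingerprints[[1]]$length))
  storage.mode(B) <- "double"
  pop <- colSums(B)
  common <- crossprod(B)
  denom <- outer(pop, pop, "+") - common
  tan <- ifelse(denom > 0, common / denom, 0)
  idx <- which(upper.tri(tan) & tan >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(cid_lo = integer(), cid_hi = integer(),
                      tanimoto_2d = numeric()))
  }
  lo <- pmin(cids[idx[, 1L]], cids[idx[, 2L]])
  hi <- pmax(cids[idx[, 1L]], cids[idx[, 2L]])
  out <- data.frame(cid_lo = lo, cid_hi = hi, tanimoto_2d = tan[idx])
  out[order(out$cid_lo, out$cid_hi), , drop = FALSE]
}

# shapes, cached principal frames and color matrices for the first k
# diverse conformers of a record
record_shape_set <- function(record, k) {
  el <- record$graph$atoms$element
  confs <- diverse_order(record$conformers, el)
  confs <- confs[seq_len(min(k, length(confs)))]
  lapply(confs, function(cf) {
    shape <- build_shape(cf, elements = el)
    colors <- assign_color_atoms(record$graph, cf)
    cm <- color_matrix(colors)
    cm$self <- color_self_total(cm)
    list(shape = shape, colors = colors, pf = principal_frame(shape),
         cm = cm, id = cf$id)
  })
}

#' 3-D neighbor pairs of a dataset
#'
#' A record pair is a 3-D neighbor iff some conformer pair (over the first
#' `k_conformers` of the diverse ordering of each record) has a
#' shape-Tanimoto of at least `st_min` AND a color-Tanimoto of at least
#' `ct_min` at the ST-optimized superposition. Among qualifying conformer
#' pairs the one with the maximal ComboT is reported. Conformer pairs whose
#' self-overlap volumes already bound the optimal ST below `st_min`
#' (Cauchy-Schwarz bound) are skipped; the bound is exact, so the neighbor
#' set is unchanged.
#'
#' @param dataset a `compound_dataset` whose records all carry conformers.
#' @param k_conformers number of diverse conformers per record (default 5).
#' @param st_min inclusive shape-Tanimoto threshold (default 0.8).
#' @param ct_min inclusive color-Tanimoto threshold (default 0.5).
#' @return data frame with columns cid_lo, cid_hi, conf_lo, conf_hi, st, ct,
#'   combo.
#' @export
neighbors_3d <- function(dataset, k_conformers = 5L, st_min = 0.8,
                         ct_min = 0.5) {
  has_conf <- vapply(dataset$records,
                     function(r) length(r$conformers) > 0L, logical(1))
  if (dataset$series == "B" && !all(has_conf)) {
    stop("series B dataset invariant violated: record(s) without conformers")
  }
  # conformer-less records (salt/mixture forms in a raw series A set) cannot
  # have 3-D neighbours and are skipped
  cids <- dataset_cids(dataset)
  n <- length(cids)
  sets <- lapply(dataset$records, function(r) {
    if (length(r$conformers) == 0L) return(list())
    record_shape_set(r, k = k_conformers)
  })
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        best <- NULL
        for (sa in sets[[i]]) {
          for (sb in sets[[j]]) {
            if (st_upper_bound(sa$shape$vself, sb$shape$vself) < st_min) next
            sim <- pair_similarity_fast(sa, sb, st_min, ct_min)
            if (!is.null(sim) &&
                (is.null(best) || sim$combo > best$combo)) {
              best <- sim
              best$conformer_pair <- c(sa$id, sb$id)
            }
          }
        }
        if (!is.null(best)) {
          lo <- min(cids[i], cids[j]); hi <- max(cids[i], cids[j])
          cp <- if (cids[i] <= cids[j]) best$conformer_pair else
            rev(best$conformer_pair)
          out[[length(out) + 1L]] <- data.frame(
            cid_lo = lo, cid_hi = hi, conf_lo = cp[1L], conf_hi = cp[2L],
            st = best$st, ct = best$ct, combo = best$combo)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cid_lo = integer(), cid_hi = integer(),
                      conf_lo = integer(), conf_hi = integer(),
                      st = numeric(), ct = numeric(), combo = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$cid_lo, res$cid_hi), , drop = FALSE]
}

pair_keys <- function(pairs) {
  if (nrow(pairs) == 0L) return(character())
  paste(pairs$cid_lo, pairs$cid_hi, sep = "_")
}

#' Classify neighbor pairs into 2-D-only, 3-D-only and common
#'
#' @param pairs2d data frame from [neighbors_2d()].
#' @param pairs3d data frame from [neighbors_3d()].
#' @return list with integer counts `n_2d_only`, `n_3d_only`, `n_common`,
#'   `n_total` and the corresponding fractions (summing to 1 when
#'   `n_total > 0`).
#' @export
classify_pairs <- function(pairs2d, pairs3d) {
  k2 <- pair_keys(pairs2d)
  k3 <- pair_keys(pairs3d)
  n_common <- length(intersect(k2, k3))
  n_2d_only <- length(setdiff(k2, k3))
  n_3d_only <- length(setdiff(k3, k2))
  n_total <- n_2d_only + n_3d_only + n_common
  fr <- if (n_total > 0L) {
    c(n_2d_only, n_3d_only, n_common) / n_total
  } else c(NA_real_, NA_real_, NA_real_)
  list(n_2d_only = n_2d_only, n_3d_only = n_3d_only, n_common = n_common,
       n_total = n_total,
       frac_2d_only = fr[1L], frac_3d_only = fr[2L], frac_common = fr[3L])
}
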