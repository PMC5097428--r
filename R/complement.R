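# Per-compound Neighbor Preference Index (NPI), histograms, delta-NPI,
# cross-dataset correlation and top-preference listings.

#' Neighbor Preference Index
#'
#' NPI = (N_2D_only - N_3D_only) / N_total for one compound within one
#' dataset: +1 when all neighbours are 2-D-only, -1 when all are 3-D-only,
#' 0 for no preference. Common neighbours enter implicitly through N_total.
#' Undefined (NA) when the compound has no neighbours.
#'
#' @param n_2d_only,n_3d_only,n_total non-negative neighbour counts with
#'   `n_total >= n_2d_only + n_3d_only`.
#' @return NPI in [-1, 1], or NA when `n_total` is 0.
#' @export
npi <- function(n_2d_only, n_3d_only, n_total) {
  if (n_2d_only < 0 || n_3d_only < 0 || n_total < n_2d_only + n_3d_only) {
    stop("inconsistent neighbour counts")
  }
  if (n_total == 0) return(NA_real_)
  (n_2d_only - n_3d_only) / n_total
}

#' Per-compound NPI table for a dataset
#'
#' Derives per-compound 2-D-only / 3-D-only / common neighbour counts from
#' the pair sets and computes each compound's NPI. Compounds without
#' neighbours get NA.
#'
#' @param dataset a `compound_dataset` (or an integer vector of cids).
#' @param pairs2d,pairs3d neighbour-pair data frames confined to the dataset.
#' @return data frame with columns cid, n_2d_only, n_3d_only, n_common,
#'   n_total, npi.
#' @export
npi_table <- function(dataset, pairs2d, pairs3d) {
  cids <- if (inherits(dataset, "compound_dataset")) {
    dataset_cids(dataset)
  } else as.integer(dataset)
  k2 <- pair_keys(pairs2d)
  k3 <- pair_keys(pairs3d)
  common <- intersect(k2, k3)
  count_ends <- function(pairs, keys, keep) {
    sel <- keys %in% keep
    tabulate(match(c(pairs$cid_lo[sel], pairs$cid_hi[sel]), cids),
             nbins = length(cids))
  }
  n2 <- count_ends(pairs2d, k2, setdiff(k2, k3))
  n3 <- count_ends(pairs3d, k3, setdiff(k3, k2))
  nc <- count_ends(pairs2d, k2, common)
  nt <- n2 + n3 + nc
  data.frame(
    cid = cids, n_2d_only = n2, n_3d_only = n3, n_common = nc, n_total = nt,
    npi = ifelse(nt > 0L, (n2 - n3) / pmax(nt, 1L), NA_real_))
}

NPI_BIN_CENTERS <- seq.int(-10L, 10L) / 10

#' Binned NPI distribution
#'
#' 21 bins centred at -1.0, -0.9, ..., +1.0 with half-width 0.05; the
#' outermost bins are truncated to [-1.00, -0.95] and [0.95, 1.00]. A value
#' falling exactly on a bin boundary is assigned to the bin whose centre is
#' nearer zero. Records with undefined NPI are counted separately.
#'
#' @param records an NPI table from [npi_table()] (or a numeric NPI vector).
#' @return list of class `npi_histogram` with `bin_centers`, `counts` and
#'   `n_undefined`.
#' @export
npi_histogram <- function(records) {
  x <- if (is.data.frame(records)) records$npi else as.numeric(records)
  n_undef <- sum(is.na(x))
  x <- x[!is.na(x)]
  # boundary at +/-(0.05 + 0.1k) goes toward zero: shrink magnitudes by eps
  # before rounding to the nearest bin centre
  idx <- pmax(pmin(round(sign(x) * pmax(abs(x) * (1 - 1e-12) - 1e-15, 0) * 10),
                   10), -10) + 11
  counts <- tabulate(idx, nbins = 21L)
  structure(list(bin_centers = NPI_BIN_CENTERS, counts = counts,
                 n_undefined = n_undef),
            class = "npi_histogram")
}

#' @export
print.npi_histogram <- function(x, ...) {
  cat("<npi_histogram>\n")
  print(stats::setNames(x$counts, sprintf("%+.1f", x$bin_centers)))
  cat("undefined:", x$n_undefined, "\n")
  invisible(x)
}

#' Per-compound NPI difference between two datasets
#'
#' delta-NPI = NPI(subset) - NPI(reference) over the cids present in both
#' tables; a positive value indicates a stronger 2-D neighbour preference in
#' the subset than in the reference. Compounds with undefined NPI in either
#' table are excluded and reported in the `excluded` attribute.
#'
#' @param subset_records,reference_records NPI tables from [npi_table()].
#' @return data frame with columns cid, npi_subset, npi_reference,
#'   delta_npi; attribute `excluded` lists skipped cids.
#' @export
delta_npi <- function(subset_records, reference_records) {
  shared <- intersect(subset_records$cid, reference_records$cid)
  if (length(shared) == 0L) {
    warning("no cids shared between the two tables")
  }
  s <- subset_records[match(shared, subset_records$cid), ]
  r <- reference_records[match(shared, reference_records$cid), ]
  ok <- !is.na(s$npi) & !is.na(r$npi)
  out <- data.frame(cid = shared[ok], npi_subset = s$npi[ok],
                    npi_reference = r$npi[ok],
                    delta_npi = s$npi[ok] - r$npi[ok])
  attr(out, "excluded") <- shared[!ok]
  out
}

#' Squared Pearson correlation of paired NPI values
#'
#' @param x_records,y_records NPI tables from [npi_table()].
#' @return R^2 of the paired defined NPI values.
#' @export
npi_r2 <- function(x_records, y_records) {
  shared <- intersect(x_records$cid, y_records$cid)
  x <- x_records$npi[match(shared, x_records$cid)]
  y <- y_records$npi[match(shared, y_records$cid)]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 paired defined NPI values required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("NPI values are constant; correlation undefined")
  }
  stats::cor(x, y)^2
}

#' Compounds with the strongest one-sided neighbour preference
#'
#' Lists compounds having zero neighbours on the opposite side (including
#' common neighbours), ranked by their same-side neighbour count descending,
#' ties broken by ascending cid.
#'
#' @param records an NPI table from [npi_table()].
#' @param side `"2d"` (most 2-D neighbours, no 3-D neighbours) or `"3d"`.
#' @param k maximum number of rows returned.
#' @return subset of `records` ranked as described.
#' @export
top_preference <- function(records, side = c("2d", "3d"), k = 10L) {
  side <- match.arg(side)
  if (side == "2d") {
    sel <- records$n_3d_only + records$n_common == 0L & records$n_2d_only > 0L
    cnt <- records$n_2d_only
  } else {
    sel <- records$n_2d_only + records$n_common == 0L & records$n_3d_only > 0L
    cnt <- records$n_3d_only
  }
  out <- records[sel, , drop = FALSE]
  out <- out[order(-cnt[sel], out$cid), , drop = FALSE]
  utils::head(out, k)
}
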