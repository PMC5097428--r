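# File formats: SDF V2000 (multi-conformer, conformers grouped by a CID data
# tag), JSON-lines compound records, and tab-separated tables with
# '#'-prefixed metadata headers.

#' Write compound records to an SDF V2000 file
#'
#' Each conformer becomes one SDF record; conformers of one compound share
#' the `CID` data tag and carry their conformer id in `NP_CONFORMER_ID`.
#' Records without conformers are written once with zero coordinates.
#' Formal charges are emitted as `M  CHG` lines; implicit hydrogen counts
#' and annotation labels travel in the `NP_HCOUNTS` and `NP_ANNOTATIONS`
#' data tags so that the round-trip is lossless.
#'
#' @param records list of `compound_record` objects (or a
#'   `compound_dataset`).
#' @param path output file path.
#' @export
write_sdf <- function(records, path) {
  if (inherits(records, "compound_dataset")) records <- records$records
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    confs <- rec$conformers
    if (length(confs) == 0L) {
      confs <- list(conformer(matrix(0, n_atoms(rec$graph), 3L), id = 0L))
    }
    for (cf in confs) {
      writeLines(sdf_block(rec, cf), con)
    }
  }
  invisible(path)
}

sdf_block <- function(rec, cf) {
  g <- rec$graph
  n <- n_atoms(g)
  nb <- nrow(g$bonds)
  lines <- c(sprintf("CID%d", rec$cid), "  neighborpref", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (k in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              cf$coords[k, 1L], cf$coords[k, 2L],
                              cf$coords[k, 3L], g$atoms$element[k]))
  }
  for (k in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", g$bonds$i[k], g$bonds$j[k],
                              g$bonds$order[k]))
  }
  chg <- which(g$atoms$charge != 0L)
  while (length(chg) > 0L) {
    take <- utils::head(chg, 8L)
    lines <- c(lines, paste0(sprintf("M  CHG%3d", length(take)),
                             paste(sprintf("%4d%4d", take,
                                           g$atoms$charge[take]),
                                   collapse = "")))
    chg <- chg[-seq_along(take)]
  }
  lines <- c(lines, "M  END",
             "> <CID>", as.character(rec$cid), "",
             "> <NP_CONFORMER_ID>", as.character(cf$id), "",
             "> <NP_HCOUNTS>", paste(g$atoms$hcount, collapse = " "), "")
  if (length(rec$annotations) > 0L) {
    lines <- c(lines, "> <NP_ANNOTATIONS>",
               paste(rec$annotations, collapse = ","), "")
  }
  c(lines, "$$$$")
}

#' Read compound records from an SDF V2000 file
#'
#' Records sharing a `CID` data tag are merged into one compound with
#' multiple conformers. Records lacking the tag are assigned the next free
#' cid with a warning. Unparseable records are skipped with a warning and
#' counted in the `n_skipped` attribute.
#'
#' @param path input file path.
#' @return list of `compound_record` objects.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  # split into molecule blocks
  ends <- which(lines == "$$$$")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  by_cid <- list()
  n_skipped <- 0L
  auto_cid <- 10^6L
  for (bi in seq_along(ends)) {
    block <- lines[starts[bi]:ends[bi]]
    parsed <- tryCatch(parse_sdf_block(block), error = function(e) e)
    if (inherits(parsed, "error")) {
      warning("skipping unparseable SDF record ", bi, ": ",
              conditionMessage(parsed))
      n_skipped <- n_skipped + 1L
      next
    }
    if (is.na(parsed$cid)) {
      auto_cid <- auto_cid + 1L
      parsed$cid <- auto_cid
      warning("SDF record ", bi, " lacks a CID tag; assigned cid ",
              parsed$cid)
    }
    key <- as.character(parsed$cid)
    if (is.null(by_cid[[key]])) {
      by_cid[[key]] <- parsed
    } else {
      by_cid[[key]]$conformers <- c(by_cid[[key]]$conformers,
                                    parsed$conformers)
    }
  }
  out <- lapply(by_cid, function(p) {
    confs <- p$conformers
    # drop the zero-coordinate placeholder emitted for conformer-less records
    if (length(confs) == 1L && confs[[1L]]$id == 0L &&
        all(confs[[1L]]$coords == 0)) confs <- list()
    compound_record(p$cid, p$graph, confs, p$annotations)
  })
  out <- unname(out[order(vapply(out, function(r) r$cid, integer(1)))])
  attr(out, "n_skipped") <- n_skipped
  out
}

parse_sdf_block <- function(block) {
  if (length(block) < 4L) stop("truncated block")
  counts <- block[4L]
  n <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n) || is.na(nb) || n < 0L || nb < 0L) {
    stop("malformed counts line")
  }
  atom_lines <- block[4L + seq_len(n)]
  coords <- matrix(0, n, 3L)
  elements <- character(n)
  for (k in seq_len(n)) {
    ln <- atom_lines[k]
    coords[k, ] <- as.numeric(c(substr(ln, 1L, 10L), substr(ln, 11L, 20L),
                                substr(ln, 21L, 30L)))
    elements[k] <- trimws(substr(ln, 31L, 34L))
  }
  if (anyNA(coords)) stop("malformed atom block")
  bond_lines <- block[4L + n + seq_len(nb)]
  bonds <- NULL
  if (nb > 0L) {
    bonds <- data.frame(
      i = as.integer(substr(bond_lines, 1L, 3L)),
      j = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L)))
    if (anyNA(bonds)) stop("malformed bond block")
  }
  charges <- integer(n)
  for (ln in grep("^M  CHG", block, value = TRUE)) {
    cnt <- as.integer(substr(ln, 7L, 9L))
    for (e in seq_len(cnt)) {
      off <- 9L + (e - 1L) * 8L
      idx <- as.integer(substr(ln, off + 1L, off + 4L))
      val <- as.integer(substr(ln, off + 5L, off + 8L))
      charges[idx] <- val
    }
  }
  tag <- function(name) {
    hit <- which(block == sprintf("> <%s>", name))
    if (length(hit) == 0L) return(NA_character_)
    block[hit[1L] + 1L]
  }
  hc_raw <- tag("NP_HCOUNTS")
  hcounts <- if (is.na(hc_raw)) integer(n) else
    as.integer(strsplit(hc_raw, " ", fixed = TRUE)[[1L]])
  ann_raw <- tag("NP_ANNOTATIONS")
  annotations <- if (is.na(ann_raw)) character() else
    strsplit(ann_raw, ",", fixed = TRUE)[[1L]]
  cid <- suppressWarnings(as.integer(tag("CID")))
  conf_id <- suppressWarnings(as.integer(tag("NP_CONFORMER_ID")))
  if (is.na(conf_id)) conf_id <- 1L
  graph <- molecular_graph(elements, charges, hcounts, bonds)
  list(cid = cid, graph = graph, annotations = annotations,
       conformers = list(conformer(coords, id = conf_id)))
}

#' Write compound records as JSON lines
#'
#' One JSON object per line with fields cid, elements, charges, hcounts,
#' bonds (list of [i, j, order], 1-based), annotations and conformers.
#'
#' @param records list of `compound_record` objects (or a dataset).
#' @param path output file path.
#' @export
write_jsonl <- function(records, path) {
  if (inherits(records, "compound_dataset")) records <- records$records
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    obj <- list(
      cid = rec$cid,
      elements = rec$graph$atoms$element,
      charges = rec$graph$atoms$charge,
      hcounts = rec$graph$atoms$hcount,
      bonds = unname(as.matrix(rec$graph$bonds[, c("i", "j", "order")])),
      annotations = rec$annotations,
      conformers = lapply(rec$conformers, function(cf) {
        list(id = cf$id, coords = unname(cf$coords))
      }))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read compound records from a JSON-lines file
#'
#' @param path input file path.
#' @return list of `compound_record` objects.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyMatrix = TRUE)
    bonds <- if (length(obj$bonds) > 0L) {
      m <- matrix(as.integer(obj$bonds), ncol = 3L)
      data.frame(i = m[, 1L], j = m[, 2L], order = m[, 3L])
    } else NULL
    graph <- molecular_graph(obj$elements, obj$charges, obj$hcounts, bonds)
    confs <- list()
    if (length(obj$conformers) > 0L) {
      confs <- lapply(seq_len(NROW(obj$conformers)), function(k) {
        cc <- if (is.data.frame(obj$conformers)) obj$conformers[k, ] else
          obj$conformers[[k]]
        conformer(matrix(unlist(cc$coords), ncol = 3L), id = cc$id)
      })
    }
    compound_record(obj$cid, graph, confs, unlist(obj$annotations))
  })
}

tsv_header <- function(stage, seed = NA, config_hash = NA) {
  sprintf("# neighborpref %s\tseed=%s\tconfig=%s", stage,
          ifelse(is.na(seed), "-", seed),
          ifelse(is.na(config_hash), "-", config_hash))
}

write_tsv_with_header <- function(df, path, stage, seed = NA,
                                  config_hash = NA, digits = 4L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(stage, seed, config_hash), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "f"))
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_meta <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  # fixed-precision columns come back numeric even when NA-padded
  for (col in intersect(c("tanimoto_2d", "st", "ct", "combo", "npi", "value"),
                        names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Merge 2-D and 3-D pair sets into one neighbour-pair table
#'
#' @param pairs2d data frame from [neighbors_2d()].
#' @param pairs3d data frame from [neighbors_3d()].
#' @return data frame with columns cid_lo, cid_hi, is_2d, is_3d,
#'   tanimoto_2d, st, ct, combo.
#' @export
merge_neighbor_pairs <- function(pairs2d, pairs3d) {
  k2 <- pair_keys(pairs2d)
  k3 <- pair_keys(pairs3d)
  keys <- union(k2, k3)
  if (length(keys) == 0L) {
    return(data.frame(cid_lo = integer(), cid_hi = integer(),
                      is_2d = logical(), is_3d = logical(),
                      tanimoto_2d = numeric(), st = numeric(),
                      ct = numeric(), combo = numeric()))
  }
  parts <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  out <- data.frame(cid_lo = as.integer(parts[, 1L]),
                    cid_hi = as.integer(parts[, 2L]),
                    is_2d = keys %in% k2, is_3d = keys %in% k3,
                    tanimoto_2d = NA_real_, st = NA_real_, ct = NA_real_,
                    combo = NA_real_)
  m2 <- match(keys, k2); ok <- !is.na(m2)
  out$tanimoto_2d[ok] <- pairs2d$tanimoto_2d[m2[ok]]
  m3 <- match(keys, k3); ok <- !is.na(m3)
  out$st[ok] <- pairs3d$st[m3[ok]]
  out$ct[ok] <- pairs3d$ct[m3[ok]]
  out$combo[ok] <- pairs3d$combo[m3[ok]]
  out[order(out$cid_lo, out$cid_hi), , drop = FALSE]
}

#' Write a merged neighbour-pair table to TSV
#'
#' @param pairs merged pair table from [merge_neighbor_pairs()].
#' @param path output file path.
#' @param seed,config_hash metadata recorded in the '#' header.
#' @export
write_neighbor_pairs <- function(pairs, path, seed = NA, config_hash = NA) {
  write_tsv_with_header(pairs, path, "neighbor_pairs", seed, config_hash)
}

#' Read a neighbour-pair TSV (native or pre-converted external exports)
#'
#' @param path input file path.
#' @return list with data frames `pairs2d` and `pairs3d` suitable for the
#'   analysis functions.
#' @export
read_neighbor_pairs <- function(path) {
  df <- read_tsv_skip_meta(path)
  df$is_2d <- as.logical(df$is_2d)
  df$is_3d <- as.logical(df$is_3d)
  list(
    pairs2d = data.frame(cid_lo = df$cid_lo[df$is_2d],
                         cid_hi = df$cid_hi[df$is_2d],
                         tanimoto_2d = df$tanimoto_2d[df$is_2d]),
    pairs3d = data.frame(cid_lo = df$cid_lo[df$is_3d],
                         cid_hi = df$cid_hi[df$is_3d],
                         conf_lo = NA_integer_, conf_hi = NA_integer_,
                         st = df$st[df$is_3d], ct = df$ct[df$is_3d],
                         combo = df$combo[df$is_3d]))
}
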