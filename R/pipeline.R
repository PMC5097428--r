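# Pipeline configuration and end-to-end orchestration.

#' Pipeline configuration
#'
#' All defaults are the established neighboring thresholds: 2-D Tanimoto
#' 0.9, shape-Tanimoto 0.8, color-Tanimoto 0.5, five diverse conformers per
#' compound.
#'
#' @param threshold_2d inclusive 2-D Tanimoto threshold.
#' @param st_min,ct_min inclusive 3-D thresholds at the ST-optimized pose.
#' @param k_conformers diverse conformers per compound used in 3-D
#'   neighboring.
#' @param seed integer seed recorded in outputs and used for generation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_2d = 0.9, st_min = 0.8, ct_min = 0.5,
                            k_conformers = 5L, seed = 1L) {
  if (threshold_2d < 0 || threshold_2d > 1 || st_min < 0 || st_min > 1 ||
      ct_min < 0 || ct_min > 1) {
    stop("thresholds must lie within the score ranges")
  }
  structure(list(threshold_2d = threshold_2d, st_min = st_min,
                 ct_min = ct_min, k_conformers = as.integer(k_conformers),
                 catalog_version = CATALOG_VERSION, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full neighboring and complementarity pipeline
#'
#' Stages, in order: dataset build (generation from a scenario config, or a
#' supplied dataset) -> 2-D fingerprints -> diverse conformer ordering and
#' 2-D/3-D neighboring -> pair classification -> per-compound NPI table and
#' histogram -> threshold-comparability report. When `out_dir` is given,
#' every tabular output is written as TSV with a '#' metadata header
#' carrying the config hash and seed.
#'
#' @param config a `pipeline_config`.
#' @param input a `compound_dataset`, or a `scenario_config` to generate
#'   one, or a path to an SDF/JSON-lines file.
#' @param out_dir optional output directory for the result bundle.
#' @return list with the dataset, fingerprints, pair sets, overlap summary,
#'   NPI table, NPI histogram and threshold comparison.
#' @export
run_pipeline <- function(config, input, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "dataset build"
  bundle <- tryCatch({
    dataset <- if (inherits(input, "compound_dataset")) {
      input
    } else if (inherits(input, "scenario_config")) {
      generate_population(input)
    } else if (is.character(input)) {
      if (!file.exists(input)) {
        stop("input path does not exist: ", input, " (flag --input)")
      }
      recs <- if (grepl("\\.jsonl?$", input)) read_jsonl(input) else
        read_sdf(input)
      compound_dataset(basename(input), "A", recs)
    } else stop("unsupported input type")

    stage <- "2-D fingerprints"
    fps <- dataset_fingerprints(dataset)

    stage <- "2-D neighboring"
    p2 <- neighbors_2d(dataset, config$threshold_2d, fps)

    stage <- "3-D neighboring"
    p3 <- neighbors_3d(dataset, config$k_conformers, config$st_min,
                       config$ct_min)

    stage <- "pair classification"
    overlap <- classify_pairs(p2, p3)

    stage <- "NPI analysis"
    tab <- npi_table(dataset, p2, p3)
    hist <- npi_histogram(tab)

    stage <- "threshold statistics"
    thr <- threshold_comparison()

    list(dataset = dataset, fingerprints = fps, pairs2d = p2, pairs3d = p3,
         pairs = merge_neighbor_pairs(p2, p3), overlap = overlap,
         npi_table = tab, npi_histogram = hist,
         threshold_comparison = thr)
  }, error = function(e) {
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    h <- config_hash(config)
    s <- config$seed
    write_neighbor_pairs(bundle$pairs, file.path(out_dir, "neighbor_pairs.tsv"),
                         s, h)
    ov <- as.data.frame(bundle$overlap)
    write_tsv_with_header(ov, file.path(out_dir, "overlap_summary.tsv"),
                          "overlap_summary", s, h)
    tab <- bundle$npi_table
    tab$npi <- round(tab$npi, 2L)
    write_tsv_with_header(tab, file.path(out_dir, "npi_table.tsv"),
                          "npi_table", s, h, digits = 2L)
    hist_df <- data.frame(bin_center = bundle$npi_histogram$bin_centers,
                          count = bundle$npi_histogram$counts)
    write_tsv_with_header(hist_df, file.path(out_dir, "npi_histogram.tsv"),
                          "npi_histogram", s, h, digits = 1L)
    thr <- bundle$threshold_comparison
    thr_df <- data.frame(quantity = c("z_2d", "z_3d", "p_2d_pct", "p_3d_pct",
                                      "ratio"),
                         value = c(thr$z_2d, thr$z_3d, 100 * thr$p_2d,
                                   100 * thr$p_3d, thr$ratio))
    con <- file(file.path(out_dir, "threshold_stats.tsv"), "w")
    writeLines(tsv_header("threshold_stats", s, h), con)
    writeLines("quantity\tvalue", con)
    writeLines(sprintf("%s\t%.6g", thr_df$quantity, thr_df$value), con)
    close(con)
    write_fingerprints(bundle$fingerprints,
                       file.path(out_dir, "fingerprints.tsv"))
  }
  bundle
}
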