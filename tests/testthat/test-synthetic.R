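test_that("generation is fully deterministic under the seed", {
  cfg <- scenario_config("mixed", n_compounds = 24L, n_clusters = 4L,
                         seed = 77L)
  d1 <- generate_population(cfg)
  d2 <- generate_population(cfg)
  expect_identical(d1, d2)

  d3 <- generate_population(scenario_config("mixed", n_compounds = 24L,
                                            n_clusters = 4L, seed = 78L))
  expect_false(identical(d1, d3))

  # serialized round trip is byte-identical
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(d1, p1)
  write_jsonl(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("configs are validated", {
  expect_error(scenario_config("identical", n_compounds = 5L, n_clusters = 6L,
                               seed = 1L), "clusters")
  expect_error(scenario_config("identical", seed = 1L, salt_fraction = 1.5),
               "\\[0, 1\\]")
  expect_error(scenario_config("identical", seed = 1L,
                               subset_fractions = c(mesh = 0.2, protein3d = 0.3,
                                                    pharmact = 0.5, drug = 0.1)),
               "nesting")
  expect_error(scenario_config("identical"), "seed")
})

test_that("generated compounds are eligible and conformers match their graphs", {
  cfg <- scenario_config("mixed", n_compounds = 30L, n_clusters = 5L,
                         seed = 5L)
  ds <- generate_population(cfg)
  expect_equal(length(ds$records), 30L)
  for (r in ds$records) {
    expect_true(is_conformer_eligible(r$graph)$eligible)
    expect_length(r$conformers, 5L)
    for (cf in r$conformers) {
      expect_equal(nrow(cf$coords), nrow(r$graph$atoms))
    }
  }
})

test_that("planted scaffolds of distinct clusters stay below the 2-D threshold", {
  for (scen in c("identical", "disjoint")) {
    cfg <- scenario_config(scen, n_compounds = 16L, n_clusters = 8L,
                           seed = 2L)
    ds <- generate_population(cfg)
    cl <- attr(ds, "clusters")
    fps <- dataset_fingerprints(ds)
    cids <- dataset_cids(ds)
    for (i in seq_along(cids)) for (j in seq_along(cids)) {
      if (i >= j) next
      if (cl$cluster[i] == cl$cluster[j]) next
      expect_lt(tanimoto(fps[[as.character(cids[i])]],
                         fps[[as.character(cids[j])]]), 0.9)
    }
  }
})

test_that("salt forms are multi-component, conformer-less and collapse to parents", {
  cfg <- scenario_config("identical", n_compounds = 12L, n_clusters = 3L,
                         seed = 9L)
  ds <- generate_population(cfg)
  parent <- ds$records[[1L]]
  salts <- make_salt_forms(parent, n_forms = 2L, seed = 4L, next_cid = 100L)
  expect_length(salts, 2L)
  for (s in salts) {
    expect_length(enumerate_components(s$graph), 2L)
    el <- is_conformer_eligible(s$graph)
    expect_true("multi_component" %in% el$reasons)
    expect_length(s$conformers, 0L)
    expect_identical(s$annotations, parent$annotations)
  }

  # build_series_b over {P, P.X, P.Y} collapses to exactly {P}
  trio <- compound_dataset("trio", "A", c(list(parent), salts))
  out <- build_series_b(trio)
  expect_equal(length(out$records), 1L)
  expect_equal(out$records[[1L]]$cid, parent$cid)

  expect_error(make_salt_forms(salts[[1L]], seed = 1L, next_cid = 200L),
               "single-component")
})

test_that("annotation subsets are nested and cluster-enriched for drugs", {
  cfg <- scenario_config("identical", n_compounds = 60L, n_clusters = 6L,
                         seed = 21L,
                         subset_fractions = c(mesh = 0.5, protein3d = 0.3,
                                              pharmact = 0.25, drug = 0.2))
  ds <- generate_population(cfg)
  anns <- lapply(ds$records, function(r) r$annotations)
  mesh <- which(vapply(anns, function(a) "mesh" %in% a, logical(1)))
  pharm <- which(vapply(anns, function(a) "pharmact" %in% a, logical(1)))
  drug <- which(vapply(anns, function(a) "drug" %in% a, logical(1)))
  expect_true(all(pharm %in% mesh))
  expect_equal(length(mesh), 30L)
  expect_equal(length(drug), 12L)

  # enrichment concentrates the drug subset in few clusters relative to
  # uniform sampling: compare cluster spread against an enrichment-free run
  cl <- attr(ds, "clusters")
  n_cl_drug <- length(unique(cl$cluster[match(drug, cl$cid)]))
  cfg_flat <- scenario_config("identical", n_compounds = 60L, n_clusters = 6L,
                              seed = 21L, drug_enrichment = 1,
                              subset_fractions = c(mesh = 0.5, protein3d = 0.3,
                                                   pharmact = 0.25, drug = 0.2))
  ds_flat <- generate_population(cfg_flat)
  drug_flat <- which(vapply(ds_flat$records,
                            function(r) "drug" %in% r$annotations, logical(1)))
  n_cl_flat <- length(unique(cl$cluster[match(drug_flat, cl$cid)]))
  expect_lte(n_cl_drug, n_cl_flat)

  # fractions of one label everything
  cfg_all <- scenario_config("identical", n_compounds = 10L, n_clusters = 2L,
                             seed = 3L,
                             subset_fractions = c(mesh = 1, protein3d = 1,
                                                  pharmact = 1, drug = 1))
  ds_all <- generate_population(cfg_all)
  for (r in ds_all$records) {
    expect_setequal(r$annotations, c("mesh", "protein3d", "pharmact", "drug"))
  }
})

test_that("salt_fraction appends salt records that keep annotation nesting", {
  cfg <- scenario_config("identical", n_compounds = 20L, n_clusters = 4L,
                         salt_fraction = 0.3, seed = 13L)
  ds <- generate_population(cfg)
  expect_equal(length(ds$records), 26L)
  n_multi <- sum(vapply(ds$records, function(r) {
    length(enumerate_components(r$graph)) > 1L
  }, logical(1)))
  expect_equal(n_multi, 6L)

  # nesting survives the series B transformation
  b <- build_series_b(ds)
  mesh_b <- vapply(b$records, function(r) "mesh" %in% r$annotations, logical(1))
  pharm_b <- vapply(b$records, function(r) "pharmact" %in% r$annotations,
                    logical(1))
  expect_true(all(!pharm_b | mesh_b))
  expect_lte(length(b$records), 20L)
})
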