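test_that("covalent units are enumerated with provenance and deduplication", {
  expect_length(enumerate_components(benzene_graph()), 1L)

  mix <- salt_of(druglike_graph(), hcl_graph())
  comps <- enumerate_components(mix)
  expect_length(comps, 2L)
  expect_equal(attr(comps[[1L]], "atom_indices"), 1:9)
  expect_equal(attr(comps[[2L]], "atom_indices"), 10L)

  # A + A + B: three components, two unique units
  aab <- neighborpref:::graph_union(
    neighborpref:::graph_union(benzene_graph(), benzene_graph()),
    hcl_graph())
  comps <- enumerate_components(aab)
  expect_length(comps, 3L)
  expect_length(attr(comps, "unique_units"), 2L)
})

test_that("canonical form is invariant under atom reordering and stereo", {
  g1 <- chain_graph(4L, c("C", "N", "C", "O"))
  # same molecule with atoms listed in reverse
  g2 <- molecular_graph(c("O", "C", "N", "C"),
                        hcounts = rev(c(3L, 2L, 2L, 3L)),
                        bonds = data.frame(i = 1:3, j = 2:4, order = 1L))
  expect_identical(canonical_form(g1), canonical_form(g2))

  g3 <- molecular_graph(c("C", "N", "C", "O"),
                        hcounts = c(3L, 2L, 2L, 3L),
                        bonds = data.frame(i = 1:3, j = 2:4, order = 1L),
                        stereo = c(0L, 1L, 0L))
  expect_identical(canonical_form(g1), canonical_form(g3))

  # different bond order -> different form
  g4 <- molecular_graph(c("C", "N", "C", "O"),
                        hcounts = c(3L, 2L, 2L, 3L),
                        bonds = data.frame(i = 1:3, j = 2:4,
                                           order = c(1L, 2L, 1L)))
  expect_false(canonical_form(g1) == canonical_form(g4))
})

test_that("parent selection applies the 70 percent carbon rule", {
  # X (9 heavy, has C) + Y (1 heavy): 90% >= 70%
  mix <- salt_of(druglike_graph(), hcl_graph())
  p <- select_parent(mix)
  expect_false(is.null(p))
  expect_equal(heavy_atom_count(p), 9L)

  # 50/50 split of two distinct units: no parent
  even <- neighborpref:::graph_union(chain_graph(5L), mk_ring(5L))
  expect_null(select_parent(even))
  # but a duplicated unit counts once, so A+A selects A
  dup <- neighborpref:::graph_union(chain_graph(5L), chain_graph(5L))
  expect_false(is.null(select_parent(dup)))

  # dominant component without carbon: no parent
  nocarbon <- neighborpref:::graph_union(
    molecular_graph(rep("O", 9L), hcounts = 1L,
                    bonds = data.frame(i = 1:8, j = 2:9, order = 1L)),
    hcl_graph())
  expect_null(select_parent(nocarbon))

  # single-component carbon graph is its own parent
  expect_equal(canonical_form(select_parent(benzene_graph())),
               canonical_form(benzene_graph()))

  # duplicated counter-ions count once in the unique-unit total:
  # P (6 C) + 2x Cl: 6 / (6 + 1) = 86% >= 70%
  psalt2 <- neighborpref:::graph_union(
    salt_of(benzene_graph()), molecular_graph("Cl", charges = -1L))
  expect_false(is.null(select_parent(psalt2)))

  # idempotence where defined
  p1 <- select_parent(mix)
  expect_identical(canonical_form(select_parent(p1)), canonical_form(p1))
})

test_that("parent neutralization adjusts protonation on N, O and S", {
  # ammonium-like N+ with H -> neutral amine
  g <- molecular_graph(c("C", "N"), charges = c(0L, 1L),
                       hcounts = c(3L, 3L),
                       bonds = data.frame(i = 1L, j = 2L, order = 1L))
  out <- neutralize(g)
  expect_equal(out$atoms$charge, c(0L, 0L))
  expect_equal(out$atoms$hcount, c(3L, 2L))

  # carboxylate-like O- -> protonated
  g2 <- molecular_graph(c("C", "O"), charges = c(0L, -1L),
                        hcounts = c(3L, 0L),
                        bonds = data.frame(i = 1L, j = 2L, order = 1L))
  out2 <- neutralize(g2)
  expect_equal(out2$atoms$charge, c(0L, 0L))
  expect_equal(out2$atoms$hcount, c(3L, 1L))

  # quaternary N+ without H stays charged
  g3 <- molecular_graph(c("N", "C", "C", "C", "C"), charges = c(1L, 0L, 0L, 0L, 0L),
                        hcounts = c(0L, 3L, 3L, 3L, 3L),
                        bonds = data.frame(i = 1L, j = 2:5, order = 1L))
  expect_equal(neutralize(g3)$atoms$charge[1L], 1L)
})

test_that("rotatable bond counting follows the single/non-ring/non-terminal rule", {
  expect_equal(count_rotatable_bonds(chain_graph(2L)), 0L) # ethane
  expect_equal(count_rotatable_bonds(chain_graph(4L)), 1L) # n-butane
  expect_equal(count_rotatable_bonds(benzene_graph()), 0L) # all-ring
  # ring + 3-chain: ring-chain bond + 1 internal chain bond
  g <- neighborpref:::graph_union(benzene_graph(), chain_graph(3L))
  g <- molecular_graph(g$atoms$element, g$atoms$charge, g$atoms$hcount,
                       bonds = rbind(g$bonds[, c("i", "j", "order")],
                                     data.frame(i = 1L, j = 7L, order = 1L)))
  expect_equal(count_rotatable_bonds(g), 2L)
  # double bond in a chain is not rotatable
  g4 <- molecular_graph(rep("C", 4L), hcounts = 2L,
                        bonds = data.frame(i = 1:3, j = 2:4,
                                           order = c(1L, 2L, 1L)))
  expect_equal(count_rotatable_bonds(g4), 0L)
  expect_error(count_rotatable_bonds(salt_of(benzene_graph())),
               "component")
})

test_that("conformer eligibility applies all four rules and lists failures", {
  ok <- is_conformer_eligible(druglike_graph())
  expect_true(ok$eligible)
  expect_length(ok$reasons, 0L)

  big <- chain_graph(51L, hcounts = rep(2L, 51L))
  res <- is_conformer_eligible(big)
  expect_false(res$eligible)
  expect_true("too_large" %in% res$reasons)
  expect_true("too_flexible" %in% res$reasons) # 51-chain also too flexible
  expect_equal(is_conformer_eligible(chain_graph(50L))$reasons,
               "too_flexible")

  salt <- salt_of(benzene_graph())
  expect_true("multi_component" %in% is_conformer_eligible(salt)$reasons)

  metal <- molecular_graph(c("C", "Fe"), hcounts = c(3L, 0L),
                           bonds = data.frame(i = 1L, j = 2L, order = 1L))
  expect_true("non_organic_element" %in% is_conformer_eligible(metal)$reasons)

  # boundary: exactly 50 heavy atoms and 15 rotatable bonds passes
  ring40 <- mk_ring(40L)
  expect_true(is_conformer_eligible(ring40)$eligible)
})

test_that("series B construction collapses salt families and drops ineligible records", {
  parent <- druglike_graph()
  coords <- matrix(stats::rnorm(27), 9L, 3L)
  p_rec <- record_from_graph(10L, parent, coords, n_conf = 2L,
                             annotations = "mesh")
  s1 <- compound_record(11L, salt_of(parent), annotations = c("drug"))
  s2 <- compound_record(12L, salt_of(parent, molecular_graph("Br", charges = -1L)),
                        annotations = "drug")
  ds <- compound_dataset("fix", "A", list(p_rec, s1, s2))
  out <- build_series_b(ds)
  expect_equal(length(out$records), 1L)
  expect_equal(out$records[[1L]]$cid, 10L)
  # annotations merged by union
  expect_setequal(out$records[[1L]]$annotations, c("mesh", "drug"))

  # 50/50 mixture of distinct units: no parent, dropped
  mix <- compound_record(13L, neighborpref:::graph_union(chain_graph(5L),
                                                         mk_ring(5L)))
  ds2 <- compound_dataset("fix2", "A", list(p_rec, mix))
  expect_equal(length(build_series_b(ds2)$records), 1L)

  # parent without conformers is dropped (no 3-D description available)
  lone_salt <- compound_dataset("fix3", "A", list(s1))
  expect_equal(length(build_series_b(lone_salt)$records), 0L)
})

test_that("series B output matches brute-force enumeration on a mixed fixture", {
  set.seed(42)
  # 4 parent scaffolds, 8 salt forms over them, 2 oversized compounds,
  # plus 6 plain eligible singletons
  parents <- list(
    druglike_graph(), benzene_graph(), mk_ring(5L), chain_graph(6L))
  records <- list()
  cid <- 0L
  for (p in parents) {
    cid <- cid + 1L
    np <- nrow(p$atoms)
    records[[cid]] <- record_from_graph(cid, p,
                                        matrix(stats::rnorm(3 * np), np, 3L))
  }
  ions <- default_counter_ions()
  for (k in 1:8) {
    cid <- cid + 1L
    host <- parents[[(k - 1L) %% 4L + 1L]]
    records[[cid]] <- compound_record(cid, salt_of(host, ions[[(k - 1L) %% 5L + 1L]]))
  }
  for (k in 1:2) {
    cid <- cid + 1L
    big <- chain_graph(51L, hcounts = rep(2L, 51L))
    records[[cid]] <- record_from_graph(cid, big, matrix(0, 51L, 3L))
  }
  for (k in 1:6) {
    cid <- cid + 1L
    g <- mk_ring(6L + k)
    records[[cid]] <- record_from_graph(cid, g, ring_coords(6L + k))
  }
  ds <- compound_dataset("enum", "A", records)
  out <- build_series_b(ds)

  # oracle: brute-force application of the rule
  expected_keys <- character()
  for (r in records) {
    comps <- enumerate_components(r$graph)
    target <- if (length(comps) == 1L) r$graph else select_parent(r$graph)
    if (is.null(target)) next
    if (!is_conformer_eligible(target)$eligible) next
    expected_keys <- c(expected_keys, canonical_form(target))
  }
  # of the unique parents, only those whose own record carries conformers
  # survive; salts contribute no conformers
  with_conf <- vapply(records, function(r) {
    length(r$conformers) > 0L &&
      length(enumerate_components(r$graph)) == 1L &&
      is_conformer_eligible(r$graph)$eligible
  }, logical(1))
  conf_keys <- vapply(records[with_conf],
                      function(r) canonical_form(r$graph), character(1))
  expected <- intersect(unique(expected_keys), conf_keys)
  got <- vapply(out$records, function(r) canonical_form(r$graph), character(1))
  expect_setequal(got, expected)
  expect_equal(length(out$records), 10L) # 4 parents + 6 singletons

  # every series B record is eligible and single-component
  for (r in out$records) {
    expect_true(is_conformer_eligible(r$graph)$eligible)
    expect_length(enumerate_components(r$graph), 1L)
  }
  expect_lte(length(out$records), length(ds$records))
})
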