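test_that("aromaticity degree matches hand counts", {
  expect_equal(aromaticity_degree(BENZENE), 1.0)
  expect_equal(aromaticity_degree(ETHANE), 0.0)
  expect_equal(aromaticity_degree(STYRENE), 6 / 8)
  expect_error(aromaticity_degree("not-a-molecule"))
})

test_that("conjugation degree follows toolkit perception", {
  expect_equal(conjugation_degree(ETHANE), 0.0)
  expect_equal(conjugation_degree(BENZENE), 1.0)
  expect_equal(conjugation_degree(BUTADIENE), 1.0)
  expect_equal(conjugation_degree("C"), 0.0)  # no heavy-heavy bonds
})

test_that("ring size extrema use the smallest set of smallest rings", {
  expect_equal(ring_size_extrema(BENZENE), c(6L, 6L))
  expect_equal(ring_size_extrema(AZULENE), c(5L, 7L))
  expect_null(ring_size_extrema(HEXANE))
})

test_that("structural counts match definitions", {
  expect_equal(unname(structural_counts(AZULENE)), c(0, 0, 0, 0, 18))
  expect_equal(unname(structural_counts(SPIROPENTANE)["spiro"]), 1)
  expect_equal(unname(structural_counts(ACETATE)["charge"]), -1)
  expect_equal(unname(structural_counts("C1CC2CCC1CC2")["bridgehead"]), 2)
})

test_that("filter verdicts apply every rule", {
  v <- apply_pi_filters(AZULENE)
  expect_true(v$passed)
  expect_named(v$per_rule, c("charge", "radicals", "bridgehead", "spiro",
                             "aromaticity", "conjugation", "ring_min",
                             "ring_max", "substructures", "atom_cap"))

  v2 <- apply_pi_filters(CYCLOPROPANE)
  expect_false(v2$passed)
  expect_false(v2$per_rule$ring_min$passed)    # ring of size 3 < 4
  expect_false(v2$per_rule$aromaticity$passed) # 0 < 0.5

  v3 <- apply_pi_filters(HEXANE)
  expect_false(v3$passed)
  expect_false(v3$per_rule$ring_min$passed)    # acyclic fails ring rules
  expect_false(v3$per_rule$ring_max$passed)
  expect_false(v3$per_rule$conjugation$passed)

  expect_error(apply_pi_filters("####"))
})

test_that("degrees use >= comparisons at the boundary", {
  cfg <- pi_filter_config(min_aromaticity_degree = 0.75,
                          min_conjugation_degree = 1.0)
  v <- apply_pi_filters(STYRENE, cfg)  # aromaticity exactly 0.75
  expect_true(v$per_rule$aromaticity$passed)
})

test_that("forbidden substructures and the atom cap are enforced", {
  cfg <- pi_filter_config(forbidden_substructures = "c1ccccc1")
  expect_false(apply_pi_filters(NAPHTHALENE, cfg)$per_rule$substructures$passed)
  expect_true(apply_pi_filters(AZULENE, cfg)$per_rule$substructures$passed)

  cfg2 <- pi_filter_config(max_total_atoms = 17L)
  expect_false(apply_pi_filters(AZULENE, cfg2)$per_rule$atom_cap$passed)  # 18
  cfg3 <- pi_filter_config(max_total_atoms = 18L)
  expect_true(apply_pi_filters(AZULENE, cfg3)$per_rule$atom_cap$passed)
})

test_that("verdict equals conjunction of rules; representation-independent", {
  d <- chem_describe(corpus_smiles())
  tab <- pi_filter_table(d, pi_filter_config())
  rules_only <- tab[setdiff(names(tab), "passed")]
  expect_identical(tab$passed, Reduce(`&`, rules_only))

  # two different SMILES of azulene give identical verdicts
  v1 <- apply_pi_filters(AZULENE)
  v2 <- apply_pi_filters("c1ccc2cccc-2cc1")
  v1$canonical <- v2$canonical <- NULL
  expect_identical(v1, v2)
})

test_that("adding a saturated carbon never raises the degrees", {
  pairs <- list(c(AZULENE, "CC1=CC2=CC=CC=CC2=C1"),
                c(BENZENE, "Cc1ccccc1"),
                c(BUTADIENE, "CC=CC=C"))
  for (p in pairs) {
    expect_lte(aromaticity_degree(p[2]), aromaticity_degree(p[1]))
    expect_lte(conjugation_degree(p[2]), conjugation_degree(p[1]))
  }
})

test_that("batch .smi filtering reports every molecule", {
  tmp_in <- tempfile(fileext = ".smi")
  tmp_out <- tempfile(fileext = ".csv")
  writeLines(c(paste(AZULENE, "azulene"), paste(HEXANE, "hexane"),
               "xxxx broken"), tmp_in)
  rep <- filter_smi_file(tmp_in, tmp_out)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$passed, c(TRUE, FALSE, FALSE))
  back <- utils::read.csv(tmp_out)
  expect_equal(nrow(back), 3L)
})
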