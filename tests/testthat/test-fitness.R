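test_that("fitness components reproduce the reference arithmetic", {
  run2 <- fitness_spec_for_run(2)
  expect_equal(stg_component(0.24, run2), 0.06)
  expect_equal(stg_component(0.5, run2), FITNESS_PENALTY)
  expect_equal(stg_component(0.3, run2), 0.0)  # boundary is non-negative

  expect_equal(os_component(0.005, run2), 0.005)
  expect_equal(os_component(-0.01, run2), FITNESS_PENALTY)
  expect_equal(os_component(0, run2), 0.0)

  run4 <- fitness_spec_for_run(4)
  expect_equal(vee_component(3.2, run4), 0.0)
  expect_equal(vee_component(2.71, run4), -0.49)
  expect_equal(vee_component(-0.1, run4), FITNESS_PENALTY)
  expect_equal(vee_component(2.71, run2), 0.0)  # no VEE term in run 2
  expect_equal(vee_component(-0.1, run2), FITNESS_PENALTY)  # requirement stays
})

test_that("total fitness sums components; seed scores 0.065 under run 2", {
  seed <- data.frame(stg = 0.24, os = 0.005, vee = 2.71)
  expect_equal(total_fitness(seed, fitness_spec_for_run(2)), 0.065)
  # penalty accumulates with a valid component
  p <- data.frame(stg = 0.5, os = 0.1, vee = 2.0)
  expect_equal(total_fitness(p, fitness_spec_for_run(2)), FITNESS_PENALTY + 0.1)
  # run 3: threshold gate without the linear term
  run3 <- fitness_spec_for_run(3)
  expect_equal(total_fitness(seed, run3), 0.005)
  expect_equal(total_fitness(data.frame(stg = 0.4, os = 0.1, vee = 2), run3),
               FITNESS_PENALTY + 0.1)
  # double violation gets a double penalty
  pp <- data.frame(stg = 0.5, os = -1, vee = 2.0)
  expect_equal(total_fitness(pp, fitness_spec_for_run(2)), 2 * FITNESS_PENALTY)
})

test_that("penalty dominance: any penalized molecule ranks below all clean ones", {
  set.seed(21)
  props <- data.frame(stg = runif(200, -0.2, 0.9), os = runif(200, -0.1, 1.5),
                      vee = runif(200, -0.5, 4))
  spec <- fitness_spec_for_run(4)
  f <- total_fitness(props, spec)
  # independent flag: violates any stated minimum requirement
  violated <- props$stg > spec$stg_threshold | props$os < 0 | props$vee < 0
  if (any(violated) && any(!violated)) {
    expect_lt(max(f[violated]), min(f[!violated]))
  }
  # monotonicity below threshold under run 2
  run2 <- fitness_spec_for_run(2)
  clean <- props[!violated & props$vee >= 0, , drop = FALSE]
  f1 <- total_fitness(clean, run2)
  f2 <- total_fitness(transform(clean, stg = stg - 0.01), run2)
  f3 <- total_fitness(transform(clean, os = os + 0.01), run2)
  expect_true(all(f2 > f1))
  expect_true(all(f3 > f1))
})

test_that("synthetic oracle matches its closed form by hand", {
  o <- synthetic_oracle(c(AZULENE, ETHANE))
  # azulene: azu 1, nN 0, donors 0, conj 1, heavy 10
  expect_equal(o$stg[1], 0.9 - 0.55 - 0 + 0.015 * 12)  # 0.53
  expect_equal(o$os[1], 0.02 + 0 + 0.3 * 1 * 10 / 40)  # 0.095
  expect_equal(o$vee[1], 1.8 + 0.04 * 10)
  # ethane: azu 0, heavy 2
  expect_equal(o$stg[2], 0.9 + 0.015 * 20)  # 1.2
  expect_true(all(o$status == "ok"))
  # purity: same molecule, same triple
  o2 <- synthetic_oracle(AZULENE)
  expect_equal(o2$stg, o$stg[1])
})

test_that("the synthetic oracle admits gap inversion at its stated minimum", {
  # azulene-like, >= 6 aromatic ring nitrogens, 22 heavy atoms -> stg = -0.13
  s <- attach_identical_substituents(c(2L, 5L, 7L), "c1ccncn1", c(4L, 8L))
  d <- chem_describe(s)
  expect_true(d$azulene_like)
  expect_gte(d$n_arom_n, 6)
  o <- synthetic_oracle(s)
  expect_equal(o$stg, -0.13 + 0.015 * abs(d$heavy - 22))
})

test_that("lookup oracle returns stored triples and explicit misses", {
  tab <- seed_property_row()
  oracle <- lookup_oracle(tab)
  res <- oracle(c(triaza_core(), BENZENE))
  expect_equal(res$stg[1], 0.24)
  expect_equal(res$os[1], 0.005)
  expect_equal(res$vee[1], 2.71)
  expect_equal(res$status, c("ok", "missing"))
  # CSV round trip preserves the triples
  tmp <- tempfile(fileext = ".csv")
  write_property_csv(tab, tmp)
  oracle2 <- lookup_oracle(read_property_csv(tmp))
  expect_equal(oracle2(triaza_core())$stg, 0.24)
})
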