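test_that("ranking is descending with deterministic canonical tie-break", {
  recs <- data.frame(canonical = c("b", "a", "c"),
                     fitness = c(0.1, 0.5, -1e6))
  r <- rank_population(recs)
  expect_equal(r$fitness, c(0.5, 0.1, -1e6))
  tied <- data.frame(canonical = c("z", "a"), fitness = c(0.3, 0.3))
  expect_equal(rank_population(tied)$canonical, c("a", "z"))
  expect_error(rank_population(data.frame(canonical = "x",
                                          fitness = NA_real_)))
  # equals an independent sort oracle on random inputs
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    recs <- data.frame(canonical = replicate(n, paste(sample(letters, 6,
                                                             TRUE),
                                                      collapse = "")),
                       fitness = sample(round(runif(n), 2), n, TRUE))
    got <- rank_population(recs)
    ref <- recs[order(-recs$fitness, recs$canonical, method = "radix"), ]
    expect_equal(got$canonical, ref$canonical)
  }
})

test_that("elite selection uses max(1, floor(fraction * N))", {
  mk <- function(n) data.frame(canonical = sprintf("m%03d", seq_len(n)),
                               fitness = rev(seq_len(n)))
  expect_equal(nrow(select_elites(mk(10))), 2L)
  expect_equal(nrow(select_elites(mk(3))), 1L)
  expect_equal(nrow(select_elites(mk(4))), 1L)  # floor(0.8) = 0 -> min 1
  expect_equal(nrow(select_elites(mk(100))), 20L)
  # elites are the argmax set
  set.seed(3)
  recs <- data.frame(canonical = sprintf("m%03d", 1:50),
                     fitness = runif(50))
  ranked <- rank_population(recs)
  el <- select_elites(ranked)
  expect_gte(min(el$fitness), max(ranked$fitness[-seq_len(nrow(el))]))
})

test_that("a desk-scale campaign is monotone, unique and capped", {
  cfg <- campaign_preset(2, population_cap = 60L, rng_seed = 17L)
  cfg$n_generations <- 5L
  res <- suppressWarnings(run_campaign(cfg, synthetic_oracle))
  expect_length(res$logs, 5L)
  expect_true(all(diff(res$summary$best_fitness) >= 0))
  expect_true(all(res$summary$n_molecules <= 60L))
  # no canonical form recurs among newly evaluated molecules across generations
  news <- lapply(seq_along(res$logs), function(g) {
    df <- res$logs[[g]]
    prev <- if (g > 1) unique(unlist(lapply(res$logs[1:(g - 1)],
                                            `[[`, "canonical"))) else character()
    setdiff(df$canonical, prev)
  })
  allnew <- unlist(news)
  expect_false(anyDuplicated(allnew) > 0)
  # run-1 preset stops after generation 11
  expect_equal(campaign_preset(1)$n_generations, 11L)
  expect_equal(campaign_preset(2)$n_generations, 15L)
})

test_that("training data collection labels every unique molecule once", {
  logs <- list(
    data.frame(generation = 1L, canonical = c("a", "b"),
               stg = c(0.5, 0.7), os = c(0.1, 0.2),
               vee = c(2, 2), status = "ok", stringsAsFactors = FALSE),
    data.frame(generation = 2L, canonical = c("b", "c", "d"),
               stg = c(0.7, 0.59, 0.2), os = c(0.2, 0.0, -1),
               vee = c(2, 2, 2), status = c("ok", "ok", "failed"),
               stringsAsFactors = FALSE)
  )
  td <- collect_training_data(logs)
  expect_equal(nrow(td), 3L)  # a, b unique; c kept; d failed
  expect_equal(td$label[td$canonical == "a"], "good")
  expect_equal(td$label[td$canonical == "b"], "bad")  # stg 0.7 >= 0.6
  expect_equal(td$label[td$canonical == "c"], "bad")  # os not > 0
  single <- list(data.frame(generation = 1L, canonical = c("a", "b"),
                            stg = c(0.1, 0.1), os = c(1, 1), vee = c(2, 2),
                            status = "ok", stringsAsFactors = FALSE))
  expect_warning(td2 <- collect_training_data(single), "single class")
  expect_true(isTRUE(attr(td2, "degenerate")))
})

test_that("campaign reports count INVEST candidates consistently", {
  cfg <- campaign_preset(6, population_cap = 40L, rng_seed = 23L)
  cfg$n_generations <- 3L
  res <- suppressWarnings(run_campaign(cfg, synthetic_oracle))
  rep <- campaign_report(res)
  expect_lte(rep$invest["n_invest_with_os"], rep$invest["n_invest"])
  expect_lte(rep$invest["n_invest"], rep$n_evaluated)
  expect_equal(rep$n_generated, rep$n_evaluated + rep$n_failed)
})
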