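test_that("label rule uses strict inequalities", {
  expect_equal(label_example(0.5, 0.1), "good")
  expect_equal(label_example(0.6, 0.1), "bad")
  expect_equal(label_example(0.5, 0.0), "bad")
  expect_equal(label_example(c(0.59999, -0.1), c(1e-9, 0.5)),
               c("good", "good"))
})

test_that("split respects the 48/32/20 contract and is seed-reproducible", {
  lab100 <- rep(c("good", "bad"), 50)
  sp <- split_dataset(100L, lab100, split_seed = 7L)
  expect_length(sp$train, 48L)
  expect_length(sp$validation, 32L)
  expect_length(sp$holdout, 20L)
  sp10 <- split_dataset(10L, rep(c("good", "bad"), 5), split_seed = 7L)
  expect_equal(lengths(sp10[c("train", "validation", "holdout")]),
               c(train = 5L, validation = 3L, holdout = 2L))
  # disjoint and exhaustive for a sweep of sizes
  for (n in c(11L, 25L, 73L, 200L)) {
    sp_n <- split_dataset(n, rep(c("good", "bad"), length.out = n), 3L)
    all_idx <- sort(unname(unlist(sp_n)))
    expect_equal(all_idx, seq_len(n))
    expect_length(sp_n$train, round(0.48 * n))
    expect_length(sp_n$validation, round(0.32 * n))
  }
  sp2 <- split_dataset(100L, lab100, split_seed = 7L)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_dataset(100L, lab100, split_seed = 8L)))
  expect_error(split_dataset(100L, rep("good", 100), 1L), "single label")
  expect_error(split_dataset(5L, rep(c("good", "bad"), length.out = 5), 1L))
})

test_that("fingerprints are deterministic with 1024 bits", {
  X <- fingerprint_matrix(c(AZULENE, AZULENE, BENZENE))
  expect_equal(dim(X), c(3L, 1024L))
  expect_equal(X[1, ], X[2, ])
  expect_false(all(X[1, ] == X[3, ]))
  expect_true(all(X %in% c(0, 1)))
})

test_that("the network separates a designated-bit rule perfectly", {
  set.seed(55)
  n <- 300L
  X <- matrix(rbinom(n * 64, 1, 0.3), n, 64)
  y <- X[, 7]
  set.seed(100)  # weight init and shuffling
  fit <- mlp_train(X[1:200, ], y[1:200], X[201:250, ], y[201:250],
                   hidden = c(32L, 16L), lr = 3e-3, epochs = 300L,
                   patience = 100L, dropout = 0)
  ph <- mlp_forward(fit$par, X[251:300, ])$p
  expect_equal(mean((ph > 0.5) == (y[251:300] == 1)), 1.0)
})

test_that("label-shuffled data trains to chance-level accuracy", {
  set.seed(56)
  n <- 240L
  X <- matrix(rbinom(n * 64, 1, 0.3), n, 64)
  y <- rbinom(n, 1, 0.5)  # labels independent of features
  fit <- mlp_train(X[1:160, ], y[1:160], X[161:200, ], y[161:200],
                   hidden = c(16L, 16L), lr = 5e-3, epochs = 40L,
                   patience = 10L, dropout = 0)
  ph <- mlp_forward(fit$par, X[201:240, ])$p
  acc <- mean((ph > 0.5) == (y[201:240] == 1))
  maj <- max(mean(y[201:240]), 1 - mean(y[201:240]))
  expect_lte(acc, maj + 0.2)  # nothing real can be learned
})

test_that("accuracy equals the hand-computed confusion matrix", {
  pred <- c("good", "good", "bad", "bad", "good", "bad", "good", "bad",
            "good", "bad")
  truth <- c("good", "bad", "bad", "good", "good", "bad", "bad", "bad",
             "good", "good")
  # by hand: correct at positions 1,3,5,6,8,9 -> 6/10
  expect_equal(accuracy(pred, truth), 0.6)
  expect_equal(accuracy(truth, truth), 1.0)
})

test_that("the gate passes exactly the predicted-good subset in order", {
  toy <- function(smiles) as.numeric(grepl("n", smiles))
  cands <- c(BENZENE, triaza_core(), AZULENE, "c1ccncc1")
  kept <- cands[gate_candidates(toy, cands)]
  expect_equal(kept, c(triaza_core(), "c1ccncc1"))
  expect_equal(gate_candidates(toy, character()), logical())
})

test_that("tuning selects by validation accuracy and reports holdout accuracy", {
  set.seed(60)
  # molecule-level separable task: aromatic-nitrogen molecules are good
  goods <- c(triaza_core(), "c1ccncc1", "c1ccncn1", "c1cnc2cncc-2cn1",
             "Nc1ncnc(N)c2cncc1-2", "c1cncc2cccc-2c1")
  bads <- c(BENZENE, AZULENE, NAPHTHALENE, "c1ccc2[nH]ccc2c1", STYRENE,
            "C#Cc1ccccc1")
  data <- data.frame(
    canonical = chem_canonical(rep(c(goods, bads), 3)),
    label = rep(rep(c("good", "bad"), c(length(goods), length(bads))), 3),
    stringsAsFactors = FALSE
  )
  m <- train_with_tuning(data, space = search_space(epochs = c(20L, 40L),
                                                    neurons = c(16L, 32L)),
                         n_trials = 3L, split_seed = 11L)
  expect_s3_class(m, "invest_classifier")
  expect_equal(nrow(m$trials), 3L)
  expect_gte(m$holdout_accuracy, 0.8)
  expect_true(all(predict_good(m, goods[1:2]) >= 0))
})
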