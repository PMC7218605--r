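test_that("parameter initialization is seeded and shape-consistent", {
  v <- test_vocab()
  cfg <- tiny_config(v)
  a <- build_model(cfg, v)
  b <- build_model(cfg, v)
  expect_identical(a$params, b$params)
  expect_equal(dim(a$params$E), c(v$V + 2L, cfg$embed_dim))
  expect_equal(unname(a$params$E[1, ]), rep(0, cfg$embed_dim))  # frozen pad row
  expect_equal(nrow(a$params$W_out), v$V)
  # gender ablation removes the gender parameters entirely
  cfg_ng <- tiny_config(v, use_gender = FALSE)
  expect_null(build_model(cfg_ng, v)$params$G)
  expect_error(build_model(tiny_config(make_synthetic_vocabulary(2, 5)), v),
               "V=")
})

test_that("embedding lookups equal explicit one-hot x projection products", {
  v <- test_vocab()
  coder <- build_model(tiny_config(v), v)
  p <- coder$params
  onehot_prod <- function(i, tab) {
    oh <- numeric(nrow(tab)); oh[i] <- 1
    as.numeric(oh %*% tab)
  }
  # codes (including pad and unknown rows), age, year, gender, row
  for (i in c(1L, 5L, v$V + 2L)) {
    expect_lt(max(abs(p$E[i, ] - onehot_prod(i, p$E))), 1e-6)
  }
  for (i in c(1L, 13L, 25L)) {
    expect_lt(max(abs(p$A[i, ] - onehot_prod(i, p$A))), 1e-6)
  }
  for (i in c(1L, 16L)) {
    expect_lt(max(abs(p$Yr[i, ] - onehot_prod(i, p$Yr))), 1e-6)
  }
  for (i in 1:2) {
    expect_lt(max(abs(p$G[i, ] - onehot_prod(i, p$G))), 1e-6)
  }
  for (i in 1:6) {
    expect_lt(max(abs(p$R[i, ] - onehot_prod(i, p$R))), 1e-6)
  }
  # and the full input construction reproduces the one-hot route end to end:
  # embed(grid) + demographic broadcast equals the explicit dummy encoding
  m <- test_cause_model()
  set.seed(4)
  ct <- sample_certificate(m)
  cfg <- coder$config
  grid <- encode_grid(ct, v, cfg$L, cfg$W)
  dem <- demographics(ct, cfg$base_year, cfg$Y)
  manual <- function(r, c) {
    x <- onehot_prod(grid[r, c] + 1L, p$E)
    if (grid[r, c] != 0L) {
      x <- x + onehot_prod(dem$age_bin + 1L, p$A) +
        onehot_prod(dem$year_index + 1L, p$Yr) +
        onehot_prod(dem$gender + 1L, p$G) + onehot_prod(r, p$R)
    }
    x
  }
  batch <- ucdcoder:::prep_batch(list(ct), v, cfg)
  fw <- ucdcoder:::coder_forward(p, cfg, batch, crop = FALSE)
  for (cell in list(c(1, 1), c(2, 1), c(5, 1), c(3, 7))) {
    got <- fw$X[, cell[1] + (cell[2] - 1) * cfg$L]
    expect_lt(max(abs(got - manual(cell[1], cell[2]))), 1e-6)
  }
})

test_that("predictions are valid, deterministic probability distributions", {
  v <- test_vocab()
  m <- test_cause_model()
  coder <- build_model(tiny_config(v), v)
  certs <- generate_dataset(m, 30, seed = 44)
  probs <- predict_proba_batch(coder, certs, v)
  expect_equal(dim(probs), c(30L, v$V))
  expect_true(all(probs >= 0))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-5))
  expect_identical(probs, predict_proba_batch(coder, certs, v))
  # a zeroed output layer yields the exactly uniform distribution
  unif <- coder
  unif$params$W_out[] <- 0
  p <- predict_proba(unif, certs[[1]], v)
  expect_equal(unname(p), rep(1 / v$V, v$V), tolerance = 1e-12)
})

test_that("top-k predictions are ranked, tie-broken, and nested", {
  v <- test_vocab()
  m <- test_cause_model()
  coder <- tiny_trained_coder()
  set.seed(3)
  ct <- sample_certificate(m)
  p <- predict_proba(coder, ct, v)
  topV <- predict_topk(coder, ct, v, v$V)
  expect_setequal(topV$code, v$codes)
  expect_true(all(diff(topV$prob) <= 0))
  top1 <- predict_topk(coder, ct, v, 1)
  expect_equal(top1$code, names(p)[which.max(p)])
  top2 <- predict_topk(coder, ct, v, 2)
  expect_true(top1$code %in% top2$code)
  expect_error(predict_topk(coder, ct, v, 0), "k must be")
  expect_error(predict_topk(coder, ct, v, v$V + 1), "k must be")
})

test_that("the coder is sensitive to row permutations (Part I vs Part II)", {
  v <- test_vocab()
  m <- test_cause_model()
  coder <- build_model(tiny_config(v), v)
  pair <- m$promotion_pairs[1, ]
  in_part2 <- new_certificate("a", part1 = list(pair$pattern),
                              part2 = list(pair$trigger), sex = "M",
                              age_value = 50, year = 2005)
  in_part1 <- new_certificate("b", part1 = list(pair$pattern, pair$trigger),
                              sex = "M", age_value = 50, year = 2005)
  pa <- predict_proba(coder, in_part2, v)
  pb <- predict_proba(coder, in_part1, v)
  expect_gt(max(abs(pa - pb)), 1e-8)
})

test_that("width padding is exactly neutral: wider grids do not change output", {
  v <- test_vocab()
  m <- test_cause_model()
  coder <- build_model(model_config(v, seed = 42), v)  # full default config
  certs <- generate_dataset(m, 20, seed = 55)
  wide <- coder
  wide$config$W <- 30L
  for (ct in certs[1:10]) {
    p20 <- predict_proba(coder, ct, v, crop = FALSE)
    p30 <- predict_proba(wide, ct, v, crop = FALSE)
    expect_lt(max(abs(p20 - p30)), 1e-10)
    expect_identical(which.max(p20), which.max(p30))
  }
  # the internal column-cropping shortcut is exact too
  for (ct in certs[11:15]) {
    expect_lt(max(abs(predict_proba(coder, ct, v, crop = TRUE) -
                        predict_proba(coder, ct, v, crop = FALSE))), 1e-12)
  }
})

test_that("training reduces the cross-entropy and is seed-deterministic", {
  v <- test_vocab()
  m <- test_cause_model()
  certs <- generate_dataset(m, 10, seed = 66)
  coder <- build_model(tiny_config(v), v)
  golds <- vapply(certs, `[[`, "", "gold_ucd")
  init_probs <- predict_proba_batch(coder, certs, v)
  init_loss <- -mean(log(init_probs[cbind(1:10, unname(v$index[golds]))]))
  fit <- train_coder(coder, certs, certs, v,
                     opt_params = list(epochs = 3, batch_size = 10, seed = 2),
                     quiet = TRUE)
  # epoch 1 records the pre-update loss; later epochs must descend below it
  expect_equal(fit$history$train_loss[1], init_loss, tolerance = 1e-10)
  expect_lt(fit$history$train_loss[3], init_loss)
  final_probs <- predict_proba_batch(fit, certs, v)
  final_loss <- -mean(log(final_probs[cbind(1:10, unname(v$index[golds]))]))
  expect_lt(final_loss, init_loss)
  fit2 <- train_coder(coder, certs, certs, v,
                      opt_params = list(epochs = 3, batch_size = 10, seed = 2),
                      quiet = TRUE)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
  # empty train set and labels outside the vocabulary are rejected
  expect_error(train_coder(coder, list(), certs, v), "empty")
  bad <- certs
  bad[[1]]$gold_ucd <- "Z999"
  expect_error(train_coder(coder, bad, certs, v, quiet = TRUE),
               "outside the vocabulary")
})

test_that("held-out agreement grows with training set size on the tiny task", {
  # scaled-down sanity version of the recovery surrogate: more data, better
  # agreement with the deterministic rule system
  v <- test_vocab()
  m <- test_cause_model()
  test <- generate_dataset(m, 300, seed = 90)
  golds <- vapply(test, `[[`, "", "gold_ucd")
  accs <- vapply(c(200, 1000), function(n) {
    fit <- train_coder(build_model(tiny_config(v), v),
                       generate_dataset(m, n, seed = 91),
                       test[1:50], v,
                       opt_params = list(epochs = 4, batch_size = 64, seed = 6),
                       quiet = TRUE)
    mean(predict_ucd(fit, test, v) == golds)
  }, 0)
  expect_gt(accs[2], accs[1])
})

test_that("checkpoints round-trip bit-identically and guard the vocabulary", {
  v <- test_vocab()
  m <- test_cause_model()
  coder <- tiny_trained_coder()
  path <- withr::local_tempfile(fileext = ".rds")
  save_coder(coder, path)
  back <- load_coder(path)
  set.seed(12)
  ct <- sample_certificate(m)
  expect_identical(predict_proba(coder, ct, v), predict_proba(back, ct, v))
  expect_identical(back$history, coder$history)
  # loading against a different vocabulary errors at prediction
  other <- make_synthetic_vocabulary(20, 10, seed = 99)
  expect_error(predict_proba(back, ct, other), "fingerprint")
  # an untrained checkpoint reproduces the seeded initialization
  fresh <- build_model(tiny_config(v), v)
  p2 <- withr::local_tempfile(fileext = ".rds")
  save_coder(fresh, p2)
  expect_identical(load_coder(p2)$params, build_model(tiny_config(v), v)$params)
  expect_error(load_coder(withr::local_tempfile(lines = "x")), "")
})

test_that("certificates with out-of-vocabulary codes are still codable", {
  v <- test_vocab()
  coder <- build_model(tiny_config(v), v)
  ct <- new_certificate("u", list(c(v$codes[1], "Z999")), sex = "F",
                        age_value = 70, year = 2010)
  p <- predict_proba(coder, ct, v)
  expect_equal(sum(p), 1, tolerance = 1e-8)
})
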