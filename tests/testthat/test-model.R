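test_that("model configuration validates its geometry", {
  expect_error(model_config(3, 16, 1), "n_classes")
  expect_error(model_config(3, 16, 3, shots = 0), "shots")
  expect_error(model_config(3, 16, 3, dropout = 1), "dropout")
  expect_error(model_config(3, 3, 3), "pooling")
  cfg <- model_config(9, 200, 4)
  expect_equal(cfg$feat_len, 50L)
})

test_that("initialization is deterministic in (config, seed)", {
  cfg <- tiny_config()
  m1 <- init_model(cfg, 42)
  m2 <- init_model(cfg, 42)
  expect_identical(m1, m2)
  m3 <- init_model(cfg, 43)
  expect_false(identical(m1$extractor$conv1$W, m3$extractor$conv1$W))
  # heads share topology but not parameters
  expect_identical(dim(m1$heads$main$fc1$W), dim(m1$heads$aux1$fc1$W))
  expect_false(identical(m1$heads$main$fc1$W, m1$heads$aux1$fc1$W))
})

test_that("feature extraction has the documented geometry and range", {
  cfg <- model_config(9, 200, 4)
  m <- init_model(cfg, 1)
  set.seed(5)
  ws <- window_set(array(rnorm(9 * 200 * 7), c(9, 200, 7)),
                   rep(0L, 7), rep("S", 7), 0:6, 1000)
  fm <- extract_features(m, ws)
  expect_equal(dim(fm), c(16L, 50L, 7L))        # 200 -> 100 -> 50
  expect_true(all(fm > -1 & fm < 1))            # pooled Softsign outputs

  # order preserved; batch equals per-window evaluation
  one <- extract_features(m, ws_subset(ws, 3))
  expect_equal(fm[, , 3], one[, , 1], tolerance = 1e-12)

  zeros <- window_set(array(0, c(9, 200, 2)), rep(0L, 2), rep("S", 2),
                      0:1, 1000)
  expect_true(all(is.finite(extract_features(m, zeros))))

  bad <- window_set(array(0, c(5, 200, 1)), 0L, "S", 0L, 1000)
  expect_error(extract_features(m, bad), "match")
})

test_that("relation-matrix combination follows the replicate-and-sum rule", {
  cfg <- tiny_config()
  m <- init_model(cfg, 1)
  ws <- tiny_windows(cfg = cfg)
  q <- extract_features(m, ws_subset(ws, 1:2))
  K <- 4
  tf <- array(rnorm(cfg$conv_filters * cfg$feat_len * K * cfg$n_classes),
              c(cfg$conv_filters, cfg$feat_len, K, cfg$n_classes))
  R <- combine_M(q, tf)
  expect_equal(dim(R), c(2L * cfg$conv_filters, cfg$feat_len,
                         cfg$n_classes, 2L))
  # query half replicated per class; template half is the K-shot sum
  for (c in seq_len(cfg$n_classes)) {
    expect_equal(R[1:cfg$conv_filters, , c, 1], q[, , 1])
    expect_equal(R[cfg$conv_filters + 1:cfg$conv_filters, , c, 1],
                 apply(tf[, , , c], c(1, 2), sum))
  }
  # K = 1: class map equals the single template map
  R1 <- combine_M(q, tf[, , 1, , drop = FALSE])
  expect_equal(R1[cfg$conv_filters + 1:cfg$conv_filters, , 2, 1],
               tf[, , 1, 2])
  # same templates, different queries: template half identical
  expect_equal(R[cfg$conv_filters + 1:cfg$conv_filters, , , 1],
               R[cfg$conv_filters + 1:cfg$conv_filters, , , 2])
  expect_false(isTRUE(all.equal(R[1:cfg$conv_filters, , 1, 1],
                                R[1:cfg$conv_filters, , 1, 2])))
})

test_that("relation scores live in (0,1) and are head- and input-consistent", {
  cfg <- tiny_config()
  m <- init_model(cfg, 2)
  ws <- tiny_windows(cfg = cfg)
  q <- extract_features(m, ws_subset(ws, 1:3))
  tm <- tiny_templates(ws, cfg)
  tf <- extract_features(m, window_set(
    array(tm$windows, c(cfg$n_channels, cfg$window_len,
                        cfg$shots * cfg$n_classes)),
    rep(0L, cfg$shots * cfg$n_classes),
    rep("S", cfg$shots * cfg$n_classes),
    seq_len(cfg$shots * cfg$n_classes), 1000))
  dim(tf) <- c(cfg$conv_filters, cfg$feat_len, cfg$shots, cfg$n_classes)
  R <- combine_M(q, tf)
  sc <- relation_scores(m, R, "main")
  expect_equal(dim(sc), c(3L, cfg$n_classes))
  expect_true(all(sc > 0 & sc < 1))

  # duplicated relation matrix -> identical scores
  Rdup <- R
  Rdup[, , 2, ] <- Rdup[, , 1, ]
  sdup <- relation_scores(m, Rdup, "main")
  expect_equal(sdup[, 1], sdup[, 2], tolerance = 1e-12)

  # independent heads generally disagree
  expect_false(isTRUE(all.equal(sc, relation_scores(m, R, "aux1"))))
  expect_error(relation_scores(m, R, "aux3"), "head")

  # eval-mode determinism, bit for bit
  expect_identical(sc, relation_scores(m, R, "main"))
})

test_that("score range holds across many random inputs", {
  cfg <- tiny_config()
  m <- init_model(cfg, 3)
  set.seed(8)
  n <- 200
  ws <- window_set(array(rnorm(cfg$n_channels * cfg$window_len * n, sd = 3),
                         c(cfg$n_channels, cfg$window_len, n)),
                   rep(0L, n), rep("S", n), seq_len(n), 1000)
  tm <- tiny_templates(tiny_windows(cfg = cfg), cfg)
  for (h in c("main", "aux1", "aux2")) {
    sc <- emgadapt:::score_windows(m, ws, tm, h)
    expect_true(all(sc > 0 & sc < 1))
  }
})

test_that("prediction is the argmax with low-index tie-breaking", {
  expect_equal(max.col(rbind(c(0.9, 0.1, 0.2, 0.3)), "first") - 1L, 0L)
  cfg <- tiny_config()
  m <- init_model(cfg, 4)
  ws <- tiny_windows(cfg = cfg)
  tm <- tiny_templates(ws, cfg)
  pred <- predict(m, ws, tm)
  expect_length(pred, n_windows(ws))
  expect_true(all(pred %in% 0:(cfg$n_classes - 1L)))
  sc <- emgadapt:::score_windows(m, ws, tm, "main")
  expect_equal(pred, max.col(sc, ties.method = "first") - 1L)

  # batch prediction equals the per-window loop
  loop <- vapply(seq_len(n_windows(ws)), function(i)
    predict(m, ws_subset(ws, i), tm), integer(1))
  expect_equal(pred, loop)
})

test_that("scores are equivariant to class order and invariant to shot order", {
  cfg <- tiny_config()
  m <- init_model(cfg, 5)
  ws <- tiny_windows(cfg = cfg)
  q <- extract_features(m, ws_subset(ws, 1:2))
  set.seed(12)
  tf <- array(rnorm(cfg$conv_filters * cfg$feat_len * 3 * cfg$n_classes),
              c(cfg$conv_filters, cfg$feat_len, 3, cfg$n_classes))
  base <- relation_scores(m, combine_M(q, tf), "main")

  perm <- c(2L, 3L, 1L)
  permuted <- relation_scores(m, combine_M(q, tf[, , , perm]), "main")
  expect_equal(permuted, base[, perm], tolerance = 1e-12)

  shuffled <- relation_scores(m, combine_M(q, tf[, , c(3, 1, 2), ]), "main")
  expect_equal(shuffled, base, tolerance = 1e-12)
})

test_that("checkpoints round-trip the model and templates", {
  cfg <- tiny_config()
  m <- init_model(cfg, 6)
  ws <- tiny_windows(cfg = cfg)
  tm <- tiny_templates(ws, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path, templates = tm)
  back <- load_model(path)
  expect_identical(back$model, m)
  expect_identical(back$templates, tm)
})
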