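test_that("template sets validate labels and record provenance", {
  ws <- tiny_windows()
  idx <- lapply(0:2, function(c) which(ws$labels == c)[1:2])
  tm <- make_template_set(ws, idx)
  expect_equal(tm$n_classes, 3L)
  expect_equal(tm$shots, 2L)
  expect_equal(nrow(tm$provenance), 6L)
  expect_equal(tm$windows[, , 1, 2], ws$windows[, , idx[[2]][1]])

  bad <- idx; bad[[1]] <- which(ws$labels == 1)[1:2]
  expect_error(make_template_set(ws, bad), "different")
})

test_that("initial templates are drawn per class, deterministically", {
  ws <- tiny_windows()
  t1 <- init_templates(ws, 3, shots = 2, seed = 5)
  t2 <- init_templates(ws, 3, shots = 2, seed = 5)
  expect_identical(t1, t2)
  expect_equal(t1$provenance$class, rep(0:2, each = 2))
  few <- ws_subset(ws, which(ws$labels == 0))
  expect_error(init_templates(few, 3, shots = 2, seed = 1), "class")
})

test_that("pool embeddings are flattened extractor features in order", {
  cfg <- model_config(9, 200, 4)
  m <- init_model(cfg, 1)
  set.seed(31)
  n <- 6
  ws <- window_set(array(rnorm(9 * 200 * n), c(9, 200, n)),
                   rep(0L, n), rep("S", n), seq_len(n), 1000)
  emb <- embed_pool(m, ws)
  expect_equal(dim(emb), c(n, 16L * 50L))          # 800 for L = 200

  dup <- ws; dup$windows[, , 2] <- dup$windows[, , 1]
  emb2 <- embed_pool(m, dup)
  expect_equal(emb2[1, ], emb2[2, ], tolerance = 1e-12)

  unlab <- ws; unlab$labels <- rep(NA_integer_, n)
  expect_error(embed_pool(m, unlab), "labeled")
})

test_that("3-d reduction is a faithful top-3 PCA", {
  set.seed(17)
  # rank-2 data embedded in 10 dimensions
  basis <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:2]
  scores2 <- matrix(rnorm(120), 60, 2) %*% t(basis) * 3
  coords <- reduce_3d(scores2 + 5)
  v <- apply(coords, 2, var)
  expect_lt(v[3], 1e-8 * sum(v))

  # pairwise distances match a from-scratch eigendecomposition oracle
  X <- matrix(rnorm(40 * 6), 40, 6)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Xc) / (nrow(X) - 1))
  oracle <- Xc %*% eig$vectors[, 1:3]
  got <- reduce_3d(X)
  expect_equal(as.matrix(dist(got)), as.matrix(dist(oracle)),
               tolerance = 1e-8)

  dup <- rbind(X, X[1:5, ])
  cd <- reduce_3d(dup)
  expect_equal(cd[41:45, ], cd[1:5, ], tolerance = 1e-9)

  expect_error(reduce_3d(X[1:3, ]), "4")
})

test_that("cluster medoids recover well-separated blobs", {
  centers <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0),
                   c(0, 0, 1.5), c(1.5, 1.5, 1.5))
  for (seed in 1:20) {
    set.seed(seed)
    pts <- do.call(rbind, lapply(1:5, function(b)
      matrix(rnorm(20 * 3, sd = 0.01), 20, 3) +
        matrix(centers[b, ], 20, 3, byrow = TRUE)))
    med <- cluster_medoids(pts, k = 5, seed = seed)
    expect_length(unique(med), 5)
    blob_of <- (med - 1) %/% 20 + 1
    expect_setequal(blob_of, 1:5)              # one medoid per blob
    for (j in seq_along(med))
      expect_lt(sqrt(sum((pts[med[j], ] - centers[blob_of[j], ])^2)),
                3 * 0.01 * sqrt(3) + 3 * 0.01)
  }
})

test_that("medoid selection is degenerate-safe and duplication-invariant", {
  set.seed(2)
  pts <- matrix(rnorm(15), 5, 3)
  expect_identical(cluster_medoids(pts, k = 5, seed = 1), 1:5)
  expect_error(cluster_medoids(pts, k = 6, seed = 1), "smaller")

  centers <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  base <- do.call(rbind, lapply(1:3, function(b)
    matrix(rnorm(12 * 3, sd = 0.02), 12, 3) +
      matrix(centers[b, ], 12, 3, byrow = TRUE)))
  m1 <- cluster_medoids(base, k = 3, seed = 4)
  dup <- rbind(base, base)
  m2 <- cluster_medoids(dup, k = 3, seed = 4)
  expect_equal(base[m1, ][order(base[m1, 1]), ],
               dup[m2, ][order(dup[m2, 1]), ], tolerance = 1e-9)
})

test_that("template update clusters the pool and falls back per class", {
  cfg <- tiny_config()
  m <- init_model(cfg, 8)
  ws <- tiny_windows(n_per_class = 10, cfg = cfg)
  old <- tiny_templates(ws, cfg)

  # pool = the old templates themselves: result is a permutation
  pool_idx <- old$provenance$window
  pool <- ws_subset(ws, pool_idx)
  new <- update_templates(m, pool, old, seed = 3)
  for (c in seq_len(cfg$n_classes)) {
    got <- apply(new$windows[, , , c], 3, function(w) paste(signif(w, 10), collapse = ","))
    want <- apply(old$windows[, , , c], 3, function(w) paste(signif(w, 10), collapse = ","))
    expect_setequal(got, want)
  }

  # every returned template is an actual pool window
  big <- tiny_windows(n_per_class = 15, cfg = cfg, seed = 6)
  upd <- update_templates(m, big, old, seed = 9)
  pool_keys <- apply(big$windows, 3, function(w) paste(signif(w, 10), collapse = ","))
  for (c in seq_len(cfg$n_classes))
    for (k in seq_len(cfg$shots))
      expect_true(paste(signif(upd$windows[, , k, c], 10), collapse = ",") %in% pool_keys)

  # missing class: old templates retained, with a warning
  partial <- ws_subset(big, which(big$labels != 2L))
  expect_warning(upd2 <- update_templates(m, partial, old, seed = 9),
                 "class 2")
  expect_equal(upd2$windows[, , , 3], old$windows[, , , 3])

  # determinism
  expect_identical(update_templates(m, big, old, seed = 9),
                   update_templates(m, big, old, seed = 9))
})
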