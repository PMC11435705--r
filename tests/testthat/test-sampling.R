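test_that("agreeing heads give zero discrepancy and zero acquisition scores", {
  cfg <- tiny_config()
  m <- init_model(cfg, 1)
  m$heads$aux1 <- m$heads$main
  m$heads$aux2 <- m$heads$main
  ws <- tiny_windows(cfg = cfg)
  tm <- tiny_templates(ws, cfg)
  rep <- score_pool(m, ws, tm, ws)
  expect_equal(rep$D, rep(0, n_windows(ws)))
  expect_equal(rep$S, rep(0, n_windows(ws)))
  expect_equal(rep$source_mean_D, 0)
})

test_that("using the pool as its own source centres the scores", {
  cfg <- tiny_config()
  m <- init_model(cfg, 2)
  ws <- tiny_windows(cfg = cfg)
  tm <- tiny_templates(ws, cfg)
  rep <- score_pool(m, ws, tm, ws)
  expect_equal(mean(rep$S), 0, tolerance = 1e-12)
  expect_equal(rep$S, rep$D - mean(rep$D), tolerance = 1e-12)
  empty <- ws_subset(ws, integer(0))
  expect_error(score_pool(m, ws, tm, empty), "source")
})

test_that("the acquisition score is the discrepancy minus the source mean", {
  # hand arithmetic on preset head outputs for a 3-window pool
  r  <- rbind(c(0.9, 0.1, 0.1, 0.1), c(0.5, 0.5, 0.1, 0.1), c(0.3, 0.3, 0.3, 0.3))
  r1 <- rbind(c(0.8, 0.2, 0.1, 0.1), c(0.5, 0.5, 0.1, 0.1), c(0.3, 0.3, 0.3, 0.3))
  r2 <- rbind(c(0.7, 0.1, 0.2, 0.1), c(0.5, 0.5, 0.1, 0.1), c(0.4, 0.3, 0.3, 0.3))
  D <- emgadapt:::discrepancy_vec(r, r1, r2)
  # window 1: d(r1,r2) = 0.075, d(r,r1) = 0.05, d(r,r2) = 0.075
  expect_equal(D, c(0.2, 0, 0.05))
  expect_equal(D, vapply(1:3, function(i)
    total_discrepancy(r[i, ], r1[i, ], r2[i, ])$total, 0))
  # source pool = windows 2 and 3 -> mean D = 0.025
  expect_equal(D - mean(D[2:3]), c(0.175, -0.025, 0.025))
})

test_that("partition matches an exhaustive-sort oracle and stays disjoint", {
  set.seed(13)
  for (trial in 1:300) {
    n <- sample(2:12, 1)
    S <- round(runif(n), sample(c(1, 2, 8), 1))   # encourage ties
    rep <- structure(list(D = S, source_mean_D = 0, S = S,
                          sample_idx = integer(0),
                          template_idx = integer(0)),
                     class = "acquisition_report")
    n1 <- sample(0:n, 1); n2 <- sample(0:(n - n1), 1)
    out <- partition_pool(rep, n1, n2)
    # oracle: stable full sort
    ord_desc <- order(-S, seq_len(n))
    expect_setequal(out$sample_idx, ord_desc[seq_len(n1)])
    rest <- setdiff(seq_len(n), ord_desc[seq_len(n1)])
    ord_asc <- rest[order(S[rest], rest)]
    expect_setequal(out$template_idx, ord_asc[seq_len(n2)])
    expect_length(intersect(out$sample_idx, out$template_idx), 0)
    if (n1 > 0 && n2 > 0)
      expect_gte(min(S[out$sample_idx]), max(S[out$template_idx]))
  }
  rep <- structure(list(D = 1:5, source_mean_D = 0, S = as.numeric(1:5),
                        sample_idx = integer(0), template_idx = integer(0)),
                   class = "acquisition_report")
  expect_error(partition_pool(rep, 3, 3), "exceeds")
  out0 <- partition_pool(rep, 0, 2)
  expect_identical(out0$sample_idx, integer(0))
  expect_identical(out0$template_idx, 1:2)
})

test_that("ties are broken deterministically toward lower indices", {
  S <- rep(0.5, 10)
  rep <- structure(list(D = S, source_mean_D = 0, S = S,
                        sample_idx = integer(0), template_idx = integer(0)),
                   class = "acquisition_report")
  out <- partition_pool(rep, 2, 2)
  expect_identical(out$sample_idx, 1:2)
  expect_identical(out$template_idx, 3:4)
  expect_identical(out, partition_pool(rep, 2, 2))
})

test_that("ranking by S equals ranking by D", {
  set.seed(21)
  for (i in 1:20) {
    D <- runif(15)
    off <- rnorm(1)
    expect_identical(order(D - off), order(D))
  }
  cfg <- tiny_config()
  m <- init_model(cfg, 3)
  ws <- tiny_windows(cfg = cfg)
  tm <- tiny_templates(ws, cfg)
  rep <- score_pool(m, ws, tm, ws_subset(ws, 1:10))
  expect_identical(order(rep$S), order(rep$D))
})

test_that("the labeling oracle counts each window once", {
  ws <- tiny_windows()
  pool <- ws; pool$labels <- rep(NA_integer_, n_windows(ws))
  oracle <- make_oracle(ws)
  expect_equal(oracle_budget(oracle), 0L)
  lab <- oracle_label(oracle, pool, 1:5)
  expect_equal(oracle_budget(oracle), 5L)
  expect_identical(lab$labels, ws$labels[1:5])
  oracle_label(oracle, pool, 3:7)              # 3:5 already counted
  expect_equal(oracle_budget(oracle), 7L)
  oracle_label(oracle, pool, integer(0))
  expect_equal(oracle_budget(oracle), 7L)
  expect_error(oracle_label(oracle, pool, 10000L), "range")
})

test_that("sampled windows sit nearer the decision boundary than template windows", {
  # qualitative screening claim, asserted at the mean over seeded cohorts:
  # "important" (high-discrepancy) windows have a smaller main-head top-2
  # score margin than "confident" (low-discrepancy) windows
  margins <- vapply(c(301, 302, 303), function(s) {
    coh <- study_cohort(seed = s)
    ws <- lapply(coh$recordings, prepare_windows)
    src <- ws_bind(ws[-4])
    tgt <- ws[[4]]
    tgt$labels <- rep(NA_integer_, n_windows(tgt))
    tc <- study_train_config(seed = 1)
    tm <- init_templates(src, 4, 5, seed = 1)
    m <- pretrain(init_model(model_config(9, 200, 4), 1), src, tm, tc)
    m <- train_auxiliary(m, src, tgt, tm, tc)
    rep <- partition_pool(score_pool(m, tgt, tm, src), 250, 200)
    sc <- emgadapt:::score_windows(m, tgt, tm, "main")
    marg <- apply(sc, 1, function(r) {
      o <- sort(r, decreasing = TRUE); o[1] - o[2]
    })
    c(mean(marg[rep$sample_idx]), mean(marg[rep$template_idx]))
  }, numeric(2))
  expect_lt(mean(margins[1, ]), mean(margins[2, ]))
})
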