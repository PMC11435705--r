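#' Relation-network model configuration
#'
#' Describes the twin relation network: a shared convolutional feature
#' extractor followed by three relation heads (one main classifier and two
#' auxiliary classifiers used only for discrepancy-based data screening).
#' The extractor has two convolution blocks (convolution with
#' `conv_filters` filters and a `1 x conv_kernel_time` kernel, stride 1,
#' same padding; batch normalization; Softsign; `1 x pool_time` max
#' pooling). Each head has two convolution blocks (no pooling) and two
#' fully connected blocks: `fc_hidden` units with batch norm, Softsign and
#' dropout, then a single sigmoid output unit producing a relation score
#' in (0, 1) per class.
#'
#' @param n_channels number of sEMG channels per window.
#' @param window_len window length L in samples.
#' @param n_classes number of activity classes C (>= 2).
#' @param shots templates per class K (default 5).
#' @param conv_filters convolution filters per layer (default 16).
#' @param conv_kernel_time temporal kernel width (odd, default 3).
#' @param pool_time max-pooling width per extractor block (default 2).
#' @param fc_hidden hidden units of the first FC block (default 100).
#' @param dropout dropout rate in the first FC block (default 0.30).
#' @return a `model_config` list, with derived field `feat_len`
#'   (`floor(floor(L / pool) / pool)`, the temporal length of extractor
#'   feature maps).
#' @examples
#' model_config(n_channels = 9, window_len = 200, n_classes = 4)
#' @export
model_config <- function(n_channels, window_len, n_classes, shots = 5L,
                         conv_filters = 16L, conv_kernel_time = 3L,
                         pool_time = 2L, fc_hidden = 100L, dropout = 0.30) {
  if (n_classes < 2L) stop_("`n_classes` must be >= 2")
  if (shots < 1L) stop_("`shots` must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_("`dropout` must be in [0, 1)")
  if (conv_kernel_time %% 2L != 1L)
    stop_("`conv_kernel_time` must be odd (same padding)")
  feat_len <- (window_len %/% pool_time) %/% pool_time
  if (feat_len < 1L)
    stop_("window_len = %d is too short for two x%d pooling stages",
          window_len, pool_time)
  structure(list(
    n_channels = as.integer(n_channels), window_len = as.integer(window_len),
    n_classes = as.integer(n_classes), shots = as.integer(shots),
    conv_filters = as.integer(conv_filters),
    conv_kernel_time = as.integer(conv_kernel_time),
    pool_time = as.integer(pool_time), fc_hidden = as.integer(fc_hidden),
    dropout = dropout, feat_len = as.integer(feat_len)),
    class = "model_config")
}

init_head <- function(cfg) {
  nf <- cfg$conv_filters
  list(conv1 = init_conv(nf, 2L * nf, cfg$conv_kernel_time),
       bn1 = init_bn(nf),
       conv2 = init_conv(nf, nf, cfg$conv_kernel_time),
       bn2 = init_bn(nf),
       fc1 = init_dense(cfg$fc_hidden, nf * cfg$feat_len),
       bnf = init_bn(cfg$fc_hidden),
       fc2 = init_dense(1L, cfg$fc_hidden))
}

#' Initialize a relation-network model
#'
#' Parameters are drawn with a seeded Glorot-uniform scheme; the three
#' relation heads share the same topology but are initialized
#' independently (each from its own derived seed).
#'
#' @param config a [model_config()].
#' @param seed integer seed; the same `(config, seed)` pair always yields
#'   bit-identical parameters.
#' @return an object of class `relation_model`.
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  nf <- config$conv_filters
  extractor <- with_seed_(derive_seed(seed, "extractor"), list(
    conv1 = init_conv(nf, config$n_channels, config$conv_kernel_time),
    bn1 = init_bn(nf),
    conv2 = init_conv(nf, nf, config$conv_kernel_time),
    bn2 = init_bn(nf)))
  heads <- list(
    main = with_seed_(derive_seed(seed, "head", "main"), init_head(config)),
    aux1 = with_seed_(derive_seed(seed, "head", "aux1"), init_head(config)),
    aux2 = with_seed_(derive_seed(seed, "head", "aux2"), init_head(config)))
  structure(list(config = config, extractor = extractor, heads = heads,
                 seed = as.integer(seed)),
            class = "relation_model")
}

#' @export
print.relation_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<relation_model> %d-channel x %d-sample windows, ",
                     "%d classes, %d-shot templates\n"),
              cfg$n_channels, cfg$window_len, cfg$n_classes, cfg$shots))
  cat(sprintf("  extractor: 2 conv blocks (%d filters, 1x%d kernel, x%d pool) -> %d x %d maps\n",
              cfg$conv_filters, cfg$conv_kernel_time, cfg$pool_time,
              cfg$conv_filters, cfg$feat_len))
  cat(sprintf("  heads: main + aux1 + aux2 (fc %d -> 1, dropout %.2f)\n",
              cfg$fc_hidden, cfg$dropout))
  invisible(x)
}

# ---- extractor forward/backward on a concatenated batch ----
# X: (n_channels, L * nwin). Returns features (nf, feat_len * nwin).

extractor_run <- function(model, X, training = FALSE) {
  cfg <- model$config
  ex <- model$extractor
  k <- cfg$conv_kernel_time
  p <- cfg$pool_time
  L1 <- cfg$window_len

  c1 <- conv_fwd(X, L1, ex$conv1, k)
  b1 <- bn_fwd(c1$Y, ex$bn1, training); ex$bn1 <- b1$p
  s1 <- softsign_fwd(b1$Y)
  p1 <- pool_fwd(s1$Y, L1, p)
  L2 <- p1$cache$Lout

  c2 <- conv_fwd(p1$Y, L2, ex$conv2, k)
  b2 <- bn_fwd(c2$Y, ex$bn2, training); ex$bn2 <- b2$p
  s2 <- softsign_fwd(b2$Y)
  p2 <- pool_fwd(s2$Y, L2, p)

  model$extractor <- ex
  list(F = p2$Y, model = model,
       cache = list(c1 = c1$cache, b1 = b1$cache, s1 = s1$cache,
                    p1 = p1$cache, c2 = c2$cache, b2 = b2$cache,
                    s2 = s2$cache, p2 = p2$cache))
}

extractor_grad <- function(model, cache, dF) {
  ex <- model$extractor
  nf <- model$config$conv_filters
  d <- pool_bwd(dF, cache$p2, nf)
  d <- softsign_bwd(d, cache$s2)
  bb2 <- bn_bwd(d, ex$bn2, cache$b2)
  cc2 <- conv_bwd(bb2$dX, ex$conv2, cache$c2, want_dx = TRUE)
  d <- pool_bwd(cc2$dX, cache$p1, nf)
  d <- softsign_bwd(d, cache$s1)
  bb1 <- bn_bwd(d, ex$bn1, cache$b1)
  cc1 <- conv_bwd(bb1$dX, ex$conv1, cache$c1, want_dx = FALSE)
  list(conv1 = cc1$grads, bn1 = bb1$grads, conv2 = cc2$grads, bn2 = bb2$grads)
}

# ---- relation head forward/backward ----
# R: (2*nf, feat_len * M) for M relation matrices; returns pre-sigmoid z and
# scores of length M.

head_run <- function(model, head, R, training = FALSE) {
  cfg <- model$config
  hd <- model$heads[[head]]
  if (is.null(hd)) stop_("unknown relation head '%s'", head)
  k <- cfg$conv_kernel_time
  Lf <- cfg$feat_len
  M <- ncol(R) %/% Lf

  c1 <- conv_fwd(R, Lf, hd$conv1, k)
  b1 <- bn_fwd(c1$Y, hd$bn1, training); hd$bn1 <- b1$p
  s1 <- softsign_fwd(b1$Y)
  c2 <- conv_fwd(s1$Y, Lf, hd$conv2, k)
  b2 <- bn_fwd(c2$Y, hd$bn2, training); hd$bn2 <- b2$p
  s2 <- softsign_fwd(b2$Y)
  flat <- s2$Y
  dim(flat) <- c(cfg$conv_filters * Lf, M)
  f1 <- dense_fwd(flat, hd$fc1)
  bf <- bn_fwd(f1$Y, hd$bnf, training); hd$bnf <- bf$p
  sf <- softsign_fwd(bf$Y)
  dr <- dropout_fwd(sf$Y, cfg$dropout, training)
  f2 <- dense_fwd(dr$Y, hd$fc2)
  z <- as.numeric(f2$Y)

  model$heads[[head]] <- hd
  list(z = z, scores = sigmoid(z), model = model,
       cache = list(c1 = c1$cache, b1 = b1$cache, s1 = s1$cache,
                    c2 = c2$cache, b2 = b2$cache, s2 = s2$cache,
                    f1 = f1$cache, bf = bf$cache, sf = sf$cache,
                    dr = dr$cache, f2 = f2$cache, M = M))
}

# dz: gradient w.r.t. the pre-sigmoid output, length M.
head_grad <- function(model, head, cache, dz, want_dx = FALSE) {
  cfg <- model$config
  hd <- model$heads[[head]]
  nf <- cfg$conv_filters
  Lf <- cfg$feat_len
  d2 <- dense_bwd(matrix(dz, 1L), hd$fc2, cache$f2, want_dx = TRUE)
  d <- dropout_bwd(d2$dX, cache$dr)
  d <- softsign_bwd(d, cache$sf)
  bbf <- bn_bwd(d, hd$bnf, cache$bf)
  d1 <- dense_bwd(bbf$dX, hd$fc1, cache$f1, want_dx = TRUE)
  d <- d1$dX
  dim(d) <- c(nf, Lf * cache$M)
  d <- softsign_bwd(d, cache$s2)
  bb2 <- bn_bwd(d, hd$bn2, cache$b2)
  cc2 <- conv_bwd(bb2$dX, hd$conv2, cache$c2, want_dx = TRUE)
  d <- softsign_bwd(cc2$dX, cache$s1)
  bb1 <- bn_bwd(d, hd$bn1, cache$b1)
  cc1 <- conv_bwd(bb1$dX, hd$conv1, cache$c1, want_dx = want_dx)
  list(grads = list(conv1 = cc1$grads, bn1 = bb1$grads,
                    conv2 = cc2$grads, bn2 = bb2$grads,
                    fc1 = d1$grads, bnf = bbf$grads, fc2 = d2$grads),
       dR = cc1$dX)
}

# ---- feature-map utilities ----

ws_matrix <- function(ws) {
  d <- dim(ws$windows)
  matrix(ws$windows, d[1], d[2] * d[3])
}

#' Extract feature maps for a batch of windows
#'
#' Runs the shared feature extractor in evaluation mode (batch norm uses
#' running statistics) over every window of a [window_set()].
#'
#' @param model a [relation_model][init_model()].
#' @param windows a [window_set()] whose channel/length dimensions match
#'   the model configuration.
#' @return numeric array `conv_filters x feat_len x n`: one feature map
#'   per window, order preserved.
#' @export
extract_features <- function(model, windows) {
  stopifnot(inherits(model, "relation_model"), inherits(windows, "window_set"))
  cfg <- model$config
  d <- dim(windows$windows)
  if (d[1] != cfg$n_channels || d[2] != cfg$window_len)
    stop_("window shape %d x %d does not match model config %d x %d",
          d[1], d[2], cfg$n_channels, cfg$window_len)
  out <- extractor_run(model, ws_matrix(windows), training = FALSE)
  array(out$F, c(cfg$conv_filters, cfg$feat_len, d[3]))
}

#' Combine query and template features into per-class relation matrices
#'
#' For each class, the feature maps of that class's K template windows are
#' summed element-wise into a single class map; the query map is then
#' replicated once per class and concatenated with each class map along
#' the feature-channel axis, yielding C relation matrices of
#' `2 * conv_filters` channels per query.
#'
#' @param query_features array `nf x feat_len x B` (from
#'   [extract_features()]).
#' @param template_features array `nf x feat_len x K x C`: feature maps of
#'   the K template windows for each of the C classes.
#' @return array `2*nf x feat_len x C x B` of relation matrices (for a
#'   single query, `B = 1`).
#' @export
combine_M <- function(query_features, template_features) {
  dq <- dim(query_features)
  dt <- dim(template_features)
  if (length(dq) == 2L) { dq <- c(dq, 1L); dim(query_features) <- dq }
  if (length(dt) != 4L)
    stop_("`template_features` must be nf x feat_len x K x C")
  if (!identical(dq[1:2], dt[1:2]))
    stop_("query and template feature maps have different shapes")
  nf <- dq[1]; Lf <- dq[2]; B <- dq[3]; K <- dt[3]; C <- dt[4]
  cmap <- array(0, c(nf, Lf, C))
  for (k in seq_len(K))
    cmap <- cmap + array(template_features[, , k, , drop = FALSE],
                         c(nf, Lf, C))
  R <- array(0, c(2L * nf, Lf, C, B))
  R[seq_len(nf), , , ] <- query_features[, , rep(seq_len(B), each = C)]
  R[nf + seq_len(nf), , , ] <- cmap[, , rep(seq_len(C), times = B)]
  R
}

#' Relation scores for a set of relation matrices
#'
#' Feeds relation matrices through one of the three relation heads in
#' evaluation mode. The C matrices of each query are processed
#' independently; each yields one sigmoid relation score in (0, 1). Scores
#' are similarities, not probabilities: they need not sum to 1.
#'
#' @param model a [relation_model][init_model()].
#' @param relation_matrices array from [combine_M()] (`2nf x Lf x C x B`
#'   or `2nf x Lf x C` for one query).
#' @param head one of `"main"`, `"aux1"`, `"aux2"`.
#' @return numeric matrix `B x C` of relation scores.
#' @export
relation_scores <- function(model, relation_matrices, head = "main") {
  stopifnot(inherits(model, "relation_model"))
  if (!head %in% c("main", "aux1", "aux2"))
    stop_("unknown relation head '%s'", head)
  d <- dim(relation_matrices)
  if (length(d) == 3L) { d <- c(d, 1L); dim(relation_matrices) <- d }
  C <- d[3]; B <- d[4]
  R <- relation_matrices
  dim(R) <- c(d[1], d[2] * C * B)
  out <- head_run(model, head, R, training = FALSE)
  t(matrix(out$scores, C, B))
}

# Class maps (summed template features) for a template set, eval mode.
# Returns nf x feat_len x C.
template_class_maps <- function(model, tset) {
  cfg <- model$config
  d <- dim(tset$windows)               # channels x L x K x C
  X <- matrix(tset$windows, d[1], d[2] * d[3] * d[4])
  Ft <- extractor_run(model, X, training = FALSE)$F
  Ftarr <- array(Ft, c(cfg$conv_filters, cfg$feat_len, d[3], d[4]))
  cmap <- array(0, c(cfg$conv_filters, cfg$feat_len, d[4]))
  for (k in seq_len(d[3]))
    cmap <- cmap + array(Ftarr[, , k, , drop = FALSE],
                         c(cfg$conv_filters, cfg$feat_len, d[4]))
  cmap
}

# Build the head input matrix (2nf, Lf * B * C) from query features
# (nf, Lf * B) and class maps (nf, Lf, C); matrix order: class fastest.
combine_rel <- function(cfg, Fq, cmap, B) {
  nf <- cfg$conv_filters; Lf <- cfg$feat_len; C <- dim(cmap)[3]
  Qarr <- array(Fq, c(nf, Lf, B))
  R <- array(0, c(2L * nf, Lf, C, B))
  R[seq_len(nf), , , ] <- Qarr[, , rep(seq_len(B), each = C)]
  R[nf + seq_len(nf), , , ] <- cmap[, , rep(seq_len(C), times = B)]
  dim(R) <- c(2L * nf, Lf * C * B)
  R
}

# Score a window set against a template set, in eval mode, batched; the
# feature extraction and relation-matrix construction are shared across
# the requested heads. Returns an n x C matrix (one head) or a named list
# of such matrices (several heads).
score_windows <- function(model, ws, tset, head = "main", batch = 256L) {
  cfg <- model$config
  C <- cfg$n_classes
  cmap <- template_class_maps(model, tset)
  n <- n_windows(ws)
  out <- lapply(head, function(h) matrix(0, n, C))
  names(out) <- head
  X <- ws_matrix(ws)
  L <- cfg$window_len
  for (ofs in seq(0L, n - 1L, by = batch)) {
    idx <- (ofs + 1L):min(ofs + batch, n)
    cols <- rep((idx - 1L) * L, each = L) + seq_len(L)
    Fq <- extractor_run(model, X[, cols, drop = FALSE], training = FALSE)$F
    R <- combine_rel(cfg, Fq, cmap, length(idx))
    for (h in head) {
      sc <- head_run(model, h, R, training = FALSE)$scores
      out[[h]][idx, ] <- t(matrix(sc, C, length(idx)))
    }
  }
  if (length(head) == 1L) out[[1L]] else out
}

#' Predict activity classes for a batch of windows
#'
#' Classifies each window as the class whose templates it relates to most
#' strongly: the argmax over the main head's relation scores. Exact ties
#' are broken toward the lowest class index.
#'
#' @param object a [relation_model][init_model()].
#' @param windows a [window_set()].
#' @param templates a [template_set][make_template_set()] with all C
#'   classes and K shots.
#' @param batch internal evaluation batch size.
#' @param ... unused.
#' @return integer vector of predicted class ids (`0 .. C-1`).
#' @export
predict.relation_model <- function(object, windows, templates,
                                   batch = 256L, ...) {
  check_template_set(templates, object$config)
  sc <- score_windows(object, windows, templates, head = "main",
                      batch = batch)
  max.col(sc, ties.method = "first") - 1L
}

#' Save / load a relation model checkpoint
#'
#' The checkpoint holds all four parameter groups (extractor and three
#' heads), the model configuration, the seed, and optionally the current
#' template set, under a versioned schema.
#'
#' @param model a [relation_model][init_model()].
#' @param path file path for the checkpoint.
#' @param templates optional [template_set][make_template_set()] stored
#'   alongside the parameters.
#' @return `save_model()`: `path`, invisibly. `load_model()`: a list with
#'   elements `model` and `templates` (possibly `NULL`).
#' @export
save_model <- function(model, path, templates = NULL) {
  stopifnot(inherits(model, "relation_model"))
  saveRDS(list(schema = "emgadapt-checkpoint-1", model = model,
               templates = templates), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, "emgadapt-checkpoint-1"))
    stop_("%s is not an emgadapt model checkpoint", path)
  x[c("model", "templates")]
}
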