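# Template sets and the forward adaptation strategy: the relation network's
# second input is a set T of K labeled windows per class; adapting T to the
# target subject (PCA to 3-d, K-means into K clusters per class, one medoid
# per cluster) shifts the model's similarity reference frame without
# touching any parameter.

#' Build a template set from selected windows
#'
#' @param ws a labeled [window_set()].
#' @param idx_per_class list of length C (names or order = class ids
#'   `0..C-1`), each an integer vector of K window indices into `ws`.
#' @return an object of class `template_set`: array
#'   `n_channels x L x K x C` plus provenance (subject ids and window
#'   starts per slot).
#' @export
make_template_set <- function(ws, idx_per_class) {
  stopifnot(inherits(ws, "window_set"))
  C <- length(idx_per_class)
  K <- length(idx_per_class[[1]])
  if (any(vapply(idx_per_class, length, 0L) != K))
    stop_("every class must contribute the same number of templates (K)")
  d <- dim(ws$windows)
  arr <- array(0, c(d[1], d[2], K, C))
  prov <- vector("list", C)
  for (c in seq_len(C)) {
    idx <- idx_per_class[[c]]
    lab <- ws$labels[idx]
    if (any(is.na(lab) | lab != c - 1L))
      stop_("template windows for class %d carry a different or missing label",
            c - 1L)
    arr[, , , c] <- ws$windows[, , idx, drop = FALSE]
    prov[[c]] <- data.frame(class = c - 1L, slot = seq_len(K),
                            subject_id = ws$subject_ids[idx],
                            start = ws$starts[idx], window = idx)
  }
  structure(list(windows = arr, n_classes = C, shots = K, fs = ws$fs,
                 provenance = do.call(rbind, prov)),
            class = "template_set")
}

check_template_set <- function(tset, cfg) {
  if (!inherits(tset, "template_set"))
    stop_("`templates` must be a template_set")
  d <- dim(tset$windows)
  if (d[4] != cfg$n_classes)
    stop_("template set has %d classes, model expects %d", d[4], cfg$n_classes)
  if (d[1] != cfg$n_channels || d[2] != cfg$window_len)
    stop_("template window shape %d x %d does not match model config %d x %d",
          d[1], d[2], cfg$n_channels, cfg$window_len)
  invisible(tset)
}

#' @export
print.template_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<template_set> %d classes x %d shots (windows 1 x %d x %d) from subject(s): %s\n",
              x$n_classes, x$shots, d[1], d[2],
              paste(unique(x$provenance$subject_id), collapse = ", ")))
  invisible(x)
}

#' Initial template set from random labeled windows
#'
#' Before any adaptation the template set is seeded with K randomly drawn
#' labeled windows per class (from the source training split).
#'
#' @param ws a labeled [window_set()] covering all C classes.
#' @param n_classes number of classes C.
#' @param shots templates per class K.
#' @param seed integer seed for the draw.
#' @return a [template_set][make_template_set()].
#' @export
init_templates <- function(ws, n_classes, shots = 5L, seed = 1L) {
  idx <- with_seed_(derive_seed(seed, "init_templates"), {
    lapply(seq_len(n_classes) - 1L, function(c) {
      pool <- which(!is.na(ws$labels) & ws$labels == c)
      if (length(pool) < shots)
        stop_("class %d has only %d labeled windows, need %d templates",
              c, length(pool), shots)
      sort(sample(pool, shots))
    })
  })
  make_template_set(ws, idx)
}

#' Embed a window pool in extractor feature space
#'
#' One flattened feature-extractor output vector per window (evaluation
#' mode), the representation in which templates are clustered.
#'
#' @param model a [relation_model][init_model()].
#' @param pool a labeled [window_set()].
#' @param require_labels error when the pool has unlabeled windows
#'   (default `TRUE`; template selection needs labels).
#' @return numeric matrix `n x (conv_filters * feat_len)`, rows in pool
#'   order.
#' @export
embed_pool <- function(model, pool, require_labels = TRUE) {
  if (require_labels && anyNA(pool$labels))
    stop_("template pool must be fully labeled")
  fmap <- extract_features(model, pool)
  d <- dim(fmap)
  t(matrix(fmap, d[1] * d[2], d[3]))
}

#' Project embeddings onto the top three principal components
#'
#' Centred PCA via [stats::prcomp()]; the three retained components have
#' non-increasing explained variance.
#'
#' @param embeddings numeric matrix, one row per window (>= 4 rows).
#' @return numeric matrix `n x 3` of scores; attribute `sdev` carries the
#'   component standard deviations.
#' @export
reduce_3d <- function(embeddings) {
  if (!is.matrix(embeddings) || nrow(embeddings) < 4L)
    stop_("need at least 4 embedding rows for a 3-component projection")
  p <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE, rank. = 3L)
  coords <- p$x
  if (ncol(coords) < 3L)  # fewer than 3 non-degenerate directions
    coords <- cbind(coords, matrix(0, nrow(coords), 3L - ncol(coords)))
  attr(coords, "sdev") <- p$sdev[seq_len(3L)]
  coords
}

#' Cluster a class pool and return one central sample per cluster
#'
#' Runs seeded K-means (`k` clusters, 10 restarts, 300 iteration cap) on
#' 3-d coordinates and returns, for each cluster, the index of the pool
#' window whose coordinate lies nearest the cluster centroid (Euclidean).
#' Templates must be real windows the network can consume, so centroids
#' themselves are never returned.
#'
#' @param coords3d numeric matrix `n x 3` of projected coordinates for
#'   one class's pool.
#' @param k number of clusters / templates (default 5).
#' @param seed integer seed for the K-means restarts.
#' @return integer vector of `k` distinct row indices into `coords3d`.
#' @export
cluster_medoids <- function(coords3d, k = 5L, seed = 1L) {
  n <- nrow(coords3d)
  if (n < k)
    stop_("pool of %d windows is smaller than k = %d clusters", n, k)
  if (n == k) return(seq_len(n))
  km <- with_seed_(derive_seed(seed, "kmeans"),
                   stats::kmeans(coords3d, centers = k, nstart = 10L,
                                 iter.max = 300L))
  medoids <- integer(k)
  for (j in seq_len(k)) {
    members <- which(km$cluster == j)
    dd <- rowSums((coords3d[members, , drop = FALSE] -
                     matrix(km$centers[j, ], length(members), 3L,
                            byrow = TRUE))^2)
    medoids[j] <- members[which.min(dd)]
  }
  sort(medoids)
}

#' Forward strategy: rebuild the template set from a labeled pool
#'
#' Embeds the pool with the feature extractor, projects all embeddings
#' (pooled across classes, so clusters stay comparable) to three
#' principal components, K-means-clusters each class's windows into K
#' clusters, and installs the K per-cluster central windows as the new
#' templates. Classes missing from the pool (or with fewer than K
#' windows) retain their previous templates, with a warning.
#'
#' @param model a [relation_model][init_model()].
#' @param labeled_pool a labeled [window_set()] (typically the "confident"
#'   windows selected by [partition_pool()]).
#' @param old the current [template_set][make_template_set()] (fallback
#'   source for uncovered classes).
#' @param seed integer seed for clustering.
#' @return a new [template_set][make_template_set()] with K templates per
#'   class, every one an actual pool (or retained old) window.
#' @export
update_templates <- function(model, labeled_pool, old, seed = 1L) {
  cfg <- model$config
  check_template_set(old, cfg)
  C <- cfg$n_classes
  K <- old$shots
  if (anyNA(labeled_pool$labels))
    stop_("template pool must be fully labeled")
  emb <- embed_pool(model, labeled_pool)
  coords <- reduce_3d(emb)
  arr <- old$windows
  prov <- old$provenance
  for (c in seq_len(C)) {
    members <- which(labeled_pool$labels == c - 1L)
    if (length(members) < K) {
      warn_("class %d has %d pool windows (< K = %d); keeping its old templates",
            c - 1L, length(members), K)
      next
    }
    med <- cluster_medoids(coords[members, , drop = FALSE], k = K,
                           seed = derive_seed(seed, "class", c))
    sel <- members[med]
    arr[, , , c] <- labeled_pool$windows[, , sel, drop = FALSE]
    prov[prov$class == c - 1L, "subject_id"] <- labeled_pool$subject_ids[sel]
    prov[prov$class == c - 1L, "start"] <- labeled_pool$starts[sel]
    prov[prov$class == c - 1L, "window"] <- sel
  }
  structure(list(windows = arr, n_classes = C, shots = K, fs = old$fs,
                 provenance = prov),
            class = "template_set")
}
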