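# Leave-one-subject-out experiment harness and the two ablation designs
# (template source; sampling strategy vs labeling budget).

# Preprocess and segment every recording of a cohort; returns a list of
# window sets, one per subject.
cohort_windows <- function(cohort, window_ms = 200, increment_ms = 25) {
  lapply(cohort$recordings, prepare_windows, window_ms = window_ms,
         increment_ms = increment_ms)
}

cohort_n_classes <- function(ws_list) {
  max(unlist(lapply(ws_list, function(w) w$labels)), na.rm = TRUE) + 1L
}

# Pretrain a model on the bound source subjects of one LOSO fold.
fit_source <- function(source_ws, C, cfg, shots = 5L) {
  d <- dim(source_ws$windows)
  mc <- model_config(n_channels = d[1], window_len = d[2], n_classes = C,
                     shots = shots)
  model <- init_model(mc, seed = derive_seed(cfg$seed, "init"))
  tmpl <- init_templates(source_ws, C, shots = shots,
                         seed = derive_seed(cfg$seed, "tmpl0"))
  model <- pretrain(model, source_ws, tmpl, cfg)
  list(model = model, templates = tmpl)
}

strip_labels <- function(ws) {
  ws$labels <- rep(NA_integer_, n_windows(ws))
  ws
}

# Split a target subject's windows into a temporally contiguous adaptation
# pool (first part, available to the labeling oracle) and a disjoint
# evaluation set (rest). Without this split, densely overlapping windows
# leak labeled training context into the evaluation and inflate methods
# that scatter labels widely.
split_target <- function(ws, pool_frac = 0.5) {
  n <- n_windows(ws)
  cut <- max(1L, floor(n * pool_frac))
  list(pool = ws_subset(ws, seq_len(cut)),
       eval = ws_subset(ws, (cut + 1L):n))
}

eval_metrics <- function(model, target_ws, templates) {
  pred <- predict(model, target_ws, templates)
  classification_metrics(pred, target_ws$labels)
}

# One LOSO fold under one or more adaptation methods sharing a single
# pre-training. The held-out subject's first half is the adaptation pool
# (oracle-labelable); evaluation is on the disjoint second half.
run_fold <- function(source_ws, target_ws, methods, cfg, shots = 5L) {
  C <- cohort_n_classes(list(source_ws, target_ws))
  fit <- fit_source(source_ws, C, cfg, shots)
  sp <- split_target(target_ws)
  pool <- strip_labels(sp$pool)
  n1 <- min(cfg$n1, n_windows(pool))

  rows <- lapply(methods, function(method) {
    model <- fit$model
    tmpl <- fit$templates
    oracle <- make_oracle(sp$pool)
    if (method == "random_sampling") {
      idx <- with_seed_(derive_seed(cfg$seed, "random-sampling"),
                        sample.int(n_windows(pool), n1))
      model <- finetune_main(model, oracle_label(oracle, pool, idx), tmpl, cfg)
    } else if (method == "importance_sampling") {
      model <- train_auxiliary(model, source_ws, pool, tmpl, cfg)
      rep <- partition_pool(score_pool(model, pool, tmpl, source_ws), n1, 0L)
      model <- finetune_main(model,
                             oracle_label(oracle, pool, rep$sample_idx),
                             tmpl, cfg)
    } else if (method == "full_framework") {
      res <- adapt(model, pool, source_ws, oracle, tmpl, cfg)
      model <- res$model
      tmpl <- res$templates
    } else if (method != "source_only") {
      stop_("unknown method '%s'", method)
    }
    m <- eval_metrics(model, sp$eval, tmpl)
    tibble::tibble(method = method, accuracy = m$accuracy,
                   precision = m$precision, recall = m$recall,
                   budget = oracle_budget(oracle))
  })
  do.call(rbind, rows)
}

#' Leave-one-subject-out evaluation of an adaptation method
#'
#' For each subject in turn: pre-train on all other subjects, adapt to
#' the held-out subject according to `method` using the subject's first
#' half of windows as the (oracle-labelable) adaptation pool, and report
#' accuracy, precision and recall (percent, macro-averaged) on the
#' disjoint second half.
#'
#' Methods: `"source_only"` (no adaptation), `"random_sampling"`
#' (fine-tune on `n1` randomly labeled target windows),
#' `"importance_sampling"` (fine-tune on the `n1` highest-discrepancy
#' windows), `"full_framework"` (the complete bidirectional loop:
#' importance-sampled fine-tuning plus confident-pool template update).
#'
#' @param cohort a cohort from [generate_cohort()] (or a list with a
#'   `recordings` field).
#' @param method one or several of the four method names above (methods
#'   run in the same call share each fold's pre-training).
#' @param cfg a [train_config()].
#' @param shots templates per class K.
#' @return a tibble with one row per held-out subject and method plus a
#'   `"(mean)"` aggregate row per method; columns `subject`, `method`,
#'   `accuracy`, `precision`, `recall`, `budget`, `seed`.
#' @export
loso_run <- function(cohort, method = "source_only",
                     cfg = train_config(), shots = 5L) {
  valid <- c("source_only", "random_sampling", "importance_sampling",
             "full_framework")
  if (!all(method %in% valid))
    stop_("unknown method '%s'", setdiff(method, valid)[1])
  ws_list <- cohort_windows(cohort)
  ns <- length(ws_list)
  if (ns < 2L) stop_("LOSO needs a cohort with >= 2 subjects")
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    source_ws <- ws_bind(ws_list[-i])
    row <- run_fold(source_ws, ws_list[[i]], method, cfg, shots)
    row$subject <- unique(ws_list[[i]]$subject_ids)[1]
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  aggs <- lapply(unique(tab$method), function(mm) {
    sub <- tab[tab$method == mm, ]
    tibble::tibble(method = mm, accuracy = mean(sub$accuracy),
                   precision = mean(sub$precision),
                   recall = mean(sub$recall),
                   budget = mean(sub$budget), subject = "(mean)")
  })
  out <- rbind(tab, do.call(rbind, aggs))
  out$seed <- cfg$seed
  out[, c("subject", "method", "accuracy", "precision", "recall",
          "budget", "seed")]
}

#' Template-count (shot) study
#'
#' Evaluates the pre-trained, non-adapted model on one held-out subject
#' with source template sets of K = 1, 5, 10, ... shots (nested draws),
#' reporting accuracy and the mean per-window inference time. Times are
#' informational (hardware-dependent) and never asserted by tests.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param cfg a [train_config()].
#' @param shots integer vector of template counts to evaluate.
#' @param target_subject 1-based index of the held-out subject (default:
#'   the last).
#' @return a tibble with columns `shots`, `accuracy`,
#'   `ms_per_window`, `seed`.
#' @export
template_count_study <- function(cohort, cfg = train_config(),
                                 shots = c(1L, 5L, 10L),
                                 target_subject = NULL) {
  ws_list <- cohort_windows(cohort)
  i <- target_subject %||% length(ws_list)
  source_ws <- ws_bind(ws_list[-i])
  target_ws <- ws_list[[i]]
  C <- cohort_n_classes(ws_list)
  kmax <- max(shots)
  per_class <- vapply(seq_len(C) - 1L,
                      function(c) sum(source_ws$labels == c, na.rm = TRUE), 0L)
  if (any(per_class < kmax))
    stop_("largest shot count (%d) exceeds the smallest per-class source pool (%d)",
          kmax, min(per_class))
  fit <- fit_source(source_ws, C, cfg, shots = 5L)
  tmpl_max <- init_templates(source_ws, C, shots = kmax,
                             seed = derive_seed(cfg$seed, "shots"))
  rows <- lapply(sort(shots), function(k) {
    tk <- tmpl_max
    tk$windows <- tmpl_max$windows[, , seq_len(k), , drop = FALSE]
    tk$shots <- as.integer(k)
    tk$provenance <- tmpl_max$provenance[tmpl_max$provenance$slot <= k, ]
    t0 <- proc.time()[["elapsed"]]
    m <- eval_metrics(fit$model, target_ws, tk)
    dt <- proc.time()[["elapsed"]] - t0
    tibble::tibble(shots = k, accuracy = m$accuracy,
                   ms_per_window = 1000 * dt / n_windows(target_ws))
  })
  out <- do.call(rbind, rows)
  out$seed <- cfg$seed
  out
}

#' Ablation: template source
#'
#' Compares the non-adapted model's target accuracy when its template
#' set is rebuilt from three pools of labeled target windows:
#' "important" (highest discrepancy), random, and "confident" (lowest
#' discrepancy). The auxiliary heads are discrepancy-trained first so
#' the acquisition statistic is meaningful.
#'
#' @inheritParams template_count_study
#' @param pool_size windows labeled per pool (default `50 * C`).
#' @return a tibble with columns `template_source`, `accuracy`, `seed`.
#' @export
ablation_templates <- function(cohort, cfg = train_config(),
                               pool_size = NULL, target_subject = NULL) {
  ws_list <- cohort_windows(cohort)
  i <- target_subject %||% length(ws_list)
  source_ws <- ws_bind(ws_list[-i])
  target_ws <- ws_list[[i]]
  C <- cohort_n_classes(ws_list)
  pool_size <- pool_size %||% (50L * C)
  fit <- fit_source(source_ws, C, cfg)
  sp <- split_target(target_ws)
  pool <- strip_labels(sp$pool)
  npool <- n_windows(pool)
  pool_size <- min(pool_size, npool %/% 2L)

  model <- train_auxiliary(fit$model, source_ws, pool, fit$templates, cfg)
  rep <- partition_pool(score_pool(model, pool, fit$templates, source_ws),
                        pool_size, pool_size)
  oracle <- make_oracle(sp$pool)
  pools <- list(
    important = rep$sample_idx,
    random = with_seed_(derive_seed(cfg$seed, "ablation-random"),
                        sample.int(npool, pool_size)),
    confident = rep$template_idx)
  rows <- lapply(names(pools), function(src) {
    labeled <- oracle_label(oracle, pool, pools[[src]])
    tmpl <- suppressWarnings(
      update_templates(model, labeled, fit$templates,
                       seed = derive_seed(cfg$seed, "ablation", src)))
    m <- eval_metrics(model, sp$eval, tmpl)
    tibble::tibble(template_source = src, accuracy = m$accuracy)
  })
  out <- do.call(rbind, rows)
  out$seed <- cfg$seed
  out
}

#' Ablation: sampling strategy vs labeling budget
#'
#' Fine-tunes the pre-trained model on increasing numbers of labeled
#' target windows chosen either by the discrepancy acquisition function
#' (importance sampling) or uniformly at random, re-training from the
#' pre-trained state at every budget so the curves are comparable.
#' Templates stay fixed at the source draw to isolate the sampling
#' effect. A budget of 0 reproduces the source-only accuracy.
#'
#' @inheritParams template_count_study
#' @param budgets ascending integer vector of labeling budgets.
#' @return a tibble with columns `sampling`, `budget`, `accuracy`,
#'   `seed`.
#' @export
ablation_budget <- function(cohort, cfg = train_config(),
                            budgets = c(0L, 100L, 250L),
                            target_subject = NULL) {
  if (is.unsorted(budgets)) stop_("`budgets` must be ascending")
  ws_list <- cohort_windows(cohort)
  i <- target_subject %||% length(ws_list)
  source_ws <- ws_bind(ws_list[-i])
  target_ws <- ws_list[[i]]
  C <- cohort_n_classes(ws_list)
  fit <- fit_source(source_ws, C, cfg)
  sp <- split_target(target_ws)
  pool <- strip_labels(sp$pool)
  npool <- n_windows(pool)
  if (max(budgets) > npool)
    stop_("largest budget (%d) exceeds the target pool size (%d)",
          max(budgets), npool)

  model_aux <- train_auxiliary(fit$model, source_ws, pool, fit$templates, cfg)
  rep <- score_pool(model_aux, pool, fit$templates, source_ws)
  imp_order <- order(rep$S, seq_len(npool), decreasing = c(TRUE, FALSE),
                     method = "radix")
  rnd_order <- with_seed_(derive_seed(cfg$seed, "budget-random"),
                          sample.int(npool))
  oracle <- make_oracle(sp$pool)
  rows <- list()
  for (sampling in c("importance", "random")) {
    ord <- if (sampling == "importance") imp_order else rnd_order
    for (b in budgets) {
      model_b <- fit$model
      if (b > 0L) {
        labeled <- oracle_label(oracle, pool, ord[seq_len(b)])
        model_b <- finetune_main(model_b, labeled, fit$templates, cfg)
      }
      m <- eval_metrics(model_b, sp$eval, fit$templates)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(sampling = sampling, budget = b,
                       accuracy = m$accuracy)
    }
  }
  out <- do.call(rbind, rows)
  out$seed <- cfg$seed
  out
}
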