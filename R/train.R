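# Training procedures: source pre-training of extractor + main head,
# discrepancy training of the two auxiliary heads (extractor and main head
# frozen), fine-tuning of the main model on actively sampled target
# windows, and the full adaptation loop combining backward (parameter) and
# forward (template) strategies.

#' Training configuration
#'
#' @param preset `"classic"` uses the method's reference schedule (100
#'   epochs, Adam with initial learning rate 0.5 decayed by 0.95 every
#'   two epochs, batch 64). That learning rate is aggressive for Adam;
#'   the `"stable"` preset (initial rate 0.01, 16 pre-training epochs,
#'   batch 32, at most 600 source windows per epoch) is the recommended
#'   setting for routine use and is what the experiment harness uses.
#' @param epochs pre-training epochs.
#' @param warmup_epochs initial pre-training epochs run against one fixed
#'   template draw before switching to per-batch episodic draws (default:
#'   40% of `epochs`). The warm-up phase learns discriminative features
#'   quickly; the episodic phase generalizes the heads across template
#'   sets.
#' @param batch_size minibatch size.
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative decay applied every two epochs.
#' @param seed integer seed governing batching, dropout and all derived
#'   randomness.
#' @param rounds adaptation rounds for [adapt()] (default 1).
#' @param n1 "important" windows labeled per round for the sample set.
#' @param n2 "confident" windows labeled per round for the template pool;
#'   `NULL` means `50 * n_classes`, shrunk to what the pool allows.
#' @param aux_epochs epochs of auxiliary-head discrepancy training.
#' @param aux_dis_weight weight of the (maximized) discrepancy term in
#'   the auxiliary objective; 1 is the full objective, 0 ablates it
#'   (auxiliary heads then converge toward the main head).
#' @param finetune_epochs epochs of main-model fine-tuning per round.
#' @param loss training loss variant: `"bce"` (binary cross-entropy over
#'   all class scores; default) or `"positive"` (true-class term only).
#' @param max_train_windows cap on source windows visited per
#'   pre-training epoch (subsampled after shuffling).
#' @param aux_init_sd scale of the seeded perturbation applied when the
#'   auxiliary heads are initialized from the trained main head.
#' @param budget total labeling budget for [adapt()] (default unlimited).
#' @return a `train_config` list.
#' @export
train_config <- function(preset = c("stable", "classic"),
                         epochs = NULL, warmup_epochs = NULL,
                         batch_size = NULL, lr0 = NULL,
                         lr_decay = 0.95, seed = 1L, rounds = 1L,
                         n1 = 250L, n2 = NULL, aux_epochs = 10L,
                         aux_dis_weight = 1,
                         finetune_epochs = NULL, loss = c("bce", "positive"),
                         max_train_windows = NULL, aux_init_sd = 0.01,
                         budget = Inf) {
  preset <- match.arg(preset)
  loss <- match.arg(loss)
  if (is.null(epochs)) epochs <- if (preset == "classic") 100L else 16L
  if (is.null(batch_size)) batch_size <- if (preset == "classic") 64L else 32L
  if (is.null(lr0)) lr0 <- if (preset == "classic") 0.5 else 0.01
  if (is.null(finetune_epochs)) finetune_epochs <- if (preset == "classic") 20L else 10L
  if (is.null(max_train_windows))
    max_train_windows <- if (preset == "classic") Inf else 600L
  if (is.null(warmup_epochs)) warmup_epochs <- max(2L, round(0.4 * epochs))
  if (lr0 <= 0) stop_("`lr0` must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stop_("`lr_decay` must be in (0, 1]")
  if (epochs < 1L) stop_("`epochs` must be >= 1")
  structure(list(preset = preset, epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay, optimizer = "adam",
                 seed = as.integer(seed), rounds = as.integer(rounds),
                 n1 = as.integer(n1), n2 = n2,
                 aux_epochs = as.integer(aux_epochs),
                 aux_dis_weight = aux_dis_weight,
                 finetune_epochs = as.integer(finetune_epochs),
                 loss = loss, max_train_windows = max_train_windows,
                 aux_init_sd = aux_init_sd, budget = budget),
            class = "train_config")
}

# Loss value and gradient w.r.t. pre-sigmoid outputs for a score matrix
# (C x B) and 0-based labels y. Gradient includes the 1/B batch averaging.
loss_grad_scores <- function(scores, y, variant) {
  C <- nrow(scores); B <- ncol(scores)
  onehot <- matrix(0, C, B)
  onehot[cbind(y + 1L, seq_len(B))] <- 1
  loss <- ce_loss(t(scores), y, negatives = (variant == "bce"))
  dz <- if (variant == "bce") (scores - onehot) / B
  else {
    d <- matrix(0, C, B)
    sel <- cbind(y + 1L, seq_len(B))
    d[sel] <- (scores[sel] - 1) / B
    d
  }
  list(loss = loss, dz = dz)
}

cols_for <- function(idx, L) rep((idx - 1L) * L, each = L) + seq_len(L)

# Loss and exact gradients of extractor + one head on a query batch
# against a template draw (training mode end to end, gradients through
# both the query and the template branch of the extractor). Xt holds K
# windows per class, class-major (shots contiguous within class).
main_grads <- function(model, Xq, y, Xt, K, head, variant) {
  cfg <- model$config
  nf <- cfg$conv_filters; Lf <- cfg$feat_len
  C <- cfg$n_classes
  B <- length(y)

  ex <- extractor_run(model, cbind(Xq, Xt), training = TRUE)
  model <- ex$model
  qcols <- seq_len(Lf * B)
  Fq <- ex$F[, qcols, drop = FALSE]
  Ftarr <- array(ex$F[, -qcols, drop = FALSE], c(nf, Lf, K, C))
  cmap <- array(0, c(nf, Lf, C))
  for (k in seq_len(K))
    cmap <- cmap + array(Ftarr[, , k, , drop = FALSE], c(nf, Lf, C))

  R <- combine_rel(cfg, Fq, cmap, B)
  h <- head_run(model, head, R, training = TRUE)
  model <- h$model
  scores <- matrix(h$scores, C, B)
  lg <- loss_grad_scores(scores, y, variant)

  hg <- head_grad(model, head, h$cache, as.numeric(lg$dz), want_dx = TRUE)
  dRarr <- array(hg$dR, c(2L * nf, Lf, C, B))
  top <- array(dRarr[seq_len(nf), , , , drop = FALSE], c(nf * Lf, C, B))
  dQ <- matrix(0, nf * Lf, B)
  for (c in seq_len(C))
    dQ <- dQ + matrix(top[, c, , drop = FALSE], nf * Lf, B)
  bot <- dRarr[nf + seq_len(nf), , , , drop = FALSE]
  dim(bot) <- c(nf * Lf * C, B)
  dTmap <- matrix(rowSums(bot), nf * Lf, C)
  dFt <- dTmap[, rep(seq_len(C), each = K), drop = FALSE]
  dF <- cbind(matrix(dQ, nf, Lf * B), matrix(dFt, nf, Lf * K * C))
  exg <- extractor_grad(model, ex$cache, dF)

  list(model = model, loss = lg$loss, extractor_grads = exg,
       head_grads = hg$grads)
}

# One Adam step of extractor + one head.
main_step <- function(model, Xq, y, Xt, K, head, lr, t, adam, variant) {
  g <- main_grads(model, Xq, y, Xt, K, head, variant)
  model <- g$model
  model$extractor <- adam_update(model$extractor, g$extractor_grads, adam,
                                 "ex", lr, t)
  model$heads[[head]] <- adam_update(model$heads[[head]], g$head_grads,
                                     adam, head, lr, t)
  list(model = model, loss = g$loss)
}

perturb_head <- function(head, sd, seed) {
  with_seed_(seed, {
    for (nm in c("conv1", "conv2", "fc1", "fc2")) {
      head[[nm]]$W <- head[[nm]]$W +
        matrix(stats::rnorm(length(head[[nm]]$W), 0, sd),
               nrow(head[[nm]]$W))
      head[[nm]]$b <- head[[nm]]$b + stats::rnorm(length(head[[nm]]$b), 0, sd)
    }
    head
  })
}

assert_all_classes <- function(labels, C, what) {
  present <- sort(unique(labels[!is.na(labels)]))
  missing <- setdiff(seq_len(C) - 1L, present)
  if (length(missing))
    stop_("class(es) %s absent from the %s windows",
          paste(missing, collapse = ", "), what)
}

#' Pre-train the relation model on labeled source windows
#'
#' Minimizes the relation-score cross-entropy of the main head over the
#' labeled source split (Adam, exponential step decay of the learning
#' rate, dropout in the heads' first FC block). Training runs in two
#' phases: a warm-up against one fixed template draw, then episodic
#' training in which the K templates per class are re-drawn from the
#' source split at every minibatch, so the heads learn a genuine
#' query-template similarity rather than memorizing one fixed template
#' set — a requirement for the forward adaptation strategy, which swaps
#' the template set at test
#' time. Gradients flow through both the query branch and the template
#' branch of the shared feature extractor. On completion the two
#' auxiliary heads are initialized as seeded, slightly perturbed copies
#' of the trained main head, so that all three classifiers start
#' near-identical and the discrepancy objective can grow their
#' disagreement on target data.
#'
#' @param model a freshly initialized [relation_model][init_model()].
#' @param source a labeled [window_set()] covering all C classes.
#' @param templates a [template_set][make_template_set()] defining the
#'   shot count K (episodic draws use `templates$shots` windows per
#'   class); typically [init_templates()] from the same source split.
#' @param cfg a [train_config()].
#' @return the trained model, with attribute `"loss_trajectory"` (mean
#'   training loss per epoch).
#' @export
pretrain <- function(model, source, templates, cfg = train_config()) {
  stopifnot(inherits(model, "relation_model"), inherits(cfg, "train_config"))
  check_template_set(templates, model$config)
  assert_all_classes(source$labels, model$config$n_classes, "source")
  if (anyNA(source$labels)) {
    keep <- which(!is.na(source$labels))
    source <- ws_subset(source, keep)
  }
  X <- ws_matrix(source)
  L <- model$config$window_len
  C <- model$config$n_classes
  K <- templates$shots
  n <- n_windows(source)
  class_pools <- lapply(seq_len(C) - 1L,
                        function(c) which(source$labels == c))
  adam <- adam_state_new()
  tstep <- 0L
  traj <- numeric(cfg$epochs)
  model <- with_seed_(derive_seed(cfg$seed, "pretrain"), {
    warm_draw <- unlist(lapply(class_pools, function(p)
      sample(p, K, replace = length(p) < K)))
    Xt_warm <- X[, cols_for(warm_draw, L), drop = FALSE]
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_schedule(epoch - 1L, cfg$lr0, cfg$lr_decay)
      idx <- sample.int(n)
      if (is.finite(cfg$max_train_windows) && n > cfg$max_train_windows)
        idx <- idx[seq_len(cfg$max_train_windows)]
      losses <- c()
      for (ofs in seq(0L, length(idx) - 1L, by = cfg$batch_size)) {
        b <- idx[(ofs + 1L):min(ofs + cfg$batch_size, length(idx))]
        if (length(b) < 2L) next
        tstep <- tstep + 1L
        # warm-up: one fixed draw; afterwards: fresh episodic draw
        Xt <- if (epoch <= cfg$warmup_epochs) Xt_warm else {
          tdraw <- unlist(lapply(class_pools, function(p)
            sample(p, K, replace = length(p) < K)))
          X[, cols_for(tdraw, L), drop = FALSE]
        }
        st <- main_step(model, X[, cols_for(b, L), drop = FALSE],
                        source$labels[b], Xt, K, "main",
                        lr, tstep, adam, cfg$loss)
        model <- st$model
        losses <- c(losses, st$loss)
      }
      traj[epoch] <- mean(losses)
    }
    model
  })
  model$heads$aux1 <- perturb_head(model$heads$main, cfg$aux_init_sd,
                                   derive_seed(cfg$seed, "aux1-init"))
  model$heads$aux2 <- perturb_head(model$heads$main, cfg$aux_init_sd,
                                   derive_seed(cfg$seed, "aux2-init"))
  attr(model, "loss_trajectory") <- traj
  model
}

# Relation matrices for a batch, from cached extractor features.
rel_from_cached <- function(cfg, Feat, idx, cmap) {
  Lf <- cfg$feat_len
  combine_rel(cfg, Feat[, cols_for(idx, Lf), drop = FALSE], cmap, length(idx))
}

#' Discrepancy-train the two auxiliary heads
#'
#' Optimizes `CE(aux1) + CE(aux2) - Ldis`: cross-entropy of both
#' auxiliary heads on a labeled set (the source split by default) minus
#' the three-way discrepancy [ldis()] on the unlabeled target pool,
#' which is thereby *maximized*. Only the two auxiliary heads' parameters
#' change; the feature extractor and main head are left bit-identical
#' (their features are computed once, in evaluation mode, and cached).
#'
#' @param model a pre-trained [relation_model][init_model()].
#' @param labeled a labeled [window_set()] for the CE terms.
#' @param unlabeled_target a non-empty [window_set()] of target windows
#'   for the discrepancy term.
#' @param templates the current [template_set][make_template_set()].
#' @param cfg a [train_config()] (`aux_epochs`, `batch_size`, `lr0`).
#' @return the model with updated auxiliary heads; attribute
#'   `"ldis_before_after"` holds the mean target-pool discrepancy before
#'   and after training.
#' @export
train_auxiliary <- function(model, labeled, unlabeled_target, templates,
                            cfg = train_config()) {
  stopifnot(inherits(model, "relation_model"))
  check_template_set(templates, model$config)
  if (n_windows(unlabeled_target) < 1L)
    stop_("empty unlabeled target set: the discrepancy loss is undefined")
  if (anyNA(labeled$labels)) stop_("`labeled` must be fully labeled")
  cfgm <- model$config
  C <- cfgm$n_classes

  # frozen-parameter features, computed once
  cmap <- template_class_maps(model, templates)
  Fl <- extractor_run(model, ws_matrix(labeled), training = FALSE)$F
  Fu <- extractor_run(model, ws_matrix(unlabeled_target), training = FALSE)$F
  nl <- n_windows(labeled)
  nu <- n_windows(unlabeled_target)
  # main-head scores on the target pool (constant during this phase)
  r_main <- score_windows(model, unlabeled_target, templates, "main")

  mean_ldis <- function(m) {
    s <- score_windows(m, unlabeled_target, templates, c("aux1", "aux2"))
    ldis(r_main, s$aux1, s$aux2)
  }
  before <- mean_ldis(model)

  adam <- adam_state_new()
  tstep <- 0L
  nl_epoch <- if (is.finite(cfg$max_train_windows))
    min(nl, cfg$max_train_windows) else nl
  model <- with_seed_(derive_seed(cfg$seed, "aux"), {
    steps_per_epoch <- max(1L, ceiling(nl_epoch / cfg$batch_size))
    for (epoch in seq_len(cfg$aux_epochs)) {
      lr <- lr_schedule(epoch - 1L, cfg$lr0, cfg$lr_decay)
      lidx <- sample.int(nl)
      uidx <- sample.int(nu)
      upos <- 0L
      for (s in seq_len(steps_per_epoch)) {
        lb <- lidx[((s - 1L) * cfg$batch_size + 1L):
                     min(s * cfg$batch_size, nl_epoch)]
        if (length(lb) < 2L) next
        nb <- min(cfg$batch_size, nu)
        ub <- uidx[((upos + seq_len(nb) - 1L) %% nu) + 1L]
        upos <- upos + nb
        tstep <- tstep + 1L
        y <- labeled$labels[lb]
        Rl <- rel_from_cached(cfgm, Fl, lb, cmap)
        Ru <- rel_from_cached(cfgm, Fu, ub, cmap)

        for (head in c("aux1", "aux2")) {
          # CE term on the labeled batch
          hl <- head_run(model, head, Rl, training = TRUE)
          model <- hl$model
          lg <- loss_grad_scores(matrix(hl$scores, C, length(lb)), y, cfg$loss)
          g_ce <- head_grad(model, head, hl$cache, as.numeric(lg$dz))$grads

          # discrepancy term on the target batch (maximized, hence -Ldis)
          hu <- head_run(model, head, Ru, training = TRUE)
          model <- hu$model
          r_this <- matrix(hu$scores, C, length(ub))
          other <- if (head == "aux1") "aux2" else "aux1"
          ho <- head_run(model, other, Ru, training = FALSE)
          r_other <- matrix(ho$scores, C, length(ub))
          r_m <- t(r_main[ub, , drop = FALSE])
          dldis_dr <- (sign(r_this - r_m) + sign(r_this - r_other)) /
            (C * length(ub))
          dz_dis <- -cfg$aux_dis_weight * dldis_dr * r_this * (1 - r_this)
          g_dis <- head_grad(model, head, hu$cache, as.numeric(dz_dis))$grads

          model$heads[[head]] <- adam_update(model$heads[[head]],
                                             grad_add(g_ce, g_dis),
                                             adam, head, lr, tstep)
        }
      }
    }
    model
  })
  attr(model, "ldis_before_after") <- c(before = before,
                                        after = mean_ldis(model))
  model
}

#' Fine-tune the main model on the sampled target windows
#'
#' The backward adaptation strategy: updates the feature extractor and
#' main head by cross-entropy on the labeled sample set (the "important"
#' high-discrepancy windows). The auxiliary heads are untouched. An empty
#' sample set is a warned no-op.
#'
#' @param model a pre-trained [relation_model][init_model()].
#' @param sample_set a labeled [window_set()] from the labeling oracle.
#' @param templates the current [template_set][make_template_set()].
#' @param cfg a [train_config()] (`finetune_epochs`, `batch_size`,
#'   `lr0`).
#' @return the fine-tuned model.
#' @export
finetune_main <- function(model, sample_set, templates,
                          cfg = train_config()) {
  stopifnot(inherits(model, "relation_model"))
  check_template_set(templates, model$config)
  if (n_windows(sample_set) < 1L) {
    warn_("empty sample set: returning the model unchanged")
    return(model)
  }
  if (anyNA(sample_set$labels)) stop_("sample set must be fully labeled")
  X <- ws_matrix(sample_set)
  L <- model$config$window_len
  n <- n_windows(sample_set)
  dt <- dim(templates$windows)
  Xt <- matrix(templates$windows, dt[1], dt[2] * dt[3] * dt[4])
  adam <- adam_state_new()
  tstep <- 0L
  with_seed_(derive_seed(cfg$seed, "finetune"), {
    for (epoch in seq_len(cfg$finetune_epochs)) {
      lr <- lr_schedule(epoch - 1L, cfg$lr0, cfg$lr_decay)
      idx <- sample.int(n)
      for (ofs in seq(0L, n - 1L, by = cfg$batch_size)) {
        b <- idx[(ofs + 1L):min(ofs + cfg$batch_size, n)]
        if (length(b) < 2L) next
        tstep <- tstep + 1L
        st <- main_step(model, X[, cols_for(b, L), drop = FALSE],
                        sample_set$labels[b], Xt, templates$shots, "main",
                        lr, tstep, adam, cfg$loss)
        model <- st$model
      }
    }
    model
  })
}

#' Full bidirectional adaptation loop
#'
#' Runs the complete active-learning adaptation for one target subject.
#' Each round: (1) discrepancy-train the auxiliary heads on labeled
#' source + unlabeled target ([train_auxiliary()]); (2) score the target
#' pool, partition it into the top-`n1` "important" and bottom-`n2`
#' "confident" windows, and have the oracle label both
#' ([score_pool()], [partition_pool()], [oracle_label()]); (3) rebuild
#' the template set from the confident windows ([update_templates()],
#' forward strategy) and fine-tune the main model on the cumulative
#' sample set ([finetune_main()], backward strategy). If the labeling
#' budget cannot cover a further round the loop stops cleanly with a
#' partial report.
#'
#' @param model a pre-trained [relation_model][init_model()].
#' @param target_pool the unlabeled target [window_set()].
#' @param source_pool the labeled source [window_set()].
#' @param oracle a [make_oracle()] built over `target_pool`.
#' @param templates the current [template_set][make_template_set()].
#' @param cfg a [train_config()] (`rounds`, `n1`, `n2`, `budget`, ...).
#' @return a list: `model` (adapted), `templates` (updated),
#'   `report` (class `adaptation_report`: per-round tibble with budget,
#'   mean D/S, target accuracy, plus the acquisition reports).
#' @export
adapt <- function(model, target_pool, source_pool, oracle, templates,
                  cfg = train_config()) {
  stopifnot(inherits(model, "relation_model"),
            inherits(oracle, "label_oracle"))
  check_template_set(templates, model$config)
  C <- model$config$n_classes
  n2 <- cfg$n2 %||% (50L * C)
  rounds <- list()
  sample_cum <- NULL
  stopped_early <- FALSE
  for (round in seq_len(cfg$rounds)) {
    npool <- n_windows(target_pool)
    n1r <- min(cfg$n1, npool)
    n2r <- min(n2, npool - n1r)
    if (oracle_budget(oracle) + n1r + n2r > cfg$budget) {
      stopped_early <- TRUE
      break
    }
    labeled_ce <- source_pool
    model <- train_auxiliary(model, labeled_ce, target_pool, templates, cfg)
    ld <- attr(model, "ldis_before_after")

    rep <- score_pool(model, target_pool, templates, source_pool)
    rep <- partition_pool(rep, n1r, n2r)
    new_samples <- oracle_label(oracle, target_pool, rep$sample_idx)
    confident <- oracle_label(oracle, target_pool, rep$template_idx)
    sample_cum <- if (is.null(sample_cum)) new_samples
    else ws_bind(list(sample_cum, new_samples))

    if (n2r > 0L)
      templates <- update_templates(model, confident, templates,
                                    seed = derive_seed(cfg$seed, "tmpl", round))
    if (n1r > 0L)
      model <- finetune_main(model, sample_cum, templates, cfg)

    truth <- oracle$labels
    acc <- if (anyNA(truth)) NA_real_ else {
      pred <- predict(model, target_pool, templates)
      mean(pred == truth) * 100
    }
    rounds[[round]] <- tibble::tibble(
      round = round, n1 = n1r, n2 = n2r,
      budget_used = oracle_budget(oracle),
      mean_D = mean(rep$D), source_mean_D = rep$source_mean_D,
      ldis_before = ld[["before"]], ldis_after = ld[["after"]],
      target_accuracy = acc)
  }
  report <- structure(
    list(rounds = if (length(rounds)) do.call(rbind, rounds)
         else tibble::tibble(),
         stopped_early = stopped_early, seed = cfg$seed,
         budget_used = oracle_budget(oracle)),
    class = "adaptation_report")
  list(model = model, templates = templates, report = report)
}

#' @export
print.adaptation_report <- function(x, ...) {
  cat(sprintf("<adaptation_report> %d round(s), %d labels spent%s\n",
              nrow(x$rounds), x$budget_used,
              if (x$stopped_early) " (stopped early: budget)" else ""))
  if (nrow(x$rounds)) print(x$rounds)
  invisible(x)
}
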