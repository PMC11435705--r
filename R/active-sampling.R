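# Discrepancy-based data acquisition: every unlabeled target window is
# scored by the total disagreement D(x) of the three relation heads; the
# source-domain mean discrepancy is subtracted as a domain-difference
# offset, S(x) = D(x) - mean_{source} D. The pool is then partitioned into
# the n1 highest-S windows ("important", fine-tuning sample set) and the
# n2 lowest ("confident", template pool).

#' Score a target pool by classifier discrepancy
#'
#' Computes `D(x)` for every window of the target pool (and of the source
#' pool, whose mean provides the offset) from the three heads' relation
#' scores in evaluation mode, and the acquisition score
#' `S(x) = D(x) - mean(D_source)`. Subtracting a constant preserves the
#' ranking, so the source pool may be subsampled for cost (see
#' `max_source`).
#'
#' @param model a [relation_model][init_model()] whose auxiliary heads
#'   have been discrepancy-trained (see [train_auxiliary()]).
#' @param target_pool an unlabeled [window_set()] to score.
#' @param templates the current [template_set][make_template_set()].
#' @param source_pool a non-empty [window_set()] from the source domain.
#' @param max_source cap on source windows used for the mean offset
#'   (default 2000; windows beyond the cap are dropped evenly).
#' @param batch evaluation batch size.
#' @return an `acquisition_report`: list with `D` (per-target-window
#'   discrepancy), `source_mean_D`, `S` (= `D - source_mean_D`), and
#'   empty partition slots filled by [partition_pool()].
#' @export
score_pool <- function(model, target_pool, templates, source_pool,
                       max_source = 2000L, batch = 256L) {
  check_template_set(templates, model$config)
  if (n_windows(target_pool) < 1L) stop_("empty target pool")
  if (n_windows(source_pool) < 1L)
    stop_("empty source pool: the mean source discrepancy is undefined")
  ns <- n_windows(source_pool)
  if (ns > max_source)
    source_pool <- ws_subset(source_pool,
                             unique(round(seq(1L, ns, length.out = max_source))))
  D_of <- function(ws) {
    s <- score_windows(model, ws, templates, c("main", "aux1", "aux2"), batch)
    discrepancy_vec(s$main, s$aux1, s$aux2)
  }
  D <- D_of(target_pool)
  srcD <- D_of(source_pool)
  structure(list(D = D, source_mean_D = mean(srcD), S = D - mean(srcD),
                 sample_idx = integer(0), template_idx = integer(0),
                 n1 = 0L, n2 = 0L),
            class = "acquisition_report")
}

#' @export
print.acquisition_report <- function(x, ...) {
  cat(sprintf("<acquisition_report> %d target windows; mean D = %.4f, source mean D = %.4f\n",
              length(x$D), mean(x$D), x$source_mean_D))
  cat(sprintf("  partition: %d sample ('important') / %d template ('confident') windows\n",
              length(x$sample_idx), length(x$template_idx)))
  invisible(x)
}

#' Partition a scored pool into sample set and template pool
#'
#' Selects the `n1` windows with the largest acquisition scores as the
#' fine-tuning sample set ("important" data) and the `n2` windows with
#' the smallest scores as the template pool ("confident" data). Ties are
#' broken toward the lower window index; the two index sets are disjoint
#' and the selection is deterministic.
#'
#' @param report an `acquisition_report` from [score_pool()].
#' @param n1 number of high-discrepancy windows for the sample set.
#' @param n2 number of low-discrepancy windows for the template pool.
#' @return the report with `sample_idx` (length `n1`) and `template_idx`
#'   (length `n2`) filled in (1-based indices into the target pool).
#' @export
partition_pool <- function(report, n1, n2) {
  stopifnot(inherits(report, "acquisition_report"))
  n <- length(report$S)
  if (n1 < 0L || n2 < 0L) stop_("n1 and n2 must be >= 0")
  if (n1 + n2 > n)
    stop_("n1 + n2 = %d exceeds the pool size (%d)", n1 + n2, n)
  ord <- order(report$S, seq_len(n), decreasing = c(TRUE, FALSE),
               method = "radix")
  report$sample_idx <- sort(ord[seq_len(n1)])
  rest <- setdiff(seq_len(n), report$sample_idx)
  asc <- rest[order(report$S[rest], rest)]
  report$template_idx <- sort(asc[seq_len(n2)])
  report$n1 <- as.integer(n1)
  report$n2 <- as.integer(n2)
  report
}

#' Labeling oracle with a budget counter
#'
#' Simulates the human annotator of the active-learning loop: it holds
#' the ground-truth labels of a target pool and reveals them on request,
#' counting each distinct window against the labeling budget once.
#'
#' @param truth_ws a [window_set()] whose labels are the ground truth.
#' @return an object of class `label_oracle`.
#' @export
make_oracle <- function(truth_ws) {
  stopifnot(inherits(truth_ws, "window_set"))
  e <- new.env(parent = emptyenv())
  e$labels <- truth_ws$labels
  e$asked <- logical(n_windows(truth_ws))
  structure(e, class = "label_oracle")
}

#' Query the oracle for labels
#'
#' Returns the selected windows of `ws` with their true labels attached
#' and advances the oracle's budget counter by the number of windows not
#' previously labeled (set semantics: re-labeling is free).
#'
#' @param oracle a [make_oracle()] object built over the same pool as
#'   `ws`.
#' @param ws the unlabeled target [window_set()] the oracle was built
#'   over.
#' @param idx integer indices (1-based) of windows to label.
#' @return a labeled [window_set()] of the selected windows.
#' @export
oracle_label <- function(oracle, ws, idx) {
  stopifnot(inherits(oracle, "label_oracle"))
  n <- length(oracle$asked)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    stop_("oracle index out of range 1..%d", n)
  oracle$asked[idx] <- TRUE
  out <- ws_subset(ws, idx)
  out$labels <- oracle$labels[idx]
  out
}

#' Labels spent so far
#' @param oracle a [make_oracle()] object.
#' @return integer count of distinct windows labeled.
#' @export
oracle_budget <- function(oracle) sum(oracle$asked)
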