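# Losses and discrepancy statistics.

#' Relation-score cross-entropy loss
#'
#' The classification objective for relation heads. By default only the
#' true-class score contributes: `-log(r[true])`, clamped away from 0 for
#' numerical safety and averaged over the batch. With `negatives = TRUE`
#' the binary cross-entropy variant is used, adding `-log(1 - r[c])` for
#' every wrong class; this is the form the training routines optimize,
#' since the positive-only form is minimized by a head that scores every
#' class 1 and therefore cannot shape a decision boundary on its own.
#'
#' @param scores numeric matrix `B x C` of relation scores in (0, 1) (a
#'   single score vector is treated as one row).
#' @param true_class integer vector of true class ids (`0 .. C-1`),
#'   length B (or length 1, recycled).
#' @param negatives include the `-log(1 - r)` terms for wrong classes.
#' @param eps clamping constant (default `1e-7`).
#' @return scalar batch-averaged loss.
#' @examples
#' ce_loss(matrix(c(0.5, 0.1, 0.2, 0.2), 1), 0) # -log(0.5)
#' @export
ce_loss <- function(scores, true_class, negatives = FALSE, eps = 1e-7) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  B <- nrow(scores); C <- ncol(scores)
  if (length(true_class) == 1L) true_class <- rep(true_class, B)
  if (length(true_class) != B)
    stop_("`true_class` length (%d) != batch size (%d)", length(true_class), B)
  if (any(true_class < 0L | true_class >= C))
    stop_("true class id out of range 0..%d", C - 1L)
  s <- pmin(pmax(scores, eps), 1 - eps)
  pos <- -log(s[cbind(seq_len(B), true_class + 1L)])
  if (!negatives) return(mean(pos))
  neg <- -log(1 - s)
  neg[cbind(seq_len(B), true_class + 1L)] <- 0
  mean(pos + rowSums(neg))
}

#' Manhattan discrepancy between two relation-score vectors
#'
#' The per-class-averaged L1 distance
#' `d(a, b) = (1/C) * sum_c |a_c - b_c|`: the disagreement measure between
#' two classifier heads on the same input. Symmetric, bounded in
#' `[0, 1]` for scores in (0, 1), and a true metric (scaled L1).
#'
#' @param r_a,r_b numeric score vectors of equal length C.
#' @return scalar discrepancy.
#' @examples
#' manhattan_d(c(1, 0, 0, 0), c(0, 1, 0, 0)) # 0.5
#' @export
manhattan_d <- function(r_a, r_b) {
  if (length(r_a) != length(r_b))
    stop_("score vectors have different lengths (%d vs %d)",
          length(r_a), length(r_b))
  mean(abs(r_a - r_b))
}

#' Discrepancy loss over a batch
#'
#' The three-way disagreement `d(r1, r) + d(r2, r) + d(r1, r2)` averaged
#' over a batch of unlabeled windows. The auxiliary-head training
#' objective *maximizes* this quantity on the target domain (it enters
#' the objective with a negative sign), pulling the two auxiliary
#' decision boundaries tight around the source distribution.
#'
#' @param r,r1,r2 score matrices `B x C` (vectors treated as one row):
#'   main, first auxiliary and second auxiliary head outputs for the same
#'   batch.
#' @return scalar batch mean of the summed pairwise discrepancies.
#' @export
ldis <- function(r, r1, r2) {
  if (is.null(dim(r))) { r <- rbind(r); r1 <- rbind(r1); r2 <- rbind(r2) }
  if (!all(dim(r) == dim(r1)) || !all(dim(r) == dim(r2)))
    stop_("score matrices have mismatched shapes")
  mean(rowMeans(abs(r1 - r)) + rowMeans(abs(r2 - r)) + rowMeans(abs(r1 - r2)))
}

#' Per-window total classifier discrepancy D(x)
#'
#' Decomposes the disagreement of the three heads on one window into its
#' three pairwise Manhattan terms and their sum
#' `D(x) = d(r1, r2) + d(r, r1) + d(r, r2)`. Large `D` flags windows near
#' the decision boundary ("important" data); small `D` flags windows near
#' the domain centre ("confident" data).
#'
#' @param r,r1,r2 score vectors of equal length C for one window.
#' @return a `discrepancy_triple` list with fields `d_r1_r2`, `d_r_r1`,
#'   `d_r_r2` and `total`.
#' @export
total_discrepancy <- function(r, r1, r2) {
  out <- list(d_r1_r2 = manhattan_d(r1, r2),
              d_r_r1 = manhattan_d(r, r1),
              d_r_r2 = manhattan_d(r, r2))
  out$total <- out$d_r1_r2 + out$d_r_r1 + out$d_r_r2
  structure(out, class = "discrepancy_triple")
}

# Vectorized D over score matrices (n x C each); returns length-n vector.
discrepancy_vec <- function(r, r1, r2) {
  rowMeans(abs(r1 - r2)) + rowMeans(abs(r - r1)) + rowMeans(abs(r - r2))
}
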