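# Composite training objective: multi-positive temperature-scaled contrastive
# loss on the two encoder views, cross-entropy on labelled edges, and L2
# regularization on weight matrices, combined with scalar weights.

#' Build the positive-pair index for a contrastive batch
#'
#' For a batch of `B` distinct nodes embedded by both encoder branches, the
#' stacked representation matrix has `2B` rows (attention view first). Row `i`
#' and row `i + B` describe the same node and are mutual positives; any
#' further rows sharing a node identity would also be positives, but batches
#' are drawn without replacement so cross-view pairs are the positive set.
#'
#' @param node_ids Integer vector of node identities, one per representation
#'   row (length `2B` for the standard two-view batch).
#' @return A list of class `dgi_positive_pairs` with `mask` (logical
#'   `n x n`, `mask[i, j]` true iff `j` is a positive for anchor `i`) and
#'   `node_ids`.
#' @export
positive_pair_index <- function(node_ids) {
  n <- length(node_ids)
  stopifnot(n >= 2)
  mask <- outer(node_ids, node_ids, `==`)
  diag(mask) <- FALSE
  structure(list(mask = mask, node_ids = node_ids), class = "dgi_positive_pairs")
}

#' Multi-positive temperature-scaled contrastive loss
#'
#' Generalizes the standard NT-Xent/InfoNCE loss to anchors with several
#' positives: `loss = -(1/|N|) sum_i log( sum_{j in P(i)} exp(sim(i,j)/tau) /
#' sum_{k != i} exp(sim(i,k)/tau) )`, with cosine similarity on L2-normalized
#' representations. The denominator runs over every batch entry except the
#' anchor itself. Anchors with an empty positive set are excluded with a
#' warning. When every `|P(i)| = 1` the value coincides with standard NT-Xent.
#'
#' @param reps `n x F` matrix of representations (rows are L2-normalized
#'   internally), or a tape node during training.
#' @param pp A [positive_pair_index()] object (or a logical positive mask).
#' @param tau Temperature, strictly positive.
#' @return Scalar loss (non-negative); a tape node when `reps` is one.
#' @export
multipos_ntxent <- function(reps, pp, tau = 0.5) {
  if (tau <= 0) stop("temperature tau must be > 0")
  mask <- if (inherits(pp, "dgi_positive_pairs")) pp$mask else pp
  n <- nrow(ad_val(reps))
  stopifnot(n >= 2, nrow(mask) == n, ncol(mask) == n)

  has_pos <- rowSums(mask) > 0
  if (!all(has_pos)) {
    warning(sprintf("%d anchor(s) with empty positive set excluded from contrastive loss", sum(!has_pos)))
    if (!any(has_pos)) stop("no anchor has a positive: contrastive loss undefined")
  }

  r <- ad_l2norm_rows(reps)
  ex <- ad_exp(ad_affine(ad_mm_nt(r, r), 1 / tau))
  pmask <- mask * 1
  dmask <- matrix(1, n, n) - diag(n)
  if (!all(has_pos)) {
    # excluded anchors get num = den = 1 below, contributing log(1) - log(1) = 0
    pmask[!has_pos, ] <- 0
    dmask[!has_pos, ] <- 0
  }
  num <- ad_rowsums_mask(ex, pmask)
  den <- ad_rowsums_mask(ex, dmask)
  if (!all(has_pos)) {
    one_fix <- matrix(0, n, 1); one_fix[!has_pos] <- 1
    num <- ad_add(num, one_fix)
    den <- ad_add(den, one_fix)
  }
  per_anchor <- ad_sub(ad_log(num), ad_log(den))
  ad_affine(ad_sum(per_anchor), -1 / sum(has_pos))
}

#' L2 regularization over model weight matrices
#'
#' Sums squared entries of weight matrices (including the attention vector).
#' The embedding table and bias vectors are excluded: in a featureless model
#' the embedding norms carry topology signal, and biases are conventionally
#' unpenalized.
#'
#' @param params Flat named parameter list (see [init_model()]); plain
#'   matrices or tape nodes.
#' @return Scalar penalty; a tape node when parameters are nodes.
#' @export
l2_regularization <- function(params) {
  nm <- names(params)
  penal <- nm[grepl("\\.(W[a-z0-9]*|a)$", nm)]
  total <- 0
  for (p in penal) total <- ad_add(total, ad_sum(ad_mul(params[[p]], params[[p]])))
  total
}

#' Cross-entropy of predicted class distributions
#'
#' `-(1/N) sum_i log p[i, y_i]`. Probabilities at the true class that are zero
#' are clamped at 1e-12 with a warning.
#'
#' @param probs `N x C` matrix of predicted distributions; rows must sum to 1
#'   within 1e-6.
#' @param labels Integer class labels in `1..C`.
#' @return Scalar mean negative log-likelihood.
#' @export
cross_entropy <- function(probs, labels) {
  stopifnot(nrow(probs) == length(labels))
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("probability rows must sum to 1")
  if (any(labels < 1 | labels > ncol(probs))) stop("labels out of class range")
  p <- probs[cbind(seq_along(labels), labels)]
  if (any(p <= 0)) {
    warning("zero probability at true class clamped to 1e-12")
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

#' Loss weights for the composite objective
#'
#' @param alpha Weight of the L2 regularization term.
#' @param beta Weight of the contrastive term.
#' @param gamma Weight of the cross-entropy term (kept dominant so the
#'   supervised signal leads).
#' @param tau Contrastive temperature.
#' @return A named list of class `dgi_loss_weights`.
#' @export
loss_weights <- function(alpha = 1e-4, beta = 0.1, gamma = 1, tau = 0.5) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, tau > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau = tau),
            class = "dgi_loss_weights")
}

#' Weighted total loss
#'
#' `alpha * reg + beta * cl + gamma * ce`.
#'
#' @param reg,cl,ce Scalar loss components (numbers or tape nodes).
#' @param w A [loss_weights()] object.
#' @return Scalar total loss.
#' @export
total_loss <- function(reg, cl, ce, w = loss_weights()) {
  ad_add(ad_add(ad_affine(reg, w$alpha), ad_affine(cl, w$beta)), ad_affine(ce, w$gamma))
}
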