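# Two topology encoders share one embedding table: a lightweight graph
# attention pass over the self-looped neighborhood structure, and a gated
# higher-order pass that routes node states through interaction hyperedges.
# All forwards are written against the autodiff ops, so they run identically
# on plain matrices (inference) and on tape nodes (training).

#' Initialize a learnable node embedding table
#'
#' Embeddings are the model's only "features": entries are drawn from a
#' zero-mean normal with standard deviation `1/sqrt(dim)` so initial rows have
#' roughly unit norm.
#'
#' @param n_nodes Number of nodes (drugs + genes).
#' @param dim Embedding dimension F.
#' @param seed Integer seed for a reproducible draw, or `NULL` to use the
#'   ambient random-number stream (as the training loop does, under its own
#'   seed).
#' @return An `n_nodes x dim` numeric matrix.
#' @export
init_embedding <- function(n_nodes, dim, seed = NULL) {
  stopifnot(n_nodes >= 1, dim >= 1)
  draw <- function() matrix(stats::rnorm(n_nodes * dim, sd = 1 / sqrt(dim)), n_nodes, dim)
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

rand_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)

#' Initialize parameters for one attention-encoder layer
#'
#' @param dim_in Input feature dimension F.
#' @param dim_out Output feature dimension F'.
#' @param leaky_slope Negative slope of the LeakyReLU used on attention
#'   logits.
#' @param attention_dropout Probability of dropping an attention weight during
#'   training (weights are renormalized afterwards); disabled at evaluation.
#' @return A list with `W` (`dim_out x dim_in`), `a` (length `2*dim_out`),
#'   `leaky_slope`, `attention_dropout`.
#' @export
gatlite_params <- function(dim_in, dim_out = dim_in, leaky_slope = 0.2,
                           attention_dropout = 0.1) {
  list(
    W = rand_mat(dim_out, dim_in),
    a = stats::rnorm(2 * dim_out, sd = 1 / sqrt(2 * dim_out)),
    leaky_slope = leaky_slope,
    attention_dropout = attention_dropout
  )
}

#' Initialize parameters for one gated-convolution layer
#'
#' The node and hyperedge transforms are 2-layer perceptrons (linear, ELU,
#' linear) of constant width `dim`; the gate is a linear map on the
#' concatenation of the node state and its aggregated hyperedge message.
#' The edge MLP's output layer starts small and the gate bias starts negative
#' (highway-style carry initialization), so each layer begins close to an
#' identity map and the structural pathway opens up as training warrants it —
#' this keeps deep stacks trainable.
#'
#' @param dim Feature dimension F (kept constant through the layer).
#' @return A list with node MLP weights `W1, b1, W2, b2`, edge MLP weights
#'   `We1, be1, We2, be2`, and gate parameters `Wg` (`dim x 2 dim`), `bg`.
#' @export
gatedgcn_params <- function(dim) {
  list(
    W1 = rand_mat(dim, dim), b1 = numeric(dim),
    W2 = rand_mat(dim, dim), b2 = numeric(dim),
    We1 = rand_mat(dim, dim), be1 = numeric(dim),
    We2 = 0.01 * rand_mat(dim, dim), be2 = numeric(dim),
    Wg = rand_mat(dim, 2 * dim), bg = rep(-2, dim)
  )
}

mlp2 <- function(x, W1, b1, W2, b2) {
  ad_add_bias(ad_mm_nt(ad_elu(ad_add_bias(ad_mm_nt(x, W1), b1)), W2), b2)
}

#' Lightweight graph attention forward pass
#'
#' Computes `z_i = W h_i`, attention logits
#' `e_ij = LeakyReLU(a^T [z_i || z_j])` for every directed neighbor pair
#' (including self-loops), a softmax over each node's neighborhood, and the
#' output `h'_i = L2Norm(ELU(sum_j alpha_ij z_j))`. During training a dropout
#' mask is applied to the attention weights, which are then renormalized per
#' neighborhood.
#'
#' @param h Node features (`n x F` matrix, or tape node during training).
#' @param adj A `dgi_adjacency` from [normalized_adjacency()]; supplies the
#'   self-looped neighbor pairs.
#' @param params A [gatlite_params()] list (entries may be tape nodes).
#' @param training Logical; enables attention dropout.
#' @param return_attention Logical; also return the attention coefficients
#'   (plain inference only).
#' @return The transformed `n x F'` features; if `return_attention`, a list
#'   with `h` and `attention` (tibble of target, source, weight).
#' @export
gatlite_forward <- function(h, adj, params, training = FALSE,
                            return_attention = FALSE) {
  stopifnot(inherits(adj, "dgi_adjacency"))
  nb <- adj$neighbors
  tgt <- nb[, "target"]
  src <- nb[, "source"]
  n <- adj$n_nodes
  if (nrow(ad_val(h)) != n) stop("feature matrix rows do not match graph order")
  if (ncol(ad_val(params$W)) != ncol(ad_val(h))) stop("projection width does not match feature dimension")

  z <- ad_mm_nt(h, params$W)
  zi <- ad_rows(z, tgt)
  zj <- ad_rows(z, src)
  avec <- params$a
  a_col <- if (is_adnode(avec)) avec else matrix(avec, ncol = 1)
  if (is_adnode(a_col) && !is.matrix(ad_val(a_col))) stop("attention vector must be a column matrix on tape")
  e <- ad_leaky_relu(ad_mm(ad_cbind(zi, zj), a_col), params$leaky_slope)
  alpha <- ad_segment_softmax(e, tgt, n)

  p_drop <- params$attention_dropout
  if (isTRUE(training) && !is.null(p_drop) && p_drop > 0) {
    keep <- matrix(as.numeric(stats::runif(length(tgt)) >= p_drop), ncol = 1)
    kept <- ad_mul(alpha, keep)
    denom <- ad_segment_sum(kept, tgt, n)
    denom_g <- ad_rows(ad_pmax(denom, matrix(1e-12, n, 1)), tgt)
    alpha <- ad_div(kept, denom_g)
  }

  out <- ad_l2norm_rows(ad_elu(ad_segment_sum(ad_rowscale(zj, alpha), tgt, n)))
  if (return_attention) {
    list(
      h = out,
      attention = tibble::tibble(
        target = tgt, source = src, weight = as.vector(ad_val(alpha))
      )
    )
  } else {
    out
  }
}

#' Gated higher-order convolution forward pass
#'
#' Node states pass through a node MLP, flow to interaction hyperedges (mean
#' of the two endpoint states), are transformed by an edge MLP, and aggregate
#' back to nodes. A sigmoid gate on `[h_i || z'_i]` blends the aggregated
#' structural message `z'_i` with the incoming state:
#' `h_i <- g_i * z'_i + (1 - g_i) * h_i`. Isolated nodes receive `z'_i = 0`.
#'
#' On heavy-tailed interaction networks a raw sum over a hub's hundreds of
#' incident hyperedges explodes in magnitude and destabilizes training, so
#' the summed message is rescaled by `1/sqrt(1 + degree)` — the same
#' symmetric-normalization philosophy the shared adjacency applies, and the
#' standard normalization in hypergraph convolutions. Sum and mean therefore
#' differ by `sqrt(1 + k)` vs `k`, preserving the distinction between the
#' two aggregators.
#'
#' @param h Node features (`n x F`).
#' @param inc A `dgi_incidence` from [incidence_structure()].
#' @param params A [gatedgcn_params()] list.
#' @param aggregation Hyperedge-to-node aggregation: `"sum"` (degree-
#'   normalized as above), `"mean"`, `"min"`, or `"max"`.
#' @return Gated node features, `n x F`.
#' @export
gatedgcn_forward <- function(h, inc, params, aggregation = "sum") {
  stopifnot(inherits(inc, "dgi_incidence"))
  n <- inc$n_nodes
  if (nrow(ad_val(h)) != n) stop("feature matrix rows do not match graph order")
  aggregation <- match.arg(aggregation, c("sum", "mean", "min", "max"))

  u <- mlp2(h, params$W1, params$b1, params$W2, params$b2)
  m <- ad_affine(ad_add(ad_rows(u, inc$drug_node), ad_rows(u, inc$gene_node)), 0.5)
  m <- mlp2(m, params$We1, params$be1, params$We2, params$be2)

  seg <- c(inc$drug_node, inc$gene_node)
  m2 <- ad_rbind(m, m)
  k <- tabulate(seg, nbins = n)
  zp <- switch(aggregation,
    sum = ad_rowscale(ad_segment_sum(m2, seg, n), matrix(1 / sqrt(1 + k), ncol = 1)),
    mean = ad_segment_mean(m2, seg, n),
    min = ad_segment_extreme(m2, seg, n, "min"),
    max = ad_segment_extreme(m2, seg, n, "max")
  )

  gate <- ad_sigmoid(ad_add_bias(ad_mm_nt(ad_cbind(h, zp), params$Wg), params$bg))
  ad_add(ad_mul(gate, zp), ad_mul(ad_affine(gate, -1, 1), h))
}

combine_views <- function(a, b, aggregation = "sum") {
  switch(match.arg(aggregation, c("sum", "mean", "min", "max")),
    sum = ad_add(a, b),
    mean = ad_affine(ad_add(a, b), 0.5),
    min = ad_pmin(a, b),
    max = ad_pmax(a, b)
  )
}

#' Run both encoder branches from a shared embedding table
#'
#' The attention branch and the gated branch each stack `num_layers` layers
#' starting from the same input `h0` (parallel dual-view design). The two
#' branch outputs are the views used by the contrastive objective; their
#' elementwise combination (by the configured aggregation) is the final node
#' representation used for edge classification.
#'
#' @param h0 Initial node features (`n x F`).
#' @param adj A `dgi_adjacency`.
#' @param inc A `dgi_incidence`.
#' @param params A list with `gat` and `gated`: per-layer parameter lists.
#' @param num_layers Number of layers in each branch.
#' @param aggregation Aggregation for hyperedge-to-node messages and for the
#'   final view combination (`"sum"` by default, the best-performing choice).
#' @param training Logical; enables attention dropout.
#' @return A list with `gat_view`, `gated_view`, and `combined`.
#' @export
stack_encoders <- function(h0, adj, inc, params, num_layers = length(params$gat),
                           aggregation = "sum", training = FALSE) {
  stopifnot(num_layers >= 1)
  ha <- h0
  hb <- h0
  for (l in seq_len(num_layers)) {
    ha <- gatlite_forward(ha, adj, params$gat[[l]], training = training)
    hb <- gatedgcn_forward(hb, inc, params$gated[[l]], aggregation = aggregation)
  }
  list(
    gat_view = ha,
    gated_view = hb,
    combined = combine_views(ha, hb, aggregation)
  )
}
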