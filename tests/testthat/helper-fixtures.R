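# Shared fixtures and independent reference implementations used as oracles.

# Random bipartite graph with uniformly placed distinct edges.
random_graph <- function(n_drugs, n_genes, n_edges, n_classes = 2L, seed = 1L) {
  stopifnot(n_edges <= n_drugs * n_genes)
  withr::with_seed(seed, {
    key <- sample.int(n_drugs * n_genes, n_edges)
    di <- ((key - 1L) %% n_drugs) + 1L
    gi <- ((key - 1L) %/% n_drugs) + 1L
    bipartite_graph(data.frame(
      drug_id = sprintf("d%04d", di),
      gene_id = sprintf("g%04d", gi),
      label = sprintf("c%02d", sample.int(n_classes, n_edges, replace = TRUE))
    ))
  })
}

all_rows <- function(g) seq_len(nrow(g$edges))

# Dense reference for the attention pass: computes every pairwise logit,
# masks non-neighbors with -Inf, softmaxes rows of the self-looped adjacency.
dense_gat_reference <- function(h, adj_matrix_binary, W, a, slope = 0.2) {
  n <- nrow(h)
  z <- h %*% t(W)
  fp <- ncol(z)
  e <- matrix(-Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj_matrix_binary[i, j] > 0) {
        v <- sum(a * c(z[i, ], z[j, ]))
        e[i, j] <- if (v > 0) v else slope * v
      }
    }
  }
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- e[i, ]
    m <- max(row)
    ex <- exp(row - m)
    ex[is.nan(ex)] <- 0
    alpha[i, ] <- ex / sum(ex)
  }
  agg <- alpha %*% z
  out <- ifelse(agg > 0, agg, exp(pmin(agg, 0)) - 1)
  nrm <- sqrt(rowSums(out^2))
  sweep(out, 1, ifelse(nrm > 1e-12, nrm, 1), "/") * (nrm > 1e-12)
}

# Self-looped binary adjacency as a dense matrix, for the dense oracle.
dense_selfloop_adjacency <- function(g, rows = all_rows(g)) {
  n <- n_nodes(g)
  A <- diag(n)
  e <- g$edges[rows, , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    A[e$node_drug[k], e$node_gene[k]] <- 1
    A[e$node_gene[k], e$node_drug[k]] <- 1
  }
  A
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
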