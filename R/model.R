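# Full model: shared embedding table -> two encoder branches -> combined
# node representations -> pair-scoring head, trained with AdamW and a
# triangular cyclic learning rate on the composite objective.

#' Model and training configuration
#'
#' Desk-scale defaults: 64-dimensional embeddings, 2 layers per branch, sum
#' aggregation, 200 epochs. Larger settings (e.g. 1024 dimensions, 4 layers)
#' improve accuracy on real interaction networks at proportionally higher
#' cost.
#'
#' @param embedding_dim Embedding dimension F.
#' @param num_layers Layers per encoder branch.
#' @param aggregation `"sum"`, `"mean"`, `"min"` or `"max"`; used both for
#'   hyperedge-to-node messages and for combining the two branch views.
#' @param epochs Training epochs (full-batch).
#' @param base_lr,max_lr,cycle Triangular cyclic learning-rate schedule in
#'   the usual CyclicLR convention: the rate is initialized at `base_lr`
#'   (0.001 by default), climbs to `max_lr` over half a cycle and descends
#'   back, with `cycle` epochs per full cycle.
#' @param weights A [loss_weights()] object (alpha, beta, gamma, tau).
#' @param attention_dropout Dropout probability on attention weights.
#' @param leaky_slope LeakyReLU negative slope for attention logits.
#' @param weight_decay Decoupled AdamW weight decay (weight matrices only).
#' @param cl_batch_max Maximum number of nodes per contrastive batch; nodes
#'   incident to training edges are subsampled to this size each epoch.
#' @param seed Integer seed controlling every random draw in training.
#' @param use_contrastive,use_gat,use_gate,use_vote Ablation switches. With
#'   `use_contrastive = FALSE` the contrastive term is never computed. With
#'   one branch disabled the remaining branch's output is the node
#'   representation and the (two-view) contrastive term is disabled as well.
#'   `use_vote` marks whether ensemble voting is intended downstream.
#' @return A named list of class `dgi_config`.
#' @export
dgi_config <- function(embedding_dim = 64L, num_layers = 2L, aggregation = "sum",
                       epochs = 200L, base_lr = 1e-3, max_lr = 1e-2, cycle = 50L,
                       weights = loss_weights(), attention_dropout = 0.1,
                       leaky_slope = 0.2, weight_decay = 1e-3,
                       cl_batch_max = 4096L, seed = 0L,
                       use_contrastive = TRUE, use_gat = TRUE, use_gate = TRUE,
                       use_vote = TRUE) {
  stopifnot(embedding_dim >= 1, num_layers >= 1, epochs >= 1,
            base_lr > 0, max_lr >= base_lr, cycle >= 2)
  aggregation <- match.arg(aggregation, c("sum", "mean", "min", "max"))
  if (!use_gat && !use_gate) stop("at least one encoder branch must be enabled")
  structure(list(
    embedding_dim = as.integer(embedding_dim), num_layers = as.integer(num_layers),
    aggregation = aggregation, epochs = as.integer(epochs),
    base_lr = base_lr, max_lr = max_lr, cycle = as.integer(cycle),
    weights = weights, attention_dropout = attention_dropout,
    leaky_slope = leaky_slope, weight_decay = weight_decay,
    cl_batch_max = as.integer(cl_batch_max), seed = as.integer(seed),
    use_contrastive = use_contrastive, use_gat = use_gat, use_gate = use_gate,
    use_vote = use_vote
  ), class = "dgi_config")
}

cyclic_lr <- function(epoch, cfg) {
  phase <- (epoch - 1L) %% cfg$cycle
  half <- cfg$cycle / 2
  frac <- 1 - abs(half - phase) / half
  cfg$base_lr + (cfg$max_lr - cfg$base_lr) * frac
}

# Flat named parameter list. Names ending in .W*, .a are "weight matrices"
# for regularization and weight decay; emb and biases are exempt.
init_model <- function(n_nodes, n_classes, cfg) {
  f <- cfg$embedding_dim
  params <- list(emb = init_embedding(n_nodes, f))
  for (l in seq_len(cfg$num_layers)) {
    if (cfg$use_gat) {
      gp <- gatlite_params(f, f, cfg$leaky_slope, cfg$attention_dropout)
      params[[sprintf("gat%d.W", l)]] <- gp$W
      params[[sprintf("gat%d.a", l)]] <- matrix(gp$a, ncol = 1)
    }
    if (cfg$use_gate) {
      hp <- gatedgcn_params(f)
      for (nm in c("W1", "b1", "W2", "b2", "We1", "be1", "We2", "be2", "Wg", "bg")) {
        params[[sprintf("gated%d.%s", l, nm)]] <- hp[[nm]]
      }
    }
  }
  params[["head.W1"]] <- rand_mat(f, 2 * f)
  params[["head.b1"]] <- numeric(f)
  params[["head.W2"]] <- rand_mat(n_classes, f)
  params[["head.b2"]] <- numeric(n_classes)
  params
}

# Structured view over a flat parameter list (plain or tape-wrapped).
nest_params <- function(params, cfg) {
  out <- list(gat = list(), gated = list(), head = list(
    W1 = params[["head.W1"]], b1 = params[["head.b1"]],
    W2 = params[["head.W2"]], b2 = params[["head.b2"]]
  ), emb = params$emb)
  for (l in seq_len(cfg$num_layers)) {
    if (cfg$use_gat) {
      out$gat[[l]] <- list(
        W = params[[sprintf("gat%d.W", l)]],
        a = params[[sprintf("gat%d.a", l)]],
        leaky_slope = cfg$leaky_slope,
        attention_dropout = cfg$attention_dropout
      )
    }
    if (cfg$use_gate) {
      out$gated[[l]] <- lapply(
        stats::setNames(nm = c("W1", "b1", "W2", "b2", "We1", "be1", "We2", "be2", "Wg", "bg")),
        function(nm) params[[sprintf("gated%d.%s", l, nm)]]
      )
    }
  }
  out
}

# Forward of the enabled branches; returns list(gat_view, gated_view, combined)
# where disabled branches are NULL and combined is the active view (or the
# aggregated pair).
model_forward <- function(params, adj, inc, cfg, training = FALSE) {
  np <- nest_params(params, cfg)
  ha <- NULL; hb <- NULL
  h0 <- np$emb
  if (cfg$use_gat) {
    ha <- h0
    for (l in seq_len(cfg$num_layers)) ha <- gatlite_forward(ha, adj, np$gat[[l]], training = training)
  }
  if (cfg$use_gate) {
    hb <- h0
    for (l in seq_len(cfg$num_layers)) hb <- gatedgcn_forward(hb, inc, np$gated[[l]], aggregation = cfg$aggregation)
  }
  combined <- if (!is.null(ha) && !is.null(hb)) combine_views(ha, hb, cfg$aggregation) else if (!is.null(ha)) ha else hb
  list(gat_view = ha, gated_view = hb, combined = combined)
}

head_logits <- function(reps, node_drug, node_gene, head) {
  x <- ad_cbind(ad_rows(reps, node_drug), ad_rows(reps, node_gene))
  mlp2(x, head$W1, head$b1, head$W2, head$b2)
}

#' Score drug-gene pairs from node representations
#'
#' Concatenates each pair's drug and gene vectors, applies a 2-layer
#' perceptron, and returns softmax class probabilities.
#'
#' @param drug_reps `m x F` matrix of drug representations.
#' @param gene_reps `n x F` matrix of gene representations.
#' @param pairs Data frame with `drug_index` (1..m) and `gene_index` (1..n).
#' @param head Named list `W1` (`H x 2F`), `b1`, `W2` (`C x H`), `b2`.
#' @return `nrow(pairs) x C` matrix of class probabilities (rows sum to 1).
#' @export
score_edges <- function(drug_reps, gene_reps, pairs, head) {
  if (any(pairs$drug_index < 1 | pairs$drug_index > nrow(drug_reps)) ||
      any(pairs$gene_index < 1 | pairs$gene_index > nrow(gene_reps))) {
    stop("pair index out of range")
  }
  x <- cbind(drug_reps[pairs$drug_index, , drop = FALSE],
             gene_reps[pairs$gene_index, , drop = FALSE])
  logits <- mlp2(x, head$W1, head$b1, head$W2, head$b2)
  ad_val(ad_softmax_rows(logits))
}

#' Train the topology-only interaction classifier
#'
#' Full-batch training on the training-edge graph: both encoder branches run
#' on an adjacency and incidence structure built from training edges only (so
#' held-out edges never leak through message passing), the composite loss is
#' computed on training pairs, and AdamW steps follow a triangular cyclic
#' learning rate. The parameters of the best validation-accuracy epoch are
#' retained. Fully deterministic given `cfg$seed`.
#'
#' @param g A `dgi_graph`.
#' @param split A `dgi_split` from [transductive_split()].
#' @param cfg A [dgi_config()].
#' @param quiet Suppress per-cycle progress messages.
#' @return An object of class `dgi_fit` with elements `params` (best-epoch
#'   parameters), `final_params`, `config`, `history` (tibble with per-epoch
#'   losses and validation accuracy), `best_epoch`, `graph_meta` (node maps
#'   and labels) and `train_rows`.
#' @export
dgi_train <- function(g, split, cfg = dgi_config(), quiet = TRUE) {
  stopifnot(inherits(g, "dgi_graph"), inherits(split, "dgi_split"))
  use_cl <- cfg$use_contrastive && cfg$use_gat && cfg$use_gate &&
    cfg$weights$beta > 0

  adj <- normalized_adjacency(g, split$train)
  inc <- incidence_structure(g, split$train)
  n <- n_nodes(g)
  train_edges <- g$edges[split$train, , drop = FALSE]
  val_edges <- g$edges[split$val, , drop = FALSE]

  cl_pool <- sort(unique(c(train_edges$node_drug, train_edges$node_gene)))

  withr::with_seed(cfg$seed, {
    params <- init_model(n, g$n_classes, cfg)
    opt <- adamw_init(params)
    history <- vector("list", cfg$epochs)
    best <- list(acc = -Inf, epoch = NA_integer_, params = NULL)

    for (epoch in seq_len(cfg$epochs)) {
      lr <- cyclic_lr(epoch, cfg)
      if (!all(vapply(params, function(p) all(is.finite(p)), logical(1)))) {
        stop(sprintf(
          "non-finite loss or parameters at epoch %d: optimization diverged; try a lower learning rate",
          epoch
        ))
      }

      ad_tape_start()
      leaves <- lapply(params, ad_leaf)
      fw <- model_forward(leaves, adj, inc, cfg, training = TRUE)
      np <- nest_params(leaves, cfg)

      loss_ce <- ad_softmax_xent(
        head_logits(fw$combined, train_edges$node_drug, train_edges$node_gene, np$head),
        train_edges$class
      )
      loss_cl <- 0
      if (use_cl) {
        batch <- if (length(cl_pool) > cfg$cl_batch_max) {
          sort(sample(cl_pool, cfg$cl_batch_max))
        } else cl_pool
        reps <- ad_rbind(ad_rows(fw$gat_view, batch), ad_rows(fw$gated_view, batch))
        loss_cl <- multipos_ntxent(reps, positive_pair_index(c(batch, batch)),
                                   tau = cfg$weights$tau)
      }
      loss_reg <- l2_regularization(leaves)
      loss <- total_loss(loss_reg, loss_cl, loss_ce, cfg$weights)
      loss_val <- ad_val(loss)
      if (!is.finite(loss_val)) {
        ad_tape_stop()
        stop(sprintf(
          "non-finite loss at epoch %d (ce=%g, cl=%g, reg=%g): try a lower learning rate",
          epoch, ad_val(loss_ce), ad_val(loss_cl), ad_val(loss_reg)
        ))
      }
      ad_backward(loss)
      grads <- lapply(leaves, ad_grad)
      ad_tape_stop()

      params <- adamw_step(params, grads, opt, lr, cfg$weight_decay)

      fw_eval <- model_forward(params, adj, inc, cfg, training = FALSE)
      val_probs <- ad_val(ad_softmax_rows(head_logits(
        fw_eval$combined, val_edges$node_drug, val_edges$node_gene,
        nest_params(params, cfg)$head
      )))
      val_acc <- mean(max.col(val_probs, ties.method = "first") == val_edges$class)
      if (!is.finite(val_acc)) {
        stop(sprintf(
          "non-finite loss or predictions at epoch %d: optimization diverged; try a lower learning rate",
          epoch
        ))
      }

      history[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, loss = loss_val,
        loss_reg = ad_val(loss_reg), loss_cl = ad_val(loss_cl),
        loss_ce = ad_val(loss_ce), val_acc = val_acc
      )
      if (val_acc > best$acc) best <- list(acc = val_acc, epoch = epoch, params = params)
      if (!quiet && epoch %% cfg$cycle == 0) {
        message(sprintf("epoch %d: loss %.4f, val acc %.4f", epoch, loss_val, val_acc))
      }
    }
  })

  structure(list(
    params = best$params,
    final_params = params,
    config = cfg,
    history = dplyr::bind_rows(history),
    best_epoch = best$epoch,
    best_val_acc = best$acc,
    graph_meta = list(
      drug_ids = g$drug_ids, gene_ids = g$gene_ids, labels = g$labels,
      n_classes = g$n_classes
    ),
    train_rows = split$train,
    train_edges = train_edges
  ), class = "dgi_fit")
}

#' @export
print.dgi_fit <- function(x, ...) {
  cat(sprintf(
    "<dgi_fit> F=%d, %d layer(s), %s aggregation; %d epochs; best val acc %.4f (epoch %d)\n",
    x$config$embedding_dim, x$config$num_layers, x$config$aggregation,
    nrow(x$history), x$best_val_acc, x$best_epoch
  ))
  invisible(x)
}

fit_node_reps <- function(fit, params = fit$params) {
  g <- fit_graph(fit)
  adj <- normalized_adjacency(g, seq_len(nrow(g$edges)))
  inc <- incidence_structure(g, seq_len(nrow(g$edges)))
  model_forward(params, adj, inc, fit$config, training = FALSE)
}

# Reconstruct the training graph (training edges only) from stored metadata.
fit_graph <- function(fit) {
  e <- fit$train_edges
  m <- length(fit$graph_meta$drug_ids)
  g <- list(
    drug_ids = fit$graph_meta$drug_ids,
    gene_ids = fit$graph_meta$gene_ids,
    labels = fit$graph_meta$labels,
    n_classes = fit$graph_meta$n_classes,
    edges = e
  )
  class(g) <- "dgi_graph"
  g
}

#' Predict interaction classes for drug-gene pairs
#'
#' Transductive: every queried drug and gene must already exist in the
#' training graph's node set; an unknown identifier raises a "transductive
#' violation" error naming it. Message passing uses training edges only.
#'
#' @param object A `dgi_fit`.
#' @param pairs Data frame with `drug_id` and `gene_id` columns (external
#'   identifiers).
#' @param ... Unused.
#' @return A tibble with the queried identifiers, `pred_class` (1-based),
#'   `pred_label`, and one `prob_<label>` column per relation class (rows sum
#'   to 1).
#' @export
predict.dgi_fit <- function(object, pairs, ...) {
  stopifnot(is.data.frame(pairs), all(c("drug_id", "gene_id") %in% names(pairs)))
  meta <- object$graph_meta
  di <- match(as.character(pairs$drug_id), meta$drug_ids)
  gi <- match(as.character(pairs$gene_id), meta$gene_ids)
  if (anyNA(di)) {
    stop(sprintf("transductive violation: drug id(s) not in training graph: %s",
                 paste(unique(pairs$drug_id[is.na(di)]), collapse = ", ")))
  }
  if (anyNA(gi)) {
    stop(sprintf("transductive violation: gene id(s) not in training graph: %s",
                 paste(unique(pairs$gene_id[is.na(gi)]), collapse = ", ")))
  }
  fw <- fit_node_reps(object)
  m <- length(meta$drug_ids)
  head <- nest_params(object$params, object$config)$head
  probs <- score_edges(
    fw$combined[seq_len(m), , drop = FALSE],
    fw$combined[-seq_len(m), , drop = FALSE],
    data.frame(drug_index = di, gene_index = gi),
    head
  )
  colnames(probs) <- paste0("prob_", meta$labels)
  pred <- max.col(probs, ties.method = "first")
  dplyr::bind_cols(
    tibble::tibble(
      drug_id = as.character(pairs$drug_id),
      gene_id = as.character(pairs$gene_id),
      pred_class = pred,
      pred_label = meta$labels[pred]
    ),
    tibble::as_tibble(probs)
  )
}

#' Majority-vote ensemble over member predictions
#'
#' Each member votes with its argmax class; ties among the most-voted classes
#' are resolved by the highest mean predicted probability. Deterministic.
#'
#' @param member_predictions A list (length >= 2) of prediction tibbles from
#'   [predict.dgi_fit()] (aligned pair order), or of `n x C` probability
#'   matrices.
#' @return A tibble with `pred_class`, `pred_label` (when label names are
#'   available) and the mean probability matrix columns.
#' @export
ensemble_vote <- function(member_predictions) {
  stopifnot(is.list(member_predictions), length(member_predictions) >= 2)
  probs <- lapply(member_predictions, function(p) {
    if (is.matrix(p)) return(p)
    as.matrix(p[, grepl("^prob_", names(p)), drop = FALSE])
  })
  n <- nrow(probs[[1]])
  if (!all(vapply(probs, nrow, integer(1)) == n)) {
    stop("ensemble members have misaligned prediction lengths")
  }
  votes <- vapply(probs, function(p) max.col(p, ties.method = "first"), integer(n))
  votes <- matrix(votes, nrow = n)
  mean_probs <- Reduce(`+`, probs) / length(probs)
  n_class <- ncol(mean_probs)
  if (is.null(colnames(mean_probs))) {
    colnames(mean_probs) <- paste0("prob_", seq_len(n_class))
  }
  pred <- vapply(seq_len(n), function(i) {
    tab <- tabulate(votes[i, ], nbins = n_class)
    top <- which(tab == max(tab))
    if (length(top) == 1L) top else top[which.max(mean_probs[i, top])]
  }, integer(1))
  out <- tibble::tibble(pred_class = pred)
  first <- member_predictions[[1]]
  if (is.data.frame(first) && "pred_label" %in% names(first)) {
    labels <- sub("^prob_", "", colnames(mean_probs))
    out$pred_label <- labels[pred]
    if (all(c("drug_id", "gene_id") %in% names(first))) {
      out <- dplyr::bind_cols(first[, c("drug_id", "gene_id")], out)
    }
  }
  dplyr::bind_cols(out, tibble::as_tibble(mean_probs))
}

#' Train an ensemble of seed variants
#'
#' @param g A `dgi_graph`.
#' @param split A `dgi_split`.
#' @param cfg A [dgi_config()]; each member trains with `seed = cfg$seed +
#'   member - 1`.
#' @param n_members Number of members (>= 2).
#' @return A list of `dgi_fit` objects of class `dgi_ensemble`.
#' @export
dgi_train_ensemble <- function(g, split, cfg = dgi_config(), n_members = 5L) {
  stopifnot(n_members >= 2)
  fits <- lapply(seq_len(n_members), function(k) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k - 1L
    dgi_train(g, split, cfg_k)
  })
  structure(fits, class = "dgi_ensemble")
}

#' @rdname dgi_train_ensemble
#' @param ensemble A `dgi_ensemble`.
#' @param pairs Data frame of `drug_id`, `gene_id` pairs.
#' @export
predict_ensemble <- function(ensemble, pairs) {
  ensemble_vote(lapply(ensemble, predict, pairs = pairs))
}

## ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
  e$v <- e$m
  e$t <- 0L
  e
}

adamw_step <- function(params, grads, opt, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  decayed <- grepl("\\.(W[a-z0-9]*|a)$", names(params))
  for (k in seq_along(params)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    if (!is.matrix(params[[k]]) && is.matrix(gk)) gk <- as.vector(gk)
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * gk
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * gk * gk
    mhat <- opt$m[[k]] / (1 - beta1^t)
    vhat <- opt$v[[k]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (decayed[k]) upd <- upd + weight_decay * params[[k]]
    params[[k]] <- params[[k]] - lr * upd
  }
  params
}
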