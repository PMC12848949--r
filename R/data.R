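# Edge-list IO, transductive split construction, frequency-smoothed negative
# sampling, and the seeded synthetic bipartite network generator.

#' Read a drug-gene edge list from TSV
#'
#' Expects a UTF-8 tab-separated file with header
#' `drug_id<TAB>gene_id<TAB>label`; lines starting with `#` are comments.
#' Both LF and CRLF line endings are accepted. A malformed line raises an
#' error naming its (1-based, physical) line number.
#'
#' @param path Path to the TSV file.
#' @return A `dgi_graph` (see [bipartite_graph()]).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("edge list needs a header and at least one edge: ", path)

  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 3L)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields, found %d",
                 lineno[bad[1]], path, nf[bad[1]]))
  }
  header <- parts[[1]]
  if (!identical(header, c("drug_id", "gene_id", "label"))) {
    stop(sprintf("malformed line %d in %s: header must be drug_id<TAB>gene_id<TAB>label",
                 lineno[1], path))
  }
  body <- parts[-1]
  bipartite_graph(tibble::tibble(
    drug_id = vapply(body, `[[`, character(1), 1L),
    gene_id = vapply(body, `[[`, character(1), 2L),
    label = vapply(body, `[[`, character(1), 3L)
  ))
}

#' Write a graph's edge list to TSV
#'
#' Canonical form: header then edges in internal (drug, gene) index order, so
#' `write_edge_list()` then [read_edge_list()] is the identity on the graph.
#'
#' @param g A `dgi_graph`.
#' @param path Output path.
#' @param rows Optional integer vector of edge rows to write.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, rows = NULL) {
  e <- g$edges
  if (!is.null(rows)) e <- e[rows, , drop = FALSE]
  ord <- order(e$drug_index, e$gene_index)
  e <- e[ord, , drop = FALSE]
  out <- c(
    "drug_id\tgene_id\tlabel",
    sprintf("%s\t%s\t%s", g$drug_ids[e$drug_index], g$gene_ids[e$gene_index],
            g$labels[e$class])
  )
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Write the node map to TSV
#'
#' Columns `external_id<TAB>internal_index<TAB>node_type` (1-based unified
#' indices, drugs first).
#'
#' @param g A `dgi_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_map <- function(g, path) {
  nm <- node_map(g)
  out <- c("external_id\tinternal_index\tnode_type",
           sprintf("%s\t%d\t%s", nm$external_id, nm$internal_index, nm$node_type))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Transductive train/validation/test split over edges
#'
#' Randomly partitions the edges at the requested fractions (default 4:1
#' train:test, then 10% of the training edges carved out for validation),
#' then repairs transductivity: any validation/test edge whose drug or gene
#' would otherwise have no training edge is swapped with a same-class
#' training edge when a safe swap exists, else moved into training. The
#' resulting edge sets are pairwise disjoint, cover the input exactly, and
#' every node incident to an evaluation edge has at least one training edge.
#'
#' @param g A `dgi_graph`.
#' @param test_fraction Fraction of edges held out for testing.
#' @param val_fraction Fraction of the (post-test) training edges moved to
#'   validation.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param ratio_tolerance Allowed drift of realized fractions, as a
#'   proportion of all edges (repairs may move edges into training).
#' @return A list of class `dgi_split` with integer edge-row vectors `train`,
#'   `val`, `test`, and `fractions`.
#' @export
transductive_split <- function(g, test_fraction = 0.2, val_fraction = 0.1,
                               seed = 0L, ratio_tolerance = 0.02) {
  stopifnot(inherits(g, "dgi_graph"))
  e <- g$edges
  m <- nrow(e)
  if (m < 10L) stop("graph too small to split: need at least 10 edges")

  withr::with_seed(as.integer(seed), {
    perm <- sample.int(m)
    n_test <- round(m * test_fraction)
    test <- perm[seq_len(n_test)]
    rest <- perm[-seq_len(n_test)]
    n_val <- round(length(rest) * val_fraction)
    val <- rest[seq_len(n_val)]
    train <- rest[-seq_len(n_val)]

    # transductive repair
    node_train_count <- tabulate(c(e$node_drug[train], e$node_gene[train]),
                                 nbins = n_nodes(g))
    in_train <- logical(m); in_train[train] <- TRUE
    for (set_name in c("val", "test")) {
      idx <- get(set_name)
      keep <- rep(TRUE, length(idx))
      for (k in seq_along(idx)) {
        ed <- idx[k]
        nd <- e$node_drug[ed]; ng <- e$node_gene[ed]
        if (node_train_count[nd] > 0L && node_train_count[ng] > 0L) next
        # try a same-class swap whose removal keeps its own nodes covered
        cand <- train[e$class[train] == e$class[ed] &
                        node_train_count[e$node_drug[train]] >= 2L &
                        node_train_count[e$node_gene[train]] >= 2L]
        if (length(cand)) {
          swap <- cand[1L]
          train[train == swap] <- ed
          idx[k] <- swap
          node_train_count[e$node_drug[swap]] <- node_train_count[e$node_drug[swap]] - 1L
          node_train_count[e$node_gene[swap]] <- node_train_count[e$node_gene[swap]] - 1L
        } else {
          train <- c(train, ed)
          keep[k] <- FALSE
        }
        node_train_count[nd] <- node_train_count[nd] + 1L
        node_train_count[ng] <- node_train_count[ng] + 1L
      }
      assign(set_name, idx[keep])
    }
  })

  got_test <- length(test) / m
  want_test <- test_fraction
  if (abs(got_test - want_test) > ratio_tolerance) {
    stop(sprintf(
      "cannot satisfy transductive constraint at the requested ratios: realized test fraction %.3f vs target %.3f; the graph has too many nodes whose every edge must stay in training",
      got_test, want_test
    ))
  }

  structure(list(
    train = sort(train), val = sort(val), test = sort(test),
    fractions = c(train = length(train) / m, val = length(val) / m,
                  test = length(test) / m)
  ), class = "dgi_split")
}

#' @export
print.dgi_split <- function(x, ...) {
  cat(sprintf("<dgi_split> %d train / %d val / %d test edges (%.1f%% / %.1f%% / %.1f%%)\n",
              length(x$train), length(x$val), length(x$test),
              100 * x$fractions["train"], 100 * x$fractions["val"],
              100 * x$fractions["test"]))
  invisible(x)
}

#' Write a split's three edge lists to TSV files
#'
#' @param g A `dgi_graph`.
#' @param split A `dgi_split`.
#' @param dir Output directory (created if needed); writes `train.tsv`,
#'   `val.tsv`, `test.tsv`.
#' @return The directory, invisibly.
#' @export
write_split <- function(g, split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in c("train", "val", "test")) {
    write_edge_list(g, file.path(dir, paste0(s, ".tsv")), rows = split[[s]])
  }
  invisible(dir)
}

#' Read a split written by [write_split()] back as edge-row indices
#'
#' @param g The `dgi_graph` the split refers to.
#' @param dir Directory containing `train.tsv`, `val.tsv`, `test.tsv`.
#' @return A `dgi_split`.
#' @export
read_split <- function(g, dir) {
  key <- paste(g$edges$drug_index, g$edges$gene_index)
  rows <- lapply(c("train", "val", "test"), function(s) {
    sg <- read_edge_list(file.path(dir, paste0(s, ".tsv")))
    se <- edge_table(sg)
    idx <- match(paste(match(se$drug_id, g$drug_ids), match(se$gene_id, g$gene_ids)), key)
    if (anyNA(idx)) stop("split file ", s, ".tsv contains edges absent from the graph")
    sort(idx)
  })
  names(rows) <- c("train", "val", "test")
  m <- nrow(g$edges)
  structure(c(rows, list(fractions = c(
    train = length(rows$train) / m, val = length(rows$val) / m,
    test = length(rows$test) / m
  ))), class = "dgi_split")
}

#' Frequency-smoothed negative sampling
#'
#' Draws non-interacting (drug, gene) pairs with drug and gene sampled
#' independently with probability proportional to `(degree + 1)^(-lambda)`,
#' so low-degree nodes are preferentially selected. Pairs that collide with
#' observed interactions or duplicate earlier draws are rejected and redrawn.
#'
#' @param g A `dgi_graph`.
#' @param n Number of negative pairs to return.
#' @param lambda Smoothing exponent (default 0.75).
#' @param seed Integer seed.
#' @param max_tries Rejection budget as a multiple of `n`.
#' @return A tibble with `drug_index`, `gene_index`, `drug_id`, `gene_id`.
#' @export
negative_sample <- function(g, n, lambda = 0.75, seed = 0L, max_tries = 200L) {
  stopifnot(inherits(g, "dgi_graph"), n >= 1)
  nd <- n_drugs(g); ng <- n_genes(g)
  n_free <- nd * ng - nrow(g$edges)
  if (n > n_free) stop(sprintf("requested %d negatives but only %d non-edges exist", n, n_free))

  deg_d <- tabulate(g$edges$drug_index, nbins = nd)
  deg_g <- tabulate(g$edges$gene_index, nbins = ng)
  w_d <- (deg_d + 1)^(-lambda)
  w_g <- (deg_g + 1)^(-lambda)
  pos_key <- g$edges$drug_index + nd * (g$edges$gene_index - 1)

  withr::with_seed(as.integer(seed), {
    have <- integer(0)
    tries <- 0L
    while (length(have) < n) {
      if (tries >= max_tries) {
        stop("negative-sampling rejection budget exhausted (graph too dense); request fewer negatives")
      }
      tries <- tries + 1L
      batch <- max(2L * (n - length(have)), 16L)
      di <- sample.int(nd, batch, replace = TRUE, prob = w_d)
      gi <- sample.int(ng, batch, replace = TRUE, prob = w_g)
      key <- di + nd * (gi - 1)
      ok <- !(key %in% pos_key) & !(key %in% have) & !duplicated(key)
      have <- c(have, key[ok])
    }
    have <- have[seq_len(n)]
  })

  di <- ((have - 1) %% nd) + 1
  gi <- ((have - 1) %/% nd) + 1
  tibble::tibble(
    drug_index = as.integer(di), gene_index = as.integer(gi),
    drug_id = g$drug_ids[di], gene_id = g$gene_ids[gi]
  )
}

#' Configuration for the synthetic bipartite network generator
#'
#' @param n_drugs,n_genes Node counts per side.
#' @param n_edges Number of distinct interactions.
#' @param n_classes Number of relation classes.
#' @param degree_exponent Power-law exponent of the degree distribution
#'   (real interaction networks are heavy-tailed; 2.5 is a typical value).
#' @param n_blocks Latent blocks per side; each node is assigned one.
#' @param class_rule Function `(drug_block, gene_block) -> class` (vectorized,
#'   values in `1..n_classes`). Default: `((db + gb) mod n_classes) + 1`, the
#'   additive planted rule (XOR for 2 blocks / 2 classes).
#' @param label_noise Probability that an edge's class is flipped to a
#'   uniformly-drawn different class.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `dgi_synth_config`.
#' @export
synth_config <- function(n_drugs = 50L, n_genes = 200L, n_edges = 2000L,
                         n_classes = 2L, degree_exponent = 2.5, n_blocks = 2L,
                         class_rule = NULL, label_noise = 0.05, seed = 0L) {
  stopifnot(n_drugs >= 2, n_genes >= 2, n_classes >= 1, n_blocks >= 1,
            label_noise >= 0, label_noise < 1, degree_exponent > 1)
  if (n_edges > n_drugs * n_genes) stop("n_edges exceeds the number of possible pairs")
  if (is.null(class_rule)) {
    class_rule <- function(db, gb) ((db + gb) %% n_classes) + 1L
  }
  structure(list(
    n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
    n_edges = as.integer(n_edges), n_classes = as.integer(n_classes),
    degree_exponent = degree_exponent, n_blocks = as.integer(n_blocks),
    class_rule = class_rule, label_noise = label_noise, seed = as.integer(seed)
  ), class = "dgi_synth_config")
}

# discrete power-law draw P(k) proportional to k^(-gamma), k in 1..kmax
rpowerlaw <- function(n, gamma, kmax) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-gamma))
}

#' Generate a synthetic drug-gene network with planted relation structure
#'
#' Node degree propensities are drawn from a discrete power law with the
#' configured exponent; edges are placed by degree-weighted sampling of
#' (drug, gene) pairs without duplicates. Each node carries a latent block;
#' an edge's relation class is `class_rule(drug_block, gene_block)`, flipped
#' to a random other class with probability `label_noise`. Because classes
#' are a deterministic function of node blocks (up to noise), a topology-only
#' model has recoverable signal: a node's labelled edges identify its block.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `dgi_synth` with `graph` (a `dgi_graph`), `truth`
#'   (tibble of `node_id`, `node_type`, `block`, and the drawn power-law
#'   degree `propensity`) and `config`.
#' @export
simulate_dgi_network <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "dgi_synth_config"))
  nd <- cfg$n_drugs; ng <- cfg$n_genes; m <- cfg$n_edges

  withr::with_seed(cfg$seed, {
    kmax_d <- max(2L, min(ng, m))
    kmax_g <- max(2L, min(nd, m))
    w_d <- rpowerlaw(nd, cfg$degree_exponent, kmax_d)
    w_g <- rpowerlaw(ng, cfg$degree_exponent, kmax_g)

    have <- integer(0)
    tries <- 0L
    while (length(have) < m) {
      tries <- tries + 1L
      if (tries > 200L) {
        warning("degree-weighted placement stalled; filling remaining edges uniformly over free pairs")
        all_pairs <- setdiff(seq_len(nd * ng), have)
        have <- c(have, sample(all_pairs, m - length(have)))
        break
      }
      batch <- max(2L * (m - length(have)), 32L)
      di <- sample.int(nd, batch, replace = TRUE, prob = w_d)
      gi <- sample.int(ng, batch, replace = TRUE, prob = w_g)
      key <- di + nd * (gi - 1)
      ok <- !(key %in% have) & !duplicated(key)
      have <- c(have, key[ok])
    }
    have <- have[seq_len(m)]
    di <- ((have - 1) %% nd) + 1L
    gi <- ((have - 1) %/% nd) + 1L

    block_d <- sample.int(cfg$n_blocks, nd, replace = TRUE)
    block_g <- sample.int(cfg$n_blocks, ng, replace = TRUE)
    cls <- as.integer(cfg$class_rule(block_d[di] - 1L, block_g[gi] - 1L))
    stopifnot(all(cls >= 1 & cls <= cfg$n_classes))

    if (cfg$label_noise > 0 && cfg$n_classes > 1L) {
      flip <- stats::runif(m) < cfg$label_noise
      if (any(flip)) {
        shift <- sample.int(cfg$n_classes - 1L, sum(flip), replace = TRUE)
        cls[flip] <- ((cls[flip] - 1L + shift) %% cfg$n_classes) + 1L
      }
    }
  })

  width_d <- nchar(as.character(nd))
  width_g <- nchar(as.character(ng))
  drug_names <- sprintf(paste0("D%0", width_d, "d"), seq_len(nd))
  gene_names <- sprintf(paste0("G%0", width_g, "d"), seq_len(ng))
  class_names <- sprintf("rel%02d", seq_len(cfg$n_classes))

  graph <- bipartite_graph(tibble::tibble(
    drug_id = drug_names[di],
    gene_id = gene_names[gi],
    label = class_names[cls]
  ))
  truth <- tibble::tibble(
    node_id = c(drug_names, gene_names),
    node_type = rep(c("drug", "gene"), c(nd, ng)),
    block = c(block_d, block_g),
    propensity = c(w_d, w_g)
  )
  structure(list(graph = graph, truth = truth, config = cfg),
            class = "dgi_synth")
}

#' Maximum-likelihood power-law exponent of a degree sequence
#'
#' Exact maximum likelihood under a truncated discrete power law
#' `P(k) = k^(-alpha) / sum_{j=xmin}^{kmax} j^(-alpha)`, the distribution the
#' synthetic generator draws degree propensities from; the exponent is found
#' by one-dimensional likelihood optimization.
#'
#' @param degrees Integer vector of node degrees (or degree propensities).
#' @param xmin Minimum degree included in the fit.
#' @param kmax Upper truncation of the support (defaults to the observed
#'   maximum).
#' @return The estimated exponent.
#' @export
fit_power_law_exponent <- function(degrees, xmin = 1L, kmax = max(degrees)) {
  d <- degrees[degrees >= xmin]
  if (length(d) < 10L) stop("too few degrees >= xmin for a stable fit")
  support <- xmin:kmax
  nll <- function(a) length(d) * log(sum(support^(-a))) + a * sum(log(d))
  stats::optimize(nll, c(1.01, 8))$minimum
}
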