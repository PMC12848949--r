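#' Build a re-indexed bipartite drug-gene interaction graph
#'
#' Unifies drug and gene identifiers into a single node set indexed
#' `1..(n_drugs + n_genes)` with drugs first, each type ordered
#' lexicographically, and maps relation labels to consecutive integer classes
#' (lexicographic label order). The bijection is deterministic, so the same
#' edge table always yields the same internal indexing.
#'
#' @param edges A data frame with columns `drug_id`, `gene_id`, `label`
#'   (character or coercible). One row per observed interaction.
#' @return An object of class `dgi_graph`: a list with `drug_ids`, `gene_ids`,
#'   `labels` (class-ordered label strings), `n_classes`, and `edges`, a tibble
#'   with `drug_index` (1..n_drugs), `gene_index` (1..n_genes), `node_drug` /
#'   `node_gene` (unified node indices), and `class` (1..n_classes).
#' @examples
#' g <- bipartite_graph(data.frame(
#'   drug_id = c("d2", "d1"), gene_id = c("gA", "gA"),
#'   label = c("up", "down")
#' ))
#' g$drug_ids # "d1" "d2"
#' @export
bipartite_graph <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) stop("edge table is empty: a bipartite graph needs at least one interaction")
  req <- c("drug_id", "gene_id", "label")
  missing_cols <- setdiff(req, names(edges))
  if (length(missing_cols)) stop("missing column(s): ", paste(missing_cols, collapse = ", "))

  drug_id <- as.character(edges$drug_id)
  gene_id <- as.character(edges$gene_id)
  label <- as.character(edges$label)
  if (anyNA(drug_id) || anyNA(gene_id) || anyNA(label)) stop("edge table contains missing values")

  key <- paste(drug_id, gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(unique(dup), function(k) length(unique(label[key == k])) > 1L, logical(1))
    if (any(conflict)) {
      bad <- unique(dup)[conflict][1]
      parts <- strsplit(bad, "\r", fixed = TRUE)[[1]]
      stop(sprintf(
        "conflicting labels for drug-gene pair (%s, %s): %s",
        parts[1], parts[2], paste(unique(label[key == bad]), collapse = " vs ")
      ))
    }
    keep <- !duplicated(key)
    drug_id <- drug_id[keep]; gene_id <- gene_id[keep]; label <- label[keep]
  }

  drug_ids <- sort(unique(drug_id))
  gene_ids <- sort(unique(gene_id))
  labels <- sort(unique(label))

  di <- match(drug_id, drug_ids)
  gi <- match(gene_id, gene_ids)
  cl <- match(label, labels)
  n_drugs <- length(drug_ids)

  g <- list(
    drug_ids = drug_ids,
    gene_ids = gene_ids,
    labels = labels,
    n_classes = length(labels),
    edges = tibble::tibble(
      drug_index = di,
      gene_index = gi,
      node_drug = di,
      node_gene = n_drugs + gi,
      class = cl
    )
  )
  class(g) <- "dgi_graph"
  g
}

#' @export
print.dgi_graph <- function(x, ...) {
  cat(sprintf(
    "<dgi_graph> %d drugs, %d genes, %d interactions, %d relation class%s\n",
    n_drugs(x), n_genes(x), nrow(x$edges), x$n_classes,
    if (x$n_classes == 1L) "" else "es"
  ))
  invisible(x)
}

#' @rdname bipartite_graph
#' @param g A `dgi_graph`.
#' @export
n_drugs <- function(g) length(g$drug_ids)

#' @rdname bipartite_graph
#' @export
n_genes <- function(g) length(g$gene_ids)

#' @rdname bipartite_graph
#' @export
n_nodes <- function(g) length(g$drug_ids) + length(g$gene_ids)

#' Export the external-id to internal-index bijection
#'
#' @param g A `dgi_graph`.
#' @return A tibble with `external_id`, `internal_index` (unified, 1-based,
#'   drugs first) and `node_type` (`"drug"` or `"gene"`).
#' @export
node_map <- function(g) {
  tibble::tibble(
    external_id = c(g$drug_ids, g$gene_ids),
    internal_index = seq_len(n_nodes(g)),
    node_type = rep(c("drug", "gene"), c(n_drugs(g), n_genes(g)))
  )
}

#' Recover the external edge table from a graph
#'
#' Inverse of [bipartite_graph()]: returns `drug_id`, `gene_id`, `label`.
#' @param g A `dgi_graph`.
#' @param rows Optional integer vector of edge rows to extract.
#' @return A tibble.
#' @export
edge_table <- function(g, rows = NULL) {
  e <- g$edges
  if (!is.null(rows)) e <- e[rows, , drop = FALSE]
  tibble::tibble(
    drug_id = g$drug_ids[e$drug_index],
    gene_id = g$gene_ids[e$gene_index],
    label = g$labels[e$class]
  )
}

#' Symmetric-normalized adjacency with self-loops
#'
#' Builds the unified bipartite adjacency `A_full` (binary: 1 iff any
#' interaction exists between a drug and a gene, whatever its class), adds
#' self-loops, and applies symmetric degree normalization
#' `A_hat = D^{-1/2} (A_full + I) D^{-1/2}`. Relation classes are supervision
#' targets and never enter the adjacency weights.
#'
#' @param g A `dgi_graph`.
#' @param edge_rows Optional integer vector restricting the adjacency to a
#'   subset of edges (e.g. training edges only); all nodes are kept, so nodes
#'   without retained edges carry only their self-loop.
#' @return A list of class `dgi_adjacency` with `matrix` (sparse symmetric
#'   `dgCMatrix` of `A_hat`), `degree` (per-node degree of the self-looped
#'   graph), `n_nodes`, and `neighbors`, a two-column integer matrix of
#'   directed (target, source) pairs including self-loops, used by the
#'   attention encoder.
#' @export
normalized_adjacency <- function(g, edge_rows = NULL) {
  stopifnot(inherits(g, "dgi_graph"))
  e <- g$edges
  if (!is.null(edge_rows)) e <- e[edge_rows, , drop = FALSE]
  n <- n_nodes(g)

  i <- c(e$node_drug, e$node_gene, seq_len(n))
  j <- c(e$node_gene, e$node_drug, seq_len(n))
  a_tilde <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  a_tilde@x[] <- 1 # collapse any duplicate-accumulated entries back to binary

  deg <- Matrix::rowSums(a_tilde)
  dinv <- 1 / sqrt(deg)
  a_hat <- Matrix::Diagonal(x = dinv) %*% a_tilde %*% Matrix::Diagonal(x = dinv)

  structure(
    list(
      matrix = methods::as(a_hat, "CsparseMatrix"),
      degree = as.numeric(deg),
      n_nodes = n,
      neighbors = cbind(target = i, source = j)
    ),
    class = "dgi_adjacency"
  )
}

#' Incidence structure linking nodes to interaction hyperedges
#'
#' Each observed drug-gene interaction defines one hyperedge containing
#' exactly its drug node and its gene node. The reverse index maps every
#' non-isolated node to the hyperedges it participates in.
#'
#' @param g A `dgi_graph`.
#' @param edge_rows Optional integer vector restricting to a subset of edges.
#' @return A list of class `dgi_incidence` with `hyperedges` (list of length-2
#'   integer vectors, `c(drug_node, gene_node)`), `node_to_hyperedges`
#'   (list over all nodes; integer vectors of incident hyperedge ids),
#'   `drug_node`, `gene_node` (integer vectors, one entry per hyperedge) and
#'   `n_nodes`.
#' @export
incidence_structure <- function(g, edge_rows = NULL) {
  stopifnot(inherits(g, "dgi_graph"))
  e <- g$edges
  if (!is.null(edge_rows)) e <- e[edge_rows, , drop = FALSE]
  n <- n_nodes(g)
  m <- nrow(e)

  node_to <- vector("list", n)
  hits <- split(rep(seq_len(m), 2L), c(e$node_drug, e$node_gene))
  node_to[as.integer(names(hits))] <- lapply(hits, sort)
  empty <- vapply(node_to, is.null, logical(1))
  node_to[empty] <- list(integer(0))

  structure(
    list(
      hyperedges = Map(c, e$node_drug, e$node_gene),
      node_to_hyperedges = node_to,
      drug_node = e$node_drug,
      gene_node = e$node_gene,
      n_nodes = n
    ),
    class = "dgi_incidence"
  )
}
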