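test_that("edge-list IO round-trips, handles CRLF, and reports malformed lines", {
  g <- random_graph(6, 9, 22, n_classes = 3L, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  canon <- function(gr) dplyr::arrange(gr$edges, drug_index, gene_index)
  expect_identical(canon(g2), canon(g))
  expect_identical(g2$drug_ids, g$drug_ids)
  expect_identical(g2$labels, g$labels)
  # write -> read -> write is byte-identical (identity on canonical files)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g2, path2)
  expect_identical(readLines(path2), readLines(path))

  # CRLF input parses identically
  crlf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste0(readLines(path), "\r"), crlf, sep = "\n")
  expect_identical(read_edge_list(crlf)$edges, g2$edges)

  # comments and blank lines are skipped
  commented <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# generated fixture", readLines(path)[1], "", readLines(path)[-1]),
             commented)
  expect_identical(read_edge_list(commented)$edges, g2$edges)

  # missing column errors with the line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(path)
  lines[4] <- sub("\t[^\t]*$", "", lines[4])
  writeLines(lines, bad)
  expect_error(read_edge_list(bad), "line 4")
})

test_that("splits honor the 4:1 ratio with a 10% validation carve-out", {
  g <- random_graph(10, 20, 100, seed = 17)
  sp <- transductive_split(g, seed = 1)
  expect_equal(length(sp$test), 20, tolerance = 2)
  expect_equal(length(sp$val), 8, tolerance = 2)
  expect_equal(length(sp$train), 72, tolerance = 3)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_len(100))
})

test_that("star graphs keep all leaf edges in training", {
  # one drug connected to k genes, every gene has degree 1: no gene edge can
  # move to evaluation without orphaning its gene
  k <- 20L
  g <- bipartite_graph(data.frame(
    drug_id = "hub", gene_id = sprintf("g%02d", 1:k), label = "x"
  ))
  sp <- suppressWarnings(try(transductive_split(g, seed = 1, ratio_tolerance = 1),
                             silent = TRUE))
  expect_false(inherits(sp, "try-error"))
  expect_length(sp$val, 0)
  expect_length(sp$test, 0)
  expect_length(sp$train, k)
  # and at the default tolerance the impossibility is reported
  expect_error(transductive_split(g, seed = 1), "transductive")
})

test_that("split contracts hold on 100 random graphs", {
  for (seed in 1:100) {
    nd <- sample(6:20, 1); ng <- sample(6:30, 1)
    m <- sample(30:min(150, nd * ng - 5), 1)
    g <- random_graph(nd, ng, m, seed = 1000 + seed)
    sp <- tryCatch(transductive_split(g, seed = seed, ratio_tolerance = 0.2),
                   error = function(e) NULL)
    if (is.null(sp)) next # legitimately infeasible sparse draw
    # disjoint and covering
    expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_len(m))
    # transductive: every eval node appears in a training edge
    train_nodes <- unique(c(g$edges$node_drug[sp$train], g$edges$node_gene[sp$train]))
    eval_rows <- c(sp$val, sp$test)
    eval_nodes <- unique(c(g$edges$node_drug[eval_rows], g$edges$node_gene[eval_rows]))
    expect_true(all(eval_nodes %in% train_nodes))
  }
})

test_that("splits are deterministic given a seed and written splits read back", {
  g <- random_graph(10, 15, 80, seed = 23)
  sp1 <- transductive_split(g, seed = 5)
  sp2 <- transductive_split(g, seed = 5)
  expect_identical(sp1, sp2)
  sp3 <- transductive_split(g, seed = 6)
  expect_false(identical(sp1$train, sp3$train))

  dir <- withr::local_tempdir()
  write_split(g, sp1, dir)
  back <- read_split(g, dir)
  expect_identical(back$train, sp1$train)
  expect_identical(back$val, sp1$val)
  expect_identical(back$test, sp1$test)
})

test_that("negative sampler returns the only available pair when one is missing", {
  # complete bipartite positives minus one pair
  full <- expand.grid(d = sprintf("d%d", 1:3), g = sprintf("g%d", 1:3),
                      stringsAsFactors = FALSE)
  missing_pair <- c("d2", "g3")
  keep <- !(full$d == missing_pair[1] & full$g == missing_pair[2])
  g <- bipartite_graph(data.frame(drug_id = full$d[keep], gene_id = full$g[keep],
                                  label = "x"))
  neg <- negative_sample(g, 1, seed = 4)
  expect_identical(c(neg$drug_id, neg$gene_id), missing_pair)
  expect_error(negative_sample(g, 2, seed = 4), "non-edges")
})

test_that("negative samples never collide with positives or each other", {
  for (trial in 1:20) {
    nd <- sample(5:15, 1); ng <- sample(5:15, 1)
    g <- random_graph(nd, ng, sample(10:min(50, nd * ng - 10), 1), seed = 2000 + trial)
    # nodes without edges drop out of the graph, shrinking the pair space
    n_req <- min(30, n_drugs(g) * n_genes(g) - nrow(g$edges))
    neg <- negative_sample(g, n_req, seed = trial)
    expect_equal(nrow(neg), n_req)
    pos_key <- paste(g$edges$drug_index, g$edges$gene_index)
    neg_key <- paste(neg$drug_index, neg$gene_index)
    expect_length(intersect(neg_key, pos_key), 0)
    expect_false(any(duplicated(neg_key)))
  }
})

test_that("sampled node frequency is negatively rank-correlated with degree", {
  syn <- simulate_dgi_network(synth_config(n_drugs = 200, n_genes = 400,
                                           n_edges = 4000, seed = 5))
  g <- syn$graph
  neg <- negative_sample(g, 10000, lambda = 0.75, seed = 0)
  deg_d <- tabulate(g$edges$drug_index, n_drugs(g))
  freq_d <- tabulate(neg$drug_index, n_drugs(g))
  expect_lt(suppressWarnings(cor(deg_d, freq_d, method = "spearman")), 0)
  deg_g <- tabulate(g$edges$gene_index, n_genes(g))
  freq_g <- tabulate(neg$gene_index, n_genes(g))
  expect_lt(suppressWarnings(cor(deg_g, freq_g, method = "spearman")), 0)
})

test_that("generation is reproducible and writes byte-identical edge lists", {
  cfg <- synth_config(n_drugs = 20, n_genes = 40, n_edges = 200, seed = 9)
  s1 <- simulate_dgi_network(cfg)
  s2 <- simulate_dgi_network(cfg)
  expect_identical(s1$graph$edges, s2$graph$edges)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_edge_list(s1$graph, f1); write_edge_list(s2$graph, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noise-free planted labels are perfectly predictable from blocks", {
  cfg <- synth_config(n_drugs = 15, n_genes = 30, n_edges = 150, n_classes = 2L,
                      label_noise = 0, seed = 13)
  syn <- simulate_dgi_network(cfg)
  g <- syn$graph
  blocks <- syn$truth$block
  e <- g$edges
  oracle_class <- ((blocks[e$node_drug] - 1L) + (blocks[e$node_gene] - 1L)) %% 2L + 1L
  expect_identical(e$class, as.integer(oracle_class))
})

test_that("a multi-relation configuration at curated-database scale generates cleanly", {
  # mirrors a multi-relation interaction database: 1185 drugs, 1664 genes,
  # 11,366 interactions, 14 relation classes
  cfg <- synth_config(n_drugs = 1185, n_genes = 1664, n_edges = 11366,
                      n_classes = 14L, n_blocks = 14L, seed = 2)
  syn <- simulate_dgi_network(cfg)
  expect_equal(nrow(syn$graph$edges), 11366L)
  expect_equal(syn$graph$n_classes, 14L)
  expect_equal(sort(unique(syn$graph$edges$class)), 1:14)
})

test_that("generated degree distribution recovers the configured exponent", {
  cfg <- synth_config(n_drugs = 800, n_genes = 2000, n_edges = 25000,
                      degree_exponent = 2.5, seed = 3)
  syn <- simulate_dgi_network(cfg)
  fitted <- fit_power_law_exponent(syn$truth$propensity)
  expect_lt(abs(fitted - 2.5), 0.3)
  # the realized network inherits the heavy tail: hubs far exceed the mean
  g <- syn$graph
  deg <- c(tabulate(g$edges$drug_index, n_drugs(g)),
           tabulate(g$edges$gene_index, n_genes(g)))
  expect_gt(max(deg), 10 * mean(deg))
  expect_gt(cor(syn$truth$propensity, deg, method = "spearman"), 0.5)
})
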