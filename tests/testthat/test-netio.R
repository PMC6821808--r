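write_mat <- function(m, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  write.table(m, path, sep = sep, row.names = FALSE, col.names = FALSE)
  path
}

test_that("load_matrix builds validated graphs from dense tables", {
  g <- load_matrix(write_mat(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(n_nodes(g), 2)
  expect_equal(graph_edges(g)$weight, 1)

  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 5
  g <- load_matrix(write_mat(m))
  expect_equal(nrow(graph_edges(g)), 1)
  expect_equal(graph_edges(g)$weight, 5)
  expect_equal(sum(g$weights[3, ]), 0) # third node isolated

  # delimiter auto-detection
  g2 <- load_matrix(write_mat(m, sep = ","))
  expect_equal(g2$weights, g$weights)

  # header row + label column
  path <- tempfile(fileext = ".tsv")
  writeLines(c("\ta\tb", "a\t0\t2", "b\t2\t0"), path)
  g3 <- load_matrix(path)
  expect_equal(g3$node_ids, c("a", "b"))
  expect_equal(g3$weights["a", "b"], 2)
})

test_that("small asymmetry is averaged with a warning, large is an error", {
  m <- matrix(c(0, 4, 3, 0), 2)
  expect_warning(g <- load_matrix(write_mat(m)), "symmetrized")
  expect_equal(g$weights[1, 2], 3.5)

  tiny <- matrix(c(0, 1, 1 + 1e-11, 0), 2)
  expect_silent(gt <- weighted_graph(tiny))
  expect_equal(gt$weights[1, 2], gt$weights[2, 1])
})

test_that("invalid matrices raise distinct errors naming the cell", {
  expect_error(load_matrix(write_mat(matrix(1:6, 2))), "square")
  m <- matrix(c(0, -1, -1, 0), 2)
  expect_error(load_matrix(write_mat(m)), "negative weight.*\\(2, 1\\)")
  m <- matrix(c(0, 1, 1, 0), 2); m[1, 2] <- NA
  expect_error(load_matrix(write_mat(m)), "\\(1, 2\\)")
  expect_error(load_matrix(tempfile()), "not found")
  expect_warning(weighted_graph(diag(2)), "diagonal")
})

test_that("hop distances are BFS path lengths with an Inf sentinel", {
  expect_equal(hop_distances(path_graph(3))[1, 3], 2)
  d4 <- hop_distances(k_n(4))
  expect_true(all(d4[upper.tri(d4)] == 1))
  two <- weighted_graph(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                              c(0, 0, 0, 1), c(0, 0, 1, 0)))
  expect_identical(hop_distances(two)[1, 3], Inf)
})

test_that("hop distance is a metric on each component", {
  set.seed(101)
  for (rep in 1:20) {
    g <- random_graph(sample(4:8, 1), 0.5)
    d <- hop_distances(g)
    expect_equal(d, t(d))
    n <- n_nodes(g)
    trips <- replicate(30, sample(n, 3), simplify = FALSE)
    for (tr in trips) {
      fin <- d[tr[1], tr[2]] + d[tr[2], tr[3]]
      if (is.finite(fin))
        expect_lte(d[tr[1], tr[3]], fin)
    }
  }
})

test_that("largest component size matches a union-find oracle", {
  expect_equal(largest_component_size(k_n(3)), 3)
  iso <- matrix(0, 5, 5); iso[1:3, 1:3] <- matrix(1, 3, 3) - diag(3)
  expect_equal(largest_component_size(weighted_graph(iso)), 3)
  expect_equal(largest_component_size(weighted_graph(matrix(0, 0, 0))), 0)

  set.seed(202)
  for (rep in 1:25) {
    g <- random_graph(sample(2:10, 1), runif(1, 0.1, 0.6))
    expect_equal(largest_component_size(g), uf_largest_component(g))
  }
})

test_that("tables round-trip losslessly at 12 significant digits", {
  g <- k_n(3)
  nm <- node_strength(generate_connectome(synthetic_spec(20, 0.4, seed = 3)))
  path <- tempfile(fileext = ".tsv")
  save_table(as.data.frame(nm), path)
  back <- load_table(path)
  expect_equal(back$value, nm$value, tolerance = 1e-12)
  expect_equal(back$node_id, nm$node_id)

  # curvature table for K_3: 3 edge rows + 3 node rows
  ct <- ricci_curvature(g)
  save_table(ct, path)
  back <- load_table(path)
  expect_equal(nrow(back$edges), 3)
  expect_equal(nrow(back$nodes), 3)
  expect_equal(back$edges$kappa, ct$edges$kappa, tolerance = 1e-12)
  expect_equal(back$nodes$kappa_node, ct$nodes$kappa_node,
               tolerance = 1e-12)

  # empty trajectory -> header-only file
  traj <- deletion_cascade(weighted_graph(matrix(0, 0, 0)))
  save_table(as.data.frame(traj), path)
  expect_equal(length(readLines(path)), 1)

  # trajectory round trip
  traj <- deletion_cascade(star_graph(3), "strength")
  save_table(as.data.frame(traj), path)
  back <- load_table(path)
  expect_equal(back$efficiency, traj$efficiency, tolerance = 1e-12)
  expect_equal(back$removed, traj$removed)
})

test_that("node metadata loads and validates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("node_id\tlabel\tcommunity", "n1\tA\t1", "n2\tB\t2"), path)
  md <- load_node_metadata(path)
  expect_equal(md$node_id, c("n1", "n2"))
  writeLines(c("foo\tbar", "1\t2"), path)
  expect_error(load_node_metadata(path), "node_id")
})
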