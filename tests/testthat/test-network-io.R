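test_that("edge lists parse into deduplicated binary matrices", {
  p <- write_edges_tsv(c("d1\tp1", "d1\tp2", "d2\tp1"))
  im <- read_edge_list(p, "Drug", "Protein")
  expect_equal(dim(im$values), c(2L, 2L))
  expect_equal(n_edges(im), 3L)
  expect_equal(im$row_ids, c("d1", "d2"))
  expect_equal(im$col_ids, c("p1", "p2"))
  expect_true(all(as.matrix(im$values) %in% c(0, 1)))

  dup <- read_edge_list(
    write_edges_tsv(c("d1\tp1", "d1\tp1", "d1\tp1")), "Drug", "Protein")
  expect_equal(n_edges(dup), 1L)
  expect_equal(as.numeric(dup$values["d1", "p1"]), 1)
})

test_that("comments, headers, malformed lines and empty files are handled", {
  p <- write_edges_tsv(c("# a comment", "d1\tp1", "", "d2\tp2"))
  expect_equal(n_edges(read_edge_list(p, "Drug", "Protein")), 2L)

  h <- write_edges_tsv(c("drug\tprotein", "d1\tp1"))
  expect_equal(n_edges(read_edge_list(h, "Drug", "Protein", header = TRUE)), 1L)

  bad <- write_edges_tsv(c("d1\tp1", "only_one_field"))
  expect_error(read_edge_list(bad, "Drug", "Protein"), "line 2")

  empty <- write_edges_tsv("# nothing here")
  expect_error(read_edge_list(empty, "Drug", "Protein"), "no interaction")
})

test_that("round-trip through write_edge_list reproduces the matrix", {
  set.seed(7)
  m <- matrix(rbinom(30, 1, 0.4), 5, 6,
              dimnames = list(sprintf("d%d", 1:5), sprintf("p%d", 1:6)))
  im <- interaction_matrix(m, "Drug", "Protein")
  p <- tempfile(fileext = ".tsv")
  write_edge_list(im, p)
  back <- read_edge_list(p, "Drug", "Protein")
  expect_identical(as.matrix(back$values), as.matrix(im$values))
})

test_that("parsing is invariant to edge order and duplication", {
  lines <- c("d2\tp1", "d1\tp2", "d1\tp1")
  a <- read_edge_list(write_edges_tsv(lines), "Drug", "Protein")
  b <- read_edge_list(write_edges_tsv(c(rev(lines), lines)), "Drug", "Protein")
  expect_identical(as.matrix(a$values), as.matrix(b$values))
  s <- network_summary(build_network(a, a_sp_stub(), a_ds_stub()))
  s2 <- network_summary(build_network(b, a_sp_stub(), a_ds_stub()))
  expect_equal(s$density, s2$density)
})

test_that("build_network aligns registries by union and pads with zeros", {
  A_dp <- read_edge_list(write_edges_tsv(c("d1\tp1", "d2\tp2")), "Drug", "Protein")
  A_sp <- read_edge_list(write_edges_tsv("s1\tp2"), "Disease", "Protein")
  A_ds <- read_edge_list(write_edges_tsv(c("d2\ts1", "d3\ts1")), "Drug", "Disease")
  net <- build_network(A_dp, A_sp, A_ds)
  expect_equal(net$drugs, c("d1", "d2", "d3"))
  expect_equal(sum(net$A_ds$values["d1", ]), 0)
  expect_equal(sum(net$A_dp$values["d3", ]), 0)
  # every layer keeps its nonzero total
  expect_equal(n_edges(net$A_dp), 2L)
  expect_equal(n_edges(net$A_sp), 1L)
  expect_equal(n_edges(net$A_ds), 2L)
})

test_that("alignment preserves every edge at its remapped position", {
  for (seed in 1:5) {
    set.seed(seed)
    dp_edges <- sprintf("d%d\tp%d", sample(1:6, 8, TRUE), sample(1:5, 8, TRUE))
    sp_edges <- sprintf("s%d\tp%d", sample(1:4, 6, TRUE), sample(1:5, 6, TRUE))
    ds_edges <- sprintf("d%d\ts%d", sample(1:6, 6, TRUE), sample(1:4, 6, TRUE))
    net <- network_from_edges(dp_edges, sp_edges, ds_edges)
    for (e in dp_edges) {
      ids <- strsplit(e, "\t")[[1]]
      expect_equal(as.numeric(net$A_dp$values[ids[1], ids[2]]), 1)
    }
    for (e in sp_edges) {
      ids <- strsplit(e, "\t")[[1]]
      expect_equal(as.numeric(net$A_sp$values[ids[1], ids[2]]), 1)
    }
    for (e in ds_edges) {
      ids <- strsplit(e, "\t")[[1]]
      expect_equal(as.numeric(net$A_ds$values[ids[1], ids[2]]), 1)
    }
  }
})

test_that("type label mismatches are rejected", {
  A <- read_edge_list(write_edges_tsv("d1\tp1"), "Drug", "Protein")
  expect_error(build_network(A, A, a_ds_stub()), "typed")
})

test_that("density matches the benchmark network's reported values", {
  expect_equal(round(compute_density(4642, 1186, 1147), 4), 0.0034)
  expect_equal(round(compute_density(1365, 449, 1147), 4), 0.0027)
  expect_equal(round(compute_density(1827, 1186, 449), 4), 0.0034)
  expect_equal(compute_density(0, 10, 10), 0)
  expect_error(compute_density(1, 0, 10), "positive")
  expect_error(compute_density(200, 10, 10), "outside")
})
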