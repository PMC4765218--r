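test_that("interaction records aggregate into weighted ties", {
  log <- tibble::tibble(source = c("PI", "PI", "PI"), target = "OCR")
  net <- build_network(log)
  expect_equal(net$ties,
               tibble::tibble(source = "PI", target = "OCR", weight = 3L))
  expect_setequal(net$nodes, c("PI", "OCR"))
  # empty log, empty network
  empty <- build_network(log[0, ])
  expect_length(empty$nodes, 0)
  expect_equal(nrow(degree_centrality(empty)), 0)
  # self-loops dropped by default
  self <- build_network(tibble::tibble(source = c("A", "A"),
                                       target = c("A", "B")))
  expect_equal(nrow(self$ties), 1)
})

test_that("degree handles canonical digraphs", {
  cyc <- build_network(adjacency_to_log(rbind(c(0, 1, 0), c(0, 0, 1),
                                              c(1, 0, 0))))
  d <- degree_centrality(cyc)
  expect_true(all(d$in_degree == 1) && all(d$out_degree == 1))

  star <- build_network(tibble::tibble(source = "hub",
                                       target = paste0("leaf", 1:4)))
  ds <- degree_centrality(star)
  expect_equal(ds$out_degree[ds$participant == "hub"], 4)
  expect_equal(ds$in_degree[ds$participant == "hub"], 0)
  expect_true(all(ds$in_degree[ds$participant != "hub"] == 1))
  # weighted variant sums interaction counts
  wlog <- tibble::tibble(source = c("a", "a", "a", "b"),
                         target = c("b", "b", "c", "c"))
  dw <- degree_centrality(build_network(wlog), weighted = TRUE)
  expect_equal(dw$out_degree[dw$participant == "a"], 3)
})

test_that("path and complete graphs give the textbook centralities", {
  path <- build_network(tibble::tibble(source = c("a", "b"),
                                       target = c("b", "c")))
  b <- betweenness_centrality(path)
  expect_equal(b$betweenness[b$participant == "b"], 1)
  expect_equal(sum(b$betweenness), 1)
  cl <- closeness_centrality(path)
  expect_equal(cl$out_closeness[cl$participant == "a"], 1 + 1 / 2)
  expect_equal(cl$out_closeness[cl$participant == "c"], 0) # no out-ties

  n <- 4
  A <- matrix(1, n, n); diag(A) <- 0
  comp <- build_network(adjacency_to_log(A))
  expect_true(all(betweenness_centrality(comp)$betweenness == 0))
  clc <- closeness_centrality(comp)
  expect_true(all(clc$in_closeness == n - 1))
  expect_true(all(clc$out_closeness == n - 1))
})

test_that("all four measures match brute force on small digraphs", {
  # exhaustive over every 3-node digraph, then random 5- and 6-node graphs
  cases <- list()
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  for (mask in 0:63) {
    A <- matrix(0, 3, 3)
    on <- which(bitwAnd(mask, 2^(0:5)) > 0)
    A[pairs[on, , drop = FALSE]] <- 1
    cases[[length(cases) + 1]] <- A
  }
  set.seed(66)
  for (i in 1:12) cases[[length(cases) + 1]] <- random_digraph(5, 0.4)
  for (i in 1:12) cases[[length(cases) + 1]] <- random_digraph(6, 0.35)

  for (A in cases) {
    if (sum(A) == 0) next
    labels <- paste0("p", seq_len(nrow(A)))
    net <- build_network(adjacency_to_log(A, labels))
    present <- match(net$nodes, labels)  # isolated nodes drop out of the log
    Ai <- A[present, present, drop = FALSE]

    d <- dplyr::arrange(degree_centrality(net), participant)
    expect_equal(d$out_degree, unname(rowSums(Ai)[order(labels[present])]))
    expect_equal(d$in_degree, unname(colSums(Ai)[order(labels[present])]))

    ord <- order(labels[present])
    b <- dplyr::arrange(betweenness_centrality(net), participant)
    expect_equal(b$betweenness, bf_betweenness(Ai)[ord], tolerance = 1e-9)

    cl <- dplyr::arrange(closeness_centrality(net), participant)
    expect_equal(cl$out_closeness, bf_harmonic(Ai, "out")[ord],
                 tolerance = 1e-9)
    expect_equal(cl$in_closeness, bf_harmonic(Ai, "in")[ord],
                 tolerance = 1e-9)

    S <- sym_binary(Ai)
    lmax <- max(abs(eigen(S, only.values = TRUE)$values))
    if (lmax > 0) {
      beta <- -0.5 / lmax
      bp <- dplyr::arrange(bonacich_power(net, beta), participant)
      oracle <- bf_bonacich_series(S, beta)[ord]
      # the quadratic scaling fixes the sign only globally
      if (sum(oracle * bp$bonacich_power) < 0) oracle <- -oracle
      expect_equal(bp$bonacich_power, oracle, tolerance = 1e-6)
    }
  }
})

test_that("Bonacich power reduces to degree as beta -> 0 and favours hubs", {
  star <- build_network(tibble::tibble(source = "hub",
                                       target = paste0("leaf", 1:4)))
  bp0 <- bonacich_power(star, beta = 0)
  deg <- degree_centrality(star)
  sym_deg <- deg$in_degree + deg$out_degree  # symmetrized binary degree
  ratio <- bp0$bonacich_power / sym_deg
  expect_true(all(abs(ratio - ratio[1]) < 1e-9))
  # negative beta: the hub, whose neighbours are unconnected, dominates
  bpn <- bonacich_power(star)
  expect_gt(bpn$bonacich_power[bpn$participant == "hub"],
            max(bpn$bonacich_power[bpn$participant != "hub"]))
  # non-convergent beta is rejected
  A <- sym_binary(matrix(1, 4, 4) - diag(4))
  lmax <- max(abs(eigen(A, only.values = TRUE)$values))
  expect_error(bonacich_power(build_network(adjacency_to_log(A)),
                              beta = 1.01 / lmax),
               class = "trialflow_error_nonconvergent_beta")
})

test_that("relabelling nodes permutes every report identically", {
  set.seed(68)
  A <- random_digraph(6, 0.4)
  labs1 <- paste0("p", 1:6)
  perm <- sample(6)
  labs2 <- paste0("q", sprintf("%02d", 1:6))[perm]
  net1 <- build_network(adjacency_to_log(A, labs1))
  net2 <- build_network(adjacency_to_log(A, labs2))
  r1 <- centrality_report(net1, beta = -0.1)
  r2 <- centrality_report(net2, beta = -0.1)
  key1 <- setNames(seq_along(labs1), labs1)
  r2_back <- r2[match(labs2[key1[r1$participant]], r2$participant), ]
  for (col in setdiff(names(r1), "participant"))
    expect_equal(r1[[col]], r2_back[[col]], tolerance = 1e-9)
})

test_that("networks export as edge list CSV and GraphML", {
  net <- build_network(tibble::tibble(source = c("a", "a", "b"),
                                      target = c("b", "b", "c")))
  csv <- tempfile(fileext = ".csv"); gml <- tempfile(fileext = ".graphml")
  on.exit(unlink(c(csv, gml)))
  write_edge_list(net, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$weight, c(2, 1))
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
})
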