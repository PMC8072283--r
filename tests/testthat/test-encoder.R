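test_that("initial embeddings stack the projection blocks in global order", {
  sp <- node_space(c(drug = 1, protein = 1, disease = 1, side_effect = 1))
  p <- three_node_params(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  h0 <- init_embeddings(p, sp)
  expect_equal(h0, rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))

  # permuting nodes within a type permutes the rows identically
  sp2 <- node_space(c(drug = 2, protein = 1, disease = 1, side_effect = 1))
  net <- tiny_network()
  prm <- init_params(net$network, dim = 4, seed = 2)
  h <- init_embeddings(prm, net$network$space)
  prm2 <- prm
  perm <- c(3, 1, 2, 4:nrow(prm$init$drug))
  prm2$init$drug <- prm$init$drug[perm, ]
  h2 <- init_embeddings(prm2, net$network$space)
  expect_equal(h2[seq_along(perm), ], h[perm, ])
})

test_that("parameter inventory matches the model: 12 channels, 8 diagonals", {
  sim <- tiny_network()
  prm <- init_params(sim$network, dim = 4, seed = 1)
  expect_length(prm$agg, 12L)
  expect_length(prm$dec, 8L)
  expect_length(prm$init, 4L)
  expect_true(all(is.finite(hetdti:::flatten_params(prm))))
  # the default embedding dimension is 1000
  expect_equal(formals(init_params)$dim, 1000L)
})

test_that("neighborhood aggregation normalizes by neighbor count after ReLU", {
  # v has two neighbors with h = [1,-1] and [3,1]; W = I, b = 0:
  # relu gives [1,0], [3,1]; mean = [2, 0.5]
  h <- rbind(c(1, -1), c(3, 1))
  adjacency <- matrix(c(1, 1), 1, 2)
  a <- aggregate_neighbors(h, adjacency, diag(2), c(0, 0))
  expect_equal(as.vector(a), c(2, 0.5))

  # empty neighborhood -> zero vector
  a0 <- aggregate_neighbors(h, matrix(0, 1, 2), diag(2), c(0, 0))
  expect_equal(as.vector(a0), c(0, 0))

  # zero parameters annihilate every aggregate
  az <- aggregate_neighbors(h, adjacency, matrix(0, 2, 2), c(0, 0))
  expect_equal(as.vector(az), c(0, 0))
})

test_that("similarity neighbors are weighted by similarity value", {
  h <- rbind(c(2, 0), c(0, 4))
  adjacency <- matrix(c(0.75, 0.25), 1, 2)  # weighted mean of relu(h)
  a <- aggregate_neighbors(h, adjacency, diag(2), c(0, 0))
  expect_equal(as.vector(a), c(1.5, 1))
})

test_that("mean update averages h0 with the non-empty aggregates", {
  h0 <- matrix(c(2, 2), 1)
  aggs <- list(
    list(values = matrix(c(0, 0), 1), dst = 1L, nonempty = TRUE),
    list(values = matrix(c(1, 4), 1), dst = 1L, nonempty = TRUE))
  expect_equal(as.vector(update_embeddings(h0, aggs)), c(1, 2))

  # empty-neighborhood channels are excluded from the denominator
  aggs[[2]]$nonempty <- FALSE
  expect_equal(as.vector(update_embeddings(h0, aggs)), c(1, 1))

  # no incident edges at all: h* = h0
  expect_equal(update_embeddings(h0, list()), h0)

  # all contributions equal to h0: h* = h0
  same <- list(list(values = h0, dst = 1L, nonempty = TRUE))
  expect_equal(update_embeddings(h0, same), h0)
})

test_that("propagation limits: restart-dominated and identity cases", {
  set.seed(42)
  H <- matrix(rnorm(12), 4)
  A <- rand_row_stochastic(4)
  expect_equal(rwr_propagate(H, A, rwr_config(alpha = 1)), H)
  expect_equal(rwr_propagate(H, diag(4), rwr_config(alpha = 0.3, max_iters = 50)), H)
})

test_that("two-node swap propagation matches the closed form computed by hand", {
  # A = [[0,1],[1,0]], alpha = 0.5, H* = [1, 0]':
  # H1 = 0.5 (I - 0.5 A)^{-1} H* = [2/3, 1/3]'
  A <- rbind(c(0, 1), c(1, 0))
  H <- matrix(c(1, 0), 2)
  z <- rwr_propagate(H, A, rwr_config(alpha = 0.5, max_iters = 500, tol = 0))
  expect_equal(as.vector(z), c(2 / 3, 1 / 3), tolerance = 1e-12)
  zc <- rwr_propagate(H, A, rwr_config(alpha = 0.5, mode = "closed_form"))
  expect_equal(as.vector(zc), c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("propagation refuses bad inputs", {
  H <- matrix(1, 2, 1)
  expect_error(rwr_propagate(H, rbind(c(0.5, 0.4), c(0, 1)), rwr_config()),
               "row-stochastic")
  big <- rand_row_stochastic(5)
  expect_error(rwr_propagate(matrix(1, 5, 1), big,
                             rwr_config(mode = "closed_form",
                                        closed_form_cap = 4L)),
               "cap")
  expect_error(rwr_config(alpha = 0), "alpha")
})

test_that("propagated rows stay in the convex hull of the input rows", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    H <- matrix(rnorm(n * 3), n)
    A <- rand_row_stochastic(n)
    Z <- rwr_propagate(H, A, rwr_config(alpha = 0.2, max_iters = 50, tol = 0))
    for (j in 1:3) {
      expect_gte(min(Z[, j]), min(H[, j]) - 1e-12)
      expect_lte(max(Z[, j]), max(H[, j]) + 1e-12)
    }
  }
})

test_that("duplicating a neighbor keeps aggregates bounded by the max term", {
  set.seed(11)
  h <- matrix(rnorm(10), 5, 2)
  W <- matrix(rnorm(4), 2); b <- rnorm(2)
  adjacency <- matrix(c(1, 1, 1, 0, 0), 1, 5)
  a1 <- aggregate_neighbors(h, adjacency, W, b)
  # duplicate neighbor 1 (add identical node + edge)
  h2 <- rbind(h, h[1, ])
  adjacency2 <- cbind(adjacency, 1)
  a2 <- aggregate_neighbors(h2, adjacency2, W, b)
  phi <- pmax(h %*% t(W) + rep(b, each = 5), 0)
  cap <- apply(phi[1:3, , drop = FALSE], 2, max)
  expect_true(all(abs(a1) <= cap + 1e-12))
  expect_true(all(abs(a2) <= cap + 1e-12))
})

test_that("encode is deterministic and collapses to aggregation at alpha 1", {
  sim <- tiny_network(seed = 9)
  prm <- init_params(sim$network, dim = 6, seed = 3)
  e1 <- encode(sim$network, prm, rwr_config(alpha = 0.2, max_iters = 10, tol = 0))
  e2 <- encode(sim$network, prm, rwr_config(alpha = 0.2, max_iters = 10, tol = 0))
  expect_identical(e1, e2)

  hstar <- encode(sim$network, prm, rwr_config(alpha = 1))
  fw <- hetdti:::encode_forward(sim$network, prm, rwr_config(alpha = 0.2))
  expect_identical(hstar, fw$hstar)
})
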