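test_that("node space lays out contiguous blocks in fixed order", {
  sp <- node_space(c(drug = 3, protein = 4, disease = 2, side_effect = 2))
  expect_equal(sp$n, 11L)
  expect_equal(unname(sp$offsets), c(0L, 3L, 7L, 9L))
  expect_equal(block_index(sp, "protein"), 4:7)
  expect_error(node_space(c(drug = 0, protein = 1, disease = 1, side_effect = 1)),
               "positive integers")
})

test_that("edge-type metadata enforces its constraints", {
  e <- edge_type_spec("drug_sim", "drug", "drug", "real_unit_interval")
  expect_false(e$in_walk)
  expect_true(e$symmetric)
  expect_true(edge_type_spec("drug_target", "drug", "protein")$in_walk)
  expect_error(edge_type_spec("x", "drug", "protein", symmetric = TRUE),
               "symmetric")
})

test_that("validation reports shape, binary, symmetry and range violations", {
  sim <- tiny_network()
  expect_equal(nrow(validate_network(sim$network)), 0L)

  net <- sim$network
  net$matrices$drug_target[2, 3] <- 0.5
  rep <- validate_network(net)
  expect_equal(rep$rule, "non_binary")
  expect_equal(c(rep$row, rep$col), c(2L, 3L))
  expect_match(rep$message, "drug_target")

  net2 <- sim$network
  m <- net2$matrices$protein_protein
  m[lower.tri(m)] <- 0
  net2$matrices$protein_protein <- m
  expect_true("symmetry" %in% validate_network(net2)$rule)

  net3 <- sim$network
  net3$matrices$drug_sim[1, 2] <- -0.1
  net3$matrices$drug_sim[2, 1] <- -0.1
  expect_true(any(validate_network(net3)$rule %in% c("negative", "unit_interval")))
})

test_that("manifest round trip reproduces matrices exactly", {
  sim <- tiny_network(seed = 5)
  dir <- withr::local_tempdir()
  man <- write_network(sim$network, dir)
  net2 <- load_network(man)
  for (nm in names(sim$network$edges)) {
    kind <- sim$network$edges[[nm]]$value_kind
    if (kind == "binary")
      expect_identical(net2$matrices[[nm]], sim$network$matrices[[nm]])
    else
      expect_lt(max(abs(net2$matrices[[nm]] - sim$network$matrices[[nm]])), 1e-12)
  }
  expect_equal(net2$space$counts, sim$network$space$counts)
})

test_that("loader snaps near-binary values and rejects the rest by cell", {
  dir <- withr::local_tempdir()
  writeLines(c("0 1", "1 0"), file.path(dir, "dd.txt"))
  writeLines("1", file.path(dir, "dt.txt"))
  man <- list(counts = list(drug = 2, protein = 1, disease = 1, side_effect = 1),
              edges = list(
                list(name = "drug_drug", file = "dd.txt", src_type = "drug",
                     dst_type = "drug", value_kind = "binary", symmetric = TRUE),
                list(name = "drug_target", file = "dt.txt", src_type = "drug",
                     dst_type = "protein", value_kind = "binary",
                     symmetric = FALSE)))
  # shape error: drug_target declared 2x1 but file has one value
  jsonlite::write_json(man, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_network(file.path(dir, "manifest.json")), "expected 2 x 1")

  writeLines(c("1", "0"), file.path(dir, "dt.txt"))
  net <- load_network(file.path(dir, "manifest.json"))
  expect_identical(net$matrices$drug_drug, matrix(c(0, 1, 1, 0), 2))

  writeLines(c("0 2", "2 0"), file.path(dir, "dd.txt"))
  expect_error(load_network(file.path(dir, "manifest.json")),
               "drug_drug.*non-binary value 2 at \\(2,1\\)")
})

test_that("an identity similarity matrix is a valid network", {
  sim <- tiny_network()
  net <- sim$network
  net$matrices$drug_sim <- diag(net$space$counts[["drug"]])
  expect_equal(nrow(validate_network(net)), 0L)
})

test_that("transition matrix row-normalizes the walk-eligible union", {
  # 3-node path a-b-c through one binary edge type: drug(1) - protein(2) - disease... use
  # drug-protein and protein-disease links so b is the middle node
  space <- node_space(c(drug = 1, protein = 1, disease = 1, side_effect = 1))
  edges <- list(
    drug_target = edge_type_spec("drug_target", "drug", "protein"),
    protein_disease = edge_type_spec("protein_disease", "protein", "disease"))
  mats <- list(drug_target = matrix(1, 1, 1), protein_disease = matrix(1, 1, 1))
  net <- hetero_network(space, edges, mats)
  A <- as.matrix(build_transition_matrix(net))
  expect_equal(A[1, ], c(0, 1, 0, 0))
  expect_equal(A[2, ], c(0.5, 0, 0.5, 0))
  expect_equal(A[3, ], c(0, 1, 0, 0))
  # isolated side-effect node: unit self-loop
  expect_equal(A[4, ], c(0, 0, 0, 1))
})

test_that("transition matrices are row-stochastic across random networks", {
  for (s in 1:100) {
    sim <- tiny_network(seed = s, noise = 0.05)
    A <- build_transition_matrix(sim$network)
    expect_lt(max(abs(Matrix::rowSums(A) - 1)), 1e-12)
    expect_true(min(A) >= 0)
  }
})

test_that("similarity edges never enter the walk", {
  sim <- tiny_network(seed = 3)
  net <- sim$network
  A1 <- build_transition_matrix(net)
  net$edges <- net$edges[!names(net$edges) %in% c("drug_sim", "protein_sim")]
  net$matrices <- net$matrices[names(net$edges)]
  A2 <- build_transition_matrix(net)
  expect_equal(as.matrix(A1), as.matrix(A2))
})
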