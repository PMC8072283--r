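test_that("negative sampling draws from zero cells at the requested ratio", {
  sim <- tiny_network(seed = 2)
  m <- sim$network$matrices$drug_target
  n_pos <- sum(m == 1)
  neg <- sample_negatives(m, 5, seed = 3)
  expect_equal(nrow(neg), 5 * n_pos)
  expect_true(all(m[neg] == 0))
  expect_identical(neg, sample_negatives(m, 5, seed = 3))
  expect_false(identical(neg, sample_negatives(m, 5, seed = 4)))

  # 'all' turns every zero entry into a negative
  expect_equal(nrow(sample_negatives(m, "all")), sum(m == 0))
  expect_error(sample_negatives(m, 0), "positive integer")
})

test_that("negative sampling caps at the available zero entries", {
  m <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3)
  expect_warning(neg <- sample_negatives(m, 10, seed = 1), "capping")
  expect_equal(nrow(neg), 5L)
  all1 <- matrix(1, 2, 2)
  expect_warning(neg0 <- sample_negatives(all1, 2, seed = 1), "capping")
  expect_equal(nrow(neg0), 0L)
})

test_that("splits realize the 0.855/0.045/0.1 division with stratification", {
  pos <- cbind(rep(1:10, 10), rep(1:10, each = 10))     # 100 positives
  neg <- cbind(rep(1:30, 30), rep(1:30, each = 30))     # 900 negatives
  folds <- make_folds(pos, neg, k = 10, seed = 7)
  expect_length(folds, 10L)
  for (s in folds) {
    sizes <- vapply(s[c("train", "val", "test")], nrow, integer(1))
    expect_equal(sum(sizes), 1000L)
    expect_true(abs(sizes[["test"]] - 100) <= 1)
    expect_true(abs(sizes[["val"]] - 45) <= 1)
    expect_true(abs(sizes[["train"]] - 855) <= 1)
    # class stratification: 9 negatives per positive, within +-1 sample
    for (part in c("train", "val", "test")) {
      np <- sum(s[[part]]$label == 1); nn <- sum(s[[part]]$label == 0)
      expect_true(abs(nn - 9 * np) <= 9)
    }
  }
})

test_that("fold test sets partition the dataset; parts never overlap", {
  set.seed(21)
  pos <- cbind(sample(1:12, 40, TRUE), sample(1:15, 40, TRUE))
  pos <- unique(pos)
  neg <- cbind(sample(1:12, 120, TRUE), sample(1:15, 120, TRUE))
  neg <- unique(neg[!paste(neg[, 1], neg[, 2]) %in% paste(pos[, 1], pos[, 2]), ])
  key <- function(d) paste(d$drug, d$protein, d$label)
  folds <- make_folds(pos, neg, k = 5, seed = 3)
  all_keys <- c(paste(pos[, 1], pos[, 2], 1), paste(neg[, 1], neg[, 2], 0))
  test_keys <- unlist(lapply(folds, function(s) key(s$test)))
  expect_setequal(test_keys, all_keys)     # tests partition the dataset
  expect_equal(anyDuplicated(test_keys), 0L)
  for (s in folds) {
    ks <- c(key(s$train), key(s$val), key(s$test))
    expect_equal(anyDuplicated(ks), 0L)
    expect_setequal(ks, all_keys)          # each fold covers everything once
  }
  # deterministic under seed
  expect_identical(make_folds(pos, neg, k = 5, seed = 3), folds)
})

test_that("masked loss matches hand-computed cases", {
  orig <- list(m = rbind(c(1, 0), c(0, 1)))
  recon_perfect <- list(m = orig$m)
  expect_equal(masked_loss(recon_perfect, orig), 0)

  recon <- list(m = rbind(c(0.5, 0), c(0, 1)))
  expect_equal(masked_loss(recon, orig), 0.25)

  masks <- list(m = matrix(0, 2, 2))
  expect_equal(masked_loss(recon, orig, masks), 0)
})

test_that("the loss is strictly increasing in lambda for nonzero parameters", {
  sim <- tiny_network()
  prm <- init_params(sim$network, dim = 3, seed = 1)
  orig <- sim$network$matrices
  recon <- lapply(orig, function(m) m * 0)
  l0 <- masked_loss(recon, orig, params = prm, lambda = 0)
  l1 <- masked_loss(recon, orig, params = prm, lambda = 1e-3)
  l2 <- masked_loss(recon, orig, params = prm, lambda = 2e-3)
  expect_lt(l0, l1)
  expect_lt(l1, l2)
})

test_that("the DTI mask marks exactly the training pairs", {
  sim <- tiny_network(seed = 3)
  net <- sim$network
  pos <- which(net$matrices$drug_target == 1, arr.ind = TRUE)
  neg <- sample_negatives(net$matrices$drug_target, 5, seed = 2)
  split <- make_split(pos, neg, seed = 1)
  masks <- build_masks(net, split)
  P <- masks$drug_target
  expect_equal(sum(P), nrow(split$train))
  expect_true(all(P[cbind(split$train$drug, split$train$protein)] == 1))
  expect_true(all(P[cbind(split$val$drug, split$val$protein)] == 0))
  expect_true(all(P[cbind(split$test$drug, split$test$protein)] == 0))
  # the seven auxiliary networks are fully observed
  expect_true(all(vapply(masks[names(masks) != "drug_target"], is.null,
                         logical(1))))
})

test_that("the homology filter removes similarity-recoverable positives", {
  space <- node_space(c(drug = 3, protein = 3, disease = 1, side_effect = 1))
  edges <- default_edge_types()
  dti <- rbind(c(1, 0, 0), c(1, 0, 1), c(0, 0, 0))
  dsim <- diag(3); dsim[1, 2] <- dsim[2, 1] <- 0.9       # drugs 1,2 similar
  psim <- diag(3); psim[1, 3] <- psim[3, 1] <- 0.5       # proteins 1,3 similar
  mats <- list(drug_target = dti,
               drug_drug = matrix(0, 3, 3), protein_protein = matrix(0, 3, 3),
               drug_disease = matrix(0, 3, 1), drug_se = matrix(0, 3, 1),
               protein_disease = matrix(0, 3, 1), drug_sim = dsim,
               protein_sim = psim)
  net <- hetero_network(space, edges, mats)
  pos <- which(dti == 1, arr.ind = TRUE)
  kept <- filter_homologous(net, pos)
  keys <- paste(kept[, 1], kept[, 2])
  # (1,1) flagged: similar drug 2 also binds protein 1; (2,1) flagged
  # symmetrically; (2,3) flagged: protein 3 similar to protein 1 which drug 2
  # binds -> everything removed
  expect_false("1 1" %in% keys)
  expect_false("2 1" %in% keys)
  expect_false("2 3" %in% keys)
  # raising thresholds above the similarities keeps all positives
  kept2 <- filter_homologous(net, pos, drug_threshold = 0.95,
                             protein_threshold = 0.95)
  expect_equal(nrow(kept2), nrow(pos))
})
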