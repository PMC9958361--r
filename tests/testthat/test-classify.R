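fake_sweep <- function(n_per = 8, sd_noise = 0.02, seed = 1) {
  # four synthetic state signatures in descriptor space
  protos <- rbind(
    aster            = c(0.2, 0.001, 0.3, 0.2, 0.1, 0.1, 0.8),
    parallel_bundle  = c(0.9, 0.001, 0.15, 0.9, 0.05, 0.05, 0.05),
    extensile_bundle = c(0.7, 0.02, 0.95, 0.1, 0.8, 0.1, 0.05),
    gliding_mesh     = c(0.15, 0.02, 1.0, 0.25, 0.25, 0.5, 0.02))
  colnames(protos) <- DESCRIPTOR_COLS
  set.seed(seed)
  m <- do.call(rbind, lapply(rownames(protos), function(g)
    matrix(rep(protos[g, ], each = n_per), n_per, 7) +
      rnorm(n_per * 7, 0, sd_noise) * rep(apply(protos, 2, sd), each = n_per)))
  colnames(m) <- DESCRIPTOR_COLS
  list(m = as.data.frame(m),
       truth = rep(rownames(protos), each = n_per))
}

test_that("PCA identifies exact low-rank structure", {
  set.seed(2)
  dir7 <- rnorm(7)
  base <- matrix(rnorm(40), 40, 1) %*% t(dir7)
  colnames(base) <- DESCRIPTOR_COLS
  pr <- pca_project(base + 0, n_components = 2)
  expect_equal(pr$explained[1], 1, tolerance = 1e-9)
})

test_that("an isotropic cloud spreads variance evenly over components", {
  set.seed(3)
  x <- matrix(rnorm(7 * 1e4), ncol = 7)
  colnames(x) <- DESCRIPTOR_COLS
  pr <- pca_project(x, n_components = 7)
  expect_lt(max(abs(pr$explained - 1 / 7)), 0.02)
})

test_that("loading signs are canonicalized and scores deterministic", {
  sw <- fake_sweep()
  p1 <- pca_project(sw$m)
  p2 <- pca_project(sw$m[, rev(seq_len(7))][, rev(seq_len(7))])  # identity
  expect_equal(p1$scores, p2$scores)
  for (j in 1:2) expect_gt(max(p1$loadings[, j]), 0)
})

test_that("constant descriptor columns are rejected by name", {
  sw <- fake_sweep()
  sw$m$fX <- 0.5
  expect_error(pca_project(sw$m), "fX")
})

test_that("z-scored matrix is reconstructed exactly from all components", {
  sw <- fake_sweep()
  pr <- pca_project(sw$m, n_components = 7)
  z <- scale(descriptor_matrix(sw$m))
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  expect_lt(max(abs(pr$scores %*% t(pr$loadings) - z)), 1e-9)
})

test_that("k-means recovers well-separated blobs for any seed", {
  set.seed(4)
  blobs <- rbind(matrix(rnorm(60, 0, 0.05), ncol = 2),
                 matrix(rnorm(60, 5, 0.05), ncol = 2),
                 cbind(rnorm(30, 0, 0.05), rnorm(30, 5, 0.05)),
                 cbind(rnorm(30, 5, 0.05), rnorm(30, 0, 0.05)))
  truth <- rep(1:4, each = 30)
  for (sd in c(1, 7, 99)) {
    cl <- kmeans_states(blobs, k = 4, seed = sd)
    # perfect agreement up to label permutation
    expect_equal(length(unique(paste(truth, cl))), 4)
  }
})

test_that("k-means handles degenerate inputs", {
  x <- matrix(rnorm(40), ncol = 2)
  cl1 <- kmeans_states(x, k = 1, seed = 1)
  expect_true(all(cl1 == 1))
  wcss <- attr(cl1, "tot_withinss")
  expect_equal(wcss, sum(scale(x, scale = FALSE)^2), tolerance = 1e-9)
  dup <- matrix(rep(c(0, 0, 1, 1, 5, 5), each = 4), ncol = 2, byrow = FALSE)
  dup <- rbind(dup, dup)
  cl2 <- kmeans_states(dup, k = 3, seed = 2)
  expect_false(any(is.na(cl2)))
  expect_error(kmeans_states(matrix(0, 3, 2), k = 4), "exceeds")
})

test_that("clustering is invariant to row order", {
  sw <- fake_sweep()
  pr <- pca_project(sw$m)
  cl <- kmeans_states(pr$scores, seed = 5)
  perm <- sample(nrow(sw$m))
  clp <- kmeans_states(pr$scores[perm, ], seed = 5)
  # same partition: co-membership matrices agree
  same <- outer(cl, cl, "==")
  same_p <- outer(clp, clp, "==")[order(perm), order(perm)]
  expect_equal(same, same_p)
})

test_that("state naming follows the signature priority rules", {
  sw <- fake_sweep()
  res <- classify_states(sw$m, seed = 6)
  expect_equal(res$labels, sw$truth, ignore_attr = TRUE)
  # explicit centroid checks
  m1 <- as.data.frame(rbind(
    c(0.2, 0.001, 0.5, 0.2, 0.1, 0.1, 0.8),       # aster
    c(0.9, 0.0, 0.1, 0.9, 0.05, 0.05, 0.0),       # parallel
    c(0.2, 0.03, 1.0, 0.2, 0.25, 0.5, 0.0),       # gliding mesh
    c(0.5, 0.0, 0.2, 0.3, 0.3, 0.4, 0.1)))        # nothing
  colnames(m1) <- DESCRIPTOR_COLS
  lab <- name_states(1:4, m1)
  expect_equal(as.character(lab),
               c("aster", "parallel_bundle", "gliding_mesh", "outlier"))
  # duplicated signatures are both named, with a warning
  m2 <- m1[c(1, 1, 2, 3), ]
  expect_warning(l2 <- name_states(1:4, m2), "share")
  expect_equal(as.character(l2[1:2]), c("aster", "aster"))
})

test_that("classification is robust to leaving out one descriptor", {
  sw <- fake_sweep()
  rb <- robustness_check(sw$m, seed = 7)
  expect_equal(nrow(rb), 7)
  expect_true(all(rb$agreement == 1))
})
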