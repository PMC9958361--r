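#' Extract the descriptor matrix from a sweep table
#' @param m data frame or matrix holding (at least) the descriptor columns
#' @param cols descriptor columns to use
#' @return numeric matrix, rows = runs
#' @export
descriptor_matrix <- function(m, cols = DESCRIPTOR_COLS) {
  if (is.matrix(m)) return(m[, intersect(colnames(m), cols), drop = FALSE])
  miss <- setdiff(cols, names(m))
  if (length(miss)) stop("missing descriptor columns: ",
                         paste(miss, collapse = ", "))
  as.matrix(m[, cols, drop = FALSE])
}

#' Principal component projection of a descriptor matrix
#'
#' Columns are z-scored (the descriptors mix incommensurate units, um/s
#' against dimensionless fractions), then the data are rotated onto the
#' eigenvectors of the correlation structure. Loading signs are
#' canonicalized so the entry of largest magnitude in each loading vector
#' is positive.
#'
#' @param m sweep table or matrix (rows = runs, the 7 descriptors)
#' @param n_components number of components to return
#' @return list with `scores` (n x n_components), `loadings`
#'   (p x n_components), `explained` (variance fractions, length
#'   n_components) and `center`, `scale` of the z-scoring
#' @export
pca_project <- function(m, n_components = 2) {
  x <- descriptor_matrix(m)
  if (nrow(x) < 3) stop("need at least 3 rows for PCA")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance descriptor column: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pr$rotation))
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  list(scores = z %*% rot,
       loadings = rot,
       explained = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)],
       center = attr(z, "scaled:center"),
       scale = attr(z, "scaled:scale"))
}

kpp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(x, 1, function(r)
      min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - r)^2)))
    if (sum(d2) <= 0) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[i, ]
  }
  centers
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' K-means clustering of the principal-component scores
#'
#' Lloyd's algorithm seeded by k-means++; the best of `n_init` restarts by
#' within-cluster sum of squares is returned. Deterministic for a given
#' seed.
#'
#' @param scores n x d score matrix
#' @param k number of clusters (4 network states by default)
#' @param seed RNG seed
#' @param n_init number of seeded restarts
#' @return integer cluster ids (1..k) with attributes `centers` and
#'   `tot_withinss`
#' @export
kmeans_states <- function(scores, k = 4, seed = 1L, n_init = 50L) {
  x <- as.matrix(scores)
  if (k > nrow(x)) stop("k exceeds the number of points")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      init <- kpp_init(x, k)
      fit <- suppressWarnings(
        try(stats::kmeans(x, centers = init, iter.max = 100,
                          algorithm = "Lloyd"), silent = TRUE))
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed on all restarts")
    structure(as.integer(best$cluster), centers = best$centers,
              tot_withinss = best$tot.withinss)
  })
}

#' Name clusters by their dominant descriptor signature
#'
#' Each cluster's centroid over the original (unscaled) descriptors is
#' matched against the four state signatures in fixed priority:
#' a large end-link fraction with low order names an aster; high order with
#' mostly parallel links a parallel bundle; antiparallel links with
#' appreciable sliding in a well-connected network an extensile bundle; and
#' many X links in a percolated, isotropic network a gliding mesh.
#' Unmatched clusters are named `outlier`; two clusters matching the same
#' rule are both named, with a warning.
#'
#' @param clusters integer cluster ids per run
#' @param m the sweep table the clusters were computed from (all 7
#'   descriptors; used for the centroids)
#' @return character vector of state labels per run; cluster-level labels
#'   in attribute `cluster_labels`
#' @export
name_states <- function(clusters, m) {
  x <- descriptor_matrix(m)
  ks <- sort(unique(clusters))
  cen <- t(vapply(ks, function(k)
    colMeans(x[clusters == k, , drop = FALSE]), numeric(ncol(x))))
  colnames(cen) <- colnames(x)
  lab <- vapply(seq_along(ks), function(i) {
    c0 <- cen[i, ]
    if (c0["fEnd"] >= 0.4 && c0["S"] < 0.5) "aster"
    else if (c0["S"] >= 0.5 && c0["fP"] >= 0.5) "parallel_bundle"
    else if (c0["fAP"] >= 0.3 && abs(c0["mobility"]) >= 0.005 &&
             c0["cluster_frac"] >= 0.5) "extensile_bundle"
    else if (c0["fX"] >= 0.3 && c0["cluster_frac"] >= 0.8 &&
             c0["S"] < 0.5) "gliding_mesh"
    else "outlier"
  }, "")
  dup <- lab[duplicated(lab) & lab != "outlier"]
  if (length(dup))
    warning("clusters share the state signature: ",
            paste(unique(dup), collapse = ", "))
  out <- lab[match(clusters, ks)]
  attr(out, "cluster_labels") <- stats::setNames(lab, ks)
  out
}

#' Full classification pipeline: PCA, K-means and state naming
#'
#' @param m sweep table with the 7 descriptor columns
#' @param k number of clusters
#' @param seed RNG seed for the clustering
#' @param n_init k-means restarts
#' @param n_components principal components used for clustering
#' @return list with `scores`, `loadings`, `explained`, `clusters`,
#'   `labels`
#' @export
classify_states <- function(m, k = 4, seed = 1L, n_init = 50L,
                            n_components = 2) {
  pca <- pca_project(m, n_components)
  cl <- kmeans_states(pca$scores, k = k, seed = seed, n_init = n_init)
  lab <- name_states(cl, m)
  c(pca[c("scores", "loadings", "explained")],
    list(clusters = cl, labels = lab))
}

#' Leave-one-descriptor-out robustness of the classification
#'
#' Repeats the PCA + K-means + naming pipeline once per descriptor with
#' that descriptor removed (centroid naming still uses all 7), and reports
#' the fraction of runs whose state label is unchanged relative to the
#' full analysis.
#'
#' @param m sweep table with the 7 descriptor columns
#' @param k,seed,n_init as in [classify_states()]
#' @return data frame with columns `dropped` and `agreement`
#' @export
robustness_check <- function(m, k = 4, seed = 1L, n_init = 50L) {
  full <- classify_states(m, k = k, seed = seed, n_init = n_init)
  x <- descriptor_matrix(m)
  res <- lapply(DESCRIPTOR_COLS, function(drop) {
    sub <- x[, setdiff(colnames(x), drop), drop = FALSE]
    pca <- pca_project(sub, 2)
    cl <- kmeans_states(pca$scores, k = k, seed = seed, n_init = n_init)
    lab <- name_states(cl, m)
    data.frame(dropped = drop, agreement = mean(lab == full$labels))
  })
  do.call(rbind, res)
}
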