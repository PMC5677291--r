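#' Train a batch self-organizing map on a hexagonal grid
#'
#' Competitive learning on a 2-D hexagonal lattice of neurons. Each
#' training epoch assigns every input to its best-matching unit (minimum
#' Euclidean distance in feature space) and then replaces every neuron's
#' weight vector by the neighborhood-weighted mean of all inputs, with a
#' Gaussian neighborhood on the grid whose radius decays linearly from
#' `radius0` to `radius_end`. The batch formulation is deterministic
#' given the seeded initialization (random draws from the input rows
#' with small jitter). Inputs are z-scored by default since the feature
#' panel mixes units spanning several orders of magnitude.
#'
#' @param X Input matrix (n x D).
#' @param rows,cols Grid dimensions (default 10 x 10).
#' @param n_epochs Training epochs (default 40).
#' @param seed Integer seed.
#' @param radius0 Initial neighborhood radius in grid units; defaults to
#'   half the larger grid dimension.
#' @param radius_end Final radius (default 0.5).
#' @param scale Z-score the inputs before training (default TRUE).
#'
#' @return A `som_grid`: list with `weights` (`rows * cols` x D, in the
#'   scaled space), `rows`, `cols`, `grid_xy` (neuron positions in grid
#'   space, unit hex spacing), `qe` (per-epoch mean quantization error),
#'   `center`, `scale`, training metadata.
#' @export
train_som <- function(X, rows = 10, cols = 10, n_epochs = 40, seed = 1,
                      radius0 = max(rows, cols) / 2, radius_end = 0.5,
                      scale = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("`X` must have at least one row", call. = FALSE)
  if (scale && nrow(X) >= 2L) {
    st <- standardize_features(X)
    Xs <- st$train; ctr <- st$center; scl <- st$scale
  } else {
    Xs <- X; ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  n_neuron <- rows * cols
  xy <- hex_grid_xy(rows, cols)
  W <- with_seed(seed, {
    pick <- sample.int(nrow(Xs), n_neuron, replace = TRUE)
    Xs[pick, , drop = FALSE] +
      matrix(stats::rnorm(n_neuron * ncol(Xs), sd = 0.01), n_neuron)
  })
  grid_d2 <- sqdist(xy, xy)
  qe <- numeric(n_epochs)
  for (ep in seq_len(n_epochs)) {
    frac <- if (n_epochs > 1) (ep - 1) / (n_epochs - 1) else 1
    radius <- radius0 + frac * (radius_end - radius0)
    d2 <- sqdist(Xs, W)
    bmu <- max.col(-d2, ties.method = "first")
    qe[ep] <- mean(sqrt(d2[cbind(seq_len(nrow(Xs)), bmu)]))
    Hn <- exp(-grid_d2 / (2 * radius^2))       # neighborhood kernel
    A <- Hn[, bmu, drop = FALSE]               # n_neuron x n inputs
    denom <- rowSums(A)
    W_new <- (A %*% Xs) / denom
    # neurons with vanishing support keep their weights
    dead <- denom < 1e-12
    if (any(dead)) W_new[dead, ] <- W[dead, ]
    W <- W_new
  }
  structure(list(weights = W, rows = rows, cols = cols, grid_xy = xy,
                 qe = qe, center = ctr, scale = scl,
                 n_epochs = n_epochs, radius0 = radius0,
                 radius_end = radius_end, seed = seed),
            class = "som_grid")
}

# Neuron positions of an offset hexagonal lattice with unit spacing:
# odd rows are shifted half a cell, row pitch is sqrt(3)/2.
hex_grid_xy <- function(rows, cols) {
  g <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
  cbind(x = g$col + 0.5 * (g$row %% 2), y = g$row * sqrt(3) / 2)
}

#' U-matrix of a trained SOM
#'
#' For every neuron, the mean Euclidean distance (in weight space)
#' to its immediate hexagonal neighbors: 6 for interior neurons, fewer
#' at edges and corners. Low values mark coherent clusters; ridges of
#' high values mark cluster boundaries.
#'
#' @param grid A `som_grid` from [train_som()].
#' @return Numeric vector of length `rows * cols` (non-negative), with
#'   the neighbor count in `attr(, "n_neighbors")`.
#' @export
u_matrix <- function(grid) {
  stopifnot(inherits(grid, "som_grid"))
  gd <- sqrt(sqdist(grid$grid_xy, grid$grid_xy))
  nb <- gd > 1e-9 & gd <= 1.01          # unit-spacing hex neighbors
  wd <- sqrt(sqdist(grid$weights, grid$weights))
  u <- vapply(seq_len(nrow(nb)), function(i) mean(wd[i, nb[i, ]]),
              numeric(1))
  attr(u, "n_neighbors") <- rowSums(nb)
  u
}

#' Cluster SOM neurons with k-means
#'
#' Partitions the neuron weight vectors into `k` clusters (default 5,
#' one per stress level) with [stats::kmeans()], 10 seeded restarts,
#' keeping the best inertia.
#'
#' @param grid A `som_grid`.
#' @param k Number of clusters (default 5); must not exceed the neuron
#'   count.
#' @param seed Integer seed.
#' @return A `neuron_cluster_map`: list with `cluster` (neuron -> id in
#'   1..k), `k`, `centers`, `inertia` (total within-cluster sum of
#'   squares).
#' @export
kmeans_neurons <- function(grid, k = 5, seed = 1) {
  stopifnot(inherits(grid, "som_grid"))
  n_neuron <- nrow(grid$weights)
  if (k > n_neuron)
    stop("`k` (", k, ") exceeds the neuron count (", n_neuron, ")",
         call. = FALSE)
  km <- with_seed(seed, {
    if (k == n_neuron) {
      list(cluster = seq_len(n_neuron), centers = grid$weights,
           tot.withinss = 0)
    } else {
      stats::kmeans(grid$weights, centers = k, nstart = 10,
                    iter.max = 100)
    }
  })
  structure(list(cluster = km$cluster, k = k, centers = km$centers,
                 inertia = km$tot.withinss),
            class = "neuron_cluster_map")
}
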