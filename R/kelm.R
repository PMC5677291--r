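#' RBF kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||X_i - Y_j||^2)`. Symmetric with unit
#' diagonal when `X` and `Y` coincide; `gamma = 0` gives the all-ones
#' matrix.
#'
#' @param X,Y Numeric matrices with matching column count (rows are
#'   observations).
#' @param gamma Non-negative kernel size.
#' @return The `nrow(X) x nrow(Y)` kernel matrix.
#' @export
rbf_kernel <- function(X, Y, gamma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("`X` and `Y` must have the same number of columns", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0)
    stop("`gamma` must be non-negative", call. = FALSE)
  exp(-gamma * sqdist(X, Y))
}

# Pairwise squared Euclidean distances, clipped at 0 against round-off.
sqdist <- function(X, Y) {
  d <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d[d < 0] <- 0
  d
}

# One-hot target matrix in {0, 1}; classes in sorted unique label order.
one_hot <- function(labels, class_labels = sort(unique(labels))) {
  Tm <- matrix(0, length(labels), length(class_labels))
  Tm[cbind(seq_along(labels), match(labels, class_labels))] <- 1
  Tm
}

#' Per-feature standardization with training statistics
#'
#' z-scores each feature using the mean and SD of the training rows only;
#' query rows are scaled with the training statistics (no leakage).
#' Zero-variance features are centered and passed through unscaled.
#'
#' @param train_X Training matrix (rows >= 2).
#' @param query_X Optional query matrix with the same columns.
#' @return List with `train`, `query` (or `NULL`), `center`, `scale`.
#' @export
standardize_features <- function(train_X, query_X = NULL) {
  train_X <- as.matrix(train_X)
  if (nrow(train_X) < 2L)
    stop("need at least 2 training rows to standardize", call. = FALSE)
  ctr <- colMeans(train_X)
  scl <- apply(train_X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  tr <- sweep(sweep(train_X, 2, ctr), 2, scl, "/")
  qr_ <- if (!is.null(query_X))
    sweep(sweep(as.matrix(query_X), 2, ctr), 2, scl, "/") else NULL
  list(train = tr, query = qr_, center = ctr, scale = scl)
}

#' Train an extreme learning machine (ELM)
#'
#' Single-hidden-layer feedforward network with random input weights:
#' hidden map `h(x)_j = g(w_j' x + b_j)` with `w_j` uniform on [-1, 1]
#' and `b_j` uniform on [0, 1] (seeded), sigmoid activation by default.
#' The output weights solve the ridge-regularized least-squares problem
#' in closed form: `B = H' (I/C + H H')^{-1} T` (the N-side form), or the
#' algebraically equivalent L-side form `(I/C + H'H)^{-1} H' T` when the
#' hidden layer is smaller than the training set. As `C` grows the
#' solution approaches the minimum-norm least-squares solution through
#' the Moore-Penrose pseudo-inverse of `H`.
#'
#' @param X Training matrix (N x D).
#' @param labels Class labels, length N.
#' @param L Number of hidden nodes.
#' @param C Positive regularization coefficient.
#' @param seed Seed for the random hidden layer.
#' @param activation `"sigmoid"` (default) or a function.
#' @param standardize Standardize features with training statistics
#'   (default TRUE).
#'
#' @return An `elm_model` with fields `W` (L x D), `b`, `B_hat` (L x M),
#'   `C`, `class_labels`, `center`, `scale`, `seed`.
#' @export
train_elm <- function(X, labels, L = 100, C = 1, seed = 1,
                      activation = "sigmoid", standardize = TRUE) {
  X <- as.matrix(X)
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  if (L < 1) stop("`L` must be at least 1", call. = FALSE)
  act <- if (is.function(activation)) activation
  else switch(activation, sigmoid = function(z) 1 / (1 + exp(-z)),
              stop("unknown activation", call. = FALSE))
  cls <- sort(unique(labels))
  Tm <- one_hot(labels, cls)
  if (standardize && nrow(X) >= 2L) {
    st <- standardize_features(X)
    Xs <- st$train; ctr <- st$center; scl <- st$scale
  } else {
    Xs <- X; ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  D <- ncol(X)
  rnd <- with_seed(seed, list(W = matrix(stats::runif(L * D, -1, 1), L, D),
                              b = stats::runif(L, 0, 1)))
  H <- act(tcrossprod(Xs, rnd$W) +
             matrix(rnd$b, nrow(Xs), L, byrow = TRUE))
  N <- nrow(H)
  B_hat <- if (L < N) {
    A <- diag(1 / C, L) + crossprod(H)
    solve_spd(A, crossprod(H, Tm))
  } else {
    A <- diag(1 / C, N) + tcrossprod(H)
    crossprod(H, solve_spd(A, Tm))
  }
  structure(list(W = rnd$W, b = rnd$b, activation = act, B_hat = B_hat,
                 C = C, class_labels = cls, center = ctr, scale = scl,
                 seed = seed),
            class = "elm_model")
}

# Cholesky solve of a symmetric positive-definite ridge system, with an
# LU fallback for systems driven to the edge of positive definiteness
# by very large C.
solve_spd <- function(A, B) {
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("ridge system contains non-finite values; check inputs",
         call. = FALSE)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(solve(A, B))
  backsolve(R, backsolve(R, B, transpose = TRUE))
}

#' Train a kernel extreme learning machine (K-ELM)
#'
#' Replaces the explicit random hidden map of the ELM with a Mercer
#' kernel: with `Omega[i, j] = k(x_i, x_j)` the training solution is
#' `alpha = (I/C + Omega)^{-1} T`, solved as a symmetric
#' positive-definite system (no explicit inverse), and the score of a
#' query `x` is `[k(x, x_1), ..., k(x, x_N)] alpha`. With an
#' inner-product kernel over a fixed hidden map this reproduces the ELM
#' exactly; the default kernel is the RBF
#' `k(x, x') = exp(-gamma ||x - x'||^2)`.
#'
#' @param X Training matrix (N x D).
#' @param labels Class labels, length N.
#' @param C Positive regularization coefficient.
#' @param gamma RBF kernel size (ignored for `kernel = "linear"`).
#' @param kernel `"rbf"` (default), `"linear"`, or a function
#'   `function(X, Y)` returning the kernel matrix.
#' @param standardize Standardize features with training statistics
#'   (default TRUE).
#'
#' @return A `kelm_model` with fields `X_train`, `alpha` (N x M),
#'   `kernel`, `gamma`, `C`, `class_labels`, `center`, `scale`.
#' @export
train_kelm <- function(X, labels, C = 1, gamma = 0.1,
                       kernel = "rbf", standardize = TRUE) {
  X <- as.matrix(X)
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  if (length(labels) != nrow(X))
    stop("`labels` must match the rows of `X`", call. = FALSE)
  cls <- sort(unique(labels))
  Tm <- one_hot(labels, cls)
  if (standardize && nrow(X) >= 2L) {
    st <- standardize_features(X)
    Xs <- st$train; ctr <- st$center; scl <- st$scale
  } else {
    Xs <- X; ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  kfun <- kernel_function(kernel, gamma)
  Omega <- kfun(Xs, Xs)
  alpha <- solve_spd(diag(1 / C, nrow(Xs)) + Omega, Tm)
  structure(list(X_train = Xs, alpha = alpha, kernel = kernel,
                 gamma = gamma, C = C, class_labels = cls,
                 center = ctr, scale = scl),
            class = "kelm_model")
}

kernel_function <- function(kernel, gamma) {
  if (is.function(kernel)) return(kernel)
  switch(kernel,
         rbf = function(X, Y) rbf_kernel(X, Y, gamma),
         linear = function(X, Y) tcrossprod(as.matrix(X), as.matrix(Y)),
         stop("unknown kernel: ", kernel, call. = FALSE))
}

#' Predict stress classes with a trained K-ELM
#'
#' Scores are `K(X_query, X_train) alpha`; the predicted label is the
#' argmax over classes, ties broken deterministically toward the lowest
#' class index.
#'
#' @param object A `kelm_model`.
#' @param X_query Query matrix (n x D, original feature scale).
#' @param ... Unused.
#' @return List with `scores` (n x M matrix, columns named by class) and
#'   `labels` (length-n vector).
#' @export
predict.kelm_model <- function(object, X_query, ...) {
  Xq <- as.matrix(X_query)
  if (ncol(Xq) != ncol(object$X_train))
    stop("query feature dimension (", ncol(Xq),
         ") does not match the model (", ncol(object$X_train), ")",
         call. = FALSE)
  Xq <- sweep(sweep(Xq, 2, object$center), 2, object$scale, "/")
  kfun <- kernel_function(object$kernel, object$gamma)
  scores <- kfun(Xq, object$X_train) %*% object$alpha
  colnames(scores) <- as.character(object$class_labels)
  idx <- max.col(scores, ties.method = "first")
  list(scores = scores, labels = object$class_labels[idx])
}

#' @rdname predict.kelm_model
#' @export
predict.elm_model <- function(object, X_query, ...) {
  Xq <- as.matrix(X_query)
  if (ncol(Xq) != ncol(object$W))
    stop("query feature dimension does not match the model", call. = FALSE)
  Xq <- sweep(sweep(Xq, 2, object$center), 2, object$scale, "/")
  H <- object$activation(tcrossprod(Xq, object$W) +
                           matrix(object$b, nrow(Xq), length(object$b),
                                  byrow = TRUE))
  scores <- H %*% object$B_hat
  colnames(scores) <- as.character(object$class_labels)
  idx <- max.col(scores, ties.method = "first")
  list(scores = scores, labels = object$class_labels[idx])
}

#' Serialize / restore a K-ELM model as JSON
#'
#' Full-precision JSON round trip of the trained model state (kernel,
#' hyperparameters, class labels, standardization statistics, training
#' inputs and solution matrix).
#'
#' @param model A `kelm_model` with a string kernel (`"rbf"` or
#'   `"linear"`).
#' @param path Output file path.
#' @return `write_kelm_model` invisibly returns `path`;
#'   `read_kelm_model` returns the restored `kelm_model`.
#' @export
write_kelm_model <- function(model, path) {
  stopifnot(inherits(model, "kelm_model"))
  if (!is.character(model$kernel))
    stop("only string kernels can be serialized", call. = FALSE)
  payload <- list(kernel = model$kernel, gamma = model$gamma, C = model$C,
                  class_labels = model$class_labels,
                  center = model$center, scale = model$scale,
                  D = ncol(model$X_train),
                  X_train = as.vector(model$X_train),
                  alpha = as.vector(model$alpha))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kelm_model
#' @export
read_kelm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(p$X_train) / p$D
  structure(list(
    X_train = matrix(p$X_train, nrow = n, ncol = p$D),
    alpha = matrix(p$alpha, nrow = n),
    kernel = p$kernel, gamma = p$gamma, C = p$C,
    class_labels = p$class_labels, center = p$center, scale = p$scale),
    class = "kelm_model")
}
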