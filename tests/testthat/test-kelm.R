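test_that("RBF kernel matches its closed form", {
  expect_equal(rbf_kernel(matrix(0), matrix(1), gamma = 1)[1, 1],
               exp(-1))
  X <- matrix(rnorm(12), 4, 3)
  K <- rbf_kernel(X, X, gamma = 0.7)
  expect_equal(diag(K), rep(1, 4))
  expect_equal(K, t(K))
  expect_true(all(rbf_kernel(X, X, gamma = 0) == 1))
  expect_error(rbf_kernel(X, matrix(0, 2, 2), 1), "same number")
  expect_error(rbf_kernel(X, X, -1), "non-negative")
})

test_that("feature standardization uses training statistics only", {
  set.seed(1)
  tr <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3)
  qr_ <- matrix(rnorm(15, mean = 5, sd = 3), 5, 3)
  st <- standardize_features(tr, qr_)
  expect_equal(colMeans(st$train), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(st$train, 2, sd), rep(1, 3), tolerance = 1e-12)
  expect_equal(st$query, sweep(sweep(qr_, 2, st$center), 2, st$scale, "/"))

  tr2 <- cbind(tr, 7)  # constant column passes through centered
  st2 <- standardize_features(tr2)
  expect_equal(st2$train[, 4], rep(0, 20))
})

test_that("ELM separates separable classes and is seed-deterministic", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 6), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  m <- train_elm(X, y, L = 50, C = 1000, seed = 5)
  expect_equal(mean(predict(m, X)$labels == y), 1)

  m2 <- train_elm(X, y, L = 50, C = 1000, seed = 5)
  expect_identical(m$W, m2$W)
  expect_identical(m$b, m2$b)
  expect_identical(m$B_hat, m2$B_hat)
  expect_error(train_elm(X, y, L = 10, C = -1), "positive")
})

test_that("ridge ELM approaches the Moore-Penrose solution as C grows", {
  set.seed(3)
  n <- 25
  L <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  y <- sample(letters[1:3], n, replace = TRUE)
  m <- train_elm(X, y, L = L, C = 1e12, seed = 1, standardize = FALSE)
  # reconstruct H exactly as the model does
  H <- m$activation(tcrossprod(X, m$W) + matrix(m$b, n, L, byrow = TRUE))
  Tm <- stresskelm:::one_hot(y)
  B_pinv <- MASS::ginv(H) %*% Tm
  expect_lt(max(abs(m$B_hat - B_pinv)) / max(abs(B_pinv)), 1e-6)
})

test_that("N-side and L-side ridge solutions agree", {
  set.seed(4)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- sample(c("u", "v"), 30, replace = TRUE)
  m_l <- train_elm(X, y, L = 10, C = 50, seed = 2)   # L < N path
  # force the N-side path by solving it directly from the same H
  H <- m_l$activation(tcrossprod(
    scale(X, m_l$center, m_l$scale), m_l$W) +
      matrix(m_l$b, 30, 10, byrow = TRUE))
  Tm <- stresskelm:::one_hot(y)
  B_n <- t(H) %*% solve(diag(1 / 50, 30) + H %*% t(H), Tm)
  expect_equal(unname(m_l$B_hat), unname(B_n), tolerance = 1e-8)
})

test_that("K-ELM with an inner-product kernel reproduces the ELM", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    d <- sample(2:6, 1)
    L <- sample(5:30, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(y)) < 2) next
    C <- 10^runif(1, 0, 3)
    elm <- train_elm(X, y, L = L, C = C, seed = i, standardize = FALSE)
    hidden <- function(Z) elm$activation(
      tcrossprod(Z, elm$W) + matrix(elm$b, nrow(Z), L, byrow = TRUE))
    kern <- function(A, B) tcrossprod(hidden(A), hidden(B))
    kelm <- train_kelm(X, y, C = C, kernel = kern, standardize = FALSE)
    Xq <- matrix(rnorm(8 * d), 8, d)
    expect_equal(predict(kelm, Xq)$scores, predict(elm, Xq)$scores,
                 tolerance = 1e-8)
  }
})

test_that("K-ELM interpolates one-hot targets in the large-C limit", {
  set.seed(6)
  X <- matrix(rnorm(6), 3, 2)
  y <- c("a", "b", "c")
  m <- train_kelm(X, y, C = 1e9, gamma = 0.5)
  sc <- predict(m, X)$scores
  expect_equal(unname(sc), diag(3), tolerance = 1e-4)

  # a query equal to a training point inherits that point's label
  X2 <- matrix(rnorm(40), 20, 2)
  y2 <- rep(c("p", "q"), 10)
  m2 <- train_kelm(X2, y2, C = 1e6, gamma = 1)
  expect_equal(predict(m2, X2)$labels, y2)
})

test_that("single-point and tied-score edge cases are deterministic", {
  m1 <- train_kelm(matrix(c(1, 2), 1, 2), "only", C = 10,
                   standardize = FALSE)
  pr <- predict(m1, matrix(c(5, 5), 1, 2))
  expect_equal(pr$labels, "only")
  expect_gt(pr$scores[1, 1], 0)

  # gamma = 0 makes every kernel entry 1: the class scores coincide
  X <- matrix(rnorm(8), 4, 2)
  m2 <- train_kelm(X, c("a", "b", "a", "b"), C = 1, gamma = 0,
                   standardize = FALSE)
  pr2 <- predict(m2, matrix(c(9, 9), 1, 2))
  expect_equal(unname(pr2$scores[1, 1]), unname(pr2$scores[1, 2]),
               tolerance = 1e-12)

  # bitwise-tied scores resolve to the lowest class index
  m3 <- structure(list(X_train = matrix(0, 1, 2),
                       alpha = matrix(c(1, 1), 1, 2), kernel = "rbf",
                       gamma = 0.5, C = 1, class_labels = c("a", "b"),
                       center = c(0, 0), scale = c(1, 1)),
                  class = "kelm_model")
  expect_equal(predict(m3, matrix(c(2, 2), 1, 2))$labels, "a")
})

test_that("huge gamma reduces K-ELM to nearest-training-neighbor", {
  set.seed(7)
  X <- matrix(runif(40, 0, 10), 20, 2)
  y <- letters[1:20]  # each point its own class
  m <- train_kelm(X, y, C = 1e6, gamma = 1e6, standardize = FALSE)
  q <- X + matrix(rnorm(40, sd = 0.01), 20, 2)
  expect_equal(predict(m, q)$labels, y)
})

test_that("ridge path and permutation invariances hold", {
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2)
  y <- sample(c("a", "b", "c"), 30, replace = TRUE)
  Tm <- stresskelm:::one_hot(y)
  errs <- vapply(10^seq(-2, 4), function(C) {
    m <- train_kelm(X, y, C = C, gamma = 0.5)
    sum((predict(m, X)$scores - Tm)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))

  perm <- sample(30)
  m1 <- train_kelm(X, y, C = 10, gamma = 0.5)
  m2 <- train_kelm(X[perm, ], y[perm], C = 10, gamma = 0.5)
  expect_equal(m2$alpha, m1$alpha[perm, ], tolerance = 1e-9)
  q <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(m1, q)$scores, predict(m2, q)$scores,
               tolerance = 1e-9)
})

test_that("the SPD solve agrees with explicit inversion", {
  set.seed(9)
  X <- matrix(rnorm(200), 100, 2)
  y <- sample(c("a", "b"), 100, replace = TRUE)
  m <- train_kelm(X, y, C = 100, gamma = 0.3)
  Omega <- rbf_kernel(m$X_train, m$X_train, 0.3)
  alpha_inv <- solve(diag(1 / 100, 100) + Omega) %*%
    stresskelm:::one_hot(y)
  expect_equal(m$alpha, alpha_inv, tolerance = 1e-8)
})

test_that("model serialization round-trips exactly", {
  set.seed(10)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), 10)
  m <- train_kelm(X, y, C = 31.7, gamma = 0.123)
  path <- tempfile(fileext = ".json")
  write_kelm_model(m, path)
  back <- read_kelm_model(path)
  expect_equal(back$alpha, m$alpha)
  expect_equal(back$X_train, m$X_train)
  expect_equal(back$gamma, m$gamma)
  q <- matrix(rnorm(10), 5, 2)
  expect_identical(predict(back, q)$labels, predict(m, q)$labels)
  expect_equal(predict(back, q)$scores, predict(m, q)$scores)
  unlink(path)
})
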