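#' Within-subject leave-one-out cross-validation of the K-ELM
#'
#' For each subject independently, every epoch is held out once while a
#' K-ELM is trained on that subject's remaining epochs (features are
#' standardized with the training fold's statistics by default); the
#' held-out epoch is then scored. A subject with 170 epochs therefore
#' contributes exactly 170 folds. Confusion counts are pooled over
#' subjects; accuracies are reported both epoch-weighted (every fold
#' counts equally) and subject-weighted (mean of per-subject
#' accuracies) -- identical when all subjects have the same epoch count.
#'
#' @param table Feature table from [build_feature_table()] (or
#'   [feature_set_slice()] output).
#' @param feature_set Which panel slice to use; see
#'   [feature_set_slice()].
#' @param C,gamma K-ELM hyperparameters.
#' @param standardize Standardize per training fold (default TRUE).
#'
#' @return A `loocv_result`: list with `confusion` (a
#'   `confusion_matrix`), `accuracy` (percent, epoch-weighted),
#'   `accuracy_subject_weighted` (percent), `per_subject` (named percent
#'   vector), `n_folds`.
#' @export
loocv <- function(table, feature_set = "IT", C = 1, gamma = 0.1,
                  standardize = TRUE) {
  sl <- feature_set_slice(table, feature_set)
  cols <- feature_names(feature_set)
  cls <- session_levels()
  subjects <- unique(sl$subject)
  true_all <- character(0)
  pred_all <- character(0)
  per_subject <- numeric(0)
  for (s in subjects) {
    sub <- sl[sl$subject == s, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("subject ", s, " has fewer than 2 epochs", call. = FALSE)
    if (length(unique(sub$session)) < length(cls))
      stop("subject ", s, " does not cover all 5 sessions", call. = FALSE)
    X <- as.matrix(sub[, cols, drop = FALSE])
    y <- as.character(sub$session)
    pred <- loocv_predictions(X, y, C_grid = C, gamma_grid = gamma,
                              standardize = standardize)[, 1L]
    true_all <- c(true_all, y)
    pred_all <- c(pred_all, pred)
    per_subject[s] <- 100 * mean(pred == y)
  }
  cm <- confusion_matrix(true_all, pred_all, cls)
  structure(list(confusion = cm,
                 accuracy = 100 * mean(pred_all == true_all),
                 accuracy_subject_weighted = mean(per_subject),
                 per_subject = per_subject,
                 n_folds = length(true_all),
                 C = C, gamma = gamma, feature_set = feature_set),
            class = "loocv_result")
}

# LOOCV predictions for every (C, gamma) grid cell on one subject's
# data. Returns a character matrix [fold, cell] with cells ordered
# gamma-major within C (cell = (ci - 1) * n_gamma + gi). The per-fold
# squared-distance matrices are computed once and shared across the
# grid; each (gamma, C) reuses the fold's kernel rows.
loocv_predictions <- function(X, y, C_grid, gamma_grid,
                              standardize = TRUE) {
  n <- nrow(X)
  n_cell <- length(C_grid) * length(gamma_grid)
  cls <- sort(unique(y))
  Tm_full <- one_hot(y, cls)
  pred <- matrix(NA_character_, n, n_cell)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    if (standardize) {
      st <- standardize_features(Xtr, X[i, , drop = FALSE])
      Xtr <- st$train
      xq <- st$query
    } else {
      xq <- X[i, , drop = FALSE]
    }
    Dtr <- sqdist(Xtr, Xtr)
    dq <- sqdist(xq, Xtr)
    Tm <- Tm_full[-i, , drop = FALSE]
    for (gi in seq_along(gamma_grid)) {
      Omega <- exp(-gamma_grid[gi] * Dtr)
      kq <- exp(-gamma_grid[gi] * dq)
      for (ci in seq_along(C_grid)) {
        alpha <- solve_spd(diag(1 / C_grid[ci], n - 1L) + Omega, Tm)
        sc <- kq %*% alpha
        pred[i, (ci - 1L) * length(gamma_grid) + gi] <-
          cls[max.col(sc, ties.method = "first")]
      }
    }
  }
  pred
}

#' Grid search over (C, gamma) by mean LOOCV accuracy
#'
#' Evaluates every combination of regularization coefficient and RBF
#' kernel size by the same within-subject LOOCV that reports accuracy
#' (the model-selection protocol is deliberately the in-sample one; a
#' truly unbiased estimate would require nested cross-validation).
#' Accuracy per cell is the epoch-weighted mean over all subjects. Ties
#' at the maximum resolve to the smallest `C`, then the smallest
#' `gamma`.
#'
#' @param table Feature table.
#' @param feature_set Panel slice; see [feature_set_slice()].
#' @param C_grid,gamma_grid Numeric grids. The conventional screening
#'   grid is the 15-point ladder `10^(-8:6)` for both.
#' @param standardize Standardize per training fold.
#' @param verbose Print per-subject progress.
#'
#' @return A `grid_result`: list with `accuracy` (matrix, rows = C,
#'   cols = gamma, percent), `C_grid`, `gamma_grid`, `best_C`,
#'   `best_gamma`, `best_accuracy`.
#' @export
grid_search <- function(table, feature_set = "IT",
                        C_grid = 10^(-8:6), gamma_grid = 10^(-8:6),
                        standardize = TRUE, verbose = FALSE) {
  if (!length(C_grid) || !length(gamma_grid))
    stop("grids must be non-empty", call. = FALSE)
  sl <- feature_set_slice(table, feature_set)
  cols <- feature_names(feature_set)
  subjects <- unique(sl$subject)
  n_cell <- length(C_grid) * length(gamma_grid)
  correct <- numeric(n_cell)
  total <- 0L
  for (s in subjects) {
    if (verbose) message("grid search: subject ", s)
    sub <- sl[sl$subject == s, , drop = FALSE]
    X <- as.matrix(sub[, cols, drop = FALSE])
    y <- as.character(sub$session)
    pred <- loocv_predictions(X, y, C_grid, gamma_grid, standardize)
    correct <- correct + colSums(pred == y)
    total <- total + nrow(sub)
  }
  acc <- matrix(100 * correct / total, nrow = length(C_grid),
                ncol = length(gamma_grid), byrow = TRUE,
                dimnames = list(C = format(C_grid, trim = TRUE),
                                gamma = format(gamma_grid, trim = TRUE)))
  # ties toward smallest C, then smallest gamma: row-major scan order
  flat <- as.vector(t(acc))
  best <- which(flat == max(flat))[1L]
  bi <- (best - 1L) %/% length(gamma_grid) + 1L
  bj <- (best - 1L) %% length(gamma_grid) + 1L
  structure(list(accuracy = acc, C_grid = C_grid, gamma_grid = gamma_grid,
                 best_C = C_grid[bi], best_gamma = gamma_grid[bj],
                 best_accuracy = acc[bi, bj], feature_set = feature_set),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "<grid_result> %s: best accuracy %.2f%% at C = %g, gamma = %g\n",
    x$feature_set, x$best_accuracy, x$best_C, x$best_gamma))
  invisible(x)
}

#' Confusion matrix of session classification
#'
#' @param true,pred Character vectors of true and predicted session
#'   labels.
#' @param class_labels Label order (default the protocol order).
#' @return A `confusion_matrix`: integer counts matrix (rows = true,
#'   cols = predicted) with a `percent` attribute holding the
#'   row-normalized view in percent.
#' @export
confusion_matrix <- function(true, pred, class_labels = session_levels()) {
  counts <- table(factor(true, class_labels), factor(pred, class_labels))
  counts <- matrix(as.integer(counts), nrow = length(class_labels),
                   dimnames = list(true = class_labels,
                                   predicted = class_labels))
  structure(counts, class = c("confusion_matrix", "matrix"),
            percent = 100 * prop.table(counts + 0, margin = 1))
}

#' Row-percentage view of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @param digits Decimals in the report view (default 2, matching the
#'   conventional presentation of session-classification tables).
#' @return Numeric matrix of row percentages.
#' @export
confusion_percent <- function(cm, digits = NULL) {
  p <- attr(cm, "percent")
  if (!is.null(digits)) p <- round_half_up(p, digits)
  p
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> counts (rows = true):\n")
  print(unclass(x)[, ])
  cat("row percent:\n")
  print(round(attr(x, "percent"), 2))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Standard one-way decomposition, `F = MS_between / MS_within`, fit via
#' [stats::aov()]. A degenerate configuration with zero within-group
#' variance but unequal group means reports `F = Inf` with the
#' `degenerate` flag set.
#'
#' @param groups List (optionally named) of numeric vectors, one per
#'   group; at least 2 groups.
#' @return An `anova_result`: list with `F`, `df_between`, `df_within`,
#'   `p`, `ms_within`, `group_means`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least 2 numeric vectors",
         call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  msw <- s["Residuals", "Mean Sq"]
  msb <- s[1, "Mean Sq"]
  degenerate <- is.finite(msb) && msb > 0 &&
    (!is.finite(msw) || msw <= 1e-12 * msb)
  Fv <- if (degenerate) Inf else s[1, "F value"]
  pv <- if (degenerate) 0 else s[1, "Pr(>F)"]
  structure(list(F = Fv, df_between = s[1, "Df"],
                 df_within = s["Residuals", "Df"], p = pv,
                 ms_within = msw,
                 group_means = vapply(groups, mean, numeric(1)),
                 degenerate = degenerate),
            class = "anova_result")
}

#' Tukey HSD pairwise comparisons
#'
#' Honestly-significant-difference test on the one-way layout; requires
#' equal group sizes. For each pair the studentized-range statistic is
#' `q = |mean_i - mean_j| / sqrt(MS_within / n)` with the adjusted
#' p-value from the studentized-range distribution (cross-checked
#' against [stats::TukeyHSD()]).
#'
#' @param groups List of numeric vectors with equal lengths; >= 2
#'   groups.
#' @return A `tukey_result`: data.frame with columns `pair`, `diff`,
#'   `q`, `p_adj`, plus attributes `ms_within`, `df_within`.
#' @export
tukey_hsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least 2 numeric vectors",
         call. = FALSE)
  n_per <- lengths(groups)
  if (length(unique(n_per)) != 1L)
    stop("Tukey HSD requires equal group sizes (observed: ",
         paste(n_per, collapse = ", "), ")", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ar <- one_way_anova(groups)
  n <- n_per[1]
  k <- length(groups)
  combs <- utils::combn(names(groups), 2)
  res <- data.frame(pair = apply(combs, 2, paste, collapse = " - "),
                    diff = NA_real_, q = NA_real_, p_adj = NA_real_)
  for (j in seq_len(ncol(combs))) {
    d <- ar$group_means[combs[2, j]] - ar$group_means[combs[1, j]]
    q <- abs(d) / sqrt(ar$ms_within / n)
    res$diff[j] <- d
    res$q[j] <- q
    res$p_adj[j] <- stats::ptukey(q, nmeans = k, df = ar$df_within,
                                  lower.tail = FALSE)
  }
  structure(res, ms_within = ar$ms_within, df_within = ar$df_within,
            class = c("tukey_result", "data.frame"))
}

#' Summary statistics of the questionnaire-score table
#'
#' Computes per-column means and sample SDs of the packaged
#' questionnaire fixture (12 subjects; age plus STAI Y-1 and VAS scores
#' for the mild, moderate and severe stress sessions). The report view
#' rounds half-up to one decimal, the convention used in summary rows
#' of questionnaire tables.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return List with `data` (the parsed table), `means`, `sds`
#'   (named numeric, full precision) and `report` (one-decimal
#'   half-up-rounded means).
#' @export
questionnaire_stats <- function(path = system.file(
  "extdata", "questionnaire_scores.csv", package = "stresskelm")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "age", "sex", "stai_mis", "vas_mis", "stai_mos",
            "vas_mos", "stai_ses", "vas_ses")
  if (!all(need %in% names(tab)))
    stop("malformed questionnaire fixture; expected columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(need, c("subject", "sex"))
  means <- vapply(tab[num_cols], mean, numeric(1))
  sds <- vapply(tab[num_cols], stats::sd, numeric(1))
  list(data = tab, means = means, sds = sds,
       report = round_half_up(means, 1))
}
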