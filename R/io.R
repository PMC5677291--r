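#' Epoch manifest of a segmented session
#'
#' @param eps An `epoch_set` from [segment_epochs()].
#' @param subject,session Identifiers recorded on each row.
#' @return Data.frame with columns `subject`, `session`, `epoch_index`,
#'   `t_start`, `t_end` (seconds).
#' @export
epoch_manifest <- function(eps, subject = NA_character_,
                           session = NA_character_) {
  stopifnot(inherits(eps, "epoch_set"))
  data.frame(subject = subject, session = session,
             epoch_index = seq_along(eps$epochs),
             t_start = eps$t_start, t_end = eps$t_end)
}

#' Dump a skin-conductance decomposition as CSV
#'
#' Writes the tonic and phasic components on the signal grid (columns
#' `t`, `tonic`, `phasic`) and, alongside, the decimated sudomotor
#' driver (`<path>_driver.csv` with columns `t`, `driver`).
#'
#' @param dec An `sc_decomposition` from [decompose_sc()].
#' @param path Output CSV path for the components.
#' @return Invisibly, `path`.
#' @export
write_sc_decomposition <- function(dec, path) {
  stopifnot(inherits(dec, "sc_decomposition"))
  utils::write.csv(data.frame(t = ts_times(dec$tonic),
                              tonic = dec$tonic$samples,
                              phasic = dec$phasic$samples),
                   path, row.names = FALSE)
  utils::write.csv(data.frame(t = ts_times(dec$driver),
                              driver = dec$driver$samples),
                   sub("\\.csv$", "_driver.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Write a confusion matrix as CSV and JSON
#'
#' The CSV holds the integer counts (rows = true session); the JSON
#' carries counts and the row-percentage view together.
#'
#' @param cm A `confusion_matrix`.
#' @param path_csv,path_json Output paths; either may be `NULL` to
#'   skip.
#' @return Invisibly, `cm`.
#' @export
write_confusion <- function(cm, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!is.null(path_csv))
    utils::write.csv(as.data.frame(unclass(cm)[, ]), path_csv)
  if (!is.null(path_json))
    jsonlite::write_json(list(counts = unclass(cm)[, ],
                              percent = attr(cm, "percent")),
                         path_json, digits = NA, matrix = "rowmajor")
  invisible(cm)
}

#' Write a grid-search accuracy surface as CSV
#'
#' Long format with columns `C`, `gamma`, `accuracy` (percent).
#'
#' @param grid A `grid_result` from [grid_search()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_grid_surface <- function(grid, path) {
  stopifnot(inherits(grid, "grid_result"))
  surf <- expand.grid(gamma = grid$gamma_grid, C = grid$C_grid)
  surf$accuracy <- as.vector(t(grid$accuracy))
  utils::write.csv(surf[, c("C", "gamma", "accuracy")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write SOM outputs (weights, U-matrix, cluster map) as CSV
#'
#' @param grid A `som_grid` from [train_som()].
#' @param dir Output directory (created if needed).
#' @param clusters Optional `neuron_cluster_map` from
#'   [kmeans_neurons()].
#' @return Invisibly, the vector of paths written.
#' @export
write_som_outputs <- function(grid, dir, clusters = NULL) {
  stopifnot(inherits(grid, "som_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- data.frame(neuron = seq_len(nrow(grid$weights)),
                     grid_x = grid$grid_xy[, "x"],
                     grid_y = grid$grid_xy[, "y"])
  w <- cbind(base, as.data.frame(grid$weights))
  p1 <- file.path(dir, "neuron_weights.csv")
  utils::write.csv(w, p1, row.names = FALSE)
  u <- u_matrix(grid)
  p2 <- file.path(dir, "u_matrix.csv")
  utils::write.csv(cbind(base, u_dist = as.numeric(u),
                         n_neighbors = attr(u, "n_neighbors")),
                   p2, row.names = FALSE)
  paths <- c(p1, p2)
  if (!is.null(clusters)) {
    p3 <- file.path(dir, "neuron_clusters.csv")
    utils::write.csv(cbind(base, cluster = clusters$cluster), p3,
                     row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
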