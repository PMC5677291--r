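# Independent brute-force oracles and small fixture builders shared
# across the test files.

# Brute-force approximate entropy: literal double-loop Pincus
# definition, self-matches included, Chebyshev distance.
apen_brute <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Brute-force sample entropy: double loop over the n - m template
# starting positions common to lengths m and m + 1, self-matches
# excluded.
sampen_brute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  count_pairs <- function(mm) {
    cnt <- 0
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  b <- count_pairs(m)
  a <- count_pairs(m + 1)
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# Noise-free session parameter set used by round-trip fixtures.
quiet_params <- function(label = "BA-S", ...) {
  args <- list(...)
  defaults <- list(session_label = label, mean_rr = 900, sd_rr = 40,
                   noise_sd = list(ppg = 0, eda = 0, skt = 0,
                                   eda_wander = 0, skt_wander = 0))
  do.call(session_params, utils::modifyList(defaults, args))
}

# A small feature table of well-separated Gaussian blobs (one blob per
# session) for classifier-level tests that do not need the signal
# pipeline.
blob_feature_table <- function(n_subjects = 1, epochs_per_session = 10,
                               d = 24, sep = 6, sd = 1, seed = 1) {
  set.seed(seed)
  cols <- stresskelm::feature_names("IT")[seq_len(d)]
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (k in seq_along(stresskelm::session_levels())) {
      centre <- rnorm(d) + sep * k
      X <- matrix(rnorm(epochs_per_session * d, sd = sd),
                  epochs_per_session, d) +
        matrix(centre, epochs_per_session, d, byrow = TRUE)
      df <- as.data.frame(X)
      names(df) <- cols
      df <- cbind(data.frame(subject = sprintf("S%02d", s),
                             session = stresskelm::session_levels()[k],
                             epoch = seq_len(epochs_per_session)),
                  df)
      rows[[length(rows) + 1]] <- df
    }
  }
  tab <- do.call(rbind, rows)
  tab$session <- factor(tab$session, levels = stresskelm::session_levels())
  # pad out to the full 24-column panel if a smaller d was requested
  for (nm in setdiff(stresskelm::feature_names("IT"), names(tab)))
    tab[[nm]] <- 0
  tab
}
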