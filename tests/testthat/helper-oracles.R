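# Independent oracles and fixture builders used across the suite. These
# stay deliberately separate from the package's own code paths.

# random log-series assemblage: abundances drawn from the log-series pmf
# and reconciled to exactly n individuals
random_logseries <- function(alpha, n, seed) {
  x <- n / (n + alpha)
  S <- max(2L, round(alpha * log1p(n / alpha)))
  withr::with_seed(seed, {
    j <- 1:20000
    p <- x^j / j
    ab <- sample(j, S, replace = TRUE, prob = p)
    deficit <- n - sum(ab)
    if (deficit > 0) ab <- ab + stats::rmultinom(1, deficit, ab / sum(ab))[, 1]
    while (deficit < 0) {
      room <- pmax(ab - 1L, 0L)
      take <- min(-deficit, sum(room))
      dec <- tabulate(sample.int(length(ab), take, TRUE, prob = room),
                      nbins = length(ab))
      ab <- ab - pmin(dec, room)
      deficit <- n - sum(ab)
    }
    ab
  })
}

# ideal (deterministic) log-series community built by quantiles of the
# log-series pmf: exactly the textbook rank-abundance shape
ideal_logseries <- function(alpha, n_target) {
  x <- n_target / (n_target + alpha)
  S <- round(alpha * log1p(n_target / alpha))
  k <- 1:200000
  p <- x^k / k
  cdf <- cumsum(p / sum(p))
  q <- (seq_len(S) - 0.5) / S
  sort(vapply(q, function(u) which(cdf >= u)[1], integer(1)),
       decreasing = TRUE)
}

# Monte-Carlo subsampling SQS: estimates the expected coverage curve
# (share-sum with the finite-sample factor) and the expected richness curve
# by repeated subsampling, and reads richness off at the quorum with the
# same coverage interpolation as the analytic method. Batch means give an
# honest standard error that includes the coverage-curve uncertainty.
mc_sqs <- function(counts, q, reps = 1000L, batches = 20L, seed = 1L) {
  ids <- rep.int(seq_along(counts), counts)
  n <- length(ids)
  share <- counts / n
  per_batch <- reps %/% batches
  batch_means <- withr::with_seed(seed, vapply(seq_len(batches), function(b) {
    S_mat <- matrix(0L, n, per_batch)
    cov_sum <- numeric(n)
    for (r in seq_len(per_batch)) {
      perm <- sample(ids)
      first <- !duplicated(perm)
      gain <- numeric(n)
      gain[first] <- share[perm[first]]
      cov_sum <- cov_sum + 1 - (n / (n - seq_len(n))) * (1 - cumsum(gain))
      S_mat[, r] <- cumsum(first)
    }
    covm <- cov_sum / per_batch
    m <- which(covm >= q)[1]
    c_lo <- if (m == 1) 0 else covm[m - 1]
    w <- (q - c_lo) / (covm[m] - c_lo)
    S_lo <- if (m == 1) rep(0, per_batch) else S_mat[m - 1, ]
    mean(S_lo + w * (S_mat[m, ] - S_lo))
  }, numeric(1)))
  list(mean = mean(batch_means),
       se = stats::sd(batch_means) / sqrt(batches))
}

# bisection oracle for Fisher's alpha (independent of the package's
# uniroot + Newton path)
bisect_alpha <- function(S, n, lo = 1e-6, hi = 1e6, iters = 200L) {
  f <- function(a) a * log1p(n / a) - S
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exhaustive k-medoid optimum
brute_pam_cost <- function(d, k) {
  n <- nrow(d)
  min(apply(utils::combn(n, k), 2, function(med)
    sum(apply(d[, med, drop = FALSE], 1, min))))
}

# small occurrence data.frame builder (text coordinates)
occ_df <- function(name, lat, lon) {
  data.frame(taxon_name = name, lat = lat, lon = lon,
             source_id = as.character(seq_along(name)),
             stringsAsFactors = FALSE)
}

# tiny cell_matrix-like fixture: counts matrix + env rows for given SSTs
tiny_cm <- function(x, sst, sst_sd = rep(1, length(sst))) {
  ids <- rownames(x)
  env <- data.frame(cell_id = ids, sst_mean = sst, sst_sd = sst_sd)
  list(x = x, env = env)
}
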