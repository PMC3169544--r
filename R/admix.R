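# Bayesian admixture estimation for dominant binary markers: a Gibbs
# sampler over per-observation ancestry origins z, cluster band frequencies
# p (Beta full conditional) and individual admixture vectors q (Dirichlet
# full conditional). Bands are modeled as haploid binary observations — the
# dominant genotype is treated as the allele itself — which keeps all full
# conditionals conjugate; a dominance-aware genotype likelihood is out of
# scope and stated so in the documentation.

#' Estimate admixture proportions by Gibbs sampling
#'
#' The model: individual `i`'s band at marker `m` originates from cluster
#' `k` with probability `q[i,k]`, and is present with that cluster's band
#' frequency `p[k,m]`. Priors are `Dirichlet(dirichlet_alpha)` on each `q`
#' row and `Beta(1,1)` on each `p`. One sweep samples all origins `z`, then
#' `p` from `Beta(1 + n1, 1 + n0)`, then `q` rows from
#' `Dirichlet(alpha + counts)`. Posterior means of `q` and `p` over the
#' collection iterations are reported. Missing bands are skipped in the
#' likelihood and the count updates. Cluster labels are arbitrary
#' (label switching is resolved across runs by [align_labels()]).
#'
#' @param aflp Marker tibble (`sample_id`, `population`, markers...).
#' @param K Number of clusters (>= 2).
#' @param burnin,iterations Burn-in sweeps discarded, then collection
#'   sweeps; scaled-down desk defaults (5,000 / 20,000). The trace has one
#'   log-likelihood value per collection iteration.
#' @param seed Integer seed.
#' @param dirichlet_alpha Symmetric Dirichlet prior weight on `q` rows.
#' @return Object of class `admixture_fit`: `K`, `q` (individuals x K
#'   posterior means, rows summing to 1), `p` (K x markers), `loglik_trace`,
#'   `samples` (ids and populations), `burnin`, `iterations`, `seed`.
#' @export
estimate_admixture <- function(aflp, K = 2, burnin = 5000, iterations = 20000,
                               seed = NULL, dirichlet_alpha = 1) {
  if (K < 2) abort("K must be >= 2.")
  x <- aflp_band_matrix(aflp)
  samples <- aflp[, c("sample_id", "population")]
  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    warn(sprintf("excluding %d individual(s) with no scored markers.",
                 sum(all_missing)))
    x <- x[!all_missing, , drop = FALSE]
    samples <- samples[!all_missing, ]
  }
  N <- nrow(x); M <- ncol(x)
  if (N < 2 * K) abort("need at least 2*K individuals.")
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0L          # placeholder; masked out of all updates
  local_seed(seed)

  q <- matrix(rgamma(N * K, dirichlet_alpha), N, K)
  q <- q / rowSums(q)
  p <- matrix(runif(K * M), K, M)
  q_sum <- matrix(0, N, K)
  p_sum <- matrix(0, K, M)
  loglik <- numeric(iterations)
  eps <- 1e-12

  total <- burnin + iterations
  for (it in seq_len(total)) {
    # per-cluster observation weights w_k[i,m] = q[i,k] * p[k,m]^x (1-p)^(1-x)
    w <- vector("list", K)
    acc <- matrix(0, N, M)
    for (k in seq_len(K)) {
      lik <- x0 * rep(p[k, ], each = N) + (1 - x0) * rep(1 - p[k, ], each = N)
      w[[k]] <- q[, k] * lik
      acc <- acc + w[[k]]
    }
    # inverse-CDF draw of z: 1 + number of cumulative weights below u
    u <- matrix(runif(N * M), N, M) * acc
    z <- matrix(1L, N, M)
    cum <- w[[1L]]
    for (k in seq_len(K - 1L)) {
      z <- z + (u >= cum)
      if (k < K - 1L) cum <- cum + w[[k + 1L]]
    }

    cnt_q <- matrix(0, N, K)
    for (k in seq_len(K)) {
      zk <- (z == k) & obs
      n1 <- colSums(zk & (x0 == 1L))
      n0 <- colSums(zk & (x0 == 0L))
      p[k, ] <- pmin(pmax(rbeta(M, 1 + n1, 1 + n0), eps), 1 - eps)
      cnt_q[, k] <- rowSums(zk)
    }
    g <- matrix(rgamma(N * K, dirichlet_alpha + cnt_q), N, K)
    q <- g / rowSums(g)

    if (it > burnin) {
      j <- it - burnin
      loglik[j] <- sum(log(acc[obs]))
      q_sum <- q_sum + q
      p_sum <- p_sum + p
    }
  }

  structure(
    list(K = K, q = q_sum / iterations, p = p_sum / iterations,
         loglik_trace = loglik, samples = as_tibble(samples),
         burnin = burnin, iterations = iterations,
         dirichlet_alpha = dirichlet_alpha, seed = seed),
    class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K=%d, %d individuals x %d markers, %d+%d sweeps\n",
              x$K, nrow(x$q), ncol(x$p), x$burnin, x$iterations))
  invisible(x)
}

#' Tidy an admixture fit into long format
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble `sample_id`, `population`, `cluster`, `q`.
#' @export
tidy.admixture_fit <- function(x, ...) {
  q <- as_tibble(x$q, .name_repair = ~ paste0("C", seq_len(x$K)))
  tidyr::pivot_longer(bind_cols(x$samples, q),
                      cols = tidyr::starts_with("C"),
                      names_to = "cluster", values_to = "q")
}

#' One-row summary of an admixture fit
#'
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble with `K`, sweep counts and log-likelihood summaries.
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, n_individuals = nrow(x$q), n_markers = ncol(x$p),
         burnin = x$burnin, iterations = x$iterations,
         mean_loglik = mean(x$loglik_trace), sd_loglik = sd(x$loglik_trace))
}

#' Per-population admixture summary
#'
#' @param fit An `admixture_fit`.
#' @param map Optional population map tibble; defaults to the populations
#'   stored with the fit.
#' @return Tibble `population`, `cluster`, `mean_q`, `sd_q`, `n`.
#' @export
admixture_summary <- function(fit, map = NULL) {
  td <- tidy.admixture_fit(fit)
  if (!is.null(map)) {
    td <- left_join(select(td, -"population"),
                    select(map, "sample_id", "population"), by = "sample_id")
  }
  summarise(group_by(td, .data$population, .data$cluster),
            mean_q = mean(.data$q), sd_q = sd(.data$q), n = n(),
            .groups = "drop")
}

#' Align cluster labels across admixture runs
#'
#' Cluster labels are exchangeable, so independent runs can return the same
#' posterior with permuted columns. The first run is the reference; each
#' other run's columns are matched to it by greedily pairing the columns of
#' `q` with the largest negative mean absolute difference (deterministic).
#'
#' @param fits List of `admixture_fit`s with equal `K` over the same
#'   individuals.
#' @return The list with `q`/`p` columns permuted to match the first run;
#'   each fit gains a `label_permutation` field.
#' @export
align_labels <- function(fits) {
  stopifnot(length(fits) >= 1L)
  K <- fits[[1L]]$K
  if (!all(map_int(fits, "K") == K)) abort("all runs must share K.")
  ref <- fits[[1L]]$q
  fits[[1L]]$label_permutation <- seq_len(K)
  for (r in seq_along(fits)[-1L]) {
    qr <- fits[[r]]$q
    cost <- outer(seq_len(K), seq_len(K),
                  Vectorize(function(a, b) mean(abs(ref[, a] - qr[, b]))))
    perm <- integer(K)
    for (step in seq_len(K)) {
      best <- which(cost == min(cost), arr.ind = TRUE)[1L, ]
      perm[best[1L]] <- best[2L]
      cost[best[1L], ] <- Inf
      cost[, best[2L]] <- Inf
    }
    fits[[r]]$q <- qr[, perm, drop = FALSE]
    fits[[r]]$p <- fits[[r]]$p[perm, , drop = FALSE]
    fits[[r]]$label_permutation <- perm
  }
  fits
}
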