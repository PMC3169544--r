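# Pairwise exact tests of association among binary polymorphisms and the
# population-level linkage-disequilibrium summary. Recent hybrids carry
# genome-wide admixture LD that halves each generation at unlinked loci, so
# the percentage of significantly associated pairs separates laboratory
# crosses and fresh swarms from an old hybrid species.

# two-sided Fisher exact p for 2x2 tables, vectorised over tables.
# a,b,c,d are the cell counts; p sums all hypergeometric outcomes with
# probability <= that of the observed table (with a small relative slack
# against floating-point ties, as fisher.test does).
fisher_exact_p <- function(a, b, c, d) {
  map_dbl(seq_along(a), function(i) {
    m <- a[i] + b[i]          # row 1 total
    n <- c[i] + d[i]          # row 2 total
    k <- a[i] + c[i]          # column 1 total
    support <- max(0L, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(a[i], m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  })
}

#' Exact test of association between two binary polymorphisms
#'
#' Two-sided Fisher exact test on the 2x2 table of joint states, after
#' pairwise deletion of individuals missing either value. A pair in which
#' either vector is monomorphic after deletion has an undefined table and
#' returns `NA` (such pairs are excluded from summary denominators).
#'
#' @param x,y Vectors of 0/1/NA over the same individuals.
#' @return A p-value, or `NA` for an undefined pair.
#' @export
pair_exact_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  fisher_exact_p(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
                 sum(x == 0 & y == 1), sum(x == 0 & y == 0))
}

# binary polymorphism matrix from marker tibble / matrix / polymorphism table
as_binary_polymorphisms <- function(data) {
  if (inherits(data, "polymorphism_table")) {
    calls <- data$calls
    cols <- map(seq_len(ncol(calls)), function(s) {
      al <- sort(unique(calls[!is.na(calls[, s]), s]))
      if (length(al) != 2L) return(NULL)  # multiallelic sites dropped
      (calls[, s] == al[2L]) * 1L
    })
    keep <- !map_lgl(cols, is.null)
    if (sum(keep) < ncol(calls)) {
      warn(sprintf("dropped %d multiallelic site(s) from LD testing.",
                   sum(!keep)))
    }
    m <- do.call(cbind, cols[keep])
    if (is.null(m)) m <- matrix(0L, nrow(calls), 0L)
    colnames(m) <- colnames(calls)[keep]
    return(m)
  }
  if (is.data.frame(data)) return(aflp_band_matrix(data))
  data
}

#' All pairwise exact association tests
#'
#' @param data Marker tibble, binary matrix, or `polymorphism_table`
#'   (biallelic sites only; multiallelic sites are dropped with a warning).
#' @return Tibble `locus_i`, `locus_j`, `p` (`NA` for undefined pairs).
#' @export
ld_pairs <- function(data) {
  m <- as_binary_polymorphisms(data)
  ids <- colnames(m) %||% paste0("P", seq_len(ncol(m)))
  if (ncol(m) < 2L) {
    warn("fewer than 2 testable polymorphisms; empty LD table.")
    return(tibble(locus_i = character(), locus_j = character(), p = double()))
  }
  pairs <- combn(ncol(m), 2L)
  tibble(
    locus_i = ids[pairs[1L, ]], locus_j = ids[pairs[2L, ]],
    p = map_dbl(seq_len(ncol(pairs)),
                ~ pair_exact_test(m[, pairs[1L, .x]], m[, pairs[2L, .x]]))
  )
}

#' Population-level linkage-disequilibrium summary
#'
#' Tests every unordered pair of polymorphisms and reports the percentage
#' significant at `alpha` (default 0.01). Undefined pairs (monomorphic after
#' pairwise deletion) are excluded from the denominator. The headline figure
#' is the percentage of significant pairs; the per-polymorphism fraction of
#' significant partners — whose mean and SD across polymorphisms are also
#' reported — feeds the between-population ANOVA in [compare_ld()].
#'
#' @param data As in [ld_pairs()].
#' @param alpha Significance level (default 0.01).
#' @param population Label carried into the output.
#' @return One-row tibble: `population`, `n_polymorphisms`,
#'   `n_pairs_tested`, `n_significant`, `percent_significant`,
#'   `per_poly_mean`, `per_poly_sd`, `alpha`; the per-polymorphism fractions
#'   are attached as `attr(, "per_polymorphism")`.
#' @export
ld_summary <- function(data, alpha = 0.01, population = "population") {
  check_alpha(alpha)
  pairs <- ld_pairs(data)
  tested <- filter(pairs, !is.na(.data$p))
  polys <- unique(c(pairs$locus_i, pairs$locus_j))
  per_poly <- map_dbl(polys, function(id) {
    sub <- filter(tested, .data$locus_i == id | .data$locus_j == id)
    if (nrow(sub) == 0L) return(NA_real_)
    mean(sub$p <= alpha)
  })
  out <- tibble(
    population = population,
    n_polymorphisms = length(polys),
    n_pairs_tested = nrow(tested),
    n_significant = sum(tested$p <= alpha),
    percent_significant = if (nrow(tested)) 100 * mean(tested$p <= alpha) else NA_real_,
    per_poly_mean = 100 * mean(per_poly, na.rm = TRUE),
    per_poly_sd = 100 * sd(per_poly, na.rm = TRUE),
    alpha = alpha
  )
  attr(out, "per_polymorphism") <-
    tibble(population = population, polymorphism = polys,
           fraction_significant = per_poly)
  out
}

#' Compare linkage disequilibrium across populations
#'
#' Runs [ld_summary()] per named dataset and orders the comparison table by
#' descending percentage of significant pairs. Differences between
#' populations are tested by one-way ANOVA on the per-polymorphism
#' significant fractions, overall and for each pair of populations.
#'
#' @param datasets Named list of datasets (each as in [ld_pairs()]).
#' @param alpha Significance level for calling a pair associated.
#' @return Tibble of per-population summaries (class `ld_comparison`),
#'   with the per-polymorphism fractions in `attr(, "per_polymorphism")`
#'   and the ANOVA table in `attr(, "tests")`.
#' @export
compare_ld <- function(datasets, alpha = 0.01) {
  stopifnot(length(datasets) >= 2L, !is.null(names(datasets)))
  sums <- imap(datasets, function(d, nm) ld_summary(d, alpha = alpha,
                                                    population = nm))
  per_poly <- list_rbind(map(sums, ~ attr(.x, "per_polymorphism")))
  out <- arrange(list_rbind(sums), dplyr::desc(.data$percent_significant))
  pp <- filter(per_poly, !is.na(.data$fraction_significant))
  pops <- unique(pp$population)
  tests <- list()
  if (length(pops) >= 2L) {
    try_anova <- function(values, groups, label) {
      tryCatch(mutate(anova_oneway(values, groups), comparison = label),
               error = function(e) NULL)
    }
    tests[[1]] <- try_anova(pp$fraction_significant, pp$population, "overall")
    pairsets <- combn(pops, 2L, simplify = FALSE)
    tests <- c(tests, map(pairsets, function(pr) {
      sub <- filter(pp, .data$population %in% pr)
      try_anova(sub$fraction_significant, sub$population,
                paste(pr, collapse = " vs "))
    }))
  }
  attr(out, "per_polymorphism") <- per_poly
  attr(out, "tests") <- list_rbind(tests)
  class(out) <- c("ld_comparison", class(out))
  out
}

#' @export
tidy.ld_comparison <- function(x, ...) attr(x, "tests")
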