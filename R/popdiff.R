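# AMOVA-style fixation indices. The molecular variance among and within
# groups is decomposed from squared inter-sequence distances; Phi_ST is the
# among-group fraction of the total variance, and significance comes from
# permuting group labels over sequences.

# sums of squares within groups and in total, from a squared-distance matrix
amova_components <- function(d2, groups) {
  n <- length(groups)
  grp <- split(seq_len(n), groups)
  if (length(grp) < 2L) abort("need at least 2 groups.")
  sizes <- lengths(grp)
  if (any(sizes < 2L)) {
    abort(sprintf("degenerate group with < 2 members: %s",
                  paste(names(grp)[sizes < 2L], collapse = ", ")))
  }
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- sum(map_dbl(grp, function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }))
  ss_among <- ss_total - ss_within
  g <- length(grp)
  df_within <- n - g
  sigma_within <- ss_within / df_within
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  sigma_among <- (ss_among / (g - 1) - sigma_within) / n0
  phi <- sigma_among / (sigma_among + sigma_within)
  list(phi = phi, sigma_among = sigma_among, sigma_within = sigma_within)
}

phi_from_perm <- function(d2, groups) amova_components(d2, groups)$phi

#' AMOVA fixation index with permutation test
#'
#' Computes Phi_ST from the AMOVA decomposition of squared pairwise
#' distances and a permutation p-value: the proportion of group-label
#' permutations whose Phi_ST is at least the observed one. With finite
#' `n_perm` the plus-one correction is applied, so the smallest attainable
#' p is `1/(n_perm + 1)`; with `n_perm = Inf` all label permutations are
#' enumerated (small samples only) and the p-value is exact. Negative
#' variance components are reported as computed, with a flag, preserving
#' the exchangeability of the permutation test.
#'
#' @param distances Square numeric matrix (or `dist`) of inter-sequence
#'   distances.
#' @param groups Group label per sequence; at least 2 groups with at least
#'   2 members each.
#' @param n_perm Number of label permutations (default 10000), or `Inf`
#'   for exhaustive enumeration.
#' @param seed Integer seed for the permutations.
#' @param locus_id Label carried into the result.
#' @return A one-row tibble: `locus_id`, `phi_st`, `p_value`,
#'   `n_permutations`, `sigma_among`, `sigma_within`,
#'   `negative_component`.
#' @export
phi_st <- function(distances, groups, n_perm = 10000, seed = NULL,
                   locus_id = "locus") {
  d <- as.matrix(distances)
  groups <- as.character(groups)
  if (nrow(d) != length(groups)) abort("distances and groups differ in size.")
  if (any(is.na(d))) abort("distance matrix contains NA.")
  d2 <- d^2
  obs <- amova_components(d2, groups)
  tol <- 1e-12
  if (is.infinite(n_perm)) {
    n <- length(groups)
    if (n > 10L) abort("exhaustive permutation is limited to <= 10 sequences.")
    perms <- all_permutations(n)
    stat <- apply(perms, 1L, function(idx) phi_from_perm(d2, groups[idx]))
    p <- mean(stat >= obs$phi - tol)
    n_used <- nrow(perms)
  } else {
    local_seed(seed)
    stat <- replicate(n_perm, phi_from_perm(d2, sample(groups)))
    p <- (1 + sum(stat >= obs$phi - tol)) / (n_perm + 1)
    n_used <- n_perm
  }
  tibble(locus_id = locus_id, phi_st = obs$phi, p_value = p,
         n_permutations = n_used, sigma_among = obs$sigma_among,
         sigma_within = obs$sigma_within,
         negative_component = obs$sigma_among < 0)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, map(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Fixation index for one binary marker column
#'
#' Each band state is treated as a haplotype of length one (distance 0/1)
#' and passed through the sequence AMOVA, so dominant markers and sequence
#' loci share one machinery. Missing individuals are dropped first.
#'
#' @param column Vector of 0/1/NA band values.
#' @param groups Group label per individual.
#' @inheritParams phi_st
#' @return A one-row tibble as for [phi_st()].
#' @export
fst_binary <- function(column, groups, n_perm = 10000, seed = NULL,
                       locus_id = "marker") {
  keep <- !is.na(column)
  column <- column[keep]
  groups <- as.character(groups)[keep]
  if (length(unique(column)) < 2L) {
    abort("monomorphic marker column; filter before testing.")
  }
  d <- outer(column, column, `!=`) * 1
  phi_st(d, groups, n_perm = n_perm, seed = seed, locus_id = locus_id)
}

#' Distance matrix from a polymorphism table
#'
#' The distance between two sequences is the number of polymorphic sites at
#' which they carry different allele codes (an indel site counts once,
#' however long), with pairwise deletion of missing calls.
#'
#' @param ptab A [extract_polymorphisms()] result.
#' @return Symmetric numeric matrix over sequences.
#' @export
polymorphism_distances <- function(ptab) {
  calls <- ptab$calls
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  if (ncol(calls) == 0L || n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      cmp <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      d[i, j] <- d[j, i] <- sum(calls[i, cmp] != calls[j, cmp])
    }
  }
  d
}

#' Locus-by-locus AMOVA over sequence loci and/or marker columns
#'
#' Applies [phi_st()] per polymorphism table and [fst_binary()] per marker
#' column, in stable input order. Per-locus failures (monomorphic columns,
#' degenerate groups) are returned as flagged rows, not errors.
#'
#' @param data Named list of `polymorphism_table`s, or a marker tibble.
#' @param groups Optional group label per sequence/individual; defaults to
#'   the `population` metadata carried by the data.
#' @param n_perm,seed Permutation settings, see [phi_st()].
#' @return Tibble of per-locus results with a `flag` column (`NA` when ok).
#' @export
locus_by_locus <- function(data, groups = NULL, n_perm = 10000, seed = NULL) {
  run_one <- function(fn, id, stream) {
    tryCatch(
      mutate(fn(substream_seed(seed %||% 0L, stream)), flag = NA_character_),
      error = function(e) tibble(
        locus_id = id, phi_st = NA_real_, p_value = NA_real_,
        n_permutations = n_perm, sigma_among = NA_real_,
        sigma_within = NA_real_, negative_component = NA, flag = conditionMessage(e))
    )
  }
  if (is.data.frame(data)) {
    grp <- groups %||% data$population
    rows <- map(aflp_marker_ids(data), function(id) {
      run_one(function(s) fst_binary(data[[id]], grp, n_perm = n_perm,
                                     seed = s, locus_id = id), id, id)
    })
  } else {
    rows <- map(data, function(ptab) {
      grp <- groups %||% ptab$meta$population
      run_one(function(s) phi_st(polymorphism_distances(ptab), grp,
                                 n_perm = n_perm, seed = s,
                                 locus_id = ptab$locus_name),
              ptab$locus_name, ptab$locus_name)
    })
  }
  list_rbind(rows)
}

#' Pairwise population Phi_ST matrix for one locus
#'
#' @param distances Distance matrix over sequences (or a
#'   `polymorphism_table`, whose distances and populations are then used).
#' @param groups Group label per sequence.
#' @return Symmetric matrix of pairwise Phi_ST with zero diagonal.
#' @export
pairwise_fst <- function(distances, groups = NULL) {
  if (inherits(distances, "polymorphism_table")) {
    groups <- groups %||% distances$meta$population
    distances <- polymorphism_distances(distances)
  }
  d2 <- as.matrix(distances)^2
  groups <- as.character(groups)
  pops <- unique(groups)
  out <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1L]) {
    for (j in seq_len(i - 1L)) {
      idx <- groups %in% pops[c(i, j)]
      out[i, j] <- out[j, i] <-
        amova_components(d2[idx, idx, drop = FALSE], groups[idx])$phi
    }
  }
  out
}
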