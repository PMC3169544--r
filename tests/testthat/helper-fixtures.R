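# Fixture builders and independent oracles used across the suite. Oracles
# are deliberately naive (direct enumeration, textbook formulas) and share
# no code with the implementation they check.

toy_locus <- function(seqs, inheritance = "z_linked", locus = "toy",
                      populations = NULL, sexes = NULL, samples = NULL) {
  n <- length(seqs)
  aligned_locus(
    tibble::tibble(
      sequence_id = names(seqs) %||% paste0("s", seq_len(n)),
      sample_id = samples %||% (names(seqs) %||% paste0("s", seq_len(n))),
      population = populations %||% rep("pop1", n),
      sex = sexes %||% rep("U", n),
      allele_index = 1L,
      sequence = unname(seqs)),
    locus_name = locus, inheritance = inheritance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_alignment <- function(n_seq, len, p_gap = 0.1) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, n_seq * len, replace = TRUE), n_seq, len)
  # shared gap events: a random interval deleted in a random subset
  n_events <- sample(0:2, 1)
  for (e in seq_len(n_events)) {
    start <- sample(len, 1); width <- sample(1:3, 1)
    cols <- start:min(len, start + width - 1)
    rows <- sample(n_seq, sample(seq_len(n_seq - 1), 1))
    m[rows, cols] <- "-"
  }
  apply(m, 1, paste, collapse = "")
}

# brute-force polymorphic-site counter: scans columns directly; indel sites
# found by grouping gapped columns on their exact row-set and splitting
# non-adjacent column groups
brute_site_count <- function(seq_strings) {
  m <- do.call(rbind, strsplit(seq_strings, ""))
  snp <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2) snp <- snp + 1L
  }
  keysets <- apply(m == "-", 2, function(g) paste(which(g), collapse = ","))
  indel <- 0L
  j <- 1L
  while (j <= ncol(m)) {
    if (keysets[j] != "") {
      k <- j
      while (k < ncol(m) && keysets[k + 1] == keysets[j]) k <- k + 1L
      gapped <- m[, j] == "-"
      if (any(gapped) && !all(gapped)) indel <- indel + 1L
      j <- k + 1L
    } else j <- j + 1L
  }
  c(snp = snp, indel = indel)
}

# textbook two-level AMOVA from first principles (independent of phi_st)
oracle_phi <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- length(groups)
  idx <- split(seq_len(n), groups)
  sst <- sum(d2[lower.tri(d2)]) / n
  ssw <- 0
  for (g in idx) {
    sub <- d2[g, g, drop = FALSE]
    ssw <- ssw + sum(sub[lower.tri(sub)]) / length(g)
  }
  ssa <- sst - ssw
  G <- length(idx)
  s2w <- ssw / (n - G)
  nc <- (n - sum(lengths(idx)^2) / n) / (G - 1)
  s2a <- (ssa / (G - 1) - s2w) / nc
  s2a / (s2a + s2w)
}

# exact permutation p by full enumeration of label orderings
oracle_exact_p <- function(d, groups) {
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- oracle_phi(d, groups)
  stats <- vapply(perm_all(seq_along(groups)),
                  function(ix) oracle_phi(d, groups[ix]), numeric(1))
  mean(stats >= obs - 1e-12)
}

# exhaustive Fitch: minimal changes over all internal-node labelings
oracle_fitch <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  tipst <- states[tree$tip.label]
  best <- Inf
  sets <- rep(list(0:1), n_int)
  grid <- expand.grid(sets)
  for (r in seq_len(nrow(grid))) {
    lab <- c(rep(NA, n_tip), as.integer(grid[r, ]))
    cost_tot <- 0
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      sv <- if (v <= n_tip) tipst[v] else lab[v]
      if (is.na(sv)) next  # unknown tip: free
      cost_tot <- cost_tot + (lab[p] != sv)
    }
    if (ok) best <- min(best, cost_tot)
  }
  best
}

# random additive distance matrix from a random tree with positive lengths
random_additive <- function(n_tip) {
  tr <- ape::rtree(n_tip, br = function(k) stats::runif(k, 0.5, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, D = cophenetic(tr))
}

# deep parental split with a recent admixture-founded hybrid whose maternal
# lineages all come from parent A while nuclear founding is mostly parent B:
# the sex-linked mosaic configuration
mosaic_scenario <- function(...) {
  scenario_params(
    Ne_parentA = 1000, Ne_parentB = 1000, Ne_hybrid = 1000, Ne_ancestral = 1000,
    T_parent_split = 8000, T_hybrid_origin = 60,
    alpha = 0.2, alpha_maternal = 1,
    m_A_to_H = 0.001, m_B_to_H = 0.001,
    n_per_pop = c(parentA = 12, parentB = 12, hybrid = 12),
    loci = tibble::tibble(
      name = c("mt1", "z1", "z2", "z3"),
      inheritance = c("mitochondrial", rep("z_linked", 3)),
      length = c(600L, 500L, 500L, 500L)),
    ...)
}

scaled_scenario <- function(...) {
  scenario_params(
    Ne_parentA = 500, Ne_parentB = 500, Ne_hybrid = 500, Ne_ancestral = 500,
    T_parent_split = 2000, T_hybrid_origin = 350,
    n_per_pop = c(parentA = 12, parentB = 12, hybrid = 12),
    loci = tibble::tibble(
      name = c("mt1", "z1", "z2"),
      inheritance = c("mitochondrial", "z_linked", "z_linked"),
      length = c(500L, 500L, 500L)),
    ...)
}
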