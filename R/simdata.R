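# Synthetic data with the statistical structure the diagnostics assume: an
# old split between two parental species, a hybrid population founded later
# by admixture with subsequent immigration only INTO it, maternal and
# Z-linked inheritance with ZW females, dominant binary markers, laboratory
# F1/F2 crosses, and a very recent hybrid swarm with elevated LD.

POPS <- c("parentA", "parentB", "hybrid")

#' Demographic and mutational parameters for the hybrid-speciation simulator
#'
#' Times are in generations before sampling (1 generation = 1 year for these
#' essentially univoltine/bivoltine butterflies). The hybrid population is
#' founded at `T_hybrid_origin` by assigning each founding lineage to parent
#' A with probability `alpha` (maternal lineages use `alpha_maternal`), and
#' afterwards receives immigrants from the parents at per-generation
#' fractions `m_A_to_H` / `m_B_to_H`; migration into the parents is zero —
#' introgression is unidirectional, into the hybrid. `theta_per_locus` is the
#' per-locus population mutation rate, calibrated so that a panmictic
#' population of parent A's size has expected pairwise diversity equal to
#' theta for that locus's inheritance mode. Defaults are a desk-scale
#' scenario: Ne = 1,000, parental split at 4 Ne generations, hybrid origin at
#' 0.7 Ne, founding fraction 1/2 from each parent.
#'
#' @param Ne_parentA,Ne_parentB,Ne_hybrid,Ne_ancestral Effective sizes
#'   (diploid individuals).
#' @param T_parent_split,T_hybrid_origin Event times in generations;
#'   `T_hybrid_origin < T_parent_split`.
#' @param alpha Founding admixture fraction from parent A, in `[0, 1]`.
#' @param alpha_maternal Maternal (mtDNA/W) founding fraction from parent A;
#'   defaults to `alpha`.
#' @param m_A_to_H,m_B_to_H Per-generation immigrant fractions into the
#'   hybrid population (defaults scale 2Nm of 2.3 and 1.8 by 2 Ne).
#' @param theta_per_locus Per-locus population mutation rate.
#' @param loci Tibble with columns `name`, `inheritance`, `length`; default
#'   one mitochondrial locus plus six Z-linked loci.
#' @param n_per_pop Named vector of sample sizes (individuals) per
#'   population, names among `parentA`, `parentB`, `hybrid`.
#' @param seed Integer seed stored with the scenario.
#' @return An object of class `scenario_params`.
#' @export
scenario_params <- function(Ne_parentA = 1000, Ne_parentB = 1000,
                            Ne_hybrid = 1000, Ne_ancestral = 1000,
                            T_parent_split = 4000, T_hybrid_origin = 700,
                            alpha = 0.5, alpha_maternal = alpha,
                            m_A_to_H = 2.3 / (2 * Ne_hybrid),
                            m_B_to_H = 1.8 / (2 * Ne_hybrid),
                            theta_per_locus = 5,
                            loci = default_loci(),
                            n_per_pop = c(parentA = 20, parentB = 20, hybrid = 20),
                            seed = 1L) {
  if (T_parent_split <= 0 || T_hybrid_origin <= 0) {
    abort("event times must be positive.")
  }
  if (T_hybrid_origin >= T_parent_split) {
    abort("T_hybrid_origin must be younger than T_parent_split.")
  }
  if (alpha < 0 || alpha > 1 || alpha_maternal < 0 || alpha_maternal > 1) {
    abort("founding fractions must lie in [0, 1].")
  }
  if (m_A_to_H < 0 || m_B_to_H < 0) abort("migration fractions must be >= 0.")
  loci <- as_tibble(loci)
  stopifnot(all(c("name", "inheritance", "length") %in% names(loci)),
            all(loci$inheritance %in% INHERITANCE_MODES))
  if (!all(names(n_per_pop) %in% POPS)) {
    abort("n_per_pop names must be among parentA, parentB, hybrid.")
  }
  structure(
    list(Ne = c(parentA = Ne_parentA, parentB = Ne_parentB,
                hybrid = Ne_hybrid, ancestral = Ne_ancestral),
         T_parent_split = T_parent_split, T_hybrid_origin = T_hybrid_origin,
         alpha = alpha, alpha_maternal = alpha_maternal,
         m_A_to_H = m_A_to_H, m_B_to_H = m_B_to_H,
         theta_per_locus = theta_per_locus, loci = loci,
         n_per_pop = n_per_pop, seed = as.integer(seed)),
    class = "scenario_params"
  )
}

#' @rdname scenario_params
#' @export
default_loci <- function() {
  tibble(
    name = c("mt1", paste0("z", 1:6)),
    inheritance = c("mitochondrial", rep("z_linked", 6)),
    length = c(600L, rep(500L, 6))
  )
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<scenario_params> split %d, hybrid origin %d generations ago\n",
    "  Ne: A=%g B=%g H=%g; alpha=%.2f (maternal %.2f); m->H: A=%.2g B=%.2g\n",
    "  %d loci, theta=%g; samples: %s\n"),
    x$T_parent_split, x$T_hybrid_origin,
    x$Ne[["parentA"]], x$Ne[["parentB"]], x$Ne[["hybrid"]],
    x$alpha, x$alpha_maternal, x$m_A_to_H, x$m_B_to_H,
    nrow(x$loci), x$theta_per_locus,
    paste(names(x$n_per_pop), x$n_per_pop, sep = "=", collapse = " ")))
  invisible(x)
}

# sampled individuals: ids, populations, alternating sexes
scenario_samples <- function(params) {
  prefix <- c(parentA = "A", parentB = "B", hybrid = "H")
  list_rbind(imap(as.list(params$n_per_pop), function(n, pop) {
    tibble(sample_id = sprintf("%s%02d", prefix[[pop]], seq_len(n)),
           population = pop,
           sex = rep(c("F", "M"), length.out = n))
  }))
}

# gene copies per deme for an inheritance mode (haploid copy numbers)
copy_number <- function(Ne, inheritance) {
  switch(inheritance,
         autosomal = 2 * Ne,
         z_linked = 1.5 * Ne,   # (3/4) * 2Ne: males two Z, females one
         mitochondrial = Ne / 2 # transmitted by females only
  )
}

# copies carried by one sampled individual
copies_per_individual <- function(sex, inheritance) {
  switch(inheritance,
         autosomal = 2L,
         z_linked = if (sex == "M") 2L else 1L,
         mitochondrial = 1L)
}

# Structured coalescent for one locus. Demes: parentA, parentB, hybrid.
# Backward in time: hybrid lineages migrate into a parent at the immigration
# fraction; at T_hybrid_origin remaining hybrid lineages are assigned to a
# parent by the founding fraction; at T_parent_split everything merges into
# the ancestral deme. Returns an edge table plus tip metadata.
make_tips <- function(samples, inheritance) {
  k <- vapply(samples$sex, copies_per_individual, integer(1L),
              inheritance = inheritance)
  idx <- rep(seq_len(nrow(samples)), k)
  allele <- sequence(k)
  tibble(
    copy_id = ifelse(k[idx] == 1L, samples$sample_id[idx],
                     paste0(samples$sample_id[idx], "_a", allele)),
    sample_id = samples$sample_id[idx],
    population = samples$population[idx],
    sex = samples$sex[idx],
    allele_index = allele)
}

sim_genealogy <- function(params, inheritance, samples,
                          tips = make_tips(samples, inheritance)) {
  founding_alpha <- if (inheritance == "mitochondrial") {
    params$alpha_maternal
  } else {
    params$alpha
  }
  n_tip <- nrow(tips)
  if (n_tip < 2L) abort("need at least two sampled gene copies.")

  deme <- match(tips$population, POPS)       # 1=A, 2=B, 3=H, 4=ancestral
  node <- seq_len(n_tip)
  node_time <- numeric(n_tip)
  parent <- integer(0)
  child <- integer(0)
  next_node <- n_tip
  sizes <- c(copy_number(params$Ne[["parentA"]], inheritance),
             copy_number(params$Ne[["parentB"]], inheritance),
             copy_number(params$Ne[["hybrid"]], inheritance),
             copy_number(params$Ne[["ancestral"]], inheritance))
  m_tot <- params$m_A_to_H + params$m_B_to_H

  t <- 0
  repeat {
    if (length(node) == 1L) break
    k <- tabulate(deme, nbins = 4L)
    coal_rate <- k * (k - 1) / 2 / sizes
    mig_rate <- if (t < params$T_hybrid_origin) k[3L] * m_tot else 0
    total <- sum(coal_rate) + mig_rate
    wait <- if (total > 0) rexp(1L, total) else Inf
    t_next <- t + wait

    if (t < params$T_hybrid_origin && t_next >= params$T_hybrid_origin) {
      # hybrid founding (backward): assign each hybrid lineage to a parent
      t <- params$T_hybrid_origin
      in_h <- deme == 3L
      deme[in_h] <- ifelse(runif(sum(in_h)) < founding_alpha, 1L, 2L)
      next
    }
    if (t < params$T_parent_split && t_next >= params$T_parent_split) {
      t <- params$T_parent_split
      deme[] <- 4L
      next
    }
    t <- t_next
    u <- runif(1L) * total
    if (u < mig_rate) {
      i <- sample(which(deme == 3L), 1L)
      deme[i] <- if (runif(1L) < params$m_A_to_H / m_tot) 1L else 2L
    } else {
      u <- u - mig_rate
      d <- which(cumsum(coal_rate) >= u)[1L]
      idx <- which(deme == d)
      pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
      next_node <- next_node + 1L
      parent <- c(parent, next_node, next_node)
      child <- c(child, node[pair])
      node_time[next_node] <- t
      node <- c(node[-pair], next_node)
      deme <- c(deme[-pair], d)
    }
  }

  edges <- tibble(parent = parent, child = child,
                  length = node_time[parent] - node_time[child])
  list(tips = tips, edges = edges, n_tip = n_tip,
       n_node = next_node, node_time = node_time)
}

# tip descendants of every node (list indexed by node id)
node_descendants <- function(gen) {
  desc <- vector("list", gen$n_node)
  for (i in seq_len(gen$n_tip)) desc[[i]] <- i
  ord <- order(gen$node_time[gen$edges$child])
  for (e in ord) {
    p <- gen$edges$parent[e]
    desc[[p]] <- c(desc[[p]], desc[[gen$edges$child[e]]])
  }
  desc
}

# drop infinite-sites mutations on a genealogy and build aligned sequences
mutate_sequences <- function(gen, mu, len, locus_name, inheritance) {
  n_mut <- rpois(nrow(gen$edges), mu * pmax(gen$edges$length, 0))
  total <- sum(n_mut)
  if (total > len) {
    abort(sprintf("locus '%s': %d mutations exceed %d sites; increase length or lower theta.",
                  locus_name, total, len))
  }
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, len, replace = TRUE)
  seqs <- matrix(rep(anc, each = gen$n_tip), nrow = gen$n_tip)
  if (total > 0) {
    sites <- sample.int(len, total)        # distinct: infinite-sites
    desc <- node_descendants(gen)
    edge_of <- rep(seq_len(nrow(gen$edges)), n_mut)
    for (i in seq_len(total)) {
      s <- sites[i]
      derived <- sample(setdiff(bases, anc[s]), 1L)
      tips <- desc[[gen$edges$child[edge_of[i]]]]
      seqs[tips, s] <- derived
    }
  }
  meta <- gen$tips
  aligned_locus(
    tibble(sequence_id = meta$copy_id, sample_id = meta$sample_id,
           population = meta$population, sex = meta$sex,
           allele_index = meta$allele_index,
           sequence = apply(seqs, 1, paste, collapse = "")),
    locus_name = locus_name, inheritance = inheritance)
}

#' Simulate aligned sequence loci under the hybrid-speciation scenario
#'
#' Each locus is an independent structured-coalescent genealogy with
#' infinite-sites mutation projected onto a finite sequence of the stated
#' length. Mitochondrial loci coalesce among `Ne/2` female-transmitted
#' copies; Z-linked loci among `1.5 Ne` copies with sampled males carrying
#' two and females one.
#'
#' @param params A [scenario_params()].
#' @param seed Integer seed; defaults to the scenario's.
#' @return Named list of [aligned_locus()] objects.
#' @export
simulate_sequences <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "scenario_params"))
  local_seed(seed)
  samples <- scenario_samples(params)
  out <- pmap(params$loci, function(name, inheritance, length) {
    gen <- sim_genealogy(params, inheritance, samples)
    mu <- params$theta_per_locus /
      (2 * copy_number(params$Ne[["parentA"]], inheritance))
    mutate_sequences(gen, mu, length, name, inheritance)
  })
  setNames(out, params$loci$name)
}

#' Simulate a dominant binary marker matrix
#'
#' Each marker is one biallelic autosomal locus: a diploid genealogy over all
#' sampled individuals receives exactly one mutation (placed on an edge with
#' probability proportional to its length, i.e. conditioned on segregating),
#' and the band is present iff the individual carries at least one presence
#' allele — the dominance that makes AFLP-style data informative only at the
#' band level. Which allele is the presence allele is random per marker.
#'
#' @param params A [scenario_params()].
#' @param n_markers Number of markers to simulate.
#' @param seed Integer seed.
#' @param filter_monomorphic Drop markers whose band state is fixed among
#'   the sampled individuals (default `TRUE`).
#' @return Marker tibble (`sample_id`, `population`, markers...) with the
#'   underlying presence-allele dosages in `attr(, "genotypes")`.
#' @export
simulate_aflp <- function(params, n_markers = 250, seed = params$seed,
                          filter_monomorphic = TRUE) {
  stopifnot(inherits(params, "scenario_params"))
  if (n_markers < 1) abort("n_markers must be >= 1.")
  local_seed(seed)
  samples <- scenario_samples(params)
  n_ind <- nrow(samples)
  tips <- make_tips(samples, "autosomal")
  geno <- matrix(0L, n_ind, n_markers,
                 dimnames = list(samples$sample_id,
                                 sprintf("M%04d", seq_len(n_markers))))
  for (mk in seq_len(n_markers)) {
    gen <- sim_genealogy(params, "autosomal", samples, tips = tips)
    e <- sample.int(nrow(gen$edges), 1L,
                    prob = pmax(gen$edges$length, .Machine$double.eps))
    desc <- node_descendants(gen)
    derived_tips <- desc[[gen$edges$child[e]]]
    derived_dose <- tabulate(match(gen$tips$sample_id[derived_tips],
                                   samples$sample_id), nbins = n_ind)
    geno[, mk] <- if (runif(1L) < 0.5) derived_dose else 2L - derived_dose
  }
  aflp <- bind_cols(samples[, c("sample_id", "population")],
                    as_tibble(geno >= 1L) * 1L)
  attr(aflp, "genotypes") <- geno
  if (filter_monomorphic) {
    keep <- aflp_marker_ids(filter_polymorphic(aflp))
    attr_g <- geno[, keep, drop = FALSE]
    aflp <- select(aflp, "sample_id", "population", all_of(keep))
    attr(aflp, "genotypes") <- attr_g
  }
  aflp
}

# one gamete per individual: for each marker pick one of the two alleles
gametes_from <- function(dose, rows) {
  # dose in {0,1,2}; heterozygotes transmit the presence allele w.p. 1/2
  d <- dose[rows, , drop = FALSE]
  (d == 2L) * 1L + (d == 1L) * matrix(rbinom(length(d), 1L, 0.5), nrow(d))
}

#' Simulate laboratory F1 / F2 crosses at unlinked dominant markers
#'
#' F1s take one gamete from a random parent-A individual and one from a
#' random parent-B individual. F2s unite two gametes drawn from the F1 pool;
#' markers assort independently (no linkage). At a marker fixed for presence
#' in A and absence in B every F1 shows the band, and the F2 band frequency
#' is the Mendelian 3/4.
#'
#' @param parentA_pool,parentB_pool Marker tibbles carrying a `genotypes`
#'   attribute (as produced by [simulate_aflp()]), or dosage matrices.
#' @param type `"F1"` or `"F2"`.
#' @param n Number of offspring.
#' @param seed Integer seed.
#' @return Marker tibble with `population` set to the cross type, plus a
#'   `genotypes` attribute.
#' @export
simulate_cross <- function(parentA_pool, parentB_pool, type = c("F1", "F2"),
                           n = 50, seed = NULL) {
  type <- match.arg(type)
  if (n <= 0) abort("n must be positive.")
  gA <- pool_genotypes(parentA_pool)
  gB <- pool_genotypes(parentB_pool)
  if (!identical(colnames(gA), colnames(gB))) {
    abort("parental pools must share the same markers.")
  }
  local_seed(seed)
  f1 <- gametes_from(gA, sample.int(nrow(gA), n, replace = TRUE)) +
    gametes_from(gB, sample.int(nrow(gB), n, replace = TRUE))
  dose <- if (type == "F1") {
    f1
  } else {
    gametes_from(f1, sample.int(n, n, replace = TRUE)) +
      gametes_from(f1, sample.int(n, n, replace = TRUE))
  }
  dimnames(dose) <- list(sprintf("%s%03d", type, seq_len(n)), colnames(gA))
  out <- bind_cols(
    tibble(sample_id = rownames(dose), population = type),
    as_tibble((dose >= 1L) * 1L))
  attr(out, "genotypes") <- dose
  out
}

pool_genotypes <- function(pool) {
  if (is.matrix(pool)) return(pool)
  g <- attr(pool, "genotypes")
  if (is.null(g)) abort("pool lacks a 'genotypes' attribute; use simulate_aflp() output.")
  g
}

#' Simulate a very recent hybrid swarm by forward-time random mating
#'
#' Founded from F1-like individuals (one gamete from each parental pool) and
#' propagated forward for `generations_since_contact` generations of random
#' mating at unlinked markers. Maternal lineages are drawn from parent B
#' only, mirroring a swarm arising from parent-B mothers, so all swarm mtDNA
#' ancestry is parent B. Admixture LD decays by half each generation at
#' unlinked markers, so one generation reproduces an F2 cross and hundreds of
#' generations approach the parental background.
#'
#' @param params A [scenario_params()] used to simulate the parental pools.
#' @param generations_since_contact Generations of random mating (>= 1).
#' @param n Swarm size (individuals per generation).
#' @param n_markers Markers to simulate in the parental pools.
#' @param seed Integer seed.
#' @return List with `aflp` (marker tibble + `genotypes` attribute) and
#'   `maternal` (tibble `sample_id`, `ancestry`, all `"parentB"`).
#' @export
simulate_recent_swarm <- function(params, generations_since_contact,
                                  n = 50, n_markers = 100,
                                  seed = params$seed) {
  stopifnot(inherits(params, "scenario_params"))
  if (generations_since_contact < 1) abort("generations_since_contact must be >= 1.")
  local_seed(seed)
  pools <- simulate_aflp(params, n_markers = n_markers, seed = NULL,
                         filter_monomorphic = FALSE)
  g <- attr(pools, "genotypes")
  gA <- g[pools$population == "parentA", , drop = FALSE]
  gB <- g[pools$population == "parentB", , drop = FALSE]
  # founding F1s: paternal gamete from A, maternal from B
  h_pat <- gametes_from(gA, sample.int(nrow(gA), n, replace = TRUE))
  h_mat <- gametes_from(gB, sample.int(nrow(gB), n, replace = TRUE))
  for (g_i in seq_len(generations_since_contact - 1L)) {
    mothers <- sample.int(n, n, replace = TRUE)
    fathers <- sample.int(n, n, replace = TRUE)
    dose <- h_pat + h_mat
    h_mat <- gametes_from(dose, mothers)
    h_pat <- gametes_from(dose, fathers)
  }
  dose <- h_pat + h_mat
  dimnames(dose) <- list(sprintf("SW%03d", seq_len(n)), colnames(g))
  aflp <- bind_cols(
    tibble(sample_id = rownames(dose), population = "swarm"),
    as_tibble((dose >= 1L) * 1L))
  attr(aflp, "genotypes") <- dose
  list(aflp = aflp,
       maternal = tibble(sample_id = rownames(dose), ancestry = "parentB"))
}

#' Simulate a complete dataset (sequence loci + marker matrix)
#'
#' @param params A [scenario_params()].
#' @param n_markers Markers for the binary matrix.
#' @param seed Integer seed.
#' @return List with `loci`, `aflp`, `samples` and the `params` used.
#' @export
simulate_dataset <- function(params, n_markers = 250, seed = params$seed) {
  list(
    loci = simulate_sequences(params, seed = substream_seed(seed, "seq")),
    aflp = simulate_aflp(params, n_markers = n_markers,
                         seed = substream_seed(seed, "aflp")),
    samples = scenario_samples(params),
    params = params
  )
}
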