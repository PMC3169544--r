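# Distance-based phylogeny for dominant marker data — there is no substitution
# model for anonymous band characters, so mean character difference feeds
# neighbor joining — plus column-resampled bootstrap supports and Fitch
# parsimony mapping of binary ecological traits on the rooted backbone.

#' Pairwise distances from a binary marker matrix
#'
#' `mean_character_difference` is the fraction of compared markers at which
#' two individuals differ; `jaccard` ignores shared band absence. Missing
#' values are deleted pairwise.
#'
#' @param aflp Marker tibble or 0/1 matrix with row names.
#' @param metric `"mean_character_difference"` (default) or `"jaccard"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
binary_distance <- function(aflp, metric = c("mean_character_difference", "jaccard")) {
  metric <- match.arg(metric)
  m <- if (is.data.frame(aflp)) aflp_band_matrix(aflp) else aflp
  n <- nrow(m)
  if (n < 3L) abort("need at least 3 individuals.")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      cmp <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (metric == "jaccard") cmp <- cmp & (m[i, ] == 1L | m[j, ] == 1L)
      if (!any(cmp)) {
        abort(sprintf("no comparable markers between '%s' and '%s'.",
                      rownames(m)[i] %||% i, rownames(m)[j] %||% j))
      }
      d[i, j] <- d[j, i] <- sum(m[i, cmp] != m[j, cmp]) / sum(cmp)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration (via `ape::nj`), which recovers any additive
#' distance matrix exactly. Negative branch lengths — an artifact of
#' non-additive noise — are clamped to zero with the deficit moved to the
#' sibling edge so path lengths are preserved as far as possible; clamped
#' edges are flagged in `attr(, "clamped_edges")`.
#'
#' @param D Symmetric distance matrix over >= 4 taxa (no `NA`/`NaN`).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D)) || any(!is.finite(D))) abort("distance matrix contains NA/NaN.")
  if (nrow(D) < 4L) abort("need at least 4 taxa.")
  tree <- ape::nj(as.dist(D))
  clamped <- integer(0)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    sibs <- which(tree$edge[, 1L] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      tree$edge.length[sibs[1L]] <- tree$edge.length[sibs[1L]] + deficit
    }
    clamped <- c(clamped, e)
  }
  attr(tree, "clamped_edges") <- clamped
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples marker columns with replacement, rebuilds the NJ tree each
#' time, and reports for each internal edge of the original tree the
#' percentage of pseudo-replicate trees containing the same bipartition.
#'
#' @param aflp Marker tibble or 0/1 matrix.
#' @param n_reps Number of pseudo-replicates (published analyses commonly
#'   use 2,000; scale down for interactive work).
#' @param seed Integer seed.
#' @param metric Distance metric, see [binary_distance()].
#' @return The NJ `phylo` tree with `node.label` holding support
#'   percentages (root label `NA`).
#' @export
bootstrap_support <- function(aflp, n_reps = 2000, seed = NULL,
                              metric = "mean_character_difference") {
  if (n_reps < 1) abort("n_reps must be >= 1.")
  m <- if (is.data.frame(aflp)) aflp_band_matrix(aflp) else aflp
  local_seed(seed)
  main <- neighbor_joining(binary_distance(m, metric = metric))
  reps <- map(seq_len(n_reps), function(r) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    neighbor_joining(binary_distance(m[, cols, drop = FALSE], metric = metric))
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- round(100 * counts / n_reps, 1)
  main$node.label[1L] <- NA  # root of the unrooted representation
  main
}

# Minimal-change (Fitch) reconstruction of one binary trait on a rooted
# tree, via the unit-cost dynamic program: down[v,s] is the minimal number
# of changes in v's subtree with v in state s; up[v,s] the minimum in the
# rest of the tree. A tip with NA contributes 0 for either state. The
# minimal change count is min_s down[root,s], and the MPR set of a node is
# every state whose down + up cost attains that minimum.
fitch_binary_dp <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  down <- matrix(0, n_node, 2L)    # columns: state 0, state 1
  for (i in seq_len(n_tip)) {
    s <- states[tree$tip.label[i]]
    if (!is.na(s)) down[i, ] <- ifelse(c(0L, 1L) == s, 0, Inf)
  }
  # postorder lists descendant edges before ancestral ones, so taking the
  # first occurrence of each parent gives internal nodes children-first
  post <- unique(tree$edge[ape::postorder(tree), 1L])
  for (v in post) {
    for (s in 1:2) {
      down[v, s] <- sum(map_dbl(kids[[as.character(v)]], function(ch) {
        min(down[ch, s], down[ch, 3L - s] + 1)
      }))
    }
  }
  up <- matrix(0, n_node, 2L)
  for (p in rev(post)) {  # parents-first
    ch_all <- kids[[as.character(p)]]
    for (v in ch_all) {
      sib_cost <- function(s_p) {
        sum(map_dbl(setdiff(ch_all, v), function(c2) {
          min(down[c2, s_p], down[c2, 3L - s_p] + 1)
        }))
      }
      for (s in 1:2) {
        up[v, s] <- min(up[p, 1L] + sib_cost(1L) + (s != 1L),
                        up[p, 2L] + sib_cost(2L) + (s != 2L))
      }
    }
  }
  total <- down + up
  best <- min(down[root, ])
  sets <- map(seq_len(n_node), function(v) {
    c(0L, 1L)[which(total[v, ] <= best + 1e-9)]
  })
  list(sets = sets, changes = as.integer(best))
}

#' Fitch parsimony mapping of binary traits on a rooted tree
#'
#' Roots the tree at the declared outgroup (the NJ tree itself stays
#' unrooted), runs the Fitch bottom-up pass per trait for the minimal
#' change count, and a top-down pass for the most-parsimonious (MPR) state
#' sets. Edges are reported as certain changes when parent and child MPR
#' sets are disjoint, and as ambiguous when reconstructions disagree — e.g.
#' a trait present in two distantly related tips can equally be two gains
#' or one gain plus a loss, and the full set of reconstructions is kept. A
#' putative hybrid taxon does not belong on a bifurcating species tree, so
#' it can be excluded from the pass and reported post hoc next to the
#' reconstruction.
#'
#' @param tree A `phylo` tree containing `outgroup`.
#' @param traits Trait tibble (`taxon`, then 0/1/NA trait columns).
#' @param outgroup Taxon to root on.
#' @param hybrid_taxon Optional taxon dropped from the pass and reported
#'   separately.
#' @return Tibble of class `fitch_map`: `trait`, `n_changes`,
#'   `certain_change_edges` / `ambiguous_edges` (list columns of
#'   parent-child label pairs), `hybrid_state`. Node MPR sets are in
#'   `attr(, "node_states")`; the rooted tree in `attr(, "tree")`.
#' @export
fitch_map <- function(tree, traits, outgroup, hybrid_taxon = NULL) {
  stopifnot("taxon" %in% names(traits))
  if (!outgroup %in% tree$tip.label) abort("outgroup not in tree.")
  work <- tree
  if (!is.null(hybrid_taxon) && hybrid_taxon %in% work$tip.label) {
    work <- ape::drop.tip(work, hybrid_taxon)
  }
  work <- ape::root(work, outgroup, resolve.root = TRUE)
  n_tip <- length(work$tip.label)
  missing_taxa <- setdiff(work$tip.label, traits$taxon)
  if (length(missing_taxa)) {
    abort(paste0("traits missing for: ", paste(missing_taxa, collapse = ", ")))
  }
  trait_cols <- setdiff(names(traits), "taxon")
  node_states <- list()
  rows <- map(trait_cols, function(tr) {
    states <- setNames(traits[[tr]], traits$taxon)[work$tip.label]
    if (all(is.na(states))) {
      warn(sprintf("trait '%s' unknown at every tip; skipped.", tr))
      return(NULL)
    }
    pass <- fitch_binary_dp(work, states)
    final <- pass$sets
    node_states[[tr]] <<- final
    labs <- c(work$tip.label, paste0("node", (n_tip + 1L):(n_tip + work$Nnode)))
    edge_tbl <- tibble(parent = labs[work$edge[, 1L]],
                       child = labs[work$edge[, 2L]],
                       disjoint = map_lgl(seq_len(nrow(work$edge)), function(e) {
                         length(intersect(final[[work$edge[e, 1L]]],
                                          final[[work$edge[e, 2L]]])) == 0L
                       }),
                       possible = map_lgl(seq_len(nrow(work$edge)), function(e) {
                         !setequal(final[[work$edge[e, 1L]]],
                                   final[[work$edge[e, 2L]]]) ||
                           length(final[[work$edge[e, 1L]]]) > 1L
                       }))
    hyb <- if (!is.null(hybrid_taxon) && hybrid_taxon %in% traits$taxon) {
      traits[[tr]][traits$taxon == hybrid_taxon]
    } else NA
    tibble(trait = tr, n_changes = pass$changes,
           certain_change_edges = list(filter(edge_tbl, .data$disjoint)),
           ambiguous_edges = list(filter(edge_tbl, !.data$disjoint & .data$possible)),
           hybrid_state = hyb)
  })
  out <- list_rbind(rows)
  attr(out, "node_states") <- node_states
  attr(out, "tree") <- work
  class(out) <- c("fitch_map", class(out))
  out
}
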