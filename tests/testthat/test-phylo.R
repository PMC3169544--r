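test_that("binary distances match direct per-pair counting", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  d <- binary_distance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)      # all four characters differ

  withr::local_seed(59)
  m2 <- matrix(rbinom(6 * 20, 1, 0.5), 6, 20,
               dimnames = list(paste0("t", 1:6), NULL))
  m2[sample(length(m2), 10)] <- NA
  d2 <- binary_distance(m2)
  for (i in 1:5) for (j in (i + 1):6) {
    cmp <- !is.na(m2[i, ]) & !is.na(m2[j, ])
    expect_equal(d2[i, j], sum(m2[i, cmp] != m2[j, cmp]) / sum(cmp),
                 tolerance = 1e-12)
  }
  expect_error(binary_distance(m2[1:2, ]), "at least 3")
})

test_that("neighbor joining recovers additive matrices exactly", {
  # hand additive tree ((A:1,B:2):1,(C:3,D:1))
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 4
  D["C", "D"] <- D["D", "C"] <- 4
  tr <- neighbor_joining(D)
  expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D, tolerance = 1e-9)
  # AB|CD is the internal bipartition
  parts <- ape::prop.part(ape::unroot(tr))
  expect_true(any(vapply(parts, function(p) {
    setequal(tr$tip.label[p], c("A", "B")) || setequal(tr$tip.label[p], c("C", "D"))
  }, logical(1))))

  withr::local_seed(61)
  for (rep in 1:20) {
    ra <- random_additive(sample(4:8, 1))
    rec <- neighbor_joining(ra$D)
    expect_equal(cophenetic(rec)[rownames(ra$D), colnames(ra$D)], ra$D,
                 tolerance = 1e-9)
  }
  bad <- D; bad[1, 2] <- NaN
  expect_error(neighbor_joining(bad), "NaN")
})

test_that("star-like equal distances give zero internal branch length", {
  D <- matrix(2, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_equal(max(abs(tr$edge.length[internal])), 0, tolerance = 1e-9)
})

test_that("fixed clade differences earn full bootstrap support", {
  bands <- rbind(matrix(1L, 4, 30), matrix(0L, 4, 30))
  rownames(bands) <- paste0("t", 1:8)
  withr::local_seed(67)
  noise <- matrix(rbinom(8 * 10, 1, 0.5), 8, 10)
  m <- cbind(bands, noise)
  colnames(m) <- paste0("M", seq_len(ncol(m)))
  tr <- bootstrap_support(m, n_reps = 100, seed = 3)
  # the clade side of the 4|4 split must carry 100% support
  clade_node <- ape::getMRCA(tr, paste0("t", 1:4))
  if (is.null(clade_node) || clade_node == length(tr$tip.label) + 1L) {
    clade_node <- ape::getMRCA(tr, paste0("t", 5:8))
  }
  support <- tr$node.label[clade_node - length(tr$tip.label)]
  expect_equal(as.numeric(support), 100)

  one <- bootstrap_support(m, n_reps = 1, seed = 4)
  sup <- as.numeric(one$node.label)
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("bootstrap support tracks the marker-inclusion probability", {
  # one informative marker among uninformative constants: the split is
  # recovered exactly when the marker enters the resample, so expected
  # support is 1 - (1 - 1/L)^L plus the (deterministic) fallback when the
  # resample carries no signal
  L <- 60
  m <- cbind(c(rep(1L, 3), rep(0L, 3)), matrix(1L, 6, L - 1))
  rownames(m) <- paste0("t", 1:6)
  colnames(m) <- paste0("M", 1:L)
  split_in <- function(tree) {
    any(vapply(ape::prop.part(ape::unroot(tree)), function(p) {
      setequal(tree$tip.label[p], paste0("t", 1:3)) ||
        setequal(tree$tip.label[p], paste0("t", 4:6))
    }, logical(1)))
  }
  # fallback topology for an all-zero distance matrix
  flat <- matrix(0, 6, 6, dimnames = list(rownames(m), rownames(m)))
  fallback <- split_in(neighbor_joining(flat + 1e-12))
  p_incl <- 1 - (1 - 1 / L)^L
  expected <- p_incl + (1 - p_incl) * as.numeric(fallback)
  n_reps <- 400
  tr <- bootstrap_support(m, n_reps = n_reps, seed = 5)
  clade_node <- ape::getMRCA(tr, paste0("t", 1:3))
  if (is.null(clade_node) || clade_node == length(tr$tip.label) + 1L) {
    clade_node <- ape::getMRCA(tr, paste0("t", 4:6))
  }
  support <- as.numeric(tr$node.label[clade_node - length(tr$tip.label)]) / 100
  se <- sqrt(expected * (1 - expected) / n_reps)
  expect_lt(abs(support - expected), 4 * max(se, 0.01))
})

test_that("trait mapping finds single gains and handles the post-hoc hybrid", {
  tree <- ape::read.tree(text = "((glaucus:1,canadensis:1):1,(rutulus:1,eurymedon:1):1,garamas:2);")
  traits <- tibble::tibble(
    taxon = c("glaucus", "canadensis", "rutulus", "eurymedon", "garamas",
              "appalachiensis"),
    diapause = c(0, 1, 0, 0, 0, 1),
    univoltine = c(0, 1, 0, 0, 0, 1),
    everywhere = c(1, 1, 1, 1, 1, 1))
  res <- fitch_map(tree, traits, outgroup = "garamas",
                   hybrid_taxon = "appalachiensis")
  dia <- dplyr::filter(res, trait == "diapause")
  expect_equal(dia$n_changes, 1L)
  edges <- dia$certain_change_edges[[1]]
  expect_equal(edges$child, "canadensis")   # gain on the terminal branch
  expect_equal(dia$hybrid_state, 1)
  expect_equal(dplyr::filter(res, trait == "everywhere")$n_changes, 0L)
})

test_that("minimal change counts equal exhaustive minimisation on small trees", {
  withr::local_seed(71)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    states <- sample(c(0L, 1L, NA), n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1))
    if (all(is.na(states)) || length(unique(stats::na.omit(states))) == 0) next
    names(states) <- tree$tip.label
    traits <- tibble::tibble(taxon = tree$tip.label, tr = unname(states))
    out <- tryCatch(
      fitch_map(tree, traits, outgroup = tree$tip.label[1]),
      warning = function(w) NULL)
    if (is.null(out)) next
    rooted <- attr(out, "tree")
    expect_equal(out$n_changes,
                 oracle_fitch(rooted, states))
  }
})

test_that("our change counts agree with phangorn's Fitch score", {
  skip_if_not_installed("phangorn")
  withr::local_seed(73)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    tree <- ape::rtree(n)
    states <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(states)) < 2) next
    names(states) <- tree$tip.label
    traits <- tibble::tibble(taxon = tree$tip.label, tr = unname(states))
    out <- fitch_map(tree, traits, outgroup = tree$tip.label[1])
    dat <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(out$n_changes, phangorn::fitch(attr(out, "tree"), dat))
  }
})
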