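make_aflp <- function(freqs, n_per_pop = 20, seed = 1) {
  # freqs: named list population -> vector of band frequencies per marker
  withr::local_seed(seed)
  rows <- lapply(names(freqs), function(pop) {
    bands <- vapply(freqs[[pop]],
                    function(f) rbinom(n_per_pop, 1, f), integer(n_per_pop))
    colnames(bands) <- sprintf("M%03d", seq_along(freqs[[pop]]))
    dplyr::bind_cols(
      tibble::tibble(sample_id = paste0(pop, seq_len(n_per_pop)),
                     population = pop),
      tibble::as_tibble(bands))
  })
  dplyr::bind_rows(rows)
}

exact_freq_column <- function(f, n) c(rep(1L, round(f * n)), rep(0L, n - round(f * n)))

test_that("the ancestry-informative screen keeps differentiated markers only", {
  aflp <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("a", 1:20), population = "parentA",
                   M1 = 1L, M2 = exact_freq_column(0.5, 20)),
    tibble::tibble(sample_id = paste0("b", 1:20), population = "parentB",
                   M1 = 0L, M2 = exact_freq_column(0.5, 20)))
  res <- select_informative(aflp, "parentA", "parentB", alpha = 0.05,
                            n_perm = 199, seed = 4)
  expect_equal(res$marker_id, c("M1", "M2"))
  expect_true(res$selected[res$marker_id == "M1"])
  expect_false(res$selected[res$marker_id == "M2"])
})

test_that("the screen's type-I error matches its nominal level on null markers", {
  # identical band frequencies in both parents: ~5% of markers selected
  aflp <- make_aflp(list(parentA = rep(0.5, 200), parentB = rep(0.5, 200)),
                    n_per_pop = 20, seed = 99)
  res <- select_informative(aflp, "parentA", "parentB", alpha = 0.05,
                            n_perm = 199, seed = 7)
  frac <- mean(res$selected, na.rm = TRUE)
  # binomial 3-sigma band around 0.05 with 200 markers (~0.046 half-width)
  expect_gt(frac, 0.003)
  expect_lt(frac, 0.11)
})

test_that("four-way marker classification follows significance and frequency rules", {
  n <- 40
  aflp <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("a", 1:n), population = "parentA",
                   Ma = exact_freq_column(0.9, n),
                   Mi = exact_freq_column(0.1, n),
                   Md = exact_freq_column(0.5, n)),
    tibble::tibble(sample_id = paste0("b", 1:n), population = "parentB",
                   Ma = exact_freq_column(0.1, n),
                   Mi = exact_freq_column(0.9, n),
                   Md = exact_freq_column(0.05, n)),
    tibble::tibble(sample_id = paste0("h", 1:n), population = "hybrid",
                   Ma = exact_freq_column(0.9, n),
                   Mi = exact_freq_column(0.5, n),
                   Md = exact_freq_column(0.95, n)))
  res <- classify_markers(aflp, "hybrid", "parentA", "parentB", alpha = 0.05,
                          markers = c("Ma", "Mi", "Md"), n_perm = 399, seed = 5)
  expect_equal(res$category[res$marker_id == "Ma"], "parentA_like")
  expect_equal(res$category[res$marker_id == "Md"], "different")
  # hybrid frequency between the parents, neither contrast significant at
  # n = 15 per group: intermediate
  n15 <- 15
  mid <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("a", 1:n15), population = "parentA",
                   Mi = exact_freq_column(0.3, n15)),
    tibble::tibble(sample_id = paste0("b", 1:n15), population = "parentB",
                   Mi = exact_freq_column(0.7, n15)),
    tibble::tibble(sample_id = paste0("h", 1:n15), population = "hybrid",
                   Mi = exact_freq_column(0.5, n15)))
  res15 <- classify_markers(mid, "hybrid", "parentA", "parentB",
                            alpha = 0.05, markers = "Mi", n_perm = 399, seed = 5)
  expect_equal(res15$category, "intermediate")
})

test_that("swapping parent labels mirrors the classification", {
  aflp <- make_aflp(list(parentA = c(0.95, 0.1, 0.5),
                         parentB = c(0.05, 0.9, 0.5),
                         hybrid = c(0.9, 0.5, 0.9)), n_per_pop = 25, seed = 3)
  fwd <- classify_markers(aflp, "hybrid", "parentA", "parentB",
                          markers = paste0("M00", 1:3), n_perm = 199, seed = 8)
  rev <- classify_markers(aflp, "hybrid", "parentB", "parentA",
                          markers = paste0("M00", 1:3), n_perm = 199, seed = 8)
  swap <- c(parentA_like = "parentB_like", parentB_like = "parentA_like",
            intermediate = "intermediate", different = "different",
            outside_nonsignificant = "outside_nonsignificant")
  expect_equal(unname(swap[fwd$category]), rev$category)
  # counts sum to the classified marker count, flags reported separately
  counts <- classification_counts(fwd)
  expect_equal(sum(counts$n[counts$category != "outside_nonsignificant_flagged"]),
               nrow(fwd))
})

test_that("sequence genotype classification codes ancestry, heterozygotes and missing", {
  # mtDNA: parental fixed difference, hybrid carries the parent-A base
  mito <- toy_locus(
    c(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA", a4 = "AAAA", a5 = "AAAA", a6 = "AAAA",
      b1 = "AATA", b2 = "AATA", b3 = "AATA", b4 = "AATA", b5 = "AATA", b6 = "AATA",
      h1 = "AAAA", h2 = "AATA"),
    inheritance = "mitochondrial", locus = "mt1",
    populations = rep(c("parentA", "parentB", "hybrid"), c(6, 6, 2)))
  # Z locus: male h1 carries one haplotype of each parental class
  zl <- toy_locus(
    c(a1 = "CCCC", a2 = "CCCC", a3 = "CCCC", a4 = "CCCC", a5 = "CCCC", a6 = "CCCC",
      b1 = "CGCC", b2 = "CGCC", b3 = "CGCC", b4 = "CGCC", b5 = "CGCC", b6 = "CGCC",
      h1_1 = "CCCC", h1_2 = "CGCC"),
    inheritance = "z_linked", locus = "z1",
    populations = rep(c("parentA", "parentB", "hybrid"), c(6, 6, 2)),
    samples = c(paste0("a", 1:6), paste0("b", 1:6), "h1", "h1"))
  tabs <- list(mt1 = extract_polymorphisms(mito), z1 = extract_polymorphisms(zl))
  res <- classify_sequence_genotypes(tabs, "parentA", "parentB", "hybrid",
                                     alpha = 0.05, n_perm = 399, seed = 6)
  expect_equal(res$call[res$locus == "mt1" & res$sample_id == "h1"], "A_like")
  expect_equal(res$call[res$locus == "mt1" & res$sample_id == "h2"], "B_like")
  expect_equal(res$call[res$locus == "z1" & res$sample_id == "h1"], "heterozygote")
  expect_equal(res$call[res$locus == "z1" & res$sample_id == "a1"], "A_like")
})

test_that("alleles absent from both parents are coded missing with a warning", {
  mito <- toy_locus(
    c(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA", a4 = "AAAA", a5 = "AAAA", a6 = "AAAA",
      b1 = "AATA", b2 = "AATA", b3 = "AATA", b4 = "AATA", b5 = "AATA", b6 = "AATA",
      h1 = "AAGA"),
    inheritance = "mitochondrial",
    populations = rep(c("parentA", "parentB", "hybrid"), c(6, 6, 1)))
  tabs <- list(mt1 = extract_polymorphisms(mito))
  expect_warning(
    res <- classify_sequence_genotypes(tabs, "parentA", "parentB", "hybrid",
                                       alpha = 0.05, n_perm = 399, seed = 6),
    "neither parent")
  expect_equal(res$call[res$sample_id == "h1"], "missing")
})

test_that("high parental-ancestry sites come back uniformly one-parental in simulation", {
  p <- mosaic_scenario(seed = 31L)
  loci <- simulate_sequences(p, seed = 31)
  tabs <- lapply(loci["mt1"], extract_polymorphisms)
  res <- classify_sequence_genotypes(tabs, "parentA", "parentB", "hybrid",
                                     alpha = 0.05, n_perm = 399, seed = 9)
  # every hybrid maternal lineage descends from parent A, so A-like calls
  # dominate (sample-level "diagnostic" alleles can still miscode a
  # minority of lineages that coalesce deeper than the parental sample)
  hyb <- dplyr::filter(res, population == "hybrid", call != "missing")
  expect_gt(nrow(hyb), 0)
  expect_gt(mean(hyb$call == "A_like"), 0.75)
  # and the locus-level fixation indices show the forced asymmetry
  m <- pairwise_fst(tabs[[1]])
  expect_lt(m["hybrid", "parentA"], 0.25)
  expect_gt(m["hybrid", "parentB"], 0.6)
})
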