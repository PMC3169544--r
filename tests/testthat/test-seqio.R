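test_that("FASTA alignments parse with metadata and survive a round trip", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">s1|parentA|F|1", "ACGT-ACGTA",
    ">s2|parentA|M|1", "ACGTTACGTA",
    ">s3|parentB|F|1", "ACGTTACGTC"), path)
  loc <- read_fasta_alignment(path, inheritance = "z_linked")
  expect_s3_class(loc, "aligned_locus")
  expect_equal(nrow(loc$seqs), 3L)
  expect_equal(loc$alignment_length, 10L)
  expect_equal(loc$seqs$population, c("parentA", "parentA", "parentB"))
  expect_equal(loc$seqs$sex, c("F", "M", "F"))
  # gaps preserved verbatim
  expect_equal(loc$seqs$sequence[1], "ACGT-ACGTA")

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(loc, out)
  back <- read_fasta_alignment(out, inheritance = "z_linked",
                               locus_name = loc$locus_name)
  expect_equal(back$seqs$sequence, loc$seqs$sequence)
  expect_equal(back$seqs$sample_id, loc$seqs$sample_id)
})

test_that("ragged and empty FASTA inputs fail loudly", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|p|F|1", "ACGTACGTAC", ">b|p|F|1", "ACGTACGTA"), path)
  expect_error(read_fasta_alignment(path, "autosomal"), "ragged.*'b")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta_alignment(empty, "autosomal"), "empty")
})

test_that("mitochondrial loci refuse duplicate sample sequences", {
  expect_error(
    toy_locus(c(a = "ACGT", a2 = "ACGT"), inheritance = "mitochondrial",
              samples = c("a", "a")),
    "more than one sequence")
})

test_that("heterozygous male expansion adds one record per listed male", {
  seqs <- setNames(strrep("A", 8) |> rep(20), sprintf("m%02d", 1:20))
  loc <- toy_locus(seqs, sexes = rep(c("M", "F"), 10))
  out <- expand_heterozygous_males(loc, list(
    m01 = c("AAAAAAAA", "AAAAAAAC"),
    m03 = c("AAAAAAAA", "AAAAAAAG")))
  expect_equal(nrow(out$seqs), 22L)             # 20 samples, 2 het males
  expect_equal(sum(out$seqs$sample_id == "m01"), 2L)
  expect_equal(out$seqs$allele_index[out$seqs$sample_id == "m01"], 1:2)

  one <- expand_heterozygous_males(loc, list(m05 = c(strrep("A", 8), strrep("C", 8))))
  expect_equal(nrow(one$seqs), 21L)
  expect_identical(expand_heterozygous_males(loc, list()), loc)
})

test_that("phased pairs for females or non-Z loci are inheritance violations", {
  loc <- toy_locus(c(f1 = "ACGT", m1 = "ACGT"), sexes = c("F", "M"))
  expect_error(expand_heterozygous_males(loc, list(f1 = c("ACGT", "ACGA"))),
               "female")
  mito <- toy_locus(c(a = "ACGT", b = "ACGT"), inheritance = "mitochondrial")
  expect_error(expand_heterozygous_males(mito, list(a = c("ACGT", "ACGA"))),
               "z_linked")
})

test_that("polymorphism extraction scores SNPs per column and indel events once", {
  # identical sequences: no sites
  same <- toy_locus(rep("ACGTACGT", 4) |> setNames(paste0("s", 1:4)))
  expect_equal(nrow(extract_polymorphisms(same)$sites), 0L)

  # one SNP column + one 3-bp deletion shared by two sequences -> 2 sites
  loc <- toy_locus(c(s1 = "ACGTACGTAA", s2 = "ACGTACGTAA",
                     s3 = "ACG---GTAC", s4 = "ACG---GTAC"))
  pt <- extract_polymorphisms(loc)
  expect_equal(sort(unique(pt$sites$kind)), c("indel", "snp"))
  expect_equal(nrow(pt$sites), 2L)
  expect_equal(pt$sites$end[pt$sites$kind == "indel"] -
                 pt$sites$start[pt$sites$kind == "indel"], 3L)

  # adjacent gap columns from a single deletion event stay one site
  loc2 <- toy_locus(c(s1 = "AC--GT", s2 = "ACTTGT", s3 = "ACTTGT"))
  pt2 <- extract_polymorphisms(loc2)
  expect_equal(sum(pt2$sites$kind == "indel"), 1L)

  # but gap runs in different sequence sets are distinct events
  loc3 <- toy_locus(c(s1 = "A--TGT", s2 = "AC--GT", s3 = "ACTTGT"))
  pt3 <- extract_polymorphisms(loc3)
  expect_equal(sum(pt3$sites$kind == "indel"), 3L)
})

test_that("site counts match a brute-force column scanner on random alignments", {
  withr::local_seed(42)
  for (rep in 1:100) {
    seqs <- random_alignment(n_seq = sample(3:6, 1), len = 30)
    names(seqs) <- paste0("s", seq_along(seqs))
    pt <- extract_polymorphisms(toy_locus(seqs))
    expected <- brute_site_count(seqs)
    expect_equal(sum(pt$sites$kind == "snp"), unname(expected["snp"]))
    expect_equal(sum(pt$sites$kind == "indel"), unname(expected["indel"]))
  }
})

test_that("marker matrices and population maps round-trip and validate", {
  aflp <- tibble::tibble(
    sample_id = c("a", "b", "c"), population = c("p1", "p1", "p2"),
    M1 = c(0, 1, 1), M2 = c(1, 1, 0), M3 = c(0, NA, 1), M4 = c(1, 0, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_aflp_matrix(aflp, path)
  back <- read_aflp_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(aflp))

  bad <- aflp; bad$M2 <- c(1, 2, 0)
  write_aflp_matrix(bad, path)
  expect_error(read_aflp_matrix(path), "0, 1 or missing")

  map_path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(sample_id = c("a", "a"),
                                  population = "p1", sex = "F"), map_path)
  expect_error(read_population_map(map_path), "duplicate")

  readr::write_tsv(tibble::tibble(sample_id = c("a", "b"),
                                  population = "p1", sex = "F"), map_path)
  map <- read_population_map(map_path)
  expect_error(validate_population_map(c("a", "z"), map), "absent.*z")
  expect_true(validate_population_map(c("a", "b"), map))
})

test_that("Newick trees round-trip topology and branch lengths", {
  withr::local_seed(7)
  tr <- ape::unroot(ape::rtree(5))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(ape::dist.topo(tr, back)[1], 0)
  expect_equal(max(abs(cophenetic(back)[rownames(cophenetic(tr)),
                                        colnames(cophenetic(tr))] -
                         cophenetic(tr))), 0, tolerance = 1e-9)
})

test_that("monomorphic marker columns are filtered out", {
  aflp <- tibble::tibble(sample_id = c("a", "b"), population = "p",
                         M1 = c(1, 1), M2 = c(0, 1), M3 = c(NA, 0))
  kept <- filter_polymorphic(aflp)
  expect_equal(setdiff(names(kept), c("sample_id", "population")), "M2")
})
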