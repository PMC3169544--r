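# Readers/writers for the standard inputs (aligned FASTA loci, binary marker
# matrices, population maps, trait tables, Newick trees) and the polymorphism
# extraction step that turns an alignment into a site-by-sequence call table.

#' Construct an aligned locus
#'
#' An aligned locus bundles one gene's aligned sequences with per-sequence
#' metadata (sample, population, sex, allele index) and its inheritance mode.
#' Lepidopteran sex chromosomes motivate the three modes: males are ZZ and may
#' carry two distinct Z haplotypes, females are ZW and hemizygous for Z;
#' mitochondria (and the W, for which mtDNA is the proxy) are maternal.
#'
#' @param seqs A data frame with columns `sequence_id`, `sample_id`,
#'   `population`, `sex` (one of `"M"`, `"F"`, `"U"`), `allele_index`, and
#'   `sequence` (aligned bases including `-` gaps and `N` missing calls).
#' @param locus_name Locus label.
#' @param inheritance One of `"mitochondrial"`, `"z_linked"`, `"autosomal"`.
#' @return An object of class `aligned_locus`.
#' @export
aligned_locus <- function(seqs, locus_name, inheritance) {
  inheritance <- check_inheritance(inheritance)
  seqs <- as_tibble(seqs)
  required <- c("sequence_id", "sample_id", "population", "sex",
                "allele_index", "sequence")
  missing_cols <- setdiff(required, names(seqs))
  if (length(missing_cols)) {
    abort(paste0("aligned_locus seqs missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(seqs) == 0L) abort("empty alignment: no sequences.")
  lens <- nchar(seqs$sequence)
  if (length(unique(lens)) != 1L) {
    bad <- seqs$sequence_id[which(lens != lens[1L])[1L]]
    abort(sprintf("ragged alignment in locus '%s': record '%s' has length %d, expected %d.",
                  locus_name, bad, lens[lens != lens[1L]][1L], lens[1L]))
  }
  if (anyDuplicated(seqs$sequence_id)) {
    abort(sprintf("duplicate sequence_id in locus '%s'.", locus_name))
  }
  if (!all(seqs$sex %in% c("M", "F", "U"))) {
    abort("sex must be one of 'M', 'F', 'U'.")
  }
  if (inheritance == "mitochondrial" && anyDuplicated(seqs$sample_id)) {
    abort(sprintf("mitochondrial locus '%s' has more than one sequence for a sample.",
                  locus_name))
  }
  structure(
    list(locus_name = locus_name, inheritance = inheritance,
         seqs = seqs, alignment_length = lens[1L]),
    class = "aligned_locus"
  )
}

#' @export
print.aligned_locus <- function(x, ...) {
  cat(sprintf("<aligned_locus> %s (%s): %d sequences x %d columns\n",
              x$locus_name, x$inheritance, nrow(x$seqs), x$alignment_length))
  invisible(x)
}

parse_fasta_headers <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) < 1L)
  tibble(
    sequence_id = headers,
    sample_id = map_chr(parts, 1L),
    population = map_chr(parts, ~ if (length(.x) >= 2) .x[[2]] else "unknown"),
    sex = map_chr(parts, ~ if (length(.x) >= 3) toupper(.x[[3]]) else "U"),
    allele_index = map_int(parts, ~ if (length(.x) >= 4) as.integer(.x[[4]]) else 1L)
  )
}

#' Read an aligned FASTA locus
#'
#' Headers follow the pipe-delimited convention
#' `sampleID|population|sex|alleleIndex`; the last three fields may be
#' omitted and default to `unknown`, `U` and `1`. Gap (`-`) and missing (`N`)
#' symbols are preserved verbatim.
#'
#' @param path Path to a FASTA file holding one multiple alignment.
#' @param inheritance Inheritance mode of the locus.
#' @param locus_name Locus label; defaults to the file name without extension.
#' @return An [aligned_locus()].
#' @export
read_fasta_alignment <- function(path, inheritance, locus_name = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  locus_name <- locus_name %||% sub("\\.[^.]*$", "", basename(path))
  meta <- parse_fasta_headers(names(set))
  meta$sequence <- unname(toupper(as.character(set)))
  lens <- nchar(meta$sequence)
  if (length(unique(lens)) != 1L) {
    bad <- names(set)[which(lens != lens[1L])[1L]]
    abort(sprintf("ragged alignment in '%s': record '%s'.", path, bad))
  }
  aligned_locus(meta, locus_name = locus_name, inheritance = inheritance)
}

#' Write an aligned locus to FASTA
#'
#' @param locus An [aligned_locus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(locus, path) {
  s <- locus$seqs
  headers <- paste(s$sample_id, s$population, s$sex, s$allele_index, sep = "|")
  lines <- character(2L * nrow(s))
  lines[c(TRUE, FALSE)] <- paste0(">", headers)
  lines[c(FALSE, TRUE)] <- s$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Duplicate heterozygous male Z-linked records from externally phased pairs
#'
#' Males are ZZ diploid, so a male sample sequenced at a Z-linked locus can
#' carry two haplotypes; females are hemizygous and always contribute one.
#' Phasing is taken as given (supplied by cloning or read-phasing upstream);
#' this function only replaces each listed male's single record with its two
#' phased sequences, which is why sequence counts can exceed sample counts.
#'
#' @param locus A `z_linked` [aligned_locus()].
#' @param phased_pairs Named list: `sample_id -> character(2)` of aligned
#'   haplotype sequences.
#' @return An [aligned_locus()] with one record per haplotype.
#' @export
expand_heterozygous_males <- function(locus, phased_pairs) {
  stopifnot(inherits(locus, "aligned_locus"))
  if (locus$inheritance != "z_linked") {
    abort("expand_heterozygous_males applies to z_linked loci only.")
  }
  if (length(phased_pairs) == 0L) return(locus)
  s <- locus$seqs
  for (sid in names(phased_pairs)) {
    row <- which(s$sample_id == sid)
    if (length(row) != 1L) {
      abort(sprintf("sample '%s' not found exactly once in locus '%s'.",
                    sid, locus$locus_name))
    }
    if (s$sex[row] == "F") {
      abort(sprintf("sample '%s' is female and hemizygous for Z; a phased pair violates inheritance.", sid))
    }
    pair <- phased_pairs[[sid]]
    if (length(pair) != 2L || any(nchar(pair) != locus$alignment_length)) {
      abort(sprintf("phased pair for '%s' must be two sequences of alignment length.", sid))
    }
    expanded <- s[c(row, row), ]
    expanded$sequence <- toupper(pair)
    expanded$allele_index <- c(1L, 2L)
    expanded$sequence_id <- paste0(sid, "_a", 1:2)
    s <- bind_rows(s[seq_len(row - 1L), ], expanded,
                   s[seq(row + 1L, length.out = nrow(s) - row), ])
  }
  aligned_locus(s, locus$locus_name, locus$inheritance)
}

# character matrix (sequences x columns) from an aligned locus
alignment_matrix <- function(locus) {
  m <- do.call(rbind, strsplit(locus$seqs$sequence, "", fixed = TRUE))
  rownames(m) <- locus$seqs$sequence_id
  m
}

#' Extract a polymorphism table from an alignment
#'
#' Variable columns become SNP sites (one per column); runs of consecutive
#' columns gapped in an identical, non-empty set of sequences collapse into a
#' single indel site, so a multi-base deletion is scored as one polymorphism.
#' `N` is treated as missing and excluded site-wise. Monomorphic columns are
#' omitted. Internally coordinates are 0-based half-open; reports are 1-based.
#'
#' @param locus An [aligned_locus()] with at least 2 sequences.
#' @return An object of class `polymorphism_table`: a list with `locus_name`,
#'   `sites` (tibble: `site_id`, `kind`, `start`, `end` 0-based half-open),
#'   `calls` (character matrix sequences x sites, `NA` = missing) and `meta`
#'   (the per-sequence metadata tibble).
#' @export
extract_polymorphisms <- function(locus) {
  stopifnot(inherits(locus, "aligned_locus"))
  if (nrow(locus$seqs) < 2L) abort("need at least 2 sequences.")
  m <- alignment_matrix(locus)
  L <- ncol(m)
  nseq <- nrow(m)

  sites <- list()
  calls <- list()

  # SNP sites: columns with >= 2 distinct bases among A/C/G/T
  for (j in seq_len(L)) {
    col <- m[, j]
    base <- col %in% c("A", "C", "G", "T")
    if (length(unique(col[base])) >= 2L) {
      cc <- ifelse(base, col, NA_character_)
      sites[[length(sites) + 1L]] <-
        tibble(site_id = sprintf("%s_snp_%d", locus$locus_name, j),
               kind = "snp", start = j - 1L, end = j)
      calls[[length(calls) + 1L]] <- cc
    }
  }

  # indel sites: maximal runs of columns gapped in an identical sequence set
  gap <- m == "-"
  gap_key <- apply(gap, 2, function(g) paste(which(g), collapse = ","))
  j <- 1L
  while (j <= L) {
    if (gap_key[j] == "") { j <- j + 1L; next }
    k <- j
    while (k < L && gap_key[k + 1L] == gap_key[j]) k <- k + 1L
    cc <- ifelse(gap[, j], "-", "+")
    # a sequence with N across the whole run is missing for this site
    all_n <- apply(m[, j:k, drop = FALSE] == "N", 1, all)
    cc[all_n] <- NA_character_
    if (length(unique(cc[!is.na(cc)])) >= 2L) {
      sites[[length(sites) + 1L]] <-
        tibble(site_id = sprintf("%s_indel_%d", locus$locus_name, j),
               kind = "indel", start = j - 1L, end = k)
      calls[[length(calls) + 1L]] <- cc
    }
    j <- k + 1L
  }

  if (length(sites) == 0L) {
    sites_tbl <- tibble(site_id = character(), kind = character(),
                        start = integer(), end = integer())
    call_mat <- matrix(NA_character_, nrow = nseq, ncol = 0,
                       dimnames = list(rownames(m), NULL))
  } else {
    sites_tbl <- list_rbind(sites)
    ord <- order(sites_tbl$start, sites_tbl$kind)
    sites_tbl <- sites_tbl[ord, ]
    call_mat <- do.call(cbind, calls)[, ord, drop = FALSE]
    dimnames(call_mat) <- list(rownames(m), sites_tbl$site_id)
  }
  structure(
    list(locus_name = locus$locus_name, inheritance = locus$inheritance,
         sites = sites_tbl, calls = call_mat, meta = locus$seqs[, 1:5]),
    class = "polymorphism_table"
  )
}

#' @export
print.polymorphism_table <- function(x, ...) {
  cat(sprintf("<polymorphism_table> %s: %d sequences x %d sites (%d snp, %d indel)\n",
              x$locus_name, nrow(x$calls), nrow(x$sites),
              sum(x$sites$kind == "snp"), sum(x$sites$kind == "indel")))
  invisible(x)
}

#' Report polymorphic sites with 1-based coordinates
#'
#' @param ptab A [extract_polymorphisms()] result.
#' @return A tibble with `site_id`, `kind`, `start_1based`, `end_1based`.
#' @export
site_report <- function(ptab) {
  mutate(ptab$sites, start_1based = .data$start + 1L, end_1based = .data$end,
         start = NULL, end = NULL)
}

# marker matrix ---------------------------------------------------------

aflp_marker_ids <- function(aflp) {
  setdiff(names(aflp), c("sample_id", "population"))
}

aflp_band_matrix <- function(aflp) {
  m <- as.matrix(aflp[, aflp_marker_ids(aflp), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- aflp$sample_id
  m
}

#' Read a binary marker (AFLP-style) matrix from TSV
#'
#' Expected layout: a header row, a `sample_id` column, an optional
#' `population` column, then one 0/1 column per marker (`NA` allowed).
#'
#' @param path TSV path.
#' @return A tibble (`sample_id`, `population`, markers...).
#' @export
read_aflp_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(x)) abort("marker matrix needs a 'sample_id' column.")
  if (!"population" %in% names(x)) x$population <- "unknown"
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in marker matrix.")
  ids <- setdiff(names(x), c("sample_id", "population"))
  if (anyDuplicated(ids)) abort("duplicate marker ids in marker matrix.")
  vals <- unlist(x[, ids], use.names = FALSE)
  if (!all(is.na(vals) | vals %in% c(0, 1))) {
    abort("marker values must be 0, 1 or missing.")
  }
  select(x, "sample_id", "population", all_of(ids))
}

#' Write a binary marker matrix to TSV
#'
#' @param aflp Marker tibble as returned by [read_aflp_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aflp_matrix <- function(aflp, path) {
  readr::write_tsv(aflp, path, progress = FALSE)
  invisible(path)
}

#' Drop band columns that are monomorphic across all scored individuals
#'
#' Dominant markers carry information only when both band states are seen;
#' fixed columns are removed before any downstream statistic.
#'
#' @param aflp Marker tibble.
#' @return The tibble restricted to polymorphic markers.
#' @export
filter_polymorphic <- function(aflp) {
  ids <- aflp_marker_ids(aflp)
  keep <- map_lgl(ids, function(id) {
    v <- aflp[[id]]
    length(unique(v[!is.na(v)])) >= 2L
  })
  select(aflp, "sample_id", "population", all_of(ids[keep]))
}

#' Read a sample-to-population map from TSV
#'
#' Columns: `sample_id`, `population`, optional `sex` (`M`/`F`/`U`).
#'
#' @param path TSV path.
#' @return A tibble with one row per sample.
#' @export
read_population_map <- function(path) {
  # plain 'F' in the sex column must not be guessed as logical FALSE
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample_id", "population") %in% names(x))) {
    abort("population map needs 'sample_id' and 'population' columns.")
  }
  if (!"sex" %in% names(x)) x$sex <- "U"
  if (anyDuplicated(x$sample_id)) {
    abort("duplicate sample_id in population map.")
  }
  if (!all(x$sex %in% c("M", "F", "U"))) abort("sex must be M, F or U.")
  select(x, "sample_id", "population", "sex")
}

#' Check that every sample in a dataset is covered by a population map
#'
#' @param sample_ids Character vector of sample ids used by a dataset.
#' @param map Population map tibble.
#' @return `TRUE`, invisibly; errors on unknown samples.
#' @export
validate_population_map <- function(sample_ids, map) {
  unknown <- setdiff(unique(sample_ids), map$sample_id)
  if (length(unknown)) {
    abort(paste0("samples absent from population map: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a binary trait table from TSV
#'
#' Columns: `taxon`, then one 0/1/`NA` column per trait (e.g. mimicry,
#' obligatory pupal diapause, univoltinism).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_trait_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"taxon" %in% names(x)) abort("trait table needs a 'taxon' column.")
  vals <- unlist(x[, setdiff(names(x), "taxon")], use.names = FALSE)
  if (!all(is.na(vals) | vals %in% c(0, 1))) abort("trait states must be 0, 1 or missing.")
  x
}

#' Write / read Newick trees
#'
#' Thin wrappers over the `ape` Newick writer/reader keeping branch lengths
#' and integer support labels; `read_newick(write_newick(x))` round-trips.
#'
#' @param tree An `ape` `phylo` object.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
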