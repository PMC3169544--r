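# Ancestry-informative marker selection, four-way classification of hybrid
# marker frequencies against the parents, and per-individual genotype
# classification at strongly differentiated sequence polymorphisms.

band_freq <- function(x) mean(x, na.rm = TRUE)

#' Select ancestry-informative markers
#'
#' A marker is ancestry-informative when its band frequencies differ
#' significantly between the two parental species, judged by the
#' locus-by-locus AMOVA permutation test at level `alpha` (default 0.05).
#'
#' @param aflp Marker tibble (`sample_id`, `population`, markers...).
#' @param parentA,parentB Population labels of the parents.
#' @param alpha Significance level of the screen.
#' @param n_perm,seed Permutation settings passed to [fst_binary()].
#' @return Tibble in stable input order: `marker_id`, `phi_st`, `p_value`,
#'   `selected`. Monomorphic-between-parents markers get `p_value = NA` and
#'   are never selected.
#' @export
select_informative <- function(aflp, parentA, parentB, alpha = 0.05,
                               n_perm = 2000, seed = NULL) {
  check_alpha(alpha)
  sub <- filter(aflp, .data$population %in% c(parentA, parentB))
  if (length(unique(sub$population)) < 2L) {
    abort("both parental populations must be sampled.")
  }
  rows <- map(aflp_marker_ids(aflp), function(id) {
    res <- tryCatch(
      fst_binary(sub[[id]], sub$population, n_perm = n_perm,
                 seed = substream_seed(seed %||% 0L, id), locus_id = id),
      error = function(e) tibble(locus_id = id, phi_st = NA_real_,
                                 p_value = NA_real_)
    )
    tibble(marker_id = id, phi_st = res$phi_st, p_value = res$p_value)
  })
  mutate(list_rbind(rows),
         selected = !is.na(.data$p_value) & .data$p_value <= alpha)
}

#' Classify ancestry-informative markers against parents and hybrid
#'
#' For each marker the hybrid population's band frequency is compared to
#' each parent by the AMOVA permutation test; the two significance outcomes
#' and the frequency ordering give the four-way classification:
#' `parentA_like` (different from B, not from A), `parentB_like` (the
#' mirror), `different` (different from both), `intermediate` (different
#' from neither, hybrid frequency within the closed parental interval). The
#' residual case — significant versus neither parent but a hybrid frequency
#' outside the parental interval — is flagged `outside_nonsignificant` and
#' counted with `intermediate` in the headline totals.
#'
#' @param aflp Marker tibble.
#' @param hybrid,parentA,parentB Population labels.
#' @param alpha Significance level (default 0.05).
#' @param markers Marker ids to classify; defaults to the
#'   [select_informative()] screen at the same `alpha`.
#' @param n_perm,seed Permutation settings.
#' @return Tibble: `marker_id`, `freq_A`, `freq_B`, `freq_H`, `p_vs_A`,
#'   `p_vs_B`, `category`.
#' @export
classify_markers <- function(aflp, hybrid, parentA, parentB, alpha = 0.05,
                             markers = NULL, n_perm = 2000, seed = NULL) {
  check_alpha(alpha)
  if (is.null(markers)) {
    sel <- select_informative(aflp, parentA, parentB, alpha = alpha,
                              n_perm = n_perm, seed = substream_seed(seed %||% 0L, "screen"))
    markers <- sel$marker_id[sel$selected]
  }
  pops <- list(A = parentA, B = parentB, H = hybrid)
  rows <- map(markers, function(id) {
    v <- aflp[[id]]
    if (is.null(v)) abort(sprintf("marker '%s' absent from matrix.", id))
    freqs <- map_dbl(pops, ~ band_freq(v[aflp$population == .x]))
    p_vs <- map_dbl(c(A = "A", B = "B"), function(par) {
      idx <- aflp$population %in% c(pops[[par]], hybrid)
      tryCatch(
        fst_binary(v[idx], aflp$population[idx], n_perm = n_perm,
                   seed = substream_seed(seed %||% 0L, paste0(id, par)),
                   locus_id = id)$p_value,
        error = function(e) 1)  # monomorphic between the pair: no difference
    })
    sig_a <- p_vs[["A"]] <= alpha
    sig_b <- p_vs[["B"]] <= alpha
    lo <- min(freqs[["A"]], freqs[["B"]])
    hi <- max(freqs[["A"]], freqs[["B"]])
    category <- if (sig_a && sig_b) {
      "different"
    } else if (sig_b && !sig_a) {
      "parentA_like"
    } else if (sig_a && !sig_b) {
      "parentB_like"
    } else if (freqs[["H"]] >= lo && freqs[["H"]] <= hi) {
      "intermediate"
    } else {
      "outside_nonsignificant"
    }
    tibble(marker_id = id, freq_A = freqs[["A"]], freq_B = freqs[["B"]],
           freq_H = freqs[["H"]], p_vs_A = p_vs[["A"]], p_vs_B = p_vs[["B"]],
           category = category)
  })
  out <- list_rbind(rows)
  class(out) <- c("marker_classification", class(out))
  out
}

#' Headline category counts for a marker classification
#'
#' @param classification A [classify_markers()] result.
#' @return Tibble of the four headline categories (the
#'   `outside_nonsignificant` flag is counted with `intermediate`) plus the
#'   flagged count on its own row for auditability.
#' @export
classification_counts <- function(classification) {
  cat4 <- c("parentA_like", "parentB_like", "intermediate", "different")
  headline <- ifelse(classification$category == "outside_nonsignificant",
                     "intermediate", classification$category)
  tibble(
    category = c(cat4, "outside_nonsignificant_flagged"),
    n = c(map_int(cat4, ~ sum(headline == .x)),
          sum(classification$category == "outside_nonsignificant"))
  )
}

#' Classify individual genotypes at strongly differentiated sequence sites
#'
#' Restricts each locus to polymorphic sites whose parental AMOVA p-value is
#' at or below `alpha` (default 0.001), then codes each individual at each
#' site: its allele(s) are associated with the parent in which they are more
#' frequent; individuals with two sequences (ZZ males) carrying one allele of
#' each class are heterozygotes; absent data — or an allele seen in neither
#' parent — are missing. This is the per-individual genomic mosaic display:
#' a hybrid species shows, e.g., uniformly parent-A-like mtDNA next to
#' parent-B-like Z-linked sites.
#'
#' @param tables Named list of `polymorphism_table`s.
#' @param parentA,parentB,hybrid Population labels (hybrid rows are coded
#'   too; all populations present in the tables are returned).
#' @param alpha Parental differentiation threshold (default 0.001).
#' @param n_perm,seed Permutation settings (n_perm should comfortably exceed
#'   `1/alpha`; default 10000).
#' @return A tibble of class `genotype_classes`: `locus`, `site_id`,
#'   `sample_id`, `population`, `call` in
#'   `A_like/B_like/heterozygote/missing`. The number of alleles observed in
#'   neither parent is attached as `attr(, "unseen_alleles")`.
#' @export
classify_sequence_genotypes <- function(tables, parentA, parentB,
                                        hybrid = NULL, alpha = 0.001,
                                        n_perm = 10000, seed = NULL) {
  check_alpha(alpha)
  unseen <- 0L
  rows <- map(tables, function(ptab) {
    meta <- ptab$meta
    in_a <- meta$population == parentA
    in_b <- meta$population == parentB
    if (!any(in_a) || !any(in_b)) return(NULL)
    site_rows <- map(seq_len(nrow(ptab$sites)), function(s) {
      calls <- ptab$calls[, s]
      par_idx <- in_a | in_b
      # significance screen on the parental subset only
      p <- tryCatch(
        site_parental_p(calls[par_idx], meta$population[par_idx],
                        n_perm = n_perm,
                        seed = substream_seed(seed %||% 0L,
                                              paste0(ptab$locus_name, s))),
        error = function(e) NA_real_)
      if (is.na(p) || p > alpha) return(NULL)
      fa <- table(factor(calls[in_a]))
      fb <- table(factor(calls[in_b]))
      alleles <- union(names(fa), names(fb))
      assoc <- setNames(rep(NA_character_, length(alleles)), alleles)
      for (al in alleles) {
        pa <- if (al %in% names(fa)) fa[[al]] / sum(fa) else 0
        pb <- if (al %in% names(fb)) fb[[al]] / sum(fb) else 0
        assoc[al] <- if (pa > pb) "A" else if (pb > pa) "B" else NA_character_
      }
      per_sample <- group_by(
        tibble(sample_id = meta$sample_id, population = meta$population,
               allele = calls),
        .data$sample_id, .data$population)
      per_sample <- summarise(per_sample, call = {
        al <- .data$allele[!is.na(.data$allele)]
        cls <- unique(assoc[match(al, names(assoc))])
        new_unseen <- sum(!al %in% names(assoc))
        if (new_unseen > 0) unseen <<- unseen + new_unseen
        cls <- cls[!is.na(cls)]
        if (length(al) == 0L || length(cls) == 0L) "missing"
        else if (length(cls) == 2L) "heterozygote"
        else if (cls == "A") "A_like" else "B_like"
      }, .groups = "drop")
      mutate(per_sample, locus = ptab$locus_name,
             site_id = ptab$sites$site_id[s])
    })
    list_rbind(site_rows)
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0L) {
    out <- tibble(locus = character(), site_id = character(),
                  sample_id = character(), population = character(),
                  call = character())
  }
  out <- select(out, "locus", "site_id", "sample_id", "population", "call")
  if (unseen > 0) {
    warn(sprintf("%d allele observations seen in neither parent were coded missing.", unseen))
  }
  attr(out, "unseen_alleles") <- unseen
  class(out) <- c("genotype_classes", class(out))
  out
}

# parental differentiation p-value for one site's allele calls:
# haplotype-level AMOVA on the 0/1 'differs from reference allele' coding
# generalised to multiallelic sites via the identity distance
site_parental_p <- function(calls, pops, n_perm, seed) {
  keep <- !is.na(calls)
  calls <- calls[keep]
  pops <- pops[keep]
  if (length(unique(calls)) < 2L) abort("monomorphic site.")
  d <- outer(calls, calls, `!=`) * 1
  phi_st(d, pops, n_perm = n_perm, seed = seed, locus_id = "site")$p_value
}
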