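# Species-specific polymorphism and haplotype statistics, their across-gene
# summaries and one-way ANOVA, the hybrid-zone fraction, and the COI
# mutation-rate split-time calibration.

# does sequence a match sequence b with NA acting as a wildcard?
calls_match <- function(a, b) {
  cmp <- !is.na(a) & !is.na(b)
  all(a[cmp] == b[cmp])
}

# greedy haplotype classes over rows of a call matrix (NA wildcard-neutral):
# each sequence joins the first existing class representative it matches.
haplotype_classes <- function(calls) {
  reps <- list()
  cls <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    hit <- 0L
    for (h in seq_along(reps)) {
      if (calls_match(calls[i, ], reps[[h]])) { hit <- h; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- calls[i, ]
      hit <- length(reps)
    }
    cls[i] <- hit
  }
  list(classes = cls, representatives = reps)
}

#' Species-specific polymorphism and haplotype counts per gene
#'
#' For each gene and species: a polymorphic site counts as that species'
#' polymorphism if the species is variable at it, or is fixed there for an
#' allele found in no other species; it is species-specific when the
#' species' minor allele (or its fixed private allele) occurs in no other
#' species. Haplotypes are distinct full-locus sequences within the species
#' (compared over polymorphic sites; missing calls are mismatch-neutral),
#' species-specific when no other species' sequence matches. An old hybrid
#' species is expected to hold private variation at rates comparable to —
#' though somewhat below — its older parents; a contemporary swarm holds
#' essentially none.
#'
#' @param tables Named list of `polymorphism_table`s (one per gene).
#' @param map Optional population map; defaults to the population metadata
#'   carried in the tables.
#' @return Tibble with one row per gene x species: sample/sequence counts,
#'   polymorphism and haplotype totals, species-specific counts, and the
#'   exact proportions.
#' @export
species_specific_counts <- function(tables, map = NULL) {
  rows <- map(tables, function(ptab) {
    meta <- ptab$meta
    species <- if (is.null(map)) {
      meta$population
    } else {
      map$population[match(meta$sample_id, map$sample_id)]
    }
    sp_list <- unique(species)
    if (length(sp_list) < 2L) {
      warn(sprintf("locus '%s' has < 2 species; omitted.", ptab$locus_name))
      return(NULL)
    }
    calls <- ptab$calls
    hap_all <- haplotype_classes(calls)
    list_rbind(map(sp_list, function(sp) {
      in_sp <- species == sp
      n_poly <- 0L; n_spec <- 0L
      for (s in seq_len(ncol(calls))) {
        own <- calls[in_sp, s]; own <- own[!is.na(own)]
        oth <- calls[!in_sp, s]; oth <- oth[!is.na(oth)]
        if (length(own) == 0L) next
        tab <- sort(table(own))
        if (length(tab) >= 2L) {
          n_poly <- n_poly + 1L
          minor <- names(tab)[tab == tab[1L]]
          if (!any(minor %in% oth)) n_spec <- n_spec + 1L
        } else if (!names(tab) %in% oth) {
          # fixed for a private allele: the species' own polymorphism
          n_poly <- n_poly + 1L
          n_spec <- n_spec + 1L
        }
      }
      cls_sp <- unique(hap_all$classes[in_sp])
      spec_hap <- sum(map_lgl(cls_sp, function(h) {
        !any(hap_all$classes[!in_sp] == h) &&
          !any(map_lgl(which(!in_sp),
                       ~ calls_match(calls[.x, ], hap_all$representatives[[h]])))
      }))
      tibble(
        gene = ptab$locus_name, species = sp,
        n_samples = length(unique(meta$sample_id[in_sp])),
        n_sequences = sum(in_sp),
        n_polymorphisms = n_poly, n_specific_polymorphisms = n_spec,
        n_haplotypes = length(cls_sp), n_specific_haplotypes = spec_hap,
        proportion_specific_polymorphisms =
          if (n_poly > 0) n_spec / n_poly else NA_real_,
        proportion_specific_haplotypes = spec_hap / length(cls_sp)
      )
    }))
  })
  list_rbind(rows)
}

#' Add exact proportion columns to a diversity count table
#'
#' Recomputes `proportion_specific_polymorphisms` and
#' `proportion_specific_haplotypes` as exact fractions from the integer
#' counts (useful when counts come from an external table).
#'
#' @param counts Tibble with the count columns of
#'   [species_specific_counts()].
#' @return The tibble with proportion columns (re)computed.
#' @export
diversity_proportions <- function(counts) {
  mutate(as_tibble(counts),
         proportion_specific_polymorphisms =
           .data$n_specific_polymorphisms / .data$n_polymorphisms,
         proportion_specific_haplotypes =
           .data$n_specific_haplotypes / .data$n_haplotypes)
}

#' Across-gene summary of species-specific proportions
#'
#' Means and (n-1)-denominator standard deviations of the per-gene exact
#' proportions, per species. Proportions enter as exact fractions; rounding
#' happens only at display.
#'
#' @param counts Diversity table ([species_specific_counts()] or
#'   [diversity_proportions()] output).
#' @param statistic `"polymorphisms"` or `"haplotypes"`.
#' @return Tibble `species`, `n_genes`, `mean_proportion`, `sd_proportion`
#'   (`NA` when only one gene is available).
#' @export
proportion_summary <- function(counts, statistic = c("polymorphisms", "haplotypes")) {
  statistic <- match.arg(statistic)
  col <- paste0("proportion_specific_", statistic)
  summarise(group_by(as_tibble(counts), .data$species),
            n_genes = sum(!is.na(.data[[col]])),
            mean_proportion = mean(.data[[col]], na.rm = TRUE),
            sd_proportion = if (sum(!is.na(.data[[col]])) > 1L) {
              sd(.data[[col]], na.rm = TRUE)
            } else NA_real_,
            .groups = "drop")
}

#' One-way fixed-effects ANOVA
#'
#' Standard decomposition on the untransformed values via `stats::lm`;
#' returns the F statistic with its degrees of freedom and p-value.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, >= 2 values each).
#' @return One-row tibble `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) abort("need at least 2 groups.")
  if (any(table(groups) < 2L)) abort("each group needs at least 2 values.")
  if (var(values) == 0) {    # constant response: no variance to partition
    return(tibble(F = 0, df_between = nlevels(groups) - 1L,
                  df_within = length(values) - nlevels(groups), p = 1))
  }
  tab <- anova(lm(values ~ groups))
  f <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  if (is.nan(f)) {             # zero variance between and within
    f <- 0; p <- 1
  } else if (is.infinite(f)) { # unequal means, zero within-group variance
    p <- .Machine$double.xmin
  }
  tibble(F = f, df_between = tab$Df[1L], df_within = tab$Df[2L], p = p)
}

#' Split-time calibration from pairwise divergence and a molecular clock
#'
#' With an outgroup divergence of `d` percent and a clock of `r` percent per
#' lineage per million years, the split time is `d / (2 r)` million years —
#' the factor two because divergence accrues along both lineages. The COI
#' clock of 1.15 %/lineage/Myr with 3.17 % average divergence dates the
#' outgroup split of the tiger swallowtails at roughly 1.4 Myr.
#'
#' @param divergence_percent Average pairwise divergence, percent.
#' @param rate_percent_per_lineage_per_Myr Clock rate.
#' @return One-row tibble with the inputs and `split_time_Myr`.
#' @export
calibrate_split_time <- function(divergence_percent,
                                 rate_percent_per_lineage_per_Myr) {
  if (divergence_percent <= 0 || rate_percent_per_lineage_per_Myr <= 0) {
    abort("divergence and rate must be positive.")
  }
  tibble(
    divergence_percent = divergence_percent,
    rate_percent_per_lineage_per_Myr = rate_percent_per_lineage_per_Myr,
    split_time_Myr = divergence_percent / (2 * rate_percent_per_lineage_per_Myr)
  )
}

#' Hybrid fraction of a contact zone
#'
#' The proportion of suspected hybrids relative to phenotypically pure
#' individuals, in percent: `100 * n_hybrid / n_pure`. (The alternative
#' convention divides by the grand total `n_hybrid + n_pure`; both are
#' reported.)
#'
#' @param n_hybrid Number of suspected hybrid individuals.
#' @param n_pure Number of phenotypically pure individuals.
#' @return One-row tibble with counts, `percent_of_pure` (headline) and
#'   `percent_of_total`.
#' @export
hybrid_zone_fraction <- function(n_hybrid, n_pure) {
  stopifnot(n_hybrid >= 0, n_pure > 0)
  tibble(n_hybrid = n_hybrid, n_pure = n_pure,
         percent_of_pure = 100 * n_hybrid / n_pure,
         percent_of_total = 100 * n_hybrid / (n_hybrid + n_pure))
}

#' Published per-gene diversity counts for the three focal swallowtails
#'
#' The published counts of polymorphisms, species-specific polymorphisms,
#' haplotypes and species-specific haplotypes for seven genes (mtDNA COI and
#' six Z-linked loci) in the two parental tiger swallowtail species and the
#' putative hybrid species. Shipped as a plain-text table so the across-gene
#' summaries and ANOVAs can be recomputed exactly.
#'
#' @return Tibble in [species_specific_counts()] layout with exact
#'   proportions attached.
#' @export
swallowtail_diversity_counts <- function() {
  path <- system.file("extdata", "swallowtail_diversity_counts.tsv",
                      package = "hybridhallmarks", mustWork = TRUE)
  diversity_proportions(readr::read_tsv(path, show_col_types = FALSE,
                                        progress = FALSE))
}
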