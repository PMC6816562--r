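# Same-breed subpopulation comparison --------------------------------------
#
# Allele distributions of two or more subpopulations of one breed are
# compared on chromosome counts (populations x alleles).  Pearson's
# chi-square is used unless any cell count falls below 5, in which case
# Fisher's exact test is used (exact for tables with at most 200
# chromosomes, seeded Monte-Carlo above that).  Significance is
# Bonferroni-corrected for the number of breeds tested (default 30,
# alpha 0.05/30 = 0.00167); pairwise follow-up uses 0.05/n with n the
# maximum number of subpopulations remaining.

#' Build the populations x alleles chromosome-count table for one gene
#'
#' @param freqs a `breed_frequency_table` grouped by breed and
#'   population.
#' @param breed,gene selectors.
#' @return integer matrix (rows = populations, columns = alleles).
#' @export
contingency_table <- function(freqs, breed, gene) {
  sub <- freqs[freqs$breed == breed & freqs$gene == gene &
                 freqs$available & !is.na(freqs$allele), , drop = FALSE]
  if (!nrow(sub)) return(matrix(integer(0), 0, 0))
  pops <- sort(unique(sub$population))
  alls <- sort(unique(sub$allele))
  tab <- matrix(0L, length(pops), length(alls),
                dimnames = list(pops, alls))
  tab[cbind(match(sub$population, pops), match(sub$allele, alls))] <-
    sub$count
  tab
}

run_count_test <- function(tab, mc_resamples = 1e5, seed = NULL) {
  if (any(tab < 5L)) {
    test <- "fisher_exact"
    if (sum(tab) <= 200L) {
      p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    } else {
      if (!is.null(seed)) set.seed(seed)
      p <- stats::fisher.test(tab, simulate.p.value = TRUE,
                              B = mc_resamples)$p.value
    }
  } else {
    test <- "pearson_chi2"
    p <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(test = test, p_value = p)
}

#' Compare allele distributions between same-breed subpopulations
#'
#' @param freqs a `breed_frequency_table` grouped by breed and
#'   population.
#' @param breed,gene selectors.
#' @param n_breeds_tested Bonferroni denominator; the default 30 gives
#'   alpha 0.00167 (use 29 when a gene is untestable in one breed, e.g.
#'   FGF5, giving 0.00142).
#' @param mc_resamples Monte-Carlo resamples for Fisher tests on tables
#'   with more than 200 chromosomes.
#' @param seed optional seed for the Monte-Carlo path (reproducibility).
#' @return object of class `comparison_result`: the contingency table,
#'   test used, p-value, alpha, significance flag; or status
#'   `"untestable"` when fewer than two populations have genotypes.
#' @export
compare_populations <- function(freqs, breed, gene, n_breeds_tested = 30,
                                mc_resamples = 1e5, seed = NULL) {
  tab <- contingency_table(freqs, breed, gene)
  empty <- nrow(tab) > 0L && any(rowSums(tab) == 0L)
  if (empty) {
    warning("dropping population(s) with zero genotyped chromosomes: ",
            paste(rownames(tab)[rowSums(tab) == 0L], collapse = ", "))
    tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
  }
  alpha <- 0.05 / n_breeds_tested
  base <- list(breed = breed, gene = gene, table = tab, alpha = alpha,
               n_breeds_tested = n_breeds_tested, pairwise = NULL)
  if (nrow(tab) < 2L) {
    return(structure(c(base, list(status = "untestable", test = NA,
                                  p_value = NA_real_, significant = NA)),
                     class = "comparison_result"))
  }
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  if (ncol(tab) < 2L) {
    # a single allele class across all populations: identical by
    # definition
    return(structure(c(base, list(status = "ok", test = "degenerate",
                                  p_value = 1, significant = FALSE)),
                     class = "comparison_result"))
  }
  res <- run_count_test(tab, mc_resamples, seed)
  structure(c(base, list(status = "ok", test = res$test,
                         p_value = res$p_value,
                         significant = res$p_value <= alpha)),
            class = "comparison_result")
}

#' Pairwise follow-up tests between subpopulations
#'
#' Intended after a significant overall comparison of a breed sampled
#' from more than two subpopulations.  Each pair is tested with the same
#' Fisher/chi-square selection rule at alpha = 0.05 / `n_max_subpops`.
#'
#' @param freqs a `breed_frequency_table` grouped by breed/population.
#' @param breed,gene selectors.
#' @param n_max_subpops `n` in 0.05/n: the maximum number of
#'   subpopulations remaining in the analysis for this gene (defaults to
#'   the number of populations present in the table).
#' @param mc_resamples,seed as in [compare_populations()].
#' @return `data.frame` with one row per population pair: `pop_a`,
#'   `pop_b`, `test`, `p_value`, `alpha`, `significant`.
#' @export
pairwise_followup <- function(freqs, breed, gene, n_max_subpops = NULL,
                              mc_resamples = 1e5, seed = NULL) {
  tab <- contingency_table(freqs, breed, gene)
  tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
  pops <- rownames(tab)
  if (length(pops) < 2L)
    stop("pairwise follow-up needs at least two populations with data")
  if (is.null(n_max_subpops)) n_max_subpops <- length(pops)
  alpha <- 0.05 / n_max_subpops
  combs <- utils::combn(pops, 2L)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    sub <- tab[combs[, i], , drop = FALSE]
    sub <- sub[, colSums(sub) > 0L, drop = FALSE]
    if (ncol(sub) < 2L) {
      res <- list(test = "degenerate", p_value = 1)
    } else {
      res <- run_count_test(sub, mc_resamples, seed)
    }
    data.frame(pop_a = combs[1L, i], pop_b = combs[2L, i],
               test = res$test, p_value = res$p_value, alpha = alpha,
               significant = res$p_value <= alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$breed, " / ", x$gene, "\n", sep = "")
  if (identical(x$status, "untestable")) {
    cat("  untestable (fewer than two populations with genotypes)\n")
    return(invisible(x))
  }
  cat(sprintf("  test: %s   p = %.4g   alpha = %.5f   significant: %s\n",
              x$test, x$p_value, x$alpha, x$significant))
  invisible(x)
}
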