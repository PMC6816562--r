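# Allele-frequency estimation ---------------------------------------------
#
# Frequencies are chromosome-count based: each dog with a usable genotype
# at a gene contributes two chromosomes.  Dogs with missing or unresolved
# calls at a gene are excluded from that gene's denominator only.  The
# cis a^yt allele is counted as its own allele class, and K^B/k^br as a
# single pooled class (the assay cannot separate them).

#' Estimate allele frequencies per breed (and optionally subpopulation)
#'
#' @param calls long genotype table from [interpret_genotypes()].
#' @param by grouping columns, `"breed"` or `c("breed", "population")`.
#' @return `data.frame` of class `breed_frequency_table`: one row per
#'   group x gene x observed allele with `count` (chromosomes), `freq`,
#'   `n_genotyped`, `n_missing`, `fixed` (is the gene fixed for a single
#'   allele in the group), and an `available` flag (FALSE rows mark
#'   gene/group combinations with zero genotyped dogs).
#' @export
estimate_frequencies <- function(calls, by = c("breed", "population")) {
  by <- match.arg(by, c("breed", "population"), several.ok = TRUE)
  if (!all(by %in% names(calls)))
    stop("grouping columns missing from calls: ",
         paste(setdiff(by, names(calls)), collapse = ", "))
  key <- interaction(c(calls[by], calls["gene"]), drop = TRUE, sep = "\r")
  pieces <- split(calls, key)
  rows <- lapply(pieces, function(d) {
    usable <- !d$missing & d$ambiguity != "unresolved"
    n_gen <- sum(usable)
    n_mis <- sum(!usable)
    meta <- d[1L, c(by, "gene"), drop = FALSE]
    if (n_gen == 0L) {
      return(cbind(meta,
                   data.frame(allele = NA_character_, count = NA_integer_,
                              freq = NA_real_, n_genotyped = 0L,
                              n_missing = n_mis, fixed = NA,
                              available = FALSE, stringsAsFactors = FALSE)))
    }
    chrom <- c(d$allele1[usable], d$allele2[usable])
    tab <- table(chrom)
    freq <- as.numeric(tab) / (2 * n_gen)
    cbind(meta[rep(1L, length(tab)), , drop = FALSE],
          data.frame(allele = names(tab), count = as.integer(tab),
                     freq = freq, n_genotyped = n_gen, n_missing = n_mis,
                     fixed = length(tab) == 1L, available = TRUE,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out[[by[1L]]], out$gene, -rank(out$freq,
                                                 ties.method = "first")), ]
  rownames(out) <- NULL
  class(out) <- c("breed_frequency_table", "data.frame")
  out
}

#' Look up one allele frequency
#'
#' @param freqs a `breed_frequency_table`.
#' @param breed,gene,allele selectors.
#' @param population optional population label.
#' @return frequency (0 when the allele was not observed but the gene
#'   was genotyped; `NA` when the gene is unavailable for the group).
#' @export
allele_freq <- function(freqs, breed, gene, allele, population = NULL) {
  sel <- freqs$breed == breed & freqs$gene == gene
  if (!is.null(population) && "population" %in% names(freqs))
    sel <- sel & freqs$population == population
  sub <- freqs[sel, , drop = FALSE]
  if (!nrow(sub) || !any(sub$available)) return(NA_real_)
  hit <- sub$freq[!is.na(sub$allele) & sub$allele == allele]
  if (length(hit)) hit[1L] else 0
}

#' Export a frequency table as delimited text
#'
#' Mirrors a breed x gene x allele long layout.
#'
#' @param freqs a `breed_frequency_table`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_frequency_table <- function(freqs, path, sep = "\t") {
  utils::write.table(freqs, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
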