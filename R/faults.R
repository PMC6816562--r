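# Breed-standard faults and random-mating probabilities -------------------
#
# A "fault" allele is one whose reachable phenotype is disallowed (N) or
# not preferred (n.p.) by a registry's written breed standard.  Under
# random mating the probability of actually producing the fault
# phenotype is a product of independent Hardy-Weinberg factors, one per
# participating gene, each computed under the expression mode that gene
# contributes (the printed equation's dominant form, or the recessive /
# heterozygous-only forms its worked examples require), optionally
# renormalized to live births at homozygous-lethal loci.

.FACTOR_MODES <- c("dominant_or_better", "homozygous_recessive",
                   "heterozygous_only", "het_or_hom")

#' One Hardy-Weinberg factor of a fault-phenotype probability
#'
#' @param p frequency of the factor's focal allele.
#' @param q frequencies of up to three same-gene alleles recessive to the
#'   focal allele (contribute carrier matings in the dominant form and
#'   join the recessive class in the recessive form).
#' @param mode expression mode:
#'   `"dominant_or_better"` = `p^2 + sum(2 p q)`;
#'   `"homozygous_recessive"` = `(p + sum(q))^2`;
#'   `"heterozygous_only"` = `2 p (1 - p)`;
#'   `"het_or_hom"` = `p^2 + 2 p (1 - p)` (co-dominant expression).
#' @return object of class `fault_factor`.
#' @export
fault_factor <- function(p, q = numeric(0), mode = "dominant_or_better") {
  mode <- match.arg(mode, .FACTOR_MODES)
  if (length(q) > 3L)
    stop("at most 3 recessive same-gene alleles are supported")
  freqs <- c(p, q)
  if (any(freqs < 0 | freqs > 1) || sum(freqs) > 1 + 1e-9)
    stop("allele frequencies must lie in [0, 1] and sum to at most 1")
  structure(list(p = p, q = q, mode = mode), class = "fault_factor")
}

factor_value <- function(f) {
  switch(f$mode,
         dominant_or_better   = f$p^2 + sum(2 * f$p * f$q),
         homozygous_recessive = (f$p + sum(f$q))^2,
         heterozygous_only    = 2 * f$p * (1 - f$p),
         het_or_hom           = f$p^2 + 2 * f$p * (1 - f$p))
}

#' Random-mating fault-phenotype probability
#'
#' Multiplies up to three gene factors (the focal gene plus up to two
#' interacting genes whose genotypes are required for expression; absent
#' genes contribute a factor of 1), then optionally renormalizes to
#' live-birth outcomes.
#'
#' @param factors a single [fault_factor()] or a list of up to three.
#' @param lethal_freqs frequencies of homozygous-lethal alleles at loci
#'   participating in (or co-segregating with) the phenotype.
#' @param live_birth apply the live-birth correction (divide by
#'   `prod(1 - p_lethal^2)`)?  Off by default: the source worked
#'   examples report unrenormalized values.
#' @return probability in `[0, 1]`.
#' @export
fault_probability <- function(factors, lethal_freqs = numeric(0),
                              live_birth = FALSE) {
  if (inherits(factors, "fault_factor")) factors <- list(factors)
  if (!length(factors) || length(factors) > 3L)
    stop("between one and three gene factors are required")
  if (!all(vapply(factors, inherits, TRUE, "fault_factor")))
    stop("all factors must be fault_factor objects")
  prob <- prod(vapply(factors, factor_value, numeric(1)))
  if (live_birth) prob <- live_birth_correction(prob, lethal_freqs)
  prob
}

#' Live-birth correction for homozygous-lethal loci
#'
#' Conception-level genotype probabilities are renormalized to the viable
#' subset: each lethal locus removes a `p^2` share of conceptions, so the
#' divisor is `prod(1 - p_lethal^2)`.  Identity when no lethal loci are
#' supplied.
#'
#' @param prob raw probability.
#' @param lethal_freqs lethal-allele frequencies.
#' @return corrected probability.
#' @export
live_birth_correction <- function(prob, lethal_freqs = numeric(0)) {
  if (any(lethal_freqs < 0 | lethal_freqs > 1))
    stop("lethal allele frequencies must lie in [0, 1]")
  if (!length(lethal_freqs)) return(prob)
  prob / prod(1 - lethal_freqs^2)
}

# Registry standards -------------------------------------------------------

.TOLERANCES <- c("N", "n.p.", "Y", "amb.", "not_recognized")

#' Read a breed-standard tolerance table
#'
#' Delimited file with columns `breed`, `registry` (AKC/UKC/KC/FCI),
#' `trait` and `tolerance` (`N` not allowed, `n.p.` not preferred, `Y`
#' allowed, `amb.` ambiguously worded, `not_recognized`).
#'
#' @param path file path; defaults to the small curated table shipped
#'   with the package (main-text breeds only).
#' @param sep field separator.
#' @return validated `data.frame`.
#' @export
read_breed_standards <- function(path = system.file("extdata",
                                                    "breed_standards.csv",
                                                    package = "caninetraits"),
                                 sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("breed", "registry", "trait", "tolerance")
  if (!all(need %in% names(df)))
    stop("standards table needs columns: ", paste(need, collapse = ", "))
  bad <- !df$tolerance %in% .TOLERANCES
  if (any(bad))
    stop("unknown tolerance codes: ",
         paste(unique(df$tolerance[bad]), collapse = ", "))
  if (anyDuplicated(df[, c("breed", "registry", "trait")]))
    stop("duplicate breed x registry x trait rows in standards table")
  df
}

#' Detect fault alleles against registry standards
#'
#' Cross-joins a breed's observed alleles (frequency > 0) with the
#' standards table: every (breed, registry, allele) whose reachable
#' phenotype trait is coded `N` or `n.p.` yields a finding; `amb.` rows
#' are returned too, flagged `ambiguous = TRUE`.  Breeds absent from the
#' standards table are skipped with a warning.
#'
#' @param freqs a `breed_frequency_table`.
#' @param standards `data.frame` from [read_breed_standards()].
#' @param models a `gene_catalogue` (supplies allele -> trait labels and
#'   inheritance classes).
#' @return `data.frame` with `breed`, `registry`, `gene`, `allele`,
#'   `trait`, `tolerance`, `inheritance`, `freq`, `ambiguous`.
#' @export
detect_fault_alleles <- function(freqs, standards,
                                 models = default_gene_models()) {
  trait_map <- do.call(rbind, lapply(models, function(m)
    m$alleles[!is.na(m$alleles$trait),
              c("gene_id", "symbol", "trait", "inheritance")]))
  obs <- freqs[freqs$available & !is.na(freqs$allele) & freqs$freq > 0, ,
               drop = FALSE]
  if ("population" %in% names(obs)) {
    # pool over populations for detection: presence anywhere counts
    key <- paste(obs$breed, obs$gene, obs$allele, sep = "\r")
    obs <- obs[!duplicated(key), , drop = FALSE]
  }
  obs <- merge(obs, trait_map,
               by.x = c("gene", "allele"), by.y = c("gene_id", "symbol"))
  missing_breeds <- setdiff(unique(obs$breed), unique(standards$breed))
  if (length(missing_breeds))
    warning("no standards for breed(s): ",
            paste(missing_breeds, collapse = ", "), "; skipped")
  hits <- merge(obs, standards, by = c("breed", "trait"))
  hits <- hits[hits$tolerance %in% c("N", "n.p.", "amb."), , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(breed = character(0), registry = character(0),
                      gene = character(0), allele = character(0),
                      trait = character(0), tolerance = character(0),
                      inheritance = character(0), freq = numeric(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(breed = hits$breed, registry = hits$registry,
                    gene = hits$gene, allele = hits$allele,
                    trait = hits$trait, tolerance = hits$tolerance,
                    inheritance = hits$inheritance, freq = hits$freq,
                    ambiguous = hits$tolerance == "amb.",
                    stringsAsFactors = FALSE)
  out <- out[order(out$breed, out$registry, out$gene, out$allele), ]
  rownames(out) <- NULL
  out
}

# Declarative fault-probability cases --------------------------------------

#' Evaluate a declarative fault-probability case against a frequency table
#'
#' A case names the breed, the factor genes with their allele lists and
#' expression modes, and optional lethal loci; allele frequencies are
#' looked up in the supplied table.  For a factor, the first listed
#' allele is the focal allele `p` and the rest are its recessives `q`.
#'
#' @param case list with elements `name`, `breed`, optional `population`,
#'   `factors` (list of lists with `gene`, `alleles`, `mode`), optional
#'   `lethal` (list of lists with `gene`, `allele`), optional logical
#'   `live_birth`.
#' @param freqs a `breed_frequency_table`.
#' @return the case list with `probability` added.
#' @export
evaluate_fault_case <- function(case, freqs) {
  pop <- case$population
  factors <- lapply(case$factors, function(fc) {
    fr <- vapply(fc$alleles, function(al)
      allele_freq(freqs, case$breed, fc$gene, al, population = pop),
      numeric(1))
    if (anyNA(fr))
      stop("case '", case$name, "': no frequency for ",
           fc$gene, " in breed ", case$breed)
    fault_factor(fr[1L], if (length(fr) > 1L) fr[-1L] else numeric(0),
                 mode = fc$mode)
  })
  lethal <- if (is.null(case$lethal)) numeric(0) else
    vapply(case$lethal, function(lt)
      allele_freq(freqs, case$breed, lt$gene, lt$allele, population = pop),
      numeric(1))
  case$probability <- fault_probability(
    factors, lethal_freqs = lethal,
    live_birth = isTRUE(case$live_birth))
  case
}
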