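# Synthetic cohorts --------------------------------------------------------
#
# Cohorts are drawn with the statistical structure the downstream
# analysis assumes: Hardy-Weinberg genotypes at stated per-gene allele
# frequencies, rejection sampling at homozygous-lethal loci (only live
# births are observed, so lethal homozygotes are redrawn), cis a^yt
# haplotypes that emit both the a^y and a^t markers from one chromosome,
# and independent sporadic missing marker calls.  True haplotypes are
# retained so interpretation can be audited against the truth.

#' Build and validate a cohort specification
#'
#' @param breeds list of breed specs: each a list with `breed` (code) and
#'   `populations`, itself a list of lists with `label`, `n` (dogs) and
#'   `freqs` (named list: gene id -> named numeric allele frequencies
#'   summing to 1; alleles omitted have frequency 0; ASIP may include
#'   `ayt`).
#' @param missing_rate per-marker, per-dog independent missing-call
#'   probability.
#' @param seed mandatory integer seed.
#' @param models a `gene_catalogue`.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(breeds, missing_rate = 0, seed,
                        models = default_gene_models()) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  for (b in breeds) {
    if (is.null(b$breed)) stop("each breed spec needs a breed code")
    for (p in b$populations) {
      if (is.null(p$label) || is.null(p$n) || p$n < 1)
        stop("each population needs a label and n >= 1")
      for (gene in names(p$freqs)) {
        fr <- p$freqs[[gene]]
        if (is.null(names(fr)) || any(names(fr) == ""))
          stop("frequencies must be named by allele (gene ", gene, ")")
        known <- c(models[[gene]]$alleles$symbol)
        bad <- setdiff(names(fr), known)
        if (length(bad))
          stop("unknown allele(s) ", paste(bad, collapse = ", "),
               " for gene ", gene)
        if (abs(sum(fr) - 1) > 1e-9)
          stop("frequencies for gene ", gene, " in ", b$breed, "/",
               p$label, " must sum to 1")
      }
    }
  }
  structure(list(breeds = breeds, missing_rate = missing_rate,
                 seed = as.integer(seed), models = models),
            class = "cohort_spec")
}

# markers emitted by one haplotype allele (a^yt carries both ASIP
# variant sets on one chromosome)
haplotype_markers <- function(model, symbols) {
  mk_of <- function(sym) {
    if (sym == "ayt") return(c("ay", "at"))
    m <- model$alleles$marker[model$alleles$symbol == sym]
    m[!is.na(m)]
  }
  lapply(symbols, mk_of)
}

#' Generate a synthetic cohort from a specification
#'
#' @param spec a [cohort_spec()].
#' @return object of class `cohort`: list with `markers` (genotype table
#'   in the [read_genotype_table()] dialect, including masked-missing
#'   calls) and `truth` (long `data.frame` of true haplotypes per dog
#'   per gene: `dog_id`, `breed`, `population`, `gene`, `hap1`, `hap2`,
#'   unordered).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  models <- spec$models
  mks <- marker_ids(models)
  marker_rows <- list(); truth_rows <- list(); idx <- 0L
  for (b in spec$breeds) {
    for (p in b$populations) {
      n <- p$n
      ids <- sprintf("%s_%s_%04d", b$breed, p$label, seq_len(n))
      copy <- matrix(0L, n, length(mks), dimnames = list(NULL, mks))
      for (gene in names(models)) {
        fr <- p$freqs[[gene]]
        model <- models[[gene]]
        if (is.null(fr)) {
          wt <- model$alleles$symbol[model$alleles$wild_type][1L]
          fr <- stats::setNames(1, wt)
        }
        syms <- names(fr)
        hap1 <- sample(syms, n, replace = TRUE, prob = fr)
        hap2 <- sample(syms, n, replace = TRUE, prob = fr)
        lethal <- model$alleles$symbol[model$alleles$lethal]
        if (length(lethal)) {
          # live-cohort sampling: redraw any dog drawn homozygous lethal
          repeat {
            bad <- hap1 %in% lethal & hap2 == hap1
            if (!any(bad)) break
            hap1[bad] <- sample(syms, sum(bad), replace = TRUE, prob = fr)
            hap2[bad] <- sample(syms, sum(bad), replace = TRUE, prob = fr)
          }
        }
        per_allele <- haplotype_markers(model, syms)
        names(per_allele) <- syms
        for (s in syms) {
          emitted <- per_allele[[s]]
          if (!length(emitted)) next
          for (m in emitted)
            copy[, m] <- copy[, m] + (hap1 == s) + (hap2 == s)
        }
        swap <- hap1 > hap2
        tmp <- hap1[swap]; hap1[swap] <- hap2[swap]; hap2[swap] <- tmp
        idx <- idx + 1L
        truth_rows[[idx]] <- data.frame(
          dog_id = ids, breed = b$breed, population = p$label,
          gene = gene, hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE)
      }
      if (spec$missing_rate > 0) {
        mask <- matrix(stats::runif(n * length(mks)) < spec$missing_rate,
                       n, length(mks))
        copy[mask] <- NA_integer_
      }
      marker_rows[[length(marker_rows) + 1L]] <- cbind(
        data.frame(dog_id = ids, breed = b$breed, population = p$label,
                   stringsAsFactors = FALSE),
        as.data.frame(copy))
    }
  }
  markers <- do.call(rbind, marker_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(markers) <- rownames(truth) <- NULL
  structure(list(markers = markers, truth = truth, spec = spec),
            class = "cohort")
}

#' Generate paired null / alternative two-population cohorts
#'
#' Both populations share the base frequencies; under the alternative
#' the first non-wild-type allele of each gene is shifted up by
#' `divergence` in population B (wild-type absorbs the shift).  Used for
#' type-I and power calibration of the subpopulation comparison.
#'
#' @param freqs named list: gene id -> named allele frequencies (the
#'   population A frequencies).
#' @param divergence frequency shift applied in population B
#'   (0 = null cohort).
#' @param n_per_pop dogs per population.
#' @param seed integer seed.
#' @param breed breed code for the synthetic breed.
#' @param models a `gene_catalogue`.
#' @return a `cohort` with populations `"A"` and `"B"`.
#' @export
generate_null_and_alternative <- function(freqs, divergence = 0,
                                          n_per_pop = 50, seed,
                                          breed = "SYN",
                                          models = default_gene_models()) {
  freqs_b <- freqs
  if (divergence != 0) {
    for (gene in names(freqs_b)) {
      fr <- freqs_b[[gene]]
      wt <- models[[gene]]$alleles$symbol[models[[gene]]$alleles$wild_type][1L]
      derived <- setdiff(names(fr), wt)
      if (!length(derived)) next
      d <- derived[1L]
      shift <- min(divergence, 1 - fr[[d]], fr[[wt]])
      fr[[d]] <- fr[[d]] + shift
      fr[[wt]] <- fr[[wt]] - shift
      freqs_b[[gene]] <- fr
    }
  }
  spec <- cohort_spec(list(list(
    breed = breed,
    populations = list(list(label = "A", n = n_per_pop, freqs = freqs),
                       list(label = "B", n = n_per_pop, freqs = freqs_b)))),
    missing_rate = 0, seed = seed, models = models)
  generate_cohort(spec)
}

#' Read a cohort specification from a JSON file
#'
#' @param path JSON file with fields `breeds`, `missing_rate`, `seed`
#'   mirroring the [cohort_spec()] arguments.
#' @param models a `gene_catalogue`.
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path, models = default_gene_models()) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  breeds <- lapply(raw$breeds, function(b) list(
    breed = b$breed,
    populations = lapply(b$populations, function(p) list(
      label = p$label, n = p$n,
      freqs = lapply(p$freqs, function(fr) unlist(fr))))))
  cohort_spec(breeds,
              missing_rate = if (is.null(raw$missing_rate)) 0 else
                raw$missing_rate,
              seed = raw$seed, models = models)
}
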