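# Phenotype prediction --------------------------------------------------
#
# An expressed coat phenotype is determined by layered epistasis:
# MC1R e/e removes all eumelanin (solid phaeomelanin, any ASIP pattern
# hidden); otherwise a dominant CBD103 K^B (indistinguishable from the
# brindle k^br in this assay) overrides ASIP patterning; otherwise the
# ASIP dominance hierarchy sets the base pattern.  Modifiers (mask,
# grizzle, saddle, brown, white spotting, harlequin) each require a
# compatible background.

#' Construct a genotype call
#'
#' @param gene_id gene identifier.
#' @param alleles character vector of length 2 (unordered allele pair), or
#'   `NULL`/`NA` when missing or unresolved.
#' @param ambiguity one of `"none"`, `"kb_vs_kbr"`, `"ayt_vs_trans"`,
#'   `"unresolved"`.
#' @param missing logical flag; `TRUE` when the underlying marker calls
#'   failed.
#' @return an object of class `genotype_call`.
#' @export
genotype_call <- function(gene_id, alleles = NULL, ambiguity = "none",
                          missing = FALSE) {
  ambiguity <- match.arg(ambiguity,
                         c("none", "kb_vs_kbr", "ayt_vs_trans", "unresolved"))
  if (ambiguity == "kb_vs_kbr" && gene_id != "CBD103")
    stop("kb_vs_kbr ambiguity is only defined for CBD103")
  if (missing || ambiguity == "unresolved") {
    alleles <- c(NA_character_, NA_character_)
  } else {
    if (length(alleles) != 2L)
      stop("allele pair must have exactly two entries for gene ", gene_id)
  }
  structure(list(gene_id = gene_id,
                 allele_pair = sort(as.character(alleles), na.last = TRUE),
                 ambiguity = ambiguity, missing = isTRUE(missing)),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  pair <- if (x$missing) "./." else paste(x$allele_pair, collapse = "/")
  cat("<genotype_call> ", x$gene_id, ": ", pair,
      if (x$ambiguity != "none") paste0(" [", x$ambiguity, "]"), "\n",
      sep = "")
  invisible(x)
}

call_usable <- function(g) {
  !is.null(g) && inherits(g, "genotype_call") && !g$missing &&
    g$ambiguity != "unresolved"
}

n_copies <- function(g, symbol) {
  if (!call_usable(g)) return(NA_integer_)
  sum(g$allele_pair == symbol)
}

#' Resolve the expressed allele of one gene
#'
#' For `hierarchy` (and `overlay`) genes the lower-rank member of the
#' pair is expressed.  For `compound_recessive` genes (TYRP1) the
#' recessive phenotype class is expressed only when both alleles are
#' recessive members; otherwise the wild-type allele is returned.
#'
#' @param genotype a [genotype_call()] (not missing, not unresolved).
#' @param model the matching [gene_model()].
#' @return a one-row allele `data.frame` (see [allele_def()]).
#' @export
resolve_expressed_allele <- function(genotype, model) {
  if (!call_usable(genotype))
    stop("cannot resolve a missing or unresolved genotype at ",
         model$gene_id)
  rows <- allele_row(model, genotype$allele_pair)
  if (model$mode == "compound_recessive") {
    wt <- model$alleles[model$alleles$wild_type, , drop = FALSE]
    if (all(!rows$wild_type)) {
      # both recessive members: compound (or homozygous) recessive class
      return(rows[which.min(rows$rank), , drop = FALSE])
    }
    return(wt[1L, , drop = FALSE])
  }
  rows[which.min(rows$rank), , drop = FALSE]
}

.PATTERNS <- c("solid_phaeomelanin", "solid_eumelanin_or_brindle",
               "fawn_sable", "wolf_sable", "tan_points", "recessive_black",
               "ayt_uncharacterized", "unknown")

asip_pattern <- function(symbol) {
  switch(symbol,
         ay  = "fawn_sable",
         aw  = "wolf_sable",
         at  = "tan_points",
         a   = "recessive_black",
         ayt = "ayt_uncharacterized",
         stop("unknown ASIP allele '", symbol, "'"))
}

#' Predict the expressed phenotype from a full diploid genotype
#'
#' Applies the epistasis cascade in fixed order: (1) MC1R e/e gives a
#' solid phaeomelanin coat and hides mask/grizzle; (2) otherwise one or
#' more CBD103 K^B/k^br copies give solid eumelanin or brindle and hide
#' the ASIP pattern; (3) otherwise the expressed ASIP allele sets the
#' base pattern, with grizzle expressed and saddle "capable" only on a
#' tan-point background; (4) a melanistic mask is visible only over a
#' phaeomelanin-bearing pattern; (5) a compound-recessive TYRP1 genotype
#' browns eumelanin and the nose (the nose browns even under e/e);
#' (6) MITF white spotting expresses per breed mode; (7) a single
#' harlequin copy is "capable if merle", two copies are lethal; (8) long
#' coat requires FGF5 long/long and gates curl expression; (9) one T
#' tailless copy gives a natural bobtail, two are lethal.  BMP3 and the
#' ear marker are echoed as genotypes with a polygenic-context qualifier.
#'
#' @param genotypes named list of [genotype_call()]s keyed by gene id;
#'   MC1R, CBD103 and ASIP are required (a missing MC1R or CBD103 yields
#'   pattern `"unknown"` with a warning, not an error).
#' @param models a `gene_catalogue`; defaults to the shipped catalogue.
#' @param breed_config optional list of breed expression settings;
#'   currently `mitf_mode` in `"codominant"`, `"recessive"` or `NA`
#'   (unknown breed background).
#' @return an object of class `phenotype_report`.
#' @export
predict_phenotype <- function(genotypes, models = default_gene_models(),
                              breed_config = list()) {
  g <- function(id) genotypes[[id]]
  rep_ <- list(
    pigment_pattern = "unknown", eumelanin_shade = "unknown",
    nose_shade = "unknown", mask = "unknown", grizzle = "unknown",
    saddle = "not_capable", white_spotting = "unknown",
    harlequin = "unknown", coat_length = "unknown", curl = "unknown",
    tail = "unknown", muzzle_genotype = NA_character_,
    ear_genotype = NA_character_, viability = TRUE,
    kb_ambiguity = FALSE, warnings = character(0))

  # viability first: lethal homozygotes are flagged regardless of pattern
  for (id in names(models)) {
    gt <- g(id)
    if (!call_usable(gt)) next
    lethal <- models[[id]]$alleles$symbol[models[[id]]$alleles$lethal]
    for (sym in lethal)
      if (n_copies(gt, sym) == 2L) rep_$viability <- FALSE
  }

  mc1r <- g("MC1R"); cbd <- g("CBD103"); asip <- g("ASIP")
  if (!call_usable(mc1r) || !call_usable(cbd)) {
    warning("MC1R or CBD103 genotype unavailable; pigment pattern unknown")
    rep_$warnings <- c(rep_$warnings, "missing MC1R or CBD103")
    rep_ <- finish_overlays(rep_, genotypes, models, breed_config)
    return(structure(rep_, class = "phenotype_report"))
  }

  ee <- n_copies(mc1r, "e") == 2L
  kb <- n_copies(cbd, "KB_kbr") >= 1L
  em <- n_copies(mc1r, "EM") >= 1L
  eg <- n_copies(mc1r, "EG") >= 1L

  if (ee) {
    rep_$pigment_pattern <- "solid_phaeomelanin"
    rep_$mask <- "masked_by_epistasis"
    rep_$grizzle <- "masked_by_epistasis"
  } else if (kb) {
    rep_$pigment_pattern <- "solid_eumelanin_or_brindle"
    rep_$kb_ambiguity <- TRUE
    rep_$mask <- if (em) "masked_by_epistasis" else "absent"
    rep_$grizzle <- if (eg) "carried_unexpressed" else "absent"
  } else {
    if (call_usable(asip)) {
      expressed <- resolve_expressed_allele(asip, models$ASIP)
      rep_$pigment_pattern <- asip_pattern(expressed$symbol)
    } else {
      rep_$pigment_pattern <- "unknown"
      rep_$warnings <- c(rep_$warnings, "missing ASIP")
    }
    on_tan <- identical(rep_$pigment_pattern, "tan_points")
    rep_$grizzle <- if (!eg) "absent"
      else if (em) "carried_unexpressed"           # E^M outranks E^G
      else if (on_tan) "expressed" else "carried_unexpressed"
    phaeo_bearing <- rep_$pigment_pattern %in%
      c("fawn_sable", "wolf_sable", "tan_points")
    rep_$mask <- if (!em) "absent"
      else if (phaeo_bearing) "present" else "masked_by_epistasis"
  }

  # saddle: requires an expressed tan-point background; never certain
  # (an unknown additional modifier is required), hence "capable"
  raly <- g("RALY")
  if (call_usable(raly)) {
    rep_$saddle <- if (n_copies(raly, "saddle_dup") >= 1L &&
                       identical(rep_$pigment_pattern, "tan_points"))
      "capable" else "not_capable"
  } else rep_$saddle <- "unknown"

  rep_ <- finish_overlays(rep_, genotypes, models, breed_config)
  structure(rep_, class = "phenotype_report")
}

# overlays that do not depend on the pattern cascade
finish_overlays <- function(rep_, genotypes, models, breed_config) {
  g <- function(id) genotypes[[id]]

  tyrp1 <- g("TYRP1")
  if (call_usable(tyrp1)) {
    expressed <- resolve_expressed_allele(tyrp1, models$TYRP1)
    brown <- !expressed$wild_type
    rep_$eumelanin_shade <- if (brown) "brown" else "black"
    rep_$nose_shade <- if (brown) "brown" else "black"
  }

  mitf <- g("MITF")
  if (call_usable(mitf)) {
    nsp <- n_copies(mitf, "sp")
    mode <- breed_config$mitf_mode
    rep_$white_spotting <-
      if (nsp == 0L) "absent"
      else if (nsp == 2L) "expressed"
      else if (is.null(mode) || is.na(mode)) "breed_dependent"
      else if (mode == "codominant") "expressed"
      else "absent"
  }

  psmb7 <- g("PSMB7")
  if (call_usable(psmb7)) {
    nh <- n_copies(psmb7, "h")
    rep_$harlequin <- if (nh == 1L) "capable_if_merle" else "absent"
  }

  fgf5 <- g("FGF5"); krt71 <- g("KRT71")
  if (call_usable(fgf5))
    rep_$coat_length <- if (n_copies(fgf5, "long") == 2L) "long" else "short"
  if (call_usable(krt71)) {
    has_curl <- n_copies(krt71, "curl") >= 1L
    rep_$curl <- if (!has_curl) "absent"
      else if (identical(rep_$coat_length, "long")) "expressed"
      else "carried_masked"
  }

  tgene <- g("T")
  if (call_usable(tgene)) {
    nt <- n_copies(tgene, "tailless")
    rep_$tail <- if (nt >= 1L) "natural_bobtail" else "normal"
  }

  bmp3 <- g("BMP3")
  if (call_usable(bmp3))
    rep_$muzzle_genotype <- paste0(paste(bmp3$allele_pair, collapse = "/"),
                                   " (polygenic context)")
  ear <- g("EAR")
  if (call_usable(ear))
    rep_$ear_genotype <- paste0(paste(ear$allele_pair, collapse = "/"),
                                " (polygenic context)")
  rep_
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat("<phenotype_report>\n")
  flds <- setdiff(names(x), "warnings")
  for (f in flds)
    cat(sprintf("  %-16s %s\n", f, as.character(x[[f]])))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
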