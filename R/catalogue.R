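#' @keywords internal
"_PACKAGE"

# Gene catalogue ----------------------------------------------------------
#
# Twelve genes drive the visible coat-colour and morphology variation
# handled here: seven pigmentation loci (ASIP, MC1R, CBD103, TYRP1, MITF,
# PSMB7, RALY) and five physical-trait loci (FGF5, KRT71, T, BMP3 and a
# chromosome-10 ear-set marker).  Each gene carries an ordered allele
# hierarchy (lower rank = more dominant), a set of assayed derived-variant
# markers, and an expression mode.  Wild-type alleles at ASIP (a^w) and
# MC1R (E) have no marker of their own and are assigned by exclusion.

.VALID_MODES <- c("hierarchy", "compound_recessive", "overlay")

#' Construct a single allele definition
#'
#' @param gene_id gene identifier, e.g. `"ASIP"`.
#' @param symbol short allele label, e.g. `"ay"`.
#' @param rank integer dominance rank within the gene; lower is more
#'   dominant.
#' @param wild_type logical; is this the ancestral allele?
#' @param lethal logical; is the homozygote incompatible with live birth?
#'   True only for PSMB7 `h` and T `tailless`.
#' @param marker assay marker id, or `NA` for by-exclusion alleles.
#' @param trait phenotype label the allele can produce (used for
#'   breed-standard fault screening), or `NA`.
#' @param inheritance `"D"` (dominant), `"R"` (recessive) or `"CH"`
#'   (compound heterozygote), or `NA`.
#' @return a one-row `data.frame`.
#' @export
allele_def <- function(gene_id, symbol, rank, wild_type = FALSE,
                       lethal = FALSE, marker = NA_character_,
                       trait = NA_character_, inheritance = NA_character_) {
  stopifnot(is.character(symbol), length(symbol) == 1L,
            is.numeric(rank), length(rank) == 1L)
  data.frame(gene_id = gene_id, symbol = symbol, rank = as.integer(rank),
             wild_type = wild_type, lethal = lethal, marker = marker,
             trait = trait, inheritance = inheritance,
             stringsAsFactors = FALSE)
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param alleles `data.frame` of [allele_def()] rows, one per allele.
#' @param mode one of `"hierarchy"`, `"compound_recessive"`, `"overlay"`.
#' @param breed_overrides optional named list of per-breed expression
#'   settings (e.g. MITF white spotting co-dominant vs recessive).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, alleles, mode = "hierarchy",
                       breed_overrides = list()) {
  mode <- match.arg(mode, .VALID_MODES)
  if (anyDuplicated(alleles$rank))
    stop("duplicate dominance ranks in gene ", gene_id)
  if (anyDuplicated(alleles$symbol))
    stop("duplicate allele symbols in gene ", gene_id)
  alleles <- alleles[order(alleles$rank), , drop = FALSE]
  rownames(alleles) <- NULL
  structure(list(gene_id = gene_id, alleles = alleles, mode = mode,
                 breed_overrides = breed_overrides),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, " (", x$mode, ")\n", sep = "")
  print(x$alleles[, c("symbol", "rank", "wild_type", "lethal", "marker")])
  invisible(x)
}

#' Default gene catalogue
#'
#' Builds the shipped 12-gene catalogue: allele symbols, dominance ranks,
#' assay markers, homozygous-lethal flags and fault-trait labels.  The
#' derived cis allele `ayt` (the `ay` point mutations and the `at` SINE
#' insertion on one chromosome) is ranked most dominant so that any
#' genotype carrying it is reported as an uncharacterized pattern rather
#' than silently as fawn; its true dominance is unknown.
#'
#' @return named list of [gene_model()] objects, class `gene_catalogue`.
#' @export
default_gene_models <- function() {
  models <- list(
    ASIP = gene_model("ASIP", rbind(
      allele_def("ASIP", "ayt", 0L, trait = "ayt_uncharacterized",
                 inheritance = "D"),
      allele_def("ASIP", "ay",  1L, marker = "ay", trait = "fawn",
                 inheritance = "D"),
      allele_def("ASIP", "aw",  2L, wild_type = TRUE),
      allele_def("ASIP", "at",  3L, marker = "at", trait = "tan_points",
                 inheritance = "R"),
      allele_def("ASIP", "a",   4L, marker = "a", trait = "recessive_black",
                 inheritance = "R"))),
    MC1R = gene_model("MC1R", rbind(
      allele_def("MC1R", "EM", 1L, marker = "EM", trait = "mask",
                 inheritance = "D"),
      allele_def("MC1R", "EG", 2L, marker = "EG", trait = "grizzle",
                 inheritance = "D"),
      allele_def("MC1R", "E",  3L, wild_type = TRUE),
      allele_def("MC1R", "e",  4L, marker = "e", trait = "red",
                 inheritance = "R"))),
    CBD103 = gene_model("CBD103", rbind(
      allele_def("CBD103", "KB_kbr", 1L, marker = "KB_kbr",
                 trait = "dominant_black_or_brindle", inheritance = "D"),
      allele_def("CBD103", "ky", 2L, wild_type = TRUE))),
    TYRP1 = gene_model("TYRP1", rbind(
      allele_def("TYRP1", "B",  1L, wild_type = TRUE),
      allele_def("TYRP1", "bs", 2L, marker = "bs", trait = "brown",
                 inheritance = "CH"),
      allele_def("TYRP1", "bc", 3L, marker = "bc", trait = "brown",
                 inheritance = "CH")), mode = "compound_recessive"),
    MITF = gene_model("MITF", rbind(
      allele_def("MITF", "S",  1L, wild_type = TRUE),
      allele_def("MITF", "sp", 2L, marker = "sp", trait = "white_spotting",
                 inheritance = "R")), mode = "overlay"),
    PSMB7 = gene_model("PSMB7", rbind(
      allele_def("PSMB7", "h", 1L, lethal = TRUE, marker = "h",
                 trait = "harlequin", inheritance = "D"),
      allele_def("PSMB7", "H", 2L, wild_type = TRUE)), mode = "overlay"),
    RALY = gene_model("RALY", rbind(
      allele_def("RALY", "saddle_dup", 1L, marker = "saddle_dup",
                 trait = "saddle", inheritance = "D"),
      allele_def("RALY", "raly_wt", 2L, wild_type = TRUE)),
      mode = "overlay"),
    FGF5 = gene_model("FGF5", rbind(
      allele_def("FGF5", "short", 1L, wild_type = TRUE),
      allele_def("FGF5", "long", 2L, marker = "long", trait = "long_coat",
                 inheritance = "R"))),
    KRT71 = gene_model("KRT71", rbind(
      allele_def("KRT71", "curl", 1L, marker = "curl", trait = "curly_coat",
                 inheritance = "D"),
      allele_def("KRT71", "no_curl", 2L, wild_type = TRUE))),
    T = gene_model("T", rbind(
      allele_def("T", "tailless", 1L, lethal = TRUE, marker = "tailless",
                 trait = "natural_bobtail", inheritance = "D"),
      allele_def("T", "t_wt", 2L, wild_type = TRUE))),
    BMP3 = gene_model("BMP3", rbind(
      allele_def("BMP3", "bmp3_wt", 1L, wild_type = TRUE),
      allele_def("BMP3", "short_muzzle", 2L, marker = "short_muzzle",
                 trait = "short_muzzle", inheritance = "R"))),
    EAR = gene_model("EAR", rbind(
      allele_def("EAR", "erect", 1L, wild_type = TRUE),
      allele_def("EAR", "drop", 2L, marker = "drop", trait = "drop_ear",
                 inheritance = "R")))
  )
  structure(models, class = "gene_catalogue")
}

#' Marker identifiers assayed by a catalogue
#'
#' @param models a `gene_catalogue`.
#' @return character vector of marker column names in catalogue order.
#' @export
marker_ids <- function(models = default_gene_models()) {
  unlist(lapply(models, function(m) {
    mk <- m$alleles$marker
    mk[!is.na(mk)]
  }), use.names = FALSE)
}

# Map an allele symbol to its model row (errors on unknown symbols).
allele_row <- function(model, symbol) {
  i <- match(symbol, model$alleles$symbol)
  if (anyNA(i))
    stop("unknown allele symbol '", paste(symbol[is.na(i)], collapse = ","),
         "' for gene ", model$gene_id)
  model$alleles[i, , drop = FALSE]
}

#' Write a gene catalogue to a JSON config file
#'
#' @param models a `gene_catalogue`.
#' @param path output file path.
#' @export
write_gene_models <- function(models, path) {
  out <- lapply(models, function(m)
    list(gene_id = m$gene_id, mode = m$mode,
         breed_overrides = m$breed_overrides,
         alleles = m$alleles))
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a gene catalogue from a JSON config file
#'
#' The shipped default config is an exact serialization of
#' [default_gene_models()].
#'
#' @param path JSON file written by [write_gene_models()].
#' @return a `gene_catalogue`.
#' @export
read_gene_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  models <- lapply(raw, function(m) {
    al <- as.data.frame(m$alleles, stringsAsFactors = FALSE)
    for (col in c("marker", "trait", "inheritance"))
      al[[col]] <- as.character(al[[col]])
    al$rank <- as.integer(al$rank)
    al$wild_type <- as.logical(al$wild_type)
    al$lethal <- as.logical(al$lethal)
    bo <- m$breed_overrides
    if (is.null(bo) || length(bo) == 0L) bo <- list()
    gene_model(m$gene_id, al, mode = m$mode, breed_overrides = bo)
  })
  names(models) <- vapply(models, function(m) m$gene_id, character(1))
  structure(models, class = "gene_catalogue")
}
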