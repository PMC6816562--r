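# Worked-example demo ------------------------------------------------------
#
# A deterministic demonstration cohort whose realized allele counts hit
# the published worked-example frequencies exactly: Bull Terrier TYRP1
# b^s = b^c = 0.03 (n = 100), UK Schipperke MC1R e = 0.50 (n = 6, three
# e/e and three E/E dogs; the US population is fixed E), Great Dane
# CBD103 K^B/k^br = 0.66, MITF s^p = 0.06, PSMB7 h = 0.21 (n = 50), and
# Shetland Sheepdog MITF s^p at 16% (UK) and 6% (US).  Frequencies are
# stated as chromosome counts, so the table is constructed, not sampled.

blank_markers <- function(dog_id, breed, population,
                          models = default_gene_models()) {
  n <- length(dog_id)
  df <- data.frame(dog_id = dog_id, breed = breed, population = population,
                   stringsAsFactors = FALSE)
  for (mk in marker_ids(models)) df[[mk]] <- 0L
  df
}

# spread `count` variant chromosomes over dogs: fill homozygotes first,
# remainder as one heterozygote (count <= 2n)
spread_copies <- function(n, count) {
  copies <- integer(n)
  hom <- count %/% 2L
  copies[seq_len(hom)] <- 2L
  if (count %% 2L) copies[hom + 1L] <- 1L
  copies
}

#' Deterministic demonstration genotype table
#'
#' @param models a `gene_catalogue`.
#' @return genotype table in the [read_genotype_table()] dialect with
#'   four breeds (BULT, SKIP, DANE, SSHP) whose allele counts reproduce
#'   the worked-example frequencies exactly.
#' @export
demo_genotype_table <- function(models = default_gene_models()) {
  bult <- blank_markers(sprintf("BULT_%03d", 1:100), "BULT", "US", models)
  bult$bs[1:6] <- 1L          # 6 / 200 chromosomes = 0.03
  bult$bc[7:12] <- 1L

  skip_uk <- blank_markers(sprintf("SKIP_UK_%03d", 1:6), "SKIP", "UK",
                           models)
  skip_uk$e[1:3] <- 2L        # three e/e, three E/E: e = 0.50
  skip_us <- blank_markers(sprintf("SKIP_US_%03d", 1:44), "SKIP", "US",
                           models)

  dane <- blank_markers(sprintf("DANE_%03d", 1:50), "DANE", "US", models)
  dane$KB_kbr <- spread_copies(50L, 66L)   # 66 / 100 = 0.66
  dane$sp <- rev(spread_copies(50L, 6L))   # 6 / 100  = 0.06
  dane$h[15:35] <- 1L                      # 21 heterozygotes = 0.21

  sshp_uk <- blank_markers(sprintf("SSHP_UK_%03d", 1:25), "SSHP", "UK",
                           models)
  sshp_uk$sp[1:8] <- 1L       # 8 / 50 = 0.16
  sshp_us <- blank_markers(sprintf("SSHP_US_%03d", 1:50), "SSHP", "US",
                           models)
  sshp_us$sp[1:6] <- 1L       # 6 / 100 = 0.06

  out <- rbind(bult, skip_uk, skip_us, dane, sshp_uk, sshp_us)
  rownames(out) <- NULL
  out
}

#' Declarative worked-example fault-probability cases
#'
#' Four cases evaluated against the demo frequencies: Bull Terrier brown
#' (compound recessive TYRP1), UK Schipperke red (recessive MC1R e),
#' Great Dane fawn-and-white (homozygous k^y with co-dominant MITF
#' spotting) and Great Dane fawn with one harlequin copy (homozygous
#' k^y with heterozygous-only PSMB7 h, unrenormalized as published).
#'
#' @return list of case lists for [evaluate_fault_case()].
#' @export
demo_fault_cases <- function() {
  list(
    list(name = "bull_terrier_brown", breed = "BULT",
         factors = list(list(gene = "TYRP1", alleles = c("bs", "bc"),
                             mode = "homozygous_recessive"))),
    list(name = "schipperke_uk_red", breed = "SKIP", population = "UK",
         factors = list(list(gene = "MC1R", alleles = "e",
                             mode = "homozygous_recessive"))),
    list(name = "great_dane_fawn_white", breed = "DANE",
         factors = list(list(gene = "CBD103", alleles = "ky",
                             mode = "homozygous_recessive"),
                        list(gene = "MITF", alleles = "sp",
                             mode = "het_or_hom"))),
    list(name = "great_dane_fawn_harlequin", breed = "DANE",
         factors = list(list(gene = "CBD103", alleles = "ky",
                             mode = "homozygous_recessive"),
                        list(gene = "PSMB7", alleles = "h",
                             mode = "heterozygous_only"))))
}

#' Write the packaged demo run into a directory
#'
#' Creates `genotypes.tsv` (from [demo_genotype_table()]) and
#' `config.json` wiring the interpret/freq/faults steps, the shipped
#' breed-standard table and the four worked-example fault cases.
#'
#' @param dir target directory (created if needed).
#' @param seed run seed recorded in the config.
#' @return path to the written config file.
#' @export
write_demo_run <- function(dir = tempfile("ctdemo"), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt_path <- file.path(dir, "genotypes.tsv")
  write_genotype_table(demo_genotype_table(), gt_path)
  config <- list(
    steps = list("interpret", "freq", "faults"),
    seed = seed,
    genotype_table = gt_path,
    standards = system.file("extdata", "breed_standards.csv",
                            package = "caninetraits"),
    fault_cases = demo_fault_cases(),
    outdir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  cfg_path
}
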