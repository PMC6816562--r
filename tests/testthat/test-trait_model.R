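models <- default_gene_models()

test_that("dominance hierarchies resolve the expressed allele", {
  expect_equal(resolve_expressed_allele(
    genotype_call("ASIP", c("ay", "a")), models$ASIP)$symbol, "ay")
  expect_equal(resolve_expressed_allele(
    genotype_call("MC1R", c("EG", "e")), models$MC1R)$symbol, "EG")
  # homozygotes express themselves, across every gene
  for (g in names(models)) {
    for (sym in models[[g]]$alleles$symbol) {
      expect_equal(resolve_expressed_allele(
        genotype_call(g, c(sym, sym)), models[[g]])$symbol, sym)
    }
  }
  expect_error(resolve_expressed_allele(
    genotype_call("ASIP", c("ay", "zz")), models$ASIP), "unknown allele")
})

test_that("TYRP1 expresses brown only as a compound or homozygous recessive", {
  brown <- function(pair) resolve_expressed_allele(
    genotype_call("TYRP1", pair), models$TYRP1)$wild_type
  expect_false(brown(c("bs", "bc")))   # compound heterozygote
  expect_false(brown(c("bs", "bs")))
  expect_true(brown(c("bs", "B")))     # carrier stays black
  expect_true(brown(c("B", "B")))
})

test_that("epistasis cascade matches the worked cases", {
  r <- predict_phenotype(wt_background(MC1R = c("e", "e"),
                                       CBD103 = c("KB_kbr", "KB_kbr")),
                         models)
  expect_equal(r$pigment_pattern, "solid_phaeomelanin")

  r <- predict_phenotype(wt_background(), models)
  expect_equal(r$pigment_pattern, "wolf_sable")
  expect_equal(r$eumelanin_shade, "black")
  expect_equal(r$mask, "absent")
  expect_equal(r$white_spotting, "absent")
  expect_equal(r$coat_length, "short")
  expect_equal(r$tail, "normal")
  expect_true(r$viability)

  # dominant black hides ASIP but not the nose-brown of TYRP1
  r <- predict_phenotype(wt_background(CBD103 = c("KB_kbr", "ky"),
                                       ASIP = c("at", "at"),
                                       TYRP1 = c("bs", "bc")), models)
  expect_equal(r$pigment_pattern, "solid_eumelanin_or_brindle")
  expect_true(r$kb_ambiguity)
  expect_equal(r$eumelanin_shade, "brown")
  expect_equal(r$nose_shade, "brown")

  # nose browns even under e/e
  r <- predict_phenotype(wt_background(MC1R = c("e", "e"),
                                       TYRP1 = c("bc", "bc")), models)
  expect_equal(r$pigment_pattern, "solid_phaeomelanin")
  expect_equal(r$nose_shade, "brown")
})

test_that("grizzle, saddle and mask require their backgrounds", {
  # grizzle expressed only on tan points
  r <- predict_phenotype(wt_background(MC1R = c("EG", "e"),
                                       ASIP = c("at", "at")), models)
  expect_equal(r$grizzle, "expressed")
  r <- predict_phenotype(wt_background(MC1R = c("EG", "e"),
                                       ASIP = c("ay", "at")), models)
  expect_equal(r$grizzle, "carried_unexpressed")
  # E^M outranks E^G
  r <- predict_phenotype(wt_background(MC1R = c("EM", "EG"),
                                       ASIP = c("at", "at")), models)
  expect_equal(r$grizzle, "carried_unexpressed")
  expect_equal(r$mask, "present")
  # saddle capable only on tan points, and never more than capable
  r <- predict_phenotype(wt_background(ASIP = c("at", "at"),
                                       RALY = c("saddle_dup", "raly_wt")),
                         models)
  expect_equal(r$saddle, "capable")
  r <- predict_phenotype(wt_background(ASIP = c("ay", "at"),
                                       RALY = c("saddle_dup", "raly_wt")),
                         models)
  expect_equal(r$saddle, "not_capable")
  # mask invisible on solid eumelanin
  r <- predict_phenotype(wt_background(MC1R = c("EM", "E"),
                                       CBD103 = c("KB_kbr", "ky")), models)
  expect_equal(r$mask, "masked_by_epistasis")
})

test_that("lethal, coat and bobtail gating behave as specified", {
  r <- predict_phenotype(wt_background(PSMB7 = c("h", "H")), models)
  expect_equal(r$harlequin, "capable_if_merle")
  expect_true(r$viability)
  r <- predict_phenotype(wt_background(PSMB7 = c("h", "h")), models)
  expect_equal(r$harlequin, "absent")
  expect_false(r$viability)
  r <- predict_phenotype(wt_background(T = c("tailless", "t_wt")), models)
  expect_equal(r$tail, "natural_bobtail")
  expect_true(r$viability)
  r <- predict_phenotype(wt_background(T = c("tailless", "tailless")),
                         models)
  expect_false(r$viability)
  # curl expressed only on a long coat
  r <- predict_phenotype(wt_background(KRT71 = c("curl", "no_curl")),
                         models)
  expect_equal(r$curl, "carried_masked")
  r <- predict_phenotype(wt_background(KRT71 = c("curl", "no_curl"),
                                       FGF5 = c("long", "long")), models)
  expect_equal(r$coat_length, "long")
  expect_equal(r$curl, "expressed")
  # polygenic loci are echoed as genotypes, not phenotypes
  r <- predict_phenotype(wt_background(BMP3 = c("short_muzzle",
                                                "short_muzzle")), models)
  expect_match(r$muzzle_genotype, "polygenic context")
})

test_that("missing MC1R or CBD103 degrades to unknown with a warning", {
  gts <- wt_background()
  gts$MC1R <- genotype_call("MC1R", missing = TRUE)
  expect_warning(r <- predict_phenotype(gts, models), "MC1R or CBD103")
  expect_equal(r$pigment_pattern, "unknown")
})

test_that("pigment cascade matches the rule-table oracle exhaustively", {
  asip_alleles <- c("ay", "aw", "at", "a")
  mc1r_alleles <- c("EM", "EG", "E", "e")
  pairs_of <- function(a) {
    idx <- which(upper.tri(diag(length(a)), diag = TRUE), arr.ind = TRUE)
    lapply(seq_len(nrow(idx)), function(i) a[c(idx[i, 1], idx[i, 2])])
  }
  asip_pairs <- pairs_of(asip_alleles)   # 10
  mc1r_pairs <- pairs_of(mc1r_alleles)   # 10
  cbd_pairs <- pairs_of(c("KB_kbr", "ky"))  # 3
  n_checked <- 0
  for (ap in asip_pairs) for (mp in mc1r_pairs) for (cp in cbd_pairs) {
    r <- predict_phenotype(wt_background(ASIP = ap, MC1R = mp,
                                         CBD103 = cp), models)
    o <- oracle_pigment(ap, mp, cp)
    expect_equal(r$pigment_pattern, o$pattern,
                 info = paste(ap[1], ap[2], mp[1], mp[2], cp[1], cp[2]))
    expect_equal(r$mask, o$mask)
    expect_equal(r$grizzle, o$grizzle)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
  # the derived cis allele surfaces as uncharacterized, never as fawn
  r <- predict_phenotype(wt_background(ASIP = c("ayt", "a")), models)
  expect_equal(r$pigment_pattern, "ayt_uncharacterized")
})

test_that("epistasis masking and dominance monotonicity invariants hold", {
  asip_pairs <- list(c("ay", "ay"), c("ay", "a"), c("aw", "at"),
                     c("at", "a"), c("a", "a"), c("ayt", "at"))
  # under e/e or K^B the report ignores ASIP entirely
  for (blocker in list(list(MC1R = c("e", "e")),
                       list(CBD103 = c("KB_kbr", "ky")))) {
    reps <- lapply(asip_pairs, function(ap) {
      args <- c(list(ASIP = ap), blocker)
      r <- predict_phenotype(do.call(wt_background, args), models)
      unlist(r[c("pigment_pattern", "mask", "grizzle", "saddle")])
    })
    for (i in seq_along(reps)[-1]) expect_identical(reps[[i]], reps[[1]])
  }
  # replacing one allele by a more dominant one never demotes expression
  for (g in c("ASIP", "MC1R")) {
    al <- models[[g]]$alleles
    al <- al[al$symbol != "ayt", ]
    syms <- al$symbol[order(al$rank)]
    for (other in syms) for (i in seq_along(syms)[-1]) {
      lo <- resolve_expressed_allele(
        genotype_call(g, c(other, syms[i])), models[[g]])$rank
      hi <- resolve_expressed_allele(
        genotype_call(g, c(other, syms[i - 1])), models[[g]])$rank
      expect_lte(hi, lo)
    }
  }
})

test_that("MITF expression honours the breed mode", {
  het <- wt_background(MITF = c("sp", "S"))
  expect_equal(predict_phenotype(het, models,
                                 breed_config = list(mitf_mode = "codominant"))$white_spotting,
               "expressed")
  expect_equal(predict_phenotype(het, models,
                                 breed_config = list(mitf_mode = "recessive"))$white_spotting,
               "absent")
  expect_equal(predict_phenotype(het, models)$white_spotting,
               "breed_dependent")
  hom <- wt_background(MITF = c("sp", "sp"))
  expect_equal(predict_phenotype(hom, models,
                                 breed_config = list(mitf_mode = "recessive"))$white_spotting,
               "expressed")
})

test_that("gene catalogue config round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_gene_models(models, path)
  back <- read_gene_models(path)
  expect_identical(names(back), names(models))
  for (g in names(models)) {
    expect_identical(back[[g]]$alleles, models[[g]]$alleles)
    expect_identical(back[[g]]$mode, models[[g]]$mode)
  }
  # shipped default config is the Table-style catalogue exactly
  shipped <- read_gene_models(system.file("extdata", "gene_models.json",
                                          package = "caninetraits"))
  expect_identical(marker_ids(shipped), marker_ids(models))
})
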