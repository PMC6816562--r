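models <- default_gene_models()

test_that("fault_probability reproduces the published worked examples", {
  # Bull Terrier brown: compound recessive b^s = b^c = 0.03
  expect_equal(fault_probability(fault_factor(0.03, 0.03,
                                              "homozygous_recessive")),
               0.0036, tolerance = 1e-12)
  # Schipperke UK red: e = 0.50 recessive
  expect_equal(fault_probability(fault_factor(0.5,
                                              mode = "homozygous_recessive")),
               0.25, tolerance = 1e-12)
  # Great Dane fawn-and-white and fawn-with-one-harlequin-copy
  fw <- fault_probability(list(
    fault_factor(0.34, mode = "homozygous_recessive"),
    fault_factor(0.06, mode = "het_or_hom")))
  expect_equal(fw, (1 - 0.66)^2 * (1 - (1 - 0.06)^2), tolerance = 1e-12)
  fh <- fault_probability(list(
    fault_factor(0.34, mode = "homozygous_recessive"),
    fault_factor(0.21, mode = "heterozygous_only")))
  expect_equal(fh, (1 - 0.66)^2 * 2 * 0.21 * 0.79, tolerance = 1e-12)
})

test_that("boundary frequencies behave", {
  expect_equal(fault_probability(fault_factor(0, mode = "dominant_or_better")),
               0)
  expect_equal(fault_probability(fault_factor(1, mode = "dominant_or_better")),
               1)
  expect_error(fault_factor(1.2), "\\[0, 1\\]")
  expect_error(fault_factor(0.5, c(0.3, 0.3, 0.3)), "sum to at most 1")
  expect_error(fault_factor(0.1, c(0.1, 0.1, 0.1, 0.1)), "at most 3")
})

test_that("live-birth correction is the analytic renormalization", {
  expect_equal(live_birth_correction(0.1), 0.1)            # identity
  expect_equal(live_birth_correction(0.3, 0.5), 0.3 / 0.75)
  expect_equal(live_birth_correction(0.2, c(0.5, 0.2)),
               0.2 / (0.75 * 0.96))
  expect_error(live_birth_correction(0.1, 1.5), "\\[0, 1\\]")
  # matches enumeration conditioned on viable genotypes
  f <- fault_factor(0.21, mode = "heterozygous_only")
  got <- fault_probability(f, lethal_freqs = 0.21, live_birth = TRUE)
  want <- oracle_fault_prob(list(list(p = 0.21, q = numeric(0),
                                      mode = "heterozygous_only")),
                            lethal_freqs = 0.21, live_birth = TRUE)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("closed form equals the enumeration oracle on a mode grid", {
  modes <- c("dominant_or_better", "homozygous_recessive",
             "heterozygous_only", "het_or_hom")
  grid_p <- c(0, 0.03, 0.21, 0.5, 0.9)
  for (m1 in modes) for (m2 in modes) for (p1 in grid_p) {
    factors <- list(fault_factor(p1, min(0.05, 1 - p1), m1),
                    fault_factor(0.3, mode = m2))
    raw <- list(list(p = p1, q = min(0.05, 1 - p1), mode = m1),
                list(p = 0.3, q = numeric(0), mode = m2))
    expect_equal(fault_probability(factors),
                 oracle_fault_prob(raw), tolerance = 1e-12,
                 info = paste(m1, m2, p1))
  }
})

test_that("fault probability is nondecreasing in the fault-allele frequency", {
  for (mode in c("dominant_or_better", "homozygous_recessive",
                 "het_or_hom")) {
    ps <- seq(0, 0.6, by = 0.05)
    vals <- vapply(ps, function(p)
      fault_probability(list(fault_factor(p, 0.1, mode),
                             fault_factor(0.4, mode = "het_or_hom"))),
      numeric(1))
    expect_true(all(diff(vals) >= -1e-15), info = mode)
  }
  # heterozygous-only is monotone on [0, 1/2]
  ps <- seq(0, 0.5, by = 0.05)
  vals <- vapply(ps, function(p)
    fault_probability(fault_factor(p, mode = "heterozygous_only")),
    numeric(1))
  expect_true(all(diff(vals) >= -1e-15))
})

test_that("the standards reader validates its input", {
  std <- read_breed_standards()
  expect_true(all(c("breed", "registry", "trait", "tolerance") %in%
                    names(std)))
  expect_true(all(std$tolerance %in% c("N", "n.p.", "Y", "amb.",
                                       "not_recognized")))
  bad <- withr::local_tempfile(lines = c("breed,registry,trait,tolerance",
                                         "X,AKC,brown,maybe"))
  expect_error(read_breed_standards(bad), "unknown tolerance")
  dup <- withr::local_tempfile(lines = c("breed,registry,trait,tolerance",
                                         "X,AKC,brown,N", "X,AKC,brown,Y"))
  expect_error(read_breed_standards(dup), "duplicate")
})

test_that("fault detection matches a hand-enumerated truth set", {
  markers <- demo_genotype_table()
  calls <- interpret_genotypes(markers, models)
  freqs <- estimate_frequencies(calls, by = c("breed", "population"))
  std <- read_breed_standards()
  findings <- detect_fault_alleles(freqs, std, models)
  # hand enumeration: BULT carries bs+bc (brown N at 4 registries ->
  # 8 rows); SKIP carries e (red N at AKC/UKC/FCI -> 3 rows, KC allows);
  # DANE carries sp and h (amb. x 4 each -> 8 flagged rows);
  # SSHP carries sp (N at AKC, n.p. at KC+FCI -> 3 rows, UKC allows)
  expect_equal(nrow(findings), 8 + 3 + 8 + 3)
  bult <- findings[findings$breed == "BULT", ]
  expect_setequal(bult$registry, c("AKC", "UKC", "KC", "FCI"))
  expect_setequal(bult$allele, c("bs", "bc"))
  expect_true(all(bult$inheritance == "CH"))
  skip <- findings[findings$breed == "SKIP", ]
  expect_setequal(skip$registry, c("AKC", "UKC", "FCI"))
  expect_false("KC" %in% skip$registry)
  dane <- findings[findings$breed == "DANE", ]
  expect_true(all(dane$ambiguous))
  sshp <- findings[findings$breed == "SSHP", ]
  expect_setequal(sshp$tolerance, c("N", "n.p."))
  # a breed fixed wild-type everywhere yields no findings
  wtm <- markers[markers$breed == "SKIP" & markers$population == "US", ]
  wtm$breed <- "BLRT"
  wtc <- interpret_genotypes(wtm, models)
  wtf <- estimate_frequencies(wtc, by = c("breed", "population"))
  expect_equal(nrow(detect_fault_alleles(wtf, std, models)), 0L)
  # breeds absent from the standards table are skipped with a warning
  unk <- markers[markers$breed == "BULT", ]
  unk$breed <- "NOPE"
  unkf <- estimate_frequencies(interpret_genotypes(unk, models),
                               by = c("breed", "population"))
  expect_warning(res <- detect_fault_alleles(unkf, std, models),
                 "no standards")
  expect_equal(nrow(res), 0L)
})

test_that("declarative fault cases resolve frequencies from the table", {
  markers <- demo_genotype_table()
  calls <- interpret_genotypes(markers, models)
  freqs <- estimate_frequencies(calls, by = c("breed", "population"))
  cases <- demo_fault_cases()
  probs <- vapply(cases, function(cs)
    evaluate_fault_case(cs, freqs)$probability, numeric(1))
  names(probs) <- vapply(cases, `[[`, "", "name")
  expect_equal(unname(probs["bull_terrier_brown"]), 0.0036,
               tolerance = 1e-12)
  expect_equal(unname(probs["schipperke_uk_red"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(probs["great_dane_fawn_white"]),
               (1 - 0.66)^2 * (1 - 0.94^2), tolerance = 1e-12)
  expect_equal(unname(probs["great_dane_fawn_harlequin"]),
               (1 - 0.66)^2 * 2 * 0.21 * 0.79, tolerance = 1e-12)
  bad <- list(name = "x", breed = "BULT",
              factors = list(list(gene = "ASIP", alleles = "a",
                                  mode = "het_or_hom")))
  # ASIP is genotyped in the demo table, so frequency 0, probability 0
  expect_equal(evaluate_fault_case(bad, freqs)$probability, 0)
})
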