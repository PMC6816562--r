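# Independent oracles used across the suite.  These re-derive expected
# values by brute force (enumeration, exhaustive subset search, direct
# tallying) and deliberately share no code with the package internals.

# --- Hardy-Weinberg enumeration oracle for fault probabilities ----------
# Enumerates ordered diploid genotypes over the alleles {P, Q1..Qk, O},
# where O pools everything outside the named class, and sums the HWE
# probability of genotypes whose phenotype indicator fires.
oracle_factor <- function(p, q, mode) {
  freqs <- c(P = p)
  if (length(q)) freqs <- c(freqs, stats::setNames(q, paste0("Q", seq_along(q))))
  freqs <- c(freqs, O = max(0, 1 - p - sum(q)))
  syms <- names(freqs)
  tot <- 0
  for (i in syms) for (j in syms) {
    nP <- (i == "P") + (j == "P")
    in_class <- (i != "O") + (j != "O")
    hit <- switch(mode,
                  dominant_or_better   = nP >= 1 && in_class == 2,
                  homozygous_recessive = in_class == 2,
                  heterozygous_only    = nP == 1,
                  het_or_hom           = nP >= 1)
    if (hit) tot <- tot + freqs[[i]] * freqs[[j]]
  }
  tot
}

oracle_fault_prob <- function(factors, lethal_freqs = numeric(0),
                              live_birth = FALSE) {
  pr <- prod(vapply(factors, function(f)
    oracle_factor(f$p, f$q, f$mode), numeric(1)))
  if (live_birth) {
    for (pl in lethal_freqs) {
      # viable conception mass at an independent homozygous-lethal locus
      viable <- 0
      for (i in c("L", "o")) for (j in c("L", "o")) {
        if (i == "L" && j == "L") next
        viable <- viable +
          (if (i == "L") pl else 1 - pl) * (if (j == "L") pl else 1 - pl)
      }
      pr <- pr / viable
    }
  }
  pr
}

# --- rule-table oracle for the ASIP x MC1R x CBD103 pigment cascade -----
oracle_pigment <- function(asip, mc1r, cbd) {
  ee <- sum(mc1r == "e") == 2
  kb <- any(cbd == "KB_kbr")
  em <- any(mc1r == "EM"); eg <- any(mc1r == "EG")
  if (ee) {
    return(list(pattern = "solid_phaeomelanin",
                mask = "masked_by_epistasis",
                grizzle = "masked_by_epistasis"))
  }
  if (kb) {
    return(list(pattern = "solid_eumelanin_or_brindle",
                mask = if (em) "masked_by_epistasis" else "absent",
                grizzle = if (eg) "carried_unexpressed" else "absent"))
  }
  ord <- c(ayt = 0, ay = 1, aw = 2, at = 3, a = 4)
  top <- asip[which.min(ord[asip])]
  pattern <- c(ayt = "ayt_uncharacterized", ay = "fawn_sable",
               aw = "wolf_sable", at = "tan_points",
               a = "recessive_black")[[top]]
  grizzle <- if (!eg) "absent"
    else if (em) "carried_unexpressed"
    else if (pattern == "tan_points") "expressed" else "carried_unexpressed"
  mask <- if (!em) "absent"
    else if (pattern %in% c("fawn_sable", "wolf_sable", "tan_points"))
      "present" else "masked_by_epistasis"
  list(pattern = pattern, mask = mask, grizzle = grizzle)
}

# --- exact two-sided Fisher 2x2 by hypergeometric enumeration -----------
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  pobs <- choose(r1, m[1, 1]) * choose(r2, m[2, 1]) / choose(n, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# --- brute-force Steiner-subset oracle ----------------------------------
# union-find connectivity on a node subset
uf_carrier_components <- function(nodes, edges, carriers) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  keep <- edges$breed_a %in% nodes & edges$breed_b %in% nodes
  for (k in which(keep)) {
    ra <- find(edges$breed_a[k]); rb <- find(edges$breed_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(carriers, find, character(1))))
}

# minimal number of connector nodes achieving the best-possible carrier
# component count (the count with every candidate included)
oracle_min_connectors <- function(edges, carriers, candidates) {
  target <- uf_carrier_components(c(carriers, candidates), edges, carriers)
  for (k in 0:length(candidates)) {
    if (k == 0) {
      if (uf_carrier_components(carriers, edges, carriers) == target)
        return(0L)
      next
    }
    combs <- utils::combn(candidates, k)
    for (ci in seq_len(ncol(combs))) {
      nodes <- c(carriers, combs[, ci])
      if (uf_carrier_components(nodes, edges, carriers) == target)
        return(k)
    }
  }
  length(candidates)
}

# --- direct tally oracle for allele frequencies -------------------------
oracle_tally <- function(calls, breed, gene) {
  sub <- calls[calls$breed == breed & calls$gene == gene &
                 !calls$missing & calls$ambiguity != "unresolved", ]
  chrom <- c(sub$allele1, sub$allele2)
  tab <- table(chrom)
  list(counts = tab, freqs = tab / sum(tab), n = nrow(sub))
}

# --- shared builders ----------------------------------------------------
# genotype list for predict_phenotype from compact symbol pairs
gt_list <- function(...) {
  pairs <- list(...)
  out <- lapply(names(pairs), function(g)
    genotype_call(g, pairs[[g]]))
  names(out) <- names(pairs)
  out
}

# full wild-type background, overridable
wt_background <- function(...) {
  base <- list(ASIP = c("aw", "aw"), MC1R = c("E", "E"),
               CBD103 = c("ky", "ky"), TYRP1 = c("B", "B"),
               MITF = c("S", "S"), PSMB7 = c("H", "H"),
               RALY = c("raly_wt", "raly_wt"), FGF5 = c("short", "short"),
               KRT71 = c("no_curl", "no_curl"), T = c("t_wt", "t_wt"),
               BMP3 = c("bmp3_wt", "bmp3_wt"), EAR = c("erect", "erect"))
  ov <- list(...)
  base[names(ov)] <- ov
  do.call(gt_list, base)
}

random_fault_factor <- function() {
  mode <- sample(c("dominant_or_better", "homozygous_recessive",
                   "heterozygous_only", "het_or_hom"), 1)
  nq <- sample(0:3, 1)
  raw <- stats::runif(1 + nq)
  raw <- raw / sum(raw) * stats::runif(1)   # total class frequency < 1
  list(p = raw[1], q = if (nq) raw[-1] else numeric(0), mode = mode)
}
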