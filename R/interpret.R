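# Genotype interpretation -------------------------------------------------
#
# The assay reports per-variant copy counts (0/1/2, or NA on sporadic
# failure).  Multi-allelic genes are assembled from several markers:
# chromosomes not accounted for by a derived variant carry the
# by-exclusion wild-type allele (ASIP a^w, MC1R E).  When the derived
# copies at ASIP exceed two, the only cis combination the assay is known
# to produce is a^y plus a^t on one chromosome (the a^yt allele); other
# excesses are left unresolved rather than guessed.

#' Assemble an ASIP genotype from marker copy counts
#'
#' Vectorized over dogs.  With total derived copies `T`: `T <= 2` pads
#' with `a^w`; `T = 3` with at least one `a^y` and one `a^t` collapses one
#' cis pair into `a^yt` (flagging `ayt_vs_trans` when the third allele is
#' `a`); `T = 4` with `a^y = a^t = 2` yields `a^yt/a^yt`; any other excess
#' is `unresolved`.  Any missing constituent marker voids the genotype.
#'
#' @param ay,at,a integer copy counts in 0..2 (NA = failed call);
#'   recycled to a common length.
#' @return `data.frame` with columns `allele1`, `allele2`, `ambiguity`,
#'   `missing`.
#' @export
interpret_asip <- function(ay, at, a) {
  n <- max(length(ay), length(at), length(a))
  ay <- rep_len(as.integer(ay), n); at <- rep_len(as.integer(at), n)
  a  <- rep_len(as.integer(a), n)
  chk <- c(ay, at, a)
  if (any(chk < 0L | chk > 2L, na.rm = TRUE))
    stop("marker copy counts must be 0, 1, 2 or NA")
  a1 <- a2 <- rep(NA_character_, n)
  amb <- rep("none", n)
  miss <- is.na(ay) | is.na(at) | is.na(a)
  tot <- ay + at + a

  ok <- !miss & tot <= 2L
  if (any(ok)) {
    pair <- pad_pair(cbind(ay = ay[ok], at = at[ok], a = a[ok]), "aw")
    a1[ok] <- pair[, 1L]; a2[ok] <- pair[, 2L]
  }

  amb[!miss & tot > 2L] <- "unresolved"   # default for any excess
  t3 <- !miss & tot == 3L
  cis <- t3 & ay >= 1L & at >= 1L
  if (any(cis)) {
    # remove one ay and one at (the cis chromosome), keep the remainder
    r_ay <- ay[cis] - 1L; r_at <- at[cis] - 1L; r_a <- a[cis]
    rem <- character(sum(cis))
    rem[r_ay == 1L] <- "ay"; rem[r_at == 1L] <- "at"; rem[r_a == 1L] <- "a"
    a1[cis] <- "ayt"; a2[cis] <- rem
    amb[cis] <- ifelse(r_a == 1L, "ayt_vs_trans", "none")
  }
  t4 <- !miss & tot == 4L
  dd <- t4 & ay == 2L & at == 2L
  a1[dd] <- "ayt"; a2[dd] <- "ayt"
  amb[dd] <- "none"

  a1[miss | amb == "unresolved"] <- NA_character_
  a2[miss | amb == "unresolved"] <- NA_character_
  pair_df(a1, a2, amb, miss)
}

#' Assemble an MC1R genotype from marker copy counts
#'
#' As [interpret_asip()] with `E` as the by-exclusion allele; no cis
#' combination is described for MC1R, so any total above two derived
#' copies is `unresolved`.
#'
#' @param EM,EG,e integer copy counts in 0..2 (NA = failed call).
#' @return `data.frame` as in [interpret_asip()].
#' @export
interpret_mc1r <- function(EM, EG, e) {
  n <- max(length(EM), length(EG), length(e))
  EM <- rep_len(as.integer(EM), n); EG <- rep_len(as.integer(EG), n)
  e  <- rep_len(as.integer(e), n)
  chk <- c(EM, EG, e)
  if (any(chk < 0L | chk > 2L, na.rm = TRUE))
    stop("marker copy counts must be 0, 1, 2 or NA")
  a1 <- a2 <- rep(NA_character_, n)
  amb <- rep("none", n)
  miss <- is.na(EM) | is.na(EG) | is.na(e)
  tot <- EM + EG + e
  ok <- !miss & tot <= 2L
  if (any(ok)) {
    pair <- pad_pair(cbind(EM = EM[ok], EG = EG[ok], e = e[ok]), "E")
    a1[ok] <- pair[, 1L]; a2[ok] <- pair[, 2L]
  }
  amb[!miss & tot > 2L] <- "unresolved"
  pair_df(a1, a2, amb, miss)
}

# counts: matrix with allele-named columns summing to <= 2 per row;
# returns a two-column character matrix padded with the exclusion allele
pad_pair <- function(counts, exclusion) {
  n <- nrow(counts)
  out <- matrix(exclusion, n, 2L)
  syms <- colnames(counts)
  for (i in seq_len(n)) {
    al <- rep(syms, counts[i, ])
    if (length(al)) out[i, seq_along(al)] <- al
  }
  out
}

pair_df <- function(a1, a2, amb, miss) {
  sw <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
  data.frame(allele1 = a1, allele2 = a2, ambiguity = amb, missing = miss,
             stringsAsFactors = FALSE)
}

#' Assemble a biallelic (or compound TYRP1) genotype from copy counts
#'
#' Single-variant genes map copies 0/1/2 to wt/wt, wt/var and var/var.
#' TYRP1 combines the `b^s` and `b^c` counts (their total must not exceed
#' two) and pads with wild-type `B`.
#'
#' @param model a [gene_model()].
#' @param ... named integer copy-count vectors, one per assayed marker of
#'   the gene (names must match the model's marker ids).
#' @return `data.frame` as in [interpret_asip()].
#' @export
interpret_biallelic <- function(model, ...) {
  calls <- list(...)
  mk <- model$alleles$marker[!is.na(model$alleles$marker)]
  if (!setequal(names(calls), mk))
    stop("expected marker calls ", paste(mk, collapse = ", "),
         " for gene ", model$gene_id)
  calls <- calls[mk]
  n <- max(vapply(calls, length, 1L))
  cnt <- vapply(calls, function(x) rep_len(as.integer(x), n),
                integer(n))
  cnt <- matrix(cnt, nrow = n, dimnames = list(NULL, mk))
  if (any(cnt < 0L | cnt > 2L, na.rm = TRUE))
    stop("marker copy counts must be 0, 1, 2 or NA")
  miss <- rowSums(is.na(cnt)) > 0L
  tot <- rowSums(cnt)
  if (any(tot > 2L, na.rm = TRUE))
    stop("total derived copies exceed 2 at gene ", model$gene_id)
  # map marker -> allele symbol; pad with the wild-type allele
  sym <- model$alleles$symbol[match(mk, model$alleles$marker)]
  wt <- model$alleles$symbol[model$alleles$wild_type][1L]
  colnames(cnt) <- sym
  a1 <- a2 <- rep(NA_character_, n)
  ok <- !miss
  if (any(ok)) {
    pair <- pad_pair(cnt[ok, , drop = FALSE], wt)
    a1[ok] <- pair[, 1L]; a2[ok] <- pair[, 2L]
  }
  pair_df(a1, a2, rep("none", n), miss)
}

#' Interpret a full marker table into per-gene genotype calls
#'
#' @param markers genotype table: `data.frame` with `dog_id`, `breed`,
#'   `population` and one integer column per marker id (see
#'   [read_genotype_table()]).
#' @param models a `gene_catalogue`.
#' @return long `data.frame` with one row per dog per gene: `dog_id`,
#'   `breed`, `population`, `gene`, `allele1`, `allele2`, `ambiguity`,
#'   `missing`.
#' @export
interpret_genotypes <- function(markers, models = default_gene_models()) {
  need <- marker_ids(models)
  absent <- setdiff(need, names(markers))
  if (length(absent))
    stop("genotype table lacks marker columns: ",
         paste(absent, collapse = ", "))
  blocks <- lapply(names(models), function(id) {
    m <- models[[id]]
    mk <- m$alleles$marker[!is.na(m$alleles$marker)]
    res <- if (id == "ASIP") {
      interpret_asip(markers$ay, markers$at, markers$a)
    } else if (id == "MC1R") {
      interpret_mc1r(markers$EM, markers$EG, markers$e)
    } else {
      do.call(interpret_biallelic,
              c(list(model = m), as.list(markers[mk])))
    }
    cbind(data.frame(dog_id = markers$dog_id, breed = markers$breed,
                     population = markers$population, gene = id,
                     stringsAsFactors = FALSE),
          res)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Extract one dog's genotype calls as a named list
#'
#' Convenience bridge from the long interpreted table to the per-dog
#' list [predict_phenotype()] consumes.
#'
#' @param calls long `data.frame` from [interpret_genotypes()].
#' @param dog_id dog identifier to extract.
#' @return named list of [genotype_call()]s.
#' @export
dog_genotypes <- function(calls, dog_id) {
  rows <- calls[calls$dog_id == dog_id, , drop = FALSE]
  if (!nrow(rows)) stop("dog '", dog_id, "' not found")
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$missing || r$ambiguity == "unresolved")
      genotype_call(r$gene, ambiguity = r$ambiguity, missing = r$missing)
    else
      genotype_call(r$gene, c(r$allele1, r$allele2), ambiguity = r$ambiguity)
  })
  names(out) <- rows$gene
  out
}

# Genotype-table dialect ---------------------------------------------------

#' Read a delimited genotype table
#'
#' Column dialect: `dog_id`, `breed`, `population`, then one column per
#' marker id with values 0/1/2 or `NA`.  Round-trip safe with
#' [write_genotype_table()].
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param models catalogue whose markers must all be present.
#' @return validated `data.frame`.
#' @export
read_genotype_table <- function(path, sep = "\t",
                                models = default_gene_models()) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  need <- c("dog_id", "breed", "population", marker_ids(models))
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("genotype table lacks columns: ", paste(absent, collapse = ", "))
  for (mk in marker_ids(models)) {
    df[[mk]] <- as.integer(df[[mk]])
    bad <- !is.na(df[[mk]]) & (df[[mk]] < 0L | df[[mk]] > 2L)
    if (any(bad))
      stop("marker ", mk, " has copy counts outside 0..2")
  }
  df$dog_id <- as.character(df$dog_id)
  df
}

#' Write a genotype table
#'
#' @param markers genotype `data.frame` in the dialect of
#'   [read_genotype_table()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_genotype_table <- function(markers, path, sep = "\t") {
  utils::write.table(markers, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
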