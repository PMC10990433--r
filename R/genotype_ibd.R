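#' Infer within-cross parental allele dosages
#'
#' Converts raw marker scores into donor-allele counts per genotype by
#' comparing each progeny score to the scores of the two parents of its
#' cross. A marker is informative for a cross when both parents are scored,
#' homozygous, and different; there the donor dosage is the number of
#' progeny alleles matching the donor score. Markers where the parents share
#' a score (or a parent is missing/heterozygous) are uninformative and the
#' dosage is missing before fill-in.
#'
#' Uninformative or missing dosages are then imputed from the nearest
#' informative flanking markers on the same chromosome: if the available
#' flanking values agree, that value is taken; otherwise the position stays
#' missing for that genotype (and the genotype is excluded from tests at
#' that position).
#'
#' @param genotypes Matrix progeny x markers of scores 0/1/2/NA (allele
#'   counts of an arbitrary reference allele), rows named by genotype id.
#' @param parent_scores Matrix parents x markers of scores, rows named by
#'   parent id.
#' @param crosses Data frame `genotype`, `cross`, `recurrent`, `donor`
#'   (optionally `subpopulation`).
#' @param map Genetic map data frame `marker`, `chr`, `pos`.
#' @param fill Impute uninformative positions from flanking consensus
#'   (default `TRUE`).
#' @return Object of class `parental_dosage`: list with `dosage` (matrix
#'   genotypes x markers of donor-allele counts after fill-in), `raw` (before
#'   fill-in), `crosses`, `map`, and `n_incompatible` (progeny scores
#'   incompatible with the parental scores, set to missing).
#' @export
infer_parental_dosage <- function(genotypes, parent_scores, crosses, map,
                                  fill = TRUE) {
  stopifnot(all(c("genotype", "cross", "recurrent", "donor") %in%
                  names(crosses)))
  miss <- setdiff(crosses$genotype, rownames(genotypes))
  if (length(miss)) {
    stop("genotypes missing from the score matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  extra <- setdiff(rownames(genotypes), crosses$genotype)
  extra <- setdiff(extra, rownames(parent_scores))
  if (length(extra)) {
    stop("genotype(s) without cross assignment: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  mk <- map$marker
  genotypes <- genotypes[crosses$genotype, mk, drop = FALSE]
  n <- nrow(crosses)
  dosage <- matrix(NA_real_, n, length(mk),
                   dimnames = list(crosses$genotype, mk))
  n_incomp <- 0L
  for (crid in unique(crosses$cross)) {
    rows <- which(crosses$cross == crid)
    rp <- crosses$recurrent[rows[1]]
    dp <- crosses$donor[rows[1]]
    if (!rp %in% rownames(parent_scores) || !dp %in% rownames(parent_scores))
      stop("missing parent scores for cross ", crid)
    rs <- parent_scores[rp, mk]
    ds <- parent_scores[dp, mk]
    informative <- !is.na(rs) & !is.na(ds) & rs %in% c(0, 2) &
      ds %in% c(0, 2) & rs != ds
    sc <- genotypes[rows, , drop = FALSE]
    bad <- !is.na(sc) & !(sc %in% 0:2)
    if (any(bad)) {
      n_incomp <- n_incomp + sum(bad)
      sc[bad] <- NA
    }
    d <- sc
    flip <- which(!is.na(ds) & ds == 0)   # donor carries reference allele 0
    d[, flip] <- 2 - d[, flip]
    d[, !informative] <- NA
    dosage[rows, ] <- d
  }
  raw <- dosage
  if (fill && anyNA(dosage)) {
    for (ch in unique(map$chr)) {
      idx <- which(map$chr == ch)
      dosage[, idx] <- .fill_flanks(dosage[, idx, drop = FALSE])
    }
  }
  if (n_incomp > 0) {
    message(n_incomp, " progeny score(s) incompatible with parental scores",
            " set to missing")
  }
  structure(list(dosage = dosage, raw = raw, crosses = crosses, map = map,
                 n_incompatible = n_incomp),
            class = "parental_dosage")
}

# Flanking-consensus fill within one chromosome: an NA cell takes the value
# of its nearest non-NA left and right neighbours if they agree (a single
# available flank counts as consensus); disagreeing flanks stay NA.
.fill_flanks <- function(d) {
  if (!anyNA(d)) return(d)
  m <- ncol(d)
  for (i in which(rowSums(is.na(d)) > 0)) {
    v <- d[i, ]
    ok <- which(!is.na(v))
    if (length(ok) == 0L) next
    for (j in which(is.na(v))) {
      left <- ok[ok < j]
      right <- ok[ok > j]
      lv <- if (length(left)) v[max(left)] else NA
      rv <- if (length(right)) v[min(right)] else NA
      cons <- stats::na.omit(c(lv, rv))
      if (length(cons) == 1L || (length(cons) == 2L && cons[1] == cons[2])) {
        v[j] <- cons[1]
      }
    }
    d[i, ] <- v
  }
  d
}

#' @export
print.parental_dosage <- function(x, ...) {
  cat(sprintf("Parental dosage: %d genotypes x %d markers (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Build the parental QTL incidence matrix at one position
#'
#' One column per donor parent present in the subpopulation; the entry for
#' genotype i and donor p is the donor-allele count if p is the donor of
#' i's cross and 0 otherwise (the recurrent parent is the reference).
#' Columns with fewer than `min_seg` carriers are dropped; genotypes with a
#' missing dosage at the position are flagged for exclusion from the test.
#'
#' @param dosage A [infer_parental_dosage()] result (or the `bcnam_sim`
#'   truth wrapped by [dosage_from_sim()]).
#' @param marker Marker id (or use `chr` + `pos`).
#' @param chr,pos Alternative position specification.
#' @param subpopulation Optional character vector of cross ids to restrict
#'   to; default all crosses.
#' @param min_seg Minimum number of donor-allele carriers per column.
#' @return List with `X` (matrix genotypes x kept donors), `genotype`,
#'   `keep` (logical; FALSE where the dosage is missing), `dropped`
#'   (donor columns removed by the `min_seg` rule) and `scannable`.
#' @export
build_design_matrix <- function(dosage, marker = NULL, chr = NULL, pos = NULL,
                                subpopulation = NULL, min_seg = 10) {
  stopifnot(inherits(dosage, "parental_dosage"))
  mi <- .find_marker(dosage$map, marker, chr, pos)
  cr <- dosage$crosses
  if (!is.null(subpopulation)) cr <- cr[cr$cross %in% subpopulation, ]
  x <- dosage$dosage[cr$genotype, mi]
  donors <- sort(unique(cr$donor))
  X <- matrix(0, nrow(cr), length(donors),
              dimnames = list(cr$genotype, donors))
  for (p in donors) {
    rows <- cr$donor == p
    X[rows, p] <- x[rows]
  }
  keep <- !is.na(x)
  X[!keep, ] <- 0
  carriers <- vapply(donors, function(p)
    sum(X[keep & cr$donor == p, p] > 0), numeric(1))
  kept <- donors[carriers >= min_seg]
  dropped <- setdiff(donors, kept)
  list(X = X[, kept, drop = FALSE], genotype = cr$genotype, keep = keep,
       dropped = dropped, scannable = length(kept) > 0L)
}

#' Wrap simulator truth as a parental_dosage object
#'
#' Convenience for recovery tests: uses the simulator's true donor-allele
#' counts directly, bypassing score-based inference.
#'
#' @param sim A `bcnam_sim` object.
#' @return A `parental_dosage` object.
#' @export
dosage_from_sim <- function(sim) {
  stopifnot(inherits(sim, "bcnam_sim"))
  structure(list(dosage = sim$dosage_true, raw = sim$dosage_true,
                 crosses = sim$crosses, map = sim$map, n_incompatible = 0L),
            class = "parental_dosage")
}
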