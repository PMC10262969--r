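#' @title Gene and site concordance factors
#' @name concordance
#' @description Concordance factors for the three four-group quartet
#'   hypotheses (I: KE|RT, II: KR|ET, III: KT|ER), with outgroups excluded.
#'   gCF is the percentage of decisive gene trees whose collapsed quartet
#'   matches a hypothesis; sCF is the mean percentage of decisive alignment
#'   sites supporting it over randomly sampled one-per-group quartets, by the
#'   parsimony criterion (a site is decisive iff its four sampled states are
#'   unambiguous nucleotides forming a 2+2 two-state pattern).
NULL

.cfRow <- function(hyp, gCF, gCF_N, sCF, sCF_N) {
  data.frame(hypothesis = hyp, gCF = gCF, gCF_N = gCF_N, sCF = sCF,
             sCF_N = sCF_N, stringsAsFactors = FALSE)
}

#' Gene concordance factors for the three quartet hypotheses
#'
#' A gene tree is decisive when, after dropping outgroup taxa, all four
#' ingroup groups are present and monophyletic; its collapsed quartet then
#' matches exactly one hypothesis. gCF_N counts decisive trees per
#' hypothesis; gCF = 100 * gCF_N / (number of decisive trees). Undecisive
#' trees (missing or non-monophyletic groups) are excluded from numerator and
#' denominator and reported separately, which is why the three gCFs need not
#' sum to 100 over all input trees.
#'
#' @param geneTrees list of `phylo` gene trees (taxa may be subsets)
#' @param groups a group map (see [asGroupMap()])
#' @return data.frame with one row per hypothesis (columns `hypothesis`,
#'   `gCF`, `gCF_N`, `sCF`, `sCF_N` — the sCF columns are NA here) plus
#'   attributes `decisive`, `undecisive` and `total`
#' @export
gcf <- function(geneTrees, groups) {
  if (!length(geneTrees)) stop("empty gene tree list")
  groups <- asGroupMap(groups)
  hyp <- vapply(geneTrees, function(tr)
    as.character(quartetHypothesis(tr, groups)), "")
  dec <- !is.na(hyp)
  n <- c(I = sum(hyp == "I", na.rm = TRUE), II = sum(hyp == "II", na.rm = TRUE),
         III = sum(hyp == "III", na.rm = TRUE))
  den <- sum(dec)
  out <- .cfRow(names(HYPOTHESES),
                if (den > 0) 100 * n / den else rep(NA_real_, 3),
                as.integer(n), NA_real_, NA_real_)
  attr(out, "decisive") <- den
  attr(out, "undecisive") <- sum(!dec)
  attr(out, "total") <- length(geneTrees)
  out
}

#' Per-quartet site support for the three hypotheses
#'
#' @param rows 4 x L character matrix in group order K, E, R, T
#' @return counts c(I, II, III) of decisive supporting sites
#' @noRd
.quartetSiteCounts <- function(rows) {
  k <- rows[1, ]; e <- rows[2, ]; r <- rows[3, ]; tt <- rows[4, ]
  ok <- k %in% ACGT & e %in% ACGT & r %in% ACGT & tt %in% ACGT
  sI <- ok & k == e & r == tt & k != r
  sII <- ok & k == r & e == tt & k != e
  sIII <- ok & k == tt & e == r & k != e
  c(I = sum(sI), II = sum(sII), III = sum(sIII))
}

.scfFromQuartets <- function(m, combos, mult, groups4) {
  nq <- sum(mult)
  supp <- matrix(0, nrow(combos), 3)
  for (i in seq_len(nrow(combos)))
    supp[i, ] <- .quartetSiteCounts(m[unlist(combos[i, ]), , drop = FALSE])
  dec <- rowSums(supp)
  use <- dec > 0
  if (!any(use)) {
    out <- .cfRow(names(HYPOTHESES), NA_real_, NA_real_, NA_real_, NA_real_)
    attr(out, "quartets") <- nq
    attr(out, "quartetsDecisive") <- 0
    return(out)
  }
  w <- mult[use] / sum(mult[use])
  frac <- sweep(supp[use, , drop = FALSE], 1, dec[use], "/")
  sCF <- 100 * as.numeric(crossprod(frac, w))
  sCF_N <- as.numeric(crossprod(supp[use, , drop = FALSE], w))
  out <- .cfRow(names(HYPOTHESES), NA_real_, NA_real_, sCF, sCF_N)
  attr(out, "quartets") <- nq
  attr(out, "quartetsDecisive") <- sum(mult[use])
  out
}

.scfGroups <- function(aln, groups) {
  groups <- asGroupMap(groups)
  taxa <- alnTaxa(aln)
  keep <- taxa[groups[taxa] != "O"]
  gt <- lapply(GROUPS_INGROUP, function(g) keep[groups[keep] == g])
  names(gt) <- GROUPS_INGROUP
  if (any(lengths(gt) == 0))
    stop(sprintf("missing group(s): %s",
                 paste(GROUPS_INGROUP[lengths(gt) == 0], collapse = ",")))
  gt
}

#' Site concordance factors by sampled one-per-group quartets
#'
#' Samples `nQuartets` quartets uniformly with replacement from the Cartesian
#' product of the four ingroup groups (outgroup rows are dropped first). Per
#' quartet, the support fraction for each hypothesis uses only decisive sites
#' (unambiguous 2+2 two-state columns); sCF is the mean support fraction
#' x 100 and sCF_N the mean supporting-site count, both averaged over
#' quartets with at least one decisive site. If no sampled quartet has a
#' decisive site, sCF is reported as NA.
#'
#' @param aln an [Alignment-class]
#' @param groups a group map
#' @param nQuartets number of quartets to sample (the reference protocol uses
#'   5000)
#' @param seed integer seed (`NULL` continues the RNG stream)
#' @return data.frame as in [gcf()] (gCF columns NA) with attributes
#'   `quartets` and `quartetsDecisive`
#' @export
scf <- function(aln, groups, nQuartets = 5000, seed = NULL) {
  stopifnot(nQuartets >= 1)
  if (!is.null(seed)) set.seed(seed)
  gt <- .scfGroups(aln, groups)
  pick <- vapply(GROUPS_INGROUP, function(g)
    gt[[g]][sample.int(length(gt[[g]]), nQuartets, replace = TRUE)],
    character(nQuartets))
  if (nQuartets == 1) pick <- matrix(pick, nrow = 1)
  key <- apply(pick, 1, paste, collapse = "\r")
  tab <- table(key)
  combos <- as.data.frame(do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE)),
                          stringsAsFactors = FALSE)
  colnames(combos) <- GROUPS_INGROUP
  .scfFromQuartets(alnMatrix(aln), combos, as.numeric(tab), gt)
}

#' Exhaustive site concordance factors
#'
#' Averages over every one-per-group quartet (the full Cartesian product);
#' deterministic oracle for the sampler.
#'
#' @inheritParams scf
#' @param maxCombos guard on the product of group sizes (default 10000)
#' @return as [scf()]
#' @export
scfExhaustive <- function(aln, groups, maxCombos = 10000) {
  gt <- .scfGroups(aln, groups)
  ncomb <- prod(lengths(gt))
  if (ncomb > maxCombos)
    stop(sprintf("quartet combinations (%d) exceed guard (%d)", ncomb,
                 maxCombos))
  combos <- expand.grid(gt, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  .scfFromQuartets(alnMatrix(aln), combos, rep(1, nrow(combos)), gt)
}

#' Concordance-factor report table
#'
#' Merges gene- and site-concordance results into the standard report layout
#' (one row per hypothesis plus a totals row) and optionally writes it as
#' TSV.
#'
#' @param gcfTab result of [gcf()] (or NULL)
#' @param scfTab result of [scf()] / [scfExhaustive()] (or NULL)
#' @param file optional path to write a TSV
#' @return the merged data.frame (invisibly when writing)
#' @export
concordanceReport <- function(gcfTab = NULL, scfTab = NULL, file = NULL) {
  out <- .cfRow(names(HYPOTHESES), NA_real_, NA_real_, NA_real_, NA_real_)
  if (!is.null(gcfTab)) out[, c("gCF", "gCF_N")] <- gcfTab[, c("gCF", "gCF_N")]
  if (!is.null(scfTab)) out[, c("sCF", "sCF_N")] <- scfTab[, c("sCF", "sCF_N")]
  tot <- data.frame(hypothesis = "total",
                    gCF = sum(out$gCF), gCF_N = sum(out$gCF_N),
                    sCF = sum(out$sCF), sCF_N = sum(out$sCF_N),
                    stringsAsFactors = FALSE)
  out <- rbind(out, tot)
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
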