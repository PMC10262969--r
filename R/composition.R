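#' @title Compositional diagnostics
#' @name composition
#' @description GC content, relative compositional variability (RCV),
#'   RY-coding, divergence-from-ancestor summaries and matched-pair symmetry
#'   tests — the diagnostics used to detect violations of the stationary
#'   time-homogeneous substitution model.
NULL

#' GC content per taxon and per group
#'
#' (G+C) / (A+C+G+T) per sequence; gaps and ambiguity codes are excluded from
#' both numerator and denominator. Group values are means over member taxa.
#' A sequence with no unambiguous base gets NA.
#'
#' @param aln an [Alignment-class]
#' @param groups optional group map; when given, per-group means are attached
#' @return named numeric vector of per-taxon GC fractions, with attribute
#'   `groups` (named per-group means) when a map is supplied
#' @examples
#' gcContent(alignment(c(a = "GGCC", b = "AATT")))
#' @export
gcContent <- function(aln, groups = NULL) {
  m <- alnMatrix(aln)
  gc <- rowSums(m == "G" | m == "C")
  tot <- rowSums(matrix(m %in% ACGT, nrow(m)))
  out <- ifelse(tot > 0, gc / tot, NA_real_)
  names(out) <- alnTaxa(aln)
  if (!is.null(groups)) {
    groups <- asGroupMap(groups)
    gs <- sort(unique(groups[alnTaxa(aln)]))
    attr(out, "groups") <- vapply(gs, function(g)
      mean(out[alnTaxa(aln)[groups[alnTaxa(aln)] == g]], na.rm = TRUE),
      0)
  }
  out
}

#' Relative compositional variability among species groups
#'
#' `RCV = sum_i (|A_i - A*| + |T_i - T*| + |C_i - C*| + |G_i - G*|) / (n t)`
#' where `A_i, ...` are the average nucleotide frequencies of species group
#' `i` (means over member species of per-species frequencies), `A*, ...` the
#' averages over all groups, `n` the number of groups and `t` the number of
#' clean sites. Only sites at which every scored taxon has an unambiguous
#' A/C/G/T enter the computation. RCV is 0 iff all group compositions are
#' equal; it is invariant to taxon order.
#'
#' @param aln an [Alignment-class]
#' @param groups a group map; outgroup (O) taxa are excluded unless
#'   `includeOutgroup = TRUE`
#' @param pooled use pooled base counts per group instead of means of
#'   per-species frequencies (default FALSE)
#' @param includeOutgroup score O as a fifth group (default FALSE)
#' @return list with elements `rcv`, `groupFreqs` (n x 4 matrix),
#'   `overallFreqs`, `nGroups`, `nSites`
#' @export
rcv <- function(aln, groups, pooled = FALSE, includeOutgroup = FALSE) {
  groups <- asGroupMap(groups)
  taxa <- alnTaxa(aln)
  use <- if (includeOutgroup) taxa else taxa[groups[taxa] != "O"]
  gl <- split(use, groups[use])
  gl <- gl[lengths(gl) > 0]
  if (length(gl) < 2) stop("need at least 2 groups")
  m <- alnMatrix(aln)[use, , drop = FALSE]
  clean <- colSums(matrix(!(m %in% ACGT), nrow(m))) == 0
  tClean <- sum(clean)
  if (tClean == 0)
    stop("no clean sites: RCV is computed only on sites with no missing or ambiguous data")
  m <- m[, clean, drop = FALSE]
  freqTaxon <- vapply(ACGT, function(s) rowSums(m == s) / tClean,
                      numeric(length(use)))
  if (length(use) == 1) freqTaxon <- matrix(freqTaxon, nrow = 1)
  rownames(freqTaxon) <- use
  gf <- t(vapply(gl, function(memb) {
    if (pooled) {
      sub <- m[memb, , drop = FALSE]
      vapply(ACGT, function(s) sum(sub == s), 0) / (length(memb) * tClean)
    } else {
      colMeans(freqTaxon[memb, , drop = FALSE])
    }
  }, numeric(4)))
  colnames(gf) <- ACGT
  ov <- colMeans(gf)
  # the printed formula sums absolute deviations of per-group nucleotide
  # *counts* and divides by n*t; with gf holding proportions (counts/t) this
  # reduces to the mean per-group absolute deviation
  val <- sum(abs(sweep(gf, 2, ov))) / nrow(gf)
  list(rcv = val, groupFreqs = gf, overallFreqs = ov, nGroups = nrow(gf),
       nSites = tClean)
}

#' RY-code an alignment
#'
#' Purines (A, G) become R, pyrimidines (C, T) become Y. N, gap and `?` are
#' preserved; all other ambiguity codes become N. With a position filter only
#' the listed columns are recoded and the rest are copied untouched;
#' `positions = "codon3"` recodes every third column (3, 6, ...), the usual
#' treatment for third codon positions.
#'
#' @param aln an [Alignment-class]
#' @param positions optional integer vector of 1-based columns to recode, or
#'   the keyword `"codon3"`
#' @return an [Alignment-class] over R/Y/N/-/? (untouched columns keep their
#'   original symbols)
#' @examples
#' alnMatrix(ryEncode(alignment(c(x = "ACGT"))))
#' @export
ryEncode <- function(aln, positions = NULL) {
  m <- alnMatrix(aln)
  if (identical(positions, "codon3"))
    positions <- seq(3, nSites(aln), by = 3)
  map <- setNames(rep("N", length(ALPHABET)), ALPHABET)
  map[c("A", "G", "R")] <- "R"
  map[c("C", "T", "Y")] <- "Y"
  map["N"] <- "N"; map["-"] <- "-"; map["?"] <- "?"
  if (is.null(positions)) {
    m[] <- map[m]
  } else {
    m[, positions] <- map[m[, positions, drop = FALSE]]
  }
  new("Alignment", seqs = m)
}

#' Divergence of species and groups from the ingroup common ancestor
#'
#' Roots the tree with the outgroup, locates the most recent common ancestor
#' of the four ingroup groups (N_CA), and reports the branch-length path from
#' N_CA to every ingroup tip, per-group means, the locus divergence (mean of
#' the four group means) and the N_CA-to-outgroup-tip paths (used for the
#' near/far outgroup divergence ratio).
#'
#' @param tree a `phylo` with branch lengths containing outgroup taxa
#' @param groups a group map
#' @return list with `species` (named per-tip path lengths), `groupMeans`
#'   (named K/E/R/T), `divergence` (mean of group means), `outgroupPaths`
#'   (named per-outgroup-tip path lengths from N_CA)
#' @export
divergenceFromNCA <- function(tree, groups) {
  groups <- asGroupMap(groups)
  tips <- tree$tip.label
  otips <- .groupTips(tips, groups, "O")
  intips <- setdiff(tips, otips)
  ing <- groups[intips]
  if (!all(GROUPS_INGROUP %in% ing) || !length(otips))
    stop("N_CA undefined: need all four ingroup groups and an outgroup")
  rt <- tree
  if (!ape::is.rooted(rt) || length(otips) < length(tips))
    rt <- ape::root(tree, outgroup = otips, resolve.root = TRUE)
  nca <- ape::getMRCA(rt, intips)
  dm <- ape::dist.nodes(rt)
  sp <- dm[nca, match(intips, rt$tip.label)]
  names(sp) <- intips
  gm <- vapply(GROUPS_INGROUP, function(g) mean(sp[ing == g]), 0)
  op <- dm[nca, match(otips, rt$tip.label)]
  names(op) <- otips
  list(species = sp, groupMeans = gm, divergence = mean(gm),
       outgroupPaths = op)
}

#' Matched-pair symmetry tests for two aligned sequences
#'
#' Builds the 4x4 divergence matrix over paired unambiguous sites and runs
#' the three matched-pair tests of substitution-model assumptions:
#' * symmetry (Bowker): `sum (n_ij - n_ji)^2 / (n_ij + n_ji)` over
#'   off-diagonal pairs with `n_ij + n_ji > 0`; df = number of such pairs;
#' * marginal symmetry (Stuart): quadratic form of the marginal differences
#'   with a generalized-inverse covariance; df = 3;
#' * internal symmetry: Bowker minus Stuart statistic, df = difference.
#'
#' An identical pair gives all statistics 0 with df 0 (reported as trivially
#' passing, p = 1). When the Bowker df is below 3 the internal test is
#' undefined and its p-value is NA.
#'
#' @param seqA,seqB equal-length character vectors (or strings) of aligned
#'   sequences
#' @return data.frame with rows `symmetry`, `marginal`, `internal` and
#'   columns `stat`, `df`, `p`
#' @export
matchedPairSymmetryTests <- function(seqA, seqB) {
  if (length(seqA) == 1) seqA <- strsplit(toupper(seqA), "")[[1]]
  if (length(seqB) == 1) seqB <- strsplit(toupper(seqB), "")[[1]]
  if (length(seqA) != length(seqB)) stop("sequences must be aligned")
  ok <- seqA %in% ACGT & seqB %in% ACGT
  if (!any(ok)) stop("no paired unambiguous sites")
  n <- table(factor(seqA[ok], ACGT), factor(seqB[ok], ACGT))
  n <- matrix(as.numeric(n), 4, 4, dimnames = dimnames(n))

  # Bowker
  stat_s <- 0; df_s <- 0L
  for (i in 1:3) for (j in (i + 1):4) {
    s <- n[i, j] + n[j, i]
    if (s > 0) {
      stat_s <- stat_s + (n[i, j] - n[j, i])^2 / s
      df_s <- df_s + 1L
    }
  }
  p_s <- if (df_s > 0) pchisq(stat_s, df_s, lower.tail = FALSE) else 1

  # Stuart: d = row - col margins (first 3), V_ii = r_i + c_i - 2 n_ii,
  # V_ij = -(n_ij + n_ji)
  d <- (rowSums(n) - colSums(n))[1:3]
  V <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    V[i, j] <- if (i == j) rowSums(n)[i] + colSums(n)[i] - 2 * n[i, i]
               else -(n[i, j] + n[j, i])
  }
  if (all(abs(d) < 1e-12) && all(abs(V) < 1e-12)) {
    stat_m <- 0; df_m <- 0L; p_m <- 1
  } else {
    stat_m <- as.numeric(t(d) %*% MASS::ginv(V) %*% d)
    df_m <- 3L
    p_m <- pchisq(stat_m, df_m, lower.tail = FALSE)
  }

  stat_i <- max(stat_s - stat_m, 0)
  df_i <- df_s - df_m
  p_i <- if (df_i > 0) pchisq(stat_i, df_i, lower.tail = FALSE)
         else if (df_s == 0) 1 else NA_real_

  data.frame(test = c("symmetry", "marginal", "internal"),
             stat = c(stat_s, stat_m, stat_i),
             df = c(df_s, df_m, df_i),
             p = c(p_s, p_m, p_i),
             stringsAsFactors = FALSE)
}
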