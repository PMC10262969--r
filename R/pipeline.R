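#' @title Pipeline stages
#' @name pipeline
#' @description Locus filtering, divergence stratification, site-rate
#'   rebinning, the outgroup-choice simulation experiment, coalescent
#'   concordance probabilities and their inversion, and gene-tree
#'   summarization.
NULL

## ---- coalescent calculations ------------------------------------------

#' Gene-tree topology probabilities under the multispecies coalescent
#'
#' For a species-tree quartet internal branch of scaled length
#' `tau = T/Ne`, the concordant gene-tree topology has probability
#' `1 - (2/3) exp(-tau/divisor)` and each discordant topology
#' `(1/3) exp(-tau/divisor)`. `divisor = 1` is the printed-formula
#' convention; `divisor = 2` measures branches in units of 2Ne generations.
#'
#' @param tau scaled internal branch length (>= 0)
#' @param divisor exponent convention, 1 (default) or 2
#' @return numeric vector `c(concordant, discordant1, discordant2)`,
#'   summing to 1
#' @examples
#' concordanceProbability(0.105)  # ~ (0.40, 0.30, 0.30)
#' @export
concordanceProbability <- function(tau, divisor = 1) {
  if (tau < 0) stop("tau must be non-negative")
  stopifnot(divisor %in% c(1, 2))
  q <- exp(-tau / divisor) / 3
  c(concordant = 1 - 2 * q, discordant1 = q, discordant2 = q)
}

#' Invert the concordance probability to the scaled branch length
#'
#' Exact inverse of [concordanceProbability()]:
#' `tau = -divisor * log(3 (1 - p) / 2)` for `1/3 < p < 1`. Applying the
#' observed 40% frequency of the concordant quartet gives
#' `tau = -log(0.9) = 0.1054`, i.e. approximately 0.11.
#'
#' @param pConcordant probability of the concordant topology, in (1/3, 1)
#' @param divisor exponent convention as in [concordanceProbability()]
#' @return tau = T/Ne
#' @examples
#' invertConcordance(0.40)
#' @export
invertConcordance <- function(pConcordant, divisor = 1) {
  if (pConcordant <= 1 / 3 || pConcordant >= 1)
    stop("pConcordant must lie strictly between 1/3 and 1")
  stopifnot(divisor %in% c(1, 2))
  -divisor * log(3 * (1 - pConcordant) / 2)
}

#' Convert a scaled coalescent branch to generations and years
#'
#' `generations = tau * Ne` under the printed-formula convention
#' (`divisor = 1`; with `divisor = 2` the branch spans `2 Ne tau`
#' generations), and `years = generations * generationTime`. With tau = 0.11,
#' Ne = 1e5 and a 3-year generation time this gives 11,000 generations and
#' 33,000 years.
#'
#' @param tau scaled internal branch length T/Ne (>= 0)
#' @param Ne effective population size (> 0)
#' @param generationTime generation time in years (> 0)
#' @param divisor exponent convention as in [concordanceProbability()]
#' @return named numeric `c(generations = , years = )`
#' @export
coalescentTime <- function(tau, Ne, generationTime, divisor = 1) {
  stopifnot(tau >= 0, Ne > 0, generationTime > 0, divisor %in% c(1, 2))
  gen <- divisor * tau * Ne
  c(generations = gen, years = gen * generationTime)
}

## ---- locus filtering and stratification -------------------------------

#' Per-species relative branch-length ratios from N_CA
#' @noRd
.relBranchRatios <- function(tree, groups) {
  d <- divergenceFromNCA(tree, groups)
  sp <- d$species
  vapply(seq_along(sp), function(i) sp[i] / mean(sp[-i]), 0) |>
    setNames(names(sp))
}

#' Filter loci by branch-length anomalies and precomputed flags
#'
#' Implements the locus exclusion rules:
#' * relative-branch rule: a locus is excluded when, for any species, its
#'   branch length from the ingroup ancestor N_CA relative to the other
#'   species (ratio of the species' path to the mean of the others') exceeds
#'   `ratioFactor` (default 5) times the same ratio on the concatenated-tree
#'   reference — strictly greater, so a ratio of exactly 5x is kept;
#' * long-branch rule (CDS mode, `cdsMode = TRUE`): excluded when any
#'   species' path from N_CA exceeds `maxPath` (default 1 substitution/site)
#'   or exceeds `ratioFactor` times the mean path of the other species in its
#'   own group;
#' * precomputed recombination / selection flags on the [Locus-class] are
#'   honored as-is.
#'
#' Every exclusion carries a machine-readable reason, the measured value and
#' the threshold.
#'
#' @param loci list of [Locus-class] objects, each with a per-locus tree
#' @param concatTree the concatenated-sequence reference tree (same topology,
#'   reference branch lengths)
#' @param groups a group map
#' @param cdsMode apply the stricter coding-data rules (default FALSE)
#' @param ratioFactor relative-branch multiplier (default 5)
#' @param maxPath absolute path cutoff for CDS mode (default 1)
#' @return list with `kept` (list of loci) and `excluded` (data.frame: id,
#'   reason, value, threshold)
#' @export
filterLoci <- function(loci, concatTree, groups, cdsMode = FALSE,
                       ratioFactor = 5, maxPath = 1) {
  if (is.null(concatTree)) stop("missing concatenated reference tree")
  groups <- asGroupMap(groups)
  refRatio <- .relBranchRatios(concatTree, groups)
  kept <- list()
  exc <- data.frame(id = character(), reason = character(),
                    value = numeric(), threshold = numeric(),
                    stringsAsFactors = FALSE)
  drop1 <- function(id, reason, value, threshold)
    rbind(exc, data.frame(id = id, reason = reason, value = value,
                          threshold = threshold, stringsAsFactors = FALSE))
  for (lc in loci) {
    fl <- lc@flags
    if (isTRUE(fl["recombination"])) {
      exc <- drop1(lc@id, "recombination", 1, 0); next
    }
    if (isTRUE(fl["selection"])) {
      exc <- drop1(lc@id, "selection", 1, 0); next
    }
    tr <- locusTree(lc)
    if (is.null(tr)) stop(sprintf("locus '%s' has no tree", lc@id))
    rat <- .relBranchRatios(tr, groups)
    common <- intersect(names(rat), names(refRatio))
    rel <- rat[common] / refRatio[common]
    if (any(rel > ratioFactor)) {
      w <- which.max(rel)
      exc <- drop1(lc@id, "relative_branch", rel[w], ratioFactor); next
    }
    if (cdsMode) {
      d <- divergenceFromNCA(tr, groups)
      if (any(d$species > maxPath)) {
        exc <- drop1(lc@id, "long_branch", max(d$species), maxPath); next
      }
      ing <- groups[names(d$species)]
      bad <- FALSE
      for (g in GROUPS_INGROUP) {
        sp <- d$species[ing == g]
        if (length(sp) < 2) next
        for (i in seq_along(sp)) {
          if (sp[i] > ratioFactor * mean(sp[-i])) {
            exc <- drop1(lc@id, "long_branch_group", sp[i] / mean(sp[-i]),
                         ratioFactor)
            bad <- TRUE; break
          }
        }
        if (bad) break
      }
      if (bad) next
    }
    kept <- c(kept, list(lc))
  }
  list(kept = kept, excluded = exc)
}

#' Stratify loci into top-k% and remaining sets by a key
#'
#' Descending stable sort by the key (ties by locus id); the top set holds
#' the first `ceiling(k% * N)` loci, the rem set the complement. Top and rem
#' partition the input.
#'
#' @param loci list of [Locus-class] objects
#' @param kPercent percentage in (0, 100)
#' @param key per-locus value to sort on; default the stored divergence
#' @return list with `top` and `rem` (lists of loci)
#' @export
stratifyLoci <- function(loci, kPercent,
                         key = vapply(loci, locusDivergence, 0)) {
  stopifnot(kPercent > 0, kPercent < 100)
  if (any(is.na(key))) stop("missing stratification key for some loci")
  ids <- vapply(loci, locusId, "")
  ord <- order(-key, ids)
  nTop <- ceiling(kPercent / 100 * length(loci))
  list(top = loci[ord[seq_len(nTop)]],
       rem = loci[ord[-seq_len(nTop)]])
}

#' Rebin concatenated sites by estimated rate into pseudo-loci
#'
#' Orders columns by ascending site-specific rate (ties keep the original
#' column order) and chunks them into consecutive bins of `binLength` sites
#' — the per-bin mean rate is non-decreasing across bins. The last bin may
#' be short and is flagged. Optionally drops (near-)invariant sites first,
#' mirroring the re-analysis in which trees could only be estimated from the
#' variable ~10% of sites.
#'
#' @param aln the concatenated [Alignment-class]
#' @param rates per-site rates (length = alignment length), e.g. from
#'   [estimateSiteRates()]
#' @param binLength pseudo-locus length (>= 1)
#' @param dropInvariant drop sites with rate below this threshold before
#'   binning (default NULL = keep all)
#' @return list of [Locus-class] pseudo-loci with attributes `meanRates`
#'   and `short` (logical, last-bin flag per locus)
#' @export
rebinSitesByRate <- function(aln, rates, binLength, dropInvariant = NULL) {
  if (length(rates) != nSites(aln))
    stop("rates length must equal alignment length")
  stopifnot(binLength >= 1)
  cols <- seq_len(nSites(aln))
  if (!is.null(dropInvariant)) {
    keep <- rates >= dropInvariant
    cols <- cols[keep]
    rates <- rates[keep]
  }
  ord <- cols[order(rates, cols)]
  bins <- split(ord, ceiling(seq_along(ord) / binLength))
  out <- vector("list", length(bins))
  mr <- numeric(length(bins))
  short <- logical(length(bins))
  r2 <- sort(rates)
  off <- 0
  for (i in seq_along(bins)) {
    out[[i]] <- locus(sprintf("bin%04d", i), aln[, bins[[i]]],
                      class = "rate-bin")
    mr[i] <- mean(r2[off + seq_along(bins[[i]])])
    off <- off + length(bins[[i]])
    short[i] <- length(bins[[i]]) < binLength
  }
  attr(out, "meanRates") <- mr
  attr(out, "short") <- short
  out
}

## ---- outgroup experiment ----------------------------------------------

#' The outgroup-choice simulation experiment
#'
#' For every (model tree, sequence length) condition: simulate `reps`
#' alignments on the model tree, prune each replicate once to every outgroup
#' configuration (`both` keeps near and far outgroups, `near` / `far` keep
#' one), run the exhaustive ML search over all topologies of the retained
#' taxa, and compare the inferred topology with the identically pruned model
#' tree. P_C is the fraction of replicates recovering the model topology
#' (RF distance 0) and mean D_RF the average Robinson-Foulds distance.
#' Sharing simulated replicates across outgroup configurations (prune-once)
#' removes between-configuration simulation noise. Fully seed-deterministic.
#'
#' @param modelTrees named list of `phylo` model trees with branch lengths,
#'   containing `nearLabel` and `farLabel` tips
#' @param outgroups subset of c("both", "near", "far")
#' @param Ls sequence lengths to simulate
#' @param reps replicates per condition
#' @param model a [GTRGamma-class]
#' @param seed integer seed
#' @param nearLabel,farLabel tip labels of the near and far outgroup
#' @param relTol,maxSweeps,brentTol optimizer settings passed to
#'   [optimizeBranchLengths()] (the defaults trade a little precision for
#'   speed, ample for topology choice)
#' @return data.frame: tree, outgroup, L, reps, P_C, se_P_C, meanDRF
#' @export
outgroupExperiment <- function(modelTrees, outgroups = c("both", "near", "far"),
                               Ls = c(300, 600, 900, 1800), reps = 100,
                               model, seed = 1, nearLabel = "ostrich",
                               farLabel = "chicken", relTol = 1e-6,
                               maxSweeps = 20, brentTol = 1e-5) {
  stopifnot(all(outgroups %in% c("both", "near", "far")), reps >= 1)
  if (is.null(names(modelTrees)))
    names(modelTrees) <- paste0("tree", seq_along(modelTrees))
  set.seed(seed)
  res <- list()
  for (tn in names(modelTrees)) {
    mt <- modelTrees[[tn]]
    dropOf <- list(both = character(0), near = farLabel, far = nearLabel)
    prunedModel <- lapply(dropOf, function(d)
      if (length(d)) ape::drop.tip(mt, d) else mt)
    cands <- lapply(prunedModel, function(p)
      enumerateTopologies(p$tip.label))
    for (L in Ls) {
      hit <- setNames(numeric(length(outgroups)), outgroups)
      drf <- setNames(numeric(length(outgroups)), outgroups)
      for (r in seq_len(reps)) {
        sim <- simulateAlignment(mt, model, L, seed = NULL)
        for (og in outgroups) {
          keep <- prunedModel[[og]]$tip.label
          fit <- exhaustiveMLSearch(sim[keep, ], keep, model,
                                    candidates = cands[[og]],
                                    relTol = relTol, maxSweeps = maxSweeps,
                                    brentTol = brentTol)
          d <- rfDistance(fit$tree, prunedModel[[og]])
          hit[og] <- hit[og] + (d == 0)
          drf[og] <- drf[og] + d
        }
      }
      for (og in outgroups) {
        p <- hit[og] / reps
        res[[length(res) + 1]] <- data.frame(
          tree = tn, outgroup = og, L = L, reps = reps, P_C = p,
          se_P_C = sqrt(p * (1 - p) / reps), meanDRF = drf[og] / reps,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, res)
}

## ---- gene tree summarization ------------------------------------------

#' Plurality four-group topology with locus-bootstrap support
#'
#' A transparent gene-tree summarizer for the four-group question: each gene
#' tree is collapsed to its quartet hypothesis (undecisive trees are
#' dropped), the plurality hypothesis wins, and support is the fraction of
#' locus-resampled replicates (resampling as many loci as observed, with
#' replacement) whose plurality agrees with the winner. Ties are flagged and
#' broken in hypothesis order I < II < III.
#'
#' @param geneTrees list of `phylo` gene trees
#' @param groups a group map
#' @param bootstrapReps number of locus resamples (default 1000)
#' @param seed integer seed (`NULL` continues the RNG stream)
#' @return list with `winner`, `support` (percent), `counts` (decisive
#'   counts per hypothesis), `undecisive`, `tie`
#' @export
geneTreeSummary <- function(geneTrees, groups, bootstrapReps = 1000,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- asGroupMap(groups)
  hyp <- vapply(geneTrees, function(tr)
    as.character(quartetHypothesis(tr, groups)), "")
  dec <- hyp[!is.na(hyp)]
  if (!length(dec)) stop("no decisive gene trees")
  counts <- c(I = sum(dec == "I"), II = sum(dec == "II"),
              III = sum(dec == "III"))
  winner <- names(counts)[which.max(counts)]
  tie <- sum(counts == max(counts)) > 1
  n <- length(dec)
  agree <- 0
  for (b in seq_len(bootstrapReps)) {
    rs <- dec[sample.int(n, n, replace = TRUE)]
    cb <- c(sum(rs == "I"), sum(rs == "II"), sum(rs == "III"))
    agree <- agree + (c("I", "II", "III")[which.max(cb)] == winner)
  }
  list(winner = winner, support = 100 * agree / bootstrapReps,
       counts = counts, undecisive = sum(is.na(hyp)), tie = tie)
}
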