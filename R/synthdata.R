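#' @title Synthetic locus-set generator
#' @name synthdata
#' @description A seeded generator of locus collections that emulate the
#'   statistical structure of the four palaeognath data-set classes
#'   (conserved nonexonic elements, introns, ultraconserved elements and
#'   protein-coding loci split by codon position): locus counts, length
#'   distributions, relative divergence, group-specific GC elevation
#'   (tinamous highest), missing-data proportions, and a far outgroup
#'   2.6-4.6x more divergent than the near one. Every pipeline stage is
#'   testable against it without any external download.
NULL

## ---- fixture species tree ---------------------------------------------

.fixtureIngroupNewick <- function(quartet = "I") {
  K <- "((kiwi1:0.01,kiwi2:0.01):0.015,(kiwi3:0.012,kiwi4:0.012):0.013)Kclade"
  E <- "(emu:0.03,cassowary:0.03)Eclade"
  R <- "(rhea1:0.018,rhea2:0.018)Rclade"
  T <- paste0("(moa:0.075,(tinamou1:0.05,(tinamou2:0.035,",
              "(tinamou3:0.025,tinamou4:0.025):0.012):0.013):0.02)Tclade")
  # rheas always diverge first in the fixture; the contested quartet decides
  # which pair forms the deepest cherry
  cherry <- switch(quartet,
    I = sprintf("(%s:0.022,%s:0.02)", K, E),     # KE|RT
    II = sprintf("(%s:0.02,%s:0.018)", E, T),    # KR|ET (T into the cherry)
    III = sprintf("(%s:0.022,%s:0.018)", K, T),  # KT|ER
    stop("quartet must be I, II or III"))
  middle <- switch(quartet, I = paste0(T, ":0.018"),
                   II = paste0(K, ":0.022"), III = paste0(E, ":0.02"))
  sprintf("(%s:0.02,(%s,%s:0.003)TKE:0.004)NCA", R, middle, cherry)
}

#' Fixture species tree for the five palaeognath groups
#'
#' A 15-leaf rooted tree (4 kiwi, emu+cassowary, 2 rheas, 4 tinamous + moa,
#' ostrich and chicken) with realistic relative branch lengths: short
#' contested internal branches (0.004 and 0.003 substitutions/site), tinamous
#' the most divergent ingroup, rheas diverging first, and the far outgroup
#' (chicken) path from the ingroup ancestor set to `outgroupRatio` times the
#' near outgroup (ostrich) path of 0.09. Key clades carry node labels
#' (Kclade, Eclade, Rclade, Tclade, TKE, NCA) usable as branch identifiers
#' for the nonstationary simulator.
#'
#' @param outgroupRatio far/near outgroup divergence ratio, in \[1, 20\]
#'   (default 3.5, inside the observed 2.6-4.6 range)
#' @param quartet which four-group quartet the tree carries ("I" default)
#' @return a rooted `phylo`
#' @export
fixtureSpeciesTree <- function(outgroupRatio = 3.5, quartet = "I") {
  if (outgroupRatio < 1 || outgroupRatio > 20)
    stop("outgroupRatio outside sanity window [1, 20]")
  chick <- outgroupRatio * 0.09 - 0.065
  txt <- sprintf("(chicken:%.6f,(ostrich:0.055,%s:0.035)ANC2:0.03)ROOT;",
                 chick, .fixtureIngroupNewick(quartet))
  ape::read.tree(text = txt)
}

#' Group map for the fixture taxa
#' @return named character vector covering the 15 fixture taxa
#' @export
fixtureGroupMap <- function() {
  asGroupMap(c(
    kiwi1 = "K", kiwi2 = "K", kiwi3 = "K", kiwi4 = "K",
    emu = "E", cassowary = "E", rhea1 = "R", rhea2 = "R",
    moa = "T", tinamou1 = "T", tinamou2 = "T", tinamou3 = "T",
    tinamou4 = "T", ostrich = "O", chicken = "O"))
}

#' Representative six-taxon model tree for one (T_G4, G_DF) relationship
#'
#' One leaf per group (K, E, R, T) plus ostrich (near outgroup) and chicken
#' (far outgroup), with branch lengths folded down from the fixture species
#' tree (group stem + mean within-group tip depth). Used as simulation model
#' trees in the outgroup experiment.
#'
#' @param tg4 quartet hypothesis "I", "II" or "III"
#' @param gdf first-diverging group "K", "E", "R", "T" or "X" (symmetric)
#' @param outgroupRatio far/near outgroup divergence ratio (default 3.5)
#' @return a rooted 6-leaf `phylo`
#' @export
paperModelTree <- function(tg4, gdf, outgroupRatio = 3.5) {
  tg4 <- match.arg(tg4, c("I", "II", "III"))
  gdf <- match.arg(gdf, c("K", "E", "R", "T", "X"))
  tip <- c(K = 0.047, E = 0.050, R = 0.038, T = 0.089)
  pairs <- switch(tg4, I = list(c("K", "E"), c("R", "T")),
                  II = list(c("K", "R"), c("E", "T")),
                  III = list(c("K", "T"), c("E", "R")))
  leaf <- function(g) sprintf("%s:%.4f", g, tip[g])
  cherry <- function(p, len) sprintf("(%s,%s):%s", leaf(p[1]), leaf(p[2]), len)
  ing <- if (gdf == "X") {
    sprintf("(%s,%s)NCA", cherry(pairs[[1]], "0.004"),
            cherry(pairs[[2]], "0.003"))
  } else {
    inPair <- vapply(pairs, function(p) gdf %in% p, TRUE)
    if (!any(inPair)) stop("G_DF inconsistent with T_G4")
    mid <- setdiff(pairs[[which(inPair)]], gdf)
    deep <- pairs[[which(!inPair)]]
    sprintf("(%s,(%s,%s)TKE:0.004)NCA", leaf(gdf), leaf(mid),
            cherry(deep, "0.003"))
  }
  chick <- outgroupRatio * 0.09 - 0.065
  ape::read.tree(text = sprintf(
    "(chicken:%.6f,(ostrich:0.055,%s:0.035)ANC2:0.03)ROOT;", chick, ing))
}

#' All 15 representative model trees
#'
#' @param outgroupRatio passed to [paperModelTree()]
#' @return named list ("I_R", "II_X", ...) of 15 rooted 6-leaf `phylo`
#' @export
modelTreeSet <- function(outgroupRatio = 3.5) {
  out <- list()
  for (tg4 in c("I", "II", "III"))
    for (gdf in c("K", "E", "R", "T", "X"))
      out[[paste(tg4, gdf, sep = "_")]] <-
        paperModelTree(tg4, gdf, outgroupRatio)
  out
}

#' Group map for the representative model trees
#' @return named character vector for K/E/R/T/ostrich/chicken tips
#' @export
modelTreeGroupMap <- function() {
  asGroupMap(c(K = "K", E = "E", R = "R", T = "T",
               ostrich = "O", chicken = "O"))
}

## ---- class configuration ----------------------------------------------

.piFromGC <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                            T = (1 - gc) / 2)

#' Configuration of one synthetic locus class
#'
#' Captures the knobs of the generator: locus count, truncated-normal length
#' distribution, divergence scale (a multiplier on every branch of the
#' fixture species tree), rate-variation shape, base and tinamou-elevated GC,
#' missing-data proportion, codon-position structure, far/near outgroup
#' ratio, and optional multispecies-coalescent topology heterogeneity.
#'
#' @param class class label
#' @param nLoci number of loci
#' @param lengthMean,lengthSd,lengthMin truncated-normal length parameters
#'   (nt)
#' @param divergence multiplier on the fixture tree's branch lengths
#' @param alpha gamma shape; `ncat` categories; `pInv` invariant proportion
#' @param ncat gamma categories (default 4)
#' @param pInv invariant-site proportion (default 0)
#' @param gc equilibrium GC content of the base model
#' @param tinamouGC target GC on the tinamou stem (shorthand for
#'   `gcTargets = c(T = tinamouGC)`)
#' @param gcTargets named per-group GC targets (names among K, E, R, T);
#'   listed group stems evolve under a generator rebuilt with that GC
#'   (nonstationary mode); unlisted groups stay at the base `gc`. Tinamou
#'   is conventionally the highest
#' @param missp missing-data proportion in \[0, 0.5\]
#' @param codonMultipliers per-codon-position rate multipliers or NULL
#' @param exch GTR exchangeabilities (AC, AG, AT, CG, CT, GT)
#' @param outgroupRatio far/near outgroup divergence ratio
#' @param tau NULL for a fixed species-tree topology, or a scaled coalescent
#'   internal branch (T/Ne) for per-locus quartet heterogeneity
#' @param dropTaxa taxa absent from this class (e.g. one kiwi in coding data)
#' @return a list of class "classConfig"
#' @export
classConfig <- function(class = "synthetic", nLoci = 100, lengthMean = 1000,
                        lengthSd = 300, lengthMin = 50, divergence = 1,
                        alpha = 1, ncat = 4, pInv = 0, gc = 0.42,
                        tinamouGC = gc, gcTargets = NULL, missp = 0,
                        codonMultipliers = NULL,
                        exch = c(1, 4, 0.7, 1.1, 4.5, 1), outgroupRatio = 3.5,
                        tau = NULL, dropTaxa = character(0)) {
  if (is.null(gcTargets) && abs(tinamouGC - gc) > 1e-12)
    gcTargets <- c(T = tinamouGC)
  cfg <- list(class = class, nLoci = nLoci, lengthMean = lengthMean,
              lengthSd = lengthSd, lengthMin = lengthMin,
              divergence = divergence, alpha = alpha, ncat = ncat,
              pInv = pInv, gc = gc, gcTargets = gcTargets, missp = missp,
              codonMultipliers = codonMultipliers, exch = exch,
              outgroupRatio = outgroupRatio, tau = tau, dropTaxa = dropTaxa)
  bad <- character(0)
  if (nLoci < 1) bad <- c(bad, "nLoci")
  if (lengthMean <= 0 || lengthSd < 0 || lengthMin < 1) bad <- c(bad, "length")
  if (divergence <= 0) bad <- c(bad, "divergence")
  if (alpha <= 0) bad <- c(bad, "alpha")
  if (pInv < 0 || pInv >= 1) bad <- c(bad, "pInv")
  if (gc <= 0 || gc >= 1 || any(gcTargets <= 0) || any(gcTargets >= 1))
    bad <- c(bad, "gc")
  if (!is.null(gcTargets) && !all(names(gcTargets) %in% GROUPS_INGROUP))
    bad <- c(bad, "gcTargets")
  if (missp < 0 || missp > 0.5) bad <- c(bad, "missp")
  if (!is.null(tau) && tau < 0) bad <- c(bad, "tau")
  if (length(bad))
    stop(sprintf("invalid class config field(s): %s",
                 paste(unique(bad), collapse = ",")))
  structure(cfg, class = "classConfig")
}

#' Preset class configurations
#'
#' Presets mirror the reported structure of the four data-set classes: locus
#' counts and length means/sds, missing-data proportions, relative divergence
#' ordering (CNEE and C12 low; UCE intermediate; intron and C3 high), higher
#' GC and stronger tinamou GC elevation in coding classes, strong
#' rate-variation in C12 (alpha = 0.02 plus invariant sites) and
#' codon-position structure in C123. Coding classes lack one kiwi.
#'
#' @param class one of "CNEE", "intron", "UCE", "C123", "C12", "C3"
#' @return a [classConfig()]
#' @export
synthPreset <- function(class = c("CNEE", "intron", "UCE", "C123", "C12", "C3")) {
  class <- match.arg(class)
  switch(class,
    CNEE = classConfig("CNEE", nLoci = 12561, lengthMean = 376.9,
                       lengthSd = 146.4, lengthMin = 50, divergence = 0.15,
                       alpha = 0.4, gc = 0.42, tinamouGC = 0.45, missp = 0.03),
    intron = classConfig("intron", nLoci = 1802, lengthMean = 2405.8,
                         lengthSd = 2736.7, lengthMin = 100, divergence = 1,
                         alpha = 1.9, gc = 0.42, tinamouGC = 0.46,
                         missp = 0.23),
    UCE = classConfig("UCE", nLoci = 1363, lengthMean = 2519.5,
                      lengthSd = 456.3, lengthMin = 100, divergence = 0.5,
                      alpha = 1.0, gc = 0.42, tinamouGC = 0.455, missp = 0.16),
    C123 = classConfig("C123", nLoci = 5374, lengthMean = 2076.8,
                       lengthSd = 1500.9, lengthMin = 99, divergence = 0.6,
                       alpha = 0.3, gc = 0.50,
                       gcTargets = c(E = 0.53, T = 0.56), missp = 0.16,
                       codonMultipliers = c(0.45, 0.45, 2.1),
                       exch = c(1, 6, 0.7, 1.1, 6.5, 1),
                       dropTaxa = "kiwi4"),
    C12 = classConfig("C12", nLoci = 5374, lengthMean = 1384.6,
                      lengthSd = 1000.6, lengthMin = 66, divergence = 0.1,
                      alpha = 0.02, pInv = 0.5, gc = 0.50,
                      gcTargets = c(E = 0.52, T = 0.55), missp = 0.16, exch = c(1, 6, 0.7, 1.1, 6.5, 1),
                      dropTaxa = "kiwi4"),
    C3 = classConfig("C3", nLoci = 5374, lengthMean = 692.3, lengthSd = 500.3,
                     lengthMin = 33, divergence = 1.6, alpha = 1.5, gc = 0.52,
                     gcTargets = c(E = 0.56, T = 0.60), missp = 0.16,
                     exch = c(1, 6, 0.7, 1.1, 6.5, 1),
                     dropTaxa = "kiwi4"))
}

## ---- generation -------------------------------------------------------

#' The GTR+Gamma model implied by a class config
#' @param cfg a [classConfig()]
#' @return a [GTRGamma-class]
#' @export
configModel <- function(cfg) {
  buildModel(.piFromGC(cfg$gc), cfg$exch, cfg$alpha, cfg$ncat, cfg$pInv)
}

#' Generate a synthetic locus set
#'
#' Per locus: draw the length from the truncated normal; draw the generating
#' quartet topology from the coalescent concordance probabilities when `tau`
#' is set (otherwise the fixture quartet I); simulate sequences on the
#' divergence-scaled fixture tree, with the tinamou stem switched to its
#' elevated GC when configured (inherited by all tinamou-clade branches);
#' inject missing data (whole-taxon dropout plus short gap runs) to hit the
#' configured proportion in expectation. Byte-identical regeneration from
#' (config, seed).
#'
#' @param cfg a [classConfig()]
#' @param seed integer seed
#' @param nLoci optional override of `cfg$nLoci` (problem-size control for
#'   tests and examples)
#' @return list with `loci` (list of [Locus-class], divergence filled in
#'   from the generating tree), `truth` (per-locus list: topology, tree),
#'   `model` (the generating [GTRGamma-class]), `speciesTree`, `groups`
#' @export
generateDataset <- function(cfg, seed, nLoci = cfg$nLoci) {
  stopifnot(inherits(cfg, "classConfig"))
  set.seed(seed)
  groups <- fixtureGroupMap()
  trees <- lapply(c(I = "I", II = "II", III = "III"), function(q) {
    tr <- fixtureSpeciesTree(cfg$outgroupRatio, quartet = q)
    if (length(cfg$dropTaxa)) tr <- ape::drop.tip(tr, cfg$dropTaxa)
    tr$edge.length <- tr$edge.length * cfg$divergence
    tr
  })
  div <- vapply(trees, function(tr)
    divergenceFromNCA(tr, groups)$divergence, 0)
  model <- configModel(cfg)
  bf <- NULL
  if (!is.null(cfg$gcTargets)) {
    cladeOf <- c(K = "Kclade", E = "Eclade", R = "Rclade", T = "Tclade")
    bf <- lapply(as.list(cfg$gcTargets), .piFromGC)
    names(bf) <- cladeOf[names(cfg$gcTargets)]
  }
  pTopo <- if (is.null(cfg$tau)) c(1, 0, 0)
           else concordanceProbability(cfg$tau)
  loci <- vector("list", nLoci)
  truth <- vector("list", nLoci)
  for (i in seq_len(nLoci)) {
    L <- max(cfg$lengthMin, round(rnorm(1, cfg$lengthMean, cfg$lengthSd)))
    topo <- c("I", "II", "III")[sample.int(3, 1, prob = pTopo)]
    tr <- trees[[topo]]
    aln <- simulateAlignment(tr, model, L, seed = NULL, branchFreqs = bf,
                             classMultipliers = cfg$codonMultipliers)
    if (cfg$missp > 0) aln <- .injectMissing(aln, cfg$missp)
    id <- sprintf("%s_%05d", cfg$class, i)
    loci[[i]] <- locus(id, aln, class = cfg$class, tree = tr,
                       divergence = div[[topo]])
    truth[[i]] <- list(id = id, topology = topo, tree = tr)
  }
  list(loci = loci, truth = truth, model = model,
       speciesTree = trees[["I"]], groups = groups)
}

#' Inject missing data: whole-taxon dropout plus short gap runs
#'
#' Half of the target proportion comes from whole-row dropout, the rest from
#' gap runs of mean length 30 at random starts, so the expected overall
#' missing fraction equals `missp`.
#' @noRd
.injectMissing <- function(aln, missp) {
  m <- alnMatrix(aln)
  L <- ncol(m)
  q <- missp / 2
  f <- (missp - q) / (1 - q)
  for (i in seq_len(nrow(m))) {
    if (runif(1) < q) {
      m[i, ] <- "-"
      next
    }
    nrun <- rpois(1, f * L / 30)
    if (nrun > 0) {
      starts <- sample.int(L, nrun, replace = TRUE)
      lens <- pmax(1, rpois(nrun, 30))
      for (j in seq_len(nrun))
        m[i, starts[j]:min(L, starts[j] + lens[j] - 1)] <- "-"
    }
  }
  new("Alignment", seqs = m)
}
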