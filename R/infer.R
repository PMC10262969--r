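#' @title Likelihood and parsimony engines
#' @name infer
#' @description Felsenstein pruning under GTR+Gamma (compiled core),
#'   coordinate-wise branch-length optimization, exhaustive ML topology
#'   selection over enumerated candidates, empirical-Bayes site rates, Fitch
#'   parsimony and parsimony-informative-site detection.
NULL

## ---- pattern compression and tip partials -----------------------------

#' Compress alignment columns into unique site patterns
#' @return list(patterns = character matrix taxa x npat, weights, index:
#'   pattern id per original site)
#' @noRd
.compressPatterns <- function(m) {
  key <- apply(m, 2, paste, collapse = "")
  f <- factor(key, levels = unique(key))
  idx <- as.integer(f)
  first <- match(levels(f), key)
  list(patterns = m[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(first))),
       index = idx)
}

#' Tip partial-likelihood masks for a set of patterns
#' @noRd
.tipPartials <- function(patterns, tipOrder, states) {
  ns <- length(states)
  npat <- ncol(patterns)
  ntip <- length(tipOrder)
  # layout matches the compiled core: pattern index fastest, then state, tip
  arr <- array(0, c(npat, ns, ntip))
  lut <- matrix(0, ns, length(ALPHABET),
                dimnames = list(states, ALPHABET))
  for (a in ALPHABET) {
    comp <- IUPAC[[a]]
    if (ns == 2) {
      # RY alphabet: R/Y literal; everything ambiguous or gap = both
      comp <- if (a %in% c("R", "Y")) a else c("R", "Y")
    }
    lut[states %in% comp, a] <- 1
  }
  for (t in seq_len(ntip)) {
    ch <- patterns[tipOrder[t], ]
    bad <- !(ch %in% ALPHABET)
    if (any(bad)) stop(sprintf("unknown symbol '%s' in sequence '%s'",
                               ch[bad][1], tipOrder[t]))
    arr[, , t] <- t(lut[, ch, drop = FALSE])
  }
  arr
}

#' Postorder edge table (0-based) and root for the compiled core
#' @noRd
.treeForCore <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  list(edge = tr$edge - 1L, len = tr$edge.length, ntip = ntip,
       nnode = ntip + tr$Nnode, root = ntip, tips = tr$tip.label, phylo = tr)
}

.checkTreeAln <- function(tree, aln) {
  miss <- setdiff(tree$tip.label, alnTaxa(aln))
  if (length(miss))
    stop(sprintf("tree taxa absent from alignment: %s",
                 paste(miss, collapse = ",")))
}

## ---- likelihood -------------------------------------------------------

#' Log-likelihood of an alignment on a tree under GTR+Gamma
#'
#' Felsenstein pruning: per site,
#' `log sum_c w_c P(pattern | tree, category c)` with equal-probability gamma
#' categories (plus the invariant class when `pInv > 0`). Ambiguity codes
#' contribute partial likelihood 1 for every compatible state; gaps and `?`
#' are fully missing. For a reversible model the value is invariant to the
#' position of the root (pulley principle).
#'
#' @param tree a `phylo` with branch lengths; leaves must be a subset of the
#'   alignment taxa
#' @param aln an [Alignment-class]
#' @param model a [GTRGamma-class]
#' @return the log-likelihood (a scalar)
#' @export
logLikelihood <- function(tree, aln, model) {
  .checkTreeAln(tree, aln)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  core <- .treeForCore(tree)
  pat <- .compressPatterns(alnMatrix(aln)[core$tips, , drop = FALSE])
  tp <- .tipPartials(pat$patterns, core$tips, model@states)
  cats <- .modelCats(model)
  .cpp_loglik(core$edge, core$len, core$ntip, core$nnode, core$root,
              as.numeric(tp), pat$weights, model@pi, model@eigenVals,
              model@eigenVecs, model@eigenInv, cats$rates, cats$weights)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise bounded Brent search per branch, sweeping in postorder,
#' until the relative log-likelihood improvement per sweep falls below
#' `relTol` or `maxSweeps` is reached. Lengths are constrained to
#' \[`minLen`, `maxLen`\]. Non-convergence is flagged, not an error.
#'
#' @inheritParams logLikelihood
#' @param init initial branch lengths: "keep" uses the tree's lengths where
#'   set, otherwise 0.05
#' @param minLen,maxLen branch-length bounds (defaults 1e-9, 10)
#' @param relTol per-sweep relative improvement threshold (default 1e-8)
#' @param maxSweeps maximum sweeps (default 100)
#' @param brentTol x-tolerance of the per-branch Brent search (default 1e-7;
#'   larger values trade branch-length precision for speed, which topology
#'   selection tolerates well)
#' @param patterns optional precompressed site patterns (internal reuse
#'   across candidate topologies; must cover all tree taxa)
#' @return list with `tree` (lengths updated), `loglik`, `sweeps`,
#'   `converged`
#' @export
optimizeBranchLengths <- function(tree, aln, model, init = "keep",
                                  minLen = 1e-9, maxLen = 10,
                                  relTol = 1e-8, maxSweeps = 100,
                                  brentTol = 1e-7, patterns = NULL) {
  .checkTreeAln(tree, aln)
  if (is.null(tree$edge.length) || !identical(init, "keep"))
    tree$edge.length <- rep(if (is.numeric(init)) init else 0.05,
                            nrow(tree$edge))
  tree$edge.length <- pmin(pmax(tree$edge.length, minLen), maxLen)
  core <- .treeForCore(tree)
  pat <- if (is.null(patterns))
    .compressPatterns(alnMatrix(aln)[core$tips, , drop = FALSE]) else patterns
  tp <- .tipPartials(pat$patterns, core$tips, model@states)
  cats <- .modelCats(model)
  res <- .cpp_optimize_branches(core$edge, core$len, core$ntip, core$nnode,
                                core$root, as.numeric(tp), pat$weights,
                                model@pi, model@eigenVals, model@eigenVecs,
                                model@eigenInv, cats$rates, cats$weights,
                                minLen, maxLen, relTol, as.integer(maxSweeps),
                                brentTol)
  out <- core$phylo
  out$edge.length <- res$lengths
  list(tree = out, loglik = res$loglik, sweeps = res$sweeps,
       converged = res$converged)
}

#' Exhaustive maximum-likelihood topology search
#'
#' Optimizes branch lengths on every candidate topology (all binary
#' topologies on the labels unless an explicit candidate list is supplied)
#' and returns the highest-likelihood tree. Ties within `tieTol` log units
#' are broken by the lowest canonical topology index and flagged.
#'
#' @param aln an [Alignment-class]
#' @param labels taxa to include (default: all alignment taxa); at most 8
#'   unless `candidates` is given
#' @param model a [GTRGamma-class]
#' @param candidates optional list of `phylo` candidate topologies
#' @param tieTol log-likelihood tie tolerance (default 1e-8)
#' @param ... passed to [optimizeBranchLengths()] (e.g. `relTol`,
#'   `maxSweeps`)
#' @return list with `tree` (the ML tree with optimized lengths), `index`
#'   (canonical candidate index), `loglik` (per-candidate vector), `tie`
#'   (logical), `converged`
#' @export
exhaustiveMLSearch <- function(aln, labels = alnTaxa(aln), model,
                               candidates = NULL, tieTol = 1e-8, ...) {
  if (is.null(candidates)) candidates <- enumerateTopologies(labels)
  sub <- aln[labels, ]
  pat <- .compressPatterns(alnMatrix(sub))
  lnl <- numeric(length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    fits[[i]] <- optimizeBranchLengths(candidates[[i]], sub, model,
                                       init = 0.05, patterns = pat, ...)
    lnl[i] <- fits[[i]]$loglik
  }
  best <- which.max(lnl)
  tie <- sum(lnl >= lnl[best] - tieTol) > 1
  if (tie) best <- which(lnl >= lnl[best] - tieTol)[1]
  list(tree = fits[[best]]$tree, index = best, loglik = lnl, tie = tie,
       converged = fits[[best]]$converged)
}

#' Empirical-Bayes site-specific substitution rates
#'
#' Posterior-mean relative rate per site: `sum_c r_c P(c | pattern)` with
#' equal category priors (and the rate-0 invariant class when `pInv > 0`).
#' Constant sites receive the smallest rates.
#'
#' @inheritParams logLikelihood
#' @return numeric vector of per-site rates (length = alignment length)
#' @export
estimateSiteRates <- function(aln, tree, model) {
  .checkTreeAln(tree, aln)
  core <- .treeForCore(tree)
  pat <- .compressPatterns(alnMatrix(aln)[core$tips, , drop = FALSE])
  tp <- .tipPartials(pat$patterns, core$tips, model@states)
  cats <- .modelCats(model)
  sl <- .cpp_site_lik(core$edge, core$len, core$ntip, core$nnode, core$root,
                      as.numeric(tp), pat$weights, model@pi, model@eigenVals,
                      model@eigenVecs, model@eigenInv, cats$rates,
                      cats$weights)
  post <- sweep(sl, 2, cats$weights, "*")
  post <- post / rowSums(post)
  rates <- as.numeric(post %*% cats$rates)
  rates[pat$index]
}

## ---- parsimony --------------------------------------------------------

.BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.charToBits <- function(ch) {
  b <- vapply(IUPAC[ch], function(s) sum(.BITS[s]), 0L)
  as.integer(b)
}

#' Fitch parsimony score
#'
#' Minimum number of state changes over the tree summed across sites, with
#' IUPAC ambiguity codes treated as state unions (gaps and `?` as the full
#' set).
#'
#' @param tree a binary `phylo`
#' @param aln an [Alignment-class] containing all tree taxa
#' @return integer parsimony score
#' @export
fitchScore <- function(tree, aln) {
  .checkTreeAln(tree, aln)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  m <- alnMatrix(aln)[tr$tip.label, , drop = FALSE]
  pat <- .compressPatterns(m)
  npat <- ncol(pat$patterns)
  sets <- matrix(0L, ntip + tr$Nnode, npat)
  for (t in seq_len(ntip)) sets[t, ] <- .charToBits(pat$patterns[t, ])
  score <- numeric(npat)
  # postorder guarantees a child's set is final when its edge is visited;
  # children are folded into the parent incrementally (handles the basal
  # trichotomy of unrooted trees too)
  started <- logical(ntip + tr$Nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c2 <- tr$edge[e, 2]
    if (!started[p]) {
      sets[p, ] <- sets[c2, ]
      started[p] <- TRUE
    } else {
      inter <- bitwAnd(sets[p, ], sets[c2, ])
      hit <- inter == 0L
      score <- score + hit
      sets[p, ] <- ifelse(hit, bitwOr(sets[p, ], sets[c2, ]), inter)
    }
  }
  as.integer(sum(score * pat$weights))
}

#' Parsimony-informative sites
#'
#' A site is parsimony-informative iff at least two distinct unambiguous
#' nucleotide states each occur in at least two sequences; ambiguity codes
#' and gaps are excluded from the counts.
#'
#' @param aln an [Alignment-class]
#' @return integer vector of 1-based informative site indices
#' @export
parsimonyInformativeSites <- function(aln) {
  m <- alnMatrix(aln)
  counts <- vapply(ACGT, function(s) colSums(m == s), numeric(nSites(aln)))
  if (nSites(aln) == 1) counts <- matrix(counts, nrow = 1)
  which(rowSums(counts >= 2) >= 2)
}
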