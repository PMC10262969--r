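#' Simulate a nucleotide alignment along a tree
#'
#' Seeded sequence simulation under the GTR+Gamma model, stationary by
#' default: root states are drawn from the equilibrium frequencies, a gamma
#' category (and, when `pInv > 0`, invariant status) is drawn once per site
#' and shared across all branches, and states evolve down the tree with
#' transition matrices `P(t * rate)`. A nonstationary variant is obtained via
#' `branchFreqs`: branches listed there substitute under a GTR generator
#' rebuilt with that branch's target frequencies (same exchangeabilities,
#' renormalized); unlisted branches inherit the parent's effective
#' frequencies, the root uses the model's. Optional per-site-class rate
#' multipliers give loci codon-position structure: multiplier `k` applies to
#' columns `k, k + nclass, ...`.
#'
#' @param tree a `phylo` with branch lengths
#' @param model a [GTRGamma-class]
#' @param L sequence length (>= 1)
#' @param seed integer seed; identical (tree, model, L, seed, ...) give
#'   byte-identical alignments. `NULL` continues the current RNG stream.
#' @param branchFreqs optional named list of length-4 frequency vectors; names
#'   are tip labels (terminal branches) or internal node labels (the branch
#'   subtending that node)
#' @param classMultipliers optional positive per-site-class rate multipliers
#'   cycling over columns (e.g. `c(0.4, 0.4, 2.2)` for codon positions)
#' @return an [Alignment-class] with one row per tip, columns over A/C/G/T
#' @examples
#' tr <- readTree("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
#' m <- buildModel(rep(0.25, 4), rep(1, 6), alpha = 1)
#' simulateAlignment(tr, m, 100, seed = 1)
#' @export
simulateAlignment <- function(tree, model, L, seed = NULL, branchFreqs = NULL,
                              classMultipliers = NULL) {
  if (L < 1) stop("L must be >= 1")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (length(model@states) != 4)
    stop("sequence simulation requires the 4-state nucleotide model")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(L)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  root <- ntip + 1L

  # per-site rates: gamma category, invariant class, cyclic class multiplier
  cats <- .modelCats(model)
  k <- sample.int(model@ncat, L, replace = TRUE)
  rate <- model@catRates[k]
  if (model@pInv > 0) rate[runif(L) < model@pInv] <- 0
  if (!is.null(classMultipliers)) {
    if (any(classMultipliers <= 0)) stop("class multipliers must be positive")
    rate <- rate * classMultipliers[(seq_len(L) - 1L) %% length(classMultipliers) + 1L]
  }

  # branch-specific generators (nonstationary mode)
  nodeFreq <- vector("list", nnode)          # effective pi per node's stem
  freqKey <- character(nnode)
  models <- list(base = model)
  nodeKey <- rep("base", nnode)
  if (!is.null(branchFreqs)) {
    ids <- .resolveBranchNodes(tree, names(branchFreqs))
    for (i in seq_along(ids)) {
      f <- branchFreqs[[i]]
      if (length(f) != 4 || abs(sum(f) - 1) > 1e-8)
        stop(sprintf("branch frequency vector '%s' must have 4 entries summing to 1",
                     names(branchFreqs)[i]))
      key <- paste(format(f, digits = 15), collapse = ",")
      if (is.null(models[[key]])) models[[key]] <- withFrequencies(model, f)
      nodeFreq[[ids[i]]] <- f
      freqKey[ids[i]] <- key
    }
  }

  states <- matrix(0L, nnode, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model@pi)
  effKey <- rep("base", nnode)
  ur <- sort(unique(rate))
  # preorder = reverse postorder edge traversal
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; len <- tr$edge.length[e]
    key <- if (nzchar(freqKey[ch])) freqKey[ch] else effKey[p]
    effKey[ch] <- key
    bm <- models[[key]]
    ps <- states[p, ]
    cs <- integer(L)
    for (r in ur) {
      idx <- which(rate == r)
      if (!length(idx)) next
      if (r == 0 || len == 0) {        # invariant site or zero-length branch
        cs[idx] <- ps[idx]
        next
      }
      P <- transitionMatrix(bm, len, r)
      for (s in 1:4) {
        ii <- idx[ps[idx] == s]
        if (length(ii))
          cs[ii] <- sample.int(4L, length(ii), replace = TRUE, prob = P[s, ])
      }
    }
    states[ch, ] <- cs
  }
  m <- matrix(ACGT[states[seq_len(ntip), , drop = FALSE]], ntip, L)
  rownames(m) <- tree$tip.label
  new("Alignment", seqs = m)
}

#' Map branch-frequency names to child node ids
#' @noRd
.resolveBranchNodes <- function(tree, nms) {
  ntip <- length(tree$tip.label)
  ids <- integer(length(nms))
  for (i in seq_along(nms)) {
    j <- match(nms[i], tree$tip.label)
    if (!is.na(j)) { ids[i] <- j; next }
    if (!is.null(tree$node.label)) {
      j <- match(nms[i], tree$node.label)
      if (!is.na(j)) { ids[i] <- ntip + j; next }
    }
    stop(sprintf("branch name '%s' matches no tip or node label", nms[i]))
  }
  ids
}

#' Simulate gene-tree quartet topologies under the multispecies coalescent
#'
#' For a species-tree quartet with scaled internal branch `tau = T/Ne`
#' (T in generations, Ne the effective population size), a gene tree matches
#' the species-tree topology with probability `1 - (2/3) exp(-tau/divisor)`
#' and each of the two discordant topologies with `(1/3) exp(-tau/divisor)`.
#' `divisor = 1` follows the printed form of the formula; `divisor = 2` gives
#' the diploid-coalescent convention in which branches are measured in units
#' of 2Ne generations.
#'
#' @param tau scaled internal branch length T/Ne (>= 0)
#' @param n number of independent gene-tree draws (>= 1)
#' @param seed integer seed (`NULL` continues the RNG stream)
#' @param divisor exponent convention, 1 (default) or 2
#' @return named integer vector `c(concordant = , discordant1 = ,
#'   discordant2 = )` summing to `n`
#' @examples
#' simulateMSCQuartetTopologies(0.105, 1000, seed = 1)
#' @export
simulateMSCQuartetTopologies <- function(tau, n, seed = NULL, divisor = 1) {
  stopifnot(tau >= 0, n >= 1, divisor %in% c(1, 2))
  if (!is.null(seed)) set.seed(seed)
  p <- concordanceProbability(tau, divisor = divisor)
  cnt <- as.vector(stats::rmultinom(1, n, prob = p))
  setNames(cnt, c("concordant", "discordant1", "discordant2"))
}
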