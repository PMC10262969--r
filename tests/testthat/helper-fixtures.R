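# Shared fixtures: tiny models, group maps and the exhaustive-state
# likelihood oracle used to validate the pruning engine.

jcModel <- function(ncat = 1, alpha = 1)
  buildModel(rep(0.25, 4), rep(1, 6), alpha = alpha, ncat = ncat)

gm1 <- c(K = "K", E = "E", R = "R", T = "T", O = "O")

randomModel <- function(ncat = 2, pInv = 0)
  buildModel(prop.table(runif(4, 0.5, 1.5)), runif(6, 0.5, 5),
             alpha = runif(1, 0.2, 2), ncat = ncat, pInv = pInv)

randomTree <- function(n) {
  tset <- enumerateTopologies(letters[seq_len(n)])
  tr <- tset[[sample(length(tset), 1)]]
  tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.8)
  tr
}

# Likelihood by explicit summation over all internal-node state assignments
# (independent of the pruning path).
bruteForceLogLik <- function(tree, aln, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  m0 <- alnMatrix(aln)[tr$tip.label, , drop = FALSE]
  cats <- phyloconcord:::.modelCats(model)
  root <- ntip + 1
  iup <- phyloconcord:::IUPAC
  ints <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  tot <- 0
  for (s in seq_len(ncol(m0))) {
    Ls <- 0
    for (ci in seq_along(cats$rates)) {
      Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
        transitionMatrix(model, tr$edge.length[e], cats$rates[ci]))
      tot_c <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[ints] <- grid[g, ]
        pr <- model@pi[st[root]]
        for (e in seq_len(nrow(tr$edge))) {
          p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
          if (ch <= ntip) {
            comp <- match(iup[[m0[ch, s]]], c("A", "C", "G", "T"))
            pr <- pr * sum(Ps[[e]][st[p], comp])
          } else pr <- pr * Ps[[e]][st[p], st[ch]]
        }
        tot_c <- tot_c + pr
      }
      Ls <- Ls + cats$weights[ci] * tot_c
    }
    tot <- tot + log(Ls)
  }
  tot
}

# Fitch score by minimization over all internal-node labelings.
bruteForceFitch <- function(tree, aln) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  m0 <- alnMatrix(aln)[tr$tip.label, , drop = FALSE]
  iup <- phyloconcord:::IUPAC
  ints <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  total <- 0
  for (s in seq_len(ncol(m0))) {
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      st <- integer(nnode)
      st[ints] <- grid[g, ]
      ch <- 0
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; c2 <- tr$edge[e, 2]
        if (c2 <= ntip) {
          comp <- match(iup[[m0[c2, s]]], c("A", "C", "G", "T"))
          ch <- ch + as.integer(!(st[p] %in% comp))
        } else ch <- ch + as.integer(st[p] != st[c2])
      }
      best <- min(best, ch)
    }
    total <- total + best
  }
  total
}
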