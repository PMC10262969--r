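#' @title Tree utilities: Newick I/O, splits, enumeration, RF distance,
#'   relationship labels
#' @name treekit
#' @description Small-tree machinery the rest of the package is built on.
#'   Trees are plain `ape::phylo` objects; all topological operations
#'   (bipartitions, Robinson-Foulds, exhaustive enumeration, four-group
#'   relationship labelling) are implemented here.
NULL

#' Read a Newick tree with validation
#'
#' Thin validating wrapper around [ape::read.tree()]. Branch lengths are
#' optional; internal node labels are kept. Malformed parentheses are reported
#' with a character offset; duplicate tip labels raise an error.
#'
#' @param text a Newick string
#' @return a `phylo` object
#' @examples
#' tr <- readTree("(A:1,B:1,(C:1,D:1):0.5);")
#' @export
readTree <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("malformed Newick: unbalanced ')' at character %d", i))
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string", depth))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick: parse failed")
  if (anyDuplicated(tr$tip.label))
    stop(sprintf("duplicate tip label '%s'",
                 tr$tip.label[duplicated(tr$tip.label)][1]))
  if (!is.null(tr$edge.length) && any(!is.finite(tr$edge.length)))
    stop("non-finite branch length")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length")
  tr
}

#' Write a tree as a Newick string
#'
#' @param tree a `phylo`
#' @param digits significant digits for branch lengths (default 12, enough for
#'   lossless round-trips of simulated lengths)
#' @return a Newick string
#' @export
writeTree <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

## ---- splits -----------------------------------------------------------

#' Tips descending from every node (internal helper)
#' @noRd
.descTips <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Canonical key of a bipartition side
#'
#' The split is stored as the side containing the lexicographically smallest
#' tip label, sorted and comma-joined: a deterministic, order-free identifier.
#' @noRd
.canonicalSplit <- function(side, tips) {
  if (!(sort(tips)[1] %in% side)) side <- setdiff(tips, side)
  paste(sort(side), collapse = ",")
}

#' Non-trivial bipartitions of a tree
#'
#' Returns one canonical key per internal branch. An n-leaf unrooted binary
#' tree yields n-3 splits; for rooted trees the two root edges describe the
#' same bipartition and are de-duplicated.
#'
#' @param tree a `phylo`
#' @return sorted character vector of canonical split keys
#' @examples
#' treeSplits(readTree("((K,E),(R,T),O);"))
#' @export
treeSplits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 4) return(character(0))
  desc <- .descTips(tree)
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next
    side <- desc[[ch]]
    if (length(side) < 2 || length(side) > n - 2) next
    keys <- c(keys, .canonicalSplit(side, tips))
  }
  sort(unique(keys))
}

#' Robinson-Foulds distance between two trees
#'
#' Twice the number of internal branches that differ: the size of the
#' symmetric difference of the two canonical split sets. Zero iff the two
#' trees have the same unrooted topology.
#'
#' @param t1,t2 `phylo` objects on the same leaf set
#' @return an even non-negative integer
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- treeSplits(t1); s2 <- treeSplits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

## ---- enumeration ------------------------------------------------------

#' All placements of leaf x inside (or directly above) a nested-list subtree
#' @noRd
.insertAll <- function(node, x) {
  out <- list(list(node, x))
  if (is.list(node)) {
    for (i in seq_along(node)) {
      for (v in .insertAll(node[[i]], x)) {
        nn <- node
        nn[[i]] <- v
        out <- c(out, list(nn))
      }
    }
  }
  out
}

.nestedToNewick <- function(node) {
  if (!is.list(node)) return(paste0(node, ":1"))
  paste0("(", paste(vapply(node, .nestedToNewick, ""), collapse = ","), "):1")
}

#' Enumerate all binary tree topologies on a label set
#'
#' Exhaustive stepwise-addition enumeration, returning every distinct binary
#' topology with unit branch lengths in a deterministic canonical order
#' (sorted by concatenated canonical split keys). Five labels give the 15
#' unrooted topologies of four ingroup lineages plus an outgroup; four labels
#' give the 3 quartet topologies.
#'
#' @param labels character vector of 3 to 8 taxon labels
#' @param rooted enumerate rooted (basal bifurcation) instead of unrooted
#'   topologies
#' @return list of `phylo` objects; counts are (2n-5)!! unrooted, (2n-3)!!
#'   rooted
#' @examples
#' length(enumerateTopologies(c("K", "E", "R", "T", "O")))  # 15
#' @export
enumerateTopologies <- function(labels, rooted = FALSE) {
  labels <- as.character(labels)
  n <- length(labels)
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (n < 3 || n > 8)
    stop(sprintf("label count %d outside the supported range 3..8", n))
  labs <- sort(labels)
  if (rooted) {
    trees <- list(list(labs[1], labs[2]))
    rest <- labs[-(1:2)]
    for (x in rest) {
      nxt <- list()
      for (tr in trees) nxt <- c(nxt, .insertAll(tr, x))
      trees <- nxt
    }
  } else {
    trees <- list(list(labs[1], labs[2], labs[3]))
    rest <- labs[-(1:3)]
    for (x in rest) {
      nxt <- list()
      for (tr in trees) {
        for (i in seq_along(tr)) {
          for (v in .insertAll(tr[[i]], x)) {
            nn <- tr
            nn[[i]] <- v
            nxt <- c(nxt, list(nn))
          }
        }
      }
      trees <- nxt
    }
  }
  phys <- lapply(trees, function(tr)
    ape::read.tree(text = paste0(.nestedToNewick(tr), ";")))
  keys <- vapply(phys, function(p) {
    sp <- treeSplits(p)
    if (rooted) {
      # include rooted clades so distinct rootings sort apart
      desc <- .descTips(p)
      n1 <- length(p$tip.label)
      cl <- sort(vapply(seq_len(p$Nnode) + n1,
                        function(nd) paste(sort(desc[[nd]]), collapse = ","), ""))
      paste(cl, collapse = ";")
    } else paste(sp, collapse = ";")
  }, "")
  phys[order(keys)]
}

## ---- group maps and relationship labels -------------------------------

#' Validate / construct a taxon-to-group map
#'
#' A group map assigns every taxon to one of the five groups: K (kiwi),
#' E (emu+cassowary), R (rheas), T (tinamous+moa), O (outgroup).
#'
#' @param x named character vector, names = taxon labels, values in
#'   K/E/R/T/O
#' @return the validated named character vector
#' @export
asGroupMap <- function(x) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("group map must be named by unique taxon labels")
  bad <- setdiff(unique(x), GROUPS_ALL)
  if (length(bad))
    stop(sprintf("unknown group(s): %s (allowed: %s)",
                 paste(bad, collapse = ","), paste(GROUPS_ALL, collapse = ",")))
  x
}

#' Read a two-column whitespace-delimited taxon-to-group table
#'
#' @param path file with taxon label in column 1, group (K/E/R/T/O) in
#'   column 2; `#` comments allowed
#' @return named character vector (see [asGroupMap()])
#' @export
readGroupMap <- function(path) {
  tb <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#",
                   col.names = c("taxon", "group"))
  asGroupMap(setNames(tb$group, tb$taxon))
}

.groupTips <- function(taxa, groups, g) {
  unmapped <- setdiff(taxa, names(groups))
  if (length(unmapped))
    stop(sprintf("taxa not in group map: %s", paste(unmapped, collapse = ",")))
  taxa[groups[taxa] %in% g]
}

#' Quartet hypothesis of a gene tree restricted to the four ingroup groups
#'
#' Drops outgroup tips, requires all four ingroup groups present and
#' monophyletic, and returns which quartet hypothesis the collapsed tree
#' matches: "I" (KE|RT), "II" (KR|ET) or "III" (KT|ER). Returns `NA` with a
#' `reason` attribute when the tree is undecisive (a group absent or
#' non-monophyletic).
#'
#' @param tree a `phylo`
#' @param groups a group map (see [asGroupMap()])
#' @return "I", "II", "III" or `NA`
#' @export
quartetHypothesis <- function(tree, groups) {
  groups <- asGroupMap(groups)
  otips <- .groupTips(tree$tip.label, groups, "O")
  if (length(otips)) {
    if (length(otips) == length(tree$tip.label))
      return(structure(NA_character_, reason = "only outgroup tips"))
    tree <- ape::drop.tip(tree, otips)
  }
  tips <- tree$tip.label
  gt <- lapply(GROUPS_INGROUP, function(g) .groupTips(tips, groups, g))
  names(gt) <- GROUPS_INGROUP
  if (any(lengths(gt) == 0))
    return(structure(NA_character_,
                     reason = paste0("missing group ",
                                     GROUPS_INGROUP[lengths(gt) == 0][1])))
  sp <- treeSplits(tree)
  mono <- vapply(GROUPS_INGROUP, function(g) {
    s <- gt[[g]]
    length(s) == 1 || length(s) == length(tips) - 1 ||
      .canonicalSplit(s, tips) %in% sp
  }, TRUE)
  if (!all(mono))
    return(structure(NA_character_,
                     reason = paste0("non-monophyletic group ",
                                     GROUPS_INGROUP[!mono][1])))
  pairSplit <- function(g1, g2) {
    side <- c(gt[[g1]], gt[[g2]])
    if (length(side) >= length(tips) - 1) return(FALSE)
    .canonicalSplit(side, tips) %in% sp
  }
  hit <- c(I = pairSplit("K", "E") || pairSplit("R", "T"),
           II = pairSplit("K", "R") || pairSplit("E", "T"),
           III = pairSplit("K", "T") || pairSplit("E", "R"))
  if (sum(hit) != 1)
    return(structure(NA_character_, reason = "unresolved quartet"))
  names(hit)[hit]
}

#' Classify a five-group tree into its (T_G4, G_DF) relationship label
#'
#' Collapses each group to a single lineage and labels the topology by the
#' quartet hypothesis of the four ingroup groups (T_G4 = I: KE|RT, II: KR|ET,
#' III: KT|ER) and the group that diverged first when the tree is rooted by
#' the outgroup (G_DF = K, E, R, T, or X for the symmetric shape in which the
#' four groups split into two pairs). The 15 five-lineage topologies map
#' bijectively onto the 15 (T_G4, G_DF) combinations.
#'
#' @param tree a `phylo` containing outgroup taxa (used for rooting)
#' @param groups a group map; every tree taxon must be mapped and every group
#'   must be monophyletic
#' @return named character vector `c(tg4 = , gdf = )`
#' @examples
#' gm <- c(K = "K", E = "E", R = "R", T = "T", O = "O")
#' classifyRelationship(readTree("(O,(R,(T,(K,E))));"), gm)  # I, R
#' @export
classifyRelationship <- function(tree, groups) {
  groups <- asGroupMap(groups)
  tips <- tree$tip.label
  gt <- lapply(GROUPS_ALL, function(g) .groupTips(tips, groups, g))
  names(gt) <- GROUPS_ALL
  if (any(lengths(gt) == 0))
    stop(sprintf("missing group(s): %s",
                 paste(GROUPS_ALL[lengths(gt) == 0], collapse = ",")))
  sp <- treeSplits(tree)
  for (g in GROUPS_ALL) {
    s <- gt[[g]]
    mono <- length(s) == 1 || length(s) == length(tips) - 1 ||
      .canonicalSplit(s, tips) %in% sp
    if (!mono) stop(sprintf("group %s is not monophyletic", g))
  }
  tg4 <- quartetHypothesis(tree, groups)
  if (is.na(tg4)) stop(attr(tg4, "reason"))
  gdf <- "X"
  for (g in GROUPS_INGROUP) {
    side <- c(gt[[g]], gt[["O"]])
    if (length(side) <= length(tips) - 2 &&
        .canonicalSplit(side, tips) %in% sp) {
      gdf <- g
      break
    }
  }
  c(tg4 = tg4, gdf = gdf)
}

#' Count (near-)zero-length branches
#'
#' Branches whose length is `<=` the threshold are counted as zero; the
#' comparison is inclusive so that a printed sentinel value of 1e-6 counts.
#' The internal-branch subset is reported separately.
#'
#' @param tree a `phylo` with all branch lengths set
#' @param threshold zero threshold (default 1e-6)
#' @return named integer vector `c(total = , internal = )`
#' @export
countZeroLengthBranches <- function(tree, threshold = 1e-6) {
  if (is.null(tree$edge.length) || any(is.na(tree$edge.length)))
    stop("tree has unset branch lengths")
  ntip <- length(tree$tip.label)
  z <- tree$edge.length <= threshold
  c(total = sum(z), internal = sum(z & tree$edge[, 2] > ntip))
}
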