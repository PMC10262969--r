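test_that("Newick round-trips preserve topology and branch lengths", {
  tr <- readTree("(A:1,B:1,(C:1,D:1):0.5);")
  expect_equal(length(tr$tip.label), 4)
  expect_equal(treeSplits(tr), "A,B")  # canonical side holds the smallest label

  tr2 <- readTree(writeTree(tr))
  expect_equal(rfDistance(tr, tr2), 0)
  expect_equal(sort(tr$edge.length), sort(tr2$edge.length), tolerance = 1e-12)

  # optional lengths accepted
  tr3 <- readTree("((A,B),(C,D),(E,F));")
  expect_null(tr3$edge.length)

  expect_error(readTree("((A,B);"), "unclosed")
  expect_error(readTree("(A,B));"), "character")
  expect_error(readTree("(A,A,(B,C));"), "duplicate")
})

test_that("topology enumeration matches the double-factorial counts", {
  counts <- vapply(3:7, function(n)
    length(enumerateTopologies(letters[seq_len(n)])), 0L)
  expect_equal(counts, c(1L, 3L, 15L, 105L, 945L))
  expect_equal(length(enumerateTopologies(letters[1:4], rooted = TRUE)), 15L)
  expect_error(enumerateTopologies(letters[1:9]), "range")
  # deterministic order
  e1 <- enumerateTopologies(c("K", "E", "R", "T", "O"))
  e2 <- enumerateTopologies(c("O", "T", "R", "E", "K"))
  expect_equal(vapply(e1, function(t) paste(treeSplits(t), collapse = ";"), ""),
               vapply(e2, function(t) paste(treeSplits(t), collapse = ";"), ""))
  # independent count cross-check
  expect_equal(length(e1), length(phangorn::allTrees(5, rooted = FALSE)))
})

test_that("splits of the 15 five-leaf topologies form the expected design", {
  trees <- enumerateTopologies(c("K", "E", "R", "T", "O"))
  sp <- lapply(trees, treeSplits)
  expect_true(all(lengths(sp) == 2))        # n - 3
  tab <- table(unlist(sp))
  expect_equal(length(tab), 10L)            # choose(5,2) pairs
  expect_true(all(tab == 3))
  expect_equal(length(treeSplits(readTree("(A,B,C);"))), 0L)
})

test_that("RF distance is the split symmetric difference and a metric", {
  trees <- enumerateTopologies(c("K", "E", "R", "T", "O"))
  n <- length(trees)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- rfDistance(trees[[i]], trees[[j]])
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))
  expect_equal(max(D), 4)
  expect_true(all(D[upper.tri(D)] %in% c(2, 4)))
  # triangle inequality, exhaustively
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D[i, k], D[i, j] + D[j, k])
  # independent oracle
  Dp <- as.matrix(phangorn::RF.dist(structure(trees, class = "multiPhylo")))
  expect_equal(D, unname(Dp))
  expect_error(rfDistance(trees[[1]], readTree("(A,B,(C,D));")), "leaf sets")
})

test_that("relationship classification is a bijection with known anchors", {
  trees <- enumerateTopologies(c("K", "E", "R", "T", "O"))
  labs <- vapply(trees, function(t)
    paste(classifyRelationship(t, gm1), collapse = "_"), "")
  expect_equal(length(unique(labs)), 15L)
  expect_setequal(labs, as.vector(outer(c("I", "II", "III"),
                                        c("K", "E", "R", "T", "X"),
                                        paste, sep = "_")))
  expect_equal(unname(classifyRelationship(readTree("(O,(R,(T,(K,E))));"), gm1)),
               c("I", "R"))
  expect_equal(unname(classifyRelationship(readTree("(O,((K,E),(R,T)));"), gm1)),
               c("I", "X"))
  expect_equal(unname(classifyRelationship(readTree("(O,(R,(K,(E,T))));"), gm1)),
               c("II", "R"))
  # multi-member groups
  gmm <- c(k1 = "K", k2 = "K", e1 = "E", r1 = "R", t1 = "T", o1 = "O", o2 = "O")
  expect_equal(
    unname(classifyRelationship(
      readTree("((o1,o2),(r1,(t1,((k1,k2),e1))));"), gmm)),
    c("I", "R"))
  expect_error(
    classifyRelationship(readTree("((o1,k1),(r1,(t1,(k2,e1))));"), gmm),
    "monophyletic")
  expect_error(classifyRelationship(readTree("(O,(R,(T,K)));"), gm1),
               "missing group")
})

test_that("the published topology-index fixture stays consistent", {
  fx <- read.table(system.file("extdata", "t_index_labels.tsv",
                               package = "phyloconcord"),
                   header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(fx), 7)
  expect_true(all(fx$tg4 %in% c("I", "II", "III")))
  expect_true(all(fx$gdf %in% c("K", "E", "R", "T", "X")))
  key <- paste(fx$tg4, fx$gdf)
  expect_equal(anyDuplicated(key), 0L)
  # every fixture label is realized by exactly one enumerated topology
  trees <- enumerateTopologies(c("K", "E", "R", "T", "O"))
  labs <- vapply(trees, function(t)
    paste(classifyRelationship(t, gm1), collapse = " "), "")
  expect_true(all(key %in% labs))
})

test_that("zero-length branch accounting is inclusive at the threshold", {
  tr <- fixtureSpeciesTree()
  tr <- ape::unroot(tr)
  n <- length(tr$tip.label)
  tr$edge.length <- rep(1e-6, nrow(tr$edge))
  z <- countZeroLengthBranches(tr)
  expect_equal(unname(z["total"]), 2 * n - 3)
  expect_equal(unname(z["internal"]), n - 3)

  tr$edge.length <- rep(0.1, nrow(tr$edge))
  expect_equal(unname(countZeroLengthBranches(tr)), c(0L, 0L))

  i <- which(tr$edge[, 2] > n)[1]
  tr$edge.length[i] <- 1e-7
  expect_equal(unname(countZeroLengthBranches(tr)), c(1L, 1L))

  tr$edge.length[2] <- NA
  expect_error(countZeroLengthBranches(tr), "unset")
})

test_that("group maps are validated and read from two-column text", {
  expect_error(asGroupMap(c(a = "K", a = "E")), "unique")
  expect_error(asGroupMap(c(a = "Q")), "unknown group")
  path <- tempfile()
  writeLines(c("# taxa", "kiwi1 K", "ostrich\tO"), path)
  gm <- readGroupMap(path)
  expect_equal(gm, c(kiwi1 = "K", ostrich = "O"))
})
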