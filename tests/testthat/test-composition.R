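test_that("GC content excludes gaps and ambiguity from both terms", {
  a <- alignment(c(x = "GGCC", y = "AATT", z = "AC-N"))
  gc <- gcContent(a)
  expect_equal(unname(gc), c(1, 0, 0.5))
  allAmb <- alignment(c(w = "N-??"))
  expect_true(is.na(gcContent(allAmb)[["w"]]))
  # group means
  gm <- c(x = "K", y = "K", z = "T")
  g <- attr(gcContent(a, gm), "groups")
  expect_equal(unname(g[c("K", "T")]), c(0.5, 0.5))
})

test_that("RCV matches the printed formula and its algebraic properties", {
  gm <- c(a1 = "K", a2 = "K", b1 = "E", b2 = "E")
  # identical compositions: zero
  eq <- alignment(c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGT", b2 = "ACGT"))
  expect_equal(rcv(eq, gm)$rcv, 0)

  # 2 groups, 1 site, group1 all A, group2 all T -> (1+1)/(2*1) = 1
  h <- alignment(c(a1 = "A", a2 = "A", b1 = "T", b2 = "T"))
  r <- rcv(h, gm)
  expect_equal(r$rcv, 1)
  expect_equal(r$nGroups, 2)
  expect_equal(r$nSites, 1)

  # adding a constant clean column decreases RCV (t grows, numerator fixed)
  h2 <- alignment(c(a1 = "AG", a2 = "AG", b1 = "TG", b2 = "TG"))
  expect_lt(rcv(h2, gm)$rcv, rcv(h, gm)$rcv)

  # sites with any missing/ambiguous base are excluded
  h3 <- alignment(c(a1 = "A-", a2 = "AC", b1 = "TC", b2 = "TN"))
  expect_equal(rcv(h3, gm)$nSites, 1)
  expect_error(rcv(alignment(c(a1 = "-", a2 = "A", b1 = "T", b2 = "T")), gm),
               "no clean sites")

  # invariant to taxon order; pooled variant agrees for equal-length groups
  set.seed(3)
  aln <- simulateAlignment(fixtureSpeciesTree(),
                           configModel(synthPreset("intron")), 400, seed = 2)
  gmf <- fixtureGroupMap()
  r1 <- rcv(aln, gmf)
  r2 <- rcv(aln[sample(alnTaxa(aln)), ], gmf)
  expect_equal(r1$rcv, r2$rcv, tolerance = 1e-12)
})

test_that("RY-coding collapses transitions and respects position filters", {
  a <- alignment(c(x = "ACGT"))
  expect_equal(paste(alnMatrix(ryEncode(a))[1, ], collapse = ""), "RYRY")

  # sequences differing only by transitions become identical
  p <- alignment(c(u = "AGCTAC", v = "GACCGT"))
  enc <- alnMatrix(ryEncode(p))
  expect_identical(enc[1, ], enc[2, ])

  # transversion counting equivalence on random pairs
  set.seed(9)
  for (i in 1:10) {
    s1 <- sample(c("A", "C", "G", "T"), 60, TRUE)
    s2 <- sample(c("A", "C", "G", "T"), 60, TRUE)
    pur <- c("A", "G")
    tv <- sum((s1 %in% pur) != (s2 %in% pur))
    e <- alnMatrix(ryEncode(alignment(c(a = paste(s1, collapse = ""),
                                        b = paste(s2, collapse = "")))))
    expect_equal(sum(e[1, ] != e[2, ]), tv)
  }

  # preservation and recoding of special symbols
  sp <- alnMatrix(ryEncode(alignment(c(x = "N-?WK"))))
  expect_equal(unname(sp[1, ]), c("N", "-", "?", "N", "N"))

  # codon mode recodes columns 3 and 6 only
  cd <- alnMatrix(ryEncode(alignment(c(x = "ACGTAC")), positions = "codon3"))
  expect_equal(paste(cd[1, ], collapse = ""), "ACRTAY")
})

test_that("divergence from the ingroup ancestor is linear and well-ordered", {
  gm <- fixtureGroupMap()
  tr <- fixtureSpeciesTree()
  d <- divergenceFromNCA(tr, gm)
  expect_true(all(d$species >= 0))
  # far/near outgroup ratio is the configured 3.5, inside the observed range
  ratio <- d$outgroupPaths[["chicken"]] / d$outgroupPaths[["ostrich"]]
  expect_equal(ratio, 3.5, tolerance = 1e-9)
  expect_true(ratio >= 2.6 && ratio <= 4.6)
  # tinamous the most divergent group
  expect_equal(names(which.max(d$groupMeans)), "T")

  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 2
  d2 <- divergenceFromNCA(tr2, gm)
  expect_equal(d2$divergence, 2 * d$divergence, tolerance = 1e-12)
  expect_equal(d2$species, 2 * d$species, tolerance = 1e-12)

  # ultrametric toy: every group mean equals the common depth
  toy <- readTree("(O:0.3,((K:0.1,E:0.1):0.0,(R:0.1,T:0.1):0.0):0.2);")
  dt <- divergenceFromNCA(toy, gm1)
  expect_equal(unname(dt$groupMeans), rep(0.1, 4))
  expect_error(divergenceFromNCA(readTree("(O:1,(K:1,E:1):1);"), gm1),
               "N_CA undefined")
})

test_that("matched-pair symmetry tests reproduce hand-computed statistics", {
  # perfectly symmetric counts: all statistics 0, p = 1
  s <- paste(rep(c("A", "C", "C", "A", "G"), 4), collapse = "")
  t <- paste(rep(c("C", "A", "A", "C", "G"), 4), collapse = "")
  r0 <- matchedPairSymmetryTests(s, t)
  expect_equal(r0$stat[1], 0, tolerance = 1e-12)
  expect_equal(r0$p[1], 1)

  # n_AC = 8, n_CA = 2: Bowker = (8-2)^2/10 = 3.6, df = 1
  a <- strrep("AC", 5) # interleave below instead
  sA <- c(rep("A", 8), rep("C", 2))
  sB <- c(rep("C", 8), rep("A", 2))
  r1 <- matchedPairSymmetryTests(paste(sA, collapse = ""),
                                 paste(sB, collapse = ""))
  expect_equal(r1$stat[1], 3.6)
  expect_equal(r1$df[1], 1)
  expect_equal(r1$p[1], pchisq(3.6, 1, lower.tail = FALSE))
  expect_equal(r1$df[2], 3)

  # identical sequences: zero off-diagonals, trivially passing
  r2 <- matchedPairSymmetryTests("ACGTACGT", "ACGTACGT")
  expect_equal(r2$stat, rep(0, 3), tolerance = 1e-12)
  expect_equal(r2$df[1], 0)
  expect_equal(r2$p[1], 1)

  expect_error(matchedPairSymmetryTests("NN--", "ACGT"), "unambiguous")

  # Stuart quadratic form against an independent computation
  set.seed(12)
  x <- sample(c("A", "C", "G", "T"), 400, TRUE, prob = c(.4, .2, .2, .2))
  y <- sample(c("A", "C", "G", "T"), 400, TRUE, prob = c(.2, .4, .2, .2))
  rr <- matchedPairSymmetryTests(paste(x, collapse = ""),
                                 paste(y, collapse = ""))
  n <- table(factor(x, c("A", "C", "G", "T")), factor(y, c("A", "C", "G", "T")))
  d <- (rowSums(n) - colSums(n))[1:3]
  V <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    V[i, j] <- if (i == j) rowSums(n)[i] + colSums(n)[i] - 2 * n[i, i] else
      -(n[i, j] + n[j, i])
  expect_equal(rr$stat[2], as.numeric(t(d) %*% solve(V) %*% d),
               tolerance = 1e-8)
  expect_gte(rr$stat[1], rr$stat[2] - 1e-9)
})
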