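test_that("pruning log-likelihood matches limits and stays taxon-order invariant", {
  m <- buildModel(c(0.4, 0.2, 0.2, 0.2), rep(1, 6), alpha = 1, ncat = 1)
  star <- readTree("(a:1e-9,b:1e-9,c:1e-9,d:1e-9);")
  aln <- alignment(c(a = "A", b = "A", c = "A", d = "A"))
  expect_equal(logLikelihood(star, aln, m), log(0.4), tolerance = 1e-6)

  set.seed(31)
  tr <- randomTree(5)
  mm <- randomModel()
  a <- simulateAlignment(tr, mm, 300, seed = 2)
  l1 <- logLikelihood(tr, a, mm)
  perm <- sample(alnTaxa(a))
  expect_equal(logLikelihood(tr, a[perm, ], mm), l1, tolerance = 1e-9)
  # rerooting changes lnL by < 1e-9 (pulley principle)
  l2 <- logLikelihood(ape::root(tr, tr$tip.label[3], resolve.root = TRUE),
                      a, mm)
  expect_lt(abs(l1 - l2), 1e-9)
  expect_error(logLikelihood(tr, a[1:3, ], mm), "absent")
})

test_that("pruning equals the exhaustive-state oracle on small instances", {
  set.seed(77)
  for (i in 1:12) {
    tr <- randomTree(sample(4:5, 1))
    mm <- randomModel(ncat = 2, pInv = sample(c(0, 0.2), 1))
    a <- simulateAlignment(tr, mm, 10, seed = i)
    am <- alnMatrix(a)
    am[1, 1] <- "N"; am[2, 2] <- "R"; am[1, 3] <- "-"
    a <- alignment(am)
    expect_lt(abs(logLikelihood(tr, a, mm) - bruteForceLogLik(tr, a, mm)),
              1e-8)
  }
})

test_that("branch-length optimization recovers truth and never degrades lnL", {
  jc <- jcModel()
  # identical sequences: all lengths at the lower bound
  same <- alignment(c(a = strrep("ACGT", 25), b = strrep("ACGT", 25),
                      c = strrep("ACGT", 25)))
  tr3 <- readTree("(a:0.1,b:0.1,c:0.1);")
  fit0 <- optimizeBranchLengths(tr3, same, jc)
  expect_true(all(fit0$tree$edge.length <= 1e-8))

  # five-taxon consistency at large L: each length within 5% of truth
  m <- buildModel(c(0.3, 0.2, 0.3, 0.2), c(1, 4, 0.7, 1.1, 4.5, 1),
                  alpha = 0.9)
  tr <- enumerateTopologies(letters[1:5])[[6]]
  set.seed(4)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  a <- simulateAlignment(tr, m, 100000, seed = 13)
  fit <- optimizeBranchLengths(tr, a, m, init = 0.05)
  expect_true(fit$converged)
  expect_equal(logLikelihood(fit$tree, a, m), fit$loglik, tolerance = 1e-8)
  truthPO <- ape::reorder.phylo(tr, "postorder")   # fitted tree edge order
  expect_true(all(abs(fit$tree$edge.length / truthPO$edge.length - 1) < 0.05))
})

test_that("exhaustive ML search evaluates all candidates and flags ties", {
  m <- jcModel()
  a4 <- simulateAlignment({
    t0 <- enumerateTopologies(letters[1:4])[[2]]
    t0$edge.length <- rep(0.1, nrow(t0$edge))
    t0
  }, m, 500, seed = 21)
  fit <- exhaustiveMLSearch(a4, letters[1:4], m)
  expect_equal(length(fit$loglik), 3L)

  # zero-variation data: tie flag, first canonical topology
  same <- alignment(setNames(rep(strrep("A", 40), 4), letters[1:4]))
  tie <- exhaustiveMLSearch(same, letters[1:4], m)
  expect_true(tie$tie)
  expect_equal(tie$index, 1L)

  # generating topology recovered under the fixture relationship tree
  mt <- ape::drop.tip(paperModelTree("I", "R"), "chicken")
  mInt <- configModel(synthPreset("intron"))
  sim <- simulateAlignment(mt, mInt, 10000, seed = 6)
  best <- exhaustiveMLSearch(sim, alnTaxa(sim), mInt, relTol = 1e-6,
                             maxSweeps = 20, brentTol = 1e-5)
  expect_equal(rfDistance(best$tree, mt), 0)
})

test_that("posterior-mean site rates are calibrated and symmetry-respecting", {
  m <- buildModel(c(0.3, 0.2, 0.3, 0.2), c(1, 4, 0.7, 1.1, 4.5, 1),
                  alpha = 0.6)
  tr <- ape::drop.tip(paperModelTree("I", "R"), "chicken")
  a <- simulateAlignment(tr, m, 5000, seed = 17)
  r <- estimateSiteRates(a, tr, m)
  expect_equal(length(r), 5000L)
  expect_equal(mean(r), 1, tolerance = 0.02)
  cst <- apply(alnMatrix(a), 2, function(x) length(unique(x)) == 1)
  expect_lte(max(r[cst]), min(r[!cst]) + 1e-9)

  # JC symmetry: base-relabelled identical columns get equal rates
  jc <- jcModel(ncat = 4, alpha = 0.5)
  q <- readTree("((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
  cols <- alignment(c(a = "AC", b = "AC", c = "TG", d = "CA"))
  rr <- estimateSiteRates(cols, q, jc)
  expect_equal(rr[1], rr[2], tolerance = 1e-10)
})

test_that("Fitch scores match hand counts and the exhaustive labeling oracle", {
  q1 <- readTree("((K,E),(R,T));")
  q2 <- readTree("((K,R),(E,T));")
  col <- alignment(c(K = "A", E = "A", R = "T", T = "T"))
  expect_equal(fitchScore(q1, col), 1L)
  expect_equal(fitchScore(q2, col), 2L)
  expect_equal(fitchScore(q1, alignment(setNames(rep("ACGT", 4),
                                                 c("K", "E", "R", "T")))), 0L)
  set.seed(55)
  for (i in 1:4) {
    n <- sample(4:6, 1)
    tr <- randomTree(n)
    a <- simulateAlignment(tr, jcModel(), 20, seed = i + 60)
    am <- alnMatrix(a); am[1, 1] <- "N"; am[2, 5] <- "Y"
    a <- alignment(am)
    expect_equal(fitchScore(tr, a), bruteForceFitch(tr, a))
  }
})

test_that("parsimony-informative sites require two states twice each", {
  a <- alignment(c(s1 = "AAAA", s2 = "ACAA", s3 = "TGAN", s4 = "TTAN"))
  # col1 AATT informative; col2 ACGT singletons; col3 constant; col4 AANN
  expect_equal(parsimonyInformativeSites(a), 1L)
  expect_length(parsimonyInformativeSites(
    alignment(c(a = "A", b = "A", c = "A", d = "N"))), 0)
})
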