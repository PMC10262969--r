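test_that("stationary simulation is seed-deterministic and model-faithful", {
  tr <- readTree("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  m <- buildModel(c(0.3, 0.2, 0.3, 0.2), c(1, 4, 0.7, 1.1, 4.5, 1),
                  alpha = 0.5)
  a1 <- simulateAlignment(tr, m, 500, seed = 42)
  a2 <- simulateAlignment(tr, m, 500, seed = 42)
  expect_identical(alnMatrix(a1), alnMatrix(a2))
  expect_false(identical(alnMatrix(a1),
                         alnMatrix(simulateAlignment(tr, m, 500, seed = 43))))

  # zero branch lengths: all rows identical to the root draw
  tr0 <- tr
  tr0$edge.length[] <- 0
  a0 <- alnMatrix(simulateAlignment(tr0, m, 200, seed = 1))
  expect_true(all(apply(a0, 2, function(x) length(unique(x)) == 1)))

  # long single branch: leaf composition approaches equilibrium
  tl <- readTree("(x:10,y:10);")
  al <- alnMatrix(simulateAlignment(tl, m, 50000, seed = 5))
  fr <- table(factor(al[1, ], c("A", "C", "G", "T"))) / 50000
  expect_lt(max(abs(as.numeric(fr) - m@pi)), 0.01)
})

test_that("two-leaf JC mismatch matches the closed-form p-distance", {
  jc <- jcModel()
  t2 <- readTree("(x:0.05,y:0.05);")
  a <- alnMatrix(simulateAlignment(t2, jc, 100000, seed = 3))
  p <- mean(a[1, ] != a[2, ])
  pExp <- 0.75 * (1 - exp(-0.4 / 3))
  se <- sqrt(pExp * (1 - pExp) / 100000)
  expect_lt(abs(p - pExp), 3 * se)
})

test_that("nonstationary mode shifts composition on the targeted clade", {
  tr <- fixtureSpeciesTree()
  m <- buildModel(rep(0.25, 4), rep(1, 6), alpha = 1)
  # degenerate case: branch frequencies equal to pi reproduce stationary bytes
  s1 <- simulateAlignment(tr, m, 300, seed = 8)
  s2 <- simulateAlignment(tr, m, 300, seed = 8,
                          branchFreqs = list(Tclade = rep(0.25, 4)))
  expect_identical(alnMatrix(s1), alnMatrix(s2))

  # GC-rich tinamou stem elevates tinamou GC at long L
  shift <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)
  big <- tr
  big$edge.length <- big$edge.length * 3   # let the shift be realized
  aln <- simulateAlignment(big, m, 50000, seed = 9,
                           branchFreqs = list(Tclade = shift))
  gc <- gcContent(aln, fixtureGroupMap())
  g <- attr(gc, "groups")
  expect_gt(g[["T"]], max(g[c("K", "E", "R", "O")]) + 0.005)

  # RCV grows monotonically with the size of the tinamou GC shift
  rcvAt <- function(gcT) {
    a <- simulateAlignment(big, m, 20000, seed = 10,
                           branchFreqs = list(Tclade = c((1 - gcT) / 2,
                                                         gcT / 2, gcT / 2,
                                                         (1 - gcT) / 2)))
    rcv(a, fixtureGroupMap())$rcv
  }
  vals <- vapply(c(0.5, 0.62, 0.75), rcvAt, 0)  # shift magnitudes 0, .12, .25
  expect_true(all(diff(vals) > 0))

  expect_error(
    simulateAlignment(tr, m, 10, seed = 1,
                      branchFreqs = list(Tclade = c(0.3, 0.3, 0.3, 0.3))),
    "summing to 1")
  expect_error(
    simulateAlignment(tr, m, 10, seed = 1,
                      branchFreqs = list(nosuch = rep(0.25, 4))),
    "matches no tip")
})

test_that("codon-position multipliers create positionwise rate structure", {
  jc <- jcModel()
  t2 <- readTree("(x:0.3,y:0.3);")
  a <- alnMatrix(simulateAlignment(t2, jc, 30000, seed = 12,
                                   classMultipliers = c(0.2, 0.2, 2.6)))
  mis <- a[1, ] != a[2, ]
  pos <- (seq_along(mis) - 1) %% 3 + 1
  p12 <- mean(mis[pos != 3])
  p3 <- mean(mis[pos == 3])
  expect_gt(p3, 2 * p12)
})

test_that("MSC topology draws follow the two-parameter multinomial", {
  # star tree limit
  c0 <- simulateMSCQuartetTopologies(0, 300000, seed = 1)
  expect_equal(sum(c0), 300000)
  se <- sqrt(1 / 3 * 2 / 3 / 300000)
  expect_true(all(abs(c0 / 300000 - 1 / 3) < 3 * se))
  # strong-signal regime, closed form
  c2 <- simulateMSCQuartetTopologies(2, 300000, seed = 2)
  pc <- 1 - (2 / 3) * exp(-2)
  expect_lt(abs(c2[["concordant"]] / 300000 - pc),
            3 * sqrt(pc * (1 - pc) / 300000))
  # diploid convention flag
  c2b <- simulateMSCQuartetTopologies(2, 300000, seed = 2, divisor = 2)
  pcb <- 1 - (2 / 3) * exp(-1)
  expect_lt(abs(c2b[["concordant"]] / 300000 - pcb),
            3 * sqrt(pcb * (1 - pcb) / 300000))
})
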