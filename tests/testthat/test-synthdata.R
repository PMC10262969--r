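test_that("fixture trees satisfy the configured outgroup geometry", {
  gm <- fixtureGroupMap()
  tr <- fixtureSpeciesTree()
  expect_equal(length(tr$tip.label), 15)
  d <- divergenceFromNCA(tr, gm)
  expect_equal(d$outgroupPaths[["chicken"]] / d$outgroupPaths[["ostrich"]],
               3.5, tolerance = 1e-9)
  # symmetric-outgroup degenerate case
  d1 <- divergenceFromNCA(fixtureSpeciesTree(outgroupRatio = 1), gm)
  expect_equal(d1$outgroupPaths[["chicken"]], d1$outgroupPaths[["ostrich"]],
               tolerance = 1e-9)
  expect_error(fixtureSpeciesTree(outgroupRatio = 30), "sanity")

  # pruning an outgroup preserves every ingroup path from N_CA
  pruned <- ape::drop.tip(tr, "chicken")
  dp <- divergenceFromNCA(pruned, gm)
  expect_equal(dp$species, d$species, tolerance = 1e-12)

  # the three quartet variants classify as intended
  for (q in c("I", "II", "III")) {
    cl <- classifyRelationship(fixtureSpeciesTree(quartet = q), gm)
    expect_equal(unname(cl), c(q, "R"))
  }
})

test_that("representative model trees span all 15 relationships", {
  mts <- modelTreeSet()
  expect_equal(length(mts), 15)
  gm <- modelTreeGroupMap()
  labs <- vapply(mts, function(t)
    paste(classifyRelationship(t, gm), collapse = "_"), "")
  expect_equal(unname(labs), names(mts))
  d <- divergenceFromNCA(mts[["II_T"]], gm)
  expect_equal(d$outgroupPaths[["chicken"]] / d$outgroupPaths[["ostrich"]],
               3.5, tolerance = 1e-6)
})

test_that("class configs validate their fields", {
  expect_error(classConfig(nLoci = 0), "nLoci")
  expect_error(classConfig(missp = 0.7), "missp")
  expect_error(classConfig(alpha = -1), "alpha")
  expect_error(classConfig(gcTargets = c(Q = 0.5)), "gcTargets")
  expect_error(classConfig(tau = -0.1), "tau")
  cfg <- synthPreset("CNEE")
  expect_equal(cfg$lengthMean, 376.9)
  expect_equal(synthPreset("intron")$missp, 0.23)
  expect_equal(synthPreset("C3")$gcTargets[["T"]], 0.60)
})

test_that("generated datasets match their configuration in expectation", {
  cfg <- synthPreset("CNEE")
  ds <- generateDataset(cfg, seed = 11, nLoci = 600)
  lens <- vapply(ds$loci, function(l) nSites(locusAlignment(l)), 0L)
  expect_lt(abs(mean(lens) / 376.9 - 1), 0.05)
  expect_gte(min(lens), cfg$lengthMin)
  missp <- mean(vapply(ds$loci, function(l)
    mean(alnMatrix(locusAlignment(l)) == "-"), 0))
  expect_lt(abs(missp - cfg$missp), 0.015)

  # byte-identical regeneration
  ds2 <- generateDataset(cfg, seed = 11, nLoci = 600)
  expect_identical(lapply(ds$loci[1:20], function(l)
    alnMatrix(locusAlignment(l))),
    lapply(ds2$loci[1:20], function(l) alnMatrix(locusAlignment(l))))

  # no missing symbols when missp = 0
  clean <- generateDataset(classConfig(nLoci = 3, lengthMean = 200,
                                       lengthSd = 10, missp = 0), seed = 1)
  expect_false(any(vapply(clean$loci, function(l)
    any(!(alnMatrix(locusAlignment(l)) %in% c("A", "C", "G", "T"))), TRUE)))

  # coding preset drops one kiwi
  cds <- generateDataset(synthPreset("C3"), seed = 2, nLoci = 2)
  expect_false("kiwi4" %in% alnTaxa(locusAlignment(cds$loci[[1]])))
})

test_that("preset summary statistics respect the configured orderings", {
  # divergence ordering: CNEE and C12 low, UCE middle, intron and C3 high
  div <- vapply(c("CNEE", "C12", "UCE", "intron", "C3"), function(cl) {
    tr <- fixtureSpeciesTree()
    tr$edge.length <- tr$edge.length * synthPreset(cl)$divergence
    divergenceFromNCA(tr, fixtureGroupMap())$divergence
  }, 0)
  expect_lt(max(div[c("CNEE", "C12")]), div[["UCE"]])
  expect_lt(div[["UCE"]], min(div[c("intron", "C3")]))

  # tinamou GC highest on a GC-shifted coding preset
  ds <- generateDataset(synthPreset("C3"), seed = 5, nLoci = 40)
  big <- do.call(cbind, lapply(ds$loci, function(l)
    alnMatrix(locusAlignment(l))))
  g <- attr(gcContent(alignment(big), ds$groups), "groups")
  expect_equal(names(which.max(g[c("K", "E", "R", "T")])), "T")
  expect_gt(g[["E"]], max(g[c("K", "R")]))

  # per-group GC and RCV rise with the configured shift (rank correlation)
  shifts <- c(0.52, 0.58, 0.66)
  stats <- vapply(shifts, function(s) {
    d <- generateDataset(classConfig("g", nLoci = 6, lengthMean = 1500,
                                     lengthSd = 10, divergence = 1.6,
                                     gc = 0.52, gcTargets = c(T = s)),
                         seed = 7)
    big <- do.call(cbind, lapply(d$loci, function(l)
      alnMatrix(locusAlignment(l))))
    a <- alignment(big)
    c(gcT = attr(gcContent(a, d$groups), "groups")[["T"]],
      rcv = rcv(a, d$groups)$rcv)
  }, c(gcT = 0, rcv = 0))
  expect_true(all(diff(stats["gcT", ]) > 0))
  expect_true(all(diff(stats["rcv", ]) > 0))
})

test_that("coalescent-mode generation matches the concordance probabilities", {
  cfg <- classConfig("msc", nLoci = 2000, lengthMean = 60, lengthSd = 5,
                     lengthMin = 40, divergence = 0.15, tau = 0.105)
  ds <- generateDataset(cfg, seed = 3)
  topo <- vapply(ds$truth, function(t) t$topology, "")
  pI <- mean(topo == "I")
  expect_lt(abs(pI - 0.4), 3 * sqrt(0.4 * 0.6 / 2000))
  # truth records point at trees carrying the drawn quartet
  i2 <- which(topo == "II")[1]
  if (!is.na(i2))
    expect_equal(unname(classifyRelationship(ds$truth[[i2]]$tree,
                                             ds$groups)["tg4"]), "II")
})

test_that("locus sets round-trip through the on-disk layout", {
  ds <- generateDataset(classConfig(nLoci = 3, lengthMean = 120,
                                    lengthSd = 10, missp = 0.1), seed = 4)
  dir <- tempfile()
  man <- writeLocusSet(ds$loci, dir)
  expect_equal(nrow(man), 3)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- readAlignment(file.path(dir, paste0(man$id[1], ".fasta")))
  expect_identical(alnMatrix(back),
                   alnMatrix(locusAlignment(ds$loci[[1]])))
  tr <- readTree(paste(readLines(file.path(dir, paste0(man$id[1], ".nwk"))),
                       collapse = ""))
  expect_equal(rfDistance(tr, locusTree(ds$loci[[1]])), 0)
})
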