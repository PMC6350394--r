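test_that("K80 distance reproduces the closed form", {
  expect_equal(k80Distance("ACGT", "ACGT"), 0)
  # 100 comparable columns, 10 transitions, 5 transversions: P=0.1, Q=0.05
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10),  # A->G transitions
              strrep("C", 5),   # A->C transversions
              strrep("A", 85))
  expect_equal(k80Distance(a, b), 0.17018, tolerance = 1e-4)
  expect_equal(k80FromProportions(0.1, 0.05),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)
})

test_that("pairwise deletion drives the comparable-column set", {
  # overlap only at gap/ambiguity columns -> error
  expect_error(k80Distance("AC--", "--GT"), "no comparable")
  expect_error(k80Distance("NNNN", "ACGT"), "no comparable")
  # gapped columns are simply dropped
  expect_equal(k80Distance("A-CGT", "AACGT"), 0)
})

test_that("saturated pairs yield NA with a warning", {
  # all transversions: Q = 1 -> both logs undefined
  expect_warning(d <- k80Distance(strrep("A", 10), strrep("C", 10)),
                 "saturated")
  expect_true(is.na(d))
})

test_that("K80 agrees with ape::dist.dna under pairwise deletion", {
  al <- generateAlignedSet(alignmentSpec(nTaxa = 8, d = 0.06, length = 800,
                                         gapFraction = 0.05, seed = 13))
  ours <- k80DistanceMatrix(al)
  bin <- ape::as.DNAbin(strsplit(tolower(as.character(dnaSequence(al))), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("K80 reduces to P+Q at small divergence", {
  set.seed(3)
  for (i in 1:10) {
    P <- runif(1, 0, 0.012)
    Q <- runif(1, 0, 0.008)
    if (P + Q >= 0.02) next
    d <- k80FromProportions(P, Q)
    expect_lt(abs(d - (P + Q)) / max(P + Q, 1e-12), 0.05)
  }
})

test_that("dmean is the mean over all pairs and ignores sequence order", {
  al <- generateAlignedSet(alignmentSpec(nTaxa = 5, d = 0.03, length = 1200,
                                         seed = 5))
  d <- k80DistanceMatrix(al)
  res <- dmean(al)
  expect_equal(res$dmean, mean(d[upper.tri(d)]))
  expect_equal(res$nTaxa, 5L)
  expect_equal(res$nPairs, 10L)
  # reordering taxa leaves dmean unchanged
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(dmean(al[perm])$dmean, res$dmean)
  # identical sequences -> 0
  al0 <- AlignedSet(rep(randomDna(500, 8), 3), taxon = paste0("t", 1:3),
                    genus = rep("G", 3))
  expect_equal(dmean(al0)$dmean, 0)
  expect_error(dmean(al0[1:2]), "more than 2")
})

test_that("Faith PD traces the root-inclusive spanning subtree", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:4);")
  expect_equal(faithPd(tr, c("A", "B")), 4)            # 1 + 2 + stem 1
  expect_equal(faithPd(tr, c("A", "B", "C")), sum(tr$edge.length))
  expect_equal(faithPd(tr, "C"), 4)                    # root-to-leaf path
  expect_error(faithPd(tr, c("A", "Z")), "Z")
})

test_that("Faith PD matches picante and never decreases when taxa are added", {
  set.seed(11)
  tr <- ape::rtree(12)
  taxa <- sample(tr$tip.label)
  pdPrev <- 0
  for (k in 2:8) {
    pdK <- faithPd(tr, taxa[1:k])
    expect_gte(pdK, pdPrev - 1e-12)
    pdPrev <- pdK
  }
  comm <- matrix(as.integer(tr$tip.label %in% taxa[1:5]), nrow = 1,
                 dimnames = list("s1", tr$tip.label))
  ref <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(faithPd(tr, taxa[1:5]), ref, tolerance = 1e-10)
})

test_that("per-genus diversity table obeys the N > 2 rule", {
  sets <- lapply(1:3, function(i)
    generateAlignedSet(alignmentSpec(nTaxa = c(5, 4, 2)[i], d = 0.02,
                                     length = 600, seed = 20 + i,
                                     genus = c("Alpha", "Beta", "Tiny")[i])))
  seqs <- do.call(c, lapply(sets, function(s) dnaSequence(s)))
  al <- AlignedSet(seqs,
                   taxon = unlist(lapply(sets, taxonLabels)),
                   genus = unlist(lapply(sets, genusLabels)))
  expect_message(tab <- genusDiversity(al), "Tiny")
  expect_setequal(tab$genus, c("Alpha", "Beta"))
  expect_equal(tab$N, c(5L, 4L))
  expect_true(all(tab$dmean >= 0))
})

test_that("index correlations behave at the extremes", {
  per <- data.frame(N = 1:10, dmean = (1:10) / 100, pd = (1:10) / 2)
  r <- indexCorrelations(per)
  expect_equal(r["N", "dmean"], 1)
  expect_equal(r["N", "pd"], 1)

  set.seed(99)
  per2 <- data.frame(N = sample(100), dmean = sample(100) / 100,
                     pd = sample(100) / 2)
  r2 <- indexCorrelations(per2)
  expect_lt(abs(r2["N", "dmean"]), 0.3)

  perZ <- data.frame(N = rep(5, 5), dmean = (1:5) / 10, pd = (1:5) / 2)
  rZ <- indexCorrelations(perZ)
  expect_true(is.na(rZ["N", "dmean"]))
  expect_error(indexCorrelations(per[1:2, ]), "at least 3")
})

test_that("simulated alignments recover the target divergence", {
  dms <- vapply(1:6, function(seed) {
    al <- generateAlignedSet(alignmentSpec(nTaxa = 10, d = 0.04,
                                           length = 1500, seed = seed))
    dmean(al)$dmean
  }, numeric(1))
  se <- sd(dms) / sqrt(length(dms))
  expect_lt(abs(mean(dms) - 0.04), 3 * se + 1e-4)
})

test_that("the kappa -> Inf limit produces transition-only evolution", {
  al <- generateAlignedSet(alignmentSpec(nTaxa = 4, d = 0.1, kappa = 1e9,
                                         length = 2000, seed = 2))
  seqs <- as.character(dnaSequence(al))
  cc <- beGenomics:::pairColumnCounts(seqs[1], seqs[2])
  expect_equal(cc$tv, 0L)
  expect_gt(cc$ts, 0L)
})
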