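test_that("HEG selection matches ribosomal/elongation-factor products only", {
  products <- c("30S ribosomal protein S12",
                "50S ribosomal protein L7/L12",
                "elongation factor Tu",
                "elongation factor G",
                "translation elongation factor Ts",
                "DNA gyrase subunit A",
                "ribosomal protein methyltransferase",
                "16S ribosomal RNA pseudouridine synthase",
                "hypothetical protein")
  cds <- S4Vectors::DataFrame(
    start = seq_along(products) * 10L, end = seq_along(products) * 10L + 5L,
    strand = "+", product = products, codonStart = 1L,
    pseudo = rep(FALSE, length(products)),
    parts = IRanges::IRangesList(lapply(seq_along(products), function(i)
      IRanges::IRanges(i * 10L, i * 10L + 5L))))
  expect_equal(identifyHeg(cds), 1:5)
  # pseudo genes are never HEG
  cds$pseudo[1] <- TRUE
  expect_equal(identifyHeg(cds), 2:5)
})

test_that("codon families are counted with frame, stop and strand handled", {
  # manual codon walk: ATG TTC TTT AAC TAA -> Phe c=1 t=1, Asn c=1, stop dropped
  s <- "ATGTTCTTTAACTAA"
  rec <- makeRecord(s, list(list(parts = cbind(1, 15))))
  cc <- countCodonFamilies(rec, hegIdx = integer())
  expect_equal(unname(cc@genome["Phe", ]), c(1, 1))
  expect_equal(unname(cc@genome["Asn", ]), c(1, 0))
  expect_equal(unname(cc@genome["Tyr", ]), c(0, 0))
  expect_equal(unname(cc@genome["Ile", ]), c(0, 0))

  # reverse-strand CDS over the reverse complement gives identical counts
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  recM <- makeRecord(rc, list(list(parts = cbind(1, 15), strand = "-")))
  ccM <- countCodonFamilies(recM, hegIdx = integer())
  expect_equal(ccM@genome, cc@genome)

  # empty gene set -> all zero
  cc0 <- countCodonFamilies(makeRecord("ATGAAATAA"), hegIdx = integer())
  expect_true(all(cc0@genome == 0))
})

test_that("codon_start shifts the reading frame", {
  # with codon_start=2 the frame is TGT TCT TTA ACT: no family codons at all
  s <- "ATGTTCTTTAACTAA"
  rec <- makeRecord(s, list(list(parts = cbind(1, 15), codonStart = 2)))
  expect_warning(cc <- countCodonFamilies(rec, hegIdx = integer()),
                 "not divisible")
  expect_true(all(cc@genome == 0))
})

test_that("genes with internal stops are skipped with a warning", {
  s <- paste0("ATGTTC", "TAA", "AACTAA")  # internal TAA
  rec <- makeRecord(s, list(list(parts = cbind(1, 15))))
  expect_warning(cc <- countCodonFamilies(rec, hegIdx = integer()),
                 "internal stop")
  expect_true(all(cc@genome == 0))
  expect_equal(cc@skippedGenes, 1L)
})

test_that("ambiguous-base codons never enter the family counts", {
  s <- "ATGTTNTTCTAA"   # TTN ignored, TTC counted
  rec <- makeRecord(s, list(list(parts = cbind(1, 12))))
  cc <- countCodonFamilies(rec, hegIdx = integer())
  expect_equal(unname(cc@genome["Phe", ]), c(1, 0))
})

test_that("S is zero when HEG usage equals the background", {
  cc <- CodonFamilyCounts(heg = cbind(c(30, 40, 50, 60), c(30, 40, 50, 60)),
                          genome = cbind(c(300, 400, 500, 600),
                                         c(300, 400, 500, 600)))
  expect_equal(estimateS(cc)$s, 0, tolerance = 1e-5)
})

test_that("single-family S has the closed form log odds ratio", {
  cc <- CodonFamilyCounts(heg = cbind(c(73, 0, 0, 0), c(27, 0, 0, 0)),
                          genome = cbind(c(500, 0, 0, 0), c(500, 0, 0, 0)))
  fit <- estimateS(cc)
  expect_equal(fit$s, log(73 / 27), tolerance = 1e-4)
  expect_equal(fit$familiesUsed, "Phe")
  # grid-search oracle at 1e-4 resolution
  grid <- seq(-2, 2, by = 1e-4)
  ll <- vapply(grid, function(s) {
    p <- 0.5 * exp(s) / (0.5 + 0.5 * exp(s))
    73 * log(p) + 27 * log(1 - p)
  }, numeric(1))
  expect_equal(fit$s, grid[which.max(ll)], tolerance = 2e-4)
})

test_that("optimizer agrees with a grid-search oracle on random count tables", {
  set.seed(42)
  gridS <- seq(-10, 10, by = 1e-3)
  for (rep in 1:50) {
    genC <- rpois(4, 400) + 50
    genT <- rpois(4, 400) + 50
    hegN <- rpois(4, 120) + 20
    hegC <- rbinom(4, hegN, runif(1, 0.2, 0.8))
    cc <- CodonFamilyCounts(heg = cbind(hegC, hegN - hegC),
                            genome = cbind(genC + hegC, genT + hegN - hegC))
    fit <- estimateS(cc)
    cf <- (genC + hegC) / (genC + genT + hegN)
    k <- hegC; n <- hegN
    deg <- k == 0 | k == n
    k[deg] <- k[deg] + 0.5; n[deg] <- n[deg] + 1
    ll <- vapply(gridS, function(s) {
      p <- cf * exp(s) / (1 - cf + cf * exp(s))
      sum(k * log(p) + (n - k) * log(1 - p))
    }, numeric(1))
    expect_lt(abs(fit$s - gridS[which.max(ll)]), 1.5e-3)
  }
})

test_that("swapping C and T counts everywhere negates S", {
  set.seed(7)
  for (rep in 1:10) {
    heg <- matrix(rpois(8, 80) + 5, 4, 2)
    extra <- matrix(rpois(8, 500) + 5, 4, 2)
    cc <- CodonFamilyCounts(heg = heg, genome = heg + extra)
    ccSwap <- CodonFamilyCounts(heg = heg[, 2:1],
                                genome = (heg + extra)[, 2:1])
    expect_lt(abs(estimateS(ccSwap)$s + estimateS(cc)$s), 1e-4)
  }
})

test_that("raising HEG C-ending counts never lowers S", {
  base <- CodonFamilyCounts(heg = cbind(c(40, 45, 50, 55), c(60, 55, 50, 45)),
                            genome = cbind(rep(1000, 4), rep(1000, 4)))
  sPrev <- estimateS(base)$s
  for (add in c(5, 15, 30)) {
    cc <- CodonFamilyCounts(heg = cbind(c(40 + add, 45, 50, 55),
                                        c(60, 55, 50, 45)),
                            genome = cbind(rep(1000, 4), rep(1000, 4)))
    sNew <- estimateS(cc)$s
    expect_gte(sNew, sPrev - 1e-8)
    sPrev <- sNew
  }
})

test_that("degenerate HEG families stay finite via the 0.5 pseudocount", {
  cc <- CodonFamilyCounts(heg = cbind(c(50, 0, 0, 0), c(0, 0, 0, 0)),
                          genome = cbind(c(500, 0, 0, 0), c(500, 0, 0, 0)))
  fit <- estimateS(cc)
  expect_true(is.finite(fit$s))
  expect_equal(fit$s, log((50.5 / 0.5)), tolerance = 1e-3)
})

test_that("an empty HEG set yields a missing S with a warning", {
  cc <- CodonFamilyCounts(heg = matrix(0, 4, 2),
                          genome = cbind(rep(100, 4), rep(100, 4)))
  expect_warning(fit <- estimateS(cc), "missing")
  expect_true(is.na(fit$s))

  rec <- makeRecord("ATGAAATTTTAA", list(list(parts = cbind(1, 12))))
  expect_warning(sv <- sValue(rec), "no highly expressed")
  expect_true(is.na(sv$s))
  expect_equal(sv$hegGeneCount, 0L)
})

test_that("families with zero genome usage are dropped", {
  cc <- CodonFamilyCounts(heg = cbind(c(60, 10, 0, 0), c(40, 10, 0, 0)),
                          genome = cbind(c(500, 100, 0, 0), c(500, 100, 0, 0)))
  fit <- estimateS(cc)
  expect_setequal(fit$familiesUsed, c("Phe", "Tyr"))
})
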