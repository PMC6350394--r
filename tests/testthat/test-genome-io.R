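test_that("a minimal single-CDS record parses with its identity intact", {
  seqTxt <- paste(rep("ATGAAATTTGGG", 5), collapse = "")  # 60 bp
  path <- writeGenBankText(genbankEntry("TST_0001", "Testus exampli", seqTxt,
                                        cdsFeature("1..60", "demo protein")))
  recs <- readGenBank(path)
  expect_length(recs, 1)
  rec <- recs[[1]]
  expect_s4_class(rec, "ChromosomeRecord")
  expect_equal(accession(rec), "TST_0001")
  expect_equal(genus(rec), "Testus")
  expect_equal(length(rec), 60L)
  expect_equal(as.character(dnaSequence(rec)), toupper(seqTxt))
  cds <- cdsTable(rec)
  expect_equal(nrow(cds), 1L)
  expect_equal(cds$start, 1)
  expect_equal(cds$end, 60)
  expect_equal(cds$strand, "+")
  expect_equal(cds$product, "demo protein")
  expect_equal(skippedFeatures(rec), 0L)
})

test_that("complement(join(...)) extracts the reverse complement of the parts", {
  seqTxt <- randomDna(60, seed = 7)
  path <- writeGenBankText(genbankEntry("TST_0002", "Testus exampli", seqTxt,
                                        cdsFeature("complement(join(10..21,30..41))")))
  rec <- readGenBank(path)[[1]]
  cs <- codingSequences(rec)
  expect_equal(Biostrings::width(cs), 24L)
  # oracle: manual reverse complement of the concatenated parts
  joined <- paste0(substr(seqTxt, 10, 21), substr(seqTxt, 30, 41))
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(joined)))
  expect_equal(as.character(cs[[1]]), expected)
  expect_equal(cdsTable(rec)$strand, "-")
})

test_that("pseudo and codon_start qualifiers pass through", {
  seqTxt <- randomDna(90, seed = 3)
  feats <- c(cdsFeature("1..30", "broken gene", pseudo = TRUE),
             cdsFeature("31..90", "shifted gene", codonStart = 2))
  path <- writeGenBankText(genbankEntry("TST_0003", "Testus exampli", seqTxt, feats))
  rec <- readGenBank(path)[[1]]
  cds <- cdsTable(rec)
  expect_equal(cds$pseudo, c(TRUE, FALSE))
  expect_equal(cds$codonStart, c(1L, 2L))
})

test_that("a record without an ORIGIN block is a hard error naming the LOCUS", {
  lines <- c("LOCUS       NOSEQ_1          60 bp    DNA     linear   BCT 01-JAN-2000",
             "DEFINITION  Testus exampli.", "//")
  path <- writeGenBankText(lines)
  expect_error(readGenBank(path), "NOSEQ_1")
})

test_that("malformed locations are skipped with a warning and counted", {
  seqTxt <- randomDna(60, seed = 5)
  feats <- c(cdsFeature("40..20", "origin spanning"),  # start > end
             cdsFeature("1..30", "good gene"))
  path <- writeGenBankText(genbankEntry("TST_0004", "Testus exampli", seqTxt, feats))
  expect_warning(recs <- readGenBank(path), "malformed location")
  rec <- recs[[1]]
  expect_equal(nrow(cdsTable(rec)), 1L)
  expect_equal(skippedFeatures(rec), 1L)
})

test_that("records round-trip through writeGenBank/readGenBank", {
  spec <- genomeSpec(length = 30000, nHeg = 3, nOther = 5, seed = 11,
                     codonsPerFamilyPerGene = 6, fillerCodonsPerGene = 40)
  rec <- generateChromosome(spec)
  path <- tempfile(fileext = ".gbk")
  writeGenBank(rec, path)
  expect_no_warning(back <- readGenBank(path)[[1]])
  expect_equal(as.character(dnaSequence(back)), as.character(dnaSequence(rec)))
  expect_equal(topology(back), "circular")
  a <- cdsTable(rec); b <- cdsTable(back)
  expect_equal(b$start, as.numeric(a$start))
  expect_equal(b$end, as.numeric(a$end))
  expect_equal(b$strand, a$strand)
  expect_equal(b$product, a$product)
  expect_equal(b$codonStart, a$codonStart)
  expect_equal(b$pseudo, a$pseudo)
})

test_that("multi-LOCUS files yield one record per LOCUS", {
  lines <- c(genbankEntry("TST_A", "Testus exampli", randomDna(100, 1)),
             genbankEntry("TST_B", "Testus exampli", randomDna(80, 2)))
  recs <- readGenBank(writeGenBankText(lines))
  expect_length(recs, 2)
  expect_equal(vapply(recs, accession, character(1)), c("TST_A", "TST_B"))
})

test_that("largest-replicon selection obeys size, tie-break and plasmid rules", {
  big <- makeRecord(randomDna(3000, 1), accession = "NC_0003")
  small <- makeRecord(randomDna(1200, 2), accession = "NC_0004")
  expect_equal(accession(selectLargestReplicon(list(small, big))), "NC_0003")
  expect_equal(accession(selectLargestReplicon(list(big))), "NC_0003")

  # equal lengths: lexicographically smallest accession wins
  t1 <- makeRecord(randomDna(500, 3), accession = "NC_0002")
  t2 <- makeRecord(randomDna(500, 4), accession = "NC_0001")
  expect_equal(accession(selectLargestReplicon(list(t1, t2))), "NC_0001")

  # order independence + idempotence
  expect_equal(accession(selectLargestReplicon(list(t2, t1))), "NC_0001")
  expect_equal(accession(selectLargestReplicon(list(
    selectLargestReplicon(list(t1, t2))))), "NC_0001")

  # a larger plasmid never outranks a chromosome, unless all are plasmids
  plas <- makeRecord(randomDna(5000, 5), accession = "NC_0005")
  plas@isPlasmid <- TRUE
  expect_equal(accession(selectLargestReplicon(list(plas, big))), "NC_0003")
  p2 <- makeRecord(randomDna(800, 6), accession = "NC_0006")
  p2@isPlasmid <- TRUE
  expect_equal(accession(selectLargestReplicon(list(p2, plas))), "NC_0005")

  expect_error(selectLargestReplicon(list()), "empty")
})

test_that("group assignment respects the publication-count threshold", {
  recs <- list(makeRecord(randomDna(100, 1), accession = "A1",
                          organismName = "Commona alpha"),
               makeRecord(randomDna(100, 2), accession = "A2",
                          organismName = "Rara beta"),
               makeRecord(randomDna(100, 3), accession = "A3",
                          organismName = "Unknowna gamma"))
  grouping <- data.frame(genus = c("Commona", "Rara"),
                         publication_count = c(6L, 5L))
  expect_warning(tab <- assignGroups(recs, grouping, threshold = 6L),
                 "Unknowna")
  expect_equal(tab$group, c("Common BE", "Other", "Other"))
  # boundary: count 5 at threshold 6 is Other; threshold 1 makes count 1 BE
  grouping2 <- data.frame(genus = "Commona", publication_count = 1L)
  tab2 <- assignGroups(recs[1], grouping2, threshold = 1L)
  expect_equal(tab2$group, "Common BE")
  # partition property
  expect_equal(sum(tab$group == "Common BE") + sum(tab$group == "Other"),
               length(recs))
})

test_that("grouping tables reject duplicate genera and parse env flags", {
  path <- writeGroupingTsv(data.frame(
    genus = c("Commona", "Rara"), publication_count = c(7L, 2L),
    group = c("", ""), env_flags = c("Human;Soil", "")))
  g <- readGroupingTable(path)
  expect_equal(g$env_flags[[1]], c("Human", "Soil"))
  expect_equal(g$env_flags[[2]], character())
  bad <- writeGroupingTsv(data.frame(genus = c("X", "X"),
                                     publication_count = c(1L, 2L)))
  expect_error(readGroupingTable(bad), "more than once")
})
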