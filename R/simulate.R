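#' @include ChromosomeRecord-methods.R
#' @include diversity.R
NULL

#' Specification for a synthetic chromosome
#'
#' Parameters of the ground-truth genome model used to validate the whole
#' pipeline. A circular chromosome gets strand-asymmetric base composition of
#' tunable strength `k`: on the leading-strand arc (replication origin to
#' terminus) `P(G) = gc/2 (1+k)` and `P(C) = gc/2 (1-k)`, reversed on the
#' lagging arc (leading strands of bacterial chromosomes are G-rich). Genes
#' are embedded non-overlapping on alternating strands; each consists of a
#' start codon, `codonsPerFamilyPerGene` codons of each two-codon family
#' (Phe/Tyr/Ile/Asn) whose C-ending probability follows the selection model
#' `p_f = c e^S / (1 - c + c e^S)` with `S = sTrue` for HEG genes and 0
#' otherwise, `fillerCodonsPerGene` filler codons, and a stop codon. Filler
#' codons exclude stop codons and the eight family codons (so family counts
#' stay under exact ground-truth control), and their base composition is
#' solved so the expected genome-wide GC matches `gc` despite the AT-rich
#' family codons.
#'
#' @param length chromosome length in bp.
#' @param gc target genome GC fraction in (0, 1).
#' @param k skew strength in [0, 1].
#' @param oriPos,terPos fractional positions of origin and terminus
#'   (defaults 0.0 and 0.5; must differ).
#' @param nHeg,nOther numbers of highly-expressed and background genes.
#' @param sTrue ground-truth selection strength S of the HEG genes.
#' @param codonsPerFamilyPerGene two-codon-family codons per family per gene.
#' @param fillerCodonsPerGene gc-matched filler codons per gene.
#' @param cBackground background C-ending proportion of the families
#'   (default 0.5).
#' @param seed RNG seed (integer); the generator is deterministic given the
#'   spec.
#' @param accession,organismName identity of the emitted record.
#' @return a validated list of class `GenomeSpec`.
#' @seealso [generateChromosome()]
#' @export
genomeSpec <- function(length = 2e6, gc = 0.5, k = 0.2,
                       oriPos = 0.0, terPos = 0.5,
                       nHeg = 20L, nOther = 980L, sTrue = 1.0,
                       codonsPerFamilyPerGene = 12L,
                       fillerCodonsPerGene = 270L,
                       cBackground = 0.5, seed = 1L,
                       accession = "SYN_000001",
                       organismName = "Synthetica exempli") {
  stopifnot(gc > 0, gc < 1, k >= 0, k <= 1, length >= 1,
            oriPos >= 0, oriPos < 1, terPos >= 0, terPos < 1,
            nHeg >= 0, nOther >= 0, sTrue > -10, sTrue < 10,
            cBackground > 0, cBackground < 1)
  if (oriPos == terPos) stop("terPos must differ from oriPos")
  spec <- list(length = as.integer(length), gc = gc, k = k,
               oriPos = oriPos, terPos = terPos,
               nHeg = as.integer(nHeg), nOther = as.integer(nOther),
               sTrue = sTrue,
               codonsPerFamilyPerGene = as.integer(codonsPerFamilyPerGene),
               fillerCodonsPerGene = as.integer(fillerCodonsPerGene),
               cBackground = cBackground, seed = as.integer(seed),
               accession = accession, organismName = organismName)
  class(spec) <- "GenomeSpec"
  spec
}

## Expected GC bases of one filler codon when each base is drawn iid with
## GC fraction g. Stop codons and the eight two-codon-family codons are
## rejection-sampled away (the latter so that family counts stay under the
## generator's exact control), and the conditional expectation accounts for
## both exclusions.
fillerCodonGc <- function(g) {
  t <- (1 - g) / 2; c <- g / 2
  pStop <- t^3 + 2 * t^2 * c            # TAA, TAG, TGA
  gcStop <- 2 * t^2 * c                 # GC bases carried by stops
  pFam <- 4 * t^2 * (c + t)             # TT/TA/AT/AA prefix, C or T third base
  gcFam <- 4 * t^2 * c                  # only the C-ending four carry 1 GC
  (3 * g - gcStop - gcFam) / (1 - pStop - pFam)
}

## Base GC of the filler codons such that the expected GC of a whole gene
## (start + family codons + filler + stop) equals the genome target.
solveFillerGc <- function(gc, nFamilyCodons, pC, nFill) {
  geneBases <- 3 * (2 + nFamilyCodons + nFill)
  target <- gc * geneBases - 1 - nFamilyCodons * pC   # ATG has 1 GC, TAA 0
  f <- function(g) nFill * fillerCodonGc(g) - target
  if (f(0.005) > 0) return(0.005)
  if (f(0.995) < 0) {
    warning("filler GC compensation clamped; genome GC will undershoot target")
    return(0.995)
  }
  stats::uniroot(f, c(0.005, 0.995), tol = 1e-9)$root
}

selectionP <- function(cB, s) cB * exp(s) / (1 - cB + cB * exp(s))

## nGenes x nCodons character matrix of family codons drawn under the
## selection model with per-gene C-ending probability p.
drawFamilyCodons <- function(nGenes, cpf, p) {
  prefixes <- c(Phe = "TT", Tyr = "TA", Ile = "AT", Asn = "AA")
  cols <- lapply(prefixes, function(pre) {
    isC <- matrix(stats::runif(nGenes * cpf) < p, nGenes, cpf)
    matrix(paste0(pre, ifelse(isC, "C", "T")), nGenes, cpf)
  })
  do.call(cbind, cols)
}

drawFillerCodons <- function(nCodons, g) {
  if (nCodons == 0L) return(character())
  letters4 <- c("A", "C", "G", "T")
  probs <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
  draw <- function(n) paste0(sample(letters4, n, TRUE, probs),
                             sample(letters4, n, TRUE, probs),
                             sample(letters4, n, TRUE, probs))
  excluded <- c(STOP_CODONS, unlist(lapply(FAMILIES, unname), use.names = FALSE))
  cod <- draw(nCodons)
  repeat {
    bad <- which(cod %in% excluded)
    if (!length(bad)) break
    cod[bad] <- draw(length(bad))
  }
  cod
}

revCompChars <- function(chars) rev(chartr("ACGT", "TGCA", chars))

#' Generate a synthetic annotated chromosome
#'
#' Draws a chromosome under the model described in [genomeSpec()]: a
#' strand-asymmetric intergenic backbone plus annotated CDSs (HEG genes
#' labeled "50S ribosomal protein L&lt;i&gt;", background genes
#' "hypothetical protein") with two-codon-family usage generated from the
#' known selection strength. Deterministic given the spec (including its
#' seed).
#'
#' @param spec a [genomeSpec()].
#' @param path optional file path; when given, the record is also written as
#'   a GenBank flat file via [writeGenBank()].
#' @return a [ChromosomeRecord-class].
#' @examples
#' rec <- generateChromosome(genomeSpec(length = 50000, nHeg = 2, nOther = 5,
#'                                      seed = 42))
#' gcsi(rec, nWindows = 64)$gcsi
#' @export
generateChromosome <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "GenomeSpec"))
  set.seed(spec$seed)
  L <- spec$length
  nGenes <- spec$nHeg + spec$nOther
  cpf <- spec$codonsPerFamilyPerGene
  nFill <- spec$fillerCodonsPerGene
  geneLen <- 3L * (2L + 4L * cpf + nFill)
  minLen <- nGenes * (geneLen + 1L) + 1L
  if (nGenes > 0L && L < minLen)
    stop("genes do not fit: length must be at least ", minLen, " bp for ",
         nGenes, " genes of ", geneLen, " bp")

  ## intergenic backbone with strand-asymmetric composition
  frac <- (seq_len(L) - 1) / L
  leading <- if (spec$oriPos < spec$terPos)
    frac >= spec$oriPos & frac < spec$terPos
  else
    frac >= spec$oriPos | frac < spec$terPos
  gc <- spec$gc; k <- spec$k
  letters4 <- c("A", "C", "G", "T")
  pLead <- c((1 - gc) / 2, gc / 2 * (1 - k), gc / 2 * (1 + k), (1 - gc) / 2)
  pLag <- pLead[c(1, 3, 2, 4)]
  chars <- character(L)
  chars[leading] <- sample(letters4, sum(leading), TRUE, pLead)
  chars[!leading] <- sample(letters4, sum(!leading), TRUE, pLag)

  cdsTab <- emptyCdsTable()
  if (nGenes > 0L) {
    hegSlots <- if (spec$nHeg > 0L) sort(sample(nGenes, spec$nHeg)) else integer()
    isHeg <- seq_len(nGenes) %in% hegSlots
    pGene <- ifelse(isHeg, selectionP(spec$cBackground, spec$sTrue),
                    spec$cBackground)

    fam <- drawFamilyCodons(nGenes, cpf, pGene)
    fill <- matrix("", nGenes, max(nFill, 1L))[, seq_len(nFill), drop = FALSE]
    if (nFill > 0L) {
      gHeg <- solveFillerGc(gc, 4 * cpf,
                            selectionP(spec$cBackground, spec$sTrue), nFill)
      gOther <- solveFillerGc(gc, 4 * cpf, spec$cBackground, nFill)
      if (any(isHeg))
        fill[isHeg, ] <- drawFillerCodons(sum(isHeg) * nFill, gHeg)
      if (any(!isHeg))
        fill[!isHeg, ] <- drawFillerCodons(sum(!isHeg) * nFill, gOther)
    }
    codons <- cbind("ATG", fam, fill, "TAA")
    genes <- apply(codons, 1L, paste0, collapse = "")

    gap <- (L - nGenes * geneLen) %/% (nGenes + 1L)
    starts <- gap + (seq_len(nGenes) - 1L) * (geneLen + gap) + 1L
    ends <- starts + geneLen - 1L
    strands <- rep(c("+", "-"), length.out = nGenes)
    prodNo <- cumsum(isHeg)
    products <- ifelse(isHeg, sprintf("50S ribosomal protein L%d", prodNo),
                       "hypothetical protein")
    for (i in seq_len(nGenes)) {
      gchars <- strsplit(genes[i], "")[[1]]
      if (strands[i] == "-") gchars <- revCompChars(gchars)
      chars[starts[i]:ends[i]] <- gchars
    }
    cdsTab <- S4Vectors::DataFrame(
      start = starts, end = ends, strand = strands, product = products,
      codonStart = rep(1L, nGenes), pseudo = rep(FALSE, nGenes),
      parts = IRanges::IRangesList(lapply(seq_len(nGenes), function(i)
        IRanges::IRanges(starts[i], ends[i])))
    )
  }

  rec <- ChromosomeRecord(
    accession = spec$accession, organism = spec$organismName,
    sequence = paste(chars, collapse = ""), topology = "circular",
    cds = cdsTab)
  if (!is.null(path)) writeGenBank(rec, path)
  rec
}

#' Specification for a synthetic aligned 16S-like set
#'
#' @param nTaxa number of taxa.
#' @param d target expected pairwise divergence (substitutions/site) under
#'   K80: every taxon evolves independently from a common ancestor along a
#'   branch of length `d/2`.
#' @param kappa transition/transversion rate ratio (default 2).
#' @param length alignment length in columns (default 1500, a full-length
#'   16S gene).
#' @param gapFraction per-sequence fraction of columns replaced by gaps
#'   (default 0: no gaps).
#' @param genus genus label for all taxa.
#' @param seed RNG seed.
#' @return a validated list of class `AlignmentSpec`.
#' @export
alignmentSpec <- function(nTaxa = 10L, d = 0.04, kappa = 2, length = 1500L,
                          gapFraction = 0, genus = "Synthetica", seed = 1L) {
  stopifnot(nTaxa >= 1, d >= 0, kappa > 0, length > 0,
            gapFraction >= 0, gapFraction < 1)
  spec <- list(nTaxa = as.integer(nTaxa), d = d, kappa = kappa,
               length = as.integer(length), gapFraction = gapFraction,
               genus = genus, seed = as.integer(seed))
  class(spec) <- "AlignmentSpec"
  spec
}

## K80 substitution probabilities for one branch of length b (expected
## substitutions/site) with ts/tv ratio kappa.
k80BranchProbs <- function(b, kappa) {
  e1 <- exp(-4 * b / (kappa + 2))
  e2 <- exp(-2 * b * (kappa + 1) / (kappa + 2))
  pTs <- 0.25 + 0.25 * e1 - 0.5 * e2
  pTvEach <- 0.25 * (1 - e1)
  c(same = 1 - pTs - 2 * pTvEach, ts = pTs, tvEach = pTvEach)
}

#' Generate an aligned set evolved under K80
#'
#' Draws a uniform-random ancestor sequence and evolves each taxon
#' independently under the K80 model along a branch of length `d/2`, so the
#' expected pairwise divergence between any two taxa is `d`. Deterministic
#' given the spec.
#'
#' @param spec an [alignmentSpec()].
#' @return an [AlignedSet-class].
#' @export
generateAlignedSet <- function(spec) {
  stopifnot(inherits(spec, "AlignmentSpec"))
  set.seed(spec$seed)
  if (exp(-2 * spec$d * (spec$kappa + 1) / (spec$kappa + 2)) < 0.1)
    warning("target divergence d = ", spec$d,
            " risks saturated distance estimates at this length")
  len <- spec$length
  ## base order A, G, C, T: transitions are 1<->2 and 3<->4
  letters4 <- c("A", "G", "C", "T")
  tsMap <- c(2L, 1L, 4L, 3L)
  tv1Map <- c(3L, 3L, 1L, 1L)
  tv2Map <- c(4L, 4L, 2L, 2L)
  pr <- k80BranchProbs(spec$d / 2, spec$kappa)
  anc <- sample.int(4L, len, replace = TRUE)
  seqs <- character(spec$nTaxa)
  for (i in seq_len(spec$nTaxa)) {
    u <- stats::runif(len)
    idx <- anc
    sel <- u >= pr["same"] & u < pr["same"] + pr["ts"]
    idx[sel] <- tsMap[anc[sel]]
    sel2 <- u >= pr["same"] + pr["ts"] & u < pr["same"] + pr["ts"] + pr["tvEach"]
    idx[sel2] <- tv1Map[anc[sel2]]
    sel3 <- u >= pr["same"] + pr["ts"] + pr["tvEach"]
    idx[sel3] <- tv2Map[anc[sel3]]
    ch <- letters4[idx]
    if (spec$gapFraction > 0) {
      nGap <- round(spec$gapFraction * len)
      if (nGap > 0) ch[sample.int(len, nGap)] <- "-"
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  taxon <- sprintf("%s_t%03d", spec$genus, seq_len(spec$nTaxa))
  AlignedSet(Biostrings::DNAStringSet(seqs), taxon = taxon,
             genus = rep(spec$genus, spec$nTaxa))
}

#' Write a synthetic genome cohort with its ground truth
#'
#' Generates one GenBank flat file per spec plus a `ground_truth.tsv`
#' (`accession genus k s_true gc seed`) into `dir`, ready for ingestion by
#' [readGenBank()] / [runAll()].
#'
#' @param specs list of [genomeSpec()] objects.
#' @param dir output directory (created if absent).
#' @return invisible data.frame of the ground truth.
#' @export
writeSyntheticCohort <- function(specs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(specs, function(sp) {
    rec <- generateChromosome(sp, path = file.path(dir, paste0(sp$accession, ".gbk")))
    data.frame(accession = sp$accession, genus = genus(rec), k = sp$k,
               s_true = sp$sTrue, gc = sp$gc, seed = sp$seed,
               stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  utils::write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}
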