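#' @include AllClasses.R
NULL

#' Construct an AlignedSet
#'
#' @param sequences a [Biostrings::DNAStringSet] or character vector of
#'   equal-length gapped sequences.
#' @param taxon per-sequence identifiers (default: names of `sequences`).
#' @param genus per-sequence genus labels; default: first token of each
#'   taxon label.
#' @return an [AlignedSet-class].
#' @export
AlignedSet <- function(sequences, taxon = NULL, genus = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(taxon)) taxon <- names(sequences)
  if (is.null(taxon)) taxon <- paste0("taxon", seq_along(sequences))
  if (is.null(genus))
    genus <- vapply(strsplit(taxon, "[ _]"), `[[`, character(1), 1)
  new("AlignedSet", sequences = sequences, taxon = as.character(taxon),
      genus = as.character(genus))
}

#' @rdname accessors
#' @export
setMethod("taxonLabels", "AlignedSet", function(x) x@taxon)
#' @rdname accessors
#' @export
setMethod("genusLabels", "AlignedSet", function(x) x@genus)
#' @rdname accessors
#' @export
setMethod("dnaSequence", "AlignedSet", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("length", "AlignedSet", function(x) length(x@sequences))

setMethod("show", "AlignedSet", function(object) {
  cat(sprintf("AlignedSet: %d sequences, aligned length %d, %d genera\n",
              length(object@sequences),
              Biostrings::width(object@sequences)[1],
              length(unique(object@genus))))
})

#' Subset an AlignedSet
#' @param x an [AlignedSet-class].
#' @param i indices or logical vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "AlignedSet", function(x, i, j, ..., drop = TRUE) {
  new("AlignedSet", sequences = x@sequences[i], taxon = x@taxon[i],
      genus = x@genus[i])
})

#' Read an aligned 16S multi-FASTA with genus labels
#'
#' Reads an aligned multi-FASTA whose headers carry the taxon identifier and
#' (LTP-style) the organism name; the genus is the first word of the
#' organism field (second header token when present, else parsed from the
#' identifier).
#'
#' @param path FASTA path.
#' @return an [AlignedSet-class].
#' @export
readAlignedFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  taxon <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1)
  genus <- vapply(strsplit(headers, "\\s+"), function(tok)
    if (length(tok) >= 2) tok[2] else strsplit(tok[1], "_")[[1]][1],
    character(1))
  names(seqs) <- taxon
  AlignedSet(seqs, taxon = taxon, genus = genus)
}

## Column pair classes for two aligned sequences, pairwise deletion:
## only columns where both sequences hold unambiguous A/C/G/T are compared.
## Purines A/G, pyrimidines C/T.
pairColumnCounts <- function(a, b) {
  av <- strsplit(toupper(as.character(a)), "")[[1]]
  bv <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(av) != length(bv))
    stop("sequences have different aligned lengths")
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  if (n == 0) return(list(n = 0L, ts = 0L, tv = 0L))
  diff <- av != bv
  purA <- av %in% c("A", "G")
  purB <- bv %in% c("A", "G")
  ts <- sum(diff & purA == purB)    # A<->G or C<->T
  tv <- sum(diff & purA != purB)
  list(n = n, ts = ts, tv = tv)
}

#' Kimura two-parameter (K80) pairwise distance
#'
#' Evolutionary distance between two aligned sequences under the K80
#' substitution model, with pairwise deletion of columns where either
#' sequence has a gap or ambiguity. With transition proportion P and
#' transversion proportion Q over the compared columns,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param a,b aligned sequences (character or [Biostrings::DNAString]).
#' @return the distance (substitutions/site); `NA` with a warning when the
#'   sequences are saturated (a log argument is non-positive). Zero
#'   comparable columns is an error.
#' @examples
#' k80Distance("ACGT", "ACGT")  # 0
#' @export
k80Distance <- function(a, b) {
  cc <- pairColumnCounts(a, b)
  if (cc$n == 0L)
    stop("k80Distance: no comparable columns (gap/ambiguity overlap only)")
  k80FromProportions(cc$ts / cc$n, cc$tv / cc$n)
}

#' @rdname k80Distance
#' @param P,Q transition and transversion proportions.
#' @export
k80FromProportions <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    warning("K80 distance undefined (saturated pair); returning NA")
    return(NA_real_)
  }
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' All pairwise K80 distances of an AlignedSet
#'
#' @param aligned an [AlignedSet-class].
#' @return a symmetric matrix of distances (NA for saturated pairs), with
#'   taxon labels as dimnames.
#' @export
k80DistanceMatrix <- function(aligned) {
  stopifnot(is(aligned, "AlignedSet"))
  n <- length(aligned)
  d <- matrix(0, n, n, dimnames = list(aligned@taxon, aligned@taxon))
  chars <- lapply(as.character(aligned@sequences), identity)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- tryCatch(
      k80Distance(chars[[i]], chars[[j]]),
      error = function(e) NA_real_)
  }
  d
}

#' Mean intra-genus pairwise distance (Dmean)
#'
#' Mean of all N(N-1)/2 pairwise K80 distances in a genus-level aligned set.
#' Defined only for N > 2 taxa; saturated (missing) pairs are excluded from
#' the mean and counted.
#'
#' @param genusSet an [AlignedSet-class] holding one genus.
#' @return list with `genus`, `nTaxa`, `dmean`, `nPairs`, `droppedPairs`.
#' @export
dmean <- function(genusSet) {
  stopifnot(is(genusSet, "AlignedSet"))
  n <- length(genusSet)
  if (n <= 2L)
    stop("dmean requires more than 2 taxa (got ", n, ")")
  d <- k80DistanceMatrix(genusSet)
  vals <- d[upper.tri(d)]
  dropped <- sum(is.na(vals))
  list(genus = unique(genusSet@genus)[1], nTaxa = n,
       dmean = mean(vals, na.rm = TRUE),
       nPairs = length(vals) - dropped, droppedPairs = dropped)
}

#' Faith's phylogenetic diversity (PD)
#'
#' Sum of branch lengths of the minimal subtree spanning a taxon set,
#' root-inclusive (the stem path down to the root is counted). For a single
#' taxon this degenerates to its root-to-leaf path length.
#'
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param taxa character vector of tip labels.
#' @return total branch length (numeric).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,C:4);")
#' faithPd(tr, c("A", "B"))  # 4
#' @export
faithPd <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  if (!length(taxa)) return(0)
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  used <- logical(max(tree$edge))
  for (tip in match(taxa, tree$tip.label)) {
    node <- tip
    while (node != root && !used[node]) {
      used[node] <- TRUE
      node <- parent[node]
    }
  }
  sum(elen[used])
}

#' Per-genus diversity table
#'
#' Computes, for every genus with more than `minTaxa - 1` taxa in the
#' aligned set, the number of taxa N, the mean pairwise K80 distance Dmean
#' and (when a tree is supplied) Faith's PD over the genus's taxa. Genera
#' with too few taxa are skipped with a notice.
#'
#' @param aligned an [AlignedSet-class] spanning several genera.
#' @param tree optional rooted [ape::phylo] whose tip labels match the
#'   taxon labels.
#' @param minTaxa minimum N for inclusion (default 3, i.e. N > 2).
#' @return data.frame with columns `genus`, `N`, `dmean`, `pd`,
#'   `dropped_pairs`.
#' @export
genusDiversity <- function(aligned, tree = NULL, minTaxa = 3L) {
  stopifnot(is(aligned, "AlignedSet"))
  out <- list()
  for (g in unique(aligned@genus)) {
    idx <- which(aligned@genus == g)
    if (length(idx) < minTaxa) {
      message("genus ", g, " skipped: only ", length(idx), " taxa")
      next
    }
    sub <- aligned[idx]
    dm <- dmean(sub)
    pd <- if (!is.null(tree)) faithPd(tree, sub@taxon) else NA_real_
    out[[g]] <- data.frame(genus = g, N = dm$nTaxa, dmean = dm$dmean,
                           pd = pd, dropped_pairs = dm$droppedPairs,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(genus = character(), N = integer(), dmean = numeric(),
                      pd = numeric(), dropped_pairs = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pearson correlations between diversity indices
#'
#' Correlation matrix of the per-genus indices N, Dmean and PD, used to
#' judge how strongly each diversity index tracks mere taxon availability.
#' A pair involving an index with zero variance yields NA.
#'
#' @param perGenus data.frame from [genusDiversity()] (columns `N`, `dmean`,
#'   `pd`).
#' @return 3 x 3 Pearson correlation matrix.
#' @export
indexCorrelations <- function(perGenus) {
  m <- as.matrix(perGenus[, c("N", "dmean", "pd")])
  keep <- stats::complete.cases(m)
  if (sum(keep) < 3)
    stop("need at least 3 genera with all three indices defined")
  m <- m[keep, , drop = FALSE]
  r <- suppressWarnings(stats::cor(m))
  sds <- apply(m, 2, stats::sd)
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r) <- 1
  r
}
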