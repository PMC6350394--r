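#' @include ChromosomeRecord-methods.R
NULL

## GenBank flat-file reading/writing. Only the parts of the format the
## feature computations need are handled: LOCUS line (name, length, topology),
## DEFINITION/SOURCE organism, CDS features with join/complement locations and
## the /product, /codon_start and /pseudo qualifiers, and the ORIGIN block.

#' Read GenBank flat files into ChromosomeRecords
#'
#' Parses one or more LOCUS entries from a GenBank flat file. Each entry must
#' carry an ORIGIN sequence block (a record without sequence is a hard error
#' naming the LOCUS). CDS features are captured with strand, joined location
#' parts, product, codon_start and pseudo flag; features whose location
#' string cannot be parsed (including origin-spanning locations) are skipped
#' with a warning and counted in `skippedFeatures()`.
#'
#' @param path path to a GenBank flat file (possibly multi-LOCUS).
#' @param genusOverride optional named character vector mapping accession to
#'   genus, honored over the first-token-of-organism default.
#' @return a list of [ChromosomeRecord-class] objects, one per LOCUS.
#' @seealso [writeGenBank()], [selectLargestReplicon()]
#' @export
readGenBank <- function(path, genusOverride = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS ", lines)
  if (!length(starts)) stop("no LOCUS entries found in ", path)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts))
    ends <- c(ends, length(lines))
  records <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    end <- ends[ends > starts[i]][1]
    records[[i]] <- parseGenBankEntry(lines[starts[i]:end], genusOverride)
  }
  records
}

parseGenBankEntry <- function(lines, genusOverride = NULL) {
  locusFields <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]]
  locusName <- locusFields[1]
  circ <- any(grepl("^circular$", locusFields, ignore.case = TRUE))

  ## accession: prefer ACCESSION/VERSION line, else LOCUS name
  accession <- locusName
  accLine <- grep("^ACCESSION", lines, value = TRUE)
  if (length(accLine)) {
    tok <- strsplit(trimws(sub("^ACCESSION", "", accLine[1])), "\\s+")[[1]]
    if (length(tok) && nzchar(tok[1])) accession <- tok[1]
  }
  verLine <- grep("^VERSION", lines, value = TRUE)
  if (length(verLine)) {
    tok <- strsplit(trimws(sub("^VERSION", "", verLine[1])), "\\s+")[[1]]
    if (length(tok) && nzchar(tok[1])) accession <- tok[1]
  }

  organism <- ""
  orgLine <- grep("^\\s+ORGANISM\\s+", lines)
  if (length(orgLine)) organism <- trimws(sub("^\\s+ORGANISM\\s+", "", lines[orgLine[1]]))
  if (!nzchar(organism)) {
    defLine <- grep("^DEFINITION", lines)
    if (length(defLine))
      organism <- trimws(sub("^DEFINITION\\s*", "", lines[defLine[1]]))
  }

  defn <- paste(grep("^DEFINITION", lines, value = TRUE), collapse = " ")
  plasmid <- grepl("plasmid", defn, ignore.case = TRUE)

  originAt <- grep("^ORIGIN", lines)
  if (!length(originAt))
    stop("LOCUS ", locusName, ": missing ORIGIN sequence block")
  seqLines <- lines[(originAt[1] + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  seqTxt <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nchar(seqTxt))
    stop("LOCUS ", locusName, ": empty ORIGIN sequence block")

  cdsTab <- emptyCdsTable()
  skipped <- 0L
  featAt <- grep("^FEATURES", lines)
  if (length(featAt)) {
    featLines <- lines[(featAt[1] + 1L):(originAt[1] - 1L)]
    parsed <- parseCdsFeatures(featLines, locusName)
    cdsTab <- parsed$cds
    skipped <- parsed$skipped
  }

  genusOv <- NULL
  if (!is.null(genusOverride) && accession %in% names(genusOverride))
    genusOv <- unname(genusOverride[[accession]])

  ChromosomeRecord(accession = accession, organism = organism,
                   sequence = seqTxt, genus = genusOv,
                   topology = if (circ) "circular" else "linear",
                   isPlasmid = plasmid, cds = cdsTab,
                   skippedFeatures = skipped)
}

## Splits the FEATURES table into individual features (new feature = key at
## column 6) and extracts the CDS ones.
parseCdsFeatures <- function(featLines, locusName) {
  keyAt <- grep("^ {1,10}\\S", featLines)
  keyAt <- keyAt[!grepl("^\\s{12,}", featLines[keyAt])]
  skipped <- 0L
  rows <- list()
  for (k in seq_along(keyAt)) {
    from <- keyAt[k]
    to <- if (k < length(keyAt)) keyAt[k + 1L] - 1L else length(featLines)
    block <- featLines[from:to]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    if (!identical(key, "CDS")) next

    ## location may continue over lines until the first qualifier line
    qualAt <- grep("^\\s+/", block)
    locEnd <- if (length(qualAt)) qualAt[1] - 1L else length(block)
    loc <- gsub("\\s", "", paste(
      c(sub("^\\s*CDS\\s*", "", block[1]),
        if (locEnd >= 2) trimws(block[2:locEnd]) else character()),
      collapse = ""))
    parsedLoc <- tryCatch(parseLocation(loc), error = function(e) NULL)
    if (is.null(parsedLoc)) {
      warning("LOCUS ", locusName, ": skipping CDS with malformed location '",
              loc, "'", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    quals <- parseQualifiers(block[if (length(qualAt)) qualAt[1]:length(block) else 0])
    rows[[length(rows) + 1L]] <- list(
      start = min(IRanges::start(parsedLoc$parts)),
      end = max(IRanges::end(parsedLoc$parts)),
      strand = parsedLoc$strand,
      product = if (!is.null(quals$product)) quals$product else "",
      codonStart = if (!is.null(quals$codon_start))
        as.integer(quals$codon_start) else 1L,
      pseudo = isTRUE(quals$pseudo),
      parts = parsedLoc$parts
    )
  }
  if (!length(rows)) return(list(cds = emptyCdsTable(), skipped = skipped))
  cds <- S4Vectors::DataFrame(
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    product = vapply(rows, `[[`, character(1), "product"),
    codonStart = vapply(rows, `[[`, integer(1), "codonStart"),
    pseudo = vapply(rows, `[[`, logical(1), "pseudo"),
    parts = do.call(IRanges::IRangesList, lapply(rows, `[[`, "parts"))
  )
  list(cds = cds, skipped = skipped)
}

## GenBank location strings: N..M, complement(...), join(...,...),
## optionally with < / > partial markers. Origin-spanning (start > end)
## segments are rejected -> caller skips the feature.
parseLocation <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("[()]", loc)) stop("unsupported nested location")
  segs <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (!length(segs)) stop("empty location")
  starts <- integer(length(segs)); ends <- integer(length(segs))
  for (i in seq_along(segs)) {
    s <- gsub("[<>]", "", segs[i])
    if (grepl("^\\d+$", s)) {
      starts[i] <- ends[i] <- as.integer(s)
    } else if (grepl("^\\d+\\.\\.\\d+$", s)) {
      ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
      starts[i] <- ab[1]; ends[i] <- ab[2]
    } else stop("unparseable location segment: ", s)
    if (starts[i] > ends[i]) stop("start > end (origin-spanning?) in: ", s)
  }
  list(strand = strand, parts = IRanges::IRanges(starts, ends))
}

parseQualifiers <- function(qualLines) {
  if (!length(qualLines)) return(list())
  ## re-join continuation lines onto their qualifier
  idx <- cumsum(grepl("^\\s+/", qualLines))
  joined <- vapply(split(trimws(qualLines), idx),
                   paste, character(1), collapse = " ")
  out <- list()
  for (q in joined) {
    if (!startsWith(q, "/")) next
    if (grepl("=", q, fixed = TRUE)) {
      name <- sub("^/([^=]+)=.*$", "\\1", q)
      val <- sub("^/[^=]+=", "", q)
      val <- gsub('^"|"$', "", val)
      out[[name]] <- val
    } else {
      out[[sub("^/", "", q)]] <- TRUE
    }
  }
  out
}

#' Write ChromosomeRecords as a GenBank flat file
#'
#' Emits a minimal but valid GenBank flat file (LOCUS, DEFINITION, ACCESSION,
#' ORGANISM, FEATURES with source and CDS entries, ORIGIN) that round-trips
#' through [readGenBank()] with identical sequence, CDS coordinates, strands
#' and products. Used by the synthetic-genome generator and for fixtures.
#'
#' @param records a [ChromosomeRecord-class] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(records, path) {
  if (is(records, "ChromosomeRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) writeGenBankEntry(rec, con)
  invisible(path)
}

writeGenBankEntry <- function(rec, con) {
  L <- length(rec@sequence)
  topo <- if (rec@topology == "circular") "circular" else "linear"
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT 01-JAN-2000",
            rec@accession, L, topo))
  w(sprintf("DEFINITION  %s%s, complete sequence.", rec@organism,
            if (rec@isPlasmid) " plasmid" else " chromosome"))
  w(sprintf("ACCESSION   %s", rec@accession))
  w("SOURCE      ", rec@organism)
  w("  ORGANISM  ", rec@organism)
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", L))
  w(sprintf('                     /organism="%s"', rec@organism))
  cds <- rec@cds
  for (i in seq_len(nrow(cds))) {
    parts <- cds$parts[[i]]
    segs <- paste0(IRanges::start(parts), "..", IRanges::end(parts))
    loc <- if (length(segs) > 1)
      paste0("join(", paste(segs, collapse = ","), ")") else segs
    if (cds$strand[i] == "-") loc <- paste0("complement(", loc, ")")
    w(sprintf("     CDS             %s", loc))
    w(sprintf('                     /product="%s"', cds$product[i]))
    w(sprintf("                     /codon_start=%d", cds$codonStart[i]))
    if (cds$pseudo[i]) w("                     /pseudo")
  }
  w("ORIGIN")
  seqTxt <- tolower(as.character(rec@sequence))
  pos <- seq(1L, nchar(seqTxt), by = 60L)
  for (p in pos) {
    chunk <- substr(seqTxt, p, min(p + 59L, nchar(seqTxt)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w(sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  w("//")
}
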