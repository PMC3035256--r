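#' Parse all-vs-all alignment hits (BLAST tabular, outfmt 6)
#'
#' Reads the standard 12-column tab-separated BLAST output (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore; extra trailing columns are tolerated) and keeps the hits whose
#' E-value passes the significance cutoff. The default cutoff of 1e-5 is
#' the standard setting for this procedure: a more liberal cutoff mostly
#' adds poor alignments that the 50/50 rule discards anyway. Self-hits
#' (query == subject) are retained here; they are ignored later when
#' forming pairs.
#'
#' @param path path to a BLAST tabular file (no header).
#' @param evalueCutoff keep hits with `evalue <= evalueCutoff`.
#' @return a data.frame with one row per retained hit, in file order:
#'   columns `qseqid`, `sseqid` (character), `pident` (percent identity
#'   over the aligned region, 0-100), `length` (aligned columns),
#'   `evalue`. An empty file yields a zero-row data.frame.
#' @export
readBlastTabular <- function(path, evalueCutoff = 1e-5) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    i <- which(nf < 12L)[1L]
    stop(sprintf("line %d: expected >= 12 tab-separated fields, got %d",
                 lineno[i], nf[i]))
  }
  pick <- function(j) vapply(fields, `[[`, character(1L), j)
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("line %d: non-numeric %s field '%s'",
                   lineno[i], what, x[i]))
    }
    v
  }
  hits <- data.frame(qseqid = pick(1L), sseqid = pick(2L),
                     pident = num(pick(3L), "identity"),
                     length = num(pick(4L), "alignment length"),
                     evalue = num(pick(11L), "E-value"),
                     stringsAsFactors = FALSE)
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("percent identity outside [0, 100]")
  if (any(hits$length < 1)) stop("alignment length < 1")
  if (any(hits$evalue < 0)) stop("negative E-value")
  hits[hits$evalue <= evalueCutoff, , drop = FALSE]
}

#' Sequence catalog: lengths and genome of origin
#'
#' The reciprocal coverage rule divides alignment lengths by the length of
#' each query sequence, and the pan-matrix needs to know which genome each
#' protein came from; a \emph{sequence catalog} holds both. It can be read
#' from a headerless three-column TSV (`seq_id`, `length`, `genome_id`) or
#' collected from one protein FASTA file per genome, in which case the
#' genome id is the file name stem and the sequence id is the first token
#' of each FASTA header.
#'
#' @param path path to the 3-column TSV.
#' @return a data.frame with columns `seqId` (character, unique), `length`
#'   (integer, >= 1) and `genomeId` (character).
#' @export
readSequenceCatalog <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (ncol(tab) != 3L)
    stop("sequence catalog must have 3 columns (seq_id, length, genome_id): ",
         path)
  cat <- data.frame(seqId = tab[[1L]],
                    length = suppressWarnings(as.integer(tab[[2L]])),
                    genomeId = tab[[3L]], stringsAsFactors = FALSE)
  validateCatalog(cat)
  cat
}

#' @rdname readSequenceCatalog
#' @param fastaFiles character vector of protein FASTA paths, one file per
#'   genome.
#' @param genomeIds genome ids; defaults to the FASTA file name stems.
#' @export
catalogFromFasta <- function(fastaFiles,
                             genomeIds = sub("\\.[^.]*$", "",
                                             basename(fastaFiles))) {
  stopifnot(length(fastaFiles) == length(genomeIds))
  parts <- lapply(seq_along(fastaFiles), function(i) {
    aa <- Biostrings::readAAStringSet(fastaFiles[i])
    ids <- vapply(strsplit(names(aa), "[ \t]"), `[[`, character(1L), 1L)
    data.frame(seqId = ids, length = Biostrings::width(aa),
               genomeId = genomeIds[i], stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, parts)
  validateCatalog(cat)
  cat
}

validateCatalog <- function(cat) {
  if (anyNA(cat$length) || any(cat$length < 1L))
    stop("sequence lengths must be integers >= 1")
  if (anyDuplicated(cat$seqId))
    stop("duplicated sequence id in catalog: ",
         cat$seqId[duplicated(cat$seqId)][1L])
  if (any(!nzchar(cat$seqId)) || any(!nzchar(cat$genomeId)))
    stop("empty sequence or genome id in catalog")
  invisible(cat)
}

#' Reciprocally qualifying sequence pairs (the 50/50 rule)
#'
#' Two distinct sequences a and b are linked when there is a significant
#' alignment between them in \emph{both} query directions, and both
#' alignments span at least `minCoverage` of the length of their query
#' sequence with at least `minIdentity` identity. Coverage for the
#' direction a -> b is `length / length(a)` (the query's length is the
#' denominator); identity is the hit's percent identity over the aligned
#' region. When several hits (HSPs) exist for one direction, the direction
#' qualifies if any single hit does; HSPs are not tiled. Self-hits are
#' ignored.
#'
#' @param hits data.frame of alignment hits, as from [readBlastTabular()].
#' @param catalog sequence catalog, as from [readSequenceCatalog()].
#' @param minCoverage,minIdentity thresholds in (0, 1]; defaults 0.5, 0.5.
#' @return a data.frame of unordered qualifying pairs with columns `id1`,
#'   `id2` (`id1 < id2`), sorted; zero rows if none qualify.
#' @export
reciprocalPairs <- function(hits, catalog, minCoverage = 0.5,
                            minIdentity = 0.5) {
  stopifnot(minCoverage > 0, minCoverage <= 1,
            minIdentity > 0, minIdentity <= 1)
  if (nrow(hits) == 0L)
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  known <- c(hits$qseqid, hits$sseqid) %in% catalog$seqId
  if (!all(known))
    stop("hit references sequence id absent from catalog: ",
         c(hits$qseqid, hits$sseqid)[!known][1L])
  qlen <- catalog$length[match(hits$qseqid, catalog$seqId)]
  ok <- hits$qseqid != hits$sseqid &
    hits$length / qlen >= minCoverage &
    hits$pident / 100 >= minIdentity
  if (!any(ok))
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  fwd <- unique(paste(hits$qseqid[ok], hits$sseqid[ok], sep = "\r"))
  rev <- unique(paste(hits$sseqid[ok], hits$qseqid[ok], sep = "\r"))
  both <- fwd[fwd %in% rev]
  if (length(both) == 0L)
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  ab <- do.call(rbind, strsplit(both, "\r", fixed = TRUE))
  id1 <- pmin(ab[, 1L], ab[, 2L])
  id2 <- pmax(ab[, 1L], ab[, 2L])
  pairs <- unique(data.frame(id1 = id1, id2 = id2,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$id1, pairs$id2, method = "radix"), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Group sequences into gene families
#'
#' Gene families are the connected components of the graph whose nodes are
#' all catalog sequences and whose edges are the reciprocally qualifying
#' pairs: the pairwise 50/50 relation is closed transitively (single
#' linkage), so a family may contain pairs that are not directly linked.
#' Sequences with no qualifying partner form singleton families. Family
#' ids are deterministic: components are ordered by their lexicographically
#' smallest member id and labelled `F0001`, `F0002`, ... (zero-padded to
#' the number of families).
#'
#' @param pairs data.frame of pairs, as from [reciprocalPairs()].
#' @param catalog sequence catalog.
#' @return a data.frame (the gene family table) with columns `familyId`,
#'   `seqId`, `genomeId`, one row per catalog sequence, sorted by family
#'   then sequence id. The families partition the catalog.
#' @export
buildFamilies <- function(pairs, catalog) {
  missing <- setdiff(unique(c(pairs$id1, pairs$id2)), catalog$seqId)
  if (length(missing) > 0L)
    stop("pair references sequence id absent from catalog: ", missing[1L])
  g <- igraph::graph_from_data_frame(
    d = pairs, directed = FALSE,
    vertices = data.frame(name = catalog$seqId))
  comp <- igraph::components(g)$membership
  comp <- comp[catalog$seqId]
  reps <- vapply(split(catalog$seqId, comp),
                 function(ids) sort(ids, method = "radix")[1L],
                 character(1L))
  ord <- match(reps, sort(reps, method = "radix"))  # component -> family index
  names(ord) <- names(reps)
  nfam <- length(reps)
  width <- max(4L, nchar(as.character(nfam)))
  famId <- sprintf(paste0("F%0", width, "d"), ord[as.character(comp)])
  fam <- data.frame(familyId = famId, seqId = catalog$seqId,
                    genomeId = catalog$genomeId, stringsAsFactors = FALSE)
  fam <- fam[order(fam$familyId, fam$seqId, method = "radix"), ,
             drop = FALSE]
  rownames(fam) <- NULL
  fam
}

#' Collapse a gene family table into a PanMatrix
#'
#' Entry (i, j) is 1 when family j contains at least one sequence from
#' genome i — presence is binary, so in-paralogs (several members of one
#' family in one genome) still yield 1. Rows are ordered by genome id and
#' columns by family id (lexicographically, byte order).
#'
#' @param families gene family table from [buildFamilies()].
#' @return a [PanMatrix-class].
#' @export
familiesToPanMatrix <- function(families) {
  gen <- sort(unique(families$genomeId), method = "radix")
  fam <- sort(unique(families$familyId), method = "radix")
  m <- matrix(0L, nrow = length(gen), ncol = length(fam),
              dimnames = list(gen, fam))
  m[cbind(match(families$genomeId, gen),
          match(families$familyId, fam))] <- 1L
  PanMatrix(m)
}

#' Write a gene family table as TSV
#'
#' Columns: `family_id`, `seq_id`, `genome_id`.
#'
#' @param families gene family table from [buildFamilies()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeFamilyTable <- function(families, path) {
  tab <- data.frame(family_id = families$familyId,
                    seq_id = families$seqId,
                    genome_id = families$genomeId)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
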