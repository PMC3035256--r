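#' Simulate a pan-matrix with planted core/shell/cloud structure
#'
#' Generates a binary pan-matrix whose occupancy spectrum has the three
#' classes observed in real pan-genomes: a \emph{core} present in every
#' genome, a \emph{shell} of families present in a majority of genomes,
#' and a \emph{cloud} of rarely occurring families. Each shell/cloud
#' family draws an occupancy uniformly from its class range and is then
#' assigned to a uniformly random genome subset of that size.
#'
#' The defaults emulate a single-species pan-genome of 14 strains (the
#' scale at which the weighting schemes are usually illustrated): 1500
#' core, 700 shell (occupancy 8-13) and 500 cloud families (occupancy
#' 1-7).
#'
#' @param G number of genomes (>= 2).
#' @param nCore,nShell,nCloud family counts per class (>= 0).
#' @param shellRange,cloudRange integer occupancy ranges `c(lo, hi)`
#'   within `[1, G]`; defaults: shell `(floor(G/2)+1, G-1)`, cloud
#'   `(1, floor(G/2))`.
#' @param seed integer seed; output is deterministic given the
#'   configuration and seed.
#' @return a [PanMatrix-class] with genomes `G01, G02, ...` and family
#'   ids prefixed by their planted class (`core...`, `shell...`,
#'   `cloud...`).
#' @export
simulatePanMatrix <- function(G = 14, nCore = 1500, nShell = 700,
                              nCloud = 500,
                              shellRange = c(floor(G / 2) + 1, G - 1),
                              cloudRange = c(1, floor(G / 2)),
                              seed = 1) {
  stopifnot(G >= 2, nCore >= 0, nShell >= 0, nCloud >= 0,
            nCore + nShell + nCloud >= 1)
  checkRange <- function(r, what) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1 || r[2L] > G)
      stop(what, " occupancy range must lie within [1, G]")
  }
  if (nShell > 0) checkRange(shellRange, "shell")
  if (nCloud > 0) checkRange(cloudRange, "cloud")
  gen <- sprintf("G%02d", seq_len(G))
  pad <- function(prefix, n)
    if (n > 0) sprintf("%s%05d", prefix, seq_len(n)) else character(0)
  fam <- c(pad("core", nCore), pad("shell", nShell), pad("cloud", nCloud))
  m <- matrix(0L, nrow = G, ncol = length(fam),
              dimnames = list(gen, fam))
  if (nCore > 0) m[, seq_len(nCore)] <- 1L
  .withSeed(seed, {
    fill <- function(offset, count, range) {
      for (j in seq_len(count)) {
        k <- if (range[1L] == range[2L]) range[1L] else
          sample(range[1L]:range[2L], 1L)
        m[sample.int(G, k), offset + j] <<- 1L
      }
    }
    fill(nCore, nShell, shellRange)
    fill(nCore + nShell, nCloud, cloudRange)
  })
  PanMatrix(m)
}

#' Simulate gene gain and loss along a known tree
#'
#' Evolves a set of gene families along a rooted binary guide tree under
#' the simplest independent-events model: starting from `rootSize`
#' families at the root, each present family survives a branch of length
#' t with probability `exp(-lossRate * t)`, and `Poisson(gainRate * t)`
#' novel families are gained on the branch. The leaves' family sets form
#' the pan-matrix (families present in no leaf are dropped). This exists
#' to produce presence/absence data with a known true tree for topology
#' and support recovery experiments.
#'
#' @param tree a rooted binary `phylo` guide tree with positive branch
#'   lengths; the default is a balanced 4-leaf tree (pendant branches 0.5,
#'   internal branches 0.3).
#' @param rootSize number of families at the root (>= 1).
#' @param gainRate,lossRate events per unit branch length (>= 0);
#'   defaults 20 and 0.1.
#' @param seed integer seed.
#' @return a list with elements `panmatrix` (a [PanMatrix-class], rows in
#'   tip-label order of the tree) and `tree` (the guide tree).
#' @export
simulateGainLoss <- function(tree = NULL, rootSize = 500, gainRate = 20,
                             lossRate = 0.1, seed = 1) {
  if (is.null(tree))
    tree <- ape::read.tree(
      text = "((A:0.5,B:0.5):0.3,(C:0.5,D:0.5):0.3);")
  stopifnot(inherits(tree, "phylo"), rootSize >= 1,
            gainRate >= 0, lossRate >= 0)
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("guide tree must be rooted and binary")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("guide tree must have positive branch lengths")
  tree <- stats::reorder(tree, "cladewise")
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  env <- new.env()
  env$counter <- rootSize
  sets <- vector("list", nt + tree$Nnode)
  sets[[root]] <- seq_len(rootSize)
  .withSeed(seed, {
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
      t <- tree$edge.length[e]
      s <- sets[[par]]
      keep <- s[runif(length(s)) <= exp(-lossRate * t)]
      ng <- rpois(1L, gainRate * t)
      gained <- if (ng > 0L) env$counter + seq_len(ng) else integer(0)
      env$counter <- env$counter + ng
      sets[[chi]] <- c(keep, gained)
    }
  })
  leaves <- sets[seq_len(nt)]
  fams <- sort(unique(unlist(leaves)))
  if (length(fams) == 0L)
    stop("all gene families were lost before reaching the leaves; ",
         "use a lower lossRate or a larger rootSize")
  width <- max(5L, nchar(as.character(env$counter)))
  m <- t(vapply(leaves, function(s) as.integer(fams %in% s),
                integer(length(fams))))
  dimnames(m) <- list(tree$tip.label,
                      sprintf(paste0("F%0", width, "d"), fams))
  list(panmatrix = PanMatrix(m), tree = tree)
}

#' Simulate an all-vs-all alignment table with planted gene families
#'
#' Emits the mock BLAST-style hits that the families module should turn
#' back into exactly the planted partition: a self-hit for every
#' sequence, reciprocal qualifying hits (coverage >= 0.8 of the query,
#' identity 60-99%, E-value <= 1e-11) for every ordered within-family
#' pair, and decoy hits between sequences of different families that fail
#' exactly one clause of the reciprocal 50/50 rule — insufficient
#' coverage (30% of the query), insufficient identity (20-45%), or a
#' missing reciprocal hit. Decoy pairs are disjoint, so no decoy can link
#' two families.
#'
#' @param families planted gene family table (columns `familyId`,
#'   `seqId`, `genomeId`), partitioning the catalog.
#' @param catalog sequence catalog ([readSequenceCatalog()] layout);
#'   sequence lengths of at least 10 residues are recommended so the
#'   coverage decoys stay below the 50% threshold.
#' @param seed integer seed.
#' @param nDecoys total number of decoy pairs to attempt (split over the
#'   three failure modes; capped by the available cross-family pairs).
#' @return a data.frame of hits in the [readBlastTabular()] layout
#'   (`qseqid`, `sseqid`, `pident`, `length`, `evalue`).
#' @export
simulateAlignmentTable <- function(families, catalog, seed = 1,
                                   nDecoys = 30) {
  stopifnot(setequal(families$seqId, catalog$seqId))
  len <- setNames(catalog$length, catalog$seqId)
  fam <- setNames(families$familyId, families$seqId)
  rows <- list()
  add <- function(q, s, pid, al, ev)
    rows[[length(rows) + 1L]] <<- data.frame(
      qseqid = q, sseqid = s, pident = pid, length = al, evalue = ev,
      stringsAsFactors = FALSE)
  .withSeed(seed, {
    # self-hits: full-length, 100% identity (ignored when pairing)
    add(catalog$seqId, catalog$seqId, 100, unname(len[catalog$seqId]), 0)
    # reciprocal qualifying hits within each planted family
    for (ids in split(families$seqId, families$familyId)) {
      if (length(ids) < 2L) next
      prs <- t(combn(sort(ids, method = "radix"), 2L))
      for (r in seq_len(nrow(prs))) {
        a <- prs[r, 1L]; b <- prs[r, 2L]
        pid <- runif(1L, 60, 99)
        ev <- 10^-runif(1L, 11, 60)
        add(a, b, pid, ceiling(0.8 * len[[a]]), ev)
        add(b, a, pid, ceiling(0.8 * len[[b]]), ev)
      }
    }
    # decoys: cross-family pairs, one failure mode each, disjoint pairs
    ids <- sort(catalog$seqId, method = "radix")
    cross <- t(combn(ids, 2L))
    cross <- cross[fam[cross[, 1L]] != fam[cross[, 2L]], , drop = FALSE]
    if (nrow(cross) > 0L && nDecoys > 0L) {
      take <- sample.int(nrow(cross), min(nDecoys, nrow(cross)))
      mode <- rep_len(c("coverage", "identity", "reciprocity"),
                      length(take))
      for (d in seq_along(take)) {
        a <- cross[take[d], 1L]; b <- cross[take[d], 2L]
        switch(mode[d],
          coverage = {  # high identity but short alignment, both ways
            la <- max(1L, floor(0.3 * len[[a]]))
            lb <- max(1L, floor(0.3 * len[[b]]))
            if (la / len[[a]] < 0.5 && lb / len[[b]] < 0.5) {
              add(a, b, runif(1L, 80, 99), la, 1e-30)
              add(b, a, runif(1L, 80, 99), lb, 1e-30)
            }
          },
          identity = {  # long alignment but low identity, both ways
            add(a, b, runif(1L, 20, 45), ceiling(0.9 * len[[a]]), 1e-20)
            add(b, a, runif(1L, 20, 45), ceiling(0.9 * len[[b]]), 1e-20)
          },
          reciprocity = {  # qualifying in one direction only
            add(a, b, runif(1L, 70, 95), ceiling(0.9 * len[[a]]), 1e-25)
          })
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write hits as 12-column BLAST tabular (outfmt 6)
#'
#' Fills the positional columns not carried by the hit table (mismatch,
#' gapopen, qstart, qend, sstart, send, bitscore) with values consistent
#' with the alignment length and identity.
#'
#' @param hits data.frame in the [readBlastTabular()] layout.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBlastTabular <- function(hits, path) {
  mism <- round(hits$length * (1 - hits$pident / 100))
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t0\t1\t%d\t1\t%d\t%.3e\t%.1f",
                   hits$qseqid, hits$sseqid, hits$pident,
                   as.integer(hits$length), as.integer(mism),
                   as.integer(hits$length), as.integer(hits$length),
                   hits$evalue, 2 * hits$length)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname readSequenceCatalog
#' @param catalog a catalog data.frame to write (headerless 3-column TSV).
#' @export
writeSequenceCatalog <- function(catalog, path) {
  write.table(catalog[, c("seqId", "length", "genomeId")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
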