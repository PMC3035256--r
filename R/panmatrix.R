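#' @describeIn nGenomes number of genomes (rows)
#' @export
setMethod("nGenomes", "PanMatrix", function(x) nrow(x@mat))

#' @describeIn nGenomes number of gene families (columns)
#' @export
setMethod("nFamilies", "PanMatrix", function(x) ncol(x@mat))

#' @describeIn genomeNames genome ids (row names)
#' @export
setMethod("genomeNames", "PanMatrix", function(x) rownames(x@mat))

#' @describeIn genomeNames family ids (column names)
#' @export
setMethod("familyNames", "PanMatrix", function(x) colnames(x@mat))

#' @export
#' @method as.matrix PanMatrix
as.matrix.PanMatrix <- function(x, ...) x@mat

setMethod("show", "PanMatrix", function(object) {
  spec <- occupancySpectrum(object)
  g <- nGenomes(object)
  cat(sprintf("PanMatrix: %d genomes x %d gene families\n",
              g, nFamilies(object)))
  cat(sprintf("  core (occupancy %d): %d   ORFans (occupancy 1): %d\n",
              g, spec[g], spec[1L]))
  cat("  genomes: ", paste(utils::head(genomeNames(object), 5L),
                           collapse = ", "),
      if (g > 5L) ", ..." else "", "\n", sep = "")
})

#' @describeIn occupancy column sums of the pan-matrix
#' @export
setMethod("occupancy", "PanMatrix", function(x) {
  k <- colSums(x@mat)
  storage.mode(k) <- "integer"
  k
})

#' @describeIn occupancySpectrum tabulate occupancies 1..G
#' @export
setMethod("occupancySpectrum", "PanMatrix", function(x) {
  g <- nGenomes(x)
  spec <- tabulate(occupancy(x), nbins = g)
  names(spec) <- as.character(seq_len(g))
  spec
})

#' Gene family weights from occupancy
#'
#' Builds the per-family weight vector \eqn{w_j} used by the weighted
#' relative Manhattan distance. Weights depend on a family's occupancy
#' \eqn{k_j} (number of genomes containing it) only, so families with
#' equal occupancy always receive equal weight:
#'
#' \describe{
#'   \item{uniform}{\eqn{w_j = 1} (the default distance).}
#'   \item{drop_orfans}{\eqn{w_j = 0} if \eqn{k_j = 1}, else 1. ORFans
#'     (families seen in a single genome) are often artifacts of
#'     over-sensitive gene callers; discarding them can make the tree more
#'     robust.}
#'   \item{shell}{\eqn{w_j = (k_j - 1)/(G - 1)}: a linear ramp emphasising
#'     families conserved in the majority of genomes.}
#'   \item{cloud}{\eqn{w_j = (G - k_j)/(G - 1)}: the opposite ramp,
#'     emphasising rarely occurring, strain-specific families.}
#' }
#'
#' The boolean flags compose with any scheme and are applied afterwards:
#' `dropOrfans` zeroes families with \eqn{k_j = 1}, `dropCore` zeroes
#' families with \eqn{k_j = G}. Core families contribute no presence
#' difference to any genome pair, so dropping them only rescales the
#' distances (through the total weight W).
#'
#' @param P a [PanMatrix-class].
#' @param scheme one of `"uniform"`, `"drop_orfans"`, `"shell"`, `"cloud"`.
#' @param dropOrfans,dropCore logical flags applied after the scheme.
#' @return named numeric weight vector aligned to `familyNames(P)`, with
#'   attribute `scheme`. An error is thrown if all weights vanish (e.g.
#'   the cloud scheme on a pure-core matrix), since the distance would be
#'   undefined (W = 0).
#' @examples
#' m <- cbind(F1 = c(1, 0, 0), F2 = c(1, 1, 0), F3 = c(1, 1, 1))
#' rownames(m) <- c("G1", "G2", "G3")
#' P <- PanMatrix(m)
#' makeWeights(P, "shell")  # (0, 0.5, 1)
#' makeWeights(P, "cloud")  # (1, 0.5, 0)
#' @export
makeWeights <- function(P, scheme = c("uniform", "drop_orfans", "shell",
                                      "cloud"),
                        dropOrfans = FALSE, dropCore = FALSE) {
  stopifnot(is(P, "PanMatrix"))
  scheme <- match.arg(scheme)
  k <- occupancy(P)
  g <- nGenomes(P)
  w <- switch(scheme,
    uniform     = rep(1, length(k)),
    drop_orfans = as.numeric(k > 1L),
    shell       = if (g == 1L) rep(1, length(k)) else (k - 1) / (g - 1),
    cloud       = if (g == 1L) rep(1, length(k)) else (g - k) / (g - 1))
  if (dropOrfans) w[k == 1L] <- 0
  if (dropCore)   w[k == g]  <- 0
  names(w) <- familyNames(P)
  if (sum(w) <= 0)
    stop("all gene family weights vanished (W = 0) for scheme '", scheme,
         "'", if (dropOrfans) " + dropOrfans", if (dropCore) " + dropCore",
         "; the weighted distance is undefined")
  attr(w, "scheme") <- scheme
  w
}

#' Read / write a pan-matrix as TSV
#'
#' The on-disk layout is a tab-separated table with a header row: first
#' column `genome`, remaining columns the family ids; one row per genome
#' with 0/1 entries. [readPanMatrix()] validates binariness and id
#' uniqueness and round-trips exactly with [writePanMatrix()].
#'
#' @param path file path.
#' @return [readPanMatrix()] returns a [PanMatrix-class];
#'   [writePanMatrix()] returns `path` invisibly.
#' @export
readPanMatrix <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character", sep = "\t")
  if (ncol(tab) < 2L || names(tab)[1L] != "genome")
    stop("pan-matrix file must have a 'genome' first column: ", path)
  fam <- names(tab)[-1L]
  gen <- tab[[1L]]
  if (anyDuplicated(fam))
    stop("duplicated family id in header: ",
         fam[duplicated(fam)][1L])
  if (anyDuplicated(gen))
    stop("duplicated genome id: ", gen[duplicated(gen)][1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m) | (m != 0 & m != 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary entry at genome '%s', family '%s'",
                 gen[bad[1L, 1L]], fam[bad[1L, 2L]]))
  rownames(m) <- gen
  colnames(m) <- fam
  PanMatrix(m)
}

#' @rdname readPanMatrix
#' @param P a [PanMatrix-class].
#' @export
writePanMatrix <- function(P, path) {
  stopifnot(is(P, "PanMatrix"))
  tab <- data.frame(genome = genomeNames(P), as.matrix(P),
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a weight vector as TSV
#'
#' Columns: `family_id`, `occupancy`, `weight`.
#'
#' @param w weight vector from [makeWeights()].
#' @param P the [PanMatrix-class] the weights belong to.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeWeights <- function(w, P, path) {
  stopifnot(length(w) == nFamilies(P))
  tab <- data.frame(family_id = familyNames(P), occupancy = occupancy(P),
                    weight = as.numeric(w))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
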