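#' PanMatrix: binary gene family presence/absence matrix
#'
#' The central exchange object of the package: a binary matrix with one row
#' per genome and one column per gene family. Entry \eqn{M_{ij} = 1} if
#' gene family \eqn{j} is present in genome \eqn{i} (with one or more
#' members), 0 if not. Each row is the \emph{pan-genome profile} of a
#' genome.
#'
#' Validity requires every entry to be 0 or 1, every column (family) to be
#' present in at least one genome, and genome and family identifiers to be
#' unique and non-empty. A single-genome matrix is valid as a container;
#' tree-building functions require at least two genomes.
#'
#' @slot mat integer matrix of 0/1, with genome ids as rownames and family
#'   ids as colnames.
#'
#' @seealso [PanMatrix()] (constructor), [occupancy()], [makeWeights()],
#'   [distManhattan()], [readPanMatrix()].
#' @exportClass PanMatrix
setClass("PanMatrix", representation(mat = "matrix"))

setValidity("PanMatrix", function(object) {
  m <- object@mat
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("pan-matrix must have genome rownames and family colnames")
  if (nrow(m) < 1L || ncol(m) < 1L)
    return("pan-matrix must have at least one genome and one family")
  if (anyDuplicated(rownames(m)))
    return("duplicated genome id")
  if (anyDuplicated(colnames(m)))
    return("duplicated family id")
  if (any(!nzchar(rownames(m))) || any(!nzchar(colnames(m))))
    return("empty genome or family id")
  if (!is.numeric(m) || anyNA(m) || !all(m == 0L | m == 1L))
    return("pan-matrix entries must all be 0 or 1")
  cs <- colSums(m)
  if (any(cs == 0))
    return(sprintf("family '%s' is present in no genome",
                   colnames(m)[which(cs == 0)[1L]]))
  TRUE
})

#' Construct a PanMatrix
#'
#' @param mat numeric/integer/logical matrix of 0/1 with genome rownames and
#'   family colnames.
#' @return A [PanMatrix-class] object.
#' @examples
#' m <- rbind(G1 = c(1, 1, 0), G2 = c(1, 0, 1))
#' colnames(m) <- c("F1", "F2", "F3")
#' PanMatrix(m)
#' @export
PanMatrix <- function(mat) {
  storage.mode(mat) <- "integer"
  new("PanMatrix", mat = mat)
}

#' ClusterTree: rooted ultrametric tree from hierarchical clustering
#'
#' Result of [upgma()]. Stored in `hclust`-style form: `merge` has one row
#' per internal node, negative entries index leaves and positive entries
#' earlier merges; `height` gives the node height of each internal node
#' (half the merge distance, so the leaf-to-root path length equals half
#' the root merge distance and the tree is ultrametric). Branch lengths
#' are differences of heights.
#'
#' @slot merge integer matrix (G-1 x 2), `hclust` merge convention.
#' @slot height numeric vector of internal node heights, non-decreasing.
#' @slot labels character vector of leaf (genome) labels.
#'
#' @seealso [upgma()], [toNewick()], [asPhylo()], [bootstrapSupports()].
#' @exportClass ClusterTree
setClass("ClusterTree",
         representation(merge = "matrix", height = "numeric",
                        labels = "character"))

setValidity("ClusterTree", function(object) {
  nmerge <- nrow(object@merge)
  g <- length(object@labels)
  if (g < 2L) return("a tree needs at least two leaves")
  if (nmerge != g - 1L) return("merge must have G-1 rows")
  if (length(object@height) != nmerge) return("one height per merge")
  if (anyNA(object@height) || any(!is.finite(object@height)))
    return("non-finite node height")
  if (length(object@height) > 1L && any(diff(object@height) < -1e-9))
    return("node heights must be non-decreasing from leaves to root")
  if (any(object@height < 0)) return("negative node height")
  if (anyDuplicated(object@labels)) return("duplicated leaf label")
  TRUE
})

#' PanBootstrap: UPGMA tree with bootstrap supports
#'
#' Result of [bootstrapSupports()]: the reference tree built from the full
#' pan-matrix, together with per-internal-node bootstrap supports. The
#' support of an internal node is the percentage of replicate trees (built
#' from pan-matrices whose columns were resampled with replacement,
#' carrying their weights) that contain a node with the identical pair of
#' child leaf sets.
#'
#' @slot tree the reference [ClusterTree-class].
#' @slot supports numeric vector, percentages in `[0, 100]`, one per
#'   internal node (aligned to rows of `merge`).
#' @slot B integer, number of bootstrap replicates.
#' @slot seed integer seed used for resampling.
#'
#' @exportClass PanBootstrap
setClass("PanBootstrap",
         representation(tree = "ClusterTree", supports = "numeric",
                        B = "integer", seed = "integer"))

setValidity("PanBootstrap", function(object) {
  if (length(object@supports) != nrow(object@tree@merge))
    return("one support value per internal node")
  if (any(object@supports < 0 | object@supports > 100))
    return("supports must be percentages in [0, 100]")
  if (object@B < 1L) return("B must be >= 1")
  TRUE
})
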