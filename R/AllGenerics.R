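#' Number of genomes / families in a PanMatrix
#'
#' @param x a [PanMatrix-class].
#' @return integer count.
#' @export
setGeneric("nGenomes", function(x) standardGeneric("nGenomes"))

#' @rdname nGenomes
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))

#' Genome and family identifiers
#'
#' @param x a [PanMatrix-class] or [ClusterTree-class].
#' @return character vector of ids.
#' @export
setGeneric("genomeNames", function(x) standardGeneric("genomeNames"))

#' @rdname genomeNames
#' @export
setGeneric("familyNames", function(x) standardGeneric("familyNames"))

#' Per-family occupancy
#'
#' Occupancy of a gene family is the number of genomes in which it is
#' present, i.e. the column sum of the pan-matrix.
#'
#' @param x a [PanMatrix-class].
#' @return named integer vector, one entry per family.
#' @seealso [occupancySpectrum()]
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' Occupancy spectrum
#'
#' The number of gene families found in exactly 1, 2, ..., G genomes.
#' Families found in every genome are the \emph{core}, those in a majority
#' the \emph{shell}, those in a minority the \emph{cloud}; families in a
#' single genome are \emph{ORFans}.
#'
#' @param x a [PanMatrix-class].
#' @return named integer vector of length G; element `k` counts the
#'   families present in exactly `k` genomes. Sums to the number of
#'   families.
#' @export
setGeneric("occupancySpectrum", function(x) standardGeneric("occupancySpectrum"))

#' Convert a ClusterTree to an ape "phylo" object
#'
#' @param x a [ClusterTree-class].
#' @param supports optional numeric vector of per-internal-node supports
#'   (as in [PanBootstrap-class]); stored as `node.label`.
#' @return an [ape::read.tree()]-style `phylo` object with branch lengths.
#' @export
setGeneric("asPhylo", function(x, supports = NULL) standardGeneric("asPhylo"))

#' Serialise a ClusterTree to a Newick string
#'
#' Branch lengths are height differences; leaf branch lengths equal the
#' parent node height, so the tree is ultrametric. Bootstrap supports, if
#' supplied, are rendered as integer internal node labels. Labels
#' containing characters reserved by the Newick standard are single-quoted
#' (embedded quotes doubled).
#'
#' @param x a [ClusterTree-class] or [PanBootstrap-class].
#' @param supports optional numeric vector of supports aligned to internal
#'   nodes (ignored for `PanBootstrap`, which carries its own).
#' @param digits significant digits for branch lengths.
#' @return a single Newick string terminated by ";".
#' @export
setGeneric("toNewick",
           function(x, supports = NULL, digits = 10) standardGeneric("toNewick"))
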