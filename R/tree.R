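# Weighted relative Manhattan on a raw 0/1 matrix; used by distManhattan
# and by the bootstrap, where resampled columns may carry duplicate names.
.wmanhattan <- function(m, w) {
  W <- sum(w)
  mw <- sweep(m, 2L, w, `*`)
  cross <- tcrossprod(mw, m)
  rw <- rowSums(mw)
  one <- rep(1, length(rw))
  D <- (outer(rw, one) + outer(one, rw) - 2 * cross) / W
  D[D < 0] <- 0
  d <- as.dist(D)
  attr(d, "Labels") <- rownames(m)
  d
}

#' UPGMA hierarchical clustering
#'
#' Builds a rooted ultrametric tree by average linkage: repeatedly merge
#' the pair of clusters at minimum distance, setting the new node's height
#' to half the merge distance, and define the merged cluster's distance to
#' every other cluster as the size-weighted arithmetic mean of its parts'
#' distances (so it always equals the plain average over all leaf pairs —
#' the "unweighted" pair-group method). Ties in the minimum are broken
#' deterministically: each cluster is labelled by its smallest member
#' genome id, and among minimal pairs the one whose (smaller, larger)
#' label pair is lexicographically least is merged.
#'
#' @param D a [stats::dist] object or symmetric numeric matrix with genome
#'   labels; at least two genomes, all values finite and non-negative.
#' @return a [ClusterTree-class].
#' @examples
#' D <- as.dist(rbind(A = c(0, 0.2, 0.6), B = c(0.2, 0, 0.6),
#'                    C = c(0.6, 0.6, 0)))
#' attr(D, "Labels") <- c("A", "B", "C")
#' tr <- upgma(D)
#' toNewick(tr)  # "((A:0.1,B:0.1):0.2,C:0.3);"
#' @export
upgma <- function(D) {
  M <- as.matrix(D)
  labels <- rownames(M)
  if (is.null(labels)) labels <- paste0("g", seq_len(nrow(M)))
  G <- nrow(M)
  if (G < 2L) stop("need at least two genomes to build a tree")
  if (anyNA(M) || any(!is.finite(M))) stop("non-finite distances")
  if (any(M < 0)) stop("negative distances")

  code <- -seq_len(G)          # hclust convention: negative = leaf
  clab <- labels               # cluster label = smallest member genome id
  size <- rep(1L, G)
  dm <- M
  merge <- matrix(0L, G - 1L, 2L)
  height <- numeric(G - 1L)

  for (step in seq_len(G - 1L)) {
    n <- length(code)
    ut <- upper.tri(dm)
    dmin <- min(dm[ut])
    # distances within a relative 1e-12 of the minimum count as tied, so
    # that float noise in the running average cannot hide a genuine tie
    tol <- 1e-12 * max(1, dmin)
    cand <- which(dm <= dmin + tol & ut, arr.ind = TRUE)
    # byte-order ranks of cluster labels, for locale-independent ties
    rk <- match(clab, sort(clab, method = "radix"))
    lo <- pmin(rk[cand[, 1L]], rk[cand[, 2L]])
    hi <- pmax(rk[cand[, 1L]], rk[cand[, 2L]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    if (rk[j] < rk[i]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(code[i], code[j])
    height[step] <- dm[i, j] / 2

    newd <- (size[i] * dm[i, ] + size[j] * dm[j, ]) / (size[i] + size[j])
    dm[i, ] <- newd; dm[, i] <- newd; dm[i, i] <- 0
    code[i] <- step
    # after the swap clab[i] is the byte-smaller of the two labels
    size[i] <- size[i] + size[j]
    keep <- setdiff(seq_len(n), j)
    code <- code[keep]; clab <- clab[keep]; size <- size[keep]
    dm <- dm[keep, keep, drop = FALSE]
  }
  new("ClusterTree", merge = merge, height = height, labels = labels)
}

#' @describeIn genomeNames leaf labels of a ClusterTree
#' @export
setMethod("genomeNames", "ClusterTree", function(x) x@labels)

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree (UPGMA): %d leaves, root height %.4g\n",
              length(object@labels),
              object@height[length(object@height)]))
  cat("  ", toNewick(object), "\n", sep = "")
})

setMethod("show", "PanBootstrap", function(object) {
  cat(sprintf(
    "PanBootstrap: %d leaves, B = %d replicates (seed %d)\n",
    length(object@tree@labels), object@B, object@seed))
  cat(sprintf("  node supports: %s\n",
              paste(round(object@supports), collapse = " ")))
  cat("  ", toNewick(object), "\n", sep = "")
})

# leaf index sets for each internal node (row of merge), as a list
.nodeLeaves <- function(merge) {
  out <- vector("list", nrow(merge))
  for (r in seq_len(nrow(merge))) {
    kids <- merge[r, ]
    out[[r]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else out[[k]]))
  }
  out
}

# canonical key of an internal node: its two child leaf-label sets,
# each sorted, the pair sorted — used for bootstrap node matching
.nodeKeys <- function(tree) {
  merge <- tree@merge
  labels <- tree@labels
  leaves <- .nodeLeaves(merge)
  vapply(seq_len(nrow(merge)), function(r) {
    sides <- vapply(merge[r, ], function(k) {
      lv <- if (k < 0) labels[-k] else labels[leaves[[k]]]
      paste(sort(lv, method = "radix"), collapse = ",")
    }, character(1L))
    paste(sort(sides, method = "radix"), collapse = "|")
  }, character(1L))
}

.quoteNewick <- function(lab) {
  reserved <- grepl("[][():;,'\"\t\n ]", lab)
  lab[reserved] <- paste0("'", gsub("'", "''", lab[reserved]), "'")
  lab
}

#' @describeIn toNewick serialise a ClusterTree
#' @export
setMethod("toNewick", "ClusterTree", function(x, supports = NULL,
                                              digits = 10) {
  merge <- x@merge
  height <- x@height
  labs <- .quoteNewick(x@labels)
  fmt <- function(v) sprintf(paste0("%.", digits, "g"), v)
  if (!is.null(supports) && length(supports) != nrow(merge))
    stop("one support per internal node required")
  rec <- function(k, parentHeight) {
    if (k < 0)
      return(paste0(labs[-k], ":", fmt(parentHeight)))
    inner <- paste(rec(merge[k, 1L], height[k]),
                   rec(merge[k, 2L], height[k]), sep = ",")
    lab <- if (is.null(supports)) "" else
      sprintf("%d", as.integer(round(supports[k])))
    paste0("(", inner, ")", lab, ":", fmt(parentHeight - height[k]))
  }
  root <- nrow(merge)
  inner <- paste(rec(merge[root, 1L], height[root]),
                 rec(merge[root, 2L], height[root]), sep = ",")
  lab <- if (is.null(supports)) "" else
    sprintf("%d", as.integer(round(supports[root])))
  paste0("(", inner, ")", lab, ";")
})

#' @describeIn toNewick serialise a bootstrap result, supports as node labels
#' @export
setMethod("toNewick", "PanBootstrap", function(x, supports = NULL,
                                               digits = 10) {
  toNewick(x@tree, supports = x@supports, digits = digits)
})

#' @describeIn asPhylo via round-trip through the Newick writer
#' @export
setMethod("asPhylo", "ClusterTree", function(x, supports = NULL) {
  ape::read.tree(text = toNewick(x, supports = supports, digits = 15))
})

#' @describeIn asPhylo reference tree with its supports
#' @export
setMethod("asPhylo", "PanBootstrap", function(x, supports = NULL) {
  asPhylo(x@tree, supports = x@supports)
})

#' @export
#' @method as.hclust ClusterTree
as.hclust.ClusterTree <- function(x, ...) {
  leaves <- .nodeLeaves(x@merge)
  structure(list(merge = x@merge, height = x@height,
                 order = leaves[[nrow(x@merge)]],
                 labels = x@labels, method = "upgma"),
            class = "hclust")
}

#' Write a Newick file
#'
#' @param x a [ClusterTree-class] or [PanBootstrap-class].
#' @param path output file (conventionally `.nwk`).
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(x, path, digits = 10) {
  writeLines(toNewick(x, digits = digits), path)
  invisible(path)
}

# run code under a given seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bootstrap supports by resampling pan-matrix columns
#'
#' Builds the reference UPGMA tree from the weighted relative Manhattan
#' distances, then for each of B replicates draws n column indices
#' uniformly with replacement (n = number of families), carries each
#' sampled column's weight with it, recomputes the distances and the
#' UPGMA tree. The support of an internal node of the reference tree is
#' the percentage of replicate trees containing a node with the identical
#' two child leaf sets (a stricter criterion than matching the combined
#' clade only). A replicate whose resampled total weight is zero is drawn
#' again, up to 100 attempts.
#'
#' @param P a [PanMatrix-class] with at least two genomes.
#' @param w per-family weights ([makeWeights()]); `NULL` for uniform.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed; the whole run is reproducible given
#'   (P, w, B, seed). The caller's RNG state is left untouched.
#' @return a [PanBootstrap-class].
#' @export
bootstrapSupports <- function(P, w = NULL, B = 100, seed = 1) {
  stopifnot(is(P, "PanMatrix"), B >= 1)
  m <- as.matrix(P)
  if (nrow(m) < 2L) stop("need at least two genomes")
  n <- ncol(m)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("weight vector does not match pan-matrix columns")
  wv <- as.numeric(w)
  if (sum(wv) <= 0) stop("total weight W = 0")

  ref <- upgma(.wmanhattan(m, wv))
  refKeys <- .nodeKeys(ref)
  counts <- numeric(length(refKeys))
  # resample over id-sorted columns so that supports do not depend on the
  # column order of the pan-matrix
  ord <- order(colnames(m), method = "radix")

  .withSeed(seed, {
    for (b in seq_len(B)) {
      attempts <- 0L
      repeat {
        idx <- ord[sample.int(n, n, replace = TRUE)]
        if (sum(wv[idx]) > 0) break
        attempts <- attempts + 1L
        if (attempts >= 100L)
          stop("resampled total weight was 0 in 100 consecutive draws; ",
               "weights are too concentrated for bootstrapping")
      }
      rep_tree <- upgma(.wmanhattan(m[, idx, drop = FALSE], wv[idx]))
      counts <- counts + (refKeys %in% .nodeKeys(rep_tree))
    }
  })
  new("PanBootstrap", tree = ref, supports = counts / B * 100,
      B = as.integer(B), seed = as.integer(seed))
}
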