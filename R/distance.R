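#' Weighted relative Manhattan distance between pan-genome profiles
#'
#' The distance between genomes i and k is
#' \deqn{D(i,k) = \frac{1}{W} \sum_{j=1}^{n} w_j \, |M_{ij} - M_{kj}|,}
#' where the sum runs over the n gene families, \eqn{w_j} is a gene family
#' specific weight and \eqn{W = \sum_j w_j}. With uniform weights this is
#' the number of families present in exactly one of the two genomes
#' divided by the total number of families: the proportion of the
#' pan-genome in which the two genomes differ. Unlike the Jaccard
#' distance, families absent from both genomes (but present elsewhere in
#' the pan-genome) make the genomes \emph{more} similar — two genomes are
#' alike also by lacking the same genes.
#'
#' @param P a [PanMatrix-class].
#' @param w per-family weights from [makeWeights()], or any non-negative
#'   numeric vector aligned to `familyNames(P)` (names, when present, must
#'   match). `NULL` means uniform weights.
#' @return a [stats::dist] object over the genomes, values in `[0, 1]`.
#' @examples
#' m <- rbind(A = c(1, 1, 0), B = c(1, 0, 1))
#' colnames(m) <- c("F1", "F2", "F3")
#' distManhattan(PanMatrix(m))  # 2/3: two of three families differ
#' @export
distManhattan <- function(P, w = NULL) {
  stopifnot(is(P, "PanMatrix"))
  m <- as.matrix(P)
  if (is.null(w)) w <- rep(1, ncol(m))
  if (length(w) != ncol(m))
    stop("length of weight vector (", length(w),
         ") does not match number of families (", ncol(m), ")")
  if (!is.null(names(w)) && !identical(names(w), colnames(m)))
    stop("weight names do not match family ids of the pan-matrix")
  if (any(w < 0)) stop("negative weight")
  W <- sum(w)
  if (W <= 0) stop("total weight W = 0; the relative distance is undefined")
  mw <- sweep(m, 2L, w, `*`)
  cross <- tcrossprod(mw, m)            # sum_j w_j M_ij M_kj
  rw <- rowSums(mw)                     # sum_j w_j M_ij (binary M)
  D <- (outer(rw, rep(1, length(rw))) + outer(rep(1, length(rw)), rw) -
          2 * cross) / W
  D[D < 0] <- 0                         # numerical guard
  d <- as.dist(D)
  attr(d, "method") <- "weighted relative Manhattan"
  d
}

#' Jaccard distance between pan-genome profiles
#'
#' For genomes A and B let a be the number of families present in both,
#' b the number present only in A and c only in B; the Jaccard distance is
#' \eqn{1 - a/(a+b+c)}. It ignores shared absences and carries no weights;
#' it is provided for comparison with [distManhattan()].
#'
#' @param P a [PanMatrix-class].
#' @return a [stats::dist] object, values in `[0, 1]`.
#' @export
distJaccard <- function(P) {
  stopifnot(is(P, "PanMatrix"))
  m <- as.matrix(P)
  a <- tcrossprod(m)
  rs <- rowSums(m)
  union <- outer(rs, rep(1, length(rs))) +
    outer(rep(1, length(rs)), rs) - a
  if (any(as.dist(union) == 0))
    stop("a genome pair shares no present family with either member; ",
         "Jaccard distance undefined")
  D <- 1 - a / union
  diag(D) <- 0
  d <- as.dist(D)
  attr(d, "method") <- "Jaccard"
  d
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' [writeDistMatrix()] writes a square tab-separated matrix with genome
#' ids as header row and first column. [writeDistPhylip()] writes the
#' square PHYLIP format (leading line with the number of genomes, then one
#' row per genome: id followed by the distances).
#'
#' @param D a [stats::dist] object (as returned by the distance functions).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeDistMatrix <- function(D, path) {
  m <- as.matrix(D)
  tab <- data.frame(genome = rownames(m), m, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistMatrix
#' @export
writeDistPhylip <- function(D, path) {
  m <- as.matrix(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(sprintf("%-10s", rownames(m)[i]),
                       sprintf("%.8f", m[i, ])), collapse = " "), con)
  invisible(path)
}
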