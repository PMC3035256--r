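# Independent oracles and fixture builders shared by the test files.
# The oracles deliberately use brute-force formulations (per-pair loops,
# boolean transitive closure, from-scratch average linkage) so they share
# no code path with the package implementation.

# brute-force weighted relative Manhattan, one pair at a time
oracleManhattan <- function(m, w = rep(1, ncol(m))) {
  G <- nrow(m)
  D <- matrix(0, G, G, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(G)) for (k in seq_len(G))
    D[i, k] <- sum(w * abs(m[i, ] - m[k, ])) / sum(w)
  D
}

oracleJaccard <- function(m) {
  G <- nrow(m)
  D <- matrix(0, G, G, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(G)) for (k in seq_len(G)) {
    a <- sum(m[i, ] == 1 & m[k, ] == 1)
    b <- sum(m[i, ] == 1 & m[k, ] == 0)
    cc <- sum(m[i, ] == 0 & m[k, ] == 1)
    D[i, k] <- if (i == k) 0 else 1 - a / (a + b + cc)
  }
  D
}

# transitive closure of the pair relation by repeated boolean squaring
oracleComponents <- function(ids, pairs) {
  n <- length(ids)
  A <- diag(TRUE, n)
  dimnames(A) <- list(ids, ids)
  if (nrow(pairs) > 0L) {
    A[cbind(pairs$id1, pairs$id2)] <- TRUE
    A[cbind(pairs$id2, pairs$id1)] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  # canonical partition: sorted members, components sorted by first member
  comp <- apply(A, 1, function(row) paste(sort(ids[row]), collapse = ","))
  sort(unique(unname(comp)))
}

partitionOf <- function(families) {
  sort(unname(vapply(split(families$seqId, families$familyId),
                     function(x) paste(sort(x), collapse = ","),
                     character(1))))
}

# naive UPGMA: cluster distance recomputed from scratch at every step as
# the plain mean over all leaf pairs; same lexicographic tie-break rule
oracleUpgma <- function(M) {
  labels <- rownames(M)
  G <- nrow(M)
  clusters <- lapply(seq_len(G), identity)  # leaf index sets
  codes <- -seq_len(G)
  merge <- matrix(0L, G - 1L, 2L)
  height <- numeric(G - 1L)
  for (step in seq_len(G - 1L)) {
    n <- length(clusters)
    best <- NULL
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- mean(M[clusters[[i]], clusters[[j]]])
      li <- min(labels[clusters[[i]]])
      lj <- min(labels[clusters[[j]]])
      key <- c(min(li, lj), max(li, lj))
      tol <- 1e-12 * max(1, d)
      if (is.null(best) || d < best$d - tol ||
          (abs(d - best$d) <= tol &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(d = d, i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    if (min(labels[clusters[[j]]]) < min(labels[clusters[[i]]])) {
      tmp <- i; i <- j; j <- tmp
    }
    merge[step, ] <- c(codes[i], codes[j])
    height[step] <- best$d / 2
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    codes[i] <- step
    clusters[[j]] <- NULL
    codes <- codes[-j]
  }
  list(merge = merge, height = height, labels = labels)
}

# random binary matrix with every family present somewhere and every
# genome carrying at least one family
randomPanMatrix <- function(G, n, p = 0.5) {
  m <- matrix(rbinom(G * n, 1L, p), nrow = G)
  empty <- colSums(m) == 0
  if (any(empty)) m[cbind(sample.int(G, sum(empty), replace = TRUE),
                          which(empty))] <- 1L
  bare <- rowSums(m) == 0
  if (any(bare)) m[cbind(which(bare),
                         sample.int(n, sum(bare), replace = TRUE))] <- 1L
  rownames(m) <- sprintf("G%02d", seq_len(G))
  colnames(m) <- sprintf("F%04d", seq_len(n))
  m
}

makeCatalog <- function(seqIds, lengths, genomes) {
  data.frame(seqId = seqIds, length = as.integer(lengths),
             genomeId = genomes, stringsAsFactors = FALSE)
}

makeHits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(qseqid = r[[1]], sseqid = r[[2]],
               pident = as.numeric(r[[3]]), length = as.numeric(r[[4]]),
               evalue = as.numeric(r[[5]]), stringsAsFactors = FALSE)))
}

noPairs <- function() data.frame(id1 = character(), id2 = character(),
                                 stringsAsFactors = FALSE)

# planted family partition over a small multi-genome catalog
plantedFixture <- function() {
  catalog <- makeCatalog(
    sprintf("s%02d", 1:8),
    c(120, 100, 90, 200, 150, 80, 60, 110),
    c("gA", "gA", "gB", "gB", "gC", "gC", "gA", "gB"))
  families <- data.frame(
    familyId = c("F1", "F1", "F1", "F2", "F2", "F3", "F4", "F4"),
    seqId = catalog$seqId,
    genomeId = catalog$genomeId, stringsAsFactors = FALSE)
  list(catalog = catalog, families = families)
}
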