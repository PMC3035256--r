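test_that("BLAST tabular parsing filters on E-value and keeps file order", {
  f <- withr::local_tempfile()
  lines <- c(
    "A\tB\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-20\t200",
    "B\tA\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-3\t50",   # fails cutoff
    "A\tC\t60.0\t90\t36\t0\t1\t90\t1\t90\t1e-8\t120",
    "C\tA\t55.5\t85\t38\t0\t1\t85\t1\t85\t2e-2\t40",      # fails cutoff
    "C\tC\t100.0\t50\t0\t0\t1\t50\t1\t50\t0.0\t100")
  writeLines(lines, f)
  hits <- readBlastTabular(f, evalueCutoff = 1e-5)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$qseqid, c("A", "A", "C"))  # file order preserved
  expect_equal(hits$pident[1], 80.0)
  expect_equal(hits$length[1], 100)
  expect_equal(hits$evalue[1], 1e-20)
  # self-hits are retained at this stage
  expect_true(any(hits$qseqid == hits$sseqid))
})

test_that("malformed alignment lines are rejected with their line number", {
  f <- withr::local_tempfile()
  writeLines(c("A\tB\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-20\t200",
               "A\tB\tonly\tthree"), f)
  expect_error(readBlastTabular(f), "line 2")
  writeLines(c("A\tB\tNOTNUM\t100\t20\t0\t1\t100\t1\t100\t1e-20\t200"), f)
  expect_error(readBlastTabular(f), "line 1.*identity")
  # empty file is an empty hit table, not an error
  writeLines(character(0), f)
  expect_equal(nrow(readBlastTabular(f)), 0L)
  expect_error(readBlastTabular(file.path(tempdir(), "nope.tsv")),
               "no such")
})

test_that("extra trailing columns are tolerated", {
  f <- withr::local_tempfile()
  writeLines("A\tB\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-20\t200\textra\tcols", f)
  expect_equal(nrow(readBlastTabular(f)), 1L)
})

test_that("reciprocal 50/50 rule requires both directions to qualify", {
  catalog <- makeCatalog(c("A", "B", "C"), c(100, 300, 100),
                         c("g1", "g2", "g3"))
  # both directions pass
  hits <- makeHits(list("A", "B", 80, 90, 1e-20),
                   list("B", "A", 80, 270, 1e-20))
  expect_equal(reciprocalPairs(hits, catalog),
               data.frame(id1 = "A", id2 = "B"))
  # one direction missing -> no pair
  hits1 <- makeHits(list("A", "B", 80, 90, 1e-20))
  expect_equal(nrow(reciprocalPairs(hits1, catalog)), 0L)
  # coverage is relative to each direction's own query length:
  # A->B spans 60/100 of A (passes), B->A spans 60/300 of B (fails)
  hits2 <- makeHits(list("A", "B", 80, 60, 1e-20),
                    list("B", "A", 80, 60, 1e-20))
  expect_equal(nrow(reciprocalPairs(hits2, catalog)), 0L)
  # identity below 50% disqualifies even at full coverage
  hits3 <- makeHits(list("A", "C", 49.9, 100, 1e-30),
                    list("C", "A", 49.9, 100, 1e-30))
  expect_equal(nrow(reciprocalPairs(hits3, catalog)), 0L)
})

test_that("any single HSP can qualify a direction; self-hits never pair", {
  catalog <- makeCatalog(c("A", "B"), c(100, 100), c("g1", "g2"))
  hits <- makeHits(list("A", "B", 90, 20, 1e-30),   # too short
                   list("A", "B", 60, 80, 1e-30),   # qualifies
                   list("B", "A", 70, 55, 1e-30),
                   list("A", "A", 100, 100, 0))
  p <- reciprocalPairs(hits, catalog)
  expect_equal(p, data.frame(id1 = "A", id2 = "B"))
})

test_that("hits naming unknown sequences are an error naming the id", {
  catalog <- makeCatalog("A", 100, "g1")
  hits <- makeHits(list("A", "ZZZ", 90, 80, 1e-30))
  expect_error(reciprocalPairs(hits, catalog), "ZZZ")
  expect_error(
    buildFamilies(data.frame(id1 = "A", id2 = "QQQ"), catalog), "QQQ")
})

test_that("families are connected components, singletons included", {
  catalog <- makeCatalog(c("A", "B", "C"), c(10, 10, 10),
                         c("g1", "g1", "g2"))
  fam <- buildFamilies(data.frame(id1 = "A", id2 = "B"), catalog)
  expect_equal(partitionOf(fam), c("A,B", "C"))
  # transitive closure: A-B, B-C chain to one family
  fam2 <- buildFamilies(data.frame(id1 = c("A", "B"), id2 = c("B", "C")),
                        catalog)
  expect_equal(partitionOf(fam2), "A,B,C")
  # no pairs -> all singletons; partition property holds
  fam3 <- buildFamilies(noPairs(), catalog)
  expect_equal(partitionOf(fam3), c("A", "B", "C"))
  expect_equal(nrow(fam3), nrow(catalog))
  # deterministic zero-padded family ids ordered by smallest member
  expect_equal(unique(fam2$familyId), "F0001")
  expect_equal(sort(unique(fam$familyId)), c("F0001", "F0002"))
})

test_that("components match a brute-force transitive closure on random graphs", {
  set.seed(42)
  for (trial in 1:25) {
    nn <- sample(2:30, 1)
    ids <- sprintf("s%02d", seq_len(nn))
    catalog <- makeCatalog(ids, rep(50L, nn), rep("g1", nn))
    ne <- sample(0:nn, 1)
    pairs <- if (ne == 0) noPairs() else {
      e <- t(replicate(ne, sort(sample(ids, 2))))
      unique(data.frame(id1 = e[, 1], id2 = e[, 2],
                        stringsAsFactors = FALSE))
    }
    expect_equal(partitionOf(buildFamilies(pairs, catalog)),
                 oracleComponents(ids, pairs))
  }
})

test_that("hit and pair order do not change the resulting partition", {
  catalog <- makeCatalog(sprintf("s%d", 1:6), rep(100L, 6),
                         rep(c("g1", "g2"), 3))
  hits <- makeHits(list("s1", "s2", 80, 80, 1e-20),
                   list("s2", "s1", 80, 80, 1e-20),
                   list("s3", "s4", 80, 80, 1e-20),
                   list("s4", "s3", 80, 80, 1e-20),
                   list("s2", "s3", 80, 80, 1e-20),
                   list("s3", "s2", 80, 80, 1e-20))
  set.seed(7)
  base <- buildFamilies(reciprocalPairs(hits, catalog), catalog)
  for (r in 1:5) {
    hs <- hits[sample.int(nrow(hits)), , drop = FALSE]
    ps <- reciprocalPairs(hs, catalog)
    ps <- ps[sample.int(nrow(ps)), , drop = FALSE]
    shuffled <- buildFamilies(ps, catalog)
    expect_equal(partitionOf(shuffled), partitionOf(base))
    expect_identical(as.matrix(familiesToPanMatrix(shuffled)),
                     as.matrix(familiesToPanMatrix(base)))
  }
})

test_that("raising thresholds never merges families", {
  set.seed(11)
  nn <- 12
  ids <- sprintf("s%02d", seq_len(nn))
  catalog <- makeCatalog(ids, sample(50:200, nn, replace = TRUE),
                         rep("g1", nn))
  e <- t(combn(ids, 2))
  hits <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
    makeHits(list(e[i, 1], e[i, 2], runif(1, 30, 100),
                  sample(20:200, 1), 1e-20),
             list(e[i, 2], e[i, 1], runif(1, 30, 100),
                  sample(20:200, 1), 1e-20))
  }))
  loose <- buildFamilies(reciprocalPairs(hits, catalog, 0.3, 0.3), catalog)
  strict <- buildFamilies(reciprocalPairs(hits, catalog, 0.6, 0.6), catalog)
  # every strict family is contained in one loose family
  looseOf <- setNames(loose$familyId, loose$seqId)
  for (members in split(strict$seqId, strict$familyId))
    expect_length(unique(looseOf[members]), 1L)
  expect_gte(length(unique(strict$familyId)),
             length(unique(loose$familyId)))
})

test_that("pan-matrix from families is binary with ordered rows/columns", {
  catalog <- makeCatalog(c("a1", "a2", "b1", "b2", "c1"),
                         rep(100L, 5),
                         c("g1", "g1", "g2", "g2", "g3"))
  fam <- data.frame(
    familyId = c("F1", "F1", "F1", "F2", "F3"),
    seqId = c("a1", "a2", "b1", "b2", "c1"),   # paralogs a1,a2 in g1
    genomeId = c("g1", "g1", "g2", "g2", "g3"))
  P <- familiesToPanMatrix(fam)
  expect_identical(genomeNames(P), c("g1", "g2", "g3"))
  expect_identical(familyNames(P), c("F1", "F2", "F3"))
  expect_identical(as.vector(as.matrix(P)),
                   c(1L, 1L, 0L,   # F1: g1 (two paralogs -> still 1), g2
                     0L, 1L, 0L,   # F2: g2 only
                     0L, 0L, 1L))  # F3: g3 only
})

test_that("family table and pan-matrix round-trip through TSV", {
  fx <- plantedFixture()
  dir <- withr::local_tempdir()
  fp <- file.path(dir, "families.tsv")
  writeFamilyTable(fx$families, fp)
  tab <- read.delim(fp)
  expect_identical(names(tab), c("family_id", "seq_id", "genome_id"))
  expect_equal(nrow(tab), nrow(fx$families))
  P <- familiesToPanMatrix(fx$families)
  pp <- file.path(dir, "panmatrix.tsv")
  writePanMatrix(P, pp)
  expect_identical(as.matrix(readPanMatrix(pp)), as.matrix(P))
})

test_that("catalogs load from TSV and from per-genome FASTA files", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "catalog.tsv")
  writeSequenceCatalog(makeCatalog(c("x", "y"), c(10, 20), c("g1", "g2")),
                       tsv)
  cat1 <- readSequenceCatalog(tsv)
  expect_equal(cat1$length, c(10L, 20L))
  f1 <- file.path(dir, "gen1.faa")
  f2 <- file.path(dir, "gen2.faa")
  writeLines(c(">p1 some description", "MKV", ">p2", "MKVLAT"), f1)
  writeLines(c(">p3", "MML"), f2)
  cat2 <- catalogFromFasta(c(f1, f2))
  expect_equal(cat2$seqId, c("p1", "p2", "p3"))
  expect_equal(cat2$length, c(3L, 6L, 3L))
  expect_equal(cat2$genomeId, c("gen1", "gen1", "gen2"))
  # duplicate ids across genomes are rejected
  writeLines(c(">p1", "MWWW"), f2)
  expect_error(catalogFromFasta(c(f1, f2)), "duplicated")
})
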