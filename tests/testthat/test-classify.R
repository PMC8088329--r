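# Build a panel whose gene g0 contains chosen substrings of a read, so the
# matching window starts are controlled exactly.  Remaining genes are
# random decoys.
.craftPanel <- function(read, pieces, k) {
  g0 <- paste(pieces, collapse = strrep("A", 40))
  GenePanel(c(g0 = g0, decoy = randomDNA(300)))
}

test_that("shared-base accumulation matches the covered-base union", {
  set.seed(71)
  k <- 5L
  read <- randomDNA(40)
  # consecutive hits at starts 0 and 1: {0..4} u {1..5} = 6 bases
  panel <- .craftPanel(read, substr(read, 1, 6), k)
  idx <- buildIndex(panel, k = k, m = 2^20)
  cards <- sharedCounts(read, idx)
  expect_equal(unname(cards["g0"]),
               oracleSharedBases(read, as.character(panelSequences(panel))[1],
                                 k))
  expect_equal(unname(cards["g0"]), 6L)  # 5 + min(5, 1+5-5)

  # disjoint hits at starts 0 and 20: {0..4} u {20..24} = 10 bases
  read2 <- randomDNA(40)
  panel2 <- .craftPanel(read2, c(substr(read2, 1, 5), substr(read2, 21, 25)),
                        k)
  idx2 <- buildIndex(panel2, k = k, m = 2^20)
  got <- unname(sharedCounts(read2, idx2)["g0"])
  oracle <- oracleSharedBases(read2,
                              as.character(panelSequences(panel2))[1], k)
  expect_equal(got, oracle)
  expect_gte(got, 10L)  # at least the two crafted windows

  # first hit from the -1 sentinel contributes exactly k bases
  read3 <- randomDNA(30)
  panel3 <- .craftPanel(read3, substr(read3, 11, 15), k)
  idx3 <- buildIndex(panel3, k = k, m = 2^20)
  expect_equal(unname(sharedCounts(read3, idx3)["g0"]),
               oracleSharedBases(read3,
                                 as.character(panelSequences(panel3))[1], k))
})

test_that("shared counts equal the brute-force union on random panels", {
  set.seed(81)
  for (rep in 1:15) {
    k <- sample(5:13, 1)
    panel <- randomPanel(sample(2:6, 1), c(80L, 300L))
    idx <- buildIndex(panel, k = k, m = 2^22)
    # half the reads are substrings of panel genes, half random
    gseq <- as.character(panelSequences(panel))
    src <- gseq[sample(length(gseq), 1)]
    a <- sample(nchar(src) - 60, 1)
    reads <- c(substr(src, a, a + 59), randomDNA(60))
    for (rd in reads) {
      cards <- sharedCounts(rd, idx)
      for (g in seq_along(gseq)) {
        expected <- oracleSharedBases(rd, gseq[g], k)
        got <- cards[geneNames(panel)[g]]
        expect_equal(if (is.na(got)) 0L else unname(got), expected)
      }
    }
  }
})

test_that("cards never exceed read length and respect quality masking", {
  set.seed(91)
  panel <- randomPanel(3L, c(200L, 400L))
  idx <- buildIndex(panel, k = 7, m = 2^20)
  src <- as.character(panelSequences(panel))[1]
  rd <- substr(src, 10, 69)
  quals <- sample(5:40, 60, replace = TRUE)
  for (q in c(0L, 10L, 20L)) {
    cards <- sharedCounts(rd, idx, quals = quals, q = q)
    expect_true(all(cards <= 60))
    got <- cards[geneNames(panel)[1]]
    expect_equal(if (is.na(got)) 0L else unname(got),
                 oracleSharedBases(rd, src, 7, quals, q))
  }
  # monotone in q: raising q can only remove windows
  cardAt <- vapply(c(0L, 10L, 20L), function(q) {
    x <- sharedCounts(rd, idx, quals = quals, q = q)[geneNames(panel)[1]]
    if (is.na(x)) 0L else unname(x)
  }, integer(1))
  expect_true(all(diff(cardAt) <= 0))
})

test_that("assignment follows the max-card + threshold criterion", {
  # tie at the threshold: multiple keeps both, single drops the read
  expect_equal(assignRead(c(A = 60, B = 60), 100, tau = 0.6),
               c(A = 60L, B = 60L))
  expect_equal(assignRead(c(A = 60, B = 60), 100, tau = 0.6,
                          mode = "single"), integer(0))
  # strict maximum wins in both modes
  expect_equal(assignRead(c(A = 60, B = 70), 100, tau = 0.6),
               c(B = 70L))
  expect_equal(assignRead(c(A = 60, B = 70), 100, tau = 0.6,
                          mode = "single"), c(B = 70L))
  # below threshold: no assignment
  expect_equal(assignRead(c(A = 59), 100, tau = 0.6), integer(0))
  # only maximal-card genes qualify even when others pass tau
  expect_equal(assignRead(c(A = 70, B = 50), 100, tau = 0.6), c(A = 70L))
  # empty map
  expect_equal(assignRead(integer(0), 100), integer(0))
})

test_that("classifySample handles empty input and exact substrings", {
  panel <- randomPanel(3L, c(300L, 500L))
  idx <- buildIndex(panel, k = 9, m = 2^20)
  empty <- Biostrings::DNAStringSet(character(0))
  a0 <- classifySample(empty, idx)
  expect_equal(nrow(a0), 0L)
  expect_equal(attr(a0, "n_reads"), 0L)

  # an error-free exact substring of one gene is assigned with card = |s|
  src <- as.character(panelSequences(panel))[2]
  rd <- Biostrings::DNAStringSet(setNames(substr(src, 50, 149), "r1"))
  a <- classifySample(rd, idx, tau = 1, q = 0)
  expect_equal(a$gene_name, geneNames(panel)[2])
  expect_equal(a$shared_bases, 100L)
  expect_equal(a$ratio, 1)

  # a read shorter than k has no windows and is never assigned
  short <- Biostrings::DNAStringSet(setNames("ACGTAC", "tiny"))
  aShort <- classifySample(short, idx, tau = 0.1)
  expect_equal(nrow(aShort), 0L)
  expect_equal(attr(aShort, "n_reads"), 1L)
})

test_that("classification is deterministic and batch-count independent", {
  sc <- smallScenario()
  idx <- buildIndex(sc$panel, k = 17, m = 2^22)
  a1 <- classifySample(sc$reads, idx, threads = 1L)
  a4 <- classifySample(sc$reads, idx, threads = 4L)
  expect_identical(a1, a4)
  expect_identical(a1, classifySample(sc$reads, idx, threads = 1L))
  # byte-identical on disk
  f1 <- tempfile(); f4 <- tempfile()
  writeAssignments(a1, f1); writeAssignments(a4, f4)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f4, "raw", file.size(f4)))
})

test_that("assignment sets shrink as tau rises and as q rises", {
  sc <- smallScenario()
  idx <- buildIndex(sc$panel, k = 17, m = 2^22)
  keySets <- lapply(c(0.2, 0.4, 0.6, 0.8), function(tau) {
    a <- classifySample(sc$reads, idx, tau = tau, q = 10)
    paste(a$read_id, a$gene_name)
  })
  for (i in 2:4) expect_true(all(keySets[[i]] %in% keySets[[i - 1]]))

  # q monotonicity at the per-association level: cards non-increasing
  byQ <- lapply(c(0L, 10L, 20L), function(q) {
    a <- classifySample(sc$reads, idx, tau = 0.2, q = q)
    setNames(a$shared_bases, paste(a$read_id, a$gene_name))
  })
  for (i in 2:3) {
    common <- intersect(names(byQ[[i]]), names(byQ[[1]]))
    expect_true(all(byQ[[i]][common] <= byQ[[1]][common]))
  }
})

test_that("single mode only drops multi-candidate reads", {
  sc <- smallScenario()
  idx <- buildIndex(sc$panel, k = 17, m = 2^22)
  aM <- classifySample(sc$reads, idx, tau = 0.4)
  aS <- classifySample(sc$reads, idx, tau = 0.4, mode = "single")
  # single-mode rows are exactly the multiple-mode rows of unambiguous reads
  tab <- table(aM$read_id)
  unamb <- names(tab)[tab == 1L]
  expect_equal(aS[, c("read_id", "gene_name")],
               aM[aM$read_id %in% unamb, c("read_id", "gene_name")],
               ignore_attr = TRUE)
})
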