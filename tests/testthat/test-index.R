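test_that("gene panels enforce names, uniqueness and non-empty sequences", {
  p <- GenePanel(c(a = "ACGT", b = "GGTT"))
  expect_equal(length(p), 2L)
  expect_equal(geneNames(p), c("a", "b"))
  expect_equal(geneIdMap(p), c(a = 0L, b = 1L))
  expect_error(GenePanel(c(a = "ACGT", a = "GGTT")), "duplicate")
  expect_error(GenePanel(c(a = "ACGT", b = "")), "non-empty")
  expect_error(GenePanel(setNames("ACGT", "")), "named")
})

test_that("a single-gene index maps every k-mer to gene 0", {
  idx <- buildIndex(GenePanel(c(g0 = "ACGTAC")), k = 4, m = 2^20)
  expect_lte(idx@onesCount, 3)  # 3 windows, canonical collisions possible
  expect_true(all(idx@geneIds == 0L))
  # P is all 1s: every segment has length 1
  expect_equal(.cpp_popcount(idx@boundary, length(idx@geneIds)),
               length(idx@geneIds))
  for (w in oracleWindows("ACGTAC", 4))
    expect_equal(queryKmer(idx, w)[[1]], 0L)
})

test_that("a shared canonical k-mer produces the merged segment [0, 1]", {
  # revcomp pair: canonical("GTTTT") == canonical("AAAAC") == "AAAAC"
  idx <- buildIndex(GenePanel(c(g0 = "AAAAC", g1 = "GTTTT")), k = 5,
                    m = 2^20)
  expect_equal(idx@onesCount, 1)
  expect_equal(queryKmer(idx, "AAAAC")[[1]], c(0L, 1L))
  expect_equal(queryKmer(idx, "GTTTT")[[1]], c(0L, 1L))

  # the near-miss pair: "TAAAA" is canonical itself (revcomp "TTTTA"),
  # so these two genes do NOT share a canonical k-mer
  oracle2 <- buildExactOracle(GenePanel(c(g0 = "AAAAC", g1 = "TAAAA")), 5)
  expect_equal(oracle2, list(AAAAC = 0L, TAAAA = 1L))
})

test_that("construction bookkeeping: one non-empty segment per set bit", {
  set.seed(21)
  for (rep in 1:5) {
    panel <- randomPanel(sample(2:8, 1), c(50L, 400L))
    idx <- buildIndex(panel, k = 9, m = 2^18)
    nI <- length(idx@geneIds)
    expect_equal(.cpp_popcount(idx@boundary, nI), idx@onesCount)
    expect_true(.cpp_select1(idx@boundary, nI, idx@onesCount) == nI)
    # segments recovered via P concatenate back to I exactly
    ends <- vapply(seq_len(idx@onesCount),
                   function(j) .cpp_select1(idx@boundary, nI, j), 0)
    starts <- c(1, head(ends, -1) + 1)
    segs <- mapply(function(a, b) idx@geneIds[a:b], starts, ends,
                   SIMPLIFY = FALSE)
    expect_equal(unlist(segs), idx@geneIds, ignore_attr = TRUE)
    # within each segment gene IDs are strictly increasing
    expect_true(all(vapply(segs, function(v) all(diff(v) > 0) || length(v) == 1L,
                           logical(1))))
  }
})

test_that("query equals the exact-dictionary oracle when no bits collide", {
  set.seed(31)
  panel <- randomPanel(10L, c(300L, 900L))
  k <- 11L
  idx <- buildIndex(panel, k = k, m = 2^22)
  oracle <- buildExactOracle(panel, k)
  pos <- hashKmer(names(oracle), 2^22)
  res <- queryKmer(idx, names(oracle))
  collides <- pos %in% pos[duplicated(pos)]
  # collision-free k-mers (the vast majority at this m) answer exactly
  expect_gt(sum(!collides), 0.99 * length(oracle))
  expect_equal(res[!collides], oracle[!collides], ignore_attr = TRUE)
  # colliding k-mers answer the union of the colliding gene sets
  for (i in which(collides)) {
    expected <- sort(unique(unlist(oracle[pos == pos[i]])))
    expect_equal(res[[i]], expected)
  }
  # absent k-mer with clear Bloom bit is a definitive negative
  absent <- setdiff(canonicalKmer(vapply(rep(k, 50), randomDNA,
                                         character(1))), names(oracle))
  hits <- queryKmer(idx, absent)
  bitSet <- vapply(hashKmer(absent, 2^22) + 1,
                   function(p) bitRank1(idx@bloom, p + 1, idx@m) -
                     bitRank1(idx@bloom, p, idx@m) == 1, logical(1))
  expect_true(all(lengths(hits)[!bitSet] == 0L))
})

test_that("colliding k-mers return the union of their gene sets", {
  set.seed(41)
  panel <- randomPanel(6L, c(100L, 300L))
  k <- 9L
  m <- 64  # tiny filter forces collisions
  idx <- buildIndex(panel, k = k, m = m)
  oracle <- buildExactOracle(panel, k)
  pos <- hashKmer(names(oracle), m)
  expect_true(anyDuplicated(pos) > 0)
  res <- queryKmer(idx, names(oracle))
  for (i in seq_along(oracle)) {
    expected <- sort(unique(unlist(oracle[pos == pos[i]])))
    expect_equal(res[[names(oracle)[i]]], expected)
  }
})

test_that("no false negatives: every true gene appears in every query", {
  set.seed(51)
  for (m in c(128, 2^12, 2^20)) {
    panel <- randomPanel(5L, c(100L, 400L))
    idx <- buildIndex(panel, k = 8, m = m)
    oracle <- buildExactOracle(panel, 8)
    res <- queryKmer(idx, names(oracle))
    expect_true(all(mapply(function(q, o) all(o %in% q), res, oracle)))
  }
})

test_that("rank and select follow the B[1,i) convention and round-trip", {
  set.seed(61)
  for (rep in 1:10) {
    bits <- runif(sample(10:200, 1)) < 0.3
    n <- length(bits)
    # rank1(B, i) counts ones strictly before 1-based position i
    for (i in sample(seq_len(n + 1), min(n + 1, 12))) {
      expect_equal(bitRank1(bits, i), sum(bits[seq_len(i - 1)]))
    }
    ones <- which(bits)
    for (j in seq_along(ones)) {
      expect_equal(bitSelect1(bits, j), ones[j])
      # select of (rank + 1) at a set position returns that position
      expect_equal(bitSelect1(bits, bitRank1(bits, ones[j]) + 1), ones[j])
    }
    if (length(ones) > 0)
      expect_error(bitSelect1(bits, length(ones) + 1), "fewer")
  }
})

test_that("rank/select round-trips on the Bloom filter itself", {
  panel <- randomPanel(4L, c(200L, 500L))
  idx <- buildIndex(panel, k = 10, m = 2^16)
  for (j in seq_len(min(idx@onesCount, 25))) {
    p <- bitSelect1(idx@bloom, j, nbits = idx@m)
    expect_equal(bitRank1(idx@bloom, p, nbits = idx@m) + 1, j)
  }
})

test_that("parameter and input errors are reported", {
  panel <- randomPanel(2L, c(60L, 80L))
  expect_error(buildIndex(panel, k = 33, m = 2^10), "\\[1, 32\\]")
  expect_error(buildIndex(panel, k = 8, m = 0), "m must be")
  expect_warning(buildIndex(GenePanel(c(a = "ACG", b = randomDNA(100))),
                            k = 10, m = 2^10), "shorter than k")
  idx <- buildIndex(panel, k = 8, m = 2^10)
  expect_error(queryKmer(idx, "ACGTACGTACGT"), "does not match index k")
})

test_that("save/load round-trips bit-exactly and rejects damaged files", {
  panel <- randomPanel(7L, c(100L, 500L))
  idx <- buildIndex(panel, k = 9, m = 2^18)
  path <- tempfile(fileext = ".idx")
  saveIndex(idx, path)
  idx2 <- loadIndex(path)
  expect_identical(idx2@bloom, idx@bloom)
  expect_identical(idx2@boundary, idx@boundary)
  expect_identical(idx2@geneIds, idx@geneIds)
  expect_identical(idx2@geneNames, idx@geneNames)
  oracle <- buildExactOracle(panel, 9)
  expect_identical(queryKmer(idx2, names(oracle)),
                   queryKmer(idx, names(oracle)))

  # truncation is a format error
  bytes <- readBin(path, "raw", file.size(path))
  trunc <- tempfile(fileext = ".idx")
  writeBin(bytes[seq_len(length(bytes) - 50L)], trunc)
  expect_error(loadIndex(trunc), "truncated")
  # wrong magic is a format error
  bad <- tempfile(fileext = ".idx")
  writeBin(c(charToRaw("XXXXXXXX"), bytes[-(1:8)]), bad)
  expect_error(loadIndex(bad), "magic")
})
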