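test_that("window grids follow the full-window convention", {
  w <- iterWindows(100000, 50000, 12500)
  expect_equal(nrow(w), 5)
  expect_equal(w$start[1], 1)
  expect_equal(w$end[1], 50000)
  expect_equal(w$start[5], 50001)
  expect_equal(w$end[5], 100000)

  expect_equal(nrow(iterWindows(50000, 50000, 12500)), 1)
  # tail shorter than one window is dropped
  expect_equal(nrow(iterWindows(59999, 50000, 12500)), 1)
  expect_warning(w2 <- iterWindows(30000, 50000, 12500), "shorter")
  expect_equal(w2, data.frame(start = 1L, end = 30000L))
  expect_error(iterWindows(1000, 100, 200), "step")
})

test_that("nucleotide diversity matches hand-worked examples", {
  # 2 identical sequences
  a <- makeAln(list(c(0L, 0L), c(0L, 0L)), genomeLength = 10)
  expect_equal(nucleotideDiversity(a), 0)
  # 2 sequences differing at 2 of 10 sites
  b <- makeAln(list(c(0L, 0L), c(1L, 1L)), genomeLength = 10)
  expect_equal(nucleotideDiversity(b), 0.2)
  # 4 sequences, 3 singletons in a window of 100: mean pairwise 1.5
  g <- rbind(s1 = c(1L, 0L, 0L), s2 = c(0L, 1L, 0L),
             s3 = c(0L, 0L, 1L), s4 = c(0L, 0L, 0L))
  d <- makeAln(list(g[1, ], g[2, ], g[3, ], g[4, ]), genomeLength = 100)
  expect_equal(nucleotideDiversity(d, end = 100), 0.015)
  expect_equal(nucleotideDiversity(d, end = 100),
               oraclePi(d, sampleIds(d), 1, 100))
  expect_warning(p1 <- nucleotideDiversity(subsetSamples(d, "s1")), "<2")
  expect_true(is.nan(p1))
})

test_that("Tajima's D reproduces the singleton micro-fixture and NaN contracts", {
  g <- rbind(s1 = c(1L, 0L, 0L), s2 = c(0L, 1L, 0L),
             s3 = c(0L, 0L, 1L), s4 = c(0L, 0L, 0L))
  a <- makeAln(lapply(seq_len(4), function(i) g[i, ]), genomeLength = 100)
  D <- tajimasD(a, end = 100)
  expect_equal(D, -0.754, tolerance = 1e-3)
  expect_equal(D, oracleTajimaD(a, sampleIds(a), 1, 100), tolerance = 1e-12)

  mono <- makeAln(list(c(0L, 0L), c(0L, 0L), c(0L, 0L)), genomeLength = 50)
  expect_true(is.nan(tajimasD(mono)))          # S = 0
  expect_true(is.nan(tajimasD(a, c("s1", "s2"))))  # n < 3
})

test_that("core statistics equal the brute-force oracle on random fixtures", {
  set.seed(20240917)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    aln <- randomAln(n, 60, genomeLength = 200,
                     pMissing = sample(c(0, 0.15), 1))
    ids <- sampleIds(aln)
    expect_equal(nucleotideDiversity(aln), oraclePi(aln, ids, 1, 200),
                 tolerance = 1e-12)
    expect_equal(segregatingSites(aln), oracleS(aln, ids, 1, 200))
    if (segregatingSites(aln) > 0)
      expect_equal(tajimasD(aln), oracleTajimaD(aln, ids, 1, 200),
                   tolerance = 1e-12)
    sa <- ids[1:floor(n / 2)]; sb <- ids[(floor(n / 2) + 1):n]
    expect_equal(dxy(aln, sa, sb), oracleDxy(aln, sa, sb, 1, 200),
                 tolerance = 1e-12)
    if (length(sa) >= 2 && length(sb) >= 2) {
      got <- suppressWarnings(fstHudson(aln, sa, sb))
      want <- oracleFst(aln, sa, sb, 1, 200)
      if (is.nan(want)) expect_true(is.nan(got))
      else expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("Fu's F(S) agrees with the exhaustive Ewens oracle at n = 4", {
  # 4 distinct haplotypes, pihat = 1.5 (the singleton fixture)
  g <- rbind(s1 = c(1L, 0L, 0L), s2 = c(0L, 1L, 0L),
             s3 = c(0L, 0L, 1L), s4 = c(0L, 0L, 0L))
  a <- makeAln(lapply(seq_len(4), function(i) g[i, ]), genomeLength = 100)
  fs <- fusF(a, end = 100)
  pk <- oracleEwensPK(4, 1.5)
  sp <- pk[4]  # P(K >= 4)
  expect_equal(fs, log(sp / (1 - sp)), tolerance = 1e-10)
  expect_equal(sum(pk), 1, tolerance = 1e-12)

  # all identical: undefined
  mono <- makeAln(list(c(0L), c(0L), c(0L)), genomeLength = 10)
  expect_true(is.nan(fusF(mono)))
  # Fu & Li's F* is finite on the fixture
  expect_true(is.finite(fusF(a, end = 100, type = "Fstar")))
})

test_that("D_XY matches examples and reduces to pooled pi when A = B", {
  # two monomorphic lineages differing at 3 of 10 sites
  g <- rbind(a1 = c(0L, 0L, 0L), a2 = c(0L, 0L, 0L),
             b1 = c(1L, 1L, 1L), b2 = c(1L, 1L, 1L))
  aln <- makeAln(g, genomeLength = 10)
  expect_equal(dxy(aln, c("a1", "a2"), c("b1", "b2")), 0.3)
  expect_error(dxy(aln, character(), "b1"), "at least one")

  set.seed(5)
  r <- randomAln(6, 30)
  ids <- sampleIds(r)
  # same content both sides: every cross pair enumerated by the oracle
  expect_equal(dxy(r, ids, ids), oracleDxy(r, ids, ids, 1, 200),
               tolerance = 1e-12)
  # H_b >= 0 always
  expect_true(dxy(r, ids[1:3], ids[4:6]) >= 0)
})

test_that("Hudson's F_ST matches brute force and honors NaN contracts", {
  # fixed difference, no within variation
  g <- rbind(a1 = 0L, a2 = 0L, b1 = 1L, b2 = 1L)
  aln <- makeAln(g, genomeLength = 1)
  expect_equal(fstHudson(aln, c("a1", "a2"), c("b1", "b2")), 1)

  # identical monomorphic lineages: H_b = 0 -> NaN
  mono <- makeAln(matrix(0L, 4, 1, dimnames = list(c("a1", "a2", "b1", "b2"),
                                                   NULL)), genomeLength = 5)
  expect_true(is.nan(fstHudson(mono, c("a1", "a2"), c("b1", "b2"))))

  # A = (A,A,A,T), B = (T,T,T,A) at one site: enumerated oracle
  g2 <- rbind(a1 = 0L, a2 = 0L, a3 = 0L, a4 = 1L,
              b1 = 1L, b2 = 1L, b3 = 1L, b4 = 0L)
  aln2 <- makeAln(g2, genomeLength = 1)
  A <- paste0("a", 1:4); B <- paste0("b", 1:4)
  expect_equal(fstHudson(aln2, A, B), oracleFst(aln2, A, B, 1, 1),
               tolerance = 1e-12)
  # symmetry
  expect_equal(fstHudson(aln2, A, B), fstHudson(aln2, B, A))
  expect_equal(dxy(aln2, A, B), dxy(aln2, B, A))
  expect_warning(f <- fstHudson(aln2, "a1", B), ">= 2")
  expect_true(is.nan(f))
})

test_that("monomorphic sites leave all statistics unchanged", {
  set.seed(9)
  aln <- randomAln(6, 40)
  ids <- sampleIds(aln)
  # append a monomorphic column
  g2 <- cbind(genotypes(aln), rep(0L, 6))
  newPos <- setdiff(seq_len(200), snpPositions(aln))[1]
  pos2 <- c(snpPositions(aln), newPos)
  o <- order(pos2)
  aln2 <- SnpAlignment(g2[, o], pos2[o], c(refAlleles(aln), "A")[o],
                       c(altAlleles(aln), "G")[o], 200L)
  expect_equal(nucleotideDiversity(aln2), nucleotideDiversity(aln))
  expect_equal(segregatingSites(aln2), segregatingSites(aln))
  expect_equal(tajimasD(aln2), tajimasD(aln))
  expect_equal(dxy(aln2, ids[1:3], ids[4:6]), dxy(aln, ids[1:3], ids[4:6]))
})
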