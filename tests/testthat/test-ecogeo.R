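test_that("great-circle distances match analytic values", {
  meta <- data.frame(sample_id = c("o", "q", "anti", "dup"),
                     latitude = c(0, 0, 0, 0),
                     longitude = c(0, 90, 180, 0))
  d <- geoDistanceMatrix(meta)
  expect_equal(d["o", "o"], 0)
  expect_equal(d["o", "dup"], 0)
  expect_equal(d["o", "q"], pi / 2 * 6371.0088, tolerance = 1e-9)
  expect_equal(d["o", "anti"], pi * 6371.0088, tolerance = 1e-9)
  expect_error(geoDistanceMatrix(data.frame(sample_id = "x", latitude = 99,
                                            longitude = 0)), "range")
})

test_that("great-circle distances satisfy the triangle inequality", {
  set.seed(15)
  for (i in 1:20) {
    meta <- data.frame(sample_id = c("a", "b", "c"),
                       latitude = runif(3, -90, 90),
                       longitude = runif(3, -180, 180))
    d <- geoDistanceMatrix(meta)
    expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-9)
  }
})

test_that("Mantel test recovers perfect correlation and is seed-stable", {
  set.seed(3)
  m <- matrix(runif(100), 10)
  d1 <- as.matrix(dist(m))
  dimnames(d1) <- list(paste0("s", 1:10), paste0("s", 1:10))
  d2 <- 2 * d1
  set.seed(42)
  r <- mantelTest(d1, d2, nPerm = 999)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 1000)  # minimum attainable p

  set.seed(42); p1 <- mantelTest(d1, d2, nPerm = 199)$p
  set.seed(42); p2 <- mantelTest(d1, d2, nPerm = 199)$p
  expect_identical(p1, p2)

  u1 <- d1; u2 <- d2[1:5, 1:5]
  dimnames(u1) <- dimnames(u2) <- NULL
  expect_error(mantelTest(u1, u2, nPerm = 99), "differ in size")
  expect_error(mantelTest(d1, d2, nPerm = 10), "nPerm")
})

test_that("Mantel r equals vegan's statistic (independent cross-check)", {
  skip_if_not_installed("vegan")
  set.seed(8)
  m <- matrix(rnorm(60), 12)
  d1 <- as.matrix(dist(m))
  d2 <- as.matrix(dist(m + rnorm(60)))
  dimnames(d1) <- dimnames(d2) <- list(paste0("s", 1:12), paste0("s", 1:12))
  ours <- mantelTest(d1, d2, nPerm = 99)
  veg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
})

test_that("Mantel p-values are uniform under the null", {
  set.seed(77)
  ps <- replicate(60, {
    a <- as.matrix(dist(rnorm(12))); b <- as.matrix(dist(rnorm(12)))
    mantelTest(a, b, nPerm = 99)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Blomberg's K is exactly 1 on a star tree and detects structure", {
  tr <- ape::stree(16, "star")
  tr$edge.length <- rep(1, 16)
  set.seed(4)
  x <- setNames(rnorm(16), tr$tip.label)
  k <- blombergK(tr, x, nPerm = 99)
  expect_equal(k$K, 1, tolerance = 1e-10)

  # shuffled traits on a deep tree: K < 1 almost always
  set.seed(10)
  deep <- ape::rcoal(32)
  below <- replicate(20, {
    xs <- setNames(sample(ape::rTraitCont(deep)), deep$tip.label)
    blombergK(deep, xs, nPerm = 99)$K < 1
  })
  expect_gte(mean(below), 0.95)
  expect_warning(kc <- blombergK(tr, setNames(rep(1, 16), tr$tip.label)),
                 "zero")
  expect_true(is.nan(kc$K))
})

test_that("Brownian traits give K near 1 and lambda near 1; noise gives low lambda", {
  set.seed(12)
  ks <- replicate(25, {
    tr <- ape::rcoal(48)
    x <- ape::rTraitCont(tr)
    blombergK(tr, x, nPerm = 99)$K
  })
  expect_lt(abs(mean(ks) - 1), 3 * sd(ks) / sqrt(length(ks)))

  set.seed(13)
  tr <- ape::rcoal(48)
  lamNoise <- replicate(20, pagelLambda(tr, setNames(rnorm(48),
                                                     tr$tip.label))$lambda)
  expect_lte(median(lamNoise), 0.1)
  lamBM <- replicate(20, pagelLambda(tr, ape::rTraitCont(tr))$lambda)
  expect_gte(mean(lamBM >= 0.9), 0.8)

  # location invariance
  x <- ape::rTraitCont(tr)
  expect_equal(pagelLambda(tr, x)$lambda, pagelLambda(tr, x + 100)$lambda,
               tolerance = 1e-4)
})

test_that("Kruskal-Wallis matches the rank formula and rank invariance", {
  r <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$H, 3.857142857, tolerance = 1e-9)
  expect_equal(r$H, oracleKwH(list(c(1, 2, 3), c(4, 5, 6))),
               tolerance = 1e-12)

  same <- kruskalWallis(list(c(2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  # invariant to strictly monotone transforms
  g1 <- list(rnorm(5), rnorm(5) + 1)
  expect_equal(kruskalWallis(g1)$H,
               kruskalWallis(lapply(g1, function(v) exp(v)))$H,
               tolerance = 1e-12)
  expect_error(kruskalWallis(list(1:3)), ">= 2")
})

test_that("Dunn's test matches the z formula with Bonferroni monotonicity", {
  v <- c(1, 2, 3, 4, 10, 11, 12, 13, 30, 31, 32, 33)
  g <- rep(c("A", "B", "C"), each = 4)
  d <- dunnPosthoc(v, g)
  # independent formula evaluation
  N <- 12; rk <- rank(v)
  mr <- tapply(rk, g, mean)
  se <- sqrt((N * (N + 1) / 12) * (1 / 4 + 1 / 4))
  zAC <- (mr[["A"]] - mr[["C"]]) / se
  expect_equal(d$z[d$groupA == "A" & d$groupB == "C"], zAC,
               tolerance = 1e-12)
  # the extreme pair carries the smallest adjusted p
  expect_equal(paste(d$groupA[which.min(d$p_adj)],
                     d$groupB[which.min(d$p_adj)]), "A C")
  expect_true(all(d$p_adj >= d$p))

  same <- dunnPosthoc(rep(1, 6), rep(c("A", "B"), each = 3))
  expect_true(all(same$p_adj == 1))
})

test_that("ANI clustering is single-linkage with the conventional threshold", {
  ids <- c("a1", "a2", "b1", "b2")
  v <- matrix(90, 4, 4, dimnames = list(ids, ids))
  v[1:2, 1:2] <- 97; v[3:4, 3:4] <- 97; diag(v) <- 100
  cl <- aniCluster(AniMatrix(v), 95)
  expect_equal(length(unique(cl)), 2)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_false(cl[["a1"]] == cl[["b1"]])

  # chain a-b 96, b-c 96, a-c 90: one cluster by single linkage
  ids3 <- c("a", "b", "c")
  w <- matrix(c(100, 96, 90, 96, 100, 96, 90, 96, 100), 3,
              dimnames = list(ids3, ids3))
  expect_equal(length(unique(aniCluster(AniMatrix(w), 95))), 1)
  # extreme threshold: every sample its own cluster
  expect_equal(length(unique(aniCluster(AniMatrix(w), 99.9))), 3)
  expect_error(aniCluster(AniMatrix(w), 0), "threshold")
})

test_that("HGT rates normalize per Mb with the documented correlations", {
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     lineage = rep(c("A", "B"), each = 4),
                     habitat = rep(c("soil", "puddle"), 4),
                     latitude = 0, longitude = 0,
                     genome_size_mb = c(7, 6, 8, 7.5, 6.5, 7, 8.5, 6),
                     hgt_count = NA)
  meta$hgt_count <- meta$genome_size_mb * 1000  # strictly proportional
  h <- hgtPerMb(meta)
  expect_equal(h$rates$hgt_per_mb, rep(1000, 8))
  expect_equal(h$spearman_rho, 1)
  expect_equal(h$pearson_r, 1, tolerance = 1e-12)

  meta$hgt_count[1] <- 7000
  expect_equal(hgtPerMb(meta)$rates$hgt_per_mb[1], 1000)
  bad <- meta; bad$genome_size_mb[1] <- 0
  expect_error(hgtPerMb(bad), "positive")

  # Poisson counts around rate * size: correlation near its simulated truth
  set.seed(21)
  sizes <- runif(200, 6, 9)
  counts <- rpois(200, 900 * sizes)
  m2 <- data.frame(sample_id = paste0("x", 1:200), lineage = "A",
                   habitat = "soil", latitude = 0, longitude = 0,
                   genome_size_mb = sizes, hgt_count = counts)
  rho <- hgtPerMb(m2)$spearman_rho
  oracle <- mean(replicate(50, {
    cnt <- rpois(200, 900 * sizes)
    suppressWarnings(cor(cnt, sizes, method = "spearman"))
  }))
  expect_lt(abs(rho - oracle), 0.1)
})
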