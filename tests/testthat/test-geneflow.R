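linmap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")

test_that("events attribute to within- and between-lineage categories", {
  ev <- makeEvents(c(1, 1, 1), c(100, 100, 100),
                   list(c("a1", "a2"), c("a1", "b1"), c("a1", "b1", "c1")))
  at <- attributeEvents(ev, linmap)
  expect_equal(at$type[at$event == 1], "within")
  expect_equal(at$lineageA[at$event == 1], "A")
  expect_equal(at[at$event == 2, c("lineageA", "lineageB")],
               data.frame(lineageA = "A", lineageB = "B", row.names = 2L))
  # three lineages: all three pairs
  p3 <- at[at$event == 3, ]
  expect_equal(nrow(p3), 3)
  expect_setequal(paste(p3$lineageA, p3$lineageB),
                  c("A B", "A C", "B C"))
  # single-carrier events are within-lineage and flagged
  ev1 <- makeEvents(5, 50, list("a1"))
  at1 <- attributeEvents(ev1, linmap)
  expect_equal(at1$type, "within")
  expect_true(at1$single_carrier)
  expect_error(attributeEvents(makeEvents(1, 2, list("ghost")), linmap),
               "unknown")
})

test_that("summed and union fractions follow their definitions", {
  # duplicate within-A events [1,100]: summed 0.2, union 0.1 of G=1000
  ev <- makeEvents(c(1, 1), c(100, 100), list(c("a1", "a2"), c("a1", "a2")))
  gfS <- geneflowFractions(ev, linmap, 1000, "summed")
  gfU <- geneflowFractions(ev, linmap, 1000, "union")
  expect_equal(unname(gfS$within["A"]), 0.2)
  expect_equal(unname(gfU$within["A"]), 0.1)

  ev2 <- makeEvents(201, 300, list(c("a1", "b1")))
  gf2 <- geneflowFractions(ev2, linmap, 1000, "summed")
  expect_equal(gf2$between["A", "B"], 0.1)
  expect_equal(gf2$between["B", "A"], 0.1)

  expect_error(geneflowFractions(makeEvents(1, 2000, list("a1")), linmap,
                                 1000), "bounds")
  expect_error(geneflowFractions(ev, linmap, 0), "positive")
})

test_that("union fractions never exceed summed fractions", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    st <- sample(900, n, replace = TRUE)
    ev <- makeEvents(st, pmin(st + sample(200, n, replace = TRUE), 1000),
                     replicate(n, sample(names(linmap),
                                         sample(1:3, 1)), simplify = FALSE))
    gfS <- geneflowFractions(ev, linmap, 1000, "summed")
    gfU <- geneflowFractions(ev, linmap, 1000, "union")
    expect_true(all(gfU$within <= gfS$within + 1e-12))
    expect_true(all(gfU$between <= gfS$between + 1e-12))
  }
})

test_that("per-strain r/m and rho/theta follow the counting rules", {
  # 10 SNPs, 6 inside the strain's events, 4 outside
  g <- matrix(1L, 1, 10, dimnames = list("a1", NULL))
  aln <- SnpAlignment(g, c(10L, 20L, 30L, 40L, 50L, 60L, 500L, 600L, 700L,
                           800L),
                      rep("A", 10), rep("T", 10), 1000L)
  ev <- makeEvents(c(1, 25), c(22, 65), list("a1", "a1"))
  r <- strainRecombParams(ev, aln, "a1")
  expect_equal(r$snps_inside, 6)
  expect_equal(r$rm, 1.5)
  expect_equal(r$rho_theta, 2 / 4)
  # no events: both ratios zero
  r0 <- strainRecombParams(makeEvents(integer(), integer(), list()), aln,
                           "a1")
  expect_equal(r0$rm, 0)
  expect_equal(r0$rho_theta, 0)
  expect_error(strainRecombParams(ev, aln, "ghost"), "no SNP data")
})

test_that("strains with more implanted tracts rank higher in r/m", {
  # 40 strains; tract rates vary strongly with the strain index
  cfg <- simConfig(seed = 17, n_lineages = 4, samples_per_lineage = 10,
                   genome_length = 50000, theta = 0.004, divergence = 0.02,
                   tract_rate = 0, n_genes = 0, n_env = 0, hgt = FALSE)
  b <- simulateContinuum(cfg)
  ids <- sampleIds(b$alignment)
  set.seed(99)
  nT <- rep(c(0, 1, 3, 6, 10), length.out = length(ids))
  evs <- list(); donors <- character()
  for (i in seq_along(ids)) {
    if (nT[i] == 0) next
    for (k in seq_len(nT[i])) {
      st <- sample(45000, 1)
      donor <- sample(setdiff(ids, ids[i]), 1)
      evs[[length(evs) + 1]] <- c(st, st + 1999, i)
      donors <- c(donors, donor)
    }
  }
  m <- do.call(rbind, evs)
  ev <- makeEvents(m[, 1], m[, 2],
                   mapply(function(i, d) c(ids[i], d), m[, 3], donors,
                          SIMPLIFY = FALSE))
  aln <- implantRecombination(b$alignment, ev, donors, quiet = TRUE)
  # events where the strain is the recipient carrier only
  summ <- strainRecombSummary(ev, aln)
  truthCount <- nT + vapply(ids, function(s) sum(donors == s), numeric(1))
  rho <- suppressWarnings(
    cor(truthCount, summ$rm, method = "spearman", use = "complete.obs"))
  expect_gte(rho, 0.8)
})

test_that("group comparison composes Kruskal-Wallis and Dunn correctly", {
  s <- data.frame(rho_theta = c(1, 2, 3, 101, 102, 103, 201, 202, 203),
                  lineage = rep(c("A", "B", "C"), each = 3))
  r <- lineageRecombComparison(s)
  expect_equal(r$H, oracleKwH(split(s$rho_theta, s$lineage)),
               tolerance = 1e-12)
  # identical groups: H = 0, p = 1
  s2 <- data.frame(rho_theta = rep(c(1, 2, 3), 2),
                   lineage = rep(c("A", "B"), each = 3))
  r2 <- lineageRecombComparison(s2)
  expect_equal(r2$H, 0)
  expect_equal(r2$p, 1)
  # groups with a single member are dropped
  s3 <- rbind(s, data.frame(rho_theta = 5, lineage = "D"))
  expect_message(r3 <- lineageRecombComparison(s3), "dropping")
  expect_false("D" %in% c(r3$dunn$groupA, r3$dunn$groupB))
  expect_error(lineageRecombComparison(s[1:3, ]), ">= 2 groups")
})

test_that("divergence probabilities and stages follow the thresholds", {
  ev <- makeEvents(c(1, 201), c(100, 300),
                   list(c("a1", "b1"), c("a1", "c1")))
  gf <- geneflowFractions(ev, linmap, 1000, "union")
  up <- upcelStages(gf)
  # no gene flow between B and C: P_div = 1, species
  bc <- up[up$lineageA == "B" & up$lineageB == "C", ]
  expect_equal(bc$p_div, 1)
  expect_equal(bc$stage, "species (stages 4-5)")

  gf2 <- gf
  gf2$between["A", "B"] <- gf2$between["B", "A"] <- 0.268
  gf2$between["A", "C"] <- gf2$between["C", "A"] <- 0.10
  up2 <- upcelStages(gf2)
  expect_equal(up2$p_div[up2$lineageA == "A" & up2$lineageB == "B"], 0.732)
  expect_equal(up2$stage[up2$lineageA == "A" & up2$lineageB == "B"],
               "early (stages 1-2)")
  expect_equal(up2$p_div[up2$lineageA == "A" & up2$lineageB == "C"], 0.90)
  expect_equal(up2$stage[up2$lineageA == "A" & up2$lineageB == "C"],
               "species (stages 4-5)")

  expect_error(upcelStages(gf, thresholds = c(species = 0.8, grey = 0.9)),
               "descending")
  gfS <- geneflowFractions(ev, linmap, 1000, "summed")
  expect_error(upcelStages(gfS), "union")

  # removing all between-lineage events drives every P_div to 1
  evW <- makeEvents(c(1, 50), c(100, 200),
                    list(c("a1", "a2"), c("b1", "b2")))
  upW <- upcelStages(geneflowFractions(evW, linmap, 1000, "union"))
  expect_true(all(upW$p_div == 1))
})
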