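test_that("identical configurations give byte-identical bundles", {
  cfg <- simConfig(seed = 7, n_lineages = 2, samples_per_lineage = 5,
                   genome_length = 10000, n_genes = 3,
                   codons_per_gene = 100)
  b1 <- simulateContinuum(cfg)
  b2 <- simulateContinuum(cfg)
  expect_identical(genotypes(b1$alignment), genotypes(b2$alignment))
  expect_identical(b1$ref_seq, b2$ref_seq)
  expect_identical(b1$metadata, b2$metadata)
  expect_identical(as.data.frame(b1$events), as.data.frame(b2$events))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- writeBundle(b1, d1); m2 <- writeBundle(b2, d2)
  expect_identical(m1$md5, m2$md5)  # checksums identical across reruns
})

test_that("a zero-rate configuration produces no variation", {
  cfg <- simConfig(seed = 3, n_lineages = 2, samples_per_lineage = 4,
                   genome_length = 5000, theta = 0, divergence = 0,
                   tract_rate = 0, n_genes = 0, n_env = 0, hgt = FALSE)
  b <- simulateContinuum(cfg)
  expect_equal(nSites(b$alignment), 0)
  expect_true(all(aniValues(b$ani) == 100))
})

test_that("infeasible configurations fail before generation", {
  expect_error(simConfig(samples_per_lineage = 0), "sample")
  expect_error(simConfig(theta = 0.5), "0.2")
  expect_error(simConfig(genome_length = 1000,
                         island = list(start = 500, end = 2000,
                                       multiplier = 2)), "island")
  expect_error(simConfig(n_genes = 100, codons_per_gene = 400,
                         genome_length = 10000), "fit")
})

test_that("mean D_XY matches the coalescent closed form over replicates", {
  # E[D_XY] = d + theta*(1 - 1/nA) + theta*(1 - 1/nB)
  est <- vapply(1:30, function(s) {
    b <- simulateContinuum(simConfig(
      seed = 1000 + s, n_lineages = 2, samples_per_lineage = 10,
      genome_length = 20000, theta = 0.005, divergence = 0.02,
      n_genes = 0, tract_rate = 0, n_env = 0, hgt = FALSE))
    lin <- setNames(b$metadata$lineage, b$metadata$sample_id)
    dxy(b$alignment, names(lin)[lin == "M1"], names(lin)[lin == "M2"])
  }, numeric(1))
  expected <- 0.02 + 2 * 0.005 * (1 - 1 / 10)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - expected), 3 * se + 1e-12)
})

test_that("implanted tracts copy the donor haplotype exactly", {
  cfg <- simConfig(seed = 5, n_lineages = 2, samples_per_lineage = 4,
                   genome_length = 10000, theta = 0.005, divergence = 0.02,
                   tract_rate = 0, n_genes = 0, n_env = 0, hgt = FALSE)
  b <- simulateContinuum(cfg)
  donor <- "M2_s01"
  carriers <- c("M1_s01", "M1_s02", "M1_s03")
  ev <- makeEvents(1, 1000, list(c(carriers, donor)))
  out <- implantRecombination(b$alignment, ev, donor)
  tract <- snpPositions(out) <= 1000
  for (s in carriers) {
    expect_identical(genotypes(out)[s, tract],
                     genotypes(out)[donor, tract])
    # untouched outside the tract
    expect_identical(genotypes(out)[s, !tract],
                     genotypes(b$alignment)[s, !tract])
  }
  # empty event list: identity
  expect_identical(
    genotypes(implantRecombination(b$alignment, makeEvents(integer(),
                                                           integer(),
                                                           list()),
                                   character())),
    genotypes(b$alignment))
  expect_error(implantRecombination(b$alignment,
                                    makeEvents(1, 20000, list("M1_s01")),
                                    "M2_s01"), "bounds")
})

test_that("a tract across the island erases the divergence signal locally", {
  b <- simulateContinuum(simConfig(
    seed = 9, n_lineages = 2, samples_per_lineage = 6,
    genome_length = 30000, theta = 0.004, divergence = 0.015,
    island = list(start = 10001, end = 15000, multiplier = 8),
    n_genes = 0, tract_rate = 0, n_env = 0, hgt = FALSE))
  lin <- setNames(b$metadata$lineage, b$metadata$sample_id)
  A <- names(lin)[lin == "M1"]
  before <- dxy(b$alignment, A, names(lin)[lin == "M2"], 10001, 15000)
  # copy one M2 donor over the island into every M1 strain
  ev <- makeEvents(10001, 15000, list(c(A, "M2_s01")))
  after <- dxy(implantRecombination(b$alignment, ev, "M2_s01"),
               A, names(lin)[lin == "M2"], 10001, 15000)
  expect_lt(after, before / 2)
})

test_that("neutral bundles have textbook windowed behavior", {
  # mean genome-wide Tajima's D across replicates stays near zero
  meanD <- vapply(1:20, function(s) {
    b <- simulateContinuum(simConfig(
      seed = 200 + s, n_lineages = 1, samples_per_lineage = 20,
      genome_length = 50000, theta = 0.002, divergence = 0,
      n_genes = 0, tract_rate = 0, n_env = 0, hgt = FALSE))
    tajimasD(b$alignment)
  }, numeric(1))
  expect_gt(mean(meanD), -0.5)
  expect_lt(mean(meanD), 0.5)
})

test_that("F_ST grows monotonically with divergence at fixed theta", {
  grid <- c(0.005, 0.02, 0.08)
  means <- vapply(grid, function(d) {
    mean(vapply(1:12, function(s) {
      b <- simulateContinuum(simConfig(
        seed = 3000 + s, n_lineages = 2, samples_per_lineage = 8,
        genome_length = 10000, theta = 0.005, divergence = d,
        n_genes = 0, tract_rate = 0, n_env = 0, hgt = FALSE))
      lin <- setNames(b$metadata$lineage, b$metadata$sample_id)
      fstHudson(b$alignment, names(lin)[lin == "M1"],
                names(lin)[lin == "M2"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("bundles round-trip through the on-disk formats", {
  cfg <- simConfig(seed = 13, n_lineages = 2, samples_per_lineage = 4,
                   genome_length = 8000, n_genes = 2, codons_per_gene = 80,
                   tract_rate = 1)
  b <- simulateContinuum(cfg)
  dir <- withr::local_tempdir()
  manifest <- writeBundle(b, dir)
  expect_equal(nrow(manifest), 8)
  expect_true(file.exists(file.path(dir, "manifest.json")))

  back <- readBundle(dir)
  expect_identical(genotypes(back$alignment), genotypes(b$alignment))
  expect_identical(back$ref_seq, b$ref_seq)
  expect_equal(S4Vectors::mcols(back$genes)$gene_id,
               S4Vectors::mcols(b$genes)$gene_id)
  expect_equal(length(back$events), length(b$events))
  expect_identical(as.list(S4Vectors::mcols(back$events)$carriers),
                   lapply(S4Vectors::mcols(b$events)$carriers, as.character))
  expect_equal(aniValues(back$ani), aniValues(b$ani), tolerance = 1e-4)
  expect_setequal(back$tree$tip.label, b$tree$tip.label)
  expect_equal(back$metadata$latitude, b$metadata$latitude,
               tolerance = 1e-4)
})
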