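# Dosage inference from marker scores and QTL design matrices.

# Tiny hand-built cross: 3 markers, donor scores (2,0,2), recurrent
# (0,2,2); marker 3 is uninformative (parents agree).
tiny_scores <- function() {
  map <- data.frame(marker = c("m1", "m2", "m3"), chr = 1,
                    pos = c(0, 10, 20))
  parents <- rbind(R = c(0L, 2L, 2L), D = c(2L, 0L, 2L))
  colnames(parents) <- map$marker
  geno <- rbind(g1 = c(2L, 0L, 2L),   # donor homozygote at m1, m2
                g2 = c(1L, 1L, 2L),   # heterozygous
                g3 = c(0L, 2L, 2L))   # recurrent homozygote
  colnames(geno) <- map$marker
  crosses <- data.frame(genotype = c("g1", "g2", "g3"), cross = "cr1",
                        recurrent = "R", donor = "D",
                        stringsAsFactors = FALSE)
  list(map = map, parents = parents, geno = geno, crosses = crosses)
}

test_that("dosage equals matches to the donor score where parents differ", {
  f <- tiny_scores()
  d <- infer_parental_dosage(f$geno, f$parents, f$crosses, f$map)
  expect_equal(unname(d$dosage[, "m1"]), c(2, 1, 0))
  expect_equal(unname(d$dosage[, "m2"]), c(2, 1, 0))
  # parents agree at m3: missing before fill-in
  expect_true(all(is.na(d$raw[, "m3"])))
  # flanking consensus fills m3 from the agreeing flank (m2 only on left)
  expect_equal(unname(d$dosage[, "m3"]), c(2, 1, 0))
})

test_that("disagreeing flanks leave the position missing", {
  map <- data.frame(marker = c("m1", "m2", "m3"), chr = 1,
                    pos = c(0, 10, 20))
  parents <- rbind(R = c(0L, 2L, 0L), D = c(2L, 2L, 2L))
  colnames(parents) <- map$marker
  geno <- rbind(g1 = c(2L, 2L, 0L))
  colnames(geno) <- map$marker
  crosses <- data.frame(genotype = "g1", cross = "cr1", recurrent = "R",
                        donor = "D", stringsAsFactors = FALSE)
  d <- infer_parental_dosage(geno, parents, crosses, map)
  expect_equal(unname(d$dosage[1, c("m1", "m3")]), c(2, 0))
  expect_true(is.na(d$dosage[1, "m2"]))
})

test_that("genotypes without a cross assignment are rejected", {
  f <- tiny_scores()
  extra <- rbind(f$geno, orphan = c(1L, 1L, 1L))
  expect_error(infer_parental_dosage(extra, f$parents, f$crosses, f$map),
               "without cross")
})

test_that("inference recovers the simulator's true dosage exactly", {
  sim <- simulate_bcnam(small_sim_config(n_progeny = 60L, seed = 4))
  parents <- sim$genotypes[c("R1", "D1", "D2"), ]
  prog <- sim$genotypes[sim$crosses$genotype, ]
  d <- infer_parental_dosage(prog, parents, sim$crosses, sim$map)
  expect_equal(unname(d$dosage), unname(sim$dosage_true * 1.0))
  # dosages are allele counts; the recurrent complement stays in range
  expect_true(all(d$dosage %in% 0:2, na.rm = TRUE))
  expect_true(all((2 - d$dosage) %in% 0:2, na.rm = TRUE))
})

test_that("uninformative markers are filled from informative flanks", {
  sim <- simulate_bcnam(small_sim_config(n_progeny = 60L, seed = 6,
                                         prop_uninformative = 0.2))
  parents <- sim$genotypes[c("R1", "D1", "D2"), ]
  prog <- sim$genotypes[sim$crosses$genotype, ]
  d <- infer_parental_dosage(prog, parents, sim$crosses, sim$map)
  expect_gt(mean(is.na(d$raw)), 0.1)          # uninformative cells exist
  expect_lt(mean(is.na(d$dosage)), mean(is.na(d$raw)))
  filled <- !is.na(d$dosage)
  expect_gt(mean(d$dosage[filled] == sim$dosage_true[filled]), 0.97)
})

test_that("design matrix respects cross membership and the min_seg rule", {
  sim <- simulate_bcnam(small_sim_config(n_progeny = 500L, seed = 2))
  dos <- dosage_from_sim(sim)
  bd <- build_design_matrix(dos, marker = "c1m11", min_seg = 10)
  expect_equal(colnames(bd$X), c("D1", "D2"))
  # sparsity: a nonzero entry implies the column donor is the genotype's
  cr <- dos$crosses
  for (p in colnames(bd$X)) {
    nz <- bd$X[, p] != 0
    expect_true(all(cr$donor[nz] == p))
  }
  # BC1F4 column mean within a cross: 2 x 1/4 donor allele frequency
  m1 <- mean(bd$X[cr$donor == "D1", "D1"])
  expect_lt(abs(m1 - 0.5), 0.08)

  # a donor fixed at the position is dropped
  dos2 <- dos
  dos2$dosage[cr$genotype[cr$donor == "D2"], "c1m11"] <- 0
  bd2 <- build_design_matrix(dos2, marker = "c1m11", min_seg = 10)
  expect_equal(colnames(bd2$X), "D1")
  expect_equal(bd2$dropped, "D2")
  expect_true(bd2$scannable)

  # all columns dropped: distinctly flagged as unscannable
  dos2$dosage[, "c1m11"] <- 0
  bd3 <- build_design_matrix(dos2, marker = "c1m11", min_seg = 10)
  expect_false(bd3$scannable)

  # restricting to one cross keeps at most that cross's donor
  bd4 <- build_design_matrix(dos, marker = "c1m11",
                             subpopulation = "cr1", min_seg = 10)
  expect_equal(colnames(bd4$X), "D1")
})
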