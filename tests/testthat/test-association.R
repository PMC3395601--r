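test_that("marker filters use strict MAF and call-rate inequalities", {
  ## MAF exactly 0.10 is filtered; call rate 104/105 is retained
  mm <- marker_map(c("m1", "m2", "m3"), pos_bp = c(1L, 2L, 3L),
                   alleles = list(c("A", "G"), c("A", "G"), c("A", "G")))
  n <- 105L
  g1 <- c(rep("A/G", 21), rep("A/A", 84))            # MAF = 21/210 = 0.10
  g2 <- c(rep("A/G", 40), rep("A/A", 64), NA)        # call rate 104/105
  g3 <- rep("A/A", n)                                # monomorphic
  ind <- data.frame(id = sprintf("i%03d", 1:n),
                    sex = rep(c("F", "M"), length.out = n),
                    population = "w", role = "unrelated")
  gm <- genotype_matrix(ind, mm, cbind(g1, g2, g3))
  filt <- apply_marker_filters(gm)
  expect_false(filt$pass[1]); expect_match(filt$reason[1], "maf")
  expect_true(filt$pass[2])
  expect_equal(filt$call_rate[2], 104 / 105)
  expect_false(filt$pass[3]); expect_equal(filt$maf[3], 0)
})

test_that("published SNP MAFs are reproduced and retained", {
  gm <- wild_fixture()
  filt <- apply_marker_filters(gm)
  expect_equal(filt$maf[filt$marker_id == "snp7271"], 47 / 210)
  expect_true(all(filt$pass))
})

test_that("build_table reproduces the published 2x2 tables", {
  gm <- wild_fixture()
  t71 <- build_table(gm, "snp7271", "genotypic_2x2")
  expect_equal(unname(t71), matrix(c(58L, 0L, 0L, 47L), 2))
  t12 <- build_table(gm, "snp7412", "genotypic_2x2")
  expect_equal(unname(t12), matrix(c(53L, 4L, 5L, 42L), 2))
  ta <- build_table(gm, "snp7271", "allelic")
  expect_equal(unname(ta), matrix(c(116L, 47L, 0L, 47L), 2))
})

test_that("fisher_exact reproduces the published p-values", {
  gm <- wild_fixture()
  p71 <- fisher_exact(build_table(gm, "snp7271", "genotypic_2x2"))
  expect_equal(signif(p71, 2), 5.6e-31)
  expect_equal(p71, 1 / choose(105, 58), tolerance = 1e-12)
  p12 <- fisher_exact(build_table(gm, "snp7412", "genotypic_2x2"))
  ## printed as 9.9e-19 (truncated); exact value 9.99e-19
  expect_equal(p12, 9.9926e-19, tolerance = 1e-4)
})

test_that("fisher_exact equals the exhaustive-enumeration oracle", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2), "one_sided"), 0.5)
  set.seed(7)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(0:6, 1)), 2)
    if (sum(tab) == 0 || sum(tab) > 25) next
    for (alt in c("two_sided", "one_sided")) {
      expect_equal(as.numeric(fisher_exact(tab, alt)),
                   fisher_oracle(tab, alt), tolerance = 1e-12,
                   info = paste(c(tab, alt), collapse = ","))
    }
    ## two-sided never below the observed-direction one-sided tail
    expect_gte(fisher_exact(tab, "two_sided") * (1 + 1e-9),
               fisher_exact(tab, "one_sided"))
    ## cross-check against the reference implementation in stats
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(fisher_exact(tab, "two_sided"),
                   stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    }
  }
})

test_that("degenerate margins give p = 1 with a flag", {
  p <- fisher_exact(matrix(c(0L, 0L, 3L, 4L), 2))
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
})

test_that("recessive discordance reproduces the published 9 discordant fish", {
  gm <- wild_fixture()
  d12 <- recessive_discordance(gm, "snp7412")
  expect_equal(d12$n_discordant, 9L)
  expect_length(d12$excluded_ids, 1L)        # the undetermined male
  d71 <- recessive_discordance(gm, "snp7271")
  expect_equal(d71$n_discordant, 0L)
  ## discordance 0 iff the 2x2 has zero off-diagonal cells
  t71 <- build_table(gm, "snp7271", "genotypic_2x2")
  expect_equal(t71[1, 2] + t71[2, 1], 0L)
  ## all-missing marker: everyone excluded
  gm2 <- gm
  gm2$geno[, 2] <- NA
  d <- recessive_discordance(gm2, "snp7412")
  expect_equal(d$n_discordant, 0L)
  expect_length(d$excluded_ids, 105L)
})

test_that("bonferroni correction and threshold", {
  b <- bonferroni(c(1e-5, 0.02, 1), alpha = 0.05, m = 13L)
  expect_equal(b$threshold, 0.05 / 13)
  expect_equal(-log10(b$threshold), 2.415, tolerance = 1e-3)
  expect_equal(b$adjusted, c(13e-5, 0.26, 1))
  expect_equal(bonferroni(0.03, m = 1L)$adjusted, 0.03)
})

test_that("permutation correction matches an exhaustive label-permutation oracle", {
  ## 8 individuals (4 F / 4 M), one marker: all C(8,4) = 70 sex labelings
  ## can be enumerated exactly
  mm <- marker_map("m1", pos_bp = 1L, alleles = list(c("A", "G")))
  geno <- c("A/A", "A/A", "A/A", "A/G", "A/G", "A/G", "A/G", "A/A")
  sex <- c("F", "F", "F", "F", "M", "M", "M", "M")
  ind <- data.frame(id = paste0("i", 1:8), sex = sex, population = "p",
                    role = "unrelated")
  gm <- genotype_matrix(ind, mm, matrix(geno, 8))
  p_obs <- fisher_exact(build_table(gm, "m1", "recessive"))
  combs <- utils::combn(8, 4)
  exact <- mean(apply(combs, 2, function(fem) {
    s <- rep("M", 8); s[fem] <- "F"
    gm2 <- gm; gm2$individuals$sex <- s
    fisher_exact(build_table(gm2, "m1", "recessive")) <= p_obs
  }))
  pc <- permutation_correction(gm, "m1", n_perm = 2000L, seed = 5L)
  se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(pc$p_corrected[["m1"]] - exact), 3 * se + 1 / 2001)
  ## add-one estimator lower bound
  expect_gte(min(pc$p_corrected), 1 / 2001)
  ## determinism
  pc2 <- permutation_correction(gm, "m1", n_perm = 2000L, seed = 5L)
  expect_identical(pc, pc2)
  expect_error(permutation_correction(gm[1:2, ], "m1", 10L, 1L),
               "fewer than 2")
})

test_that("assoc_scan ranks the causal SNP first on simulated wild data", {
  hits <- 0L
  for (seed in 1:8) {
    sim <- simulate_wild_population(wild_sim_params(seed = seed))
    res <- assoc_scan(sim$matrix)
    keep <- !res$filtered
    top <- res$marker_id[keep][which.min(res$p_two_sided[keep])]
    hits <- hits + (top == sim$truth$causal_marker)
  }
  expect_gte(hits, 7L)
})

test_that("permutation-corrected p controls type-I error on null data (property)", {
  ## sex completely unlinked to genotype: corrected p < 0.05 in at most
  ## ~5% of replicates (max-T controls the family-wise rate; the discrete
  ## test makes it conservative)
  set.seed(1234)
  mm <- marker_map(sprintf("m%d", 1:4), pos_bp = 1:4 * 100L,
                   alleles = replicate(4, c("A", "G"), simplify = FALSE))
  n <- 40L
  reps <- 60L
  hits <- 0L
  for (r in seq_len(reps)) {
    geno <- sapply(1:4, function(j) {
      a <- matrix(sample(c("A", "G"), 2 * n, TRUE), n)
      paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]), sep = "/")
    })
    ind <- data.frame(id = paste0("i", 1:n),
                      sex = sample(rep(c("F", "M"), n / 2)),
                      population = "p", role = "unrelated")
    gm <- genotype_matrix(ind, mm, geno)
    pc <- permutation_correction(gm, n_perm = 199L, seed = r)
    hits <- hits + any(pc$p_corrected < 0.05)
  }
  rate <- hits / reps
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
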