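test_that("every generator is bit-identical under the same seed", {
  w1 <- simulate_wild_population(wild_sim_params(
    n_females = 10L, n_males = 8L, n_markers = 6L, founder_haplotypes = 24L,
    generations = 6L, seed = 9L))
  w2 <- simulate_wild_population(wild_sim_params(
    n_females = 10L, n_males = 8L, n_markers = 6L, founder_haplotypes = 24L,
    generations = 6L, seed = 9L))
  expect_identical(w1, w2)

  mm <- toy_map(c(1000L, 5000L, 7271L, 12000L))
  f1 <- simulate_family(family_sim_params(30L, mm, "m03", seed = 4L))
  f2 <- simulate_family(family_sim_params(30L, mm, "m03", seed = 4L))
  expect_identical(f1, f2)

  c1 <- simulate_clone_pair(clone_pair_params(2000L, 0.99, seed = 2L))
  expect_identical(c1, simulate_clone_pair(clone_pair_params(2000L, 0.99,
                                                             seed = 2L)))
  p1 <- simulate_species_panels(seed = 8L)
  expect_identical(p1, simulate_species_panels(seed = 8L))
})

test_that("wild simulation: males heterozygous, females homozygous at the causal SNP", {
  for (seed in c(1L, 23L)) {
    sim <- simulate_wild_population(wild_sim_params(
      n_females = 20L, n_males = 15L, n_markers = 10L,
      founder_haplotypes = 60L, generations = 15L, seed = seed))
    gm <- sim$matrix
    expect_silent(validate_genotype_matrix(gm))
    j <- match(sim$truth$causal_marker, gm$markers$marker_id)
    sp <- do.call(rbind, strsplit(gm$geno[, j], "/"))
    het <- sp[, 1] != sp[, 2]
    expect_true(all(het[gm$individuals$sex == "M"]))
    expect_false(any(het[gm$individuals$sex == "F"]))
    ## truth haplotypes match the unphased matrix
    expect_equal(sum(sim$truth$hap_pat[, j] + sim$truth$hap_mat[, j] == 1L),
                 sum(het))
  }
})

test_that("zero recombination preserves founder haplotypes and complete LD", {
  sim <- simulate_wild_population(wild_sim_params(
    n_females = 20L, n_males = 20L, n_markers = 12L,
    founder_haplotypes = 16L, generations = 10L,
    recomb_rate_per_bp_per_meiosis = 0, seed = 3L))
  haps <- apply(rbind(sim$truth$hap_pat, sim$truth$hap_mat), 1, paste,
                collapse = "")
  founders <- apply(sim$truth$founders, 1, paste, collapse = "")
  expect_true(all(haps %in% founders))
  ## complete LD on the phased truth: founder variation is tree-like
  ## (infinite sites), so without recombination every pair of polymorphic
  ## markers shows at most 3 of the 4 gamete classes, i.e. D' = 1.
  ## (The EM estimate from unphased genotypes can land in the interior for
  ## weakly correlated pairs - phase ambiguity, not recombination.)
  G <- rbind(sim$truth$hap_pat, sim$truth$hap_mat)
  poly <- which(apply(G, 2, function(x) length(unique(x)) > 1))
  for (i in poly) for (j in poly) if (i < j)
    expect_lte(length(unique(paste(G[, i], G[, j]))), 3L)
})

test_that("a marker in complete coupling with the causal SNP has r2 = 1", {
  ## The simulator deliberately never places a neutral mutation on the Y
  ## clade or its complement (the causal SNP is the unique perfectly
  ## sex-linked variant by construction), so a founder-linked neutral
  ## marker cannot arise there. The complete-LD consequence of zero
  ## recombination is checked on a matrix built the way such a world would
  ## produce it: a second marker carrying the causal pattern exactly.
  mm <- marker_map(c("causal", "linked"), pos_bp = c(7271L, 7400L),
                   alleles = list(c("C", "G"), c("A", "T")))
  sex <- rep(c("F", "M"), each = 15L)
  geno <- cbind(ifelse(sex == "F", "C/C", "C/G"),
                ifelse(sex == "F", "A/A", "A/T"))
  ind <- data.frame(id = sprintf("i%02d", seq_along(sex)), sex = sex,
                    population = "w", role = "unrelated")
  gm <- genotype_matrix(ind, mm, geno)
  h <- em_haplotypes(joint_genotype_counts(gm, "causal", "linked"))
  s <- ld_stats(h)
  expect_equal(s$r2, 1, tolerance = 1e-9)
  expect_equal(s$Dprime, 1, tolerance = 1e-9)
})

test_that("default wild population shows low LD far from the causal site", {
  sim <- simulate_wild_population(wild_sim_params())   # defaults, seed 1
  filt <- apply_marker_filters(sim$matrix)
  ld <- ld_matrix(sim$matrix, filt$marker_id[filt$pass])
  pos <- sim$matrix$markers$pos_bp
  pi_ <- pos[match(ld$marker_i, sim$matrix$markers$marker_id)]
  pj <- pos[match(ld$marker_j, sim$matrix$markers$marker_id)]
  far <- abs(pi_ - 7271L) > 5000L & abs(pj - 7271L) > 5000L & ld$defined
  expect_gte(sum(far), 1L)
  expect_lt(mean(ld$r2[far]), 0.2)
})

test_that("family simulator: zero-length map gives zero recombinants", {
  mm <- toy_map(c(1000L, 7271L, 14000L), cm_female = c(0, 0, 0),
                cm_male = c(0, 0, 0))
  sim <- simulate_family(family_sim_params(200L, mm, "m02", seed = 1L))
  expect_true(all(sim$truth$labels %in% c("X", "Y")))
  expect_equal(nrow(unique(sim$truth$labels)), 2L)  # all-X or all-Y rows
  rep_ <- find_recombinants(sim$matrix, "m01", "m03")
  expect_length(rep_$recombinant_ids, 0L)
})

test_that("family recombinant count matches the Binomial(1445, 0.016) oracle", {
  ## two markers 1.6 cM apart on the male map, 1445 offspring: the
  ## recombinant fraction under Haldane is (1 - exp(-2 * 0.016)) / 2,
  ## indistinguishable from 0.016 at this scale; the study screened 1445
  ## sibs and found 23 recombinants
  mm <- toy_map(c(1000L, 14000L), cm_male = c(0, 1.6), cm_female = c(0, 3.2))
  sim <- simulate_family(family_sim_params(1445L, mm, "m01", seed = 11L))
  lab <- sim$truth$labels
  n_rec <- sum(lab[, 1] != lab[, 2])
  expectation <- 1445 * 0.016
  sigma <- sqrt(1445 * 0.016 * 0.984)
  expect_lt(abs(n_rec - expectation), 3 * sigma)
})

test_that("family sex ratio is Mendelian", {
  mm <- toy_map(c(1000L, 7271L))
  sim <- simulate_family(family_sim_params(10000L, mm, "m02", seed = 2L))
  sex <- sim$matrix$individuals$sex[sim$matrix$individuals$role == "offspring"]
  p_hat <- mean(sex == "M")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))
  ## offspring sex is exactly the paternal causal-label rule
  expect_equal(unname(sex == "M"),
               unname(sim$truth$labels[, "m02"] == "Y"))
})

test_that("father homozygous at the causal marker is an invalid parent", {
  mm <- toy_map(c(1000L, 7271L))
  expect_error(simulate_family(family_sim_params(5L, mm, "m02", seed = 1L),
                               father_phase = list(x = c("A", "A"),
                                                   y = c("G", "A"))),
               "invalid-parent")
})

test_that("clone pairs carry exactly floor((1-identity)*L) substitutions", {
  cp <- simulate_clone_pair(clone_pair_params(14000L, 0.994, seed = 6L))
  expect_equal(nrow(cp$substitutions), 84L)
  expect_equal(sequence_identity(cp$x, cp$y), 0.994)
  ## identity 1 -> identical sequences
  cp1 <- simulate_clone_pair(clone_pair_params(500L, 1, seed = 6L))
  expect_identical(cp1$x, cp1$y)
  expect_error(clone_pair_params(0L), "zero-length")
})

test_that("species panels plant the shared SNP with perfect sex association", {
  pan <- simulate_species_panels(n_species = 3L, seed = 12L)
  expect_named(pan, c("species1", "species2", "species3"))
  for (p in pan) {
    expect_silent(validate_genotype_matrix(p))
    j <- match(7271L, p$markers$pos_bp)
    expect_false(is.na(j))
    sex <- p$individuals$sex
    expect_true(all(p$geno[sex == "M", j] == "C/G"))
    expect_true(all(p$geno[sex == "F", j] == "C/C"))
    expect_equal(sum(p$markers$pos_bp != 7271L), 3L)  # requested private count
  }
  ## without the shared SNP no panel carries the causal position
  pan0 <- simulate_species_panels(n_species = 2L, shared_snp = FALSE,
                                  seed = 12L)
  expect_true(all(vapply(pan0, function(p) !7271L %in% p$markers$pos_bp,
                         TRUE)))
})
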