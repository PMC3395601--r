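test_that("sequence identity counts matches, excludes N, rejects misalignment", {
  s <- paste(rep("ACGT", 250), collapse = "")
  expect_equal(sequence_identity(s, s), 1)
  expect_equal(sequence_identity("acgt", "ACGT"), 1)    # case-insensitive
  expect_equal(sequence_identity("ACGTN", "ACCTN"), 3 / 4)
  expect_error(sequence_identity("ACG", "ACGT"), "alignment-required")
  expect_error(sequence_identity("NNN", "NNN"), "undefined")
  ## 84 substitutions in 14,000 bp -> 0.994
  cp <- simulate_clone_pair(clone_pair_params(14000L, 0.994, seed = 1L))
  expect_equal(sequence_identity(cp$x, cp$y), 1 - 84 / 14000)
})

test_that("call_variants recovers exactly the planted substitutions", {
  for (seed in c(2L, 5L, 9L)) {
    cp <- simulate_clone_pair(clone_pair_params(3000L, 0.99, seed = seed))
    calls <- call_variants(list(male1 = list(x = cp$x, y = cp$y)), cp$x)
    expect_equal(calls$variants$pos_bp, cp$substitutions$pos)
    expect_equal(calls$variants$ref_allele, cp$substitutions$x_base)
    expect_equal(calls$variants$alt_allele, cp$substitutions$y_base)
    ## every call for this male is het (X = ref, Y differs)
    sp <- do.call(rbind, strsplit(calls$genotypes$geno[1, ], "/"))
    expect_true(all(sp[, 1] != sp[, 2]))
  }
})

test_that("males sharing no variant are ref/ref at each other's sites", {
  ref <- strrep("ACGT", 25)
  x1 <- ref; y1 <- ref
  substr(y1, 10, 10) <- "T"
  x2 <- ref; y2 <- ref
  substr(y2, 50, 50) <- "A"
  calls <- call_variants(list(m1 = list(x = x1, y = y1),
                              m2 = list(x = x2, y = y2)), ref)
  expect_equal(calls$variants$pos_bp, c(10L, 50L))
  g <- calls$genotypes$geno
  expect_equal(unname(g["m1", ]), c("C/T", "C/C"))
  expect_equal(unname(g["m2", ]), c("C/C", "A/C"))
})

test_that("the XY-pattern screen applies the strict all-males rule", {
  ref <- strrep("A", 100)
  mk_pair <- function(het_at) {
    y <- ref
    for (p in het_at) substr(y, p, p) <- "G"
    list(x = ref, y = y)
  }
  ## causal position 40 het in all 9 males; position 70 het in only 8
  pairs <- lapply(1:9, function(i) mk_pair(c(40L, if (i > 1) 70L)))
  names(pairs) <- sprintf("male%d", 1:9)
  calls <- call_variants(pairs, ref)
  screen <- screen_xy_pattern(calls$genotypes)
  expect_equal(screen$marker_id[screen$candidate], "var00040")
  expect_equal(screen$n_het_males[screen$marker_id == "var00070"], 8L)
  expect_false(screen$candidate[screen$marker_id == "var00070"])
  ## invariant under individual reordering
  perm <- calls$genotypes[sample(9), ]
  screen2 <- screen_xy_pattern(perm)
  expect_equal(screen2, screen)
})

test_that("females must be homozygous for a variant to remain a candidate", {
  mm <- marker_map("v1", pos_bp = 40L, alleles = list(c("A", "G")))
  ind <- data.frame(id = c("m1", "m2", "f1"), sex = c("M", "M", "F"),
                    population = "p", role = "unrelated")
  gm <- genotype_matrix(ind, mm, matrix(c("A/G", "A/G", "A/G"), 3))
  expect_false(screen_xy_pattern(gm)$candidate)
  gm2 <- genotype_matrix(ind, mm, matrix(c("A/G", "A/G", "A/A"), 3))
  expect_true(screen_xy_pattern(gm2)$candidate)
  gm3 <- genotype_matrix(ind[3, ], mm, matrix("A/G", 1))
  expect_error(screen_xy_pattern(gm3), "screen-undefined")
})

test_that("neutral-variant pass rate decreases with the number of males", {
  set.seed(99)
  pass_rate <- vapply(c(2L, 5L, 9L), function(m) {
    mean(replicate(400, {
      ## neutral site at frequency 0.5: each male het with prob 1/2
      all(stats::rbinom(m, 1L, 0.5) == 1L)
    }))
  }, 1)
  expect_true(all(diff(pass_rate) < 0))
  expect_lt(pass_rate[3], 0.02)
})

test_that("missense annotation matches the published His384Asp pattern", {
  ## exon with a CAC (His) codon; C>G at codon position 1 gives GAC (Asp)
  genome <- paste0("TTTT", "ATGCACAAATGA", "GGGG")
  cds <- cds_model(5L, 16L)
  ann <- annotate_missense(8L, "C", "G", cds, genome)
  expect_equal(ann$consequence, "missense")
  expect_equal(ann$codon_ref, "CAC")
  expect_equal(ann$codon_alt, "GAC")
  expect_equal(ann$aa_ref, "H")
  expect_equal(ann$aa_alt, "D")
  expect_equal(ann$protein_pos, 2L)
  ## synonymous third-position change (CAC -> CAT, both His)
  syn <- annotate_missense(10L, "C", "T", cds, genome)
  expect_equal(syn$consequence, "synonymous")
  ## intronic position -> non-coding
  expect_equal(annotate_missense(2L, "T", "A", cds, genome)$consequence,
               "non-coding")
  ## frame inconsistency is a model error
  expect_error(annotate_missense(8L, "C", "G", cds_model(5L, 15L), genome),
               "frame")
})

test_that("annotation agrees with brute-force translation of the mutated CDS", {
  set.seed(42)
  for (rep in 1:5) {
    n_codons <- sample(10:30, 1)
    cds_seq <- paste0("ATG", paste(sample(names(protosex:::GENETIC_CODE_STD)[
      protosex:::GENETIC_CODE_STD != "*"], n_codons, replace = TRUE),
      collapse = ""), "TGA")
    lead <- sample(3:20, 1)
    genome <- paste0(paste(sample(c("A", "C", "G", "T"), lead, TRUE),
                           collapse = ""), cds_seq,
                     paste(sample(c("A", "C", "G", "T"), 7, TRUE),
                           collapse = ""))
    cds <- cds_model(lead + 1L, lead + nchar(cds_seq))
    pos <- sample(seq_len(nchar(cds_seq)), 5) + lead
    for (p in pos) {
      ref <- substr(genome, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      ann <- annotate_missense(p, ref, alt, cds, genome)
      mut <- genome
      substr(mut, p, p) <- alt
      prot_ref <- protosex:::translate_cds(protosex:::cds_sequence(cds, genome))
      prot_alt <- protosex:::translate_cds(protosex:::cds_sequence(cds, mut))
      d <- which(strsplit(prot_ref, "")[[1]] != strsplit(prot_alt, "")[[1]])
      if (length(d) == 0) {
        expect_equal(ann$consequence, "synonymous")
      } else {
        expect_equal(ann$protein_pos, d)
        expect_equal(ann$aa_alt, substr(prot_alt, d, d))
        expect_true(ann$consequence %in% c("missense", "stop_gained"))
      }
    }
  }
})

test_that("minus-strand CDS annotation reverse-complements correctly", {
  ## genome forward: 5'-AAA TCA TGT GGC ATT-3'; CDS on minus strand over
  ## 4..12 reads revcomp(TCATGTGGC) = GCCACATGA
  genome <- "AAATCATGTGGCATT"
  cds <- cds_model(4L, 12L, strand = "-")
  expect_equal(protosex:::cds_sequence(cds, genome), "GCCACATGA")
  ann <- annotate_missense(6L, "A", "C", cds, genome)
  ## A>C forward is T>G on the coding strand, third codon GTA... compute:
  mut <- genome; substr(mut, 6, 6) <- "C"
  expect_equal(ann$codon_alt,
               substr(protosex:::cds_sequence(cds, mut),
                      (ann$protein_pos - 1) * 3 + 1,
                      ann$protein_pos * 3))
})
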