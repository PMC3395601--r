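# Fixtures built in code and independent oracles used across test files.

# Wild-panel fixture reconstructed from the published genotype counts:
# 58 females / 47 males; at the coding SNP (offset 7271) every female is C/C
# and every male C/G; at the intronic SNP (offset 7412) females are
# 53 GG + 5 CG and males 4 GG + 40 CG + 2 CC + 1 undetermined.
wild_fixture <- function() {
  mm <- marker_map(c("snp7271", "snp7412"), chrom = "SD3-14k",
                   pos_bp = c(7271L, 7412L), kind = "snp",
                   alleles = list(c("C", "G"), c("C", "G")))
  sex <- c(rep("F", 58), rep("M", 47))
  g71 <- c(rep("C/C", 58), rep("C/G", 47))
  g12 <- c(rep("G/G", 53), rep("C/G", 5),
           rep("G/G", 4), rep("C/G", 40), rep("C/C", 2), NA)
  ind <- data.frame(id = sprintf("w%03d", 1:105), sex = sex,
                    population = "wild", role = "unrelated",
                    stringsAsFactors = FALSE)
  genotype_matrix(ind, mm, cbind(g71, g12))
}

# map of n equally informative SNPs used by family tests
toy_map <- function(pos_bp, cm_male = NULL, cm_female = NULL,
                    alleles = c("A", "G")) {
  n <- length(pos_bp)
  if (is.null(cm_female)) cm_female <- (pos_bp - pos_bp[1]) / 1e4
  if (is.null(cm_male)) cm_male <- cm_female / 2
  marker_map(sprintf("m%02d", seq_len(n)), chrom = "SD", pos_bp = pos_bp,
             kind = "snp",
             alleles = replicate(n, alleles, simplify = FALSE),
             cm_female = cm_female, cm_male = cm_male)
}

# hand-built family genotype matrix from explicit paternal labels:
# father A/G at every marker (X = A, Y = G), mother A/A, offspring genotype
# determined by the given label matrix ("X" -> A/A, "Y" -> A/G).
family_from_labels <- function(labels, sexes, map = NULL) {
  n <- nrow(labels); m <- ncol(labels)
  if (is.null(map)) map <- toy_map(seq_len(m) * 1000L)
  geno <- rbind(rep("A/G", m), rep("A/A", m),
                ifelse(labels == "X", "A/A",
                       ifelse(labels == "Y", "A/G", NA)))
  ind <- data.frame(
    id = c("father", "mother", rownames(labels) %||% sprintf("off%02d", 1:n)),
    sex = c("M", "F", sexes),
    population = "fam", role = c("father", "mother", rep("offspring", n)),
    stringsAsFactors = FALSE)
  genotype_matrix(ind, map, geno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive-enumeration Fisher oracle: iterate over every table with the
# observed margins using exact rational-ish arithmetic via choose()
fisher_oracle <- function(tab, alternative = "two_sided") {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, xs) * choose(n - c1, r1 - xs) / choose(n, r1)
  pobs <- probs[match(a, xs)]
  if (alternative == "one_sided") {
    ex <- r1 * c1 / n
    if (a >= ex) sum(probs[xs >= a]) else sum(probs[xs <= a])
  } else {
    sum(probs[probs <= pobs * (1 + 1e-7)])
  }
}

# 2-D grid-search oracle for the two-locus haplotype likelihood: maximize
# over (p_AB, p_Ab) with p_aB determined by the fixed allele-frequency MLEs.
# Returns the best log-likelihood found on the grid.
em_grid_oracle <- function(counts, steps = 200L) {
  n <- as.matrix(counts)
  N <- sum(n)
  pA <- sum(n * matrix(c(2, 1, 0), 3, 3)) / (2 * N)
  pB <- sum(n * matrix(c(2, 1, 0), 3, 3, byrow = TRUE)) / (2 * N)
  ll <- function(p) protosex:::hap_loglik(n, p)
  best <- -Inf
  ## p_AB free in [max(0, pA+pB-1), min(pA, pB)]; others follow from margins
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  for (pAB in seq(lo, hi, length.out = steps)) {
    p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    if (any(p < -1e-12)) next
    best <- max(best, ll(pmax(p, 0)))
  }
  best
}

# random joint genotype counts for two biallelic loci drawn from random
# haplotype frequencies (used in EM oracle tests)
random_joint_counts <- function(n_ind, seed) {
  set.seed(seed)
  p <- as.vector(stats::rmultinom(1, 40, rep(1, 4))) / 40
  p <- pmax(p, 0.02); p <- p / sum(p)
  hap <- sample(1:4, 2 * n_ind, replace = TRUE, prob = p)
  h1 <- hap[seq_len(n_ind)]; h2 <- hap[n_ind + seq_len(n_ind)]
  dA <- (h1 <= 2) + (h2 <= 2)              # copies of allele A
  dB <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
  tab <- table(factor(dA, levels = 2:0), factor(dB, levels = 2:0))
  matrix(as.integer(tab), 3, 3,
         dimnames = list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb")))
}

# brute-force SD-placement oracle: which marker positions / inter-marker
# gaps are consistent with every recombinant's labels and sex?  A marker j
# is consistent for an offspring when its label there is uninformative or
# equals the sex-type; a gap (j, j+1) is consistent when the sex-type
# matches either adjacent label (a crossover may fall on either side of the
# causal point within the gap).
interval_oracle <- function(labels, sexes) {
  m <- ncol(labels)
  want <- ifelse(sexes == "M", "Y", "X")
  marker_ok <- rep(TRUE, m)
  gap_ok <- rep(TRUE, m - 1L)
  for (i in seq_len(nrow(labels))) {
    l <- labels[i, ]
    marker_ok <- marker_ok & (l == "uninformative" | l == want[i])
    for (g in seq_len(m - 1L)) {
      lg <- l[c(g, g + 1L)]
      lg <- lg[lg != "uninformative"]
      if (length(lg) && !(want[i] %in% lg)) gap_ok[g] <- FALSE
    }
  }
  list(marker_ok = marker_ok, gap_ok = gap_ok)
}
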