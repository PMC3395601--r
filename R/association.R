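#' Exact genotype-count association testing under a recessive penetrance model
#'
#' Sex association is tested marker by marker with an exact test on a 2x2
#' genotype-count table (rows: females, males; columns: homozygous for the
#' major allele vs other genotypes), matching a recessive model of penetrance
#' in which homozygosity for one allele is required for the female phenotype.
#' Markers are pre-filtered on minor allele frequency (> 0.1) and call rate
#' (> 0.99); multiple testing is handled by Bonferroni and by a max-T
#' (min-P) permutation of the sex labels.
#'
#' @name association
NULL

allele_count_table <- function(gm, j) {
  g <- gm$geno[, j]
  sp <- split_geno(g[!is.na(g)])
  table(factor(as.vector(sp), levels = marker_alleles(gm$markers)[[j]]))
}

#' Major allele of a marker across the whole sample
#'
#' Ties are broken lexicographically (and flagged via attribute `tie`).
#' @param gm a [genotype_matrix()]
#' @param marker marker id
#' @return single allele string
#' @export
major_allele <- function(gm, marker) {
  j <- marker_index(gm, marker)
  tab <- allele_count_table(gm, j)
  top <- names(tab)[tab == max(tab)]
  structure(sort(top)[1L], tie = length(top) > 1L)
}

#' Per-marker MAF and call-rate filters
#'
#' MAF is computed from non-missing alleles; call rate is the fraction of
#' genotyped individuals. Both filters are strict inequalities (MAF > 0.1,
#' call rate > 0.99), so a marker at exactly the boundary is filtered.
#' Filtered markers are carried with reason codes, never dropped silently;
#' a monomorphic marker has MAF 0 and is filtered, not an error.
#'
#' @param gm a [genotype_matrix()]
#' @param maf_min,call_rate_min strict lower bounds.
#' @return data.frame `marker_id`, `maf`, `call_rate`, `pass`, `reason`.
#' @export
apply_marker_filters <- function(gm, maf_min = 0.1, call_rate_min = 0.99) {
  n <- nrow(gm$geno)
  out <- do.call(rbind, lapply(seq_len(ncol(gm$geno)), function(j) {
    tab <- allele_count_table(gm, j)
    tot <- sum(tab)
    maf <- if (tot == 0L || length(tab) < 2L) 0 else min(tab) / tot
    cr <- sum(!is.na(gm$geno[, j])) / n
    reason <- c(if (maf <= maf_min) "maf",
                if (cr <= call_rate_min) "call_rate")
    data.frame(marker_id = gm$markers$marker_id[j], maf = maf,
               call_rate = cr, pass = length(reason) == 0L,
               reason = paste(reason, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build the 2x2 (or allelic) sex-association count table for a marker
#'
#' `model = "recessive"` (alias `"genotypic_2x2"`): rows females/males,
#' columns homozygous-major vs other genotypes. `model = "allelic"`: allele
#' counts by sex. Individuals of unknown sex or with a missing genotype at
#' this marker are excluded (pairwise deletion).
#'
#' @param gm a [genotype_matrix()]
#' @param marker marker id (biallelic)
#' @param model `"recessive"`, `"genotypic_2x2"` or `"allelic"`.
#' @return 2x2 integer matrix with informative dimnames.
#' @export
build_table <- function(gm, marker,
                        model = c("recessive", "genotypic_2x2", "allelic")) {
  model <- match.arg(model)
  j <- marker_index(gm, marker)
  g <- gm$geno[, j]
  sex <- gm$individuals$sex
  keep <- !is.na(g) & sex %in% c("F", "M")
  assert_that(any(keep), "zero informative individuals")
  g <- g[keep]; sex <- sex[keep]
  maj <- major_allele(gm, marker)
  if (model == "allelic") {
    sp <- split_geno(g)
    a <- factor(ifelse(sp == maj, "major", "minor"),
                levels = c("major", "minor"))
    tab <- rbind(F = table(a[rep(sex, 2L) == "F"]),
                 M = table(a[rep(sex, 2L) == "M"]))
    colnames(tab) <- c(maj, "other")
  } else {
    hom_major <- g == paste(maj, maj, sep = "/")
    tab <- rbind(F = c(sum(sex == "F" & hom_major),
                       sum(sex == "F" & !hom_major)),
                 M = c(sum(sex == "M" & hom_major),
                       sum(sex == "M" & !hom_major)))
    colnames(tab) <- c(paste0("hom_", maj), "other")
  }
  storage.mode(tab) <- "integer"
  tab
}

#' Exact test on a 2x2 contingency table
#'
#' Own implementation of the conditional exact (hypergeometric) test in
#' log-space. `two_sided` uses the point-probability rule: the sum of
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed the observed one (relative tie tolerance
#' 1e-7). `one_sided` sums the observed-direction tail. Degenerate margins
#' (an all-zero row or column) give p = 1 with attribute `degenerate`.
#'
#' @param tab 2x2 non-negative integer matrix.
#' @param alternative `"two_sided"` or `"one_sided"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(tab, alternative = c("two_sided", "one_sided")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  assert_that(all(dim(tab) == 2L) && all(tab >= 0L),
              "need a non-negative 2x2 table")
  a <- tab[1L, 1L]
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  assert_that(n > 0L, "empty table")
  if (r1 == 0L || c1 == 0L || r1 == n || c1 == n)
    return(structure(1, degenerate = TRUE))
  xs <- max(0L, r1 + c1 - n):min(r1, c1)
  lp <- stats::dhyper(xs, c1, n - c1, r1, log = TRUE)
  lobs <- lp[match(a, xs)]
  if (alternative == "one_sided") {
    ex <- r1 * c1 / n            # expected count under independence
    sel <- if (a >= ex) xs >= a else xs <= a
  } else {
    sel <- lp <= lobs + log(1 + 1e-7)
  }
  min(1, exp(logsumexp(lp[sel])))
}

#' Individuals discordant with the recessive sex-prediction rule
#'
#' Predicted sex is female iff homozygous for the major allele, male
#' otherwise; discordant individuals are those whose prediction differs from
#' phenotypic sex. Missing-genotype (and unknown-sex) individuals are
#' excluded and reported separately.
#'
#' @param gm a [genotype_matrix()]
#' @param marker marker id
#' @return list `discordant_ids`, `n_discordant`, `excluded_ids`.
#' @export
recessive_discordance <- function(gm, marker) {
  j <- marker_index(gm, marker)
  g <- gm$geno[, j]
  sex <- gm$individuals$sex
  id <- gm$individuals$id
  excluded <- is.na(g) | !(sex %in% c("F", "M"))
  maj <- major_allele(gm, marker)
  pred <- ifelse(g == paste(maj, maj, sep = "/"), "F", "M")
  disc <- !excluded & pred != sex
  list(discordant_ids = id[disc], n_discordant = sum(disc),
       excluded_ids = id[excluded])
}

#' Bonferroni correction
#'
#' @param p vector of p-values (markers passing filters).
#' @param alpha family-wise level.
#' @param m number of tests; defaults to `length(p)`.
#' @return list `adjusted` (`min(1, m * p)`) and `threshold` (`alpha / m`).
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  assert_that(m >= 1L, "need at least one test")
  list(adjusted = pmin(1, m * p), threshold = alpha / m)
}

#' Family-wise permutation correction (max-T / min-P)
#'
#' Sex labels are permuted across individuals; for each permutation the
#' minimum two-sided exact p across markers is recorded, and each marker's
#' corrected p is `(1 + #{permutation minima <= observed p}) /
#' (n_perm + 1)` (add-one estimator, so corrected p >= 1/(n_perm+1)).
#' Deterministic given `seed`.
#'
#' @param gm a [genotype_matrix()]
#' @param markers marker ids to include (default: all).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list `p_observed`, `p_corrected` (named by marker), `n_perm`.
#' @export
permutation_correction <- function(gm, markers = gm$markers$marker_id,
                                   n_perm = 1000L, seed = 1L) {
  assert_that(n_perm >= 1L, "n_perm must be >= 1")
  sex <- gm$individuals$sex
  known <- sex %in% c("F", "M")
  assert_that(sum(sex == "F") >= 2L && sum(sex == "M") >= 2L,
              "permutation meaningless with fewer than 2 per sex")
  js <- vapply(markers, marker_index, 1L, gm = gm)
  ## per-marker fixed quantities: hom-major indicator among genotyped
  prep <- lapply(js, function(j) {
    g <- gm$geno[, j]
    maj <- major_allele(gm, gm$markers$marker_id[j])
    list(nonmiss = which(!is.na(g) & known),
         hom = g == paste(maj, maj, sep = "/"))
  })
  two_sided_from_counts <- function(a, r1, c1, n) {
    if (r1 == 0L || c1 == 0L || r1 == n || c1 == n) return(1)
    xs <- max(0L, r1 + c1 - n):min(r1, c1)
    lp <- stats::dhyper(xs, c1, n - c1, r1, log = TRUE)
    min(1, exp(logsumexp(lp[lp <= lp[match(a, xs)] + log(1 + 1e-7)])))
  }
  marker_p <- function(sexvec) {
    vapply(prep, function(pr) {
      idx <- pr$nonmiss
      s <- sexvec[idx]; hom <- pr$hom[idx]
      two_sided_from_counts(sum(s == "F" & hom), sum(s == "F"),
                            sum(hom), length(idx))
    }, 1)
  }
  p_obs <- marker_p(sex)
  set.seed(seed)
  mins <- vapply(seq_len(n_perm), function(b) {
    perm <- sex
    perm[known] <- sample(sex[known])
    min(marker_p(perm))
  }, 1)
  p_corr <- vapply(p_obs, function(p) (1 + sum(mins <= p)) / (n_perm + 1), 1)
  names(p_obs) <- names(p_corr) <- markers
  list(p_observed = p_obs, p_corrected = p_corr, n_perm = n_perm)
}

#' Marker-by-marker association scan
#'
#' Applies the MAF/call-rate filters, tests every passing marker with the
#' exact recessive-model test, and attaches Bonferroni (m = number of
#' passing markers) and optional max-T permutation corrections.
#'
#' @param gm a [genotype_matrix()]
#' @param model table model, see [build_table()].
#' @param maf_min,call_rate_min filter bounds, see [apply_marker_filters()].
#' @param n_perm permutations for the family-wise correction (0 = skip).
#' @param alpha level for the Bonferroni threshold.
#' @param seed permutation seed.
#' @return data.frame of class `assoc_result`: one row per marker with
#'   `marker_id`, `pos_bp`, `maf`, `call_rate`, `filtered`, `reason`,
#'   `p_one_sided`, `p_two_sided`, `p_bonferroni`, `p_permutation`,
#'   `neg_log10_p`; attribute `bonferroni_threshold` and `m_tests`.
#' @export
assoc_scan <- function(gm, model = "recessive", maf_min = 0.1,
                       call_rate_min = 0.99, n_perm = 0L, alpha = 0.05,
                       seed = 1L) {
  filt <- apply_marker_filters(gm, maf_min, call_rate_min)
  res <- data.frame(marker_id = gm$markers$marker_id,
                    pos_bp = gm$markers$pos_bp,
                    maf = filt$maf, call_rate = filt$call_rate,
                    filtered = !filt$pass, reason = filt$reason,
                    p_one_sided = NA_real_, p_two_sided = NA_real_,
                    p_bonferroni = NA_real_, p_permutation = NA_real_,
                    stringsAsFactors = FALSE)
  pass <- which(filt$pass)
  m <- length(pass)
  for (k in pass) {
    tab <- build_table(gm, res$marker_id[k], model = if (model == "allelic")
      "allelic" else "recessive")
    res$p_two_sided[k] <- fisher_exact(tab, "two_sided")
    res$p_one_sided[k] <- fisher_exact(tab, "one_sided")
  }
  if (m >= 1L) {
    bf <- bonferroni(res$p_two_sided[pass], alpha = alpha, m = m)
    res$p_bonferroni[pass] <- bf$adjusted
    attr(res, "bonferroni_threshold") <- bf$threshold
  }
  if (n_perm >= 1L && m >= 1L) {
    pc <- permutation_correction(gm, res$marker_id[pass], n_perm, seed)
    res$p_permutation[pass] <- pc$p_corrected
  }
  res$neg_log10_p <- -log10(res$p_two_sided)
  attr(res, "m_tests") <- m
  class(res) <- c("assoc_result", "data.frame")
  res
}
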