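#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by EM over the
#' double-heterozygote phase ambiguity (the only unphased configuration),
#' then summarized as D, D', r-squared and a LOD score against the D = 0
#' model. EM rather than composite genotype correlation is used because the
#' haplotype-level estimate is what flows through double heterozygotes —
#' e.g. the 40 double-heterozygous males behind the wild-panel r² = 0.7.
#'
#' @name linkage_disequilibrium
NULL

#' Joint genotype counts for two biallelic markers
#'
#' @param gm a [genotype_matrix()]
#' @param marker_i,marker_j marker ids
#' @return 3x3 integer matrix; rows = copies of the first allele at locus 1
#'   (2, 1, 0), columns likewise at locus 2. The "first allele" is each
#'   marker's major allele. Individuals missing at either marker are
#'   excluded. Attributes `alleles_i`, `alleles_j` give (major, minor).
#' @export
joint_genotype_counts <- function(gm, marker_i, marker_j) {
  ji <- marker_index(gm, marker_i); jj <- marker_index(gm, marker_j)
  gi <- gm$geno[, ji]; gj <- gm$geno[, jj]
  keep <- !is.na(gi) & !is.na(gj)
  maj_i <- as.character(major_allele(gm, marker_i))
  maj_j <- as.character(major_allele(gm, marker_j))
  dose <- function(g, maj) {
    sp <- split_geno(g)
    rowSums(sp == maj)
  }
  di <- dose(gi[keep], maj_i); dj <- dose(gj[keep], maj_j)
  tab <- table(factor(di, levels = 2:0), factor(dj, levels = 2:0))
  out <- matrix(as.integer(tab), 3L, 3L,
                dimnames = list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb")))
  min_i <- setdiff(marker_alleles(gm$markers)[[ji]], maj_i)[1L]
  min_j <- setdiff(marker_alleles(gm$markers)[[jj]], maj_j)[1L]
  attr(out, "alleles_i") <- c(maj_i, min_i)
  attr(out, "alleles_j") <- c(maj_j, min_j)
  out
}

# log-likelihood of 3x3 genotype counts given haplotype freqs p = (AB,Ab,aB,ab)
hap_loglik <- function(n, p) {
  gp <- matrix(0, 3L, 3L)
  gp[1L, 1L] <- p[1L]^2
  gp[1L, 2L] <- 2 * p[1L] * p[2L]
  gp[1L, 3L] <- p[2L]^2
  gp[2L, 1L] <- 2 * p[1L] * p[3L]
  gp[2L, 2L] <- 2 * p[1L] * p[4L] + 2 * p[2L] * p[3L]
  gp[2L, 3L] <- 2 * p[2L] * p[4L]
  gp[3L, 1L] <- p[3L]^2
  gp[3L, 2L] <- 2 * p[3L] * p[4L]
  gp[3L, 3L] <- p[4L]^2
  use <- n > 0L
  if (any(gp[use] <= 0)) return(-Inf)
  sum(n[use] * log(gp[use]))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' @param counts 3x3 joint genotype count matrix as from
#'   [joint_genotype_counts()] (rows: 2/1/0 copies of allele A, columns
#'   likewise for allele B).
#' @param tol convergence tolerance on the max absolute frequency change.
#' @param max_iter iteration cap.
#' @return object of class `haplotype_freqs`: list with `p` (named
#'   frequencies `AB`, `Ab`, `aB`, `ab`), `loglik`, `loglik_path`, `n_iter`,
#'   `converged`, `n_used`, `defined`. When either locus is monomorphic in
#'   the pairwise-complete subset, a flagged null result (`defined = FALSE`)
#'   is returned rather than an error.
#' @export
em_haplotypes <- function(counts, tol = 1e-10, max_iter = 1000L) {
  n <- as.matrix(counts)
  N <- sum(n)
  assert_that(N >= 1L, "need at least one individual genotyped at both loci")
  pA <- sum(n * matrix(c(2, 1, 0), 3L, 3L)) / (2 * N)
  pB <- sum(n * matrix(c(2, 1, 0), 3L, 3L, byrow = TRUE)) / (2 * N)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(structure(list(p = c(AB = NA_real_, Ab = NA_real_,
                                aB = NA_real_, ab = NA_real_),
                          loglik = NA_real_, loglik_path = numeric(0),
                          n_iter = 0L, converged = FALSE, n_used = N,
                          defined = FALSE),
                     class = "haplotype_freqs"))
  }
  ## known haplotype counts (all genotype classes except double hets)
  cAB <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  cAb <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
  caB <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  cab <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  dh <- n[2, 2]
  ## initialization: double heterozygotes split 50/50 between phases
  p <- c(cAB + dh / 2, cAb + dh / 2, caB + dh / 2, cab + dh / 2) / (2 * N)
  path <- hap_loglik(n, p)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    newp <- c(cAB + dh * w, cAb + dh * (1 - w),
              caB + dh * (1 - w), cab + dh * w) / (2 * N)
    path <- c(path, hap_loglik(n, newp))
    delta <- max(abs(newp - p))
    p <- newp
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(p = stats::setNames(p, c("AB", "Ab", "aB", "ab")),
                 loglik = path[length(path)], loglik_path = path,
                 n_iter = it, converged = converged, n_used = N,
                 defined = TRUE, counts = n),
            class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  if (!x$defined) {
    cat("<haplotype_freqs> undefined (monomorphic locus)\n")
  } else {
    cat(sprintf("<haplotype_freqs> AB=%.4f Ab=%.4f aB=%.4f ab=%.4f (n=%d, %d EM iterations%s)\n",
                x$p[1], x$p[2], x$p[3], x$p[4], x$n_used, x$n_iter,
                if (x$converged) "" else ", NOT converged"))
  }
  invisible(x)
}

#' LD statistics from estimated haplotype frequencies
#'
#' `D = p_AB - p_A p_B`; `D'` is `|D|/Dmax` with
#' `Dmax = min(p_A p_b, p_a p_B)` for `D > 0` and `min(p_A p_B, p_a p_b)`
#' for `D < 0`; `r² = D² / (p_A p_a p_B p_b)`; LOD is `log10` of the
#' likelihood ratio of the EM fit against the D = 0 model with allele
#' frequencies fixed at their MLEs (the usual definition behind "LOD >= 2"
#' shading in LD plots).
#'
#' @param h a [em_haplotypes()] result.
#' @return list of class `ld_pair`: `D`, `Dprime` (absolute, in `[0, 1]`),
#'   `r2`, `LOD`, `n_used`, `defined`.
#' @export
ld_stats <- function(h) {
  if (!isTRUE(h$defined)) {
    return(structure(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                          LOD = NA_real_, n_used = h$n_used,
                          defined = FALSE), class = "ld_pair"))
  }
  p <- h$p
  pA <- p[["AB"]] + p[["Ab"]]; pB <- p[["AB"]] + p[["aB"]]
  pa <- 1 - pA; pb <- 1 - pB
  if (pA <= 0 || pa <= 0 || pB <= 0 || pb <= 0) {
    return(structure(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                          LOD = NA_real_, n_used = h$n_used,
                          defined = FALSE), class = "ld_pair"))
  }
  D <- p[["AB"]] - pA * pB
  Dmax <- if (D >= 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  Dprime <- if (Dmax == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * pa * pB * pb)
  LOD <- if (is.null(h$counts)) NA_real_ else {
    p0 <- c(pA * pB, pA * pb, pa * pB, pa * pb)
    (hap_loglik(h$counts, p) - hap_loglik(h$counts, p0)) / log(10)
  }
  structure(list(D = unname(D), Dprime = unname(min(1, Dprime)),
                 r2 = unname(min(1, r2)), LOD = unname(LOD),
                 n_used = h$n_used, defined = TRUE),
            class = "ld_pair")
}

#' All-pairs LD matrix
#'
#' @param gm a [genotype_matrix()]
#' @param markers marker ids to include (default: all); pairs are ordered by
#'   marker index.
#' @param tol,max_iter EM controls passed to [em_haplotypes()].
#' @return data.frame with one row per unordered pair: `marker_i`,
#'   `marker_j`, `distance_bp`, `D`, `Dprime`, `r2`, `LOD`, `n_used`,
#'   `defined`.
#' @export
ld_matrix <- function(gm, markers = gm$markers$marker_id, tol = 1e-10,
                      max_iter = 1000L) {
  assert_that(length(markers) >= 2L, "need at least two markers")
  idx <- vapply(markers, marker_index, 1L, gm = gm)
  pos <- gm$markers$pos_bp[idx]
  out <- list()
  k <- 0L
  for (i in seq_along(markers)[-length(markers)]) {
    for (j in (i + 1L):length(markers)) {
      k <- k + 1L
      h <- em_haplotypes(joint_genotype_counts(gm, markers[i], markers[j]),
                         tol = tol, max_iter = max_iter)
      s <- ld_stats(h)
      out[[k]] <- data.frame(marker_i = markers[i], marker_j = markers[j],
                             distance_bp = abs(pos[j] - pos[i]),
                             D = s$D, Dprime = s$Dprime, r2 = s$r2,
                             LOD = s$LOD, n_used = s$n_used,
                             defined = s$defined, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
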