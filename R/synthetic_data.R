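#' Synthetic data generators
#'
#' Every input the discovery pipeline needs can be generated with the
#' statistical structure the analysis assumes: a wild population whose sex is
#' determined by heterozygosity at one causal SNP on otherwise freely
#' recombining proto-sex chromosomes; F1 families segregating the causal SNP
#' over a marker map with reduced male recombination; X/Y clone pairs more
#' than 99% identical; and multi-species panels sharing one trans-species
#' SNP. All generators are fully deterministic given their integer seed.
#'
#' @name synthetic_data
NULL

#' Parameters for the wild-population simulator
#'
#' Defaults emulate the study scale: a sample of 58 females and 47 males
#' genotyped at ~30 SNPs across a 17.5 kb region, with the causal SNP at
#' offset 7271. The population recombines freely across the region (no
#' suppression around the causal site); male recombination is reduced by the
#' `male_female_recomb_ratio` factor.
#'
#' @param n_females,n_males sample sizes of the final wild panel.
#' @param n_markers total markers incl. the causal SNP.
#' @param region_length_bp length of the simulated region.
#' @param causal_pos_bp offset of the causal SNP (heterozygote = male).
#' @param founder_haplotypes founder pool size; each discrete generation has
#'   `founder_haplotypes/2` individuals.
#' @param generations number of discrete non-overlapping generations.
#' @param recomb_rate_per_bp_per_meiosis female crossover rate per bp.
#' @param male_female_recomb_ratio male map length relative to female, in
#'   (0, 1].
#' @param mutation_rate per-site per-meiosis allele flip probability for
#'   neutral markers (the causal site never mutates, preserving the sex rule).
#' @param seed integer seed; same seed gives bit-identical output.
#' @return a list of class `wild_sim_params`
#' @export
wild_sim_params <- function(n_females = 58L, n_males = 47L, n_markers = 30L,
                            region_length_bp = 17500L, causal_pos_bp = 7271L,
                            founder_haplotypes = 400L, generations = 200L,
                            recomb_rate_per_bp_per_meiosis = 1e-5,
                            male_female_recomb_ratio = 0.5,
                            mutation_rate = 0, seed = 1L) {
  p <- list(n_females = as.integer(n_females), n_males = as.integer(n_males),
            n_markers = as.integer(n_markers),
            region_length_bp = as.integer(region_length_bp),
            causal_pos_bp = as.integer(causal_pos_bp),
            founder_haplotypes = as.integer(founder_haplotypes),
            generations = as.integer(generations),
            recomb_rate_per_bp_per_meiosis = recomb_rate_per_bp_per_meiosis,
            male_female_recomb_ratio = male_female_recomb_ratio,
            mutation_rate = mutation_rate, seed = as.integer(seed))
  assert_that(p$causal_pos_bp >= 1L &&
                p$causal_pos_bp <= p$region_length_bp,
              "causal_pos_bp must lie within the region")
  assert_that(p$recomb_rate_per_bp_per_meiosis >= 0 &&
                p$recomb_rate_per_bp_per_meiosis <= 1 &&
                p$mutation_rate >= 0 && p$mutation_rate <= 1,
              "rates must be in [0, 1]")
  assert_that(p$male_female_recomb_ratio > 0 &&
                p$male_female_recomb_ratio <= 1,
              "male_female_recomb_ratio must be in (0, 1]")
  assert_that(p$founder_haplotypes >= 4L && p$founder_haplotypes %% 2L == 0L,
              "founder_haplotypes must be an even number >= 4")
  assert_that(p$n_males >= 1L || p$generations == 0L,
              "impossible sex counts: fathers are required")
  class(p) <- "wild_sim_params"
  p
}

# One batch of gametes. H1/H2: (n_parent x m) 0/1 haplotype matrices;
# idx: parent row per gamete; crossover count is Poisson on the physical
# map (rate per bp, no interference), allele taken by crossover parity.
meiose <- function(H1, H2, idx, pos, region_len, rate) {
  n <- length(idx)
  m <- length(pos)
  k <- stats::rpois(n, rate * region_len)
  start <- sample.int(2L, n, replace = TRUE) - 1L   # 0 -> H1 first
  G <- matrix(0L, n, m)
  plain <- which(k == 0L)
  if (length(plain)) {
    use2 <- start[plain] == 1L
    G[plain[!use2], ] <- H1[idx[plain[!use2]], , drop = FALSE]
    G[plain[use2], ] <- H2[idx[plain[use2]], , drop = FALSE]
  }
  for (g in which(k > 0L)) {
    cuts <- sort(stats::runif(k[g], 0, region_len))
    strand <- (start[g] + findInterval(pos, cuts)) %% 2L
    G[g, ] <- ifelse(strand == 0L, H1[idx[g], ], H2[idx[g], ])
  }
  G
}

#' Forward-time simulation of a wild XY population
#'
#' Founder haplotype pool carries the derived allele at the causal SNP on
#' "Y-type" haplotypes only. Each generation, fathers are causal-site
#' heterozygotes and mothers homozygotes; gametes recombine X with Y freely
#' along the region (no suppression); offspring sex is its genotype at the
#' causal site (heterozygote = male). The final sample has the requested sex
#' counts.
#'
#' @param params a [wild_sim_params()]
#' @return list with `matrix` (unphased [genotype_matrix()]), and `truth`:
#'   phased haplotypes (`hap_pat`, `hap_mat`, 0 = ancestral, 1 = derived),
#'   the `map`, `causal_marker` id and allele lookup.
#' @export
simulate_wild_population <- function(params = wild_sim_params()) {
  p <- params
  set.seed(p$seed)
  ## marker map: causal + uniformly placed neutral SNPs
  stopifnot(p$n_markers >= 1L)
  other <- sample(setdiff(seq_len(p$region_length_bp), p$causal_pos_bp),
                  p$n_markers - 1L)
  pos <- sort(c(p$causal_pos_bp, other))
  causal_j <- match(p$causal_pos_bp, pos)
  bases <- c("A", "C", "G", "T")
  anc <- character(p$n_markers); der <- character(p$n_markers)
  for (j in seq_len(p$n_markers)) {
    ab <- sample(bases, 2L)
    anc[j] <- ab[1L]; der[j] <- ab[2L]
  }
  anc[causal_j] <- "C"; der[causal_j] <- "G"
  ids <- sprintf("snp%05d", pos)
  cm_f <- (pos - pos[1L]) * p$recomb_rate_per_bp_per_meiosis * 100
  mm <- marker_map(ids, chrom = "SD3-14k", pos_bp = pos, kind = "snp",
                   alleles = mapply(function(a, d) sort(c(a, d)), anc, der,
                                    SIMPLIFY = FALSE),
                   cm_female = cm_f,
                   cm_male = cm_f * p$male_female_recomb_ratio)

  n_ind <- p$founder_haplotypes %/% 2L
  n_m0 <- max(1L, n_ind %/% 2L)
  n_hap <- 2L * n_ind
  ## Founder variation follows an infinite-sites model on a random genealogy
  ## of the founder haplotypes: each neutral marker's derived allele is
  ## placed on one clade (sampled with probability proportional to clade
  ## size), so founder LD is tree-like (D' = 1 for every pair) and decays
  ## only through recombination. The Y-type haplotypes (the founder
  ## fathers' second haplotypes) form one clade carrying the causal derived
  ## allele.
  y_set <- n_ind + seq_len(n_m0)           # rows of H2 holding Y haplotypes
  clades <- list()
  split_clade <- function(set) {
    if (length(set) < 2L) return(invisible(NULL))
    repeat {
      grp <- stats::rbinom(length(set), 1L, 0.5)
      if (any(grp == 0L) && any(grp == 1L)) break
    }
    a <- set[grp == 0L]; b <- set[grp == 1L]
    clades[[length(clades) + 1L]] <<- a
    clades[[length(clades) + 1L]] <<- b
    split_clade(a); split_clade(b)
  }
  clades[[1L]] <- y_set
  clades[[2L]] <- setdiff(seq_len(n_hap), y_set)
  split_clade(clades[[1L]]); split_clade(clades[[2L]])
  sizes <- lengths(clades)
  ## neutral mutations never land on the Y clade or its complement: the
  ## causal SNP is the unique perfectly sex-linked founder variant by
  ## construction (neutral markers are sex-associated only by chance)
  neutral_ok <- seq_along(clades)[-(1:2)]
  H <- matrix(0L, n_hap, p$n_markers)      # rows 1..n_ind = H1, rest = H2
  for (j in seq_len(p$n_markers)) {
    if (j == causal_j) next
    cl <- clades[[sample(neutral_ok, 1L, prob = sizes[neutral_ok])]]
    H[cl, j] <- 1L
  }
  H[y_set, causal_j] <- 1L
  H1 <- H[seq_len(n_ind), , drop = FALSE]
  H2 <- H[n_ind + seq_len(n_ind), , drop = FALSE]
  founders <- H

  rate_f <- p$recomb_rate_per_bp_per_meiosis
  rate_m <- rate_f * p$male_female_recomb_ratio
  next_gen <- function(H1, H2, n_off) {
    g <- H1[, causal_j] + H2[, causal_j]
    fathers <- which(g == 1L)
    mothers <- which(g != 1L)
    assert_that(length(fathers) > 0L && length(mothers) > 0L,
                "population lost one sex; increase founder_haplotypes")
    fi <- fathers[sample.int(length(fathers), n_off, replace = TRUE)]
    mi <- mothers[sample.int(length(mothers), n_off, replace = TRUE)]
    pat <- meiose(H1, H2, fi, pos, p$region_length_bp, rate_m)
    mat <- meiose(H1, H2, mi, pos, p$region_length_bp, rate_f)
    if (p$mutation_rate > 0) {
      for (M in c("pat", "mat")) {
        X <- get(M)
        flip <- matrix(stats::rbinom(length(X), 1L, p$mutation_rate),
                       nrow(X))
        flip[, causal_j] <- 0L
        assign(M, abs(X - flip) %% 2L + 0L)
      }
    }
    list(pat = pat, mat = mat)
  }

  for (gen in seq_len(p$generations)) {
    off <- next_gen(H1, H2, n_ind)
    H1 <- off$mat; H2 <- off$pat
  }

  ## final brood: draw until requested sex counts are met
  need_f <- p$n_females; need_m <- p$n_males
  pat_keep <- NULL; mat_keep <- NULL; sex_keep <- character(0)
  tries <- 0L
  while ((need_f > 0L || need_m > 0L) && tries < 200L) {
    tries <- tries + 1L
    off <- next_gen(H1, H2, max(2L * (need_f + need_m), 20L))
    sex <- ifelse(off$pat[, causal_j] + off$mat[, causal_j] == 1L, "M", "F")
    take_f <- which(sex == "F")[seq_len(min(need_f, sum(sex == "F")))]
    take_m <- which(sex == "M")[seq_len(min(need_m, sum(sex == "M")))]
    take <- c(take_f, take_m)
    pat_keep <- rbind(pat_keep, off$pat[take, , drop = FALSE])
    mat_keep <- rbind(mat_keep, off$mat[take, , drop = FALSE])
    sex_keep <- c(sex_keep, sex[take])
    need_f <- need_f - length(take_f); need_m <- need_m - length(take_m)
  }
  assert_that(need_f == 0L && need_m == 0L,
              "could not realize requested sex counts")
  o <- order(sex_keep, decreasing = FALSE)   # females first
  pat_keep <- pat_keep[o, , drop = FALSE]
  mat_keep <- mat_keep[o, , drop = FALSE]
  sex_keep <- sex_keep[o]

  to_base <- function(H) {
    out <- matrix(anc, nrow(H), ncol(H), byrow = TRUE)
    out[H == 1L] <- matrix(der, nrow(H), ncol(H), byrow = TRUE)[H == 1L]
    out
  }
  A1 <- to_base(pat_keep); A2 <- to_base(mat_keep)
  geno <- matrix(geno_string(as.vector(A1), as.vector(A2)),
                 nrow(A1), ncol(A1))
  n <- length(sex_keep)
  ind <- data.frame(id = sprintf("wild%03d", seq_len(n)), sex = sex_keep,
                    population = "wild", role = "unrelated",
                    stringsAsFactors = FALSE)
  gm <- genotype_matrix(ind, mm, geno)
  list(matrix = gm,
       truth = list(hap_pat = pat_keep, hap_mat = mat_keep, map = mm,
                    causal_marker = ids[causal_j],
                    founders = founders,
                    ancestral = stats::setNames(anc, ids),
                    derived = stats::setNames(der, ids)))
}

#' Parameters for the F1 family simulator
#'
#' @param n_offspring number of offspring to generate.
#' @param map a [marker_map()] with cumulative `cm_female` / `cm_male`.
#' @param causal_marker id of the sex-determining marker on the map.
#' @param informative_fraction fraction of markers at which the cross is
#'   informative for paternal transmission (father heterozygous, mother
#'   homozygous for one paternal allele).
#' @param seed integer seed.
#' @return a list of class `family_sim_params`
#' @export
family_sim_params <- function(n_offspring, map, causal_marker,
                              informative_fraction = 1, seed = 1L) {
  assert_that(causal_marker %in% map$marker_id, "causal marker not on map")
  structure(list(n_offspring = as.integer(n_offspring), map = map,
                 causal_marker = causal_marker,
                 informative_fraction = informative_fraction,
                 seed = as.integer(seed)),
            class = "family_sim_params")
}

# Haldane gamete along a cumulative cM map: crossovers ~ Poisson(L/100),
# positions uniform on the cM scale, no interference.
haldane_gamete <- function(hapA, hapB, cm) {
  L <- max(cm) - min(cm)
  k <- if (L > 0) stats::rpois(1L, L / 100) else 0L
  start <- sample.int(2L, 1L) - 1L
  if (k == 0L) {
    strand <- rep(start, length(cm))
    cuts <- numeric(0)
  } else {
    cuts <- sort(stats::runif(k, min(cm), max(cm)))
    strand <- (start + findInterval(cm, cuts)) %% 2L
  }
  list(alleles = ifelse(strand == 0L, hapA, hapB),
       from_A = strand == 0L, cuts = cuts)
}

#' Simulate an F1 family segregating an XY causal marker
#'
#' Offspring receive a paternal gamete generated by a Poisson/Haldane
#' crossover process on the male map (`cm_male`) and a maternal gamete on the
#' female map. Offspring sex is assigned by the paternal allele at the causal
#' marker (Y-type allele = male). The phased truth (transmitted X/Y labels
#' and crossover points) is returned alongside the unphased matrix.
#'
#' @param params a [family_sim_params()]
#' @param father_phase optional list with character vectors `x` and `y`
#'   (paternal haplotype alleles along the map). Defaults to an informative
#'   cross: X carries each marker's first allele, Y the second, at markers
#'   selected by `informative_fraction`; elsewhere the father is homozygous.
#' @param mother_genotypes optional character vector of the mother's
#'   genotypes (`"A/B"`); defaults to homozygous first-allele everywhere.
#' @return list with `matrix` (father, mother and offspring rows) and
#'   `truth` (per-offspring transmitted labels `"X"`/`"Y"` per marker,
#'   paternal crossover positions in cM, father phase).
#' @export
simulate_family <- function(params, father_phase = NULL,
                            mother_genotypes = NULL) {
  p <- params
  set.seed(p$seed)
  mm <- p$map
  m <- nrow(mm)
  al <- marker_alleles(mm)
  cj <- match(p$causal_marker, mm$marker_id)
  informative <- stats::runif(m) <= p$informative_fraction
  informative[cj] <- TRUE
  if (is.null(father_phase)) {
    father_phase <- list(
      x = vapply(al, `[`, "", 1L),
      y = ifelse(informative,
                 vapply(al, function(a) a[min(2L, length(a))], ""),
                 vapply(al, `[`, "", 1L)))
  }
  fx <- father_phase$x; fy <- father_phase$y
  if (fx[cj] == fy[cj])
    stop("invalid-parent: father homozygous at the causal marker",
         call. = FALSE)
  if (is.null(mother_genotypes))
    mother_genotypes <- geno_string(vapply(al, `[`, "", 1L),
                                    vapply(al, `[`, "", 1L))
  msp <- split_geno(mother_genotypes)

  n <- p$n_offspring
  geno <- matrix(NA_character_, n + 2L, m)
  geno[1L, ] <- geno_string(fx, fy)
  geno[2L, ] <- mother_genotypes
  labels <- matrix(NA_character_, n, m)
  cuts <- vector("list", n)
  sex <- character(n)
  for (i in seq_len(n)) {
    pg <- haldane_gamete(fx, fy, mm$cm_male)
    mg <- haldane_gamete(msp[, 1L], msp[, 2L], mm$cm_female)
    geno[i + 2L, ] <- geno_string(pg$alleles, mg$alleles)
    labels[i, ] <- ifelse(pg$from_A, "X", "Y")
    cuts[[i]] <- pg$cuts
    sex[i] <- if (labels[i, cj] == "Y") "M" else "F"
  }
  ids <- c("father", "mother", sprintf("off%04d", seq_len(n)))
  ind <- data.frame(id = ids,
                    sex = c("M", "F", sex),
                    population = "fam1",
                    role = c("father", "mother", rep("offspring", n)),
                    stringsAsFactors = FALSE)
  rownames(labels) <- ids[-(1:2)]
  colnames(labels) <- mm$marker_id
  gm <- genotype_matrix(ind, mm, geno)
  list(matrix = gm,
       truth = list(labels = labels, crossovers_cm = cuts,
                    father_phase = list(x = fx, y = fy),
                    causal_marker = p$causal_marker,
                    informative = stats::setNames(informative, mm$marker_id)))
}

#' Parameters for the X/Y clone-pair simulator
#'
#' @param length_bp clone length (default 14 kb, the sequenced clone size).
#' @param target_identity fraction of identical positions; the study's clones
#'   were 99.4% (SD2-14k) and 99.6% (SD3-14k) identical.
#' @param seed integer seed.
#' @return a list of class `clone_pair_params`
#' @export
clone_pair_params <- function(length_bp = 14000L, target_identity = 0.994,
                              seed = 1L) {
  assert_that(length_bp >= 1L, "zero-length clone")
  assert_that(target_identity > 0 && target_identity <= 1,
              "target_identity must be in (0, 1]")
  structure(list(length_bp = as.integer(length_bp),
                 target_identity = target_identity, seed = as.integer(seed)),
            class = "clone_pair_params")
}

#' Simulate an X/Y clone pair
#'
#' Generates a random reference (X) and a copy (Y) with
#' `floor((1 - identity) * L)` substitutions at distinct positions; no
#' indels.
#'
#' @param params a [clone_pair_params()]
#' @return list with `x`, `y` (character sequences) and `substitutions`
#'   (data.frame `pos`, `x_base`, `y_base`).
#' @export
simulate_clone_pair <- function(params = clone_pair_params()) {
  p <- params
  set.seed(p$seed)
  x <- sample(c("A", "C", "G", "T"), p$length_bp, replace = TRUE)
  n_sub <- floor((1 - p$target_identity) * p$length_bp)
  pos <- sort(sample.int(p$length_bp, n_sub))
  y <- x
  for (i in pos) y[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
  list(x = paste(x, collapse = ""), y = paste(y, collapse = ""),
       substitutions = data.frame(pos = pos, x_base = x[pos], y_base = y[pos],
                                  stringsAsFactors = FALSE))
}

#' Write an X/Y clone pair as FASTA
#' @param pair result of [simulate_clone_pair()]
#' @param path output FASTA
#' @param names sequence names
#' @return `path`, invisibly
#' @export
write_clone_fasta <- function(pair, path, names = c("cloneX", "cloneY")) {
  seqs <- Biostrings::DNAStringSet(c(pair$x, pair$y))
  names(seqs) <- names
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Simulate per-species SNP panels sharing (or not) one trans-species SNP
#'
#' Each species' panel has a causal SNP segregating with perfect sex
#' association when `shared_snp` (same position, same C/G alleles in every
#' species), plus species-private neutral SNPs that are sex-associated only
#' by chance. Coordinates are on a common pre-mapped reference region.
#'
#' @param n_species number of species.
#' @param n_females,n_males per-species sample sizes (recycled); defaults are
#'   the study's panels (8/8, 8/8, 6/7).
#' @param shared_snp include the shared causal SNP in all species?
#' @param n_private species-private neutral SNPs per species.
#' @param causal_pos_bp common coordinate of the shared SNP.
#' @param seed integer seed.
#' @return named list of [genotype_matrix()] objects, one per species.
#' @export
simulate_species_panels <- function(n_species = 3L,
                                    n_females = c(8L, 8L, 6L),
                                    n_males = c(8L, 8L, 7L),
                                    shared_snp = TRUE, n_private = 3L,
                                    causal_pos_bp = 7271L, seed = 1L) {
  n_females <- rep_len(as.integer(n_females), n_species)
  n_males <- rep_len(as.integer(n_males), n_species)
  assert_that(all(n_females >= 1L) && all(n_males >= 1L),
              "need >= 1 individual per sex per species")
  set.seed(seed)
  region <- c(causal_pos_bp - 200L, causal_pos_bp + 400L)
  avail <- setdiff(seq(region[1L], region[2L]), causal_pos_bp)
  panels <- list()
  for (s in seq_len(n_species)) {
    set.seed(derive_seed(seed, s))
    nf <- n_females[s]; nm <- n_males[s]; n <- nf + nm
    priv_pos <- sort(sample(avail, n_private))
    avail <- setdiff(avail, priv_pos)   # private = unique to this species
    pos <- sort(c(if (shared_snp) causal_pos_bp, priv_pos))
    mcount <- length(pos)
    alleles <- lapply(seq_len(mcount), function(j) sort(sample(c("A", "C", "G", "T"), 2L)))
    geno <- matrix(NA_character_, n, mcount)
    for (j in seq_len(mcount)) {
      if (shared_snp && pos[j] == causal_pos_bp) {
        alleles[[j]] <- c("C", "G")
        geno[, j] <- c(rep("C/C", nf), rep("C/G", nm))
      } else {
        f <- stats::runif(1L, 0.2, 0.8)
        a <- matrix(sample(alleles[[j]], 2L * n, replace = TRUE,
                           prob = c(f, 1 - f)), n)
        geno[, j] <- geno_string(a[, 1L], a[, 2L])
      }
    }
    mm <- marker_map(sprintf("sp%d_%05d", s, pos), chrom = "amhr2_exon9",
                     pos_bp = pos, kind = "snp", alleles = alleles)
    ## marker_map orders by pos; geno columns built in pos order already
    ind <- data.frame(id = sprintf("sp%d_ind%02d", s, seq_len(n)),
                      sex = c(rep("F", nf), rep("M", nm)),
                      population = sprintf("species%d", s),
                      role = "unrelated", stringsAsFactors = FALSE)
    panels[[sprintf("species%d", s)]] <- genotype_matrix(ind, mm, geno)
  }
  panels
}
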