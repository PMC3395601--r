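#' Pedigree recombinant screening and SD-interval refinement
#'
#' In an XY family, the father's two haplotypes across the SD region can be
#' labelled X-type and Y-type: the alleles transmitted to nonrecombinant
#' females define the X haplotype and those transmitted to nonrecombinant
#' males the Y haplotype. Offspring whose transmitted paternal type switches
#' along the map are recombinants, and markers at which any offspring's
#' transmitted type contradicts its phenotypic sex are excluded from the
#' candidate region; the SD interval is the maximal run of consecutive
#' non-excluded markers, bounded by the innermost excluding markers.
#'
#' @name linkage_mapping
NULL

# paternal transmitted allele for one offspring at one marker, or NA when
# transmission cannot be resolved against the mother's genotype
resolve_paternal <- function(off, father, mother) {
  if (is.na(off) || is.na(father)) return(NA_character_)
  fo <- strsplit(off, "/", fixed = TRUE)[[1L]]
  fa <- unique(strsplit(father, "/", fixed = TRUE)[[1L]])
  if (length(fa) < 2L) return(NA_character_)      # father homozygous
  mo <- if (is.na(mother)) NULL else strsplit(mother, "/", fixed = TRUE)[[1L]]
  cand <- character(0)
  for (p in fa) {
    rest <- fo
    hit <- match(p, rest)
    if (is.na(hit)) next
    q <- rest[-hit]
    if (is.null(mo) || q %in% mo) cand <- c(cand, p)
  }
  cand <- unique(cand)
  if (length(cand) == 1L) cand else NA_character_
}

# matrix of resolved paternal transmitted alleles (offspring x markers)
paternal_allele_matrix <- function(gm) {
  roles <- gm$individuals$role
  fi <- which(roles == "father"); mi <- which(roles == "mother")
  oi <- which(roles == "offspring")
  assert_that(length(fi) == 1L, "family must contain exactly one father")
  assert_that(length(oi) >= 1L, "phase-undetermined: no offspring")
  m <- ncol(gm$geno)
  out <- matrix(NA_character_, length(oi), m,
                dimnames = list(gm$individuals$id[oi],
                                gm$markers$marker_id))
  for (j in seq_len(m)) {
    fg <- gm$geno[fi, j]
    mg <- if (length(mi) == 1L) gm$geno[mi, j] else NA_character_
    for (k in seq_along(oi))
      out[k, j] <- resolve_paternal(gm$geno[oi[k], j], fg, mg)
  }
  out
}

majority <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return(NA_character_) # tie
  names(tab)[1L]
}

#' Infer the father's X and Y haplotypes from transmission
#'
#' Two-pass majority vote. First, at every marker where the paternal
#' transmitted allele is resolvable, the allele transmitted to the majority
#' of male offspring is provisionally labelled Y-type and to the majority of
#' females X-type. Offspring whose provisional labels are constant along the
#' map are taken as nonrecombinant anchors, and the vote is repeated over
#' those anchors only, which makes the labels robust to isolated genotyping
#' errors and to recombinants. Markers where the father is homozygous, or
#' where the X and Y votes conflict, are flagged uninformative.
#'
#' @param gm family [genotype_matrix()] with father/mother/offspring roles.
#' @param anchor marker id at which the father must be heterozygous (usually
#'   the causal or closest sex-linked marker).
#' @return object of class `paternal_phase`: data.frame with `marker_id`,
#'   `x_allele`, `y_allele`, `informative`.
#' @export
infer_paternal_phase <- function(gm, anchor) {
  ja <- marker_index(gm, anchor)
  fi <- which(gm$individuals$role == "father")
  assert_that(length(fi) == 1L && !is.na(gm$geno[fi, ja]),
              "father not genotyped at anchor")
  fa <- strsplit(gm$geno[fi, ja], "/", fixed = TRUE)[[1L]]
  assert_that(fa[1L] != fa[2L], "father must be heterozygous at the anchor")
  pat <- paternal_allele_matrix(gm)
  oi <- which(gm$individuals$role == "offspring")
  sex <- gm$individuals$sex[oi]

  vote <- function(rows) {
    t(vapply(seq_len(ncol(pat)), function(j) {
      y <- majority(pat[rows & sex == "M", j])
      x <- majority(pat[rows & sex == "F", j])
      if (!is.na(x) && !is.na(y) && x == y) c(NA_character_, NA_character_)
      else c(x, y)
    }, character(2L)))
  }
  all_rows <- rep(TRUE, nrow(pat))
  v1 <- vote(all_rows)
  ## provisional per-offspring labels; nonrecombinant = constant label
  lab1 <- label_against_phase(pat, v1[, 1L], v1[, 2L])
  nonrec <- apply(lab1, 1L, function(l) {
    l <- l[l != "uninformative"]
    length(l) > 0L && length(unique(l)) == 1L
  })
  assert_that(any(nonrec & sex == "M") && any(nonrec & sex == "F"),
              "phase-undetermined: no nonrecombinant offspring of each sex")
  v2 <- vote(nonrec)
  out <- data.frame(marker_id = gm$markers$marker_id,
                    x_allele = v2[, 1L], y_allele = v2[, 2L],
                    stringsAsFactors = FALSE)
  out$informative <- !is.na(out$x_allele) & !is.na(out$y_allele) &
    out$x_allele != out$y_allele
  out$x_allele[!out$informative] <- NA_character_
  out$y_allele[!out$informative] <- NA_character_
  class(out) <- c("paternal_phase", "data.frame")
  out
}

label_against_phase <- function(pat, x_allele, y_allele) {
  lab <- matrix("uninformative", nrow(pat), ncol(pat),
                dimnames = dimnames(pat))
  for (j in seq_len(ncol(pat))) {
    if (is.na(x_allele[j]) || is.na(y_allele[j]) ||
        x_allele[j] == y_allele[j]) next
    lab[, j] <- ifelse(is.na(pat[, j]), "uninformative",
                       ifelse(pat[, j] == x_allele[j], "X",
                              ifelse(pat[, j] == y_allele[j], "Y",
                                     "uninformative")))
  }
  lab
}

#' Transmitted paternal haplotype labels for every offspring
#'
#' @param gm family [genotype_matrix()]
#' @param phase a [infer_paternal_phase()] result (or compatible data.frame
#'   with `x_allele` / `y_allele`).
#' @return list per offspring with `labels` (`"X"`, `"Y"`, `"uninformative"`
#'   along the map) and `crossover_intervals` (data.frame `left_marker`,
#'   `right_marker`: adjacent informative markers where the label switches).
#' @export
transmitted_haplotypes <- function(gm, phase) {
  pat <- paternal_allele_matrix(gm)
  lab <- label_against_phase(pat, phase$x_allele, phase$y_allele)
  mk <- gm$markers$marker_id
  lapply(stats::setNames(seq_len(nrow(lab)), rownames(lab)), function(i) {
    l <- lab[i, ]
    inf <- which(l != "uninformative")
    sw <- inf[which(l[inf[-1L]] != l[inf[-length(inf)]])]
    swr <- inf[which(l[inf[-1L]] != l[inf[-length(inf)]]) + 1L]
    list(offspring_id = rownames(lab)[i],
         labels = stats::setNames(l, mk),
         crossover_intervals = data.frame(left_marker = mk[sw],
                                          right_marker = mk[swr],
                                          stringsAsFactors = FALSE))
  })
}

#' Screen offspring for recombinants between two flanking markers
#'
#' @param gm family [genotype_matrix()]
#' @param flank_left,flank_right marker ids of the screening flanks.
#' @param phase optional precomputed [infer_paternal_phase()]; inferred with
#'   `flank_left` as anchor when omitted.
#' @return object of class `recombinant_report`: list with `recombinant_ids`,
#'   `haplotypes` (per-recombinant transmitted haplotypes),
#'   `uninformative_ids` (offspring unresolvable at either flank, reported
#'   separately, never guessed) and `n_screened`.
#' @export
find_recombinants <- function(gm, flank_left, flank_right, phase = NULL) {
  jl <- marker_index(gm, flank_left)
  jr <- marker_index(gm, flank_right)
  if (is.null(phase)) phase <- infer_paternal_phase(gm, flank_left)
  haps <- transmitted_haplotypes(gm, phase)
  ll <- vapply(haps, function(h) h$labels[[jl]], "")
  lr <- vapply(haps, function(h) h$labels[[jr]], "")
  informative <- ll != "uninformative" & lr != "uninformative"
  rec <- informative & ll != lr
  structure(list(recombinant_ids = names(haps)[rec],
                 haplotypes = haps[rec],
                 uninformative_ids = names(haps)[!informative],
                 n_screened = length(haps),
                 phase = phase,
                 sexes = stats::setNames(
                   gm$individuals$sex[match(names(haps),
                                            gm$individuals$id)],
                   names(haps))),
            class = "recombinant_report")
}

#' @export
print.recombinant_report <- function(x, ...) {
  cat(sprintf("<recombinant_report> %d recombinant(s) / %d screened (%d uninformative at a flank)\n",
              length(x$recombinant_ids), x$n_screened,
              length(x$uninformative_ids)))
  invisible(x)
}

#' Write a recombinant report as TSV (one row per recombinant, one column
#' per marker with X/Y/. labels), mirroring the classic box diagram.
#' @param report a `recombinant_report`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_recombinant_report <- function(report, path) {
  mk <- names(report$haplotypes[[1]]$labels) %||% character(0)
  header <- paste(c("offspring_id", "sex", mk), collapse = "\t")
  rows <- vapply(report$haplotypes, function(h) {
    l <- h$labels
    l[l == "uninformative"] <- "."
    paste(c(h$offspring_id, report$sexes[[h$offspring_id]], l),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Refine the SD interval from recombinant offspring
#'
#' A marker is excluded when any recombinant's transmitted paternal type
#' there contradicts its phenotypic sex (male = Y-type, female = X-type).
#' The candidate interval is the maximal run of consecutive non-excluded
#' markers; its bounds are the positions of the innermost excluding markers
#' on each side (an open interval, as the region is defined by its boundary
#' markers). If several maximal runs exist, all are returned and the result
#' is flagged ambiguous. Offspring with uninformative labels at a marker
#' contribute no constraint there.
#'
#' @param reports one `recombinant_report` or a list of them (multiple
#'   families); sexes are taken from the reports.
#' @param map a [marker_map()] covering the screened markers.
#' @return list with `interval` (an [sd_interval()], for the run containing
#'   the most markers; ties resolved to the first and flagged), `intervals`
#'   (all maximal runs), `mismatch` per-marker exclusion table, `ambiguous`.
#' @export
refine_sd_interval <- function(reports, map) {
  if (inherits(reports, "recombinant_report")) reports <- list(reports)
  assert_that(sum(vapply(reports, function(r) length(r$recombinant_ids),
                         1L)) >= 1L, "need at least one recombinant")
  mk <- map$marker_id
  mismatch <- matrix(0L, length(mk), 2L,
                     dimnames = list(mk, c("n_informative", "n_conflict")))
  for (r in reports) {
    for (h in r$haplotypes) {
      sex <- r$sexes[[h$offspring_id]]
      assert_that(sex %in% c("F", "M"),
                  "recombinant sexes must be known for refinement")
      want <- if (sex == "M") "Y" else "X"
      l <- h$labels[mk]
      inf <- !is.na(l) & l != "uninformative"
      mismatch[inf, 1L] <- mismatch[inf, 1L] + 1L
      bad <- inf & l != want
      mismatch[bad, 2L] <- mismatch[bad, 2L] + 1L
    }
  }
  excluded <- mismatch[, "n_conflict"] > 0L
  if (all(excluded))
    stop("no-interval: every marker contradicts some recombinant's sex",
         call. = FALSE)
  ## maximal runs of consecutive non-excluded markers
  r <- rle(!excluded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  runs <- lapply(keep, function(k) starts[k]:ends[k])
  make_int <- function(run) {
    li <- min(run) - 1L; ri <- max(run) + 1L
    left_id <- if (li >= 1L) mk[li] else NA_character_
    right_id <- if (ri <= length(mk)) mk[ri] else NA_character_
    start <- if (li >= 1L) map$pos_bp[li] else map$pos_bp[1L]
    end <- if (ri <= length(mk)) map$pos_bp[ri] else map$pos_bp[length(mk)]
    sd_interval(map$chrom[1L], start, end, left_id, right_id)
  }
  intervals <- lapply(runs, make_int)
  widths <- lengths(runs)
  best <- which.max(widths)
  ambiguous <- length(runs) > 1L
  iv <- intervals[[best]]
  iv$ambiguous <- ambiguous
  list(interval = iv, intervals = intervals,
       mismatch = as.data.frame(mismatch), ambiguous = ambiguous)
}
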