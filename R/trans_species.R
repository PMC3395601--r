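#' Trans-species polymorphism detection and pooled association
#'
#' A polymorphism maintained across species that diverged millions of years
#' ago is strong evidence of balancing selection — here, selection on sex.
#' Variants are matched across species panels by position *and* allele pair
#' on a common pre-mapped reference region; a variant is conserved-associated
#' only when it shows perfect genotype-sex correspondence (zero recessive
#' discordance) in every species where it is present.
#'
#' @name trans_species
NULL

panel_markers <- function(panel) {
  mm <- panel$markers
  data.frame(pos_bp = mm$pos_bp, marker_id = mm$marker_id,
             alleles = vapply(marker_alleles(mm),
                              function(a) paste(sort(a), collapse = "/"), ""),
             stringsAsFactors = FALSE)
}

is_polymorphic <- function(panel, marker) {
  j <- marker_index(panel, marker)
  tab <- allele_count_table(panel, j)
  sum(tab > 0L) >= 2L
}

#' Variants polymorphic in two or more species
#'
#' @param panels named list of per-species [genotype_matrix()] panels on a
#'   shared coordinate system.
#' @return data.frame per variant position: `pos_bp`, `alleles`,
#'   `present_in` (comma-joined species where both alleles segregate),
#'   `n_species`. Positions typed in several species with inconsistent
#'   allele definitions raise a coordinate-conflict error.
#' @export
shared_polymorphisms <- function(panels) {
  if (length(panels) == 0L)
    return(data.frame(pos_bp = integer(0), alleles = character(0),
                      present_in = character(0), n_species = integer(0)))
  species <- names(panels) %||% sprintf("species%d", seq_along(panels))
  rows <- do.call(rbind, lapply(seq_along(panels), function(s) {
    pm <- panel_markers(panels[[s]])
    pm$species <- species[s]
    pm$polymorphic <- vapply(pm$marker_id, is_polymorphic, TRUE,
                             panel = panels[[s]])
    pm
  }))
  out <- list()
  for (pos in sort(unique(rows$pos_bp))) {
    sub <- rows[rows$pos_bp == pos & rows$polymorphic, , drop = FALSE]
    if (nrow(sub) == 0L) next
    if (length(unique(sub$alleles)) > 1L)
      stop(sprintf("coordinate-conflict at %d: allele sets %s", pos,
                   paste(unique(sub$alleles), collapse = " vs ")),
           call. = FALSE)
    out[[length(out) + 1L]] <-
      data.frame(pos_bp = pos, alleles = sub$alleles[1L],
                 present_in = paste(sub$species, collapse = ","),
                 n_species = nrow(sub), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(pos_bp = integer(0), alleles = character(0),
               present_in = character(0), n_species = integer(0))
  rownames(res) <- NULL
  res
}

panel_marker_at <- function(panel, pos_bp) {
  j <- match(pos_bp, panel$markers$pos_bp)
  if (is.na(j)) NA_character_ else panel$markers$marker_id[j]
}

#' Per-species exact sex association at one position
#'
#' A genotypic 2x2 test (homozygous-major vs other, by sex) per species,
#' using the point-probability two-sided exact test. Species where the site
#' is monomorphic are flagged with `NA` p.
#'
#' @param panels named list of species panels.
#' @param pos_bp shared variant position.
#' @return data.frame `species`, `p_two_sided`, `n_discordant`, `n_used`,
#'   `monomorphic`.
#' @export
per_species_association <- function(panels, pos_bp) {
  species <- names(panels) %||% sprintf("species%d", seq_along(panels))
  out <- do.call(rbind, lapply(seq_along(panels), function(s) {
    panel <- panels[[s]]
    mk <- panel_marker_at(panel, pos_bp)
    if (is.na(mk))
      return(data.frame(species = species[s], p_two_sided = NA_real_,
                        n_discordant = NA_integer_, n_used = 0L,
                        monomorphic = NA, stringsAsFactors = FALSE))
    mono <- !is_polymorphic(panel, mk)
    if (mono)
      return(data.frame(species = species[s], p_two_sided = NA_real_,
                        n_discordant = NA_integer_, n_used = 0L,
                        monomorphic = TRUE, stringsAsFactors = FALSE))
    tab <- build_table(panel, mk, "genotypic_2x2")
    disc <- recessive_discordance(panel, mk)
    data.frame(species = species[s],
               p_two_sided = fisher_exact(tab, "two_sided"),
               n_discordant = disc$n_discordant, n_used = sum(tab),
               monomorphic = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled allele-count association across species
#'
#' Allele counts by sex are summed across all species where the site is
#' typed, into one 2x2 (allele x sex) table tested with the two-sided exact
#' test. Alleles are oriented by the across-species major allele so counts
#' add coherently.
#'
#' @param panels named list of species panels.
#' @param pos_bp shared variant position.
#' @return list `p_pooled`, `table` (2x2 allele-by-sex counts),
#'   `per_species` (the [per_species_association()] frame).
#' @export
pooled_association <- function(panels, pos_bp) {
  typed <- Filter(function(p) !is.na(panel_marker_at(p, pos_bp)), panels)
  assert_that(length(typed) >= 1L, "variant typed in no panel")
  ## pooled allele counts by sex
  tot <- matrix(0L, 2L, 2L, dimnames = list(c("F", "M"), NULL))
  allele_names <- NULL
  for (panel in typed) {
    mk <- panel_marker_at(panel, pos_bp)
    j <- marker_index(panel, mk)
    al <- sort(marker_alleles(panel$markers)[[j]])
    if (is.null(allele_names)) allele_names <- al
    assert_that(identical(al, allele_names),
                sprintf("coordinate-conflict at %d", pos_bp))
    g <- panel$geno[, j]
    sex <- panel$individuals$sex
    keep <- !is.na(g) & sex %in% c("F", "M")
    sp <- split_geno(g[keep])
    sx <- rep(sex[keep], 2L)
    for (r in 1:2) for (cc in 1:2)
      tot[r, cc] <- tot[r, cc] +
        sum(sx == c("F", "M")[r] & as.vector(sp) == allele_names[cc])
  }
  colnames(tot) <- allele_names
  list(p_pooled = fisher_exact(tot, "two_sided"), table = tot,
       per_species = per_species_association(panels, pos_bp))
}

#' Conservation report over all variant positions
#'
#' Verdicts: `conserved_associated` — polymorphic in >= 2 species with zero
#' recessive discordance in *every* species where present; `private` —
#' polymorphic in exactly one species; `conserved_unassociated` — shared but
#' discordant somewhere.
#'
#' @param panels named list of species panels.
#' @return data.frame per variant: `pos_bp`, `alleles`, `present_in`,
#'   `associated_in`, `p_pooled`, `verdict`; invariant under species
#'   ordering.
#' @export
conservation_report <- function(panels) {
  shared <- shared_polymorphisms(panels)
  species <- names(panels) %||% sprintf("species%d", seq_along(panels))
  all_pos <- sort(unique(unlist(lapply(panels,
                                       function(p) p$markers$pos_bp))))
  out <- do.call(rbind, lapply(all_pos, function(pos) {
    pres <- species[vapply(seq_along(panels), function(s) {
      mk <- panel_marker_at(panels[[s]], pos)
      !is.na(mk) && is_polymorphic(panels[[s]], mk)
    }, TRUE)]
    if (length(pres) == 0L) return(NULL)
    ps <- per_species_association(panels, pos)
    ps <- ps[ps$species %in% pres, , drop = FALSE]
    assoc <- ps$species[!is.na(ps$n_discordant) & ps$n_discordant == 0L]
    pooled <- if (length(pres) >= 1L) pooled_association(panels, pos)$p_pooled
              else NA_real_
    verdict <- if (length(pres) == 1L) "private"
               else if (setequal(assoc, pres)) "conserved_associated"
               else "conserved_unassociated"
    data.frame(pos_bp = pos,
               alleles = shared$alleles[match(pos, shared$pos_bp)] %||%
                 NA_character_,
               present_in = paste(sort(pres), collapse = ","),
               associated_in = paste(sort(assoc), collapse = ","),
               p_pooled = pooled, verdict = verdict,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
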