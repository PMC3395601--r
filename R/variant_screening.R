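#' X/Y clone comparison, XY-pattern screening and missense annotation
#'
#' The causal-variant screen rests on a simple genetic argument: if a single
#' site determines maleness through heterozygosity, that site must be
#' heterozygous in every male and homozygous in every female examined.
#' Variants are enumerated by comparing per-male X- and Y-derived clone
#' sequences against a reference (substitutions only; sequences are assumed
#' pre-aligned and indel calling is not implemented), then filtered by the
#' XY pattern, and coding candidates are annotated against a CDS model under
#' the standard genetic code.
#'
#' @name variant_screening
NULL

#' Fraction of identical positions between two pre-aligned sequences
#'
#' Case-insensitive; positions where either sequence has the ambiguity code
#' `N` are excluded from both numerator and denominator.
#'
#' @param a,b character sequences of equal length
#' @return fraction in `[0, 1]`
#' @export
sequence_identity <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  if (length(av) != length(bv))
    stop("alignment-required: sequences differ in length", call. = FALSE)
  keep <- av != "N" & bv != "N"
  if (!any(keep))
    stop("identity undefined: no unambiguous positions", call. = FALSE)
  sum(av[keep] == bv[keep]) / sum(keep)
}

#' Call substitution variants from per-male X/Y clone pairs
#'
#' Every position where any clone differs from the reference becomes a
#' variant; each male's genotype at a variant is the unordered pair of its X
#' and Y clone bases (males whose clones both match the reference are
#' ref/ref there).
#'
#' @param pairs named list, one element per male, each a list with character
#'   sequences `x` and `y` equal in length to `ref`.
#' @param ref reference sequence.
#' @param chrom name for the reference clone.
#' @return list with `variants` (data.frame `chrom`, `pos_bp`, `ref_allele`,
#'   `alt_allele`, `source = "cloned"`) and `genotypes`, a
#'   [genotype_matrix()] of the males over the variant positions.
#' @export
call_variants <- function(pairs, ref, chrom = "SD") {
  rv <- strsplit(toupper(ref), "")[[1L]]
  seqs <- lapply(pairs, function(p) {
    xv <- strsplit(toupper(p$x), "")[[1L]]
    yv <- strsplit(toupper(p$y), "")[[1L]]
    if (length(xv) != length(rv) || length(yv) != length(rv))
      stop("alignment-required: clone length differs from reference",
           call. = FALSE)
    list(x = xv, y = yv)
  })
  diff_pos <- sort(unique(unlist(lapply(seqs, function(s)
    which(s$x != rv | s$y != rv)))))
  if (length(diff_pos) == 0L) {
    return(list(variants = data.frame(chrom = character(0),
                                      pos_bp = integer(0),
                                      ref_allele = character(0),
                                      alt_allele = character(0),
                                      source = character(0)),
                genotypes = NULL))
  }
  alt <- vapply(diff_pos, function(i) {
    obs <- unique(unlist(lapply(seqs, function(s) c(s$x[i], s$y[i]))))
    paste(sort(setdiff(obs, rv[i])), collapse = ",")
  }, "")
  variants <- data.frame(chrom = chrom, pos_bp = diff_pos,
                         ref_allele = rv[diff_pos], alt_allele = alt,
                         source = "cloned", stringsAsFactors = FALSE)
  geno <- do.call(rbind, lapply(seqs, function(s)
    geno_string(s$x[diff_pos], s$y[diff_pos])))
  mm <- marker_map(sprintf("var%05d", diff_pos), chrom = chrom,
                   pos_bp = diff_pos, kind = "snp",
                   alleles = lapply(seq_along(diff_pos), function(k)
                     sort(unique(c(rv[diff_pos[k]],
                                   strsplit(alt[k], ",")[[1L]])))))
  ind <- data.frame(id = names(pairs) %||% sprintf("male%02d",
                                                   seq_along(pairs)),
                    sex = "M", population = "families", role = "unrelated",
                    stringsAsFactors = FALSE)
  list(variants = variants,
       genotypes = genotype_matrix(ind, mm, geno))
}

#' Screen variants for the XY pattern
#'
#' A variant passes when it is heterozygous in *every* genotyped male and —
#' when females are present — homozygous in every genotyped female. This is
#' the strict all-males rule: one homozygous male excludes a variant.
#'
#' @param gm a [genotype_matrix()] with sexes (e.g. from [call_variants()],
#'   optionally augmented with directly sequenced females).
#' @return data.frame per variant: `marker_id`, `n_het_males`, `n_males`,
#'   `n_hom_females`, `n_females`, `candidate`.
#' @export
screen_xy_pattern <- function(gm) {
  sex <- gm$individuals$sex
  if (sum(sex == "M") == 0L)
    stop("screen-undefined: no males genotyped", call. = FALSE)
  is_het <- function(g) {
    sp <- split_geno(g)
    !is.na(g) & sp[, 1L] != sp[, 2L]
  }
  out <- do.call(rbind, lapply(seq_len(ncol(gm$geno)), function(j) {
    g <- gm$geno[, j]
    gm_m <- g[sex == "M"]; gm_f <- g[sex == "F"]
    n_m <- sum(!is.na(gm_m)); n_f <- sum(!is.na(gm_f))
    assert_that(n_m >= 1L,
                sprintf("variant %s: no genotyped male",
                        gm$markers$marker_id[j]))
    het_m <- sum(is_het(gm_m), na.rm = TRUE)
    hom_f <- sum(!is_het(gm_f) & !is.na(gm_f))
    data.frame(marker_id = gm$markers$marker_id[j],
               n_het_males = het_m, n_males = n_m,
               n_hom_females = hom_f, n_females = n_f,
               candidate = het_m == n_m && hom_f == n_f,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## ------------------------------------------------------------ annotation

#' CDS model: ordered exon intervals on the coding strand
#'
#' @param exon_start,exon_end 1-based closed exon intervals on the genome,
#'   non-overlapping; given in genomic order.
#' @param strand `"+"` or `"-"`; exons are read 5' to 3' on the coding
#'   strand.
#' @param transcript_id label.
#' @return list of class `cds_model`
#' @export
cds_model <- function(exon_start, exon_end, strand = "+",
                      transcript_id = "tx1") {
  o <- order(exon_start)
  exon_start <- as.integer(exon_start[o]); exon_end <- as.integer(exon_end[o])
  assert_that(all(exon_end >= exon_start), "exon end before start")
  if (length(exon_start) > 1L)
    assert_that(all(exon_start[-1L] > exon_end[-length(exon_end)]),
                "exons overlap")
  assert_that(strand %in% c("+", "-"), "strand must be + or -")
  structure(list(exon_start = exon_start, exon_end = exon_end,
                 strand = strand, transcript_id = transcript_id),
            class = "cds_model")
}

# Standard genetic code, hard-coded (alternative codes are rejected by
# design: this annotator serves a vertebrate nuclear gene).
GENETIC_CODE_STD <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1L]]]), collapse = "")
}

cds_sequence <- function(cds, genome) {
  gv <- strsplit(toupper(genome), "")[[1L]]
  parts <- mapply(function(s, e) paste(gv[s:e], collapse = ""),
                  cds$exon_start, cds$exon_end)
  seq <- paste(parts, collapse = "")
  if (cds$strand == "-") seq <- revcomp(seq)
  seq
}

# genomic position -> 1-based CDS coordinate, or NA when intronic/outside
cds_coordinate <- function(cds, pos) {
  lens <- cds$exon_end - cds$exon_start + 1L
  before <- c(0L, cumsum(lens))[-length(lens) - 1L]
  for (k in seq_along(lens)) {
    if (pos >= cds$exon_start[k] && pos <= cds$exon_end[k]) {
      fwd <- before[k] + (pos - cds$exon_start[k] + 1L)
      if (cds$strand == "+") return(fwd)
      return(sum(lens) - fwd + 1L)
    }
  }
  NA_integer_
}

translate_cds <- function(seq, code = GENETIC_CODE_STD) {
  n <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(code[codons], collapse = "")
}

#' Annotate the coding consequence of a substitution
#'
#' @param pos_bp,ref_allele,alt_allele the variant (single bases, genomic
#'   forward strand).
#' @param cds a [cds_model()]
#' @param genome the reference sequence the CDS model indexes into.
#' @param code genetic code; only the built-in standard code is accepted.
#' @return list with `consequence` (`"missense"`, `"synonymous"`,
#'   `"stop_gained"` or `"non-coding"`), and for coding variants
#'   `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`, `protein_pos`.
#' @export
annotate_missense <- function(pos_bp, ref_allele, alt_allele, cds, genome,
                              code = GENETIC_CODE_STD) {
  if (!identical(code, GENETIC_CODE_STD))
    stop("only the standard genetic code is supported", call. = FALSE)
  gv <- strsplit(toupper(genome), "")[[1L]]
  assert_that(pos_bp >= 1L && pos_bp <= length(gv), "position outside genome")
  assert_that(gv[pos_bp] == toupper(ref_allele),
              sprintf("reference mismatch at %d: genome has %s", pos_bp,
                      gv[pos_bp]))
  cpos <- cds_coordinate(cds, pos_bp)
  if (is.na(cpos)) return(list(consequence = "non-coding"))
  ref_cds <- cds_sequence(cds, genome)
  if (nchar(ref_cds) %% 3L != 0L)
    stop("frame inconsistency: CDS length is not a multiple of 3",
         call. = FALSE)
  gv2 <- gv; gv2[pos_bp] <- toupper(alt_allele)
  alt_cds <- cds_sequence(cds, paste(gv2, collapse = ""))
  codon_i <- (cpos - 1L) %/% 3L + 1L
  cr <- substr(ref_cds, 3L * codon_i - 2L, 3L * codon_i)
  ca <- substr(alt_cds, 3L * codon_i - 2L, 3L * codon_i)
  aar <- unname(code[cr]); aaa <- unname(code[ca])
  cons <- if (aar == aaa) "synonymous"
          else if (aaa == "*") "stop_gained" else "missense"
  list(consequence = cons, codon_ref = cr, codon_alt = ca,
       aa_ref = aar, aa_alt = aaa, protein_pos = codon_i)
}
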