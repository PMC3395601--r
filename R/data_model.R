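#' Core genotype-data containers and plain-text readers/writers
#'
#' The pipeline operates on three lightweight S3 containers:
#'
#' * a **marker map** (`marker_map`): a `data.frame` of markers ordered by
#'   physical position, with 1-based coordinates measured from the 5' end of
#'   the named reference clone and cumulative sex-specific genetic positions
#'   in centiMorgans;
#' * a **genotype matrix** (`genotype_matrix`): individuals x markers with
#'   unordered allele pairs (phase is never stored here) plus phenotypic sex
#'   and population/family labels;
#' * **intervals** (`sd_interval`): closed 1-based intervals whose length is
#'   `end_bp - start_bp + 1`.
#'
#' @name data_model
NULL

SEX_LEVELS <- c("F", "M", "U")
ROLE_LEVELS <- c("father", "mother", "offspring", "unrelated")
MARKER_KINDS <- c("snp", "microsatellite")

#' Construct a marker map
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom scaffold/clone name (recycled).
#' @param pos_bp 1-based physical positions from the 5' end of the reference
#'   clone; must be strictly increasing after ordering.
#' @param kind `"snp"` or `"microsatellite"`.
#' @param alleles list of character vectors (or `"A,B"` strings) of the
#'   alleles segregating at each marker. SNP alleles must be single bases.
#' @param cm_female,cm_male cumulative genetic positions (cM); non-decreasing.
#'   Male map totals are typically smaller than female totals where male
#'   recombination is reduced.
#' @return a `data.frame` of class `marker_map`, ordered by `pos_bp`.
#' @export
marker_map <- function(marker_id, chrom = "SD", pos_bp,
                       kind = "snp", alleles,
                       cm_female = 0, cm_male = 0) {
  n <- length(marker_id)
  if (is.list(alleles)) alleles <- vapply(alleles, paste, "", collapse = ",")
  mm <- data.frame(
    marker_id = as.character(marker_id),
    chrom = rep_len(as.character(chrom), n),
    pos_bp = as.integer(pos_bp),
    kind = rep_len(as.character(kind), n),
    alleles = as.character(alleles),
    cm_female = rep_len(as.numeric(cm_female), n),
    cm_male = rep_len(as.numeric(cm_male), n),
    stringsAsFactors = FALSE
  )
  mm <- mm[order(mm$pos_bp), , drop = FALSE]
  rownames(mm) <- NULL
  class(mm) <- c("marker_map", "data.frame")
  validate_marker_map(mm)
  mm
}

validate_marker_map <- function(mm) {
  assert_that(all(c("marker_id", "chrom", "pos_bp", "kind", "alleles",
                    "cm_female", "cm_male") %in% names(mm)),
              "marker map is missing required columns")
  assert_that(!anyDuplicated(mm$marker_id), "duplicate marker ids")
  assert_that(all(mm$pos_bp >= 1L), "pos_bp must be >= 1")
  assert_that(all(diff(mm$pos_bp) > 0L), "pos_bp must be strictly increasing")
  assert_that(all(mm$kind %in% MARKER_KINDS), "unknown marker kind")
  al <- marker_alleles(mm)
  assert_that(all(lengths(al) >= 1L), "every marker needs alleles")
  snp <- mm$kind == "snp"
  assert_that(all(unlist(lapply(al[snp], nchar)) == 1L),
              "snp markers must have 1-bp alleles")
  assert_that(all(diff(mm$cm_female) >= 0) && all(diff(mm$cm_male) >= 0),
              "cumulative cM must be non-decreasing")
  invisible(mm)
}

#' @return list of allele character vectors, named by marker id
#' @rdname marker_map
#' @param mm a `marker_map`
#' @export
marker_alleles <- function(mm) {
  al <- strsplit(mm$alleles, ",", fixed = TRUE)
  names(al) <- mm$marker_id
  al
}

#' Construct a genotype matrix
#'
#' @param individuals `data.frame` with columns `id`, `sex` (`"F"`, `"M"`,
#'   `"U"`), `population`, `role`.
#' @param markers a [marker_map()].
#' @param geno character matrix (individuals x markers) of unordered allele
#'   pairs `"A/B"` (stored lexicographically sorted) with `NA` for missing.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(individuals, markers, geno) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  geno <- as.matrix(geno)
  sp <- split_geno(as.vector(geno))
  geno <- matrix(geno_string(sp[, 1L], sp[, 2L]),
                 nrow(geno), ncol(geno))
  rownames(geno) <- individuals$id
  colnames(geno) <- markers$marker_id
  gm <- structure(list(individuals = individuals, markers = markers,
                       geno = geno),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype matrix
#'
#' Checks dimension consistency, unique individual ids, legal sex and role
#' codes, and that every called allele belongs to its marker's allele set.
#'
#' @param gm a `genotype_matrix`
#' @return `gm`, invisibly; errors describe the first violation found.
#' @export
validate_genotype_matrix <- function(gm) {
  ind <- gm$individuals
  assert_that(all(c("id", "sex", "population", "role") %in% names(ind)),
              "individuals need id/sex/population/role columns")
  assert_that(!anyDuplicated(ind$id), "duplicate individual id")
  assert_that(all(ind$sex %in% SEX_LEVELS), "sex must be F, M or U")
  assert_that(all(ind$role %in% ROLE_LEVELS), "unknown role")
  validate_marker_map(gm$markers)
  assert_that(nrow(gm$geno) == nrow(ind) &&
                ncol(gm$geno) == nrow(gm$markers),
              "genotype matrix dimensions inconsistent")
  al <- marker_alleles(gm$markers)
  for (j in seq_len(ncol(gm$geno))) {
    g <- gm$geno[, j]
    sp <- split_geno(g[!is.na(g)])
    bad <- !(sp %in% al[[j]])
    if (any(bad)) {
      stop(sprintf("marker %s: allele(s) %s not in its allele set",
                   gm$markers$marker_id[j],
                   paste(unique(sp[bad]), collapse = ",")), call. = FALSE)
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%d F, %d M, %d U)\n",
              nrow(x$geno), ncol(x$geno),
              sum(x$individuals$sex == "F"), sum(x$individuals$sex == "M"),
              sum(x$individuals$sex == "U")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by individuals and/or markers
#' @param x a `genotype_matrix`
#' @param i individual index (logical/integer/character)
#' @param j marker index
#' @param ... unused
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(nrow(x$markers))
  if (is.character(i)) i <- match(i, x$individuals$id)
  if (is.character(j)) j <- match(j, x$markers$marker_id)
  ind <- x$individuals[i, , drop = FALSE]
  rownames(ind) <- NULL
  mm <- x$markers[j, , drop = FALSE]
  rownames(mm) <- NULL
  class(mm) <- c("marker_map", "data.frame")
  structure(list(individuals = ind, markers = mm,
                 geno = x$geno[i, j, drop = FALSE]),
            class = "genotype_matrix")
}

marker_index <- function(gm, marker) {
  j <- match(marker, gm$markers$marker_id)
  assert_that(!is.na(j), sprintf("unknown marker id: %s", marker))
  j
}

## ------------------------------------------------------------------ I/O

#' Read a genotype table (TSV dialect)
#'
#' The first line is a header `#individual_id<TAB>sex<TAB>population<TAB>role`
#' followed by one column per marker id. Sex is coded F/M/U, genotype cells
#' are `A/B` (any order; stored sorted) and missing is `./.`.
#'
#' @param path file path.
#' @param markers optional [marker_map()] supplying marker metadata. When
#'   omitted, a map is inferred: positions from numeric suffixes of marker
#'   ids where possible (else rank order), alleles from the observed calls.
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, markers = NULL) {
  lines <- readLines(path)
  assert_that(length(lines) >= 1L, sprintf("%s: empty file", path))
  header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  assert_that(identical(header[1:4],
                        c("individual_id", "sex", "population", "role")),
              sprintf("%s:1: malformed header", path))
  marker_ids <- header[-(1:4)]
  body <- lines[-1L][nzchar(lines[-1L])]
  n <- length(body)
  ind <- data.frame(id = character(n), sex = character(n),
                    population = character(n), role = character(n),
                    stringsAsFactors = FALSE)
  geno <- matrix(NA_character_, n, length(marker_ids))
  for (k in seq_len(n)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L + length(marker_ids))
      stop(sprintf("%s:%d: expected %d fields, got %d", path, k + 1L,
                   4L + length(marker_ids), length(f)), call. = FALSE)
    ind$id[k] <- f[1L]; ind$sex[k] <- f[2L]
    ind$population[k] <- f[3L]; ind$role[k] <- f[4L]
    g <- f[-(1:4)]
    g[g == MISSING_GENO] <- NA_character_
    geno[k, ] <- g
  }
  dup <- ind$id[duplicated(ind$id)]
  if (length(dup))
    stop(sprintf("%s: duplicate individual id: %s", path, dup[1L]),
         call. = FALSE)
  if (is.null(markers)) {
    al <- lapply(seq_along(marker_ids), function(j) {
      sp <- split_geno(geno[, j][!is.na(geno[, j])])
      a <- sort(unique(as.vector(sp)))
      if (length(a) == 0L) a <- "N"
      a
    })
    pos <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1", marker_ids)))
    if (anyNA(pos) || anyDuplicated(pos)) pos <- seq_along(marker_ids)
    o <- order(pos)
    markers <- marker_map(
      marker_id = marker_ids[o], pos_bp = pos[o],
      kind = ifelse(vapply(al[o], function(a) all(nchar(a) == 1L), TRUE),
                    "snp", "microsatellite"),
      alleles = al[o])
    geno <- geno[, o, drop = FALSE]
  } else {
    o <- match(markers$marker_id, marker_ids)
    assert_that(!anyNA(o), sprintf("%s: header markers do not match map", path))
    geno <- geno[, o, drop = FALSE]
  }
  tryCatch(genotype_matrix(ind, markers, geno),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                    call. = FALSE))
}

#' Write a genotype table (TSV dialect)
#' @param gm a [genotype_matrix()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genotype_table <- function(gm, path) {
  geno <- gm$geno
  geno[is.na(geno)] <- MISSING_GENO
  header <- paste(c("#individual_id", "sex", "population", "role",
                    gm$markers$marker_id), collapse = "\t")
  rows <- apply(cbind(gm$individuals$id, gm$individuals$sex,
                      gm$individuals$population, gm$individuals$role, geno),
                1L, paste, collapse = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write a marker map TSV
#'
#' Columns: `marker_id chrom pos_bp kind alleles cM_female cM_male`.
#' @param path file path
#' @return a [marker_map()]
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "", check.names = FALSE)
  names(df) <- sub("^cM_", "cm_", names(df))
  marker_map(df$marker_id, df$chrom, df$pos_bp, df$kind, df$alleles,
             df$cm_female, df$cm_male)
}

#' @rdname read_marker_map
#' @param mm a `marker_map`
#' @export
write_marker_map <- function(mm, path) {
  out <- mm
  names(out) <- sub("^cm_", "cM_", names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export SNP genotypes as VCF v4.2
#'
#' Unordered pairs are written as unphased `GT` calls (`0/0`, `0/1`, `1/1`,
#' `./.`). Only biallelic-or-monomorphic SNP markers are supported.
#'
#' @param gm a [genotype_matrix()] of SNP markers
#' @param path output file
#' @param ref_alleles named character vector giving the REF base per marker;
#'   defaults to the first allele in each marker's allele set.
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path, ref_alleles = NULL) {
  if (any(gm$markers$kind != "snp"))
    stop("write_vcf supports snp markers only (unsupported-marker)",
         call. = FALSE)
  al <- marker_alleles(gm$markers)
  if (is.null(ref_alleles))
    ref_alleles <- vapply(al, `[`, "", 1L)
  ref <- ref_alleles[gm$markers$marker_id]
  assert_that(!anyNA(ref), "ref_alleles missing for some markers")
  lines <- c("##fileformat=VCFv4.2",
             "##source=protosex",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$individuals$id), collapse = "\t"))
  for (j in seq_len(nrow(gm$markers))) {
    alt <- setdiff(al[[j]], ref[j])
    if (length(alt) == 0L) alt <- "."
    assert_that(length(alt) <= 1L,
                sprintf("marker %s is not biallelic", gm$markers$marker_id[j]))
    code <- function(a) ifelse(a == ref[j], "0", "1")
    sp <- split_geno(gm$geno[, j])
    gt <- ifelse(is.na(gm$geno[, j]), "./.",
                 paste(pmin(code(sp[, 1L]), code(sp[, 2L])),
                       pmax(code(sp[, 1L]), code(sp[, 2L])), sep = "/"))
    lines <- c(lines, paste(c(gm$markers$chrom[j], gm$markers$pos_bp[j],
                              gm$markers$marker_id[j], ref[j], alt, ".",
                              "PASS", ".", "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Genotype-count summary by sex at one marker
#'
#' Counts each genotype class per sex plus the missing count, the raw
#' material of the exact association tests (e.g. the wild-panel counts
#' "53 GG and 5 CG in females; 4 GG, 40 CG, 2 CC and 1 undetermined in
#' males").
#'
#' @param gm a [genotype_matrix()]
#' @param marker marker id
#' @return a data.frame with columns `sex`, `genotype` (or `"missing"`) and
#'   `count`; counts sum to the number of individuals.
#' @export
summarize_counts <- function(gm, marker) {
  j <- marker_index(gm, marker)
  g <- gm$geno[, j]
  sex <- gm$individuals$sex
  out <- do.call(rbind, lapply(SEX_LEVELS, function(s) {
    gs <- g[sex == s]
    tab <- table(gs, useNA = "no")
    data.frame(sex = s,
               genotype = c(names(tab), "missing"),
               count = c(as.integer(tab), sum(is.na(gs))),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$count > 0L | out$genotype == "missing", , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --------------------------------------------------------------- interval

#' Closed genomic interval for the SD region
#'
#' Length follows the closed-interval convention `end_bp - start_bp + 1`.
#'
#' @param chrom reference clone name
#' @param start_bp,end_bp 1-based bounds, `start_bp < end_bp`
#' @param left_flank_marker,right_flank_marker marker ids defining the bounds
#' @param ambiguous whether more than one candidate run existed
#' @return an object of class `sd_interval`
#' @export
sd_interval <- function(chrom, start_bp, end_bp,
                        left_flank_marker = NA_character_,
                        right_flank_marker = NA_character_,
                        ambiguous = FALSE) {
  assert_that(start_bp < end_bp, "start_bp must be < end_bp")
  structure(list(chrom = chrom,
                 start_bp = as.integer(start_bp),
                 end_bp = as.integer(end_bp),
                 left_flank_marker = left_flank_marker,
                 right_flank_marker = right_flank_marker,
                 length_bp = as.integer(end_bp - start_bp + 1L),
                 ambiguous = isTRUE(ambiguous)),
            class = "sd_interval")
}

#' @export
print.sd_interval <- function(x, ...) {
  cat(sprintf("<sd_interval> %s:%d-%d (%.1f kb, flanks %s / %s%s)\n",
              x$chrom, x$start_bp, x$end_bp, x$length_bp / 1000,
              x$left_flank_marker, x$right_flank_marker,
              if (x$ambiguous) ", ambiguous" else ""))
  invisible(x)
}
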