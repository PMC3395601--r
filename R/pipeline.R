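#' End-to-end discovery pipeline
#'
#' Runs the full workflow — simulate inputs, pedigree linkage screen,
#' X/Y variant screen, association scan, LD matrix, trans-species report —
#' from one plain-text (JSON) config with per-stage seeds, writing TSV/JSON
#' outputs and a run manifest with checksums. Identical config and seeds
#' give byte-identical outputs.
#'
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param out_dir output directory.
#' @param n_perm permutations for the association stage (small by default so
#'   the demo runs in seconds; raise for production use).
#' @return nested list of class `pipeline_config` with stage toggles and
#'   parameters, serializable to/from JSON via [write_pipeline_config()].
#' @export
pipeline_config <- function(seed = 1L, out_dir = "protosex_run",
                            n_perm = 200L) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, linkage = TRUE, variants = TRUE,
                  association = TRUE, ld = TRUE, trans_species = TRUE),
    wild = list(n_females = 58L, n_males = 47L, n_markers = 30L,
                region_length_bp = 17500L, causal_pos_bp = 7271L,
                founder_haplotypes = 400L, generations = 200L,
                recomb_rate_per_bp_per_meiosis = 1e-5,
                male_female_recomb_ratio = 0.5, mutation_rate = 0),
    family = list(n_offspring = 120L, n_markers = 12L,
                  region_length_bp = 17500L, causal_pos_bp = 7271L,
                  cm_per_mb_female = 1000, male_female_recomb_ratio = 0.5),
    clones = list(length_bp = 14000L, target_identity = 0.994),
    species = list(n_species = 3L, n_females = c(8L, 8L, 6L),
                   n_males = c(8L, 8L, 7L), shared_snp = TRUE,
                   n_private = 3L),
    association = list(maf_min = 0.1, call_rate_min = 0.99,
                       n_perm = as.integer(n_perm), alpha = 0.05),
    n_clone_males = 9L
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline config as JSON
#' @param path JSON file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  merge_into <- function(base, new) {
    for (k in names(new)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
        merge_into(base[[k]], new[[k]]) else new[[k]]
    }
    base
  }
  cfg <- merge_into(unclass(base), cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

family_map_from_config <- function(fam, seed) {
  set.seed(seed)
  pos <- sort(c(fam$causal_pos_bp,
                sample(setdiff(seq_len(fam$region_length_bp),
                               fam$causal_pos_bp), fam$n_markers - 1L)))
  cm_f <- (pos - pos[1L]) / 1e6 * fam$cm_per_mb_female
  marker_map(sprintf("fm%05d", pos), chrom = "SD", pos_bp = pos,
             kind = "snp",
             alleles = replicate(length(pos),
                                 sort(sample(c("A", "C", "G", "T"), 2L)),
                                 simplify = FALSE),
             cm_female = cm_f,
             cm_male = cm_f * fam$male_female_recomb_ratio)
}

#' Run the discovery pipeline
#'
#' Stages run in dependency order; a stage failure aborts with the stage
#' name. Returns (and writes as `manifest.json`) a run manifest recording
#' the package version, a config checksum, per-stage output checksums and
#' wall-clock times.
#'
#' @param config a [pipeline_config()] (or path to a JSON config).
#' @param verbose print INFO-level stage summaries?
#' @return the manifest, invisibly; outputs under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  info <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(tool = "protosex",
                   version = as.character(utils::packageVersion("protosex")),
                   stages = list())
  cfg_path <- file.path(cfg$out_dir, "config.json")
  write_pipeline_config(cfg, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  outputs <- character(0)
  stage <- function(name, enabled, fn) {
    if (!isTRUE(enabled)) return(NULL)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  path_of <- function(f) {
    p <- file.path(cfg$out_dir, f)
    outputs <<- c(outputs, p)
    p
  }

  ## --- simulate -----------------------------------------------------
  sims <- stage("simulate", cfg$stages$simulate, function() {
    wild <- simulate_wild_population(do.call(wild_sim_params,
      c(cfg$wild, list(seed = derive_seed(cfg$seed, 1L)))))
    fam_map <- family_map_from_config(cfg$family, derive_seed(cfg$seed, 2L))
    causal <- fam_map$marker_id[match(cfg$family$causal_pos_bp,
                                      fam_map$pos_bp)]
    fam <- simulate_family(family_sim_params(
      cfg$family$n_offspring, fam_map, causal,
      seed = derive_seed(cfg$seed, 3L)))
    clone_seeds <- vapply(seq_len(cfg$n_clone_males), function(i)
      derive_seed(cfg$seed, 100L + i), 1L)
    clones <- lapply(clone_seeds, function(s)
      simulate_clone_pair(clone_pair_params(cfg$clones$length_bp,
                                            cfg$clones$target_identity,
                                            seed = s)))
    panels <- do.call(simulate_species_panels,
                      c(cfg$species, list(seed = derive_seed(cfg$seed, 4L))))
    write_genotype_table(wild$matrix, path_of("wild_genotypes.tsv"))
    write_marker_map(wild$matrix$markers, path_of("wild_markers.tsv"))
    write_genotype_table(fam$matrix, path_of("family_genotypes.tsv"))
    info("INFO simulate: wild %d ind x %d markers; family %d offspring; %d clone pairs; %d species panels",
         nrow(wild$matrix$geno), ncol(wild$matrix$geno),
         cfg$family$n_offspring, length(clones), length(panels))
    list(wild = wild, fam = fam, clones = clones, panels = panels,
         causal = causal)
  })

  ## --- linkage ------------------------------------------------------
  lk <- stage("linkage", cfg$stages$linkage && cfg$stages$simulate, function() {
    fam <- sims$fam
    mk <- fam$matrix$markers$marker_id
    rep_ <- find_recombinants(fam$matrix, mk[1L], mk[length(mk)])
    iv <- refine_sd_interval(rep_, fam$matrix$markers)
    write_recombinant_report(rep_, path_of("recombinants.tsv"))
    jsonlite::write_json(unclass(iv$interval),
                         path_of("sd_interval.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    info("INFO linkage: %d recombinants / %d screened; interval %d-%d (%0.1f kb)",
         length(rep_$recombinant_ids), rep_$n_screened,
         iv$interval$start_bp, iv$interval$end_bp,
         iv$interval$length_bp / 1000)
    iv
  })

  ## --- variants -----------------------------------------------------
  vs <- stage("variants", cfg$stages$variants && cfg$stages$simulate,
              function() {
    ## plant the causal C/G het into every male's clone pair: clone X keeps
    ## the reference base, clone Y carries a G at the causal offset
    set.seed(derive_seed(cfg$seed, 6L))
    ref <- sims$clones[[1L]]$x
    cpos <- min(cfg$wild$causal_pos_bp, nchar(ref))
    rv <- strsplit(ref, "")[[1L]]
    pairs <- lapply(seq_along(sims$clones), function(i) {
      yv <- strsplit(sims$clones[[i]]$y, "")[[1L]]
      xv <- strsplit(sims$clones[[i]]$x, "")[[1L]]
      if (i > 1L) {
        ## each male's clones differ from the shared reference only at a few
        ## private sites plus the causal SNP
        keep <- sample(which(yv != xv), min(3L, sum(yv != xv)))
        yv2 <- rv; yv2[keep] <- yv[keep]
        xv2 <- rv
      } else {
        yv2 <- yv; xv2 <- xv
      }
      yv2[cpos] <- if (rv[cpos] == "G") "C" else "G"
      list(x = paste(xv2, collapse = ""), y = paste(yv2, collapse = ""))
    })
    names(pairs) <- sprintf("male%02d", seq_along(pairs))
    calls <- call_variants(pairs, ref, chrom = "SD3-14k")
    screen <- screen_xy_pattern(calls$genotypes)
    utils::write.table(screen, path_of("xy_screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ident <- vapply(sims$clones, function(cl)
      sequence_identity(cl$x, cl$y), 1)
    info("INFO variants: %d variant sites, %d XY-pattern candidate(s); mean X/Y clone identity %.4f",
         nrow(calls$variants), sum(screen$candidate), mean(ident))
    list(calls = calls, screen = screen, identity = ident,
         causal_pos = cpos)
  })

  ## --- association --------------------------------------------------
  assoc <- stage("association", cfg$stages$association && cfg$stages$simulate,
                 function() {
    res <- assoc_scan(sims$wild$matrix,
                      maf_min = cfg$association$maf_min,
                      call_rate_min = cfg$association$call_rate_min,
                      n_perm = cfg$association$n_perm,
                      alpha = cfg$association$alpha,
                      seed = derive_seed(cfg$seed, 5L))
    utils::write.table(as.data.frame(res), path_of("association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    track <- res[!res$filtered, c("marker_id", "pos_bp", "neg_log10_p")]
    utils::write.table(track, path_of("assoc_track.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    top <- res$marker_id[which.min(res$p_two_sided)]
    info("INFO association: %d/%d markers pass filters; top marker %s (p=%.3g)",
         sum(!res$filtered), nrow(res), top, min(res$p_two_sided,
                                                 na.rm = TRUE))
    res
  })

  ## --- ld -----------------------------------------------------------
  ld <- stage("ld", cfg$stages$ld && cfg$stages$simulate, function() {
    filt <- apply_marker_filters(sims$wild$matrix,
                                 cfg$association$maf_min,
                                 cfg$association$call_rate_min)
    mk <- filt$marker_id[filt$pass]
    res <- ld_matrix(sims$wild$matrix, mk)
    utils::write.table(res, path_of("ld_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    info("INFO ld: %d pairs over %d filtered markers; mean r2 %.3f",
         nrow(res), length(mk), mean(res$r2, na.rm = TRUE))
    res
  })

  ## --- trans-species ------------------------------------------------
  ts <- stage("trans_species", cfg$stages$trans_species && cfg$stages$simulate,
              function() {
    rep_ <- conservation_report(sims$panels)
    utils::write.table(rep_, path_of("trans_species.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(rep_, path_of("trans_species.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    info("INFO trans-species: %d variant positions, %d conserved-associated",
         nrow(rep_), sum(rep_$verdict == "conserved_associated"))
    rep_
  })

  manifest$outputs <- as.list(tools::md5sum(sort(unique(outputs))))
  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest, sims = sims, linkage = lk,
                 variants = vs, association = assoc, ld = ld,
                 trans_species = ts))
}
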