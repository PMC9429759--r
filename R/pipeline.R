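# Demo pipeline: simulate -> profile species -> profile strains.
#
# One root seed drives every stage (child streams via derive_seed), so a
# rerun with the same configuration is bitwise identical.

#' Default pipeline configuration
#'
#' All simulator and profiling parameters with their package defaults:
#' 5 species x 3 strains, lambda = 0.3 loading into 1e5 droplets, three
#' replicate droplet cultures per medium (BHI, MRS) for 120 h, plus the
#' uncultured community as a baseline sample.
#'
#' @return Named list of parameters; pass (optionally modified) to
#'   [run_pipeline()].
#' @export
default_config <- function() {
  list(seed = 42L,
       n_species = 5L, strains_per_species = 3L,
       rare_strain_fraction = 0.2,
       media = c("BHI", "MRS"), n_replicates = 3L,
       n_droplets = 1e5, lambda = 0.3,
       hours = 120, droplet_capacity = 1e4,
       genome_length = 20000L, coding_fraction = 0.85,
       divergence_rate = 0.01,
       mean_coverage = 60, error_rate = 0.001,
       marker_depth = 200, read_length = 150L,
       min_depth = 5L, min_maf = 0.05, min_minor_count = 2L,
       prevalence_threshold = 0.05)
}

#' Load a JSON configuration, overriding the defaults
#'
#' @param path JSON file with a subset of [default_config()] keys;
#'   unknown keys are rejected.
#' @param overrides named list applied after the file (e.g. from command
#'   line flags).
#' @return Full configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  extra <- if (is.null(path)) list()
           else jsonlite::read_json(path, simplifyVector = TRUE)
  for (src in list(extra, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown))
      .err("dropstrain_config_error", "unknown config key(s): %s",
           paste(unknown, collapse = ", "))
    cfg[names(src)] <- src
  }
  cfg
}

#' Run the full demo pipeline
#'
#' Simulates a strain-structured community, cultivates it in droplets
#' (per medium, with replicates) alongside the uncultured baseline,
#' sequences every sample into marker counts and pileups, then runs the
#' species- and strain-level profilers. All tables are written under
#' `outdir` in the package TSV dialect together with a JSON manifest
#' (seed + full parameter set) sufficient to reproduce them bitwise.
#'
#' @param config configuration list from [default_config()] /
#'   [load_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`community`,
#'   `genomes`, `outcomes`, `abundance`, `catalog`, ...) and `files`.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      .err("dropstrain_pipeline_error", "stage '%s' failed: %s",
           name, conditionMessage(e)))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  community <- stage("simulate/community", make_community(
    n_species = cfg$n_species, strains_per_species = cfg$strains_per_species,
    media = cfg$media, rare_strain_fraction = cfg$rare_strain_fraction,
    seed = cfg$seed))
  genomes <- stage("simulate/genomes", make_strain_genomes(
    community, genome_length = cfg$genome_length,
    coding_fraction = cfg$coding_fraction,
    divergence_rate = cfg$divergence_rate, seed = cfg$seed))

  outcomes <- list(GUT = stage("simulate/baseline",
                               grow_bulk(community, cfg$media[1], hours = 0)))
  for (med in cfg$media) for (r in seq_len(cfg$n_replicates)) {
    sid <- sprintf("%s_D%d", med, r)
    ens <- encapsulate(community, cfg$n_droplets, cfg$lambda,
                       seed = derive_seed(cfg$seed, sid))
    outcomes[[sid]] <- stage(paste0("simulate/grow/", sid),
                             grow_droplets(ens, community, med,
                                           hours = cfg$hours,
                                           droplet_capacity = cfg$droplet_capacity))
  }

  markers <- default_markers(community)
  counts <- do.call(rbind, lapply(names(outcomes), function(sid)
    simulate_marker_counts(outcomes[[sid]], markers, depth = cfg$marker_depth,
                           read_length = cfg$read_length,
                           seed = derive_seed(cfg$seed, sid), sample_id = sid)))
  pileup <- stage("simulate/sequence", data.table::rbindlist(
    lapply(names(outcomes), function(sid)
      sequence_to_pileup(outcomes[[sid]], genomes,
                         mean_coverage = cfg$mean_coverage,
                         error_rate = cfg$error_rate,
                         seed = derive_seed(cfg$seed, sid), sample_id = sid))))

  ab <- stage("profile-species", relative_abundance(counts, cfg$read_length))
  alpha <- data.frame(sample = rownames(ab),
                      shannon = alpha_diversity(ab, "shannon"),
                      simpson = alpha_diversity(ab, "simpson"))
  bray <- beta_diversity(ab, "bray_curtis")
  jac <- beta_diversity(ab, "jaccard")
  ord <- pcoa(bray, n_axes = 2)

  calls <- stage("profile-strains/calls",
                 call_sites(pileup, min_depth = cfg$min_depth,
                            min_maf = cfg$min_maf,
                            min_minor_count = cfg$min_minor_count))
  catalog <- stage("profile-strains/catalog",
                   build_catalog(calls, cfg$prevalence_threshold))
  divers <- snv_fraction(catalog, calls)
  snv_jac <- shared_snv_jaccard(catalog)
  snv_ord <- pcoa(snv_jac, n_axes = 2)

  files <- list()
  wt <- function(name, df) {
    p <- file.path(outdir, name); write_tsv(df, p); files[[name]] <<- p
  }
  truth <- community$strains[order(community$strains$strain), ]
  wt("community_truth.tsv", truth)
  wt("truth_variants.tsv",
     genomes$variants[order(genomes$variants$strain, genomes$variants$gpos0), ])
  write_fasta(genomes$reference, file.path(outdir, "references.fasta"))
  files[["references.fasta"]] <- file.path(outdir, "references.fasta")
  write_bed(genomes$coding, file.path(outdir, "coding.bed"))
  files[["coding.bed"]] <- file.path(outdir, "coding.bed")
  wt("marker_counts.tsv", counts[order(counts$sample, counts$gene), ])
  write_pileup(pileup, file.path(outdir, "pileup.tsv"))
  files[["pileup.tsv"]] <- file.path(outdir, "pileup.tsv")
  wt("abundance.tsv", data.frame(sample = rownames(ab),
                                 as.data.frame(ab), check.names = FALSE))
  wt("alpha_diversity.tsv", alpha)
  write_distance(bray, file.path(outdir, "beta_bray.tsv"))
  write_distance(jac, file.path(outdir, "beta_jaccard.tsv"))
  wt("pcoa_species.tsv",
     data.frame(sample = rownames(ord$coordinates),
                ord$coordinates, check.names = FALSE))
  wt("snv_catalog.tsv", as.data.frame(catalog$sites))
  wt("snv_fraction.tsv", data.frame(species = rownames(divers),
                                    as.data.frame(divers), check.names = FALSE))
  write_distance(snv_jac, file.path(outdir, "snv_jaccard.tsv"))
  wt("pcoa_snv.tsv",
     data.frame(sample = rownames(snv_ord$coordinates),
                snv_ord$coordinates, check.names = FALSE))
  manifest <- list(package = "dropstrain",
                   version = as.character(utils::packageVersion("dropstrain")),
                   seed = cfg$seed, parameters = cfg,
                   files = names(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(community = community, genomes = genomes,
                 outcomes = outcomes, abundance = ab, alpha = alpha,
                 bray = bray, jaccard = jac, pcoa = ord, calls = calls,
                 catalog = catalog, snv_fraction = divers,
                 snv_jaccard = snv_jac, files = files))
}
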