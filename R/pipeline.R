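## Pipeline orchestration: validated configuration, stage execution in
## dependency order, tabular outputs, and a JSON run manifest.

pipeline_config_defaults <- function() {
  list(
    input_prefix = NULL,          # PLINK prefix; NULL -> simulate
    metadata = NULL,              # sidecar TSV
    sim = NULL,                   # list of sim_config arguments
    qc_profile = "full",
    qc = list(animal_min = 0.95, marker_min = 0.95, maf_min = 0.05,
              hwe_min = 1e-6),
    stages = c("qc", "grm", "pca", "diversity", "fst", "tree", "ld", "cgp",
               "roh", "gpsm"),
    ld_max_distance_bp = 1e6,
    roh = list(),                 # roh_params overrides
    annotation = list(qtl_table = NULL, flank_bp = 1e5),
    seed = 1,
    output_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected before any computation; defaults fill the rest.
#'
#' @param config Named list of overrides.
#' @return The completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  if (is.null(out$output_dir)) stop("config needs an output_dir")
  known_stages <- pipeline_config_defaults()$stages
  bad <- setdiff(out$stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order on either a PLINK
#' dataset or a freshly simulated study, writing one tab-separated output per
#' stage plus a JSON manifest recording parameters, seed, and stage status.
#' Identical configurations (including seed) give byte-identical statistical
#' outputs.
#'
#' @param config A list accepted by \code{\link{pipeline_config}}.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(package_version = as.character(utils::packageVersion("selmap")),
                   seed = cfg$seed, stages = list(),
                   config = cfg[setdiff(names(cfg), "output_dir")])
  tsv <- function(x, name) {
    utils::write.table(x, file.path(cfg$output_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), st, units = "secs")), 2))
    res
  }

  ## ---- input ----
  if (!is.null(cfg$input_prefix)) {
    ds <- stage("load", read_plink(cfg$input_prefix, cfg$metadata))
    pops <- split_populations(ds)
  } else {
    sim_args <- cfg$sim
    if (is.null(sim_args)) sim_args <- list()
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    study <- stage("simulate", simulate_study(do.call(sim_config, sim_args)))
    ds <- study$merged
    pops <- study$datasets
  }

  ## ---- qc (two profiles, per population) ----
  roh_pops <- pops; full_pops <- pops
  if ("qc" %in% cfg$stages) {
    reports_full <- list(); reports_roh <- list()
    for (nm in names(pops)) {
      qf <- stage(paste0("qc_full_", nm),
                  run_qc(pops[[nm]], "full",
                         animal_min = cfg$qc$animal_min, marker_min = cfg$qc$marker_min,
                         maf_min = cfg$qc$maf_min, hwe_min = cfg$qc$hwe_min,
                         autosome_labels = unique(pops[[nm]]$markers$chrom)))
      qr <- run_qc(pops[[nm]], "roh", animal_min = cfg$qc$animal_min,
                   marker_min = cfg$qc$marker_min)
      full_pops[[nm]] <- qf$ds; reports_full[[nm]] <- qf$report
      roh_pops[[nm]] <- qr$ds; reports_roh[[nm]] <- qr$report
    }
    write_qc_report(reports_full, file.path(cfg$output_dir, "qc_full.tsv"))
    write_qc_report(reports_roh, file.path(cfg$output_dir, "qc_roh.tsv"))
  }
  shared <- if (length(full_pops) > 1) harmonize_and_intersect(full_pops) else full_pops

  ## ---- relationship / stratification ----
  if ("grm" %in% cfg$stages || "pca" %in% cfg$stages) {
    merged_shared <- if (length(shared) > 1) {
      genotype_dataset(do.call(rbind, lapply(shared, `[[`, "calls")),
                       do.call(rbind, lapply(shared, `[[`, "samples")),
                       shared[[1]]$markers, sort_markers = FALSE)
    } else shared[[1]]
    kept <- stage("prune", prune_r2(merged_shared))
    pruned <- subset_dataset(merged_shared, markers = kept)
    G <- stage("grm", grm_vanraden(pruned, method = "per_snp"))
    if ("pca" %in% cfg$stages) {
      pc <- stage("pca", pca_from_grm(G, k = 10))
      tsv(data.frame(sample_id = rownames(pc$scores),
                     population = merged_shared$samples$population,
                     pc$scores), "pca_scores")
      tsv(data.frame(component = seq_along(pc$explained_fraction),
                     explained_fraction = pc$explained_fraction), "pca_explained")
    }
  }

  ## ---- diversity / distance ----
  if ("diversity" %in% cfg$stages) {
    rows <- lapply(names(full_pops), function(nm) {
      d <- full_pops[[nm]]
      het <- heterozygosity(d)
      kept <- prune_vif(d)
      dst <- pairwise_shared_distance(subset_dataset(d, markers = kept))
      data.frame(population = nm,
                 polymorphic_proportion = polymorphic_proportion(d),
                 ho_mean = het$summary["ho_mean"], ho_sd = het$summary["ho_sd"],
                 he_mean = het$summary["he_mean"], he_sd = het$summary["he_sd"],
                 shared_mean = dst$summary["shared_mean"],
                 distance_mean = dst$summary["distance_mean"],
                 stringsAsFactors = FALSE)
    })
    tsv(do.call(rbind, rows), "diversity")
  }

  ## ---- F_ST / tree ----
  if ("fst" %in% cfg$stages && length(shared) > 1) {
    fst <- stage("fst", fst_matrix(shared))
    tsv(data.frame(population = rownames(fst$mean), fst$mean), "fst_mean")
    tsv(data.frame(population = rownames(fst$sd), fst$sd), "fst_sd")
  }
  if ("tree" %in% cfg$stages && length(shared) > 2) {
    tr <- stage("tree", population_tree(shared))
    write_newick(tr$tree, file.path(cfg$output_dir, "population_tree.nwk"))
    tsv(data.frame(population = rownames(tr$distances), tr$distances),
        "ibs_distances")
  }

  ## ---- LD / CGP ----
  ld_tables <- NULL
  if (any(c("ld", "cgp") %in% cfg$stages)) {
    ld_tables <- lapply(names(full_pops), function(nm) {
      stage(paste0("ld_", nm),
            ld_scan(full_pops[[nm]], cfg$ld_max_distance_bp,
                    with_em = "cgp" %in% cfg$stages))
    })
    names(ld_tables) <- names(full_pops)
    decay <- do.call(rbind, lapply(names(ld_tables), function(nm) {
      cbind(population = nm, bin_ld_decay(ld_tables[[nm]]))
    }))
    tsv(decay, "ld_decay")
  }
  if ("cgp" %in% cfg$stages && length(full_pops) > 1) {
    shared_ld <- harmonize_and_intersect(full_pops)
    tabs <- lapply(shared_ld, ld_scan, max_distance_bp = cfg$ld_max_distance_bp,
                   with_em = TRUE)
    nms <- names(tabs)
    curves <- list()
    for (i in seq_len(length(tabs) - 1)) for (j in (i + 1):length(tabs)) {
      curves[[paste(nms[i], nms[j], sep = "|")]] <- cgp_curve(tabs[[i]], tabs[[j]])
    }
    tsv(do.call(rbind, lapply(names(curves), function(nm) {
      cbind(pair = nm, curves[[nm]])
    })), "cgp")
  }

  ## ---- ROH ----
  segments <- NULL
  if ("roh" %in% cfg$stages) {
    params <- do.call(roh_params, cfg$roh)
    segs <- lapply(names(roh_pops), function(nm) {
      stage(paste0("roh_", nm), call_roh(roh_pops[[nm]], params))
    })
    segments <- do.call(rbind, segs)
    tsv(segments, "roh_segments")
    tsv(roh_summary(segments, ds$samples), "roh_summary")
    islands <- do.call(rbind, lapply(names(roh_pops), function(nm) {
      isl <- roh_islands(segments[segments$population == nm, , drop = FALSE],
                         roh_pops[[nm]])
      if (nrow(isl)) cbind(population = nm, isl) else NULL
    }))
    if (!is.null(islands) && nrow(islands)) tsv(islands, "roh_islands")
  }

  ## ---- GPSM ----
  if ("gpsm" %in% cfg$stages) {
    gp <- lapply(names(full_pops), function(nm) {
      d <- full_pops[[nm]]
      if (all(is.na(d$samples$birth_year))) return(NULL)
      fit <- stage(paste0("gpsm_", nm), gpsm(d))
      tsv(fit$results, paste0("gpsm_", nm))
      data.frame(population = nm, pve = fit$vc$pve,
                 sigma2_g = fit$vc$sigma2_g, sigma2_e = fit$vc$sigma2_e,
                 threshold = fit$threshold, lambda = fit$qq$lambda,
                 n_significant = sum(fit$results$significant, na.rm = TRUE))
    })
    gp <- do.call(rbind, gp)
    if (!is.null(gp)) tsv(gp, "gpsm_summary")
  }

  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
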