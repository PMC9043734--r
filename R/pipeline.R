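# End-to-end orchestration of the synthetic study: simulate -> distances ->
# Mantel/sweeps -> cophylogeny -> placement sensitivity -> biogeography,
# from one config (R list or YAML), with a manifest recording seeds and
# parameters so any stage can be replayed in isolation.

#' Default pipeline configuration
#'
#' @return A nested list understood by [run_pipeline()]: a `simulate` block
#'   (see [sim_config()]) plus per-stage parameter blocks and toggles.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(),   # overrides for sim_config()
    stages = list(distances = TRUE, mantel = TRUE, sweeps = TRUE,
                  cophylo = TRUE, placement = TRUE, biogeo = TRUE),
    mantel = list(n_perm = 999),
    sweeps = list(radii = seq(100, 2000, by = 100), min_cluster = 5,
                  n_perm = 199, n_slices = 10),
    cophylo = list(n_perm = 999),
    placement = list(loci_counts = c(1, 3, 7, 14), reps_per_count = 10),
    biogeo = list(max_range_size = 2, n_maps = 3000, starts = 3)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge_lists(base, config %||% list())
}

#' Run the full synthetic cophylogeography pipeline
#'
#' Deterministic given `config$seed`; every stage derives its own seed via
#' [stage_seed()].  Writes per-stage outputs (Newick trees, FASTA loci,
#' CSV tables and matrices, JSON results) plus a manifest under `out_dir`
#' when given, and returns all results invisibly.
#'
#' @param config A config list, a YAML path, or `NULL` for defaults.
#' @param out_dir Optional output directory.
#' @param force Overwrite a non-empty `out_dir`.
#' @return Invisibly, a list with elements `data`, `distances`, `mantel`,
#'   `sweeps`, `cophylo`, `placement`, `biogeo`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, force = FALSE) {
  cfg <- read_pipeline_config(config)
  seed <- as.integer(cfg$seed)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
      stop("output directory not empty (use force = TRUE): ", out_dir)
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  t0 <- Sys.time()
  manifest <- list(seed = seed, config = cfg, stages = list())
  note <- function(stage, params) {
    manifest$stages[[stage]] <<- list(seed = stage_seed(seed, stage),
                                      params = params)
  }
  res <- list()

  # --- simulate -----------------------------------------------------------
  simcfg <- do.call(sim_config, cfg$simulate)
  data <- simulate_dataset(simcfg, seed = seed)
  res$data <- data
  note("simulate", cfg$simulate)
  if (!is.null(out_dir)) {
    writeLines(write_newick(data$tree), file.path(out_dir, "tree.nwk"))
    writeLines(write_newick(data$parasite$tree), file.path(out_dir, "parasite.nwk"))
    write_assoc_csv(data$parasite$assoc, file.path(out_dir, "assoc.csv"))
    write_sample_table(data$samples, file.path(out_dir, "samples.csv"))
    write_multilocus_fasta(data$host_aln, file.path(out_dir, "loci"))
  }

  # --- distances ----------------------------------------------------------
  if (isTRUE(cfg$stages$distances)) {
    host_ids <- data$samples$id
    dist <- list(
      genetic = genetic_distance(data$host_aln, samples = host_ids),
      geographic = haversine_matrix(data$samples),
      climatic = climate_distance_matrix(data$samples),
      parasite = genetic_distance(data$parasite_aln)
    )
    res$distances <- dist
    note("distances", list(correction = "none"))
    if (!is.null(out_dir)) {
      for (nm in names(dist)) {
        write_dist_csv(dist[[nm]], file.path(out_dir, paste0("dist_", nm, ".csv")))
      }
    }
  }

  # --- Mantel tests -------------------------------------------------------
  if (isTRUE(cfg$stages$mantel)) {
    sseed <- stage_seed(seed, "mantel")
    np <- cfg$mantel$n_perm
    # parasite matrix relabelled by host id for direct comparison
    par_as_host <- relabel_parasite(res$distances$parasite, data$parasite$assoc)
    res$mantel <- list(
      ibd_geographic = mantel_test(res$distances$genetic,
                                   res$distances$geographic, np, seed = sseed),
      ibd_climatic = mantel_test(res$distances$genetic,
                                 res$distances$climatic, np, seed = sseed + 1L),
      host_parasite = mantel_test(res$distances$genetic, par_as_host,
                                  np, seed = sseed + 2L)
    )
    note("mantel", cfg$mantel)
  }

  # --- sweeps -------------------------------------------------------------
  if (isTRUE(cfg$stages$sweeps)) {
    sseed <- stage_seed(seed, "sweeps")
    sw <- cfg$sweeps
    H <- tree_height(data$tree)
    ages <- seq(0, 0.9 * H, length.out = sw$n_slices)
    par_as_host <- relabel_parasite(res$distances$parasite, data$parasite$assoc)
    res$sweeps <- list(
      ibd_radius = geographic_cluster_sweep(
        res$distances$genetic, res$distances$geographic, radii = sw$radii,
        min_cluster = sw$min_cluster, n_perm = sw$n_perm, seed = sseed),
      cophylo_radius = geographic_cluster_sweep(
        res$distances$genetic, par_as_host, radii = sw$radii,
        min_cluster = sw$min_cluster, n_perm = sw$n_perm, seed = sseed + 1L,
        cluster_on = res$distances$geographic),
      ibd_depth = time_slice_sweep(data$tree, res$distances$geographic,
                                   ages = ages, n_perm = sw$n_perm,
                                   seed = sseed + 2L),
      cophylo_depth = time_slice_sweep(data$tree, par_as_host, ages = ages,
                                       n_perm = sw$n_perm, seed = sseed + 3L)
    )
    note("sweeps", sw)
    if (!is.null(out_dir)) {
      for (nm in names(res$sweeps)) {
        write.csv(as.data.frame(res$sweeps[[nm]]),
                  file.path(out_dir, paste0("sweep_", nm, ".csv")),
                  row.names = FALSE)
      }
    }
  }

  # --- cophylogeny --------------------------------------------------------
  if (isTRUE(cfg$stages$cophylo)) {
    sseed <- stage_seed(seed, "cophylo")
    np <- cfg$cophylo$n_perm
    dh <- patristic_matrix(data$tree)
    dp <- patristic_matrix(data$parasite$tree)
    A <- data$parasite$assoc
    A2 <- assoc_matrix(unclass(A)[rownames(dp), rownames(dh)])
    res$cophylo <- list(
      parafit = parafit_test(dh, dp, A2, n_perm = np, seed = sseed,
                             per_link = FALSE),
      paco = paco_test(dh, dp, A2, n_perm = np, seed = sseed + 1L)
    )
    note("cophylo", cfg$cophylo)
  }

  # --- placement sensitivity ---------------------------------------------
  if (isTRUE(cfg$stages$placement)) {
    sseed <- stage_seed(seed, "placement")
    pc <- cfg$placement
    model <- substitution_model(simcfg$model, simcfg$base_freq, simcfg$kappa)
    res$placement <- loci_sensitivity(
      data$tree_subs, data$host_aln,
      loci_counts = pc$loci_counts[pc$loci_counts <= length(data$host_aln$loci)],
      reps_per_count = pc$reps_per_count, model = model, seed = sseed)
    note("placement", pc)
    if (!is.null(out_dir)) {
      write.csv(as.data.frame(res$placement),
                file.path(out_dir, "loci_sensitivity.csv"), row.names = FALSE)
    }
  }

  # --- biogeography -------------------------------------------------------
  if (isTRUE(cfg$stages$biogeo)) {
    sseed <- stage_seed(seed, "biogeo")
    bg <- cfg$biogeo
    regions <- names(simcfg$regions)
    tip_regions <- setNames(data$samples$region, data$samples$id)
    rng <- range_data(as.list(tip_regions), regions = regions,
                      max_size = bg$max_range_size)
    fits <- list(
      DEC = fit_range_model(data$tree, rng, "DEC", starts = bg$starts,
                            seed = sseed),
      DECJ = fit_range_model(data$tree, rng, "DEC+J", starts = bg$starts,
                             seed = sseed + 1L)
    )
    maps <- mk_stochastic_maps(data$tree, tip_regions, regions = regions,
                               n_maps = bg$n_maps, seed = sseed + 2L)
    res$biogeo <- list(fits = fits, maps = maps,
                       delta_aic = fits$DEC$aic - fits$DECJ$aic)
    note("biogeo", bg)
    if (!is.null(out_dir)) {
      write.csv(as.data.frame(maps$mean_counts),
                file.path(out_dir, "mean_transitions.csv"))
    }
  }

  manifest$wall_time_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(summarize_pipeline(res),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(res)
}

# relabel a parasite distance matrix by host ids via the association
relabel_parasite <- function(d_par, assoc) {
  A <- unclass(assoc)
  hosts <- colnames(A)[apply(A[rownames(d_par), , drop = FALSE], 1, which.max)]
  m <- unclass(d_par)
  dimnames(m) <- list(hosts, hosts)
  dist_matrix(m[sort(hosts), sort(hosts)], kind = attr(d_par, "kind"))
}

# machine-readable scalar summary of a pipeline result
summarize_pipeline <- function(res) {
  out <- list(seed = res$manifest$seed)
  d <- res$data
  out$n_samples <- length(d$samples$id)
  out$mean_loci_per_sample <- mean(rowSums(d$host_aln$mask))
  out$host_mean_divergence <- mean_pairwise_distance(d$host_aln)
  out$parasite_mean_divergence <- mean_pairwise_distance(d$parasite_aln)
  if (!is.null(res$mantel)) {
    for (nm in names(res$mantel)) {
      out[[paste0("mantel_", nm, "_r")]] <- res$mantel[[nm]]$r
      out[[paste0("mantel_", nm, "_p")]] <- res$mantel[[nm]]$p
    }
  }
  if (!is.null(res$sweeps)) {
    sr <- res$sweeps$ibd_radius
    ok <- !is.na(sr$mean_r)
    if (any(ok)) {
      out$ibd_best_radius_km <- sr$control[ok][which.max(sr$mean_r[ok])]
    }
  }
  if (!is.null(res$cophylo)) {
    out$parafit_p <- res$cophylo$parafit$p_global
    out$paco_m2 <- res$cophylo$paco$m2
    out$paco_p <- res$cophylo$paco$p
  }
  if (!is.null(res$placement)) {
    pl <- res$placement
    out$placement_confidence_max_loci <- pl$mean_confidence[which.max(pl$k)]
    out$placement_correct_max_loci <- pl$frac_correct[which.max(pl$k)]
  }
  if (!is.null(res$biogeo)) {
    out$delta_aic_dec_minus_decj <- res$biogeo$delta_aic
    out$mean_range_changes <- res$biogeo$maps$mean_total
  }
  out
}
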