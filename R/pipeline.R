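# Orchestration: run configuration and the two-system comparison report.

#' Default run configuration
#'
#' Aggregates every tunable the pipeline uses, at the package defaults:
#' contact cutoff 4.5 A, stable-contact threshold 0.70, network persistence
#' 0.75, minimum community size 3, temperature 310 K, 5 clusters,
#' 100 x 100 FEL bins.
#'
#' @param structure,trajectory,params input file paths (may be `NA` when the
#'   objects are passed in memory).
#' @param label system label used in outputs.
#' @param groupA,groupB chain ids of the two binding partners.
#' @param start first analysis frame.
#' @param seed RNG seed for the clustering stage.
#' @return Object of class `run_config` (a validated named list).
#' @export
run_config <- function(structure = NA_character_,
                       trajectory = NA_character_,
                       params = NA_character_,
                       label = "system",
                       groupA = "M", groupB = "P",
                       start = 1L, seed = 1L) {
  cfg <- list(structure = structure, trajectory = trajectory,
              params = params, label = label,
              groupA = groupA, groupB = groupB,
              start = as.integer(start), seed = as.integer(seed),
              contact_cutoff = 4.5, stable_threshold = 0.70,
              persistence = 0.75, min_community = 3L,
              temperature = 310, fel_bins = 100L, k_clusters = 5L,
              n_pcs = 10L, sasa_points = 240L, energy_stride = 10L,
              interface_stride = 5L)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$contact_cutoff > 0,
            cfg$stable_threshold >= 0, cfg$stable_threshold <= 1,
            cfg$persistence >= 0, cfg$persistence <= 1,
            cfg$min_community >= 1, cfg$temperature > 0,
            cfg$fel_bins >= 2, cfg$k_clusters >= 1, cfg$n_pcs >= 1,
            cfg$start >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#' Configurations round-trip losslessly through [write_run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- unclass(run_config())
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  base[names(raw)] <- raw
  base$start <- as.integer(base$start)
  base$seed <- as.integer(base$seed)
  base$min_community <- as.integer(base$min_community)
  base$fel_bins <- as.integer(base$fel_bins)
  base$k_clusters <- as.integer(base$k_clusters)
  base$n_pcs <- as.integer(base$n_pcs)
  base$sasa_points <- as.integer(base$sasa_points)
  base$energy_stride <- as.integer(base$energy_stride)
  base$interface_stride <- as.integer(base$interface_stride)
  validate_run_config(base)
}

#' Write a run configuration as YAML
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config '", x$label, "': cutoff ", x$contact_cutoff,
      " A, stable >= ", x$stable_threshold, ", persistence >= ",
      x$persistence, ", T = ", x$temperature, " K\n", sep = "")
  invisible(x)
}

load_system <- function(cfg, dataset = NULL) {
  if (!is.null(dataset))
    return(list(model = dataset$model,
                traj = within_start(dataset$trajectory, cfg$start),
                truth = dataset$truth))
  model <- read_structure(cfg$structure)
  if (!is.na(cfg$params)) model <- read_ff_params(cfg$params, model)
  traj <- read_trajectory(cfg$trajectory, model, start = cfg$start)
  list(model = model, traj = traj, truth = NULL)
}

within_start <- function(traj, start) {
  traj$start <- as.integer(start)
  traj
}

# run every analysis stage for one system; a failing stage is recorded and
# skipped by its dependents instead of aborting the run
run_stages <- function(sys, cfg, outdir = NULL, shared_model = NULL) {
  traj <- sys$traj
  model <- sys$model
  stage <- list()
  timings <- list()
  failed <- character(0)
  run1 <- function(name, expr, needs = character(0)) {
    if (any(needs %in% failed)) {
      failed <<- c(failed, name)
      return(invisible())
    }
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      failed <<- c(failed, name)
      NULL
    })
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    if (!is.null(res)) stage[[name]] <<- res
    invisible()
  }
  run1("rmsd", rmsd_series(traj, "ca"))
  run1("rmsf", rmsf(traj, "ca"))
  run1("dccm", dccm(traj, "ca"))
  run1("pca", if (is.null(shared_model)) fit_pca(traj, "ca") else shared_model)
  run1("proj", project_frames(stage$pca, traj, "ca", components = 1:2),
       needs = "pca")
  run1("fel", fel(stage$proj[, 1], stage$proj[, 2],
                  bins = min(cfg$fel_bins, 40L),
                  temperature = cfg$temperature), needs = "proj")
  run1("clusters", kmeans_representatives(stage$proj, k = cfg$k_clusters,
                                          seed = cfg$seed), needs = "proj")
  run1("interface", interface_area(traj, cfg$groupA, cfg$groupB,
                                   points = cfg$sasa_points,
                                   stride = cfg$interface_stride))
  run1("interactions",
       classify_interface(traj, cfg$groupA, cfg$groupB,
                          stable_threshold = cfg$stable_threshold))
  run1("energy", binding_energy(traj, cfg$groupB, cfg$groupA,
                                points = cfg$sasa_points,
                                stride = cfg$energy_stride))
  run1("network", build_network(traj, stage$dccm,
                                cutoff = cfg$contact_cutoff,
                                persistence = cfg$persistence),
       needs = "dccm")
  run1("communities", girvan_newman(stage$network,
                                    min_size = cfg$min_community),
       needs = "network")
  run1("coupling", intercommunity_strength(stage$network, stage$communities),
       needs = c("network", "communities"))
  stage$failed <- failed
  stage$timings <- data.frame(stage = names(timings),
                              seconds = unlist(timings, use.names = FALSE),
                              status = ifelse(names(timings) %in% failed,
                                              "failed", "ok"))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(cfg, file.path(outdir, "config.yaml"))
    w <- function(name, writer) if (!is.null(stage[[name]])) writer()
    w("rmsd", function() write_rmsd(stage$rmsd, file.path(outdir, "rmsd.tsv")))
    w("rmsf", function() write_rmsf(stage$rmsf, file.path(outdir, "rmsf.tsv")))
    w("dccm", function() write_dccm(stage$dccm, file.path(outdir, "dccm.tsv")))
    w("pca", function() write_eigenvalues(stage$pca,
                                          file.path(outdir, "eigenvalues.tsv")))
    w("proj", function() write_projection(stage$proj,
                                          file.path(outdir, "projection.tsv")))
    w("fel", function() write_fel(stage$fel, file.path(outdir, "fel.tsv")))
    w("interface", function() write_interface(stage$interface,
                                              file.path(outdir, "interface.tsv")))
    w("interactions", function() write_interactions(
      stage$interactions, file.path(outdir, "interactions.tsv")))
    w("energy", function() write_energy(stage$energy,
                                        file.path(outdir, "energy.tsv")))
    w("network", function() write_network_edges(
      stage$network, file.path(outdir, "network_edges.tsv")))
    w("communities", function() write_communities(
      stage$network, stage$communities, file.path(outdir, "communities.tsv")))
    w("pca", function() porcupine(
      stage$pca, 1, scale = 10,
      topology = subset_structure(model, select_atoms(model, "ca")),
      path = file.path(outdir, "porcupine_pc1.pdb")))
    utils::write.table(stage$timings, file.path(outdir, "stages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage
}

# selection-restricted copy of a structure (used for porcupine PDB output)
subset_structure <- function(model, idx) {
  md_structure(model$atoms[idx, , drop = FALSE],
               model$xyz[idx, , drop = FALSE])
}

chain_of_node <- function(graph) stats::setNames(graph$nodes$chain,
                                                 graph$nodes$id)

# summed |C| over edges joining the two chains (interface network strength)
interchain_strength <- function(graph) {
  if (!nrow(graph$edges)) return(0)
  ch <- chain_of_node(graph)
  cross <- ch[graph$edges$from] != ch[graph$edges$to]
  sum(graph$edges$absC[cross])
}

# does some reported community span both chains and contain the hub?
hub_spanning_community <- function(graph, partition, hub_id) {
  ch <- chain_of_node(graph)
  for (comm in partition$communities) {
    if (hub_id %in% comm && length(unique(ch[comm])) > 1L) return(TRUE)
  }
  FALSE
}

system_metrics <- function(stage, cfg, hub_id = NULL) {
  val <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  occ_of <- function(type) {
    t2 <- stage$interactions[stage$interactions$type == type, , drop = FALSE]
    if (!nrow(t2)) 0 else max(t2$occupancy)
  }
  c(mean_rmsd_A = val(mean(stage$rmsd[-1])),
    mean_rmsf_A = val(mean(stage$rmsf)),
    pc1_fraction = val(unname(variance_fractions(stage$pca)[1])),
    pc2_fraction = val(unname(variance_fractions(stage$pca)[2])),
    interface_mode_A2 = val(interface_mode(stage$interface)),
    dG_binding = val(energy_component(stage$energy, "dG_binding")),
    max_saltbridge_occupancy = val(occ_of("saltbridge")),
    max_hbond_occupancy = val(occ_of("hbond")),
    max_hydrophobic_occupancy = val(occ_of("hydrophobic")),
    n_stable_contacts = val(sum(stage$interactions$stable)),
    n_communities = val(length(stage$communities$communities)),
    interchain_strength = val(interchain_strength(stage$network)),
    hub_spanning_community = if (is.null(hub_id)) NA else
      val(as.numeric(hub_spanning_community(stage$network,
                                            stage$communities, hub_id))))
}

#' Run the full two-system comparison
#'
#' Executes the whole analysis sequence for each system — RMSD/RMSF, DCCM,
#' shared-space PCA, RMSIP/overlap, FEL, clusters, porcupine, interface
#' area, typed interactions, binding energetics, residue network and
#' communities — and assembles a paired metric report. When `outdir` is
#' given, every stage's table is written beneath `outdir/<label>/`.
#'
#' @param configA,configB `run_config`s for the two systems.
#' @param datasetA,datasetB optional in-memory datasets (as produced by
#'   [make_scenario_pair()]); when omitted, inputs are read from the config
#'   paths.
#' @param outdir optional output directory.
#' @param hub_id optional residue id whose community membership is reported.
#' @return Object of class `compare_report`: data.frame `report` (metric,
#'   valueA, valueB), `rmsip` of the two systems' own essential subspaces,
#'   `overlap` matrix, and both systems' full stage results. A failing stage
#'   is recorded in `failed` (and warned about) while independent stages
#'   still run; its metrics appear as `NA`.
#' @export
run_compare <- function(configA, configB, datasetA = NULL, datasetB = NULL,
                        outdir = NULL, hub_id = NULL) {
  sysA <- load_system(configA, datasetA)
  sysB <- load_system(configB, datasetB)
  outA <- if (is.null(outdir)) NULL else file.path(outdir, configA$label)
  outB <- if (is.null(outdir)) NULL else file.path(outdir, configB$label)
  stageA <- run_stages(sysA, configA, outA)
  stageB <- run_stages(sysB, configB, outB)
  if (!is.null(stageA$pca) && !is.null(stageB$pca)) {
    k <- min(configA$n_pcs, ncol(stageA$pca$vectors), ncol(stageB$pca$vectors))
    rms <- rmsip(stageA$pca, stageB$pca, k = k)
    ov <- overlap_matrix(stageA$pca, stageB$pca, k = k)
  } else {
    rms <- NA_real_
    ov <- NULL
  }
  mA <- system_metrics(stageA, configA, hub_id)
  mB <- system_metrics(stageB, configB, hub_id)
  report <- data.frame(metric = names(mA), valueA = unname(mA),
                       valueB = unname(mB))
  res <- structure(list(report = report, rmsip = rms, overlap = ov,
                        labels = c(configA$label, configB$label),
                        failed = list(A = stageA$failed, B = stageB$failed),
                        stagesA = stageA, stagesB = stageB),
                   class = "compare_report")
  if (!is.null(outdir)) {
    utils::write.table(report, file.path(outdir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(utils::capture.output(print(res)),
               file.path(outdir, "report.txt"))
  }
  res
}

#' @export
print.compare_report <- function(x, ...) {
  cat("compare_report:", x$labels[1], "vs", x$labels[2], "\n")
  if (!is.null(x$overlap))
    cat(sprintf("  subspace RMSIP (first %d PCs): %.3f\n",
                nrow(x$overlap), x$rmsip))
  tab <- x$report
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-28s %10.4f  %10.4f\n", tab$metric[i], tab$valueA[i],
                tab$valueB[i]))
  for (side in c("A", "B"))
    if (length(x$failed[[side]]))
      cat("  [", x$labels[match(side, c("A", "B"))], "] failed stage(s): ",
          paste(x$failed[[side]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract one paired metric from a comparison report
#' @param x a `compare_report`.
#' @param metric metric name as listed in `x$report`.
#' @return Named length-2 numeric (valueA, valueB).
#' @export
report_metric <- function(x, metric) {
  i <- match(metric, x$report$metric)
  if (is.na(i)) stop("no metric '", metric, "'")
  stats::setNames(c(x$report$valueA[i], x$report$valueB[i]), x$labels)
}
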