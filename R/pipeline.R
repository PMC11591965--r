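PIPELINE_STAGES <- c("simulate", "rmsd", "dccm", "network", "pca",
                     "nj", "counts", "diverge", "integrate")

#' Pipeline configuration
#'
#' Builds (and validates) the configuration list consumed by [run_stage()]
#' and [run_pipeline()]. `config` may be a named list of overrides or the
#' path of a YAML file containing them. All randomness in a run derives
#' from `seed`, so two runs with the same configuration produce identical
#' artifacts.
#'
#' @param config named list or YAML file path with overrides.
#' @param outdir output directory (created if needed); overrides `config`.
#' @return a validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list(), outdir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_nd("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    outdir = "netdiverge_run",
    seed = 1L,
    n_residues = 50L, n_frames = 2000L,
    hubs = 1:3, rho = 0.6,
    theta_true = 0.5, n_taxa = 8L, branch_length = 0.15,
    alpha = 0.5, beta = 0.5,
    correlation_cutoff = 0.5,
    q_min = 0.5, c_min = 0.5, band = 0.15,
    n_boot = 200L,
    superpose_reference = "mean")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_nd("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  cfg$seed <- check_count(cfg$seed, "seed", lower = 0L)
  check_number(cfg$theta_true, "theta_true", lower = 0, upper = 1)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

stage_path <- function(cfg, ...) file.path(cfg$outdir, ...)

require_artifact <- function(cfg, file, produced_by) {
  p <- stage_path(cfg, file)
  if (!file.exists(p))
    stop_nd("missing artifact '", file, "': run the '", produced_by,
            "' stage first")
  p
}

write_manifest <- function(cfg, stage, inputs, outputs, params) {
  checksum <- function(files) {
    if (length(files) == 0L) return(structure(list(), names = character()))
    as.list(tools::md5sum(vapply(files, function(f) stage_path(cfg, f), "")))
  }
  man <- list(stage = stage,
              package_version = as.character(packageVersion("netdiverge")),
              seed = cfg$seed,
              params = params,
              inputs = setNames(checksum(inputs), inputs),
              outputs = setNames(checksum(outputs), outputs))
  path <- stage_path(cfg, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man)
}

read_counts_artifacts <- function(cfg) {
  cpath <- require_artifact(cfg, "counts.tsv", "counts")
  tpath <- require_artifact(cfg, "times.json", "counts")
  list(counts = read.table(cpath, header = TRUE, sep = "\t"),
       times = jsonlite::read_json(tpath, simplifyVector = TRUE))
}

load_superposed <- function(cfg) {
  tpath <- require_artifact(cfg, "trajectory.xyz", "simulate")
  superpose(read_trajectory(tpath), cfg$superpose_reference)
}

#' Run one pipeline stage
#'
#' Executes a single stage of the synthetic end-to-end study on disk.
#' Stages exchange plain-text artifacts inside `outdir` and each writes a
#' `manifest_<stage>.json` recording parameters, seed and md5 checksums of
#' its inputs and outputs, so deterministic stages can be verified to
#' reproduce bit-identical results.
#'
#' Stages and their artifacts:
#' \describe{
#'   \item{simulate}{`trajectory.xyz`, `alignment.fasta`, `tree1.nwk`,
#'     `tree2.nwk`, `clusters.tsv`, `truth.tsv`}
#'   \item{rmsd}{`rmsd.tsv`, `rmsf.tsv` (first-frame reference)}
#'   \item{dccm}{`dccm.tsv` (matrix), `dccm_long.csv`}
#'   \item{network}{`edges.csv`, `centrality.csv`}
#'   \item{pca}{`scree.csv`, `projections.csv`}
#'   \item{nj}{`dist1.phy`, `dist2.phy` (PHYLIP square), `nj1.nwk`,
#'     `nj2.nwk`}
#'   \item{counts}{`counts.tsv` (site, X1, X2), `times.json` (T1, T2)}
#'   \item{diverge}{`divergence.csv`, `divergence_summary.json`}
#'   \item{integrate}{`integration.csv`, `integration_summary.json`}
#' }
#'
#' @param name stage name, one of
#'   `simulate, rmsd, dccm, network, pca, nj, counts, diverge, integrate`.
#' @param config a [pipeline_config()], override list, or YAML path.
#' @return the stage manifest, invisibly.
#' @export
run_stage <- function(name, config = list()) {
  name <- match.arg(name, PIPELINE_STAGES)
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  switch(name,
    simulate = stage_simulate(cfg),
    rmsd = stage_rmsd(cfg),
    dccm = stage_dccm(cfg),
    network = stage_network(cfg),
    pca = stage_pca(cfg),
    nj = stage_nj(cfg),
    counts = stage_counts(cfg),
    diverge = stage_diverge(cfg),
    integrate = stage_integrate(cfg))
}

#' Run the whole pipeline
#'
#' All stages of [run_stage()] in dependency order.
#'
#' @param config a [pipeline_config()], override list, or YAML path.
#' @param outdir optional output directory override.
#' @return list of stage manifests, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config, outdir)
  invisible(lapply(setNames(nm = PIPELINE_STAGES), run_stage, config = cfg))
}

stage_simulate <- function(cfg) {
  C <- hub_correlation(cfg$n_residues, cfg$hubs, cfg$rho)
  traj <- simulate_trajectory(
    trajectory_spec(cfg$n_residues, cfg$n_frames, C, seed = cfg$seed))
  write_trajectory(traj, stage_path(cfg, "trajectory.xyz"), "xyz")
  tree1 <- balanced_tree(cfg$n_taxa, cfg$branch_length, "a")
  tree2 <- balanced_tree(cfg$n_taxa, cfg$branch_length, "b")
  states <- with_seed(cfg$seed + 1L,
                      ifelse(runif(cfg$n_residues) < cfg$theta_true,
                             "F1", "F0"))
  states[cfg$hubs] <- "F1"
  la <- simulate_two_cluster_alignment(
    evolution_spec(cfg$n_residues, cfg$theta_true, tree1, tree2,
                   alpha = cfg$alpha, beta = cfg$beta, seed = cfg$seed + 1L),
    site_state = states)
  write_alignment(la$alignment, stage_path(cfg, "alignment.fasta"))
  ape::write.tree(tree1, stage_path(cfg, "tree1.nwk"))
  ape::write.tree(tree2, stage_path(cfg, "tree2.nwk"))
  write.table(data.frame(taxon = names(la$cluster), cluster = la$cluster),
              stage_path(cfg, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_truth_labels(la, stage_path(cfg, "truth.tsv"))
  write_manifest(cfg, "simulate", character(),
                 c("trajectory.xyz", "alignment.fasta", "tree1.nwk",
                   "tree2.nwk", "clusters.tsv", "truth.tsv"),
                 cfg[c("n_residues", "n_frames", "hubs", "rho", "theta_true",
                       "n_taxa", "branch_length", "alpha", "beta")])
}

stage_rmsd <- function(cfg) {
  tpath <- require_artifact(cfg, "trajectory.xyz", "simulate")
  sup <- superpose(read_trajectory(tpath), "first")
  write.table(data.frame(frame = seq_along(sup$per_frame_rmsd),
                         rmsd = rmsd_series(sup)),
              stage_path(cfg, "rmsd.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sup_mean <- superpose(read_trajectory(tpath), "mean")
  write.table(data.frame(residue = seq_len(n_residues(sup_mean$aligned)),
                         rmsf = rmsf_profile(sup_mean)),
              stage_path(cfg, "rmsf.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(cfg, "rmsd", "trajectory.xyz", c("rmsd.tsv", "rmsf.tsv"),
                 list(reference = "first (rmsd) / mean (rmsf)"))
}

stage_dccm <- function(cfg) {
  # synthetic frames are already in a common reference frame
  tpath <- require_artifact(cfg, "trajectory.xyz", "simulate")
  dccm <- compute_dccm(read_trajectory(tpath))
  write.table(round(unclass(dccm), 6), stage_path(cfg, "dccm.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  idx <- which(upper.tri(dccm), arr.ind = TRUE)
  long <- data.frame(res_i = rownames(dccm)[idx[, 1]],
                     res_j = colnames(dccm)[idx[, 2]],
                     C_ij = round(dccm[idx], 6))
  write.table(long, stage_path(cfg, "dccm_long.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "dccm", "trajectory.xyz",
                 c("dccm.tsv", "dccm_long.csv"),
                 list(reference = cfg$superpose_reference))
}

stage_network <- function(cfg) {
  dpath <- require_artifact(cfg, "dccm.tsv", "dccm")
  C <- as.matrix(read.table(dpath, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE))
  colnames(C) <- rownames(C)
  C <- (C + t(C)) / 2; diag(C) <- 1
  graph <- build_graph(C, cfg$correlation_cutoff)
  write.table(graph$edges, stage_path(cfg, "edges.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(centrality_table(graph), stage_path(cfg, "centrality.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "network", "dccm.tsv",
                 c("edges.csv", "centrality.csv"),
                 list(correlation_cutoff = cfg$correlation_cutoff))
}

stage_pca <- function(cfg) {
  p <- pca_trajectory(load_superposed(cfg))
  write.table(scree_table(p), stage_path(cfg, "scree.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  k <- min(3L, ncol(p$projections))
  proj <- data.frame(frame = seq_len(nrow(p$projections)),
                     p$projections[, seq_len(k), drop = FALSE])
  write.table(proj, stage_path(cfg, "projections.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "pca", "trajectory.xyz",
                 c("scree.csv", "projections.csv"), list())
}

read_clusters <- function(cfg) {
  cl <- read.table(require_artifact(cfg, "clusters.tsv", "simulate"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  split(cl$taxon, cl$cluster)
}

stage_nj <- function(cfg) {
  aln <- read_alignment(require_artifact(cfg, "alignment.fasta", "simulate"))
  clusters <- read_clusters(cfg)
  outs <- character()
  for (c_id in names(clusters)) {
    d <- p_distance_matrix(aln[clusters[[c_id]], , drop = FALSE])
    dfile <- sprintf("dist%s.phy", c_id)
    write_phylip_square(d, stage_path(cfg, dfile))
    tfile <- sprintf("nj%s.nwk", c_id)
    ape::write.tree(neighbor_joining(d), stage_path(cfg, tfile))
    outs <- c(outs, dfile, tfile)
  }
  write_manifest(cfg, "nj", c("alignment.fasta", "clusters.tsv"), outs,
                 list(distance = "p-distance, pairwise deletion"))
}

stage_counts <- function(cfg) {
  aln <- read_alignment(require_artifact(cfg, "alignment.fasta", "simulate"))
  clusters <- read_clusters(cfg)
  t1 <- ape::read.tree(require_artifact(cfg, "nj1.nwk", "nj"))
  t2 <- ape::read.tree(require_artifact(cfg, "nj2.nwk", "nj"))
  X1 <- fitch_site_changes(aln, t1, clusters[["1"]])
  X2 <- fitch_site_changes(aln, t2, clusters[["2"]])
  write.table(data.frame(site = seq_along(X1), X1 = X1, X2 = X2),
              stage_path(cfg, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(T1 = tree_length(t1), T2 = tree_length(t2)),
                       stage_path(cfg, "times.json"), auto_unbox = TRUE,
                       digits = NA)
  write_manifest(cfg, "counts",
                 c("alignment.fasta", "clusters.tsv", "nj1.nwk", "nj2.nwk"),
                 c("counts.tsv", "times.json"),
                 list(counter = "Fitch parsimony"))
}

stage_diverge <- function(cfg) {
  art <- read_counts_artifacts(cfg)
  div <- functional_divergence(art$counts$X1, art$counts$X2,
                               art$times$T1, art$times$T2,
                               n_boot = cfg$n_boot, seed = cfg$seed + 2L)
  write.table(data.frame(site = art$counts$site, X1 = div$X1, X2 = div$X2,
                         posterior = div$posterior),
              stage_path(cfg, "divergence.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(div[c("theta", "theta_se", "r_lambda", "alpha",
                             "beta")],
                       stage_path(cfg, "divergence_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "diverge", c("counts.tsv", "times.json"),
                 c("divergence.csv", "divergence_summary.json"),
                 list(n_boot = cfg$n_boot))
}

stage_integrate <- function(cfg) {
  div <- read.table(require_artifact(cfg, "divergence.csv", "diverge"),
                    header = TRUE, sep = ",")
  cent <- read.table(require_artifact(cfg, "centrality.csv", "network"),
                     header = TRUE, sep = ",", stringsAsFactors = FALSE)
  class(cent) <- c("centrality_table", "data.frame")
  tab <- integration_table(div$posterior, cent,
                           q_min = cfg$q_min, c_min = cfg$c_min,
                           band = cfg$band)
  write.table(as.data.frame(tab), stage_path(cfg, "integration.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(correlations = attr(tab, "correlations"),
         hotspots = select_hotspots(tab, cfg$q_min, cfg$c_min, cfg$band)),
    stage_path(cfg, "integration_summary.json"), auto_unbox = TRUE,
    digits = NA)
  write_manifest(cfg, "integrate", c("divergence.csv", "centrality.csv"),
                 c("integration.csv", "integration_summary.json"),
                 cfg[c("q_min", "c_min", "band")])
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric matrix with taxon dimnames.
#' @param path output file.
#' @export
write_phylip_square <- function(d, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = "  ")), con)
  invisible(path)
}
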