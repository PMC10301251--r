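#' @title End-to-end pipeline: conflict, ILS test and network scan
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param gene_trees Path to a multi-Newick gene-tree file, or a list of
#'   trees.
#' @param out_dir Output directory.
#' @param outgroup Outgroup leaf label.
#' @param species_tree Optional path/tree; inferred from the gene trees by
#'   quartet-score search when `NULL`. A supplied tree with branch lengths
#'   is used as the coalescent-unit guide tree directly; without lengths,
#'   coalescent units are estimated from quartet frequencies. Note that a
#'   topology inferred from hybrid-bearing gene trees can itself be
#'   distorted, which weakens the downstream ILS test.
#' @param min_support Bootstrap filter for concordance mapping (default 50).
#' @param qs_replicates Quartet-sampling replicates per branch (default
#'   1000).
#' @param n_sim Simulated null gene trees for the ILS test (default 20000).
#' @param overlap_threshold ILS-test verdict threshold (default 0.75).
#' @param max_reticulations Maximum retained reticulations (default 5).
#' @param improvement_threshold Minimum PL gain to retain a reticulation
#'   (default 1 percent of |tree PL|).
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gene_trees, out_dir, outgroup,
                            species_tree = NULL, min_support = 50,
                            qs_replicates = 1000, n_sim = 20000,
                            overlap_threshold = 0.75, max_reticulations = 5,
                            improvement_threshold = NULL, seed = 1) {
  stopifnot(min_support >= 0, min_support <= 100, qs_replicates >= 1,
            n_sim >= 1, overlap_threshold >= 0, overlap_threshold <= 1,
            max_reticulations >= 0)
  structure(list(gene_trees = gene_trees, out_dir = out_dir,
                 outgroup = outgroup, species_tree = species_tree,
                 min_support = min_support, qs_replicates = qs_replicates,
                 n_sim = n_sim, overlap_threshold = overlap_threshold,
                 max_reticulations = max_reticulations,
                 improvement_threshold = improvement_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, t0, ...) {
  extra <- c(...)
  kv <- if (length(extra)) paste(names(extra), extra, sep = "=", collapse = " ") else ""
  message(sprintf("stage=%s elapsed=%.2fs %s", stage,
                  as.numeric(Sys.time() - t0, units = "secs"), kv))
}

#' Run the full pipeline
#'
#' Stages, in order: load and validate gene trees; infer (or accept) the
#' species tree and root it on the outgroup; estimate coalescent-unit
#' branch lengths; concordance mapping with ICA and quartet sampling; the
#' coalescent ILS test; the network scan. Each stage writes its artifact
#' under `config$out_dir` and logs a `key=value` line to stderr; the run is
#' byte-identical for a fixed master seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  gt <- config$gene_trees
  if (is.character(gt)) gt <- read_gene_trees(gt)
  if (length(gt) == 0L) stop("stage=load: empty gene-tree input")
  taxa <- sort(unique(unlist(lapply(gt, `[[`, "tip.label"))))
  if (!(config$outgroup %in% taxa)) {
    stop("stage=load: outgroup ", config$outgroup, " absent from the gene trees")
  }
  stage_log("load", t0, n_trees = length(gt), n_taxa = length(taxa))

  t0 <- Sys.time()
  sp <- config$species_tree
  if (is.null(sp)) {
    sp <- infer_species_tree(gt, seed = derive_seed(config$seed, "speciestree"))
  } else if (is.character(sp)) {
    sp <- parse_newick(readLines(sp, warn = FALSE)[1])
  }
  sp <- reroot(sp, config$outgroup)
  if (!is.null(sp$edge.length)) {
    # a supplied guide tree with branch lengths is taken at face value
    # (lengths in coalescent units), as when the coalescent species tree
    # comes from an upstream summary method
    model <- sp
    tab <- data.frame(branch = bipartition_set(sp)$split,
                      pbar = NA_real_,
                      t_hat = bipartition_set(sp)$length,
                      resolved = NA_integer_)
  } else {
    model <- estimate_coalescent_branch_lengths(
      sp, gt, seed = derive_seed(config$seed, "branchlengths"))
    tab <- attr(model, "branch_estimates")
  }
  writeLines(write_newick(model), file.path(config$out_dir, "species_tree.nwk"))
  utils::write.table(tab, file.path(config$out_dir, "branch_lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("speciestree", t0)

  t0 <- Sys.time()
  conf <- map_concordance(model, gt, min_support = config$min_support)
  qs <- quartet_sampling(model, gt, replicates_per_branch = config$qs_replicates,
                         seed = derive_seed(config$seed, "qs"))
  write_conflict_tsv(conf, file.path(config$out_dir, "conflict.tsv"), qs = qs)
  writeLines(conflict_annotated_newick(model, conf),
             file.path(config$out_dir, "conflict_annotated.nwk"))
  stage_log("conflict", t0)

  t0 <- Sys.time()
  ils <- ils_discordance_test(gt, model, n_sim = config$n_sim,
                              seed = derive_seed(config$seed, "ilstest"),
                              overlap_threshold = config$overlap_threshold)
  jsonlite::write_json(list(
    observed_hist = as.list(ils$observed_hist),
    simulated_hist = as.list(ils$simulated_hist),
    overlap = ils$overlap, ks = ils$ks, verdict = ils$verdict,
    params = ils$params), file.path(config$out_dir, "ils_test.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(
    data.frame(normalized_rf = ils$observed_values),
    file.path(config$out_dir, "rf_distances_observed.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("ilstest", t0, overlap = sprintf("%.3f", ils$overlap),
            verdict = ils$verdict)

  t0 <- Sys.time()
  scan <- scan_and_rank_networks(gt, model, config$outgroup,
                                 max_reticulations = config$max_reticulations,
                                 improvement_threshold = config$improvement_threshold)
  utils::write.table(scan$table, file.path(config$out_dir, "network_ranked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scan$selected)) {
    write_network_model(scan$selected,
                        file.path(config$out_dir, "selected_network.txt"))
  }
  stage_log("network", t0, retained = length(scan$retained))

  report <- write_report(config, model, conf, qs, ils, scan,
                         file.path(config$out_dir, "manifest.json"))
  invisible(report)
}

#' Assemble and write the machine-readable pipeline report
#'
#' One JSON manifest with the config echo, per-stage file inventory and
#' headline results (ICA range, QS summary, ILS overlap and verdict, the
#' selected network with its inheritance-probability pair). Numbers are
#' serialized with 6 significant digits.
#'
#' @param config The [pipeline_config()] used.
#' @param model,conf,qs,ils,scan Stage outputs.
#' @param path Output path for the JSON manifest.
#' @return The report list, invisibly written to `path`.
#' @export
write_report <- function(config, model, conf, qs, ils, scan, path) {
  sig <- function(x) signif(x, 6)
  sel <- if (length(scan$retained) > 0L) {
    f <- scan$retained[[1]]
    list(recipient = paste(f$recipient, collapse = "+"),
         donor = paste(f$donor, collapse = "+"),
         gamma_minor = sig(f$gamma), gamma_major = sig(1 - f$gamma),
         tau = sig(f$tau), logpl = sig(f$value))
  } else NULL
  report <- list(
    package = "ilsnet",
    config = list(outgroup = config$outgroup, min_support = config$min_support,
                  qs_replicates = config$qs_replicates, n_sim = config$n_sim,
                  overlap_threshold = config$overlap_threshold,
                  max_reticulations = config$max_reticulations,
                  seed = config$seed),
    files = list(species_tree = "species_tree.nwk",
                 branch_lengths = "branch_lengths.tsv",
                 conflict = "conflict.tsv",
                 conflict_annotated = "conflict_annotated.nwk",
                 ils_test = "ils_test.json",
                 rf_distances = "rf_distances_observed.tsv",
                 network_ranked = "network_ranked.tsv",
                 selected_network = if (is.null(sel)) NULL else "selected_network.txt"),
    headline = list(
      species_tree = write_newick(model),
      ica_range = sig(range(conf$ica, na.rm = TRUE)),
      mean_prop_concordant = sig(mean(conf$prop_concordant)),
      qs_qc_range = sig(range(qs$qc, na.rm = TRUE)),
      ils_overlap = sig(ils$overlap),
      ils_verdict = ils$verdict,
      n_reticulations = length(scan$retained),
      selected_network = sel
    )
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}
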