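#' Pipeline configuration
#'
#' Collects every setting the full workflow needs: either paths to input TPS
#' files plus a Newick tree, or a `simulate` block describing a synthetic
#' study; permutation counts for the three test families; and the seed.
#' Defaults follow the replicated design the package emulates: 999
#' permutations for the Procrustes ANOVAs, 9999 for the phylogenetic-signal
#' tests, 999 for the phylogenetic PLS.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param n_perm_anova,n_perm_signal,n_perm_pls permutation counts.
#' @param out_dir optional output directory for CSV/JSON result files.
#' @param simulate list of overrides for [sim_params()] (e.g. `n_species`,
#'   `n_individuals`, `n_replicates`, variance components), or `NULL` to
#'   analyze supplied files.
#' @param n_lobulate number of species carrying 3rd-order lobules (digitized
#'   with the 15-landmark scheme); the remainder are analyzed with the
#'   7-landmark scheme only.
#' @param tps_7,tps_15 paths to TPS files for the 7- and 15-landmark
#'   datasets (ignored when simulating).
#' @param newick path to the Newick tree for the 7-landmark species set
#'   (ignored when simulating).
#' @param lobulate_species character vector naming the species analyzed at 15
#'   landmarks (ignored when simulating; a dataset annotation, not inferred
#'   from shapes).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_perm_anova = 999, n_perm_signal = 9999,
                            n_perm_pls = 999, out_dir = NULL,
                            simulate = list(), n_lobulate = 14,
                            tps_7 = NULL, tps_15 = NULL, newick = NULL,
                            lobulate_species = NULL) {
  structure(list(seed = as.integer(seed), n_perm_anova = as.integer(n_perm_anova),
                 n_perm_signal = as.integer(n_perm_signal),
                 n_perm_pls = as.integer(n_perm_pls), out_dir = out_dir,
                 simulate = simulate, n_lobulate = as.integer(n_lobulate),
                 tps_7 = tps_7, tps_15 = tps_15, newick = newick,
                 lobulate_species = lobulate_species),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

## Tiny rolling hash of a serialized object, for provenance stamping.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate the full study design
#'
#' Builds the inputs of the complete workflow: a pure-birth species tree, a
#' 7-landmark dataset covering all species, and a 15-landmark dataset for the
#' subset of species flagged as possessing 3rd-order lobules (sharing the
#' pruned tree). Species asymmetry vectors for the two landmark schemes are
#' drawn independently on the same tree.
#'
#' @param config a [pipeline_config()] with a `simulate` block.
#' @return A list of class `study_inputs` with `tree` (all species),
#'   `tree_lob` (pruned to lobulate species), `lobulate` (species names),
#'   `truth_7`, `truth_15` (the [simulate_dataset()] results), `datasets`
#'   (named list: `sublobes_7`, `full_15`, `lobules_lls`, `lobules_uls`),
#'   and `maps` (matching [symmetry_map()]s).
#' @export
simulate_study <- function(config) {
  sim <- config$simulate
  get_par <- function(name, default) if (!is.null(sim[[name]])) sim[[name]] else default
  n_sp <- get_par("n_species", 19L)
  n_lob <- min(config$n_lobulate, n_sp)
  seed <- config$seed
  tree <- simulate_tree(n_sp, seed = seed)
  set.seed(seed + 1L)
  lobulate <- sort(sample(tree$tip.label, n_lob))
  tree_lob <- if (n_lob < n_sp) ape::keep.tip(tree, lobulate) else tree
  p_common <- sim[names(sim) %in% setdiff(names(formals(sim_params)),
                                          c("base_shape", "map", "seed",
                                            "n_species"))]
  params7 <- do.call(sim_params, c(p_common, list(
    n_species = n_sp, base_shape = base_lobe_shape(7), seed = seed + 2L)))
  params15 <- do.call(sim_params, c(p_common, list(
    n_species = n_lob, base_shape = base_lobe_shape(15), seed = seed + 3L)))
  means7 <- simulate_species_means(tree, params7)
  means15 <- simulate_species_means(tree_lob, params15)
  truth7 <- simulate_dataset(means7, params7, seed = seed + 4L)
  truth15 <- simulate_dataset(means15, params15, seed = seed + 5L)
  ds15 <- truth15$dataset
  structure(list(
    tree = tree, tree_lob = tree_lob, lobulate = lobulate,
    truth_7 = truth7, truth_15 = truth15,
    datasets = list(sublobes_7 = truth7$dataset, full_15 = ds15,
                    lobules_lls = extract_landmarks(ds15, 1:7),
                    lobules_uls = extract_landmarks(ds15, 9:15)),
    maps = list(sublobes_7 = default_symmetry_map(7),
                full_15 = default_symmetry_map(15),
                lobules_lls = default_symmetry_map(7, roles = c("ltl1", "ltl2")),
                lobules_uls = default_symmetry_map(7, roles = c("utl1", "utl2")))
  ), class = "study_inputs")
}

#' Load study inputs from files
#'
#' File-based counterpart of [simulate_study()]: reads the TPS datasets and
#' the Newick tree named in the configuration and assembles the same
#' `study_inputs` structure. Which species carry 3rd-order lobules is a
#' dataset annotation supplied in the configuration.
#'
#' @param config a [pipeline_config()] with `tps_7`, `tps_15`, `newick` and
#'   `lobulate_species` set (`tps_15` may be `NULL` to skip the 15-landmark
#'   analyses).
#' @return A `study_inputs` list; see [simulate_study()].
#' @export
load_study <- function(config) {
  if (is.null(config$tps_7) || is.null(config$newick))
    stop("config must name 'tps_7' and 'newick' inputs (or use a simulate block)")
  ds7 <- read_tps(config$tps_7)
  tree <- read_newick(config$newick)
  if (!setequal(unique(ds7$species), tree$tip.label))
    stop("species in TPS data and tree tips differ: ",
         paste(union(setdiff(unique(ds7$species), tree$tip.label),
                     setdiff(tree$tip.label, unique(ds7$species))),
               collapse = ", "))
  datasets <- list(sublobes_7 = ds7)
  maps <- list(sublobes_7 = default_symmetry_map(7))
  lobulate <- config$lobulate_species
  tree_lob <- tree
  if (!is.null(config$tps_15)) {
    ds15 <- read_tps(config$tps_15)
    if (is.null(lobulate)) lobulate <- sort(unique(ds15$species))
    tree_lob <- ape::keep.tip(tree, lobulate)
    datasets$full_15 <- ds15
    datasets$lobules_lls <- extract_landmarks(ds15, 1:7)
    datasets$lobules_uls <- extract_landmarks(ds15, 9:15)
    maps$full_15 <- default_symmetry_map(15)
    maps$lobules_lls <- default_symmetry_map(7, roles = c("ltl1", "ltl2"))
    maps$lobules_uls <- default_symmetry_map(7, roles = c("utl1", "utl2"))
  }
  structure(list(tree = tree, tree_lob = tree_lob, lobulate = lobulate,
                 truth_7 = NULL, truth_15 = NULL,
                 datasets = datasets, maps = maps),
            class = "study_inputs")
}

## Subset a landmark_dataset to one species.
dataset_for_species <- function(ds, sp) {
  keep <- ds$species == sp
  landmark_dataset(ds$coords[, , keep, drop = FALSE], ds$species[keep],
                   ds$specimen[keep], ds$replicate[keep])
}

#' Per-species Procrustes ANOVAs of object symmetry
#'
#' Runs [symmetry_anova()] separately for every species in every applicable
#' analysis (the 7-landmark sublobe analysis for all species; the 15-landmark
#' and the two terminal-lobule analyses only for species flagged as
#' possessing 3rd-order lobules) and assembles the positional-asymmetry MS,
#' R-squared and p-value into one table per analysis, with explicit
#' not-applicable entries (`NA`) for species outside an analysis.
#'
#' @param study a `study_inputs` list from [simulate_study()] or
#'   [load_study()].
#' @param config a [pipeline_config()].
#' @return A list of class `symmetry_stage` with `table` (data frame: one row
#'   per species, columns `<analysis>_MS`, `<analysis>_R2`, `<analysis>_p`)
#'   and `anovas` (nested list of `symmetry_anova` objects).
#' @export
run_symmetry_stage <- function(study, config) {
  all_species <- sort(study$tree$tip.label)
  analyses <- names(study$datasets)
  anovas <- list()
  tab <- data.frame(row.names = all_species)
  for (a in analyses) {
    ds <- study$datasets[[a]]
    map <- study$maps[[a]]
    res <- list()
    ms <- r2 <- pv <- rep(NA_real_, length(all_species))
    names(ms) <- names(r2) <- names(pv) <- all_species
    for (sp in sort(unique(ds$species))) {
      sub <- dataset_for_species(ds, sp)
      if (sub$n_specimens < 2L) {
        warning("species ", sp, " has < 2 specimens; skipped in ", a)
        next
      }
      an <- symmetry_anova(sub, map, n_perm = config$n_perm_anova,
                           seed = config$seed + match(sp, all_species))
      res[[sp]] <- an
      ms[sp] <- an$table["positional_asymmetry", "MS"]
      r2[sp] <- an$table["positional_asymmetry", "Rsq"]
      pv[sp] <- an$table["positional_asymmetry", "p"]
    }
    anovas[[a]] <- res
    tab[[paste0(a, "_MS")]] <- ms
    tab[[paste0(a, "_R2")]] <- r2
    tab[[paste0(a, "_p")]] <- pv
  }
  structure(list(table = tab, anovas = anovas, analyses = analyses,
                 seed = config$seed, n_perm = config$n_perm_anova),
            class = "symmetry_stage")
}

#' @export
print.symmetry_stage <- function(x, digits = 3, ...) {
  cat("Per-species Procrustes ANOVAs of positional asymmetry\n")
  cat(sprintf("  analyses: %s; %d permutations\n",
              paste(x$analyses, collapse = ", "), x$n_perm))
  print(round(x$table, digits))
  invisible(x)
}

#' Phylogenetic stage: morphospaces, signal tests, integration
#'
#' For every analysis: species asymmetry means, the mirrored and asymmetric
#' PCA morphospaces, a squared-change-parsimony phylomorphospace, and the
#' tip-permutation test of phylogenetic signal on the full species asymmetry
#' vectors. Then the three pre-wired phylogenetic two-block PLS comparisons
#' among the 15-landmark sublobe asymmetry and the two terminal-lobule
#' asymmetry blocks.
#'
#' @param study a `study_inputs` list.
#' @param config a [pipeline_config()].
#' @return A list of class `phylo_stage` with `means`, `mirrored`,
#'   `asym_space`, `signal`, `phylomorpho` (per analysis), and
#'   `integration` (named list of `phylo_pls` results).
#' @export
run_phylo_stage <- function(study, config) {
  analyses <- names(study$datasets)
  means <- mirrored <- asym_space <- signal <- phylomorpho <- list()
  for (a in analyses) {
    tree_a <- if (a == "sublobes_7") study$tree else study$tree_lob
    m <- species_asymmetry_means(study$datasets[[a]], study$maps[[a]])
    means[[a]] <- m
    mirrored[[a]] <- mirrored_pca(m)
    asym_space[[a]] <- asymmetric_pca(m)
    delta_hat <- m$asymmetry
    signal[[a]] <- phylo_signal_test(tree_a, delta_hat,
                                     n_perm = config$n_perm_signal,
                                     seed = config$seed + 101L + match(a, analyses))
    phylomorpho[[a]] <- phylomorphospace(tree_a, asym_space[[a]])
  }
  integration <- list()
  if (all(c("full_15", "lobules_lls", "lobules_uls") %in% analyses)) {
    blocks <- lapply(means[c("full_15", "lobules_lls", "lobules_uls")],
                     function(m) m$asymmetry)
    pairs <- list(full15_vs_lls = c("full_15", "lobules_lls"),
                  full15_vs_uls = c("full_15", "lobules_uls"),
                  lls_vs_uls = c("lobules_lls", "lobules_uls"))
    for (nm in names(pairs)) {
      pr <- pairs[[nm]]
      integration[[nm]] <- phylo_pls(study$tree_lob,
                                     blocks[[pr[1]]], blocks[[pr[2]]],
                                     n_perm = config$n_perm_pls,
                                     seed = config$seed + 201L + match(nm, names(pairs)))
    }
  }
  structure(list(means = means, mirrored = mirrored, asym_space = asym_space,
                 signal = signal, phylomorpho = phylomorpho,
                 integration = integration, seed = config$seed),
            class = "phylo_stage")
}

#' @export
print.phylo_stage <- function(x, ...) {
  cat("Phylogenetic stage\n")
  for (a in names(x$signal))
    cat(sprintf("  signal [%s]: Q = %.5g, p = %.4g\n",
                a, x$signal[[a]]$Q_obs, x$signal[[a]]$p))
  for (nm in names(x$integration))
    cat(sprintf("  integration [%s]: r_PLS = %.3f, p = %.4g\n",
                nm, x$integration[[nm]]$r_pls, x$integration[[nm]]$p))
  invisible(x)
}

#' Run the complete workflow
#'
#' Simulates (or loads) the study inputs, runs the per-species symmetry
#' ANOVAs, builds the morphospaces and phylogenetic analyses, and — when
#' `config$out_dir` is set — writes the result tables (CSV), trees (Newick),
#' simulated landmarks (TPS) and a provenance-stamped JSON report. Identical
#' seeds produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_report` with `study`, `symmetry`,
#'   `phylo`, `config`, `config_hash`.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  study <- if (length(config$simulate) || is.null(config$tps_7))
    simulate_study(config) else load_study(config)
  message(sprintf("[stage simulate/load] %d species, seed %d (%.1fs)",
                  length(study$tree$tip.label), config$seed,
                  as.numeric(Sys.time() - t0, units = "secs")))
  t1 <- Sys.time()
  sym <- run_symmetry_stage(study, config)
  message(sprintf("[stage symmetry] %d analyses (%.1fs)", length(sym$analyses),
                  as.numeric(Sys.time() - t1, units = "secs")))
  t2 <- Sys.time()
  phy <- run_phylo_stage(study, config)
  message(sprintf("[stage phylo] %d signal tests, %d integrations (%.1fs)",
                  length(phy$signal), length(phy$integration),
                  as.numeric(Sys.time() - t2, units = "secs")))
  report <- structure(list(study = study, symmetry = sym, phylo = phy,
                           config = config, config_hash = config_hash(config)),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report a `pipeline_report` from [run_all()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$symmetry$table,
                   file.path(dir, "positional_asymmetry_anova.csv"))
  ape::write.tree(report$study$tree, file.path(dir, "tree.nwk"))
  if (!is.null(report$study$truth_7))
    write_tps(report$study$truth_7$dataset, file.path(dir, "sublobes_7.tps"))
  for (a in names(report$phylo$asym_space)) {
    sc <- report$phylo$asym_space[[a]]$scores
    utils::write.csv(data.frame(species = report$phylo$asym_space[[a]]$labels,
                                sc, check.names = FALSE),
                     file.path(dir, paste0("scores_", a, ".csv")),
                     row.names = FALSE)
  }
  js <- list(
    config_hash = report$config_hash,
    seed = report$config$seed,
    n_perm = list(anova = report$config$n_perm_anova,
                  signal = report$config$n_perm_signal,
                  pls = report$config$n_perm_pls),
    signal = lapply(report$phylo$signal, function(s)
      list(Q = s$Q_obs, p = s$p, seed = s$seed)),
    integration = lapply(report$phylo$integration, function(z)
      list(r_pls = z$r_pls, p = z$p, seed = z$seed))
  )
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (config hash", x$config_hash, ")\n\n")
  print(x$symmetry)
  cat("\n")
  print(x$phylo)
  invisible(x)
}
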