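#' Run the delineation / gene-content pipeline from a config
#'
#' Chains the package's stages in dependency order — tree acquisition
#' (`simulate` or a Newick input), `red` annotation, `delineate`,
#' `occurrence` profiling and `reconcile` summarisation — from a single YAML
#' (or list) configuration, writing each stage's table under `out_dir` plus a
#' run manifest with checksums of every input and output. Progress is logged
#' to standard error with stage-tagged lines; nothing is printed to standard
#' output. Reruns with the same config produce byte-identical outputs.
#'
#' Config schema (all keys optional unless noted):
#' \describe{
#'   \item{seed}{integer, default 1; drives every simulated input.}
#'   \item{out_dir}{output directory (or pass `out_dir` argument).}
#'   \item{stages}{subset of `simulate`, `red`, `delineate`, `occurrence`,
#'     `reconcile`; prerequisites are added automatically.}
#'   \item{tree}{path to a Newick tree; when absent the tree is simulated.}
#'   \item{outgroup}{leaf names treated as outgroup during delineation.}
#'   \item{delineation}{list of [delineation_params()] arguments.}
#'   \item{families}{path to a genome x family TSV; simulated when absent.}
#'   \item{annotations}{path to a `family<TAB>category` TSV.}
#'   \item{reconciliation}{list: `path` (simple_tsv file; simulated when
#'     absent), `tau` (default 0.3), `inclusive` (default FALSE).}
#'   \item{sim}{overrides passed to [sim_config()].}
#' }
#' Unknown keys are rejected before any stage runs.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#' @return A `run_manifest` (invisibly): command, config hash, inputs and
#'   outputs with MD5 checksums, package version and timestamp. Also written
#'   as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    yaml::read_yaml(config)
  } else {
    config
  }
  allowed <- c("seed", "out_dir", "stages", "tree", "outgroup", "delineation",
               "families", "annotations", "reconciliation", "sim")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  all_stages <- c("simulate", "red", "delineate", "occurrence", "reconcile")
  stages <- cfg$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  # close over prerequisites, then run in canonical order
  prereq <- list(red = "simulate", delineate = "red",
                 occurrence = "delineate", reconcile = character())
  repeat {
    need <- unique(c(stages, unlist(prereq[intersect(stages, names(prereq))])))
    if ("simulate" %in% need && !is.null(cfg$tree)) {
      need <- setdiff(need, "simulate")
    }
    if (setequal(need, stages)) break
    stages <- need
  }
  stages <- intersect(all_stages, stages)

  out_dir <- out_dir %||% cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  scfg <- do.call(sim_config, c(list(seed = seed), cfg$sim))

  log_stage <- function(stage, ...) {
    message("[", stage, "] ", ...)
  }
  inputs <- character(0)
  outputs <- character(0)
  out_path <- function(name) file.path(out_dir, name)

  tree <- NULL
  if (!is.null(cfg$tree)) {
    if (!file.exists(cfg$tree)) {
      abort(paste0("stage red: input tree not found: ", cfg$tree))
    }
    log_stage("red", "reading tree ", cfg$tree)
    tree <- read_newick(cfg$tree)
    inputs <- c(inputs, cfg$tree)
    if (length(cfg$outgroup %||% character()) > 0 &&
        !ape::is.rooted(tree)) {
      tree <- root_by_outgroup(tree, cfg$outgroup)
    }
  } else if ("simulate" %in% stages) {
    log_stage("simulate", "seed ", seed, ": tree with ",
              nrow(scfg$planted_clades), " planted clades")
    sim <- sim_tree_with_clades(scfg)
    tree <- sim$tree
    writeLines(sim$newick, out_path("sim_tree.nwk"))
    readr::write_tsv(sim$truth, out_path("sim_tree_truth.tsv"))
    outputs <- c(outputs, out_path("sim_tree.nwk"),
                 out_path("sim_tree_truth.tsv"))
  }

  rt <- NULL
  if ("red" %in% stages) {
    if (is.null(tree)) abort("stage red: no tree (give 'tree' or run simulate)")
    log_stage("red", "annotating ", n_tips(tree), " leaves")
    rt <- red_annotate(tree)
    readr::write_tsv(tidy(rt), out_path("red.tsv"))
    outputs <- c(outputs, out_path("red.tsv"))
  }

  asg <- NULL
  if ("delineate" %in% stages) {
    params <- do.call(delineation_params, cfg$delineation %||% list())
    asg <- delineate_subgroups(rt, params,
                               outgroup = cfg$outgroup %||% character())
    log_stage("delineate", nrow(asg$subgroups), " subgroups, ",
              sum(asg$leaves$subgroup == "UNGROUPED"), " ungrouped")
    readr::write_tsv(asg$leaves, out_path("assignment.tsv"))
    readr::write_tsv(asg$subgroups, out_path("subgroups.tsv"))
    outputs <- c(outputs, out_path("assignment.tsv"),
                 out_path("subgroups.tsv"))
  }

  annotations <- NULL
  if (!is.null(cfg$annotations)) {
    if (!file.exists(cfg$annotations)) {
      abort(paste0("stage occurrence: annotations not found: ",
                   cfg$annotations))
    }
    annotations <- readr::read_tsv(cfg$annotations, show_col_types = FALSE)
    inputs <- c(inputs, cfg$annotations)
  }

  if ("occurrence" %in% stages) {
    if (!is.null(cfg$families)) {
      if (!file.exists(cfg$families)) {
        abort(paste0("stage occurrence: family matrix not found: ",
                     cfg$families))
      }
      fm <- read_count_matrix(cfg$families)
      inputs <- c(inputs, cfg$families)
    } else {
      famsim <- sim_family_matrix(scfg, asg)
      fm <- famsim$matrix
      annotations <- annotations %||% famsim$annotations
    }
    occ <- occurrence_by_subgroup(fm, asg)
    log_stage("occurrence", nrow(occ), " (family, subgroup) cells")
    readr::write_tsv(occ, out_path("occurrence.tsv"))
    outputs <- c(outputs, out_path("occurrence.tsv"))
  }

  if ("reconcile" %in% stages) {
    rcfg <- cfg$reconciliation %||% list()
    tau <- rcfg$tau %||% 0.3
    if (!is.null(rcfg$path)) {
      if (!file.exists(rcfg$path)) {
        abort(paste0("stage reconcile: table not found: ", rcfg$path))
      }
      rec <- read_reconciliation(rcfg$path, dialect = "simple_tsv")
      inputs <- c(inputs, rcfg$path)
    } else {
      rec <- sim_reconciliation(scfg)$table
    }
    es <- threshold_events(rec, tau = tau,
                           inclusive = isTRUE(rcfg$inclusive))
    log_stage("reconcile", "tau ", tau, ": ",
              sum(es$branches$n_gain), " gains counted")
    readr::write_tsv(summarize_gains(es), out_path("summary.tsv"))
    readr::write_tsv(es$gains, out_path("gains.tsv"))
    outputs <- c(outputs, out_path("summary.tsv"), out_path("gains.tsv"))
  }

  manifest <- list(
    command = "run_pipeline",
    config_hash = digest_config(cfg),
    inputs = checksum_table(inputs),
    outputs = checksum_table(outputs),
    version = as.character(utils::packageVersion("cladeforge")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  missing_out <- outputs[!file.exists(outputs)]
  if (length(missing_out) > 0) {
    abort(paste0("declared outputs missing: ",
                 paste(missing_out, collapse = ", ")))
  }
  invisible(structure(manifest, class = "run_manifest"))
}

digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

checksum_table <- function(paths) {
  if (length(paths) == 0) {
    return(list())
  }
  map(paths, function(p) list(path = p, md5 = unname(tools::md5sum(p))))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", x$command, " v", x$version, " at ", x$timestamp,
      "\n  outputs:\n", sep = "")
  for (o in x$outputs) cat("   ", o$path, " ", o$md5, "\n", sep = "")
  invisible(x)
}
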