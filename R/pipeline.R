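# End-to-end orchestration: simulate (or ingest) -> contrasts -> fold
# filter/clustering -> network ego-modules -> pathway activity -> behaviour
# statistics, with a reproducibility manifest. Stages communicate only via
# files in the run directory, so every intermediate is inspectable.

.config_defaults <- list(
  simulate = TRUE,
  scenario = list(),
  behavior = list(),
  inputs = list(),
  control_group = NULL,
  contrast_summary = "linear-mean",
  fold = 1.5,
  alpha = 0.05,
  n_perm_modules = 1000,
  n_perm_pathways = 1000,
  null = "sets",
  null_signs = "carry",
  min_total_s = 5,
  seed = 1
)

.fill_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out <- utils::modifyList(.config_defaults, config)
  if (is.null(out$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  out
}

#' Validate a pipeline run configuration
#'
#' Checks every cross-field constraint before any computation and reports
#' the full list of violations, not just the first.
#'
#' @param config a named list (or path to a YAML file) with at least
#'   `out_dir`; see [run_pipeline()] for the recognised fields.
#' @return the completed config (defaults filled), invisibly; errors with
#'   all violations otherwise.
#' @export
validate_config <- function(config) {
  config <- .fill_config(config)
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "alpha must be in (0, 1)")
  chk(is.numeric(config$fold) && config$fold > 1, "fold must be > 1")
  chk(config$n_perm_modules >= 1, "n_perm_modules must be >= 1")
  chk(config$n_perm_pathways >= 1, "n_perm_pathways must be >= 1")
  chk(config$null %in% c("sets", "ego"), "null must be 'sets' or 'ego'")
  chk(config$null_signs %in% c("carry", "all-positive"),
      "null_signs must be 'carry' or 'all-positive'")
  chk(config$contrast_summary %in% c("linear-mean", "log-mean"),
      "contrast_summary must be 'linear-mean' or 'log-mean'")
  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed must be a single number")
  if (!isTRUE(config$simulate)) {
    needed <- c("abundance", "samples", "edges", "gmt")
    for (nm in needed) {
      path <- config$inputs[[nm]]
      if (is.null(path)) {
        bad <- c(bad, paste0("inputs$", nm, " is required when simulate is FALSE"))
      } else if (!file.exists(path)) {
        bad <- c(bad, paste0("inputs$", nm, " does not exist: ", path))
      }
    }
    if (!is.null(config$inputs$samples) && file.exists(config$inputs$samples) &&
        !is.null(config$control_group)) {
      sheet <- utils::read.delim(config$inputs$samples, sep = "\t",
                                 colClasses = "character")
      if (!config$control_group %in% sheet$group)
        bad <- c(bad, paste0("control group '", config$control_group,
                             "' absent from the sample sheet"))
    }
  }
  if (length(bad))
    stop("invalid config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — `simulate` (or ingest),
#' `contrasts`, `differential`, `network_modules`, `pathway_activity`,
#' `behavior` — writing every intermediate as TSV under `out_dir` and a
#' JSON reproducibility manifest (config echo, package version, per-stage
#' output checksums and record counts, every derived seed) last. Any stage
#' failure aborts with the stage name in the error.
#'
#' Recognised config fields: `out_dir`; `simulate` (logical) with
#' `scenario` / `behavior` argument lists for [simulation_scenario()] and
#' [behavior_scenario()], or `inputs` (paths `abundance`, `samples`,
#' `edges`, `gmt`, optionally `arm_entries`, `exploration`, `marker`) plus
#' `control_group`; `contrast_summary`, `fold`, `alpha`,
#' `n_perm_modules`, `n_perm_pathways`, `null`, `null_signs`,
#' `min_total_s`, `seed`.
#'
#' @param config named list or YAML path; see [validate_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- .fill_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("egoperm")),
                   stages = list())
  note <- function(stage, outputs, counts) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(tools::md5sum(outputs)),
      record_counts = counts)
  }

  # -- stage 1: simulate or ingest ------------------------------------
  has_behavior <- FALSE
  if (isTRUE(config$simulate)) {
    mat <- .stage("simulate", {
      scen_args <- config$scenario
      if (is.null(scen_args$seed)) scen_args$seed <- config$seed
      scenario <- do.call(simulation_scenario, scen_args)
      beh_args <- config$behavior
      if (is.null(beh_args$seed)) beh_args$seed <- config$seed
      bscenario <- do.call(behavior_scenario, beh_args)
      in_dir <- file.path(out_dir, "inputs")
      paths <- simulate_inputs(scenario, bscenario, in_dir)
      config$inputs <- as.list(paths)
      has_behavior <- TRUE
      mat <- read_abundance(paths[["abundance"]], paths[["samples"]])
      note("simulate", unname(paths),
           list(proteins = nrow(mat$values), samples = ncol(mat$values)))
      mat
    })
  } else {
    mat <- .stage("ingest", {
      mat <- read_abundance(config$inputs$abundance, config$inputs$samples,
                            config$control_group)
      has_behavior <- !is.null(config$inputs$arm_entries)
      note("ingest", unlist(config$inputs),
           list(proteins = nrow(mat$values), samples = ncol(mat$values)))
      mat
    })
  }

  # -- stage 2: contrasts ---------------------------------------------
  contrasts <- .stage("contrasts", {
    case_groups <- setdiff(abundance_groups(mat), mat$control_group)
    cts <- lapply(case_groups, function(g) {
      compute_contrast(mat, g, config$contrast_summary)
    })
    names(cts) <- case_groups
    tab <- data.frame(protein_id = rownames(mat$values))
    for (g in case_groups) tab[[paste0("logfc_", g)]] <- cts[[g]]$logfc
    path <- file.path(out_dir, "contrasts.tsv")
    write_results(tab, path)
    note("contrasts", path, list(proteins = nrow(tab),
                                 contrasts = length(cts)))
    cts
  })

  # -- stage 3: fold filter + clustering + set comparison -------------
  .stage("differential", {
    de_sets <- lapply(contrasts, fold_change_filter, fold = config$fold)
    union_sel <- sort(unique(unlist(lapply(de_sets, `[[`, "members"))))
    paths <- file.path(out_dir, c("differential_sets.tsv",
                                  "cluster_order.tsv",
                                  "cluster_merges.tsv",
                                  "set_overlap.tsv"))
    sets_tab <- do.call(rbind, lapply(de_sets, function(s) {
      if (!length(s$members)) return(NULL)
      data.frame(contrast = s$label, protein_id = s$members,
                 fold = s$fold, stringsAsFactors = FALSE)
    }))
    if (is.null(sets_tab))
      sets_tab <- data.frame(contrast = character(0),
                             protein_id = character(0), fold = numeric(0))
    write_results(sets_tab, paths[1L])
    n_clustered <- 0L
    if (length(union_sel) >= 2L && length(contrasts) >= 2L) {
      cl <- cluster_expression(contrasts,
                               intersect(union_sel,
                                         valid_proteins(contrasts)))
      write_results(data.frame(protein_id = cl$order), paths[2L])
      write_results(data.frame(merge_a = cl$hclust$merge[, 1L],
                               merge_b = cl$hclust$merge[, 2L],
                               height = cl$hclust$height), paths[3L])
      n_clustered <- nrow(cl$logfc)
    } else {
      write_results(data.frame(protein_id = character(0)), paths[2L])
      write_results(data.frame(merge_a = integer(0), merge_b = integer(0),
                               height = numeric(0)), paths[3L])
    }
    if (length(de_sets) >= 2L) {
      write_results(compare_sets(de_sets), paths[4L])
    } else {
      write_results(data.frame(region = character(0), count = integer(0)),
                    paths[4L])
    }
    note("differential", paths,
         list(selected = nrow(sets_tab), clustered = n_clustered))
  })

  # -- stage 4: network ego-modules -----------------------------------
  .stage("network_modules", {
    network <- read_edge_list(config$inputs$edges)
    res <- select_de_proteins(network, contrasts, alpha = config$alpha,
                              n_perm = config$n_perm_modules,
                              seed = derive_seed(config$seed, "modules"),
                              null = config$null)
    paths <- file.path(out_dir, c("module_per_seed.tsv",
                                  "module_pair_per_seed.tsv"))
    write_results(res$per_seed, paths[1L])
    if (!is.null(res$pair_per_seed)) {
      write_results(res$pair_per_seed, paths[2L])
    } else {
      write_results(data.frame(pair = character(0)), paths[2L])
    }
    note("network_modules", paths,
         list(seeds_tested = nrow(res$per_seed),
              selected = sum(res$per_seed$selected),
              untestable = length(unique(unlist(res$untestable)))))
  })

  # -- stage 5: pathway activity --------------------------------------
  .stage("pathway_activity", {
    pathways <- read_signed_gmt(config$inputs$gmt)
    tab <- score_all_pathways(pathways, contrasts,
                              n_perm = config$n_perm_pathways,
                              seed = derive_seed(config$seed, "pathways"),
                              null_signs = config$null_signs)
    path <- file.path(out_dir, "pathway_activity.tsv")
    write_results(tab, path)
    note("pathway_activity", path,
         list(cells = nrow(tab), significant = sum(tab$p < config$alpha,
                                                   na.rm = TRUE)))
  })

  # -- stage 6: behaviour ---------------------------------------------
  .stage("behavior", {
    if (has_behavior) {
      beh <- read_behavior(config$inputs$arm_entries,
                           config$inputs$exploration)
      summ <- behavior_summary(beh, config$min_total_s)
      paths <- file.path(out_dir, c("behavior_per_animal.tsv",
                                    "behavior_group_stats.tsv"))
      write_results(summ$per_animal, paths[1L])
      stats_tab <- do.call(rbind, lapply(names(summ$group_stats), function(m) {
        gs <- summ$group_stats[[m]]
        data.frame(metric = m, F = gs$anova$F, df1 = gs$anova$df1,
                   df2 = gs$anova$df2, p = gs$anova$p,
                   levene_p = gs$levene$p, stringsAsFactors = FALSE)
      }))
      write_results(stats_tab, paths[2L])
      counts <- list(animals = nrow(summ$per_animal),
                     metrics = nrow(stats_tab))
      if (!is.null(config$inputs$marker)) {
        mk <- utils::read.delim(config$inputs$marker, sep = "\t")
        keep <- !summ$per_animal$excluded_nor
        mm <- marker_memory_correlation(
          mk$marker[match(summ$per_animal$animal_id[keep], mk$animal_id)],
          summ$per_animal$ri_nor[keep])
        path_mm <- file.path(out_dir, "marker_memory.tsv")
        write_results(data.frame(r = mm$r, r2 = mm$r2, p = mm$p, n = mm$n),
                      path_mm)
        paths <- c(paths, path_mm)
        counts$marker_pairs <- mm$n
      }
      note("behavior", paths, counts)
    } else {
      path <- file.path(out_dir, "behavior_per_animal.tsv")
      write_results(data.frame(animal_id = character(0)), path)
      note("behavior", path, list(animals = 0L))
    }
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
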