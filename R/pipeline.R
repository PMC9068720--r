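# End-to-end orchestration: one configuration drives simulation (or
# reading of user inputs), alignment, and every enabled analysis stage,
# with per-stage seeds derived deterministically from one master seed so
# that toggling a stage never changes another stage's random stream.

.STAGES <- c("hill", "betanull", "qpe", "lottery", "recruitment",
             "robustness", "bvstep")

.stage_seed <- function(master, stage) {
  i <- match(stage, .STAGES)
  as.integer((as.numeric(master) + 1000003 * i) %% 2147483647)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, checks parameter domains, and warns (not errors) on
#' unknown keys. The configuration may be a list or a YAML file path.
#'
#' @param config list or YAML path. Recognized keys: `seed`, `outdir`,
#'   `stages` (character subset of hill, betanull, qpe, lottery,
#'   recruitment, robustness, bvstep), `inputs` (paths: table, tree,
#'   taxonomy, metadata, functions), `sim` (arguments of [sim_config()]
#'   plus `n_otus`), and `params` (n_iter, alpha, q_max, q_step,
#'   lottery_threshold, presence_floor, perturbations, n_boot, n_rep,
#'   rho_target, restarts, recruitment_group).
#' @return normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("seed", "outdir", "stages", "inputs", "sim", "params")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- list(
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    outdir = if (is.null(config$outdir)) "assemblage_out" else config$outdir,
    stages = if (is.null(config$stages)) .STAGES else config$stages,
    inputs = config$inputs,
    sim = config$sim,
    params = config$params
  )
  bad <- setdiff(out$stages, .STAGES)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  p <- out$params
  defaults <- list(n_iter = 999, alpha = 0.5, q_max = 3, q_step = 0.25,
                   lottery_threshold = 0.9, presence_floor = 0.001,
                   perturbations = 100, n_boot = 2000, n_rep = 200,
                   rho_target = 0.95, restarts = 10,
                   recruitment_group = NULL)
  unknown_p <- setdiff(names(p), names(defaults))
  if (length(unknown_p) > 0)
    warning("ignoring unknown param(s): ", paste(unknown_p, collapse = ", "))
  p <- utils::modifyList(defaults, if (is.null(p)) list() else
    p[intersect(names(p), names(defaults))])
  errs <- character(0)
  if (p$n_iter < 1) errs <- c(errs, "n_iter must be >= 1")
  if (p$alpha < 0 || p$alpha > 1) errs <- c(errs, "alpha must be in [0, 1]")
  if (p$q_max < 0) errs <- c(errs, "q_max must be >= 0")
  if (p$lottery_threshold <= 0 || p$lottery_threshold >= 1)
    errs <- c(errs, "lottery_threshold must be in (0, 1)")
  if (p$rho_target <= 0 || p$rho_target > 1)
    errs <- c(errs, "rho_target must be in (0, 1]")
  if (p$perturbations < 5) errs <- c(errs, "perturbations must be >= 5")
  if (length(errs) > 0) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  out$params <- p
  out
}

.write_stage_tsv <- function(df, path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s: %s", k, paste(params[[k]], collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full assembly-analysis pipeline
#'
#' Executes the enabled stages in dependency order on either user-supplied
#' inputs (`config$inputs`) or a synthetic dataset (`config$sim`), writing
#' one TSV per stage plus a JSON manifest into `config$outdir`. Reruns
#' with an identical configuration produce byte-identical outputs; inputs
#' on disk are never modified.
#'
#' @param config see [validate_config()].
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tax <- NULL; funcs <- NULL
  if (!is.null(cfg$inputs)) {
    ins <- cfg$inputs
    if (is.null(ins$table)) stop("config$inputs$table is required")
    table <- read_count_table(ins$table)
    tree <- if (!is.null(ins$tree)) read_tree(ins$tree) else NULL
    metadata <- if (!is.null(ins$metadata)) read_metadata(ins$metadata) else
      stop("config$inputs$metadata is required")
    if (!is.null(ins$taxonomy)) tax <- read_taxonomy(ins$taxonomy)
    if (!is.null(ins$functions)) funcs <- read_functions(ins$functions)
  } else {
    sim_args <- cfg$sim
    n_otus <- if (is.null(sim_args$n_otus)) 150 else sim_args$n_otus
    sim_args$n_otus <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    sc <- do.call(sim_config, sim_args)
    tree <- simulate_tree(n_otus, seed = sc$seed)
    meta_vec <- simulate_metacommunity(tree, seed = sc$seed)
    sim <- run_stage("simulate",
                     simulate_community_series(tree, meta_vec, sc))
    table <- sim$table
    metadata <- sim$metadata
    planted <- plant_lottery_clades(table, seed = sc$seed)
    table <- planted$table
    tax <- planted$taxonomy
    funcs <- simulate_genome_functions(colnames(table),
                                       n_functions = max(60, n_otus),
                                       redundancy = "mid",
                                       seed = sc$seed)$funcs
  }
  needs_tree <- intersect(cfg$stages,
                          c("betanull", "qpe", "recruitment", "robustness"))
  if (length(needs_tree) > 0 && is.null(tree))
    stop("stage(s) ", paste(needs_tree, collapse = ", "),
         " need a tree but none was provided")
  bundle <- align_inputs(table, tree, tax = tax, funcs = funcs)
  table <- bundle$table
  tree <- bundle$tree
  metadata <- metadata[rownames(table), , drop = FALSE]
  groups <- metadata$group_time
  names(groups) <- rownames(metadata)
  q_grid <- seq(0, p$q_max, by = p$q_step)
  manifest <- list(package_version = as.character(utils::packageVersion("assemblage")),
                   seed = cfg$seed, stages = cfg$stages, params = p,
                   dropped = as.list(bundle$dropped), outputs = list())
  add_output <- function(stage, file) {
    manifest$outputs[[stage]] <<- basename(file)
  }
  fp <- function(name) file.path(cfg$outdir, name)

  if ("hill" %in% cfg$stages) {
    res <- run_stage("hill", hill_null_expectation(
      table, groups, q_grid = q_grid, n_iter = p$n_iter,
      seed = .stage_seed(cfg$seed, "hill")))
    add_output("hill", .write_stage_tsv(
      as.data.frame(res), fp("hill.tsv"),
      list(stage = "hill", n_iter = p$n_iter,
           seed = .stage_seed(cfg$seed, "hill"))))
  }
  if ("betanull" %in% cfg$stages) {
    res <- run_stage("betanull", beta_null_deviation(
      table, tree, groups, alpha = p$alpha, n_iter = p$n_iter,
      seed = .stage_seed(cfg$seed, "betanull")))
    add_output("betanull", .write_stage_tsv(
      res$pairs, fp("betanull.tsv"),
      list(stage = "betanull", alpha = p$alpha, n_iter = p$n_iter,
           seed = .stage_seed(cfg$seed, "betanull"))))
  }
  if ("qpe" %in% cfg$stages) {
    res <- run_stage("qpe", qpe(
      table, tree, groups, n_iter = p$n_iter,
      seed = .stage_seed(cfg$seed, "qpe")))
    add_output("qpe", .write_stage_tsv(
      res$pairs, fp("qpe_pairs.tsv"),
      list(stage = "qpe", n_iter = p$n_iter,
           seed = .stage_seed(cfg$seed, "qpe"))))
    manifest$outputs[["qpe_summary"]] <- basename(.write_stage_tsv(
      res$summary, fp("qpe_summary.tsv"), list(stage = "qpe_summary")))
  }
  if ("lottery" %in% cfg$stages) {
    if (is.null(tax)) stop("stage 'lottery' needs a taxonomy")
    tp <- as.character(metadata$time_point)
    names(tp) <- rownames(metadata)
    res <- run_stage("lottery", lottery_report(
      table, bundle$tax, tp, threshold = p$lottery_threshold,
      presence_floor = p$presence_floor))
    add_output("lottery", .write_stage_tsv(
      as.data.frame(res), fp("lottery.tsv"),
      list(stage = "lottery", threshold = p$lottery_threshold)))
  }
  if ("recruitment" %in% cfg$stages) {
    rgroups <- if (!is.null(p$recruitment_group)) p$recruitment_group else
      unique(metadata$group)
    rows <- list()
    for (g in rgroups) {
      # a group without enough taxon turnover has no estimable dispersion;
      # record it as missing rather than aborting the whole run
      fit <- tryCatch({
        ds <- detection_series(table, metadata, g)
        fit_dispersion(ds, tree, n_rep = p$n_rep, n_boot = p$n_boot,
                       seed = .stage_seed(cfg$seed, "recruitment"))
      }, error = function(e) {
        message("recruitment: group '", g, "' skipped: ",
                conditionMessage(e))
        NULL
      })
      rows[[g]] <- if (is.null(fit))
        data.frame(group = g, D_hat = NA_real_, ci_lo = NA_real_,
                   ci_hi = NA_real_, n_timepoints = NA_integer_,
                   unidentifiable = NA, stringsAsFactors = FALSE)
      else
        data.frame(group = g, D_hat = fit$D_hat,
                   ci_lo = fit$ci95[1], ci_hi = fit$ci95[2],
                   n_timepoints = fit$n_timepoints,
                   unidentifiable = fit$flags$unidentifiable,
                   stringsAsFactors = FALSE)
    }
    add_output("recruitment", .write_stage_tsv(
      do.call(rbind, rows), fp("recruitment.tsv"),
      list(stage = "recruitment", n_boot = p$n_boot,
           seed = .stage_seed(cfg$seed, "recruitment"))))
  }
  if ("robustness" %in% cfg$stages) {
    if (is.null(funcs)) stop("stage 'robustness' needs a function table")
    res <- run_stage("robustness", robustness(
      table, tree, bundle$funcs, n_perturb = p$perturbations,
      seed = .stage_seed(cfg$seed, "robustness")))
    add_output("robustness", .write_stage_tsv(
      res$samples, fp("robustness.tsv"),
      list(stage = "robustness", perturbations = p$perturbations,
           seed = .stage_seed(cfg$seed, "robustness"))))
  }
  if ("bvstep" %in% cfg$stages) {
    res <- run_stage("bvstep", bvstep_search(
      table, rho_target = p$rho_target, max_restarts = p$restarts,
      seed = .stage_seed(cfg$seed, "bvstep")))
    add_output("bvstep", .write_stage_tsv(
      data.frame(otu = res$selected, rho = res$rho,
                 stringsAsFactors = FALSE),
      fp("bvstep.tsv"),
      list(stage = "bvstep", rho_target = p$rho_target,
           seed = .stage_seed(cfg$seed, "bvstep"))))
  }
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
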