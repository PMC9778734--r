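.validation_error <- function(msg) {
  stop(structure(class = c("glycopmf_validation", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run configuration
#'
#' A validated, JSON-serializable description of one analysis run: input
#' paths, atom selections, CV definitions, umbrella-window manifest,
#' binning, cutoffs, temperature, seed and output directory. Validation is
#' performed up front so a bad config aborts before any compute.
#'
#' @param config named list or path to a JSON file with (a subset of)
#'   fields: `trajectory`, `cv_table`, `selections` (name -> index vector
#'   or metadata filter), `cvs` (name -> list(a, b, mode) or
#'   list(formula = "d_actsite"/"d_react"/"reaction_coordinate",
#'   args = cv names)), `windows` (list of list(file, center,
#'   force_constant)), `ring_atoms` (6 indices, O5 first), `temperature`,
#'   `n_bins`, `cutoff`, `t_eq`, `seed`, `out_dir`, `axes`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .validation_error(paste("config not found:", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(temperature = default_temperature, n_bins = 200,
                   cutoff = 1.2, t_eq = 2, seed = 1, out_dir = ".",
                   axes = NULL)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (config$temperature <= 0) .validation_error("temperature must be > 0")
  for (f in c("trajectory", "cv_table")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      .validation_error(sprintf("%s file does not exist: %s", f, config[[f]]))
    }
  }
  if (!is.null(config$windows)) {
    for (w in config$windows) {
      if (is.null(w$file) || is.null(w$center) || is.null(w$force_constant)) {
        .validation_error("each window needs file, center, force_constant")
      }
      if (!file.exists(w$file)) {
        .validation_error(paste("window file does not exist:", w$file))
      }
    }
  }
  # composite CVs must reference defined CVs
  if (!is.null(config$cvs)) {
    defined <- names(config$cvs)
    for (nm in defined) {
      cv <- config$cvs[[nm]]
      if (!is.null(cv$formula)) {
        missing <- setdiff(unlist(cv$args), defined)
        if (length(missing)) {
          .validation_error(sprintf("composite CV '%s' references undefined CV(s): %s",
                                    nm, paste(missing, collapse = ", ")))
        }
      } else if (is.null(cv$a) || is.null(cv$b)) {
        .validation_error(sprintf("CV '%s' needs selections a and b (or a formula)", nm))
      }
    }
  }
  structure(config, class = "run_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.resolve_cv <- function(name, config, traj, cache) {
  if (!is.null(cache[[name]])) return(cache)
  cv <- config$cvs[[name]]
  if (!is.null(cv$formula)) {
    for (a in unlist(cv$args)) cache <- .resolve_cv(a, config, traj, cache)
    args <- lapply(unlist(cv$args), function(a) cache[[a]])
    cache[[name]] <- switch(cv$formula,
      reaction_coordinate = do.call(reaction_coordinate, args),
      d_actsite = do.call(d_actsite, args),
      d_react = do.call(d_react, args),
      .validation_error(paste("unknown CV formula:", cv$formula)))
  } else {
    sel <- function(s) {
      if (is.character(s)) {
        v <- config$selections[[s]]
        if (is.null(v)) .validation_error(paste("undefined selection:", s))
        s <- v
      }
      if (is.list(s)) do.call(atom_selection,
                              c(list(label = name), s)) else as.integer(s)
    }
    a <- sel(cv$a); b <- sel(cv$b)
    mode <- if (is.null(cv$mode)) "min_pair" else cv$mode
    cache[[name]] <- vapply(traj$coords, function(fr) {
      pair_distance(fr, a, b, mode = mode, atoms = traj$atoms)
    }, numeric(1))
  }
  cache
}

#' Compute configured CV series from a trajectory
#'
#' @param traj an `md_trajectory`.
#' @param config a `run_config` with `cvs` definitions.
#' @return a `cv_series`, one column per configured CV.
#' @export
extract_cvs <- function(traj, config) {
  if (is.null(config$cvs)) .validation_error("config has no cvs section")
  cache <- list()
  for (nm in names(config$cvs)) cache <- .resolve_cv(nm, config, traj, cache)
  cv_series(traj$times, do.call(cbind, cache[names(config$cvs)]),
            temperature = config$temperature, labels = names(config$cvs))
}

#' Run a complete analysis workflow
#'
#' `cmd_projection`: read the trajectory, extract configured CVs, write
#' direct Gibbs-energy projections along each requested axis, Gromos-cluster
#' the configured selection and suggest the next sampling seed.
#' `umbrella_wham`: read the window manifest, discard equilibration, solve
#' WHAM, run direct/reverse convergence checks, compute per-conformation
#' weights, write reweighted projections onto any auxiliary CV columns, and
#' summarize ring puckering when ring atoms are configured. Every artifact
#' is listed in a provenance manifest (inputs, config hash, seed, package
#' version).
#'
#' @param config a `run_config` (or path / list coerced to one).
#' @param workflow `"cmd_projection"` or `"umbrella_wham"`.
#' @return invisible manifest: list of output paths plus the key in-memory
#'   results.
#' @export
run_pipeline <- function(config, workflow = c("cmd_projection",
                                              "umbrella_wham")) {
  workflow <- match.arg(workflow)
  if (!inherits(config, "run_config")) config <- run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "glycopmf_validation")) stop(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (workflow == "cmd_projection") {
    series <- stage("read", {
      if (!is.null(config$cv_table)) {
        read_cv_table(config$cv_table, temperature = config$temperature)
      } else {
        traj <- read_trajectory(config$trajectory)
        extract_cvs(traj, config)
      }
    })
    outputs$cvs <- file.path(out_dir, "cvs.tsv")
    write_cv_table(series, outputs$cvs)
    axes <- config$axes
    if (is.null(axes)) axes <- colnames(series$values)
    profiles <- stage("projection", lapply(axes, function(a) {
      p <- direct_projection(series, axes = a,
                             n_bins = if (is.null(config$n_bins)) "auto"
                                      else config$n_bins)
      f <- file.path(out_dir, paste0("dG_", gsub("[^A-Za-z0-9_]", "_", a),
                                     ".tsv"))
      write_profile(p, f)
      f
    }))
    outputs$profiles <- unlist(profiles)
    cluster <- NULL
    if (!is.null(config$trajectory) && !is.null(config$cluster_selection)) {
      cluster <- stage("cluster", {
        traj <- read_trajectory(config$trajectory)
        idx <- resolve_selection(config$cluster_selection, traj$atoms)
        cs <- conformation_set(lapply(traj$coords, function(f) {
          f[idx, , drop = FALSE]
        }), times = traj$times, selection = "configured")
        cr <- gromos_cluster(cs, cutoff = config$cutoff)
        seed_pick <- select_seed(cr, cs, start = 1)
        outputs$clusters <<- file.path(out_dir, "clusters.tsv")
        df <- data.frame(frame = seq_along(cr$assignment),
                         time = cs$times, cluster = cr$assignment,
                         is_centroid = seq_along(cr$assignment) %in%
                           cr$centroids)
        utils::write.table(df, outputs$clusters, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        list(result = cr, seed = seed_pick)
      })
    }
    result <- list(series = series, cluster = cluster)
  } else {
    windows <- stage("read_windows", lapply(config$windows, function(w) {
      s <- read_cv_table(w$file, temperature = config$temperature)
      umbrella_window(s, w$center, w$force_constant)
    }))
    windows <- stage("equilibration_discard",
                     lapply(windows, equilibration_discard,
                            t_eq = config$t_eq))
    wh <- stage("wham", wham_solve(windows, n_bins = config$n_bins))
    outputs$pmf <- file.path(out_dir, "pmf.tsv")
    write_profile(wh$profile, outputs$pmf)
    conv <- stage("convergence", {
      list(direct = convergence_check(windows, "direct",
                                      n_bins = config$n_bins),
           reverse = convergence_check(windows, "reverse",
                                       n_bins = config$n_bins))
    })
    outputs$convergence <- file.path(out_dir, "convergence.json")
    jsonlite::write_json(list(
      direct = list(deviations = conv$direct$deviations,
                    converged = conv$direct$converged),
      reverse = list(deviations = conv$reverse$deviations,
                     converged = conv$reverse$converged)),
      outputs$convergence, auto_unbox = TRUE, digits = NA)
    wts <- stage("weights", conformation_weights(windows, wh$solution))
    outputs$weights <- file.path(out_dir, "weights.tsv")
    utils::write.table(
      data.frame(window = wts$window, x = wts$x, p = wts$weights),
      outputs$weights, sep = "\t", row.names = FALSE, quote = FALSE)
    # reweighted projections on every auxiliary CV column
    aux <- setdiff(colnames(windows[[1]]$series$values),
                   colnames(windows[[1]]$series$values)[1])
    if (length(aux)) {
      vals <- do.call(rbind, lapply(windows, function(w) w$series$values))
      outputs$projections <- vapply(aux, function(a) {
        p <- reweighted_projection(vals, wts$weights, axes = a,
                                   temperature = config$temperature)
        f <- file.path(out_dir, paste0("dG_", a, ".tsv"))
        write_profile(p, f)
        f
      }, character(1))
    }
    result <- list(wham = wh, convergence = conv, weights = wts)
  }

  outputs$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(list(
    workflow = workflow, seed = config$seed,
    config_hash = .config_hash(config),
    temperature = config$temperature,
    package = as.character(utils::packageVersion("glycopmf")),
    outputs = lapply(outputs[names(outputs) != "provenance"], identity)),
    outputs$provenance, auto_unbox = TRUE)
  invisible(c(outputs, list(result = result)))
}
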