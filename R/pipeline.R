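#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file) with an `input` section
#' (either `pdb: <path>` or `fixture: {motif, n_residues}`), an `output_dir`,
#' a top-level `seed`, optionally `model: {flavour}` and per-stage sections
#' `simulate` (temperatures, n_md_steps), `wham` (t_grid bounds), `refold`
#' (n_traj, temperature_factor, n_md_steps, protein_mode) and toggles
#' `classify` / `fitk`. Referenced paths must exist and seeds must be
#' explicit.
#'
#' @param config list or path to a YAML file.
#' @return the validated configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config needs output_dir")
  if (is.null(config$seed)) stop("config needs an explicit seed")
  inp <- config$input
  if (is.null(inp)) stop("config needs an input section")
  if (!is.null(inp$pdb)) {
    if (!file.exists(inp$pdb)) stop("input PDB does not exist: ", inp$pdb)
  } else if (is.null(inp$fixture)) {
    stop("input needs either pdb or fixture")
  }
  config
}

pipeline_sidecar <- function(path, stage, params) {
  meta <- list(stage = stage, package = "entfold",
               version = as.character(utils::packageVersion("entfold")),
               params = params)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the end-to-end folding analysis pipeline
#'
#' Executes the requested stages in dependency order: build the native
#' topology, run an equilibrium temperature ladder, solve WHAM for the
#' folding temperature, sample unfolded conformations, run a refolding
#' batch, classify pathways and (optionally) fit per-contact kinetics.
#' Every artifact is a plain-text table with a JSON sidecar recording the
#' stage parameters and seeds; re-running with the same configuration
#' reproduces deterministic outputs bit for bit.
#'
#' @param config see [validate_config()].
#' @param dry_run print the execution plan without computing.
#' @return (invisibly) a list of stage results; artifacts under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  config <- validate_config(config)
  stages <- c("topology",
              if (!is.null(config$simulate)) c("simulate", "wham"),
              if (!is.null(config$refold)) "refold",
              if (isTRUE(config$classify)) "classify",
              if (isTRUE(config$fitk)) "fitk")
  if (dry_run) {
    cat("plan:", paste(stages, collapse = " -> "), "\n")
    return(invisible(stages))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  run_stage <- function(name, fn) {
    message("[entfold] stage ", name)
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  flavour <- config$model$flavour %||% "12-6"
  params <- go_parameters(lj_flavour = flavour)

  out$topology <- run_stage("topology", function() {
    topo <- if (!is.null(config$input$pdb)) {
      extract_native_geometry(read_pdb(config$input$pdb,
                                       chain = config$input$chain))
    } else {
      fx <- config$input$fixture
      make_toy_native(fx$n_residues, fx$motif)$topology
    }
    p <- file.path(config$output_dir, "topology.json")
    write_topology_json(topo, p)
    pipeline_sidecar(p, "topology", config$input)
    topo
  })
  topo <- out$topology

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    out$equilibrium <- run_stage("simulate", function() {
      runs <- lapply(seq_along(sim$temperatures), function(k) {
        tt <- sim$temperatures[[k]]
        st <- integrator_settings(temperature = tt,
                                  seed = config$seed + k)
        tr <- run_langevin(topo$ca, topo, params, st, sim$n_md_steps)
        p <- file.path(config$output_dir, sprintf("equilibrium_T%.4f.tsv", tt))
        write_observables(tr$series, p)
        pipeline_sidecar(p, "simulate",
                         list(temperature = tt, seed = config$seed + k,
                              n_md_steps = sim$n_md_steps, flavour = flavour))
        list(temperature = tt, series = tr$series)
      })
      runs
    })
    out$wham <- run_stage("wham", function() {
      wi <- build_wham_input(out$equilibrium, nrow(topo$contacts))
      sol <- solve_wham(wi)
      tg <- config$wham$t_grid %||%
        seq(0.8 * min(unlist(sim$temperatures)),
            1.2 * max(unlist(sim$temperatures)), by = 0.005)
      th <- thermo_curves(sol, tg, topo$n_residues)
      p <- file.path(config$output_dir, "thermo.tsv")
      write.table(data.frame(T = th$t_grid, Cv = th$cv), p, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      pipeline_sidecar(p, "wham", list(t_f = th$t_f))
      list(solution = sol, thermo = th)
    })
  }

  if (!is.null(config$refold)) {
    rf <- config$refold
    t_f <- rf$t_fold %||% out$wham$thermo$t_f
    if (is.null(t_f)) stop("refold stage needs t_fold (or a wham stage)")
    out$refold <- run_stage("refold", function() {
      inits <- sample_unfolded(topo, params, t_fold = t_f,
                               c_factor = rf$unfold_factor %||% 1.25,
                               n_samples = rf$n_traj,
                               decorrelation_interval = rf$decorrelation %||% 20,
                               seed = config$seed + 1000)
      batch <- run_refolding_batch(topo, params,
                                   temperature = (rf$temperature_factor %||% 0.9) * t_f,
                                   initials = inits,
                                   n_md_steps = rf$n_md_steps,
                                   seeds = config$seed + 2000 + seq_len(rf$n_traj),
                                   keep_frames = isTRUE(config$fitk))
      for (k in seq_along(batch)) {
        p <- file.path(config$output_dir, sprintf("refold_%03d.tsv", k))
        write_observables(batch[[k]]$series, p)
      }
      pipeline_sidecar(file.path(config$output_dir, "refold_001.tsv"),
                       "refold", attr(batch, "metadata"))
      batch
    })
  }

  if (isTRUE(config$classify) && !is.null(out$refold)) {
    out$pathways <- run_stage("classify", function() {
      mode <- config$refold$protein_mode %||% "plain"
      win <- config$window %||% 555
      recs <- lapply(out$refold, function(tr) {
        classify_pathway(tr$series, window = min(win, nrow(tr$series)),
                         protein_mode = mode)
      })
      tab <- data.frame(
        trajectory = seq_along(recs),
        label = vapply(recs, `[[`, character(1), "label"),
        folding_time = vapply(recs, `[[`, numeric(1), "folding_time")
      )
      p <- file.path(config$output_dir, "pathways.tsv")
      write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      pipeline_sidecar(p, "classify", list(window = win, mode = mode))
      tab
    })
  }

  if (isTRUE(config$fitk) && !is.null(out$refold)) {
    out$kinetics <- run_stage("fitk", function() {
      nct <- nrow(topo$contacts)
      fits <- lapply(seq_len(nct), function(cc) {
        curve <- contact_formation_curve(out$refold, cc, topo)
        fit_contact_kinetics(curve,
                             block_window = config$fitk_block %||% 100)
      })
      tab <- data.frame(
        i = topo$contacts$i, j = topo$contacts$j,
        label_i = topo$residue_labels[topo$contacts$i],
        label_j = topo$residue_labels[topo$contacts$j],
        A = vapply(fits, `[[`, numeric(1), "A"),
        B = vapply(fits, `[[`, numeric(1), "B"),
        k = vapply(fits, `[[`, numeric(1), "k"),
        flagged = vapply(fits, `[[`, logical(1), "flagged")
      )
      p <- file.path(config$output_dir, "contact_kinetics.tsv")
      write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      pipeline_sidecar(p, "fitk", list(block = config$fitk_block %||% 100))
      tab
    })
  }
  invisible(out)
}
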