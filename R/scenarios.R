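# Scenario registry reproducing the in-silico experiments: single-cell
# cis/trans dose-responses, lattice patterning under a VEGF gradient,
# line-of-cells mutants and engineered ligand stripes, two-cell
# bifurcation sweeps, and the mutual-inactivation sweep.

steady_single <- function(params, model = 1, trans = trans_input(),
                          Next = 0, clamps = NULL, V_local = 0,
                          t_end = 1000, h = 0.01, steady_tol = 1e-6) {
  init <- if (model == 2) cell_state2() else cell_state()
  rhs <- if (model == 2) {
    function(s) rhs_model2(s, params, V_local, trans, Next)
  } else {
    function(s) rhs_model1(s, params, trans, Next)
  }
  rk4_integrate(rhs, init, h = h, t_end = t_end, clamps = clamps,
                steady_tol = steady_tol, record_every = 1e6)$final_state
}

scenario_defaults <- function() {
  list(
    fig4b_cis_dll4 = list(
      model = 1, dext = 1000, bJ = 0, bD_grid = seq(0, 2000, by = 100)),
    fig4c_cis_jag1 = list(
      model = 1, dext = 1000, bD = 2000,
      bJ_grid = seq(0, 2000, by = 100),
      khe_values = c(1e-3, 0), alpha_values = c(1e-4, 1)),
    fig4e_trans_dll4 = list(
      model = 1, n_clamp = NULL, sender_bJ = 0,
      bD_grid = seq(0, 2000, by = 100)),
    fig4f_trans_jag1 = list(
      model = 1, n_clamp = NULL, sender_bD = 2000,
      bJ_grid = seq(0, 2000, by = 100),
      khe_values = c(1e-3, 0), alpha_values = c(1e-4, 1)),
    fig5_lattice = list(
      model = 2, n_rows = 10, n_cols = 10, a = 1, t_end = 1000, h = 0.01,
      init_range = c(0, 100)),
    fig5cd_twocell_sweep = list(
      model = 2, khe = 0, range = c(0, 400), n_points = 21),
    fig6_line_mutants = list(
      model = 2, n_cols = 15, ligand = "D", multipliers = c(0.5, 1, 4),
      t_end = 1000, h = 0.01, init_range = c(0, 100)),
    fig6c_twocell_sweep = list(
      model = 2, range = c(0, 400), n_points = 21,
      bJ_values = c(50, 100, 200)),
    fig7_stripes = list(
      model = 2, n_cols = 20, species = c("J", "D"), alpha = 0,
      stripe_cells = NULL, stripe_max = 200,
      t_end = 1000, h = 0.01, init_range = c(0, 100)),
    fig7de_twocell_sweep = list(
      model = 2, alpha = 0, range = c(0, 200), n_points = 11,
      directions = c("jext_add", "dext_add")),
    fig7f_phase = list(
      model = 2, jext_grid = seq(0, 200, by = 50),
      alpha_grid = c(0, 1e-4, 1e-2, 1)),
    s3_mutual_inactivation = list(
      khe = 0.1, bD = 100, bJ_grid = seq(0, 200, by = 5)),
    s6_gradient_sharpness = list(
      model = 2, n_rows = 10, n_cols = 10, a_values = c(1/2, 1/5, 1/35),
      t_end = 1000, h = 0.01, init_range = c(0, 100)),
    s7b_no_het_sweep = list(
      model = 2, khe = 0, range = c(0, 400), n_points = 21,
      bJ_values = c(50, 200))
  )
}

#' List registered scenarios
#'
#' @return Character vector of scenario names accepted by
#'   [run_scenario()].
#' @export
list_scenarios <- function() names(scenario_defaults())

resolve_config <- function(scenario, overrides = list(), seed = 1) {
  defs <- scenario_defaults()
  if (!scenario %in% names(defs)) {
    stop(sprintf("unknown scenario '%s'; registered scenarios: %s",
                 scenario, paste(names(defs), collapse = ", ")),
         call. = FALSE)
  }
  cfg <- defs[[scenario]]
  bad <- setdiff(names(overrides), c(names(cfg), "params"))
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s) for '%s': %s", scenario,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, overrides)
  cfg$scenario <- scenario
  cfg$seed <- as.integer(seed)
  cfg
}

base_params <- function(cfg) {
  over <- cfg$params %||% list()
  do.call(signalling_params, over)
}

#' Run a registered scenario
#'
#' Executes one of the in-silico experiment setups end-to-end and
#' (optionally) writes its tables, summary and resolved configuration to
#' disk. All scenarios are deterministic given `(overrides, seed)`.
#'
#' @param scenario A scenario name from [list_scenarios()], or a config
#'   list previously written to `resolved_config.json` (reloaded configs
#'   reproduce identical outputs).
#' @param overrides Named list of configuration overrides; unknown keys
#'   are rejected. Use `params = list(...)` to override baseline
#'   [signalling_params()] fields.
#' @param seed Integer seed for every stochastic element (random initial
#'   states, multistart equilibrium searches).
#' @param out_dir If non-NULL, a directory `<out_dir>/<scenario>/` is
#'   created holding one CSV per result table, `summary.json` and
#'   `resolved_config.json`.
#' @param quiet Suppress per-stage progress messages (written to stderr).
#' @return Invisibly, a list with `tables` (named list of tibbles),
#'   `summary` (list), and `config` (the resolved configuration).
#' @export
run_scenario <- function(scenario, overrides = list(), seed = 1,
                         out_dir = NULL, quiet = TRUE) {
  if (is.list(scenario)) {
    cfg <- scenario
    stopifnot(!is.null(cfg$scenario), !is.null(cfg$seed))
    nm <- cfg$scenario
    defs <- scenario_defaults()
    if (!nm %in% names(defs)) {
      stop(sprintf("unknown scenario '%s'; registered scenarios: %s",
                   nm, paste(names(defs), collapse = ", ")), call. = FALSE)
    }
  } else {
    cfg <- resolve_config(scenario, overrides, seed)
    nm <- scenario
  }
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[", nm, "] ", fmt), ...))
  }
  t0 <- Sys.time()
  runner <- switch(
    nm,
    fig4b_cis_dll4 = scenario_fig4b,
    fig4c_cis_jag1 = scenario_fig4c,
    fig4e_trans_dll4 = scenario_fig4e,
    fig4f_trans_jag1 = scenario_fig4f,
    fig5_lattice = scenario_fig5_lattice,
    fig5cd_twocell_sweep = scenario_fig5cd,
    fig6_line_mutants = scenario_fig6_line,
    fig6c_twocell_sweep = scenario_fig6c,
    fig7_stripes = scenario_fig7_stripes,
    fig7de_twocell_sweep = scenario_fig7de,
    fig7f_phase = scenario_fig7f,
    s3_mutual_inactivation = scenario_s3,
    s6_gradient_sharpness = scenario_s6,
    s7b_no_het_sweep = scenario_s7b)
  out <- runner(cfg)
  say("computed %d table(s) in %.1f s", length(out$tables),
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out$summary <- c(list(scenario = nm, seed = cfg$seed,
                        package_version =
                          as.character(utils::packageVersion("notchsim"))),
                   out$summary)
  out$config <- cfg
  if (!is.null(out_dir)) {
    dir <- file.path(out_dir, nm)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (tn in names(out$tables)) {
      write_csv_checked(out$tables[[tn]], file.path(dir,
                                                    paste0(tn, ".csv")))
    }
    jsonlite::write_json(out$summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(cfg, file.path(dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote %s", dir)
  }
  invisible(out)
}

# -- single-cell dose-response scenarios (cis/trans assays) -------------

scenario_fig4b <- function(cfg) {
  params0 <- base_params(cfg)
  tab <- purrr::map_dfr(cfg$bD_grid, function(bD) {
    p <- update_params(params0, bD = bD, bJ = cfg$bJ)
    st <- steady_single(p, model = cfg$model,
                        trans = trans_input(Dext = cfg$dext))
    tibble::tibble(bD = bD, S = st[["S"]], D = st[["D"]], J = st[["J"]])
  })
  list(tables = list(dose_response = tab),
       summary = list(dext = cfg$dext,
                      S_range = range(tab$S)))
}

scenario_fig4c <- function(cfg) {
  params0 <- base_params(cfg)
  combos <- tidyr::expand_grid(khe = cfg$khe_values,
                               alpha = cfg$alpha_values,
                               bJ = cfg$bJ_grid)
  tab <- purrr::pmap_dfr(combos, function(khe, alpha, bJ) {
    p <- update_params(params0, bD = cfg$bD, bJ = bJ, khe = khe,
                       alpha = alpha)
    st <- steady_single(p, model = cfg$model,
                        trans = trans_input(Dext = cfg$dext))
    tibble::tibble(khe = khe, alpha = alpha, bJ = bJ, S = st[["S"]],
                   D = st[["D"]], J = st[["J"]])
  })
  list(tables = list(dose_response = tab),
       summary = list(bD = cfg$bD, dext = cfg$dext))
}

# Trans assays: the sending cell expresses the ligands (facing the
# receiver's clamped Notch); the receiving cell's Notch level is clamped
# at its solo steady level bN/beta and its activity S integrates the
# sender's steady surface ligands.
receiver_activity <- function(params, sender, n_clamp) {
  (params$kt * sender[["D"]] + params$alpha * params$kt * sender[["J"]]) *
    n_clamp / params$betaS
}

scenario_fig4e <- function(cfg) {
  params0 <- base_params(cfg)
  n_clamp <- cfg$n_clamp %||% (params0$bN / params0$beta)
  tab <- purrr::map_dfr(cfg$bD_grid, function(bD) {
    p <- update_params(params0, bD = bD, bJ = cfg$sender_bJ)
    sender <- steady_single(p, model = cfg$model, Next = n_clamp)
    tibble::tibble(bD_sender = bD,
                   S_receiver = receiver_activity(p, sender, n_clamp),
                   D_sender = sender[["D"]], J_sender = sender[["J"]])
  })
  list(tables = list(dose_response = tab),
       summary = list(n_clamp = n_clamp))
}

scenario_fig4f <- function(cfg) {
  params0 <- base_params(cfg)
  n_clamp <- cfg$n_clamp %||% (params0$bN / params0$beta)
  combos <- tidyr::expand_grid(khe = cfg$khe_values,
                               alpha = cfg$alpha_values,
                               bJ = cfg$bJ_grid)
  tab <- purrr::pmap_dfr(combos, function(khe, alpha, bJ) {
    p <- update_params(params0, bD = cfg$sender_bD, bJ = bJ, khe = khe,
                       alpha = alpha)
    sender <- steady_single(p, model = cfg$model, Next = n_clamp)
    tibble::tibble(khe = khe, alpha = alpha, bJ_sender = bJ,
                   S_receiver = receiver_activity(p, sender, n_clamp),
                   D_sender = sender[["D"]], J_sender = sender[["J"]])
  })
  list(tables = list(dose_response = tab),
       summary = list(bD_sender = cfg$sender_bD, n_clamp = n_clamp))
}

# -- lattice / line scenarios -------------------------------------------

scenario_fig5_lattice <- function(cfg) {
  params <- base_params(cfg)
  lat <- build_lattice("hex", cfg$n_rows, cfg$n_cols)
  sim <- simulate_tissue(lat, params, model = cfg$model,
                         vegf = vegf_spec(Vext = params$Vext_base,
                                          a = cfg$a),
                         t_end = cfg$t_end, h = cfg$h, seed = cfg$seed,
                         init_range = cfg$init_range)
  list(tables = list(pattern = sim$final),
       summary = list(converged = sim$converged,
                      final_residual = sim$final_residual,
                      tip_fraction = sim$pattern$tip_fraction,
                      front_alternation_index =
                        sim$pattern$front_alternation_index))
}

scenario_fig6_line <- function(cfg) {
  params <- base_params(cfg)
  b0 <- if (cfg$ligand == "D") params$bD else params$bJ
  tab <- purrr::map_dfr(cfg$multipliers, function(mult) {
    p <- if (cfg$ligand == "D") update_params(params, bD = mult * b0)
         else update_params(params, bJ = mult * b0)
    lat <- build_lattice("line", 1, cfg$n_cols)
    sim <- simulate_tissue(lat, p, model = cfg$model,
                           t_end = cfg$t_end, h = cfg$h,
                           seed = cfg$seed + round(100 * mult),
                           init_range = cfg$init_range)
    lig <- if (cfg$ligand == "D") "DLL4" else "JAG1"
    dplyr::mutate(sim$final, multiplier = mult, ligand = cfg$ligand,
                  group = dplyr::case_when(
                    mult < 1 ~ paste0(lig, "+/-"),
                    mult == 1 ~ "WT",
                    TRUE ~ paste0(lig, "iGOF")),
                  .before = 1)
  })
  list(tables = list(mutant_lines = tab),
       summary = list(ligand = cfg$ligand,
                      multipliers = cfg$multipliers))
}

scenario_fig7_stripes <- function(cfg) {
  params <- update_params(base_params(cfg), alpha = cfg$alpha)
  # default: two contiguous stripes, each a fifth of the line, centred
  # at the first and third quarters
  stripes <- cfg$stripe_cells
  if (is.null(stripes)) {
    w <- max(1L, floor(cfg$n_cols / 5))
    s1 <- floor(cfg$n_cols / 4 - w / 2) + 1L
    s2 <- floor(3 * cfg$n_cols / 4 - w / 2) + 1L
    stripes <- list(seq(s1, length.out = w), seq(s2, length.out = w))
  }
  cfg$stripe_cells <- stripes
  tab <- purrr::map_dfr(cfg$species, function(sp) {
    lat <- build_lattice("line", 1, cfg$n_cols)
    for (stripe in cfg$stripe_cells) {
      lat <- add_ligand_stripes(lat, species = sp, cells = stripe,
                                from = 0, to = cfg$stripe_max)
    }
    sim <- simulate_tissue(lat, params, model = cfg$model,
                           t_end = cfg$t_end, h = cfg$h, seed = cfg$seed,
                           init_range = cfg$init_range)
    in_stripe <- lat$cells$cell %in% unlist(cfg$stripe_cells)
    dplyr::mutate(sim$final, species_striped = sp,
                  in_stripe = in_stripe, .before = 1)
  })
  list(tables = list(stripes = tab),
       summary = list(alpha = cfg$alpha, stripe_max = cfg$stripe_max))
}

scenario_s6 <- function(cfg) {
  params <- base_params(cfg)
  tab <- purrr::map_dfr(cfg$a_values, function(a) {
    lat <- build_lattice("hex", cfg$n_rows, cfg$n_cols)
    sim <- simulate_tissue(lat, params, model = cfg$model,
                           vegf = vegf_spec(Vext = params$Vext_base,
                                            a = a),
                           t_end = cfg$t_end, h = cfg$h, seed = cfg$seed,
                           init_range = cfg$init_range)
    dplyr::mutate(sim$final, a = a, .before = 1)
  })
  list(tables = list(pattern = tab),
       summary = list(a_values = cfg$a_values))
}

# -- two-cell bifurcation scenarios -------------------------------------

scenario_fig5cd <- function(cfg) {
  params <- update_params(base_params(cfg), khe = cfg$khe)
  br <- continue_branch(params, model = cfg$model, param_name = "bD",
                        range = cfg$range, n_points = cfg$n_points,
                        seed = cfg$seed)
  list(tables = list(equilibria = equilibria_table(br)),
       summary = list(khe = cfg$khe,
                      stable_counts = rle_string(br$n_stable),
                      n_events = nrow(br$events)))
}

scenario_fig6c <- function(cfg) {
  params0 <- base_params(cfg)
  tab <- purrr::map_dfr(cfg$bJ_values, function(bJ) {
    br <- continue_branch(update_params(params0, bJ = bJ),
                          model = cfg$model, param_name = "bD",
                          range = cfg$range, n_points = cfg$n_points,
                          seed = cfg$seed)
    dplyr::mutate(equilibria_table(br), bJ = bJ, .before = 1)
  })
  list(tables = list(equilibria = tab),
       summary = list(bJ_values = cfg$bJ_values))
}

scenario_fig7de <- function(cfg) {
  params <- update_params(base_params(cfg), alpha = cfg$alpha)
  tab <- purrr::map_dfr(cfg$directions, function(dir) {
    br <- continue_branch(params, model = cfg$model, param_name = dir,
                          range = cfg$range, n_points = cfg$n_points,
                          seed = cfg$seed)
    equilibria_table(br)
  })
  list(tables = list(equilibria = tab),
       summary = list(alpha = cfg$alpha))
}

scenario_fig7f <- function(cfg) {
  params <- base_params(cfg)
  tab <- phase_diagram(params, jext_grid = cfg$jext_grid,
                       alpha_grid = cfg$alpha_grid, model = cfg$model,
                       seed = cfg$seed)
  list(tables = list(phase = tab),
       summary = list(n_patterning = sum(tab$patterning)))
}

scenario_s7b <- function(cfg) {
  params0 <- update_params(base_params(cfg), khe = cfg$khe)
  tab <- purrr::map_dfr(cfg$bJ_values, function(bJ) {
    br <- continue_branch(update_params(params0, bJ = bJ),
                          model = cfg$model, param_name = "bD",
                          range = cfg$range, n_points = cfg$n_points,
                          seed = cfg$seed)
    dplyr::mutate(equilibria_table(br), bJ = bJ, .before = 1)
  })
  list(tables = list(equilibria = tab),
       summary = list(khe = cfg$khe, bJ_values = cfg$bJ_values))
}

scenario_s3 <- function(cfg) {
  params0 <- update_params(base_params(cfg), khe = cfg$khe, bD = cfg$bD)
  tab <- purrr::map_dfr(cfg$bJ_grid, function(bJ) {
    ss <- solve_ligand_steady_state(update_params(params0, bJ = bJ))
    lim <- strong_het_limit(update_params(params0, bJ = bJ))
    tibble::tibble(bJ = bJ, Dbar = ss$Dbar, Jbar = ss$Jbar,
                   Dbar_limit = lim$Dbar, Jbar_limit = lim$Jbar)
  })
  list(tables = list(mutual_inactivation = tab),
       summary = list(khe = cfg$khe, bD = cfg$bD,
                      crossing_bJ = cfg$bD))
}

rle_string <- function(x) paste(rle(x)$values, collapse = " -> ")

equilibria_table <- function(branch) {
  tab <- branch$equilibria
  if (nrow(tab) == 0) return(tab)
  ycol <- if (branch$model == 2) "V1" else "S1"
  tab <- dplyr::arrange(tab, .data$param_value,
                        dplyr::desc(.data[[ycol]]))
  dplyr::mutate(dplyr::group_by(tab, .data$param_value),
                branch_id = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::relocate("param_name", "param_value", "branch_id",
                    "sym_class", "stability")
}

# -- serialization -------------------------------------------------------

#' Write result tables to CSV
#'
#' Writes the standard CSV representation (RFC 4180, header row, UTF-8,
#' shortest round-trip number formatting) of a package result object:
#' time-series (`time_h`, `cell_id`, species columns) for trajectories,
#' equilibrium tables (`param_name`, `param_value`, `branch_id`,
#' `sym_class`, `stability`, state columns) for bifurcation branches, and
#' per-cell pattern tables (`cell_id`, `x`, `y`, `label`, state columns)
#' for tissue simulations.
#'
#' @param x An `rk4_trajectory`, `bifurcation_branch`, `tissue_sim`, or
#'   data frame.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_tables <- function(x, path) UseMethod("write_tables")

#' @export
write_tables.rk4_trajectory <- function(x, path) {
  tab <- dplyr::mutate(x$states, cell_id = 1L, .after = "time_h")
  write_csv_checked(tab, path)
}

#' @export
write_tables.bifurcation_branch <- function(x, path) {
  write_csv_checked(equilibria_table(x), path)
}

#' @export
write_tables.tissue_sim <- function(x, path) {
  tab <- dplyr::rename(x$final, cell_id = "cell")
  write_csv_checked(tab, path)
}

#' @export
write_tables.data.frame <- function(x, path) {
  write_csv_checked(tibble::as_tibble(x), path)
}

write_csv_checked <- function(tab, path) {
  # doubles rendered at 17 significant digits so values round-trip exactly
  fmt <- dplyr::mutate(tab, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
  tryCatch(readr::write_csv(fmt, path),
           error = function(e) {
             stop(sprintf("failed writing '%s': %s", path,
                          conditionMessage(e)), call. = FALSE)
           })
  invisible(tab)
}
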