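#' Coupled right-hand side for two interacting cells
#'
#' Builds the 10- (model 1) or 14-dimensional (model 2) vector field of
#' two cells coupled by pure pairwise exchange: each cell's trans inputs
#' are the other cell's free ligand (and Notch) levels, plus any common
#' engineered external trans-ligand.
#'
#' @param params A [signalling_params()] object.
#' @param model 1 or 2.
#' @param dext_add,jext_add External trans DLL4/JAG1 added to both cells
#'   (molecules).
#' @param V_local Free VEGF at both cells (model 2; defaults to
#'   `params$Vext_base`, the front level).
#' @return A function mapping the concatenated state vector (cell 1 block
#'   then cell 2 block, species order `D, J, C, N, S[, R, V]`) to its
#'   derivative.
#' @export
two_cell_rhs <- function(params, model = 2, dext_add = 0, jext_add = 0,
                         V_local = params$Vext_base) {
  stopifnot(inherits(params, "signalling_params"), model %in% c(1, 2))
  ns <- if (model == 2) 7L else 5L
  species <- c("D", "J", "C", "N", "S", "R", "V")[seq_len(ns)]
  function(x) {
    s1 <- x[seq_len(ns)]
    s2 <- x[ns + seq_len(ns)]
    names(s1) <- names(s2) <- species
    # no nonnegativity check here: Newton iterates may probe slightly
    # negative states
    tr1 <- c(Dext = s2[["D"]] + dext_add, Jext = s2[["J"]] + jext_add)
    tr2 <- c(Dext = s1[["D"]] + dext_add, Jext = s1[["J"]] + jext_add)
    if (model == 2) {
      c(rhs_model2(s1, params, V_local, tr1, Next = s2[["N"]]),
        rhs_model2(s2, params, V_local, tr2, Next = s1[["N"]]))
    } else {
      c(rhs_model1(s1, params, tr1, Next = s2[["N"]]),
        rhs_model1(s2, params, tr2, Next = s1[["N"]]))
    }
  }
}

#' Finite-difference Jacobian
#'
#' Central-difference Jacobian of a vector field, with per-component step
#' `eps * max(|x_i|, 1)`.
#'
#' @param rhs Function mapping a numeric vector to a numeric vector of the
#'   same length.
#' @param state Point of evaluation.
#' @param eps Relative step (default 1e-6).
#' @return The square Jacobian matrix.
#' @export
jacobian_fd <- function(rhs, state, eps = 1e-6) {
  m <- length(state)
  jac <- matrix(0, m, m)
  for (i in seq_len(m)) {
    hstep <- eps * max(abs(state[i]), 1)
    xp <- state; xp[i] <- xp[i] + hstep
    xm <- state; xm[i] <- xm[i] - hstep
    jac[, i] <- (rhs(xp) - rhs(xm)) / (2 * hstep)
  }
  jac
}

#' Classify linear stability from a Jacobian
#'
#' @param jacobian Square Jacobian matrix at an equilibrium.
#' @param tol Margin on eigenvalue real parts (1/hour): stable if all
#'   below `-tol`, unstable if any above `+tol`, otherwise marginal.
#' @return A list with `stability` (`"stable"`, `"unstable"` or
#'   `"marginal"`) and `leading_eig` (largest real part).
#' @export
classify_stability <- function(jacobian, tol = 1e-6) {
  stopifnot(is.matrix(jacobian), nrow(jacobian) == ncol(jacobian))
  re <- Re(eigen(jacobian, only.values = TRUE)$values)
  lead <- max(re)
  stability <- if (lead < -tol) "stable"
               else if (lead > tol) "unstable"
               else "marginal"
  list(stability = stability, leading_eig = lead)
}

newton_solve <- function(rhs, x0, max_iter = 60, tol = NULL) {
  x <- x0
  f <- rhs(x)
  scale <- max(abs(x), 1)
  if (is.null(tol)) tol <- 1e-10 * max(scale, 1)
  for (it in seq_len(max_iter)) {
    nf <- max(abs(f))
    if (!is.finite(nf)) return(NULL)
    if (nf < tol) return(x)
    jac <- jacobian_fd(rhs, x)
    step <- tryCatch(solve(jac, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- rhs(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < nf) break
      lam <- lam / 2
      if (lam < 1e-6) { xn <- x + step; fn <- rhs(xn); break }
    }
    x <- xn; f <- fn
  }
  if (max(abs(f)) < tol) x else NULL
}

# Long-time two-cell integration (pairwise exchange) on the compiled
# lattice path: a 2-cell line with truncated neighbour averaging is
# exactly the paired coupling.
two_cell_attractor <- function(params, model, dext_add = 0, jext_add = 0,
                               V_local = params$Vext_base, init,
                               t_end = 800, h = 0.02, steady_tol = 1e-4) {
  lat <- build_lattice("line", 1, 2)
  lat$dext_add <- rep(dext_add, 2)
  lat$jext_add <- rep(jext_add, 2)
  sim <- simulate_tissue(lat, params, model = model,
                         vegf = vegf_spec(Vext = V_local, a = 0),
                         t_end = t_end, h = h, init = init,
                         boundary = "truncate", steady_tol = steady_tol)
  mat <- as.matrix(sim$final[, species_for(model)])
  c(mat[1, ], mat[2, ])
}

species_for <- function(model) {
  if (model == 2) c("D", "J", "C", "N", "S", "R", "V")
  else c("D", "J", "C", "N", "S")
}

two_cell_colnames <- function(model) {
  sp <- species_for(model)
  c(paste0(sp, 1), paste0(sp, 2))
}

swap_cells <- function(x, model) {
  ns <- if (model == 2) 7L else 5L
  c(x[ns + seq_len(ns)], x[seq_len(ns)])
}

#' Find equilibria of the two-cell system
#'
#' Multistart Newton search for equilibria of [two_cell_rhs()]. Starting
#' points are (a) the long-time attractor of the dynamics from the empty
#' state, (b) the homogeneous (symmetric) equilibrium found on the
#' symmetric subspace, (c) symmetry-broken perturbations of it, and (d)
#' seeded random states. Converged roots are merged at `1e-4` relative
#' distance, classified as stable/unstable/marginal by Jacobian
#' eigenvalues, and as homogeneous (cell blocks equal to 1e-6 relative) or
#' heterogeneous.
#'
#' @inheritParams two_cell_rhs
#' @param n_starts Number of random starting points (>= 8).
#' @param seed Seed for the random starts.
#' @param extra_starts Optional list of additional starting state vectors
#'   (used by [continue_branch()] for warm starts).
#' @return A tibble, one row per equilibrium: state columns (`D1`, ...,
#'   `V2`), `residual` (max |RHS|, molecules/hour), `stability`,
#'   `sym_class` and `leading_eig`, sorted by decreasing `V1` (model 2)
#'   or `S1`.
#' @export
find_equilibria <- function(params, model = 2, dext_add = 0, jext_add = 0,
                            V_local = params$Vext_base, n_starts = 16,
                            seed = 1, extra_starts = NULL) {
  stopifnot(n_starts >= 8)
  rhs <- two_cell_rhs(params, model, dext_add, jext_add, V_local)
  ns <- if (model == 2) 7L else 5L
  m <- 2L * ns

  # (a) forward-integrated attractor from the (near-)empty state, via the
  # compiled two-cell path
  att <- two_cell_attractor(params, model, dext_add, jext_add, V_local,
                            init = matrix(1e-3, 2, ns))
  starts <- list(att)

  # (b) homogeneous equilibrium via the symmetric subspace
  sym_rhs <- function(half) rhs(c(half, half))[seq_len(ns)]
  half0 <- (att[seq_len(ns)] + att[ns + seq_len(ns)]) / 2
  hom <- newton_solve(sym_rhs, half0)
  if (!is.null(hom)) {
    starts <- c(starts, list(c(hom, hom)))
    # (c) symmetry-broken perturbations
    for (f in c(0.2, 0.5, 0.9)) {
      up <- hom * (1 + f); dn <- hom * (1 - f)
      starts <- c(starts, list(c(up, dn)), list(c(dn, up)))
    }
  }

  # (d) seeded random starts, scaled to production/degradation magnitudes
  scale_sp <- c(D = 3000, J = 3000, C = 2000, N = 6000, S = 2000,
                R = 10000, V = 10000)[species_for(model)]
  rand <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(n_starts * m), nrow = n_starts) *
      matrix(rep(scale_sp, 2), nrow = n_starts, ncol = m, byrow = TRUE)
  })
  starts <- c(starts, lapply(seq_len(n_starts), function(i) rand[i, ]),
              as.list(extra_starts %||% list()))

  scale <- max(params$bD, params$bJ, params$bN, params$bR, 1)
  tol <- 1e-8 * scale
  sols <- list()
  for (x0 in starts) {
    x <- newton_solve(rhs, x0, tol = tol)
    if (is.null(x) || any(x < -1e-6 * scale)) next
    x <- pmax(x, 0)
    if (max(abs(rhs(x))) > tol) next
    dup <- any(vapply(sols, function(s) {
      max(abs(s - x)) <= 1e-4 * max(abs(s), abs(x), 1)
    }, TRUE))
    if (!dup) sols <- c(sols, list(x))
  }
  # exchange symmetry: the cell-swap of any equilibrium is one too
  for (x in sols) {
    xs <- swap_cells(x, model)
    dup <- any(vapply(sols, function(s) {
      max(abs(s - xs)) <= 1e-4 * max(abs(s), abs(xs), 1)
    }, TRUE))
    if (!dup) sols <- c(sols, list(xs))
  }
  if (length(sols) == 0) {
    return(tibble::tibble())
  }
  rows <- purrr::map(sols, function(x) {
    jac <- jacobian_fd(rhs, x)
    st <- classify_stability(jac)
    rel <- max(abs(x[seq_len(ns)] - x[ns + seq_len(ns)])) /
      max(abs(x), 1)
    out <- tibble::as_tibble(as.list(stats::setNames(x,
                                                     two_cell_colnames(model))))
    out$residual <- max(abs(rhs(x)))
    out$stability <- st$stability
    out$leading_eig <- st$leading_eig
    out$sym_class <- if (rel < 1e-6) "homogeneous" else "heterogeneous"
    out
  })
  tab <- dplyr::bind_rows(rows)
  ord <- if (model == 2) order(-tab$V1) else order(-tab$S1)
  tab[ord, ]
}

#' Natural-parameter continuation of two-cell equilibrium branches
#'
#' Sweeps one parameter over a grid; at each grid value the equilibria are
#' found by Newton iteration warm-started from the previous value's
#' equilibria plus a fresh multistart (to catch branch births), and
#' classified by stability and symmetry. Grid intervals where the number
#' of stable equilibria changes are recorded as events.
#'
#' @inheritParams find_equilibria
#' @param param_name Parameter to sweep: any scalar field of
#'   [signalling_params()] or `"dext_add"`/`"jext_add"` (external
#'   trans-ligand level).
#' @param range Length-2 numeric range of the sweep.
#' @param n_points Number of grid points.
#' @return An object of class `bifurcation_branch`: list with
#'   `equilibria` (tibble with `param_name`, `param_value` and the
#'   [find_equilibria()] columns), `events` (tibble of intervals where the
#'   stable-equilibrium count changes) and `param_name`.
#' @export
continue_branch <- function(params, model = 2, param_name, range,
                            n_points = 25, dext_add = 0, jext_add = 0,
                            V_local = params$Vext_base, n_starts = 12,
                            seed = 1) {
  stopifnot(length(range) == 2, n_points >= 2)
  grid <- seq(range[1], range[2], length.out = n_points)
  prev <- NULL
  rows <- vector("list", n_points)
  n_stable <- integer(n_points)
  for (g in seq_along(grid)) {
    val <- grid[g]
    p_g <- params; d_g <- dext_add; j_g <- jext_add
    if (param_name == "dext_add") d_g <- val
    else if (param_name == "jext_add") j_g <- val
    else p_g <- do.call(update_params,
                        c(list(params), stats::setNames(list(val),
                                                        param_name)))
    warm <- if (is.null(prev)) NULL else {
      lapply(seq_len(nrow(prev)), function(i) {
        unname(unlist(prev[i, two_cell_colnames(model)]))
      })
    }
    eq <- tryCatch(
      find_equilibria(p_g, model, dext_add = d_g, jext_add = j_g,
                      V_local = V_local, n_starts = max(n_starts, 8),
                      seed = seed + g, extra_starts = warm),
      error = function(e) tibble::tibble())
    if (nrow(eq) > 0) {
      prev <- eq
      eq$param_value <- val
      rows[[g]] <- eq
      n_stable[g] <- sum(eq$stability == "stable")
    } else {
      n_stable[g] <- NA_integer_
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab$param_name <- param_name
  tab <- dplyr::relocate(tab, "param_name", "param_value")
  chg <- which(diff(n_stable) != 0 & !is.na(diff(n_stable)))
  events <- tibble::tibble(
    param_lo = grid[chg], param_hi = grid[chg + 1],
    stable_before = n_stable[chg], stable_after = n_stable[chg + 1])
  structure(list(equilibria = tab, events = events,
                 param_name = param_name, grid = grid,
                 n_stable = n_stable, model = model),
            class = "bifurcation_branch")
}

#' @export
print.bifurcation_branch <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_branch> %s over [%g, %g], %d points; stable counts %s\n",
    x$param_name, min(x$grid), max(x$grid), length(x$grid),
    paste(rle(x$n_stable)$values, collapse = " -> ")))
  if (nrow(x$events) > 0) {
    cat(sprintf("  %d stable-count change(s)\n", nrow(x$events)))
  }
  invisible(x)
}

#' Tidy a bifurcation branch
#'
#' @param x A `bifurcation_branch`.
#' @param ... Unused.
#' @return The equilibria tibble (one row per equilibrium per grid value).
#' @export
tidy.bifurcation_branch <- function(x, ...) x$equilibria

#' @export
glance.bifurcation_branch <- function(x, ...) {
  tibble::tibble(param_name = x$param_name,
                 n_points = length(x$grid),
                 max_stable = max(x$n_stable, na.rm = TRUE),
                 n_events = nrow(x$events))
}

#' @export
autoplot.bifurcation_branch <- function(object,
                                        y = if (object$model == 2) "V1"
                                            else "S1",
                                        ...) {
  ggplot2::ggplot(object$equilibria,
                  ggplot2::aes(x = .data$param_value, y = .data[[y]],
                               colour = .data$sym_class,
                               shape = .data$stability)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$param_name, y = y)
}

#' Two-parameter patterning phase diagram
#'
#' For every combination of external trans-JAG1 level and JAG1-Notch
#' affinity ratio, reports whether the two-cell system admits a stable
#' heterogeneous equilibrium — the signature of alternating (patterned)
#' cell fates.
#'
#' @inheritParams find_equilibria
#' @param jext_grid Numeric grid of external trans-JAG1 levels
#'   (molecules).
#' @param alpha_grid Numeric grid of affinity ratios in `[0, 1]`.
#' @return A tibble with columns `jext_add`, `alpha`, `patterning`
#'   (logical) and `n_stable`.
#' @export
phase_diagram <- function(params, jext_grid, alpha_grid, model = 2,
                          V_local = params$Vext_base, n_starts = 10,
                          seed = 1) {
  combos <- tidyr::expand_grid(alpha = alpha_grid, jext_add = jext_grid)
  res <- purrr::pmap(combos, function(alpha, jext_add) {
    p_a <- update_params(params, alpha = alpha)
    eq <- tryCatch(
      find_equilibria(p_a, model, jext_add = jext_add, V_local = V_local,
                      n_starts = max(n_starts, 8), seed = seed),
      error = function(e) tibble::tibble())
    het <- nrow(eq) > 0 &&
      any(eq$stability == "stable" & eq$sym_class == "heterogeneous")
    tibble::tibble(patterning = het,
                   n_stable = if (nrow(eq)) sum(eq$stability == "stable")
                              else 0L)
  })
  dplyr::bind_cols(combos, dplyr::bind_rows(res))
}
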