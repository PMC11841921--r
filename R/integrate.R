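#' Fixed-step classical Runge-Kutta integration
#'
#' Integrates `dx/dt = rhs(x)` with the classical fourth-order Runge-Kutta
#' scheme on a fixed grid, with optional species clamping and steady-state
#' detection. Tiny negative excursions (above `-1e-9`) produced by
#' floating-point round-off are clipped to zero; anything more negative, or
#' any NaN/Inf, aborts with the failure time.
#'
#' @param rhs Function of one argument (the named state vector) returning
#'   the named derivative vector.
#' @param init Named nonnegative initial state vector.
#' @param h Step size (hours, > 0).
#' @param t_end Final time (hours, >= h).
#' @param clamps Named numeric vector of species held fixed: the state is
#'   reset to these values after every step (and before the first), and the
#'   clamped components are excluded from the steady-state residual.
#' @param steady_tol Convergence threshold on `max |dx/dt|`
#'   (molecules/hour); integration stops early once reached.
#' @param check_every Steps between convergence checks.
#' @param record_every Steps between recorded trajectory rows (the initial
#'   and final states are always recorded).
#' @return An object of class `rk4_trajectory`: a list with `states` (a
#'   tibble with column `time_h` and one column per species), `final_state`
#'   (named vector), `converged`, `final_residual` (molecules/hour), and
#'   `t_final`.
#' @examples
#' tr <- rk4_integrate(function(x) c(x = -0.1 * x[["x"]]), c(x = 100),
#'                     h = 0.01, t_end = 10)
#' tr$final_state # 100 * exp(-1)
#' @export
rk4_integrate <- function(rhs, init, h = 0.01, t_end = 1000,
                          clamps = NULL, steady_tol = 1e-6,
                          check_every = 100L, record_every = 1000L) {
  stopifnot(is.function(rhs), is.numeric(init), !is.null(names(init)),
            h > 0, t_end >= h)
  check_state(init)
  state <- init
  if (!is.null(clamps)) {
    stopifnot(is.numeric(clamps), !is.null(names(clamps)),
              all(names(clamps) %in% names(state)))
    state[names(clamps)] <- clamps
  }
  # positional indexing: a rhs may name its output differently
  free <- if (is.null(clamps)) seq_along(state) else
    which(!(names(state) %in% names(clamps)))
  n_steps <- ceiling(t_end / h - 1e-9)
  n_rec <- floor(n_steps / record_every) + 2L
  rec <- matrix(NA_real_, nrow = n_rec, ncol = length(state),
                dimnames = list(NULL, names(state)))
  rec_t <- numeric(n_rec)
  ri <- 1L
  rec[ri, ] <- state; rec_t[ri] <- 0
  converged <- FALSE
  step <- 0L
  while (step < n_steps) {
    k1 <- rhs(state)
    k2 <- rhs(state + (h / 2) * k1)
    k3 <- rhs(state + (h / 2) * k2)
    k4 <- rhs(state + h * k3)
    state <- state + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.null(clamps)) state[names(clamps)] <- clamps
    step <- step + 1L
    bad <- !is.finite(state)
    if (any(bad)) {
      stop(sprintf(
        "rk4_integrate(): non-finite state (%s) at t = %.4g h",
        paste(names(state)[bad], collapse = ", "), step * h), call. = FALSE)
    }
    neg <- state < 0
    if (any(neg)) {
      if (any(state < -1e-9)) {
        stop(sprintf(
          "rk4_integrate(): negative state (%s = %.3e) at t = %.4g h",
          names(state)[which.min(state)], min(state), step * h),
          call. = FALSE)
      }
      state[neg] <- 0
    }
    if (step %% record_every == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- state; rec_t[ri] <- step * h
    }
    if (step %% check_every == 0L || step == n_steps) {
      resid <- max(abs(rhs(state)[free]))
      if (resid < steady_tol) { converged <- TRUE; break }
    }
  }
  if (rec_t[ri] < step * h) {
    ri <- ri + 1L
    rec[ri, ] <- state; rec_t[ri] <- step * h
  }
  final_residual <- max(abs(rhs(state)[free]))
  states <- tibble::as_tibble(rec[seq_len(ri), , drop = FALSE])
  states <- dplyr::bind_cols(tibble::tibble(time_h = rec_t[seq_len(ri)]),
                             states)
  structure(
    list(states = states, final_state = state, converged = converged,
         final_residual = final_residual, t_final = step * h, h = h),
    class = "rk4_trajectory"
  )
}

#' @export
print.rk4_trajectory <- function(x, ...) {
  cat(sprintf(
    "<rk4_trajectory> t = 0..%g h (h = %g), %s, final residual %.3g/h\n",
    x$t_final, x$h, if (x$converged) "converged" else "not converged",
    x$final_residual))
  print(utils::tail(x$states, 1))
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x An `rk4_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time_h`, `species`, `level`.
#' @export
tidy.rk4_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$states, -"time_h",
                      names_to = "species", values_to = "level")
}

#' @export
glance.rk4_trajectory <- function(x, ...) {
  tibble::tibble(t_final = x$t_final, h = x$h, converged = x$converged,
                 final_residual = x$final_residual,
                 n_recorded = nrow(x$states))
}

#' @export
autoplot.rk4_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy.rk4_trajectory(object),
                  ggplot2::aes(x = .data$time_h, y = .data$level,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "level (molecules)")
}
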