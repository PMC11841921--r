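#' Steady-state cubic equations for the ligand subsystem
#'
#' At steady state the free-ligand balances of the ligand-competition model
#' close onto a pair of monic cubic polynomials, one in the steady free
#' DLL4 level `Dbar` and one in the steady free JAG1 level `Jbar`, with
#' composite coefficients
#' `A1 = (beta + kt*Next) / (2*kho)`, `B1 = (beta + alpha*kt*Next) / khe`,
#' `A2 = (beta + kt*Next) / khe`, `B2 = 2*kho / khe^2`.
#'
#' @param params A [signalling_params()] object with `khe > 0` (at
#'   `khe = 0` the ligands decouple and the cubics are undefined; use
#'   [solve_ligand_steady_state()], which handles that regime).
#' @param Next Free Notch presented by neighbouring cells (molecules).
#' @return An object of class `ligand_cubic`: list with the composites
#'   `A1, B1, A2, B2`, coefficient vectors `cubic_D` and `cubic_J` in
#'   increasing-power order (constant first, monic), and `evaluate(D)`,
#'   the polynomial `F(D; bD, bJ)` of the DLL4 cubic.
#' @export
ligand_cubic <- function(params, Next = 0) {
  stopifnot(inherits(params, "signalling_params"), Next >= 0)
  p <- params
  if (p$khe <= 0) {
    stop(paste("ligand_cubic(): khe = 0 decouples the ligands; the cubic",
               "is undefined (use solve_ligand_steady_state)"),
         call. = FALSE)
  }
  pp <- p$beta + p$kt * Next          # total linear loss of D
  qq <- p$beta + p$alpha * p$kt * Next # total linear loss of J
  A1 <- pp / (2 * p$kho)
  B1 <- qq / p$khe
  A2 <- pp / p$khe
  B2 <- 2 * p$kho / p$khe^2
  cubic_D <- c(-p$bD * B1 / (2 * p$kho),
               (p$bJ - p$bD) / (2 * p$kho) + A1 * B1,
               A1 + B1,
               1)
  cubic_J <- c(-p$bJ^2 * B2 / qq,
               2 * p$bJ * B2 - p$bJ * A2 / qq,
               (p$bD - p$bJ) / qq + A2 - qq * B2,
               1)
  evaluate <- function(D) {
    cubic_D[1] + cubic_D[2] * D + cubic_D[3] * D^2 + cubic_D[4] * D^3
  }
  structure(list(A1 = A1, B1 = B1, A2 = A2, B2 = B2,
                 cubic_D = cubic_D, cubic_J = cubic_J,
                 evaluate = evaluate, params = params, Next = Next),
            class = "ligand_cubic")
}

# Real roots of a monic cubic given increasing-power coefficients, via
# companion-matrix eigenvalues, Newton-polished on the polynomial.
# Closed-form cubic formulas lose precision here because the coefficients
# span several orders of magnitude.
cubic_real_roots <- function(coefs) {
  stopifnot(length(coefs) == 4, coefs[4] == 1)
  companion <- matrix(0, 3, 3)
  companion[2, 1] <- 1
  companion[3, 2] <- 1
  companion[, 3] <- -coefs[1:3]
  ev <- eigen(companion, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) < 1e-8 * (1 + abs(ev))])
  f <- function(x) coefs[1] + coefs[2] * x + coefs[3] * x^2 + x^3
  fp <- function(x) coefs[2] + 2 * coefs[3] * x + 3 * x^2
  vapply(re, function(r) {
    for (i in 1:50) {
      d <- fp(r)
      if (d == 0) break
      stepv <- f(r) / d
      r2 <- r - stepv
      if (!is.finite(r2) || abs(stepv) < 1e-14 * (1 + abs(r))) {
        r <- if (is.finite(r2)) r2 else r
        break
      }
      r <- r2
    }
    r
  }, 0)
}

#' Steady free-ligand levels of a single cell
#'
#' Solves the steady-state ligand balances of the ligand-competition model
#' for the steady free DLL4 (`Dbar`) and JAG1 (`Jbar`) levels, given the
#' neighbour Notch level `Next`. For `khe > 0` the DLL4 cubic is solved
#' (companion matrix + Newton polish), `Jbar` is recovered from the JAG1
#' balance, and the nonnegative root pair consistent with both original
#' balance equations is returned; if several qualify, the one reached by
#' integrating the dynamics from the empty state breaks the tie. At
#' `khe = 0` the ligands decouple and the quadratic/linear solutions are
#' used directly.
#'
#' @inheritParams ligand_cubic
#' @return A one-row tibble with columns `Dbar`, `Jbar`, `residual_D`,
#'   `residual_J` (absolute residuals of the two balance equations,
#'   molecules/hour).
#' @export
solve_ligand_steady_state <- function(params, Next = 0) {
  stopifnot(inherits(params, "signalling_params"), Next >= 0)
  p <- params
  pp <- p$beta + p$kt * Next
  qq <- p$beta + p$alpha * p$kt * Next
  bal <- function(D, J) {
    c(D = p$bD - pp * D - 2 * p$kho * D^2 - p$khe * J * D,
      J = p$bJ - qq * J - p$khe * D * J)
  }
  if (p$khe == 0) {
    # decoupled: quadratic in D (or linear when kho = 0), linear in J
    D <- if (p$kho > 0) {
      (-pp + sqrt(pp^2 + 8 * p$kho * p$bD)) / (4 * p$kho)
    } else {
      p$bD / pp
    }
    J <- p$bJ / qq
    r <- abs(bal(D, J))
    return(tibble::tibble(Dbar = D, Jbar = J,
                          residual_D = r[["D"]], residual_J = r[["J"]]))
  }
  cub <- ligand_cubic(p, Next)
  roots <- cubic_real_roots(cub$cubic_D)
  roots <- sort(unique(pmax(roots, -Inf)))
  cand <- roots[roots >= -1e-9]
  cand <- pmax(cand, 0)
  tol <- 1e-6 * max(p$bD, p$bJ, 1)
  rows <- purrr::map(cand, function(D) {
    J <- p$bJ / (qq + p$khe * D)
    r <- abs(bal(D, J))
    tibble::tibble(Dbar = D, Jbar = J,
                   residual_D = r[["D"]], residual_J = r[["J"]])
  })
  tab <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(tab, .data$residual_D < tol, .data$residual_J < tol)
  if (nrow(ok) == 0) {
    stop(sprintf(
      paste("solve_ligand_steady_state(): no consistent nonnegative root;",
            "candidates D = %s with residuals %s"),
      paste(signif(tab$Dbar, 6), collapse = ", "),
      paste(signif(pmax(tab$residual_D, tab$residual_J), 3),
            collapse = ", ")), call. = FALSE)
  }
  if (nrow(ok) > 1) {
    # tie-break on the attractor of the dynamics from the empty state
    tr <- rk4_integrate(
      function(s) {
        b <- bal(s[["D"]], s[["J"]])
        c(D = b[["D"]], J = b[["J"]])
      },
      c(D = 0, J = 0), h = 0.01, t_end = 2000, steady_tol = 1e-8)
    d <- abs(ok$Dbar - tr$final_state[["D"]])
    ok <- ok[which.min(d), ]
  }
  ok[1, ]
}

#' Strong-heterodimerization limit of the ligand steady state
#'
#' In the limit where the heterodimerization rate dominates every other
#' loss process (`khe >> max(beta + kt*Next, kho)`), the ligands mutually
#' inactivate: only the one produced in excess survives. For `bD > bJ`,
#' `Jbar = 0` and `Dbar` solves the residual quadratic; for `bJ > bD`,
#' `Dbar = 0` and `Jbar = (bJ - bD) / (beta + alpha*kt*Next)`; at
#' `bD = bJ` both vanish.
#'
#' @inheritParams ligand_cubic
#' @return A one-row tibble with columns `Dbar`, `Jbar`.
#' @export
strong_het_limit <- function(params, Next = 0) {
  stopifnot(inherits(params, "signalling_params"), Next >= 0)
  p <- params
  pp <- p$beta + p$kt * Next
  qq <- p$beta + p$alpha * p$kt * Next
  if (p$bD > p$bJ) {
    if (p$kho == 0) {
      stop("strong_het_limit(): kho = 0 with bD > bJ has no finite limit",
           call. = FALSE)
    }
    D <- sqrt((pp / (4 * p$kho))^2 + (p$bD - p$bJ) / (2 * p$kho)) -
      pp / (4 * p$kho)
    tibble::tibble(Dbar = D, Jbar = 0)
  } else if (p$bJ > p$bD) {
    tibble::tibble(Dbar = 0, Jbar = (p$bJ - p$bD) / qq)
  } else {
    tibble::tibble(Dbar = 0, Jbar = 0)
  }
}

#' Signs of the steady-ligand responses to production rates
#'
#' Central-difference estimates of the four partial derivatives of
#' `(Dbar, Jbar)` with respect to `(bD, bJ)`. For valid positive
#' parameters the implicit-function analysis of the ligand cubic predicts
#' the sign pattern `(+, -, -, +)`: each ligand rises with its own
#' production rate and falls with the other's.
#'
#' @inheritParams ligand_cubic
#' @param delta Relative step for the central difference.
#' @return A one-row tibble with character columns `dD_dbD`, `dD_dbJ`,
#'   `dJ_dbD`, `dJ_dbJ`, each `"+"`, `"-"`, `"0"` or `"indeterminate"`,
#'   and the numeric derivative estimates (`*_value` columns).
#' @export
ligand_monotonicity <- function(params, Next = 0, delta = 1e-3) {
  stopifnot(inherits(params, "signalling_params"), delta > 0)
  solve_at <- function(bD, bJ) {
    ss <- solve_ligand_steady_state(update_params(params, bD = bD, bJ = bJ),
                                    Next = Next)
    c(D = ss$Dbar, J = ss$Jbar)
  }
  deriv <- function(wrt) {
    b0 <- params[[wrt]]
    hstep <- delta * max(b0, 1)
    lo <- solve_at(if (wrt == "bD") b0 - hstep else params$bD,
                   if (wrt == "bJ") b0 - hstep else params$bJ)
    hi <- solve_at(if (wrt == "bD") b0 + hstep else params$bD,
                   if (wrt == "bJ") b0 + hstep else params$bJ)
    (hi - lo) / (2 * hstep)
  }
  dD <- deriv("bD")
  dJ <- deriv("bJ")
  base <- solve_at(params$bD, params$bJ)
  noise <- 1e-9 * (1 + max(abs(base)))
  sign_of <- function(v) {
    if (abs(v) <= noise) {
      if (v == 0) "0" else "indeterminate"
    } else if (v > 0) "+" else "-"
  }
  tibble::tibble(
    dD_dbD = sign_of(dD[["D"]]), dD_dbJ = sign_of(dJ[["D"]]),
    dJ_dbD = sign_of(dD[["J"]]), dJ_dbJ = sign_of(dJ[["J"]]),
    dD_dbD_value = dD[["D"]], dD_dbJ_value = dJ[["D"]],
    dJ_dbD_value = dD[["J"]], dJ_dbJ_value = dJ[["J"]])
}

#' Effective irreversible heterodimerization rate
#'
#' Maps the reversible DLL4-JAG1 binding rates onto the irreversible
#' heterodimerization rate that produces the same ligand steady state:
#' `khe = beta * kplus / (beta + kminus)`.
#'
#' @param rev A [reversible_binding()] object.
#' @param beta Degradation rate of the heterodimer (1/hour, > 0).
#' @return The effective rate (1/(molecule hour)).
#' @export
reversible_equivalent_khe <- function(rev, beta) {
  stopifnot(inherits(rev, "reversible_binding"), is.numeric(beta),
            beta > 0)
  beta * rev$kplus / (beta + rev$kminus)
}
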