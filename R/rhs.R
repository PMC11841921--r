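#' Per-cell state vectors
#'
#' Helpers constructing named state vectors for the three model variants.
#' Species: `D` free DLL4 monomer, `J` free JAG1 monomer, `C` DLL4
#' homodimer (the cis-inhibitory species), `N` free Notch1 receptor,
#' `S` Notch activity (free intracellular domain), and for the VEGF model
#' `R` free VEGFR2 and `V` VEGFR2 activity; the reversible variant adds the
#' explicit DLL4-JAG1 heterodimer `DJ`. All in molecules per cell.
#'
#' @param D,J,C,N,S,R,V,DJ Species levels (molecules, >= 0).
#' @return A named numeric vector.
#' @export
cell_state <- function(D = 0, J = 0, C = 0, N = 0, S = 0) {
  st <- c(D = D, J = J, C = C, N = N, S = S)
  check_state(st)
  st
}

#' @rdname cell_state
#' @export
cell_state2 <- function(D = 0, J = 0, C = 0, N = 0, S = 0, R = 0, V = 0) {
  st <- c(D = D, J = J, C = C, N = N, S = S, R = R, V = V)
  check_state(st)
  st
}

#' @rdname cell_state
#' @export
cell_state_rev <- function(D = 0, J = 0, DJ = 0, C = 0, N = 0, S = 0) {
  st <- c(D = D, J = J, DJ = DJ, C = C, N = N, S = S)
  check_state(st)
  st
}

check_state <- function(state) {
  if (!is.numeric(state) || any(!is.finite(state)) || any(state < 0)) {
    stop("state must be a finite nonnegative numeric vector", call. = FALSE)
  }
  invisible(state)
}

#' Trans-ligand input seen by one cell
#'
#' @param Dext,Jext Trans DLL4 and JAG1 presented to the cell by its
#'   neighbours and/or an engineered external source (molecules, >= 0).
#' @return A named numeric vector `c(Dext =, Jext =)`.
#' @export
trans_input <- function(Dext = 0, Jext = 0) {
  stopifnot(is.numeric(Dext), is.numeric(Jext), Dext >= 0, Jext >= 0,
            is.finite(Dext), is.finite(Jext))
  c(Dext = Dext, Jext = Jext)
}

#' Right-hand side of the ligand-competition Notch model
#'
#' Time derivatives of `(D, J, C, N, S)` under irreversible mass-action
#' kinetics: DLL4 is lost to homodimerization (two monomers per dimer `C`),
#' to heterodimerization with JAG1 (the inert complex is not tracked), and
#' to trans-binding of neighbour Notch; homodimers cis-inhibit Notch; trans
#' DLL4 (and, at relative efficiency `alpha`, trans JAG1) releases Notch
#' activity `S`, which decays at rate `betaS`.
#'
#' @param state Named state vector as from [cell_state()].
#' @param params A [signalling_params()] object.
#' @param trans A [trans_input()] vector; `Next` is the neighbour Notch
#'   level bound in trans by this cell's ligands.
#' @param Next Free Notch presented by the neighbouring cell(s) (molecules).
#' @return Named numeric vector of derivatives (molecules/hour).
#' @export
rhs_model1 <- function(state, params, trans = trans_input(), Next = 0) {
  stopifnot(inherits(params, "signalling_params"))
  p <- params
  D <- state[["D"]]; J <- state[["J"]]; C <- state[["C"]]
  N <- state[["N"]]; S <- state[["S"]]
  Dext <- trans[["Dext"]]; Jext <- trans[["Jext"]]
  c(D = p$bD - p$beta * D - 2 * p$kho * D^2 - p$khe * J * D -
        p$kt * Next * D,
    J = p$bJ - p$beta * J - p$khe * D * J - p$alpha * p$kt * Next * J,
    C = p$kho * D^2 - p$beta * C - p$kci * N * C,
    N = p$bN - p$beta * N - p$kci * C * N - p$kt * Dext * N -
        p$alpha * p$kt * Jext * N,
    S = p$kt * Dext * N + p$alpha * p$kt * Jext * N - p$betaS * S)
}

#' Right-hand side of the Notch-VEGF model
#'
#' Extends [rhs_model1()] with VEGFR2 feedback: local free VEGF `V_local`
#' binds VEGFR2 (`R`) at rate `kv`, producing VEGFR2 activity `V`; `V`
#' upregulates DLL4 production through `hill_D`, and Notch activity `S`
#' downregulates VEGFR2 production through `hill_R` (baseline `lam_R = 0`:
#' complete shutdown at saturating `S`). With `bR = 0` and `R = V = 0` the
#' `(D, J, C, N, S)` derivatives reduce exactly to [rhs_model1()].
#'
#' @inheritParams rhs_model1
#' @param state Named state vector as from [cell_state2()] (must carry
#'   `R` and `V`).
#' @param V_local Free VEGF concentration at this cell (molecules).
#' @return Named numeric vector of derivatives (molecules/hour).
#' @export
rhs_model2 <- function(state, params, V_local, trans = trans_input(),
                       Next = 0) {
  stopifnot(inherits(params, "signalling_params"))
  if (!all(c("R", "V") %in% names(state))) {
    stop("rhs_model2(): state must contain species 'R' and 'V'",
         call. = FALSE)
  }
  stopifnot(is.numeric(V_local), V_local >= 0)
  p <- params
  D <- state[["D"]]; J <- state[["J"]]; C <- state[["C"]]
  N <- state[["N"]]; S <- state[["S"]]; R <- state[["R"]]; V <- state[["V"]]
  Dext <- trans[["Dext"]]; Jext <- trans[["Jext"]]
  # hill inputs floored at 0 so root-finders may probe slightly negative
  # iterates without leaving the model's domain
  c(D = hill(max(V, 0), p$hill_D) * p$bD - p$beta * D - 2 * p$kho * D^2 -
        p$khe * J * D - p$kt * Next * D,
    J = p$bJ - p$beta * J - p$khe * D * J - p$alpha * p$kt * Next * J,
    C = p$kho * D^2 - p$beta * C - p$kci * N * C,
    N = p$bN - p$beta * N - p$kci * C * N - p$kt * Dext * N -
        p$alpha * p$kt * Jext * N,
    S = p$kt * Dext * N + p$alpha * p$kt * Jext * N - p$betaS * S,
    R = hill(max(S, 0), p$hill_R) * p$bR - p$beta * R - p$kv * V_local * R,
    V = p$kv * V_local * R - p$betaS * V)
}

#' Right-hand side of the reversible-heterodimer variant
#'
#' Same as [rhs_model1()] except that the DLL4-JAG1 heterodimer `DJ` is an
#' explicit species with association rate `kplus`, dissociation rate
#' `kminus` and degradation rate `beta`. The `khe` field of `params` is
#' ignored here; at steady state this variant coincides with the
#' irreversible model at the effective rate
#' [reversible_equivalent_khe()]`(rev, beta)`.
#'
#' @inheritParams rhs_model1
#' @param state Named state vector as from [cell_state_rev()].
#' @param rev A [reversible_binding()] object.
#' @return Named numeric vector of derivatives (molecules/hour).
#' @export
rhs_reversible <- function(state, params, rev, trans = trans_input(),
                           Next = 0) {
  stopifnot(inherits(params, "signalling_params"),
            inherits(rev, "reversible_binding"))
  if (!"DJ" %in% names(state)) {
    stop("rhs_reversible(): state must contain species 'DJ'", call. = FALSE)
  }
  p <- params
  D <- state[["D"]]; J <- state[["J"]]; DJ <- state[["DJ"]]
  C <- state[["C"]]; N <- state[["N"]]; S <- state[["S"]]
  Dext <- trans[["Dext"]]; Jext <- trans[["Jext"]]
  assoc <- rev$kplus * D * J
  dissoc <- rev$kminus * DJ
  c(D = p$bD - p$beta * D - 2 * p$kho * D^2 - assoc + dissoc -
        p$kt * Next * D,
    J = p$bJ - p$beta * J - assoc + dissoc - p$alpha * p$kt * Next * J,
    DJ = assoc - dissoc - p$beta * DJ,
    C = p$kho * D^2 - p$beta * C - p$kci * N * C,
    N = p$bN - p$beta * N - p$kci * C * N - p$kt * Dext * N -
        p$alpha * p$kt * Jext * N,
    S = p$kt * Dext * N + p$alpha * p$kt * Jext * N - p$betaS * S)
}
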