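#' Hill regulation specification
#'
#' Describes one Hill-type transcriptional regulation,
#' \eqn{H(x) = (\lambda x^n + \theta^n) / (x^n + \theta^n)}.
#' `lam > 1` encodes upregulation, `lam < 1` downregulation and `lam = 0`
#' full shutdown at saturating input; `H` always equals 1 at `x = 0`.
#'
#' @param theta Half-saturation constant (molecules, > 0).
#' @param lam Fold change at saturation (dimensionless, >= 0).
#' @param n Hill exponent (dimensionless, > 0).
#' @return An object of class `hill_spec`.
#' @examples
#' hill(200, hill_spec(theta = 200, lam = 10, n = 2)) # (10 + 1)/2
#' @export
hill_spec <- function(theta, lam, n) {
  stopifnot(is.numeric(theta), length(theta) == 1, is.finite(theta), theta > 0)
  stopifnot(is.numeric(lam), length(lam) == 1, is.finite(lam), lam >= 0)
  stopifnot(is.numeric(n), length(n) == 1, is.finite(n), n > 0)
  structure(list(theta = theta, lam = lam, n = n), class = "hill_spec")
}

#' Evaluate a Hill regulation function
#'
#' @param x Nonnegative input level (molecules); vectorised.
#' @param spec A [hill_spec()].
#' @return `(lam * x^n + theta^n) / (x^n + theta^n)`, which lies in
#'   `[min(1, lam), max(1, lam)]` for all `x >= 0`.
#' @export
hill <- function(x, spec) {
  stopifnot(inherits(spec, "hill_spec"), is.numeric(x), all(is.finite(x)))
  if (any(x < 0)) stop("hill(): `x` must be nonnegative", call. = FALSE)
  xn <- x^spec$n
  tn <- spec$theta^spec$n
  (spec$lam * xn + tn) / (xn + tn)
}

#' Parameter set for the ligand-competition signalling models
#'
#' Constructs the full rate-constant set shared by the ligand-competition
#' model (free DLL4 `D`, free JAG1 `J`, DLL4 homodimer `C`, Notch receptor
#' `N`, Notch activity `S`) and its VEGF extension (additionally VEGFR2 `R`
#' and VEGFR2 activity `V`). The defaults are the baseline values used in
#' all simulations; call `signalling_params()` with no arguments to obtain
#' exactly that baseline. Units are molecules per cell and hours.
#'
#' @param bD,bJ,bN,bR Production rates of DLL4, JAG1, Notch1 and VEGFR2
#'   (molecules/hour, >= 0).
#' @param beta Degradation rate of ligands, receptors and dimers (1/hour).
#' @param betaS Degradation rate of the free intracellular signals `S`
#'   (Notch intracellular domain) and `V` (VEGFR2 activity) (1/hour).
#' @param kho DLL4 homodimerization rate (1/(molecule hour)).
#' @param khe DLL4-JAG1 heterodimerization rate (1/(molecule hour)); set to
#'   0 to remove ligand heterodimerization.
#' @param kt Trans-activation rate of Notch1 by DLL4 (1/(molecule hour)).
#' @param kci Cis-inhibition rate of Notch1 by DLL4 homodimers
#'   (1/(molecule hour)).
#' @param kv VEGF-VEGFR2 binding rate (1/(molecule hour)).
#' @param alpha Ratio of trans JAG1-Notch1 to DLL4-Notch1 activation
#'   efficiency, in `[0, 1]`; `alpha = 0` makes trans-JAG1 inert.
#' @param hill_D Hill regulation of DLL4 production by VEGFR2 activity.
#' @param hill_R Hill regulation of VEGFR2 production by Notch activity
#'   (`lam = 0` by default: Notch signalling shuts VEGFR2 production down).
#' @param Vext_base Free VEGF at the angiogenic front (molecules).
#' @return An object of class `signalling_params`.
#' @examples
#' p <- signalling_params()        # baseline
#' p2 <- signalling_params(khe = 0) # no heterodimerization
#' @export
signalling_params <- function(bD = 100, bJ = 100, bN = 500, bR = 800,
                              beta = 0.1, betaS = 0.5,
                              kho = 1e-4, khe = 1e-3, kt = 5e-5,
                              kci = 6e-4, kv = 5e-5, alpha = 1e-4,
                              hill_D = hill_spec(theta = 200, lam = 10, n = 2),
                              hill_R = hill_spec(theta = 30, lam = 0, n = 2),
                              Vext_base = 2500) {
  rates <- c(bD = bD, bJ = bJ, bN = bN, bR = bR, kho = kho, khe = khe,
             kt = kt, kci = kci, kv = kv, Vext_base = Vext_base)
  if (!all(is.finite(rates)) || any(rates < 0)) {
    stop("signalling_params(): all rates must be finite and nonnegative",
         call. = FALSE)
  }
  stopifnot(is.finite(beta), beta > 0, is.finite(betaS), betaS > 0)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("signalling_params(): `alpha` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(hill_D, "hill_spec"), inherits(hill_R, "hill_spec"))
  structure(
    list(bD = bD, bJ = bJ, bN = bN, bR = bR, beta = beta, betaS = betaS,
         kho = kho, khe = khe, kt = kt, kci = kci, kv = kv, alpha = alpha,
         hill_D = hill_D, hill_R = hill_R, Vext_base = Vext_base),
    class = "signalling_params"
  )
}

#' @export
print.signalling_params <- function(x, ...) {
  cat("<signalling_params>\n")
  num <- vapply(x[!vapply(x, inherits, TRUE, "hill_spec")], identity, 0)
  cat(paste0("  ", names(num), " = ", signif(num, 6), collapse = "\n"), "\n")
  cat(sprintf("  hill_D: theta=%g lam=%g n=%g\n",
              x$hill_D$theta, x$hill_D$lam, x$hill_D$n))
  cat(sprintf("  hill_R: theta=%g lam=%g n=%g\n",
              x$hill_R$theta, x$hill_R$lam, x$hill_R$n))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named scalar fields replaced.
#' Hill-shape fields are addressed as `theta_D`, `lam_D`, `n_D`,
#' `theta_R`, `lam_R`, `n_R`.
#'
#' @param params A [signalling_params()] object.
#' @param ... Named replacements, e.g. `update_params(p, khe = 0, bD = 50)`.
#' @return A validated `signalling_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "signalling_params"))
  repl <- list(...)
  if (length(repl) == 0) return(params)
  if (is.null(names(repl)) || any(names(repl) == "")) {
    stop("update_params(): replacements must be named", call. = FALSE)
  }
  hd <- params$hill_D; hr <- params$hill_R
  scalar <- setdiff(names(params), c("hill_D", "hill_R"))
  args <- params[scalar]
  for (nm in names(repl)) {
    val <- repl[[nm]]
    if (nm %in% scalar) {
      args[[nm]] <- val
    } else if (nm %in% c("theta_D", "lam_D", "n_D")) {
      hd[[sub("_D$", "", nm)]] <- val
    } else if (nm %in% c("theta_R", "lam_R", "n_R")) {
      hr[[sub("_R$", "", nm)]] <- val
    } else {
      stop(sprintf("update_params(): unknown parameter '%s'", nm),
           call. = FALSE)
    }
  }
  do.call(signalling_params,
          c(args, list(hill_D = hill_spec(hd$theta, hd$lam, hd$n),
                       hill_R = hill_spec(hr$theta, hr$lam, hr$n))))
}

#' Reversible DLL4-JAG1 binding parameters
#'
#' Association/dissociation rates for the variant of the ligand model in
#' which the DLL4-JAG1 heterodimer `DJ` is an explicit species that can
#' dissociate back into monomers.
#'
#' @param kplus Association rate of `D + J -> DJ` (1/(molecule hour)).
#' @param kminus Dissociation rate of `DJ -> D + J` (1/hour).
#' @return An object of class `reversible_binding`.
#' @seealso [reversible_equivalent_khe()] for the effective irreversible
#'   heterodimerization rate of the matching steady state.
#' @export
reversible_binding <- function(kplus, kminus) {
  stopifnot(is.numeric(kplus), length(kplus) == 1, is.finite(kplus),
            kplus >= 0,
            is.numeric(kminus), length(kminus) == 1, is.finite(kminus),
            kminus >= 0)
  structure(list(kplus = kplus, kminus = kminus),
            class = "reversible_binding")
}
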