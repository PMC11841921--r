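#' Build a cell lattice
#'
#' Constructs either a hexagonal sheet (pointy-top regular hexagons of
#' side 1, odd rows offset by half a cell, so row centres are 1.5 apart
#' vertically and sqrt(3) apart horizontally) or a one-dimensional line of
#' cells. Rows are numbered from the front (`row = 1` is the lowest `y`,
#' the angiogenic front). Adjacency is the set of touching hexagons
#' (interior cells have 6 neighbours) or the chain neighbours for a line
#' (at most 2).
#'
#' @param geometry `"hex"` or `"line"`.
#' @param n_rows,n_cols Grid dimensions (`n_rows` is forced to 1 for
#'   lines).
#' @return An object of class `notch_lattice`: list with `geometry`,
#'   `n_rows`, `n_cols`, `n_cells`, a `cells` tibble (`cell`, `row`,
#'   `col`, `x`, `y`), `neighbours` (list of integer vectors), `slots`
#'   (the full neighbour-slot count: 6 for hex, 2 for line), and empty
#'   per-cell fields `bD_cell`, `bJ_cell`, `dext_add`, `jext_add`, `vegf`.
#' @examples
#' lat <- build_lattice("hex", 3, 3)
#' lengths(lat$neighbours)[5] # centre cell touches 6 others
#' @export
build_lattice <- function(geometry = c("hex", "line"), n_rows = 1,
                          n_cols = 10) {
  geometry <- match.arg(geometry)
  stopifnot(n_rows >= 1, n_cols >= 1)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (geometry == "line") n_rows <- 1L
  cells <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  if (geometry == "hex") {
    cells <- dplyr::mutate(
      cells,
      x = sqrt(3) * (.data$col - 1) + ifelse(.data$row %% 2 == 0,
                                             sqrt(3) / 2, 0),
      y = 1.5 * (.data$row - 1))
  } else {
    cells <- dplyr::mutate(cells, x = sqrt(3) * (.data$col - 1), y = 0)
  }
  cells <- dplyr::mutate(cells, cell = dplyr::row_number(),
                         .before = "row")
  idx <- matrix(cells$cell, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  at <- function(r, c) {
    if (r < 1 || r > n_rows || c < 1 || c > n_cols) NA_integer_
    else idx[r, c]
  }
  neighbours <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- cells$row[i]; cc <- cells$col[i]
    nb <- if (geometry == "line") {
      c(at(1, cc - 1), at(1, cc + 1))
    } else {
      # odd rows sit left, even rows are offset right by half a cell
      off <- if (r %% 2 == 0) c(0L, 1L) else c(-1L, 0L)
      c(at(r, cc - 1), at(r, cc + 1),
        at(r - 1, cc + off[1]), at(r - 1, cc + off[2]),
        at(r + 1, cc + off[1]), at(r + 1, cc + off[2]))
    }
    neighbours[[i]] <- nb[!is.na(nb)]
  }
  n <- nrow(cells)
  structure(
    list(geometry = geometry, n_rows = n_rows, n_cols = n_cols,
         n_cells = n, cells = cells, neighbours = neighbours,
         slots = if (geometry == "hex") 6L else 2L,
         bD_cell = NULL, bJ_cell = NULL,
         dext_add = numeric(n), jext_add = numeric(n),
         vegf = NULL),
    class = "notch_lattice"
  )
}

#' @export
print.notch_lattice <- function(x, ...) {
  cat(sprintf("<notch_lattice> %s, %d x %d (%d cells)\n", x$geometry,
              x$n_rows, x$n_cols, x$n_cells))
  invisible(x)
}

#' VEGF field specification
#'
#' An exponentially decaying VEGF field,
#' `V(y) = Vext * exp(-a * (y - y0))`, evaluated at each cell-centre `y`.
#' `y0` is the vertical coordinate of the first-row cell centres, so the
#' front row sees exactly `Vext`; behind it the field decays with
#' sharpness `a`. Line lattices represent the growing front itself and
#' receive the uniform level `Vext`.
#'
#' @param Vext Free VEGF at the front (molecules, >= 0).
#' @param a Gradient sharpness (1/hexagon-side, >= 0; `a = 0` gives a
#'   uniform field).
#' @param y0 Vertical coordinate of the first-row cell centres.
#' @return An object of class `vegf_spec`.
#' @export
vegf_spec <- function(Vext = 2500, a = 1, y0 = 0) {
  stopifnot(is.numeric(Vext), Vext >= 0, is.numeric(a), a >= 0,
            is.numeric(y0))
  structure(list(Vext = Vext, a = a, y0 = y0), class = "vegf_spec")
}

#' Evaluate a VEGF field on a lattice
#'
#' @param lattice A [build_lattice()] object.
#' @param spec A [vegf_spec()].
#' @return Numeric vector of per-cell free-VEGF levels (molecules).
#' @export
vegf_field <- function(lattice, spec = vegf_spec()) {
  stopifnot(inherits(lattice, "notch_lattice"), inherits(spec, "vegf_spec"))
  if (lattice$geometry == "line") {
    return(rep(spec$Vext, lattice$n_cells))
  }
  spec$Vext * exp(-spec$a * (lattice$cells$y - spec$y0))
}

#' Trans-ligand inputs from neighbour averaging
#'
#' Computes the trans DLL4/JAG1 each cell sees: the average of the free
#' ligand over the cell's neighbour slots plus any engineered external
#' addition. Under the default `"slots"` boundary rule every cell divides
#' by its full slot count (6 for hex, 2 for line) and off-lattice slots
#' contribute zero ligand (Dirichlet boundary); `"truncate"` divides by the
#' realized neighbour count instead.
#'
#' @param lattice A [build_lattice()] object (its `dext_add`/`jext_add`
#'   fields are added to the averages).
#' @param states Matrix of per-cell states (rows = cells) with columns
#'   including `D` and `J`, or a data frame with those columns.
#' @param boundary `"slots"` (default) or `"truncate"`.
#' @return A tibble with columns `cell`, `Dext`, `Jext`.
#' @export
trans_inputs <- function(lattice, states, boundary = c("slots", "truncate")) {
  stopifnot(inherits(lattice, "notch_lattice"))
  boundary <- match.arg(boundary)
  states <- as.matrix(states[, c("D", "J"), drop = FALSE])
  stopifnot(nrow(states) == lattice$n_cells)
  div <- if (boundary == "slots") rep(lattice$slots, lattice$n_cells)
         else pmax(lengths(lattice$neighbours), 1L)
  sums <- t(vapply(lattice$neighbours, function(nb) {
    if (length(nb) == 0) c(0, 0) else colSums(states[nb, , drop = FALSE])
  }, c(D = 0, J = 0)))
  tibble::tibble(cell = lattice$cells$cell,
                 Dext = unname(sums[, "D"]) / div + lattice$dext_add,
                 Jext = unname(sums[, "J"]) / div + lattice$jext_add)
}

#' Per-cell production-rate ramps and external-ligand stripes
#'
#' `set_production_ramp()` assigns a linear per-cell ramp of a ligand
#' production rate along the lattice's long axis (column order for lines,
#' row order for sheets). `add_ligand_stripes()` adds engineered external
#' trans-ligand to the named cells, ramping linearly from `from` to `to`
#' along the stripe in cell order.
#'
#' @param lattice A [build_lattice()] object.
#' @param param `"bD"` or `"bJ"`.
#' @param from,to Endpoints of the linear ramp (molecules/hour for
#'   production rates, molecules for external ligand).
#' @param species `"D"` or `"J"`: which external trans-ligand to add.
#' @param cells Integer vector of cell indices forming the stripe(s).
#' @return The modified lattice.
#' @export
set_production_ramp <- function(lattice, param = c("bD", "bJ"), from, to) {
  stopifnot(inherits(lattice, "notch_lattice"), from >= 0, to >= 0)
  param <- match.arg(param)
  axis <- if (lattice$geometry == "line") lattice$cells$col
          else lattice$cells$row
  frac <- if (max(axis) == 1) rep(0, length(axis))
          else (axis - 1) / (max(axis) - 1)
  lattice[[paste0(param, "_cell")]] <- from + frac * (to - from)
  lattice
}

#' @rdname set_production_ramp
#' @export
add_ligand_stripes <- function(lattice, species = c("D", "J"), cells,
                               from = 0, to = 200) {
  stopifnot(inherits(lattice, "notch_lattice"),
            all(cells %in% lattice$cells$cell), from >= 0, to >= 0)
  species <- match.arg(species)
  cells <- sort(unique(as.integer(cells)))
  ramp <- if (length(cells) == 1) (from + to) / 2
          else from + (seq_along(cells) - 1) / (length(cells) - 1) * (to - from)
  field <- if (species == "D") "dext_add" else "jext_add"
  lattice[[field]][cells] <- lattice[[field]][cells] + ramp
  lattice
}
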