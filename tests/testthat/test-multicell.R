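test_that("lattice geometry and adjacency are as constructed", {
  lat <- build_lattice("hex", 3, 3)
  deg <- lengths(lat$neighbours)
  expect_equal(deg[5], 6L) # interior cell touches all six slots
  expect_true(all(deg <= 6))
  # adjacency is symmetric
  for (i in seq_len(lat$n_cells)) {
    for (j in lat$neighbours[[i]]) {
      expect_true(i %in% lat$neighbours[[j]])
    }
  }
  # row spacing 1.5, column spacing sqrt(3) (hexagon side 1)
  expect_equal(unique(diff(sort(unique(lat$cells$y)))), 1.5)
  r1 <- dplyr::filter(lat$cells, row == 1)
  expect_equal(unique(diff(r1$x)), sqrt(3))
  # neighbours are geometrically touching (centre distance sqrt(3))
  for (j in lat$neighbours[[5]]) {
    d <- with(lat$cells, sqrt((x[5] - x[j])^2 + (y[5] - y[j])^2))
    expect_equal(d, sqrt(3))
  }

  line <- build_lattice("line", 1, 2)
  expect_equal(lengths(line$neighbours), c(1L, 1L))
  expect_error(build_lattice("hex", 0, 3))
})

test_that("VEGF field decays exponentially from the front row", {
  lat <- build_lattice("hex", 4, 3)
  v <- vegf_field(lat, vegf_spec(Vext = 2500, a = 1, y0 = 0))
  expect_equal(v[lat$cells$row == 1], rep(2500, 3))
  # one hexagon side behind the front: 2500 / e at y = y0 + 1
  expect_equal(2500 * exp(-1), 919.6986, tolerance = 1e-6)
  expect_equal(unique(v[lat$cells$row == 2]), 2500 * exp(-1.5))
  expect_equal(vegf_field(lat, vegf_spec(2500, a = 0)), rep(2500, 12))
  # lines are front cells: uniform Vext
  expect_equal(vegf_field(build_lattice("line", 1, 5),
                          vegf_spec(2500, a = 1)),
               rep(2500, 5))
})

test_that("trans inputs average neighbours with Dirichlet boundaries", {
  line <- build_lattice("line", 1, 2)
  st <- cbind(D = c(100, 40), J = c(10, 20))
  ti <- trans_inputs(line, st) # 2 slots each, one off-lattice
  expect_equal(ti$Dext, c(20, 50))
  expect_equal(ti$Jext, c(10, 5))
  tt <- trans_inputs(line, st, boundary = "truncate")
  expect_equal(tt$Dext, c(40, 100))
  # an isolated cell sees nothing
  single <- build_lattice("line", 1, 1)
  t1 <- trans_inputs(single, cbind(D = 5, J = 5))
  expect_equal(c(t1$Dext, t1$Jext), c(0, 0))
  # engineered stripes add on top of the average
  striped <- add_ligand_stripes(line, "J", cells = 1:2, from = 200,
                                to = 200)
  ts <- trans_inputs(striped, cbind(D = c(0, 0), J = c(0, 0)))
  expect_equal(ts$Jext, c(200, 200))
  # interior hex cell averages its six neighbours
  hex <- build_lattice("hex", 3, 3)
  sth <- cbind(D = 1:9, J = rep(0, 9))
  th <- trans_inputs(hex, sth)
  expect_equal(th$Dext[5], sum(sth[hex$neighbours[[5]], "D"]) / 6)
})

test_that("tip/stalk classification uses the population midpoint", {
  expect_equal(classify_tip_stalk(cbind(V = c(4000, 50))),
               c("tip", "stalk"))
  expect_equal(classify_tip_stalk(cbind(V = c(10, 11, 1000))),
               c("stalk", "stalk", "tip"))
  expect_equal(classify_tip_stalk(cbind(V = rep(7, 4))),
               rep("uniform", 4))
})

test_that("pattern metrics quantify front-row alternation", {
  line <- build_lattice("line", 1, 10)
  strict <- rep(c("tip", "stalk"), 5)
  pm <- pattern_metrics(strict, line)
  expect_equal(pm$front_alternation_index, 1)
  expect_equal(pm$tip_fraction, 0.5)
  expect_equal(pattern_metrics(rep("stalk", 10),
                               line)$front_alternation_index, 0)
  # independent fair-coin labels alternate half the time on average
  idx <- vapply(1:200, function(s) {
    lab <- withr::with_seed(s, sample(c("tip", "stalk"), 10,
                                      replace = TRUE))
    pattern_metrics(lab, line)$front_alternation_index
  }, 0)
  expect_equal(mean(idx), 0.5, tolerance = 0.1)
})

test_that("tissue simulation is deterministic and symmetry-preserving", {
  lat <- build_lattice("hex", 4, 4)
  s1 <- simulate_tissue(lat, baseline, model = 2, seed = 7, t_end = 150,
                        vegf = vegf_spec(2500, a = 1))
  s2 <- simulate_tissue(lat, baseline, model = 2, seed = 7, t_end = 150,
                        vegf = vegf_spec(2500, a = 1))
  expect_identical(s1$final, s2$final) # bit-identical given the seed
  s3 <- simulate_tissue(lat, baseline, model = 2, seed = 8, t_end = 150,
                        vegf = vegf_spec(2500, a = 1))
  expect_false(identical(s1$final$V, s3$final$V))

  # identical cells + identical (non-random) init + uniform field +
  # truncated averaging (slot-averaging breaks boundary symmetry by
  # design): the uniform trajectory is preserved exactly
  init <- matrix(rep(c(10, 20, 5, 50, 2, 30, 8), each = lat$n_cells),
                 nrow = lat$n_cells)
  su <- simulate_tissue(lat, baseline, model = 2, init = init,
                        t_end = 100, vegf = vegf_spec(2500, a = 0),
                        boundary = "truncate")
  sp <- as.matrix(su$final[, c("D", "J", "C", "N", "S", "R", "V")])
  expect_equal(max(apply(sp, 2, function(col) diff(range(col)))), 0)

  # mirror symmetry on a line: reversing the initial condition reverses
  # the final state
  line <- build_lattice("line", 1, 6)
  init6 <- withr::with_seed(3, matrix(runif(6 * 7, 0, 100), 6, 7))
  a <- simulate_tissue(line, baseline, model = 2, init = init6,
                       t_end = 120)
  b <- simulate_tissue(line, baseline, model = 2, init = init6[6:1, ],
                       t_end = 120)
  am <- as.matrix(a$final[, c("D", "J", "S", "V")])
  bm <- as.matrix(b$final[, c("D", "J", "S", "V")])
  expect_equal(am, bm[6:1, ], tolerance = 1e-12)
})

test_that("the compiled lattice path matches the R integrator", {
  # 2-cell line with truncated averaging == pure pairwise coupling
  for (model in c(1, 2)) {
    ns <- if (model == 2) 7 else 5
    line <- build_lattice("line", 1, 2)
    init <- withr::with_seed(11, matrix(runif(2 * ns, 0, 100), 2, ns))
    sim <- simulate_tissue(line, baseline, model = model, init = init,
                           boundary = "truncate", t_end = 25,
                           vegf = vegf_spec(2500, a = 0),
                           steady_tol = 0)
    rhs <- two_cell_rhs(baseline, model)
    x0 <- stats::setNames(c(init[1, ], init[2, ]),
                          paste0("x", seq_len(2 * ns)))
    tr <- rk4_integrate(rhs, x0, h = 0.01, t_end = 25, steady_tol = 0)
    sp <- c("D", "J", "C", "N", "S", "R", "V")[seq_len(ns)]
    got <- as.matrix(sim$final[, sp])
    want <- rbind(tr$final_state[1:ns], tr$final_state[ns + 1:ns])
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("engineered trans-JAG1 is inert at alpha = 0, trans-DLL4 is not", {
  p0 <- update_params(baseline, alpha = 0)
  line <- build_lattice("line", 1, 12)
  init <- withr::with_seed(5, matrix(runif(12 * 7, 0, 100), 12, 7))
  plain <- simulate_tissue(line, p0, model = 2, init = init, t_end = 600)
  jlat <- add_ligand_stripes(line, "J", cells = 4:9, from = 0, to = 200)
  jsim <- simulate_tissue(jlat, p0, model = 2, init = init, t_end = 600)
  expect_equal(jsim$final$V, plain$final$V, tolerance = 1e-6)
  # strong trans-DLL4 stripes suppress VEGFR2 activity in stripe cells
  dlat <- add_ligand_stripes(line, "D", cells = 4:9, from = 2000,
                             to = 2000)
  dsim <- simulate_tissue(dlat, p0, model = 2, init = init, t_end = 600)
  expect_lt(max(dsim$final$V[4:9]), 0.2 * max(plain$final$V[4:9]))
})

test_that("patterned fronts anticorrelate the ligands and order tip vs stalk", {
  sim <- simulate_tissue(build_lattice("hex", 10, 10), baseline,
                         model = 2, vegf = vegf_spec(2500, a = 1),
                         seed = 1)
  expect_true(sim$converged)
  front <- dplyr::filter(sim$final, row == 1)
  # free DLL4 and free JAG1 are strongly anticorrelated along the front
  expect_lt(stats::cor(front$D, front$J), -0.8)
  tips <- dplyr::filter(front, label == "tip")
  stalks <- dplyr::filter(front, label == "stalk")
  expect_gt(nrow(tips), 0)
  # tip cells: DLL4 dominates JAG1 outright
  expect_true(all(tips$J < 0.1 * tips$D))
  # tips carry more DLL4, less Notch activity than every front stalk cell
  expect_gt(min(tips$D), max(stalks$D))
  expect_lt(max(tips$S), min(stalks$S))
  expect_gt(min(tips$V), max(stalks$V))
})

test_that("tissue tidiers expose per-cell results", {
  sim <- simulate_tissue(build_lattice("hex", 3, 3), baseline, model = 2,
                         seed = 2, t_end = 80, record_every = 2000L)
  expect_named(glance(sim),
               c("model", "geometry", "n_cells", "t_final", "converged",
                 "final_residual", "tip_fraction",
                 "front_alternation_index"))
  expect_equal(nrow(tidy(sim)), 9)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_true(all(c("time_h", "cell", "species", "level") %in%
                    names(sim$trajectory)))
})
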