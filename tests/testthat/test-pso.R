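test_that("window composition counts residues and non-straddling CpGs", {
  w <- window_composition("ACGT", 0, 4)
  expect_equal(w[c("a_count", "c_count", "g_count", "t_count", "cpg_count")],
               list(a_count = 1L, c_count = 1L, g_count = 1L, t_count = 1L,
                    cpg_count = 1L))
  w <- window_composition("CGCG", 0, 3)
  expect_equal(w$c_count, 2L)
  expect_equal(w$g_count, 1L)
  expect_equal(w$cpg_count, 1L)  # second CG straddles the window end
  w <- window_composition("NNNN", 0, 4)
  expect_equal(w$a_count + w$c_count + w$g_count + w$t_count, 0L)
  expect_equal(w$window_length, 4L)
  expect_error(window_composition("ACGT", 3, 2), "bounds")
})

test_that("window composition agrees with direct substring counting", {
  set.seed(11)
  s <- random_dna(500)
  for (i in 1:50) {
    a <- sample(0:498, 1)
    b <- sample((a + 1):500, 1)
    w <- window_composition(s, a, b)
    sub <- substr(s, a + 1, b)
    expect_equal(w$c_count, lengths(regmatches(sub, gregexpr("C", sub))))
    expect_equal(w$cpg_count,
                 lengths(regmatches(sub, gregexpr("CG", sub))))
  }
})

test_that("GC content and O/E ratio follow their definitions", {
  expect_equal(gc_content(window_composition("CCGG", 0, 4)), 1.0)
  expect_equal(gc_content(window_composition("ACGT", 0, 4)), 0.5)
  expect_equal(gc_content(window_composition("AATT", 0, 4)), 0.0)
  expect_equal(gc_content(window_composition("NNNN", 0, 4)), 0)

  expect_equal(oe_ratio(window_composition("ACGT", 0, 4)), 4.0)
  expect_equal(oe_ratio(window_composition(cg_repeat(200), 0, 400)), 2.0)
  expect_equal(oe_ratio(window_composition("AATT", 0, 4)), 0.0)
})

test_that("normalized length is the window fraction of its region", {
  region <- list(start = 0L, end = 400L)
  expect_equal(normalized_length(400, region), 1.0)
  expect_equal(normalized_length(200, region), 0.5)
  expect_equal(normalized_length(200, list(start = 0L, end = 697L)),
               200 / 697)
})

test_that("fitness sums the three terms for feasible windows only", {
  s <- cg_repeat(200)
  region <- list(start = 0L, end = 400L)
  expect_equal(island_fitness(s, 0, 400, region), 4.0)
  expect_equal(island_fitness(s, 0, 100, region), -Inf)  # too short
  expect_equal(island_fitness(paste(rep("A", 400), collapse = ""),
                              0, 400, region), -Inf)
})

test_that("inertia weight is affine with the stated endpoints", {
  expect_equal(inertia_weight(0, 100), 0.9)
  expect_equal(inertia_weight(100, 100), 0.4)
  expect_equal(inertia_weight(50, 100), 0.65)
  mv <- 0:100
  w <- inertia_weight(mv, 100)
  expect_equal(diff(w), rep(-0.005, 100))
})

make_swarm <- function(fs, fl, vfs = 0, vfl = 0, fit = -Inf,
                       pb_fs = fs, pb_fl = fl, pb_fit = fit,
                       gb_fs = NA, gb_fl = NA, gb_fit = -Inf) {
  list(Fs = as.integer(fs), Fl = as.integer(fl),
       vFs = vfs, vFl = vfl, fit = fit,
       pb_Fs = as.integer(pb_fs), pb_Fl = as.integer(pb_fl), pb_fit = pb_fit,
       gb_Fs = gb_fs, gb_Fl = gb_fl, gb_fit = gb_fit, generation = 0L)
}

test_that("a particle at rest on its own best stays stationary", {
  s <- cg_repeat(300)
  region <- list(start = 0L, end = 600L)
  f0 <- island_fitness(s, 100, 300, region)
  sw <- make_swarm(100, 300, fit = f0, pb_fit = f0,
                   gb_fs = 100L, gb_fl = 300L, gb_fit = f0)
  out <- step_swarm(sw, s, region, pso_params(population = 1), move_i = 1)
  expect_equal(out$Fs, 100L)
  expect_equal(out$Fl, 300L)
  expect_equal(out$vFs, 0)
  expect_equal(out$vFl, 0)
})

test_that("with r1 = r2 = 0 the velocity reduces to pure inertia", {
  s <- cg_repeat(300)
  region <- list(start = 0L, end = 600L)
  sw <- make_swarm(100, 250, vfs = 10, vfl = -6,
                   pb_fs = 50, pb_fl = 220, pb_fit = 2,
                   gb_fs = 300L, gb_fl = 240L, gb_fit = 3)
  zero <- list(r1s = 0, r2s = 0, r1l = 0, r2l = 0)
  params <- pso_params(population = 1, max_generations = 100)
  out <- step_swarm(sw, s, region, params, move_i = 50, rand = zero)
  w <- inertia_weight(50, 100)
  expect_equal(out$vFs, w * 10)
  expect_equal(out$vFl, w * -6)
  expect_equal(out$Fs, as.integer(round(100 + w * 10)))
  expect_equal(out$Fl, as.integer(round(250 + w * -6)))
})

test_that("one hand-traced velocity/position update matches the formulas", {
  # x = (100, 250), v = (4, -2), pbest = (90, 260), gbest = (120, 230),
  # move_i = 25 of 100 so w = 0.775, c1 = c2 = 2,
  # r1 = (0.5, 0.25), r2 = (0.1, 0.75)
  s <- cg_repeat(300)
  region <- list(start = 0L, end = 600L)
  sw <- make_swarm(100, 250, vfs = 4, vfl = -2,
                   pb_fs = 90, pb_fl = 260, pb_fit = 2,
                   gb_fs = 120L, gb_fl = 230L, gb_fit = 3)
  rand <- list(r1s = 0.5, r2s = 0.1, r1l = 0.25, r2l = 0.75)
  out <- step_swarm(sw, s, region, pso_params(population = 1),
                    move_i = 25, rand = rand)
  v_fs <- 0.775 * 4 + 2 * 0.5 * (90 - 100) + 2 * 0.1 * (120 - 100)  # -2.9
  v_fl <- 0.775 * -2 + 2 * 0.25 * (260 - 250) + 2 * 0.75 * (230 - 250)
  expect_equal(out$vFs, v_fs)
  expect_equal(out$vFl, v_fl)                        # -26.55
  expect_equal(out$Fl, as.integer(round(250 + v_fl)))  # clamped inside
  expect_equal(out$Fs, as.integer(round(100 + v_fs)))
})

test_that("positions stay inside the region and pbest never decreases", {
  set.seed(5)
  s <- paste0(random_dna(150), cg_repeat(150), random_dna(150))
  region <- list(start = 0L, end = 600L)
  params <- pso_params(population = 40, max_generations = 30)
  set.seed(99)
  idx <- sequence_index(s)
  sw <- cpgswarm:::init_swarm(idx, region, params, 200, 0.5, 0.6)
  prev_pb <- sw$pb_fit
  prev_gb <- sw$gb_fit
  for (g in 1:30) {
    sw <- step_swarm(sw, idx, region, params, move_i = g)
    expect_true(all(sw$Fs >= region$start))
    expect_true(all(sw$Fs + sw$Fl <= region$end))
    expect_true(all(sw$Fl >= 1))
    expect_true(all(sw$pb_fit >= prev_pb))
    expect_gte(sw$gb_fit, prev_gb)
    expect_equal(sw$gb_fit, max(sw$pb_fit))
    prev_pb <- sw$pb_fit
    prev_gb <- sw$gb_fit
  }
})

test_that("swarm returns nothing when no feasible window exists", {
  s <- paste(rep("A", 600), collapse = "")
  region <- list(start = 0L, end = 600L)
  expect_null(run_pso(s, region, pso_params(population = 20,
                                            max_generations = 10),
                      seed = 1))
  # region narrower than the minimum island length: trivially no call
  expect_null(run_pso(cg_repeat(50), list(start = 0L, end = 100L),
                      pso_params(), seed = 1))
})

test_that("swarm finds a GGF-compliant block and the call satisfies GGF", {
  set.seed(3)
  s <- paste0(random_dna(150, c(A = .45, C = .05, G = .05, T = .45)),
              cg_repeat(150),
              random_dna(150, c(A = .45, C = .05, G = .05, T = .45)))
  region <- list(start = 0L, end = 600L)
  call <- run_pso(s, region, pso_params(population = 100,
                                        max_generations = 50), seed = 7)
  expect_false(is.null(call))
  expect_gte(call$length, 200)
  expect_gte(call$gc, 0.5)
  expect_gte(call$oe, 0.6)
  expect_gte(call$start, region$start)
  expect_lte(call$end, region$end)
})

test_that("identical seed and input give bit-identical calls", {
  set.seed(21)
  s <- paste0(random_dna(100), cg_repeat(200), random_dna(100))
  region <- list(start = 0L, end = 600L)
  a <- run_pso(s, region, pso_params(population = 50,
                                     max_generations = 20), seed = 123)
  b <- run_pso(s, region, pso_params(population = 50,
                                     max_generations = 20), seed = 123)
  expect_identical(a, b)
})

test_that("gbest trace is monotonically non-decreasing", {
  set.seed(8)
  s <- paste0(random_dna(100), cg_repeat(200), random_dna(100))
  region <- list(start = 0L, end = 600L)
  call <- run_pso(s, region, pso_params(population = 50,
                                        max_generations = 40),
                  seed = 5, trace = TRUE)
  tr <- attr(call, "trace")
  expect_length(tr, 40)
  expect_true(all(diff(tr[is.finite(tr)]) >= 0))
})
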