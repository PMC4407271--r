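test_that("input validation rejects impossible models and sizes", {
  expect_error(sim_model(1e6, -0.1), "non-negative")
  expect_error(sim_model(1e6, 0.1, nu = 0), "positive")
  expect_error(sim_model(1e6, 0.1, escape_fraction = 1.2), "0, 1")
  expect_error(sim_model(1e6, 0.1,
                         region_modifiers = list(c(10, 5, 1))), "start")
  expect_error(sim_model(1e6, map_points = data.frame(bp = c(0, 1e6),
                                                      morgan = c(0.2, 0.1))),
               "non-decreasing")
  mod <- sim_model(1e6, 0.1)
  expect_error(simulate_meioses(mod, 0), "positive count")
  expect_error(simulate_f2_population(mod, two_marker_layout("seed"),
                                      data.frame(chrom = "1", pos_bp = 1e5),
                                      n_individuals = 0), "positive count")
  expect_error(simulate_f2_population(mod, two_marker_layout("seed"),
                                      data.frame(chrom = character(0),
                                                 pos_bp = numeric(0)),
                                      n_individuals = 5), "empty marker")
  expect_error(simulate_tetrad_counts(mod, two_marker_layout("pollen2"), 10),
               "tetrad layout")
  expect_error(simulate_pollen_two_colour(mod, two_marker_layout("pollen2"),
                                          10, artifact_fraction = 1), "0, 1")
})

test_that("region modifiers rescale local map density", {
  # doubling density on half the chromosome adds half the base map again
  mod <- sim_model(1e6, 0.1,
                   region_modifiers = list(c(0, 5e5, 2)))
  expect_equal(total_morgan(mod), 0.15)
  expect_equal(bp_to_morgan(mod, 5e5), 0.10)
  # zero factor flattens the map inside the window
  mod0 <- sim_model(1e6, 0.1, region_modifiers = list(c(0, 5e5, 0)))
  expect_equal(bp_to_morgan(mod0, 5e5), 0)
  expect_equal(total_morgan(mod0), 0.05)
})

test_that("recombinant chromatid fraction matches the Haldane expectation under Poisson placement", {
  d <- 0.05
  mod <- sim_model(1e6, d, nu = 1, rng_seed = 101)
  sim <- simulate_meioses(mod, 4e4)
  A <- chromatid_origins(sim, bp_to_morgan(mod, 1))
  B <- chromatid_origins(sim, bp_to_morgan(mod, 1e6))
  rec <- A != B
  per_meiosis <- rowMeans(rec)
  se <- sd(per_meiosis) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec) - haldane_r(d)), 3 * se)
})

test_that("a single crossover makes exactly two recombinant chromatids for every strand pair", {
  # exhaustive enumeration over the four non-sister strand-pair choices
  mod <- sim_model(1e6, 0.1)
  for (a in 1:2) for (b in 3:4) {
    sim <- structure(list(
      events = data.frame(meiosis = 1L, pos = 0.05, sa = a, sb = b,
                          pos_bp = 5e5),
      n = 1L, model = mod), class = "ftl_meioses")
    left <- chromatid_origins(sim, 0)
    right <- chromatid_origins(sim, 0.1)
    expect_identical(sum(left != right), 2L)
    # reciprocal exchange: two homolog-1 and two homolog-2 alleles remain
    expect_identical(sum(right), 2L)
  }
})

test_that("zero crossover rate produces only parental classes in every modality", {
  mod <- sim_model(1e6, 0)
  tt <- simulate_tetrad_counts(mod, two_marker_layout("tetrad"), 500, seed = 1)
  expect_equal(tt$PD, 500); expect_equal(tt$NPD, 0); expect_equal(tt$T, 0)
  p2 <- simulate_pollen_two_colour(mod, two_marker_layout("pollen2"), 500,
                                   seed = 1)
  expect_equal(p2$R5, 0); expect_equal(p2$red_alone, 0)
  p3 <- simulate_pollen_three_colour(mod, three_marker_layout(), 500, seed = 1)
  v <- p3$counts
  expect_equal(sum(v[c("BYR", "---")]), 500)
  expect_true(all(v[setdiff(names(v), c("BYR", "---"))] == 0))
})

test_that("small intervals yield tetratype fraction ~ 2m with negligible NPD", {
  m <- 0.01
  tt <- simulate_tetrad_counts(sim_model(1e6, m, rng_seed = 5),
                               two_marker_layout("tetrad"), 4e4)
  n <- tt$PD + tt$NPD + tt$T
  se <- sqrt(2 * m * (1 - 2 * m) / n)
  expect_lt(abs(tt$T / n - 2 * m), 3 * se)
  expect_lt(tt$NPD / n, 1e-3)
})

test_that("estimators round-trip the simulator inputs", {
  # tetrads: Perkins estimate recovers the input map distance within 2 SE
  d <- 0.08
  tt <- simulate_tetrad_counts(sim_model(1e6, d, rng_seed = 42),
                               two_marker_layout("tetrad"), 5e4)
  est <- tetrad_cm(tt)
  expect_lt(abs(est$cM - 100 * d), 2 * est$se)
  # two-colour pollen at r = 0.10 with artifacts: estimate immune to the
  # red-alone excess
  r <- 0.10
  p2 <- simulate_pollen_two_colour(
    sim_model(1e6, haldane_d(r), rng_seed = 7),
    two_marker_layout("pollen2"), 5e4, artifact_fraction = 0.05)
  e2 <- pollen2_cm(p2)
  expect_lt(abs(e2$cM - 100 * r), 3 * e2$se)
  # selfed seed at r = 0.18
  s <- simulate_selfed_seed(0.18, 1e4, seed = 3)
  es <- seed_cm(s$counts)
  expect_lt(abs(es$cM - 18), 3 * es$se)
  # three-colour pollen at interval maps 0.2 / 0.11 Morgan under nu = 1
  p3 <- simulate_pollen_three_colour(three_marker_model(seed = 9),
                                     three_marker_layout(), 4e4)
  cms <- threecolour_cms(p3)
  expect_lt(abs(cms$b$cM - 100 * haldane_r(0.2)), 3 * cms$b$se)
  expect_lt(abs(cms$c$cM - 100 * haldane_r(0.11)), 3 * cms$c$se)
})

test_that("artifact objects inflate red-alone counts without touching green classes", {
  mod <- sim_model(1e6, haldane_d(0.05), rng_seed = 21)
  p <- simulate_pollen_two_colour(mod, two_marker_layout("pollen2"), 2e4,
                                  artifact_fraction = 0.05)
  expect_gt(p$red_alone, p$R5)   # ~1500 artifacts vs ~500 true recombinants
  total <- p$R3 + p$R5 + p$red_alone + p$none
  expect_gte(total, 2e4)
})

test_that("identical seeds reproduce identical counts bit-for-bit", {
  mod <- sim_model(2e6, 0.12, nu = 3, escape_fraction = 0.1, rng_seed = 77)
  a <- simulate_tetrad_counts(mod, two_marker_layout("tetrad", 2e6), 2000)
  b <- simulate_tetrad_counts(mod, two_marker_layout("tetrad", 2e6), 2000)
  expect_identical(unclass(a), unclass(b))
  c3 <- simulate_pollen_three_colour(mod, three_marker_layout(L = 2e6), 2000)
  d3 <- simulate_pollen_three_colour(mod, three_marker_layout(L = 2e6), 2000)
  expect_identical(c3$counts, d3$counts)
  e <- simulate_tetrad_counts(mod, two_marker_layout("tetrad", 2e6), 2000,
                              seed = 78)
  expect_false(identical(unclass(a), unclass(e)))
})

test_that("class counts are non-negative integers summing to the requested n", {
  grid <- expand.grid(nu = c(1, 5), esc = c(0, 0.2), d = c(0.02, 0.3))
  for (i in seq_len(nrow(grid))) {
    mod <- sim_model(1e6, grid$d[i], nu = grid$nu[i],
                     escape_fraction = grid$esc[i], rng_seed = 300 + i)
    tt <- simulate_tetrad_counts(mod, two_marker_layout("tetrad"), 777)
    expect_equal(tt$PD + tt$NPD + tt$T, 777)
    expect_true(all(unlist(tt) == round(unlist(tt))))
    p3 <- simulate_pollen_three_colour(mod, three_marker_layout(L = 1e6), 777)
    expect_equal(unname(p3$N_total), 777)
    sc <- simulate_selfed_seed(min(2 * grid$d[i], 0.5), 777)$counts
    expect_equal(unname(sc$N_T), 777)
  }
})

test_that("nested intervals have monotone recombinant fractions", {
  mod <- sim_model(3e6, 0.3, nu = 2, rng_seed = 15)
  sim <- simulate_meioses(mod, 5e3)
  o <- lapply(c(0.05, 0.15, 0.25), function(p) chromatid_origins(sim, p))
  frac_inner <- mean(o[[1]] != o[[2]])
  frac_outer <- mean(o[[1]] != o[[3]])
  expect_lte(frac_inner, frac_outer)
})

test_that("selfed-seed class frequencies follow the segregation algebra", {
  s <- simulate_selfed_seed(0.2, 2e4, seed = 12)$counts
  exp_freq <- c(0.66, 0.09, 0.09, 0.16)
  obs <- c(s$N_GR, s$N_G, s$N_R, s$N_N) / s$N_T
  se <- sqrt(exp_freq * (1 - exp_freq) / s$N_T)
  expect_true(all(abs(obs - exp_freq) < 3 * se))
  s0 <- simulate_selfed_seed(0, 5e3, seed = 13)$counts
  expect_equal(s0$N_G + s0$N_R, 0)
  expect_lt(abs(s0$N_N / s0$N_T - 0.25), 3 * sqrt(0.25 * 0.75 / 5e3))
  expect_error(simulate_selfed_seed(1.2, 10), "0, 1")
})

test_that("F2 individuals are reporter-heterozygous with 1:2:1 segregation off the selected region", {
  mod <- sim_model(23e6, 0.9, rng_seed = 31)
  lay <- reporter_layout(data.frame(name = c("GFP", "dsRed"),
                                    pos_bp = c(256516, 5361637),
                                    colour = c("G", "R")), "seed")
  mk <- rbind(data.frame(chrom = "3", pos_bp = c(256516, 5361637, 12e6, 22e6)),
              data.frame(chrom = "1", pos_bp = c(5e6, 25e6)))
  pop <- simulate_f2_population(mod, lay, mk, reporter_chrom = "3",
                                n_individuals = 300,
                                seeds_per_individual = 500)
  expect_equal(nrow(pop$pheno), 300)
  expect_equal(dim(pop$geno), c(300, 6))
  # markers at the selected T-DNA positions are heterozygous by construction
  expect_true(all(pop$geno[, 1] == "HET"))
  expect_true(all(pop$geno[, 2] == "HET"))
  # unlinked marker segregates 1:2:1
  g <- table(factor(pop$geno[, 5], c("HOM_REF", "HET", "HOM_ALT"))) / 300
  expect_true(all(abs(g - c(0.25, 0.5, 0.25)) <
                    3 * sqrt(c(.25, .5, .25) * c(.75, .5, .75) / 300)))
  expect_true(all(pop$pheno$cM >= 0))
})
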