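test_that("two-colour pollen estimator follows the conditioning formula", {
  e <- pollen2_cm(pollen2_counts(R3 = 900, R5 = 100))
  expect_equal(e$cM, 10)
  expect_equal(e$recombinant_total, 200)
  expect_equal(e$se, 100 * sqrt(0.1 * 0.9 / 1000))
  expect_equal(pollen2_cm(pollen2_counts(500, 0))$cM, 0)
  # invariant to red-alone and colourless counts (conditioning on green)
  e2 <- pollen2_cm(pollen2_counts(900, 100, red_alone = 5000, none = 123))
  expect_equal(e2$cM, e$cM)
  expect_equal(e2$se, e$se)
  expect_error(pollen2_cm(pollen2_counts(0, 0)), "positive")
})

test_that("seed estimator inverts the selfing segregation model exactly", {
  e <- seed_cm(seed_counts(N_GR = 700, N_G = 90, N_R = 90, N_N = 120))
  expect_equal(e$cM, 100 * (1 - sqrt(0.64)))   # (N_G+N_R)/N_T = 0.18
  expect_equal(seed_cm(seed_counts(750, 0, 0, 250))$cM, 0)
  # closed-form inverse: expected class counts at r give back exactly 100 r
  for (r in seq(0.05, 0.5, by = 0.05))
    expect_equal(seed_cm(expected_seed_counts(r, 1e4))$cM, 100 * r)
  expect_error(seed_cm(seed_counts(100, 300, 300, 100)), "radicand")
})

test_that("seed estimator warns above the 50 cM saturation point", {
  cnt <- expected_seed_counts(0.55, 1e4)
  expect_warning(seed_cm(cnt), "50")
})

test_that("Perkins tetrad estimator and delta-method SE are correct", {
  e <- tetrad_cm(tetrad_counts(PD = 100, NPD = 0, T = 0))
  expect_equal(e$cM, 0); expect_equal(e$se, 0)
  e2 <- tetrad_cm(tetrad_counts(1000, 10, 300))
  expect_equal(e2$cM, 100 * (150 + 30) / 1310)
  expect_error(tetrad_cm(tetrad_counts(0, 0, 0)), "positive")
})

test_that("delta-method tetrad SE agrees with a parametric bootstrap", {
  counts <- c(PD = 3976, NPD = 3, T = 742)
  n <- sum(counts)
  set.seed(71)
  draws <- rmultinom(1e4, n, counts / n)
  boot_cm <- 100 * (draws[3, ] / 2 + 3 * draws[2, ]) / n
  delta_se <- tetrad_cm(tetrad_counts(counts[1], counts[2], counts[3]))$se
  expect_lt(abs(delta_se - sd(boot_cm)) / sd(boot_cm), 0.10)
})

test_that("estimators are scale-equivariant in the counts", {
  k <- 4
  pairs <- list(
    list(tetrad_cm(tetrad_counts(1000, 10, 300)),
         tetrad_cm(tetrad_counts(1000 * k, 10 * k, 300 * k))),
    list(pollen2_cm(pollen2_counts(900, 100)),
         pollen2_cm(pollen2_counts(900 * k, 100 * k))),
    list(seed_cm(seed_counts(700, 90, 90, 120)),
         seed_cm(seed_counts(700 * k, 90 * k, 90 * k, 120 * k))))
  for (p in pairs) {
    expect_equal(p[[2]]$cM, p[[1]]$cM)
    expect_equal(p[[2]]$se, p[[1]]$se / sqrt(k))
  }
})

test_that("three-colour estimator scores interval-discordant classes", {
  tc <- constructed_threecolour()
  cms <- threecolour_cms(tc)
  expect_equal(cms$b$cM, 20)
  expect_equal(cms$c$cM, 11)
  parental <- threecolour_counts(c(BYR = 800, `BY-` = 0, `B-R` = 0,
                                   `B--` = 0, `-YR` = 0, `-Y-` = 0,
                                   `--R` = 0, `---` = 200))
  cms0 <- threecolour_cms(parental)
  expect_equal(cms0$b$cM, 0); expect_equal(cms0$c$cM, 0)
  expect_error(threecolour_counts(c(BYR = 1)), "eight")
})

test_that("seed-object classification recovers known mixture labels", {
  s <- simulate_selfed_seed(0.2, 3000,
                            intensity_params = list(base = 30, fold = 8,
                                                    sdlog = 0.25),
                            seed = 41)
  auto <- classify_seed_objects(s$objects)
  truth <- s$counts
  for (f in c("N_GR", "N_G", "N_R", "N_N"))
    expect_lt(abs(auto[[f]] - truth[[f]]), 0.01 * truth$N_T)
  # explicit zero cuts leave nothing in the colourless category
  zero <- classify_seed_objects(s$objects, thresholds = c(0, 0))
  expect_equal(zero$N_N, 0)
  # cuts above every intensity put everything in the colourless category
  hi <- max(s$objects$red, s$objects$green) + 1
  allnone <- classify_seed_objects(s$objects, thresholds = c(hi, hi))
  expect_equal(allnone$N_N, allnone$N_T)
})

test_that("automatic thresholding refuses unimodal intensity histograms", {
  set.seed(5)
  flat <- data.frame(red = rlnorm(500, log(30), 0.2),
                     green = rlnorm(500, log(30), 0.2))
  expect_error(classify_seed_objects(flat), "unimodal|valley")
})

test_that("configuration calls separate cis from trans seed patterns", {
  # cis at r = 0.2: colourless fraction 0.16
  cis <- seed_counts(660, 90, 90, 160)
  expect_equal(as.character(call_configuration(cis)), "cis")
  # trans: parental gametes R+ and +G; colourless seed nearly absent
  trans <- seed_counts(510, 240, 240, 10)
  expect_equal(as.character(call_configuration(trans)), "trans")
  # the same weak evidence becomes ambiguous under a wider margin
  weak <- seed_counts(6, 1, 1, 2)
  expect_equal(as.character(call_configuration(weak, margin = 50)),
               "ambiguous")
})

test_that("interval heterozygosity sums SNPs and indel lengths per kb", {
  v <- data.frame(position = c(100, 2000, 9000, 15000),
                  type = c("SNP", "indel", "SNP", "SNP"),
                  length = c(NA, 10, NA, NA))
  # 10 SNPs + one 10-bp indel in 10 kb = 2.0 per kb
  v10 <- data.frame(position = seq(500, 9500, length.out = 10), type = "SNP",
                    length = NA)
  v10 <- rbind(v10, data.frame(position = 5000, type = "indel", length = 10))
  expect_equal(interval_heterozygosity(v10, c(1, 10000)), 2.0)
  expect_equal(interval_heterozygosity(v[0, ], c(1, 10000)), 0)
  # variants outside the region do not contribute
  expect_equal(interval_heterozygosity(v, c(1, 10000)),
               interval_heterozygosity(rbind(v,
                 data.frame(position = 2e4, type = "SNP", length = NA)),
                 c(1, 10000)))
  expect_error(interval_heterozygosity(v, c(10, 5)), "start <= end")
})
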