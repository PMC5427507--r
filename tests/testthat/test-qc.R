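test_that("polarization enforces parental criteria and flips polarity", {
  calls <- rbind(
    ok      = c("AA", "BB", "AA", "AB", "BB"),
    flipped = c("BB", "AA", "BB", "AB", "AA"),
    hetpar  = c("AB", "BB", "AA", "AA", "AA"),
    mono    = c("AA", "AA", "AB", "BB", "AA"),
    mispar  = c(NA, "BB", "AA", "AA", "AA"))
  colnames(calls) <- c("P1", "P2", "i1", "i2", "i3")
  g <- genmat(calls, parents = c("P1", "P2"))
  pol <- polarize(g)
  expect_setequal(markers(pol), c("ok", "flipped"))
  rep <- attr(pol, "polarize_report")
  expect_equal(rep$reason[rep$marker == "hetpar"], "het_parent")
  expect_equal(rep$reason[rep$marker == "mono"], "monomorphic")
  expect_equal(rep$reason[rep$marker == "mispar"], "missing_parent")
  # polarity oracle: after recoding, AA always means the parent-1 allele
  expect_identical(unname(pol$calls["flipped", ]),
                   c("AA", "BB", "AA", "AB", "BB"))
  expect_identical(unname(pol$calls["ok", ]), unname(calls["ok", ]))
  expect_error(polarize(g, "P1", "nope"), "parent")
})

test_that("marker statistics match closed-form chi-square on 2 df", {
  g <- gm_from(rbind(a = marker_row(30, 60, 30),
                     b = marker_row(50, 50, 20),
                     c = marker_row(10, 20, 10, nmiss = 80)))
  st <- marker_stats(g)
  expect_equal(st$chi2[st$marker == "a"], 0)
  expect_equal(st$p_value[st$marker == "a"], 1)
  # counts (50,50,20): chi2 = 18.333, p = exp(-chi2/2)
  expect_equal(st$chi2[st$marker == "b"], 55 / 3, tolerance = 1e-12)
  expect_equal(st$p_value[st$marker == "b"], exp(-55 / 6), tolerance = 1e-12)
  expect_equal(st$p_value[st$marker == "b"], 1.0446e-04, tolerance = 1e-4)
  # missing calls excluded from n
  expect_equal(st$n_AA[st$marker == "c"] + st$n_AB[st$marker == "c"] +
                 st$n_BB[st$marker == "c"], 40)
  expect_equal(st$chi2[st$marker == "c"], 0)
  # maf: heterozygote contributes one copy of each allele
  expect_equal(st$maf[st$marker == "b"],
               min(2 * 50 + 50, 2 * 20 + 50) / (2 * 120))
})

test_that("chi-square p-values agree with an independent CDF to 1e-10", {
  set.seed(42)
  for (k in 1:25) {
    n <- sample(50:300, 1)
    cnt <- as.integer(rmultinom(1, n, c(0.25, 0.5, 0.25)))
    g <- gm_from(rbind(x = marker_row(cnt[1], cnt[2], cnt[3])))
    st <- marker_stats(g)
    e <- c(n / 4, n / 2, n / 4)
    x2 <- sum((cnt - e)^2 / e)
    expect_equal(st$p_value, exp(-x2 / 2), tolerance = 1e-10)
  }
})

test_that("filters remove markers strictly past each threshold, in order", {
  calls <- rbind(
    pass      = marker_row(25, 50, 25),
    maf_low   = marker_row(85, 10, 5),           # maf 0.10
    miss_hi   = marker_row(22, 45, 22, nmiss = 11),  # 11% missing
    het_hi    = marker_row(5, 90, 5),            # het 0.90
    distorted = marker_row(55, 30, 15),          # strongly non-1:2:1
    pass2     = marker_row(30, 48, 22))
  g <- gm_from(calls)
  res <- apply_filters(g, filter_policy("framework"))
  rep <- res$report
  expect_setequal(markers(res$genmat), c("pass", "pass2"))
  expect_equal(rep$criterion[rep$marker == "maf_low"], "maf")
  expect_equal(rep$criterion[rep$marker == "miss_hi"], "missing")
  expect_equal(rep$criterion[rep$marker == "het_hi"], "het")
  expect_equal(rep$criterion[rep$marker == "distorted"], "distortion")
  # first-failure attribution: a marker failing maf AND distortion reports maf
  g2 <- gm_from(rbind(both = marker_row(90, 5, 5)))
  rep2 <- suppressWarnings(apply_filters(g2, filter_policy("framework")))$report
  expect_equal(rep2$criterion, "maf")
})

test_that("boundary markers survive strict thresholds", {
  # an exactly-on-threshold marker survives: thresholds are strict removals.
  # (het 0.80 and maf 0.20 are incompatible with a 1:2:1 fit, so the
  # distortion filter is disabled to isolate each boundary.)
  pol <- filter_policy("framework", distortion_alpha = 0)
  g <- gm_from(rbind(
    miss_edge = marker_row(23, 45, 22, nmiss = 10),  # missing exactly 0.10
    het_edge  = marker_row(10, 80, 10),              # het exactly 0.80
    maf_edge  = marker_row(70, 20, 10)))             # maf exactly 0.20
  res <- apply_filters(g, pol)
  expect_setequal(markers(res$genmat), c("miss_edge", "het_edge", "maf_edge"))
  # placement policy keeps 40% missing but not 45%
  g2 <- gm_from(rbind(m40 = marker_row(15, 30, 15, nmiss = 40),
                      m45 = marker_row(14, 27, 14, nmiss = 45)))
  res2 <- apply_filters(g2, filter_policy("placement"))
  expect_true("m40" %in% markers(res2$genmat))
  expect_false("m45" %in% markers(res2$genmat))
})

test_that("engineered ten-marker matrix leaves exactly the expected survivors", {
  g <- gm_from(rbind(
    s1 = marker_row(25, 50, 25),
    s2 = marker_row(30, 50, 20),
    s3 = marker_row(22, 52, 26),
    s4 = marker_row(28, 44, 28),
    f1 = marker_row(88, 6, 6),                    # maf
    f2 = marker_row(20, 40, 20, nmiss = 20),      # missing
    f3 = marker_row(4, 92, 4),                    # het
    f4 = marker_row(60, 30, 10),                  # distortion
    f5 = marker_row(0, 0, 0, nmiss = 100),        # all missing
    f6 = marker_row(55, 35, 10)))                 # distortion
  res <- apply_filters(g, filter_policy("framework"))
  expect_setequal(markers(res$genmat), c("s1", "s2", "s3", "s4"))
  expect_equal(sum(res$report$pass), 4)
})

test_that("filtering is idempotent", {
  set.seed(7)
  tm <- make_true_map(1, 40, 100, seed = 30)
  cfg <- sim_config(n_individuals = 120, missing_rate = 0.15, mean_depth = 4,
                    seed = 31)
  g <- polarize(simulate_population(tm, cfg))
  once <- apply_filters(g, filter_policy("framework"))
  twice <- apply_filters(once$genmat, filter_policy("framework"))
  expect_identical(markers(twice$genmat), markers(once$genmat))
  expect_true(all(twice$report$pass))
})

test_that("distortion filter has approximately nominal type-I error", {
  tm <- make_true_map(1, 600, 3000, seed = 32)  # sparse: essentially unlinked
  cfg <- sim_config(n_individuals = 200, seed = 33)
  g <- simulate_f2(tm, cfg)
  st <- marker_stats(g)
  frac <- mean(st$p_value < 0.01)
  expect_gt(frac, 0.002)
  expect_lt(frac, 0.025)
})
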