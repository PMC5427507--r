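chrom_df <- function(markers, pos) {
  data.frame(marker = markers, pos_cM = pos, stringsAsFactors = FALSE)
}

test_that("a single component merges to itself with zero RMSE", {
  comp <- chrom_df(c("a", "b", "c", "d"), c(0, 5, 12, 30))
  fit <- merge_maps(list(comp), K = 2)
  expect_equal(fit$map$marker, comp$marker)
  expect_equal(fit$map$pos_cM, comp$pos_cM, tolerance = 1e-8)
  expect_equal(unname(fit$rmse), 0, tolerance = 1e-8)
})

test_that("identical components agree exactly and K=1 wins the tie", {
  comp <- chrom_df(c("a", "b", "c"), c(0, 8, 20))
  fit <- select_k(list(comp, comp), Ks = 1:4)
  expect_equal(fit$K, 1)
  expect_equal(fit$map$pos_cM, comp$pos_cM, tolerance = 1e-8)
  expect_true(all(abs(fit$rmse) < 1e-8))
  expect_equal(nrow(fit$deleted), 0)
})

test_that("a uniformly stretched copy keeps order with positions in between", {
  comp1 <- chrom_df(c("a", "b", "c"), c(0, 10, 25))
  comp2 <- chrom_df(c("a", "b", "c"), c(0, 12, 30))   # x 1.2
  fit <- merge_maps(list(comp1, comp2), K = 2, weights = c(1, 1))
  expect_identical(fit$map$marker, c("a", "b", "c"))
  gap1 <- diff(fit$map$pos_cM)
  expect_true(all(gap1 >= c(10, 15) - 1e-6 & gap1 <= c(12, 18) + 1e-6))
})

test_that("population-size weights pull the consensus toward the larger population", {
  comp1 <- chrom_df(c("a", "b"), c(0, 10))
  comp2 <- chrom_df(c("a", "b"), c(0, 20))
  heavy1 <- merge_maps(list(comp1, comp2), K = 1, weights = c(1000, 1))
  heavy2 <- merge_maps(list(comp1, comp2), K = 1, weights = c(1, 1000))
  expect_equal(diff(heavy1$map$pos_cM), 10, tolerance = 1e-6)
  expect_equal(diff(heavy2$map$pos_cM), 20, tolerance = 1e-6)
})

test_that("order conflicts are resolved by logged constraint deletion", {
  comp1 <- chrom_df(c("a", "b", "c", "d"), c(0, 5, 10, 15))
  comp2 <- chrom_df(c("a", "c", "b", "d"), c(0, 5, 10, 15))  # b/c swapped
  fit <- merge_maps(list(comp1, comp2), K = 2, weights = c(2, 1))
  expect_gt(nrow(fit$deleted), 0)
  expect_false(is.unsorted(fit$map$pos_cM))
  # all retained markers present and the ends undisputed
  expect_setequal(fit$map$marker, c("a", "b", "c", "d"))
  expect_equal(fit$map$marker[1], "a")
  expect_equal(fit$map$marker[4], "d")
})

test_that("returned positions satisfy every retained order constraint", {
  set.seed(100)
  for (k in 1:5) {
    n <- 8
    truth <- sort(runif(n, 0, 50))
    mk <- sprintf("m%02d", 1:n)
    mk1 <- sort(sample(n, 6)); mk2 <- sort(sample(n, 6))
    comp1 <- chrom_df(mk[mk1], truth[mk1] + rnorm(6, 0, 1))
    comp2 <- chrom_df(mk[mk2], truth[mk2] + rnorm(6, 0, 1))
    comp1 <- comp1[order(comp1$pos_cM), ]
    comp2 <- comp2[order(comp2$pos_cM), ]
    fit <- merge_maps(list(comp1, comp2), K = 2)
    pos <- setNames(fit$map$pos_cM, fit$map$marker)
    for (comp in list(comp1, comp2)) {
      o <- comp$marker[order(comp$pos_cM)]
      for (i in seq_len(length(o) - 1)) {
        for (j in seq(i + 1, min(i + 2, length(o)))) {
          pair_deleted <- nrow(fit$deleted) > 0 &&
            any(fit$deleted$from == o[i] & fit$deleted$to == o[j])
          if (!pair_deleted && comp$pos_cM[match(o[j], comp$marker)] >
                comp$pos_cM[match(o[i], comp$marker)])
            expect_gte(pos[o[j]], pos[o[i]] - 1e-8)
        }
      }
    }
  }
})

test_that("the LP objective beats the naive single-component solution", {
  set.seed(101)
  truth <- sort(runif(10, 0, 60))
  mk <- sprintf("m%02d", 1:10)
  comp1 <- chrom_df(mk, truth + rnorm(10, 0, 1.5))
  comp2 <- chrom_df(mk, truth * 1.1 + rnorm(10, 0, 1.5))
  comp1 <- comp1[order(comp1$pos_cM), ]
  comp2 <- comp2[order(comp2$pos_cM), ]
  fit <- merge_maps(list(comp1, comp2), K = 2)
  objective_of <- function(pos_by_marker) {
    tot <- 0
    for (ci in 1:2) {
      comp <- list(comp1, comp2)[[ci]]
      comp <- comp[order(comp$pos_cM), ]
      d <- diff(comp$pos_cM - min(comp$pos_cM))
      dx <- diff(pos_by_marker[comp$marker])
      tot <- tot + 0.5 * mean(abs(dx - d))
    }
    tot
  }
  naive <- setNames(comp1$pos_cM - min(comp1$pos_cM), comp1$marker)
  expect_lte(fit$objective, objective_of(naive) + 1e-8)
})

test_that("two noisy maps from one truth merge back to the truth's order", {
  set.seed(102)
  tm <- make_true_map(2, 15, c(80, 100), seed = 103)
  c1 <- sim_config(n_individuals = 140, shared_marker_fraction = 0.8,
                   seed = 104)
  c2 <- sim_config(n_individuals = 154, seed = 105)
  tp <- simulate_two_populations(tm, c1, c2)
  maps <- lapply(list(tp$pop1, tp$pop2), function(p) {
    build_component_map(polarize(p))
  })
  cons <- build_consensus(maps, Ks = 1:4, weights = c(140, 154))
  expect_gte(length(unique(cons$chrom)), 2)
  for (ch in unique(cons$chrom)) {
    sub <- cons[cons$chrom == ch, ]
    truth <- tm$pos_cM[match(sub$marker, tm$marker)]
    expect_gte(abs(spearman_rho(sub$pos_cM, truth)), 0.99)
  }
  # and against each component (the published-style agreement check)
  for (cmp in maps) {
    for (gr in unique(cmp$group)) {
      sub <- cmp[cmp$group == gr, ]
      ch <- unique(cons$chrom[match(sub$marker, cons$marker)])
      ch <- ch[!is.na(ch)]
      if (length(ch) == 1) {
        rho <- consensus_vs_component_ranks(cons[cons$chrom == ch, ], sub)
        if (!is.na(rho)) expect_gte(abs(rho), 0.99)
      }
    }
  }
})

test_that("rank agreement helper handles identity, reversal and small n", {
  comp <- chrom_df(letters[1:5], c(0, 3, 7, 12, 20))
  expect_equal(consensus_vs_component_ranks(comp, comp), 1)
  revd <- chrom_df(letters[1:5], rev(c(0, 3, 7, 12, 20)))
  expect_equal(consensus_vs_component_ranks(comp, revd), -1)
  expect_true(is.na(consensus_vs_component_ranks(comp[1:2, ], comp[1:2, ])))
})

test_that("components without shared markers are rejected", {
  comp1 <- chrom_df(c("a", "b"), c(0, 10))
  comp2 <- chrom_df(c("x", "y"), c(0, 10))
  expect_error(merge_maps(list(comp1, comp2), K = 1), "disconnected")
})
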