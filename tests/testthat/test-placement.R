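# Genotype vectors of homozygous-only calls let us dial exact rf values:
# with only parental-class counts the ML rf is the mismatch fraction.
homo_vec <- function(n, flips = integer(0)) {
  v <- rep(c("AA", "BB"), each = n / 2)
  v[flips] <- ifelse(v[flips] == "AA", "BB", "AA")
  v
}

test_that("a marker is placed at the position of its minimum-rf anchor", {
  n <- 100
  m1 <- homo_vec(n)
  m2 <- homo_vec(n, c(1:10, 51:60))              # rf(U, m2) computed below
  u <- homo_vec(n, c(1:3, 51:52))                # rf(U, M1) = 0.05
  # rf(U, M2): mismatches = symmetric difference = 5 + 20 - 2*overlap(= 3+2) -> 0.15
  g <- gm_from(rbind(M1 = m1, M2 = m2, U = u))
  map <- umbmap:::new_component_map(
    data.frame(group = "LG1", marker = c("M1", "M2"), pos_cM = c(10, 20)))
  res <- place_unmapped("U", map, g, rf_max = 0.1)
  expect_equal(res$status, "placed")
  expect_equal(res$pos_cM, 10)
  expect_equal(res$group, "LG1")
  expect_equal(res$min_rf, 0.05, tolerance = 1e-6)
  expect_equal(res$anchors, "M1")
})

test_that("a tie at the minimum places the marker at the mean position", {
  n <- 100
  m1 <- homo_vec(n)
  m2 <- homo_vec(n, c(1:6, 51:54))           # rf(M1, M2) = 0.10
  u <- homo_vec(n, c(1:3, 51:52))            # rf(U, M1) = 0.05
  # rf(U, M2) = |{1:6,51:54} xor {1:3,51:52}| / 100 = (3 + 2) / 100 = 0.05
  g <- gm_from(rbind(M1 = m1, M2 = m2, U = u))
  map <- umbmap:::new_component_map(
    data.frame(group = "LG1", marker = c("M1", "M2"), pos_cM = c(10, 20)))
  res <- place_unmapped("U", map, g, rf_max = 0.1)
  expect_equal(res$status, "placed")
  expect_equal(res$pos_cM, 15)
  expect_equal(res$anchors, "M1,M2")
})

test_that("markers beyond the rf threshold stay unplaced; 0.1 itself is usable", {
  n <- 100
  m1 <- homo_vec(n)
  u_far <- homo_vec(n, c(1:10, 51:55))       # rf 0.15
  u_edge <- homo_vec(n, c(1:5, 51:55))       # rf 0.10 exactly
  g <- gm_from(rbind(M1 = m1, Ufar = u_far, Uedge = u_edge))
  map <- umbmap:::new_component_map(
    data.frame(group = "LG1", marker = "M1", pos_cM = 5))
  res <- place_unmapped(c("Ufar", "Uedge"), map, g, rf_max = 0.1)
  expect_equal(res$status[res$marker == "Ufar"], "unplaced")
  expect_equal(res$reason[res$marker == "Ufar"], "rf_above_max")
  expect_equal(res$status[res$marker == "Uedge"], "placed")
})

test_that("no informative overlap gives reason no_data", {
  n <- 20
  m1 <- homo_vec(n)
  u <- rep(NA_character_, n)
  u[1] <- "AA"   # a single informative individual is not enough
  g0 <- rbind(M1 = m1, U = u)
  g0["M1", 1] <- "AA"
  g <- gm_from(g0)
  map <- umbmap:::new_component_map(
    data.frame(group = "LG1", marker = "M1", pos_cM = 0))
  res <- place_unmapped("U", map, g)
  expect_equal(res$status, "unplaced")
  expect_equal(res$reason, "no_data")
})

test_that("placement agrees with the brute-force oracle on random data", {
  set.seed(90)
  n_checked <- 0
  for (rep in 1:10) {
    tm <- make_true_map(2, 12, c(60, 70), seed = 9000 + rep)
    cfg <- sim_config(n_individuals = 80, missing_rate = 0.3, mean_depth = 3,
                      seed = 9100 + rep)
    g <- apply_observation_model(simulate_f2(tm, cfg), cfg)
    mapped_mk <- tm$marker[seq(1, 24, by = 2)]
    unmapped_mk <- setdiff(tm$marker, mapped_mk)
    mapdf <- data.frame(group = tm$chrom[match(mapped_mk, tm$marker)],
                        marker = mapped_mk,
                        pos_cM = tm$pos_cM[match(mapped_mk, tm$marker)])
    map <- umbmap:::new_component_map(mapdf)
    res <- place_unmapped(unmapped_mk, map, g, rf_max = 0.1)
    tab <- rf_table(g, markers1 = unmapped_mk, markers2 = mapped_mk)
    for (i in seq_along(unmapped_mk)) {
      o <- oracle_place_one(tab$rf[i, ], tab$n[i, ], mapdf, rf_max = 0.1)
      r <- res[res$marker == unmapped_mk[i], ]
      expect_equal(r$status, o$status)
      if (o$status == "placed") {
        expect_equal(r$pos_cM, o$pos)
        expect_equal(r$group, o$group)
        expect_equal(r$min_rf, o$min_rf, tolerance = 1e-12)
      } else {
        expect_equal(r$reason, o$reason)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("raising rf_max can only grow the placed set", {
  set.seed(91)
  tm <- make_true_map(1, 16, 90, seed = 92)
  cfg <- sim_config(n_individuals = 100, seed = 93)
  g <- simulate_f2(tm, cfg)
  mapped_mk <- tm$marker[seq(1, 16, by = 2)]
  map <- umbmap:::new_component_map(
    data.frame(group = "LG1", marker = mapped_mk,
               pos_cM = tm$pos_cM[match(mapped_mk, tm$marker)]))
  un <- setdiff(tm$marker, mapped_mk)
  placed_at <- function(rfmax)
    place_unmapped(un, map, g, rf_max = rfmax)
  p1 <- placed_at(0.05); p2 <- placed_at(0.1); p3 <- placed_at(0.2)
  s1 <- p1$marker[p1$status == "placed"]
  s2 <- p2$marker[p2$status == "placed"]
  s3 <- p3$marker[p3$status == "placed"]
  expect_true(all(s1 %in% s2))
  expect_true(all(s2 %in% s3))
})

test_that("held-out markers are re-placed near their true positions", {
  set.seed(94)
  tm <- make_true_map(1, 40, 100, seed = 95)
  cfg <- sim_config(n_individuals = 200, seed = 96)
  g <- simulate_f2(tm, cfg)
  mapped_mk <- tm$marker[seq(1, 40, by = 2)]
  map <- umbmap:::new_component_map(
    data.frame(group = "1U", marker = mapped_mk,
               pos_cM = tm$pos_cM[match(mapped_mk, tm$marker)]))
  un <- setdiff(tm$marker, mapped_mk)
  res <- place_unmapped(un, map, g, rf_max = 0.1)
  placed <- res[res$status == "placed", ]
  expect_gt(nrow(placed), 0.8 * length(un))
  err <- abs(placed$pos_cM - tm$pos_cM[match(placed$marker, tm$marker)])
  expect_gte(mean(err <= 10), 0.9)
})

test_that("merging placed markers preserves the framework scaffold", {
  map <- umbmap:::new_component_map(
    data.frame(group = "LG1", marker = c("A", "B", "C"),
               pos_cM = c(0, 10, 20)))
  none <- place_unmapped(character(0), map,
                         gm_from(matrix("AA", 1, 4,
                                        dimnames = list("A", NULL))))
  merged0 <- merge_placed(map, none)
  expect_equal(as.data.frame(merged0)[, c("group", "marker", "pos_cM")],
               as.data.frame(map), ignore_attr = TRUE)

  pl <- data.frame(marker = c("U1", "U2"), status = "placed", group = "LG1",
                   pos_cM = c(10, 5), min_rf = 0.02, anchors = "B",
                   reason = NA_character_)
  merged <- merge_placed(map, pl)
  expect_false(is.unsorted(merged$pos_cM))
  fw <- merged[merged$source == "framework", ]
  expect_identical(fw$marker, c("A", "B", "C"))
  expect_identical(fw$pos_cM, c(0, 10, 20))
  # co-positioned: framework marker precedes the placed one
  at10 <- merged$marker[merged$pos_cM == 10]
  expect_identical(at10, c("B", "U1"))
})
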