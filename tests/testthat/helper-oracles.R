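# Independent oracles and small fixture builders used across the suite.

# genotype matrix from a markers x individuals character matrix
gm_from <- function(m, parents = character()) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("m%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("i%02d", seq_len(ncol(m)))
  genmat(m, parents = parents)
}

# one marker row with given genotype counts (order AA, AB, BB, missing)
marker_row <- function(nAA, nAB, nBB, nmiss = 0) {
  c(rep("AA", nAA), rep("AB", nAB), rep("BB", nBB), rep(NA, nmiss))
}

# F2 two-locus class probabilities, written out independently of the package
f2_probs_oracle <- function(r) {
  q <- 1 - r
  c(q^2 / 4, r * q / 2, r^2 / 4,
    r * q / 2, (q^2 + r^2) / 2, r * q / 2,
    r^2 / 4, r * q / 2, q^2 / 4)  # order: (0,0),(0,1),(0,2),(1,0),...,(2,2)
}

# draw 9-class counts for n F2 individuals at true recombination fraction r
sim_pair_counts <- function(r, n) {
  x <- as.integer(stats::rmultinom(1, n, f2_probs_oracle(r)))
  names(x) <- c("n00", "n01", "n02", "n10", "n11", "n12", "n20", "n21", "n22")
  as.list(x)
}

# grid-search maximum-likelihood rf estimate: direct multinomial likelihood
# maximized over a fine grid (independent of the EM code path)
oracle_rf_grid <- function(cn, step = 1e-4) {
  rs <- seq(0, 0.5, by = step)
  counts <- unlist(cn)
  ll <- numeric(length(rs))
  for (i in seq_along(rs)) {
    p <- pmax(f2_probs_oracle(rs[i]), 1e-300)
    ll[i] <- sum(counts * log(p))
  }
  rs[which.max(ll)]
}

# counts list from two genotype vectors coded AA/AB/BB/NA
counts_from_calls <- function(a, b) {
  code <- function(x) match(x, c("AA", "AB", "BB")) - 1L
  ca <- code(a); cb <- code(b)
  out <- list()
  for (i in 0:2) for (j in 0:2)
    out[[sprintf("n%d%d", i, j)]] <-
      sum(!is.na(ca) & !is.na(cb) & ca == i & cb == j)
  out
}

# brute-force placement of one marker: scan the full rf row and apply the
# minimum-rf rule from scratch
oracle_place_one <- function(rf_row, n_row, mapped, rf_max = 0.1,
                             tie_tol = 1e-9) {
  rf_row[n_row < 2] <- NA
  if (all(is.na(rf_row))) return(list(status = "unplaced", reason = "no_data"))
  mn <- min(rf_row, na.rm = TRUE)
  if (mn > rf_max) return(list(status = "unplaced", reason = "rf_above_max"))
  tie <- which(!is.na(rf_row) & rf_row <= mn + tie_tol)
  grp <- unique(mapped$group[tie])
  if (length(grp) > 1)
    return(list(status = "unplaced", reason = "ambiguous_group"))
  list(status = "placed", group = grp, pos = mean(mapped$pos_cM[tie]),
       min_rf = mn)
}

# run-length scanner for distorted regions, written as a plain loop
oracle_regions <- function(sig) {
  regions <- list()
  i <- 1
  n <- length(sig)
  while (i <= n) {
    if (sig[i]) {
      j <- i
      while (j < n && sig[j + 1]) j <- j + 1
      if (j - i + 1 >= 2)
        regions[[length(regions) + 1]] <- c(start = i, end = j)
      i <- j + 1
    } else i <- i + 1
  }
  regions
}

# exhaustive minimum of the adjacent-rf path cost over all marker orders
oracle_min_path_cost <- function(D) {
  n <- nrow(D)
  stopifnot(n <= 8)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(D[cbind(p[-n], p[-1])])
    if (cost < best) best <- cost
  }
  best
}

path_cost_of <- function(ord, D) sum(D[cbind(ord[-length(ord)], ord[-1])])

# quick single-chromosome clean simulation
quick_sim <- function(n_markers, length_cM, n_ind, seed, ...) {
  tm <- make_true_map(1, n_markers, length_cM, seed = seed)
  cfg <- sim_config(n_individuals = n_ind, seed = seed + 1000, ...)
  list(map = tm, g = simulate_f2(tm, cfg), cfg = cfg)
}
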