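#' Kosambi map function and its inverse
#'
#' Converts a recombination fraction to an additive map distance allowing for
#' crossover interference: `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans.
#' The inverse is `r = tanh(d / 50) / 2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in centimorgans, non-negative.
#' @return Distances in cM, or recombination fractions. Vectorized.
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("recombination fraction must lie in [0, 0.5); r = 0.5 maps to an infinite distance")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("map distance must be non-negative")
  tanh(d / 50) / 2
}

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure: two markers are linked when the
#' p-value of the chi-square independence test of their two-locus contingency
#' table falls below `cutoff_p`; linkage groups are the connected components
#' of the resulting graph, returned largest first (ties by the smallest
#' marker id).
#'
#' @param rfs a symmetric [rf_table()].
#' @param cutoff_p linkage threshold on the independence-test p-value
#'   (default `1e-8`).
#' @return list of character vectors of marker ids.
#' @export
group_markers <- function(rfs, cutoff_p = 1e-8) {
  stopifnot(inherits(rfs, "rf_table"), isTRUE(rfs$symmetric))
  m <- rfs$markers1
  adj <- rfs$p_indep < cutoff_p
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, length(m))
  cur <- 0L
  for (i in seq_along(m)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  groups <- split(m, comp)
  ord <- order(-lengths(groups), vapply(groups, min, ""))
  unname(groups[ord])
}

# union-find bins of co-segregating markers (rf == 0), representative =
# lexicographically smallest id
coseg_bins <- function(mk, rf) {
  parent <- seq_along(mk)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  zero <- which(rf[mk, mk, drop = FALSE] <= 0 &
                  !is.na(rf[mk, mk, drop = FALSE]), arr.ind = TRUE)
  for (k in seq_len(nrow(zero))) {
    a <- find(zero[k, 1]); b <- find(zero[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(mk), find, 1L)
  split(mk, root)
}

path_cost <- function(ordkey, D) sum(D[cbind(ordkey[-length(ordkey)], ordkey[-1])])

# 2-opt improvement of a path under adjacent-distance sum
two_opt <- function(ord, D, max_pass = 60) {
  n <- length(ord)
  if (n < 3) return(ord)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        # reversing ord[i..j] changes only the two boundary edges
        delta <- 0
        if (i > 1) delta <- delta + D[ord[i - 1], ord[j]] - D[ord[i - 1], ord[i]]
        if (j < n) delta <- delta + D[ord[i], ord[j + 1]] - D[ord[j], ord[j + 1]]
        if (delta < -1e-12) {
          ord[i:j] <- ord[j:i]
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

# or-opt improvement: relocate segments of 1-3 markers (optionally reversed)
# to a better slot; catches single displaced markers that 2-opt reversals
# cannot repair
or_opt <- function(ord, D, max_seg = 3) {
  n <- length(ord)
  if (n < 4) return(list(ord = ord, improved = FALSE))
  any_improved <- FALSE
  for (L in seq_len(min(max_seg, n - 2))) {
    i <- 1
    while (i + L - 1 <= n) {
      seg <- ord[i:(i + L - 1)]
      rest <- ord[-(i:(i + L - 1))]
      left <- if (i > 1) ord[i - 1] else NA
      right <- if (i + L <= n) ord[i + L] else NA
      removal <- 0
      if (!is.na(left)) removal <- removal + D[left, seg[1]]
      if (!is.na(right)) removal <- removal + D[seg[L], right]
      if (!is.na(left) && !is.na(right)) removal <- removal - D[left, right]
      best_delta <- -1e-12; best_k <- NA; best_rev <- FALSE
      m <- length(rest)
      for (k in 0:m) {
        if (k == i - 1) next   # original slot
        a <- if (k >= 1) rest[k] else NA
        b <- if (k < m) rest[k + 1] else NA
        for (rv in c(FALSE, TRUE)) {
          s1 <- if (rv) seg[L] else seg[1]
          s2 <- if (rv) seg[1] else seg[L]
          ins <- 0
          if (!is.na(a)) ins <- ins + D[a, s1]
          if (!is.na(b)) ins <- ins + D[s2, b]
          if (!is.na(a) && !is.na(b)) ins <- ins - D[a, b]
          delta <- ins - removal
          if (delta < best_delta) {
            best_delta <- delta; best_k <- k; best_rev <- rv
          }
        }
      }
      if (!is.na(best_k)) {
        if (best_rev) seg <- rev(seg)
        ord <- append(rest, seg, after = best_k)
        any_improved <- TRUE
        n <- length(ord)
      } else {
        i <- i + 1
      }
    }
  }
  list(ord = ord, improved = any_improved)
}

# alternate 2-opt and or-opt until neither improves
refine_path <- function(ord, D, max_round = 25) {
  for (r in seq_len(max_round)) {
    before <- ord
    ord <- two_opt(ord, D)
    oo <- or_opt(ord, D)
    ord <- oo$ord
    if (identical(ord, before)) break
  }
  ord
}

#' Order the markers of one linkage group
#'
#' Heuristic search for the order minimizing the sum of adjacent
#' recombination fractions (the maximum-likelihood order criterion when
#' crossovers are sparse): co-segregating markers (rf = 0) are collapsed into
#' bins; an initial path is grown by nearest-neighbour from one end of the
#' most-distant (max rf) bin pair; the path is then refined by alternating
#' 2-opt segment reversals and or-opt relocations of 1-3 marker segments
#' (displacements that reversals alone cannot express). Bins expand in
#' lexicographic id order, and the whole procedure is deterministic.
#'
#' @param group character vector of marker ids forming one linkage group.
#' @param rfs a symmetric [rf_table()] covering the group.
#' @return Character vector: the markers in estimated map order.
#' @export
order_markers <- function(group, rfs) {
  stopifnot(inherits(rfs, "rf_table"))
  group <- sort(group)
  if (length(group) <= 2) return(group)
  bins <- coseg_bins(group, rfs$rf)
  bins <- lapply(bins, sort)
  reps <- vapply(bins, `[`, "", 1)
  names(bins) <- reps
  if (length(bins) >= 3) {
    D <- rfs$rf[reps, reps, drop = FALSE]
    D[is.na(D)] <- 0.5          # uninformative pairs look unlinked
    diag(D) <- 0
    # putative ends: the pair at maximum rf; start from its lexicographically
    # smaller member for determinism
    far <- which(D == max(D), arr.ind = TRUE)[1, ]
    start <- sort(c(reps[far[1]], reps[far[2]]))[1]
    ord <- start
    left <- setdiff(reps, start)
    while (length(left)) {
      d <- D[ord[length(ord)], left]
      nxt <- left[order(d, left)][1]
      ord <- c(ord, nxt)
      left <- setdiff(left, nxt)
    }
    ord <- refine_path(ord, D)
  } else {
    ord <- reps
  }
  unlist(bins[ord], use.names = FALSE)
}

#' Build a component linkage map for one population
#'
#' Runs the whole per-population mapping chain: all-pairs recombination
#' fractions, linkage grouping at `cutoff_p`, marker ordering within each
#' group, and cumulative Kosambi distances between adjacent markers. Groups
#' smaller than `min_group_size` are dropped. Orientation of each group is
#' arbitrary up to reversal and is normalized so the lexicographically
#' smaller end marker sits at 0 cM (or, when an anchor table is supplied, so
#' genetic and anchored physical positions correlate positively).
#'
#' @param g a polarized, filtered [genmat()].
#' @param cutoff_p linkage-grouping threshold (default `1e-8`).
#' @param min_group_size smallest group retained on the map (default 2).
#' @param anchors optional anchor table (see [read_anchor_table()]) used only
#'   to orient groups.
#' @param population optional population label stored on the map.
#' @param rfs optional precomputed symmetric [rf_table()] for `g`.
#' @return A `component_map`: data.frame `group`, `marker`, `pos_cM` with
#'   attributes `population` and `params`. Adjacent-pair rf estimates of 0.5
#'   or above (possible with noisy data) are clamped just below 0.5 before
#'   the Kosambi transform.
#' @export
build_component_map <- function(g, cutoff_p = 1e-8, min_group_size = 2,
                                anchors = NULL, population = NULL,
                                rfs = NULL) {
  mk <- setdiff(markers(g), character(0))
  if (length(mk) == 0) {
    warning("empty genotype matrix: returning an empty map")
    return(new_component_map(data.frame(group = character(), marker = character(),
                                        pos_cM = numeric()), population))
  }
  if (is.null(rfs)) rfs <- rf_table(g)
  groups <- group_markers(rfs, cutoff_p)
  groups <- groups[lengths(groups) >= min_group_size]
  rows <- list()
  for (i in seq_along(groups)) {
    ord <- order_markers(groups[[i]], rfs)
    adj <- rfs$rf[cbind(ord[-length(ord)], ord[-1])]
    adj[is.na(adj)] <- 0.499
    adj <- pmin(adj, 0.4999)
    pos <- c(0, cumsum(kosambi(adj)))
    if (decide_flip(ord, pos, anchors)) {
      ord <- rev(ord)
      pos <- max(pos) - rev(pos)
    }
    rows[[i]] <- data.frame(group = sprintf("LG%d", i), marker = ord,
                            pos_cM = pos, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  new_component_map(out, population,
                    params = list(cutoff_p = cutoff_p,
                                  min_group_size = min_group_size))
}

# helpers for group orientation -------------------------------------------

decide_flip <- function(ord, pos, anchors) {
  if (!is.null(anchors)) {
    hit <- anchors[anchors$marker %in% ord, , drop = FALSE]
    if (nrow(hit) >= 3) {
      best <- names(sort(table(hit$ref_chrom), decreasing = TRUE))[1]
      hit <- hit[hit$ref_chrom == best, , drop = FALSE]
      if (nrow(hit) >= 3) {
        gen <- pos[match(hit$marker, ord)]
        rho <- suppressWarnings(stats::cor(gen, hit$bp, method = "spearman"))
        if (!is.na(rho)) return(rho < 0)
      }
    }
  }
  # no usable anchors: lexicographically smaller end marker first
  ord[length(ord)] < ord[1]
}

new_component_map <- function(df, population = NULL, params = list()) {
  structure(df, population = population, params = params,
            class = c("component_map", "data.frame"))
}

#' @export
print.component_map <- function(x, ...) {
  pop <- attr(x, "population")
  cat(sprintf("component_map%s: %d markers in %d linkage groups\n",
              if (is.null(pop)) "" else paste0(" [", pop, "]"),
              nrow(x), length(unique(x$group))))
  if (nrow(x)) {
    s <- stats::aggregate(pos_cM ~ group, as.data.frame(x), max)
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %s: %d markers, %.2f cM\n", s$group[i],
                  sum(x$group == s$group[i]), s$pos_cM[i]))
  }
  invisible(x)
}

#' Read and write linkage maps as TSV
#'
#' Columns `group` (or `chrom`), `marker`, `pos_cM`.
#'
#' @param map a `component_map` or `consensus_map`.
#' @param path file path.
#' @return `read_map()` returns a `component_map`.
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("chrom" %in% names(df) && !"group" %in% names(df))
    names(df)[names(df) == "chrom"] <- "group"
  new_component_map(df[, c("group", "marker", "pos_cM")])
}
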