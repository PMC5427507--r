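# --- constraint-cycle machinery -------------------------------------------
# Order conflicts between component maps show up as directed cycles in the
# strict precedence graph. They are resolved greedily: the edge carrying the
# most cycle traffic is deleted, and the process repeats until the graph is
# acyclic. Cycle participation of an edge u -> v is scored by the number of
# closed walks through it, (sum_k A^k)[v, u], computed by matrix powers --
# exact for short simple cycles and a faithful ranking for longer ones,
# without enumerating cycles explicitly.

# nodes that can lie on a cycle: iteratively strip nodes with no incoming
# or no outgoing edge; what survives contains every cycle
cycle_core <- function(edges, n_nodes) {
  alive <- rep(FALSE, n_nodes)
  alive[unique(c(edges$from, edges$to))] <- TRUE
  repeat {
    keep <- edges$from != edges$to & alive[edges$from] & alive[edges$to]
    e <- edges[keep, , drop = FALSE]
    has_out <- has_in <- rep(FALSE, n_nodes)
    has_out[unique(e$from)] <- TRUE
    has_in[unique(e$to)] <- TRUE
    newalive <- alive & has_out & has_in
    if (identical(newalive, alive)) break
    alive <- newalive
  }
  which(alive)
}

# returns list(edges = retained edges, deleted = log of removed edges)
resolve_conflicts <- function(edges, n_nodes) {
  deleted <- edges[0, , drop = FALSE]
  repeat {
    core <- cycle_core(edges, n_nodes)
    if (length(core) == 0) break
    idx <- match(seq_len(n_nodes), core)      # node -> core position
    in_core <- edges$from %in% core & edges$to %in% core
    ce <- edges[in_core, , drop = FALSE]
    nc <- length(core)
    A <- matrix(0, nc, nc)
    A[cbind(idx[ce$from], idx[ce$to])] <- 1
    S <- matrix(0, nc, nc)
    P <- A
    for (k in seq_len(nc)) {
      S <- S + P
      P <- P %*% A
      mx <- max(P)
      if (mx == 0) break
      if (mx > 1e12) P <- P / mx    # keep the ranking, avoid overflow
    }
    score <- S[cbind(idx[ce$to], idx[ce$from])]  # walks closing each edge
    on_cycle <- score > 0
    if (!any(on_cycle)) break      # peeled core holds no reachable cycle
    cand <- which(on_cycle)
    best <- cand[order(-score[cand], ce$from[cand], ce$to[cand])][1]
    drop <- which(in_core)[best]
    deleted <- rbind(deleted, edges[drop, , drop = FALSE])
    edges <- edges[-drop, , drop = FALSE]
  }
  list(edges = edges, deleted = deleted)
}

as_chrom_frame <- function(x) {
  df <- as.data.frame(x)
  if (!all(c("marker", "pos_cM") %in% names(df)))
    stop("each component needs columns marker and pos_cM")
  if ("group" %in% names(df) && length(unique(df$group)) > 1)
    stop("merge_maps() works on one linkage group/chromosome at a time")
  df <- df[order(df$pos_cM, df$marker), c("marker", "pos_cM")]
  df$pos_cM <- df$pos_cM - min(df$pos_cM)   # each component anchored at 0
  rownames(df) <- NULL
  df
}

#' Merge component maps of one chromosome by linear programming
#'
#' Builds a consensus map over the union of markers by minimizing the
#' weighted mean absolute deviation between consensus inter-marker distances
#' and each component's distances, subject to the order constraints implied
#' by the components: for every pair of markers at most `K` positions apart
#' in some component, the consensus must not reverse their order. Order
#' conflicts between components (directed constraint cycles) are resolved by
#' greedily deleting the constraint participating in the most cycles; every
#' deletion is logged. Component weights are typically population sizes.
#'
#' @param components list of maps for one chromosome: each a `component_map`
#'   (single group) or data.frame with `marker`, `pos_cM`. The maps must be
#'   linked by shared markers.
#' @param K maximum marker-interval span generating order constraints (1-4
#'   in practice).
#' @param weights numeric vector, one weight per component (default equal).
#' @return list of class `consensus_chrom`: `map` (data.frame `marker`,
#'   `pos_cM`, sorted, minimum at 0), `rmse` (per component, after removing
#'   the mean offset), `deleted` (constraint-deletion log), `objective`,
#'   `K`.
#' @export
merge_maps <- function(components, K = 1, weights = NULL) {
  stopifnot(length(components) >= 1, K >= 1)
  comps <- lapply(components, as_chrom_frame)
  if (is.null(weights)) weights <- rep(1, length(comps))
  stopifnot(length(weights) == length(comps), all(weights > 0))
  weights <- weights / sum(weights)
  mk <- unique(unlist(lapply(comps, `[[`, "marker")))
  nm <- length(mk)
  if (length(comps) > 1) {
    shared <- Reduce(intersect, lapply(comps, `[[`, "marker"))
    if (length(shared) == 0) stop("disconnected maps: no shared markers")
  }
  idx <- stats::setNames(seq_len(nm), mk)
  # order constraints: strict precedences within K positions in a component
  ef <- integer(0); et <- integer(0); esrc <- integer(0)
  for (ci in seq_along(comps)) {
    df <- comps[[ci]]
    n <- nrow(df)
    for (i in seq_len(n)) {
      for (j in seq(i + 1, length.out = min(K, n - i))) {
        if (df$pos_cM[j] > df$pos_cM[i]) {
          ef <- c(ef, idx[[df$marker[i]]])
          et <- c(et, idx[[df$marker[j]]])
          esrc <- c(esrc, ci)
        }
      }
    }
  }
  edges <- data.frame(from = ef, to = et, component = esrc)
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  res <- resolve_conflicts(edges, nm)
  deleted <- res$deleted
  if (nrow(deleted)) {
    deleted$from <- mk[deleted$from]
    deleted$to <- mk[deleted$to]
  }
  # objective terms: adjacent-pair distances per component
  tf <- integer(0); tt <- integer(0); td <- numeric(0); tw <- numeric(0)
  for (ci in seq_along(comps)) {
    df <- comps[[ci]]
    if (nrow(df) < 2) next
    a <- df$marker[-nrow(df)]; b <- df$marker[-1]
    tf <- c(tf, idx[a]); tt <- c(tt, idx[b])
    td <- c(td, diff(df$pos_cM))
    tw <- c(tw, rep(weights[ci] / (nrow(df) - 1), nrow(df) - 1))
  }
  nt <- length(tf)
  if (nt == 0) {
    x <- rep(0, nm)
    objective <- 0
  } else {
    # The LP is solved as weighted L1 (median) regression of the component
    # inter-marker distances on position differences, under the retained
    # order constraints: min sum_t w_t |d_t - (x_to - x_from)| s.t. Rx >= 0.
    # Positions are identifiable up to translation, so marker 1 is the
    # anchor (column dropped, position 0).
    difrow <- function(from, to, p) {
      v <- numeric(p)
      if (to > 1) v[to - 1] <- v[to - 1] + 1
      if (from > 1) v[from - 1] <- v[from - 1] - 1
      v
    }
    p <- nm - 1
    X <- t(matrix(vapply(seq_len(nt), function(t) difrow(tf[t], tt[t], p),
                         numeric(p)), nrow = p))
    ne <- nrow(res$edges)
    R <- if (ne > 0)
      t(matrix(vapply(seq_len(ne),
                      function(k) difrow(res$edges$from[k], res$edges$to[k], p),
                      numeric(p)), nrow = p))
    else matrix(0, 1, p)   # vacuous constraint keeps the solver interface happy
    rvec <- if (ne > 0) rep(0, ne) else -1
    fit <- quantreg::rq.fit.fnc(X * tw, td * tw, R = R, r = rvec, tau = 0.5)
    x <- c(0, fit$coefficients)
    objective <- sum(tw * abs(td - as.numeric(X %*% fit$coefficients)))
  }
  x <- x - min(x)
  # interior-point solutions carry ~1e-8 numerical noise; positions are
  # snapped to 1e-6 cM so exact agreement (e.g. identical components) is
  # reported as exactly zero RMSE
  x <- round(x, 6)
  out <- data.frame(marker = mk, pos_cM = x, stringsAsFactors = FALSE)
  out <- out[order(out$pos_cM, out$marker), ]
  rownames(out) <- NULL
  rmse <- vapply(comps, function(df) {
    d <- out$pos_cM[match(df$marker, out$marker)] - df$pos_cM
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    sqrt(mean((d - mean(d))^2))
  }, 0)
  structure(list(map = out, rmse = rmse, deleted = deleted,
                 objective = objective, K = K),
            class = "consensus_chrom")
}

#' Select the interval parameter K by minimum mean RMSE and SD
#'
#' Runs [merge_maps()] for each candidate `K`, scores each consensus by the
#' mean over components of the consensus-vs-component RMSE plus the standard
#' deviation of those RMSEs, and returns the consensus at the best K (ties
#' go to the smaller K). RMSE is not monotone in K, so every candidate is
#' evaluated.
#'
#' @inheritParams merge_maps
#' @param Ks candidate interval sizes (default `1:4`).
#' @return The winning `consensus_chrom`, with a per-K diagnostics
#'   data.frame (`K`, per-component RMSE, `mean_rmse`, `sd_rmse`, `score`)
#'   in `$diagnostics`.
#' @export
select_k <- function(components, Ks = 1:4, weights = NULL) {
  fits <- lapply(Ks, function(k) merge_maps(components, K = k, weights))
  diag <- do.call(rbind, lapply(seq_along(Ks), function(i) {
    rm <- fits[[i]]$rmse
    sdv <- if (length(rm) > 1) stats::sd(rm) else 0
    data.frame(K = Ks[i], t(stats::setNames(rm, paste0("rmse_", seq_along(rm)))),
               mean_rmse = mean(rm), sd_rmse = sdv,
               score = mean(rm) + sdv)
  }))
  best <- which(diag$score <= min(diag$score) + 1e-12)[1]
  fit <- fits[[best]]
  fit$diagnostics <- diag
  fit
}

# pair linkage groups across component maps by shared-marker counts
match_groups <- function(maps) {
  base <- maps[[1]]
  bg <- unique(base$group)
  lapply(bg, function(g) {
    mk <- base$marker[base$group == g]
    sel <- lapply(maps[-1], function(m) {
      if (nrow(m) == 0) return(NULL)
      ov <- vapply(unique(m$group),
                   function(h) length(intersect(mk, m$marker[m$group == h])), 0L)
      if (max(ov) == 0) return(NULL)
      best <- unique(m$group)[which.max(ov)]
      m[m$group == best, c("marker", "pos_cM")]
    })
    c(list(base[base$group == g, c("marker", "pos_cM")]),
      Filter(Negate(is.null), sel))
  })
}

#' Build a consensus map across populations
#'
#' Pairs the linkage groups of the component maps by shared-marker overlap,
#' merges each chromosome with [select_k()], and stacks the results. With a
#' single component the consensus is the component itself.
#'
#' @param maps list of `component_map`s (one per population).
#' @param Ks candidate interval sizes passed to [select_k()].
#' @param weights per-population weights (e.g. population sizes).
#' @return A `consensus_map`: data.frame `chrom`, `marker`, `pos_cM` with
#'   attributes `chosen_k`, `diagnostics` and `deleted` (per chromosome).
#' @export
build_consensus <- function(maps, Ks = 1:4, weights = NULL) {
  stopifnot(length(maps) >= 1)
  sets <- match_groups(maps)
  labels <- unique(maps[[1]]$group)
  rows <- list(); kk <- list(); dg <- list(); del <- list()
  for (i in seq_along(sets)) {
    fit <- select_k(sets[[i]], Ks = Ks, weights =
                      if (is.null(weights)) NULL else
                        weights[seq_along(sets[[i]])])
    rows[[i]] <- data.frame(chrom = labels[i], fit$map,
                            stringsAsFactors = FALSE)
    kk[[labels[i]]] <- fit$K
    dg[[labels[i]]] <- fit$diagnostics
    del[[labels[i]]] <- fit$deleted
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, chosen_k = kk, diagnostics = dg, deleted = del,
            class = c("consensus_map", "data.frame"))
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("consensus_map: %d markers on %d chromosomes\n",
              nrow(x), length(unique(x$chrom))))
  k <- attr(x, "chosen_k")
  if (length(k))
    cat("chosen K:", paste(names(k), unlist(k), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Rank agreement between a consensus map and a component map
#'
#' Spearman rank correlation (via [spearman_rho()]) of the shared-marker
#' orders on one chromosome.
#'
#' @param consensus data.frame with `marker`, `pos_cM` (one chromosome).
#' @param component data.frame with `marker`, `pos_cM` (one chromosome).
#' @return Spearman's rho, or `NA` with fewer than 3 shared markers.
#' @export
consensus_vs_component_ranks <- function(consensus, component) {
  shared <- intersect(consensus$marker, component$marker)
  if (length(shared) < 3) return(NA_real_)
  spearman_rho(consensus$pos_cM[match(shared, consensus$marker)],
               component$pos_cM[match(shared, component$marker)])
}
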