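#' Read an anchor table of reference best hits
#'
#' BED-like TSV with columns `marker`, `ref_chrom`, `bp`, `e_value` giving
#' each marker tag's best sequence hit on a reference genome. Hits above the
#' e-value threshold are discarded and only the single best (smallest
#' e-value) hit per marker is kept.
#'
#' @param path file path.
#' @param e_max e-value threshold (default `1e-5`).
#' @return data.frame `marker`, `ref_chrom`, `bp`, `e_value`, one row per
#'   marker.
#' @export
read_anchor_table <- function(path, e_max = 1e-5) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  filter_anchors(df, e_max)
}

#' @rdname read_anchor_table
#' @param anchors data.frame with the same columns, already in memory.
#' @export
filter_anchors <- function(anchors, e_max = 1e-5) {
  need <- c("marker", "ref_chrom", "bp")
  if (!all(need %in% names(anchors)))
    stop("anchor table needs columns ", paste(need, collapse = ", "))
  if (!"e_value" %in% names(anchors)) anchors$e_value <- 0
  anchors <- anchors[anchors$e_value <= e_max, , drop = FALSE]
  anchors <- anchors[order(anchors$marker, anchors$e_value), ]
  anchors <- anchors[!duplicated(anchors$marker), , drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}

# homeologous-group label: the digits of a chromosome name ("3A", "chr3B",
# "3H" all collapse to "3")
chrom_group <- function(chrom) {
  g <- gsub("[^0-9]", "", as.character(chrom))
  ifelse(nchar(g) > 0, g, NA_character_)
}

#' Assign linkage groups to chromosomes by anchor plurality
#'
#' Each linkage group is labelled with the homeologous chromosome group
#' (e.g. wheat 3A/3B/3D collapse to "3") holding the plurality of its
#' anchored markers. Plurality ties, or groups without any anchored marker,
#' are left unassigned (`NA`) with a warning.
#'
#' @param map a `component_map` or `consensus_map`.
#' @param anchors a filtered anchor table ([read_anchor_table()]).
#' @return Named character vector: linkage group -> chromosome group label.
#' @export
assign_chromosomes <- function(map, anchors) {
  df <- as.data.frame(map)
  gcol <- if ("group" %in% names(df)) "group" else "chrom"
  groups <- unique(df[[gcol]])
  out <- stats::setNames(rep(NA_character_, length(groups)), groups)
  for (g in groups) {
    mk <- df$marker[df[[gcol]] == g]
    hit <- anchors[anchors$marker %in% mk, , drop = FALSE]
    if (nrow(hit) == 0) {
      warning("linkage group ", g, " has no anchored markers")
      next
    }
    votes <- table(chrom_group(hit$ref_chrom))
    top <- votes[votes == max(votes)]
    if (length(top) > 1) {
      warning("linkage group ", g, " has a plurality tie: ",
              paste(names(top), collapse = " vs "))
      next
    }
    out[g] <- names(top)
  }
  out
}

#' Spearman's rank correlation by the classic formula
#'
#' `rho = 1 - 6 * sum(d_i^2) / (n (n^2 - 1))` where `d_i` are the rank
#' differences of the paired observations. Ties in either variable are
#' resolved by average ranks; the classic formula assumes none, so with ties
#' this is an approximation to the moment correlation of the ranks.
#'
#' @param x,y paired numeric vectors (e.g. genetic cM and physical bp
#'   positions), length at least 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(NA_real_)
  d <- rank(x, ties.method = "average") - rank(y, ties.method = "average")
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Synteny and collinearity summary against a reference genome
#'
#' Quantifies how the genetic map lines up with an anchored reference:
#' the fraction of map markers with a retained best hit; the syntenic
#' fraction (anchored markers whose hit lies on the homeologous group
#' expected for their linkage group); Spearman's rho between genetic and
#' physical position per (linkage group, reference group) pair with at least
#' 3 shared markers; and the underlying dot-plot table.
#'
#' @param map a `component_map` or `consensus_map`.
#' @param anchors a filtered anchor table.
#' @param expected optional named vector mapping linkage group ->
#'   homeologous group label; default [assign_chromosomes()].
#' @return list of class `synteny_summary`: `hit_fraction`,
#'   `syntenic_fraction`, `assignments`, `rho` (data.frame `group`,
#'   `ref_group`, `n`, `rho`), `dotplot` (data.frame `group`, `marker`,
#'   `pos_cM`, `ref_chrom`, `bp`, `syntenic`).
#' @export
synteny_summary <- function(map, anchors, expected = NULL) {
  df <- as.data.frame(map)
  gcol <- if ("group" %in% names(df)) "group" else "chrom"
  if (nrow(anchors) == 0) {
    return(structure(list(hit_fraction = 0, syntenic_fraction = 0,
                          assignments = NULL,
                          rho = data.frame(group = character(),
                                           ref_group = character(),
                                           n = integer(), rho = numeric()),
                          dotplot = data.frame()),
                     class = "synteny_summary"))
  }
  if (is.null(expected))
    expected <- suppressWarnings(assign_chromosomes(map, anchors))
  hit <- merge(df[, c(gcol, "marker", "pos_cM")], anchors, by = "marker")
  hit$ref_group <- chrom_group(hit$ref_chrom)
  hit$syntenic <- !is.na(expected[hit[[gcol]]]) &
    hit$ref_group == expected[hit[[gcol]]]
  rho <- list()
  for (g in unique(hit[[gcol]])) {
    for (rg in unique(hit$ref_group[hit[[gcol]] == g])) {
      sel <- hit[[gcol]] == g & hit$ref_group == rg
      if (sum(sel) >= 3)
        rho[[length(rho) + 1]] <- data.frame(
          group = g, ref_group = rg, n = sum(sel),
          rho = spearman_rho(hit$pos_cM[sel], hit$bp[sel]),
          stringsAsFactors = FALSE)
    }
  }
  rho <- if (length(rho)) do.call(rbind, rho)
  else data.frame(group = character(), ref_group = character(),
                  n = integer(), rho = numeric())
  dot <- hit[order(hit[[gcol]], hit$pos_cM),
             c(gcol, "marker", "pos_cM", "ref_chrom", "bp", "syntenic")]
  names(dot)[1] <- "group"
  rownames(dot) <- NULL
  structure(list(hit_fraction = nrow(hit) / length(unique(df$marker)),
                 syntenic_fraction = mean(hit$syntenic),
                 assignments = expected, rho = rho, dotplot = dot),
            class = "synteny_summary")
}

#' @export
print.synteny_summary <- function(x, ...) {
  cat(sprintf("synteny_summary: %.1f%% of markers anchored, %.1f%% syntenic\n",
              100 * x$hit_fraction, 100 * x$syntenic_fraction))
  if (nrow(x$rho)) print(x$rho, row.names = FALSE)
  invisible(x)
}
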