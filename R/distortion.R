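#' Scan a map for segregation distortion
#'
#' For every mapped marker present in the genotype matrix, tests the
#' genotype counts against the Mendelian 1:2:1 expectation (chi-square,
#' 2 df, via [marker_stats()]) and assembles the profiles the scan is read
#' from: `-log10(p)` and the three genotype-class frequencies along the map,
#' the per-chromosome proportion of distorted markers (`p <= alpha`), and
#' the distorted regions (runs of at least two consecutive significant
#' markers, see [find_regions()]).
#'
#' @param g a polarized [genmat()].
#' @param map a `consensus_map` or `component_map` (column `chrom` or
#'   `group` names the chromosome).
#' @param alpha significance level (default 0.01, uncorrected, as is
#'   conventional for distortion scans).
#' @param max_gap_cM optional: bridge non-significant gaps up to this many
#'   cM when calling regions (default `NULL`, off).
#' @return list of class `distortion_scan`: `markers` (data.frame `chrom`,
#'   `marker`, `pos_cM`, `chi2`, `p_value`, `neg_log10_p`, `f_AA`, `f_AB`,
#'   `f_BB`), `chromosomes` (data.frame `chrom`, `n_markers`, `n_distorted`,
#'   `prop_distorted`), `regions` (see [find_regions()]), `alpha`.
#' @export
scan_distortion <- function(g, map, alpha = 0.01, max_gap_cM = NULL) {
  df <- as.data.frame(map)
  if (!"chrom" %in% names(df) && "group" %in% names(df))
    names(df)[names(df) == "group"] <- "chrom"
  df <- df[df$marker %in% markers(g), c("chrom", "marker", "pos_cM")]
  df <- df[order(match(df$chrom, unique(df$chrom)), df$pos_cM, df$marker), ]
  st <- marker_stats(g, df$marker)
  n <- st$n_AA + st$n_AB + st$n_BB
  out <- data.frame(df, chi2 = st$chi2, p_value = st$p_value,
                    neg_log10_p = -log10(st$p_value),
                    f_AA = st$n_AA / n, f_AB = st$n_AB / n,
                    f_BB = st$n_BB / n, row.names = NULL)
  sig <- !is.na(out$p_value) & out$p_value <= alpha
  chromtab <- do.call(rbind, lapply(unique(out$chrom), function(ch) {
    sel <- out$chrom == ch
    data.frame(chrom = ch, n_markers = sum(sel), n_distorted = sum(sig[sel]),
               prop_distorted = mean(sig[sel]), stringsAsFactors = FALSE)
  }))
  scan <- structure(list(markers = out, chromosomes = chromtab,
                         regions = NULL, alpha = alpha),
                    class = "distortion_scan")
  scan$regions <- find_regions(scan, alpha, max_gap_cM)
  scan
}

#' Identify distorted regions
#'
#' A distorted region is a maximal run of two or more consecutive
#' map-ordered markers, each significant at `alpha`. Optionally,
#' non-significant stretches up to `max_gap_cM` wide may be bridged.
#'
#' @param scan a [scan_distortion()] result (or its `markers` data.frame).
#' @param alpha significance level.
#' @param max_gap_cM bridge gaps up to this many cM (`NULL` = off).
#' @return data.frame: `chrom`, `start_cM`, `end_cM`, `n_markers`.
#' @export
find_regions <- function(scan, alpha = 0.01, max_gap_cM = NULL) {
  df <- if (inherits(scan, "distortion_scan")) scan$markers else scan
  regions <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    sub <- sub[order(sub$pos_cM), ]
    sig <- !is.na(sub$p_value) & sub$p_value <= alpha
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (!is.null(max_gap_cM) && nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (k in seq(2, nrow(runs))) {
        gap <- sub$pos_cM[runs$start[k]] - sub$pos_cM[merged$end[nrow(merged)]]
        if (gap <= max_gap_cM) {
          merged$end[nrow(merged)] <- runs$end[k]
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
      runs <- merged
    }
    nsig <- vapply(seq_len(nrow(runs)), function(k)
      sum(sig[runs$start[k]:runs$end[k]]), 0L)
    runs <- runs[nsig >= 2, , drop = FALSE]
    if (nrow(runs))
      regions[[length(regions) + 1]] <- data.frame(
        chrom = ch, start_cM = sub$pos_cM[runs$start],
        end_cM = sub$pos_cM[runs$end], n_markers = nsig[nsig >= 2],
        stringsAsFactors = FALSE)
  }
  if (length(regions)) do.call(rbind, c(regions, list(make.row.names = FALSE)))
  else data.frame(chrom = character(), start_cM = numeric(),
                  end_cM = numeric(), n_markers = integer())
}

#' @export
print.distortion_scan <- function(x, ...) {
  cat(sprintf("distortion_scan: %d markers, alpha = %g\n",
              nrow(x$markers), x$alpha))
  print(x$chromosomes, row.names = FALSE)
  cat(sprintf("%d distorted region(s)\n", nrow(x$regions)))
  invisible(x)
}
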