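#' Polarize SNP calls against the two parents
#'
#' Markers are kept only when both parents are called, homozygous and carry
#' opposite alleles. Surviving calls are recoded so that `AA` is the
#' `parent1` homozygote and `BB` the `parent2` homozygote (labels are swapped
#' for markers where parent1 was called `BB`).
#'
#' @param g a [genmat()] whose columns include both parents.
#' @param parent1,parent2 parental column ids; default the flagged parents.
#' @return A polarized [genmat()] restricted to surviving markers, with a
#'   data.frame of dropped markers and reasons (`missing_parent`,
#'   `het_parent`, `monomorphic`) in `attr(, "polarize_report")`.
#' @export
polarize <- function(g, parent1 = g$parents[1], parent2 = g$parents[2]) {
  if (is.na(parent1) || is.na(parent2) ||
      !all(c(parent1, parent2) %in% individuals(g)))
    stop("both parent columns must be present")
  p1 <- g$calls[, parent1]
  p2 <- g$calls[, parent2]
  reason <- rep(NA_character_, nrow(g$calls))
  reason[is.na(p1) | is.na(p2)] <- "missing_parent"
  het <- is.na(reason) & (p1 == "AB" | p2 == "AB")
  reason[het] <- "het_parent"
  mono <- is.na(reason) & p1 == p2
  reason[mono] <- "monomorphic"
  keep <- is.na(reason)
  report <- data.frame(marker = markers(g)[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  calls <- g$calls[keep, , drop = FALSE]
  swap <- p1[keep] == "BB"
  if (any(swap)) {
    sw <- calls[swap, , drop = FALSE]
    sw[] <- c(AA = "BB", AB = "AB", BB = "AA")[sw]
    calls[swap, ] <- sw
  }
  depth <- if (!is.null(g$depth)) g$depth[keep, , drop = FALSE]
  out <- genmat(calls, depth, c(parent1, parent2))
  attr(out, "polarize_report") <- report
  out
}

#' Per-marker segregation and quality statistics
#'
#' Counts the three genotype classes over non-missing progeny calls and tests
#' them against the Mendelian F2 expectation `(n/4, n/2, n/4)` with a
#' chi-square statistic on 2 degrees of freedom. The minor allele frequency is
#' computed from genotype-derived allele counts (a heterozygote contributes
#' one copy of each allele).
#'
#' @param g a [genmat()] (parental columns are excluded from all statistics).
#' @param which_markers marker ids; default all.
#' @return data.frame with one row per marker: `n_AA`, `n_AB`, `n_BB`,
#'   `n_missing`, `missing_fraction`, `maf`, `het_fraction`, `chi2`,
#'   `p_value`. Markers with zero non-missing calls get `NA` statistics.
#' @export
marker_stats <- function(g, which_markers = markers(g)) {
  codes <- gm_codes(g)[which_markers, , drop = FALSE]
  n_ind <- ncol(codes)
  nAA <- rowSums(codes == 0L, na.rm = TRUE)
  nAB <- rowSums(codes == 1L, na.rm = TRUE)
  nBB <- rowSums(codes == 2L, na.rm = TRUE)
  n <- nAA + nAB + nBB
  miss <- n_ind - n
  # allele counts kept integral so boundary frequencies are exact
  maf <- pmin(2 * nAA + nAB, 2 * nBB + nAB) / (2 * n)
  hetf <- nAB / n
  e <- cbind(n / 4, n / 2, n / 4)
  o <- cbind(nAA, nAB, nBB)
  chi2 <- rowSums((o - e)^2 / e)
  p <- stats::pchisq(chi2, df = 2, lower.tail = FALSE)
  empty <- n == 0
  maf[empty] <- hetf[empty] <- chi2[empty] <- p[empty] <- NA_real_
  data.frame(marker = which_markers, n_AA = nAA, n_AB = nAB, n_BB = nBB,
             n_missing = miss, missing_fraction = miss / n_ind,
             maf = maf, het_fraction = hetf, chi2 = chi2, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker filter policies
#'
#' Two stock policies mirror the two marker sets of the mapping workflow:
#' the `framework` set (strict: at most 10% missing, MAF at least 20%,
#' heterozygosity at most 80%, segregation p at least 0.01) used to build
#' component maps, and the `placement` set (at most 40% missing, no other
#' thresholds) used only to place extra markers by recombination fraction.
#' All thresholds are strict removals: a marker sitting exactly on a
#' boundary survives.
#'
#' @param set `"framework"` or `"placement"`, or pass thresholds directly.
#' @param maf_min,het_max,missing_max,distortion_alpha threshold overrides.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(set = c("framework", "placement"),
                          maf_min = NULL, het_max = NULL, missing_max = NULL,
                          distortion_alpha = NULL) {
  set <- match.arg(set)
  pol <- if (set == "framework") {
    list(maf_min = 0.20, het_max = 0.80, missing_max = 0.10,
         distortion_alpha = 0.01)
  } else {
    list(maf_min = 0, het_max = 1, missing_max = 0.40, distortion_alpha = 0)
  }
  for (nm in c("maf_min", "het_max", "missing_max", "distortion_alpha")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]")
      pol[[nm]] <- v
    }
  }
  structure(c(pol, list(set = set)), class = "filter_policy")
}

#' Apply a marker filter policy
#'
#' Filters are applied in the fixed order missing -> MAF -> heterozygosity ->
#' segregation distortion (parental criteria having already been enforced by
#' [polarize()]); each removed marker is attributed to the first criterion it
#' fails, so per-criterion counts are reproducible.
#'
#' @param g a polarized [genmat()].
#' @param policy a [filter_policy()].
#' @return list with `genmat` (surviving markers) and `report` (data.frame
#'   `marker`, `pass`, `criterion` where `criterion` is one of `missing`,
#'   `maf`, `het`, `distortion`, or `NA` for survivors).
#' @export
apply_filters <- function(g, policy = filter_policy("framework")) {
  st <- marker_stats(g)
  crit <- rep(NA_character_, nrow(st))
  bad_stats <- is.na(st$maf)  # all-missing markers auto-fail
  crit[bad_stats | st$missing_fraction > policy$missing_max] <- "missing"
  sel <- is.na(crit) & st$maf < policy$maf_min
  crit[sel] <- "maf"
  sel <- is.na(crit) & st$het_fraction > policy$het_max
  crit[sel] <- "het"
  sel <- is.na(crit) & st$p_value < policy$distortion_alpha
  crit[sel] <- "distortion"
  keep <- is.na(crit)
  if (!any(keep)) warning("no markers survive the filter policy")
  report <- data.frame(marker = st$marker, pass = keep, criterion = crit,
                       stringsAsFactors = FALSE)
  list(genmat = g[st$marker[keep], ], report = report)
}
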