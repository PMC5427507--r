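# Two-locus F2 intercross class probabilities. Genotypes coded 0/1/2 at each
# marker; classes indexed (i, j). Under recombination fraction r and coupling
# phase, gamete types have probabilities (1-r)/2 (parental) and r/2
# (recombinant); the double heterozygote (1,1) pools the two-parental and
# two-recombinant routes: ((1-r)^2 + r^2) / 2.
f2_class_probs <- function(r) {
  q <- 1 - r
  matrix(c(q^2 / 4,     r * q / 2, r^2 / 4,
           r * q / 2, (q^2 + r^2) / 2, r * q / 2,
           r^2 / 4,     r * q / 2, q^2 / 4),
         3, 3, byrow = TRUE)
}

# expected recombinant gametes (out of 2) carried by each class; the (1,1)
# class is a mixture handled inside the EM
f2_rec_gametes <- matrix(c(0, 1, 2,
                           1, NA, 1,
                           2, 1, 0), 3, 3, byrow = TRUE)

# Vectorized EM over parallel 9-class count sets. Each argument is an array
# of counts for the class (i,j); all must share a shape. Returns an array of
# ML recombination fractions in [0, 0.5].
rf_em_counts <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22,
                         tol = 1e-12, max_iter = 200) {
  N <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  fixed <- n01 + n10 + n12 + n21 + 2 * (n02 + n20)
  r <- array(0.25, dim = if (is.null(dim(N))) length(N) else dim(N))
  ok <- N > 0
  for (it in seq_len(max_iter)) {
    q <- 1 - r
    e11 <- 2 * r^2 / (q^2 + r^2)          # E[rec gametes | double het]
    rn <- (fixed + n11 * e11) / (2 * N)
    rn <- pmin(pmax(rn, 0), 0.5)
    if (max(abs(rn - r)[ok], 0) < tol) { r <- rn; break }
    r <- rn
  }
  r[!ok] <- NA_real_
  r
}

# log10-likelihood of the 9-class counts at recombination fraction r,
# vectorized over parallel count sets
f2_loglik10 <- function(counts, r) {
  q <- 1 - r
  safe <- function(x) log10(pmax(x, 1e-300))
  counts$n00 * safe(q^2 / 4) + counts$n22 * safe(q^2 / 4) +
    counts$n02 * safe(r^2 / 4) + counts$n20 * safe(r^2 / 4) +
    (counts$n01 + counts$n10 + counts$n12 + counts$n21) * safe(r * q / 2) +
    counts$n11 * safe((q^2 + r^2) / 2)
}

pair_counts <- function(c1, c2) {
  out <- list()
  for (a in 0:2) for (b in 0:2)
    out[[sprintf("n%d%d", a, b)]] <-
      sum(!is.na(c1) & !is.na(c2) & c1 == a & c2 == b)
  out
}

#' Estimate the recombination fraction between two markers (F2, EM)
#'
#' Maximum-likelihood estimation of the recombination fraction between two
#' co-dominant markers in an F2 intercross. The nine two-locus genotype
#' classes have closed-form probabilities in `r`; the double-heterozygote
#' class, a mixture of the two-parental-gamete and two-recombinant-gamete
#' routes, is resolved by expectation (EM). Individuals missing either call
#' are excluded. `lod` is `log10 L(r_hat) / L(0.5)`, floored at 0.
#'
#' @param g a polarized [genmat()].
#' @param m1,m2 marker ids.
#' @return list of class `pairwise_rf`: `rf`, `lod`, `n_informative`, and the
#'   9 class counts. Fewer than 2 doubly informative individuals gives
#'   `rf = NA` with `flag = "insufficient_data"`.
#' @export
estimate_rf_f2 <- function(g, m1, m2) {
  codes <- gm_codes(g)
  cn <- pair_counts(codes[m1, ], codes[m2, ])
  n <- sum(unlist(cn))
  if (n < 2) {
    return(structure(list(markers = c(m1, m2), rf = NA_real_, lod = NA_real_,
                          n_informative = n, counts = cn,
                          flag = "insufficient_data"),
                     class = "pairwise_rf"))
  }
  r <- as.numeric(rf_em_counts(cn$n00, cn$n01, cn$n02, cn$n10, cn$n11,
                               cn$n12, cn$n20, cn$n21, cn$n22))
  lod <- max(0, f2_loglik10(cn, r) - f2_loglik10(cn, 0.5))
  structure(list(markers = c(m1, m2), rf = r, lod = lod, n_informative = n,
                 counts = cn, flag = NA_character_),
            class = "pairwise_rf")
}

# 9 cross-tabulation count matrices between the rows of two code matrices,
# via indicator-matrix products; rows of the result index `codes1` markers
cross_counts <- function(codes1, codes2) {
  ind <- function(m, v) {
    x <- (!is.na(m) & m == v) * 1
    x
  }
  I1 <- lapply(0:2, function(v) ind(codes1, v))
  I2 <- lapply(0:2, function(v) ind(codes2, v))
  out <- list()
  for (a in 0:2) for (b in 0:2)
    out[[sprintf("n%d%d", a, b)]] <- tcrossprod(I1[[a + 1]], I2[[b + 1]])
  out
}

# chi-square independence test of the 3x3 two-locus table, vectorized over
# the count matrices; returns upper-tail p-values
indep_pvalue <- function(cn) {
  R <- list(cn$n00 + cn$n01 + cn$n02,
            cn$n10 + cn$n11 + cn$n12,
            cn$n20 + cn$n21 + cn$n22)
  C <- list(cn$n00 + cn$n10 + cn$n20,
            cn$n01 + cn$n11 + cn$n21,
            cn$n02 + cn$n12 + cn$n22)
  N <- R[[1]] + R[[2]] + R[[3]]
  X2 <- 0
  for (a in 1:3) for (b in 1:3) {
    E <- R[[a]] * C[[b]] / pmax(N, 1)
    O <- cn[[sprintf("n%d%d", a - 1, b - 1)]]
    term <- (O - E)^2 / ifelse(E > 0, E, 1)
    term[E == 0] <- 0
    X2 <- X2 + term
  }
  nzr <- (R[[1]] > 0) + (R[[2]] > 0) + (R[[3]] > 0)
  nzc <- (C[[1]] > 0) + (C[[2]] > 0) + (C[[3]] > 0)
  df <- pmax(nzr - 1, 0) * pmax(nzc - 1, 0)
  p <- array(1, dim = dim(X2))
  pos <- df > 0 & N > 0
  p[pos] <- stats::pchisq(X2[pos], df[pos], lower.tail = FALSE)
  p
}

#' All-pairs recombination fractions, LODs and independence p-values
#'
#' Computes, for every marker pair (or every cross pair between two marker
#' sets), the EM recombination fraction, the LOD score and the p-value of the
#' chi-square independence test of the two-locus contingency table. Built on
#' indicator-matrix products, so it scales to thousands of markers.
#'
#' @param g a polarized [genmat()].
#' @param markers1 row marker set (default all markers).
#' @param markers2 column marker set (default `markers1`, the symmetric case).
#' @return list of class `rf_table` with matrices `rf`, `lod`, `n`
#'   (informative individuals) and `p_indep`, plus the marker id vectors.
#'   Pairs with fewer than 2 informative individuals get `NA` rf/lod.
#' @export
rf_table <- function(g, markers1 = markers(g), markers2 = NULL) {
  codes <- gm_codes(g)
  symmetric <- is.null(markers2)
  if (symmetric) markers2 <- markers1
  c1 <- codes[markers1, , drop = FALSE]
  c2 <- codes[markers2, , drop = FALSE]
  cn <- cross_counts(c1, c2)
  n <- Reduce(`+`, cn)
  rf <- rf_em_counts(cn$n00, cn$n01, cn$n02, cn$n10, cn$n11, cn$n12,
                     cn$n20, cn$n21, cn$n22)
  lod <- f2_loglik10(cn, rf) - f2_loglik10(cn, 0.5)
  lod[lod < 0] <- 0
  low <- n < 2
  rf[low] <- NA_real_
  lod[low] <- NA_real_
  p <- indep_pvalue(cn)
  dn <- list(markers1, markers2)
  dimnames(rf) <- dimnames(lod) <- dimnames(n) <- dimnames(p) <- dn
  if (symmetric) diag(rf) <- 0
  structure(list(rf = rf, lod = lod, n = n, p_indep = p,
                 markers1 = markers1, markers2 = markers2,
                 symmetric = symmetric),
            class = "rf_table")
}
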