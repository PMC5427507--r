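#' Construct a true marker map for simulation
#'
#' Lays out markers uniformly at random along each chromosome of a simulated
#' genome. This is the ground truth that the mapping pipeline is later asked
#' to recover.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom integer vector (length 1 or `n_chrom`) of marker
#'   counts, each at least 2.
#' @param lengths_cM numeric vector (length 1 or `n_chrom`) of chromosome
#'   lengths in centimorgans, all positive.
#' @param seed integer seed; the same call with the same seed is bit-identical.
#' @param chrom_names optional chromosome names; default `"1U"`, `"2U"`, ...
#' @return A `true_map`: data.frame with columns `marker`, `chrom`, `pos_cM`,
#'   sorted by chromosome then position, with the chromosome lengths in
#'   `attr(, "lengths_cM")`.
#' @export
make_true_map <- function(n_chrom, markers_per_chrom, lengths_cM, seed,
                          chrom_names = NULL) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  markers_per_chrom <- rep_len(as.integer(markers_per_chrom), n_chrom)
  lengths_cM <- rep_len(as.numeric(lengths_cM), n_chrom)
  if (any(markers_per_chrom < 2)) stop("each chromosome needs >= 2 markers")
  if (any(lengths_cM <= 0)) stop("chromosome lengths must be positive")
  if (is.null(chrom_names)) chrom_names <- paste0(seq_len(n_chrom), "U")
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n_chrom), function(i) {
    pos <- sort(stats::runif(markers_per_chrom[i], 0, lengths_cM[i]))
    data.frame(
      marker = sprintf("c%dm%04d", i, seq_len(markers_per_chrom[i])),
      chrom = chrom_names[i], pos_cM = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, lengths_cM = stats::setNames(lengths_cM, chrom_names),
            class = c("true_map", "data.frame"))
}

#' Simulation settings for a synthetic F2 GBS population
#'
#' Bundles the knobs of the generator: population size, the observation model
#' (sequencing depth, genotyping error, missingness) and viability selection.
#' Heterozygote undercalling is not a free parameter: it follows mechanically
#' from `mean_depth` because a heterozygous site sequenced to depth `d` yields
#' reads from a single allele with probability `2 * (1/2)^d`.
#'
#' @param n_individuals F2 population size.
#' @param missing_rate target overall missing-call rate in `[0, 1]`
#'   (missingness from zero-depth cells counts toward it).
#' @param genotyping_error_rate probability that a non-missing call is
#'   replaced by one of the two other genotype classes.
#' @param mean_depth Poisson mean of per-call read depth; `Inf` disables the
#'   depth model (no undercalling, no zero-depth missingness).
#' @param distortion_loci `NULL`, or a data.frame with columns `chrom`,
#'   `pos_cM`, `w_AA`, `w_AB`, `w_BB`: viability weights in `[0, 1]` applied
#'   multiplicatively to each simulated individual (rejection sampling keeps
#'   the population size fixed).
#' @param shared_marker_fraction fraction of markers polymorphic in both
#'   populations when two populations are generated.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 140, missing_rate = 0,
                       genotyping_error_rate = 0, mean_depth = Inf,
                       distortion_loci = NULL, shared_marker_fraction = 0.15,
                       seed = 1) {
  stopifnot(n_individuals >= 1)
  for (p in c(missing_rate, genotyping_error_rate, shared_marker_fraction))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (!is.null(distortion_loci)) {
    need <- c("chrom", "pos_cM", "w_AA", "w_AB", "w_BB")
    if (!all(need %in% names(distortion_loci)))
      stop("distortion_loci needs columns ", paste(need, collapse = ", "))
    w <- as.matrix(distortion_loci[, c("w_AA", "w_AB", "w_BB")])
    if (any(w < 0 | w > 1)) stop("viability weights must lie in [0, 1]")
    if (any(rowSums(w) == 0)) stop("all-zero viability weights at a locus")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 missing_rate = missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 mean_depth = mean_depth,
                 distortion_loci = distortion_loci,
                 shared_marker_fraction = shared_marker_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Haldane map function: cM distance -> recombination fraction, used to drive
# the no-interference (Poisson) crossover process marker-to-marker.
haldane_rf <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# one set of n gametes for one chromosome: m x n 0/1 allele-origin matrix
sim_gametes <- function(pos, n) {
  m <- length(pos)
  start <- stats::rbinom(n, 1, 0.5)
  if (m == 1) return(matrix(start, 1, n))
  r <- haldane_rf(diff(pos))
  sw <- matrix(stats::runif((m - 1) * n) < r, m - 1, n)
  apply(rbind(start, sw), 2, cumsum) %% 2
}

#' Simulate true F2 genotypes by a no-interference crossover process
#'
#' Each individual is the union of two independent gametes; each gamete is a
#' realisation of a Poisson crossover process on the Morgan scale (Haldane's
#' map function gives the marker-to-marker recombination fraction). Before any
#' observation noise, every marker segregates 1:2:1 in expectation.
#'
#' @param map a [make_true_map()] result.
#' @param config a [sim_config()].
#' @return A [genmat()] of true genotypes (no parents, no depth), individuals
#'   named `F2_001`, ...
#' @export
simulate_f2 <- function(map, config) {
  stopifnot(inherits(map, "true_map"), inherits(config, "sim_config"))
  set.seed(config$seed)
  simulate_f2_batch(map, config$n_individuals)
}

# raw generator used both by simulate_f2 and by the rejection-sampling refill
# in apply_distortion; consumes the current RNG stream
simulate_f2_batch <- function(map, n, id_offset = 0) {
  chroms <- unique(map$chrom)
  codes <- do.call(rbind, lapply(chroms, function(ch) {
    sub <- map[map$chrom == ch, ]
    g1 <- sim_gametes(sub$pos_cM, n)
    g2 <- sim_gametes(sub$pos_cM, n)
    m <- g1 + g2
    rownames(m) <- sub$marker
    m
  }))
  colnames(codes) <- sprintf("F2_%03d", id_offset + seq_len(n))
  genmat(codes_to_calls(codes))
}

#' Impose the GBS observation model on true genotypes
#'
#' Per call: a read depth `d` is drawn from Poisson(`mean_depth`); `d = 0`
#' gives a missing call; a true heterozygote is observed as `AA` or `BB`
#' (equal odds) with total probability `2 * (1/2)^d`, the chance that all `d`
#' reads sample one allele; an independent miscall then occurs with
#' `genotyping_error_rate`; finally extra calls are masked so the overall
#' missing rate reaches `missing_rate`. Parental columns are left untouched.
#'
#' @param g a [genmat()] of true genotypes.
#' @param config a [sim_config()].
#' @return A [genmat()] with observed calls and, when `mean_depth` is finite,
#'   a depth matrix.
#' @export
apply_observation_model <- function(g, config) {
  stopifnot(inherits(g, "genmat"), inherits(config, "sim_config"))
  set.seed((config$seed + 101L) %% .Machine$integer.max)
  prog <- progeny_ids(g)
  codes <- gm_codes(g)
  n_cell <- length(codes)
  depth <- NULL
  if (is.finite(config$mean_depth)) {
    depth <- matrix(stats::rpois(n_cell, config$mean_depth),
                    nrow(codes), ncol(codes), dimnames = dimnames(codes))
    # heterozygote undercalling: all d reads from one allele
    het <- which(!is.na(codes) & codes == 1L & depth > 0)
    if (length(het)) {
      u <- stats::runif(length(het))
      p1 <- 0.5 ^ depth[het]
      codes[het[u < p1]] <- 0L
      codes[het[u >= p1 & u < 2 * p1]] <- 2L
    }
    codes[depth == 0] <- NA_integer_
  }
  if (config$genotyping_error_rate > 0) {
    obs <- which(!is.na(codes))
    err <- obs[stats::runif(length(obs)) < config$genotyping_error_rate]
    if (length(err)) {
      shift <- sample(c(1L, 2L), length(err), replace = TRUE)
      codes[err] <- (codes[err] + shift) %% 3L
    }
  }
  cur <- mean(is.na(codes))
  if (config$missing_rate > cur) {
    extra <- (config$missing_rate - cur) / (1 - cur)
    obs <- which(!is.na(codes))
    codes[obs[stats::runif(length(obs)) < extra]] <- NA_integer_
  }
  calls <- g$calls
  calls[, prog] <- codes_to_calls(codes)
  dep_full <- NULL
  if (!is.null(depth)) {
    dep_full <- matrix(NA_integer_, nrow(calls), ncol(calls),
                       dimnames = dimnames(calls))
    dep_full[, prog] <- depth
  }
  genmat(calls, dep_full, g$parents)
}

# survival probability of each individual under the viability weights
viability_prob <- function(codes, map, loci) {
  p <- rep(1, ncol(codes))
  for (k in seq_len(nrow(loci))) {
    sub <- map[map$chrom == loci$chrom[k], ]
    if (nrow(sub) == 0) stop("distortion locus on unknown chromosome: ",
                             loci$chrom[k])
    mk <- sub$marker[which.min(abs(sub$pos_cM - loci$pos_cM[k]))]
    w <- as.numeric(loci[k, c("w_AA", "w_AB", "w_BB")])
    gk <- codes[mk, ]
    wk <- ifelse(is.na(gk), 1, w[gk + 1L])
    p <- p * wk
  }
  p
}

#' Apply viability selection at distortion loci
#'
#' Each simulated individual survives with probability equal to the product of
#' the viability weights of its genotypes at the configured distortion loci
#' (locus = nearest mapped marker). Rejected individuals are replaced by
#' freshly simulated ones until the configured population size is restored, so
#' markers linked to a distortion locus show 1:2:1 departures that decay with
#' map distance.
#'
#' @param g a [genmat()] of true genotypes from [simulate_f2()].
#' @param map the [make_true_map()] the genotypes were simulated from.
#' @param config a [sim_config()] with non-`NULL` `distortion_loci`.
#' @return A [genmat()] of true genotypes for `config$n_individuals` survivors.
#' @export
apply_distortion <- function(g, map, config) {
  stopifnot(inherits(g, "genmat"), inherits(config, "sim_config"))
  loci <- config$distortion_loci
  if (is.null(loci)) return(g)
  set.seed((config$seed + 7919L) %% .Machine$integer.max)
  target <- config$n_individuals
  codes <- gm_codes(g, progeny_only = FALSE)
  keep <- stats::runif(ncol(codes)) < viability_prob(codes, map, loci)
  kept <- codes[, keep, drop = FALSE]
  tries <- 0
  while (ncol(kept) < target) {
    batch <- simulate_f2_batch(map, target)
    bc <- gm_codes(batch, progeny_only = FALSE)
    ok <- stats::runif(ncol(bc)) < viability_prob(bc, map, loci)
    kept <- cbind(kept, bc[, ok, drop = FALSE])
    tries <- tries + 1
    if (tries > 1000) stop("viability selection too severe to refill population")
  }
  kept <- kept[, seq_len(target), drop = FALSE]
  colnames(kept) <- sprintf("F2_%03d", seq_len(target))
  genmat(codes_to_calls(kept))
}

#' Simulate one observed F2 GBS population with parents
#'
#' Convenience wrapper chaining [simulate_f2()], [apply_distortion()] and
#' [apply_observation_model()], then prepending clean homozygous parental
#' columns (`P1` all `AA`, `P2` all `BB`; parents are sequenced much deeper
#' than progeny, so they are modelled error-free).
#'
#' @inheritParams apply_distortion
#' @return A [genmat()] with parental columns `P1`, `P2` flagged.
#' @export
simulate_population <- function(map, config) {
  g <- simulate_f2(map, config)
  g <- apply_distortion(g, map, config)
  g <- apply_observation_model(g, config)
  calls <- cbind(P1 = rep("AA", nrow(g$calls)),
                 P2 = rep("BB", nrow(g$calls)), g$calls)
  rownames(calls) <- markers(g)
  depth <- NULL
  if (!is.null(g$depth)) {
    depth <- cbind(P1 = rep(NA_integer_, nrow(g$calls)),
                   P2 = rep(NA_integer_, nrow(g$calls)), g$depth)
    rownames(depth) <- markers(g)
  }
  genmat(calls, depth, parents = c("P1", "P2"))
}

#' Simulate two F2 populations with a partially shared marker set
#'
#' Each marker of the true map is polymorphic in both populations with
#' probability `shared_marker_fraction` (from `config1`), otherwise in exactly
#' one population (either, with equal odds). Each population then runs through
#' the full single-population generator on its own marker subset.
#'
#' @param map a [make_true_map()] result.
#' @param config1,config2 [sim_config()]s for the two populations.
#' @return list with elements `pop1`, `pop2` ([genmat()]s) and
#'   `shared_markers` (character vector).
#' @export
simulate_two_populations <- function(map, config1, config2) {
  set.seed((config1$seed + 311L) %% .Machine$integer.max)
  s <- config1$shared_marker_fraction
  u <- stats::runif(nrow(map))
  grp <- ifelse(u < s, "both", ifelse(u < s + (1 - s) / 2, "pop1", "pop2"))
  m1 <- map[grp %in% c("both", "pop1"), ]
  m2 <- map[grp %in% c("both", "pop2"), ]
  class(m1) <- class(m2) <- class(map)
  attr(m1, "lengths_cM") <- attr(m2, "lengths_cM") <- attr(map, "lengths_cM")
  list(pop1 = simulate_population(m1, config1),
       pop2 = simulate_population(m2, config2),
       shared_markers = map$marker[grp == "both"])
}

#' Read and write true maps as TSV
#'
#' @param map a `true_map`.
#' @param path file path.
#' @return `read_true_map()` returns a `true_map`; the writer returns `path`
#'   invisibly.
#' @export
write_true_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_true_map
#' @export
read_true_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[order(match(df$chrom, unique(df$chrom)), df$pos_cM), ]
  rownames(df) <- NULL
  lens <- tapply(df$pos_cM, df$chrom, max)
  structure(df, lengths_cM = lens[unique(df$chrom)],
            class = c("true_map", "data.frame"))
}
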