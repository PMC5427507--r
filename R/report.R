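#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.835 -> 0.84` at 2 decimals),
#' the convention of printed map-summary tables, unlike R's banker's
#' rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a whole
#'
#' @param part,whole counts, `whole > 0`.
#' @param decimals decimal places (default 2), rounded half-up.
#' @return `100 * part / whole`, rounded.
#' @export
percentage <- function(part, whole, decimals = 2) {
  if (any(whole <= 0)) stop("whole must be positive")
  round_half_up(100 * part / whole, decimals)
}

#' Per-chromosome map summary table
#'
#' For each chromosome (or linkage group): number of markers, map size
#' (largest position, cM), average gap size `size / (n - 1)` rounded to 2
#' decimals, and marker density `n / size` (SNP/cM) rounded to 1 decimal.
#' A `Total` row sums markers and sizes, and a `Mean` row holds the
#' arithmetic means of marker count, size and density across chromosomes
#' (density averaged before rounding). Gap is undefined for single-marker
#' chromosomes and for the Total/Mean rows.
#'
#' @param map a `component_map`, `consensus_map`, or data.frame with
#'   `chrom`/`group`, `marker`, `pos_cM`.
#' @return data.frame: `chrom`, `n_markers`, `map_size_cM`, `avg_gap_cM`,
#'   `snp_per_cM`.
#' @export
map_summary <- function(map) {
  df <- as.data.frame(map)
  gcol <- if ("chrom" %in% names(df)) "chrom" else "group"
  if (nrow(df) == 0) stop("empty map")
  chroms <- unique(df[[gcol]])
  rows <- lapply(chroms, function(ch) {
    sub <- df[df[[gcol]] == ch, ]
    n <- nrow(sub)
    size <- max(sub$pos_cM)
    data.frame(chrom = ch, n_markers = n, map_size_cM = size,
               avg_gap_cM = if (n > 1) round_half_up(size / (n - 1), 2)
                            else NA_real_,
               snp_per_cM = if (size > 0) round_half_up(n / size, 1)
                            else NA_real_,
               density_raw = if (size > 0) n / size else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(chrom = "Total", n_markers = sum(tab$n_markers),
                      map_size_cM = round_half_up(sum(tab$map_size_cM), 2),
                      avg_gap_cM = NA_real_, snp_per_cM = NA_real_,
                      density_raw = NA_real_)
  mean_row <- data.frame(chrom = "Mean",
                         n_markers = round_half_up(mean(tab$n_markers), 1),
                         map_size_cM = round_half_up(mean(tab$map_size_cM), 2),
                         avg_gap_cM = NA_real_,
                         snp_per_cM = round_half_up(mean(tab$density_raw), 1),
                         density_raw = NA_real_)
  out <- rbind(tab, total, mean_row)
  out$density_raw <- NULL
  rownames(out) <- NULL
  out
}

#' Published framework-map geometry for Aegilops umbellulata
#'
#' The per-chromosome marker counts and map sizes of the published
#' U-genome framework consensus map (7 chromosomes, 3009 SNPs). Used as the
#' realistic geometry for the synthetic data generator and as the input of
#' the worked summary-table examples.
#'
#' @return data.frame: `chrom`, `n_markers`, `map_size_cM`.
#' @export
umbellulata_framework_geometry <- function() {
  path <- system.file("extdata", "umbellulata_framework_geometry.tsv",
                      package = "umbmap")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the whole mapping pipeline on one or two populations
#'
#' Chains the package end to end for each population: parental polarization,
#' framework QC filtering, a preliminary component map, one sliding-window
#' error-correction pass, re-mapping on the corrected calls, placement of
#' the unmapped placement-QC markers by minimum recombination fraction, then
#' across populations: consensus merging (identity when only one population
#' is given), a segregation distortion scan of each population's high-density
#' map, and synteny summaries when an anchor table is supplied. All
#' artifacts are returned; with `out_dir` they are also written as TSV.
#'
#' @param pops list of one or two [genmat()]s with flagged parents.
#' @param cutoff_p per-population linkage-grouping cutoffs (recycled).
#' @param window,agree_fraction error-correction settings.
#' @param rf_max placement threshold.
#' @param Ks candidate consensus interval sizes.
#' @param weights per-population consensus weights; default the number of
#'   progeny in each population.
#' @param anchors optional anchor table for synteny.
#' @param alpha distortion-scan significance level.
#' @param out_dir optional output directory for TSV artifacts.
#' @return list: `component_maps`, `highdensity_maps`, `placements`,
#'   `consensus`, `distortion`, `synteny`, `qc_reports`, `summaries`.
#' @export
run_pipeline <- function(pops, cutoff_p = 1e-8, window = 15,
                         agree_fraction = 0.8, rf_max = 0.1, Ks = 1:4,
                         weights = NULL, anchors = NULL, alpha = 0.01,
                         out_dir = NULL) {
  if (inherits(pops, "genmat")) pops <- list(pops)
  stopifnot(length(pops) >= 1)
  cutoff_p <- rep_len(cutoff_p, length(pops))
  if (is.null(weights))
    weights <- vapply(pops, function(g) length(progeny_ids(g)), 0)
  comp <- list(); hd <- list(); plc <- list(); qcrep <- list(); scans <- list()
  for (i in seq_along(pops)) {
    pol <- polarize(pops[[i]])
    fw <- apply_filters(pol, filter_policy("framework"))
    pre <- build_component_map(fw$genmat, cutoff_p = cutoff_p[i],
                               population = paste0("pop", i))
    corr <- sliding_window_correct(fw$genmat, pre, window = window,
                                   agree_fraction = agree_fraction)
    cmap <- build_component_map(corr$genmat, cutoff_p = cutoff_p[i],
                                population = paste0("pop", i))
    pl_set <- apply_filters(pol, filter_policy("placement"))
    un <- setdiff(markers(pl_set$genmat), cmap$marker)
    placed <- place_unmapped(un, cmap, pl_set$genmat, rf_max = rf_max)
    hmap <- merge_placed(cmap, placed)
    scans[[i]] <- scan_distortion(pl_set$genmat, hmap, alpha = alpha)
    comp[[i]] <- cmap; hd[[i]] <- hmap; plc[[i]] <- placed
    qcrep[[i]] <- list(polarize = attr(pol, "polarize_report"),
                       framework = fw$report, placement = pl_set$report)
  }
  consensus <- if (length(comp) > 1)
    build_consensus(comp, Ks = Ks, weights = weights)
  else {
    one <- data.frame(chrom = comp[[1]]$group, marker = comp[[1]]$marker,
                      pos_cM = comp[[1]]$pos_cM)
    structure(one, class = c("consensus_map", "data.frame"))
  }
  syn <- if (!is.null(anchors)) synteny_summary(consensus, anchors)
  summaries <- list(consensus = map_summary(consensus),
                    components = lapply(comp, map_summary))
  out <- list(component_maps = comp, highdensity_maps = hd,
              placements = plc, consensus = consensus, distortion = scans,
              synteny = syn, qc_reports = qcrep, summaries = summaries)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(comp)) {
      write_map(comp[[i]], file.path(out_dir, sprintf("component_map_pop%d.tsv", i)))
      write_map(hd[[i]], file.path(out_dir, sprintf("highdensity_map_pop%d.tsv", i)))
      utils::write.table(plc[[i]], file.path(out_dir, sprintf("placement_pop%d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(scans[[i]]$markers,
                         file.path(out_dir, sprintf("distortion_pop%d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(as.data.frame(consensus),
                       file.path(out_dir, "consensus_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summaries$consensus,
                       file.path(out_dir, "consensus_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
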