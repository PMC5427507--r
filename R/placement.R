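#' Place unmapped markers by minimum recombination fraction
#'
#' For each unmapped marker the recombination fraction against every mapped
#' marker is estimated and sorted; the marker is assigned the map position
#' (and linkage group) of the mapped marker with the smallest rf, provided
#' that minimum is at most `rf_max`. When exactly two mapped markers tie at
#' the minimum and share a group, the marker is placed at the arithmetic mean
#' of their two positions. Ties spanning several mapped markers on one group
#' also take the mean position; ties spanning different groups are left
#' unplaced (`ambiguous_group`). Markers with no informative overlap against
#' any mapped marker are unplaced with reason `no_data`.
#'
#' @param unmapped character vector of marker ids to place.
#' @param mapped a `component_map` (the framework map).
#' @param g a polarized [genmat()] containing both mapped and unmapped
#'   markers (typically the more permissive placement QC set).
#' @param rf_max largest usable recombination fraction (default 0.1).
#' @param tie_tol numeric tolerance for declaring a tie at the minimum.
#' @return data.frame of class `placement_result`: `marker`, `status`
#'   (`placed`/`unplaced`), `group`, `pos_cM`, `min_rf`, `anchors`
#'   (comma-separated), `reason` (`NA`, `rf_above_max`, `no_data`,
#'   `ambiguous_group`).
#' @export
place_unmapped <- function(unmapped, mapped, g, rf_max = 0.1,
                           tie_tol = 1e-9) {
  stopifnot(inherits(mapped, "component_map"))
  mapmk <- mapped$marker
  unmapped <- setdiff(unmapped, mapmk)
  avail <- intersect(unmapped, markers(g))
  if (!all(unmapped %in% avail))
    stop("unmapped markers absent from the genotype matrix: ",
         paste(utils::head(setdiff(unmapped, avail), 3), collapse = ", "))
  if (length(unmapped) == 0 || nrow(mapped) == 0) {
    return(empty_placement())
  }
  rfs <- rf_table(g, markers1 = unmapped, markers2 = mapmk)
  res <- lapply(seq_along(unmapped), function(i) {
    rr <- rfs$rf[i, ]
    nn <- rfs$n[i, ]
    rr[nn < 2] <- NA_real_
    if (all(is.na(rr)))
      return(placement_row(unmapped[i], "unplaced", reason = "no_data"))
    mn <- min(rr, na.rm = TRUE)
    if (mn > rf_max)
      return(placement_row(unmapped[i], "unplaced", min_rf = mn,
                           reason = "rf_above_max"))
    tie <- which(!is.na(rr) & rr <= mn + tie_tol)
    anchors <- mapmk[tie]
    grp <- unique(mapped$group[match(anchors, mapped$marker)])
    if (length(grp) > 1)
      return(placement_row(unmapped[i], "unplaced", min_rf = mn,
                           anchors = anchors, reason = "ambiguous_group"))
    pos <- mean(mapped$pos_cM[match(anchors, mapped$marker)])
    placement_row(unmapped[i], "placed", group = grp, pos = pos,
                  min_rf = mn, anchors = anchors)
  })
  out <- do.call(rbind, res)
  class(out) <- c("placement_result", "data.frame")
  out
}

placement_row <- function(marker, status, group = NA_character_,
                          pos = NA_real_, min_rf = NA_real_,
                          anchors = character(), reason = NA_character_) {
  data.frame(marker = marker, status = status, group = group, pos_cM = pos,
             min_rf = min_rf,
             anchors = if (length(anchors)) paste(anchors, collapse = ",")
                       else NA_character_,
             reason = reason, stringsAsFactors = FALSE)
}

empty_placement <- function() {
  structure(data.frame(marker = character(), status = character(),
                       group = character(), pos_cM = numeric(),
                       min_rf = numeric(), anchors = character(),
                       reason = character(), stringsAsFactors = FALSE),
            class = c("placement_result", "data.frame"))
}

#' Insert placed markers into a component map
#'
#' Framework markers keep their positions and relative order; placed markers
#' are inserted at their assigned positions. Markers sharing a position are
#' ordered deterministically: framework markers first, then placed markers by
#' id. A `source` column records the origin of every marker.
#'
#' @param mapped a `component_map`.
#' @param placements a [place_unmapped()] result.
#' @return A `component_map` with the extra column `source`
#'   (`framework`/`placed`).
#' @export
merge_placed <- function(mapped, placements) {
  base <- as.data.frame(mapped)
  base$source <- "framework"
  pl <- placements[placements$status == "placed", , drop = FALSE]
  if (nrow(pl)) {
    add <- data.frame(group = pl$group, marker = pl$marker,
                      pos_cM = pl$pos_cM, source = "placed",
                      stringsAsFactors = FALSE)
    base <- rbind(base, add)
  }
  prio <- ifelse(base$source == "framework", 0L, 1L)
  base <- base[order(match(base$group, unique(mapped$group)),
                     base$pos_cM, prio, base$marker), ]
  rownames(base) <- NULL
  new_component_map(base, attr(mapped, "population"), attr(mapped, "params"))
}
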