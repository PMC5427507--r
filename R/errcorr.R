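#' Sliding-window correction of genotyping errors
#'
#' Apparent double recombinants (isolated calls disagreeing with both
#' flanking regions of the same individual) are overwhelmingly genotyping
#' errors in low-coverage data and inflate map length. For each call, the
#' window of `window` markers centred on it (same individual, map order,
#' missing calls ignored) is split into its left and right flank; the call is
#' corrected only when both flanks agree on the same consensus genotype with
#' support at least `agree_fraction` on each side, so genuine crossovers --
#' where the flanks disagree -- are preserved. A heterozygous call whose
#' flanks agree on *opposite* homozygotes (a crossover through the window) is
#' set to missing rather than guessed, heterozygotes being the least reliable
#' class under low coverage. Parental columns are never altered.
#'
#' @param g a [genmat()].
#' @param order marker ordering: a character vector, a list of character
#'   vectors (one per linkage group), or a `component_map`.
#' @param window odd window size, at least 3 (default 15). Windows truncate
#'   at group ends; a window larger than a group triggers a warning.
#' @param agree_fraction minimum fraction of non-missing calls per flank
#'   supporting the consensus (default 0.8).
#' @param mode `"replace"` corrects to the consensus; `"missing"` masks the
#'   disagreeing call instead.
#' @return list with `genmat` (corrected) and `changes` (data.frame
#'   `marker`, `individual`, `before`, `after`).
#' @export
sliding_window_correct <- function(g, order, window = 15,
                                   agree_fraction = 0.8,
                                   mode = c("replace", "missing")) {
  mode <- match.arg(mode)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (agree_fraction <= 0.5 || agree_fraction > 1)
    stop("agree_fraction must lie in (0.5, 1]")
  if (inherits(order, "component_map") ||
      (is.data.frame(order) && all(c("group", "marker") %in% names(order))))
    order <- split(order$marker, order$group)
  if (!is.list(order)) order <- list(order)
  codes <- gm_codes(g)
  half <- (window - 1) %/% 2
  changes <- list()
  for (blk in order) {
    blk <- intersect(blk, rownames(codes))
    if (length(blk) < 2) next
    if (length(blk) < window)
      warning("window (", window, ") exceeds group size (", length(blk),
              "); truncating")
    M <- codes[blk, , drop = FALSE]
    m <- nrow(M)
    shift <- function(off) {
      # marker-axis shift: row i of the result is M[i + off, ]
      out <- matrix(NA_integer_, m, ncol(M))
      src <- seq_len(m) + off
      ok <- src >= 1 & src <= m
      out[ok, ] <- M[src[ok], , drop = FALSE]
      out
    }
    flank <- function(side) {
      cnt <- list(`0` = 0, `1` = 0, `2` = 0)
      for (off in seq_len(half)) {
        S <- shift(if (side == "left") -off else off)
        for (v in 0:2)
          cnt[[v + 1]] <- cnt[[v + 1]] + (!is.na(S) & S == v)
      }
      tot <- cnt[[1]] + cnt[[2]] + cnt[[3]]
      best <- pmax(cnt[[1]], cnt[[2]], cnt[[3]])
      cons <- ifelse(tot == 0, NA_integer_,
                     ifelse(cnt[[1]] == best, 0L,
                            ifelse(cnt[[2]] == best, 1L, 2L)))
      list(cons = cons, support = ifelse(tot > 0, best / tot, 0), n = tot)
    }
    L <- flank("left")
    R <- flank("right")
    usable <- L$n > 0 & R$n > 0 & !is.na(M) &
      L$support >= agree_fraction & R$support >= agree_fraction
    fix <- usable & L$cons == R$cons & M != L$cons
    blank <- usable & M == 1L & L$cons != R$cons &
      L$cons != 1L & R$cons != 1L
    idx <- which(fix | blank, arr.ind = TRUE)
    if (nrow(idx)) {
      before <- M[idx]
      after <- ifelse(blank[idx] | mode == "missing", NA_integer_,
                      L$cons[idx])
      changes[[length(changes) + 1]] <- data.frame(
        marker = blk[idx[, 1]], individual = colnames(M)[idx[, 2]],
        before = c("AA", "AB", "BB")[before + 1L],
        after = ifelse(is.na(after), NA_character_,
                       c("AA", "AB", "BB")[after + 1L]),
        stringsAsFactors = FALSE)
      M[idx] <- after
      codes[blk, ] <- M
    }
  }
  calls <- g$calls
  calls[, progeny_ids(g)] <- codes_to_calls(codes)
  out <- genmat(calls, g$depth, g$parents)
  list(genmat = out,
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(marker = character(), individual = character(),
                                 before = character(), after = character()))
}
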