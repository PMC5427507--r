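#' Genotype matrix for an F2 intercross population
#'
#' The central data structure of the package: a markers-by-individuals matrix
#' of biallelic genotype calls coded `"AA"`, `"AB"`, `"BB"` or `NA` (missing),
#' with an optional per-call read-depth matrix and a flag naming the parental
#' columns. After [polarize()], `"AA"` means homozygous for the first parent's
#' allele and `"BB"` for the second parent's.
#'
#' @param calls character matrix with marker ids as rownames and individual
#'   ids as colnames; entries in `c("AA","AB","BB", NA)`.
#' @param depth optional integer matrix of read depths, same dimensions and
#'   dimnames as `calls`.
#' @param parents character vector of column names that are parental samples
#'   (possibly empty).
#' @return An object of class `genmat`.
#' @export
genmat <- function(calls, depth = NULL, parents = character()) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("`calls` must be a character matrix")
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    stop("`calls` must have marker rownames")
  if (is.null(colnames(calls)) && ncol(calls) > 0)
    stop("`calls` must have individual colnames")
  if (is.null(rownames(calls))) rownames(calls) <- character(0)
  if (is.null(colnames(calls))) colnames(calls) <- character(0)
  if (anyDuplicated(rownames(calls)))
    stop("marker ids must be unique")
  if (anyDuplicated(colnames(calls)))
    stop("individual ids must be unique")
  bad <- !is.na(calls) & !(calls %in% c("AA", "AB", "BB"))
  if (any(bad))
    stop("calls must be AA, AB, BB or NA; found: ",
         paste(utils::head(unique(calls[bad]), 3), collapse = ", "))
  if (!is.null(depth)) {
    if (!is.matrix(depth) || !identical(dim(depth), dim(calls)))
      stop("`depth` must be a matrix with the same dimensions as `calls`")
    dimnames(depth) <- dimnames(calls)
  }
  parents <- as.character(parents)
  if (!all(parents %in% colnames(calls)))
    stop("parent columns not found: ",
         paste(setdiff(parents, colnames(calls)), collapse = ", "))
  structure(list(calls = calls, depth = depth, parents = parents),
            class = "genmat")
}

#' @export
print.genmat <- function(x, ...) {
  cat(sprintf("genmat: %d markers x %d individuals (%d parental)\n",
              nrow(x$calls), ncol(x$calls), length(x$parents)))
  nm <- sum(is.na(x$calls[, progeny_ids(x), drop = FALSE]))
  tot <- nrow(x$calls) * length(progeny_ids(x))
  if (tot > 0)
    cat(sprintf("progeny missing rate: %.3f\n", nm / tot))
  invisible(x)
}

#' @export
dim.genmat <- function(x) dim(x$calls)

#' Marker and individual accessors
#'
#' @param g a [genmat()].
#' @return Character vectors of ids. `progeny_ids()` excludes parental columns.
#' @export
markers <- function(g) rownames(g$calls)

#' @rdname markers
#' @export
individuals <- function(g) colnames(g$calls)

#' @rdname markers
#' @export
progeny_ids <- function(g) setdiff(colnames(g$calls), g$parents)

#' Subset a genotype matrix
#'
#' @param x a [genmat()].
#' @param i marker ids or indices.
#' @param j individual ids or indices.
#' @param ... ignored.
#' @return A `genmat` restricted to the selected markers/individuals. Parent
#'   flags are kept for parents that survive the column subset.
#' @export
`[.genmat` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  depth <- if (!is.null(x$depth)) x$depth[i, j, drop = FALSE]
  genmat(calls, depth, intersect(x$parents, colnames(calls)))
}

# integer codes 0 = AA, 1 = AB, 2 = BB, NA = missing; markers x individuals
gm_codes <- function(g, progeny_only = TRUE) {
  cc <- if (progeny_only) g$calls[, progeny_ids(g), drop = FALSE] else g$calls
  m <- matrix(NA_integer_, nrow(cc), ncol(cc), dimnames = dimnames(cc))
  m[cc == "AA"] <- 0L
  m[cc == "AB"] <- 1L
  m[cc == "BB"] <- 2L
  m
}

codes_to_calls <- function(m) {
  cc <- matrix(NA_character_, nrow(m), ncol(m), dimnames = dimnames(m))
  cc[m == 0L] <- "AA"
  cc[m == 1L] <- "AB"
  cc[m == 2L] <- "BB"
  cc
}

#' Read and write genotype matrices as HapMap-like TSV
#'
#' One marker per row; first column `marker`, remaining columns one per
#' individual with calls `AA`/`AB`/`BB`/`NA`. An optional companion depth
#' matrix uses the same layout.
#'
#' @param path file path.
#' @param parents individual ids to flag as parental samples on read.
#' @param depth_path optional path of the companion depth TSV.
#' @return `read_genotypes()` returns a [genmat()]; `write_genotypes()`
#'   returns `path` invisibly.
#' @export
read_genotypes <- function(path, parents = character(), depth_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = "NA")
  if (names(df)[1] != "marker") stop("first column must be `marker`")
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$marker
  depth <- NULL
  if (!is.null(depth_path)) {
    dd <- utils::read.delim(depth_path, check.names = FALSE)
    depth <- as.matrix(dd[, -1, drop = FALSE])
    rownames(depth) <- dd$marker
    depth <- depth[rownames(calls), colnames(calls), drop = FALSE]
  }
  genmat(calls, depth, parents)
}

#' @rdname read_genotypes
#' @param g a [genmat()].
#' @export
write_genotypes <- function(g, path, depth_path = NULL) {
  df <- data.frame(marker = markers(g), g$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(depth_path) && !is.null(g$depth)) {
    dd <- data.frame(marker = markers(g), g$depth, check.names = FALSE)
    utils::write.table(dd, depth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
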