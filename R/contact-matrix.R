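#' Contact matrix for one chromosome
#'
#' A `contact_matrix` is a square symmetric matrix of nonnegative contact
#' values between fixed-size genomic bins of a single chromosome, plus the
#' bin-coordinate metadata needed to map matrix indices back to the genome.
#' Bins are 0-based and half-open: bin `k` covers
#' `[k * resolution, (k + 1) * resolution)` in bp.
#'
#' @param values Square numeric matrix, symmetric with nonnegative entries.
#'   `NA` entries are allowed and mark pixels with no information (for
#'   example, pixels outside the predicted diagonal band).
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp (default 40000, i.e. 40 kb).
#'
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, chrom = "chrS", resolution = 40000) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stopf("contact matrix must be square, got %d x %d", nrow(values), ncol(values))
  }
  if (!isTRUE(all.equal(values, t(values), check.attributes = FALSE))) {
    stopf("contact matrix must be symmetric")
  }
  if (any(values < 0, na.rm = TRUE)) stopf("contact matrix entries must be nonnegative")
  if (!is_count(resolution)) stopf("resolution must be a positive integer (bp)")
  structure(
    list(
      values = unname(values),
      chrom = as.character(chrom),
      resolution = as.integer(resolution)
    ),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s: %d bins @ %d bp (total signal %.4g)\n",
    x$chrom, n_bins(x), x$resolution, sum(x$values, na.rm = TRUE)
  ))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param x A `contact_matrix`.
#' @return Integer number of bins.
#' @export
n_bins <- function(x) {
  stopifnot(inherits(x, "contact_matrix"))
  nrow(x$values)
}

#' Spatiotemporal stack of contact matrices
#'
#' An ordered series of [contact_matrix()] objects on the same bin grid, one
#' per time-step (for example, successive developmental stages).
#'
#' @param matrices List of `contact_matrix` objects with identical chromosome,
#'   resolution and bin count.
#'
#' @return An object of class `hic_stack` (a list of contact matrices with
#'   shared-grid metadata).
#' @export
hic_stack <- function(matrices) {
  if (length(matrices) < 1) stopf("a stack needs at least one time-step")
  for (m in matrices) stopifnot(inherits(m, "contact_matrix"))
  nb <- vapply(matrices, n_bins, integer(1))
  res <- vapply(matrices, function(m) m$resolution, integer(1))
  chrom <- vapply(matrices, function(m) m$chrom, character(1))
  if (length(unique(nb)) != 1 || length(unique(res)) != 1 || length(unique(chrom)) != 1) {
    stopf("all time-steps must share chromosome, resolution and bin grid")
  }
  structure(matrices, class = "hic_stack")
}

#' @export
print.hic_stack <- function(x, ...) {
  cat(sprintf(
    "<hic_stack> %s: %d time-steps, %d bins @ %d bp\n",
    x[[1]]$chrom, length(x), n_bins(x[[1]]), x[[1]]$resolution
  ))
  invisible(x)
}

#' @rdname n_bins
#' @export
n_steps <- function(x) {
  stopifnot(inherits(x, "hic_stack"))
  length(x)
}
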