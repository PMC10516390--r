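#' Read Hi-C valid read pairs from text
#'
#' Parses whitespace/tab-separated valid-pair files. The default column
#' mapping matches the HiC-Pro "allValidPairs" convention
#' (read name, chrom1, pos1, strand1, chrom2, pos2, strand2, ...), i.e.
#' chromosomes in columns 2 and 5 and 1-based bp positions in columns 3 and 6.
#'
#' @param path Path to the pairs file.
#' @param dialect Named integer vector mapping the fields `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b` to 1-based column indices.
#'
#' @return A tibble with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`.
#'   Malformed lines (too few columns, non-numeric or non-positive positions)
#'   raise an error naming the offending line number.
#' @export
read_valid_pairs <- function(path,
                             dialect = c(chrom_a = 2L, pos_a = 3L, chrom_b = 5L, pos_b = 6L)) {
  if (!file.exists(path)) stopf("pairs file not found: %s", path)
  need <- c("chrom_a", "pos_a", "chrom_b", "pos_b")
  if (!all(need %in% names(dialect))) {
    stopf("dialect must name columns %s", paste(need, collapse = ", "))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(
      chrom_a = character(), pos_a = double(),
      chrom_b = character(), pos_b = double()
    ))
  }
  fields <- strsplit(lines, "[ \t]+")
  maxcol <- max(dialect[need])
  nf <- lengths(fields)
  if (any(nf < maxcol)) {
    stopf("line %d: expected at least %d columns, found %d",
      which(nf < maxcol)[1], maxcol, nf[which(nf < maxcol)[1]])
  }
  pick <- function(k) vapply(fields, `[[`, character(1), dialect[[k]])
  pos_a <- suppressWarnings(as.numeric(pick("pos_a")))
  pos_b <- suppressWarnings(as.numeric(pick("pos_b")))
  bad <- which(!is.finite(pos_a) | !is.finite(pos_b) | pos_a < 1 | pos_b < 1)
  if (length(bad)) {
    stopf("line %d: malformed position field ('%s' / '%s')",
      bad[1], pick("pos_a")[bad[1]], pick("pos_b")[bad[1]])
  }
  chrom_a <- pick("chrom_a")
  chrom_b <- pick("chrom_b")
  if (any(!nzchar(chrom_a)) || any(!nzchar(chrom_b))) stopf("empty chromosome name")
  tibble::tibble(chrom_a = chrom_a, pos_a = pos_a, chrom_b = chrom_b, pos_b = pos_b)
}

#' Keep long-range intra-chromosomal pairs
#'
#' Retains read pairs with both mates on the same chromosome separated by
#' strictly more than `min_distance` bp. This is the standard depth-balancing
#' filter applied before binning spatiotemporal Hi-C: short-range and
#' inter-chromosomal pairs are discarded.
#'
#' @param pairs Tibble as returned by [read_valid_pairs()].
#' @param min_distance Distance threshold in bp (default 20000; strict `>`).
#'
#' @return Filtered tibble.
#' @export
filter_long_range_intra <- function(pairs, min_distance = 20000) {
  keep <- pairs$chrom_a == pairs$chrom_b &
    abs(pairs$pos_a - pairs$pos_b) > min_distance
  pairs[keep, , drop = FALSE]
}

#' Downsample read pairs to a target count
#'
#' Uniform random subset without replacement, used to balance sequencing
#' depth across time-steps before binning.
#'
#' @param pairs Tibble of pairs.
#' @param target Number of pairs to keep (`<= nrow(pairs)`).
#' @param seed Integer seed; the same seed reproduces the same subset.
#'
#' @return Tibble with exactly `target` rows (original order preserved).
#' @export
downsample_pairs <- function(pairs, target, seed = 1L) {
  n <- nrow(pairs)
  if (target > n) stopf("target (%s) exceeds available pairs (%s)", target, n)
  idx <- with_seed(seed, sample.int(n, target))
  pairs[sort(idx), , drop = FALSE]
}

#' Bin read pairs into a contact matrix
#'
#' Each pair increments the symmetric cell pair `(bin_a, bin_b)` and
#' `(bin_b, bin_a)` by one (a diagonal cell is incremented once when the two
#' bins coincide, so the stored value counts the pair once). Bins are
#' 0-based half-open intervals: `bin = floor((pos - 1) / resolution)`.
#'
#' @param pairs Tibble of pairs (assumed already filtered to one chromosome,
#'   rows with a different `chrom_a`/`chrom_b` are ignored).
#' @param chrom Chromosome to bin.
#' @param chrom_length Chromosome length in bp; pairs with a position beyond
#'   it are skipped with a warning reporting how many.
#' @param resolution Bin size in bp (default 40000).
#'
#' @return A [contact_matrix()] with `ceiling(chrom_length / resolution)` bins.
#' @export
bin_pairs <- function(pairs, chrom, chrom_length, resolution = 40000) {
  if (!is_count(resolution)) stopf("resolution must be a positive integer")
  nb <- as.integer(ceiling(chrom_length / resolution))
  keep <- pairs$chrom_a == chrom & pairs$chrom_b == chrom
  pa <- pairs$pos_a[keep]
  pb <- pairs$pos_b[keep]
  out_of_range <- pa > chrom_length | pb > chrom_length
  if (any(out_of_range)) {
    warning(sprintf(
      "%d pair(s) beyond %s length %s skipped", sum(out_of_range), chrom,
      format(chrom_length, scientific = FALSE)
    ), call. = FALSE)
    pa <- pa[!out_of_range]
    pb <- pb[!out_of_range]
  }
  m <- matrix(0, nb, nb)
  if (length(pa)) {
    ba <- floor((pa - 1) / resolution)
    bb <- floor((pb - 1) / resolution)
    i <- pmin(ba, bb)
    j <- pmax(ba, bb)
    tab <- table(i * nb + j) # upper-triangle linear key
    key <- as.numeric(names(tab))
    ii <- key %/% nb + 1
    jj <- key %% nb + 1
    m[cbind(ii, jj)] <- as.numeric(tab)
    m[cbind(jj, ii)] <- as.numeric(tab)
  }
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' Choose a depth-adaptive rescaling cap (maxHiC)
#'
#' The cap used to map raw contact counts into `[0, 1]` must adapt to the
#' sequencing depth of the dataset. Default rule: the 99.9th percentile of
#' the nonzero entries pooled over all time-steps of the supplied stack(s),
#' so at most ~0.1% of nonzero pixels saturate.
#'
#' @param stacks An [hic_stack()] or list of stacks to pool.
#' @param quantile Percentile of nonzero entries to use (default 0.999).
#'
#' @return Positive real cap.
#' @export
choose_max_hic <- function(stacks, quantile = 0.999) {
  if (inherits(stacks, "hic_stack")) stacks <- list(stacks)
  vals <- unlist(lapply(stacks, function(st) {
    lapply(st, function(m) {
      v <- m$values[upper.tri(m$values, diag = TRUE)]
      v[v > 0]
    })
  }))
  if (!length(vals)) stopf("no nonzero entries to pool")
  # inverse-ECDF quantile: guarantees at most (1 - quantile) of the pooled
  # nonzero entries exceed the cap
  as.numeric(stats::quantile(vals, quantile, names = FALSE, type = 1))
}

#' Rescale contact counts into the unit interval
#'
#' Maps every entry to `min(value, max_hic) / max_hic` (clip-and-divide).
#' Symmetry is preserved; values already below the cap are divided exactly.
#'
#' @param x A [contact_matrix()] or [hic_stack()].
#' @param max_hic Positive cap; see [choose_max_hic()].
#'
#' @return Object of the same class with entries in `[0, 1]`.
#' @export
rescale_hic <- function(x, max_hic) {
  if (!(is.numeric(max_hic) && length(max_hic) == 1 && max_hic > 0)) {
    stopf("max_hic must be a positive real")
  }
  if (inherits(x, "hic_stack")) {
    return(hic_stack(lapply(x, rescale_hic, max_hic = max_hic)))
  }
  stopifnot(inherits(x, "contact_matrix"))
  contact_matrix(pmin(x$values, max_hic) / max_hic,
    chrom = x$chrom, resolution = x$resolution
  )
}

#' Write / read contact matrices as plain text
#'
#' Two formats are supported. `"dense"` stores one matrix row per line
#' (whitespace-separated, full precision); `"coo"` stores the upper triangle
#' only as `bin_i bin_j value` triplets (0-based, `i <= j`), mirrored on
#' read. Both carry a header line
#' `#hicforecast chrom=<chrom> resolution=<bp> n_bins=<n>`.
#'
#' @param m A [contact_matrix()].
#' @param path Output/input file path.
#' @param format `"dense"` or `"coo"`.
#'
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` returns
#'   a [contact_matrix()]. A dense file whose cells are not symmetric is
#'   rejected.
#' @export
write_matrix <- function(m, path, format = c("dense", "coo")) {
  stopifnot(inherits(m, "contact_matrix"))
  format <- match.arg(format)
  header <- sprintf(
    "#hicforecast chrom=%s resolution=%d n_bins=%d",
    m$chrom, m$resolution, n_bins(m)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (format == "dense") {
    writeLines(apply(m$values, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  } else {
    idx <- which(upper.tri(m$values, diag = TRUE) & m$values != 0, arr.ind = TRUE)
    df <- data.frame(
      i = idx[, 1] - 1L, j = idx[, 2] - 1L,
      value = m$values[idx]
    )
    df <- df[order(df$i, df$j), , drop = FALSE]
    utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
      con,
      row.names = FALSE, col.names = FALSE, quote = FALSE, sep = " "
    )
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, format = c("dense", "coo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#hicforecast")) stopf("missing '#hicforecast' header in %s", path)
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  meta <- stats::setNames(
    sub("^[a-z_]+=", "", kv),
    sub("=.*$", "", kv)
  )
  nb <- as.integer(meta[["n_bins"]])
  res <- as.integer(meta[["resolution"]])
  chrom <- meta[["chrom"]]
  if (format == "dense") {
    vals <- utils::read.table(path, skip = 1, header = FALSE)
    vals <- as.matrix(vals)
    if (nrow(vals) != nb || ncol(vals) != nb) {
      stopf("dense matrix is %d x %d but header says %d bins", nrow(vals), ncol(vals), nb)
    }
    if (!isTRUE(all.equal(unname(vals), unname(t(vals)), check.attributes = FALSE))) {
      stopf("dense matrix in %s is not symmetric", path)
    }
    m <- unname(vals)
  } else {
    m <- matrix(0, nb, nb)
    if (length(readLines(path)) > 1) {
      df <- utils::read.table(path, skip = 1, header = FALSE)
      if (ncol(df) != 3) stopf("COO file must have 3 columns")
      if (any(df[[1]] > df[[2]])) stopf("COO file must store the upper triangle (i <= j)")
      if (any(df[[1]] < 0 | df[[2]] >= nb)) stopf("COO bin index outside [0, n_bins)")
      m[cbind(df[[1]] + 1L, df[[2]] + 1L)] <- df[[3]]
      m[cbind(df[[2]] + 1L, df[[1]] + 1L)] <- df[[3]]
    }
  }
  contact_matrix(m, chrom = chrom, resolution = res)
}

#' @rdname write_matrix
#' @param stack An [hic_stack()]; `write_stack()` writes one file per
#'   time-step named `<prefix>_t<step>.txt`, `read_stack()` reads them back.
#' @param prefix Path prefix for per-step files.
#' @export
write_stack <- function(stack, prefix, format = c("dense", "coo")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "hic_stack"))
  paths <- sprintf("%s_t%d.txt", prefix, seq_along(stack))
  for (k in seq_along(stack)) write_matrix(stack[[k]], paths[k], format)
  invisible(paths)
}

#' @rdname write_matrix
#' @export
read_stack <- function(prefix, format = c("dense", "coo")) {
  format <- match.arg(format)
  paths <- Sys.glob(sprintf("%s_t*.txt", prefix))
  if (!length(paths)) stopf("no files matching %s_t*.txt", prefix)
  steps <- as.integer(sub("^.*_t(\\d+)\\.txt$", "\\1", paths))
  hic_stack(lapply(paths[order(steps)], read_matrix, format = format))
}
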