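#' Contact map container
#'
#' A symmetric nonnegative matrix of pairwise contact weights between bins
#' (genomic loci or polymer monomers), with bin metadata and a mask of
#' unmappable bins. Self-contacts are excluded throughout: the diagonal is
#' forced to zero on construction, before balancing and before community
#' detection.
#'
#' @param matrix symmetric nonnegative numeric matrix.
#' @param bin_size genomic length per bin in bp, or 1 for polymer monomers.
#' @param mask integer indices (1-based) of unmappable bins; their rows and
#'   columns are zeroed.
#' @param balanced logical; whether Knight-Ruiz balancing has been applied.
#' @param tol symmetry tolerance relative to the largest entry.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(matrix, bin_size = 1, mask = integer(),
                        balanced = FALSE, tol = 1e-8) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("contact matrix must be square")
  storage.mode(m) <- "double"
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > tol * scale)
    stop("contact matrix is not symmetric within tolerance")
  m <- (m + t(m)) / 2
  if (min(m) < -tol * scale) stop("contact matrix has negative entries")
  m[m < 0] <- 0
  diag(m) <- 0
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1 || max(mask) > nrow(m)))
    stop("mask indices out of range")
  m[mask, ] <- 0
  m[, mask] <- 0
  dimnames(m) <- NULL
  structure(list(matrix = m, bin_size = bin_size, mask = mask,
                 balanced = isTRUE(balanced)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d bins x %d bins, bin size %g, %d masked%s\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_size, length(x$mask),
              if (x$balanced) ", KR-balanced" else ""))
  invisible(x)
}

#' Number of bins of a contact map
#' @param map a [contact_map()].
#' @return integer bin count (including masked bins).
#' @export
n_bins <- function(map) nrow(map$matrix)

unmasked_bins <- function(map) setdiff(seq_len(n_bins(map)), map$mask)

#' Mask bins whose contact row is entirely zero
#'
#' @param map a [contact_map()].
#' @return the map with zero-sum bins added to the mask. Idempotent.
#' @export
mask_zero_bins <- function(map) {
  rs <- rowSums(map$matrix)
  zero <- which(rs == 0)
  contact_map(map$matrix, bin_size = map$bin_size,
              mask = union(map$mask, zero), balanced = map$balanced)
}

#' Build a contact map from an ensemble of conformations
#'
#' Entry (i, j), i != j, counts the snapshots in which monomers i and j lie
#' within `threshold` of each other (strict inequality); the default of
#' three lattice spacings is deliberately coarse, and downstream community
#' structure is insensitive to moderate changes of it.
#'
#' @param snapshots list of [conformation()] objects of equal length,
#'   typically from [anneal_snapshots()].
#' @param threshold contact distance in lattice units.
#' @return a [contact_map()] with `bin_size = 1`.
#' @export
contacts_from_snapshots <- function(snapshots, threshold = 3) {
  stopifnot(length(snapshots) >= 1, threshold > 0)
  if (inherits(snapshots, "conformation")) snapshots <- list(snapshots)
  ns <- vapply(snapshots, n_monomers, integer(1))
  if (length(unique(ns)) != 1L)
    stop("snapshots differ in length: ", paste(unique(ns), collapse = ", "))
  counts <- cpp_contact_counts(lapply(snapshots, `[[`, "coords"), threshold)
  contact_map(counts, bin_size = 1)
}

#' Ensemble contact probability versus contour separation
#'
#' Averages the contact weight over all unmasked pairs at each contour
#' (bin-index) separation s. Separations are always measured on original
#' bin indices, so masked bins reduce the sample size at a given s but do
#' not distort it.
#'
#' @param map a [contact_map()].
#' @param n_snapshots optional number of snapshots the counts were
#'   aggregated over; when given, `p` is a bona fide contact frequency in
#'   \[0, 1\] instead of a mean count.
#' @return data.frame with columns `s`, `p` (mean weight or frequency) and
#'   `n_pairs`.
#' @export
contact_probability <- function(map, n_snapshots = NULL) {
  N <- n_bins(map)
  keep <- !logical(N)
  keep[map$mask] <- FALSE
  A <- map$matrix
  s <- seq_len(N - 1)
  p <- numeric(N - 1)
  np <- numeric(N - 1)
  for (k in s) {
    i <- seq_len(N - k)
    ok <- keep[i] & keep[i + k]
    np[k] <- sum(ok)
    p[k] <- if (np[k] > 0) sum(A[cbind(i[ok], i[ok] + k)]) / np[k] else NA_real_
  }
  if (!is.null(n_snapshots)) p <- p / n_snapshots
  data.frame(s = s, p = p, n_pairs = np)
}

#' Write a contact map to text
#'
#' Two plain-text dialects are supported: `"dense"`, a whitespace-separated
#' full matrix, and `"sparse"`, coordinate triples `i j count` with 0-based
#' bin indices covering the upper triangle (entries are symmetrized on
#' read). A `#`-prefixed header carries bin size, dimension and mask.
#'
#' @param map a [contact_map()].
#' @param path file path.
#' @param format `"dense"` or `"sparse"`.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(map, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  hdr <- sprintf("# chromcomm contact_map: n=%d bin_size=%.17g balanced=%d format=%s",
                 n_bins(map), map$bin_size, as.integer(map$balanced), format)
  if (length(map$mask))
    hdr <- c(hdr, paste("# mask:", paste(map$mask - 1L, collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "dense") {
    writeLines(apply(map$matrix, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  } else {
    idx <- which(upper.tri(map$matrix) & map$matrix != 0, arr.ind = TRUE)
    writeLines(sprintf("%d\t%d\t%.17g", idx[, 1] - 1L, idx[, 2] - 1L,
                       map$matrix[idx]), con)
  }
  invisible(path)
}

#' Read a contact map from text
#'
#' Reads the dialects written by [write_contact_matrix()]. Sparse input is
#' taken as upper-triangle-plus-diagonal and symmetrized; a triple below
#' the diagonal is mirrored likewise. Bins whose row is entirely zero are
#' auto-masked with a message. Asymmetric dense input (beyond tolerance)
#' and malformed lines are errors.
#'
#' @param path file path.
#' @param format `"auto"` (sniff from header or column count), `"dense"` or
#'   `"sparse"`.
#' @param bin_size bin size, used when the header does not carry one.
#' @param n_bins matrix dimension, required for headerless sparse files.
#' @return a [contact_map()].
#' @export
read_contact_matrix <- function(path, format = c("auto", "dense", "sparse"),
                                bin_size = 1, n_bins = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- lines[hdr]
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data lines in ", path)

  get_num <- function(key, default) {
    m <- regmatches(meta, regexpr(paste0(key, "=[0-9.eE+-]+"), meta))
    m <- unlist(m)
    if (length(m)) as.numeric(sub(paste0(key, "="), "", m[[1]])) else default
  }
  n_hdr <- get_num("n", NA)
  bin_size <- get_num("bin_size", bin_size)
  mask_hdr <- integer()
  mm <- grep("^# mask:", meta, value = TRUE)
  if (length(mm))
    mask_hdr <- as.integer(strsplit(trimws(sub("^# mask:", "", mm[[1]])),
                                    "[[:space:]]+")[[1]]) + 1L

  fields <- strsplit(trimws(body), "[[:space:]]+")
  ncols <- lengths(fields)
  if (format == "auto") {
    fm <- regmatches(meta, regexpr("format=[a-z]+", meta))
    fm <- unlist(fm)
    format <- if (length(fm)) sub("format=", "", fm[[1]])
              else if (all(ncols == 3L) && length(body) != 3L) "sparse"
              else "dense"
  }

  if (format == "dense") {
    if (length(unique(ncols)) != 1L)
      stop("malformed dense matrix: ragged rows in ", path)
    m <- do.call(rbind, lapply(fields, as.numeric))
    if (anyNA(m)) stop("malformed numeric field in ", path)
    if (nrow(m) != ncol(m)) stop("dense matrix is not square in ", path)
    if (max(abs(m - t(m))) > 1e-8 * max(abs(m), 1))
      stop("asymmetric dense matrix in ", path)
  } else {
    if (any(ncols != 3L)) stop("malformed sparse triple in ", path)
    tr <- do.call(rbind, lapply(fields, as.numeric))
    if (anyNA(tr)) stop("malformed numeric field in ", path)
    n <- if (!is.na(n_hdr)) as.integer(n_hdr)
         else if (!is.null(n_bins)) as.integer(n_bins)
         else as.integer(max(tr[, 1:2]) + 1L)
    m <- matrix(0, n, n)
    for (r in seq_len(nrow(tr))) {
      i <- tr[r, 1] + 1L
      j <- tr[r, 2] + 1L
      if (i > n || j > n || i < 1 || j < 1)
        stop("sparse index out of range in ", path)
      m[i, j] <- m[i, j] + tr[r, 3]
      if (i != j) m[j, i] <- m[j, i] + tr[r, 3]
    }
  }
  map <- contact_map(m, bin_size = bin_size, mask = mask_hdr)
  rs <- rowSums(map$matrix)
  zero <- setdiff(which(rs == 0), map$mask)
  if (length(zero)) {
    message(sprintf("auto-masking %d zero-contact bin(s): %s", length(zero),
                    paste(head(zero, 10), collapse = ", ")))
    map <- mask_zero_bins(map)
  }
  map
}
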