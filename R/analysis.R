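#' Decompose a partition into contiguous segments
#'
#' A 3D community need not be one contiguous stretch of the chain: maximal
#' runs of a single label ("segments") can alternate, e.g. A-B-C-A-B.
#' Masked bins break runs and belong to no segment.
#'
#' @param part a `partition` from [louvain_communities()], or a plain label
#'   vector (`NA` = masked).
#' @return data.frame with columns `start`, `end` (1-based, inclusive) and
#'   `community`, in chain order; attribute `"segments_per_community"` is
#'   the named count of segments per community, and communities with at
#'   least two segments are flagged in attribute `"non_contiguous"`.
#' @export
decompose_segments <- function(part) {
  labels <- if (inherits(part, "partition")) part$labels else part
  n <- length(labels)
  if (!n) stop("empty label vector")
  key <- ifelse(is.na(labels), "<mask>", as.character(labels))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values != "<mask>"
  seg <- data.frame(start = starts[ok], end = ends[ok],
                    community = r$values[ok], stringsAsFactors = FALSE)
  if (is.integer(labels)) seg$community <- as.integer(seg$community)
  else if (is.numeric(labels)) seg$community <- as.numeric(seg$community)
  counts <- table(seg$community)
  attr(seg, "segments_per_community") <- counts
  attr(seg, "non_contiguous") <- names(counts)[counts >= 2]
  seg
}

#' Community borders of a partition
#'
#' A border is the first bin of each new segment. Chain ends are not
#' borders, and neither are bins adjacent to masked stretches (those
#' boundaries are artifacts of mappability, not structure).
#'
#' @param part a `partition` or label vector.
#' @return sorted integer vector of border bin indices (1-based).
#' @export
community_borders <- function(part) {
  labels <- if (inherits(part, "partition")) part$labels else part
  seg <- decompose_segments(part)
  if (nrow(seg) < 2) return(integer())
  b <- seg$start[-1]
  # drop borders whose preceding bin is masked (mask-adjacent)
  b[!is.na(labels[b - 1L])]
}

#' End-to-end distance versus contour separation
#'
#' For `subchains = "all"`, averages the Euclidean distance between
#' monomers `i` and `i + s` over all pairs of every conformation in the
#' ensemble. For `subchains = "segments"`, each contiguous community
#' segment contributes one point at `s = end - start` (bonds): the
#' distance between its two boundary monomers. Conformations and
#' partitions are aligned by position in their lists.
#'
#' @param confs a [conformation()] or list of them.
#' @param partitions optional `partition` (or list, one per conformation);
#'   required for `subchains = "segments"`.
#' @param subchains `"all"` or `"segments"`.
#' @return a data.frame of class `scaling_curve` with columns `s`,
#'   `mean_R`, `sem` and `n` (pair count).
#' @export
end_to_end_curve <- function(confs, partitions = NULL,
                             subchains = c("all", "segments")) {
  subchains <- match.arg(subchains)
  if (inherits(confs, "conformation")) confs <- list(confs)
  if (subchains == "all") {
    acc_sum <- acc_sq <- acc_n <- NULL
    for (conf in confs) {
      cur <- cpp_ee_curve(conf$coords)
      if (is.null(acc_sum)) {
        acc_sum <- cur$sum; acc_sq <- cur$sumsq; acc_n <- cur$count
      } else {
        if (length(cur$sum) != length(acc_sum))
          stop("conformations differ in length")
        acc_sum <- acc_sum + cur$sum
        acc_sq <- acc_sq + cur$sumsq
        acc_n <- acc_n + cur$count
      }
    }
    s <- seq_along(acc_sum)
    mean_R <- acc_sum / acc_n
    vr <- pmax(acc_sq / acc_n - mean_R^2, 0)
    curve <- data.frame(s = s, mean_R = mean_R,
                        sem = sqrt(vr / pmax(acc_n - 1, 1)), n = acc_n)
  } else {
    if (is.null(partitions)) stop("subchains = \"segments\" needs partitions")
    if (inherits(partitions, "partition")) partitions <- list(partitions)
    if (length(partitions) != length(confs))
      stop("need one partition per conformation")
    ss <- rr <- numeric(0)
    for (i in seq_along(confs)) {
      conf <- confs[[i]]
      seg <- decompose_segments(partitions[[i]])
      seg <- seg[seg$end > seg$start, , drop = FALSE]
      if (!nrow(seg)) next
      d <- conf$coords[seg$end, , drop = FALSE] -
        conf$coords[seg$start, , drop = FALSE]
      ss <- c(ss, seg$end - seg$start)
      rr <- c(rr, sqrt(rowSums(d^2)))
    }
    if (!length(ss)) stop("no multi-bin segments found")
    agg_n <- tapply(rr, ss, length)
    agg_m <- tapply(rr, ss, mean)
    agg_sd <- tapply(rr, ss, sd)
    s <- as.integer(names(agg_m))
    curve <- data.frame(s = s, mean_R = as.numeric(agg_m),
                        sem = as.numeric(agg_sd) / sqrt(as.numeric(agg_n)),
                        n = as.numeric(agg_n))
  }
  class(curve) <- c("scaling_curve", "data.frame")
  curve
}

#' Fit a log-log scaling exponent
#'
#' Least-squares slope of `log(mean_R)` (or any positive quantity) against
#' `log(s)` over a stated window of intermediate separations. The default
#' window \[8, N^(2/3)\] avoids short-range lattice artifacts at small `s`
#' and finite-size effects at large `s`.
#'
#' @param curve a `scaling_curve` (or any data.frame with `s` and a value
#'   column).
#' @param s_min,s_max fit window (inclusive); `s_max = NULL` uses
#'   `max(s)^(2/3)` scaled from the longest separation, i.e. `N^(2/3)`.
#' @param value name of the value column (default `"mean_R"`; use `"p"`
#'   for contact-probability curves).
#' @return list with `exponent`, `se`, `intercept`, `window` and
#'   `n_points`.
#' @export
fit_scaling_exponent <- function(curve, s_min = 8, s_max = NULL,
                                 value = "mean_R") {
  s <- curve$s
  y <- curve[[value]]
  if (is.null(y)) stop("no column '", value, "' in curve")
  if (is.null(s_max)) s_max <- (max(s) + 1)^(2 / 3)
  ok <- is.finite(y) & y > 0 & s >= s_min & s <= s_max
  if (sum(ok) < 3) stop("fewer than 3 points in the fit window")
  fit <- lm(log(y[ok]) ~ log(s[ok]))
  list(exponent = unname(coef(fit)[2]),
       se = suppressWarnings(unname(sqrt(diag(vcov(fit)))[2])),
       intercept = unname(coef(fit)[1]),
       window = c(s_min, s_max), n_points = sum(ok))
}

#' Radius of gyration
#'
#' `R_g = sqrt( (1 / 2N^2) * sum_{i,j} ||r_i - r_j||^2 )`, computed via the
#' equivalent mean-centered second moment.
#'
#' @param conf a [conformation()] or a coordinate matrix.
#' @return the radius of gyration (lattice units).
#' @export
radius_of_gyration <- function(conf) {
  coords <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Normalize a scaling curve by the chain size
#'
#' Divides the distance axis by the average chain size, taken as
#' `chain_size_factor * R_g` (factor 2 by default, i.e. twice the radius
#' of gyration), so curves from chains of different compactness can be
#' compared on one axis.
#'
#' @param curve a `scaling_curve`.
#' @param rg radius of gyration (scalar, e.g. ensemble mean).
#' @param chain_size_factor multiplier on `rg` (default 2).
#' @return the curve with `mean_R` and `sem` rescaled.
#' @export
normalize_by_rg <- function(curve, rg, chain_size_factor = 2) {
  stopifnot(rg > 0)
  curve$mean_R <- curve$mean_R / (chain_size_factor * rg)
  curve$sem <- curve$sem / (chain_size_factor * rg)
  curve
}

#' Gyration-tensor asphericity
#'
#' `b = (lambda1 - (lambda2 + lambda3) / 2) / (lambda1 + lambda2 +
#' lambda3)` with `lambda1 >= lambda2 >= lambda3` the eigenvalues of the
#' gyration tensor. 0 for spherically symmetric point sets, 1 for
#' collinear ones.
#'
#' @param conf a [conformation()], a coordinate matrix, or a subset of
#'   rows of one (e.g. a community segment).
#' @return asphericity in \[0, 1\].
#' @export
asphericity <- function(conf) {
  coords <- if (inherits(conf, "conformation")) conf$coords else as.matrix(conf)
  if (nrow(coords) < 2) stop("need at least two points")
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  S <- crossprod(X) / nrow(X)
  lam <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  tr <- sum(lam)
  if (tr <= 0) return(0)
  (lam[1] - (lam[2] + lam[3]) / 2) / tr
}

#' Overlap between predicted community borders and reference positions
#'
#' Fraction of predicted borders that have a reference position within
#' `window` bins, plus the reciprocal fraction (reference positions near a
#' predicted border).
#'
#' @param part a `partition` (its borders are extracted with
#'   [community_borders()]) or an integer vector of already-extracted
#'   border bins.
#' @param reference sorted integer vector of reference positions (bins,
#'   1-based), e.g. reference TAD boundaries or CTCF site bins.
#' @param window matching tolerance in bins (default 1).
#' @return list with `fraction` (predicted borders matched),
#'   `reciprocal` (reference positions matched), `n_predicted`,
#'   `n_reference`.
#' @export
border_overlap <- function(part, reference, window = 1) {
  borders <- if (inherits(part, "partition")) community_borders(part)
             else as.integer(part)
  reference <- sort(unique(as.integer(reference)))
  near <- function(x, ref) {
    if (!length(x)) return(numeric(0))
    if (!length(ref)) return(rep(FALSE, length(x)))
    vapply(x, function(b) min(abs(ref - b)) <= window, logical(1))
  }
  list(fraction = if (length(borders)) mean(near(borders, reference)) else 0,
       reciprocal = if (length(reference)) mean(near(reference, borders)) else 0,
       n_predicted = length(borders), n_reference = length(reference))
}

#' Communities and contiguous blocks per community
#'
#' Contiguous blocks ("TAD-like" segments) of one community are counted by
#' [decompose_segments()]; the summary reports how many communities a
#' partition has and how many blocks a community holds on average, i.e.
#' how many TAD-scale units assemble into one 3D community.
#'
#' @param part a `partition` or label vector.
#' @return list with `n_communities`, `mean_segments`, and the per-
#'   community segment counts.
#' @export
tads_per_community <- function(part) {
  seg <- decompose_segments(part)
  counts <- attr(seg, "segments_per_community")
  list(n_communities = length(counts),
       mean_segments = mean(as.numeric(counts)),
       segments_per_community = counts)
}

#' Per-community summary of a bin-level signal track
#'
#' Median and quartiles of a per-bin signal (e.g. RNA-seq coverage) over
#' the member bins of each community, largest community first. Small
#' communities are excluded.
#'
#' @param part a `partition` or label vector.
#' @param track numeric vector, one value per bin.
#' @param min_size smallest community size reported (default 50 bins).
#' @return data.frame with `community`, `size`, `q1`, `median`, `q3`,
#'   ordered by decreasing size.
#' @export
signal_by_community <- function(part, track, min_size = 50) {
  labels <- if (inherits(part, "partition")) part$labels else part
  if (length(track) != length(labels))
    stop("track must have one value per bin")
  keep <- !is.na(labels)
  groups <- split(track[keep], labels[keep])
  sizes <- lengths(groups)
  groups <- groups[sizes >= min_size]
  sizes <- sizes[sizes >= min_size]
  if (!length(groups))
    return(data.frame(community = integer(), size = integer(),
                      q1 = numeric(), median = numeric(), q3 = numeric()))
  qs <- vapply(groups, quantile, numeric(3), probs = c(0.25, 0.5, 0.75),
               names = FALSE)
  out <- data.frame(community = names(groups), size = as.integer(sizes),
                    q1 = qs[1, ], median = qs[2, ], q3 = qs[3, ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}
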