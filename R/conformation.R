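#' Polymer conformation container
#'
#' An ordered chain of monomer coordinates. On-lattice conformations have
#' integer coordinates and exact unit bonds; off-lattice conformations
#' (e.g. annealed variants) keep the bond length within a small numerical
#' tolerance.
#'
#' @param coords numeric matrix with one row per monomer and columns x, y, z;
#'   row order is chain order.
#' @param lattice logical; `TRUE` if the coordinates are integer lattice
#'   sites.
#' @param bond_length fixed distance between consecutive monomers, in
#'   lattice units.
#' @param params named list of generation parameters (model, seed, ...)
#'   carried along for provenance.
#' @return an object of class `conformation`.
#' @export
conformation <- function(coords, lattice = FALSE, bond_length = 1,
                         params = list()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have three columns (x, y, z)")
  if (nrow(coords) < 2L) stop("a conformation needs at least two monomers")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(coords = coords, lattice = isTRUE(lattice),
                 bond_length = bond_length, params = params),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d monomers, %s, bond length %g\n",
              nrow(x$coords), if (x$lattice) "on-lattice" else "off-lattice",
              x$bond_length))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Number of monomers in a conformation
#' @param conf a [conformation()].
#' @return integer chain length.
#' @export
n_monomers <- function(conf) nrow(conf$coords)

bond_lengths <- function(conf) {
  d <- diff(conf$coords)
  sqrt(rowSums(d^2))
}

#' Validate chain constraints of a conformation
#'
#' Checks that all consecutive monomers sit at the stated bond length and
#' that the chain is self-avoiding: on-lattice, no two monomers share a
#' site; off-lattice, no two monomers are closer than the excluded-volume
#' diameter.
#'
#' @param conf a [conformation()].
#' @param tol bond-length tolerance (absolute, lattice units).
#' @param ev_diameter minimum allowed pairwise distance for off-lattice
#'   chains; defaults to 0.8 * bond_length, the excluded-volume diameter
#'   used during annealing.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
check_conformation <- function(conf, tol = 1e-6, ev_diameter = NULL) {
  stopifnot(inherits(conf, "conformation"))
  b <- bond_lengths(conf)
  if (any(abs(b - conf$bond_length) > tol))
    stop(sprintf("bond-length violation: max deviation %.3g exceeds tol %.3g",
                 max(abs(b - conf$bond_length)), tol))
  if (conf$lattice) {
    key <- paste(conf$coords[, 1], conf$coords[, 2], conf$coords[, 3])
    if (anyDuplicated(key))
      stop("self-avoidance violation: duplicated lattice site")
  } else {
    if (is.null(ev_diameter)) ev_diameter <- 0.8 * conf$bond_length
    mind <- cpp_min_pairdist(conf$coords, ev_diameter)
    if (is.finite(mind))
      stop(sprintf("self-avoidance violation: pair distance %.4g < %.4g",
                   mind, ev_diameter))
  }
  invisible(TRUE)
}

#' Write / read conformations as XYZ-style text
#'
#' Plain 3-column whitespace-separated text, one monomer per line in chain
#' order, with `#`-prefixed header lines carrying the bond length, lattice
#' flag and generation parameters.
#'
#' @param conf a [conformation()].
#' @param path file path.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` returns a
#'   [conformation()].
#' @export
write_xyz <- function(conf, path) {
  stopifnot(inherits(conf, "conformation"))
  hdr <- c(sprintf("# chromcomm conformation: n=%d lattice=%d bond_length=%.17g",
                   nrow(conf$coords), as.integer(conf$lattice),
                   conf$bond_length),
           if (length(conf$params))
             sprintf("# param %s=%s", names(conf$params),
                     vapply(conf$params, function(p) format(p, digits = 17),
                            character(1))))
  body <- sprintf("%.17g %.17g %.17g", conf$coords[, 1], conf$coords[, 2],
                  conf$coords[, 3])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- lines[hdr]
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(trimws(body))]
  coords <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                                  function(x) as.numeric(x[1:3])))
  if (anyNA(coords)) stop("malformed coordinate line in ", path)
  lattice <- any(grepl("lattice=1", meta))
  bond <- 1
  m <- regmatches(meta, regexpr("bond_length=[0-9.eE+-]+", meta))
  if (length(m)) bond <- as.numeric(sub("bond_length=", "", m[[1]]))
  params <- list()
  pm <- grep("^# param ", meta, value = TRUE)
  if (length(pm)) {
    kv <- strsplit(sub("^# param ", "", pm), "=")
    params <- setNames(lapply(kv, function(x) {
      v <- suppressWarnings(as.numeric(x[2]))
      if (is.na(v)) x[2] else v
    }), vapply(kv, `[[`, character(1), 1))
  }
  conformation(coords, lattice = lattice, bond_length = bond, params = params)
}
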