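#' Generate a self-contained simulation fixture bundle
#'
#' Runs the full desk-scale workflow — simulate fractal and equilibrium
#' globules, anneal, build and balance contact maps, detect communities
#' over a gamma grid, and tabulate scaling curves — writing every artifact
#' into a directory. The bundle regenerates deterministically from its
#' seed (byte-identical outputs) and serves as the package's stand-in for
#' external Hi-C data.
#'
#' @param dir output directory; created (recursively) if missing.
#' @param N chain length per polymer.
#' @param n_chains chains per ensemble.
#' @param gammas resolution values for the scan.
#' @param seed base seed; chain c of model m uses an offset derived from
#'   it.
#' @param n_snapshots annealed snapshots per chain.
#' @param threshold contact distance (lattice units).
#' @param n_restarts Louvain restarts per gamma.
#' @return invisibly, a list with the file manifest and the run metadata
#'   (also written to `metadata.json`).
#' @export
pipeline_fixture <- function(dir, N = 512, n_chains = 5,
                             gammas = c(0.4, 0.6, 0.8), seed = 1,
                             n_snapshots = 50, threshold = 3,
                             n_restarts = 3) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("output directory not writable: ", dir)
  manifest <- character()
  summaries <- list()

  for (model in c("fg", "eg")) {
    confs <- list()
    maps <- list()
    for (c_i in seq_len(n_chains)) {
      s <- seed + 1000L * c_i + ifelse(model == "eg", 500L, 0L)
      conf <- if (model == "fg") generate_cdp(N, seed = s)
              else generate_equilibrium_globule(N, seed = s)
      snaps <- anneal_snapshots(conf, n_snapshots = n_snapshots, seed = s + 1,
                                validate = FALSE)
      map <- kr_balance(contacts_from_snapshots(snaps, threshold = threshold))
      confs[[c_i]] <- conf
      maps[[c_i]] <- map
      fx <- file.path(dir, sprintf("%s_chain%02d.xyz", model, c_i))
      fm <- file.path(dir, sprintf("%s_chain%02d_map.txt", model, c_i))
      write_xyz(conf, fx)
      write_contact_matrix(map, fm, format = "sparse")
      manifest <- c(manifest, fx, fm)
    }

    parts <- gamma_scan(maps[[1]], gammas, seed = seed,
                        n_restarts = n_restarts)
    for (g_i in seq_along(gammas)) {
      fp <- file.path(dir, sprintf("%s_partition_gamma%s.tsv", model,
                                   gsub("\\.", "p", format(gammas[g_i]))))
      write_partition(parts[[g_i]], fp, bin_size = 1)
      manifest <- c(manifest, fp)
    }
    fs <- file.path(dir, sprintf("%s_gamma_summary.tsv", model))
    write.table(attr(parts, "summary"), fs, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- c(manifest, fs)

    curve <- end_to_end_curve(confs)
    fc <- file.path(dir, sprintf("%s_scaling.tsv", model))
    write.table(format(curve, digits = 10), fc, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <- c(manifest, fc)
    summaries[[model]] <- list(
      ee_exponent = fit_scaling_exponent(curve)$exponent,
      mean_rg = mean(vapply(confs, radius_of_gyration, numeric(1))),
      gamma_summary = attr(parts, "summary"))
  }

  meta <- list(tool = "chromcomm", version = as.character(packageVersion("chromcomm")),
               N = N, n_chains = n_chains, gammas = gammas, seed = seed,
               n_snapshots = n_snapshots, threshold = threshold,
               n_restarts = n_restarts, summaries = summaries)
  fj <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- c(manifest, fj)
  invisible(list(manifest = manifest, metadata = meta))
}

#' Write a partition as TSV
#'
#' One row per bin: `bin_index` (0-based), `coord_start` (bin start in bp,
#' 0-based half-open) and `community_id` (`NA` for masked bins).
#'
#' @param part a `partition`.
#' @param path output file.
#' @param bin_size bin width in bp (1 for monomers).
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path, bin_size = 1) {
  stopifnot(inherits(part, "partition"))
  n <- length(part$labels)
  df <- data.frame(bin_index = seq_len(n) - 1L,
                   coord_start = (seq_len(n) - 1L) * bin_size,
                   community_id = part$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write run metadata JSON next to a result
#' @param meta named list.
#' @param path output file.
#' @return `path`, invisibly.
#' @keywords internal
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
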