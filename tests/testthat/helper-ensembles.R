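# Shared full-scale simulation ensembles for the acceptance suite.
# Generated lazily once per test run and memoized; each chain is reduced to
# the summaries the tests need (conformation, P(s), gamma = 0.4 partition)
# so only one full contact map is in memory at a time.

.ens_cache <- new.env(parent = emptyenv())

ensemble_chain <- function(model, i, N = 4096, n_snapshots = 100,
                           threshold = 3, gamma = 0.4) {
  seed <- 5000 + i + ifelse(model == "eg", 100, 0)
  conf <- if (model == "fg") generate_cdp(N, seed = seed)
          else generate_equilibrium_globule(N, seed = seed)
  snaps <- anneal_snapshots(conf, n_snapshots = n_snapshots, seed = seed + 1000,
                            validate = FALSE)
  map <- contacts_from_snapshots(snaps, threshold = threshold)
  ps <- contact_probability(map, n_snapshots = n_snapshots)
  part <- louvain_communities(kr_balance(map), gamma = gamma, seed = 1,
                              n_restarts = 2)
  list(conf = conf, ps = ps, part = part)
}

acceptance_ensemble <- function(model, n_chains = 20) {
  key <- paste0(model, n_chains)
  if (!is.null(.ens_cache[[key]])) return(.ens_cache[[key]])
  res <- lapply(seq_len(n_chains), function(i) ensemble_chain(model, i))
  .ens_cache[[key]] <- res
  res
}

# ensemble-average contact probability curve (equal chain weighting)
ensemble_ps <- function(ens) {
  p <- Reduce(`+`, lapply(ens, function(x) x$ps$p)) / length(ens)
  data.frame(s = ens[[1]]$ps$s, p = p)
}

# weighted log2-binned comparison of segment vs all-subchain end-to-end
# distance at matched s (bins with s >= 4)
compactness_bins <- function(ens) {
  confs <- lapply(ens, `[[`, "conf")
  parts <- lapply(ens, `[[`, "part")
  all_c <- end_to_end_curve(confs)
  seg_c <- end_to_end_curve(confs, partitions = parts, subchains = "segments")
  sg <- seg_c[seg_c$s >= 4, ]
  grp <- split(seq_len(nrow(sg)), findInterval(sg$s, 2^(2:12)))
  out <- t(vapply(grp, function(ix) {
    ntot <- sum(sg$n[ix])
    segR <- sum(sg$mean_R[ix] * sg$n[ix]) / ntot
    allR <- sum(all_c$mean_R[sg$s[ix]] * sg$n[ix]) / ntot
    c(s_mid = exp(mean(log(sg$s[ix]))), segR = segR, allR = allR, n = ntot)
  }, numeric(4)))
  data.frame(out)
}
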