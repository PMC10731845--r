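# brute-force step-up FDR: q_i = min over j >= rank(i) of p_(j)*m/j, cap 1
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) p[o[j]] * m / j)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# exact permutation null for the pathway statistic: enumerate all C(n, k)
# placements of k significant labels over the mapped features
pathway_exact_p <- function(map, n_sig, pathway_sets, s_obs) {
  feats <- names(map$feature_metabolites)
  combos <- utils::combn(length(feats), n_sig)
  tail_ct <- numeric(length(pathway_sets))
  for (j in seq_len(ncol(combos))) {
    s_star <- metabomwas:::pathway_stat(map, feats[combos[, j]], pathway_sets)
    tail_ct <- tail_ct + (s_star >= s_obs - 1e-12)
  }
  tail_ct / ncol(combos)
}

mk_hits <- function(df) {
  data.frame(feature_id = df$f, metabolite_id = df$m,
             adduct = "[M+H]+", ppm_error = 0, rt_error = NA_real_,
             tier = 2L, stringsAsFactors = FALSE)
}
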