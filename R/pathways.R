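#' Read / write pathway sets in GMT format
#'
#' One pathway per line: name, description, then tab-separated member ids.
#'
#' @param path file path.
#' @return named list of character vectors (descriptions kept in attribute
#'   `"descriptions"`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Multiple-matching weight map for pathway testing
#'
#' Each (feature, metabolite) match gets weight `1 / (number of distinct
#' metabolites that feature matches)`; each metabolite's contribution is
#' `u_m = min(1, sum of weights of its matched features)`.  Features from
#' both ion modes feed one joint map, so a metabolite matched on both
#' columns is counted once (capped at 1) rather than double counted.
#'
#' @param hits annotation hits from [match_features()].
#' @return list of class `weight_map`: `pair_weights` (data.frame
#'   feature_id, metabolite_id, weight), `u` (named metabolite
#'   contributions), `feature_metabolites` (list: metabolites per feature).
#' @export
build_weight_map <- function(hits) {
  pairs <- unique(hits[, c("feature_id", "metabolite_id")])
  n_met <- table(pairs$feature_id)
  w <- 1 / as.numeric(n_met[pairs$feature_id])
  pair_weights <- data.frame(pairs, weight = w, stringsAsFactors = FALSE,
                             row.names = NULL)
  u_raw <- tapply(pair_weights$weight, pair_weights$metabolite_id, sum)
  u <- pmin(1, as.numeric(u_raw))
  names(u) <- names(u_raw)
  structure(list(pair_weights = pair_weights, u = u,
                 feature_metabolites = split(pair_weights$metabolite_id,
                                             pair_weights$feature_id)),
            class = "weight_map")
}

# weighted significant-metabolite statistic for each pathway given the set
# of significant features
pathway_stat <- function(map, sig_features, pathway_sets) {
  sig_mets <- unique(unlist(map$feature_metabolites[
    intersect(sig_features, names(map$feature_metabolites))]))
  vapply(pathway_sets, function(mets) {
    hit <- intersect(mets, sig_mets)
    sum(map$u[hit])
  }, numeric(1))
}

#' Permutation-based weighted pathway enrichment test
#'
#' A metabolite is "significant-mapped" when at least one significant
#' feature matches it.  The observed pathway statistic is the sum, over the
#' pathway's mapped metabolites, of the multiple-matching contribution
#' `u_m` of significant-mapped members.  The null permutes the
#' significant/non-significant labels uniformly over all mapped features `B`
#' times; `p = (1 + #{S* >= S}) / (B + 1)`, BH-adjusted across pathways.
#' Pathway members absent from the weight map are dropped (with a notice);
#' an empty significant set returns p = 1 everywhere.
#'
#' @param map [build_weight_map()] output.
#' @param sig_features character vector of significant feature ids.
#' @param pathways named list of metabolite-id sets (see [read_gmt()]).
#' @param B number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return data.frame: pathway, n_metabolites_mapped, S, p, fdr.
#' @export
pathway_permutation_test <- function(map, sig_features, pathways, B = 9999,
                                     seed = 1L) {
  stopifnot(B >= 99)
  mapped_features <- names(map$feature_metabolites)
  mapped_mets <- names(map$u)
  kept_sets <- lapply(pathways, function(mets) intersect(mets, mapped_mets))
  n_dropped <- sum(lengths(pathways) - lengths(kept_sets))
  if (n_dropped > 0)
    message(sprintf("pathway test: %d pathway members not in the weight map were dropped",
                    n_dropped))
  sig <- intersect(sig_features, mapped_features)
  n_sig <- length(sig)
  s_obs <- pathway_stat(map, sig, kept_sets)
  if (n_sig == 0L) {
    p <- rep(1, length(kept_sets))
  } else {
    exceed <- numeric(length(kept_sets))
    with_seed(seed, {
      for (b in seq_len(B)) {
        perm_sig <- sample(mapped_features, n_sig)
        s_star <- pathway_stat(map, perm_sig, kept_sets)
        exceed <- exceed + (s_star >= s_obs - 1e-12)
      }
    })
    p <- (1 + exceed) / (B + 1)
  }
  data.frame(pathway = names(pathways),
             n_metabolites_mapped = lengths(kept_sets),
             S = s_obs, p = p, fdr = bh_fdr(p),
             stringsAsFactors = FALSE, row.names = NULL)
}
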