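# Synthetic multi-dataset studies and reference databases with planted
# ground truth.
#
# The expression model is deliberately the simplest one under which the
# paired t-test is exact: each gene has a Gaussian log2 baseline, each
# subject a Gaussian offset shared by its tumour and normal samples, and
# the tumour sample of a planted differentially expressed gene (DEG) is
# shifted by a fixed log2 effect (present per dataset with a given
# probability, occasionally with flipped sign, to exercise the
# score-cancellation behaviour of the combiner). The reference database
# plants "inhibitor" compounds whose profiles put the signature genes at
# the extreme ranks with opposite signs, "mimic" compounds with matching
# signs, and null compounds with uniformly random signed-rank permutations.

#' Generate a multi-dataset paired expression study with planted DEGs
#'
#' @param n_datasets Number of datasets (default 5).
#' @param n_genes Shared gene-universe size (default 2000).
#' @param pairs_per_dataset Integer vector of tumour/normal pair counts, one
#'   per dataset (default `c(15, 19, 4, 18, 15)`, mixing well-powered and
#'   under-powered studies).
#' @param n_deg Number of planted DEGs (default 100).
#' @param effect_log2 Absolute log2 effect size of planted DEGs (default 2).
#' @param presence_prob Probability that a planted DEG is actually perturbed
#'   in a given dataset (default 0.8).
#' @param flip_prob Probability that a present DEG's effect sign is flipped
#'   in a given dataset (default 0.05).
#' @param noise_sd SD of the tumour-specific log2 noise (default 0.5).
#' @param subject_sd SD of the per-subject baseline offset (default 1).
#' @param baseline_mean,baseline_sd Gene baseline distribution on the log2
#'   scale (defaults 8 and 2, typical of microarray intensities).
#' @param seed Integer seed.
#' @return List with `datasets` (list of [paired_dataset]) and `truth`
#'   (fields `deg_ids`, `effects` named signed log2 effects, and logical
#'   DEG x dataset matrices `presence` and `flipped`).
#' @export
generate_study <- function(n_datasets = 5, n_genes = 2000,
                           pairs_per_dataset = c(15, 19, 4, 18, 15),
                           n_deg = 100, effect_log2 = 2,
                           presence_prob = 0.8, flip_prob = 0.05,
                           noise_sd = 0.5, subject_sd = 1,
                           baseline_mean = 8, baseline_sd = 2, seed) {
  .assert_scalar_number(n_genes, "n_genes", lower = 2)
  .assert_scalar_number(n_deg, "n_deg", lower = 0, upper = n_genes - 1)
  .assert_scalar_number(effect_log2, "effect_log2", lower = 0)
  .assert_scalar_number(presence_prob, "presence_prob", lower = 0, upper = 1)
  .assert_scalar_number(flip_prob, "flip_prob", lower = 0, upper = 1)
  if (length(pairs_per_dataset) != n_datasets) {
    stop("'pairs_per_dataset' must have one entry per dataset", call. = FALSE)
  }
  if (any(pairs_per_dataset < 2)) {
    stop("each dataset needs at least 2 pairs", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    genes <- sprintf("g%05d", seq_len(n_genes))
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    deg_ids <- sort(sample(genes, n_deg))
    effects <- stats::setNames(
      sample(c(-1, 1), n_deg, replace = TRUE) * effect_log2, deg_ids)
    presence <- matrix(stats::runif(n_deg * n_datasets) < presence_prob,
                       nrow = n_deg, ncol = n_datasets,
                       dimnames = list(deg_ids, paste0("sim", seq_len(n_datasets))))
    flipped <- matrix(stats::runif(n_deg * n_datasets) < flip_prob,
                      nrow = n_deg, ncol = n_datasets,
                      dimnames = dimnames(presence)) & presence
    datasets <- vector("list", n_datasets)
    for (d in seq_len(n_datasets)) {
      np <- pairs_per_dataset[d]
      delta <- numeric(n_genes)
      names(delta) <- genes
      eff <- effects * ifelse(flipped[, d], -1, 1)
      delta[deg_ids] <- ifelse(presence[, d], eff, 0)
      subj <- sprintf("s%d_%02d", d, seq_len(np))
      subj_off <- stats::rnorm(np, 0, subject_sd)
      normal <- matrix(baseline, n_genes, np) +
        matrix(subj_off, n_genes, np, byrow = TRUE) +
        matrix(stats::rnorm(n_genes * np, 0, noise_sd), n_genes, np)
      tumour <- normal + delta +
        matrix(stats::rnorm(n_genes * np, 0, noise_sd), n_genes, np)
      vals <- cbind(tumour, normal)
      colnames(vals) <- c(paste0(subj, "_T"), paste0(subj, "_N"))
      rownames(vals) <- genes
      pairs <- data.frame(tumour = paste0(subj, "_T"),
                          normal = paste0(subj, "_N"),
                          subject = subj,
                          stage = sample(c("II", "III", "IV"), np,
                                         replace = TRUE),
                          stringsAsFactors = FALSE)
      datasets[[d]] <- paired_dataset(colnames(presence)[d], vals, pairs)
    }
    list(datasets = datasets,
         truth = list(deg_ids = deg_ids, effects = effects,
                      presence = presence, flipped = flipped))
  })
}

#' Generate a synthetic compound reference database with planted truth
#'
#' Null compounds receive uniformly random signed-rank permutations.
#' Planted inhibitors (mimics) receive, in each replicate, profiles whose
#' extreme rank magnitudes (`N`, `N-1`, ...) sit on a random `strength`
#' fraction of the supplied signature genes with opposite (matching) signs;
#' the remaining magnitudes are randomly assigned.
#'
#' @param universe Character vector of gene ids.
#' @param n_compounds Total number of compounds (default 200).
#' @param replicates_range Inclusive range of per-compound replicate counts,
#'   drawn uniformly (default `c(2, 8)`, mean 5, emulating the roughly 4.7
#'   replicate profiles per compound of the large public compound-profile
#'   reference collections).
#' @param n_inhibitors,n_mimics Numbers of planted inhibitor/mimic compounds
#'   (defaults 12 and 0); the rest are null compounds.
#' @param strength Fraction of signature genes forced to the extreme ranks
#'   in each planted replicate, in `(0, 1]` (default 0.8).
#' @param signature A [query_signature] over `universe` to plant against
#'   (required when `n_inhibitors + n_mimics > 0`).
#' @param seed Integer seed.
#' @return List with `db` (a `reference_db`) and `truth` (fields
#'   `inhibitor_ids`, `mimic_ids`, `null_ids`, `strength`).
#' @export
generate_reference_db <- function(universe, n_compounds = 200,
                                  replicates_range = c(2, 8),
                                  n_inhibitors = 12, n_mimics = 0,
                                  strength = 0.8, signature = NULL, seed) {
  N <- length(universe)
  .assert_scalar_number(n_compounds, "n_compounds", lower = 1)
  .assert_scalar_number(strength, "strength",
                        lower = .Machine$double.eps, upper = 1)
  if (n_inhibitors + n_mimics > n_compounds) {
    stop("planted compounds exceed n_compounds", call. = FALSE)
  }
  planted <- n_inhibitors + n_mimics > 0
  if (planted) {
    if (is.null(signature)) {
      stop("'signature' is required to plant inhibitors or mimics", call. = FALSE)
    }
    stopifnot(inherits(signature, "query_signature"))
    sig_idx <- match(signature$gene_id, universe)
    if (anyNA(sig_idx)) stop("signature genes must be in 'universe'", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("cmpd%03d", seq_len(n_compounds))
    inhibitor_ids <- if (n_inhibitors) ids[seq_len(n_inhibitors)] else character()
    mimic_ids <- if (n_mimics) ids[n_inhibitors + seq_len(n_mimics)] else character()
    null_ids <- setdiff(ids, c(inhibitor_ids, mimic_ids))
    n_rep <- sample(seq(replicates_range[1], replicates_range[2]),
                    n_compounds, replace = TRUE)
    meta <- data.frame(
      compound = rep(ids, times = n_rep),
      replicate_id = unlist(lapply(n_rep, function(k) sprintf("r%d", seq_len(k)))),
      stringsAsFactors = FALSE
    )
    # strength is a per-compound property: each planted compound forces the
    # same `strength` fraction of the signature genes in all its replicates
    # (replicates differ in rank assignment and in the unforced genes)
    forced_sets <- lapply(ids, function(cmp) {
      if (!cmp %in% c(inhibitor_ids, mimic_ids)) return(integer())
      sort(sample(seq_len(nrow(signature)),
                  max(1L, round(strength * nrow(signature)))))
    })
    names(forced_sets) <- ids
    ranks <- matrix(0L, nrow = N, ncol = nrow(meta))
    for (j in seq_len(nrow(meta))) {
      cmp <- meta$compound[j]
      kind <- if (cmp %in% inhibitor_ids) "inhibitor" else
        if (cmp %in% mimic_ids) "mimic" else "null"
      col <- integer(N)
      if (kind == "null") {
        col <- sample(c(-1L, 1L), N, replace = TRUE) * sample.int(N)
      } else {
        forced <- forced_sets[[cmp]]
        k <- length(forced)
        sgn_mult <- if (kind == "inhibitor") -1L else 1L
        top_mags <- N - seq_len(k) + 1L
        col[sig_idx[forced]] <- sgn_mult * as.integer(signature$sign[forced]) *
          sample(top_mags)
        rest <- setdiff(seq_len(N), sig_idx[forced])
        col[rest] <- sample(c(-1L, 1L), length(rest), replace = TRUE) *
          sample(seq_len(N - k))
      }
      ranks[, j] <- col
    }
    list(db = reference_db(universe, ranks, meta),
         truth = list(inhibitor_ids = inhibitor_ids, mimic_ids = mimic_ids,
                      null_ids = null_ids, strength = strength))
  })
}
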