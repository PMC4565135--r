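# Perturbation stability of drug connections.
#
# A connection worth acting on should not hinge on a handful of signature
# genes. Each hit compound is re-tested under many perturbed versions of the
# final signature (random or exhaustive removal of a few genes); its
# stability is the fraction of perturbations under which the connection
# stays significant at the same Efp/Nc threshold and direction.

#' Perturbed versions of a query signature
#'
#' Each perturbation removes `n_remove` genes, preserving the order and
#' signs of the rest. In `"exhaustive"` mode with `n_remove = 1` the
#' leave-one-out set (all m signatures of length m-1) is returned,
#' deterministically; `"random"` mode draws `n_perturbations` independent
#' uniform subsets to remove. `"auto"` picks exhaustive leave-one-out when
#' `n_remove = 1` and `m <= 200`, else random.
#'
#' @param signature A [query_signature] of length m.
#' @param n_remove Genes removed per perturbation (`1 <= n_remove < m`).
#' @param n_perturbations Number of perturbations in random mode.
#' @param seed Integer seed (random mode).
#' @param mode `"auto"`, `"exhaustive"` or `"random"`.
#' @return List of [query_signature] objects; attribute `mode` records the
#'   mode actually used.
#' @export
perturb_signature <- function(signature, n_remove = 1, n_perturbations = 100,
                              seed = NULL, mode = c("auto", "exhaustive",
                                                    "random")) {
  stopifnot(inherits(signature, "query_signature"))
  mode <- match.arg(mode)
  m <- nrow(signature)
  .assert_scalar_number(n_remove, "n_remove", lower = 1)
  if (n_remove >= m) {
    stop("'n_remove' must be smaller than the signature length", call. = FALSE)
  }
  if (mode == "auto") {
    mode <- if (n_remove == 1 && m <= 200) "exhaustive" else "random"
  }
  if (mode == "exhaustive") {
    if (choose(m, n_remove) > 1e4) {
      stop("exhaustive perturbation infeasible: choose(m, n_remove) = ",
           choose(m, n_remove), call. = FALSE)
    }
    drop_sets <- utils::combn(m, n_remove, simplify = FALSE)
  } else {
    .assert_scalar_number(n_perturbations, "n_perturbations", lower = 1)
    if (is.null(seed)) stop("'seed' is required in random mode", call. = FALSE)
    drop_sets <- withr::with_seed(as.integer(seed),
      lapply(seq_len(n_perturbations), function(i) sample.int(m, n_remove)))
  }
  out <- lapply(drop_sets, function(drop) {
    keep <- setdiff(seq_len(m), drop)
    query_signature(signature$gene_id[keep], signature$sign[keep])
  })
  attr(out, "mode") <- mode
  out
}

#' Perturbation-stability scores for significant drug hits
#'
#' For every compound in `hits`, recomputes its connection against each
#' perturbed signature and reports the fraction of perturbations under which
#' it remains significant (same one-sided threshold `Efp / Nc`, same
#' direction). Only the hit compounds' profiles are rescored, but the
#' significance threshold keeps the full database's compound count `Nc`.
#'
#' @param signature The unperturbed final [query_signature].
#' @param db The `reference_db` the hits were found in.
#' @param hits A significant `connection_results` (see
#'   [significant_connections()]).
#' @param n_remove,n_perturbations,mode Passed to [perturb_signature()].
#' @param Efp Expected false positives tolerated (threshold `Efp / Nc`).
#' @param n_null Monte-Carlo null size per perturbation.
#' @param seed Base integer seed; each perturbation uses a derived seed.
#' @param direction_filter `"negative"` (default) or `"positive"`.
#' @return Data frame with columns `compound`, `n_perturbations`,
#'   `n_retained`, `stability`, in the order of `hits`; attribute `mode`.
#' @export
stability_scores <- function(signature, db, hits, n_remove = 1,
                             n_perturbations = 100, mode = "auto",
                             Efp = 1, n_null = 1000, seed,
                             direction_filter = "negative") {
  stopifnot(inherits(signature, "query_signature"),
            inherits(db, "reference_db"))
  if (nrow(hits) == 0L) stop("'hits' is empty", call. = FALSE)
  Nc <- attr(hits, "Nc") %||% db$Nc
  perturbed <- perturb_signature(signature, n_remove = n_remove,
                                 n_perturbations = n_perturbations,
                                 seed = seed, mode = mode)
  sub <- subset_reference_db(db, hits$compound)
  retained <- stats::setNames(integer(nrow(hits)), hits$compound)
  for (k in seq_along(perturbed)) {
    res <- map_signature(perturbed[[k]], sub, n_null = n_null,
                         seed = derive_seed(seed, k))
    sig_k <- significant_connections(res, Efp = Efp,
                                     direction_filter = direction_filter,
                                     Nc = Nc)
    retained[sig_k$compound[sig_k$compound %in% names(retained)]] <-
      retained[sig_k$compound[sig_k$compound %in% names(retained)]] + 1L
  }
  n_pert <- length(perturbed)
  out <- data.frame(compound = hits$compound,
                    n_perturbations = n_pert,
                    n_retained = as.integer(retained[hits$compound]),
                    stability = as.numeric(retained[hits$compound]) / n_pert,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "mode") <- attr(perturbed, "mode")
  out
}

#' Attach stability scores to a hit table
#'
#' @param hits A `connection_results` data frame.
#' @param stability Output of [stability_scores()].
#' @return `hits` with an added `stability` column.
#' @export
add_stability <- function(hits, stability) {
  hits$stability <- stability$stability[match(hits$compound,
                                              stability$compound)]
  hits
}
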