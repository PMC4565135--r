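# Signed-rank connectivity mapping.
#
# A query signature (genes with +/- regulation signs) is matched against a
# reference profile by summing, over the signature genes, the product of the
# signature sign and the profile's signed rank. The sum is normalized by the
# largest value attainable by any signature of the same length (the m
# largest rank magnitudes, N + (N-1) + ... + (N-m+1)), giving a connection
# score in [-1, 1]: +1 = the profile mimics the signature perfectly,
# -1 = it reverses it perfectly.
#
# Statistical significance is assessed against the null of a random
# signature: a uniformly random gene subset of the same size with
# independent uniform +/- signs. The null is evaluated by Monte-Carlo
# sampling, or exactly by exhaustive enumeration when C(N, m) * 2^m is small.

.max_abs_raw <- function(N, m) sum(N - seq_len(m) + 1)

.sig_index <- function(signature, universe) {
  idx <- match(signature$gene_id, universe)
  if (anyNA(idx)) {
    stop("signature gene(s) absent from the reference universe: ",
         paste(utils::head(signature$gene_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  idx
}

# n_null random signatures of length m over a universe of size N:
# gene-index matrix and sign matrix, both m x n_null.
.random_signatures <- function(N, m, n_null) {
  idx <- vapply(seq_len(n_null), function(i) sample.int(N, m), integer(m))
  sgn <- matrix(sample(c(-1, 1), m * n_null, replace = TRUE), nrow = m)
  list(idx = matrix(idx, nrow = m), sign = sgn)
}

# Raw (unnormalized) null scores of the random signatures against one
# profile column of signed ranks.
.null_raw_one <- function(signed_ranks, sigs) {
  colSums(matrix(signed_ranks[sigs$idx], nrow = nrow(sigs$idx)) * sigs$sign)
}

#' Connection score between a signature and one reference profile
#'
#' @param signature A [query_signature].
#' @param profile Named numeric vector of signed ranks over the gene
#'   universe (magnitudes a permutation of `1..N`), e.g. one column of a
#'   `reference_db` via [get_profile()].
#' @return Connection score in `[-1, 1]`.
#' @export
connection_score <- function(signature, profile) {
  stopifnot(inherits(signature, "query_signature"))
  if (is.null(names(profile))) stop("'profile' must be named by gene id", call. = FALSE)
  N <- length(profile)
  m <- nrow(signature)
  if (m > N) stop("signature longer than the profile universe", call. = FALSE)
  idx <- .sig_index(signature, names(profile))
  raw <- sum(signature$sign * profile[idx])
  raw / .max_abs_raw(N, m)
}

#' Extract one profile from a reference database
#'
#' @param db A `reference_db`.
#' @param compound Compound name.
#' @param replicate_id Replicate identifier; defaults to the compound's first
#'   profile.
#' @return Named numeric vector of signed ranks.
#' @export
get_profile <- function(db, compound, replicate_id = NULL) {
  stopifnot(inherits(db, "reference_db"))
  sel <- db$profile_meta$compound == compound
  if (!is.null(replicate_id)) sel <- sel & db$profile_meta$replicate_id == replicate_id
  j <- which(sel)
  if (length(j) == 0L) stop("no such profile: ", compound, call. = FALSE)
  stats::setNames(as.numeric(db$ranks[, j[1]]), db$universe)
}

# All signed signatures of length m over N genes, as (idx, sign) matrices.
.enumerate_signatures <- function(N, m) {
  subsets <- utils::combn(N, m)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  idx <- subsets[, rep(seq_len(ncol(subsets)), each = nrow(signs)), drop = FALSE]
  sgn <- t(signs)[, rep(seq_len(nrow(signs)), times = ncol(subsets)), drop = FALSE]
  list(idx = matrix(idx, nrow = m), sign = matrix(sgn, nrow = m))
}

#' p-value of a connection score against one profile
#'
#' One-sided p-value for the observed connection score under the
#' random-signature null (uniform gene subsets of the observed length with
#' independent uniform signs). `tail = "auto"` takes the tail in the
#' direction of the observed score (upper for scores >= 0); fixed tails are
#' available for calibration studies. Monte-Carlo p-values use the
#' `(r + 1) / (n_null + 1)` estimator, so they are never exactly 0;
#' exhaustive mode enumerates every signed subset and is exact.
#'
#' @param signature A [query_signature].
#' @param profile Named signed-rank vector (see [connection_score()]).
#' @param n_null Number of Monte-Carlo null signatures (>= 1000 recommended).
#' @param seed Integer seed (required in Monte-Carlo mode).
#' @param mode `"montecarlo"`, `"exhaustive"`, or `"auto"` (exhaustive when
#'   `C(N, m) * 2^m <= 1e6`).
#' @param tail `"auto"`, `"upper"` or `"lower"`.
#' @return The p-value.
#' @export
profile_p_value <- function(signature, profile, n_null = 1000, seed = NULL,
                            mode = c("auto", "montecarlo", "exhaustive"),
                            tail = c("auto", "upper", "lower")) {
  mode <- match.arg(mode)
  tail <- match.arg(tail)
  obs <- connection_score(signature, profile)
  N <- length(profile)
  m <- nrow(signature)
  if (tail == "auto") tail <- if (obs >= 0) "upper" else "lower"
  n_total <- choose(N, m) * 2^m
  if (mode == "auto") mode <- if (n_total <= 1e6) "exhaustive" else "montecarlo"
  maxraw <- .max_abs_raw(N, m)
  if (mode == "exhaustive") {
    if (n_total > 1e6) {
      stop("exhaustive enumeration infeasible: C(N,m)*2^m = ", n_total,
           call. = FALSE)
    }
    sigs <- .enumerate_signatures(N, m)
    scores <- .null_raw_one(unname(profile), sigs) / maxraw
    hits <- if (tail == "upper") sum(scores >= obs - 1e-12) else
      sum(scores <= obs + 1e-12)
    return(hits / length(scores))
  }
  if (n_null < 1) stop("'n_null' must be >= 1", call. = FALSE)
  if (is.null(seed)) stop("'seed' is required in Monte-Carlo mode", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    sigs <- .random_signatures(N, m, n_null)
    scores <- .null_raw_one(unname(profile), sigs) / maxraw
    hits <- if (tail == "upper") sum(scores >= obs - 1e-12) else
      sum(scores <= obs + 1e-12)
    (hits + 1) / (n_null + 1)
  })
}

# Core engine: observed and null compound-level scores for every compound of
# a database. Null signatures are shared across compounds so that one call
# prices the whole database consistently; each compound's null statistic is
# the mean of its replicate profiles' scores for the same random signature.
.map_engine <- function(signature, db, n_null, seed) {
  idx <- .sig_index(signature, db$universe)
  m <- nrow(signature)
  maxraw <- .max_abs_raw(db$N, m)
  obs_prof <- as.numeric(crossprod(db$ranks[idx, , drop = FALSE],
                                   signature$sign)) / maxraw
  sigs <- withr::with_seed(as.integer(seed),
                           .random_signatures(db$N, m, n_null))
  P <- ncol(db$ranks)
  null_prof <- matrix(0, nrow = n_null, ncol = P)
  for (j in seq_len(P)) {
    null_prof[, j] <- .null_raw_one(db$ranks[, j], sigs) / maxraw
  }
  comp <- db$profile_meta$compound
  list(obs_prof = obs_prof, null_prof = null_prof, compound = comp)
}

.aggregate_compound <- function(engine, compounds) {
  vapply(compounds, function(cmp) {
    cols <- which(engine$compound == cmp)
    obs <- mean(engine$obs_prof[cols])
    nul <- rowMeans(engine$null_prof[, cols, drop = FALSE])
    n_null <- length(nul)
    hits <- if (obs >= 0) sum(nul >= obs - 1e-12) else sum(nul <= obs + 1e-12)
    p <- (hits + 1) / (n_null + 1)
    sdn <- stats::sd(nul)
    z <- if (sdn > 0) (obs - mean(nul)) / sdn else 0
    c(cscore = obs, p_value = p, z_score = z, replicate_count = length(cols))
  }, numeric(4))
}

#' Map a query signature against every compound of a reference database
#'
#' Computes, per compound, the connection score (mean over its replicate
#' profiles), a one-sided Monte-Carlo p-value in the direction of the
#' observed score, and a z-score (observed vs. null mean/SD). The same
#' random-signature null set is scored against every profile, and a
#' compound's null statistic is the replicate mean for each random
#' signature, so replicate-rich compounds have tighter nulls.
#'
#' @param signature A [query_signature].
#' @param db A `reference_db`.
#' @param n_null Number of Monte-Carlo null signatures.
#' @param seed Integer seed.
#' @return Object of class `connection_results`: data frame with columns
#'   `compound`, `replicate_count`, `cscore`, `p_value`, `z_score`,
#'   `direction`; attributes `Nc`, `m`, `n_null`, `seed`.
#' @export
map_signature <- function(signature, db, n_null = 1000, seed) {
  stopifnot(inherits(signature, "query_signature"), inherits(db, "reference_db"))
  if (n_null < 1) stop("'n_null' must be >= 1", call. = FALSE)
  engine <- .map_engine(signature, db, n_null, seed)
  agg <- .aggregate_compound(engine, db$compounds)
  out <- data.frame(
    compound = db$compounds,
    replicate_count = as.integer(agg["replicate_count", ]),
    cscore = agg["cscore", ],
    p_value = agg["p_value", ],
    z_score = agg["z_score", ],
    direction = ifelse(agg["cscore", ] < 0, "negative", "positive"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("connection_results", "data.frame"),
            Nc = db$Nc, m = nrow(signature), n_null = n_null,
            seed = as.integer(seed))
}

#' Connection result for a single compound
#'
#' Convenience wrapper around [map_signature()] restricted to one compound;
#' the p-value and z-score are computed against that compound's replicate
#' set with a fresh null of `n_null` random signatures.
#'
#' @inheritParams map_signature
#' @param compound Compound name present in `db`.
#' @return One-row `connection_results` data frame.
#' @export
compound_connection <- function(signature, db, compound, n_null = 1000, seed) {
  if (!compound %in% db$compounds) {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  sub <- subset_reference_db(db, compound)
  res <- map_signature(signature, sub, n_null = n_null, seed = seed)
  attr(res, "Nc") <- db$Nc
  res
}

#' Significance threshold for compound connections
#'
#' The per-compound p-value cut-off `Efp / Nc` that tolerates an expected
#' `Efp` false-positive compounds among the `Nc` compounds of the database.
#'
#' @param Efp Expected false positives tolerated (> 0).
#' @param Nc Number of compounds in the database.
#' @return The threshold `Efp / Nc`.
#' @export
connection_threshold <- function(Efp, Nc) {
  .assert_scalar_number(Efp, "Efp", lower = .Machine$double.eps)
  .assert_scalar_number(Nc, "Nc", lower = 1)
  Efp / Nc
}

#' Filter connection results to the significant ones
#'
#' Keeps compounds with `p_value <= Efp / Nc`, optionally restricted to one
#' direction of action (for inhibitor discovery: negative scores, i.e.
#' compounds that reverse the signature).
#'
#' @param results A `connection_results` from [map_signature()].
#' @param Efp Expected false positives tolerated (default 1).
#' @param direction_filter `"negative"`, `"positive"`, or `"both"`.
#' @param Nc Compound count defining the threshold; defaults to the `Nc` of
#'   the database the results were computed on.
#' @return The significant subset, ordered by z-score (most negative first
#'   for the negative direction), with attribute `Ns` (its row count).
#' @export
significant_connections <- function(results, Efp = 1,
                                    direction_filter = c("negative",
                                                         "positive", "both"),
                                    Nc = attr(results, "Nc")) {
  direction_filter <- match.arg(direction_filter)
  thr <- connection_threshold(Efp, Nc)
  keep <- results$p_value <= thr
  if (direction_filter == "negative") keep <- keep & results$cscore < 0
  if (direction_filter == "positive") keep <- keep & results$cscore > 0
  out <- results[keep, , drop = FALSE]
  ord <- if (direction_filter == "positive") order(-out$z_score) else
    order(out$z_score)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "Ns") <- nrow(out)
  attr(out, "Nc") <- Nc
  attr(out, "threshold") <- thr
  out
}

#' Write connection results to TSV
#'
#' Columns: `Compound`, `Replicate`, `cscore`, `pvalue`, `zscore`, plus
#' `PerturbStability` when present.
#'
#' @param results A `connection_results` data frame.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_connection_results <- function(results, path) {
  out <- data.frame(Compound = results$compound,
                    Replicate = results$replicate_count,
                    cscore = results$cscore,
                    pvalue = results$p_value,
                    zscore = results$z_score,
                    stringsAsFactors = FALSE)
  if (!is.null(results$stability)) out$PerturbStability <- results$stability
  .write_tsv(out, path)
}
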