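# Gene-signature progression: choose the signature length by growing the
# query from the top of the combined ranking until the empirical FDR of the
# drug hits reaches the target.
#
# With Efp tolerated false-positive compounds and Ns significant hits, the
# empirical FDR is Efp / Ns; with the defaults Efp = 1 and target 0.10, the
# procedure stops at the smallest signature length yielding at least 10
# significant compounds in the desired (negative) direction.

#' Empirical FDR of a drug-hit list
#'
#' @param Ns Number of significant drug hits (>= 0).
#' @param Efp Expected false positives tolerated (> 0).
#' @return `Efp / Ns`, or `Inf` when `Ns = 0` (no hit list can pass).
#' @export
fdr_of <- function(Ns, Efp = 1) {
  .assert_scalar_number(Ns, "Ns", lower = 0)
  .assert_scalar_number(Efp, "Efp", lower = .Machine$double.eps)
  if (Ns == 0) Inf else Efp / Ns
}

#' Progression configuration
#'
#' @param Efp Expected false positives tolerated among drug hits (default 1).
#' @param fdr_target Target empirical FDR (default 0.10).
#' @param m_start,m_step Starting signature length and increment (default 1).
#' @param m_max Optional cap on the signature length; defaults to the number
#'   of nonzero-total genes in the combined ranking (exhaustion).
#' @return A list of class `progression_config`.
#' @export
progression_config <- function(Efp = 1, fdr_target = 0.10, m_start = 1,
                               m_step = 1, m_max = NULL) {
  .assert_scalar_number(Efp, "Efp", lower = .Machine$double.eps)
  .assert_scalar_number(fdr_target, "fdr_target",
                        lower = .Machine$double.eps, upper = 1 - 1e-12)
  .assert_scalar_number(m_start, "m_start", lower = 1)
  .assert_scalar_number(m_step, "m_step", lower = 1)
  if (!is.null(m_max)) .assert_scalar_number(m_max, "m_max", lower = m_start)
  structure(list(Efp = Efp, fdr_target = fdr_target,
                 m_start = as.integer(m_start), m_step = as.integer(m_step),
                 m_max = if (is.null(m_max)) NULL else as.integer(m_max)),
            class = "progression_config")
}

#' Run the gene-signature progression procedure
#'
#' Starting at `m = m_start`, queries the reference database with the top-m
#' signature, counts the compounds with significant negative connections
#' (`p <= Efp / Nc`, cscore < 0), and grows m until `Efp / Ns <= fdr_target`
#' or the ranked genes with nonzero total score are exhausted. The
#' Monte-Carlo seed for each length m is derived deterministically from the
#' base seed (XOR with m), so every iteration is independent yet the whole
#' trace is reproducible.
#'
#' @param combined A `combined_signature` from [combine_scores()].
#' @param db A `reference_db`.
#' @param config A [progression_config()].
#' @param n_null Monte-Carlo null size per signature length.
#' @param seed Base integer seed.
#' @param direction_filter Direction of desired drug action
#'   (default `"negative"`: compounds reversing the disease signature).
#' @param verbose Print one line per iteration.
#' @return Object of class `progression_state`: `trace` (data frame of
#'   m, Ns, FDR), `final_m`, `converged` (FALSE = exhausted), `final_hits`
#'   (the significant `connection_results` at `final_m`), `signature`
#'   (the final [query_signature]), `config`.
#' @export
run_progression <- function(combined, db, config = progression_config(),
                            n_null = 1000, seed,
                            direction_filter = "negative", verbose = FALSE) {
  stopifnot(inherits(combined, "combined_signature"),
            inherits(db, "reference_db"),
            inherits(config, "progression_config"))
  if (combined$nonzero_total == 0L) {
    stop("combined signature has no genes with nonzero total score", call. = FALSE)
  }
  if (db$Nc == 0L) stop("reference database is empty", call. = FALSE)
  m_max <- min(config$m_max %||% combined$nonzero_total,
               combined$nonzero_total)
  trace <- data.frame(m = integer(), Ns = integer(), FDR = numeric())
  best <- NULL
  m <- config$m_start
  while (m <= m_max) {
    sig <- take_top(combined, m)
    res <- map_signature(sig, db, n_null = n_null, seed = derive_seed(seed, m))
    hits <- significant_connections(res, Efp = config$Efp,
                                    direction_filter = direction_filter)
    Ns <- attr(hits, "Ns")
    fdr <- fdr_of(Ns, config$Efp)
    trace <- rbind(trace, data.frame(m = m, Ns = Ns, FDR = fdr))
    if (verbose) {
      message(sprintf("m = %d: Ns = %d, FDR = %s", m, Ns, format(fdr)))
    }
    if (is.null(best) || Ns > best$Ns) {
      best <- list(m = m, Ns = Ns, hits = hits, signature = sig)
    }
    if (fdr <= config$fdr_target) {
      return(structure(list(trace = trace, final_m = m, converged = TRUE,
                            final_hits = hits, signature = sig,
                            config = config),
                       class = "progression_state"))
    }
    m <- m + config$m_step
  }
  structure(list(trace = trace, final_m = best$m, converged = FALSE,
                 final_hits = best$hits, signature = best$signature,
                 config = config),
            class = "progression_state")
}

#' @export
print.progression_state <- function(x, ...) {
  status <- if (x$converged) "converged" else "exhausted"
  last <- x$trace[x$trace$m == x$final_m, ]
  cat(sprintf("progression_state: %s at m = %d (Ns = %d, FDR = %s) after %d iteration(s)\n",
              status, x$final_m, last$Ns, format(last$FDR), nrow(x$trace)))
  invisible(x)
}

#' Write a progression trace to TSV (columns m, Ns, FDR)
#'
#' @param state A `progression_state`.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_progression_trace <- function(state, path) {
  stopifnot(inherits(state, "progression_state"))
  .write_tsv(state$trace, path)
}
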