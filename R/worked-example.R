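# Worked example: published per-dataset scores of the top colorectal-cancer
# signature genes across five study sub-datasets (two stage-II/III groups,
# three stage-IV groups). The fixture carries each gene's signed normalized
# rank score per dataset together with the published total and overall rank,
# and a flag marking rows whose published total matches the column sum
# exactly (the remaining rows differ by 1-2e-4 from rounding of the
# published per-dataset scores).

#' Published worked-example score table
#'
#' Loads the packaged table of 15 signature genes (the top gene of each of
#' five colorectal-cancer sub-datasets plus the overall top 10) with their
#' per-dataset signed normalized rank scores, published total scores and
#' overall ranks.
#'
#' @return List with `table` (the raw data frame), `score_vectors` (one
#'   [score_vector] per dataset column, over the 15-gene universe, with the
#'   study-reported significant-gene counts M), and `dataset_names`.
#' @export
worked_example <- function() {
  path <- system.file("extdata", "worked_example_scores.tsv",
                      package = "mdcmap", mustWork = TRUE)
  tab <- .read_tsv(path)
  dataset_names <- c("GSE21510S2-3", "GSE41258S2-3", "GSE21510S4",
                     "GSE41258S4", "GSE49355S4")
  M <- c("GSE21510S2-3" = 4025, "GSE41258S2-3" = 929, "GSE21510S4" = 7,
         "GSE41258S4" = 663, "GSE49355S4" = 1323)
  svs <- lapply(dataset_names, function(d) {
    score_vector(d, stats::setNames(tab[[d]], tab$probe_id), M[[d]])
  })
  list(table = tab, score_vectors = svs, dataset_names = dataset_names)
}
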