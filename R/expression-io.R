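# Paired expression datasets: construction, TSV I/O, gene-universe handling
# and stage filtering.
#
# A paired dataset holds a genes x samples matrix of log2 intensities plus a
# pairing table that matches each tumour sample to the normal sample from the
# same subject. All downstream statistics (paired t-tests, fold changes) are
# computed on the per-pair tumour - normal differences.

.STAGE_LEVELS <- c("I", "II", "III", "IV")

# Accepts Roman (I..IV) or Arabic (1..4) stage labels; returns Roman.
.normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  arabic <- c("1" = "I", "2" = "II", "3" = "III", "4" = "IV")
  s <- ifelse(s %in% names(arabic), arabic[s], s)
  bad <- !(s %in% .STAGE_LEVELS)
  if (any(bad)) {
    stop("unrecognised stage label(s): ", paste(unique(s[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(s)
}

.normalize_phenotype <- function(x) {
  p <- tolower(trimws(as.character(x)))
  p[p %in% c("tumor", "tumour", "cancer", "case")] <- "tumour"
  p[p %in% c("normal", "control")] <- "normal"
  bad <- !(p %in% c("tumour", "normal"))
  if (any(bad)) {
    stop("phenotype must be 'tumour' or 'normal'; got: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  p
}

#' Construct a paired tumour/normal expression dataset
#'
#' @param name Dataset name (e.g. a study accession plus stage group).
#' @param values Numeric matrix of log2 expression, genes in rows (rownames =
#'   gene identifiers), samples in columns (colnames = sample identifiers).
#' @param pairs Data frame with columns `tumour`, `normal`, `subject`, `stage`:
#'   one row per subject, naming the tumour and normal sample columns of
#'   `values` and the tumour stage (Roman I--IV or Arabic 1--4).
#' @return An object of class `paired_dataset` with fields `name`, `values`,
#'   `pairs` and `n_pairs`.
#' @export
paired_dataset <- function(name, values, pairs) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  req <- c("tumour", "normal", "subject", "stage")
  if (!all(req %in% names(pairs))) {
    stop("'pairs' needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(pairs) == 0L) stop("dataset has zero tumour/normal pairs", call. = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  pairs$stage <- .normalize_stage(pairs$stage)
  used <- c(pairs$tumour, pairs$normal)
  if (anyDuplicated(used)) {
    stop("a sample appears in more than one pair", call. = FALSE)
  }
  missing <- setdiff(used, colnames(values))
  if (length(missing)) {
    stop("paired samples absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) stop("expression matrix contains missing values", call. = FALSE)
  structure(
    list(name = name, values = values, pairs = pairs, n_pairs = nrow(pairs)),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("paired_dataset '%s': %d genes, %d pairs (stages: %s)\n",
              x$name, nrow(x$values), x$n_pairs,
              paste(sort(unique(x$pairs$stage)), collapse = ",")))
  invisible(x)
}

#' Gene universe of an object
#'
#' @param x A `paired_dataset`, `reference_db`, or character vector of ids.
#' @return Character vector of gene identifiers.
#' @export
gene_universe <- function(x) {
  if (inherits(x, "paired_dataset")) return(rownames(x$values))
  if (inherits(x, "reference_db")) return(x$universe)
  if (is.character(x)) return(x)
  stop("no gene universe defined for class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' Read a paired expression dataset from TSV files
#'
#' The expression matrix is a TSV whose first column (`gene_id`) holds gene
#' identifiers and whose remaining columns are samples. The metadata TSV has
#' columns `sample_id`, `subject_id`, `phenotype` (tumour/normal) and `stage`.
#' Pairs are formed by matching subjects that have both a tumour and a normal
#' sample; unpartnered samples are dropped with a warning.
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param name Dataset name; defaults to the matrix file name.
#' @param log2_input If `FALSE`, values are assumed linear-scale intensities
#'   and are log2-transformed (with a +1 offset) on read. Default `TRUE`:
#'   values are already log2.
#' @return A [paired_dataset].
#' @export
read_expression <- function(matrix_path, metadata_path, name = NULL,
                            log2_input = TRUE) {
  name <- name %||% sub("\\.[^.]*$", "", basename(matrix_path))
  raw <- tryCatch(
    .read_tsv(matrix_path),
    error = function(e) stop("failed to parse expression TSV '", matrix_path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (ncol(raw) < 2L || names(raw)[1] != "gene_id") {
    stop("expression TSV must have a 'gene_id' first column and >=1 sample column",
         call. = FALSE)
  }
  if (anyDuplicated(raw$gene_id)) {
    dup <- raw$gene_id[duplicated(raw$gene_id)][1]
    stop("duplicate gene id in '", matrix_path, "': ", dup, call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    # locate the first non-numeric cell for the error message
    for (j in seq_len(ncol(vals))) {
      suppressWarnings(num <- as.numeric(raw[[j + 1]]))
      bad <- which(is.na(num) & !is.na(raw[[j + 1]]))
      if (length(bad)) {
        stop(sprintf("non-numeric value in '%s' at data line %d, column '%s'",
                     matrix_path, bad[1], names(raw)[j + 1]), call. = FALSE)
      }
    }
    stop("expression matrix contains non-numeric values", call. = FALSE)
  }
  rownames(vals) <- raw$gene_id
  if (!log2_input) vals <- log2(vals + 1)

  meta <- .read_tsv(metadata_path)
  req <- c("sample_id", "subject_id", "phenotype", "stage")
  if (!all(req %in% names(meta))) {
    stop("metadata TSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  meta$phenotype <- .normalize_phenotype(meta$phenotype)
  meta$stage <- .normalize_stage(meta$stage)
  meta <- meta[meta$sample_id %in% colnames(vals), , drop = FALSE]

  tum <- meta[meta$phenotype == "tumour", , drop = FALSE]
  nrm <- meta[meta$phenotype == "normal", , drop = FALSE]
  if (anyDuplicated(tum$subject_id) || anyDuplicated(nrm$subject_id)) {
    stop("a subject has more than one sample of the same phenotype", call. = FALSE)
  }
  shared <- intersect(tum$subject_id, nrm$subject_id)
  unpaired <- setdiff(meta$sample_id,
                      c(tum$sample_id[tum$subject_id %in% shared],
                        nrm$sample_id[nrm$subject_id %in% shared]))
  if (length(unpaired)) {
    warning(sprintf("dropping %d unpartnered sample(s): %s", length(unpaired),
                    paste(unpaired, collapse = ", ")), call. = FALSE)
  }
  if (length(shared) == 0L) stop("zero tumour/normal pairs in metadata", call. = FALSE)
  tum <- tum[match(shared, tum$subject_id), ]
  nrm <- nrm[match(shared, nrm$subject_id), ]
  pairs <- data.frame(tumour = tum$sample_id, normal = nrm$sample_id,
                      subject = shared, stage = tum$stage,
                      stringsAsFactors = FALSE)
  keep <- c(pairs$tumour, pairs$normal)
  paired_dataset(name, vals[, keep, drop = FALSE], pairs)
}

#' Write a paired dataset to expression + metadata TSVs
#'
#' Inverse of [read_expression()]: values are written at full precision so
#' that a read/write round trip reproduces the dataset.
#'
#' @param dataset A [paired_dataset].
#' @param matrix_path,metadata_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  stopifnot(inherits(dataset, "paired_dataset"))
  df <- data.frame(gene_id = rownames(dataset$values), dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, matrix_path)
  p <- dataset$pairs
  meta <- data.frame(
    sample_id = c(p$tumour, p$normal),
    subject_id = c(p$subject, p$subject),
    phenotype = rep(c("tumour", "normal"), each = nrow(p)),
    stage = c(p$stage, p$stage),
    stringsAsFactors = FALSE
  )
  .write_tsv(meta, metadata_path)
  invisible(c(matrix_path, metadata_path))
}

#' Intersect the gene universes of several datasets
#'
#' Returns the sorted intersection of the gene identifier sets, i.e. the
#' probes shared by all platforms, which become the genes analysed jointly.
#'
#' @param datasets List of [paired_dataset] objects (or character vectors).
#' @return Character vector of shared gene identifiers (sorted).
#' @export
intersect_universes <- function(datasets) {
  if (inherits(datasets, "paired_dataset") || is.character(datasets)) {
    datasets <- list(datasets)
  }
  if (length(datasets) == 0L) stop("need at least one dataset", call. = FALSE)
  ids <- lapply(datasets, gene_universe)
  out <- Reduce(intersect, ids)
  if (length(out) == 0L) stop("gene universes have empty intersection", call. = FALSE)
  sort(out)
}

#' Restrict a dataset to a gene universe
#'
#' @param dataset A [paired_dataset].
#' @param universe Character vector of gene ids (all must be present).
#' @return The dataset restricted to `universe`, in `universe` order.
#' @export
restrict_universe <- function(dataset, universe) {
  stopifnot(inherits(dataset, "paired_dataset"))
  missing <- setdiff(universe, rownames(dataset$values))
  if (length(missing)) {
    stop("universe genes absent from dataset '", dataset$name, "': ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  paired_dataset(dataset$name, dataset$values[universe, , drop = FALSE],
                 dataset$pairs)
}

#' Keep only pairs whose tumour sample is at given stages
#'
#' Subsets a dataset to the pairs whose tumour stage falls in `stages`, the
#' way studies group e.g. stage II--III pairs separately from stage IV. The
#' dataset name gains a stage-group suffix (e.g. `"S2-3"`).
#'
#' @param dataset A [paired_dataset].
#' @param stages Character vector, subset of `I`,`II`,`III`,`IV` (Arabic also
#'   accepted).
#' @return A [paired_dataset] with the retained pairs.
#' @export
filter_by_stage <- function(dataset, stages) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (length(stages) == 0L) stop("'stages' must be nonempty", call. = FALSE)
  stages <- .normalize_stage(stages)
  keep <- dataset$pairs$stage %in% stages
  if (!any(keep)) {
    stop("no pairs remain after stage filter {",
         paste(stages, collapse = ","), "}", call. = FALSE)
  }
  pairs <- dataset$pairs[keep, , drop = FALSE]
  samples <- c(pairs$tumour, pairs$normal)
  suffix <- paste0("S", paste(match(stages, .STAGE_LEVELS), collapse = "-"))
  paired_dataset(paste0(dataset$name, suffix),
                 dataset$values[, samples, drop = FALSE], pairs)
}

# Per-pair tumour - normal difference matrix (genes x pairs).
.pair_differences <- function(dataset) {
  d <- dataset$values[, dataset$pairs$tumour, drop = FALSE] -
    dataset$values[, dataset$pairs$normal, drop = FALSE]
  colnames(d) <- dataset$pairs$subject
  d
}
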