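#' Read a gene-expression matrix from tab-separated text
#'
#' Expression matrices are plain numeric matrices (features x samples) with
#' feature identifiers as row names and sample identifiers as column names.
#' The on-disk format is tab-separated text: a header row of sample ids and a
#' first column of feature ids.  Values are expected on the log2 scale after
#' preprocessing (see [log2_transform()]).
#'
#' Duplicate sample ids are an error.  Duplicate feature ids are allowed at
#' load time (multi-probe platforms) and are resolved by
#' [collapse_by_iqr()].
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix with feature row names and sample column names.
#' @seealso [write_expression()], [load_clinical()]
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("expression file is empty: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) stop("expression file has no sample columns: ", path)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- lines[-1L]
  if (length(body) < 1L) stop("expression file has no feature rows: ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield != length(header))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d: expected %d fields, found %d",
                 bad[1L] + 1L, length(header), nfield[bad[1L]]))
  }
  feature_ids <- vapply(fields, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, nrow = length(sample_ids))  # guard length-1 collapse
  if (anyNA(vals)) {
    bad_row <- which(apply(is.na(vals), 2L, any))[1L]
    stop(sprintf("non-numeric expression value at line %d (feature '%s')",
                 bad_row + 1L, feature_ids[bad_row]))
  }
  m <- t(vals)
  dimnames(m) <- list(feature_ids, sample_ids)
  m
}

#' Write an expression matrix as tab-separated text
#'
#' @param m Numeric matrix, features x samples, with dimnames.
#' @param path Output path.
#' @param id_column Name for the feature-id column in the header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_column = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c(id_column, colnames(m)), collapse = "\t")
  rows <- paste(rownames(m),
                apply(m, 1L, function(v) paste(format(v, digits = 17, trim = TRUE,
                                                      scientific = FALSE),
                                               collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

# Required clinical columns and their checkers.
.clinical_columns <- c("sample_id", "tp53_mutant", "bcr", "rfs_time", "rfs_event",
                       "gleason_primary", "gleason_secondary", "t_stage", "age")

#' Validate a clinical table
#'
#' A clinical table is a data frame with one row per sample and columns
#' `sample_id`, `tp53_mutant` (logical), `bcr` (-1/+1 integer, the binary
#' biochemical-recurrence endpoint), `rfs_time` (non-negative relapse-free
#' survival time), `rfs_event` (logical), `gleason_primary` /
#' `gleason_secondary` (3, 4 or 5), `t_stage` ("T1", "T2", "T3" or `NA`)
#' and `age` (years).  Under the binary-endpoint convention used throughout,
#' `bcr == +1` if and only if `rfs_event` is `TRUE`.
#'
#' @param clinical A data frame.
#' @return The validated data frame, invisibly.
#' @export
validate_clinical <- function(clinical) {
  missing_cols <- setdiff(.clinical_columns, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(clinical$sample_id)) stop("duplicate sample_id in clinical table")
  if (!all(clinical$bcr %in% c(-1, 1))) stop("bcr must be -1 or +1")
  if (any(clinical$rfs_time < 0)) stop("rfs_time must be non-negative")
  if (!all((clinical$bcr == 1) == as.logical(clinical$rfs_event))) {
    stop("bcr = +1 must coincide with rfs_event = TRUE (binary-endpoint convention)")
  }
  gp <- clinical$gleason_primary; gs <- clinical$gleason_secondary
  if (!all(gp %in% 3:5) || !all(gs %in% 3:5)) {
    stop("gleason_primary/gleason_secondary must be 3, 4 or 5")
  }
  ts <- clinical$t_stage
  if (!all(is.na(ts) | ts %in% c("T1", "T2", "T3"))) {
    stop("t_stage must be T1, T2, T3 or NA")
  }
  invisible(clinical)
}

#' Read / write a clinical table
#'
#' Tab-separated text with the exact column names of the clinical schema
#' (see [validate_clinical()]).
#'
#' @param path File path.
#' @return `load_clinical()` returns a validated data frame.
#' @export
load_clinical <- function(path) {
  clinical <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                na.strings = "NA", check.names = FALSE)
  clinical$tp53_mutant <- as.logical(clinical$tp53_mutant)
  clinical$rfs_event <- as.logical(clinical$rfs_event)
  clinical$t_stage <- as.character(clinical$t_stage)
  validate_clinical(clinical)
  clinical
}

#' @rdname load_clinical
#' @param clinical A validated clinical table.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align a clinical table with the sample columns of an expression matrix.
# Errors if the sample sets differ; reorders clinical rows to column order.
align_cohort <- function(m, clinical) {
  validate_clinical(clinical)
  if (!setequal(colnames(m), clinical$sample_id)) {
    stop("expression matrix and clinical table cover different samples")
  }
  clinical[match(colnames(m), clinical$sample_id), , drop = FALSE]
}
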