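#' Construct a QDExperiment
#'
#' @param pre,post numeric matrices (indicators x patients) of positive
#'   laboratory values; `NA` marks a missing measurement. Row names must
#'   match the registry.
#' @param registry indicator registry ([indicatorRegistry()]); becomes
#'   rowData.
#' @param colData patient annotations (`arm`, optionally `outcome` and
#'   the clinical-status flag columns).
#'
#' @return a validated [QDExperiment-class].
#' @export
QDExperiment <- function(pre, post, registry = defaultRegistry(),
                         colData = NULL) {
  if (!identical(dim(pre), dim(post)))
    stop("'pre' and 'post' must have identical dimensions")
  if (is.null(rownames(pre))) rownames(pre) <- rownames(registry)
  if (is.null(rownames(post))) rownames(post) <- rownames(pre)
  if (!setequal(rownames(pre), rownames(registry)))
    stop("matrix rows and registry cover different indicator sets")
  ord <- rownames(registry)
  pre <- pre[ord, , drop = FALSE]
  post <- post[ord, , drop = FALSE]
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(
      patient_id = colnames(pre),
      arm = rep("unknown", ncol(pre)),
      row.names = colnames(pre))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(pre = pre, post = post),
    rowData = registry, colData = colData)
  new("QDExperiment", se)
}

#' Combine cohorts column-wise
#'
#' Binds the patients of several cohorts sharing one registry, e.g. the
#' two treatment arms of a study, into one [QDExperiment-class].
#'
#' @param ... [QDExperiment-class] objects with identical rowData.
#' @param deparse.level ignored, for generic compatibility.
#' @return a [QDExperiment-class].
#' @export
setMethod("cbind", "QDExperiment", function(..., deparse.level = 1) {
  args <- lapply(list(...), function(x) as(x, "SummarizedExperiment"))
  new("QDExperiment", do.call(cbind, args))
})

.COHORT_COLUMNS <- c("patient_id", "arm", "outcome", .CLINICAL_FLAGS,
                     "indicator", "pre", "post")

#' Read a cohort from a delimited long-format file
#'
#' One row per (patient, indicator) pair; required header
#' `patient_id, arm, outcome, fatigue, abdominal_distension, anorexia,
#' jaundice, lower_limb_oedema, indicator, pre, post`. Comma-separated
#' UTF-8 with decimal points. Missing pre/post cells are allowed and are
#' flagged at scoring time; rows with non-positive or non-numeric
#' laboratory values are rejected individually, reported by line number in
#' a warning, and attached as the `"row_errors"` attribute. A header
#' missing required columns is a hard error.
#'
#' @param path file path.
#' @param registry indicator registry the panel is validated against.
#'
#' @return a [QDExperiment-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(path, registry = defaultRegistry()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(.COHORT_COLUMNS, names(df))
  if (length(miss))
    stop("cohort file lacks required columns: ",
         paste(miss, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  num <- function(x) suppressWarnings(as.numeric(x))
  df$pre <- num(df$pre)
  df$post <- num(df$post)
  bad_ind <- !df$indicator %in% rownames(registry)
  bad_val <- (!is.na(df$pre) & df$pre <= 0) | (!is.na(df$post) & df$post <= 0)
  bad <- bad_ind | bad_val
  if (any(bad)) {
    report <- sprintf("line %d: %s (%s)", line[bad], df$indicator[bad],
                      ifelse(bad_ind[bad], "unknown indicator",
                             "non-positive value"))
    warning(sprintf("%d malformed row(s) rejected:\n  %s", sum(bad),
                    paste(report, collapse = "\n  ")), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  } else {
    report <- character()
  }
  if (!nrow(df)) stop("no valid rows in cohort file")
  if (anyDuplicated(df[, c("patient_id", "indicator")]))
    stop("duplicated (patient_id, indicator) pairs in cohort file")
  ids <- unique(df$patient_id)
  ind <- rownames(registry)
  pre <- post <- matrix(NA_real_, length(ind), length(ids),
                        dimnames = list(ind, ids))
  ii <- cbind(match(df$indicator, ind), match(df$patient_id, ids))
  pre[ii] <- df$pre
  post[ii] <- df$post
  first <- df[!duplicated(df$patient_id),
              c("patient_id", "arm", "outcome", .CLINICAL_FLAGS)]
  cd <- S4Vectors::DataFrame(first, row.names = first$patient_id)[ids, ]
  out <- QDExperiment(pre, post, registry, colData = cd)
  attr(out, "row_errors") <- report
  out
}

#' Long-format table view of a cohort
#'
#' @param x a [QDExperiment-class].
#' @return data.frame in the documented long schema, one row per
#'   (patient, indicator) pair, patients in column order and indicators in
#'   registry order.
#' @export
asLongTable <- function(x) {
  stopifnot(is(x, "QDExperiment"))
  pre <- SummarizedExperiment::assay(x, "pre")
  post <- SummarizedExperiment::assay(x, "post")
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  for (col in c("outcome", .CLINICAL_FLAGS))
    if (!col %in% names(cd)) cd[[col]] <- NA_character_
  ids <- colnames(x)
  ind <- rownames(x)
  df <- data.frame(
    patient_id = rep(ids, each = length(ind)),
    indicator = rep(ind, times = length(ids)),
    pre = as.vector(pre), post = as.vector(post),
    stringsAsFactors = FALSE)
  meta <- cd[df$patient_id, c("arm", "outcome", .CLINICAL_FLAGS),
             drop = FALSE]
  out <- cbind(df["patient_id"], meta, df[c("indicator", "pre", "post")])
  rownames(out) <- NULL
  out
}

#' Write a cohort to the delimited long format
#'
#' Inverse of [readCohort()]: the written file round-trips losslessly up
#' to floating-point formatting (15 significant digits are kept).
#'
#' @param x a [QDExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(x, path) {
  df <- asLongTable(x)
  for (col in c("pre", "post"))
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        formatC(df[[col]], digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
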