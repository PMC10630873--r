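#' Load an indicator registry
#'
#' The registry defines each laboratory indicator: name, units, reference
#' interval, and liver-panel membership. It is shipped as an editable CSV
#' (`inst/extdata/indicator_registry.csv`) holding standard adult reference
#' intervals for the 21 indicators of the study panel; intervals are data,
#' not code. Every indicator must carry at least one usable reference
#' bound — an indicator with neither is a configuration error caught here,
#' at load time, not during scoring.
#'
#' @param path CSV with columns `name`, `units`, `ref_low`, `ref_high`,
#'   `is_liver_panel`. Empty cells in the bound columns mean "no bound".
#'
#' @return a [S4Vectors::DataFrame] with the registry, rownames = indicator
#'   names.
#' @examples
#' reg <- defaultRegistry()
#' reg[reg$is_liver_panel, ]
#' @export
indicatorRegistry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "units", "ref_low", "ref_high", "is_liver_panel")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("registry is missing columns: ", paste(miss, collapse = ", "))
  df$ref_low <- as.numeric(df$ref_low)
  df$ref_high <- as.numeric(df$ref_high)
  df$is_liver_panel <- as.logical(df$is_liver_panel)
  nobound <- is.na(df$ref_low) & is.na(df$ref_high)
  if (any(nobound))
    stop("registry entries without any reference bound: ",
         paste(df$name[nobound], collapse = ", "))
  both <- !is.na(df$ref_low) & !is.na(df$ref_high)
  if (any(both & df$ref_low >= df$ref_high))
    stop("registry entries with ref_low >= ref_high: ",
         paste(df$name[both & df$ref_low >= df$ref_high], collapse = ", "))
  if (any(df$ref_low <= 0, na.rm = TRUE) || any(df$ref_high <= 0, na.rm = TRUE))
    stop("reference bounds must be positive")
  if (anyDuplicated(df$name))
    stop("duplicated indicator names in registry")
  out <- S4Vectors::DataFrame(df[, need])
  rownames(out) <- df$name
  out
}

#' @describeIn indicatorRegistry the registry shipped with the package.
#' @export
defaultRegistry <- function() {
  indicatorRegistry(system.file("extdata", "indicator_registry.csv",
                                package = "qdscore", mustWork = TRUE))
}

# relative distance of a value to its reference interval: 0 inside,
# |distance to nearer bound| / bound outside. Absent bounds act as -Inf/+Inf.
.ref_distance <- function(v, lo, hi) {
  d <- numeric(length(v))
  below <- !is.na(lo) & v < lo
  above <- !is.na(hi) & v > hi
  d[below] <- (lo - v[below]) / lo
  d[above] <- (v[above] - hi) / hi
  d
}
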