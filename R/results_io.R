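# Flat serialization of result objects. JSON (default) round-trips the
# object field-for-field; CSV writes the scalar fields as one row.

result_classes <- c("join_count_result", "cluster_size_result",
                    "abnormal_grouping_result", "bmrf_fit",
                    "group_comparison", "section_summary")

#' Write a result object to JSON or CSV
#'
#' Serializes any test result or model fit produced by the package
#' (statistic names, values, envelopes, p-values, permutation counts and
#' seeds), together with the package version. JSON output round-trips
#' losslessly through [read_results()]; CSV output keeps the scalar fields
#' only.
#'
#' @param result a result object (one of: `join_count_result`,
#'   `cluster_size_result`, `abnormal_grouping_result`, `bmrf_fit`,
#'   `group_comparison`, or a `section_summary` bundle).
#' @param path output path; format chosen by extension (`.json` default,
#'   `.csv` for the flat table).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  cls <- intersect(class(result), result_classes)
  if (!length(cls))
    stop("not a serializable result object: ",
         paste(class(result), collapse = "/"), call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    flat <- Filter(function(v) is.atomic(v) && length(v) <= 2 && !is.null(v),
                   unclass(result))
    row <- unlist(flat)
    utils::write.csv(as.data.frame(t(row)), path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- list(class = cls[1],
                  package = "myofibspat",
                  version = as.character(utils::packageVersion("myofibspat")),
                  fields = strip_heavy(unclass(result)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# drop unserializable / heavy components (function closures, bases)
strip_heavy <- function(x) {
  x <- x[!vapply(x, is.function, logical(1))]
  if (!is.null(x$basis)) x$basis <- NULL
  if (!is.null(x$network)) x$network <- NULL
  lapply(x, function(v) {
    if (inherits(v, result_classes)) return(strip_heavy(unclass(v)))
    # other classed list components (e.g. encoded labels) flatten to lists
    if (is.object(v) && is.list(v)) return(strip_heavy(unclass(v)))
    # named atomic vectors (e.g. envelopes) keep their names as JSON keys
    if (is.atomic(v) && !is.null(names(v))) return(as.list(v))
    v
  })
}

#' Read back a result written by [write_results()]
#'
#' @param path a JSON file produced by [write_results()].
#' @return The reconstructed result object (same class and fields).
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$class) || !payload$class %in% result_classes)
    stop("not a myofibspat result file: ", path, call. = FALSE)
  fields <- payload$fields
  # JSON objects come back as named lists; restore named numeric vectors
  fields <- lapply(fields, function(v) {
    if (is.list(v) && length(v) && !is.null(names(v)) &&
        all(vapply(v, function(e) is.numeric(e) && length(e) == 1, TRUE)))
      unlist(v)
    else v
  })
  # restore integer-vector fields stored as arrays
  for (nm in c("flagged_fibers", "marked_fibers"))
    if (!is.null(fields[[nm]])) fields[[nm]] <- as.integer(fields[[nm]])
  if (!is.null(fields$clusters))
    fields$clusters <- lapply(fields$clusters, as.integer)
  structure(fields, class = payload$class)
}
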