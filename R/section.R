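#' Construct a fiber section object
#'
#' A fiber section holds one muscle cross-section: per-fiber centroid
#' coordinates `(x, y)` (unitless; all methods are invariant to translation
#' and uniform scaling) and a categorical fiber-type label. Row order is
#' preserved and defines `fiber_id` (1-based).
#'
#' @param x,y numeric vectors of centroid coordinates.
#' @param type character vector of fiber-type labels (trimmed on input).
#' @param validate logical; run invariant checks (n >= 3, finite coordinates,
#'   no duplicate points).
#' @return An object of class `fiber_section`: a data frame with columns
#'   `fiber_id`, `x`, `y`, `type`.
#' @export
fiber_section <- function(x, y, type, validate = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  type <- trimws(as.character(type))
  n <- length(x)
  if (length(y) != n || length(type) != n)
    stop("x, y and type must have equal length", call. = FALSE)
  sec <- data.frame(fiber_id = seq_len(n), x = x, y = y, type = type,
                    stringsAsFactors = FALSE)
  class(sec) <- c("fiber_section", "data.frame")
  if (validate) validate_section(sec)
  sec
}

validate_section <- function(sec, require_two_types = FALSE) {
  n <- nrow(sec)
  if (n < 3L) stop("a section needs at least 3 fibers, got ", n, call. = FALSE)
  if (!all(is.finite(sec$x)) || !all(is.finite(sec$y))) {
    bad <- which(!is.finite(sec$x) | !is.finite(sec$y))
    stop("non-finite coordinates at rows ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(sec$x, sec$y, sep = "\r")
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    rows <- which(key %in% dup_keys)
    stop("duplicate (x, y) coordinates at rows ",
         paste(rows, collapse = ", "), call. = FALSE)
  }
  if (require_two_types && length(unique(tolower(sec$type))) < 2L)
    stop("section has fewer than 2 distinct fiber types", call. = FALSE)
  invisible(sec)
}

#' @export
print.fiber_section <- function(x, ...) {
  cat("Fiber section:", nrow(x), "fibers\n")
  tab <- table(x$type)
  cat("Types:", paste(sprintf("%s=%d (%.1f%%)", names(tab), tab,
                              100 * tab / nrow(x)), collapse = ", "), "\n")
  cat(sprintf("Extent: x [%.4g, %.4g], y [%.4g, %.4g]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Read a per-fiber section CSV
#'
#' Reads a comma-separated file with one row per fiber and columns for the
#' x coordinate, y coordinate and fiber type (default header names `x`, `y`,
#' `type`; any dialect can be absorbed via `column_map`). The file must have
#' a header row; labels are whitespace-trimmed and the validated section must
#' contain at least two distinct types.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector mapping the roles
#'   `x`, `y`, `type` to the file's column names, e.g.
#'   `c(x = "X_um", y = "Y_um", type = "fibre_class")`.
#' @param quiet logical; suppress the log record of n and per-type counts.
#' @return A validated [fiber_section].
#' @export
read_section_csv <- function(path, column_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  map <- c(x = "x", y = "y", type = "type")
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || !all(names(column_map) %in% names(map)))
      stop("column_map names must be among 'x', 'y', 'type'", call. = FALSE)
    map[names(column_map)] <- unname(column_map)
  }
  for (role in names(map)) {
    if (!map[[role]] %in% names(raw))
      stop("missing column '", map[[role]], "' (role: ", role, ") in ", path,
           call. = FALSE)
  }
  xs <- raw[[map[["x"]]]]; ys <- raw[[map[["y"]]]]
  for (nm in c("x", "y")) {
    v <- raw[[map[[nm]]]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) {
      bad <- which(is.na(num))
      stop("non-numeric ", nm, " coordinate at row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  sec <- fiber_section(as.numeric(xs), as.numeric(ys), raw[[map[["type"]]]],
                       validate = FALSE)
  validate_section(sec, require_two_types = TRUE)
  if (!quiet) {
    tab <- table(sec$type)
    message("read ", nrow(sec), " fibers from ", basename(path), ": ",
            paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  sec
}

#' Write a section to CSV
#'
#' Inverse of [read_section_csv()]: writes the `x`, `y`, `type` columns so
#' that reading the file back reproduces the section exactly.
#'
#' @param section a [fiber_section].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_section_csv <- function(section, path) {
  df <- data.frame(x = section$x, y = section$y, type = section$type)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode fiber types as binary spins
#'
#' Maps each fiber to a spin: +1 for fast fibers, -1 for slow fibers. The
#' fast group is given explicitly via `fast_labels`; every other observed
#' label is treated as slow. Labels are compared case-insensitively after
#' trimming whitespace; no built-in guessing of staining nomenclature.
#'
#' @param section a [fiber_section].
#' @param fast_labels character vector of type labels to treat as fast.
#' @return An object of class `binary_labels`: list with `z` (spin vector,
#'   slow = -1, fast = +1), `n_slow`, `n_fast`, `fast_labels`, `slow_labels`.
#' @export
encode_binary <- function(section, fast_labels) {
  lab <- tolower(trimws(section$type))
  fl <- tolower(trimws(as.character(fast_labels)))
  if (anyNA(lab)) stop("missing type labels", call. = FALSE)
  unused <- setdiff(fl, unique(lab))
  if (length(unused))
    warning("fast_labels not present in section: ",
            paste(unused, collapse = ", "), call. = FALSE)
  is_fast <- lab %in% fl
  observed_fast <- unique(section$type[is_fast])
  observed_slow <- unique(section$type[!is_fast])
  z <- ifelse(is_fast, 1L, -1L)
  n_fast <- sum(is_fast); n_slow <- sum(!is_fast)
  if (n_fast == 0L || n_slow == 0L)
    stop("degenerate section: all fibers map to one group (",
         if (n_fast == 0L) "no fast" else "no slow", " fibers)",
         call. = FALSE)
  structure(list(z = as.integer(z), n_slow = n_slow, n_fast = n_fast,
                 fast_labels = observed_fast, slow_labels = observed_slow),
            class = "binary_labels")
}

#' @export
print.binary_labels <- function(x, ...) {
  n <- x$n_slow + x$n_fast
  cat(sprintf("Binary labels: n=%d, slow=%d (%.1f%%), fast=%d (%.1f%%)\n",
              n, x$n_slow, 100 * x$n_slow / n, x$n_fast, 100 * x$n_fast / n))
  invisible(x)
}

# internal constructor used by simulators and permutation machinery
binary_labels_from_z <- function(z) {
  z <- as.integer(z)
  stopifnot(all(z %in% c(-1L, 1L)))
  structure(list(z = z, n_slow = sum(z == -1L), n_fast = sum(z == 1L),
                 fast_labels = "fast", slow_labels = "slow"),
            class = "binary_labels")
}
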