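# Batch fitting over a manifest of sections and group comparison of the
# per-section BMRF parameters (young vs aged cohorts and the like).

#' Fit the BMRF to every section in a manifest
#'
#' Processes a cohort: for each section, builds the neighbor network, fits
#' the binary Markov random field, and (optionally) the permutation
#' envelope. Per-section failures are logged and reported in the table, not
#' fatal.
#'
#' @param manifest a data frame with columns `path` and `group` (and
#'   optionally `section`), or the path of such a CSV file. Alternatively a
#'   named list of [fiber_section] objects together with `groups`.
#' @param fast_labels labels to treat as fast, passed to [encode_binary()].
#' @param groups group vector, only when `manifest` is a list of sections.
#' @param envelope logical; also compute the beta permutation envelope.
#' @param n_perm,seed envelope settings (per-section seeds are derived as
#'   `seed + section index`).
#' @param prune network pruning configuration.
#' @return A data frame of class `bmrf_fit_table`: one row per section with
#'   `section`, `group`, `n`, `alpha`, `beta` (and envelope columns when
#'   requested), `ok`, `note`.
#' @export
batch_fit <- function(manifest, fast_labels = "fast", groups = NULL,
                      envelope = FALSE, n_perm = 999, seed = NULL,
                      prune = prune_config()) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.data.frame(manifest)) {
    if (!all(c("path", "group") %in% names(manifest)))
      stop("manifest needs 'path' and 'group' columns", call. = FALSE)
    if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
    sections <- manifest$path
    groups <- manifest$group
    ids <- manifest$section %||% basename(manifest$path)
    loader <- function(i) read_section_csv(sections[i], quiet = TRUE)
  } else if (is.list(manifest)) {
    if (is.null(groups) || length(groups) != length(manifest))
      stop("groups must accompany a list manifest", call. = FALSE)
    ids <- names(manifest) %||% paste0("section_", seq_along(manifest))
    loader <- function(i) manifest[[i]]
  } else stop("unsupported manifest", call. = FALSE)
  k <- length(groups)
  rows <- lapply(seq_len(k), function(i) {
    res <- tryCatch({
      sec <- loader(i)
      lab <- encode_binary(sec, fast_labels)
      net <- delaunay_network(sec, prune = prune)
      fit <- if (envelope)
        fit_bmrf_with_envelope(net, lab, n_perm = n_perm,
                               seed = if (is.null(seed)) NULL else seed + i)
      else fit_bmrf(net, lab)
      data.frame(section = ids[i], group = groups[i], n = net$n,
                 alpha = fit$alpha, beta = fit$beta,
                 envelope_lo = if (envelope) fit$envelope[["lo"]] else NA_real_,
                 envelope_hi = if (envelope) fit$envelope[["hi"]] else NA_real_,
                 verdict = fit$verdict %||% NA_character_,
                 ok = TRUE, note = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("section ", ids[i], " failed: ", conditionMessage(e),
              call. = FALSE)
      data.frame(section = ids[i], group = groups[i], n = NA_integer_,
                 alpha = NA_real_, beta = NA_real_,
                 envelope_lo = NA_real_, envelope_hi = NA_real_,
                 verdict = NA_character_, ok = FALSE,
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bmrf_fit_table", "data.frame")
  out
}

#' Compare BMRF parameters between two groups
#'
#' Given per-section parameter estimates for exactly two groups, runs a
#' Welch two-sample t test (pooled-variance optional) and a two-sided
#' Mann-Whitney U test on the chosen parameter.
#'
#' @param fit_table a `bmrf_fit_table` from [batch_fit()], or any data
#'   frame with `group` and the parameter column.
#' @param parameter `"alpha"` or `"beta"`.
#' @param var_equal logical; `FALSE` (default) for the Welch t test.
#' @return An object of class `group_comparison` with group means, the two
#'   p-values and the per-section estimates used.
#' @export
compare_group_params <- function(fit_table, parameter = c("beta", "alpha"),
                                 var_equal = FALSE) {
  parameter <- match.arg(parameter)
  tb <- fit_table[is.finite(fit_table[[parameter]]), , drop = FALSE]
  gs <- unique(tb$group)
  if (length(gs) != 2L)
    stop("need exactly two groups, got ", length(gs), call. = FALSE)
  sizes <- table(tb$group)
  if (any(sizes < 3L))
    stop("each group needs at least 3 sections", call. = FALSE)
  v1 <- tb[[parameter]][tb$group == gs[1]]
  v2 <- tb[[parameter]][tb$group == gs[2]]
  tt <- stats::t.test(v1, v2, var.equal = var_equal)
  mw <- suppressWarnings(stats::wilcox.test(v1, v2, exact = NULL,
                                            correct = TRUE))
  structure(list(parameter = parameter,
                 group_labels = as.character(gs),
                 group_means = stats::setNames(c(mean(v1), mean(v2)),
                                               as.character(gs)),
                 t_p = tt$p.value, mw_p = mw$p.value,
                 t_stat = unname(tt$statistic),
                 per_section_estimates = tb[, c("section", "group", "alpha",
                                                "beta")]),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (%s vs %s)\n", x$parameter,
              x$group_labels[1], x$group_labels[2]))
  cat(sprintf("  group means: %.4g vs %.4g\n",
              x$group_means[1], x$group_means[2]))
  cat(sprintf("  t test p = %.4g; Mann-Whitney U p = %.4g\n", x$t_p, x$mw_p))
  invisible(x)
}
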