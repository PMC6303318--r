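#' Tally end calls into a per-sample 3'-end distribution
#'
#' Every assigned call contributes one count to its end-coordinate bin
#' regardless of whether it carries a non-templated addition; class and
#' sub-bin fractions are computed over assigned reads only, and failure
#' statuses are tabulated separately.
#'
#' @param calls data.frame of end calls (from [assign_ends()] or
#'   [map_ends()]).
#' @param model The `race_reference` the calls were produced against.
#' @param sample Sample label.
#' @return An object of class `race_dist` with components `sample`,
#'   `counts` (named integer vector over the window), `total_assigned`,
#'   `status_counts`, `class_fractions`, `sub_bin_fractions`,
#'   `ntna_fraction`, `pure_a_fraction`, `window`.
#' @export
tally <- function(calls, model, sample = "sample") {
  stopifnot(inherits(model, "race_reference"), is.data.frame(calls))
  coords <- model$window_start:model$window_end
  counts <- integer(length(coords))
  names(counts) <- coords
  assigned <- calls[!is.na(calls$status) & calls$status == "assigned", ,
                    drop = FALSE]
  if (nrow(assigned)) {
    tab <- table(factor(assigned$end_coord, levels = coords))
    counts <- as.integer(tab)
    names(counts) <- coords
  }
  total <- sum(counts)
  status_counts <- table(factor(calls$status,
                                levels = c("assigned", "no_linker",
                                           "short_match", "no_anchor",
                                           "out_of_window")))
  frac_in <- function(start, end) {
    if (total == 0L) return(NA_real_)
    sum(counts[as.character(start:end)]) / total
  }
  cb <- model$class_bounds
  class_fractions <- mapply(frac_in, cb$start, cb$end)
  names(class_fractions) <- cb$label
  sb <- model$sub_bins
  sub_bin_fractions <- if (nrow(sb)) {
    x <- mapply(frac_in, sb$start, sb$end)
    names(x) <- sb$label
    x
  } else numeric(0)
  ntna_fraction <- if (total) mean(nchar(assigned$ntna) > 0L) else NA_real_
  pure_a <- if (total) {
    comp <- tail_composition(assigned$ntna)
    mean(comp$pure_A)
  } else NA_real_
  structure(
    list(sample = sample, counts = counts, total_assigned = total,
         status_counts = status_counts,
         class_fractions = class_fractions,
         sub_bin_fractions = sub_bin_fractions,
         ntna_fraction = ntna_fraction, pure_a_fraction = pure_a,
         window = c(model$window_start, model$window_end)),
    class = "race_dist")
}

#' @export
print.race_dist <- function(x, ...) {
  cat("3'-end distribution for sample '", x$sample, "'\n", sep = "")
  cat("  window [", x$window[1], ", ", x$window[2], "], assigned reads: ",
      x$total_assigned, "\n", sep = "")
  st <- x$status_counts
  st <- st[st > 0]
  if (length(st))
    cat("  statuses:", paste(names(st), st, sep = "=", collapse = ", "),
        "\n")
  if (x$total_assigned > 0) {
    cat("  class fractions:\n")
    for (i in seq_along(x$class_fractions))
      cat(sprintf("    %-10s %.4f\n", names(x$class_fractions)[i],
                  x$class_fractions[i]))
    cat(sprintf("  NTNA fraction: %.4f (pure oligo-A: %.4f)\n",
                x$ntna_fraction, x$pure_a_fraction))
  }
  invisible(x)
}

#' @export
plot.race_dist <- function(x, from = NULL, to = NULL, ...) {
  coords <- as.integer(names(x$counts))
  if (is.null(from)) from <- x$window[1]
  if (is.null(to)) to <- x$window[2]
  sel <- coords >= from & coords <= to
  frac <- if (x$total_assigned) x$counts / x$total_assigned else x$counts
  graphics::barplot(frac[sel], names.arg = coords[sel],
                    xlab = "3'-end coordinate",
                    ylab = "fraction of assigned reads",
                    main = x$sample, border = NA, ...)
  invisible(x)
}

#' Compare two 3'-end distributions (treatment - control)
#'
#' Signed per-coordinate and per-class fraction differences; the deltas
#' sum to zero across bins (both sets of fractions sum to one). The two
#' distributions must share the same window.
#'
#' @param treatment,control `race_dist` objects over the same model.
#' @return An object of class `race_comparison`: list with `per_coordinate`
#'   (data.frame `coord`, `treatment`, `control`, `delta`) and `per_class`
#'   (data.frame `label`, `treatment`, `control`, `delta`), plus the sample
#'   labels.
#' @export
compare_distributions <- function(treatment, control) {
  stopifnot(inherits(treatment, "race_dist"), inherits(control, "race_dist"))
  if (!identical(treatment$window, control$window))
    stop("distributions were tallied over different windows")
  tf <- treatment$counts / max(treatment$total_assigned, 1L)
  cf <- control$counts / max(control$total_assigned, 1L)
  per_coord <- data.frame(coord = as.integer(names(treatment$counts)),
                          treatment = as.numeric(tf),
                          control = as.numeric(cf),
                          delta = as.numeric(tf - cf))
  if (!identical(names(treatment$class_fractions),
                 names(control$class_fractions)))
    stop("distributions use different class schemes")
  per_class <- data.frame(label = names(treatment$class_fractions),
                          treatment = as.numeric(treatment$class_fractions),
                          control = as.numeric(control$class_fractions),
                          stringsAsFactors = FALSE)
  per_class$delta <- per_class$treatment - per_class$control
  structure(list(treatment = treatment$sample, control = control$sample,
                 per_coordinate = per_coord, per_class = per_class),
            class = "race_comparison")
}

#' @export
print.race_comparison <- function(x, ...) {
  cat("3'-end distribution shift: ", x$treatment, " vs ", x$control,
      "\n", sep = "")
  df <- x$per_class
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-10s %+.4f (%.4f vs %.4f)\n", df$label[i], df$delta[i],
                df$treatment[i], df$control[i]))
  invisible(x)
}

#' Write distributions and comparisons to TSV / JSON reports
#'
#' Emits, per distribution, a per-coordinate TSV (`<sample>_coords.tsv`
#' with counts and fractions) and one `class_summary.json` covering all
#' samples (class fractions, sub-bin fractions, NTNA fractions, status
#' counts); per comparison, `<treatment>_vs_<control>.tsv` with the signed
#' per-coordinate deltas.
#'
#' @param distributions List of `race_dist` objects (a single object is
#'   accepted).
#' @param comparisons Optional list of `race_comparison` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(distributions, comparisons = list(), dir) {
  if (inherits(distributions, "race_dist"))
    distributions <- list(distributions)
  if (inherits(comparisons, "race_comparison"))
    comparisons <- list(comparisons)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  summaries <- list()
  for (d in distributions) {
    df <- data.frame(coord = as.integer(names(d$counts)),
                     count = as.integer(d$counts),
                     fraction = if (d$total_assigned)
                       as.numeric(d$counts / d$total_assigned) else
                         rep(NA_real_, length(d$counts)))
    p <- file.path(dir, paste0(d$sample, "_coords.tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    summaries[[d$sample]] <- list(
      total_assigned = d$total_assigned,
      status_counts = as.list(d$status_counts),
      class_fractions = as.list(d$class_fractions),
      sub_bin_fractions = as.list(d$sub_bin_fractions),
      ntna_fraction = d$ntna_fraction,
      pure_a_fraction = d$pure_a_fraction)
  }
  pj <- file.path(dir, "class_summary.json")
  jsonlite::write_json(summaries, pj, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- c(paths, pj)
  for (cmp in comparisons) {
    p <- file.path(dir, paste0(cmp$treatment, "_vs_", cmp$control, ".tsv"))
    utils::write.table(cmp$per_coordinate, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Re-read a per-coordinate distribution TSV written by [write_report()]
#'
#' @param path TSV path.
#' @return data.frame with `coord`, `count`, `fraction`.
#' @export
read_distribution_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
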