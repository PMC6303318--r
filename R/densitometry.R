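#' Read a gel densitometry table
#'
#' Long-format TSV with columns `species`, `time` (minutes), `replicate`,
#' `intensity` (arbitrary units, >= 0). Band quantification from gel images
#' is out of scope — intensities arrive pre-measured.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_densitometry <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("species", "time", "replicate", "intensity")
  if (!all(need %in% names(df)))
    stop("densitometry table must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' Normalize a decay time course to the loading control and to t = 0
#'
#' For each species and replicate, the normalized signal is
#' `s(t) = (I_species(t) / I_control(t)) / (I_species(0) / I_control(0))`,
#' so `s(0) = 1` exactly and the series is invariant to rescaling all
#' intensities of a lane or replicate by a constant (gel-exposure
#' invariance). Replicate means and standard errors are computed per time
#' point.
#'
#' @param table Long-format data.frame (`species`, `time`, `replicate`,
#'   `intensity`); must contain `t = 0` and the loading control at every
#'   used (time, replicate).
#' @param control Loading-control species label (default `"Actin"`).
#' @return List with `per_replicate` (data.frame `species`, `time`,
#'   `replicate`, `normalized`) and `summary` (data.frame `species`,
#'   `time`, `mean`, `se`, `n`), control species excluded from both.
#' @export
normalize_timecourse <- function(table, control = "Actin") {
  stopifnot(is.data.frame(table),
            all(c("species", "time", "replicate", "intensity") %in%
                  names(table)))
  if (!control %in% table$species)
    stop("loading control '", control, "' not found in table")
  ctrl <- table[table$species == control, ]
  if (any(ctrl$intensity <= 0, na.rm = TRUE))
    stop("loading-control intensity must be > 0 at every time point")
  key <- function(t, r) paste(t, r, sep = "\r")
  ctrl_val <- ctrl$intensity
  names(ctrl_val) <- key(ctrl$time, ctrl$replicate)

  sp <- table[table$species != control, ]
  cv <- ctrl_val[key(sp$time, sp$replicate)]
  if (any(is.na(cv)))
    stop("missing loading-control measurement for some (time, replicate)")
  ratio <- sp$intensity / cv
  # divide by the t=0 ratio of the same species x replicate
  k0 <- paste(sp$species, sp$replicate, sep = "\r")
  at0 <- sp$time == 0
  if (!all(unique(k0) %in% k0[at0]))
    stop("t = 0 measurement missing for some species x replicate")
  r0 <- ratio[at0]
  names(r0) <- k0[at0]
  norm <- ratio / r0[k0]

  per_rep <- data.frame(species = sp$species, time = sp$time,
                        replicate = sp$replicate, normalized = norm,
                        stringsAsFactors = FALSE, row.names = NULL)
  agg <- stats::aggregate(normalized ~ species + time, data = per_rep,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  summary <- data.frame(species = agg$species, time = agg$time,
                        mean = agg$normalized[, "mean"],
                        se = agg$normalized[, "sd"] /
                          sqrt(agg$normalized[, "n"]),
                        n = as.integer(agg$normalized[, "n"]),
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$species, summary$time), ]
  rownames(summary) <- NULL
  list(per_replicate = per_rep, summary = summary)
}

#' Time at which a normalized decay series reaches 50%
#'
#' Log-linear interpolation between the two time points flanking 0.5 (the
#' first downward crossing), making no kinetic assumption; with
#' `method = "exponential"` a single-exponential fit
#' `log(s) = -lambda t` is used instead and `ln(2)/lambda` returned.
#' If the series never reaches 0.5 the result is `NA` with attribute
#' `last_time` (the "not reached" sentinel).
#'
#' @param time Numeric vector of time points (minutes), starting at 0.
#' @param value Normalized signal at those times; `value[time == 0]` must
#'   be 1.
#' @param method `"interpolation"` (default) or `"exponential"`.
#' @return Minutes to 50% decay (numeric scalar), or `NA` with attribute
#'   `last_time` when 0.5 is never reached.
#' @examples
#' time_to_half(c(0, 30), c(1, 0.5))              # exactly 30
#' time_to_half(c(0, 15, 45), c(1, 0.8, 0.4))
#' @export
time_to_half <- function(time, value,
                         method = c("interpolation", "exponential")) {
  method <- match.arg(method)
  stopifnot(length(time) == length(value), length(time) >= 2)
  o <- order(time)
  time <- time[o]; value <- value[o]
  if (time[1] != 0 || abs(value[1] - 1) > 1e-9)
    stop("series must start at time 0 with normalized value 1")
  if (method == "exponential") {
    if (any(value <= 0)) stop("exponential fit requires positive values")
    lambda <- -stats::coef(stats::lm(log(value) ~ time + 0))[[1]]
    if (lambda <= 0)
      return(structure(NA_real_, last_time = time[length(time)]))
    return(log(2) / lambda)
  }
  below <- which(value <= 0.5)
  if (!length(below))
    return(structure(NA_real_, last_time = time[length(time)]))
  i2 <- below[1]                      # first downward crossing
  if (value[i2] == 0.5) return(time[i2])
  i1 <- i2 - 1L
  v1 <- value[i1]; v2 <- value[i2]
  if (v2 <= 0) {                      # log undefined; fall back to linear
    return(time[i1] + (time[i2] - time[i1]) * (v1 - 0.5) / (v1 - v2))
  }
  time[i1] + (time[i2] - time[i1]) *
    (log(v1) - log(0.5)) / (log(v1) - log(v2))
}

#' Fold change between two replicate groups with a Student's t-test
#'
#' Fold change is `mean(condition) / mean(reference)`; its standard error
#' is computed from the per-replicate ratios `condition_i /
#' mean(reference)`. Significance is a two-sided two-sample t-test on the
#' (pre-normalized) replicate values — equal-variance Student's t by
#' default, Welch with `var_equal = FALSE`. With fewer than two replicates
#' in either group the fold change is returned with `p_value = NA`. When
#' both groups have zero variance the t statistic is undefined; the result
#' is flagged `degenerate` with `p_value` 1 (equal means) or 0 (different
#' means).
#'
#' @param values_condition,values_reference Numeric replicate values,
#'   already normalized to their loading / transfection control.
#' @param var_equal Pool variances (classical Student's t, default TRUE).
#' @return List: `fold_change`, `se`, `p_value`, `t`, `df`, `n`,
#'   `degenerate`.
#' @examples
#' fold_change_test(c(2.1, 1.9, 2.0), c(1.0, 1.1, 0.9))
#' @export
fold_change_test <- function(values_condition, values_reference,
                             var_equal = TRUE) {
  x <- as.numeric(values_condition)
  y <- as.numeric(values_reference)
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (mean(y) == 0) stop("reference mean is zero; fold change undefined")
  fc <- mean(x) / mean(y)
  ratios <- x / mean(y)
  se <- if (length(x) >= 2) stats::sd(ratios) / sqrt(length(x)) else
    NA_real_
  n <- c(condition = length(x), reference = length(y))
  if (length(x) < 2 || length(y) < 2)
    return(list(fold_change = fc, se = se, p_value = NA_real_,
                t = NA_real_, df = NA_real_, n = n, degenerate = FALSE))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(fold_change = fc, se = se,
                p_value = if (same) 1 else 0,
                t = if (same) 0 else Inf, df = NA_real_, n = n,
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(fold_change = fc, se = se, p_value = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter), n = n,
       degenerate = FALSE)
}
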