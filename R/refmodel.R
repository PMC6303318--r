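#' Default 3' linker sequence
#'
#' Constant 3' adapter assumed by the simulator and the default reference
#' model. A 17-nt linker of the kind ligated to RNA 3' ends in RLM-RACE
#' protocols; real analyses should supply the linker actually used.
#' @export
DEFAULT_LINKER <- "CTGTAGGCACCATCAAT"

#' Build a transcript reference model
#'
#' Holds the transcript sequence (sense strand), the coordinate frame, the
#' end-assignment window, the constant 3' linker, and the 3'-isoform
#' classification scheme. Coordinates are 1-based and inclusive, with
#' position 1 the transcription start; an "end coordinate" is the position
#' of the last templated base of a molecule.
#'
#' Default classes follow the standard nomenclature for human telomerase
#' RNA 3' isoforms: the mature form ends exactly at `mature_end` (451),
#' the 3'-extended short form (exS) ends at 452-460, the 3'-extended long
#' form (exL) ends beyond 460, and ends upstream of the mature coordinate
#' are reported as `sub_mature`. The class intervals must be disjoint,
#' ordered, and jointly cover the window.
#'
#' @param sequence Nucleotide string (A/C/G/T, case-insensitive), at least
#'   `window_end` long.
#' @param linker Constant 3' adapter sequence ligated downstream of the
#'   transcript 3' end.
#' @param mature_end 1-based coordinate of the mature 3' end (default 451).
#' @param window_start,window_end Inclusive bounds of the permitted
#'   end-assignment range (defaults 366 and 641).
#' @param exs_max Largest coordinate classified as exS (default 460); exL
#'   covers `exs_max + 1` through `window_end`.
#' @param class_bounds Optional data.frame with columns `label`, `start`,
#'   `end` replacing the default four-class scheme entirely.
#' @param sub_bins Optional data.frame (`label`, `start`, `end`) of
#'   reporting sub-bins inside the window; defaults to 452-453, 454-457,
#'   458-459.
#' @return An object of class `race_reference`.
#' @examples
#' ref <- random_reference(700, seed = 1)
#' ref
#' @export
build_reference <- function(sequence, linker = DEFAULT_LINKER,
                            mature_end = 451L,
                            window_start = 366L, window_end = 641L,
                            exs_max = 460L,
                            class_bounds = NULL, sub_bins = NULL) {
  sequence <- toupper(as.character(sequence)[1L])
  linker <- toupper(as.character(linker)[1L])
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence contains non-A/C/G/T characters")
  if (grepl("[^ACGT]", linker))
    stop("linker contains non-A/C/G/T characters")
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  mature_end <- as.integer(mature_end)
  if (nchar(sequence) < window_end)
    stop("reference sequence (", nchar(sequence),
         " nt) is shorter than window_end (", window_end, ")")
  if (!(window_start <= mature_end && mature_end <= window_end))
    stop("require window_start <= mature_end <= window_end")
  if (nchar(linker) < 1L) stop("linker must be non-empty")

  if (is.null(class_bounds)) {
    exs_max <- as.integer(exs_max)
    class_bounds <- data.frame(
      label = c("sub_mature", "mature", "exS", "exL"),
      start = c(window_start, mature_end, mature_end + 1L, exs_max + 1L),
      end   = c(mature_end - 1L, mature_end, exs_max, window_end),
      stringsAsFactors = FALSE)
    # a window starting at the mature end has no sub_mature interval
    class_bounds <- class_bounds[class_bounds$start <= class_bounds$end, ]
  } else {
    class_bounds <- as.data.frame(class_bounds, stringsAsFactors = FALSE)
    stopifnot(all(c("label", "start", "end") %in% names(class_bounds)))
    class_bounds$start <- as.integer(class_bounds$start)
    class_bounds$end <- as.integer(class_bounds$end)
  }
  .validate_class_bounds(class_bounds, window_start, window_end)
  class_bounds <- class_bounds[order(class_bounds$start), , drop = FALSE]
  rownames(class_bounds) <- NULL

  if (is.null(sub_bins)) {
    sub_bins <- data.frame(
      label = c("452-453", "454-457", "458-459"),
      start = c(452L, 454L, 458L),
      end   = c(453L, 457L, 459L),
      stringsAsFactors = FALSE)
    sub_bins <- sub_bins[sub_bins$start >= window_start &
                           sub_bins$end <= window_end, ]
  }

  structure(
    list(sequence = sequence, linker = linker,
         mature_end = mature_end,
         window_start = window_start, window_end = window_end,
         class_bounds = class_bounds, sub_bins = sub_bins),
    class = "race_reference")
}

.validate_class_bounds <- function(cb, window_start, window_end) {
  if (nrow(cb) < 1L) stop("class_bounds is empty")
  o <- order(cb$start)
  cb <- cb[o, ]
  if (any(cb$end < cb$start))
    stop("class interval with end < start: ", cb$label[cb$end < cb$start][1L])
  if (cb$start[1L] != window_start || cb$end[nrow(cb)] != window_end)
    stop("class intervals must cover [window_start, window_end] exactly")
  if (nrow(cb) > 1L) {
    gaps <- cb$start[-1L] - cb$end[-nrow(cb)]
    if (any(gaps != 1L))
      stop("class intervals must be disjoint and contiguous (no gaps/overlaps)")
  }
  invisible(TRUE)
}

#' @export
print.race_reference <- function(x, ...) {
  cat("Transcript reference model (", nchar(x$sequence), " nt)\n", sep = "")
  cat("  end-assignment window: [", x$window_start, ", ", x$window_end,
      "]\n", sep = "")
  cat("  mature 3' end: ", x$mature_end, "\n", sep = "")
  cat("  linker: ", x$linker, "\n", sep = "")
  cat("  classes:\n")
  for (i in seq_len(nrow(x$class_bounds)))
    cat(sprintf("    %-10s [%d, %d]\n", x$class_bounds$label[i],
                x$class_bounds$start[i], x$class_bounds$end[i]))
  invisible(x)
}

#' Classify a 3'-end coordinate into its isoform class
#'
#' Maps each coordinate inside the model's end-assignment window to the
#' unique class interval containing it (by default `sub_mature`, `mature`,
#' `exS` or `exL`). Coordinates outside the window are an error: callers
#' must handle out-of-window ends explicitly, never classify them silently.
#'
#' @param coord Integer vector of 1-based end coordinates.
#' @param model A `race_reference`.
#' @return Character vector of class labels, same length as `coord`.
#' @examples
#' ref <- random_reference(700, seed = 1)
#' classify_end(c(448, 451, 455, 461), ref)
#' @export
classify_end <- function(coord, model) {
  stopifnot(inherits(model, "race_reference"))
  coord <- as.integer(coord)
  if (any(is.na(coord)))
    stop("classify_end: NA coordinate")
  bad <- coord < model$window_start | coord > model$window_end
  if (any(bad))
    stop("coordinate(s) outside the end-assignment window [",
         model$window_start, ", ", model$window_end, "]: ",
         paste(utils::head(coord[bad], 5L), collapse = ", "))
  cb <- model$class_bounds
  idx <- findInterval(coord, cb$start)
  cb$label[idx]
}

#' Serialize a reference model to a plain list / JSON
#'
#' The config representation round-trips: `reference_from_config(
#' reference_to_config(m))` reproduces `m` exactly.
#'
#' @param model A `race_reference`.
#' @return A named list suitable for `jsonlite::toJSON`.
#' @export
reference_to_config <- function(model) {
  stopifnot(inherits(model, "race_reference"))
  list(sequence = model$sequence, linker = model$linker,
       mature_end = model$mature_end,
       window_start = model$window_start, window_end = model$window_end,
       class_bounds = model$class_bounds, sub_bins = model$sub_bins)
}

#' @rdname reference_to_config
#' @param config A list as produced by `reference_to_config` (or parsed
#'   from its JSON form).
#' @export
reference_from_config <- function(config) {
  build_reference(config$sequence, linker = config$linker,
                  mature_end = config$mature_end,
                  window_start = config$window_start,
                  window_end = config$window_end,
                  class_bounds = as.data.frame(config$class_bounds),
                  sub_bins = as.data.frame(config$sub_bins))
}

#' @rdname reference_to_config
#' @param path File path for the JSON serialization.
#' @export
write_reference_json <- function(model, path) {
  jsonlite::write_json(reference_to_config(model), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname reference_to_config
#' @export
read_reference_json <- function(path) {
  reference_from_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read a reference sequence from a single-record FASTA file
#'
#' @param path FASTA file with exactly one record (the transcript, sense
#'   strand, position 1 = transcription start).
#' @param ... Passed to [build_reference()] (linker, window, classes).
#' @return A `race_reference`.
#' @export
read_reference_fasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("expected a single-record FASTA, found ", length(seqs), " records")
  build_reference(as.character(seqs[[1L]]), ...)
}
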