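#' Run the full 3'-RACE end-mapping pipeline on a read set
#'
#' Convenience wrapper chaining the two analysis stages: (1) linker
#' location, insert trimming, barcode extraction and PCR-duplicate
#' collapsing ([preprocess_reads()]); (2) anchored templated 3'-end
#' assignment and NTNA calling ([assign_ends()]). Returns the per-read
#' end-call table; feed it to [tally()] for a per-sample distribution.
#'
#' @param reads data.frame with `id` and `seq` columns ([read_fastq()] or
#'   [simulate_library()] output).
#' @param model A `race_reference`.
#' @param min_match Linker-match threshold (default 10).
#' @param barcode_len Molecular-barcode length (default 10).
#' @param dedup Collapse PCR duplicates (default TRUE).
#' @param ... Passed to [assign_ends()] (anchor_len, max_mismatch,
#'   exact_terminal, max_tail, terminal_free).
#' @return data.frame with `id`, `status`, `end_coord`, `ntna`,
#'   `tail_trim`, `anchor_mismatches`, `barcode`, `family_size`.
#' @examples
#' ref <- random_reference(700, seed = 1)
#' cfg <- simulation_config(100, class_fraction_probs(
#'   ref, c(mature = 0.6, exS = 0.25, exL = 0.15)), seed = 3)
#' lib <- simulate_library(ref, cfg)
#' calls <- map_ends(lib$reads, ref)
#' tally(calls, ref, sample = "simulated")
#' @export
map_ends <- function(reads, model, min_match = 10L, barcode_len = 10L,
                     dedup = TRUE, ...) {
  pre <- preprocess_reads(reads, model, min_match = min_match,
                          barcode_len = barcode_len, dedup = dedup)
  calls <- assign_ends(pre$insert, model, ...)
  cbind(data.frame(id = pre$id, stringsAsFactors = FALSE),
        calls,
        data.frame(barcode = pre$barcode, family_size = pre$family_size,
                   stringsAsFactors = FALSE))
}

#' Write a per-read end-call table as TSV
#' @param calls data.frame from [map_ends()] or [assign_ends()].
#' @param path TSV path.
#' @export
write_end_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_end_calls
#' @export
read_end_calls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
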