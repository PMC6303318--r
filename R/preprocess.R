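#' Locate the 3' linker in reads
#'
#' Finds, for each read, the 5'-most position at which the first
#' `min_match` bases of the constant linker occur. Matching is exact by
#' default — the published filter requires 10 nt of linker match and the
#' simplest reading of that threshold is an exact 10-mer; a
#' mismatch-tolerant mode (`max_mismatch > 0`) is available but off by
#' default. The earliest match wins, which yields the shorter,
#' conservative insert when the linker seed occurs more than once.
#'
#' @param seqs Character vector of read sequences.
#' @param model A `race_reference` supplying the linker.
#' @param min_match Number of linker 5' bases that must match (default 10).
#' @param max_mismatch Substitutions tolerated in the linker seed
#'   (default 0, exact).
#' @return Integer vector of 1-based linker start positions; `NA` where no
#'   match exists (such reads fail the filter downstream — absence is a
#'   value, not an error).
#' @export
locate_linker <- function(seqs, model, min_match = 10L, max_mismatch = 0L) {
  stopifnot(inherits(model, "race_reference"))
  min_match <- as.integer(min_match)
  if (min_match < 1L || min_match > nchar(model$linker))
    stop("min_match must be between 1 and the linker length (",
         nchar(model$linker), ")")
  pat <- substr(model$linker, 1L, min_match)
  if (max_mismatch == 0L) {
    pos <- regexpr(pat, seqs, fixed = TRUE)
    pos <- as.integer(pos)
    pos[pos < 0L] <- NA_integer_
    return(pos)
  }
  pat_int <- utf8ToInt(pat)
  vapply(seqs, function(s) {
    si <- utf8ToInt(s)
    n <- length(si)
    if (n < min_match) return(NA_integer_)
    for (off in seq_len(n - min_match + 1L)) {
      if (sum(si[off:(off + min_match - 1L)] != pat_int) <= max_mismatch)
        return(off)
    }
    NA_integer_
  }, integer(1L), USE.NAMES = FALSE)
}

#' Extract the molecular barcode from reads
#'
#' The barcode (UMI) is read immediately 3' of the full constant linker:
#' position `linker_pos + nchar(linker)` through
#' `linker_pos + nchar(linker) + barcode_len - 1`. Reads truncated before
#' the full barcode get `NA` and are passed through deduplication
#' uncollapsed.
#'
#' @param seqs Character vector of read sequences.
#' @param linker_pos 1-based linker start positions from [locate_linker()]
#'   (`NA` allowed).
#' @param model A `race_reference`.
#' @param barcode_len Barcode length (default 10); 0 yields empty barcodes
#'   so the dedup key degenerates to the insert sequence alone.
#' @return Character vector of barcodes (`NA` where unavailable).
#' @export
extract_barcode <- function(seqs, linker_pos, model, barcode_len = 10L) {
  stopifnot(inherits(model, "race_reference"),
            length(seqs) == length(linker_pos))
  barcode_len <- as.integer(barcode_len)
  start <- linker_pos + nchar(model$linker)
  end <- start + barcode_len - 1L
  bc <- substr(seqs, start, end)
  bc[is.na(linker_pos) | nchar(bc) < barcode_len] <- NA_character_
  if (barcode_len == 0L) bc[!is.na(linker_pos)] <- ""
  bc
}

#' Collapse PCR duplicates by molecular barcode + insert sequence
#'
#' Retains exactly one representative (the first occurrence, preserving
#' input order) per `(barcode, insert)` key. The insert is part of the key
#' because distinct molecules can collide on a 10-nt barcode; collapsing on
#' the barcode alone would merge them. Reads without a barcode pass through
#' unchanged.
#'
#' @param reads data.frame with at least `barcode` and `insert` columns.
#' @return The subset of `reads` retained after collapsing, with a
#'   `family_size` column giving the number of reads sharing each key.
#' @export
deduplicate <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("barcode", "insert") %in% names(reads)))
  if (nrow(reads) == 0L) {
    reads$family_size <- integer(0)
    return(reads)
  }
  no_bc <- is.na(reads$barcode)
  key <- ifelse(no_bc,
                paste0("__nobc__", seq_len(nrow(reads))),
                paste0(reads$barcode, "|", reads$insert))
  keep <- !duplicated(key)
  fam <- table(key)
  out <- reads[keep, , drop = FALSE]
  out$family_size <- as.integer(fam[key[keep]])
  rownames(out) <- NULL
  out
}

#' Preprocess a read set: linker location, insert trimming, UMI, dedup
#'
#' Stage 1 of the pipeline. For every read, locates the linker, trims the
#' insert (bases 5' of the linker), extracts the molecular barcode, and
#' optionally collapses PCR duplicates. Reads without a linker match are
#' kept in the log with `insert = NA` and counted as `no_linker`
#' downstream.
#'
#' @param reads data.frame with `id` and `seq` (e.g. from [read_fastq()]
#'   or [simulate_library()]).
#' @param model A `race_reference`.
#' @param min_match Linker-match threshold, see [locate_linker()].
#' @param max_mismatch Linker mismatches tolerated (default 0).
#' @param barcode_len Barcode length (default 10).
#' @param dedup Collapse PCR duplicates (default TRUE).
#' @return data.frame: `id`, `seq`, `linker_pos`, `insert`, `barcode`, and
#'   `family_size` (1 for reads that were never collapsible).
#' @export
preprocess_reads <- function(reads, model, min_match = 10L,
                             max_mismatch = 0L, barcode_len = 10L,
                             dedup = TRUE) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  pos <- locate_linker(reads$seq, model, min_match = min_match,
                       max_mismatch = max_mismatch)
  insert <- substr(reads$seq, 1L, ifelse(is.na(pos), 0L, pos - 1L))
  insert[is.na(pos)] <- NA_character_
  bc <- extract_barcode(reads$seq, pos, model, barcode_len = barcode_len)
  out <- data.frame(id = reads$id, seq = reads$seq, linker_pos = pos,
                    insert = insert, barcode = bc,
                    stringsAsFactors = FALSE)
  if (dedup) {
    # reads with no linker have no insert; exclude them from collapsing
    has_insert <- !is.na(out$insert)
    with_ins <- deduplicate(out[has_insert, , drop = FALSE])
    without <- out[!has_insert, , drop = FALSE]
    if (nrow(without)) without$family_size <- 1L
    out <- rbind(with_ins, without)
    out <- out[order(match(out$id, reads$id)), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$family_size <- 1L
  }
  out
}
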