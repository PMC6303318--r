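#' Generate a random reference model
#'
#' Uniform-random A/C/G/T sequence with the default linker and default
#' coordinate scheme; deterministic for a given seed. Used as the stand-in
#' transcript for tests and simulations — the package never embeds the real
#' telomerase RNA sequence, which users supply via FASTA.
#'
#' @param length Sequence length; must be at least the default window end
#'   (641) or the `window_end` override.
#' @param seed Integer seed.
#' @param ... Passed to [build_reference()].
#' @return A `race_reference`.
#' @export
random_reference <- function(length, seed = 1L, ...) {
  dots <- list(...)
  wend <- if (!is.null(dots$window_end)) dots$window_end else 641L
  if (length < wend)
    stop("reference length (", length, ") below window_end (", wend, ")")
  seq <- local({
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  })
  build_reference(seq, ...)
}

#' Simulation configuration for a synthetic RLM-RACE library
#'
#' Describes the generative model for one sequencing library: how many RNA
#' molecules, the distribution of true templated 3'-end coordinates, the
#' non-templated tail model (probability of carrying a tail, geometric tail
#' length, tail composition), the molecular-barcode length, PCR duplication,
#' substitution sequencing error, and read length.
#'
#' Each simulated read is laid out 5'->3' as
#' `[templated segment ending at the true end][tail][linker][barcode][filler]`,
#' truncated to `read_len`. Tail lengths are `1 + Geometric` with the stated
#' mean, capped at `tail_cap`; PCR copy numbers are `1 + Geometric` with mean
#' `dup_mean`. By default substitution errors are applied once per molecule
#' before PCR copying, so all copies of a molecule are exact duplicates and
#' deduplication has unambiguous ground truth; set `errors_per_copy = TRUE`
#' to apply errors independently per read instead.
#'
#' @param n_molecules Number of distinct RNA molecules.
#' @param end_probs Named numeric vector: probability of each true 3'-end
#'   coordinate (names are coordinates inside the model window); must sum
#'   to 1 within 1e-9.
#' @param tail_prob Probability a molecule carries a non-templated tail.
#' @param tail_mean Mean tail length (geometric, support >= 1); default 5,
#'   mirroring the oligo(A)5 tails typical of these libraries.
#' @param tail_cap Maximum tail length (default 30).
#' @param tail_nona Per-base probability a tail base is C/G/T instead of A
#'   (default 0: pure oligo-A).
#' @param barcode_len Molecular-barcode length (default 10).
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param dup_mean Mean PCR copy number per molecule (default 2).
#' @param read_len Read length (default 250, single-end).
#' @param templated_min,templated_max Range of the templated-segment length
#'   (5' start drawn uniformly); defaults 40 and 180 so that tail, linker
#'   and barcode fit inside the read.
#' @param errors_per_copy Apply substitution errors per read rather than per
#'   molecule (default FALSE).
#' @param seed Integer seed; the simulation is bit-identical for identical
#'   configuration including the seed.
#' @return An object of class `race_sim_config`.
#' @export
simulation_config <- function(n_molecules, end_probs,
                              tail_prob = 0.5, tail_mean = 5,
                              tail_cap = 30L, tail_nona = 0,
                              barcode_len = 10L, error_rate = 0.001,
                              dup_mean = 2, read_len = 250L,
                              templated_min = 40L, templated_max = 180L,
                              errors_per_copy = FALSE, seed = 1L) {
  n_molecules <- as.integer(n_molecules)
  if (is.na(n_molecules) || n_molecules < 0L)
    stop("n_molecules must be a non-negative count")
  end_probs <- unlist(end_probs)
  if (is.null(names(end_probs)) || any(names(end_probs) == ""))
    stop("end_probs must be named by coordinate")
  if (any(end_probs < 0) || any(end_probs > 1))
    stop("end_probs entries must be probabilities in [0, 1]")
  if (abs(sum(end_probs) - 1) > 1e-9)
    stop("end_probs must sum to 1 (got ", sum(end_probs), ")")
  stopifnot(tail_prob >= 0, tail_prob <= 1, tail_mean >= 1,
            tail_nona >= 0, tail_nona <= 1,
            error_rate >= 0, error_rate <= 1, dup_mean >= 1,
            templated_min >= 1, templated_max >= templated_min)
  structure(
    list(n_molecules = n_molecules, end_probs = end_probs,
         tail_prob = tail_prob, tail_mean = tail_mean,
         tail_cap = as.integer(tail_cap), tail_nona = tail_nona,
         barcode_len = as.integer(barcode_len), error_rate = error_rate,
         dup_mean = dup_mean, read_len = as.integer(read_len),
         templated_min = as.integer(templated_min),
         templated_max = as.integer(templated_max),
         errors_per_copy = isTRUE(errors_per_copy),
         seed = as.integer(seed)),
    class = "race_sim_config")
}

#' Helper: uniform class-fraction end distribution
#'
#' Spreads the given class fractions uniformly over the coordinates of each
#' class interval of the model, producing an `end_probs` vector for
#' [simulation_config()].
#'
#' @param model A `race_reference`.
#' @param class_fractions Named numeric vector over the model's class
#'   labels, summing to 1.
#' @return Named probability vector over coordinates.
#' @export
class_fraction_probs <- function(model, class_fractions) {
  stopifnot(inherits(model, "race_reference"))
  cb <- model$class_bounds
  if (!all(names(class_fractions) %in% cb$label))
    stop("unknown class label(s): ",
         paste(setdiff(names(class_fractions), cb$label), collapse = ", "))
  probs <- numeric(0)
  for (lab in names(class_fractions)) {
    row <- cb[cb$label == lab, ]
    coords <- row$start:row$end
    p <- rep(class_fractions[[lab]] / length(coords), length(coords))
    names(p) <- coords
    probs <- c(probs, p)
  }
  probs[order(as.integer(names(probs)))]
}

.random_bases <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.apply_substitutions <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  n <- nchar(seq)
  hits <- which(stats::runif(n) < rate)
  if (!length(hits)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  for (i in hits) {
    choices <- strsplit(alt[[chars[i]]], "", fixed = TRUE)[[1L]]
    chars[i] <- choices[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

#' Simulate an RLM-RACE library with known ground truth
#'
#' Draws `n_molecules` RNA molecules from the configured 3'-end and tail
#' model, attaches the constant linker, a random molecular barcode, and
#' random filler, applies substitution errors, emits each molecule as a
#' geometric number of identical PCR copies, and returns the reads together
#' with a per-molecule truth table.
#'
#' @param model A `race_reference`.
#' @param config A `race_sim_config`; all `end_probs` coordinates must lie
#'   inside the model window.
#' @return A list with components:
#'   \describe{
#'     \item{reads}{data.frame with `id`, `molecule`, `seq` (one row per
#'       read; copies of a molecule are adjacent).}
#'     \item{truth}{data.frame with one row per molecule: `molecule`,
#'       `true_end`, `tail`, `barcode`, `n_copies`, `templated_start`.}
#'   }
#' @examples
#' ref <- random_reference(700, seed = 1)
#' cfg <- simulation_config(50, class_fraction_probs(ref, c(mature = 1)),
#'                          seed = 7)
#' lib <- simulate_library(ref, cfg)
#' head(lib$truth)
#' @export
simulate_library <- function(model, config) {
  stopifnot(inherits(model, "race_reference"),
            inherits(config, "race_sim_config"))
  coords <- as.integer(names(config$end_probs))
  if (any(coords < model$window_start | coords > model$window_end))
    stop("end_probs includes coordinates outside the model window")
  min_insert <- config$templated_min + nchar(model$linker) +
    config$barcode_len
  if (config$read_len < min_insert)
    stop("read_len too short for templated segment + linker + barcode")

  n <- config$n_molecules
  empty_truth <- data.frame(molecule = integer(0), true_end = integer(0),
                            tail = character(0), barcode = character(0),
                            n_copies = integer(0),
                            templated_start = integer(0),
                            stringsAsFactors = FALSE)
  empty_reads <- data.frame(id = character(0), molecule = integer(0),
                            seq = character(0), stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(reads = empty_reads, truth = empty_truth))

  set.seed(config$seed)
  true_end <- coords[sample.int(length(coords), n, replace = TRUE,
                                prob = config$end_probs)]
  has_tail <- stats::runif(n) < config$tail_prob
  tail_len <- ifelse(has_tail,
                     pmin(1L + stats::rgeom(n, 1 / config$tail_mean),
                          config$tail_cap),
                     0L)
  tmpl_len <- sample(config$templated_min:config$templated_max, n,
                     replace = TRUE)
  tmpl_len <- pmin(tmpl_len, true_end)  # cannot start before position 1
  n_copies <- 1L + stats::rgeom(n, 1 / config$dup_mean)

  base_pool <- c("A", "C", "G", "T")
  tails <- character(n)
  barcodes <- character(n)
  mol_seq <- character(n)
  tmpl_start <- true_end - tmpl_len + 1L
  for (i in seq_len(n)) {
    tl <- tail_len[i]
    tail <- if (tl > 0L) {
      bases <- ifelse(stats::runif(tl) < config$tail_nona,
                      sample(c("C", "G", "T"), tl, replace = TRUE),
                      "A")
      paste(bases, collapse = "")
    } else ""
    tails[i] <- tail
    barcodes[i] <- .random_bases(config$barcode_len)
    templated <- substr(model$sequence, tmpl_start[i], true_end[i])
    core <- paste0(templated, tail, model$linker, barcodes[i])
    filler_n <- config$read_len - nchar(core)
    read <- if (filler_n > 0L) paste0(core, .random_bases(filler_n)) else
      substr(core, 1L, config$read_len)
    if (!config$errors_per_copy)
      read <- .apply_substitutions(read, config$error_rate)
    mol_seq[i] <- read
  }

  total_reads <- sum(n_copies)
  read_mol <- rep.int(seq_len(n), n_copies)
  copy_idx <- sequence(n_copies)
  seqs <- mol_seq[read_mol]
  if (config$errors_per_copy && config$error_rate > 0)
    seqs <- vapply(seqs, .apply_substitutions, character(1L),
                   rate = config$error_rate, USE.NAMES = FALSE)
  ids <- sprintf("m%06d_c%d", read_mol, copy_idx)

  list(
    reads = data.frame(id = ids, molecule = read_mol, seq = seqs,
                       stringsAsFactors = FALSE),
    truth = data.frame(molecule = seq_len(n), true_end = true_end,
                       tail = tails, barcode = barcodes,
                       n_copies = n_copies, templated_start = tmpl_start,
                       stringsAsFactors = FALSE))
}

#' Write simulated reads as FASTQ
#'
#' Qualities are constant high quality ('I', Phred 40): the end-mapping
#' pipeline is match-based and never consults qualities.
#'
#' @param reads data.frame with `id` and `seq` columns (as returned in
#'   `simulate_library()$reads`).
#' @param path Output FASTQ path (a `.gz` suffix gzip-compresses).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a data.frame of id and sequence
#'
#' @param path FASTQ path (gzipped accepted).
#' @return data.frame with `id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, seq = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write / read a simulation truth table as TSV
#' @param truth Truth data.frame from [simulate_library()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(molecule = "integer",
                                   true_end = "integer",
                                   tail = "character",
                                   barcode = "character",
                                   n_copies = "integer",
                                   templated_start = "integer"),
                    stringsAsFactors = FALSE)
}
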