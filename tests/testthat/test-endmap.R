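test_that("error-free templated inserts are assigned at their true end", {
  ref <- fixture_ref()
  for (end in c(366L, 420L, 451L, 460L, 641L)) {
    call <- assign_end(ref_segment(ref, end, 40L), ref)
    expect_equal(call$status, "assigned")
    expect_equal(call$end_coord, end)
    expect_equal(call$ntna, "")
    expect_equal(call$tail_trim, 0L)
    expect_equal(call$anchor_mismatches, 0L)
  }
})

test_that("oligo-A tails are trimmed as NTNA (frozen oracle values)", {
  ref <- fixture_ref()
  # at 455 the reference continues TGGGA...: no tail base can be absorbed
  call <- assign_end(paste0(ref_segment(ref, 455L, 40L), "AAAAA"), ref)
  expect_equal(call$status, "assigned")
  expect_equal(call$end_coord, 455L)
  expect_equal(call$ntna, "AAAAA")
  expect_equal(call$tail_trim, 5L)
  # at 451 the reference continues A...: one tail base is absorbed as
  # templated -- inherent to taking the most 3' compatible coordinate
  call <- assign_end(paste0(ref_segment(ref, 451L, 40L), "AAAAA"), ref)
  expect_equal(call$end_coord, 452L)
  expect_equal(call$ntna, "AAAA")
})

test_that("three substitutions in the anchor body reject the read", {
  ref <- fixture_ref()
  ins <- ref_segment(ref, 451L, 20L)          # anchor only, tmax = 0
  flip <- function(s, i) {
    b <- substr(s, i, i)
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), b)[1]
    s
  }
  two <- flip(flip(ins, 3), 8)
  three <- flip(two, 13)
  expect_equal(assign_end(two, ref)$status, "assigned")
  expect_equal(assign_end(two, ref)$anchor_mismatches, 2L)
  got <- assign_end(three, ref)
  expect_equal(got$status, oracle_assign_end(three, ref)$status)
  expect_equal(got$status, "no_anchor")
})

test_that("a mismatch in the two most-3' anchor bases is not tolerated by default", {
  ref <- fixture_ref()
  ins <- ref_segment(ref, 455L, 25L)
  b <- substr(ins, 25, 25)
  substr(ins, 25, 25) <- setdiff(c("A", "C", "G", "T"), b)[1]
  got <- assign_end(ins, ref)
  # default: terminal base must match, so the mismatched base is trimmed
  # as a 1-nt NTNA and the end steps back
  expect_equal(got$tail_trim, 1L)
  expect_equal(got$end_coord, 454L)
  # alternative reading: terminal mismatches uncounted
  free <- assign_end(ins, ref, terminal_free = TRUE)
  expect_equal(free$end_coord, 455L)
  expect_equal(free$tail_trim, 0L)
})

test_that("inserts shorter than the anchor fail the minimum-match filter", {
  ref <- fixture_ref()
  expect_equal(assign_end(ref_segment(ref, 451L, 19L), ref)$status,
               "short_match")
  expect_equal(assign_end("", ref)$status, "short_match")
  expect_equal(assign_end(ref_segment(ref, 451L, 20L), ref)$end_coord,
               451L)
})

test_that("reads ending beyond the window are reported out_of_window", {
  ref <- fixture_ref()
  got <- assign_end(ref_segment(ref, 660L, 40L), ref)
  expect_equal(got$status, "out_of_window")
  expect_true(is.na(got$end_coord))
  below <- assign_end(ref_segment(ref, 300L, 40L), ref)
  expect_equal(below$status, "out_of_window")
})

test_that("fast mapper is equivalent to the naive oracle on random inserts", {
  ref <- fixture_ref()
  lib <- simulate_library(ref, fixture_config(500, seed = 77,
                                              error_rate = 0.01))
  pre <- preprocess_reads(lib$reads, ref)
  ins <- pre$insert[!is.na(pre$insert)]
  ins <- ins[seq_len(min(length(ins), 600L))]
  fast <- assign_ends(ins, ref)
  slow <- do.call(rbind, lapply(ins, oracle_assign_end, model = ref))
  rownames(slow) <- NULL
  expect_equal(fast, slow)
})

test_that("raising max_mismatch never loses assigned reads", {
  ref <- fixture_ref()
  lib <- simulate_library(ref, fixture_config(300, seed = 23,
                                              error_rate = 0.02))
  pre <- preprocess_reads(lib$reads, ref)
  ins <- pre$insert[!is.na(pre$insert)]
  assigned <- function(mm)
    which(assign_ends(ins, ref, max_mismatch = mm)$status == "assigned")
  a0 <- assigned(0L); a2 <- assigned(2L); a4 <- assigned(4L)
  expect_true(all(a0 %in% a2))
  expect_true(all(a2 %in% a4))
})

test_that("assigned ends dominate true ends on noise-free libraries", {
  ref <- fixture_ref()
  lib <- simulate_library(ref, fixture_config(400, seed = 31,
                                              error_rate = 0))
  pre <- preprocess_reads(lib$reads, ref, dedup = FALSE)
  calls <- assign_ends(pre$insert, ref)
  ok <- calls$status == "assigned"
  true_end <- lib$truth$true_end[lib$reads$molecule]
  tails <- lib$truth$tail[lib$reads$molecule]
  expect_true(all(calls$end_coord[ok] >= true_end[ok]))
  # equality whenever no tail base can be absorbed into the template
  exp <- mapply(expected_end, true_end, tails, MoreArgs = list(model = ref))
  expect_equal(calls$end_coord[ok], exp[ok])
  # out_of_window or no match only where reconciliation predicts it
  expect_equal(which(calls$status == "out_of_window"), which(is.na(exp)))
})

test_that("max_tail caps the trimmed tail length", {
  ref <- fixture_ref()
  ins <- paste0(ref_segment(ref, 455L, 40L), "AAAAA")
  expect_equal(assign_end(ins, ref, max_tail = 2L)$status, "no_anchor")
  expect_equal(assign_end(ins, ref, max_tail = 5L)$end_coord, 455L)
})

test_that("tail composition counts bases and flags pure oligo-A", {
  comp <- tail_composition(c("AAAAA", "", "AAT"))
  expect_equal(comp$A, c(5L, 0L, 2L))
  expect_equal(comp$T, c(0L, 0L, 1L))
  expect_equal(comp$pure_A, c(TRUE, FALSE, FALSE))
  expect_error(tail_composition(NA_character_), "assigned")
})
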