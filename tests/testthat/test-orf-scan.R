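test_that("frame map classifies every column and cycles codon phase", {
  aln <- codon_alignment(c(ref = "ATGGAACCCTTT", other = "ATGGAACCCTTT"),
                         "ref")
  fm <- build_frame_map(aln)
  expect_false(any(fm$inserted))
  expect_equal(fm$codon_index, rep(1:4, each = 3))
  expect_equal(fm$codon_pos, rep(1:3, 4))

  # frame anchor shifts the phase of column 1
  aln2 <- codon_alignment(c(ref = "TGGAACCC", other = "TGGAACCC"), "ref",
                          frame_offset = 2)
  fm2 <- build_frame_map(aln2)
  expect_equal(fm2$codon_pos[1:4], c(2L, 3L, 1L, 2L))

  # reference gaps are flagged inserted; others carry reference positions
  aln3 <- codon_alignment(c(ref = "ATG--AAA", other = "ATGCCAAA"), "ref")
  fm3 <- build_frame_map(aln3)
  expect_equal(which(fm3$inserted), 4:5)
  expect_equal(sum(!fm3$inserted), 6L)
})

test_that("fixture frame map flags exactly the planted insertion columns", {
  sim <- get_fixture(1)
  fm <- build_frame_map(sim$alignment)
  expect_equal(which(fm$inserted), c(188:191, 297:298))
  expect_equal(sum(!fm$inserted), 447L)
})

test_that("indel detection reports only frame-shifting runs", {
  sim <- get_fixture(1)
  fm <- build_frame_map(sim$alignment)
  dels <- detect_indels(sim$alignment, fm, "n_elephant_seal")
  del <- dels[vapply(dels, `[[`, character(1), "kind") ==
                "frameshift_deletion"][[1]]
  expect_equal(del$start_col, 61L)
  expect_equal(del$length_bp, 1L)

  # in-frame deletion is not inactivating
  aln <- codon_alignment(c(ref = "ATGGAACCCTTT", tx = "ATG---CCCTTT"), "ref")
  expect_length(detect_indels(aln, build_frame_map(aln), "tx"), 0L)

  # identical to reference: nothing
  expect_length(detect_indels(sim$alignment, fm, "domestic_dog"), 0L)
})

test_that("nonsense detection works in the reference frame", {
  sim <- get_fixture(1)
  fm <- build_frame_map(sim$alignment)
  aus <- detect_nonsense(sim$alignment, fm, "australian_sea_lion")
  expect_equal(vapply(aus, `[[`, integer(1), "start_col"), 61L)
  # detected despite the taxon's own upstream 1-bp deletion
  ele <- detect_nonsense(sim$alignment, fm, "n_elephant_seal")
  expect_equal(vapply(ele, `[[`, integer(1), "start_col"), 248L)
  expect_length(detect_nonsense(sim$alignment, fm, "domestic_dog"), 0L)
})

test_that("introduced stops are located in the shifted frame", {
  # nonsense: the stop is the mutation itself
  sim <- get_fixture(1)
  fm <- build_frame_map(sim$alignment)
  scan <- classify_orf(sim$alignment)
  non61 <- scan$mutations[[which(vapply(scan$mutations, mutation_id,
                                        character(1)) ==
                                   "nonsense_substitution_61_63")]]
  expect_equal(locate_introduced_stop(sim$alignment, fm,
                                      "australian_sea_lion", non61), 61L)

  # constructed 1-bp insertion whose shifted frame starts with TAA
  aln <- codon_alignment(c(ref = "ATG-AACCC", tx = "ATGTAACCC"), "ref")
  fm2 <- build_frame_map(aln)
  ins <- detect_indels(aln, fm2, "tx")[[1]]
  expect_equal(ins$kind, "frameshift_insertion")
  expect_equal(locate_introduced_stop(aln, fm2, "tx", ins), 4L)

  # mutation/taxon mismatch
  expect_error(locate_introduced_stop(aln, fm2, "ref", ins),
               class = "pseudophy_usage_error")
})

test_that("compensated frameshifts leave no attributable stop", {
  # alphabet {A,C} downstream: no stop codon can arise in any frame
  ref <- paste0("ATG", "CAA", "ACA", "-", "CCA", "AAC", "ACC")
  tx <- paste0("ATG", "CAA", "AC-", "A", "CCA", "AAC", "ACC")
  aln <- codon_alignment(c(ref = ref, tx = tx), "ref")
  fm <- build_frame_map(aln)
  muts <- detect_indels(aln, fm, "tx")
  expect_length(muts, 2L)   # a -1 deletion and a +1 insertion
  for (m in muts) {
    expect_true(is.na(locate_introduced_stop(aln, fm, "tx", m)))
  }
  # and the reference frame downstream of the pair is restored
  expect_length(detect_nonsense(aln, fm, "tx"), 0L)
})

test_that("classify_orf merges shared events and is deterministic", {
  sim <- get_fixture(1)
  scan1 <- classify_orf(sim$alignment)
  scan2 <- classify_orf(sim$alignment)
  expect_identical(scan1, scan2)
  expect_length(scan1$mutations, 5L)
  groups <- fixture_groups()
  ins <- scan1$mutations[[which(vapply(scan1$mutations, mutation_id,
                                       character(1)) ==
                                  "frameshift_insertion_188_191")]]
  expect_setequal(ins$taxa, groups$phocids)

  # all-identical alignment: everything intact
  aln <- codon_alignment(c(a = "ATGGAACCC", b = "ATGGAACCC",
                           c = "ATGGAACCC"), "a")
  expect_true(all(classify_orf(aln)$orf_status$status == "intact"))
})

test_that("planted events are recovered exactly across seeds", {
  for (seed in 1:20) {
    sim <- simulate_pinniped_fixture(seed = seed)
    scan <- classify_orf(sim$alignment)
    got <- lapply(scan$mutations, function(m)
      list(kind = m$kind, start = m$start_col, end = m$end_col,
           taxa = m$taxa))
    want <- lapply(sim$truth, function(m)
      list(kind = m$kind, start = m$start_col, end = m$end_col,
           taxa = m$taxa))
    ord <- function(x) x[order(vapply(x, function(e)
      paste(e$kind, e$start), character(1)))]
    expect_identical(ord(got), ord(want), info = paste("seed", seed))
    # every planted event introduces a locatable premature stop
    expect_false(any(is.na(vapply(scan$mutations, `[[`, integer(1),
                                  "introduced_stop_col"))),
                 info = paste("seed", seed))
    # the reference is always intact, and the intact/disrupted split holds
    st <- scan$orf_status
    expect_equal(st$status[st$taxon == "domestic_dog"], "intact")
    expect_equal(sum(st$status == "disrupted"), 7L)
  }
})
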