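test_that("FASTA alignments read with normalisation and validation", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref", "atggaaccc", ">other", "atgGu-ccN"), path)
  aln <- read_fasta_alignment(path, "ref")
  expect_s3_class(aln, "codon_alignment")
  expect_equal(aln$n_columns, 9L)
  expect_equal(paste(aln$seqs["other", ], collapse = ""), "ATGGT-CCN")

  # single record: reference is itself
  path1 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">only", "ATG"), path1)
  solo <- read_fasta_alignment(path1, "only")
  expect_equal(solo$n_columns, 3L)
  expect_equal(solo$taxa, "only")

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGATGATG", ">b", "ATGATGAT"), ragged)
  expect_error(read_fasta_alignment(ragged, "a"),
               class = "pseudophy_alignment_error")
  expect_error(read_fasta_alignment(path, "nope"),
               class = "pseudophy_lookup_error")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGR", ">b", "ATGC"), bad)
  expect_error(read_fasta_alignment(bad, "a"),
               class = "pseudophy_alphabet_error")

  nref <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGN", ">b", "ATGC"), nref)
  expect_error(read_fasta_alignment(nref, "a"),
               class = "pseudophy_alignment_error")
})

test_that("FASTA round-trips are lossless for random alignments", {
  withr::local_seed(42)
  for (i in 1:10) {
    n_tax <- sample(2:6, 1)
    n_col <- 3 * sample(2:10, 1)
    mat <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n_tax * n_col,
                         replace = TRUE, prob = c(rep(0.22, 4), 0.08, 0.04)),
                  n_tax, n_col, dimnames = list(paste0("tx", 1:n_tax), NULL))
    mat[1, mat[1, ] == "N"] <- "A"   # reference carries no N
    aln <- codon_alignment(mat, "tx1")
    path <- withr::local_tempfile(fileext = ".fasta")
    write_fasta_alignment(aln, path)
    back <- read_fasta_alignment(path, "tx1")
    expect_identical(back$seqs, aln$seqs)
    expect_identical(back$taxa, aln$taxa)
  }
})

test_that("Newick reading attaches lengths and supports, and validates", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:0.1,B:0.2);", path)
  tr <- read_newick(path)
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(sort(tr$edge.length), c(0.1, 0.2))

  writeLines("((A:1,B:1)95:1,C:1);", path)
  tr2 <- read_newick(path)
  expect_true("95" %in% tr2$node.label)

  writeLines("((A:1,B:1:1,C:1);", path)
  expect_error(read_newick(path), class = "pseudophy_parse_error")

  writeLines("(A:-0.1,B:0.2);", path)
  expect_error(read_newick(path), class = "pseudophy_validation_error")
})

test_that("Newick round-trips preserve random 8-leaf trees", {
  withr::local_seed(7)
  for (i in 1:20) {
    tr <- random_phylo(8)
    tr$edge.length <- round(tr$edge.length, 6)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    back <- read_newick(path)
    expect_identical(tree_bipartitions(back), tree_bipartitions(tr))
    m1 <- setNames(tr$edge.length, tr$edge[, 2])
    m2 <- setNames(back$edge.length, back$edge[, 2])
    # same leaf numbering is not guaranteed; compare sorted multisets and
    # per-tip pendant lengths
    expect_equal(sort(unname(m1)), sort(unname(m2)), tolerance = 1e-9)
    p1 <- tr$edge.length[match(seq_len(8), tr$edge[, 2])]
    names(p1) <- tr$tip.label
    p2 <- back$edge.length[match(seq_len(8), back$edge[, 2])]
    names(p2) <- back$tip.label
    expect_equal(p1[sort(names(p1))], p2[sort(names(p1))], tolerance = 1e-9)
  }
})

test_that("scan reports round-trip through write_report/read_report", {
  withr::local_seed(11)
  taxa <- paste0("sp", 1:5)
  for (i in 1:10) {
    n_mut <- sample(0:3, 1)
    muts <- lapply(seq_len(n_mut), function(j) {
      kind <- sample(c("frameshift_insertion", "frameshift_deletion",
                       "nonsense_substitution"), 1)
      start <- sample(1:100, 1) * 3 + 1
      len <- if (kind == "nonsense_substitution") 3L else
        sample(c(1L, 2L, 4L), 1)
      inactivating_mutation(kind, start, start + len - 1L, len,
                            sample(taxa, sample(1:3, 1)),
                            bases = paste(sample(c("A", "C", "G", "T"), len,
                                                 replace = TRUE),
                                          collapse = ""),
                            introduced_stop_col = sample(c(NA, 150L), 1))
    })
    orf <- data.frame(taxon = taxa,
                      status = sample(c("intact", "disrupted"), 5,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_report(muts, orf, path)
    back <- read_report(path)
    expect_equal(length(back$mutations), n_mut)
    for (j in seq_len(n_mut)) {
      got <- back$mutations[[j]]
      for (f in c("kind", "start_col", "end_col", "length_bp", "taxa",
                  "bases", "introduced_stop_col")) {
        expect_identical(got[[f]], muts[[j]][[f]])
      }
    }
    expect_equal(back$orf_status$taxon, orf$taxon)
    expect_equal(back$orf_status$status, orf$status)
  }
})

test_that("empty mutation list still yields a valid report", {
  orf <- data.frame(taxon = c("a", "b"), status = c("intact", "intact"),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(list(), orf, path)
  back <- read_report(path)
  expect_length(back$mutations, 0L)
  expect_equal(back$orf_status$status, c("intact", "intact"))
})

test_that("report/column coordinates invert over the reference mapping", {
  sim <- get_fixture(1)
  fm <- build_frame_map(sim$alignment)
  cols <- which(!fm$inserted)
  expect_equal(ref_pos_to_column(fm, column_to_ref_pos(fm, cols)), cols)
  expect_true(all(is.na(column_to_ref_pos(fm, which(fm$inserted)))))
})
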