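#' Codon alignment objects
#'
#' A `codon_alignment` is the shared data model of the pipeline: a gapped DNA
#' matrix over the alphabet `A,C,G,T,N,-` with 1-based column coordinates, a
#' designated reference taxon whose open reading frame is taken as intact, and
#' a frame anchor giving the codon position (1, 2 or 3) of the first non-gap
#' reference column.
#'
#' Invariants enforced by the constructor: all rows have identical length,
#' taxa labels are unique, the reference taxon is present, and the reference
#' row contains no `N`.
#'
#' @param seqs Named character vector of aligned sequences (one string per
#'   taxon), or a character matrix of single characters with taxa as rownames.
#' @param reference_taxon Label of the intact-ORF reference taxon.
#' @param frame_offset Codon position (1, 2 or 3) of the first non-gap
#'   reference column. Defaults to 1.
#' @return An object of class `codon_alignment` with fields `taxa`, `seqs`
#'   (character matrix, taxa x columns), `n_columns`, `reference_taxon`,
#'   `frame_offset`.
#' @examples
#' aln <- codon_alignment(c(ref = "ATGAAA", other = "ATGTAA"), "ref")
#' aln$n_columns
#' @export
codon_alignment <- function(seqs, reference_taxon, frame_offset = 1L) {
  if (is.matrix(seqs)) {
    mat <- seqs
    taxa <- rownames(mat)
  } else {
    taxa <- names(seqs)
    if (is.null(taxa)) {
      stop_pseudophy("usage_error", "sequences must be named by taxon")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop_pseudophy("alignment_error", sprintf(
        "aligned rows have unequal lengths (%s)",
        paste(unique(lens), collapse = ", ")))
    }
    mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
    rownames(mat) <- taxa
  }
  if (is.null(taxa) || anyNA(taxa) || any(taxa == "")) {
    stop_pseudophy("usage_error", "all taxa must be labelled")
  }
  if (anyDuplicated(taxa)) {
    stop_pseudophy("alignment_error", "duplicate taxon labels")
  }
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0L) {
    stop_pseudophy("alphabet_error", sprintf(
      "illegal character(s) in alignment: %s", paste(bad, collapse = " ")))
  }
  if (!reference_taxon %in% taxa) {
    stop_pseudophy("lookup_error", sprintf(
      "reference taxon '%s' not found in alignment", reference_taxon))
  }
  if (any(mat[reference_taxon, ] == "N")) {
    stop_pseudophy("alignment_error", "reference row must contain no N")
  }
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 1:3) {
    stop_pseudophy("usage_error", "frame_offset must be 1, 2 or 3")
  }
  structure(
    list(taxa = taxa, seqs = mat, n_columns = ncol(mat),
         reference_taxon = reference_taxon, frame_offset = frame_offset),
    class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa x %d columns (reference: %s, frame offset %d)\n",
              length(x$taxa), x$n_columns, x$reference_taxon, x$frame_offset))
  invisible(x)
}

#' Alignment rows as strings
#'
#' @param alignment A [codon_alignment()].
#' @return Named character vector, one aligned string per taxon.
#' @export
alignment_strings <- function(alignment) {
  setNames(apply(alignment$seqs, 1L, paste, collapse = ""), alignment$taxa)
}

#' Read a gapped multi-FASTA codon alignment
#'
#' Records are uppercased and `U` is mapped to `T`. All records must have the
#' same aligned length. `N` is allowed in non-reference rows only; IUPAC
#' ambiguity codes beyond `N` are rejected.
#'
#' @inheritParams codon_alignment
#' @param path Path to a FASTA file.
#' @return A [codon_alignment()].
#' @export
read_fasta_alignment <- function(path, reference_taxon, frame_offset = 1L) {
  if (!file.exists(path)) {
    stop_pseudophy("io_error", sprintf("file not found: %s", path))
  }
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  seqs <- setNames(vapply(recs, as.character, character(1)), names(recs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop_pseudophy("alignment_error", sprintf(
      "FASTA records are not aligned: lengths %s",
      paste(unique(lens), collapse = ", ")))
  }
  codon_alignment(seqs, reference_taxon, frame_offset)
}

#' Write a codon alignment to FASTA
#'
#' @param alignment A [codon_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  seqinr::write.fasta(
    sequences = lapply(seq_along(alignment$taxa),
                       function(i) alignment$seqs[i, ]),
    names = alignment$taxa, file.out = path, nbchar = 60)
  invisible(path)
}

#' Inactivating mutation records
#'
#' An `inactivating_mutation` is a typed, positioned, taxon-attributed event:
#' a frameshift insertion, frameshift deletion, or nonsense substitution, with
#' 1-based inclusive alignment-column bounds, the set of taxa sharing the
#' identical mutation, the inserted/deleted/substituted bases, and (when
#' located) the alignment column of the first base of the earliest premature
#' stop codon the mutation introduces.
#'
#' @param kind One of `"frameshift_insertion"`, `"frameshift_deletion"`,
#'   `"nonsense_substitution"`.
#' @param start_col,end_col 1-based inclusive alignment columns.
#' @param length_bp Number of bases inserted/deleted, or 3 for a nonsense
#'   substitution.
#' @param taxa Character vector of taxa carrying the identical mutation.
#' @param bases The inserted bases, deleted reference bases, or the stop codon
#'   created by a nonsense substitution.
#' @param introduced_stop_col Alignment column of the first base of the
#'   earliest premature stop attributable to the mutation, or `NA`.
#' @return An object of class `inactivating_mutation`.
#' @export
inactivating_mutation <- function(kind, start_col, end_col, length_bp, taxa,
                                  bases = "", introduced_stop_col = NA_integer_) {
  kinds <- c("frameshift_insertion", "frameshift_deletion",
             "nonsense_substitution")
  if (!kind %in% kinds) {
    stop_pseudophy("usage_error", sprintf("unknown mutation kind '%s'", kind))
  }
  length_bp <- as.integer(length_bp)
  if (kind == "nonsense_substitution") {
    if (length_bp != 3L) {
      stop_pseudophy("usage_error", "nonsense substitutions span one codon (3 bp)")
    }
  } else if (length_bp %% 3L == 0L) {
    stop_pseudophy("usage_error",
                   "frameshift indel length must not be a multiple of 3")
  }
  if (length(taxa) == 0L) {
    stop_pseudophy("usage_error", "mutation must affect at least one taxon")
  }
  structure(
    list(kind = kind, start_col = as.integer(start_col),
         end_col = as.integer(end_col), length_bp = length_bp,
         taxa = sort(unique(taxa)), bases = toupper(bases),
         introduced_stop_col = as.integer(introduced_stop_col)),
    class = "inactivating_mutation")
}

#' @export
print.inactivating_mutation <- function(x, ...) {
  cat(sprintf("%s %d-%d (%d bp) in %s; stop at %s\n",
              x$kind, x$start_col, x$end_col, x$length_bp,
              paste(x$taxa, collapse = ","),
              ifelse(is.na(x$introduced_stop_col), "none",
                     x$introduced_stop_col)))
  invisible(x)
}

mutation_id <- function(m) paste(m$kind, m$start_col, m$end_col, sep = "_")

#' Tabulate mutations
#'
#' @param mutations List of [inactivating_mutation()] records.
#' @return A data frame with one row per mutation.
#' @export
mutation_table <- function(mutations) {
  if (length(mutations) == 0L) {
    return(data.frame(event = character(), kind = character(),
                      start_col = integer(), end_col = integer(),
                      length_bp = integer(), taxa = character(),
                      bases = character(), introduced_stop_col = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    event = vapply(mutations, mutation_id, character(1)),
    kind = vapply(mutations, `[[`, character(1), "kind"),
    start_col = vapply(mutations, `[[`, integer(1), "start_col"),
    end_col = vapply(mutations, `[[`, integer(1), "end_col"),
    length_bp = vapply(mutations, `[[`, integer(1), "length_bp"),
    taxa = vapply(mutations, function(m) paste(m$taxa, collapse = ","),
                  character(1)),
    bases = vapply(mutations, `[[`, character(1), "bases"),
    introduced_stop_col = vapply(mutations, `[[`, integer(1),
                                 "introduced_stop_col"),
    stringsAsFactors = FALSE)
}

#' Write / read the tab-delimited scan report
#'
#' The report holds one `mutation` row per detected mutation (kind, columns,
#' length, carrier taxa, bases, introduced stop column and -- when placements
#' are supplied -- the assigned branch) and one `taxon` row per taxon with its
#' ORF status (`intact` or `disrupted`). `read_report()` reverses
#' `write_report()` losslessly.
#'
#' @param mutations List of [inactivating_mutation()] records.
#' @param orf_statuses Data frame with columns `taxon` and `status`, as
#'   returned by [classify_orf()].
#' @param path Output (input) path.
#' @param placements Optional data frame from [place_events()]; its `branch`
#'   label is merged into the matching mutation rows.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   a list with `mutations` and `orf_status` (and the `branch` column
#'   populated when it was written).
#' @export
write_report <- function(mutations, orf_statuses, path, placements = NULL) {
  mt <- mutation_table(mutations)
  mt$branch <- rep(NA_character_, nrow(mt))
  if (!is.null(placements) && nrow(mt) > 0L) {
    idx <- match(mt$event, placements$event)
    mt$branch <- placements$branch[idx]
  }
  mut_rows <- data.frame(record = rep("mutation", nrow(mt)), mt,
                         taxon = rep(NA_character_, nrow(mt)),
                         status = rep(NA_character_, nrow(mt)),
                         stringsAsFactors = FALSE)
  tax_rows <- data.frame(
    record = "taxon", event = NA, kind = NA, start_col = NA, end_col = NA,
    length_bp = NA, taxa = NA, bases = NA, introduced_stop_col = NA,
    branch = NA, taxon = orf_statuses$taxon, status = orf_statuses$status,
    stringsAsFactors = FALSE)
  out <- rbind(mut_rows, tax_rows)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_pseudophy("io_error", sprintf("cannot write report to '%s'", path))
  })
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    stop_pseudophy("io_error", sprintf("file not found: %s", path))
  }
  tab <- read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE,
                    colClasses = c(
                      record = "character", event = "character",
                      kind = "character", start_col = "integer",
                      end_col = "integer", length_bp = "integer",
                      taxa = "character", bases = "character",
                      introduced_stop_col = "integer", branch = "character",
                      taxon = "character", status = "character"))
  mrows <- tab[tab$record == "mutation", , drop = FALSE]
  mutations <- lapply(seq_len(nrow(mrows)), function(i) {
    r <- mrows[i, ]
    m <- inactivating_mutation(
      r$kind, r$start_col, r$end_col, r$length_bp,
      strsplit(r$taxa, ",", fixed = TRUE)[[1]],
      bases = ifelse(is.na(r$bases), "", r$bases),
      introduced_stop_col = r$introduced_stop_col)
    attr(m, "branch") <- r$branch
    m
  })
  trows <- tab[tab$record == "taxon", c("taxon", "status")]
  rownames(trows) <- NULL
  list(mutations = mutations, orf_status = trows)
}

#' Read / write Newick trees
#'
#' Thin validating wrappers around [ape::read.tree()] and [ape::write.tree()].
#' Branch lengths are required to be non-negative and finite; internal node
#' labels, when present, are kept (they carry bootstrap support percentages in
#' this package's output).
#'
#' @param path File path.
#' @param tree An [ape::phylo] tree.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    stop_pseudophy("io_error", sprintf("file not found: %s", path))
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop_pseudophy("parse_error", sprintf("cannot parse Newick in '%s'", path))
  }
  validate_tree(tree)
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    stop_pseudophy("validation_error", "duplicate leaf labels in tree")
  }
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
      stop_pseudophy("validation_error",
                     "branch lengths must be non-negative and finite")
    }
  }
  invisible(tree)
}
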