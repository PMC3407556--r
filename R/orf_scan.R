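STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Map alignment columns onto the reference reading frame
#'
#' Each alignment column is classified either as part of the reference codon
#' structure (codon index and codon position 1-3, cycling from the alignment's
#' `frame_offset`) or as inserted relative to the reference (the reference row
#' has a gap there). The reference frame defines the "correct" open reading
#' frame against which all taxa are scanned.
#'
#' @param alignment A [codon_alignment()].
#' @return A data frame (class `frame_map`) with columns `column`, `inserted`,
#'   `ref_pos` (1-based position in the ungapped reference, `NA` for inserted
#'   columns), `codon_index` and `codon_pos`.
#' @export
build_frame_map <- function(alignment) {
  ref <- alignment$seqs[alignment$reference_taxon, ]
  inserted <- ref == "-"
  n <- alignment$n_columns
  ref_pos <- rep(NA_integer_, n)
  ref_pos[!inserted] <- seq_len(sum(!inserted))
  # codon phase cycles from frame_offset over successive non-inserted columns
  phase <- rep(NA_integer_, n)
  idx <- rep(NA_integer_, n)
  u <- ref_pos[!inserted]
  phase[!inserted] <- ((u + alignment$frame_offset - 2L) %% 3L) + 1L
  idx[!inserted] <- ((u + alignment$frame_offset - 2L) %/% 3L) + 1L
  fm <- data.frame(column = seq_len(n), inserted = inserted,
                   ref_pos = ref_pos, codon_index = idx, codon_pos = phase)
  class(fm) <- c("frame_map", "data.frame")
  fm
}

#' Convert between alignment columns and reference positions
#'
#' For non-inserted columns these two conversions are mutually inverse.
#'
#' @param frame_map A [build_frame_map()] result.
#' @param column,ref_pos Coordinates to convert (vectorised).
#' @return Integer vector of converted coordinates (`NA` where a column is
#'   inserted relative to the reference).
#' @export
column_to_ref_pos <- function(frame_map, column) {
  frame_map$ref_pos[match(column, frame_map$column)]
}

#' @rdname column_to_ref_pos
#' @export
ref_pos_to_column <- function(frame_map, ref_pos) {
  frame_map$column[match(ref_pos, frame_map$ref_pos)]
}

#' Detect frameshift indels in one taxon
#'
#' Insertions are maximal runs of inserted columns (reference gap) where the
#' taxon has bases; deletions are maximal runs -- contiguous in reference
#' coordinates -- of reference-bearing columns where the taxon has gaps. Only
#' runs whose length is not a multiple of 3 are inactivating and returned;
#' in-frame indels are ignored.
#'
#' @param alignment A [codon_alignment()].
#' @param frame_map Matching [build_frame_map()] result.
#' @param taxon Taxon label to scan.
#' @return List of [inactivating_mutation()] records (possibly empty).
#' @export
detect_indels <- function(alignment, frame_map, taxon) {
  row <- alignment$seqs[taxon, ]
  ref <- alignment$seqs[alignment$reference_taxon, ]
  out <- list()

  ins <- frame_map$inserted & row != "-"
  for (run in run_ranges(ins)) {
    len <- run[2] - run[1] + 1L
    if (len %% 3L != 0L) {
      out[[length(out) + 1L]] <- inactivating_mutation(
        "frameshift_insertion", run[1], run[2], len, taxon,
        bases = paste(row[run[1]:run[2]], collapse = ""))
    }
  }

  # deletions: runs over the non-inserted columns only, so a run stays intact
  # when an unrelated insertion block interrupts it in alignment coordinates
  ref_cols <- which(!frame_map$inserted)
  del <- row[ref_cols] == "-"
  for (run in run_ranges(del)) {
    cols <- ref_cols[run[1]:run[2]]
    len <- length(cols)
    if (len %% 3L != 0L) {
      out[[length(out) + 1L]] <- inactivating_mutation(
        "frameshift_deletion", cols[1], cols[len], len, taxon,
        bases = paste(ref[cols], collapse = ""))
    }
  }
  out
}

# maximal runs of TRUE as list of c(start, end) indices
run_ranges <- function(flag) {
  if (!any(flag)) return(list())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}

#' Detect nonsense substitutions in one taxon
#'
#' Every complete reference-frame codon of the taxon is inspected (inserted
#' columns are skipped; codons containing gaps or `N` in either the taxon or
#' the reference are not called). A nonsense substitution is reported when the
#' taxon codon is a stop (`TAA`, `TAG`, `TGA`) and the reference codon is
#' sense. Detection is deliberately performed in the reference frame even
#' downstream of a frameshift in the same taxon, mirroring how such alignments
#' are annotated against the intact frame.
#'
#' @inheritParams detect_indels
#' @return List of [inactivating_mutation()] records (possibly empty).
#' @export
detect_nonsense <- function(alignment, frame_map, taxon) {
  row <- alignment$seqs[taxon, ]
  ref <- alignment$seqs[alignment$reference_taxon, ]
  out <- list()
  for (cod in split(which(!frame_map$inserted),
                    frame_map$codon_index[!frame_map$inserted])) {
    if (length(cod) != 3L) next                      # truncated edge codon
    if (any(frame_map$codon_pos[cod] != 1:3)) next   # partial leading codon
    tx <- row[cod]
    if (any(tx %in% c("-", "N"))) next
    rf <- ref[cod]
    tx_codon <- paste(tx, collapse = "")
    if (tx_codon %in% STOP_CODONS &&
        !(paste(rf, collapse = "") %in% STOP_CODONS)) {
      out[[length(out) + 1L]] <- inactivating_mutation(
        "nonsense_substitution", cod[1], cod[3], 3L, taxon, bases = tx_codon)
    }
  }
  out
}

#' Locate the premature stop codon a mutation introduces
#'
#' For a nonsense substitution the answer is its own start column. For a
#' frameshift, the taxon's own ungapped sequence is translated through the
#' mutation in the shifted frame (the taxon's other deletions shift the frame
#' as well; other taxa's insertion columns are skipped) and the alignment
#' column of the first base of the first stop codon at or beyond the mutation
#' start is returned, or `NA` if no complete stop occurs before the end of the
#' segment (a stop truncated by the segment edge is not called).
#'
#' @inheritParams detect_indels
#' @param mutation An [inactivating_mutation()] affecting `taxon`.
#' @return Alignment column (integer) or `NA_integer_`.
#' @export
locate_introduced_stop <- function(alignment, frame_map, taxon, mutation) {
  if (!taxon %in% mutation$taxa) {
    stop_pseudophy("usage_error", sprintf(
      "mutation %s does not affect taxon '%s'", mutation_id(mutation), taxon))
  }
  if (mutation$kind == "nonsense_substitution") {
    return(mutation$start_col)
  }
  row <- alignment$seqs[taxon, ]
  # the taxon's own ungapped sequence: every base it actually carries,
  # including its own inserted blocks (its deletions shift the frame too)
  keep <- which(row != "-")
  if (length(keep) < 3L) return(NA_integer_)
  # anchor translation at the first readable column on codon position 1
  first <- which(!frame_map$inserted[keep] &
                   frame_map$codon_pos[keep] == 1L)[1]
  if (is.na(first)) return(NA_integer_)
  keep <- keep[first:length(keep)]
  n_cod <- length(keep) %/% 3L
  for (i in seq_len(n_cod)) {
    cols <- keep[(3L * i - 2L):(3L * i)]
    if (cols[1] < mutation$start_col) next
    codon <- paste(row[cols], collapse = "")
    if (codon %in% STOP_CODONS) return(cols[1])
  }
  NA_integer_
}

#' Classify every taxon's open reading frame
#'
#' Runs [detect_indels()] and [detect_nonsense()] for each taxon, locates the
#' premature stop of every mutation, and merges identical mutations across
#' taxa (same kind, same columns, same inserted/deleted/substituted bases)
#' into shared records -- the merged record's `introduced_stop_col` is the
#' earliest located stop over its carriers. A taxon is `disrupted` if and only
#' if at least one mutation affects it; the reference taxon is intact by
#' construction.
#'
#' @param alignment A [codon_alignment()].
#' @return List with `mutations` (merged [inactivating_mutation()] records,
#'   ordered by start column, kind, taxa) and `orf_status` (data frame with
#'   `taxon`, `status`, `n_mutations`).
#' @examples
#' sim <- simulate_pinniped_fixture(seed = 1)
#' scan <- classify_orf(sim$alignment)
#' table(scan$orf_status$status)
#' @export
classify_orf <- function(alignment) {
  fm <- build_frame_map(alignment)
  per_taxon <- list()
  for (taxon in alignment$taxa) {
    muts <- c(detect_indels(alignment, fm, taxon),
              detect_nonsense(alignment, fm, taxon))
    muts <- lapply(muts, function(m) {
      m$introduced_stop_col <- locate_introduced_stop(alignment, fm, taxon, m)
      m
    })
    per_taxon[[taxon]] <- muts
  }
  flat <- unlist(per_taxon, recursive = FALSE, use.names = FALSE)
  merged <- list()
  if (length(flat) > 0L) {
    keys <- vapply(flat, function(m)
      paste(m$kind, m$start_col, m$end_col, m$bases, sep = "|"), character(1))
    for (k in unique(keys)) {
      grp <- flat[keys == k]
      m <- grp[[1]]
      m$taxa <- sort(unique(unlist(lapply(grp, `[[`, "taxa"))))
      stops <- vapply(grp, `[[`, integer(1), "introduced_stop_col")
      m$introduced_stop_col <- if (all(is.na(stops))) NA_integer_ else
        min(stops, na.rm = TRUE)
      merged[[length(merged) + 1L]] <- m
    }
    ord <- order(vapply(merged, `[[`, integer(1), "start_col"),
                 vapply(merged, `[[`, character(1), "kind"),
                 vapply(merged, function(m) paste(m$taxa, collapse = ","),
                        character(1)))
    merged <- merged[ord]
  }
  n_mut <- vapply(alignment$taxa, function(tx)
    sum(vapply(merged, function(m) tx %in% m$taxa, logical(1))), integer(1))
  orf <- data.frame(taxon = alignment$taxa,
                    status = ifelse(n_mut > 0L, "disrupted", "intact"),
                    n_mutations = unname(n_mut), stringsAsFactors = FALSE,
                    row.names = NULL)
  list(mutations = merged, orf_status = orf)
}
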