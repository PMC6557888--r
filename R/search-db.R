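# Target + decoy search database: FASTA input, sequence deduplication,
# reversed decoys, in-silico (semi-)tryptic digestion and monoisotopic
# peptide masses.

#' Read a protein FASTA file into a data frame
#'
#' @param path Path to a protein FASTA file.
#' @return A data.frame with columns `accession`, `description`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA: ", path, call. = FALSE)
  header <- names(aa)
  acc <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  data.frame(accession = acc, description = desc,
             sequence = as.character(aa), row.names = NULL)
}

#' Write protein records to FASTA
#'
#' @param records A data.frame with at least `accession` and `sequence`
#'   columns; an optional `description` column is appended to the header.
#' @param path Output path.
#' @export
write_protein_fasta <- function(records, path) {
  stopifnot(all(c("accession", "sequence") %in% names(records)))
  header <- records$accession
  if (!is.null(records$description)) {
    has_desc <- nzchar(records$description)
    header[has_desc] <- paste(header[has_desc], records$description[has_desc])
  }
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- header
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Assemble a target + decoy search database
#'
#' Builds the protein collection used by the peptide-spectrum-match search.
#' Target sequences are deduplicated (a sequence present under several
#' accessions is kept once, listing all accessions); contaminant entries
#' (e.g. trypsin, keratins) are appended as targets flagged
#' `is_contaminant`; one decoy is generated per target or contaminant
#' sequence by reversing it, under the reserved accession prefix `"REV_"`.
#'
#' @param targets Target proteins: a FASTA path or a data.frame as returned
#'   by [read_protein_fasta()].
#' @param contaminants Optional contaminant proteins, same formats.
#' @return An object of class `search_db`: a list with `records`
#'   (data.frame with `accession`, `description`, `sequence`, `is_decoy`,
#'   `is_contaminant`) and counts `n_target`, `n_decoy`.
#' @export
build_database <- function(targets, contaminants = NULL) {
  as_records <- function(x) {
    if (is.character(x) && length(x) == 1) x <- read_protein_fasta(x)
    stopifnot(is.data.frame(x),
              all(c("accession", "sequence") %in% names(x)))
    if (is.null(x$description)) x$description <- ""
    for (s in x$sequence) check_residues(s, "protein sequence")
    x
  }
  tg <- as_records(targets)
  if (nrow(tg) == 0) stop("no target sequences", call. = FALSE)
  # Deduplicate identical sequences, concatenating accessions.
  grp <- split(seq_len(nrow(tg)), tg$sequence)
  keep <- vapply(grp, `[`, integer(1), 1)
  dedup <- tg[sort(keep), , drop = FALSE]
  acc_of <- vapply(dedup$sequence, function(s)
    paste(tg$accession[grp[[s]]], collapse = ";"), character(1))
  dedup$accession <- unname(acc_of)
  dedup$is_contaminant <- FALSE

  if (!is.null(contaminants)) {
    ct <- as_records(contaminants)
    ct <- ct[!duplicated(ct$sequence) & !(ct$sequence %in% dedup$sequence), ,
             drop = FALSE]
    if (nrow(ct) > 0) {
      ct$accession <- paste0(CONTAMINANT_PREFIX, ct$accession)
      ct$is_contaminant <- TRUE
      dedup <- rbind(dedup[, c("accession", "description", "sequence",
                               "is_contaminant")],
                     ct[, c("accession", "description", "sequence",
                            "is_contaminant")])
    }
  }
  dedup <- dedup[, c("accession", "description", "sequence", "is_contaminant")]
  dedup$is_decoy <- FALSE

  decoys <- dedup
  decoys$accession <- paste0(DECOY_PREFIX, dedup$accession)
  decoys$sequence <- reverse_sequence(dedup$sequence)
  decoys$is_decoy <- TRUE

  records <- rbind(dedup, decoys)
  rownames(records) <- NULL
  structure(list(records = records,
                 n_target = nrow(dedup),
                 n_decoy = nrow(decoys)),
            class = "search_db")
}

#' @export
print.search_db <- function(x, ...) {
  cat("search_db:", x$n_target, "target +", x$n_decoy, "decoy sequences (",
      sum(x$records$is_contaminant & !x$records$is_decoy),
      "contaminant targets )\n")
  invisible(x)
}

#' Reverse protein sequences (decoy generation)
#'
#' @param sequence Character vector of residue strings.
#' @return The reversed strings. Reversal is an involution, so the decoy of
#'   a decoy is the original target.
#' @export
reverse_sequence <- function(sequence) {
  vapply(strsplit(sequence, ""), function(r) paste(rev(r), collapse = ""),
         character(1))
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water; with the fixed
#' carbamidomethyl modification active, +57.02146 Da per cysteine.
#'
#' @param sequence Peptide residue string (vectorized).
#' @param carbamidomethyl Apply fixed carbamidomethylation of cysteine
#'   (default `TRUE`, the package-wide convention).
#' @return Numeric vector of monoisotopic masses (Da).
#' @export
peptide_mass <- function(sequence, carbamidomethyl = TRUE) {
  vapply(sequence, function(s) {
    res <- check_residues(s, "peptide")
    m <- sum(RESIDUE_MASS[res]) + MASS_WATER
    if (carbamidomethyl) m <- m + MASS_CARBAMIDOMETHYL * sum(res == "C")
    m
  }, numeric(1), USE.NAMES = FALSE)
}

# Positions after which trypsin cleaves: after K/R, not before P.
cleavage_sites <- function(residues, no_cleave_before_P = TRUE) {
  n <- length(residues)
  if (n < 2) return(integer(0))
  pos <- which(residues[-n] %in% c("K", "R"))
  if (no_cleave_before_P) pos <- pos[residues[pos + 1] != "P"]
  pos
}

#' In-silico tryptic or semi-tryptic digestion
#'
#' Cleaves after K/R (not before P by default). Tryptic mode emits fully
#' tryptic peptides with at most `max_missed` internal K/R cleavage sites;
#' semi-tryptic mode additionally emits every peptide with exactly one
#' non-tryptic terminus (the other terminus a cleavage site or the protein
#' end), under the same missed-cleavage cap and length range.
#'
#' @param sequence Protein residue string.
#' @param mode `"tryptic"` or `"semi"`.
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param len_range Length range kept, default `c(6, 35)`.
#' @param no_cleave_before_P Suppress cleavage when the following residue is
#'   proline (default `TRUE`).
#' @param accession Optional parent accession recorded on the output.
#' @return A data.frame with columns `sequence`, `start`, `end` (0-based
#'   half-open coordinates in the parent), `n_missed`, `tryptic_termini`
#'   (2 = fully tryptic, 1 = semi), `mass` (monoisotopic, fixed
#'   carbamidomethyl) and `accession`.
#' @export
digest <- function(sequence, mode = c("semi", "tryptic"), max_missed = 2,
                   len_range = c(6, 35), no_cleave_before_P = TRUE,
                   accession = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(max_missed >= 0, length(len_range) == 2)
  res <- check_residues(sequence, "protein")
  n <- length(res)
  lmin <- len_range[1]; lmax <- len_range[2]
  sites <- cleavage_sites(res, no_cleave_before_P)
  bounds <- c(0L, sites, n)            # tryptic boundaries (0-based cut points)
  is_bound <- logical(n + 1)
  is_bound[bounds + 1L] <- TRUE

  starts <- integer(0); ends <- integer(0)
  # Fully tryptic: all boundary pairs with <= max_missed internal sites.
  nb <- length(bounds)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):min(nb, i + 1 + max_missed)) {
      starts <- c(starts, bounds[i]); ends <- c(ends, bounds[j])
    }
  }
  if (mode == "semi") {
    # One tryptic terminus, the other free; internal sites still capped.
    for (i in seq_len(nb - 1)) {
      s <- bounds[i]
      jmax <- bounds[min(nb, i + 1 + max_missed)]
      for (e in (s + 1):min(jmax, s + lmax, n)) {
        if (!is_bound[e + 1L]) { starts <- c(starts, s); ends <- c(ends, e) }
      }
    }
    for (j in 2:nb) {
      e <- bounds[j]
      imin <- bounds[max(1, j - 1 - max_missed)]
      for (s in max(imin, e - lmax):(e - 1)) {
        if (!is_bound[s + 1L]) { starts <- c(starts, s); ends <- c(ends, e) }
      }
    }
  }
  len <- ends - starts
  keep <- len >= lmin & len <= lmax
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), n_missed = integer(0),
                      tryptic_termini = integer(0), mass = numeric(0),
                      accession = character(0)))
  }
  site_cum <- cumsum(is_bound)          # boundaries at positions <= k
  n_internal <- site_cum[ends] - site_cum[starts + 1L]
  termini <- (is_bound[starts + 1L]) + (is_bound[ends + 1L])
  seqs <- substring(sequence, starts + 1L, ends)
  out <- data.frame(sequence = seqs, start = starts, end = ends,
                    n_missed = as.integer(n_internal),
                    tryptic_termini = as.integer(termini),
                    mass = NA_real_, accession = accession)
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  # Masses from residue cumsums: O(n + peptides), identical to peptide_mass().
  cum <- c(0, cumsum(RESIDUE_MASS[res] + MASS_CARBAMIDOMETHYL * (res == "C")))
  out$mass <- cum[out$end + 1L] - cum[out$start + 1L] + MASS_WATER
  rownames(out) <- NULL
  out
}

#' Digest every record of a search database
#'
#' @param db A `search_db` object from [build_database()].
#' @inheritParams digest
#' @return One data.frame of peptides over all records, with `accession`
#'   and an `is_decoy` flag; sorted by mass for windowed candidate lookup.
#' @export
digest_database <- function(db, mode = c("semi", "tryptic"), max_missed = 2,
                            len_range = c(6, 35)) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "search_db"))
  per <- lapply(seq_len(nrow(db$records)), function(i) {
    rec <- db$records[i, ]
    pep <- digest(rec$sequence, mode = mode, max_missed = max_missed,
                  len_range = len_range, accession = rec$accession)
    if (nrow(pep) > 0) pep$is_decoy <- rec$is_decoy
    pep
  })
  out <- do.call(rbind, per[vapply(per, nrow, integer(1)) > 0])
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}
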