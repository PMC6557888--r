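# Peptide-spectrum matching: candidate selection by precursor mass,
# shared-peak Poisson scoring, two-stage target-decoy search, purge rules
# and peptide-level FDR. The scorer is a deliberately simple stand-in
# with the same score semantics as spectrum E-value engines (reported as
# -log10 E-value); it is isolated behind score_psm() so a stricter
# scorer can be swapped in.

#' Search settings
#'
#' Parameters of the peptide-spectrum-match search: parent-ion mass
#' tolerance 0.5 Da, precursor charges 1-6, peptide lengths 6-35, isotope
#' error 0-2 (multiples of 1.00335 Da), semi-tryptic cleavage with at most
#' two missed cleavages, fixed carbamidomethylation of cysteine, and a
#' fragment tolerance equal to the parent tolerance.
#'
#' @param parent_tolerance Precursor mass tolerance (Da).
#' @param charge_range Precursor charge range, `c(min, max)`.
#' @param peptide_length Peptide length range, `c(min, max)`.
#' @param isotope_error Allowed isotope offsets, `c(min, max)` in units of
#'   1.00335 Da.
#' @param cleavage `"semi"` or `"tryptic"`.
#' @param max_missed Missed-cleavage cap.
#' @param fragment_tolerance Fragment-ion match tolerance (Da).
#' @param fdr_threshold Peptide-level FDR cut.
#' @param keep_contaminants Keep contaminant best-hits in the FDR input
#'   (default `FALSE`: they are removed after the purge).
#' @return A validated list of class `search_settings`.
#' @export
search_settings <- function(parent_tolerance = 0.5,
                            charge_range = c(1, 6),
                            peptide_length = c(6, 35),
                            isotope_error = c(0, 2),
                            cleavage = c("semi", "tryptic"),
                            max_missed = 2,
                            fragment_tolerance = 0.5,
                            fdr_threshold = 0.01,
                            keep_contaminants = FALSE) {
  cleavage <- match.arg(cleavage)
  stopifnot(parent_tolerance > 0, fragment_tolerance > 0,
            length(charge_range) == 2, charge_range[1] <= charge_range[2],
            length(peptide_length) == 2,
            peptide_length[1] <= peptide_length[2],
            isotope_error[1] >= 0, isotope_error[1] <= isotope_error[2],
            max_missed >= 0, fdr_threshold > 0)
  structure(list(parent_tolerance = parent_tolerance,
                 charge_range = charge_range,
                 peptide_length = peptide_length,
                 isotope_error = isotope_error,
                 cleavage = cleavage, max_missed = max_missed,
                 fragment_tolerance = fragment_tolerance,
                 fdr_threshold = fdr_threshold,
                 keep_contaminants = keep_contaminants),
            class = "search_settings")
}

#' Theoretical b/y fragment ions of a peptide
#'
#' @param sequence Peptide residue string.
#' @param charges Fragment charges to emit (default 1:2).
#' @param carbamidomethyl Apply the fixed cysteine modification.
#' @return A data.frame with `ion` (e.g. `"b3^1"`), `mz`.
#' @export
fragment_ions <- function(sequence, charges = 1:2, carbamidomethyl = TRUE) {
  res <- check_residues(sequence, "peptide")
  n <- length(res)
  if (n < 2)
    return(data.frame(ion = character(0), mz = numeric(0)))
  mres <- RESIDUE_MASS[res]
  if (carbamidomethyl) mres <- mres + MASS_CARBAMIDOMETHYL * (res == "C")
  bm <- cumsum(mres)[-n]                      # b_i neutral fragment masses
  ym <- rev(cumsum(rev(mres))[-n]) + MASS_WATER
  out <- lapply(charges, function(z) data.frame(
    ion = c(sprintf("b%d^%d", seq_len(n - 1), z),
            sprintf("y%d^%d", rev(seq_len(n - 1)), z)),
    mz = (c(bm, ym) + z * MASS_PROTON) / z))
  do.call(rbind, out)
}

# Neutral precursor mass of one spectrum (PEPMASS is m/z).
precursor_neutral_mass <- function(spectrum) {
  spectrum$pepmass * spectrum$charge - spectrum$charge * MASS_PROTON
}

#' Candidate peptides for a spectrum
#'
#' Peptides whose monoisotopic mass matches the precursor neutral mass
#' within the parent tolerance after allowing isotope offsets of
#' `isotope_error` times 1.00335 Da; the precursor charge must lie within
#' the settings' range.
#'
#' @param spectrum One spectrum (list with `pepmass`, `charge`).
#' @param peptides Peptide table sorted by mass (see [digest_database()]).
#' @param settings A [search_settings()].
#' @return The matching rows of `peptides`, with an `isotope` column (the
#'   offset minimizing the residual mass error) and `error` (measured
#'   minus calculated parent mass after that offset, Da).
#' @export
candidates <- function(spectrum, peptides, settings = search_settings()) {
  if (is.null(spectrum$pepmass) || is.na(spectrum$pepmass) ||
      is.null(spectrum$charge) || is.na(spectrum$charge)) {
    warning("spectrum without precursor information skipped")
    return(peptides[0, ])
  }
  if (spectrum$charge < settings$charge_range[1] ||
      spectrum$charge > settings$charge_range[2])
    return(peptides[0, ])
  neutral <- precursor_neutral_mass(spectrum)
  ks <- seq(settings$isotope_error[1], settings$isotope_error[2])
  hit <- integer(0)
  for (k in ks) {
    target <- neutral - k * MASS_ISOTOPE
    lo <- findInterval(target - settings$parent_tolerance, peptides$mass) + 1L
    hi <- findInterval(target + settings$parent_tolerance, peptides$mass)
    if (hi >= lo) hit <- c(hit, lo:hi)
  }
  hit <- sort(unique(hit))
  out <- peptides[hit, , drop = FALSE]
  if (nrow(out) == 0) { out$isotope <- integer(0); out$error <- numeric(0); return(out) }
  errs <- outer(neutral - out$mass, ks * MASS_ISOTOPE, "-")
  best <- apply(abs(errs), 1, which.min)
  out$isotope <- ks[best]
  out$error <- errs[cbind(seq_len(nrow(out)), best)]
  rownames(out) <- NULL
  out
}

# Number of theoretical ions with at least one observed peak within tol.
count_matched_ions <- function(theo_mz, peak_mz_sorted, tol) {
  if (length(peak_mz_sorted) == 0 || length(theo_mz) == 0) return(0L)
  idx <- findInterval(theo_mz, peak_mz_sorted)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(peak_mz_sorted))
  d <- pmin(abs(theo_mz - peak_mz_sorted[lo]),
            abs(theo_mz - peak_mz_sorted[hi]))
  sum(d <= tol)
}

#' Score one peptide-spectrum match
#'
#' Shared-peak Poisson score: the raw score is the number of theoretical
#' b/y ions (fragment charges 1-2) matched by an observed peak within the
#' fragment tolerance; the E-value is the Poisson upper tail
#' `P(X >= raw)` with rate
#' `n_theoretical * (2 * tol / mz_span) * n_peaks`, multiplied by the
#' number of competing candidates; the reported score is `-log10` of the
#' E-value.
#'
#' @param spectrum One spectrum (list with `mz`, `intensity`).
#' @param peptide Candidate peptide sequence.
#' @param fragment_tolerance Match tolerance (Da).
#' @param n_candidates Size of the candidate set the peptide competed in.
#' @return List with `raw_score`, `e_value`, `score`.
#' @export
score_psm <- function(spectrum, peptide, fragment_tolerance = 0.5,
                      n_candidates = 1) {
  if (length(spectrum$mz) == 0)
    return(list(raw_score = 0L, e_value = 1, score = 0))
  theo <- fragment_ions(peptide, charges = 1:2)
  peaks <- sort(spectrum$mz)
  raw <- count_matched_ions(theo$mz, peaks, fragment_tolerance)
  span <- max(peaks) - min(peaks)
  p_hit <- if (span > 0) min(1, 2 * fragment_tolerance / span) else 1
  lambda <- nrow(theo) * p_hit * length(peaks)
  tail <- stats::ppois(raw - 1, lambda, lower.tail = FALSE)
  e <- n_candidates * tail
  list(raw_score = as.integer(raw), e_value = e,
       score = -log10(max(e, .Machine$double.xmin)))
}

empty_psm_frame <- function() {
  data.frame(spectrum_id = character(0), spot_id = character(0),
             peptide = character(0), accession = character(0),
             is_decoy = logical(0), is_contaminant = logical(0),
             raw_score = integer(0), score = numeric(0),
             e_value = numeric(0), error = numeric(0), charge = integer(0),
             n_missed = integer(0), tryptic_termini = integer(0),
             n_candidates = integer(0),
             best_target_raw = numeric(0), best_decoy_raw = numeric(0))
}

#' Single-stage PSM search
#'
#' For every spectrum of every spectrum set, candidate peptides (targets
#' and decoys competing) are scored and the best-scoring one is retained:
#' highest raw score, ties broken by smallest absolute parent-mass error,
#' then lexicographic peptide and accession (decoy-status-blind, so ties
#' do not bias the target/decoy balance). The best target and best decoy
#' raw scores per spectrum are recorded for the purge step.
#'
#' @param sets List of `spectrum_set` objects.
#' @param db A `search_db`.
#' @param settings A [search_settings()].
#' @param peptides Optional pre-digested peptide table for `db` (computed
#'   when missing).
#' @return A data.frame of best-hit PSMs, one row per spectrum with at
#'   least one candidate.
#' @export
search_stage <- function(sets, db, settings = search_settings(),
                         peptides = NULL) {
  stopifnot(inherits(db, "search_db"))
  if (inherits(sets, "spectrum_set")) sets <- list(sets)
  if (is.null(peptides))
    peptides <- digest_database(db, mode = settings$cleavage,
                                max_missed = settings$max_missed,
                                len_range = settings$peptide_length)
  contaminant_acc <- db$records$accession[db$records$is_contaminant]
  theo_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (set in sets) {
    for (sp in set$spectra) {
      cand <- candidates(sp, peptides, settings)
      if (nrow(cand) == 0) next
      peaks <- sort(sp$mz)
      n_peaks <- length(peaks)
      span <- if (n_peaks > 1) max(peaks) - min(peaks) else 0
      raw <- integer(nrow(cand)); n_theo <- integer(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        pep <- cand$sequence[i]
        theo <- get0(pep, envir = theo_cache)
        if (is.null(theo)) {
          theo <- fragment_ions(pep, charges = 1:2)$mz
          assign(pep, theo, envir = theo_cache)
        }
        n_theo[i] <- length(theo)
        raw[i] <- count_matched_ions(theo, peaks,
                                     settings$fragment_tolerance)
      }
      ord <- order(-raw, abs(cand$error), cand$sequence, cand$accession)
      b <- ord[1]
      p_hit <- if (span > 0)
        min(1, 2 * settings$fragment_tolerance / span) else 1
      lambda <- n_theo[b] * p_hit * n_peaks
      tail <- stats::ppois(raw[b] - 1, lambda, lower.tail = FALSE)
      e <- nrow(cand) * tail
      tg <- raw[!cand$is_decoy]; dc <- raw[cand$is_decoy]
      rows[[length(rows) + 1]] <- data.frame(
        spectrum_id = sp$title, spot_id = set$spot_id,
        peptide = cand$sequence[b], accession = cand$accession[b],
        is_decoy = cand$is_decoy[b],
        is_contaminant = sub(paste0("^", DECOY_PREFIX), "",
                             cand$accession[b]) %in%
          sub(paste0("^", DECOY_PREFIX), "", contaminant_acc),
        raw_score = raw[b],
        score = -log10(max(e, .Machine$double.xmin)), e_value = e,
        error = cand$error[b], charge = sp$charge,
        n_missed = cand$n_missed[b],
        tryptic_termini = cand$tryptic_termini[b],
        n_candidates = nrow(cand),
        best_target_raw = if (length(tg)) max(tg) else NA_real_,
        best_decoy_raw = if (length(dc)) max(dc) else NA_real_)
    }
  }
  if (length(rows) == 0) return(empty_psm_frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-stage target-decoy search
#'
#' Stage 1 searches the full database. Every protein with at least one
#' stage-1 best hit (target or decoy) seeds stage 2: the stage-2 database
#' holds the union of surviving targets and the targets behind surviving
#' decoys, each paired with its reversed decoy, so the stage-2
#' target:decoy ratio is exactly 1:1 and the FDR estimate stays unbiased.
#' Final PSMs come from stage 2.
#'
#' @inheritParams search_stage
#' @return The stage-2 PSM data.frame (attribute `"stage1"` carries the
#'   stage-1 PSMs).
#' @export
two_stage_search <- function(sets, db, settings = search_settings()) {
  stage1 <- search_stage(sets, db, settings)
  if (nrow(stage1) == 0) {
    warning("no stage-1 best hits; returning empty PSM list")
    return(stage1)
  }
  surv <- unique(stage1$accession)
  target_acc <- unique(sub(paste0("^", DECOY_PREFIX), "", surv))
  rec <- db$records
  # Deduplicated accessions may be "A;B" strings; match whole entries.
  tg <- rec[!rec$is_decoy & rec$accession %in% target_acc, , drop = FALSE]
  dc <- rec[rec$is_decoy &
              rec$accession %in% paste0(DECOY_PREFIX, target_acc), ,
            drop = FALSE]
  db2 <- structure(list(records = rbind(tg, dc),
                        n_target = nrow(tg), n_decoy = nrow(dc)),
                   class = "search_db")
  stage2 <- search_stage(sets, db2, settings)
  attr(stage2, "stage1") <- stage1
  stage2
}

#' Purge rules applied before FDR computation
#'
#' Removes (i) spectra that match a target and a decoy equally well,
#' i.e. whose best target and best decoy raw scores tie (raw scores
#' are integer shared-peak counts so ties are exact), (ii) PSMs whose
#' peptide has a semi-tryptic terminus, and (iii) PSMs with more than two
#' missed cleavages. The three rules are independent filters, so the
#' purge is idempotent and order-independent.
#'
#' @param psms PSM data.frame from [search_stage()] or
#'   [two_stage_search()].
#' @param max_missed Missed-cleavage cap of rule (iii), default 2.
#' @return The surviving PSM rows.
#' @export
purge_psms <- function(psms, max_missed = 2) {
  if (nrow(psms) == 0) return(psms)
  tie <- !is.na(psms$best_target_raw) & !is.na(psms$best_decoy_raw) &
    psms$best_target_raw == psms$best_decoy_raw
  keep <- !tie & psms$tryptic_termini == 2 & psms$n_missed <= max_missed
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peptide-level FDR from target-decoy competition
#'
#' PSMs are collapsed to the best-scoring record per distinct peptide
#' sequence; at every observed score threshold the FDR is
#' `n_decoy / n_target` over peptides scoring at or above it (thresholds
#' with no target peptide are skipped). Peptides whose FDR at their own
#' score is at or below `fdr_threshold` pass. Contaminant best-hits are
#' removed first unless `keep_contaminants` is set in the settings.
#'
#' @param psms Purged PSM data.frame.
#' @param settings A [search_settings()] (uses `fdr_threshold` and
#'   `keep_contaminants`).
#' @return List with `records` (data.frame `score_threshold`, `n_target`,
#'   `n_decoy`, `fdr`), `peptides` (collapsed table with an `fdr`
#'   column) and `passing` (subset with `fdr <= fdr_threshold`).
#' @export
compute_fdr <- function(psms, settings = search_settings()) {
  if (!settings$keep_contaminants && nrow(psms) > 0)
    psms <- psms[!psms$is_contaminant, , drop = FALSE]
  if (nrow(psms) == 0)
    return(list(records = data.frame(score_threshold = numeric(0),
                                     n_target = integer(0),
                                     n_decoy = integer(0), fdr = numeric(0)),
                peptides = psms, passing = psms))
  ord <- order(-psms$score, psms$is_decoy, psms$peptide)
  pep <- psms[ord, , drop = FALSE]
  pep <- pep[!duplicated(pep$peptide), , drop = FALSE]  # best per peptide
  pep <- pep[order(-pep$score, pep$peptide), , drop = FALSE]
  cum_t <- cumsum(!pep$is_decoy)
  cum_d <- cumsum(pep$is_decoy)
  # FDR at each distinct score threshold (last row of each tie block).
  last <- !duplicated(pep$score, fromLast = TRUE)
  recs <- data.frame(score_threshold = pep$score[last],
                     n_target = cum_t[last], n_decoy = cum_d[last])
  skip <- recs$n_target == 0
  if (any(skip)) message(sum(skip), " threshold(s) without target hits skipped")
  recs <- recs[!skip, , drop = FALSE]
  recs$fdr <- recs$n_decoy / recs$n_target
  # Each peptide carries the FDR of the threshold at its own score.
  idx <- match(round(pep$score, 12), round(recs$score_threshold, 12))
  pep$fdr <- recs$fdr[idx]
  rownames(pep) <- NULL
  rownames(recs) <- NULL
  # Decoy peptides inform the estimate but are never reported as passing.
  passing <- pep[!is.na(pep$fdr) & pep$fdr <= settings$fdr_threshold &
                   !pep$is_decoy, , drop = FALSE]
  list(records = recs, peptides = pep, passing = passing)
}

#' Protein-identification rule
#'
#' A protein is identified when more than two (i.e. at least three)
#' distinct peptide sequences map to its accession among the
#' FDR-passing peptides.
#'
#' @param passing_psms FDR-passing peptide table (see [compute_fdr()]).
#' @return A data.frame with `accession`, `n_peptides`, `peptides`
#'   (semicolon-joined) and `identified`.
#' @export
identify_proteins <- function(passing_psms) {
  if (nrow(passing_psms) == 0)
    return(data.frame(accession = character(0), n_peptides = integer(0),
                      peptides = character(0), identified = logical(0)))
  by_acc <- split(passing_psms$peptide, passing_psms$accession)
  out <- data.frame(
    accession = names(by_acc),
    n_peptides = vapply(by_acc, function(p) length(unique(p)), integer(1)),
    peptides = vapply(by_acc, function(p)
      paste(sort(unique(p)), collapse = ";"), character(1)))
  out$identified <- out$n_peptides >= 3
  out <- out[order(-out$n_peptides, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
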