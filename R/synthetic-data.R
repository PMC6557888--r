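# Ground-truthed synthetic inputs: morph proteomes with shared and
# morph-unique proteins, noisy replicate 2-DE spot maps, and per-spot
# MS/MS spectrum sets. The generator is the benchmark that the gel,
# search and distance modules are calibrated and tested against.

#' Generator configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' conditions of a three-morph femoral-gland comparison: one proteome per
#' colour morph (W, Y, R) built from a pool of shared proteins plus
#' morph-unique ones, with the white morph roughly 1.5-fold richer in
#' spots than yellow and red; quadruplicate gels with positional jitter,
#' spot dropout and speckle noise; and per-spot MS/MS spectrum sets of
#' noisy b/y fragment spectra from tryptic peptides.
#'
#' @param n_shared_proteins Proteins common to all three morphs.
#' @param n_unique_per_morph Named counts of morph-unique proteins,
#'   `c(W = , Y = , R = )`.
#' @param n_replicates Gel replicates per morph (default 4; the best 3 are
#'   used downstream).
#' @param jitter_pI SD of positional noise on the IEF axis (pH units).
#' @param jitter_logmw SD of positional noise on the mass axis
#'   (log10 kDa).
#' @param dropout_prob Probability that a true spot is missed in one
#'   replicate.
#' @param speckle_rate Expected number of spurious speckle spots per
#'   replicate (uniform over the gel rectangle).
#' @param spectra_per_spot MS/MS spectra acquired per excised spot.
#' @param noise_peaks Spurious peaks added to each spectrum.
#' @param fragment_dropout Probability that a theoretical fragment ion is
#'   missing from a spectrum.
#' @param seq_len_range Protein lengths (residues), uniform.
#' @param kr_density Probability that a residue is K or R (tryptic-site
#'   density, about 1 per 10 residues in real proteomes).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_shared_proteins = 18,
                             n_unique_per_morph = c(W = 18, Y = 6, R = 7),
                             n_replicates = 4,
                             jitter_pI = 0.02,
                             jitter_logmw = 0.005,
                             dropout_prob = 0.1,
                             speckle_rate = 2,
                             spectra_per_spot = 12,
                             noise_peaks = 5,
                             fragment_dropout = 0.1,
                             seq_len_range = c(80, 400),
                             kr_density = 0.1) {
  cfg <- list(n_shared_proteins = n_shared_proteins,
              n_unique_per_morph = n_unique_per_morph,
              n_replicates = n_replicates,
              jitter_pI = jitter_pI, jitter_logmw = jitter_logmw,
              dropout_prob = dropout_prob, speckle_rate = speckle_rate,
              spectra_per_spot = spectra_per_spot,
              noise_peaks = noise_peaks,
              fragment_dropout = fragment_dropout,
              seq_len_range = seq_len_range, kr_density = kr_density)
  probs <- c(dropout_prob = dropout_prob, fragment_dropout = fragment_dropout,
             kr_density = kr_density)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (n_shared_proteins < 0 || any(n_unique_per_morph < 0))
    stop("protein counts must be non-negative", call. = FALSE)
  if (n_shared_proteins + min(n_unique_per_morph) <= 0)
    stop("each morph needs at least one protein", call. = FALSE)
  if (!all(c("W", "Y", "R") %in% names(n_unique_per_morph)))
    stop("n_unique_per_morph must name morphs W, Y and R", call. = FALSE)
  if (n_replicates < 3 || spectra_per_spot < 1)
    stop("n_replicates must be >= 3 and spectra_per_spot >= 1",
         call. = FALSE)
  if (jitter_pI < 0 || jitter_logmw < 0 || speckle_rate < 0 ||
      noise_peaks < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  structure(cfg, class = "generator_config")
}

MORPHS <- c("W", "Y", "R")

random_protein <- function(len, kr_density) {
  kr <- c("K", "R")
  other <- setdiff(STANDARD_RESIDUES, kr)
  p <- c(rep(kr_density / 2, 2), rep((1 - kr_density) / length(other),
                                     length(other)))
  paste(sample(c(kr, other), len, replace = TRUE, prob = p), collapse = "")
}

#' Simulate morph proteomes and the ground-truth manifest
#'
#' Draws random protein sequences (uniform lengths, K/R density near one
#' tryptic site per 10 residues) for a pool shared by all morphs plus a
#' morph-unique set per morph, and records which protein underlies which
#' gel spot. One 2-DE spot per (morph, protein) pair is assumed.
#'
#' @param config A [generator_config()].
#' @param seed Integer root seed; fixed seed gives byte-identical output.
#' @return A list of class `synthetic_truth` with elements `proteins`
#'   (data.frame: `accession`, `sequence`, `origin`), `morph_proteins`
#'   (list W/Y/R of accessions), `spot_protein` (named map spot-id to
#'   accession), `unique_flags` (spot-id to `"shared"` or its morph) and
#'   `seed`.
#' @export
simulate_proteomes <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  nS <- config$n_shared_proteins
  nU <- config$n_unique_per_morph[MORPHS]
  with_seed(derive_seed(seed, "proteomes"), {
    lens <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]),
                   nS + sum(nU), replace = TRUE)
    seqs <- vapply(lens, random_protein, character(1),
                   kr_density = config$kr_density)
  })
  acc <- c(if (nS > 0) sprintf("SHARED%03d", seq_len(nS)),
           unlist(lapply(MORPHS, function(m) {
             if (nU[[m]] > 0) sprintf("%sUNIQ%03d", m, seq_len(nU[[m]]))
           })))
  origin <- c(rep("shared", nS), rep(MORPHS, times = nU))
  proteins <- data.frame(accession = acc, sequence = seqs, origin = origin)

  morph_proteins <- lapply(stats::setNames(MORPHS, MORPHS), function(m)
    acc[origin %in% c("shared", m)])
  spot_protein <- unlist(lapply(MORPHS, function(m) {
    p <- morph_proteins[[m]]
    stats::setNames(p, paste0(m, ":", p))
  }))
  unique_flags <- stats::setNames(
    ifelse(grepl("^SHARED", spot_protein), "shared",
           substr(names(spot_protein), 1, 1)),
    names(spot_protein))
  structure(list(proteins = proteins, morph_proteins = morph_proteins,
                 spot_protein = spot_protein, unique_flags = unique_flags,
                 seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", nrow(x$proteins), "proteins;",
      length(x$spot_protein), "true spots;",
      sum(x$unique_flags != "shared"), "morph-unique; seed", x$seed, "\n")
  invisible(x)
}

#' Isoelectric point of a protein or peptide
#'
#' Solves for the pH at which the net charge of the standard per-residue
#' pKa model (termini plus K/R/H positive and D/E/C/Y negative side
#' chains, [PKA_TABLE]) is zero, by bisection on (0, 14) to a tolerance of
#' 1e-4 pH units.
#'
#' @param sequence Residue string (standard residues only).
#' @param tol Bisection tolerance in pH units.
#' @return The isoelectric point (pH units).
#' @seealso [net_charge()]
#' @export
compute_pI <- function(sequence, tol = 1e-4) {
  check_residues(sequence)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Net charge of a sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups of [PKA_TABLE]:
#' positive groups contribute `1/(1 + 10^(pH - pKa))`, negative groups
#' `-1/(1 + 10^(pKa - pH))`.
#'
#' @param sequence Residue string.
#' @param pH pH at which to evaluate the charge.
#' @return Net charge (elementary charges).
#' @export
net_charge <- function(sequence, pH) {
  res <- check_residues(sequence)
  counts <- table(factor(res, levels = STANDARD_RESIDUES))
  pos <- 1 / (1 + 10^(pH - PKA_TABLE["Nterm"])) +
    sum(vapply(.PKA_POSITIVE, function(r)
      counts[[r]] / (1 + 10^(pH - PKA_TABLE[[r]])), numeric(1)))
  neg <- 1 / (1 + 10^(PKA_TABLE["Cterm"] - pH)) +
    sum(vapply(.PKA_NEGATIVE, function(r)
      counts[[r]] / (1 + 10^(PKA_TABLE[[r]] - pH)), numeric(1)))
  unname(pos - neg)
}

# True (pI, log10 MW) coordinates of every protein in the truth manifest.
# Protein MW is the monoisotopic peptide-chain mass (no fixed mods), in kDa.
truth_positions <- function(truth) {
  p <- truth$proteins
  data.frame(accession = p$accession,
             pI = vapply(p$sequence, compute_pI, numeric(1),
                         USE.NAMES = FALSE),
             log10_mw = log10(peptide_mass(p$sequence,
                                           carbamidomethyl = FALSE) / 1000))
}

#' Simulate replicate 2-DE spot maps
#'
#' For each morph, produces `n_replicates` gel replicates: every true spot
#' appears at its protein's (pI, log10 MW) position plus Gaussian jitter,
#' with a log-normal intensity, and is omitted independently with
#' probability `dropout_prob`; Poisson-distributed speckle spots (spot ids
#' prefixed `"speckle_"`) are scattered uniformly over the gel rectangle.
#'
#' @param truth A `synthetic_truth` from [simulate_proteomes()].
#' @param config A [generator_config()].
#' @param seed Integer root seed.
#' @return A data.frame of spots with columns `spot_id`, `pI`, `log10_mw`,
#'   `intensity`, `replicate`, `morph`.
#' @export
simulate_gels <- function(truth, config, seed) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "generator_config"))
  pos <- truth_positions(truth)
  rownames(pos) <- pos$accession
  gel_box <- list(pI = c(3, 10),
                  log10_mw = range(pos$log10_mw) + c(-0.05, 0.05))
  out <- list()
  for (m in MORPHS) {
    spot_ids <- names(truth$spot_protein)[startsWith(names(truth$spot_protein),
                                                     paste0(m, ":"))]
    accs <- truth$spot_protein[spot_ids]
    for (r in seq_len(config$n_replicates)) {
      with_seed(derive_seed(seed, paste0("gel_", m, "_", r)), {
        present <- stats::runif(length(spot_ids)) >= config$dropout_prob
        n <- sum(present)
        true_spots <- data.frame(
          spot_id = spot_ids[present],
          pI = pos[accs[present], "pI"] +
            stats::rnorm(n, 0, config$jitter_pI),
          log10_mw = pos[accs[present], "log10_mw"] +
            stats::rnorm(n, 0, config$jitter_logmw),
          intensity = stats::rlnorm(n, log(1000), 0.5))
        n_spk <- stats::rpois(1, config$speckle_rate)
        speckles <- data.frame(
          spot_id = if (n_spk > 0)
            sprintf("speckle_%s_r%d_%02d", m, r, seq_len(n_spk))
          else character(0),
          pI = stats::runif(n_spk, gel_box$pI[1], gel_box$pI[2]),
          log10_mw = stats::runif(n_spk, gel_box$log10_mw[1],
                                  gel_box$log10_mw[2]),
          intensity = stats::rlnorm(n_spk, log(200), 0.5))
        rep_spots <- rbind(true_spots, speckles)
      })
      if (nrow(rep_spots) > 0) {
        rep_spots$replicate <- r
        rep_spots$morph <- m
        out[[paste0(m, r)]] <- rep_spots
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(spot_id = character(0), pI = numeric(0),
                      log10_mw = numeric(0), intensity = numeric(0),
                      replicate = integer(0), morph = character(0))
  rownames(res) <- NULL
  res
}

# Fully tryptic peptides of a protein that are suitable for simulated
# spectra; selection is deterministic per accession so that two spots
# backed by the same protein yield the same peptide panel.
select_spot_peptides <- function(accession, sequence, n_distinct) {
  pep <- digest(sequence, mode = "tryptic", max_missed = 0,
                len_range = c(6, 30), accession = accession)
  if (nrow(pep) == 0)
    stop("protein ", accession, " has no tryptic peptide of usable length",
         call. = FALSE)
  idx <- with_seed(derive_seed(7, paste0("pepsel_", accession)),
                   sample(nrow(pep), min(n_distinct, nrow(pep))))
  pep[sort(idx), , drop = FALSE]
}

#' Simulate the MS/MS spectrum set of one excised spot
#'
#' Samples tryptic peptides of the spot's underlying protein (the panel is
#' a deterministic function of the protein, so spots sharing a protein
#' share peptides) and emits, for each spectrum, the singly charged b/y
#' fragment ions of one peptide with log-normal intensity noise, fragment
#' dropout, uniform noise peaks, and a doubly charged precursor with a
#' small mass error. Peptides are cycled over the `spectra_per_spot`
#' spectra so each appears at least twice when the budget allows, giving
#' every spectrum a noisy within-spot replicate -- the property that makes
#' leave-one-out self-distances finite and small.
#'
#' @param spot_id A spot id present in `truth$spot_protein`.
#' @param truth A `synthetic_truth`.
#' @param config A [generator_config()].
#' @param seed Integer root seed.
#' @return A `spectrum_set`: list with `spot_id`, `morph`, `spectra` (list
#'   of peak lists with `mz`, `intensity`, `pepmass`, `charge`, `title`,
#'   `peptide`).
#' @export
simulate_spectra <- function(spot_id, truth, config, seed) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "generator_config"))
  if (!spot_id %in% names(truth$spot_protein))
    stop("unknown spot id: ", spot_id, call. = FALSE)
  acc <- truth$spot_protein[[spot_id]]
  sequence <- truth$proteins$sequence[truth$proteins$accession == acc]
  n_spec <- config$spectra_per_spot
  n_distinct <- max(1L, n_spec %/% 2L)
  panel <- select_spot_peptides(acc, sequence, n_distinct)
  pep_idx <- rep_len(seq_len(nrow(panel)), n_spec)

  spectra <- with_seed(derive_seed(seed, paste0("spec_", spot_id)), {
    lapply(seq_len(n_spec), function(k) {
      pep <- panel[pep_idx[k], ]
      ions <- fragment_ions(pep$sequence, charges = 1L)
      keep <- stats::runif(nrow(ions)) >= config$fragment_dropout
      mz <- ions$mz[keep]
      int <- stats::rlnorm(sum(keep), log(100), 0.4)
      if (config$noise_peaks > 0) {
        mz <- c(mz, stats::runif(config$noise_peaks, 100, 2000))
        int <- c(int, stats::rlnorm(config$noise_peaks, log(20), 0.5))
      }
      o <- order(mz)
      charge <- 2L
      pepmass <- (pep$mass + stats::runif(1, -0.05, 0.05) +
                    charge * MASS_PROTON) / charge
      list(mz = round(mz[o], 4), intensity = round(int[o], 2),
           pepmass = round(pepmass, 4), charge = charge,
           title = sprintf("%s.scan%02d", spot_id, k),
           peptide = pep$sequence)
    })
  })
  structure(list(spot_id = spot_id,
                 morph = substr(spot_id, 1, 1),
                 spectra = spectra),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("spectrum_set", x$spot_id, "(morph", x$morph, "):",
      length(x$spectra), "spectra\n")
  invisible(x)
}
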