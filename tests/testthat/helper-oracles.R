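# Independent brute-force oracles and small fixture builders. Every
# oracle is written against the rule definitions directly (loops,
# enumeration, exhaustive scans) and shares no code path with the
# implementation it checks.

# ---- digestion oracle: scan all substrings ---------------------------

oracle_digest <- function(sequence, mode = "semi", max_missed = 2,
                          len_range = c(6, 35)) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_cut <- function(p) {          # valid cleavage point after residue p
    p == 0 || p == n ||
      (res[p] %in% c("K", "R") && res[p + 1] != "P")
  }
  rows <- list()
  for (s in 0:(n - 1)) {
    for (e in (s + 1):n) {
      len <- e - s
      if (len < len_range[1] || len > len_range[2]) next
      st <- is_cut(s); et <- is_cut(e)
      termini <- sum(st, et)
      if (mode == "tryptic" && termini < 2) next
      if (mode == "semi" && termini < 1) next
      internal <- if (e - s > 1) sum(vapply((s + 1):(e - 1), function(p)
        res[p] %in% c("K", "R") && res[p + 1] != "P", logical(1))) else 0
      if (internal > max_missed) next
      rows[[length(rows) + 1]] <- data.frame(
        sequence = paste(res[(s + 1):e], collapse = ""),
        start = s, end = e, n_missed = internal,
        tryptic_termini = termini)
    }
  }
  if (length(rows) == 0)
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), n_missed = integer(0),
                      tryptic_termini = integer(0)))
  do.call(rbind, rows)
}

digest_key <- function(df) {
  sort(sprintf("%s|%d|%d|%d|%d", df$sequence, df$start, df$end,
               df$n_missed, df$tryptic_termini))
}

# ---- spot-matching oracle: exhaustive assignment ---------------------

# Maximum-cardinality, then minimum-total-distance assignment between two
# spot tables under the tolerance box, by recursive enumeration.
oracle_match <- function(a, b, tol_pI = 0.1, tol_logmw = 0.02) {
  na <- nrow(a); nb <- nrow(b)
  allowed <- vector("list", na)
  for (i in seq_len(na)) {
    ok <- which(abs(a$pI[i] - b$pI) <= tol_pI &
                  abs(a$log10_mw[i] - b$log10_mw) <= tol_logmw)
    d <- sqrt(((a$pI[i] - b$pI[ok]) / tol_pI)^2 +
                ((a$log10_mw[i] - b$log10_mw[ok]) / tol_logmw)^2)
    allowed[[i]] <- list(j = ok, d = d)
  }
  best <- list(count = -1, cost = Inf)
  recurse <- function(i, used_b, count, cost) {
    if (i > na) {
      if (count > best$count ||
          (count == best$count && cost < best$cost - 1e-12))
        best <<- list(count = count, cost = cost)
      return(invisible())
    }
    # upper bound prune
    if (count + (na - i + 1) < best$count) return(invisible())
    cand <- allowed[[i]]
    for (k in seq_along(cand$j)) {
      j <- cand$j[k]
      if (!used_b[j]) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, count + 1, cost + cand$d[k])
        used_b[j] <- FALSE
      }
    }
    recurse(i + 1, used_b, count, cost)
  }
  recurse(1, logical(nb), 0, 0)
  best
}

# ---- Wilcoxon oracle: full sign enumeration via expand.grid ----------

oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wstar <- as.numeric(signs %*% r)
  list(W = W, p = mean(Wstar <= W + 1e-9), n = n)
}

# ---- binning / set-distance oracles: plain loops ---------------------

oracle_bin <- function(spectrum, bin_width = 1.0, mz_range = c(100, 2000)) {
  n_bins <- ceiling((mz_range[2] - mz_range[1]) / bin_width)
  v <- numeric(n_bins)
  for (k in seq_along(spectrum$mz)) {
    mz <- spectrum$mz[k]
    if (is.na(mz) || mz < mz_range[1] || mz >= mz_range[2]) next
    b <- floor((mz - mz_range[1]) / bin_width) + 1
    v[b] <- v[b] + sqrt(spectrum$intensity[k])
  }
  v
}

oracle_set_distance <- function(a, b, bin_width = 1.0,
                                mz_range = c(100, 2000), self = FALSE) {
  va <- lapply(a$spectra, oracle_bin, bin_width = bin_width,
               mz_range = mz_range)
  vb <- lapply(b$spectra, oracle_bin, bin_width = bin_width,
               mz_range = mz_range)
  dmin <- function(from, to, skip_index = FALSE) {
    vapply(seq_along(from), function(i) {
      ds <- vapply(seq_along(to), function(j) {
        if (skip_index && i == j) return(Inf)
        cosine_distance(from[[i]], to[[j]])
      }, numeric(1))
      min(ds)
    }, numeric(1))
  }
  mean(c(mean(dmin(va, vb, self)), mean(dmin(vb, va, self))))
}

# ---- candidate-selection oracle: exhaustive mass scan ----------------

oracle_candidates <- function(spectrum, peptides, settings) {
  neutral <- spectrum$pepmass * spectrum$charge -
    spectrum$charge * 1.00727646688
  if (spectrum$charge < settings$charge_range[1] ||
      spectrum$charge > settings$charge_range[2])
    return(character(0))
  ks <- seq(settings$isotope_error[1], settings$isotope_error[2])
  hit <- vapply(seq_len(nrow(peptides)), function(i) {
    any(abs(neutral - ks * 1.00335 - peptides$mass[i]) <=
          settings$parent_tolerance)
  }, logical(1))
  sort(unique(sprintf("%s@%d", peptides$sequence[hit],
                      peptides$start[hit])))
}

# ---- fixture builders ------------------------------------------------

make_spectrum <- function(mz, intensity = rep(1, length(mz)),
                          pepmass = NA_real_, charge = 2L,
                          title = "t", peptide = NA_character_) {
  list(mz = mz, intensity = intensity, pepmass = pepmass, charge = charge,
       title = title, peptide = peptide)
}

make_set <- function(spot_id, spectra, morph = substr(spot_id, 1, 1)) {
  structure(list(spot_id = spot_id, morph = morph, spectra = spectra),
            class = "spectrum_set")
}

make_spots <- function(pI, log10_mw, ids = sprintf("s%02d", seq_along(pI)),
                       intensity = rep(100, length(pI)),
                       morph = "W", replicate = 1) {
  data.frame(spot_id = ids, pI = pI, log10_mw = log10_mw,
             intensity = intensity, replicate = replicate, morph = morph)
}

# Random peak-list spectrum set whose spectra carry a precursor drawn
# uniformly over a mass window (noise spectra for null searches).
make_noise_set <- function(spot_id, n_spectra, mass_range, n_peaks = 40) {
  spectra <- lapply(seq_len(n_spectra), function(k) {
    mass <- stats::runif(1, mass_range[1], mass_range[2])
    make_spectrum(mz = sort(stats::runif(n_peaks, 100, 2000)),
                  intensity = stats::rlnorm(n_peaks, log(50), 0.5),
                  pepmass = (mass + 2 * 1.00727646688) / 2,
                  charge = 2L,
                  title = sprintf("%s.noise%03d", spot_id, k))
  })
  make_set(spot_id, spectra)
}
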