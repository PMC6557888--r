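# Binned-cosine distances between per-spot MS/MS spectrum sets, the
# spot-by-spot distance matrix, and per-spot (self, minimum non-self)
# distance pairs.

#' Bin a spectrum into a fixed intensity vector
#'
#' Peaks are accumulated into fixed-width m/z bins over `mz_range` after a
#' square-root intensity transform (square roots are summed within a
#' bin); peaks outside the range are dropped. A zero vector is allowed.
#'
#' @param spectrum List with `mz` and `intensity`.
#' @param bin_width Bin width in Da (default 1.0).
#' @param mz_range m/z range covered, default `c(100, 2000)`.
#' @return Numeric intensity vector of length
#'   `ceiling(diff(mz_range) / bin_width)`.
#' @export
bin_spectrum <- function(spectrum, bin_width = 1.0, mz_range = c(100, 2000)) {
  stopifnot(bin_width > 0, length(mz_range) == 2, mz_range[1] < mz_range[2])
  n_bins <- ceiling((mz_range[2] - mz_range[1]) / bin_width)
  v <- numeric(n_bins)
  mz <- spectrum$mz; int <- spectrum$intensity
  keep <- !is.na(mz) & mz >= mz_range[1] & mz < mz_range[2]
  if (!any(keep)) return(v)
  bin <- floor((mz[keep] - mz_range[1]) / bin_width) + 1L
  bin[bin > n_bins] <- n_bins
  acc <- tapply(sqrt(int[keep]), bin, sum)
  v[as.integer(names(acc))] <- as.numeric(acc)
  v
}

#' Cosine distance between two intensity vectors
#'
#' `1 - (u . v) / (|u| |v|)`. If exactly one vector has zero norm the
#' distance is defined as 1; if both are zero it is 0.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Distance in `[0, 1]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must have the same length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 && nv == 0) return(0)
  if (nu == 0 || nv == 0) return(1)
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 1)
}

# Bin all spectra of a set into a matrix (rows = spectra) of unit-norm
# vectors; zero-norm rows are kept as zeros and handled by the caller.
bin_set_matrix <- function(set, bin_width, mz_range) {
  m <- t(vapply(set$spectra, bin_spectrum,
                numeric(ceiling(diff(mz_range) / bin_width)),
                bin_width = bin_width, mz_range = mz_range))
  m
}

cross_cosine_distance <- function(ma, mb) {
  na <- sqrt(rowSums(ma^2)); nb <- sqrt(rowSums(mb^2))
  dot <- ma %*% t(mb)
  denom <- outer(na, nb)
  d <- 1 - dot / denom
  d[denom == 0] <- 1
  both0 <- outer(na == 0, nb == 0, "&")
  d[both0] <- 0
  pmin(pmax(d, 0), 1)
}

#' Set-to-set spectral distance
#'
#' Symmetrized mean-of-best-matches: for every spectrum of A the minimum
#' binned-cosine distance to B's spectra is taken; the two directed means
#' are averaged. When A and B are the same set (self-distance) the
#' identical spectrum index is excluded from each minimum (leave-one-out),
#' so the self-distance measures within-spot spectral dispersion and is
#' strictly positive for heterogeneous sets. For singleton sets the
#' measure reduces to the plain cosine distance of the two spectra; a
#' self-distance of a singleton set is undefined and returned as `NA`.
#'
#' @param a,b `spectrum_set` objects.
#' @param bin_width,mz_range Binning parameters (see [bin_spectrum()]).
#' @param self Compare a set with itself in leave-one-out mode. Defaults
#'   to `TRUE` when `a` and `b` share the same `spot_id`.
#' @return Distance in `[0, 1]`, or `NA` for a singleton self-distance.
#' @export
set_distance <- function(a, b, bin_width = 1.0, mz_range = c(100, 2000),
                         self = identical(a$spot_id, b$spot_id)) {
  ma <- bin_set_matrix(a, bin_width, mz_range)
  mb <- if (self) ma else bin_set_matrix(b, bin_width, mz_range)
  d <- cross_cosine_distance(ma, mb)
  if (self) {
    if (nrow(ma) < 2) return(NA_real_)
    diag(d) <- Inf
  }
  mean(c(mean(apply(d, 1, min)), mean(apply(d, 2, min))))
}

#' Spot-by-spot distance matrix
#'
#' Computes the symmetric matrix of set distances over all unordered pairs
#' of spectrum sets (n(n-1)/2 off-diagonal comparisons) plus the n
#' leave-one-out self-distances on the diagonal.
#'
#' @param sets List of `spectrum_set` objects (at least 2).
#' @inheritParams set_distance
#' @return A `distance_matrix`: symmetric numeric matrix with spot ids as
#'   dimnames, morph labels in attribute `"morphs"` and the off-diagonal
#'   comparison count in attribute `"n_pairs"`.
#' @export
distance_matrix <- function(sets, bin_width = 1.0, mz_range = c(100, 2000)) {
  n <- length(sets)
  stopifnot(n >= 2)
  ids <- vapply(sets, `[[`, character(1), "spot_id")
  morphs <- vapply(sets, `[[`, character(1), "morph")
  mats <- lapply(sets, bin_set_matrix, bin_width = bin_width,
                 mz_range = mz_range)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    di <- cross_cosine_distance(mats[[i]], mats[[i]])
    if (nrow(mats[[i]]) < 2) {
      m[i, i] <- NA_real_
    } else {
      diag(di) <- Inf
      m[i, i] <- mean(c(mean(apply(di, 1, min)), mean(apply(di, 2, min))))
    }
    for (j in seq_len(n)[-seq_len(i)]) {
      d <- cross_cosine_distance(mats[[i]], mats[[j]])
      m[i, j] <- m[j, i] <- mean(c(mean(apply(d, 1, min)),
                                   mean(apply(d, 2, min))))
    }
  }
  structure(m, morphs = stats::setNames(morphs, ids),
            n_pairs = n * (n - 1) / 2, class = c("distance_matrix", "matrix"))
}

#' Per-spot self and minimum non-self distances
#'
#' For every spot, pairs the diagonal self-distance with the minimum
#' off-diagonal distance, restricted either to spots of a different morph
#' (`mode = "different-morph"`, the default) or to any other spot
#' (`mode = "any"`).
#'
#' @param m A `distance_matrix`.
#' @param mode `"different-morph"` or `"any"`.
#' @return A data.frame with `spot_id`, `morph`, `self_distance`,
#'   `min_nonself`, `argmin` (spot id attaining the minimum), `mode`.
#'   Spots with an undefined (singleton) self-distance are dropped with a
#'   message.
#' @export
extract_minima <- function(m, mode = c("different-morph", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "distance_matrix"))
  morphs <- attr(m, "morphs")
  ids <- rownames(m)
  out <- lapply(seq_along(ids), function(i) {
    if (mode == "different-morph") {
      cols <- which(morphs != morphs[i])
      if (length(cols) == 0)
        stop("no spot of a different morph for ", ids[i], call. = FALSE)
    } else {
      cols <- setdiff(seq_along(ids), i)
    }
    vals <- m[i, cols]
    j <- cols[which.min(vals)]
    data.frame(spot_id = ids[i], morph = unname(morphs[i]),
               self_distance = m[i, i], min_nonself = min(vals),
               argmin = ids[j], mode = mode)
  })
  out <- do.call(rbind, out)
  undef <- is.na(out$self_distance)
  if (any(undef)) {
    message("dropping ", sum(undef),
            " spot(s) with undefined singleton self-distance")
    out <- out[!undef, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
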