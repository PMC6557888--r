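# Per-morph master gels from replicate spot lists, pairwise high master
# gels (HMG), the combined high master gel (CHMG) and excisable
# morph-unique spots.

#' Mutual-nearest spot matching between two spot tables
#'
#' Candidate pairs are spots within the tolerance box (`|dpI| <= tol_pI`
#' and `|dlog10MW| <= tol_logmw`); pairs are accepted greedily by
#' increasing normalized Euclidean distance
#' `sqrt((dpI/tol_pI)^2 + (dlogMW/tol_logmw)^2)` with lexicographic
#' spot-id tie-breaks, each spot matched at most once. The globally
#' closest remaining pair is always mutual-nearest, so this realizes
#' mutual-nearest matching deterministically.
#'
#' @param a,b Spot data.frames with columns `spot_id`, `pI`, `log10_mw`.
#' @param tol_pI,tol_logmw Tolerance box half-widths (pH units, log10 kDa).
#' @return A data.frame of matched pairs: `id_a`, `id_b`, `dist`
#'   (normalized units).
#' @export
match_spots <- function(a, b, tol_pI = 0.1, tol_logmw = 0.02) {
  stopifnot(tol_pI > 0, tol_logmw > 0)
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      dist = numeric(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  dpi <- outer(a$pI, b$pI, "-") / tol_pI
  dmw <- outer(a$log10_mw, b$log10_mw, "-") / tol_logmw
  ok <- abs(dpi) <= 1 & abs(dmw) <= 1
  if (!any(ok)) return(empty)
  idx <- which(ok, arr.ind = TRUE)
  d <- sqrt(dpi[ok]^2 + dmw[ok]^2)
  ord <- order(d, a$spot_id[idx[, 1]], b$spot_id[idx[, 2]])
  idx <- idx[ord, , drop = FALSE]; d <- d[ord]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  data.frame(id_a = a$spot_id[idx[keep, 1]],
             id_b = b$spot_id[idx[keep, 2]],
             dist = d[keep])
}

#' Build a per-morph master gel from three replicates
#'
#' Spots are clustered across the three replicates by mutual-nearest
#' matching within the tolerance box on every replicate pair; clusters
#' supported by at least two replicates become consensus spots at the
#' member-mean position -- the "present in at least two of the three best
#' gels" rule.
#'
#' @param replicates List of exactly 3 spot data.frames of the same morph
#'   (columns `spot_id`, `pI`, `log10_mw`, `intensity`, `morph`).
#' @param tol_pI,tol_logmw Matching tolerances.
#' @return A `master_gel`: list with `morph` and `spots` (data.frame
#'   `spot_id`, `pI`, `log10_mw`, `intensity`, `support`, `member_ids`).
#'   The consensus `spot_id` is the lexicographically smallest member id,
#'   which traces back to the truth manifest on synthetic data.
#' @export
match_replicates <- function(replicates, tol_pI = 0.1, tol_logmw = 0.02) {
  if (length(replicates) != 3)
    stop("exactly 3 replicates are required", call. = FALSE)
  morphs <- unique(unlist(lapply(replicates, function(r) unique(r$morph))))
  morphs <- morphs[!is.na(morphs)]
  if (length(morphs) > 1)
    stop("replicates mix morphs: ", paste(morphs, collapse = ", "),
         call. = FALSE)
  morph <- if (length(morphs) == 1) morphs else NA_character_

  sizes <- vapply(replicates, nrow, integer(1))
  off <- cumsum(c(0L, sizes))
  all_spots <- do.call(rbind, lapply(replicates, function(r)
    r[, c("spot_id", "pI", "log10_mw", "intensity")]))
  parent <- seq_len(nrow(all_spots))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    a <- replicates[[pair[1]]]; b <- replicates[[pair[2]]]
    m <- match_spots(a, b, tol_pI, tol_logmw)
    if (nrow(m) == 0) next
    ia <- off[pair[1]] + match(m$id_a, a$spot_id)
    ib <- off[pair[2]] + match(m$id_b, b$spot_id)
    for (k in seq_along(ia)) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(nrow(all_spots)), find, integer(1))
  rep_of <- rep(seq_len(3), times = sizes)
  clusters <- split(seq_len(nrow(all_spots)), root)
  support <- vapply(clusters, function(ix) length(unique(rep_of[ix])),
                    integer(1))
  keep <- clusters[support >= 2]
  spots <- do.call(rbind, lapply(keep, function(ix) {
    ids <- all_spots$spot_id[ix]
    real <- ids[!startsWith(ids, "speckle_")]
    data.frame(spot_id = if (length(real)) min(real) else min(ids),
               pI = mean(all_spots$pI[ix]),
               log10_mw = mean(all_spots$log10_mw[ix]),
               intensity = mean(all_spots$intensity[ix]),
               support = length(unique(rep_of[ix])),
               member_ids = paste(sort(all_spots$spot_id[ix]),
                                  collapse = ";"))
  }))
  if (is.null(spots))
    spots <- data.frame(spot_id = character(0), pI = numeric(0),
                        log10_mw = numeric(0), intensity = numeric(0),
                        support = integer(0), member_ids = character(0))
  spots <- spots[order(spots$spot_id), , drop = FALSE]
  rownames(spots) <- NULL
  structure(list(morph = morph, spots = spots), class = "master_gel")
}

#' @export
print.master_gel <- function(x, ...) {
  cat("master_gel morph", x$morph, ":", nrow(x$spots), "consensus spots\n")
  invisible(x)
}

#' Select the three best of four gel replicates
#'
#' The reproducibility surrogate for visual gel quality: each replicate is
#' scored by its mean unmatched-spot fraction against the other three
#' (mutual-nearest matching within the tolerance box) and the worst one is
#' dropped. Ties drop the largest `replicate` id, so four identical
#' replicates keep the first three. Exactly three replicates pass through
#' unchanged.
#'
#' @param replicates List of 4 (or 3) spot data.frames with a `replicate`
#'   column.
#' @inheritParams match_spots
#' @return List of 3 spot data.frames.
#' @export
select_best_replicates <- function(replicates, tol_pI = 0.1,
                                   tol_logmw = 0.02) {
  if (length(replicates) == 3) return(replicates)
  if (length(replicates) != 4)
    stop("expected 4 replicates (or exactly 3 to pass through)",
         call. = FALSE)
  rid <- vapply(replicates, function(r) unique(r$replicate)[1], numeric(1))
  unmatched <- vapply(seq_len(4), function(i) {
    others <- setdiff(seq_len(4), i)
    fr <- vapply(others, function(j) {
      n <- nrow(replicates[[i]])
      if (n == 0) return(0)
      1 - nrow(match_spots(replicates[[i]], replicates[[j]],
                           tol_pI, tol_logmw)) / n
    }, numeric(1))
    mean(fr)
  }, numeric(1))
  worst <- which(unmatched == max(unmatched))
  drop <- worst[which.max(rid[worst])]
  replicates[setdiff(seq_len(4), drop)]
}

#' Percentage conventions of the HMG summary
#'
#' Reporting convention for a pairwise master-gel comparison: the common
#' percentage is the matched-pair count relative to the *mean* of the two
#' master-gel sizes, while each unique percentage is relative to the *sum*
#' of the sizes; all rounded to one decimal. The mixed denominators are a
#' deliberate reporting quirk of this pipeline, chosen so that common and
#' unique percentages of standard 2-DE comparison reports are reproduced
#' exactly.
#'
#' @param common Matched-pair count.
#' @param n_a,n_b Master-gel spot counts.
#' @return Named numeric vector `pct_common`, `pct_unique_a`,
#'   `pct_unique_b` (percent, one decimal).
#' @export
summarize_hmg <- function(common, n_a, n_b) {
  if (common > min(n_a, n_b))
    stop("common count exceeds a master-gel size", call. = FALSE)
  if (common < 0 || n_a < 0 || n_b < 0)
    stop("counts must be non-negative", call. = FALSE)
  c(pct_common = round(100 * common / ((n_a + n_b) / 2), 1),
    pct_unique_a = round(100 * (n_a - common) / (n_a + n_b), 1),
    pct_unique_b = round(100 * (n_b - common) / (n_a + n_b), 1))
}

#' Compare two master gels into a high master gel (HMG)
#'
#' Mutual-nearest matching between the consensus spots of two morphs'
#' master gels; matched spots are common, the rest unique to their morph.
#'
#' @param a,b `master_gel` objects of distinct morphs.
#' @inheritParams match_spots
#' @return An `hmg_comparison`: list with `morph_a`, `morph_b`, `n_a`,
#'   `n_b`, `common`, `unique_a`, `unique_b`, `pairs` (data.frame `id_a`,
#'   `id_b`), percentages per [summarize_hmg()], and the two spot tables.
#' @export
compare_master_gels <- function(a, b, tol_pI = 0.1, tol_logmw = 0.02) {
  stopifnot(inherits(a, "master_gel"), inherits(b, "master_gel"))
  if (identical(a$morph, b$morph))
    stop("master gels must belong to distinct morphs", call. = FALSE)
  pairs <- match_spots(a$spots, b$spots, tol_pI, tol_logmw)
  n_a <- nrow(a$spots); n_b <- nrow(b$spots); common <- nrow(pairs)
  pct <- summarize_hmg(common, n_a, n_b)
  structure(list(morph_a = a$morph, morph_b = b$morph,
                 n_a = n_a, n_b = n_b, common = common,
                 unique_a = n_a - common, unique_b = n_b - common,
                 pairs = pairs,
                 pct_common = pct[["pct_common"]],
                 pct_unique_a = pct[["pct_unique_a"]],
                 pct_unique_b = pct[["pct_unique_b"]],
                 spots_a = a$spots, spots_b = b$spots),
            class = "hmg_comparison")
}

#' @export
print.hmg_comparison <- function(x, ...) {
  cat(sprintf(
    "HMG %s vs %s: %d (%.1f%%) common; %d (%.1f%%) unique to %s; %d (%.1f%%) unique to %s\n",
    x$morph_a, x$morph_b, x$common, x$pct_common,
    x$unique_a, x$pct_unique_a, x$morph_a,
    x$unique_b, x$pct_unique_b, x$morph_b))
  invisible(x)
}

#' Combine the three pairwise HMGs into the CHMG
#'
#' Superimposes the three high master gels. Master-gel spots linked by any
#' pairwise match are merged into one CHMG record labelled `"shared"`; a
#' spot unmatched in both comparisons involving its morph is labelled
#' unique to that morph.
#'
#' @param hmg_wy,hmg_wr,hmg_yr The three `hmg_comparison` objects covering
#'   morph pairs W-Y, W-R and Y-R (any order of arguments with those
#'   morphs).
#' @return A `chmg`: list with `spots` (data.frame `spot_id`, `morph`,
#'   `pI`, `log10_mw`, `intensity`, `label` in
#'   `shared`/`unique_W`/`unique_Y`/`unique_R`).
#' @export
combine_hmgs <- function(hmg_wy, hmg_wr, hmg_yr) {
  hmgs <- list(hmg_wy, hmg_wr, hmg_yr)
  covered <- sort(vapply(hmgs, function(h)
    paste(sort(c(h$morph_a, h$morph_b)), collapse = "-"), character(1)))
  if (!identical(covered, c("R-W", "R-Y", "W-Y")))
    stop("the three HMGs must cover morph pairs W-Y, W-R and Y-R",
         call. = FALSE)
  # One node per (morph, master spot id); union by matched pairs.
  nodes <- unique(do.call(rbind, lapply(hmgs, function(h) rbind(
    data.frame(morph = h$morph_a, spot_id = h$spots_a$spot_id,
               pI = h$spots_a$pI, log10_mw = h$spots_a$log10_mw,
               intensity = h$spots_a$intensity),
    data.frame(morph = h$morph_b, spot_id = h$spots_b$spot_id,
               pI = h$spots_b$pI, log10_mw = h$spots_b$log10_mw,
               intensity = h$spots_b$intensity)))))
  key <- paste(nodes$morph, nodes$spot_id)
  parent <- seq_len(nrow(nodes))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (h in hmgs) {
    if (nrow(h$pairs) == 0) next
    ia <- match(paste(h$morph_a, h$pairs$id_a), key)
    ib <- match(paste(h$morph_b, h$pairs$id_b), key)
    for (k in seq_along(ia)) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(nrow(nodes)), find, integer(1))
  clusters <- split(seq_len(nrow(nodes)), root)
  spots <- do.call(rbind, lapply(clusters, function(ix) {
    ms <- unique(nodes$morph[ix])
    label <- if (length(ms) > 1) "shared" else paste0("unique_", ms)
    data.frame(spot_id = min(nodes$spot_id[ix]),
               morph = paste(sort(ms), collapse = ";"),
               pI = mean(nodes$pI[ix]),
               log10_mw = mean(nodes$log10_mw[ix]),
               intensity = mean(nodes$intensity[ix]),
               label = label)
  }))
  spots <- spots[order(spots$spot_id), , drop = FALSE]
  rownames(spots) <- NULL
  structure(list(spots = spots), class = "chmg")
}

#' @export
print.chmg <- function(x, ...) {
  cat("CHMG:", nrow(x$spots), "spots (",
    paste(names(table(x$spots$label)), table(x$spots$label),
          collapse = ", "), ")\n")
  invisible(x)
}

#' Select excisable morph-unique CHMG spots
#'
#' A morph-unique spot is excisable when its nearest CHMG neighbour of any
#' label lies beyond `min_separation` (Euclidean distance in raw
#' (pI, log10 MW) units) -- the in-silico counterpart of picking spots
#' that do not overlap others on the gel. Order is deterministic: morph
#' W, Y, R, then intensity descending.
#'
#' @param chmg A `chmg` from [combine_hmgs()].
#' @param min_separation Minimum neighbour distance (default 0.05).
#' @return Character vector of excisable spot ids.
#' @export
select_excisable <- function(chmg, min_separation = 0.05) {
  stopifnot(inherits(chmg, "chmg"), min_separation > 0)
  sp <- chmg$spots
  uniq <- which(sp$label != "shared")
  if (length(uniq) == 0) return(character(0))
  d <- as.matrix(stats::dist(sp[, c("pI", "log10_mw")]))
  diag(d) <- Inf
  nn <- apply(d[uniq, , drop = FALSE], 1, min)
  sel <- sp[uniq[nn > min_separation], , drop = FALSE]
  morph_rank <- match(sub("^unique_", "", sel$label), MORPHS)
  sel <- sel[order(morph_rank, -sel$intensity, sel$spot_id), , drop = FALSE]
  sel$spot_id
}
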