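# Plain-text file formats: MGF spectrum sets, CSV spot lists, TSV truth
# manifest. MGF is read and written directly here -- the format is a
# simple line protocol (BEGIN IONS / PEPMASS / CHARGE / peak rows).

#' Write a spectrum set to Mascot Generic Format (MGF)
#'
#' @param set A `spectrum_set` (see [simulate_spectra()]).
#' @param path Output path.
#' @export
write_mgf <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in set$spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$title),
                 paste0("PEPMASS=", format(sp$pepmass, nsmall = 4,
                                           scientific = FALSE)),
                 paste0("CHARGE=", sp$charge, "+"),
                 sprintf("%.4f %.2f", sp$mz, sp$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Read an MGF file into a spectrum set
#'
#' @param path Path to an MGF file.
#' @param spot_id Spot identifier to attach; defaults to the file name
#'   without extension.
#' @param morph Morph label; defaults to the first character of `spot_id`.
#' @return A `spectrum_set`.
#' @export
read_mgf <- function(path, spot_id = NULL,
                     morph = NULL) {
  if (is.null(spot_id))
    spot_id <- sub("\\.mgf$", "", basename(path), ignore.case = TRUE)
  if (is.null(morph)) morph <- substr(spot_id, 1, 1)
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: ", path, call. = FALSE)
  spectra <- lapply(seq_along(begins), function(i) {
    blk <- lines[(begins[i] + 1):(ends[i] - 1)]
    is_hdr <- grepl("=", blk, fixed = TRUE)
    hdr <- blk[is_hdr]
    key <- sub("=.*$", "", hdr)
    val <- sub("^[^=]*=", "", hdr)
    peaks <- blk[!is_hdr & nzchar(blk)]
    pk <- do.call(rbind, lapply(strsplit(peaks, "[ \t]+"), as.numeric))
    pepmass <- as.numeric(strsplit(val[key == "PEPMASS"][1], " ")[[1]][1])
    charge <- as.integer(sub("\\+$", "", val[key == "CHARGE"][1]))
    list(mz = if (length(peaks)) pk[, 1] else numeric(0),
         intensity = if (length(peaks)) pk[, 2] else numeric(0),
         pepmass = pepmass, charge = charge,
         title = if (any(key == "TITLE")) val[key == "TITLE"][1] else
           paste0(spot_id, ".scan", i),
         peptide = NA_character_)
  })
  structure(list(spot_id = spot_id, morph = morph, spectra = spectra),
            class = "spectrum_set")
}

#' Write / read replicate spot lists as CSV
#'
#' Columns: `spot_id`, `pI`, `log10_mw` (log10 kDa), `intensity`,
#' `replicate`, `morph`.
#'
#' @param spots Spot data.frame (see [simulate_gels()]).
#' @param path File path.
#' @export
write_spot_csv <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @export
read_spot_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the ground-truth manifest as TSV
#'
#' One row per true spot: `spot_id`, `morph`, `accession`, `unique_flag`.
#'
#' @param truth A `synthetic_truth`.
#' @param path File path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(spot_id = names(truth$spot_protein),
                   morph = substr(names(truth$spot_protein), 1, 1),
                   accession = unname(truth$spot_protein),
                   unique_flag = unname(truth$unique_flags))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
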