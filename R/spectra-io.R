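# Peak-list containers and I/O (two-column CSV and MGF), plus ppm-tolerance
# matching of observed peaks against an expected ion list.

#' Construct a spectrum
#'
#' @param peaks data.frame with columns `mz`, `intensity` (any order; it is
#'   sorted ascending by m/z).
#' @param precursor_mz Precursor m/z (sodiated molecular ion by default
#'   convention). May be smaller than fragment m/z values (water-loss
#'   precursors are allowed).
#' @param adduct_spec Adduct of the precursor (default sodium).
#' @param id Free-text identifier.
#' @return A `spectrum` object.
#' @export
spectrum <- function(peaks, precursor_mz, adduct_spec = adduct("M+Na"), id = "") {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) == 0L) stop("no peaks")
  if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)) stop("m/z must be positive")
  if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0)) {
    stop("intensities must be non-negative")
  }
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L, precursor_mz > 0)
  peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, precursor_mz = precursor_mz,
                 adduct = adduct(adduct_spec), id = id),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", if (nzchar(x$id)) paste0(x$id, "  ") else "",
      nrow(x$peaks), " peaks, precursor ", format_mz(x$precursor_mz), " ",
      x$adduct$name, "\n", sep = "")
  invisible(x)
}

#' Read a peak list (CSV or MGF)
#'
#' CSV dialect: header `mz,intensity`. MGF: standard
#' `BEGIN IONS`/`TITLE`/`PEPMASS` blocks; the first block is read.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"mgf"`.
#' @param precursor_mz Precursor override for CSV input (CSV carries none);
#'   required there unless the file has an `# precursor_mz=` comment.
#' @param id Identifier; defaults to the file name or MGF TITLE.
#' @return A `spectrum`.
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "mgf"),
                          precursor_mz = NULL, id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
  }
  if (format == "csv") {
    lines <- readLines(path)
    meta <- grep("^#\\s*precursor_mz\\s*=", lines, value = TRUE)
    if (is.null(precursor_mz) && length(meta)) {
      precursor_mz <- as.numeric(sub("^#\\s*precursor_mz\\s*=", "", meta[1]))
    }
    if (is.null(precursor_mz)) stop("precursor_mz required for CSV peak lists")
    df <- utils::read.csv(textConnection(lines), comment.char = "#",
                          stringsAsFactors = FALSE)
    if (!all(c("mz", "intensity") %in% names(df))) {
      stop("CSV peak list needs header 'mz,intensity'")
    }
    return(spectrum(df, precursor_mz, id = id %||% basename(path)))
  }
  # MGF
  lines <- readLines(path)
  b <- which(trimws(lines) == "BEGIN IONS")
  e <- which(trimws(lines) == "END IONS")
  if (!length(b) || !length(e) || e[1] < b[1]) stop("malformed MGF: no ion block")
  block <- lines[(b[1] + 1L):(e[1] - 1L)]
  title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
  pep <- grep("^PEPMASS=", block, value = TRUE)
  if (!length(pep)) stop("malformed MGF: missing PEPMASS")
  pm <- as.numeric(strsplit(sub("^PEPMASS=", "", pep[1]), "\\s+")[[1]][1])
  peakln <- block[!grepl("^[A-Z_]+=", block) & nzchar(trimws(block))]
  if (!length(peakln)) stop("no peaks")
  vals <- lapply(seq_along(peakln), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(peakln[i]), "[[:space:],]+")[[1]]))
    if (length(v) < 2 || anyNA(v)) {
      stop("malformed MGF peak line ", b[1] + which(block == peakln[i])[1],
           ": ", peakln[i])
    }
    v[1:2]
  })
  m <- do.call(rbind, vals)
  spectrum(data.frame(mz = m[, 1], intensity = m[, 2]),
           precursor_mz = precursor_mz %||% pm,
           id = id %||% (if (!is.na(title)) title else basename(path)))
}

#' Write a peak list (CSV or MGF)
#'
#' @param spec A `spectrum`.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"csv"` or `"mgf"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spec, path, format = c("auto", "csv", "mgf")) {
  stopifnot(inherits(spec, "spectrum"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
  }
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# precursor_mz=%.6f", spec$precursor_mz), con)
    utils::write.csv(
      data.frame(mz = sprintf("%.6f", spec$peaks$mz),
                 intensity = sprintf("%.6f", spec$peaks$intensity)),
      con, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", spec$id),
      sprintf("PEPMASS=%.6f", spec$precursor_mz),
      "CHARGE=1+",
      sprintf("%.6f %.6f", spec$peaks$mz, spec$peaks$intensity),
      "END IONS"), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match observed peaks to expected ions within a ppm tolerance
#'
#' Each expected ion is matched to the nearest observed peak (smallest
#' absolute ppm error, ties broken by higher intensity) within `tol_ppm`.
#' One observed peak may satisfy several expected ions; such degeneracy is
#' recorded. Unmatched expected ions are returned separately.
#'
#' @param spec A `spectrum`.
#' @param expected data.frame from [expected_peaks()] (needs `label`, `mz`;
#'   other columns are carried through).
#' @param tol_ppm Tolerance in ppm (default 5, the confirmation rule).
#' @return List of class `peak_matches`: `matches` (expected columns +
#'   `observed_mz`, `intensity`, `ppm`, `degenerate`), `unmatched`
#'   (expected rows with no peak in tolerance), `tol_ppm`.
#' @export
match_peaks <- function(spec, expected, tol_ppm = 5.0) {
  stopifnot(inherits(spec, "spectrum"), tol_ppm > 0)
  stopifnot(is.data.frame(expected), all(c("label", "mz") %in% names(expected)))
  obs <- spec$peaks
  idx <- integer(nrow(expected))
  ppm <- numeric(nrow(expected))
  for (i in seq_len(nrow(expected))) {
    p <- ppm_error(obs$mz, expected$mz[i])
    ok <- which(p <= tol_ppm)
    if (!length(ok)) { idx[i] <- NA_integer_; next }
    best <- ok[order(p[ok], -obs$intensity[ok])][1]
    idx[i] <- best
    ppm[i] <- p[best]
  }
  hit <- !is.na(idx)
  matches <- expected[hit, , drop = FALSE]
  if (nrow(matches)) {
    names(matches)[names(matches) == "mz"] <- "expected_mz"
    matches$observed_mz <- obs$mz[idx[hit]]
    matches$intensity <- obs$intensity[idx[hit]]
    matches$ppm <- ppm[hit]
    matches$degenerate <- duplicated(idx[hit]) | duplicated(idx[hit], fromLast = TRUE)
    rownames(matches) <- NULL
  }
  structure(list(matches = matches,
                 unmatched = expected[!hit, , drop = FALSE],
                 tol_ppm = tol_ppm),
            class = "peak_matches")
}

#' @export
print.peak_matches <- function(x, ...) {
  cat("<peak_matches> ", nrow(x$matches), " matched, ", nrow(x$unmatched),
      " unmatched (tol ", x$tol_ppm, " ppm)\n", sep = "")
  invisible(x)
}
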