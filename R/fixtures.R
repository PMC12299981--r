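# The 21 identified sirolimus metabolites and their packaged synthetic
# spectra. No raw spectra are deposited with the source study, so the
# packaged per-metabolite MGF files are generated by the package's own
# simulator (1 ppm mass error, 5 decoys, fixed per-metabolite seeds) and
# are regenerable with make_srl_fixture_spectra().

#' The 21 identified sirolimus metabolites (truth table)
#'
#' One row per reported metabolite; the four chromatographically separated
#' hydroxy-piperidine isomers (a-d) are distinct entries with the same
#' (unresolvable) site assignment, and 45- and 46-hydroxy are distinct
#' entries sharing the MS-ambiguous 45/46 pair.
#'
#' @return data.frame with `id`, `mods` (compact modification string) and
#'   `class`.
#' @export
srl_metabolite_truths <- function() {
  df <- data.frame(
    id = c("46-hydroxy", "45-hydroxy", "23/24-hydroxy", "12-hydroxy",
           "25-hydroxy", "11-hydroxy",
           "hydroxy-piperidine-a", "hydroxy-piperidine-b",
           "hydroxy-piperidine-c", "hydroxy-piperidine-d",
           "14-hydroxy", "49-hydroxy",
           "12,23/24-dihydroxy",
           "16-O-desmethyl", "27-O-desmethyl", "39-O-desmethyl",
           "16,39-O-didesmethyl", "27,39-O-didesmethyl",
           "hydroxy-piperidine-39-O-desmethyl",
           "12-hydroxy-39-O-desmethyl",
           "11-hydroxy-16-O-desmethyl"),
    mods = c("OH@45/46", "OH@45/46", "OH@23/24", "OH@12",
             "OH@25", "OH@11",
             "OH@pip", "OH@pip", "OH@pip", "OH@pip",
             "OH@14", "OH@49",
             "OH@12+OH@23/24",
             "DM@16", "DM@27", "DM@39",
             "DM@16+DM@39", "DM@27+DM@39",
             "OH@pip+DM@39",
             "OH@12+DM@39",
             "OH@11+DM@16"),
    stringsAsFactors = FALSE
  )
  df$class <- vapply(df$mods, function(m) classify(parse_mods(m)), "")
  df
}

.fixture_filename <- function(id) paste0(gsub("[/,]", "-", id), ".mgf")

#' Regenerate the packaged synthetic metabolite spectra
#'
#' Writes one MGF per metabolite in [srl_metabolite_truths()], simulated at
#' `ppm_sigma = 1`, 5 decoys, seed `base_seed + row`.
#'
#' @param dir Output directory.
#' @param lib Fragment library (default packaged).
#' @param ppm_sigma,n_decoys,base_seed Simulation settings.
#' @return Character vector of file paths, invisibly.
#' @export
make_srl_fixture_spectra <- function(dir, lib = srl_fragment_library(),
                                     ppm_sigma = 1, n_decoys = 5,
                                     base_seed = 20250720) {
  truths <- srl_metabolite_truths()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(truths))
  for (i in seq_len(nrow(truths))) {
    sp <- simulate_spectrum(lib, truths$mods[i], ppm_sigma = ppm_sigma,
                            n_decoys = n_decoys, seed = base_seed + i,
                            id = truths$id[i])
    paths[i] <- file.path(dir, .fixture_filename(truths$id[i]))
    write_peaklist(sp, paths[i], format = "mgf")
  }
  invisible(paths)
}

#' Load the packaged synthetic metabolite spectra
#'
#' @param dir Directory of MGF fixtures (default: the packaged set).
#' @return Named list of `spectrum` objects, in [srl_metabolite_truths()]
#'   order.
#' @export
srl_metabolite_spectra <- function(dir = system.file("extdata", "synthetic_spectra",
                                                     package = "metsom")) {
  truths <- srl_metabolite_truths()
  paths <- file.path(dir, .fixture_filename(truths$id))
  missing <- !file.exists(paths)
  if (any(missing)) stop("missing fixture spectra: ",
                         paste(truths$id[missing], collapse = ", "))
  stats::setNames(lapply(paths, read_peaklist), truths$id)
}
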