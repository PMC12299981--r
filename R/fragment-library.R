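# The sirolimus fragment library: sodiated alpha-cleavage fragments A-R,
# the molecular ion, and hydroxylation-diagnostic ions, each with a
# carbon-coverage set and a position in the fragmentation tree. The forward
# model (expected_peaks) maps a modification hypothesis to the peak set it
# predicts.

# Published 4-dp reference masses used to validate any loaded library.
.SRL_PRINTED_MZ <- c(
  SRL = 936.5444, A = 731.4493, B = 763.4756, C = 642.3249, D = 345.2036,
  E = 703.4544, F = 399.2506, G = 614.3300, H = 485.2510, I = 459.2717,
  J = 409.2349, K = 607.3969, L = 397.2349, M = 582.3037, N = 453.2248,
  O = 441.2611, P = 381.2400, Q = 320.1105, R = 413.2662
)

# IUPAC -> Chemical Abstracts numbering for the demethylation sites (the
# same metabolite is named differently under the two systems).
.IUPAC_TO_CAS <- c("39" = "41", "16" = "7", "27" = "32")

# Expand a coverage string like "17-49,51-52,pip" into a character vector
# of positions.
.parse_coverage <- function(s) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s)) return(character())
  out <- unlist(lapply(strsplit(s, ",", fixed = TRUE)[[1]], function(tok) {
    tok <- trimws(tok)
    if (tok == "pip") return("pip")
    if (grepl("^[0-9]+-[0-9]+$", tok)) {
      r <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
      return(as.character(seq(r[1], r[2])))
    }
    if (grepl("^[0-9]+$", tok)) return(tok)
    stop("cannot parse coverage token: ", tok)
  }))
  bad <- setdiff(out, .ALL_POSITIONS)
  if (length(bad)) stop("coverage positions outside 1-52/pip: ",
                        paste(bad, collapse = ", "))
  unique(out)
}

#' Load a fragment library from a structured text file
#'
#' Reads a CSV with columns `label, mz, kind, parent, site, coverage`
#' (`#` comment lines allowed) and validates it: unique labels, positive
#' masses, parent links forming a tree rooted at the molecular ion, child
#' coverage a subset of its parent's coverage, non-empty coverage for
#' alpha-cleavage fragments, and (for the sirolimus library) every stored
#' mass matching the published 4-dp reference value to within 0.0001 Da.
#'
#' @param path CSV file; defaults to the packaged sirolimus library.
#' @param reference_mz Named vector of 4-dp reference masses to validate
#'   against, or `NULL` to skip. Default: the published sirolimus values.
#' @return A `fragment_library`: list with `fragments` (data.frame with a
#'   `coverage` list-column), `molecular_formula`, `adduct`, `numbering`.
#' @export
read_fragment_library <- function(path = system.file("extdata", "srl_fragments.csv",
                                                     package = "metsom"),
                                  reference_mz = .SRL_PRINTED_MZ) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(site = "character"))
  need <- c("label", "mz", "kind", "parent", "site", "coverage")
  if (!all(need %in% names(df))) {
    stop("library file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$label)) {
    stop("duplicate fragment label: ",
         paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
  }
  if (any(!is.finite(df$mz)) || any(df$mz <= 0)) stop("fragment masses must be positive")
  df$coverage <- lapply(df$coverage, .parse_coverage)
  df$site <- trimws(ifelse(is.na(df$site), "", df$site))

  root <- df$label[df$kind == "molecular_ion"]
  if (length(root) != 1L) stop("library must contain exactly one molecular ion")

  alpha <- df$kind == "alpha_cleavage"
  if (any(lengths(df$coverage[alpha]) == 0)) {
    stop("alpha-cleavage fragments must have non-empty coverage: ",
         paste(df$label[alpha][lengths(df$coverage[alpha]) == 0], collapse = ", "))
  }
  diag <- df$kind == "hydroxylation_diagnostic"
  if (any(!nzchar(df$site[diag]))) stop("diagnostic ions need a site")

  # tree structure: every non-root parent exists, no cycles, rooted at the
  # molecular ion, child coverage within parent coverage
  for (i in seq_len(nrow(df))) {
    if (df$label[i] == root) next
    p <- df$parent[i]
    if (is.na(p) || !nzchar(p)) stop("fragment ", df$label[i], " has no parent")
    if (!p %in% df$label) stop("unknown parent ", p, " for fragment ", df$label[i])
    pcov <- df$coverage[[match(p, df$label)]]
    extra <- setdiff(df$coverage[[i]], pcov)
    if (length(extra)) {
      stop("coverage of ", df$label[i], " is not a subset of its parent ", p,
           " (extra: ", paste(extra, collapse = ", "), ")")
    }
    # walk to root to guard against cycles
    seen <- df$label[i]
    while (nzchar(p) && !is.na(p)) {
      if (p %in% seen) stop("fragmentation tree contains a cycle at ", p)
      seen <- c(seen, p)
      p <- df$parent[match(p, df$label)]
    }
    if (seen[length(seen)] != root) stop("tree not rooted at the molecular ion")
  }

  lib <- structure(list(
    fragments = df,
    molecular_formula = chem_formula("C51H79NO13"),
    adduct = adduct("M+Na"),
    numbering = list(system = "IUPAC", to_cas = .IUPAC_TO_CAS)
  ), class = "fragment_library")

  # the stored molecular-ion mass must agree with the formula arithmetic
  calc <- adduct_mz(lib$molecular_formula, lib$adduct)
  if (abs(df$mz[df$label == root] - calc) > 0.0001) {
    stop("stored molecular-ion mass disagrees with the formula-derived value")
  }
  if (!is.null(reference_mz)) {
    chk <- intersect(names(reference_mz), df$label)
    dev <- abs(round_half_up(df$mz[match(chk, df$label)], 4) - reference_mz[chk])
    if (any(dev > 0.0001 + 1e-9)) {
      stop("library masses disagree with reference table: ",
           paste(chk[dev > 0.0001 + 1e-9], collapse = ", "))
    }
  }
  lib
}

#' The packaged sirolimus fragment library
#' @return A validated `fragment_library` (18 alpha-cleavage fragments A-R,
#'   the sodiated molecular ion at 936.5444, and 9 diagnostic ions).
#' @export
srl_fragment_library <- function() read_fragment_library()

#' @export
print.fragment_library <- function(x, ...) {
  k <- table(x$fragments$kind)
  cat("<fragment_library> ", format(x$molecular_formula), " ", x$adduct$name,
      " ", format_mz(adduct_mz(x$molecular_formula, x$adduct)), "\n  ",
      paste(names(k), unname(k), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Does a site unit (character vector of positions) intersect a coverage set?
.unit_covered <- function(unit, coverage) any(unit %in% coverage)

#' Expected peak set under a modification hypothesis (forward model)
#'
#' Every fragment is shifted by the summed deltas of the modification
#' entries whose site unit intersects its coverage (candidate pairs shift a
#' fragment iff the pair intersects the coverage). Diagnostic ions for
#' hydroxylated sites are appended, themselves shifted by any other entry
#' whose site intersects the diagnostic's coverage. With rule R1 active,
#' fragments shifted by a methyl-carbon hydroxylation (C45/C46) emit a
#' methanol-loss satellite; with rule R2, fragments shifted by a C23/C24
#' hydroxylation emit a water-loss satellite flagged as expected to
#' dominate its parent's intensity.
#'
#' @param lib A `fragment_library`.
#' @param mods A `mod_set` (or a string for [parse_mods()]).
#' @param rules_on Character subset of `c("R1", "R2")`.
#' @return data.frame with `label`, `mz`, `shift_trail` (comma-separated
#'   shift labels), `kind`, `dominant_intensity` (logical, R2 satellites).
#' @examples
#' lib <- srl_fragment_library()
#' expected_peaks(lib, parse_mods("DM@39"))
#' @export
expected_peaks <- function(lib, mods = mod_set(), rules_on = c("R1", "R2")) {
  stopifnot(inherits(lib, "fragment_library"))
  if (is.character(mods)) mods <- parse_mods(mods)
  stopifnot(inherits(mods, "mod_set"))
  rules_on <- intersect(rules_on, c("R1", "R2"))
  fr <- lib$fragments
  oh_sites <- unlist(lapply(mods$entries, function(e)
    if (e$type == "hydroxylation") list(e$site) else NULL), recursive = FALSE)

  rows <- list()
  add <- function(label, mz, trail, kind, dom = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, mz = mz,
      shift_trail = paste(trail, collapse = ","),
      kind = kind, dominant_intensity = dom, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(fr))) {
    kind <- fr$kind[i]
    if (kind == "hydroxylation_diagnostic") next
    hits <- Filter(function(e) .unit_covered(e$site, fr$coverage[[i]]), mods$entries)
    trail <- vapply(hits, `[[`, "", "type")
    mz <- apply_shift(fr$mz[i], trail)
    add(fr$label[i], mz, trail, kind)
    if (length(hits)) {
      shifted_oh <- Filter(function(e) e$type == "hydroxylation", hits)
      for (e in shifted_oh) {
        if ("R1" %in% rules_on && any(e$site %in% c("45", "46"))) {
          add(paste0(fr$label[i], "-CH3OH"), apply_shift(mz, "methanol_loss"),
              c(trail, "methanol_loss"), "satellite")
        }
        if ("R2" %in% rules_on && any(e$site %in% c("23", "24"))) {
          add(paste0(fr$label[i], "-H2O"), apply_shift(mz, "water_loss"),
              c(trail, "water_loss"), "satellite", dom = TRUE)
        }
      }
    }
  }

  # diagnostic ions for hydroxylation entries whose unit carries one
  di <- which(fr$kind == "hydroxylation_diagnostic")
  for (i in di) {
    owner <- Filter(function(e) e$type == "hydroxylation" &&
                      fr$site[i] %in% e$site, mods$entries)
    if (!length(owner)) next
    others <- Filter(function(e) !identical(e, owner[[1]]) &&
                       .unit_covered(e$site, fr$coverage[[i]]), mods$entries)
    trail <- vapply(others, `[[`, "", "type")
    add(fr$label[i], apply_shift(fr$mz[i], trail), trail, "hydroxylation_diagnostic")
  }

  out <- do.call(rbind, rows)
  out[order(out$mz), , drop = FALSE]
}
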