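# Modification hypotheses. A modification is an O-demethylation or a
# hydroxylation at a site "unit": a single carbon position, an unresolvable
# candidate pair (23/24 or 45/46), or the piperidine ring token "pip"
# (C3-C6, never resolved further by MS). A modification set holds at most
# two entries: first- and second-generation metabolites.

# Legal site units per modification type. Demethylation can only occur at
# the three methoxy carbons; hydroxylation at the experimentally established
# positions (piperidine ring plus C11, C12, C14, C23, C24, C25, C45, C46,
# C49). C23/C24 and C45/C46 are modelled as first-class candidate pairs.
.DM_UNITS <- list("16", "27", "39")
.OH_UNITS <- list("11", "12", "14", c("23", "24"), "25", c("45", "46"),
                  "49", "pip")

.unit_id <- function(sites) paste(sites, collapse = "/")

.ALL_POSITIONS <- c(as.character(1:52), "pip")

#' A single metabolic modification
#'
#' @param type `"demethylation"` or `"hydroxylation"`.
#' @param site A carbon position (number or string), a candidate pair such
#'   as `c(23, 24)`, or `"pip"` for the piperidine ring.
#' @return A `modification` object.
#' @examples
#' modification("demethylation", 16)
#' modification("hydroxylation", c(45, 46))
#' @export
modification <- function(type = c("demethylation", "hydroxylation"), site) {
  type <- match.arg(type)
  site <- as.character(site)
  if (!all(site %in% .ALL_POSITIONS)) {
    stop("site must be a carbon position 1-52 or \"pip\", got: ",
         paste(site, collapse = "/"))
  }
  units <- if (type == "demethylation") .DM_UNITS else .OH_UNITS
  ok <- any(vapply(units, function(u) setequal(u, site), logical(1)))
  if (!ok) {
    stop("illegal ", type, " site unit: ", .unit_id(site),
         " (legal: ", paste(vapply(units, .unit_id, ""), collapse = ", "), ")")
  }
  structure(list(type = type, site = sort(site)), class = "modification")
}

#' A modification set (0-2 entries)
#'
#' @param ... `modification` objects (or a single list of them).
#' @return A `mod_set` object.
#' @examples
#' mod_set(modification("hydroxylation", 12), modification("demethylation", 39))
#' @export
mod_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      !inherits(entries[[1]], "modification")) {
    entries <- entries[[1]]
  }
  stopifnot(all(vapply(entries, inherits, logical(1), "modification")))
  if (length(entries) > 2L) {
    stop("at most two modifications (second-generation metabolites)")
  }
  ids <- vapply(entries, function(e) paste(e$type, .unit_id(e$site)), "")
  if (anyDuplicated(ids)) stop("duplicate modification entries")
  structure(list(entries = entries), class = "mod_set")
}

#' @export
format.mod_set <- function(x, ...) {
  if (!length(x$entries)) return("(unmodified)")
  lab <- vapply(x$entries, function(e) {
    paste0(if (e$type == "demethylation") "DM@" else "OH@", .unit_id(e$site))
  }, "")
  paste(sort(lab), collapse = "+")
}

#' @export
print.mod_set <- function(x, ...) {
  cat("<mod_set>", format(x), "\n")
  invisible(x)
}

#' Parse a compact modification-set string
#'
#' Inverse of `format()` on a `mod_set`: `"DM@16"`, `"OH@45/46"`,
#' `"OH@12+DM@39"`, `""` (unmodified).
#'
#' @param x A single string.
#' @return A `mod_set`.
#' @export
parse_mods <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x) || identical(x, "(unmodified)")) return(mod_set())
  parts <- strsplit(x, "+", fixed = TRUE)[[1]]
  mod_set(lapply(parts, function(p) {
    kv <- strsplit(trimws(p), "@", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("cannot parse modification: ", p)
    type <- switch(toupper(kv[1]), DM = "demethylation", OH = "hydroxylation",
                   stop("unknown modification type: ", kv[1]))
    modification(type, strsplit(kv[2], "/", fixed = TRUE)[[1]])
  }))
}

# Net shift (Da) of a modification set.
.mods_delta <- function(mods) {
  if (!length(mods$entries)) return(0)
  sum(vapply(mods$entries, function(e) unname(mass_shift(e$type)), 0))
}

#' Enumerate the legal modification hypothesis space
#'
#' All modification sets with 0-2 entries over the legal demethylation and
#' hydroxylation site units (distinct units within a type). This is the
#' space the site-of-metabolism solver searches implicitly and the space
#' the round-trip validation sweeps explicitly.
#'
#' @param max_entries Cap on simultaneous modifications (default 2).
#' @return List of `mod_set` objects (includes the empty set).
#' @export
legal_hypotheses <- function(max_entries = 2) {
  dm <- lapply(.DM_UNITS, function(u) modification("demethylation", u))
  oh <- lapply(.OH_UNITS, function(u) modification("hydroxylation", u))
  out <- list(mod_set())
  if (max_entries >= 1) {
    out <- c(out, lapply(c(dm, oh), mod_set))
  }
  if (max_entries >= 2) {
    pair_within <- function(lst) {
      if (length(lst) < 2) return(list())
      idx <- utils::combn(length(lst), 2, simplify = FALSE)
      lapply(idx, function(i) mod_set(lst[[i[1]]], lst[[i[2]]]))
    }
    mixed <- unlist(lapply(dm, function(d) lapply(oh, function(h) mod_set(d, h))),
                    recursive = FALSE)
    out <- c(out, pair_within(dm), pair_within(oh), mixed)
  }
  out
}
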