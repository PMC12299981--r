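# Elemental-formula arithmetic, monoisotopic masses, adduct ions, mass
# shifts and ppm errors. All internal math is done at full precision;
# rounding (half-up, matching how exact masses are conventionally printed)
# happens only at display time via format_mz()/round_half_up().

# Monoisotopic atomic masses (Da). Frozen constants; the 4-dp agreement of
# every derived ion with the reference values depends on this exact table.
.ATOMIC_MASS <- c(
  C  = 12.000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928,
  K  = 38.9637069,
  S  = 31.97207069
)

.ELECTRON_MASS <- 0.00054858

# Net mass changes of the metabolic / fragmentation events handled by the
# pipeline, frozen at 6 dp (within 1e-6 of the exact formula differences).
.SHIFT_DELTA <- c(
  demethylation = -14.015650, # -CH2
  hydroxylation = +15.994915, # +O
  water_loss    = -18.010565, # -H2O
  methanol_loss = -32.026215, # -CH4O
  none          = 0
)

#' Elemental formula
#'
#' Construct an elemental formula from a Hill-style string (e.g.
#' `"C51H79NO13"`) or a named integer vector. Supported elements are C, H,
#' N, O, Na, K and S; all counts must be non-negative.
#'
#' @param x A formula string such as `"H2O"`, or a named numeric vector
#'   (e.g. `c(C = 51, H = 79, N = 1, O = 13)`), or a `chem_formula`.
#' @return An object of class `chem_formula`: a named integer vector over
#'   the supported elements.
#' @examples
#' srl <- chem_formula("C51H79NO13")
#' monoisotopic_mass(srl)
#' chem_formula("H2O") + chem_formula("H2O")
#' @export
chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  elements <- names(.ATOMIC_MASS)
  counts <- stats::setNames(integer(length(elements)), elements)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    s <- gsub("\\s", "", x)
    if (nzchar(s)) {
      m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
      parts <- regmatches(s, list(m))[[1]]
      if (sum(nchar(parts)) != nchar(s)) {
        stop("cannot parse formula string: ", x)
      }
      for (p in parts) {
        el <- gsub("[0-9]", "", p)
        n <- sub("^[A-Za-z]+", "", p)
        n <- if (nzchar(n)) as.integer(n) else 1L
        if (!el %in% elements) stop("unsupported element symbol: ", el)
        counts[el] <- counts[el] + n
      }
    }
  } else if (is.numeric(x)) {
    if (length(x) > 0 && is.null(names(x))) stop("numeric input must be named")
    bad <- setdiff(names(x), elements)
    if (length(bad)) stop("unsupported element symbol: ", paste(bad, collapse = ", "))
    if (any(x < 0)) stop("element counts must be non-negative")
    if (any(x != round(x))) stop("element counts must be integers")
    counts[names(x)] <- as.integer(x)
  } else {
    stop("cannot construct a formula from class ", class(x)[1])
  }
  structure(counts, class = "chem_formula")
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  chem_formula(unclass(chem_formula(e1)) + unclass(chem_formula(e2)))
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is not defined for formulas")
  out <- unclass(chem_formula(e1)) - unclass(chem_formula(e2))
  if (any(out < 0)) {
    stop("formula subtraction would give a negative count for: ",
         paste(names(out)[out < 0], collapse = ", "))
  }
  chem_formula(out)
}

#' @export
format.chem_formula <- function(x, ...) {
  n <- unclass(x)
  n <- n[n > 0]
  if (!length(n)) return("(empty)")
  paste0(names(n), ifelse(n > 1, n, ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (", format_mz(monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' @param formula Anything accepted by [chem_formula()].
#' @return Mass in Da (full precision).
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(formula) {
  f <- chem_formula(formula)
  sum(unclass(f) * .ATOMIC_MASS[names(f)])
}

#' Adduct specifications
#'
#' The four positive-mode adducts observed for sirolimus and its
#' metabolites. The sodium adduct carries the structural information and is
#' the default throughout the package.
#'
#' @param name One of `"M+Na"`, `"M+H"`, `"M+K"`, `"M+NH4"` (a surrounding
#'   `[...]+` is tolerated).
#' @return An `adduct_spec`: list with `name`, `added_formula`, `charge`.
#' @examples
#' adduct_mz("C51H79NO13", adduct("M+Na")) # 936.5444 at 4 dp
#' @export
adduct <- function(name = c("M+Na", "M+H", "M+K", "M+NH4")) {
  if (is.list(name) && inherits(name, "adduct_spec")) return(name)
  key <- gsub("^\\[|\\]\\+?$", "", name[1])
  key <- match.arg(key, c("M+Na", "M+H", "M+K", "M+NH4"))
  added <- switch(key,
    "M+H"   = chem_formula("H"),
    "M+Na"  = chem_formula("Na"),
    "M+K"   = chem_formula("K"),
    "M+NH4" = chem_formula("NH4")
  )
  structure(list(name = paste0("[", key, "]+"), added_formula = added,
                 charge = 1L),
            class = "adduct_spec")
}

#' Adduct-ion m/z
#'
#' m/z of the cation formed by attaching the adduct species, with the
#' electron mass subtracted (the printed 4-dp reference masses are only
#' reproduced when the correction is applied).
#'
#' @param formula Neutral molecule, anything accepted by [chem_formula()].
#' @param adduct_spec An [adduct()] (or its name). Default sodium.
#' @return m/z at full precision.
#' @export
adduct_mz <- function(formula, adduct_spec = adduct("M+Na")) {
  a <- adduct(adduct_spec)
  if (a$charge < 1) stop("charge must be a positive integer")
  (monoisotopic_mass(chem_formula(formula) + a$added_formula) -
     a$charge * .ELECTRON_MASS) / a$charge
}

#' Mass shift of a metabolic or neutral-loss event
#'
#' @param label One or more of `"demethylation"`, `"hydroxylation"`,
#'   `"water_loss"`, `"methanol_loss"`, `"none"`.
#' @return Named numeric vector of signed deltas in Da.
#' @examples
#' mass_shift("demethylation") # -14.01565
#' @export
mass_shift <- function(label) {
  label <- match.arg(label, names(.SHIFT_DELTA), several.ok = TRUE)
  .SHIFT_DELTA[label]
}

#' Apply mass shifts to an m/z value
#'
#' Shifts compose additively and commutatively; an empty shift list is the
#' identity.
#'
#' @param mz Positive m/z.
#' @param shifts Character vector of shift labels (see [mass_shift()]),
#'   possibly empty.
#' @return Shifted m/z.
#' @examples
#' apply_shift(607.3969, "demethylation")
#' @export
apply_shift <- function(mz, shifts = character()) {
  stopifnot(is.numeric(mz), mz > 0)
  out <- mz + if (length(shifts)) sum(mass_shift(shifts)) else 0
  if (any(out <= 0)) stop("shift composition gives a non-positive m/z")
  out
}

#' Relative mass error in ppm
#'
#' `|measured - theoretical| / theoretical * 1e6`. Values below the 5.0 ppm
#' tolerance are treated as confirmatory throughout the pipeline.
#'
#' @param measured,theoretical m/z values; `theoretical` must be > 0.
#'   Vectorised.
#' @return Non-negative ppm error(s).
#' @examples
#' ppm_error(397.2363, 397.2349) # 3.5 at 1 dp
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be > 0")
  abs(measured - theoretical) / theoretical * 1e6
}

#' Half-up rounding for display
#'
#' Exact masses are conventionally printed with half-up rounding (4 dp for
#' m/z, 1 dp for ppm); base `round()` rounds half to even. A small epsilon
#' guards against binary representation noise on exact .5 ties.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 4) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-6) / s
}

#' Format an m/z value the way reference tables print it (4 dp, half-up).
#' @param x Numeric m/z.
#' @param digits Decimal places (default 4).
#' @return Character vector.
#' @export
format_mz <- function(x, digits = 4) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}
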