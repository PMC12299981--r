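# Inverse site-of-metabolism solver: from a metabolite precursor mass and
# its MS/MS peaks, infer the modification set (type + site units) the way
# the fragmentation argument runs by hand -- unshifted fragments exclude
# their covered sites, shifted fragments support sites inside their
# coverage, diagnostic ions pin a site, methanol-loss satellites restrict a
# hydroxylation to the methyl carbons C45/C46 (rule R1), and dominant
# water-loss satellites restrict it to C23/C24 (rule R2).

.NET_COMBOS <- list(
  character(0),
  "demethylation",
  "hydroxylation",
  c("demethylation", "demethylation"),
  c("hydroxylation", "hydroxylation"),
  c("demethylation", "hydroxylation")
)

#' Infer the net modification from precursor masses
#'
#' Finds the unique combination of up to two events from {-CH2, +O} whose
#' summed delta explains `precursor_mz - parent_mz` within tolerance.
#'
#' @param precursor_mz Metabolite precursor m/z (same adduct as parent).
#' @param parent_mz Parent-drug precursor m/z.
#' @param tol_ppm Tolerance in ppm of the precursor (default 5).
#' @return Character vector of modification types (possibly empty).
#' @examples
#' infer_net_modification(922.5287, 936.5444) # demethylation
#' @export
infer_net_modification <- function(precursor_mz, parent_mz, tol_ppm = 5.0) {
  stopifnot(precursor_mz > 0, parent_mz > 0, tol_ppm > 0)
  deltas <- vapply(.NET_COMBOS, function(tt)
    if (length(tt)) sum(mass_shift(tt)) else 0, 0)
  err <- abs(precursor_mz - (parent_mz + deltas))
  hit <- which(err <= tol_ppm * precursor_mz / 1e6)
  if (!length(hit)) {
    stop(sprintf(
      "no combination of up to two -CH2/+O events explains a delta of %.4f Da",
      precursor_mz - parent_mz))
  }
  if (length(hit) > 1L) stop("ambiguous net modification (multiple combinations in tolerance)")
  .NET_COMBOS[[hit]]
}

#' Metabolite class from a net modification multiset
#'
#' @param x A `som_assignment`, a `mod_set`, or a character vector of
#'   modification types.
#' @return One of `"unmodified"`, `"O-demethylated"`, `"hydroxylated"`,
#'   `"didemethylated"`, `"di-hydroxylated"`, `"hydroxylated/demethylated"`.
#' @export
classify <- function(x) {
  types <-
    if (inherits(x, "som_assignment")) x$net
    else if (inherits(x, "mod_set")) vapply(x$entries, `[[`, "", "type")
    else as.character(x)
  key <- paste(sort(types), collapse = "+")
  if (key == "") return("unmodified")
  switch(key,
    "demethylation" = "O-demethylated",
    "hydroxylation" = "hydroxylated",
    "demethylation+demethylation" = "didemethylated",
    "hydroxylation+hydroxylation" = "di-hydroxylated",
    "demethylation+hydroxylation" = "hydroxylated/demethylated",
    stop("not a legal net modification multiset: ", key)
  )
}

# encode a hypothesis (list of entries as type/unit) as a canonical string
.hyp_key <- function(types, units) {
  paste(sort(paste0(substr(types, 1, 2), "@",
                    vapply(units, .unit_id, ""))), collapse = "+")
}

#' Localize the sites of metabolism from an MS/MS spectrum
#'
#' Runs the inverse of [expected_peaks()]: infers the net modification from
#' the precursor, then narrows the legal site hypotheses using, in order,
#' unshifted-fragment exclusions, shifted-fragment support, diagnostic-ion
#' pins, and the neutral-loss rules R1 (methanol loss from hydroxylated
#' methyl carbons C45/C46) and R2 (dominant water loss from C23/C24
#' hydroxylation). Candidate pairs that the evidence cannot split (23/24,
#' 45/46, the piperidine ring) are reported jointly with `ambiguous = TRUE`.
#'
#' @param spec A `spectrum`.
#' @param lib A `fragment_library`.
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @param rules_on Character subset of `c("R1", "R2")`.
#' @param waterloss_ratio Rule-R2 threshold: the water-loss satellite must
#'   exceed `waterloss_ratio` times its parent shifted-fragment intensity
#'   (default 1.0).
#' @return A `som_assignment`: list with `id`, `net` (types), `class_label`,
#'   `mods` (a `mod_set` when uniquely resolved, else `NULL`), `hypotheses`
#'   (remaining site assignments), `candidate_sites_remaining`, `ambiguous`,
#'   `consistent`, `evidence` (data.frame).
#' @export
localize <- function(spec, lib, tol_ppm = 5.0, rules_on = c("R1", "R2"),
                     waterloss_ratio = 1.0) {
  stopifnot(inherits(spec, "spectrum"), inherits(lib, "fragment_library"))
  rules_on <- intersect(rules_on, c("R1", "R2"))
  parent_mz <- adduct_mz(lib$molecular_formula, lib$adduct)
  net <- infer_net_modification(spec$precursor_mz, parent_mz, tol_ppm)

  fr <- lib$fragments
  alpha <- fr[fr$kind == "alpha_cleavage", , drop = FALSE]
  diags <- fr[fr$kind == "hydroxylation_diagnostic", , drop = FALSE]
  obs <- spec$peaks

  evidence <- list()
  note <- function(kind, label, sites, detail) {
    evidence[[length(evidence) + 1L]] <<- data.frame(
      kind = kind, fragment_label = label,
      affected_sites = paste(sites, collapse = ","),
      detail = detail, stringsAsFactors = FALSE)
  }

  # nearest observed peak within tolerance; NA if none
  find_peak <- function(mz) {
    p <- ppm_error(obs$mz, mz)
    ok <- which(p <= tol_ppm)
    if (!length(ok)) return(NA_integer_)
    ok[order(p[ok], -obs$intensity[ok])][1]
  }

  # enumerate remaining hypotheses as lists of (types, units)
  units_of <- function(type) if (type == "demethylation") .DM_UNITS else .OH_UNITS
  hyps <- list()
  if (length(net) == 0L) {
    hyps <- list(list(types = character(0), units = list()))
  } else if (length(net) == 1L) {
    hyps <- lapply(units_of(net), function(u)
      list(types = net, units = list(u)))
  } else if (net[1] == net[2]) {
    uu <- units_of(net[1])
    idx <- utils::combn(length(uu), 2, simplify = FALSE)
    hyps <- lapply(idx, function(i)
      list(types = net, units = list(uu[[i[1]]], uu[[i[2]]])))
  } else {
    for (u1 in units_of(net[1])) for (u2 in units_of(net[2]))
      hyps[[length(hyps) + 1L]] <- list(types = net, units = list(u1, u2))
  }

  keep <- rep(TRUE, length(hyps))
  restrict <- function(pred) {
    for (i in which(keep)) if (!pred(hyps[[i]])) keep[i] <<- FALSE
  }
  deltas <- if (length(net)) vapply(net, function(t) unname(mass_shift(t)), 0) else numeric(0)

  # shift variants: all sub-multisets of the net modification
  subsets <- list(integer(0))
  if (length(net) >= 1) subsets <- c(subsets, list(1L))
  if (length(net) == 2) subsets <- c(subsets, list(2L), list(1:2))

  # Ambiguity pool for diagnostic and neutral-loss probes: a probe position
  # that is isobaric (within tolerance) with a different ion's expected
  # variant, or with a possible neutral-loss satellite of a different
  # fragment, is uninformative and is skipped. This protects against
  # built-in isobaric coincidences of the library (fragment pairs differing
  # by exactly CH4O or H2O, diagnostics close to satellite positions).
  pool_ion <- rep(fr$label, each = length(subsets))
  pool_mz <- as.vector(vapply(seq_len(nrow(fr)), function(i)
    vapply(subsets, function(s) fr$mz[i] + sum(deltas[s]), 0),
    numeric(length(subsets))))
  sat_ion <- character(0); sat_mz <- numeric(0)
  if (any(net == "hydroxylation")) {
    oh_sub <- Filter(function(s) any(net[s] == "hydroxylation"), subsets)
    for (i in seq_len(nrow(alpha))) {
      for (s in oh_sub) {
        v <- alpha$mz[i] + sum(deltas[s])
        sat_ion <- c(sat_ion, alpha$label[i], alpha$label[i])
        sat_mz <- c(sat_mz, v + unname(mass_shift("water_loss")),
                    v + unname(mass_shift("methanol_loss")))
      }
    }
  }
  probe_ambiguous <- function(z, self) {
    any(ppm_error(z, pool_mz[pool_ion != self]) <= tol_ppm) ||
      (length(sat_mz) > 0 && any(ppm_error(z, sat_mz[sat_ion != self]) <= tol_ppm))
  }

  if (length(net) > 0L) {
    for (i in seq_len(nrow(alpha))) {
      cov <- alpha$coverage[[i]]
      vmz <- vapply(subsets, function(s) alpha$mz[i] + sum(deltas[s]), 0)
      # a variant position isobaric with a different ion's variant (or a
      # possible satellite) cannot be attributed to this fragment: skip it
      usable <- !vapply(vmz, probe_ambiguous, TRUE, self = alpha$label[i])
      hit <- rep(NA_integer_, length(vmz))
      hit[usable] <- vapply(vmz[usable], function(z) find_peak(z), 0L)
      matched <- !is.na(hit)
      # which entry-subsets are matched, by the *set of entries shifted*
      msub <- unique(lapply(subsets[matched], function(s) sort(s)))
      if (length(msub) == 0L) next
      # entry-count interpretation: for same-type nets only the number of
      # shifted entries is identifiable
      if (length(net) == 2L && net[1] == net[2]) {
        ks <- unique(lengths(msub))
        if (length(ks) != 1L) {
          note("isobaric_tie", alpha$label[i], cov, "multiple shift states in tolerance")
          next
        }
        k <- ks
        restrict(function(h) sum(vapply(h$units, .unit_covered, TRUE, cov)) == k)
        note(if (k == 0) "unshifted_exclusion" else "shifted_support",
             alpha$label[i], cov,
             sprintf("matched with %d shifted entr%s", k, if (k == 1) "y" else "ies"))
      } else {
        if (length(msub) > 1L) {
          note("isobaric_tie", alpha$label[i], cov, "multiple shift states in tolerance")
          next
        }
        s <- msub[[1]]
        restrict(function(h) {
          covd <- which(vapply(h$units, .unit_covered, TRUE, cov))
          setequal(covd, s)
        })
        note(if (length(s) == 0) "unshifted_exclusion" else "shifted_support",
             alpha$label[i], cov,
             if (length(s) == 0) "matched at the unshifted mass"
             else paste("matched shifted by", paste(net[s], collapse = "+")))
      }

      # neutral-loss rules apply to fragments observed shifted by >= 1
      # hydroxylation
      s <- msub[[1]]
      if (length(s) && any(net[s] == "hydroxylation")) {
        base <- alpha$mz[i] + sum(deltas[s])
        if ("R1" %in% rules_on) {
          z <- base + unname(mass_shift("methanol_loss"))
          j <- if (probe_ambiguous(z, alpha$label[i])) NA_integer_ else find_peak(z)
          if (!is.na(j)) {
            restrict(function(h) any(vapply(seq_along(h$units), function(e)
              h$types[e] == "hydroxylation" &&
                setequal(h$units[[e]], c("45", "46")), TRUE)))
            note("methanol_loss_rule", alpha$label[i], c("45", "46"),
                 "methanol-loss satellite on a shifted fragment")
          }
        }
        if ("R2" %in% rules_on) {
          jf <- find_peak(base)
          z <- base + unname(mass_shift("water_loss"))
          j <- if (probe_ambiguous(z, alpha$label[i])) NA_integer_ else find_peak(z)
          if (!is.na(j) && !is.na(jf) &&
              obs$intensity[j] > waterloss_ratio * obs$intensity[jf]) {
            restrict(function(h) any(vapply(seq_along(h$units), function(e)
              h$types[e] == "hydroxylation" &&
                setequal(h$units[[e]], c("23", "24")), TRUE)))
            note("waterloss_intensity_rule", alpha$label[i], c("23", "24"),
                 "dominant water-loss satellite on a shifted fragment")
          }
        }
      }
    }

    # diagnostic ions pin a hydroxylation site; they may themselves be
    # shifted by the other modification entry
    if (any(net == "hydroxylation")) {
      other <- if (length(net) == 2L) 2L else integer(0)
      for (i in seq_len(nrow(diags))) {
        cov <- diags$coverage[[i]]
        site <- diags$site[i]
        cand_shifts <- list(integer(0))
        if (length(net) == 2L) cand_shifts <- c(cand_shifts, list(1L), list(2L))
        matched_shift <- NULL
        for (s in cand_shifts) {
          z <- diags$mz[i] + sum(deltas[s])
          if (probe_ambiguous(z, diags$label[i])) next
          if (!is.na(find_peak(z))) {
            matched_shift <- s
            break
          }
        }
        if (is.null(matched_shift)) next
        restrict(function(h) {
          oh <- which(h$types == "hydroxylation" &
                        vapply(h$units, function(u) site %in% u, TRUE))
          if (!length(oh)) return(FALSE)
          # remaining entries must shift the diagnostic exactly as observed
          rest <- setdiff(seq_along(h$units), oh[1])
          shifted <- rest[vapply(rest, function(e)
            .unit_covered(h$units[[e]], cov), TRUE)]
          sum(deltas[shifted]) - sum(deltas[matched_shift]) == 0 ||
            abs(sum(deltas[shifted]) - sum(deltas[matched_shift])) < 1e-9
        })
        note("diagnostic_support", diags$label[i], site,
             sprintf("diagnostic ion %s matched", format_mz(diags$mz[i])))
      }
    }
  }

  hyps <- hyps[keep]
  evidence <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(kind = character(), fragment_label = character(),
               affected_sites = character(), detail = character())

  consistent <- length(hyps) > 0L
  unit_ids <- unique(unlist(lapply(hyps, function(h)
    vapply(h$units, .unit_id, ""))))
  mods <- NULL
  if (consistent && length(hyps) == 1L && length(net)) {
    mods <- mod_set(lapply(seq_along(net), function(e)
      modification(hyps[[1]]$types[e], hyps[[1]]$units[[e]])))
  }
  if (consistent && length(net) == 0L) mods <- mod_set()
  ambiguous <- consistent && length(net) > 0L &&
    (length(hyps) > 1L ||
       any(vapply(hyps[[1]]$units, function(u)
         length(u) > 1L || identical(u, "pip"), TRUE)))

  structure(list(
    id = spec$id,
    precursor_mz = spec$precursor_mz,
    net = net,
    class_label = classify(net),
    mods = mods,
    hypotheses = hyps,
    candidate_sites_remaining = unit_ids,
    ambiguous = ambiguous,
    consistent = consistent,
    evidence = evidence
  ), class = "som_assignment")
}

#' @export
print.som_assignment <- function(x, ...) {
  cat("<som_assignment> ", if (nzchar(x$id)) paste0(x$id, "  ") else "",
      x$class_label, "\n", sep = "")
  if (!x$consistent) {
    cat("  INCONSISTENT evidence (", nrow(x$evidence), " items)\n", sep = "")
  } else if (!is.null(x$mods)) {
    cat("  sites: ", format(x$mods),
        if (x$ambiguous) "  (ambiguous)" else "", "\n", sep = "")
  } else {
    cat("  unresolved; candidates: ",
        paste(x$candidate_sites_remaining, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tabular report over a batch of assignments
#'
#' One row per assignment plus per-class summary counts. Distinct entries
#' with the same (ambiguous) site assignment -- e.g. chromatographically
#' separable hydroxy-piperidine isomers -- stay distinct rows.
#'
#' @param assignments List of `som_assignment` objects.
#' @return data.frame with columns `id`, `class`, `sites`, `ambiguous`,
#'   `consistent`, `n_evidence`; attribute `"summary"` holds per-class
#'   counts and `"n_metabolites"` the number of modified, consistent
#'   assignments.
#' @export
batch_report <- function(assignments) {
  if (!length(assignments)) {
    out <- data.frame(id = character(), class = character(), sites = character(),
                      ambiguous = logical(), consistent = logical(),
                      n_evidence = integer())
    attr(out, "summary") <- table(character())
    attr(out, "n_metabolites") <- 0L
    return(out)
  }
  rows <- lapply(assignments, function(a) {
    data.frame(
      id = a$id,
      class = a$class_label,
      sites = if (!is.null(a$mods)) format(a$mods)
              else paste(a$candidate_sites_remaining, collapse = "|"),
      ambiguous = a$ambiguous,
      consistent = a$consistent,
      n_evidence = nrow(a$evidence),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  modified <- out$consistent & out$class != "unmodified"
  attr(out, "summary") <- table(out$class[modified])
  attr(out, "n_metabolites") <- sum(modified)
  out
}
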