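# Shared fixtures and small utilities for the test suite.

# Load the packaged library once per test run.
test_lib <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- srl_fragment_library()
    lib
  }
})

# Canonical string for a modification set ("DM@16+OH@11" style, sorted).
mods_key <- function(mods) {
  if (is.character(mods)) mods <- parse_mods(mods)
  format(mods)
}

# Canonical strings for the hypotheses remaining in an assignment.
hyp_keys <- function(assignment) {
  vapply(assignment$hypotheses, function(h) {
    lab <- vapply(seq_along(h$units), function(i) {
      paste0(if (h$types[i] == "demethylation") "DM@" else "OH@",
             paste(h$units[[i]], collapse = "/"))
    }, "")
    paste(sort(lab), collapse = "+")
  }, "")
}

# Does the assignment's candidate set still contain the truth?
assignment_contains <- function(assignment, truth) {
  if (is.character(truth)) truth <- parse_mods(truth)
  if (!assignment$consistent) return(FALSE)
  if (!length(truth$entries)) return(length(assignment$net) == 0L)
  mods_key(truth) %in% hyp_keys(assignment)
}

# Written-out fixture directory (works installed and in-source).
fixture_spectra_dir <- function() {
  system.file("extdata", "synthetic_spectra", package = "metsom")
}
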