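# Reference 4-dp masses of the sodiated fragments (printed table), used as
# the identity oracle for the forward model.
PRINTED <- c(
  SRL = 936.5444, A = 731.4493, B = 763.4756, C = 642.3249, D = 345.2036,
  E = 703.4544, F = 399.2506, G = 614.3300, H = 485.2510, I = 459.2717,
  J = 409.2349, K = 607.3969, L = 397.2349, M = 582.3037, N = 453.2248,
  O = 441.2611, P = 381.2400, Q = 320.1105, R = 413.2662
)

test_that("the packaged library loads and matches the reference table", {
  lib <- test_lib()
  fr <- lib$fragments
  expect_equal(sum(fr$kind == "alpha_cleavage"), 18L)
  expect_setequal(fr$label[fr$kind == "alpha_cleavage"], setdiff(names(PRINTED), "SRL"))
  for (lab in names(PRINTED)) {
    expect_equal(round_half_up(fr$mz[fr$label == lab], 4), unname(PRINTED[lab]),
                 info = lab)
  }
  expect_equal(lib$numbering$to_cas[["39"]], "41")
  expect_equal(lib$numbering$to_cas[["16"]], "7")
})

test_that("library validation rejects corrupted fixtures", {
  src <- system.file("extdata", "srl_fragments.csv", package = "metsom")
  lines <- readLines(src)

  corrupt <- function(pattern, replacement) {
    f <- tempfile(fileext = ".csv")
    writeLines(sub(pattern, replacement, lines), f)
    f
  }
  # fragment K mass edited off the reference value
  expect_error(read_fragment_library(corrupt("^K,607.396918", "K,607.4000")),
               "reference")
  # child coverage escaping its parent
  expect_error(read_fragment_library(corrupt('^Q,320.1105,alpha_cleavage,N,,"1-9,pip"',
                                             'Q,320.1105,alpha_cleavage,N,,"1-16,pip"')),
               "subset")
  # duplicate label
  expect_error(read_fragment_library(corrupt("^R,413.2662", "Q,413.2662")),
               "duplicate")
  # missing molecular ion
  expect_error(read_fragment_library(corrupt("^SRL,936.544362,molecular_ion",
                                             "SRL,936.544362,alpha_cleavage")),
               "molecular ion")
})

test_that("the identity hypothesis reproduces the reference table exactly", {
  ep <- expected_peaks(test_lib(), mod_set())
  alpha <- ep[ep$kind %in% c("alpha_cleavage", "molecular_ion"), ]
  expect_equal(nrow(alpha), 19L)
  expect_equal(sum(ep$kind == "satellite"), 0L)
  expect_equal(sum(ep$kind == "hydroxylation_diagnostic"), 0L)
  for (i in seq_len(nrow(alpha))) {
    expect_equal(round_half_up(alpha$mz[i], 4), unname(PRINTED[alpha$label[i]]),
                 info = alpha$label[i])
  }
})

test_that("forward model reproduces the published metabolite fragments", {
  lib <- test_lib()
  get_mz <- function(ep, lab) ep$mz[ep$label == lab]

  ep39 <- expected_peaks(lib, "DM@39")
  expect_equal(round_half_up(get_mz(ep39, "C"), 4), 628.3092)
  expect_equal(round_half_up(get_mz(ep39, "D"), 4), 331.1880)
  # K also covers C39, so it shifts too
  expect_equal(round_half_up(get_mz(ep39, "K"), 4), 593.3813)
  expect_equal(round_half_up(get_mz(ep39, "SRL"), 4), 922.5287)

  # 16-O-demethylation leaves K, D, P, J at the parent-drug masses
  ep16 <- expected_peaks(lib, "DM@16")
  for (lab in c("K", "D", "P", "J")) {
    expect_equal(round_half_up(get_mz(ep16, lab), 4), unname(PRINTED[lab]),
                 info = lab)
  }

  # 27-O-demethylation shifts K but not C or D
  ep27 <- expected_peaks(lib, "DM@27")
  expect_equal(round_half_up(get_mz(ep27, "K"), 4), 593.3813)
  expect_equal(round_half_up(get_mz(ep27, "C"), 4), unname(PRINTED["C"]))
  expect_equal(round_half_up(get_mz(ep27, "D"), 4), unname(PRINTED["D"]))

  # methyl-carbon hydroxylation: K + O plus a methanol-loss satellite
  ep45 <- expected_peaks(lib, "OH@45/46")
  expect_equal(round_half_up(get_mz(ep45, "K"), 4), 623.3918)
  expect_true("K-CH3OH" %in% ep45$label)
  expect_equal(get_mz(ep45, "K-CH3OH"), get_mz(ep45, "K") - 32.026215,
               tolerance = 1e-9)

  # C23/C24 hydroxylation: G + O with a dominant water-loss satellite
  ep23 <- expected_peaks(lib, "OH@23/24")
  expect_equal(round_half_up(get_mz(ep23, "G"), 4), 630.3249)
  expect_equal(round_half_up(get_mz(ep23, "G-H2O"), 4), 612.3144)
  expect_true(ep23$dominant_intensity[ep23$label == "G-H2O"])
  expect_equal(round_half_up(get_mz(ep23, "O"), 4), 457.2561)

  # rules can be switched off
  expect_false("G-H2O" %in% expected_peaks(lib, "OH@23/24", rules_on = "R1")$label)
})

test_that("single hydroxylation shifts are all-or-nothing (+O only)", {
  lib <- test_lib()
  base <- expected_peaks(lib, mod_set())
  base_mz <- setNames(base$mz, base$label)
  for (unit in list("11", "12", "14", c("23", "24"), "25", c("45", "46"), "49", "pip")) {
    ep <- expected_peaks(lib, mod_set(modification("hydroxylation", unit)))
    main <- ep[ep$kind %in% c("alpha_cleavage", "molecular_ion"), ]
    d <- main$mz - base_mz[main$label]
    expect_true(all(abs(d) < 1e-9 | abs(d - 15.994915) < 1e-9),
                info = paste(unit, collapse = "/"))
  }
})

test_that("coverage is consistent along the fragmentation tree", {
  lib <- test_lib()
  fr <- lib$fragments
  base <- expected_peaks(lib, mod_set())
  base_mz <- setNames(base$mz, base$label)
  ancestors <- function(lab) {
    out <- character()
    p <- fr$parent[match(lab, fr$label)]
    while (!is.na(p) && nzchar(p)) {
      out <- c(out, p)
      p <- fr$parent[match(p, fr$label)]
    }
    out
  }
  for (h in legal_hypotheses(max_entries = 1)) {
    if (!length(h$entries)) next
    ep <- expected_peaks(lib, h)
    main <- ep[ep$kind %in% c("alpha_cleavage", "molecular_ion"), ]
    shifted <- main$label[abs(main$mz - base_mz[main$label]) > 1e-9]
    for (lab in shifted) {
      anc <- ancestors(lab)
      cov_site <- h$entries[[1]]$site
      for (a in anc) {
        if (any(cov_site %in% fr$coverage[[match(a, fr$label)]])) {
          expect_true(a %in% shifted, info = paste(format(h), lab, "->", a))
        }
      }
    }
    # the molecular ion always shifts by the net delta
    expect_equal(main$mz[main$label == "SRL"] - base_mz["SRL"],
                 unname(mass_shift(h$entries[[1]]$type)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("illegal sites are rejected", {
  expect_error(modification("demethylation", 11), "illegal")
  expect_error(modification("hydroxylation", 16), "illegal")
  expect_error(modification("hydroxylation", 60), "carbon position")
  expect_error(mod_set(modification("demethylation", 16),
                       modification("demethylation", 16)), "duplicate")
  expect_error(mod_set(modification("demethylation", 16),
                       modification("demethylation", 27),
                       modification("demethylation", 39)), "at most two")
})
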