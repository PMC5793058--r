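ms_peak <- function(rt, mz, area = 1) {
  data.frame(rt = rt, mz = mz, area = area, channel = "ms",
             stringsAsFactors = FALSE)
}

test_that("printed anchor peaks identify their eicosanoids", {
  a <- assign_peaks(rbind(ms_peak(17.2, 319.2), ms_peak(6.9, 353.2),
                          ms_peak(8.5, 351.2)))
  expect_equal(a$metabolite, c("8-HETE", "PGF2a", "PGE2"))
  expect_false(any(a$ambiguous))
  # 8-HETE lists its same-m/z isomer neighbours as alternatives
  expect_match(a$alternatives[1], "11-HETE")
})

test_that("peaks outside every tolerance stay unassigned", {
  a <- assign_peaks(ms_peak(12.0, 500.0))
  expect_equal(a$metabolite, "unassigned")
  expect_false(a$ambiguous)
})

test_that("m/z-only matches at shared m/z are flagged ambiguous", {
  # 351.2 without a compatible retention time: PGE2/PGD2 cannot be separated
  a <- assign_peaks(ms_peak(12.0, 351.2))
  expect_equal(a$metabolite, "PGD2")
  expect_true(a$ambiguous)
  expect_match(a$alternatives, "PGE2")
})

test_that("the HETE isomer ladder resolves by retention time", {
  a <- assign_peaks(rbind(ms_peak(16.8, 319.2), ms_peak(17.0, 319.2),
                          ms_peak(17.4, 319.2)))
  expect_equal(a$metabolite, c("15-HETE", "11-HETE", "5-HETE"))
})

test_that("an empty reference table is a configuration error", {
  expect_error(assign_peaks(ms_peak(17.2, 319.2), refs = NULL),
               class = "coralox_config_error")
})

test_that("shrinking tolerances never assigns more peaks", {
  set.seed(113)
  refs <- eicosanoid_refs()
  for (k in 1:10) {
    n <- 15
    peaks <- data.frame(rt = runif(n, 5, 21), mz = sample(refs$mz[!is.na(refs$mz)],
                                                          n, replace = TRUE) +
                          rnorm(n, 0, 0.05),
                        area = runif(n, 1, 100), channel = "ms",
                        stringsAsFactors = FALSE)
    wide <- sum(assign_peaks(peaks, rt_tol = 0.3, mz_tol = 0.08)$metabolite !=
                  "unassigned")
    narrow <- sum(assign_peaks(peaks, rt_tol = 0.1, mz_tol = 0.02)$metabolite !=
                    "unassigned")
    expect_lte(narrow, wide)
  }
})

test_that("conversion rate is the product-area fraction of the radiochromatogram", {
  radio <- function(rt, area) data.frame(rt = rt, mz = NA_real_, area = area,
                                         channel = "radio",
                                         stringsAsFactors = FALSE)
  expect_equal(conversion_rate(rbind(radio(17.2, 53), radio(19.9, 47))), 53)
  expect_equal(conversion_rate(rbind(radio(17.2, 60), radio(19.9, 40))), 60)
  expect_equal(conversion_rate(radio(19.9, 100)), 0)
  # scaling invariance
  expect_equal(conversion_rate(rbind(radio(17.2, 5.3), radio(19.9, 4.7))), 53)
  # zero total area is undefined
  expect_error(conversion_rate(radio(19.9, 0)),
               class = "coralox_undefined_rate_error")
  # substrate without an rt anchor
  expect_error(conversion_rate(radio(19.9, 10), substrate = "PGD2"),
               class = "coralox_config_error")
})

test_that("peak tables validate channel/mz consistency and round trip CSV", {
  bad <- data.frame(rt = 1, mz = 300, area = 1, channel = "radio")
  expect_error(assign_peaks(bad), class = "coralox_format_error")
  nochan <- data.frame(rt = 1, area = 1)
  expect_error(assign_peaks(nochan), "channel", class = "coralox_format_error")

  peaks <- rbind(ms_peak(17.2, 319.2), ms_peak(6.9, 353.2))
  peaks$condition <- c("standard", "EDTA")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(peaks, path, row.names = FALSE)
  back <- read_peaks(path)
  expect_equal(back$rt, peaks$rt)
  expect_equal(back$condition, c("standard", "EDTA"))
})

test_that("synthetic peak tables hit the anchors exactly at zero noise", {
  gen <- generate_peak_table(
    data.frame(metabolite = c("8-HETE", "AA"), area = c(53, 47)),
    sigma_rt = 0, sigma_mz = 0, seed = 3, channel = "radio")
  expect_equal(gen$peaks$rt, c(17.2, 19.9))
  expect_true(all(is.na(gen$peaks$mz)))
  expect_equal(conversion_rate(gen$peaks), 53)

  ms <- generate_peak_table(
    data.frame(metabolite = "8-HETE", area = 1), seed = 3, channel = "ms")
  expect_equal(ms$peaks$mz, 319.2)

  empty <- generate_peak_table(data.frame(metabolite = character(),
                                          area = numeric()), seed = 1)
  expect_equal(nrow(empty$peaks), 0L)

  expect_error(generate_peak_table(data.frame(metabolite = "nonesuch",
                                              area = 1), seed = 1),
               class = "coralox_config_error")
})

test_that("planted identities are recovered under moderate noise", {
  # main-product panel: anchors separated far beyond the noise scale
  refs <- eicosanoid_refs()
  main <- refs[refs$name %in% c("AA", "8-HETE", "PGF2a", "PGE2", "PGD2",
                                "alpha-ketol", "cyclopentenone"), ]
  truth <- data.frame(metabolite = c("8-HETE", "PGF2a", "PGE2"),
                      area = c(50, 30, 20))
  hits <- 0L
  total <- 0L
  for (s in 1:100) {
    gen <- generate_peak_table(truth, sigma_rt = 0.05, sigma_mz = 0.01,
                               seed = s, refs = main)
    a <- assign_peaks(gen$peaks, refs = main)
    hits <- hits + sum(a$metabolite == truth$metabolite)
    total <- total + nrow(truth)
  }
  expect_gte(hits / total, 0.99)
})
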