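test_that("fingerprint reading normalizes rows and validates structure", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,b1,b2,b3", "s1,2,1,1", "s2,0,4,0"), tf)
  fp <- read_fingerprint(tf)
  m <- band_matrix(fp)
  expect_equal(unname(m["s1", ]), c(0.5, 0.25, 0.25))
  expect_equal(unname(m["s2", ]), c(0, 1, 0))

  fp_raw <- read_fingerprint(tf, normalize = FALSE)
  expect_equal(unname(band_matrix(fp_raw)["s1", ]), c(2, 1, 1))

  # tab-delimited dialect is sniffed
  tt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tb1\tb2", "s1\t1\t3"), tt)
  expect_equal(unname(band_matrix(read_fingerprint(tt))["s1", ]), c(0.25, 0.75))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,b1", "s1,1", "s1,2"), dup)
  expect_error(read_fingerprint(dup), class = "lagbeta_format_error")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,b1,b2", "s1,-1,2"), neg)
  expect_error(read_fingerprint(neg), class = "lagbeta_validation_error")

  zero <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,b1,b2", "s1,0,0"), zero)
  expect_error(read_fingerprint(zero), class = "lagbeta_validation_error")
  expect_silent(read_fingerprint(zero, normalize = FALSE))
})

test_that("read/write round trip is the identity on valid matrices", {
  for (seed in 1:5) {
    fp <- normalize_fingerprint(random_fingerprint(6, 9, seed = seed))
    tf <- withr::local_tempfile(fileext = ".csv")
    write_fingerprint(fp, tf)
    back <- read_fingerprint(tf, normalize = FALSE)
    expect_equal(band_matrix(back), band_matrix(fp), tolerance = 1e-12)
    expect_identical(back$sample_id, fp$sample_id)
  }
})

test_that("metadata parsing enforces dates and the texture vocabulary", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,site_id,date,replicate,texture",
    "B_200906_r1,B,2009-06-15,1,sandy",
    "B_200904_r1,B,2009-04,1,sandy"
  ), tf)
  md <- read_sample_metadata(tf)
  # month-only input becomes day 15; records come back date-ordered
  expect_equal(md$date, as.Date(c("2009-04-15", "2009-06-15")))
  expect_equal(md$sample_id[1], "B_200904_r1")

  bad_tex <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,site_id,date,replicate,texture",
    "x,B,2009-04-15,1,loamy"
  ), bad_tex)
  expect_error(read_sample_metadata(bad_tex), class = "lagbeta_validation_error")

  bad_date <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,site_id,date,replicate,texture",
    "x,B,April-09,1,sandy"
  ), bad_date)
  expect_error(read_sample_metadata(bad_date), class = "lagbeta_format_error")
})

test_that("chemistry validation enforces physical ranges", {
  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site_id,date,pH,no3,nh4,om,clay",
    "B,2009-04,5.1,75.6,13.3,4.2,6",
    "B,2009-06,5.2,,12.1,4.0,6"
  ), ok)
  chem <- read_chemistry(ok)
  expect_true(is.na(chem$no3[2])) # ragged cells permitted
  expect_named(chem, c("site_id", "date", "ph", "no3", "nh4", "om", "clay"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,date,pH", "B,2009-04,15.2"), bad)
  expect_error(read_chemistry(bad), class = "lagbeta_validation_error")
})

test_that("alignment drops unmatched samples, broadcasts chemistry, never invents rows", {
  fp <- random_fingerprint(4, 5, seed = 1)
  md <- series_metadata(
    fp$sample_id[1:3],
    c("2009-04-15", "2009-04-15", "2009-06-15")
  )
  md$replicate <- c(1L, 2L, 1L)
  chem <- tibble::tibble(
    site_id = "A",
    date = as.Date(c("2009-04-15", "2009-06-15")),
    no3 = c(75, 40)
  )
  ds <- align_samples(fp, md, chem)
  expect_equal(nrow(ds$fingerprint), 3)
  expect_setequal(ds$dropped, fp$sample_id[4])
  # (site, date)-keyed chemistry broadcasts to both April replicates
  expect_equal(sum(ds$chemistry$no3 == 75), 2)
  expect_lte(nrow(ds$fingerprint), min(nrow(fp), nrow(md)))

  md_disjoint <- series_metadata("nope", "2009-04-15")
  expect_error(align_samples(fp, md_disjoint), class = "lagbeta_alignment_error")
})
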