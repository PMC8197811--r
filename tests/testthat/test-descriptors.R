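# A collinear O-C-Cl transition state with prescribed forming (df) and
# leaving (dl) distances, with group charges on a pseudo-atom nucleophile.
make_record <- function(label = "x", df = 2.04, dl = 2.47,
                        qrc = -0.94, qts = -0.73, barrier = 15.4) {
  ts <- stationary_point("TS",
    geometry(c("O", "C", "Cl"),
             rbind(c(0, 0, 0), c(0, 0, df), c(0, 0, df + dl))),
    charges = charge_table(1, "Nu", qts))
  rc <- stationary_point("RC",
    geometry(c("O", "C", "Cl"),
             rbind(c(0, 0, 0), c(0, 0, 3), c(0, 0, 4.8))),
    charges = charge_table(1, "Nu", qrc))
  reaction_record(label, rc = rc, ts = ts,
                  leaving_bond = c(2, 3), forming_bond = c(1, 2),
                  nucleophile = 1, barrier = barrier)
}

test_that("the distance descriptor is the TS bond-length difference", {
  expect_equal(compute_dcat(make_record(df = 2.04, dl = 2.47)), 0.43)
  expect_equal(compute_dcat(make_record(df = 2.24, dl = 2.14)), -0.10)
  expect_equal(compute_dcat(make_record(df = 2.1, dl = 2.1)), 0)
})

test_that("swapping the leaving and forming bond roles negates it", {
  set.seed(21)
  for (rep in 1:10) {
    r <- make_record(df = runif(1, 1.5, 2.5), dl = runif(1, 1.5, 2.5))
    swapped <- r
    swapped$leaving_bond <- rev(r$forming_bond)
    swapped$forming_bond <- rev(r$leaving_bond)
    expect_equal(compute_dcat(swapped), -compute_dcat(r))
  }
})

test_that("the distance descriptor needs a TS geometry", {
  r <- make_record()
  r$points$TS <- NULL
  expect_error(compute_dcat(r), "no TS geometry")
  r2 <- make_record()
  r2$points$TS$geometry <- NULL
  expect_error(compute_dcat(r2), "no TS geometry")
})

test_that("the charge-transfer descriptor is the TS minus RC group charge", {
  expect_equal(compute_qcat(make_record(qrc = -0.94, qts = -0.73)), 0.21)
  expect_equal(compute_qcat(make_record(qrc = -0.66, qts = -0.62)), 0.04)
  expect_equal(compute_qcat(make_record(qrc = -0.5, qts = -0.5)), 0)
})

test_that("charge transfer ignores atoms outside the nucleophile selection", {
  r <- make_record()
  base <- compute_qcat(r)
  r$points$TS$charges <- charge_table(1:3, c("Nu", "C1", "Cl1"),
                                      c(-0.73, 99, -99))
  r$points$RC$charges <- charge_table(1:3, c("Nu", "C1", "Cl1"),
                                      c(-0.94, -5, 7))
  expect_equal(compute_qcat(r), base)
})

test_that("charge transfer fails precisely when charges are missing", {
  r <- make_record()
  r$points$RC$charges <- NULL
  expect_error(compute_qcat(r), "RC has no charge table")
  r <- make_record()
  r$points$TS$charges <- NULL
  expect_error(compute_qcat(r), "TS has no charge table")
})

test_that("descriptor_table reproduces the bundled series values", {
  tab <- descriptor_table(load_series(dhla_example_config()))
  expect_s3_class(tab, "descriptor_table")
  expect_equal(tab$label, c("3", "2", "1", "0", "water"))
  expect_equal(tab$qcat, c(0.21, 0.17, 0.09, 0.05, 0.04))
  expect_equal(tab$dcat, c(0.43, 0.30, 0.04, NA, -0.10))
  expect_equal(tab$barrier, c(15.4, 17.1, 19.3, 24.3, 25.2))
})

test_that("descriptor_table recovers prescribed synthetic targets exactly", {
  sp <- series_spec(
    data.frame(label = c("a", "b", "c"),
               dcat = c(0.43, -0.10, 0),
               qcat = c(0.21, 0.04, -0.02),
               barrier = c(15.4, 25.2, 20)),
    sigma = 0, seed = 42)
  tab <- descriptor_table(generate_series(sp, withr::local_tempdir()))
  expect_equal(tab$dcat, c(0.43, -0.10, 0), tolerance = 1e-12)
  expect_equal(tab$qcat, c(0.21, 0.04, -0.02), tolerance = 1e-12)
  expect_equal(tab$barrier, c(15.4, 25.2, 20))
})

test_that("a record with neither descriptor computable is an error", {
  r <- make_record()
  r$points$TS$geometry <- NULL
  r$points$TS$charges <- NULL
  expect_error(descriptor_table(environment_series(list(r))),
               "neither descriptor")
})

test_that("reactivity ordering reports descending descriptor and verdict", {
  rows <- qcat_demo_rows()
  o <- reactivity_order(rows, "qcat")
  expect_equal(o$labels, c("3", "2", "1", "0"))
  expect_true(o$monotone)

  rev_rows <- rows
  rev_rows$barrier <- rev(rows$barrier)  # constructed counterexample
  expect_false(reactivity_order(rev_rows, "qcat")$monotone)

  tied <- rows
  tied$qcat[2] <- tied$qcat[1]
  expect_warning(ot <- reactivity_order(tied, "qcat"), "tied")
  expect_setequal(ot$ties, c("3", "2"))
  expect_false(ot$monotone)

  expect_error(reactivity_order(rows[1, ], "qcat"), "at least 2")
})
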