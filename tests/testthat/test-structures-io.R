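test_that("read_xyz parses a standard file and checks its count line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "", "O 0 0 0", "C 0 0 2.04"), f)
  g <- read_xyz(f)
  expect_equal(n_atoms(g), 2L)
  expect_equal(g$elements, c("O", "C"))
  expect_equal(bond_length(g, 1, 2), 2.04)

  writeLines(c("3", "", "O 0 0 0", "C 0 0 2.04"), f)
  expect_error(read_xyz(f), "count line says 3")
  writeLines(c("2", "", "O 0 0 0", "C 0 0 zz"), f)
  expect_error(read_xyz(f), "line 4")
  writeLines(c("x", "", "O 0 0 0"), f)
  expect_error(read_xyz(f), "line 1")
})

test_that("write/read round trip preserves coordinates and comment", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(1:12, 1)
    g <- geometry(sample(c("C", "H", "O", "Cl"), n, replace = TRUE),
                  matrix(runif(3 * n, -30, 30), n, 3),
                  comment = "energy=15.4")
    f <- withr::local_tempfile(fileext = ".xyz")
    write_xyz(g, f)
    g2 <- read_xyz(f)
    expect_equal(g2$coords, g$coords, tolerance = 1e-6)
    expect_identical(g2$elements, g$elements)
    expect_identical(g2$comment, "energy=15.4")
  }
})

test_that("geometry constructor enforces its invariants", {
  expect_error(geometry(character(0), matrix(0, 0, 3)), "at least one")
  expect_error(geometry(c("C", ""), matrix(0, 2, 3)), "non-empty")
  expect_error(geometry("C", matrix(c(0, 0, Inf), 1, 3)), "finite")
})

test_that("bond_length is a metric on atom triples", {
  expect_equal(bond_length(geometry(c("C", "Cl"),
                                    rbind(c(0, 0, 0), c(0, 0, 2.47))),
                           1, 2), 2.47)
  set.seed(11)
  for (rep in 1:20) {
    g <- geometry(c("C", "O", "Cl"), matrix(rnorm(9, sd = 3), 3, 3))
    d12 <- bond_length(g, 1, 2)
    # direct formula oracle
    expect_equal(d12, sqrt(sum((g$coords[1, ] - g$coords[2, ])^2)))
    expect_identical(d12, bond_length(g, 2, 1))
    expect_gt(d12, 0)
    expect_lte(d12, bond_length(g, 1, 3) + bond_length(g, 3, 2) + 1e-12)
  }
  g <- geometry(c("C", "O"), matrix(0, 2, 3))
  expect_equal(bond_length(g, 1, 2), 0)
  expect_error(bond_length(g, 1, 3), "out of range")
  expect_error(bond_length(g, 1, 1), "distinct")
})

test_that("charge tables reject duplicates, bad numbers and empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("index,label,charge", "1,O1,-0.88", "2,Cl1,-0.34"), f)
  ct <- read_charge_table(f)
  expect_s3_class(ct, "charge_table")
  expect_equal(nrow(ct), 2L)
  expect_equal(group_charge(ct, c(1, 2)), -1.22)

  writeLines(c("index,label,charge", "1,O1,-0.88", "1,Cl1,-0.34"), f)
  expect_error(read_charge_table(f), "duplicate")
  writeLines(c("index,label,charge", "1,O1,abc"), f)
  expect_error(read_charge_table(f), "non-numeric")
  writeLines("index,label,charge", f)
  expect_error(read_charge_table(f), "no rows")
  writeLines(c("idx,lab,q", "1,O1,-0.88"), f)
  expect_error(read_charge_table(f), "header")
})

test_that("group_charge sums signed charges and is additive", {
  ct <- charge_table(1:3, c("a", "b", "c"), c(-0.80, 0.30, -0.44))
  expect_equal(group_charge(ct, 1:3), -0.94)       # direct summation
  expect_equal(group_charge(ct, 2), 0.30)          # singleton
  expect_equal(group_charge(ct, c(1, 3)) + group_charge(ct, 2),
               group_charge(ct, 1:3))
  expect_error(group_charge(ct, c(1, 9)), "9")
})

test_that("reaction_record validates bond topology and selections", {
  g <- geometry(c("O", "C", "Cl"),
                rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 4)))
  ts <- stationary_point("TS", g)
  expect_error(
    reaction_record("x", ts = ts, leaving_bond = c(2, 3),
                    forming_bond = c(1, 4), nucleophile = 1),
    "share")
  expect_error(
    reaction_record("x", ts = ts, leaving_bond = c(2, 3),
                    forming_bond = c(1, 2), nucleophile = 3),
    "leaving-group")
  expect_error(
    reaction_record("x", ts = ts, leaving_bond = c(2, 3),
                    forming_bond = c(1, 2), nucleophile = integer(0)),
    "empty")
  expect_error(stationary_point("QQ", g), "one of")
  expect_error(stationary_point("TS"), "geometry, a charge table")
})

test_that("load_series loads the bundled example and validates configs", {
  s <- load_series(dhla_example_config())
  expect_s3_class(s, "environment_series")
  expect_length(s, 5L)
  expect_setequal(names(s$records), c("3", "2", "1", "0", "water"))
  expect_true(s[["water"]]$predict_only)
  expect_false(s[["3"]]$predict_only)
  # charges-only stationary points are allowed at load time
  expect_null(s[["0"]]$points$TS$geometry)
  expect_s3_class(s[["0"]]$points$TS$charges, "charge_table")

  # duplicate labels rejected
  cfg <- yaml::read_yaml(dhla_example_config())
  cfg$environments[[2]]$label <- "3"
  tmp <- withr::local_tempdir()
  file.copy(list.files(dirname(dhla_example_config()), full.names = TRUE),
            tmp)
  bad <- file.path(tmp, "bad.yaml")
  yaml::write_yaml(cfg, bad)
  expect_error(load_series(bad), "duplicate")

  # out-of-range selection rejected
  cfg <- yaml::read_yaml(dhla_example_config())
  cfg$environments[[1]]$nucleophile_indices <- list(99L)
  yaml::write_yaml(cfg, bad)
  expect_error(load_series(bad), "out of range")

  # missing file rejected
  cfg <- yaml::read_yaml(dhla_example_config())
  cfg$environments[[1]]$ts_xyz <- "nope.xyz"
  yaml::write_yaml(cfg, bad)
  expect_error(load_series(bad), "missing file")
})

test_that("load_series is total on generated series", {
  set.seed(3)
  for (rep in 1:3) {
    n <- sample(3:6, 1)
    sp <- series_spec(
      data.frame(label = paste0("e", 1:n),
                 dcat = runif(n, -0.5, 0.8),
                 qcat = runif(n, 0, 0.3),
                 barrier = runif(n, 10, 25)),
      sigma = runif(1, 0, 1), seed = 100 + rep)
    out <- withr::local_tempdir()
    expect_no_error(generate_series(sp, out))
  }
})
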