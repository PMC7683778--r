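test_that("disturbance series satisfy their spectral contracts", {
  dp <- make_disturbance(disturbance_spec("pure_sine", t_aboard = 300))
  expect_gte(spectral_dominance(dp$d, 0.05, 0.25), 0.99)

  db <- make_disturbance(disturbance_spec("broadband", seed = 3))
  expect_lte(spectral_dominance(db$d, 0.05), 0.2)

  dn <- make_disturbance(disturbance_spec("sine_plus_noise", seed = 3))
  expect_gt(spectral_dominance(dn$d, 0.05, 0.25), 0.5)

  # property: contracts hold across random specs
  set.seed(14)
  for (k in 1:5) {
    f <- stats::runif(1, 0.2, 0.3)
    dt <- sample(c(0.05, 0.1), 1)
    ta <- sample(c(200, 400), 1)
    dpk <- make_disturbance(disturbance_spec("pure_sine", frequency = f,
                                             dt = dt, t_aboard = ta))
    expect_gte(spectral_dominance(dpk$d, dt, f), 0.99)
    dbk <- make_disturbance(disturbance_spec("broadband", frequency = f,
                                             dt = dt, t_aboard = ta,
                                             seed = k))
    expect_lte(spectral_dominance(dbk$d, dt), 0.2)
  }

  # determinism by seed
  d1 <- make_disturbance(disturbance_spec("broadband", seed = 8))
  d2 <- make_disturbance(disturbance_spec("broadband", seed = 8))
  expect_identical(d1$d, d2$d)

  expect_error(disturbance_spec(frequency = 0.25, dt = 2.1), "Nyquist")
})

test_that("sweep CSV round-trips losslessly and reports parse errors", {
  sw <- sweep_oscillation(w_inh = c(1, 5, 30), w_exc = c(1, 100),
                          n_samples = 500, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, path)
  back <- read_sweep_csv(path)
  expect_identical(back$p_osc, sw$p_osc)
  expect_identical(back$se, sw$se)
  expect_identical(back$seed, sw$seed)
  expect_identical(back$n_samples, sw$n_samples)

  # permuted header accepted (header-keyed parsing)
  lines <- readLines(path)
  hdr <- strsplit(lines[1], ",")[[1]]
  perm <- c(3, 1, 2, 5, 4, 7, 6)
  lines2 <- vapply(lines, function(l)
    paste(strsplit(l, ",")[[1]][perm], collapse = ","), character(1))
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines2, path2)
  expect_identical(read_sweep_csv(path2)$p_osc, sw$p_osc)

  # truncated row and non-numeric cell: errors with the line number
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1:3], "1,2,3"), path3)
  expect_error(read_sweep_csv(path3), "line 4")
  path4 <- withr::local_tempfile(fileext = ".csv")
  lines4 <- lines
  lines4[2] <- sub("^[0-9.]+", "oops", lines4[2])
  writeLines(lines4, path4)
  expect_error(read_sweep_csv(path4), "line 2")
})

test_that("run_experiment dispatches, validates, and is reproducible", {
  expect_error(run_experiment(list(experiment = "nope")), "unknown experiment")
  expect_error(run_experiment(list(experiment = "classify")), "matrix")
  expect_error(run_experiment(list(experiment = "inhibition_sweep",
                                   n_samples = 0)), "n_samples")

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- list(experiment = "inhibition_sweep", n_samples = 300, step = 50,
              seed = 5)
  r1 <- run_experiment(c(cfg, list(out_dir = d1)))
  r2 <- run_experiment(c(cfg, list(out_dir = d2)))
  expect_identical(readLines(file.path(d1, "sweep.csv")),
                   readLines(file.path(d2, "sweep.csv")))
  expect_identical(r1$config_hash, r2$config_hash)
  expect_identical(r1$manifest$md5, r2$manifest$md5)
  sw <- read_sweep_csv(file.path(d1, "sweep.csv"))
  expect_equal(nrow(sw), 3 * 3)           # w_inh {1,50,100} x w_exc {1,10,100}
  expect_true(all(sw$w_self == 1))

  # classification round trip through a matrix file
  d3 <- withr::local_tempdir()
  mfile <- file.path(d3, "J.csv")
  J <- rbind(c(0.1, -1, 0, 0), c(1, 0.1, 0, 0),
             c(0, 0, -1, 0), c(0, 0, 0, -1))
  utils::write.table(J, mfile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  rec <- run_experiment(list(experiment = "classify", matrix = mfile,
                             out_dir = d3))
  rep <- jsonlite::fromJSON(file.path(d3, "classification.json"))
  expect_identical(rep$category, "unstable_oscillatory")
  expect_true(rep$oscillatory)
  expect_true(rep$time_domain$oscillatory)
})

test_that("the standard sweep configuration covers the full printed grid", {
  d <- withr::local_tempdir()
  run_experiment(list(experiment = "inhibition_sweep", n_samples = 40,
                      step = 1, seed = 2, out_dir = d))
  sw <- read_sweep_csv(file.path(d, "sweep.csv"))
  expect_equal(nrow(sw), 100 * 3)
  expect_setequal(unique(sw$w_inh), 1:100)
  expect_setequal(unique(sw$w_exc), c(1, 10, 100))
})
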