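test_that("identical pump and dark data give all-zero differences", {
  obs <- cached_observed()
  ds <- suppressMessages(difference_amplitudes(obs$dark_obs, obs$dark_obs))
  expect_true(all(ds$data$delta_f == 0))
  expect_equal(ds$report$n_common, nrow(obs$dark_obs$data))
})

test_that("reflections absent from one set are dropped and counted", {
  obs <- cached_observed()
  pump <- obs$pump_obs
  drop_key <- trxmap:::hkl_key(pump$data)[5]
  pump$data <- pump$data[-5, ]
  ds <- suppressMessages(difference_amplitudes(pump, obs$dark_obs))
  expect_false(drop_key %in% trxmap:::hkl_key(ds$data))
  expect_equal(ds$report$dropped_from_dark, 1)
  expect_equal(ds$report$n_common, nrow(obs$dark_obs$data) - 1)
})

test_that("observed differences track the simulation truth", {
  # noise scales with the shell-mean amplitude, so individual weak
  # differences are noise-dominated at 3%; use a low-noise experiment to
  # check the measurement itself and the noisy one for the strong signal
  obs <- cached_observed(p = 0.05, noise = 0.005, seed = 7)
  sc <- scale_datasets(obs$dark_obs, obs$pump_obs)
  ds <- difference_amplitudes(sc$scaled, obs$dark_obs)
  truth <- Mod(0.95 * obs$fc_dark$f + 0.05 * obs$fc_light$f) -
    Mod(obs$fc_dark$f)
  ord <- match(trxmap:::hkl_key(ds$data),
               paste(obs$fc_dark$hkl[, 1], obs$fc_dark$hkl[, 2],
                     obs$fc_dark$hkl[, 3]))
  strong <- abs(truth[ord]) > stats::quantile(abs(truth), 0.95)
  expect_gt(stats::cor(ds$data$delta_f[strong], truth[ord][strong]), 0.95)
  # at the study noise level the strong differences still correlate
  obs3 <- cached_observed(p = 0.05, noise = 0.03, seed = 7)
  sc3 <- scale_datasets(obs3$dark_obs, obs3$pump_obs)
  ds3 <- difference_amplitudes(sc3$scaled, obs3$dark_obs)
  expect_gt(stats::cor(ds3$data$delta_f[strong], truth[ord][strong]), 0.5)
})

test_that("q-weights follow the closed form and punish outliers", {
  obs <- cached_observed()
  sc <- scale_datasets(obs$dark_obs, obs$pump_obs)
  ds <- difference_amplitudes(sc$scaled, obs$dark_obs)
  # equal sigmas, alpha = 0  ->  all weights exactly 1/2
  ds_eq <- ds
  ds_eq$data$sig_delta <- 1.23
  w <- weight_differences(ds_eq, alpha = 0)
  expect_equal(w$data$weight, rep(0.5, nrow(ds$data)), tolerance = 1e-12)
  # a gross delta outlier gets the strictly smallest weight
  ds_out <- ds_eq
  ds_out$data$delta_f[10] <- sqrt(100 * mean(ds_eq$data$delta_f^2))
  w2 <- weight_differences(ds_out, alpha = 1)
  expect_equal(which.min(w2$data$weight), 10)
  expect_lt(w2$data$weight[10], min(w2$data$weight[-10]))
  # all-zero differences are rejected
  ds0 <- ds
  ds0$data$delta_f <- 0
  expect_error(weight_differences(ds0), "zero")
})

test_that("weighting improves map fidelity under spike noise", {
  set.seed(31)
  obs <- cached_observed(p = 0.05, noise = 0.03, seed = 7)
  sc <- scale_datasets(obs$dark_obs, obs$pump_obs)
  ds <- difference_amplitudes(sc$scaled, obs$dark_obs)
  # contaminate 2% of reflections with spikes
  n <- nrow(ds$data)
  bad <- sample(n, round(0.02 * n))
  ds$data$delta_f[bad] <- ds$data$delta_f[bad] +
    sample(c(-1, 1), length(bad), TRUE) * 8 * sd(ds$data$delta_f)
  # noise-free reference difference map
  exp <- cached_experiment(p = 0.05, noise = 0.03, seed = 7)
  truth_ds <- ds
  ord <- match(trxmap:::hkl_key(ds$data),
               paste(obs$fc_dark$hkl[, 1], obs$fc_dark$hkl[, 2],
                     obs$fc_dark$hkl[, 3]))
  truth_ds$data$delta_f <-
    (Mod(0.95 * obs$fc_dark$f + 0.05 * obs$fc_light$f) -
       Mod(obs$fc_dark$f))[ord]
  truth_ds$data$weight <- 1
  truth_ds$weighted <- TRUE
  ref <- difference_map(truth_ds, obs$fc_dark)
  unw <- suppressMessages(difference_map(ds, obs$fc_dark))
  wtd <- difference_map(weight_differences(ds), obs$fc_dark)
  cor_unw <- stats::cor(as.vector(unw$values), as.vector(ref$values))
  cor_wtd <- stats::cor(as.vector(wtd$values), as.vector(ref$values))
  expect_gt(cor_wtd, cor_unw)
})

test_that("single-reflection synthesis is the textbook cosine wave", {
  cell <- unit_cell(10, 10, 10)
  rs <- reflection_set(cell, rbind(c(1, 0, 0)), f = 7, phi = 0,
                       d_min = 5)
  mp <- fourier_map(rs, grid = c(20, 20, 20), sigma_scale = FALSE)
  x <- (0:19) / 20
  expect_equal(mp$values[, 1, 1], 2 * 7 * cos(2 * pi * x) / cell$volume,
               tolerance = 1e-12)
  # zero amplitudes -> uniformly zero map
  rs0 <- reflection_set(cell, rbind(c(1, 0, 0), c(0, 2, 1)), f = c(0, 0),
                        phi = c(0, 90), d_min = 4)
  mp0 <- fourier_map(rs0, grid = c(12, 12, 12), sigma_scale = FALSE)
  expect_true(all(mp0$values == 0))
  # missing phases are refused with a count
  rs_np <- reflection_set(cell, rbind(c(1, 0, 0)), f = 1)
  expect_error(fourier_map(rs_np), "1 reflection")
})

test_that("difference maps are linear, flat for identical inputs, and odd", {
  obs <- cached_observed()
  sc <- scale_datasets(obs$dark_obs, obs$pump_obs)
  ds <- weight_differences(difference_amplitudes(sc$scaled, obs$dark_obs))
  raw <- difference_map(ds, obs$fc_dark, sigma_scale = FALSE)
  ds3 <- ds
  ds3$data$delta_f <- 3 * ds3$data$delta_f
  ds3$data$weight <- ds$data$weight      # same weights: test map linearity
  raw3 <- difference_map(ds3, obs$fc_dark, sigma_scale = FALSE)
  expect_equal(max(abs(raw3$values - 3 * raw$values)) / max(abs(raw$values)),
               0, tolerance = 1e-9)
  dneg <- ds
  dneg$data$delta_f <- -dneg$data$delta_f
  rawneg <- difference_map(dneg, obs$fc_dark, sigma_scale = FALSE)
  expect_equal(rawneg$values, -raw$values, tolerance = 1e-12)
  # pump = dark -> flat
  dsid <- suppressMessages(difference_amplitudes(obs$dark_obs, obs$dark_obs))
  dsid$weighted <- TRUE
  flat <- difference_map(dsid, obs$fc_dark, sigma_scale = FALSE)
  expect_lt(max(abs(flat$values)), 1e-6 * sd(raw$values))
})

test_that("sigma scaling yields mean 0 / sd 1 and peak heights are stable
           under grid oversampling", {
  obs <- cached_observed()
  sc <- scale_datasets(obs$dark_obs, obs$pump_obs)
  ds <- weight_differences(difference_amplitudes(sc$scaled, obs$dark_obs))
  dmap <- difference_map(ds, obs$fc_dark)
  expect_lt(abs(mean(dmap$values)), 1e-6)
  expect_equal(sd(dmap$values), 1, tolerance = 1e-6)
  pk1 <- find_peaks(dmap, 5)
  fine <- difference_map(ds, obs$fc_dark, spacing = obs$fc_dark$d_min / 4.5)
  pk2 <- find_peaks(fine, 5)
  expect_equal(pk2$height[1], pk1$height[1], tolerance = 0.02)
  neg1 <- min(pk1$height); neg2 <- min(pk2$height)
  expect_equal(neg2, neg1, tolerance = 0.02)
})

test_that("peak search finds and attributes simulated features", {
  # flat map -> nothing
  flat <- density_map(array(0, c(8, 8, 8)), unit_cell(10, 10, 10))
  flat <- sigma_scale_map(flat)
  expect_equal(nrow(find_peaks(flat, 3)), 0)
  # a constructed Gaussian blob of peak 8 sigma
  g <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  blob <- array(exp(-((g$x - 12)^2 + (g$y - 12)^2 + (g$z - 12)^2) / 4),
                c(24, 24, 24))
  m <- density_map(blob, unit_cell(12, 12, 12))
  sm <- sigma_scale_map(m)
  target <- max(sm$values)
  pk <- find_peaks(sm, threshold = target / 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$height, target, tolerance = 1e-9)
  # ion displacement: strongest negative near dark ion, positive toward
  # the light position
  exp <- cached_experiment()
  obs <- cached_observed()
  sc <- scale_datasets(obs$dark_obs, obs$pump_obs)
  ds <- weight_differences(difference_amplitudes(sc$scaled, obs$dark_obs))
  dmap <- difference_map(ds, obs$fc_dark)
  pk <- find_peaks(dmap, 3, model = exp$dark)
  neg <- pk[pk$height < 0, ][1, ]
  ion_dark <- atom_xyz(exp$dark, select_atoms(exp$dark, "element CL"))
  ion_light <- atom_xyz(exp$light, select_atoms(exp$light, "element CL"))
  expect_lt(sqrt(sum((unlist(neg[c("x", "y", "z")]) - ion_dark)^2)), 1.0)
  expect_equal(exp$dark$atoms$element[neg$atom], "CL")
  pos <- pk[pk$height > 0, ][1, ]
  expect_lt(sqrt(sum((unlist(pos[c("x", "y", "z")]) - ion_light)^2)), 1.0)
})

test_that("CCP4 map files round-trip", {
  obs <- cached_observed()
  mp <- fourier_map(obs$fc_dark, sigma_scale = TRUE)
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4_map(mp, path)
  back <- read_ccp4_map(path)
  expect_equal(dim(back$values), dim(mp$values))
  expect_equal(back$values, mp$values, tolerance = 1e-6)
  expect_equal(back$cell$a, 30, tolerance = 1e-4)
})
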