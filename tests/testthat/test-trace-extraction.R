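test_that("fixed-threshold segmentation finds exactly the bright disk", {
  img <- matrix(0, 32, 32)
  mask <- rsfpfit:::disk_mask(c(32, 32), c(15, 16), 6)
  img[mask] <- 1
  om <- segment_objects(img, method = "fixed", threshold = 0.5)
  expect_identical(om$n_objects, 1L)
  expect_identical(om$areas, sum(mask))
  expect_lt(max(abs(om$centroids[1, ] - c(15, 16))), 0.2)
})

test_that("blank images give an empty map with a warning", {
  expect_warning(om <- segment_objects(matrix(0, 16, 16), method = "fixed",
                                       threshold = 0.5),
                 "empty")
  expect_identical(om$n_objects, 0L)
  expect_warning(segment_objects(matrix(0.3, 16, 16)), "empty")
})

test_that("labelling is 8-connected and min_area filters", {
  m <- matrix(0, 8, 8)
  m[cbind(c(2, 3, 4), c(2, 3, 4))] <- 1  # diagonal chain = one object
  m[7, 7] <- 1                           # isolated single pixel
  om <- segment_objects(m, method = "fixed", threshold = 0.5)
  expect_identical(om$n_objects, 2L)
  om2 <- segment_objects(m, method = "fixed", threshold = 0.5, min_area = 2)
  expect_identical(om2$n_objects, 1L)
  expect_identical(om2$areas, 3L)
})

test_that("thresholding recovers a random colony layout", {
  lay <- random_colony_layout(12, image_shape = c(128, 128),
                              background_level = 0.05, seed = 77)
  tr <- single_species_truth(seed = 7)
  ex <- simulate_switching(protocol_colony(), tr, n_objects = 12)
  stack <- render_colony_stack(ex, lay)
  ref <- stack[, , normalization_frame(protocol_colony())]
  # fixed threshold between background and the dimmest colony: Otsu's
  # between-class criterion is unreliable when foreground covers only a few
  # percent of the image and spans a wide brightness range
  om <- segment_objects(ref, method = "fixed", threshold = 0.15,
                        min_area = 5)
  expect_identical(om$n_objects, 12L)
  # match centroids to ground truth within 1 px
  d <- vapply(seq_len(12), function(i) {
    min(sqrt(rowSums(sweep(om$centroids, 2, lay$centers[i, ])^2)))
  }, numeric(1))
  expect_lt(max(d), 1)
})

test_that("noise-free round trip recovers the generated traces", {
  lay <- random_colony_layout(5, image_shape = c(96, 96),
                              background_level = 0.2, seed = 12)
  proto <- switching_protocol(3, 5, 10, 0.2)
  tr <- ground_truth(two_state_kinetics(8, 1, f_B = 0.2, c = 0),
                     popdyn_params(0.05, 0.01, 0.02, a0 = 1, b0 = 0.1),
                     seed = 5)
  ex <- simulate_switching(proto, tr, n_objects = 5)
  stack <- render_colony_stack(ex, lay)
  om <- segment_objects(stack[, , normalization_frame(proto)],
                        method = "otsu", min_area = 5)
  got <- extract_traces(stack, om, proto)
  expect_identical(got$n_objects, 5L)
  # population mean traces agree after normalisation
  expect_lt(max(abs(got$mean_trace - ex$mean_trace)), 1e-6)
  # and per-object normalised traces match the generator ground truth
  sim <- matrix(ex$traces$intensity, ncol = 5)
  rec <- matrix(got$traces$intensity, ncol = 5)
  # match extracted objects to layout objects by centroid
  match_idx <- vapply(seq_len(5), function(i) {
    which.min(rowSums(sweep(om$centroids, 2, lay$centers[i, ])^2))
  }, integer(1))
  for (i in seq_len(5)) {
    a <- rec[, match_idx[i]] / rec[normalization_frame(proto), match_idx[i]]
    b <- sim[, i] / sim[normalization_frame(proto), i]
    expect_lt(max(abs(a - b)), 1e-6)
  }
})

test_that("noisy round trip stays within the noise envelope", {
  lay <- random_colony_layout(4, image_shape = c(64, 64),
                              background_level = 0.1, seed = 21)
  proto <- switching_protocol(2, 5, 10, 0.2)
  ex <- simulate_switching(proto, single_species_truth(seed = 8),
                           n_objects = 4)
  nm <- noise_model(read_sigma = 0.02)
  stack <- render_colony_stack(ex, lay, noise = nm, seed = 99)
  om <- segment_objects(stack[, , normalization_frame(proto)],
                        method = "otsu", min_area = 5)
  got <- extract_traces(stack, om, proto)
  # per-object mean of >= ~50 pixels: 3 sigma of the object mean
  min_px <- min(om$areas)
  expect_lt(max(abs(got$mean_trace - ex$mean_trace)),
            3 * 0.02 / sqrt(min_px))
})

test_that("normalisation is anchored and idempotent", {
  proto <- switching_protocol(2, 4, 8, 0.5)
  ex <- simulate_switching(proto, single_species_truth(seed = 3, c = 0.05))
  idx <- ex$normalization_frame_index
  expect_identical(idx, normalization_frame(proto))
  expect_equal(ex$mean_trace[idx], 1)
  renorm <- ex$mean_trace / ex$mean_trace[idx]
  expect_identical(renorm, ex$mean_trace)
})

test_that("uniform stacks extract a constant normalised trace", {
  proto <- switching_protocol(1, 4, 8, 0.5)
  stack <- array(0.6, dim = c(12, 12, n_frames(proto)))
  om <- segment_objects(stack[, , 1] + 0, method = "fixed", threshold = 0.1)
  got <- extract_traces(stack, om, proto, background_subtract = TRUE)
  expect_true(all(abs(got$mean_trace - 1) < 1e-12))
  expect_identical(got$n_objects, 1L)
})

test_that("object brightness averages the per-object maxima", {
  proto <- switching_protocol(1, 4, 8, 0.5)
  sched <- frame_schedule(proto)
  mk <- function(v) data.frame(frame = sched$frame, time_s = sched$time_s,
                               cycle = sched$cycle,
                               half_cycle = sched$half_cycle,
                               illumination = sched$illumination,
                               object_id = NA, intensity = v)
  df1 <- mk(seq(0, 10, length.out = nrow(sched))); df1$object_id <- 1L
  df2 <- mk(seq(0, 20, length.out = nrow(sched))); df2$object_id <- 2L
  ex <- rsfpfit:::new_switch_experiment(proto, rbind(df1, df2))
  ob <- object_brightness(ex)
  expect_equal(ob$mean_max, 15)
  expect_equal(ob$per_object$max_intensity, c(10, 20))
  # lognormal colony scales: means of generated maxima match metadata
  lay <- random_colony_layout(6, seed = 55, background_level = 0)
  exs <- simulate_switching(proto, single_species_truth(seed = 6),
                            n_objects = 6)
  stack <- render_colony_stack(exs, lay)
  om <- segment_objects(stack[, , normalization_frame(proto)],
                        method = "fixed", threshold = 0.1, min_area = 5)
  got <- extract_traces(stack, om, proto)
  obs <- sort(object_brightness(got)$per_object$max_intensity)
  truth_max <- sort(lay$intensity_scale * max(exs$traces$intensity))
  expect_equal(obs, truth_max, tolerance = 1e-6)
})

test_that("geometry and emptiness guards fire", {
  proto <- switching_protocol(1, 2, 6, 0.5)
  stack <- array(1, dim = c(8, 8, n_frames(proto)))
  om <- segment_objects(matrix(c(0, 1), 8, 8), method = "fixed",
                        threshold = 0.5)
  bad <- array(1, dim = c(6, 6, n_frames(proto)))
  expect_error(extract_traces(bad, om, proto), "geometry")
  expect_error(extract_traces(stack[, , 1:3], om, proto), "frame count")
  em <- suppressWarnings(segment_objects(matrix(0, 8, 8), method = "fixed",
                                         threshold = 0.5))
  expect_error(extract_traces(stack, em, proto), "empty")
  expect_error(object_brightness(structure(list(n_objects = 0),
                                           class = "switch_experiment")),
               "no objects")
})

test_that("TIFF stack round trip preserves intensities", {
  stack <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  f <- tempfile(fileext = ".tif")
  write_stack_tiff(stack, f, bits_per_sample = 32)
  back <- read_stack_tiff(f)
  expect_equal(back, stack, tolerance = 1e-6)
})
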