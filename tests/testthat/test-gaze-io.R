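test_that("fixation tables parse, sort, and round-trip", {
  tsv <- paste(
    "# Tobii-style export",
    "participant_id\tgroup\tstimulus_id\tx_px\ty_px\tonset_ms\tduration_ms",
    "p1\tclinician\ts1\t10\t20\t0\t100",
    "p1\tclinician\ts1\t30\t40\t150\t200",
    "p1\tclinician\ts1\t50\t60\t400\t120",
    sep = "\n")
  seqs <- read_fixation_table(textConnection(tsv))
  expect_length(seqs, 1)
  expect_equal(nrow(seqs[[1]]$fixations), 3)
  expect_equal(seqs[[1]]$fixations$x_px, c(10, 30, 50))

  # header only -> empty list
  hdr <- "participant_id\tgroup\tstimulus_id\tx_px\ty_px\tonset_ms\tduration_ms"
  expect_length(read_fixation_table(textConnection(hdr)), 0)

  # out-of-order rows come back sorted by onset
  shuffled <- paste(hdr,
    "p1\tclinician\ts1\t3\t3\t900\t100",
    "p1\tclinician\ts1\t1\t1\t0\t100",
    "p1\tclinician\ts1\t2\t2\t400\t100", sep = "\n")
  s <- read_fixation_table(textConnection(shuffled))[[1]]
  expect_equal(s$fixations$onset_ms, sort(c(900, 0, 400)))
  expect_equal(s$fixations$x_px, c(1, 3, 2)[order(c(0, 900, 400))])

  # write -> read round trip preserves all fields
  cfg <- small_cfg(seed = 3)
  st <- gen_stimuli(cfg)
  seqs <- gen_fixations(cfg, st, "clin01", "clinician")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_table(seqs, path)
  back <- read_fixation_table(path)
  keep <- Filter(function(s) nrow(s$fixations) > 0, seqs)
  expect_equal(length(back), length(keep))
  for (i in seq_along(keep)) {
    expect_equal(back[[i]]$fixations, keep[[i]]$fixations)
    expect_equal(back[[i]]$group, keep[[i]]$group)
  }
})

test_that("fixation table errors name the problem", {
  bad_col <- paste("participant_id\tgroup\tstimulus_id\tx_px\ty_px\tonset_ms",
                   "p1\tclinician\ts1\t1\t2\t0", sep = "\n")
  expect_error(read_fixation_table(textConnection(bad_col)), "duration_ms")
  bad_num <- paste(
    "participant_id\tgroup\tstimulus_id\tx_px\ty_px\tonset_ms\tduration_ms",
    "p1\tclinician\ts1\t1\t2\t0\t100",
    "p1\tclinician\ts1\toops\t2\t200\t100", sep = "\n")
  expect_error(read_fixation_table(textConnection(bad_num)), "line 2")
  missing_xy <- paste(
    "participant_id\tgroup\tstimulus_id\tx_px\ty_px\tonset_ms\tduration_ms",
    "p1\tclinician\ts1\t1\t2\t0\t100",
    "p1\tclinician\ts1\t\t2\t200\t100", sep = "\n")
  expect_message(s <- read_fixation_table(textConnection(missing_xy)), "dropped")
  expect_equal(nrow(s[[1]]$fixations), 1)
})

test_that("heat-map images decode to ordinal levels and encode back", {
  scheme <- color_scheme()
  # 2x2: [high, low; background, medium]
  img <- array(0, dim = c(2, 2, 4))
  put <- function(i, j, hex) {
    rgb <- grDevices::col2rgb(hex)[, 1] / 255
    img[i, j, 1:3] <<- rgb; img[i, j, 4] <<- 1
  }
  put(1, 1, "#943126"); put(1, 2, "#CB4335"); put(2, 2, "#B03A2E")
  m <- decode_heatmap_image(img, scheme)
  expect_equal(unclass(m), matrix(c(3, 0, 1, 2), 2, 2), ignore_attr = TRUE)

  # all-background image -> all-zero map
  blank <- array(0, dim = c(3, 3, 4))
  expect_true(all(decode_heatmap_image(blank, scheme) == 0))

  # off-palette foreground pixel warns and maps to the nearest code
  offimg <- img
  offimg[2, 1, ] <- c(0, 0, 1, 1)  # pure blue
  expect_warning(m2 <- decode_heatmap_image(offimg, scheme), "tolerance")
  expect_true(m2[2, 1] %in% 1:3)

  # encoding rejects negatives
  neg <- attention_map(matrix(c(-1, 0, 0, 0), 2, 2), kind = "difference")
  expect_error(encode_heatmap_image(neg), "negative")

  # continuous values quantize to terciles: three distinct colors
  cont <- attention_map(matrix(c(0.1, 0.5, 0.9, 0), 2, 2))
  rgba <- encode_heatmap_image(cont, scheme)
  cols <- apply(rgba, c(1, 2), function(p) paste(round(p * 255), collapse = ","))
  expect_length(unique(cols[unclass(cont) > 0]), 3)
})

test_that("decode is the left inverse of encode on random level maps", {
  schemes <- list(color_scheme(),
                  color_scheme("#FF0000", "#00FF00", "#0000FF"))
  set.seed(42)
  for (scheme in schemes) {
    for (rep in 1:5) {
      lv <- attention_map(matrix(sample(0:3, 48, replace = TRUE), 6, 8))
      rgba <- encode_heatmap_image(lv, scheme)
      expect_equal(unclass(decode_heatmap_image(rgba, scheme)), unclass(lv),
                   ignore_attr = TRUE)
    }
  }
})

test_that("AOI sets validate polygons and round-trip through JSON", {
  tri <- list(eyebrows = rbind(c(10, 10), c(40, 10), c(25, 30)))
  a <- aoi_set("s1", tri, width_px = 64, height_px = 64)
  expect_length(a$aois, 1)

  # out-of-bounds vertex
  expect_error(
    aoi_set("s1", list(a1 = rbind(c(10, 10), c(80, 10), c(25, 30))),
            width_px = 64, height_px = 64),
    "bounds")
  # degenerate and self-intersecting polygons
  expect_error(aoi_set("s1", list(a1 = rbind(c(0, 0), c(1, 1)))), "3 vertices")
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(aoi_set("s1", list(bow = bow)), "self-intersecting")
  # duplicate names
  two <- list(rbind(c(0, 0), c(5, 0), c(0, 5)), rbind(c(1, 1), c(6, 1), c(1, 6)))
  names(two) <- c("eye", "eye")
  expect_error(aoi_set("s1", two), "duplicate")

  path <- withr::local_tempfile(fileext = ".json")
  write_aoi_set(a, path)
  back <- read_aoi_set(path, width_px = 64, height_px = 64)
  expect_equal(back$stimulus_id, "s1")
  expect_equal(back$aois$eyebrows, a$aois$eyebrows, ignore_attr = TRUE)
})

test_that("continuous attention maps persist losslessly enough at 16 bit", {
  m <- random_map(20, 30, kind = "saliency")
  path <- withr::local_tempfile(fileext = ".tiff")
  write_attention_map(m, path)
  back <- read_attention_map(path)
  expect_equal(map_kind(back), "saliency")
  expect_lt(max(abs(unclass(back) - unclass(m))), max(m) / 2^15)
})
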