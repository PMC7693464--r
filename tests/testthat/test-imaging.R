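# Grayscale encoding, layout, frame building, exclusion and resizing.

test_that("gray scaling hits the endpoints, midpoint and degenerate case", {
  expect_equal(scale_to_gray(c(0, 1), 0, 1), c(0L, 255L))
  expect_equal(scale_to_gray(-2, -2, 4), 0L)
  expect_equal(scale_to_gray(4, -2, 4), 255L)
  # midpoint: 127.5 rounds half-up to 128
  expect_equal(scale_to_gray(0.5, 0, 1), 128L)
  # degenerate scope: everything mid-gray
  expect_equal(scale_to_gray(c(3, 3, NA), 3, 3), c(127L, 127L, NA))
  # clipping
  expect_equal(scale_to_gray(c(-10, 10), 0, 1), c(0L, 255L))
  # NA preserved, other non-finite rejected
  expect_equal(scale_to_gray(NA_real_, 0, 1), NA_integer_)
  expect_error(scale_to_gray(Inf, 0, 1), class = "nc_internal_error")
  expect_error(scale_to_gray(1, 1, 0), class = "nc_parameter_error")
  # monotone in v for fixed bounds
  v <- sort(stats::runif(50, -1, 2))
  codes <- scale_to_gray(v, 0, 1)
  expect_true(all(diff(codes) >= 0))
})

test_that("default layout is 22 non-overlapping in-grid blocks and round-trips as JSON", {
  layout <- default_channel_layout()
  expect_equal(nrow(layout), 22L)
  occupied <- matrix(FALSE, 5, 10)
  for (i in 1:22) {
    cells <- cbind(layout$row[i], layout$col_start[i] + 0:1)
    expect_false(any(occupied[cells]))
    occupied[cells] <- TRUE
  }
  expect_equal(sum(occupied), 44L)  # 6 background cells remain
  expect_equal(sum(layout$region == "SFG"), 6L)
  expect_equal(sum(layout$region == "IFG"), 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_channel_layout(layout, path)
  back <- read_channel_layout(path)
  expect_equal(back$row, layout$row)
  expect_equal(back$col_start, layout$col_start)
  expect_equal(back$region, layout$region)
  # overlapping blocks rejected
  bad <- layout
  bad$col_start[2] <- bad$col_start[1]
  bad$row[2] <- bad$row[1]
  expect_error(nirsclench:::validate_layout(bad), class = "nc_layout_error")
})

test_that("render_frame fills blocks by modality and flags missing channels", {
  layout <- default_channel_layout()
  maxed <- rep(255L, 22)
  zero <- rep(0L, 22)
  f <- render_frame(oxy_codes = maxed, layout = layout, modality = "oxy")
  expect_true(f$valid)
  expect_equal(sum(f$pixels == 255L), 44L)
  expect_equal(sum(f$pixels == 0L), 6L)   # background black
  # OD: left pixel oxy, right pixel deoxy
  fod <- render_frame(oxy_codes = maxed, deoxy_codes = zero, layout = layout,
                      modality = "od")
  expect_equal(sum(fod$pixels == 255L), 22L)
  dec <- decode_frame(fod$pixels, layout, "od")
  expect_equal(dec$oxy, maxed)
  expect_equal(dec$deoxy, zero)
  # one masked channel invalidates the frame for that modality only
  with_na <- maxed
  with_na[7] <- NA_integer_
  f2 <- render_frame(oxy_codes = with_na, layout = layout, modality = "oxy")
  expect_false(f2$valid)
  expect_equal(f2$reason, "missing channel")
  f3 <- render_frame(deoxy_codes = zero, layout = layout, modality = "deoxy")
  expect_true(f3$valid)
  expect_error(render_frame(oxy_codes = maxed[1:10], layout = layout,
                            modality = "oxy"), class = "nc_layout_error")
})

test_that("encoder round-trip recovers the input codes exactly", {
  layout <- default_channel_layout()
  set.seed(31)
  codes <- sample(0:255, 22)
  f <- render_frame(oxy_codes = codes, layout = layout, modality = "oxy")
  expect_identical(decode_frame(f$pixels, layout, "oxy"), codes)
})

test_that("frame bookkeeping: counts, exclusion and OD intersection", {
  # no masking anywhere -> full candidate set is valid
  ed <- synthetic_deltas(function(i, ch) sin(i / 50 + ch),
                         function(i, ch) cos(i / 50 + ch))
  s <- build_image_set(ed)
  expect_equal(s$counts$candidates, rep(1150L, 3))
  expect_equal(s$counts$valid, rep(1150L, 3))
  expect_equal(sum(s$meta$label == "rest" & s$meta$modality == "oxy"), 600L)
  expect_equal(sum(s$meta$label == "clench" & s$meta$modality == "oxy"), 550L)

  # random masks: valid OD timepoints = valid oxy AND valid deoxy timepoints
  set.seed(17)
  ed$mask$oxy$rest <- matrix(stats::runif(600 * 22) < 0.02, 600, 22)
  ed$mask$deoxy$rest <- matrix(stats::runif(600 * 22) < 0.02, 600, 22)
  ed$mask$oxy$clench <- matrix(stats::runif(550 * 22) < 0.02, 550, 22)
  ed$mask$deoxy$clench <- matrix(stats::runif(550 * 22) < 0.02, 550, 22)
  s2 <- build_image_set(ed)
  m <- s2$meta
  key <- function(mod) {
    sel <- m$modality == mod
    paste(m$window[sel], m$sample_index[sel])[m$valid[sel]]
  }
  expect_setequal(key("od"), intersect(key("oxy"), key("deoxy")))
  # valid counts never exceed candidates
  expect_true(all(s2$counts$valid <= s2$counts$candidates))
  # OD count is the smallest
  vc <- setNames(s2$counts$valid, s2$counts$modality)
  expect_lte(vc[["od"]], vc[["oxy"]])
  expect_lte(vc[["od"]], vc[["deoxy"]])
})

test_that("squash resize keeps uniform frames uniform and blocks near-proportional", {
  uni <- matrix(7L, 5, 10)
  r <- resize_squash(uni, 256)
  expect_equal(dim(r), c(256L, 256L))
  expect_true(all(r == 7L))
  # nearest-neighbor only emits values present in the input
  set.seed(5)
  f <- matrix(sample(0:255, 50, replace = TRUE), 5, 10)
  r2 <- resize_squash(f, 256)
  expect_true(all(r2 %in% f))
  # each source cell maps to a block of ~(256/5) x (256/10) output pixels
  counts_row <- table(floor((seq_len(256) - 1) * 5 / 256) + 1)
  expect_true(all(abs(counts_row - 256 / 5) <= 1))
  counts_col <- table(floor((seq_len(256) - 1) * 10 / 256) + 1)
  expect_true(all(abs(counts_col - 256 / 10) <= 1))
  # bilinear agrees on uniform input
  expect_true(all(resize_squash(uni, 64, "bilinear") == 7))
})

test_that("PNG export writes valid frames plus an index CSV", {
  ed <- synthetic_deltas(function(i, ch) (i %% 30) / 30, function(i, ch) ch / 22)
  s <- build_image_set(ed, modalities = "oxy", stride = 100L)
  dir <- withr::local_tempdir()
  idx <- write_frames_png(s, dir)
  expect_true(file.exists(file.path(dir, "index.csv")))
  expect_equal(nrow(idx), nrow(s$meta))
  written <- idx$path[idx$valid]
  expect_true(all(file.exists(file.path(dir, written))))
  img <- png::readPNG(file.path(dir, written[1]))
  expect_equal(dim(img), c(5L, 10L))
})
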