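test_that("luma conversion matches the closed form", {
  white <- array(255, c(2, 2, 3))
  expect_true(all(to_gray(white) == 255))
  g <- array(0, c(1, 1, 3)); g[1, 1, ] <- c(137, 137, 137)
  expect_equal(to_gray(g)[1, 1], 137) # weights sum to 1
  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(to_gray(red)[1, 1], 76) # 0.299 * 255 = 76.245, half-up -> 76
  m <- matrix(5, 2, 2)
  expect_identical(to_gray(m), m) # gray input passes through
})

test_that("the hand-countable square cell reproduces every morphometric exactly", {
  sq <- square_cell_gray()
  f <- extract_morphometrics(sq$gray, sq$nucleus, sq$cytoplasm)
  expect_equal(unname(f["nucleus_area"]), 100)
  expect_equal(unname(f["nucleus_length"]), 10)
  expect_equal(unname(f["nucleus_width"]), 10)
  expect_equal(unname(f["aspect_ratio"]), 1.0)
  expect_equal(unname(f["nucleus_perimeter"]), 36)
  expect_equal(unname(f["nucleus_roundness"]), 4 * pi * 100 / 36^2)
  expect_equal(unname(f["nucleus_homogeneity"]), 1.0)
  expect_equal(unname(f["nucleus_brightness"]), 100)
  expect_equal(unname(f["cytoplasm_max"]), 180)
  expect_equal(unname(f["cytoplasm_min"]), 180)
  expect_equal(unname(f["cytoplasm_brightness"]), 180)
  expect_equal(unname(f["cell_area"]), 400)
  expect_equal(unname(f["nucleus_cell_ratio"]), 0.25)
  expect_identical(names(f), morpho_names())
})

test_that("empty or overlapping masks are rejected by name", {
  sq <- square_cell_gray()
  none <- matrix(FALSE, 30, 30)
  expect_error(extract_morphometrics(sq$gray, none, sq$cytoplasm),
               "nucleus_mask")
  expect_error(extract_morphometrics(sq$gray, sq$nucleus, none),
               "cytoplasm_mask")
  expect_error(extract_morphometrics(sq$gray, sq$nucleus, sq$nucleus),
               "disjoint")
})

test_that("disk morphometrics agree with the pixel-enumeration oracle", {
  n <- 51
  nucleus <- disk_mask(n, 20)
  cytoplasm <- !nucleus & disk_mask(n, 25)
  gray <- matrix(150, n, n)
  f <- extract_morphometrics(gray, nucleus, cytoplasm)
  oracle <- disk_oracle(20)
  expect_equal(unname(f["nucleus_area"]), oracle$area)
  expect_lt(abs(f["nucleus_area"] - pi * 20^2) / (pi * 20^2), 0.01)
  expect_equal(unname(f["nucleus_perimeter"]), oracle$perimeter)
  expect_equal(unname(f["nucleus_roundness"]),
               4 * pi * oracle$area / oracle$perimeter^2)
})

test_that("doubling linear dimensions scales area ~4x and leaves shape features stable", {
  n <- 101
  gray <- matrix(120, n, n)
  small_n <- disk_mask(n, 10); small_c <- !small_n & disk_mask(n, 14)
  big_n <- disk_mask(n, 20); big_c <- !big_n & disk_mask(n, 28)
  fs <- extract_morphometrics(gray, small_n, small_c)
  fb <- extract_morphometrics(gray, big_n, big_c)
  expect_lt(abs(fb["nucleus_area"] / fs["nucleus_area"] - 4), 4 * 0.05)
  for (nm in c("aspect_ratio", "nucleus_cell_ratio", "nucleus_roundness"))
    expect_lt(abs(fb[nm] - fs[nm]) / fs[nm], 0.05)
})

test_that("a constant intensity shift moves intensity features by exactly c", {
  sq <- square_cell_gray()
  f0 <- extract_morphometrics(sq$gray, sq$nucleus, sq$cytoplasm)
  f1 <- extract_morphometrics(sq$gray + 17, sq$nucleus, sq$cytoplasm)
  for (nm in c("nucleus_brightness", "cytoplasm_brightness",
               "cytoplasm_max", "cytoplasm_min"))
    expect_equal(unname(f1[nm] - f0[nm]), 17)
  geom <- c("nucleus_area", "nucleus_length", "nucleus_width", "aspect_ratio",
            "nucleus_perimeter", "nucleus_roundness", "nucleus_homogeneity",
            "cell_area", "nucleus_cell_ratio")
  expect_equal(f1[geom], f0[geom])
})

test_that("extract_features composes the parts deterministically", {
  cell <- generate_cell(default_profiles()$in_situ, seed = 21)
  f1 <- extract_features(cell)
  f2 <- extract_features(cell)
  expect_identical(f1, f2)
  # morphometrics match a direct recount on the ground-truth masks
  expect_equal(unname(f1$morpho["nucleus_area"]), sum(cell$nucleus_mask))
  expect_equal(unname(f1$morpho["cell_area"]),
               sum(cell$nucleus_mask) + sum(cell$cytoplasm_mask))
  gray <- to_gray(cell$pixels)
  expect_equal(unname(f1$morpho["nucleus_brightness"]),
               mean(gray[cell$nucleus_mask]))
  # empty cytoplasm mask propagates the precondition error
  broken <- cell
  broken$cytoplasm_mask[] <- FALSE
  expect_error(extract_features(broken), "cytoplasm_mask")
})

test_that("feature reduction keeps the requested groups in canonical order", {
  cell <- generate_cell(default_profiles()$columnar, seed = 2)
  fv <- extract_features(cell)
  full <- reduce_features(fv, "all")
  expect_identical(full, c(fv$morpho, fv$bhf))
  p7 <- reduce_features(fv, "pruned7")
  expect_identical(names(p7)[1:6],
                   c("nucleus_area", "nucleus_roundness", "nucleus_brightness",
                     "cytoplasm_brightness", "cell_area", "nucleus_cell_ratio"))
  expect_identical(grep("^bhf_", names(p7)), 7:length(p7))
  only_area <- reduce_features(fv, c(1, rep(0, 13)))
  expect_identical(only_area, fv$morpho["nucleus_area"])
  expect_error(reduce_features(fv, rep(0, 14)), "at least one")
  expect_error(reduce_features(fv, rep(1, 5)), "length")
})

test_that("feature tables round-trip through CSV", {
  cells <- lapply(1:3, function(s)
    generate_cell(default_profiles()$moderate_squamous, seed = s,
                  image_id = paste0("c", s)))
  tab <- feature_table(cells)
  expect_equal(nrow(tab), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(tab, path)
  expect_match(readLines(path, n = 1), "^#")
  back <- read_features(path)
  expect_equal(back$image_id, tab$image_id)
  fm <- feature_matrix(back)
  expect_equal(fm$x, feature_matrix(tab)$x, tolerance = 1e-12)
  expect_identical(fm$y, tab$label)
})
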