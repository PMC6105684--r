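# Catalogue I/O and photographic-quality grading.

pq_labels <- list(
  clarity = c("poor", "reasonable", "excellent"),
  contrast = c("poor", "reasonable", "excellent"),
  angle = c("poor", "reasonable", "excellent"),
  edge = c("poor_reasonable", "excellent")
)

# Independent score map, written out by hand from the grading protocol.
oracle_total <- function(cl, co, an, ed) {
  sum(c(poor = 1, reasonable = 4, excellent = 9)[cl],
      c(poor = 1, reasonable = 3, excellent = 9)[co],
      c(poor = 1, reasonable = 2, excellent = 9)[an],
      c(poor_reasonable = 1, excellent = 8)[ed])
}

test_that("pq_score maps the printed category scores and sums them", {
  expect_equal(pq_score("excellent", "excellent", "excellent", "excellent")$total, 35)
  expect_equal(pq_score("poor", "poor", "poor", "poor_reasonable")$total, 4)
  g <- pq_score("poor", "excellent", "excellent", "excellent")
  expect_equal(g$total, 27)
  expect_equal(g$grade_label, "poor")  # one inadequate category forces poor
  expect_error(pq_score("great", "poor", "poor", "excellent"), "unknown")
})

test_that("all 54 category combinations match the enumeration oracle", {
  combos <- expand.grid(cl = pq_labels$clarity, co = pq_labels$contrast,
                        an = pq_labels$angle, ed = pq_labels$edge,
                        stringsAsFactors = FALSE)
  expect_equal(nrow(combos), 54L)
  for (r in seq_len(nrow(combos))) {
    g <- pq_score(combos$cl[r], combos$co[r], combos$an[r], combos$ed[r])
    expect_equal(g$total, oracle_total(combos$cl[r], combos$co[r],
                                       combos$an[r], combos$ed[r]))
    expect_true(g$total >= 4 && g$total <= 35)
    any_min <- combos$cl[r] == "poor" || combos$co[r] == "poor" ||
      combos$an[r] == "poor" || combos$ed[r] == "poor_reasonable"
    if (any_min) expect_equal(g$grade_label, "poor")
  }
})

test_that("write/read round-trips a synthetic catalogue bit-identically", {
  cat_ <- generate_catalogue(3, 2, master_seed = 9)
  d <- withr::local_tempdir()
  write_catalogue(cat_, d)
  cat2 <- read_catalogue(file.path(d, "metadata.csv"))
  expect_equal(length(cat2$photos), 6L)
  expect_setequal(cat2$individuals, cat_$individuals)
  for (id in names(cat_$photos)) {
    p1 <- cat_$photos[[id]]; p2 <- cat2$photos[[id]]
    expect_equal(unname(p2$pixels), unname(p1$pixels))
    expect_identical(p2$mask, p1$mask)
    expect_identical(p2$date, p1$date)
    expect_identical(p2$session_id, p1$session_id)
    expect_identical(p2$grade, p1$grade)
  }
  expect_equal(cat2$ground_truth$h11, cat_$ground_truth$h11, tolerance = 1e-12)
})

test_that("read_catalogue rejects bad inputs with the offending row", {
  d <- withr::local_tempdir()
  img <- matrix(0.5, 8, 8)
  msk <- matrix(0, 8, 8); msk[3:6, 3:6] <- 1
  png::writePNG(img, file.path(d, "a.png"))
  png::writePNG(msk, file.path(d, "a_m.png"))
  meta <- data.frame(image_id = "a", individual_id = "X", date = "2010-01-02",
                     session_id = "s1", image_file = "a.png",
                     mask_file = "a_m.png")
  ok_csv <- file.path(d, "metadata.csv")
  write.csv(meta, ok_csv, row.names = FALSE)
  expect_s3_class(read_catalogue(ok_csv), "fin_catalogue")

  # empty mask
  png::writePNG(matrix(0, 8, 8), file.path(d, "empty_m.png"))
  m2 <- meta; m2$mask_file <- "empty_m.png"
  write.csv(m2, ok_csv, row.names = FALSE)
  expect_error(read_catalogue(ok_csv), "empty mask")

  # shape mismatch
  png::writePNG(matrix(1, 5, 5), file.path(d, "small_m.png"))
  m3 <- meta; m3$mask_file <- "small_m.png"
  write.csv(m3, ok_csv, row.names = FALSE)
  expect_error(read_catalogue(ok_csv), "shape mismatch")

  # missing file
  m4 <- meta; m4$image_file <- "nope.png"
  write.csv(m4, ok_csv, row.names = FALSE)
  expect_error(read_catalogue(ok_csv), "missing file")

  # duplicate image_id
  write.csv(rbind(meta, meta), ok_csv, row.names = FALSE)
  expect_error(read_catalogue(ok_csv), "duplicate image_id")

  # multi-component masks rejected unless explicitly kept
  mm <- matrix(0, 8, 8); mm[2:3, 2:3] <- 1; mm[6:7, 6:7] <- 1
  png::writePNG(mm, file.path(d, "multi_m.png"))
  m5 <- meta; m5$mask_file <- "multi_m.png"
  write.csv(m5, ok_csv, row.names = FALSE)
  expect_error(read_catalogue(ok_csv), "multiple components")
  cat_ <- read_catalogue(ok_csv, keep_largest_component = TRUE)
  expect_equal(sum(cat_$photos[[1]]$mask), 4L)
})

test_that("filter_by_grade keeps the right photos untouched", {
  cat_ <- generate_catalogue(6, 3, master_seed = 4)
  labs <- vapply(cat_$photos, function(p)
    pq_score(p$grade$clarity, p$grade$contrast, p$grade$angle,
             p$grade$edge)$grade_label, character(1))
  kept <- filter_by_grade(cat_, c("good", "excellent"))
  expect_equal(length(kept$photos), sum(labs != "poor"))
  expect_equal(names(kept$photos), names(cat_$photos)[labs != "poor"])
  for (id in names(kept$photos))
    expect_identical(kept$photos[[id]], cat_$photos[[id]])
  # keep-all is the identity on photos
  all_labs <- c("poor", "good", "excellent")
  expect_identical(filter_by_grade(cat_, all_labs)$photos, cat_$photos)
  # keep only excellent matches brute-force re-evaluation
  exc <- filter_by_grade(cat_, "excellent")
  expect_equal(names(exc$photos), names(cat_$photos)[labs == "excellent"])
  expect_warning(filter_by_grade(cat_, character(0)), "no photos")
})
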