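test_that("well-separated clusters are split exactly at the gaps", {
  x <- c(1, 2, 3, 10, 11, 12, 100, 101, 102)
  b <- jenks_breaks(x, 3)
  lab <- findInterval(x, b$breaks, left.open = TRUE) + 1
  expect_equal(lab, rep(1:3, each = 3))
  # brute-force oracle over all split placements
  expect_equal(ssw_of_breaks(x, b$breaks), brute_jenks(x, 3)$ssw, tolerance = 1e-12)
  # three distinct values: one class each, perfect variance fit
  b3 <- jenks_breaks(c(4, 9, 2), 3)
  expect_equal(b3$gvf, 1)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct values")
})

test_that("exact dynamic programming equals exhaustive search", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    x <- round(rnorm(n, 0, 10), 2)
    if (length(unique(x)) < 3) x <- x + seq_len(n) * 1e-3
    b <- jenks_breaks(x, 3)
    expect_equal(ssw_of_breaks(x, b$breaks), brute_jenks(x, 3)$ssw,
                 tolerance = 1e-9)
  }
})

test_that("sampled breaks are deterministic and tagged", {
  set.seed(5)
  x <- rnorm(30000)
  b1 <- jenks_breaks(x, 3, max_exact = 2000, sample_seed = 4)
  b2 <- jenks_breaks(x, 3, max_exact = 2000, sample_seed = 4)
  expect_identical(b1, b2)
  expect_equal(b1$method, "sampled")
  expect_true(b1$gvf > 0 && b1$gvf <= 1)
})

test_that("classification follows the closed-right boundary convention", {
  br <- c(2, 5)
  r <- matrix(c(1, 2, 2.5, 5, 5.5, 7), 2, 3)
  cls <- classify_three(r, br)
  expect_equal(c(cls), c("low", "low", "moderate", "moderate", "high", "high"))
  # strictly increasing raster -> nondecreasing labels
  inc <- matrix(seq(0, 10, length.out = 12), 3, 4)
  lab <- classify_three(inc, br)
  expect_true(all(diff(match(c(lab), c("low", "moderate", "high"))) >= 0))
  mid <- matrix(c(3, 4, 4.5), 1, 3)
  expect_true(all(classify_three(mid, br) == "moderate"))
  r_na <- r; r_na[1, 1] <- NA
  expect_true(is.na(classify_three(r_na, br)[1, 1]))
  expect_error(classify_three(r, br, labels = c("a", "b")), "labels")
})

test_that("the 27-combination overlay matches the zoning rule table", {
  combos <- expand.grid(q = c("low", "moderate", "high"),
                        r = c("low", "moderate", "high"),
                        p = c("low", "moderate", "high"),
                        stringsAsFactors = FALSE)
  m <- function(v) matrix(v, 3, 9)
  zones <- overlay_zones(m(combos$q), m(combos$r), m(combos$p))
  # independent rule oracle
  want <- with(combos, ifelse(q == "low", "LQZ",
                ifelse(q == "moderate" & r != "high", "QILZ",
                 ifelse(q == "moderate", "QRPZ",
                  ifelse(p == "low", "HQSZ", "HQPZ")))))
  expect_equal(c(zones), want)
  expect_false(anyNA(zones))                       # every combination labeled
  expect_setequal(unique(c(zones)), names(zone_codes()))
  # spot checks from the rule table
  one <- function(q, r, p) overlay_zones(matrix(q), matrix(r), matrix(p))[1, 1]
  expect_equal(one("high", "moderate", "low"), "HQSZ")
  expect_equal(one("moderate", "high", "high"), "QRPZ")
  expect_error(overlay_zones(matrix("HQ"), matrix("low"), matrix("low")),
               "low/moderate/high")
})

test_that("area fractions count, percent and conserve mass", {
  z <- matrix("LQZ", 2, 5)
  af <- area_fractions(z)
  expect_equal(af$percent[af$label == "LQZ"], 100)
  combos <- expand.grid(q = c("low", "moderate", "high"),
                        r = c("low", "moderate", "high"),
                        p = c("low", "moderate", "high"),
                        stringsAsFactors = FALSE)
  zones <- overlay_zones(matrix(combos$q, 3, 9), matrix(combos$r, 3, 9),
                         matrix(combos$p, 3, 9))
  af2 <- area_fractions(zones)
  counts <- setNames(af2$count, af2$label)
  expect_equal(counts[c("LQZ", "QILZ", "QRPZ", "HQSZ", "HQPZ")],
               c(LQZ = 9L, QILZ = 6L, QRPZ = 3L, HQSZ = 3L, HQPZ = 6L))
  expect_equal(af2$percent[af2$label == "LQZ"], 33.33)
  expect_lt(abs(sum(af2$percent) - 100), 0.011)
  # per-type accounting and absent types
  mask <- matrix("AM", 3, 9); mask[, 1] <- "other"
  af3 <- area_fractions(zones, mask)
  expect_true(all(af3$type == "AM"))
  expect_equal(sum(af3$count), 24)
  for (ty in unique(af3$type)) {
    expect_lt(abs(sum(af3$percent[af3$type == ty]) - 100), 0.011)
  }
})

test_that("classification is idempotent under relabelling round trips", {
  set.seed(3)
  r <- matrix(runif(100), 10, 10)
  b <- jenks_breaks(c(r), 3)
  c1 <- classify_three(r, b)
  c2 <- classify_three(r, b)
  expect_identical(c1, c2)
})
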