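# small cube built directly from the recursion, bypassing the generator
hand_cube <- function(nr = 2, nc = 2, nt = 40, a = 0.03, b = 0.005, c = 0.6,
                      k = 0.2, noise = 0, seed = 1) {
  set.seed(seed)
  months <- rep(5:9, length.out = nt)
  years <- cumsum(c(1, diff(months) < 0))
  lai <- array(0, c(nr, nc, nt)); tem <- array(0, c(nr, nc, nt))
  pre <- array(0, c(nr, nc, nt))
  for (p in seq_len(nr * nc)) {
    tv <- rnorm(nt, 8, 2); pv <- rnorm(nt, 60, 15)
    lv <- numeric(nt)
    lv[1] <- (a * 8 + b * 60 + k) / (1 - c)
    for (t in 2:nt) {
      lv[t] <- a * tv[t] + b * pv[t] + c * lv[t - 1] + k + rnorm(1, 0, noise)
    }
    ij <- arrayInd(p, c(nr, nc))
    tem[ij[1], ij[2], ] <- tv; pre[ij[1], ij[2], ] <- pv
    lai[ij[1], ij[2], ] <- lv
  }
  structure(list(lai = lai, tem = tem, pre = pre,
                 month_index = data.frame(year = years, month = months)),
            class = "climate_cube")
}

test_that("the lag rule pairs months only within a growing season", {
  mi <- data.frame(year = rep(1:2, each = 5), month = rep(5:9, 2))
  ts <- lag_pairs(mi)
  expect_equal(ts, c(2:5, 7:10))  # May (t = 1, 6) is lag source only
  expect_equal(lag_pairs(mi, "naive"), 2:10)
})

test_that("an exact recursion is recovered to machine precision", {
  cube <- hand_cube(noise = 0)
  fit <- fit_pixel_ar(cube, min_pairs = 20)
  expect_equal(c(fit$a), rep(0.03, 4), tolerance = 1e-8)
  expect_equal(c(fit$b), rep(0.005, 4), tolerance = 1e-8)
  expect_equal(c(fit$c), rep(0.6, 4), tolerance = 1e-8)
  expect_equal(c(fit$k), rep(0.2, 4), tolerance = 1e-8)
  expect_true(all(fit$reason == "ok"))
})

test_that("coefficients equal the normal-equations solution on a toy series", {
  # 6 contiguous observations -> 5 naive lag pairs, hand-solvable 4x4 system
  cube <- hand_cube(nr = 1, nc = 1, nt = 6, noise = 0.5, seed = 3)
  fit <- fit_pixel_ar(cube, min_pairs = 2, lag_rule = "naive")
  ts <- 2:6
  X <- cbind(cube$tem[1, 1, ts], cube$pre[1, 1, ts], cube$lai[1, 1, ts - 1], 1)
  y <- cube$lai[1, 1, ts]
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(c(fit$a, fit$b, fit$c, fit$k)[c(1, 2, 3, 4)],
               drop(beta), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("noisy fits recover the lag coefficient with small error", {
  cfg <- synthetic_config(seed = 2, grid_shape = c(8, 12), n_months = 100,
                          noise_sd_climate = 0.05)
  cf <- gen_coeff_fields(cfg)
  cube <- gen_climate_cube(cfg, cf)
  fit <- fit_pixel_ar(cube)
  err <- abs(fit$c - cf$c)
  expect_lt(mean(err), 0.05)
  expect_gt(cor(c(fit$c), c(cf$c), method = "spearman"), 0.95)
})

test_that("degenerate pixels get nodata with a reason code", {
  cube <- hand_cube(noise = 0.1)
  cube$tem[1, 1, ] <- 5  # constant regressor -> singular design
  fit <- fit_pixel_ar(cube, min_pairs = 20)
  expect_equal(fit$reason[1, 1], "singular")
  expect_true(is.na(fit$c[1, 1]))
  short <- hand_cube(nt = 35)
  expect_true(all(fit_pixel_ar(short, min_pairs = 30)$reason == "too_few_pairs"))
})

test_that("coefficient normalization is a per-type min-max map", {
  fit <- list(a = matrix(1:6, 2), b = matrix(c(2, 4, 6, 1, 3, 5), 2),
              c = matrix(c(0.2, 0.5, 0.8, 0.3, 0.4, 0.5), 2))
  mask <- matrix("AM", 2, 3)
  norm <- normalize_coefficients(fit, mask)
  expect_equal(c(norm$c_norm), c(0, 0.5, 1, 1 / 6, 1 / 3, 0.5))
  expect_equal(range(norm$a_norm), c(0, 1))   # endpoints map to 0 and 1
  expect_equal(order(c(norm$b_norm)), order(c(fit$b)))  # monotone
  const <- list(a = matrix(1, 2, 3), b = fit$b, c = fit$c)
  expect_error(normalize_coefficients(const, mask), "constant a")
})

test_that("sensitivity equals the residual-variance ratio of simple fits", {
  cube <- hand_cube(nr = 3, nc = 3, nt = 45, noise = 0.05, seed = 5)
  sens <- sensitivity_components(cube, scale = FALSE)
  for (p in 1:9) {
    ij <- arrayInd(p, c(3, 3))
    lai <- cube$lai[ij[1], ij[2], ]
    for (v in c("tem", "pre")) {
      x <- cube[[v]][ij[1], ij[2], ]
      # independent oracle: 1 - Var(residuals) / Var(LAI) from a linear fit
      res <- residuals(lm(lai ~ x))
      want <- 1 - sum((res - mean(res))^2) / sum((lai - mean(lai))^2)
      got <- sens[[paste0("sens_", v)]][ij[1], ij[2]]
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("sensitivity saturates for exact dependence and vanishes for none", {
  cube <- hand_cube(nr = 1, nc = 1, nt = 40, noise = 0)
  cube$lai[1, 1, ] <- 2 + 0.1 * cube$tem[1, 1, ]  # LAI exactly linear in tem
  s <- sensitivity_components(cube, scale = FALSE)
  expect_equal(s$sens_tem[1, 1], 1, tolerance = 1e-12)
  # orthogonalize LAI against pre: raw sensitivity drops to zero
  cube2 <- hand_cube(nr = 1, nc = 1, nt = 40, noise = 0.2, seed = 9)
  lai <- cube2$lai[1, 1, ]
  cube2$lai[1, 1, ] <- residuals(lm(lai ~ cube2$pre[1, 1, ])) + mean(lai)
  s2 <- sensitivity_components(cube2, scale = FALSE)
  expect_lt(abs(s2$sens_pre[1, 1]), 1e-8)
})

test_that("SI and RI follow their defining identities", {
  m <- function(v) matrix(v, 2, 2)
  sens <- list(sens_tem = m(1), sens_pre = m(0.5))
  expect_equal(compute_si(m(0), m(0), sens), m(0))
  expect_equal(compute_si(m(1), m(0), sens), m(1))
  # symmetry under swapping the climate roles
  s_sw <- list(sens_tem = m(0.5), sens_pre = m(1))
  expect_equal(compute_si(m(0.3), m(0.7), sens), compute_si(m(0.7), m(0.3), s_sw))
  c_norm <- m(c(0, 1, 0.25, 0.75))
  expect_equal(compute_ri(c_norm) + c_norm, m(1))
})
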