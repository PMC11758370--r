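test_that("hazard follows the declining-then-flat shape", {
  p <- overall_params()
  # at the origin the hazard is the acute rate by construction
  expect_equal(1000 * jp_hazard(3, p), 0.917)
  # at the join point it equals the background rate (continuity)
  expect_equal(1000 * jp_hazard(23.8, p), 0.185)
  # halfway along the decline, linear interpolation
  expect_equal(1000 * jp_hazard((3 + 23.8) / 2, p), (0.917 + 0.185) / 2)
  # beyond the join: flat
  expect_equal(1000 * jp_hazard(c(30, 100, 180), p), rep(0.185, 3))
  # degenerate flat model
  pc <- jp_params(2e-4, 2e-4, 50)
  expect_equal(jp_hazard(c(3, 40, 170), pc), rep(2e-4, 3))
})

test_that("hazard is continuous at the join and non-increasing", {
  set.seed(42)
  for (i in 1:20) {
    b <- runif(1, 0, 5e-4)
    p <- jp_params(b + runif(1, 0, 2e-3), b, runif(1, 4, 120))
    eps <- 10^-(4:8)
    gap <- abs(jp_hazard(p$shift - eps, p) - jp_hazard(p$shift + eps, p))
    expect_true(all(diff(gap) < 0))
    expect_lt(gap[length(gap)], 1e-9)
    grid <- seq(3, 180, length.out = 500)
    expect_true(all(diff(jp_hazard(grid, p)) <= 1e-15))
  }
})

test_that("hazard and friends reject times before the origin", {
  p <- overall_params()
  expect_error(jp_hazard(2, p), "origin")
  expect_error(jp_cum_hazard(2.9, p), "origin")
  expect_error(jp_survival(0, p), "origin")
})

test_that("parameter validation enforces the decline-to-plateau shape", {
  expect_error(jp_params(1e-4, 2e-4, 20), "acute")
  expect_error(jp_params(2e-4, -1e-5, 20), "non-negative")
  expect_error(jp_params(2e-4, 1e-4, 3), "phase shift")
  expect_error(jp_params(2e-4, 1e-4, 2, origin = 3), "phase shift")
  expect_silent(jp_params(2e-4, 0, 20))
})

test_that("cumulative hazard matches quadrature of the hazard", {
  p <- overall_params()
  expect_equal(jp_cum_hazard(3, p), 0)
  q <- integrate(function(t) jp_hazard(t, p), 3, 180, rel.tol = 1e-12)$value
  expect_lt(abs(jp_cum_hazard(180, p) - q) / q, 1e-10)
  set.seed(7)
  for (i in 1:15) {
    b <- runif(1, 0, 5e-4)
    p <- jp_params(b + runif(1, 0, 2e-3), b, runif(1, 4, 150))
    tt <- runif(1, 3, 200)
    q <- integrate(function(t) jp_hazard(t, p), 3, tt, rel.tol = 1e-12)$value
    expect_lt(abs(jp_cum_hazard(tt, p) - q), 1e-9 * max(1, q))
  }
  # constant-hazard limit: b * (t - origin)
  pc <- jp_params(2e-4, 2e-4, 50)
  expect_equal(jp_cum_hazard(103, pc), 0.02)
  # strictly increasing when background > 0
  grid <- seq(3, 250, by = 0.25)
  expect_true(all(diff(jp_cum_hazard(grid, overall_params())) > 0))
})

test_that("conditional survival obeys the exponential identities", {
  p <- overall_params()
  expect_equal(jp_survival(3, p), 1)
  pc <- jp_params(3e-4, 3e-4, 40)
  expect_equal(jp_survival(100, pc), exp(-3e-4 * 97))
  # hazard equals the negative log-survival derivative
  tt <- c(5, 14.7, 23.8, 60)
  h <- 1e-6
  num <- -(log(jp_survival(tt + h, p)) - log(jp_survival(tt - h, p))) / (2 * h)
  expect_equal(num, jp_hazard(tt, p), tolerance = 1e-6)
})

test_that("inverse cumulative hazard round-trips and matches bisection", {
  for (p in param_rows()) {
    expect_equal(jp_quantile(0, p), p$origin)
    set.seed(11)
    h <- runif(200, 0, jp_cum_hazard(400, p))
    t_inv <- jp_quantile(h, p)
    expect_lt(max(abs(jp_cum_hazard(t_inv, p) - h)), 1e-9)
    # independent bisection oracle on a subsample
    for (hh in h[1:12]) {
      t_bis <- uniroot(function(t) jp_cum_hazard(t, p) - hh,
                       c(p$origin, 1e4), tol = 1e-12)$root
      expect_equal(jp_quantile(hh, p), t_bis, tolerance = 1e-7)
    }
  }
  # constant hazard: origin + h / b
  pc <- jp_params(4e-4, 4e-4, 30)
  expect_equal(jp_quantile(0.01, pc), 3 + 0.01 / 4e-4)
  # zero background: hazard mass is finite, larger h is unattainable
  p0 <- jp_params(5e-4, 0, 30)
  hmax <- jp_cum_hazard(30, p0)
  expect_equal(jp_quantile(hmax * 0.5, p0),
               uniroot(function(t) jp_cum_hazard(t, p0) - hmax * 0.5,
                       c(3, 30), tol = 1e-12)$root, tolerance = 1e-7)
  expect_error(jp_quantile(hmax * 1.1, p0), "attainable")
})
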