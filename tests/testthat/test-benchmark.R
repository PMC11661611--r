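test_that("the series reference reduces to the scaled profile at t = 0", {
  for (r in c(0, 0.5, 1)) {
    for (br in c("lower", "upper")) {
      s <- r_cut_branch(fuzzy_triangular(0.75, 1, 1.25), r, br)
      expect_equal(exact_solution(2, 0, alpha = 0.6, r = r, branch = br),
                   s * exp(-2))
    }
  }
})

test_that("the alpha = 1 reference matches the two-term Taylor structure", {
  # with k_exp = -1 the series is e^(-x) (s + t + t^2/2)
  for (t in c(0.01, 0.05)) {
    expect_equal(exact_solution(4, t, 1, 0, "lower"),
                 exp(-4) * (0.75 + t + t^2 / 2))
  }
  expect_equal(exact_solution(4, 0.05, 1, 1, "lower"),
               exact_solution(4, 0.05, 1, 1, "upper"))
})

test_that("direct evaluation of the series at the report point", {
  # frozen from the printed three-term formula with k_exp = -1
  expect_equal(exact_solution(4, 0.05, 1, 0, "lower"),
               exp(-4) * (0.75 + 0.05 + 0.00125))
  expect_equal(exact_solution(4, 0.05, 0.5, 0, "upper"),
               exp(-4) * (1.25 + sqrt(0.05) / gamma(1.5) + 0.05 / gamma(2)))
})

test_that("absolute error is a nonnegative symmetric distance", {
  expect_equal(absolute_error(0.5, 0.5), 0)
  expect_equal(absolute_error(1, 3), absolute_error(3, 1))
  expect_equal(absolute_error(0.01437086, exact_solution(4, 0.05, 1, 0, "lower")),
               abs(exp(-4) * 0.80125 - 0.01437086))
})

test_that("exponent calibration selects -1 and rejects all other candidates", {
  k <- calibrate_ic_exponent()
  expect_equal(as.integer(k), -1L)
  trace <- attr(k, "trace")
  expect_equal(sum(trace$accepted), 1L)
  expect_equal(trace$candidate[trace$accepted], -1)
  expect_gt(trace$value[trace$candidate == 1], 40)  # three orders off
  expect_false(trace$accepted[trace$candidate == -2])
})

test_that("the benchmark problem is internally consistent at the corners", {
  bp <- benchmark_problem(alpha = 0.7)
  for (r in c(0, 0.3, 1)) {
    br <- defuzzify_problem(bp$problem, r)
    expect_equal(br$lower$ic(0), br$lower$bc_left(0))
    expect_equal(br$upper$ic(5), br$upper$bc_right(0))
    expect_equal(br$lower$ic(4), r_cut_branch(fuzzy_triangular(0.75, 1, 1.25), r, "lower") * exp(-4))
  }
  expect_equal(br$lower$k(1, 0.3), 0.09)  # killing rate t^2, space-independent
})

test_that("the error table covers the full grid and keeps the envelope", {
  tab <- benchmark_table()
  expect_equal(nrow(tab), 30L)
  expect_true(all(tab$abs_error >= 0))
  expect_equal(tab$abs_error, abs(tab$exact - tab$numerical))
  wide <- tidyr::pivot_wider(tab, id_cols = c("r", "alpha"),
                             names_from = "branch", values_from = "numerical")
  expect_true(all(wide$lower <= wide$upper))
})

test_that("halving the time step reduces the report-point error at alpha = 1", {
  coarse <- benchmark_table(alpha_grid = 1, r_grid = 0, dt = 0.01)
  fine <- benchmark_table(alpha_grid = 1, r_grid = 0, dt = 0.005)
  expect_lt(max(fine$abs_error), max(coarse$abs_error))
})

test_that("upper-branch report-point errors shrink monotonically as alpha -> 1", {
  tab <- benchmark_table(r_grid = 0)
  up <- tab$abs_error[tab$branch == "upper"][order(tab$alpha[tab$branch == "upper"])]
  expect_true(all(diff(up) < 0))
})
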