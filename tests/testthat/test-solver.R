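# unit tests of the interior-point machinery on small closed-form problems

test_that("the interior-point solver finds constrained optima with bounds", {
  # minimize (x1-2)^2 + (x2+1)^2 + x3^2  s.t.  x1 + x2 + x3 = 1, x in [-5, 5]
  eval_f <- function(z, derivs = TRUE) {
    g <- 2 * (z - c(2, -1, 0))
    out <- list(f = sum((z - c(2, -1, 0))^2))
    if (derivs) {
      out$g <- g
      out$H <- Matrix::Diagonal(3, 2)
    }
    out
  }
  eval_c <- function(z, jac = TRUE) {
    out <- list(c = sum(z) - 1)
    if (jac) out$A <- Matrix::Matrix(matrix(1, 1, 3), sparse = TRUE)
    out
  }
  res <- gaitrec:::.ipsolve(c(0, 0, 0), rep(-5, 3), rep(5, 3), eval_f, eval_c,
                            opts = list(tol = 1e-8, max_iter = 100))
  expect_equal(res$status, "converged")
  expect_equal(res$z, c(2, -1, 0) + rep(0, 3) + (1 - 1) / 3 + c(0, 0, 0),
               tolerance = 1e-5, ignore_attr = TRUE)
  # analytic solution: project the unconstrained optimum onto the plane
  expect_equal(res$z, c(2, -1, 0) + (1 - sum(c(2, -1, 0))) / 3,
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_lt(abs(sum(res$z) - 1), 1e-8)

  # an active bound: shift the target outside the box
  eval_f2 <- function(z, derivs = TRUE) {
    out <- list(f = sum((z - c(9, 0, 0))^2))
    if (derivs) { out$g <- 2 * (z - c(9, 0, 0)); out$H <- Matrix::Diagonal(3, 2) }
    out
  }
  res2 <- gaitrec:::.ipsolve(c(0, 0, 0), rep(-5, 3), rep(5, 3), eval_f2, eval_c,
                             opts = list(tol = 1e-8, max_iter = 200))
  expect_true(res2$status %in% c("converged", "acceptable"))
  expect_equal(res2$z[1], 5, tolerance = 1e-4)
  expect_lt(abs(sum(res2$z) - 1), 1e-8)
})

test_that("equal lower and upper bounds pin a variable exactly", {
  eval_f <- function(z, derivs = TRUE) {
    out <- list(f = sum(z^2))
    if (derivs) { out$g <- 2 * z; out$H <- Matrix::Diagonal(2, 2) }
    out
  }
  eval_c <- function(z, jac = TRUE) {
    out <- list(c = z[1] + z[2] - 2)
    if (jac) out$A <- Matrix::Matrix(matrix(1, 1, 2), sparse = TRUE)
    out
  }
  res <- gaitrec:::.ipsolve(c(0.7, 0), c(0.7, -10), c(0.7, 10), eval_f, eval_c,
                            opts = list(tol = 1e-8, max_iter = 50))
  expect_identical(res$z[1], 0.7)
  expect_equal(res$z[2], 1.3, tolerance = 1e-7)
})

test_that("infeasible bounds are rejected before solving", {
  expect_error(gaitrec:::.ipsolve(0, 1, -1,
                                  function(z, d = TRUE) list(f = 0, g = 0, H = Matrix::Diagonal(1)),
                                  function(z, j = TRUE) list(c = numeric(0))),
               "infeasible bounds")
})
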