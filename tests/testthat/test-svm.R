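# Linear SVM: separability, degeneracy, QP oracle, libsvm cross-check.

test_that("separable clusters are classified perfectly", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, mean = 3), 20, 2),
             matrix(rnorm(40, mean = -3), 20, 2))
  y <- rep(c(1, 0), each = 20)
  fit <- linear_svc(X, y)
  expect_equal(predict(fit, X), y)
  expect_true(fit$converged)
})

test_that("single-class and degenerate training sets are handled", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(linear_svc(X, rep(1, 10)), "single class")
  Xsame <- matrix(1, 10, 3)
  expect_warning(fit <- linear_svc(Xsame, rep(c(0, 1), c(4, 6))),
                 "majority")
  expect_equal(predict(fit, Xsame), rep(1L, 10))
})

test_that("the fitted hyperplane matches a brute-force maximum-margin oracle", {
  # hand-built 2-d set; the hard-margin solution is w = (2, 0), b = -1
  X <- rbind(c(2, 0), c(1, 0), c(-1, 0), c(-2, 0), c(0, 1))
  y <- c(1, 1, 0, 0, 0)
  oracle <- qp_max_margin(X, y)
  expect_false(is.null(oracle))
  fit <- linear_svc(X, y, cost = 1, eps = 1e-8)
  # same decision boundary: proportional (w, b) and identical signs
  expect_equal(fit$w / sqrt(sum(fit$w^2)),
               oracle$w / sqrt(sum(oracle$w^2)), tolerance = 1e-4)
  expect_equal(fit$b / sqrt(sum(fit$w^2)),
               unname(oracle$b) / sqrt(sum(oracle$w^2)), tolerance = 1e-4)
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  expect_equal(predict(fit, grid),
               as.integer(drop(grid %*% oracle$w) + oracle$b > 0))
})

test_that("the SMO solver agrees with libsvm on random problems", {
  skip_if_not_installed("e1071")
  set.seed(123)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    d <- sample(3:40, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    X[y == 1, 1] <- X[y == 1, 1] + runif(1, 0.5, 2)
    fit <- linear_svc(X, y, cost = 1, eps = 1e-6)
    m <- e1071::svm(x = X, y = factor(y), kernel = "linear", cost = 1,
                    scale = FALSE, tolerance = 1e-6)
    w_e <- drop(t(m$coefs) %*% m$SV)
    b_e <- -m$rho
    if (m$labels[1] == 1) {
      w_e <- -w_e
      b_e <- -b_e
    }
    # both must reach the same primal objective (the optimum is shared
    # even when flat directions leave w slightly underdetermined)
    expect_equal(svc_primal_objective(fit$w, fit$b, X, y),
                 svc_primal_objective(w_e, b_e, X, y),
                 tolerance = 1e-4)
    Xt <- matrix(rnorm(100 * d), 100, d)
    agree <- mean(predict(fit, Xt) ==
                    as.integer(as.character(predict(m, Xt))))
    expect_gte(agree, 0.98)
  }
})

test_that("class weights rescale the per-class cost", {
  set.seed(5)
  X <- rbind(matrix(rnorm(30, 1, 2), 15, 2), matrix(rnorm(90, -1, 2), 45, 2))
  y <- rep(c(1, 0), c(15, 45))
  fit_w <- linear_svc(X, y, class_weights = c("0" = 1, "1" = 3))
  fit_u <- linear_svc(X, y)
  # upweighting the minority class labels at least as many positives
  expect_gte(sum(predict(fit_w, X)[y == 1]), sum(predict(fit_u, X)[y == 1]))
})

test_that("train_hyperplane / score count confusion proportions correctly", {
  set.seed(6)
  X <- matrix(rnorm(64 * 5), 64, 5)
  obj <- rep(1:4, each = 16)
  X[obj == 2, 1] <- X[obj == 2, 1] + 4
  fit <- train_hyperplane(X, obj, 2)
  cp <- score(fit, X, obj, 2)
  expect_s3_class(cp, "confusion_proportions")
  expect_equal(cp$n_pos, 16L)
  expect_equal(cp$n_neg, 48L)
  expect_gt(cp$tp, 0.9)
  expect_lt(cp$fp, 0.1)
  # hand-counted proportions: 6 of 8 positives and 6 of 24 negatives hit
  all_one <- structure(list(w = numeric(5), b = 1), class = "linear_svc")
  cp1 <- score(all_one, X, obj, 2)
  expect_equal(cp1$tp, 1)
  expect_equal(cp1$fp, 1)
  pred_counts <- function(tp_n, fp_n, n_pos, n_neg) {
    list(tp = tp_n / n_pos, fp = fp_n / n_neg, n_pos = n_pos, n_neg = n_neg)
  }
  cp2 <- pred_counts(6, 6, 8, 24)
  expect_equal(cp2$tp, 0.75)
  expect_equal(cp2$fp, 0.25)
  expect_error(score(fit, X[0, , drop = FALSE], obj[0], 2), "empty test set")
})

test_that("d-prime anchors, clipping and monotonicity", {
  # a proportion of 0.5 maps to z = 0, so d'(0.5, 0.5) = 0
  expect_equal(qnorm(0.5), 0)
  expect_equal(dprime_stat(0.5, 0.5, 10, 10), 0)
  expect_equal(dprime(list(tp = 0.84, fp = 0.16, n_pos = 50, n_neg = 50)),
               2 * qnorm(0.84), tolerance = 1e-9)
  expect_equal(dprime_stat(0.84, 0.16, 50, 50), 1.98891, tolerance = 1e-4)
  # clipping: tp = 1, fp = 0 with 25 test vectors each -> 2 * z(49/50)
  expect_equal(dprime_stat(1, 0, 25, 25), 2 * qnorm(49 / 50),
               tolerance = 1e-12)
  expect_equal(dprime_stat(1, 0, 25, 25), 4.107, tolerance = 1e-3)
  # strictly increasing in tp, decreasing in fp on the clipped interior
  tps <- seq(0.1, 0.9, 0.1)
  expect_true(all(diff(dprime_stat(tps, 0.3, 20, 20)) > 0))
  expect_true(all(diff(dprime_stat(0.6, tps, 20, 20)) < 0))
  expect_error(dprime_stat(1.2, 0.5, 10, 10), "proportions")
})
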