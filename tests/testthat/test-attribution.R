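# Attribution tests run on a small briefly-trained model (see helpers): the
# axioms (completeness, SmoothGrad reduction, zero-baseline behaviour) hold
# for any parameters; the seed-region ranking is covered by the acceptance
# suite on the full study fixture.

test_that("saliency maps have the input shape and are non-negative", {
  fx <- attr_fixture()
  sal <- gradient_saliency(fx$model, fx$pair)
  expect_equal(dim(sal$target), c(5L, 26L))
  expect_equal(dim(sal$offtarget), c(5L, 26L))
  expect_true(all(sal$target >= 0))
  expect_true(all(sal$offtarget >= 0))
  # regression head attribution also works; unknown heads fail
  salr <- gradient_saliency(fx$model, fx$pair, head = "regression")
  expect_equal(salr$head, "regression")
  expect_error(gradient_saliency(fx$model, fx$pair, head = "bogus"))
})

test_that("smoothed saliency reduces to plain saliency at n = 1, sigma = 0", {
  fx <- attr_fixture()
  sal <- gradient_saliency(fx$model, fx$pair)
  sm0 <- smoothed_saliency(fx$model, fx$pair, n = 1, sigma = 0)
  expect_equal(sm0$target, sal$target)
  expect_equal(sm0$offtarget, sal$offtarget)
  # fixed seed reproducibility
  a <- smoothed_saliency(fx$model, fx$pair, n = 5, sigma = 0.1, seed = 3)
  b <- smoothed_saliency(fx$model, fx$pair, n = 5, sigma = 0.1, seed = 3)
  expect_equal(a$offtarget, b$offtarget)
  d <- smoothed_saliency(fx$model, fx$pair, n = 5, sigma = 0.1, seed = 4)
  expect_false(identical(a$offtarget, d$offtarget))
})

test_that("integrated gradients satisfy completeness and refine with steps", {
  fx <- attr_fixture()
  ig50 <- integrated_gradients(fx$model, fx$pair, steps = 50)
  delta <- attr(ig50, "delta_f")
  gap50 <- attr(ig50, "completeness_gap")
  expect_lt(gap50, 1e-2 * max(abs(delta), 1))
  ig500 <- integrated_gradients(fx$model, fx$pair, steps = 500)
  expect_lte(attr(ig500, "completeness_gap"), gap50 + 1e-12)

  # x == baseline gives the zero map
  ig0 <- integrated_gradients(fx$model, fx$pair, baseline = fx$pair)
  expect_equal(max(abs(ig0$target)), 0)
  expect_equal(max(abs(ig0$offtarget)), 0)

  # baseline shape mismatch is rejected
  short <- list(target = matrix(0, 5, 10), offtarget = matrix(0, 5, 10))
  expect_error(integrated_gradients(fx$model, fx$pair, baseline = short),
               "shape")
})

test_that("expected gradients behave like SHAP sampling", {
  fx <- attr_fixture()
  # background equal to the input itself -> zero map
  eg0 <- expected_gradients(fx$model, fx$pair, background = list(fx$pair),
                            n_samples = 10)
  expect_equal(max(abs(eg0$target)), 0)
  # single zero baseline converges towards integrated gradients
  zero <- list(target = matrix(0, 5, 26), offtarget = matrix(0, 5, 26))
  ig <- integrated_gradients(fx$model, fx$pair, steps = 200)
  eg <- expected_gradients(fx$model, fx$pair, background = list(zero),
                           n_samples = 600, seed = 8)
  scale <- max(abs(ig$offtarget), abs(ig$target), 1e-8)
  expect_lt(max(abs(eg$offtarget - ig$offtarget)) / scale, 0.35)
  corr <- cor(as.numeric(eg$offtarget), as.numeric(ig$offtarget))
  expect_gt(corr, 0.95)
  # reproducible under a fixed seed
  eg2 <- expected_gradients(fx$model, fx$pair, background = list(zero),
                            n_samples = 50, seed = 8)
  eg3 <- expected_gradients(fx$model, fx$pair, background = list(zero),
                            n_samples = 50, seed = 8)
  expect_equal(eg2$offtarget, eg3$offtarget)
  expect_error(expected_gradients(fx$model, fx$pair, background = list(),
                                  n_samples = 5), "non-empty")
})

test_that("maps average elementwise and collapse to a sequence view", {
  fx <- attr_fixture()
  m1 <- integrated_gradients(fx$model, fx$pair)
  expect_equal(average_maps(list(m1))$target, m1$target)
  neg <- m1
  neg$target <- -m1$target
  neg$offtarget <- -m1$offtarget
  avg <- average_maps(list(m1, neg))
  expect_equal(max(abs(avg$target)), 0)
  # three hand-built maps: elementwise mean
  mk <- function(v) structure(list(
    target = matrix(v, 5, 26), offtarget = matrix(v, 5, 26),
    method = "integrated_gradients", head = "classification",
    baseline = NULL, n = 1L), class = "ot_attribution")
  expect_equal(average_maps(list(mk(1), mk(2), mk(6)))$target[1, 1], 3)
  # mixed shapes are rejected
  bad <- mk(1)
  bad$target <- matrix(0, 5, 10)
  expect_error(average_maps(list(m1, bad)), "shape|method")

  # a controlled bulged pair: padding is numbered negatively, positions run
  # 1..23, and gap columns report the gap row's score
  tg <- toy_target()
  ot <- paste0(substr(tg, 1, 9), substr(tg, 11, 23))   # deletion at pos 10
  ap <- align_pair(tg, ot)
  m4 <- integrated_gradients(fx$model, encode_pair(ap, 26))
  sv <- sequence_view(m4, ap)
  expect_equal(nrow(sv), 26L)
  expect_equal(sum(!sv$padding), nchar(ap$target_aln))
  expect_true(all(sv$position[sv$padding] < 0))
  expect_equal(sv$position[!sv$padding], 1:23)
  gap_col <- which(sv$call == "gap_in_offtarget")
  expect_equal(sv$score_offtarget[gap_col], unname(m4$offtarget["-", gap_col]))
  j <- which(!sv$padding)[5]
  expect_equal(sv$score_offtarget[j],
               unname(m4$offtarget[sv$offtarget_base[j], j]))
})

test_that("a constant-output model yields an all-zero saliency map", {
  fx <- attr_fixture()
  m <- fx$model
  # zero the final dense layers of both heads: output no longer depends on x
  m$params$cls_W3 <- m$params$cls_W3 * 0
  m$params$reg_W3 <- m$params$reg_W3 * 0
  sal <- gradient_saliency(m, fx$pair)
  expect_equal(max(abs(sal$target)), 0)
  expect_equal(max(abs(sal$offtarget)), 0)
})
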