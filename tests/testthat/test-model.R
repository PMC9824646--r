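test_that("the assembled network maps images to K class scores at every grid SR", {
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  for (sr in c(0.05, 0.7)) {
    net <- build_network(model_config(sr = sr, num_classes = 4), seed = 1)
    s <- ns$net_forward(net, x)$scores
    expect_identical(dim(s), c(4L, 1L))
    expect_true(all(is.finite(s)))
  }
})

test_that("ledgers differ only by the attention entry when toggling attention", {
  base <- count_params(model_config(sr = 0.7, num_classes = 4, attention = "none"))
  with_se <- count_params(model_config(sr = 0.7, num_classes = 4, attention = "se"))
  expect_equal(dplyr::filter(as.data.frame(with_se), layer != "se"),
               as.data.frame(base), ignore_attr = TRUE)
  expect_identical(attr(with_se, "total") - attr(base, "total"), 2184L)
})

test_that("classifier stack and class-count dependence follow dense-layer arithmetic", {
  lg <- count_params(model_config(sr = 0.7, num_classes = 4))
  fc <- lg$params[lg$layer %in% c("fc1", "fc2", "fc3")]
  expect_identical(fc, c(525312L, 2099200L, 8196L))
  expect_identical(sum(fc), 2632708L)
  t4 <- attr(count_params(model_config(sr = 0.7, num_classes = 4)), "total")
  t5 <- attr(count_params(model_config(sr = 0.7, num_classes = 5)), "total")
  expect_identical(t5 - t4, 2049L)  # only the last dense layer sees K
})

test_that("totals are affine in X with slope 65 + 2352 = 2417", {
  totals <- vapply(c(0.3, 0.4, 0.5), function(sr)
    attr(count_params(model_config(sr = sr, num_classes = 4)), "total"), numeric(1))
  Xs <- vapply(c(0.3, 0.4, 0.5), channels_for_sr, integer(1))
  expect_equal(diff(totals) / diff(Xs), c(2417, 2417))
})

test_that("ledger totals are invariant to weights and seeds; size uses float32", {
  cfg <- model_config(sr = 0.6, num_classes = 4)
  l1 <- count_params(build_network(cfg, seed = 1))
  l2 <- count_params(build_network(cfg, seed = 999))
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  expect_equal(attr(l1, "params_size_mb"),
               round(attr(l1, "total") * 4 / 2^20, 2))
})

test_that("width reconstruction recovers the published architecture exactly", {
  cfg <- reconstruct_widths(6003328, 6001144)
  expect_true(attr(cfg, "exact"))
  expect_identical(attr(cfg, "residual"), 0)
  # the SE delta admits exactly one biased bottleneck: C = 128, r = 16
  expect_identical(unname(attr(cfg, "se")), c(128L, 16L))
  se_hits <- ns$se_solutions_for_delta(2184)
  expect_length(se_hits, 1L)
  expect_identical(cfg$feat_widths[4], 128L)
  # both published totals reproduce from the recovered widths
  with_se <- attr(count_params(cfg), "total")
  cfg_no <- model_config(sr = 0.7, num_classes = 4, feat_widths = cfg$feat_widths,
                         attention = "none", se_reduction = cfg$se_reduction)
  expect_identical(with_se, 6003328L)
  expect_identical(attr(count_params(cfg_no), "total"), 6001144L)
})

test_that("reconstruction search contract: single-point grids and unsatisfiable targets", {
  # a grid containing exactly the matching configuration returns it
  hit <- reconstruct_widths(6003328, 6001144,
                            grid = list(c2 = 187L, c3 = 626L, c4 = 249L))
  expect_true(attr(hit, "exact"))
  expect_identical(hit$feat_widths[1:3], c(187L, 626L, 249L))
  # a 1-point grid that cannot reach the targets is flagged non-exact
  miss <- reconstruct_widths(6003328, 6001144,
                             grid = list(c2 = 100L, c3 = 100L, c4 = 100L))
  expect_false(attr(miss, "exact"))
  expect_gt(attr(miss, "residual"), 0)
  expect_error(reconstruct_widths(1, 1, grid = list(c2 = integer(0), c3 = 1L, c4 = 1L)),
               class = "csbnet_bad_config")
})

test_that("checkpoints round-trip through save/load", {
  net <- build_network(model_config(sr = 0.3, num_classes = 3,
                                    fc_dims = c(512, 1024, 2048)), seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(net, path)
  back <- load_model(path)
  expect_equal(back, net)
})
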