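test_that("the feature vector matches the versioned schema on every fixture", {
  cfg <- default_config()
  schema <- feature_schema(cfg)
  expect_equal(nrow(schema), 263)
  expect_setequal(unique(schema$family),
                  c("signature", "pharmacophore", "contacts", "sasa",
                    "distances", "evolutionary"))
  sim <- fix_sim()
  expect_identical(names(sim$features), schema$name)
  expect_false(any(vapply(sim$features[setdiff(schema$name,
    grep("^pssm", schema$name, value = TRUE))], anyNA, TRUE)))
})

test_that("identity mutation zeroes all delta families; singles use the 0 sentinel", {
  cx <- fix_complex()
  cfg <- default_config()
  sp <- parse_mutation_list("H.K2A;H.W4F")
  fv <- featurize(cx, sp, cfg, identity = TRUE)
  schema <- feature_schema(cfg)
  delta_cols <- schema$name[schema$family %in% c("pharmacophore", "contacts", "sasa")]
  expect_true(all(abs(as.numeric(fv[delta_cols])) < 1e-9))
  single <- featurize(cx, parse_mutation_list("H.K2A"), cfg)
  expect_equal(single$dist.mut.min, 0)
  expect_equal(single$dist.mut.max, 0)
  expect_equal(single$n_sites, 1)
})

test_that("the ensemble memorizes a noiseless set and is seed-deterministic", {
  sim0 <- memo("sim0_300", function()
    make_synthetic_dataset(fix_panel(), n_records = 300, sigma = 0, seed = 9,
                           n_non_binders = 0, n_additive = 0, n_synergistic = 0))
  n <- nrow(sim0$records)
  set.seed(4); te <- sample(n, 70); tr <- setdiff(seq_len(n), te)
  m1 <- train_ddg(sim0$features[tr, ], sim0$records$ddg[tr], seed = 6)
  # memorization: training rows reproduced almost exactly
  expect_gte(cor(predict(m1, sim0$features[tr, ]), sim0$records$ddg[tr]), 0.99)
  # bitwise determinism
  m2 <- train_ddg(sim0$features[tr, ], sim0$records$ddg[tr], seed = 6)
  expect_identical(predict(m1, sim0$features[te, ]),
                   predict(m2, sim0$features[te, ]))
  # noiseless recovery on held-out rows
  expect_gte(cor(predict(m1, sim0$features[te, ]), sim0$records$ddg[te]), 0.95)
  expect_error(train_ddg(sim0$features[tr, ], rep(1, length(tr)), seed = 1),
               "zero variance")
})

test_that("a trained model refuses a different feature schema", {
  sim <- fix_sim()
  tr <- which(sim$records$partition == "train")
  m <- train_ddg(sim$features[tr, ], sim$records$ddg[tr], seed = 2)
  renamed <- sim$features[tr, ]
  names(renamed)[1] <- "intruder"
  expect_error(predict(m, renamed), "schema hash")
  # persisted model round-trips with identical predictions
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tmp)
  m2 <- load_model(tmp)
  expect_identical(predict(m2, sim$features[tr, ]), predict(m, sim$features[tr, ]))
})

test_that("greedy selection finds the informative feature first", {
  set.seed(10)
  x <- tibble::as_tibble(matrix(rnorm(150 * 6), 150,
                                dimnames = list(NULL, paste0("f", 1:6))))
  y <- 2 * x$f3 + rnorm(150, 0, 0.2)
  sel <- greedy_select(x, y, seed = 3)
  expect_equal(sel[1], "f3")
  # epsilon = Inf stops after exactly one feature
  sel1 <- greedy_select(x, y, seed = 3, config = default_config(epsilon = Inf))
  expect_length(sel1, 1)
})

test_that("greedy selection mostly excludes pure-noise columns", {
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    x <- tibble::as_tibble(matrix(rnorm(120 * 5), 120,
                                  dimnames = list(NULL, paste0("f", 1:5))))
    y <- 1.5 * x$f1 + 1.0 * x$f2 + rnorm(120, 0, 0.2)
    sel <- greedy_select(x, y, seed = s)
    if (all(sel %in% c("f1", "f2"))) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("metrics: exact agreement, hand RMSE and hand-computed MCC", {
  y <- c(-2, -1, 0.2, 0.8, 1.5, -0.7)
  m <- ddg_metrics(y, y)
  expect_equal(m$pearson, 1)
  expect_equal(m$spearman, 1)
  expect_equal(m$kendall, 1)
  expect_equal(m$rmse, 0)
  expect_warning(m0 <- ddg_metrics(c(0, 0), c(1, 1)), "zero-variance")
  expect_equal(m0$rmse, 1)
  expect_true(is.na(m0$pearson))
  # contingency oracle on a printed toy pair (neutral band dropped)
  yt <- c(1.2, 0.9, -1.0, -2.0, 0.7, -0.6)
  yp <- c(1.1, -0.8, -1.5, 0.8, 0.9, -2.0)
  # classes: t = I I D D I D ; p = I D D I I D -> tp=2 tn=2 fp=1 fn=1
  mcc_hand <- (2 * 2 - 1 * 1) / sqrt(3 * 3 * 3 * 3)
  m2 <- ddg_metrics(yt, yp)
  expect_equal(m2$mcc, mcc_hand)
  expect_equal(m2$f1, 2 * 2 / (2 * 2 + 1 + 1))
  expect_warning(ddg_metrics(c(1, 1), c(0, 1)), "zero-variance")
})

test_that("leave-one-complex-out folds never split a complex (leakage audit)", {
  sim <- fix_sim()
  idx <- which(sim$records$partition == "train")
  feats <- sim$features[idx, ]
  ddg <- sim$records$ddg[idx]
  groups <- sim$records$complex_id[idx]
  cfg <- default_config(num_trees = 100)
  ev <- cross_validate(feats, ddg, groups, scheme = "loco", seed = 1, config = cfg)
  expect_equal(nrow(ev$per_fold), length(unique(groups)))
  # audit: every complex appears in exactly one fold
  audit <- table(ev$predictions$group, ev$predictions$fold)
  expect_true(all(rowSums(audit > 0) == 1))
  expect_true(all(is.finite(ev$predictions$ddg_pred)))
})

test_that("augmented reverses co-travel with their forwards in k-fold", {
  for (s in 1:10) {
    ddg <- rnorm(40, -1, 1.2)
    train <- tibble::tibble(
      complex_id = "c", mutations = paste0("H.A", 1:40, "G"), kd_wt = 1e-9,
      kd_mut = exp(log(1e-9) - ddg / (1.987e-3 * 298)), temperature = 298,
      ddg = NA, is_reverse = FALSE, is_non_binder = FALSE, source = "t")
    aug <- augment_reverse(train, 2)
    fold <- abddg:::stratified_folds(ddg_of(aug), k = 5, seed = s,
                                     unit = aug$forward_id)
    expect_true(all(tapply(fold, aug$forward_id, function(f)
      length(unique(f)) == 1)), info = paste("seed", s))
  }
})

test_that("kfold(n) degenerates to leave-one-out and runs", {
  set.seed(1)
  x <- tibble::as_tibble(matrix(rnorm(24 * 3), 24,
                                dimnames = list(NULL, paste0("f", 1:3))))
  y <- x$f1 + rnorm(24, 0, 0.1)
  ev <- cross_validate(x, y, scheme = "kfold", k = 24, seed = 2,
                       config = default_config(num_trees = 60))
  expect_equal(sort(unique(ev$predictions$fold)), 1:24)
  expect_true(is.finite(ev$pooled$pearson))
  expect_error(cross_validate(x, y, scheme = "kfold", k = 25, seed = 1),
               "exceeds")
})

test_that("predictions are invariant under rigid motion of the input", {
  sim <- fix_sim()
  tr <- which(sim$records$partition == "train")
  m <- train_ddg(sim$features[tr, ], sim$records$ddg[tr], seed = 2,
                 config = default_config(num_trees = 100))
  cx <- fix_panel()$toy2
  sp <- parse_mutation_list("H.K2A")
  p1 <- predict_ddg(m, cx, sp)
  p2 <- predict_ddg(m, rotate_complex(cx, 11), sp)
  # signatures, contacts and distances are exactly invariant; the SASA
  # lattice is fixed in space, so predictions agree to sampling tolerance
  expect_equal(p1$ddg_pred, p2$ddg_pred, tolerance = 0.05)
  expect_s3_class(p1$class, "factor")
})

test_that("tidy/glance/autoplot surface the fitted objects", {
  sim <- fix_sim()
  tr <- which(sim$records$partition == "train")
  m <- train_ddg(sim$features[tr, ], sim$records$ddg[tr], seed = 2,
                 config = default_config(num_trees = 60))
  td <- generics::tidy(m)
  expect_true(all(c("feature", "importance") %in% names(td)))
  expect_gte(nrow(td), 200)
  gl <- generics::glance(m)
  expect_equal(gl$num_trees, 60)
  ev <- cross_validate(sim$features[tr, ], sim$records$ddg[tr],
                       scheme = "kfold", k = 4, seed = 3,
                       config = default_config(num_trees = 60))
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
  expect_s3_class(generics::glance(ev), "tbl_df")
})
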