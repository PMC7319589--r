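test_that("K_D to binding energy follows R T ln(K_D)", {
  expect_equal(delta_g_from_kd(1, 310), 0)
  expect_equal(delta_g_from_kd(1e-9, 298), 1.987e-3 * 298 * log(1e-9),
               tolerance = 1e-12)
  expect_equal(delta_g_from_kd(1e-9, 298), -12.27, tolerance = 1e-3)
  # x10 K_D shift adds RT ln 10 exactly
  expect_equal(delta_g_from_kd(1e-8, 298) - delta_g_from_kd(1e-9, 298),
               1.987e-3 * 298 * log(10), tolerance = 1e-12)
  expect_error(delta_g_from_kd(0), "positive")
})

test_that("ddG is dG_wild - dG_mutant and antisymmetric under swapping", {
  rec <- tibble::tibble(kd_wt = 1e-9, kd_mut = 1e-8, temperature = 298)
  expect_equal(ddg_of(rec), -1.364, tolerance = 1e-3)
  expect_equal(ddg_of(tibble::tibble(kd_wt = 3e-8, kd_mut = 3e-8,
                                     temperature = 298)), 0)
  swapped <- tibble::tibble(kd_wt = 1e-8, kd_mut = 1e-9, temperature = 298)
  expect_equal(ddg_of(rec), -ddg_of(swapped), tolerance = 1e-12)
  expect_error(ddg_of(tibble::tibble(kd_wt = 1e-9, kd_mut = NA_real_,
                                     temperature = 298)), "without")
  expect_error(ddg_of(tibble::tibble(kd_wt = 1e-9, kd_mut = 1e-8,
                                     temperature = 298, is_non_binder = TRUE)),
               "non-binder")
})

toy_train <- function(ddg) {
  n <- length(ddg)
  rt <- 1.987e-3 * 298
  tibble::tibble(
    complex_id = "c1",
    mutations = paste0("H.A", seq_len(n), "G"),
    kd_wt = 1e-9, kd_mut = exp(log(1e-9) - ddg / rt), temperature = 298,
    ddg = NA_real_, is_reverse = FALSE, is_non_binder = FALSE, source = "toy")
}

test_that("reverse augmentation applies the |ddG| < threshold rule", {
  train <- toy_train(c(-2.5, -1.0, 0.0, 1.9, 2.1))
  aug <- augment_reverse(train, 2)
  rev <- aug[aug$is_reverse, ]
  expect_equal(nrow(rev), 3)  # -1.0, 0.0, +1.9 qualify
  expect_equal(sort(rev$ddg), sort(-c(-1.0, 0.0, 1.9)), tolerance = 1e-9)
  # letters swapped
  expect_true(all(grepl("^H\\.G[0-9]+A$", rev$mutations)))
  # forward ddg -1 -> reverse +1
  expect_equal(rev$ddg[rev$forward_id == 2], 1, tolerance = 1e-9)
})

test_that("augmentation doubles at threshold Inf and is a no-op at 0", {
  train <- toy_train(c(-2.5, -1.0, 0.0, 1.9, 2.1))
  expect_equal(nrow(augment_reverse(train, Inf)), 10)
  expect_equal(nrow(augment_reverse(train, 0)), 5)
  # ddg_of(reverse) = -ddg_of(forward) for every augmented pair
  aug <- augment_reverse(train, Inf)
  rev <- aug[aug$is_reverse, ]
  fwd <- aug[match(rev$forward_id, aug$forward_id), ]
  expect_equal(ddg_of(rev), -ddg_of(fwd), tolerance = 1e-9)
  expect_error(augment_reverse(toy_train(0) |>
                                 dplyr::mutate(mutations = "H.A1G;H.A2G")),
               "single-point")
})

test_that("additive/synergistic labelling uses the 1 kcal/mol rule", {
  singles <- toy_train(c(-1.5, -0.5))
  multi <- singles[1, ]
  multi$mutations <- paste(singles$mutations, collapse = ";")
  rt <- 1.987e-3 * 298
  set_ddg <- function(m, v) { m$kd_mut <- exp(log(1e-9) - v / rt); m }
  expect_equal(label_additivity(set_ddg(multi, -2.5), singles), "additive")
  expect_equal(label_additivity(set_ddg(multi, -4.0), singles), "synergistic")
  expect_equal(label_additivity(set_ddg(multi, -2.5), singles[1, ]),
               "unlabelable")
})

test_that("ddG classification thresholds are > 0.5 and <= -0.5", {
  expect_equal(as.character(classify_ddg(c(0.6, -0.5, 0.0, 0.5, -0.49))),
               c("increasing", "decreasing", "neutral", "neutral", "neutral"))
})

test_that("affinity CSV round-trips and flags inconsistent records", {
  train <- toy_train(c(-1, 0.5, 2))
  train$ddg <- ddg_of(train)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_affinity_csv(train, tmp)
  back <- read_affinity_csv(tmp)
  expect_equal(nrow(back), 3)
  expect_equal(back$ddg, train$ddg, tolerance = 1e-9)
  expect_equal(back[c("complex_id", "mutations", "kd_wt", "kd_mut")],
               train[c("complex_id", "mutations", "kd_wt", "kd_mut")])
  # inconsistent direct ddg vs kd pair
  bad <- train
  bad$ddg[2] <- bad$ddg[2] + 0.5
  write_affinity_csv(bad, tmp)
  expect_error(read_affinity_csv(tmp), "line 3.*inconsistent")
  # non-binder carrying a ddg
  nb <- train[1, ]; nb$is_non_binder <- TRUE; nb$kd_mut <- NA
  write_affinity_csv(nb, tmp)
  expect_error(read_affinity_csv(tmp), "non-binder")
})

test_that("curation keeps non-binders out of training and partitions disjointly", {
  sim <- fix_sim()
  rec <- sim$records
  expect_true(all(rec$partition[rec$is_non_binder] == "non_binder"))
  expect_false(any(rec$is_non_binder & rec$partition == "train"))
  key <- paste(rec$complex_id, rec$mutations)
  expect_equal(anyDuplicated(key[rec$partition != "non_binder"]), 0)
  expect_true(all(is.na(rec$ddg[rec$partition == "non_binder"])))
})
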