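# The regression model: an ensemble of extremely randomized trees (ranger,
# splitrule "extratrees", no bootstrap) over the feature schema, with greedy
# forward feature selection, stratified k-fold and leave-one-complex-out
# cross validation, and regression + classification metrics.

#' Train the ddG regressor
#'
#' Extremely randomized trees: every tree sees the full training set
#' (no bootstrap) and splits are drawn at random cut points. Deterministic
#' given (data, seed).
#'
#' @param features Feature tibble ([featurize_dataset()]).
#' @param ddg Numeric targets, kcal/mol.
#' @param seed Integer seed (required).
#' @param config A [default_config()] (`num_trees`).
#' @param selected Optional feature-name subset (from [greedy_select()]);
#'   default uses every schema feature.
#' @return An `abddg_model`: the fitted ensemble, the selected feature
#'   names, imputation medians, the schema hash and the seed.
#' @export
train_ddg <- function(features, ddg, seed, config = default_config(),
                      selected = NULL) {
  stopifnot(nrow(features) == length(ddg))
  if (nrow(features) < 10) stop("need at least 10 training rows")
  if (stats::sd(ddg) == 0) stop("degenerate targets: zero variance")
  schema_hash <- rlang::hash(names(features))
  imp <- impute_features(features)
  x <- imp$features
  if (!is.null(selected)) {
    stopifnot(all(selected %in% names(x)))
    x <- x[selected]
  }
  if (anyNA(x)) stop("NaN left after imputation")
  fit <- ranger::ranger(
    x = as.data.frame(x), y = ddg,
    num.trees = config$num_trees, splitrule = "extratrees",
    num.random.splits = 1, mtry = ncol(x), replace = FALSE,
    sample.fraction = 1, importance = "impurity", seed = seed, num.threads = 1
  )
  structure(list(fit = fit, features = names(x), medians = imp$medians,
                 schema_hash = schema_hash, seed = seed,
                 n_train = nrow(features),
                 fingerprint = rlang::hash(list(names(features), ddg))),
            class = "abddg_model")
}

#' @export
print.abddg_model <- function(x, ...) {
  cat(sprintf("<abddg_model> %d trees, %d/%d features, %d training rows (seed %d)\n",
              x$fit$num.trees, length(x$features),
              length(x$fit$variable.importance) + 0, x$n_train, x$seed))
  invisible(x)
}

#' Predict ddG for feature rows
#'
#' @param object An `abddg_model`.
#' @param features Feature tibble in the same schema the model was trained
#'   on (checked via the embedded schema hash).
#' @param ... Unused.
#' @return Numeric predictions, kcal/mol.
#' @export
predict.abddg_model <- function(object, features, ...) {
  if (!identical(rlang::hash(names(features)), object$schema_hash))
    stop("feature schema does not match the trained model (schema hash mismatch)")
  x <- impute_features(features, object$medians)$features[object$features]
  ranger::predictions(stats::predict(object$fit, as.data.frame(x), num.threads = 1))
}

#' Predict ddG for mutations on a structure
#'
#' @param model An `abddg_model`.
#' @param complex Wild-type complex.
#' @param specs Spec tibble; each `set` is one multi-mutation.
#' @param config,pssm Passed to [featurize()].
#' @return Tibble: `mutation`, `ddg_pred`, `class`.
#' @export
predict_ddg <- function(model, complex, specs, config = default_config(),
                        pssm = NULL) {
  wt_pre <- precompute_wt(complex, config)
  feats <- purrr::map_dfr(split(specs, specs$set), featurize,
                          complex = complex, config = config, pssm = pssm,
                          wt_pre = wt_pre)
  pred <- predict(model, feats)
  tibble::tibble(mutation = format_mutation(specs), ddg_pred = pred,
                 class = classify_ddg(pred))
}

#' Greedy forward feature selection
#'
#' Starting from the empty set, repeatedly adds the feature whose addition
#' maximizes cross-validated Pearson correlation; ties are broken by schema
#' order; stops when the best improvement is `<= epsilon`. The first
#' feature is always added.
#'
#' @param features Feature tibble.
#' @param ddg Targets.
#' @param seed Integer seed (controls fold assignment and tree randomness).
#' @param config `epsilon` and `num_trees` are read from here; selection
#'   uses a lighter ensemble (`num_trees/3`, minimum 50) for speed.
#' @param k Folds for the internal CV.
#' @param max_features Optional cap on the selected-set size.
#' @return Character vector of selected feature names, in selection order.
#' @export
greedy_select <- function(features, ddg, seed, config = default_config(),
                          k = 5, max_features = Inf) {
  stopifnot(ncol(features) >= 2)
  imp <- impute_features(features)
  x <- imp$features
  folds <- stratified_folds(ddg, k, seed)
  n_trees <- max(50, round(config$num_trees / 3))
  cv_pearson <- function(cols) {
    preds <- numeric(length(ddg))
    for (f in seq_len(k)) {
      te <- folds == f
      fit <- ranger::ranger(x = as.data.frame(x[!te, cols, drop = FALSE]),
                            y = ddg[!te], num.trees = n_trees,
                            splitrule = "extratrees", num.random.splits = 1,
                            mtry = length(cols), replace = FALSE,
                            sample.fraction = 1, seed = seed + f, num.threads = 1)
      preds[te] <- ranger::predictions(
        stats::predict(fit, as.data.frame(x[te, cols, drop = FALSE]), num.threads = 1))
    }
    if (stats::sd(preds) == 0) return(-1)
    stats::cor(ddg, preds)
  }
  selected <- character()
  best_score <- -Inf
  candidates <- names(x)
  repeat {
    if (length(selected) >= max_features) break
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    scores <- vapply(remaining, function(f) cv_pearson(c(selected, f)), 0)
    top <- remaining[which.max(scores)]  # which.max: first max = schema order
    gain <- max(scores) - ifelse(is.finite(best_score), best_score, 0)
    if (length(selected) > 0 && gain <= config$epsilon) break
    selected <- c(selected, top)
    best_score <- max(scores)
    if (length(selected) == 1 && config$epsilon == Inf) break
  }
  selected
}

# k-fold assignment stratified by target quartile; units sharing `unit`
# always land in the same fold (reverse records travel with their forward).
stratified_folds <- function(ddg, k, seed, unit = seq_along(ddg)) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  uu <- !duplicated(unit)
  unit_ddg <- ddg[uu]
  unit_id <- unit[uu]
  breaks <- unique(stats::quantile(unit_ddg, 0:4 / 4))
  q <- if (length(breaks) < 3) rep(1L, length(unit_ddg)) else
    cut(unit_ddg, breaks, include.lowest = TRUE, labels = FALSE)
  # interleave fold labels across stratum-ordered units (random order
  # within each stratum) so folds stay balanced within every stratum and
  # k = n degenerates to leave-one-out
  ord <- order(q, stats::runif(length(q)))
  fold_of <- integer(length(unit_id))
  fold_of[ord] <- rep_len(sample(seq_len(k)), length(ord))
  fold_of[match(unit, unit_id)]
}

#' Regression and classification metrics
#'
#' Pearson, Spearman and Kendall correlations, RMSE, and (after
#' [classify_ddg()] on both vectors, positive class `increasing`) MCC, F1
#' and AUC. Neutral-band values are dropped from the binary metrics unless
#' `binarize = "at_zero"`.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @param binarize `"drop_neutral"` (default) or `"at_zero"`.
#' @return One-row tibble of metrics (classification columns `NA` when a
#'   class is absent).
#' @export
ddg_metrics <- function(y_true, y_pred, binarize = c("drop_neutral", "at_zero")) {
  binarize <- match.arg(binarize)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  degenerate <- stats::sd(y_true) == 0 || stats::sd(y_pred) == 0
  if (degenerate)
    warning("zero-variance input: correlations undefined (reported as NA)")
  out <- tibble::tibble(
    pearson = if (degenerate) NA_real_ else stats::cor(y_true, y_pred),
    spearman = if (degenerate) NA_real_ else
      stats::cor(y_true, y_pred, method = "spearman"),
    kendall = if (degenerate) NA_real_ else
      stats::cor(y_true, y_pred, method = "kendall"),
    rmse = sqrt(mean((y_true - y_pred)^2))
  )
  if (binarize == "at_zero") {
    pos_t <- y_true > 0; pos_p <- y_pred > 0; keep <- rep(TRUE, length(y_true))
  } else {
    ct <- classify_ddg(y_true); cp <- classify_ddg(y_pred)
    keep <- ct != "neutral" & cp != "neutral"
    pos_t <- ct == "increasing"; pos_p <- cp == "increasing"
  }
  tp <- sum(keep & pos_t & pos_p); tn <- sum(keep & !pos_t & !pos_p)
  fp <- sum(keep & !pos_t & pos_p); fn <- sum(keep & pos_t & !pos_p)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  out$mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  out$f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  auc_keep <- if (binarize == "at_zero") rep(TRUE, length(y_true)) else classify_ddg(y_true) != "neutral"
  resp <- (if (binarize == "at_zero") y_true > 0 else classify_ddg(y_true) == "increasing")[auc_keep]
  out$auc <- if (length(unique(resp)) == 2) {
    as.numeric(pROC::auc(pROC::roc(response = resp, predictor = y_pred[auc_keep],
                                   quiet = TRUE, direction = "<")))
  } else NA_real_
  out
}

#' Cross-validate the pipeline
#'
#' `kfold`: stratified by ddG quartile, with reverse records always
#' assigned to their forward record's fold (no leakage). `loco`
#' (leave-one-complex-out): every fold is one complex; folds never split a
#' complex.
#'
#' @param features Feature tibble.
#' @param ddg Targets.
#' @param groups Complex ID per row (required for `loco`).
#' @param scheme `"kfold"` or `"loco"`.
#' @param k Folds for `kfold`.
#' @param seed Integer seed.
#' @param config A [default_config()].
#' @param pair_unit Fold-assignment unit per row (e.g. forward-record ID so
#'   augmented reverses co-travel). Defaults to each row on its own.
#' @param selected Optional feature subset.
#' @return An `abddg_eval`: list with `pooled` metrics, `per_fold` metrics
#'   and the out-of-fold `predictions` tibble.
#' @export
cross_validate <- function(features, ddg, groups = NULL,
                           scheme = c("kfold", "loco"), k = 5, seed = 1,
                           config = default_config(), pair_unit = NULL,
                           selected = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(features)
  if (scheme == "loco") {
    if (is.null(groups)) stop("leave-one-complex-out needs per-complex groups")
    fold <- match(groups, unique(groups))
  } else {
    if (k > n) stop("k exceeds the number of rows")
    if (is.null(pair_unit)) pair_unit <- seq_len(n)
    fold <- stratified_folds(ddg, k, seed, unit = pair_unit)
  }
  preds <- rep(NA_real_, n)
  for (f in sort(unique(fold))) {
    te <- fold == f
    m <- train_ddg(features[!te, , drop = FALSE], ddg[!te], seed = seed + f,
                   config = config, selected = selected)
    preds[te] <- predict(m, features[te, , drop = FALSE])
  }
  per_fold <- purrr::map_dfr(sort(unique(fold)), function(f) {
    te <- fold == f
    if (sum(te) >= 3 && stats::sd(ddg[te]) > 0 && stats::sd(preds[te]) > 0) {
      dplyr::bind_cols(tibble::tibble(fold = f, n = sum(te)),
                       ddg_metrics(ddg[te], preds[te]))
    } else tibble::tibble(fold = f, n = sum(te))
  })
  structure(list(
    scheme = scheme, seed = seed,
    pooled = ddg_metrics(ddg, preds),
    per_fold = per_fold,
    predictions = tibble::tibble(fold = fold, ddg_true = ddg, ddg_pred = preds,
                                 group = groups %||% NA_character_)
  ), class = "abddg_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.abddg_eval <- function(x, ...) {
  cat(sprintf("<abddg_eval> %s (%d folds)\n", x$scheme, nrow(x$per_fold)))
  print(x$pooled)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Feature importances of a trained model
#' @param x An `abddg_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance` (impurity), sorted decreasing.
#' @method tidy abddg_model
#' @export
tidy.abddg_model <- function(x, ...) {
  imp <- x$fit$variable.importance
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row model summary
#' @param x An `abddg_model`.
#' @param ... Unused.
#' @method glance abddg_model
#' @export
glance.abddg_model <- function(x, ...) {
  tibble::tibble(num_trees = x$fit$num.trees,
                 num_features = length(x$features),
                 n_train = x$n_train, seed = x$seed,
                 r_squared = x$fit$r.squared)
}

#' Pooled metrics of an evaluation
#' @param x An `abddg_eval`.
#' @param ... Unused.
#' @method glance abddg_eval
#' @export
glance.abddg_eval <- function(x, ...) x$pooled

#' Per-fold metrics of an evaluation
#' @param x An `abddg_eval`.
#' @param ... Unused.
#' @method tidy abddg_eval
#' @export
tidy.abddg_eval <- function(x, ...) x$per_fold

#' Save / load a trained model
#'
#' The serialized object embeds the schema hash, seed and training
#' fingerprint; predictions are identical across processes.
#'
#' @param model An `abddg_model`.
#' @param path File path (`.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "abddg_model")) stop("not an abddg model file: ", path)
  m
}
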